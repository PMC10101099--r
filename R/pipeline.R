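#' Pipeline configuration
#'
#' Collects every threshold of the analysis in one validated list. Defaults
#' follow the study design the package implements: a 5,000-read depth
#' filter, rarefaction to the minimum library size, core detection at 0.001
#' relative abundance with 85% prevalence, gLV inference restricted to
#' participants with at least nine samples, a 1,000-OTU abundance pool for
#' NRI/NTI and BVSTEP, and 999 null randomizations.
#'
#' @param min_reads depth-filter threshold (reads).
#' @param depth rarefaction depth, or `"auto"` for the minimum library size.
#' @param detection,prevalence core-microbiota thresholds.
#' @param min_series minimum samples per participant for gLV inference.
#' @param top_k abundance pool size for NRI/NTI and BVSTEP.
#' @param n_null null randomizations for NRI/NTI.
#' @param rho_target BVSTEP stopping correlation.
#' @param lcbd_metric dissimilarity used for LCBD (default `"hellinger"`).
#' @param n_bags,test_fraction,improvement_threshold [limits_glv()] settings.
#' @param r_inv,a_inv_inv invader traits for the invasibility test.
#' @param stability_tol,delta stability / permanence tolerances.
#' @param n_max boundary-enumeration cap.
#' @param seed master seed; every stochastic stage derives its stream from it.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_reads = 5000, depth = "auto",
                            detection = 0.001, prevalence = 0.85,
                            min_series = 9, top_k = 1000, n_null = 999,
                            rho_target = 0.95, lcbd_metric = "hellinger",
                            n_bags = 100, test_fraction = 0.5,
                            improvement_threshold = 0,
                            r_inv = 0, a_inv_inv = 0,
                            stability_tol = 1e-9, delta = 1e-6, n_max = 20,
                            seed = 1) {
  stopifnot(min_reads >= 0, identical(depth, "auto") || depth >= 1,
            detection > 0, detection < 1, prevalence > 0, prevalence <= 1,
            min_series >= 3, top_k >= 2, n_null >= 1,
            rho_target > 0, rho_target <= 1, n_bags >= 1,
            test_fraction > 0, test_fraction < 1, improvement_threshold >= 0,
            stability_tol > 0, delta > 0, n_max >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full longitudinal stability pipeline
#'
#' Executes, in order: joint validation; read-depth filtering; rarefaction;
#' alpha diversity (Hill numbers q = 0, 1, 2 on the rarefied table);
#' dissimilarity matrices (Bray-Curtis, Hellinger and, when a tree is
#' given, both UniFrac variants); LCBD; NRI/NTI; BVSTEP; per-participant
#' core extraction; gLV inference for participants with at least
#' `min_series` samples (others are skipped with a logged reason); and the
#' stability / permanence / invasibility report per inferred model. Group
#' summaries (per smoking status: mean and SD of dominant eigenvalues, a
#' one-way F statistic, and counts of locally stable / permanent /
#' invasible networks) are computed from the per-participant reports.
#'
#' The run is a pure function of `(table, metadata, tree, config)`: every
#' random stage draws from a stream derived from `config$seed`, so reruns
#' are byte-identical. When `out_dir` is given all results are written
#' there as TSV/CSV/JSON (floats at 6 significant digits) along with a
#' manifest carrying the configuration, its hash and per-stage row counts.
#'
#' @param table an [otu_table].
#' @param metadata a `study_metadata` data frame.
#' @param tree optional rooted `phylo` covering the table's OTUs.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return an object of class `pipeline_result`: list with `alpha`,
#'   `dissimilarity` (named list of matrices), `lcbd`, `ses`, `bvstep`,
#'   `cores`, `models`, `reports`, `skipped` (data frame of participants
#'   excluded from inference), `summary` (group summary), `config` and
#'   `manifest`.
#' @export
run_pipeline <- function(table, metadata, tree = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_study(table, metadata, tree)
  stage <- function(...) msg(...)

  stage("filter: %d samples in", nrow(table))
  filtered <- filter_low_depth(table, config$min_reads)
  stage("filter: %d samples retained", nrow(filtered))

  rare <- rarefy(filtered, config$depth, seed = derive_seed(config$seed, "rarefy"))
  stage("rarefied to depth %d", sum(rare[1, ]))

  alpha <- alpha_diversity(rare)

  metrics <- c("bray_curtis", "hellinger")
  if (!is.null(tree)) metrics <- c(metrics, "unifrac_unweighted", "unifrac_weighted")
  diss <- lapply(stats::setNames(metrics, metrics), function(met) {
    tr <- if (startsWith(met, "unifrac"))
      ape::keep.tip(tree, otu_ids(rare)) else NULL
    dissimilarity(rare, met, tree = tr)
  })
  stage("dissimilarity matrices: %s", paste(metrics, collapse = ", "))

  lcbd_vals <- lcbd(diss[[config$lcbd_metric]])

  ses <- if (!is.null(tree))
    ses_phylo(rare, tree, n_null = config$n_null, top_k = config$top_k,
              seed = derive_seed(config$seed, "ses")) else NULL
  if (!is.null(ses)) stage("NRI/NTI computed for %d samples", nrow(ses) / 2)

  bv <- bvstep_select(rare, metric = "bray_curtis",
                      rho_target = config$rho_target, top_k = config$top_k,
                      seed = derive_seed(config$seed, "bvstep"))
  stage("bvstep: %d OTUs, rho = %.3f", length(bv$selected_otu_ids), bv$rho)

  participants <- unique(metadata$participant_id[metadata$sample_id %in%
                                                   rownames(rare)])
  cores <- list()
  models <- list()
  reports <- list()
  skipped <- list()
  for (pid in participants) {
    n_samp <- sum(metadata$participant_id == pid &
                    metadata$sample_id %in% rownames(rare))
    if (n_samp < config$min_series) {
      stage("participant %s: %d samples < %d; skipped from inference",
            pid, n_samp, config$min_series)
      skipped[[pid]] <- data.frame(participant_id = pid, n_samples = n_samp,
                                   reason = "too few samples",
                                   stringsAsFactors = FALSE)
      next
    }
    core <- tryCatch(
      core_microbiota(rare, metadata, pid,
                      detection = config$detection,
                      prevalence = config$prevalence),
      error = function(e) e)
    if (inherits(core, "error"))
      stop("stage core_microbiota failed for participant ", pid, ": ",
           conditionMessage(core))
    cores[[pid]] <- core
    fit <- tryCatch(
      limits_glv(core, n_bags = config$n_bags,
                 test_fraction = config$test_fraction,
                 improvement_threshold = config$improvement_threshold,
                 seed = derive_seed(config$seed, paste0("limits_", pid)),
                 min_samples = config$min_series),
      error = function(e) e)
    if (inherits(fit, "error"))
      stop("stage limits_glv failed for participant ", pid, ": ",
           conditionMessage(fit))
    models[[pid]] <- fit
    rep <- tryCatch(
      suppressWarnings(stability_report(
        fit, participant_id = pid, r_inv = config$r_inv,
        a_inv_inv = config$a_inv_inv, tol = config$stability_tol,
        delta = config$delta, n_max = config$n_max)),
      error = function(e) e)
    if (inherits(rep, "error"))
      stop("stage stability failed for participant ", pid, ": ",
           conditionMessage(rep))
    reports[[pid]] <- rep
    stage("participant %s: %d core OTUs, lambda = %.3g, permanent = %s",
          pid, length(core$core_otu_ids), rep$dominant_eigenvalue,
          rep$permanent)
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(participant_id = character(0), n_samples = integer(0),
               reason = character(0))

  summary_df <- summarize_reports(reports, metadata)

  manifest <- list(
    package_version = as.character(utils::packageVersion("microstab")),
    seed = config$seed,
    stage_counts = list(
      samples_in = nrow(table), samples_filtered = nrow(filtered),
      otus_filtered = ncol(filtered),
      participants = length(participants),
      inferred = length(models), skipped = nrow(skipped)))

  res <- structure(list(
    alpha = alpha, dissimilarity = diss, lcbd = lcbd_vals, ses = ses,
    bvstep = bv, cores = cores, models = models, reports = reports,
    skipped = skipped, summary = summary_df,
    config = config, manifest = manifest), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

# group means/SDs of dominant eigenvalues by smoking status, a one-way F
# statistic, and counts of stable / permanent / invasible networks
summarize_reports <- function(reports, metadata) {
  if (!length(reports))
    return(data.frame(smoking = character(0), n = integer(0)))
  per <- do.call(rbind, lapply(reports, function(r) {
    smoking <- unique(metadata$smoking[metadata$participant_id == r$participant_id])
    data.frame(participant_id = r$participant_id, smoking = smoking[1],
               dominant_eigenvalue = r$dominant_eigenvalue,
               locally_stable = r$locally_stable, permanent = r$permanent,
               invasible = r$invasible, stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(per, per$smoking), function(g)
    data.frame(smoking = g$smoking[1], n = nrow(g),
               mean_eigenvalue = mean(g$dominant_eigenvalue),
               sd_eigenvalue = stats::sd(g$dominant_eigenvalue),
               n_locally_stable = sum(g$locally_stable),
               n_permanent = sum(g$permanent),
               n_invasible = sum(g$invasible), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  f_stat <- if (length(unique(per$smoking)) > 1) {
    a <- suppressWarnings(
      stats::anova(stats::lm(dominant_eigenvalue ~ smoking, data = per)))
    a$`F value`[1]
  } else NA_real_
  attr(agg, "f_statistic") <- f_stat
  attr(agg, "per_participant") <- per
  agg
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d samples, %d models inferred, %d skipped\n",
              nrow(x$alpha), length(x$models), nrow(x$skipped)))
  if (nrow(x$summary)) {
    print(x$summary)
    cat(sprintf("one-way F (eigenvalue ~ smoking): %.4g\n",
                attr(x$summary, "f_statistic")))
  }
  invisible(x)
}

# serialize a stability report for JSON output
report_to_list <- function(r) {
  list(participant_id = r$participant_id,
       equilibrium = as.list(r$equilibrium),
       feasible = r$feasible,
       dominant_eigenvalue = r$dominant_eigenvalue,
       dominant_eigenvalue_A = r$dominant_eigenvalue_A,
       locally_stable = r$locally_stable, marginal = r$marginal,
       permanent = r$permanent,
       lyapunov_certificate = if (is.null(r$lyapunov_certificate)) NULL
                              else as.list(r$lyapunov_certificate),
       dissipative = r$dissipative, invasible = r$invasible,
       invasion_eigenvalue = r$invasion_eigenvalue,
       invader_config = r$invader_config, notes = r$notes)
}

write_pipeline_result <- function(res, out_dir) {
  for (d in c("", "core", "models", "reports"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  cfg <- res$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  fmt_df <- function(df) {
    df[] <- lapply(df, function(col) if (is.numeric(col) && !is.integer(col))
      fmt_num(col) else col)
    df
  }
  w <- function(df, name) utils::write.table(
    fmt_df(df), file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)

  w(cbind(res$alpha, config_hash = cfg_hash), "alpha.tsv")
  for (met in names(res$dissimilarity))
    write_tsv_matrix(res$dissimilarity[[met]],
                     file.path(out_dir, paste0("dissimilarity_", met, ".tsv")),
                     "sample_id")
  w(data.frame(sample_id = names(res$lcbd), lcbd = res$lcbd,
               config_hash = cfg_hash), "lcbd.tsv")
  if (!is.null(res$ses)) w(cbind(res$ses, config_hash = cfg_hash), "ses.tsv")
  jsonlite::write_json(
    list(selected_otu_ids = res$bvstep$selected_otu_ids,
         rho = res$bvstep$rho, converged = res$bvstep$converged,
         n_evaluations = res$bvstep$n_evaluations, config_hash = cfg_hash),
    file.path(out_dir, "bvstep.json"), auto_unbox = TRUE, digits = NA)
  for (pid in names(res$cores)) {
    cs <- res$cores[[pid]]
    m <- cs$abundances
    rownames(m) <- cs$weeks
    write_tsv_matrix(m, file.path(out_dir, "core", paste0(pid, ".tsv")), "week")
  }
  for (pid in names(res$models)) {
    fit <- res$models[[pid]]
    write_tsv_matrix(fit$A, file.path(out_dir, "models", paste0(pid, "_A.tsv")),
                     "otu_id")
    utils::write.table(
      data.frame(otu_id = fit$otu_ids, r = fmt_num(fit$r)),
      file.path(out_dir, "models", paste0(pid, "_r.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (pid in names(res$reports))
    jsonlite::write_json(
      c(report_to_list(res$reports[[pid]]), list(config_hash = cfg_hash)),
      file.path(out_dir, "reports", paste0(pid, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  w(res$skipped, "skipped.tsv")
  if (nrow(res$summary))
    w(cbind(res$summary, f_statistic = attr(res$summary, "f_statistic"),
            config_hash = cfg_hash), "summary.tsv")
  jsonlite::write_json(
    c(res$manifest, list(config_hash = cfg_hash)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}
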