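#' Draw a random gLV model
#'
#' Off-diagonal interactions are present independently with probability
#' `connectance` and drawn from `Normal(0, strength_sd^2)`; diagonal entries
#' (self-limitation) are strictly negative, drawn around `diag_mean`; growth
#' rates are positive.
#'
#' @param n species count (>= 1).
#' @param connectance probability in `[0, 1]` that an off-diagonal entry is
#'   nonzero.
#' @param strength_sd standard deviation of nonzero off-diagonal entries.
#' @param diag_mean negative centre of the self-limitation terms.
#' @param seed optional integer seed; a fixed seed reproduces the model
#'   bitwise.
#' @param otu_ids optional species labels.
#' @return a [glv_model()].
#' @export
random_glv <- function(n, connectance = 0.3, strength_sd = 0.15, diag_mean = -1,
                       seed = NULL, otu_ids = NULL) {
  stopifnot(n >= 1, connectance >= 0, connectance <= 1, strength_sd > 0,
            diag_mean < 0)
  with_seed(seed, {
    A <- matrix(stats::rnorm(n * n, 0, strength_sd) *
                  (stats::runif(n * n) < connectance), n, n)
    diag(A) <- -abs(stats::rnorm(n, diag_mean, abs(diag_mean) / 5))
    r <- abs(stats::rnorm(n, 1, 0.25))
    glv_model(A, r, otu_ids)
  })
}

#' Draw a random gLV model with a feasible, locally stable equilibrium
#'
#' Rejection-samples [random_glv()] until the interior equilibrium is
#' strictly positive and the continuous-time Jacobian `diag(x*) A` has all
#' eigenvalue real parts negative. Used to build ground-truth panels for
#' recovery and concordance checks.
#'
#' @inheritParams random_glv
#' @param max_tries rejection-sampling cap (default 1000).
#' @return a [glv_model()] with attributes carrying the accepted draw index.
#' @export
random_stable_glv <- function(n, connectance = 0.3, strength_sd = 0.15,
                              diag_mean = -1, seed = NULL, otu_ids = NULL,
                              max_tries = 1000) {
  for (k in seq_len(max_tries)) {
    m <- random_glv(n, connectance, strength_sd, diag_mean,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, k),
                    otu_ids = otu_ids)
    if (rcond(m$A) < 1e-10) next
    x <- drop(solve(m$A, -m$r))
    if (any(x <= 0)) next
    if (dominant_eigenvalue(diag(x, n) %*% m$A) < -1e-9) {
      attr(m, "draws") <- k
      return(m)
    }
  }
  stop("no stable model found in ", max_tries, " draws; ",
       "weaken the interactions (lower connectance or strength_sd)")
}

#' Multinomial read sampling from a trajectory
#'
#' Each trajectory row becomes one sample: `library_size` reads drawn from a
#' multinomial with probabilities proportional to the row. This emulates
#' shotgun/amplicon sequencing of the latent community state.
#'
#' @param trajectory T x n non-negative matrix with OTU ids as column names;
#'   every row must have at least one positive entry.
#' @param library_size reads per sample.
#' @param seed optional integer seed.
#' @param sample_ids optional row labels; defaults to `T1, T2, ...`.
#' @return an [otu_table] whose row sums all equal `library_size`.
#' @export
counts_from_trajectory <- function(trajectory, library_size = 10000, seed = NULL,
                                   sample_ids = NULL) {
  trajectory <- as.matrix(trajectory)
  if (any(trajectory < 0)) stop("trajectory must be non-negative")
  dead <- rowSums(trajectory) <= 0
  if (any(dead)) stop("community extinct (all-zero trajectory row) at row ",
                      which(dead)[1])
  if (is.null(colnames(trajectory)))
    colnames(trajectory) <- sprintf("OTU_%03d", seq_len(ncol(trajectory)))
  if (is.null(sample_ids)) sample_ids <- sprintf("T%d", seq_len(nrow(trajectory)))
  with_seed(seed, {
    counts <- matrix(0, nrow(trajectory), ncol(trajectory),
                     dimnames = list(sample_ids, colnames(trajectory)))
    for (i in seq_len(nrow(trajectory)))
      counts[i, ] <- stats::rmultinom(1, size = library_size,
                                      prob = trajectory[i, ])[, 1]
    otu_table(counts)
  })
}

#' Generate a synthetic longitudinal study with known ground truth
#'
#' Emulates the structure of a weekly oropharyngeal-microbiota study:
#' `participants` individuals (40% smokers by default, as in a 30-participant
#' cohort of 18 nonsmokers and 12 smokers) sampled weekly for `weeks` weeks.
#' Each participant carries a core community of `n_core` OTUs drawn from a
#' shared OTU pool, following noisy Ricker-map gLV dynamics anchored at a
#' feasible interior equilibrium (growth rates are set to `r = -A x*` so the
#' drawn equilibrium is exact). Reads are sampled multinomially at
#' `library_size` per sample, with a small fluctuating "background" of
#' non-core OTUs so that core extraction is non-trivial. A random coalescent
#' tree over the OTU pool provides the phylogeny.
#'
#' @param participants number of participants (>= 1).
#' @param weeks number of weekly samples per participant (>= 2).
#' @param n_core core community size; a single count or a `c(min, max)` range
#'   sampled per participant.
#' @param seed integer master seed; the fixture is a pure function of the
#'   arguments and this seed.
#' @param config optional list overriding generation defaults:
#'   `pool_size` (total OTUs, default 60), `library_size` (default 10000),
#'   `noise_sigma` (weekly process noise sd, default 0.05), `connectance`
#'   (default 0.3), `background_fraction` (share of reads from non-core OTUs,
#'   default 0.05), `cold_fraction` and `abx_fraction` (per-week probability
#'   of cold / antibiotics status, defaults 0.07 and 0.03), `smoker_fraction`
#'   (default 0.4), `extinction_floor` (default 1e-6).
#' @return an object of class `synthetic_study`: a list with elements
#'   `table` ([otu_table] over all samples), `metadata` (`study_metadata`),
#'   `tree` (`phylo`), `truth` (per-participant list of `model` ([glv_model]),
#'   `equilibrium`, `core_otu_ids`, `trajectory`), and `config`.
#' @export
make_study_fixture <- function(participants = 30, weeks = 30, n_core = c(5, 12),
                               seed = 1, config = list()) {
  stopifnot(participants >= 1, weeks >= 2)
  cfg <- utils::modifyList(list(
    pool_size = 60, library_size = 10000, noise_sigma = 0.05,
    connectance = 0.3, background_fraction = 0.05,
    cold_fraction = 0.07, abx_fraction = 0.03, smoker_fraction = 0.4,
    extinction_floor = 1e-6), config)
  if (length(n_core) == 1) n_core <- c(n_core, n_core)
  pool <- sprintf("OTU_%03d", seq_len(cfg$pool_size))
  tree <- with_seed(derive_seed(seed, "tree"), {
    tr <- ape::rcoal(cfg$pool_size)
    tr$tip.label <- pool[as.integer(sub("^t", "", tr$tip.label))]
    tr
  })

  pids <- sprintf("P%02d", seq_len(participants))
  n_smokers <- round(cfg$smoker_fraction * participants)
  smoking <- c(rep("smoker", n_smokers),
               rep("nonsmoker", participants - n_smokers))

  truth <- vector("list", participants)
  names(truth) <- pids
  counts_all <- NULL
  meta_rows <- list()

  for (i in seq_len(participants)) {
    pseed <- derive_seed(seed, paste0("participant_", pids[i]))
    part <- with_seed(pseed, {
      k <- sample(n_core[1]:n_core[2], 1)
      core <- sort(sample(pool, k))
      # equilibrium-anchored model: draw x*, then r = -A x* makes it exact
      g <- stats::rgamma(k, 2)
      xstar <- (1 - cfg$background_fraction) * g / sum(g)
      A <- matrix(stats::rnorm(k * k, 0, 1) *
                    (stats::runif(k * k) < cfg$connectance), k, k)
      diag(A) <- -abs(stats::rnorm(k, 5, 1))
      model <- glv_model(A, r = -drop(A %*% xstar), otu_ids = core)
      x0 <- xstar * exp(stats::rnorm(k, 0, 0.2))
      traj <- simulate_ricker(model, x0, steps = weeks,
                              noise_sigma = cfg$noise_sigma, seed = NULL,
                              extinction_floor = cfg$extinction_floor)
      # background: non-core OTUs appearing sporadically at low abundance
      bg_pool <- sample(setdiff(pool, core), min(15, cfg$pool_size - k))
      prob <- matrix(0, weeks, cfg$pool_size, dimnames = list(NULL, pool))
      prob[, core] <- traj
      for (t in seq_len(weeks)) {
        on <- stats::runif(length(bg_pool)) < 0.5
        if (any(on)) {
          w <- stats::rgamma(sum(on), 1)
          prob[t, bg_pool[on]] <- cfg$background_fraction * w / sum(w)
        }
      }
      sample_id <- sprintf("%s_W%02d", pids[i], seq_len(weeks))
      counts <- counts_from_trajectory(prob, cfg$library_size, seed = NULL,
                                       sample_ids = sample_id)
      health <- sample(c("healthy", "cold", "antibiotics"), weeks, replace = TRUE,
                       prob = c(1 - cfg$cold_fraction - cfg$abx_fraction,
                                cfg$cold_fraction, cfg$abx_fraction))
      meta <- data.frame(
        sample_id = sample_id, participant_id = pids[i],
        week = seq_len(weeks), smoking = smoking[i], health = health,
        sex = sample(c("female", "male"), 1, prob = c(0.7, 0.3)),
        age = sample(18:40, 1), stringsAsFactors = FALSE)
      list(model = model, equilibrium = xstar, core_otu_ids = core,
           trajectory = traj, counts = counts, meta = meta)
    })
    truth[[i]] <- part[c("model", "equilibrium", "core_otu_ids", "trajectory")]
    counts_all <- rbind(counts_all, unclass(part$counts))
    meta_rows[[i]] <- part$meta
  }

  structure(list(
    table = otu_table(counts_all),
    metadata = study_metadata(do.call(rbind, meta_rows)),
    tree = tree,
    truth = truth,
    config = c(cfg, list(participants = participants, weeks = weeks,
                         n_core = n_core, seed = seed))),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d participants x %d weeks (%d samples, %d OTUs), seed %d\n",
              x$config$participants, x$config$weeks, nrow(x$table),
              ncol(x$table), x$config$seed))
  invisible(x)
}

#' Write a synthetic study fixture to disk
#'
#' Writes `otu_table.tsv` (OTUs in rows), `otu_table_biom.json` (BIOM v1),
#' `meta_data.csv`, `otus.nwk` and, under `truth/`, the ground-truth `A` and
#' `r` matrices per participant for parameter-recovery checks.
#'
#' @param fixture a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "synthetic_study"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_otu_table(fixture$table, file.path(dir, "otu_table.tsv"), "tsv")
  write_otu_table(fixture$table, file.path(dir, "otu_table_biom.json"), "biom_json")
  write_metadata(fixture$metadata, file.path(dir, "meta_data.csv"))
  ape::write.tree(fixture$tree, file.path(dir, "otus.nwk"))
  for (pid in names(fixture$truth)) {
    m <- fixture$truth[[pid]]$model
    write_tsv_matrix(m$A, file.path(dir, "truth", paste0(pid, "_A.tsv")), "otu_id")
    utils::write.table(
      data.frame(otu_id = m$otu_ids, r = fmt_num(m$r)),
      file.path(dir, "truth", paste0(pid, "_r.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
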