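#' Discard low-depth samples
#'
#' Removes samples whose library size (row sum) is below `min_reads`; the
#' comparison is strict, so a sample with exactly `min_reads` reads is kept.
#' OTUs left with zero total count are dropped and listed in a message.
#'
#' @param table an [otu_table].
#' @param min_reads minimum library size (default 5000).
#' @return the filtered [otu_table].
#' @export
filter_low_depth <- function(table, min_reads = 5000) {
  stopifnot(min_reads >= 0)
  depth <- rowSums(table)
  keep <- depth >= min_reads
  if (!any(keep)) stop("all samples fall below ", min_reads, " reads")
  if (any(!keep))
    msg("discarded %d sample(s) below %d reads: %s", sum(!keep), min_reads,
        paste(rownames(table)[!keep], collapse = ", "))
  out <- unclass(table)[keep, , drop = FALSE]
  empty <- colSums(out) == 0
  if (any(empty)) {
    msg("dropped %d OTU(s) with zero count after filtering: %s", sum(empty),
        paste(colnames(out)[empty], collapse = ", "))
    out <- out[, !empty, drop = FALSE]
  }
  otu_table(out, taxonomy = attr(table, "taxonomy"))
}

#' Rarefy samples to a common depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads
#' (via [vegan::rrarefy()]), making richness and diversity comparable across
#' samples. `depth = "auto"` uses the minimum library size of the table.
#'
#' @param table an [otu_table]; every sample must have at least `depth` reads.
#' @param depth target reads per sample, or `"auto"`.
#' @param seed optional integer seed for reproducible subsampling.
#' @return a rarefied [otu_table] with all row sums equal to `depth`.
#' @export
rarefy <- function(table, depth = "auto", seed = NULL) {
  sums <- rowSums(table)
  if (identical(depth, "auto")) depth <- min(sums)
  stopifnot(depth >= 1)
  shallow <- sums < depth
  if (any(shallow))
    stop("sample(s) shallower than rarefaction depth ", depth, ": ",
         paste(rownames(table)[shallow], collapse = ", "))
  out <- with_seed(seed, vegan::rrarefy(unclass(table), depth))
  otu_table(out, taxonomy = attr(table, "taxonomy"))
}

#' Relative abundances
#'
#' Divides each sample's counts by its library size; rows of the result sum
#' to 1.
#'
#' @param table an [otu_table] (or count matrix) with no all-zero sample.
#' @return a samples x OTUs matrix of proportions in `[0, 1]`.
#' @export
relative_abundance <- function(table) {
  m <- unclass(as.matrix(table))
  sums <- rowSums(m)
  if (any(sums == 0))
    stop("all-zero sample(s): ", paste(rownames(m)[sums == 0], collapse = ", "))
  sweep(m, 1, sums, "/")
}

#' Extract one participant's core time series
#'
#' The core microbiota of a participant is the set of OTUs whose relative
#' abundance reaches `detection` in at least `ceiling(prevalence * T)` of the
#' participant's `T` samples. Abundances are returned as fractions of the
#' whole sample (not renormalized to the core) so that states are comparable
#' across participants; rows are ordered by metadata week, which is the time
#' axis of downstream gLV inference.
#'
#' @param table an [otu_table] covering the participant's samples.
#' @param metadata a `study_metadata` data frame.
#' @param participant participant id.
#' @param detection relative-abundance detection threshold in `(0, 1)`
#'   (default 0.001, i.e. 0.1% compositional abundance).
#' @param prevalence fraction of samples in `(0, 1]` in which a core OTU must
#'   be detected (default 0.85).
#' @return an object of class `core_series`: list with `participant_id`,
#'   `weeks` (ordered integer vector), `abundances` (T x k relative-abundance
#'   matrix), `core_otu_ids`, `detection`, `prevalence`.
#' @export
core_microbiota <- function(table, metadata, participant,
                            detection = 0.001, prevalence = 0.85) {
  stopifnot(detection > 0, detection < 1, prevalence > 0, prevalence <= 1)
  meta <- metadata[metadata$participant_id == participant, , drop = FALSE]
  meta <- meta[meta$sample_id %in% rownames(table), , drop = FALSE]
  if (nrow(meta) < 2)
    stop("participant ", participant, " has fewer than 2 samples in the table")
  meta <- meta[order(meta$week), , drop = FALSE]
  rel <- relative_abundance(unclass(table)[meta$sample_id, , drop = FALSE])
  n_detected <- colSums(rel >= detection)
  need <- ceiling(prevalence * nrow(rel))
  core <- colnames(rel)[n_detected >= need]
  if (!length(core))
    stop("empty core for participant ", participant,
         " at detection ", detection, " / prevalence ", prevalence,
         "; consider relaxing the thresholds")
  structure(list(
    participant_id = participant,
    weeks = meta$week,
    abundances = rel[, core, drop = FALSE],
    core_otu_ids = core,
    detection = detection,
    prevalence = prevalence), class = "core_series")
}

#' @export
print.core_series <- function(x, ...) {
  cat(sprintf("core_series %s: %d weekly samples x %d core OTUs (detection %g, prevalence %g)\n",
              x$participant_id, length(x$weeks), length(x$core_otu_ids),
              x$detection, x$prevalence))
  invisible(x)
}
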