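#' OTU count tables
#'
#' An `otu_table` is an integer matrix of sequencing read counts with samples
#' in rows and OTUs (operational taxonomic units) in columns. Row names are
#' sample identifiers, column names OTU identifiers; both must be unique and
#' all entries must be non-negative integers. An optional taxonomy (a named
#' character vector of lineage strings, one per OTU) travels as an attribute.
#'
#' @param counts numeric matrix, samples x OTUs, non-negative integers with
#'   unique row and column names.
#' @param taxonomy optional named character vector mapping OTU ids to lineage
#'   strings.
#' @return an object of class `otu_table` (a classed integer matrix).
#' @examples
#' m <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("OTU_1", "OTU_2")))
#' otu_table(m)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  validate_counts(counts)
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in sums
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !all(colnames(counts) %in% names(taxonomy)))
      stop("taxonomy must be a named vector covering all OTU ids")
    taxonomy <- taxonomy[colnames(counts)]
  }
  structure(counts, taxonomy = taxonomy, class = c("otu_table", "matrix", "array"))
}

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample ids as row names and OTU ids as column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ", paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ", paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0))
    stop("negative counts at ", which(counts < 0)[1], "; counts must be >= 0")
  if (any(counts != round(counts)))
    stop("non-integer counts at entry ", which(counts != round(counts))[1])
  invisible(TRUE)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s reads total, %.1f%% zero entries\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ","),
              100 * mean(x == 0)))
  invisible(x)
}

sample_ids <- function(table) rownames(table)
otu_ids <- function(table) colnames(table)

#' Read an OTU table
#'
#' Two dialects are supported: `tsv`, the classic QIIME layout with OTUs in
#' rows, a header line of sample ids and the OTU id in the first column
#' (optionally headed `#OTU ID`); and `biom_json`, the BIOM v1 JSON schema
#' (dense or sparse), read via the biomformat package. HDF5 BIOM is not
#' supported.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"biom_json"`.
#' @param samples_in_rows for the TSV dialect only: set `TRUE` if the file
#'   has samples in rows rather than the default OTUs-in-rows orientation.
#' @return an [otu_table].
#' @seealso [write_otu_table()]
#' @export
read_otu_table <- function(path, dialect = c("tsv", "biom_json"),
                           samples_in_rows = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    df <- tryCatch(
      utils::read.delim(path, check.names = FALSE, comment.char = "",
                        stringsAsFactors = FALSE),
      error = function(e) stop("malformed TSV in ", path, ": ", conditionMessage(e)))
    if (ncol(df) < 2) stop("malformed TSV in ", path, ": fewer than two columns")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- colnames(df)[-1][!vapply(df[-1], is.numeric, logical(1))][1]
      stop("malformed TSV in ", path, ": non-numeric counts in column '", bad, "'")
    }
    rownames(m) <- as.character(df[[1]])
    if (!samples_in_rows) m <- t(m)
    otu_table(m)
  } else {
    b <- tryCatch(biomformat::read_biom(path),
                  error = function(e) stop("malformed BIOM JSON in ", path, ": ",
                                           conditionMessage(e)))
    m <- as(biomformat::biom_data(b), "matrix")  # OTUs x samples
    otu_table(t(m))
  }
}

#' Write an OTU table
#'
#' @param table an [otu_table].
#' @param path output file path.
#' @inheritParams read_otu_table
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, dialect = c("tsv", "biom_json"),
                            samples_in_rows = FALSE) {
  dialect <- match.arg(dialect)
  table <- otu_table(unclass(table))
  if (dialect == "tsv") {
    m <- if (samples_in_rows) unclass(table) else t(unclass(table))
    df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c(if (samples_in_rows) "#Sample ID" else "#OTU ID", colnames(m))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- biomformat::make_biom(t(unclass(table)))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read and validate sample metadata
#'
#' The metadata CSV must carry one row per sample with columns `sample_id`,
#' `participant_id`, `week` (integer >= 0), `smoking` (`smoker`/`nonsmoker`),
#' `health` (`healthy`/`cold`/`antibiotics`), `sex` (`male`/`female`) and
#' `age` (years). Extra columns are preserved but ignored. Duplicate sample
#' ids or duplicate (participant, week) pairs are rejected.
#'
#' @param path CSV file path.
#' @return a validated data frame of class `study_metadata`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  study_metadata(df)
}

#' Construct validated study metadata from a data frame
#'
#' @param df data frame with the columns documented in [read_metadata()].
#' @return a data frame of class `study_metadata`.
#' @export
study_metadata <- function(df) {
  required <- c("sample_id", "participant_id", "week", "smoking", "health", "sex", "age")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) stop("metadata missing required column(s): ",
                            paste(missing, collapse = ", "))
  enum_check <- function(col, levels) {
    bad <- setdiff(unique(df[[col]]), levels)
    if (length(bad))
      stop("metadata column '", col, "' has unknown level(s): ",
           paste(bad, collapse = ", "), " (allowed: ", paste(levels, collapse = ", "), ")")
  }
  enum_check("smoking", c("smoker", "nonsmoker"))
  enum_check("health", c("healthy", "cold", "antibiotics"))
  enum_check("sex", c("male", "female"))
  if (anyNA(df$week) || any(df$week < 0) || any(df$week != round(df$week)))
    stop("metadata column 'week' must contain non-negative integers")
  df$week <- as.integer(df$week)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  key <- paste(df$participant_id, df$week)
  if (anyDuplicated(key))
    stop("duplicate (participant_id, week) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  class(df) <- c("study_metadata", "data.frame")
  df
}

#' Write study metadata as CSV
#' @param metadata a `study_metadata` data frame.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(as.data.frame(metadata), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree (Newick)
#'
#' Wraps [ape::read.tree()] with validation: unique leaf labels, non-negative
#' branch lengths. Missing branch lengths are set to 0 with a warning.
#'
#' @param path Newick file path.
#' @return an `ape::phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path, ": no tree found")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all lengths to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("tree has missing branch lengths; defaulting them to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch length(s) in tree")
  tr
}

#' Jointly validate an OTU table, metadata and (optionally) a tree
#'
#' Every sample in the table must have exactly one metadata row, and when a
#' tree is supplied its leaf set must match the table's OTU ids exactly —
#' mismatches raise an error rather than being silently pruned.
#'
#' @param table an [otu_table].
#' @param metadata a `study_metadata` data frame.
#' @param tree optional `phylo` tree.
#' @return `TRUE`, invisibly; stops on any mismatch.
#' @export
validate_study <- function(table, metadata, tree = NULL) {
  missing_meta <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(missing_meta))
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "))
  if (!is.null(tree)) {
    extra <- setdiff(tree$tip.label, otu_ids(table))
    absent <- setdiff(otu_ids(table), tree$tip.label)
    if (length(extra) || length(absent))
      stop("tree/table OTU mismatch; in tree only: ",
           paste(utils::head(extra, 5), collapse = ", "),
           if (length(extra) > 5) " ..." else "",
           "; in table only: ",
           paste(utils::head(absent, 5), collapse = ", "),
           if (length(absent) > 5) " ..." else "")
  }
  invisible(TRUE)
}
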