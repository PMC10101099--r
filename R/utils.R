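# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Per-unit seeds (one per sample, participant or stage) are derived by a
#' deterministic string hash so that results for one unit do not depend on
#' the order in which other units are processed.
#'
#' @param master integer master seed.
#' @param key character key (e.g. a sample id).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master))
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
# seed = NULL evaluates the code with the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(seed)
  code
}

# format numeric values at 6 significant digits for all text output
fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

# write a numeric matrix as TSV with a leading id column, 6 significant digits
write_tsv_matrix <- function(m, path, id_col = "id") {
  stopifnot(is.matrix(m))
  body <- matrix(fmt_num(m), nrow = nrow(m))
  df <- data.frame(rownames(m), body, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

msg <- function(...) message("[microstab] ", sprintf(...))
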