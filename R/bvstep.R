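#' BVSTEP subset selection
#'
#' Searches for a small OTU subset whose dissimilarity structure best
#' matches that of the full community. The fixed matrix is the chosen
#' dissimilarity computed on the table restricted to the `top_k` most
#' abundant OTUs; the match statistic `rho` is the Spearman rank correlation
#' between the lower triangles of the fixed and the subset dissimilarity
#' matrices. The search forward-adds the OTU maximizing `rho` (ties broken
#' lexicographically), then backward-drops any OTU whose removal reduces
#' `rho` by at most `1e-6`, iterating until `rho >= rho_target` or no
#' improving move exists.
#'
#' For `bray_curtis` the per-pair numerator and denominator are accumulated
#' incrementally over OTUs, which makes each candidate evaluation linear in
#' the number of sample pairs; other metrics recompute the subset matrix
#' through [dissimilarity()].
#'
#' @param table an [otu_table] with at least 3 samples.
#' @param metric dissimilarity metric, as in [dissimilarity()].
#' @param rho_target stopping correlation in `(0, 1]` (default 0.95).
#' @param top_k abundance-ranked pool size (default 1000).
#' @param seed optional seed used only when `restarts > 0`.
#' @param max_steps cap on add/drop actions (default 500).
#' @param restarts number of additional seeded random initial sets to try
#'   beyond the deterministic empty start (default 0).
#' @param tree tree passed through to [dissimilarity()] for UniFrac metrics.
#' @return an object of class `bvstep`: list with `selected_otu_ids`
#'   (sorted), `rho`, `converged`, `n_evaluations`, and `trace` (data frame
#'   of `action`, `otu_id`, `rho` replaying to the final set).
#' @export
bvstep_select <- function(table, metric = "bray_curtis", rho_target = 0.95,
                          top_k = 1000, seed = NULL, max_steps = 500,
                          restarts = 0, tree = NULL) {
  stopifnot(nrow(table) >= 3, rho_target > 0, rho_target <= 1)
  m <- unclass(as.matrix(table))
  total <- colSums(m)
  pool <- colnames(m)[order(-total, colnames(m))]
  pool <- sort(pool[seq_len(min(top_k, length(pool)))])
  m <- m[, pool, drop = FALSE]
  fixed <- dissimilarity(otu_table(m), metric, tree = tree)
  rank_fixed <- data.table::frank(fixed[lower.tri(fixed)])
  n_eval <- 0L

  spearman <- function(dvec) {
    r <- suppressWarnings(stats::cor(rank_fixed, data.table::frank(dvec)))
    if (is.na(r)) -Inf else r
  }

  if (metric == "bray_curtis") {
    lt <- which(lower.tri(diag(nrow(m))), arr.ind = TRUE)
    ia <- lt[, 1]; ib <- lt[, 2]
    pair_num <- function(j) { v <- m[, j]; abs(v[ia] - v[ib]) }
    pair_den <- function(j) { v <- m[, j]; v[ia] + v[ib] }
    base_of <- function(set) {
      num <- den <- numeric(length(ia))
      for (j in set) { num <- num + pair_num(j); den <- den + pair_den(j) }
      list(num = num, den = den)
    }
    rho_pair <- function(num, den) {
      n_eval <<- n_eval + 1L
      d <- num / den
      d[den == 0] <- 0
      spearman(d)
    }
    rho_of <- function(set) { b <- base_of(set); rho_pair(b$num, b$den) }
    rho_add <- function(base, j) rho_pair(base$num + pair_num(j),
                                          base$den + pair_den(j))
    rho_drop <- function(base, j) rho_pair(base$num - pair_num(j),
                                           base$den - pair_den(j))
  } else {
    base_of <- function(set) set
    rho_of <- function(set) {
      n_eval <<- n_eval + 1L
      # candidate subsets can leave samples empty; vegdist warns, rho handles it
      sub <- suppressWarnings(
        dissimilarity(otu_table(m[, set, drop = FALSE]), metric,
                      tree = if (is.null(tree)) NULL else ape::keep.tip(tree, set)))
      spearman(sub[lower.tri(sub)])
    }
    rho_add <- function(base, j) rho_of(c(base, j))
    rho_drop <- function(base, j) rho_of(setdiff(base, j))
  }

  run_search <- function(start) {
    set <- start
    rho <- if (length(set)) rho_of(set) else -Inf
    trace <- list()
    seen <- character(0)
    steps <- 0L
    repeat {
      if (rho >= rho_target || steps >= max_steps) break
      # forward: best single addition (pool is sorted, so ties break
      # lexicographically)
      cands <- setdiff(pool, set)
      if (!length(cands)) break
      base <- base_of(set)
      cand_rho <- vapply(cands, function(o) rho_add(base, o), numeric(1))
      best <- which(cand_rho == max(cand_rho))[1]
      # the first member is always admitted (singleton matrices can be
      # degenerate, e.g. proportions of a single OTU); later adds must
      # strictly improve
      if (length(set) && cand_rho[best] <= rho) break
      set <- c(set, cands[best])
      rho <- cand_rho[[best]]
      steps <- steps + 1L
      trace[[length(trace) + 1]] <- data.frame(action = "add",
        otu_id = cands[best], rho = rho, stringsAsFactors = FALSE)
      # backward: drop members whose removal costs at most 1e-6
      while (length(set) > 1 && steps < max_steps) {
        bfull <- base_of(set)
        drop_rho <- vapply(set, function(o) rho_drop(bfull, o), numeric(1))
        j <- which(drop_rho == max(drop_rho))[1]
        if (drop_rho[j] < rho - 1e-6) break
        dropped <- set[j]
        set <- setdiff(set, dropped)
        rho <- drop_rho[[j]]
        steps <- steps + 1L
        trace[[length(trace) + 1]] <- data.frame(action = "drop",
          otu_id = dropped, rho = rho, stringsAsFactors = FALSE)
      }
      key <- paste(sort(set), collapse = ";")
      if (key %in% seen) break                     # cycle guard
      seen <- c(seen, key)
    }
    list(set = set, rho = rho,
         trace = if (length(trace)) do.call(rbind, trace)
                 else data.frame(action = character(0), otu_id = character(0),
                                 rho = numeric(0)))
  }

  best <- run_search(character(0))
  if (restarts > 0) {
    starts <- with_seed(seed, lapply(seq_len(restarts), function(i)
      sample(pool, sample.int(max(1, length(pool) %/% 4), 1))))
    for (s in starts) {
      cand <- run_search(sort(s))
      if (cand$rho > best$rho) best <- cand
    }
  }
  structure(list(selected_otu_ids = sort(best$set), rho = best$rho,
                 converged = best$rho >= rho_target, metric = metric,
                 rho_target = rho_target, n_evaluations = n_eval,
                 trace = best$trace),
            class = "bvstep")
}

#' @export
print.bvstep <- function(x, ...) {
  cat(sprintf("bvstep: %d OTU(s) selected, rho = %.4f (%s; target %.2f, %d evaluations)\n",
              length(x$selected_otu_ids), x$rho,
              if (x$converged) "converged" else "not converged",
              x$rho_target, x$n_evaluations))
  invisible(x)
}
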