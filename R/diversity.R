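#' Hill number (effective species count) of order q
#'
#' For a proportion vector `p`, the Hill number is
#' `(sum_i p_i^q)^(1/(1-q))` over positive entries, with the continuity limit
#' `exp(-sum p_i log p_i)` at `q = 1`. `q = 0` is richness, `q = 1` the
#' exponential of Shannon entropy, `q = 2` inverse Simpson concentration.
#'
#' @param p non-negative proportion vector summing to 1 (within 1e-9).
#' @param q diversity order (>= 0).
#' @return the effective species count.
#' @examples
#' hill_number(rep(0.25, 4), 2)        # 4: uniform community
#' hill_number(c(0.9, 0.1), 2)         # 1/(0.81 + 0.01)
#' @export
hill_number <- function(p, q) {
  p <- as.numeric(p)
  if (!length(p) || all(p == 0)) stop("p must contain a positive entry")
  if (any(p < 0)) stop("p must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("p must sum to 1 (got ", sum(p), ")")
  stopifnot(length(q) == 1, q >= 0)
  p <- p[p > 0]
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Per-sample alpha diversity at several Hill orders
#'
#' Intended for rarefied tables: filter low-depth samples, rarefy to the
#' minimum library size, then compute diversity.
#'
#' @param table an [otu_table].
#' @param q numeric vector of Hill orders (default `c(0, 1, 2)`).
#' @return a data frame with `sample_id` and one column `q<order>` per order.
#' @export
alpha_diversity <- function(table, q = c(0, 1, 2)) {
  rel <- relative_abundance(table)
  out <- data.frame(sample_id = rownames(rel), stringsAsFactors = FALSE)
  for (qq in q)
    out[[paste0("q", qq)]] <- apply(rel, 1, hill_number, q = qq)
  out
}

#' Pairwise community dissimilarity matrix
#'
#' Supported metrics:
#' * `bray_curtis`: `sum|x_i - y_i| / sum(x_i + y_i)` on counts.
#' * `hellinger`: Euclidean distance between square-rooted proportion
#'   vectors (range `[0, sqrt(2)]`).
#' * `unifrac_unweighted`: branch length leading exclusively to leaves
#'   present in exactly one of the two samples, over the branch length of
#'   the union.
#' * `unifrac_weighted`: `sum_b l_b |p_A(b) - p_B(b)| / sum_b l_b (p_A(b) +
#'   p_B(b))`, where `p(b)` is the fraction of a sample's reads descending
#'   from branch `b` (normalized, hence in `[0, 1]`).
#'
#' @param table an [otu_table].
#' @param metric one of `"bray_curtis"`, `"hellinger"`,
#'   `"unifrac_unweighted"`, `"unifrac_weighted"`.
#' @param tree rooted `phylo` tree covering exactly the table's OTUs;
#'   required for the UniFrac metrics.
#' @return a symmetric samples x samples matrix with zero diagonal and a
#'   `"metric"` attribute.
#' @export
dissimilarity <- function(table,
                          metric = c("bray_curtis", "hellinger",
                                     "unifrac_unweighted", "unifrac_weighted"),
                          tree = NULL) {
  metric <- match.arg(metric)
  m <- unclass(as.matrix(table))
  d <- switch(metric,
    bray_curtis = as.matrix(vegan::vegdist(m, method = "bray")),
    hellinger = as.matrix(stats::dist(vegan::decostand(m, "hellinger"))),
    {
      if (is.null(tree)) stop("metric '", metric, "' requires a tree")
      unifrac_matrix(m, tree, weighted = metric == "unifrac_weighted")
    })
  d[!is.finite(d)] <- 0  # pairs with empty union (both samples blank)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "metric") <- metric
  d
}

# Branch-proportion UniFrac over all sample pairs.
# For each edge e (child node v), P[e, s] is the fraction of sample s's reads
# on leaves descending from v, accumulated in postorder. Both variants then
# reduce to weighted Manhattan structure over edges and close in matrix form.
unifrac_matrix <- function(counts, tree, weighted) {
  extra <- setdiff(tree$tip.label, colnames(counts))
  absent <- setdiff(colnames(counts), tree$tip.label)
  if (length(extra) || length(absent))
    stop("tree leaves and table OTUs must match exactly (",
         length(extra), " only in tree, ", length(absent), " only in table)")
  # the basal node of the phylo object is treated as the root; a star tree
  # (root polytomy) is a valid input
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  rel <- counts / rowSums(counts)
  # node x sample matrix of descending proportions
  node_p <- matrix(0, nnode, nrow(counts))
  node_p[seq_len(ntip), ] <- t(rel[, tree$tip.label, drop = FALSE])
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  elen <- po$edge.length
  for (k in seq_len(nrow(edges)))
    node_p[edges[k, 1], ] <- node_p[edges[k, 1], ] + node_p[edges[k, 2], ]
  P <- node_p[edges[, 2], , drop = FALSE]              # edge x sample
  if (weighted) {
    num <- as.matrix(stats::dist(t(P * elen), method = "manhattan"))
    s <- colSums(P * elen)
    den <- outer(s, s, "+")
  } else {
    B <- (P > 0) * 1
    s <- colSums(B * elen)
    inter <- crossprod(B * elen, B)                    # sum_b l_b B_i B_j
    num <- outer(s, s, "+") - 2 * inter                # symmetric difference
    den <- outer(s, s, "+") - inter                    # union
  }
  d <- num / den
  d[den == 0] <- 0
  d
}

#' Local contributions to beta diversity (LCBD)
#'
#' Gower-centres the matrix of squared dissimilarities,
#' `G = -1/2 C D^2 C` with `C = I - 11'/n`, and returns each sample's share
#' of the total variance, `LCBD_i = G_ii / trace(G)`. Values sum to 1; large
#' values flag samples with unusual community structure.
#'
#' @param d a square symmetric dissimilarity matrix (e.g. from
#'   [dissimilarity()]) or a `dist` object.
#' @return a named numeric vector of LCBD values summing to 1.
#' @export
lcbd <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("LCBD needs at least 2 samples")
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% (d^2) %*% C
  tr <- sum(diag(G))
  if (tr <= 1e-12) stop("no beta diversity: all samples identical")
  stats::setNames(diag(G) / tr, rownames(d))
}

#' Standardized phylogenetic community structure (NRI / NTI)
#'
#' For each sample, restricted to the `top_k` most abundant OTUs overall
#' (ties broken lexicographically by OTU id), computes the observed mean
#' pairwise patristic distance (MPD) and mean nearest-taxon distance (MNTD)
#' among the OTUs present (presence/absence only), and standardizes them
#' against a richness null model: `n_null` random draws of the same number
#' of OTUs, uniformly from the pool. `SES = (observed - null mean)/null sd`;
#' the net relatedness index is `NRI = -SES(MPD)` and the nearest taxon
#' index `NTI = -SES(MNTD)`. Index values above 2 are conventionally read as
#' strong phylogenetic clustering (environmental filtering).
#'
#' Null draws for a sample are seeded from `seed` and the sample id, so each
#' sample's result is independent of the processing order. Degenerate nulls
#' (zero standard deviation) yield `NA` with a warning rather than a
#' fabricated index.
#'
#' @param table an [otu_table].
#' @param tree rooted `phylo` covering the table's OTUs.
#' @param metric character vector, subset of `c("MPD", "MNTD")` (default both).
#' @param n_null number of null randomizations (default 999).
#' @param top_k size of the abundance-ranked OTU pool (default 1000).
#' @param seed integer master seed.
#' @return a data frame with one row per sample x metric: `sample_id`,
#'   `metric`, `observed`, `null_mean`, `null_sd`, `ses`, `index_name`
#'   (`NRI` or `NTI`), `index_value`, `n_null`, `clustered`
#'   (`index_value > 2`).
#' @export
ses_phylo <- function(table, tree, metric = c("MPD", "MNTD"), n_null = 999,
                      top_k = 1000, seed = 1) {
  metric <- match.arg(metric, several.ok = TRUE)
  stopifnot(top_k >= 2, n_null >= 1)
  m <- unclass(as.matrix(table))
  absent <- setdiff(colnames(m), tree$tip.label)
  if (length(absent))
    stop("OTUs missing from tree: ", paste(utils::head(absent, 5), collapse = ", "))
  total <- colSums(m)
  pool <- colnames(m)[order(-total, colnames(m))]
  pool <- pool[seq_len(min(top_k, length(pool)))]
  ptree <- if (length(setdiff(tree$tip.label, pool)))
    ape::keep.tip(tree, pool) else tree
  D <- stats::cophenetic(ptree)[pool, pool]
  npool <- length(pool)
  Dinf <- D
  diag(Dinf) <- Inf

  obs_mpd <- function(idx) {
    s <- D[idx, idx]
    sum(s) / (length(idx) * (length(idx) - 1))
  }
  obs_mntd <- function(idx) {
    s <- Dinf[idx, idx]
    mean(vapply(seq_along(idx), function(j) min(s[, j]), numeric(1)))
  }
  # null MPD for all draws at once: with E the pool x draws indicator,
  # sum of within-draw pairwise distances = colSums(E * (D %*% E))
  null_mpd <- function(draws, k) {
    E <- matrix(0, npool, ncol(draws))
    E[cbind(as.vector(draws), rep(seq_len(ncol(draws)), each = k))] <- 1
    colSums(E * (D %*% E)) / (k * (k - 1))
  }
  null_mntd <- function(draws, k) {
    vapply(seq_len(ncol(draws)), function(b) obs_mntd(draws[, b]), numeric(1))
  }

  rows <- list()
  for (sid in rownames(m)) {
    present <- which(pool %in% colnames(m)[m[sid, ] > 0])
    k <- length(present)
    if (k < 2) {
      warning("sample ", sid, " has fewer than 2 pool OTUs present; skipped")
      for (met in metric)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, metric = met, observed = NA_real_,
          null_mean = NA_real_, null_sd = NA_real_, ses = NA_real_,
          index_name = if (met == "MPD") "NRI" else "NTI",
          index_value = NA_real_, n_null = n_null, clustered = NA,
          stringsAsFactors = FALSE)
      next
    }
    draws <- with_seed(derive_seed(seed, sid),
      vapply(seq_len(n_null), function(b) sample.int(npool, k),
             integer(k)))
    draws <- matrix(draws, nrow = k)
    for (met in metric) {
      observed <- if (met == "MPD") obs_mpd(present) else obs_mntd(present)
      nulls <- if (met == "MPD") null_mpd(draws, k) else null_mntd(draws, k)
      null_mean <- mean(nulls)
      null_sd <- stats::sd(nulls)
      if (!is.finite(null_sd) || null_sd < 1e-12) {
        warning("degenerate null (sd = 0) for sample ", sid, ", metric ", met,
                "; index undefined")
        ses <- NA_real_
      } else ses <- (observed - null_mean) / null_sd
      idx <- -ses
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, metric = met, observed = observed,
        null_mean = null_mean, null_sd = null_sd, ses = ses,
        index_name = if (met == "MPD") "NRI" else "NTI",
        index_value = idx, n_null = n_null,
        clustered = if (is.na(idx)) NA else idx > 2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
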