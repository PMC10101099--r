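# Independent oracles and shared fixtures for the test suite.
# These deliberately re-derive quantities from first principles (recursive
# leaf sets, exhaustive enumeration, direct iteration) so they share no code
# path with the package implementation they check.

# --- brute-force per-branch UniFrac -----------------------------------------

# leaf labels below each edge, found by naive recursion over the edge list
edge_leafsets <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], rec))
  }
  lapply(seq_len(nrow(tree$edge)), function(k) rec(tree$edge[k, 2]))
}

brute_unifrac <- function(x, y, tree, weighted) {
  ls <- edge_leafsets(tree)
  l <- tree$edge.length
  if (weighted) {
    px <- x / sum(x); py <- y / sum(y)
    pa <- vapply(ls, function(s) sum(px[s]), numeric(1))
    pb <- vapply(ls, function(s) sum(py[s]), numeric(1))
    sum(l * abs(pa - pb)) / sum(l * (pa + pb))
  } else {
    inA <- vapply(ls, function(s) any(x[s] > 0), logical(1))
    inB <- vapply(ls, function(s) any(y[s] > 0), logical(1))
    sum(l[xor(inA, inB)]) / sum(l[inA | inB])
  }
}

# --- deterministic gLV flow (h-step exponential Euler), multi-start ---------

# Simulates the continuous-time gLV flow with the positivity-preserving map
# x <- x * exp(h (r + A x)) from a matrix of starts (species x starts).
# Returns the minimum abundance ever reached and the final states; values
# exploding past `cap` mark the run as divergent.
sim_flow <- function(model, X0, h, steps, cap = 1e8) {
  X <- as.matrix(X0)
  mins <- X
  diverged <- FALSE
  for (t in seq_len(steps)) {
    X <- X * exp(h * (model$r + model$A %*% X))
    if (any(!is.finite(X)) || any(X > cap)) { diverged <- TRUE; break }
    mins <- pmin(mins, X)
  }
  list(min_abundance = min(mins), final = X, diverged = diverged)
}

# --- gLV inference benchmark series -----------------------------------------

# Short deterministic segments from dispersed starts (a converged trajectory
# carries no information about A), with week gaps separating the segments so
# transitions never straddle them.
benchmark_series <- function(model, segments = 12, seg_len = 8, seed = 1,
                             spread = 0.8, noise_sigma = 0) {
  n <- length(model$r)
  xs <- solve(model$A, -model$r)
  set.seed(seed)
  segs <- lapply(seq_len(segments), function(s)
    simulate_ricker(model, xs * exp(stats::rnorm(n, 0, spread)), seg_len,
                    noise_sigma = noise_sigma, extinction_floor = 0))
  weeks <- as.vector(vapply(seq_len(segments),
                            function(s) (s - 1) * (seg_len + 1) + seq_len(seg_len),
                            numeric(seg_len)))
  list(x = do.call(rbind, segs), weeks = weeks)
}

# --- planted-structure table for BVSTEP -------------------------------------

# 12 samples; three OTUs carry independent strong gradients (linear ramp,
# sine wave, alternation), seven are flat and contribute no structure
make_bv_table <- function() {
  n <- 12
  v1 <- round(seq(10, 400, length.out = n))
  v2 <- round(400 * (sin(seq(0, 2 * pi, length.out = n)) + 1.2))
  v3 <- round(rep(c(30, 350), length.out = n) + seq(0, 60, length.out = n))
  m <- cbind(v1, v2, v3, matrix(40L, n, 7))
  dimnames(m) <- list(sprintf("S%02d", 1:n),
                      c("OTU_V1", "OTU_V2", "OTU_V3", sprintf("OTU_N%d", 1:7)))
  otu_table(m)
}

# exhaustive best subset of size <= kmax by Spearman match to the full matrix
bvstep_oracle <- function(tab, metric = "bray_curtis", kmax = 3) {
  full <- dissimilarity(tab, metric)
  fv <- full[lower.tri(full)]
  ids <- colnames(tab)
  best <- NULL; best_rho <- -Inf
  for (k in seq_len(kmax)) {
    for (S in utils::combn(ids, k, simplify = FALSE)) {
      d <- suppressWarnings(
        dissimilarity(otu_table(unclass(tab)[, S, drop = FALSE]), metric))
      r <- suppressWarnings(stats::cor(fv, d[lower.tri(d)], method = "spearman"))
      if (!is.na(r) && r > best_rho) { best_rho <- r; best <- S }
    }
  }
  list(subset = best, rho = best_rho)
}

# --- misc --------------------------------------------------------------------

read_tsv_matrix_for_test <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

random_counts_table <- function(n_samples, n_otus, seed, lambda = 50) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_otus, lambda), n_samples, n_otus,
              dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                              sprintf("OTU_%03d", seq_len(n_otus))))
  otu_table(m)
}
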