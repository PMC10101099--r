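#' Generalized Lotka-Volterra models
#'
#' A `glv` object couples an interaction matrix `A` (per-capita effect of
#' species j's abundance on species i's growth rate) with an intrinsic
#' growth-rate vector `r`. The continuous-time dynamics are
#' `dx_i/dt = x_i (r_i + sum_j A_ij x_j)`; the discrete-time (Ricker)
#' analogue used for weekly time series is
#' `x_i(t+1) = x_i(t) exp(r_i + sum_j A_ij x_j(t))`.
#'
#' @param A n x n numeric interaction matrix.
#' @param r length-n numeric growth-rate vector.
#' @param otu_ids optional length-n character labels; defaults to
#'   `OTU_001, ...` or `A`'s dimnames.
#' @return an object of class `glv` with elements `A`, `r`, `otu_ids`.
#' @examples
#' m <- glv_model(A = matrix(-1, 1, 1), r = 1)
#' predict(m, newdata = 1)   # interior equilibrium: stays at 1
#' @export
glv_model <- function(A, r, otu_ids = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (!all(is.finite(A))) stop("A must be finite")
  r <- as.numeric(r)
  if (length(r) != nrow(A)) stop("length(r) must equal nrow(A)")
  if (!all(is.finite(r))) stop("r must be finite")
  n <- nrow(A)
  if (is.null(otu_ids)) otu_ids <- rownames(A) %||% sprintf("OTU_%03d", seq_len(n))
  if (length(otu_ids) != n || anyDuplicated(otu_ids))
    stop("otu_ids must be ", n, " unique labels")
  dimnames(A) <- list(otu_ids, otu_ids)
  names(r) <- otu_ids
  structure(list(A = A, r = r, otu_ids = otu_ids), class = "glv")
}

#' @export
print.glv <- function(x, ...) {
  n <- length(x$r)
  off <- x$A[row(x$A) != col(x$A)]
  cat(sprintf("gLV model: %d species, %d/%d nonzero off-diagonal interactions\n",
              n, sum(off != 0), length(off)))
  cat(sprintf("  diag(A) in [%.3g, %.3g]; r in [%.3g, %.3g]\n",
              min(diag(x$A)), max(diag(x$A)), min(x$r), max(x$r)))
  invisible(x)
}

#' Coefficients of a gLV model
#'
#' @param object a `glv` object.
#' @param ... unused.
#' @return a matrix with one row per species: the growth rate in column `r`
#'   followed by the interaction coefficients.
#' @export
coef.glv <- function(object, ...) {
  cbind(r = object$r, object$A)
}

#' One-step Ricker prediction from a gLV model
#'
#' Applies the map `x_i exp(r_i + (A x)_i)` to a state vector, or row-wise to
#' a matrix of states. Species at zero abundance stay at zero (the boundary
#' is absorbing).
#'
#' @param object a `glv` object.
#' @param newdata numeric state vector of length n, or a matrix with n
#'   columns (one state per row).
#' @param ... unused.
#' @return the next state, same shape as `newdata`.
#' @export
predict.glv <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    out <- t(apply(newdata, 1, function(x) predict.glv(object, x)))
    dimnames(out) <- dimnames(newdata)
    return(out)
  }
  x <- as.numeric(newdata)
  if (length(x) != length(object$r)) stop("state length must equal the species count")
  if (any(x < 0)) stop("state must be non-negative")
  unname(x * exp(object$r + drop(object$A %*% x)))
}

#' Simulate Ricker-map trajectories from a gLV model
#'
#' @param object a `glv` object.
#' @param nsim number of trajectories; a list is returned when `nsim > 1`.
#' @param seed integer seed (the caller's RNG state is restored afterwards).
#' @param x0 positive initial state vector.
#' @param steps number of time points returned (the first row is `x0`).
#' @param noise_sigma standard deviation of the multiplicative log-normal
#'   process noise; `0` gives a deterministic trajectory.
#' @param extinction_floor states below this value are set to 0 and remain 0.
#' @param ... unused.
#' @return a `steps` x n matrix (or a list of them for `nsim > 1`).
#' @export
simulate.glv <- function(object, nsim = 1, seed = NULL, x0, steps = 100,
                         noise_sigma = 0, extinction_floor = 1e-6, ...) {
  if (nsim == 1)
    return(simulate_ricker(object, x0, steps, noise_sigma, seed, extinction_floor))
  with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_ricker(object, x0, steps, noise_sigma, seed = NULL, extinction_floor)))
}

#' Simulate a noisy Ricker-map gLV trajectory
#'
#' Iterates `x_i(t+1) = x_i(t) exp(r_i + (A x(t))_i + eps_i(t))` with
#' `eps ~ Normal(0, noise_sigma^2)` drawn independently per species and step.
#' With `noise_sigma = 0` the map is deterministic and no random numbers are
#' consumed. Values falling below `extinction_floor` are set to 0 and stay 0.
#'
#' @param model a `glv` object.
#' @param x0 positive initial state (length n).
#' @param steps number of rows of the returned trajectory (>= 1); the first
#'   row is `x0`, so `steps` rows contain `steps - 1` transitions.
#' @param noise_sigma process-noise standard deviation (>= 0).
#' @param seed optional integer seed.
#' @param extinction_floor absorbing lower threshold (>= 0).
#' @return a `steps` x n matrix of abundances with OTU ids as column names.
#' @export
simulate_ricker <- function(model, x0, steps, noise_sigma = 0, seed = NULL,
                            extinction_floor = 1e-6) {
  stopifnot(inherits(model, "glv"))
  n <- length(model$r)
  x0 <- as.numeric(x0)
  if (length(x0) != n) stop("x0 must have length ", n)
  if (any(x0 <= 0)) stop("x0 must be strictly positive")
  if (steps < 1) stop("steps must be >= 1")
  with_seed(seed, {
    traj <- matrix(0, steps, n, dimnames = list(NULL, model$otu_ids))
    x <- x0
    traj[1, ] <- x
    if (steps > 1) for (t in 2:steps) {
      eps <- if (noise_sigma > 0) stats::rnorm(n, 0, noise_sigma) else 0
      x <- x * exp(model$r + drop(model$A %*% x) + eps)
      x[x < extinction_floor] <- 0
      if (any(!is.finite(x)) || any(x > 1e8))
        stop("trajectory diverged at step ", t,
             " (species ", which(!is.finite(x) | x > 1e8)[1], ")")
      traj[t, ] <- x
    }
    traj
  })
}
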