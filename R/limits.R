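#' Infer a gLV interaction matrix from a core time series (LIMITS-style)
#'
#' Fits the discrete-time (Ricker) generalized Lotka-Volterra model to one
#' participant's core community time series by sparse forward-stepwise
#' regression with bagging. For each species i, the regression target over
#' consecutive-week transitions is the log abundance change
#' `y_i(t) = log x_i(t+1) - log x_i(t)`, which under the Ricker map equals
#' `r_i + sum_j A_ij x_j(t)` plus noise. Predictors are the abundances
#' `x_j(t)`; the intercept gives `r_i` and the self-term `x_i(t)` is always
#' in the model. Candidates are added one at a time, choosing the predictor
#' that minimizes the median held-out mean-squared error across `n_bags`
#' random train/test splits, and accepted only if the relative error
#' improvement exceeds `improvement_threshold`. Final coefficients are the
#' elementwise median over bag fits; never-selected predictors get
#' `A_ij = 0`.
#'
#' Transitions are only formed between consecutive weeks; gaps break the
#' chain. Time points where species i is absent are excluded from species
#' i's regression (no pseudo-counts). Bags whose train design is rank
#' deficient are dropped.
#'
#' @param series a [core_microbiota()] `core_series`, or a T x n abundance
#'   matrix with OTU ids as column names (then `weeks` defaults to
#'   `1:T`).
#' @param n_bags number of random train/test splits (default 100).
#' @param test_fraction fraction of transitions held out per bag (default 0.5).
#' @param improvement_threshold minimum relative improvement in median
#'   held-out MSE required to accept a predictor (default 0: any strict
#'   improvement).
#' @param max_predictors cap on predictors per species (default: all).
#' @param seed integer seed; per-species bag splits are derived from it.
#' @param min_samples minimum number of time points required (default 9).
#' @param weeks optional integer week index when `series` is a matrix.
#' @return an object of class `c("limits_glv", "glv")`: the fitted `A`, `r`
#'   and `otu_ids` plus `fit` (per-species selected predictors, held-out
#'   error, observation counts), `transitions`, `config` and `call`.
#'   Methods: [print][print.limits_glv], [summary][summary.limits_glv],
#'   [coef][coef.glv], [predict][predict.glv], [simulate][simulate.glv],
#'   [residuals][residuals.limits_glv], [fitted][fitted.limits_glv],
#'   [plot][plot.limits_glv].
#' @export
limits_glv <- function(series, n_bags = 100, test_fraction = 0.5,
                       improvement_threshold = 0, max_predictors = NULL,
                       seed = NULL, min_samples = 9, weeks = NULL) {
  stopifnot(n_bags >= 1, test_fraction > 0, test_fraction < 1,
            improvement_threshold >= 0, min_samples >= 3)
  if (inherits(series, "core_series")) {
    x <- series$abundances
    weeks <- series$weeks
    participant <- series$participant_id
  } else {
    x <- as.matrix(series)
    if (is.null(weeks)) weeks <- seq_len(nrow(x))
    participant <- NULL
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("OTU_%03d", seq_len(ncol(x)))
  n <- ncol(x)
  ids <- colnames(x)
  if (nrow(x) < min_samples)
    stop("series has ", nrow(x), " samples; at least ", min_samples, " required")
  if (all(apply(x, 2, stats::var) == 0)) stop("no dynamics to fit: constant series")
  max_predictors <- max_predictors %||% n

  trans <- which(diff(weeks) == 1)
  if (length(trans) < 2)
    stop("fewer than 2 consecutive-week transitions in the series")
  X0 <- x[trans, , drop = FALSE]
  X1 <- x[trans + 1, , drop = FALSE]

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  r <- stats::setNames(rep(NA_real_, n), ids)
  fit_info <- vector("list", n)
  names(fit_info) <- ids

  for (i in seq_len(n)) {
    v <- which(X0[, i] > 0 & X1[, i] > 0)
    m_i <- length(v)
    if (m_i < 3) {
      fit_info[[i]] <- list(selected = character(0), n_obs = m_i,
                            heldout_mse = NA_real_, skipped = TRUE)
      r[i] <- 0
      next
    }
    y <- log(X1[v, i] / X0[v, i])
    Xp <- X0[v, , drop = FALSE]
    n_train <- max(2L, round((1 - test_fraction) * m_i))
    bags <- with_seed(derive_seed(seed %||% 0, paste0("bags_", ids[i])),
      lapply(seq_len(n_bags), function(b) sample.int(m_i, n_train)))

    # OLS via .lm.fit, returning coefficients in original column order
    # (the LAPACK QR may pivot); NULL flags a rank-deficient design
    ols <- function(Xd, yd) {
      f <- stats::.lm.fit(Xd, yd)
      if (f$rank < ncol(Xd)) return(NULL)
      b <- numeric(ncol(Xd))
      b[f$pivot] <- f$coefficients
      b
    }

    bag_mse <- function(S) {
      mses <- vapply(bags, function(tr) {
        b <- ols(cbind(1, Xp[tr, S, drop = FALSE]), y[tr])
        if (is.null(b)) return(NA_real_)
        te <- setdiff(seq_len(m_i), tr)
        pred <- cbind(1, Xp[te, S, drop = FALSE]) %*% b
        mean((y[te] - pred)^2)
      }, numeric(1))
      if (all(is.na(mses))) Inf else stats::median(mses, na.rm = TRUE)
    }

    S <- i  # self-term always in the model
    err <- bag_mse(S)
    while (length(S) < max_predictors) {
      cands <- setdiff(seq_len(n), S)
      if (!length(cands)) break
      # an error at machine-noise scale means the fit is already exact;
      # "relative improvement" below that floor is rounding noise
      if (!is.finite(err) || err <= 1e-24) break
      cand_err <- vapply(cands, function(j) bag_mse(c(S, j)), numeric(1))
      o <- order(cand_err, ids[cands])  # ties: lexicographic on OTU id
      best <- o[1]
      if ((err - cand_err[best]) / err <= improvement_threshold) break
      S <- c(S, cands[best])
      err <- cand_err[best]
    }

    coefs <- vapply(bags, function(tr) {
      b <- ols(cbind(1, Xp[tr, S, drop = FALSE]), y[tr])
      if (is.null(b)) rep(NA_real_, length(S) + 1) else b
    }, numeric(length(S) + 1))
    ok <- colSums(is.na(coefs)) == 0
    beta <- if (any(ok)) apply(coefs[, ok, drop = FALSE], 1, stats::median)
            else ols(cbind(1, Xp[, S, drop = FALSE]), y) %||%
                 rep(0, length(S) + 1)
    r[i] <- beta[1]
    A[i, S] <- beta[-1]
    fit_info[[i]] <- list(selected = ids[S], n_obs = m_i, heldout_mse = err,
                          skipped = FALSE)
  }

  model <- glv_model(A, r, ids)
  model$fit <- fit_info
  model$transitions <- trans
  model$series <- x
  model$weeks <- weeks
  model$participant_id <- participant
  model$config <- list(n_bags = n_bags, test_fraction = test_fraction,
                       improvement_threshold = improvement_threshold,
                       max_predictors = max_predictors, seed = seed,
                       min_samples = min_samples)
  model$call <- match.call()
  class(model) <- c("limits_glv", "glv")
  model
}

#' @export
print.limits_glv <- function(x, ...) {
  cat("LIMITS-style gLV fit",
      if (!is.null(x$participant_id)) paste0(" (participant ", x$participant_id, ")"),
      "\n", sep = "")
  cat(sprintf("  %d species, %d consecutive-week transitions, %d bags\n",
              length(x$r), length(x$transitions), x$config$n_bags))
  off <- x$A[row(x$A) != col(x$A)]
  cat(sprintf("  nonzero off-diagonal interactions: %d/%d\n",
              sum(off != 0), length(off)))
  invisible(x)
}

#' Summarize a LIMITS gLV fit
#' @param object a `limits_glv` fit.
#' @param ... unused.
#' @return a data frame with one row per species: number of selected
#'   predictors, observations used and median held-out MSE.
#' @export
summary.limits_glv <- function(object, ...) {
  df <- data.frame(
    otu_id = object$otu_ids,
    r = unname(object$r),
    n_predictors = vapply(object$fit, function(f) length(f$selected), integer(1)),
    n_obs = vapply(object$fit, function(f) f$n_obs, numeric(1)),
    heldout_mse = vapply(object$fit, function(f) f$heldout_mse %||% NA_real_,
                         numeric(1)),
    stringsAsFactors = FALSE)
  class(df) <- c("summary.limits_glv", "data.frame")
  df
}

# one-step predictions over the observed transitions (log-change scale)
limits_pred_obs <- function(object) {
  x <- object$series
  tr <- object$transitions
  X0 <- x[tr, , drop = FALSE]
  X1 <- x[tr + 1, , drop = FALSE]
  valid <- X0 > 0 & X1 > 0
  obs <- matrix(NA_real_, length(tr), ncol(x), dimnames = list(NULL, colnames(x)))
  obs[valid] <- log(X1 / X0)[valid]
  pred <- sweep(X0 %*% t(object$A), 2, object$r, "+")
  pred[!valid] <- NA_real_
  list(obs = obs, pred = pred)
}

#' @export
fitted.limits_glv <- function(object, ...) limits_pred_obs(object)$pred

#' Residual log-change errors of a LIMITS gLV fit
#' @param object a `limits_glv` fit.
#' @param ... unused.
#' @return a transitions x species matrix of `observed - fitted` log
#'   abundance changes; `NA` where a species was absent at either endpoint.
#' @export
residuals.limits_glv <- function(object, ...) {
  p <- limits_pred_obs(object)
  p$obs - p$pred
}

#' Diagnostic plot: observed vs fitted one-step log changes
#' @param x a `limits_glv` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.limits_glv <- function(x, ...) {
  p <- limits_pred_obs(x)
  graphics::plot(as.vector(p$pred), as.vector(p$obs),
                 xlab = "fitted log change", ylab = "observed log change", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
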