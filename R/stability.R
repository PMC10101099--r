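#' Interior equilibrium of a gLV model
#'
#' Solves `A x = -r`. The equilibrium is feasible when every entry is
#' strictly positive; infeasible equilibria are returned with the flag set,
#' never clamped.
#'
#' @param model a [glv_model()].
#' @param max_condition reject `A` whose reciprocal condition number implies
#'   a condition number above this bound (default 1e12).
#' @return list with `x_star` (named numeric) and `feasible` (logical).
#' @export
interior_equilibrium <- function(model, max_condition = 1e12) {
  stopifnot(inherits(model, "glv"))
  if (rcond(model$A) < 1 / max_condition)
    stop("interaction matrix is singular or ill-conditioned (rcond = ",
         format(rcond(model$A), digits = 3), ")")
  x <- drop(solve(model$A, -model$r))
  names(x) <- model$otu_ids
  list(x_star = x, feasible = all(x > 0))
}

#' Continuous-time gLV Jacobian at an equilibrium
#'
#' For interior species, `J_ij = x*_i A_ij` (`J = diag(x*) A`). A species at
#' zero abundance decouples: its row is zero except the diagonal, which
#' holds its invasion growth rate `r_i + (A x*)_i`.
#'
#' @param model a [glv_model()].
#' @param x_star non-negative equilibrium state.
#' @return the n x n Jacobian matrix.
#' @export
glv_jacobian <- function(model, x_star) {
  stopifnot(inherits(model, "glv"), all(x_star >= 0))
  x_star <- as.numeric(x_star)
  J <- diag(x_star, length(x_star)) %*% model$A
  absent <- which(x_star == 0)
  growth <- model$r + drop(model$A %*% x_star)
  for (i in absent) {
    J[i, ] <- 0
    J[i, i] <- growth[i]
  }
  dimnames(J) <- dimnames(model$A)
  J
}

#' Dominant eigenvalue (maximum real part) of a matrix
#'
#' @param J a square numeric matrix.
#' @return the largest real part over the spectrum.
#' @export
dominant_eigenvalue <- function(J) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J), all(is.finite(J)))
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' Enumerate non-negative boundary equilibria of a gLV model
#'
#' For every proper subset S of species (including the empty set, i.e. the
#' origin) solves the restricted system `A[S,S] x_S = -r[S]` and keeps
#' solutions with all entries non-negative, embedded with zeros for the
#' absent species. Subsets with a singular restricted matrix have no
#' isolated equilibrium and are skipped. Coincident points within 1e-10 are
#' deduplicated. Enumeration is exponential in n and refused above `n_max`.
#'
#' @param model a [glv_model()].
#' @param n_max maximum species count (default 20).
#' @return a list of equilibria; each element is a list with `subset`
#'   (integer indices of the present species) and `x_hat` (length-n state).
#' @export
boundary_equilibria <- function(model, n_max = 20) {
  n <- length(model$r)
  if (n > n_max)
    stop("boundary enumeration is exponential; n = ", n, " exceeds n_max = ",
         n_max, " (raise n_max or reduce the community)")
  out <- list(list(subset = integer(0), x_hat = rep(0, n)))  # origin
  subsets <- if (n == 1) list() else
    unlist(lapply(seq_len(n - 1), function(k)
      utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  for (S in subsets) {
    As <- model$A[S, S, drop = FALSE]
    if (rcond(As) < 1e-12) next
    xs <- drop(solve(As, -model$r[S]))
    if (any(xs < -1e-12)) next
    x <- rep(0, n)
    x[S] <- pmax(xs, 0)
    out[[length(out) + 1]] <- list(subset = S, x_hat = x)
  }
  # deduplicate coincident points
  keys <- vapply(out, function(e) paste(round(e$x_hat / 1e-10), collapse = ","),
                 character(1))
  out[!duplicated(keys)]
}

#' Dissipativity proxy check
#'
#' Operational test that trajectories remain bounded: all self-limitation
#' terms `A_ii` strictly negative (so each single-species subsystem has a
#' finite carrying capacity `r_i / -A_ii`).
#'
#' @param model a [glv_model()].
#' @return logical.
#' @export
dissipativity_check <- function(model) {
  all(is.finite(model$r)) && all(diag(model$A) < 0)
}

#' Permanence (global stability) via an average Lyapunov function LP
#'
#' A gLV community is permanent — no species tends to extinction from any
#' interior start — if it is dissipative and an average Lyapunov function
#' `V(x) = prod_i x_i^{p_i}` exists whose growth rate is positive at every
#' boundary equilibrium (Jansen's sufficient condition). That reduces to a
#' linear feasibility problem: find `p_i >= 1` such that
#' `sum_i p_i (r_i + (A x_hat)_i) >= delta` for every boundary equilibrium
#' `x_hat`. The LP is solved with [boot::simplex()] (substituting
#' `q = p - 1 >= 0`; constraint rows with negative right-hand side are
#' flipped into `<=` form, as the solver requires non-negative constants).
#' Any certificate found is re-verified against every constraint before
#' being reported.
#'
#' @param model a [glv_model()] with a feasible interior equilibrium.
#' @param delta strictness margin of the boundary constraints (default 1e-6).
#' @param n_max passed to [boundary_equilibria()].
#' @return list with `permanent` (logical), `p_certificate` (named numeric
#'   or `NULL`), `dissipative`, `n_boundary` and `margins` (constraint
#'   values of the certificate, or `NULL`).
#' @export
permanence_lp <- function(model, delta = 1e-6, n_max = 20) {
  eq <- interior_equilibrium(model)
  if (!eq$feasible)
    stop("permanence test requires a feasible (positive) interior equilibrium")
  n <- length(model$r)
  be <- boundary_equilibria(model, n_max = n_max)
  Fm <- t(vapply(be, function(e) model$r + drop(model$A %*% e$x_hat),
                 numeric(n)))                      # one row per boundary point
  d <- delta - rowSums(Fm)                         # constraints: Fm q >= d
  dissip <- dissipativity_check(model)

  pos <- d >= 0
  sol <- tryCatch(
    boot::simplex(a = rep(1, n),
                  A1 = if (any(!pos)) -Fm[!pos, , drop = FALSE],
                  b1 = if (any(!pos)) -d[!pos],
                  A2 = if (any(pos)) Fm[pos, , drop = FALSE],
                  b2 = if (any(pos)) d[pos],
                  maxi = FALSE),
    error = function(e) stop("LP solver failure: ", conditionMessage(e)))
  if (sol$solved != 1)
    return(list(permanent = FALSE, p_certificate = NULL, dissipative = dissip,
                n_boundary = length(be), margins = NULL))
  p <- unname(sol$soln) + 1
  margins <- drop(Fm %*% p)
  verified <- all(margins >= delta / 2)            # independent re-check
  list(permanent = verified && dissip,
       p_certificate = if (verified) stats::setNames(p, model$otu_ids) else NULL,
       dissipative = dissip, n_boundary = length(be),
       margins = if (verified) margins else NULL)
}

#' Invasibility of a resident community
#'
#' Augments the interaction matrix with one "invader" row and column of
#' zeros (except its own diagonal `a_inv_inv`) and the growth-rate vector
#' with `r_inv`, keeps the resident equilibrium with the invader at zero
#' abundance, and computes the dominant eigenvalue of the augmented
#' Jacobian. The community is invasible when that eigenvalue exceeds `tol`
#' (the invader grows when rare).
#'
#' @param model a resident [glv_model()] with a feasible, locally stable
#'   interior equilibrium (a warning is emitted otherwise; the result is
#'   still reported).
#' @param r_inv invader intrinsic growth rate (default 0, the literal
#'   zero-rows/columns convention).
#' @param a_inv_inv invader self-limitation (default 0).
#' @param tol positivity tolerance on the dominant eigenvalue (default 1e-9).
#' @return list with `invasible`, `dominant_eigenvalue` (of the augmented
#'   Jacobian), and `invader_config`.
#' @export
invasibility_test <- function(model, r_inv = 0, a_inv_inv = 0, tol = 1e-9) {
  eq <- interior_equilibrium(model)
  if (!eq$feasible)
    warning("resident equilibrium is not feasible; invasibility verdict is formal")
  n <- length(model$r)
  A_aug <- rbind(cbind(model$A, 0), 0)
  A_aug[n + 1, n + 1] <- a_inv_inv
  ids <- c(model$otu_ids, "invader")
  aug <- glv_model(A_aug, c(model$r, r_inv), ids)
  x_res <- pmax(eq$x_star, 0)   # formal state when the equilibrium is infeasible
  x_aug <- c(x_res, 0)
  J_res <- glv_jacobian(model, x_res)
  if (dominant_eigenvalue(J_res) >= -tol)
    warning("resident community is not locally stable at its interior equilibrium")
  J_aug <- glv_jacobian(aug, x_aug)
  lam <- dominant_eigenvalue(J_aug)
  list(invasible = lam > tol, dominant_eigenvalue = lam,
       invader_config = list(r_inv = r_inv, a_inv_inv = a_inv_inv))
}

#' Full stability report for a gLV community
#'
#' Computes the interior equilibrium, the continuous-time Jacobian
#' `diag(x*) A` and its dominant eigenvalue, the local-stability verdict
#' (`locally_stable` iff the dominant eigenvalue is below `-tol`, with
#' eigenvalues within `tol` of zero flagged `marginal`), the permanence
#' verdict with its average-Lyapunov certificate, the dissipativity proxy
#' and the invasibility verdict under the given invader traits. The
#' dominant eigenvalue of `A` itself is reported alongside, since stability
#' statements about "the interaction matrix" can refer to either matrix.
#'
#' @param model a [glv_model()].
#' @param participant_id optional label carried into the report.
#' @param r_inv,a_inv_inv invader traits for [invasibility_test()].
#' @param tol local-stability tolerance (default 1e-9).
#' @param delta permanence LP margin (default 1e-6).
#' @param n_max boundary-enumeration cap (default 20).
#' @return an object of class `stability_report` (a list of the fields
#'   above; `notes` records degeneracies such as an infeasible interior
#'   equilibrium, in which case permanence is reported `FALSE` with no
#'   certificate).
#' @export
stability_report <- function(model, participant_id = NULL, r_inv = 0,
                             a_inv_inv = 0, tol = 1e-9, delta = 1e-6,
                             n_max = 20) {
  eq <- interior_equilibrium(model)
  J <- glv_jacobian(model, pmax(eq$x_star, 0))
  lam <- dominant_eigenvalue(J)
  notes <- character(0)
  if (!eq$feasible)
    notes <- c(notes, "interior equilibrium infeasible (non-positive entries)")
  perm <- if (eq$feasible) {
    permanence_lp(model, delta = delta, n_max = n_max)
  } else {
    list(permanent = FALSE, p_certificate = NULL,
         dissipative = dissipativity_check(model), n_boundary = NA_integer_)
  }
  inv <- withCallingHandlers(
    invasibility_test(model, r_inv = r_inv, a_inv_inv = a_inv_inv, tol = tol),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  structure(list(
    participant_id = participant_id,
    equilibrium = eq$x_star,
    feasible = eq$feasible,
    jacobian = J,
    dominant_eigenvalue = lam,
    dominant_eigenvalue_A = dominant_eigenvalue(model$A),
    locally_stable = lam < -tol,
    marginal = abs(lam) <= tol,
    permanent = perm$permanent,
    lyapunov_certificate = perm$p_certificate,
    dissipative = perm$dissipative,
    n_boundary = perm$n_boundary,
    invasible = inv$invasible,
    invasion_eigenvalue = inv$dominant_eigenvalue,
    invader_config = inv$invader_config,
    notes = notes), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report",
      if (!is.null(x$participant_id)) paste0(" (", x$participant_id, ")"),
      ": ", length(x$equilibrium), " species\n", sep = "")
  cat(sprintf("  interior equilibrium %s; dominant eigenvalue %.4g (%s%s)\n",
              if (x$feasible) "feasible" else "infeasible",
              x$dominant_eigenvalue,
              if (x$locally_stable) "locally stable" else "not locally stable",
              if (x$marginal) ", marginal" else ""))
  cat(sprintf("  permanent: %s; dissipative: %s; invasible: %s (lambda = %.4g)\n",
              x$permanent, x$dissipative, x$invasible, x$invasion_eigenvalue))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
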