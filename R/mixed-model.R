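#' Incidence map: observation-to-level assignment
#'
#' Builds the 0/1 incidence matrix `Z` of the model `y = mu + Z x + e`. A
#' transcript assigned to k > 1 terms contributes a 1 in each of the k
#' columns (row sum k). Transcripts absent from the mapping are dropped with
#' a message (they contribute no estimable level).
#'
#' @param expr an [expression_vector()].
#' @param mapping a [term_mapping()], or `NULL` for the transcript-based
#'   model in which every observation is its own level (`Z = I`).
#' @param weighted logical; if `TRUE`, rows are scaled to sum 1 instead of
#'   carrying multiple 1s.
#' @return object of class `incidence_map`: list with sparse matrix `Z`
#'   (observations x levels, dimnames set), `observations`, `levels`,
#'   and `dropped` (ids excluded for lack of annotation).
#' @export
build_incidence <- function(expr, mapping = NULL, weighted = FALSE) {
  stopifnot(inherits(expr, "expression_vector"))
  obs <- names(expr)
  if (is.null(mapping)) {
    n <- length(obs)
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = seq_len(n), x = 1,
                              dims = c(n, n), dimnames = list(obs, obs))
    return(structure(list(Z = Z, observations = obs, levels = obs,
                          dropped = character(0)),
                     class = "incidence_map"))
  }
  stopifnot(inherits(mapping, "term_mapping"))
  keep <- obs[obs %in% names(mapping$assignments)]
  dropped <- setdiff(obs, keep)
  if (length(keep) == 0L)
    stop("build_incidence: no overlap between expression ids and mapping")
  if (length(dropped) > 0L)
    message("build_incidence: dropped ", length(dropped),
            " transcript(s) without annotation")
  asn <- mapping$assignments[keep]
  levels <- sort(unique(unlist(asn, use.names = FALSE)))
  i <- rep.int(seq_along(keep), lengths(asn))
  j <- match(unlist(asn, use.names = FALSE), levels)
  x <- if (weighted) 1 / lengths(asn)[i] else rep(1, length(i))
  Z <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(keep), length(levels)),
                            dimnames = list(keep, levels))
  structure(list(Z = Z, observations = keep, levels = levels,
                 dropped = dropped),
            class = "incidence_map")
}

#' @exportS3Method base::print
print.incidence_map <- function(x, ...) {
  cat(sprintf("incidence_map: %d observations x %d levels (%d dropped)\n",
              length(x$observations), length(x$levels), length(x$dropped)))
  invisible(x)
}

# One-time spectral preparation of the mixed model equations.
#
# Finds T with V = T T' and T' Z'Z T = diag(theta) (simultaneous
# diagonalization), so that for any lambda = sigma2_e / sigma2_x the
# random-effect block W = Z'Z + lambda V^-1 satisfies T' W T =
# diag(theta + lambda). All per-iteration EM quantities then reduce to O(q)
# vector arithmetic. Done per block when V is block-diagonal and Z'Z is
# block-conformal, densely otherwise. A ridge is added to V's diagonal only
# when its condition number exceeds 1e12.
.mme_precompute <- function(Z, V, ridge = 1e-8) {
  ZtZ <- Matrix::crossprod(Z)
  q <- ncol(Z)
  ridge_applied <- FALSE
  prep_block <- function(Vb, Ab) {
    e <- eigen(Vb, symmetric = TRUE)
    if (min(e$values) <= max(e$values) / 1e12) {
      Vb <- Vb + diag(ridge, nrow(Vb))
      e <- eigen(Vb, symmetric = TRUE)
      ridge_applied <<- TRUE
    }
    if (min(e$values) <= 0) stop("solve_mme: covariance block not positive definite")
    L <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
    K <- crossprod(L, Ab %*% L)
    K <- (K + t(K)) / 2
    ek <- eigen(K, symmetric = TRUE)
    list(T = L %*% ek$vectors, theta = pmax(ek$values, 0))
  }
  bs <- V$block_structure
  use_blocks <- FALSE
  if (!is.null(bs) && nrow(bs) > 1L) {
    # Z'Z must have no entries linking levels of different blocks
    block_of <- rep.int(seq_len(nrow(bs)), bs$end - bs$start + 1L)
    G <- methods::as(methods::as(ZtZ, "generalMatrix"), "TsparseMatrix")
    use_blocks <- !any(block_of[G@i + 1L] != block_of[G@j + 1L])
  }
  if (use_blocks) {
    parts <- lapply(seq_len(nrow(bs)), function(b) {
      idx <- bs$start[b]:bs$end[b]
      prep_block(as.matrix(V$matrix[idx, idx, drop = FALSE]),
                 as.matrix(ZtZ[idx, idx, drop = FALSE]))
    })
    Tmat <- Matrix::bdiag(lapply(parts, `[[`, "T"))
    theta <- unlist(lapply(parts, `[[`, "theta"), use.names = FALSE)
  } else {
    p <- prep_block(as.matrix(V$matrix), as.matrix(ZtZ))
    Tmat <- p$T
    theta <- p$theta
  }
  ones <- rep(1, nrow(Z))
  list(T = Tmat, theta = theta, q = q, n = nrow(Z),
       Zt1 = as.vector(Matrix::crossprod(Z, ones)),
       b_tilde = as.vector(Matrix::crossprod(Tmat, Matrix::crossprod(Z, ones))),
       ridge_applied = ridge_applied)
}

# Solve the MME at given variances using the spectral preparation.
# Returns the scalar summaries the EM updates and REML log-likelihood need,
# plus the solution in the transformed basis (x = T x_tilde).
.mme_solve_at <- function(pre, stats_y, sigma2_x, sigma2_e) {
  lambda <- sigma2_e / sigma2_x
  w <- 1 / (pre$theta + lambda)
  bt <- pre$b_tilde
  ct <- stats_y$c_tilde
  zWz <- sum(bt^2 * w)
  s <- pre$n - zWz
  mu <- (stats_y$sum_y - sum(bt * ct * w)) / s
  x_tilde <- w * (ct - bt * mu)
  quad <- stats_y$yy - mu * stats_y$sum_y - sum(x_tilde * ct)
  list(lambda = lambda, w = w, s = s, mu = mu, x_tilde = x_tilde,
       xVx = sum(x_tilde^2),                      # x' V^-1 x
       tr_VC = sum(w) + sum(w^2 * bt^2) / s,       # tr(V^-1 Cxx), scaled MME
       quad = quad)                               # y'y - mu 1'y - x'Z'y
}

.y_stats <- function(pre, Z, y) {
  list(sum_y = sum(y), yy = sum(y^2),
       c_tilde = as.vector(Matrix::crossprod(pre$T, Matrix::crossprod(Z, y))))
}

# REML log-likelihood from MME scalar summaries (identity form); agrees with
# the dense marginal-covariance evaluation in reml_loglik().
.reml_loglik_mme <- function(pre, sol, sigma2_x, sigma2_e) {
  n <- pre$n
  q <- pre$q
  -0.5 * ((n - q - 1) * log(sigma2_e) + q * log(sigma2_x) +
            sum(log(pre$theta + sol$lambda)) + log(sol$s) +
            sol$quad / sigma2_e) - ((n - 1) / 2) * log(2 * pi)
}

#' Estimate variance components by EM-REML
#'
#' Iterates the expectation-maximization REML updates for the single
#' random-effect model `y = mu + Z x + e`, `x ~ N(0, V sigma2_x)`,
#' `e ~ N(0, I sigma2_e)`: at the current variances the mixed model
#' equations are solved, then
#' `sigma2_x <- (x' V^-1 x + sigma2_e tr(V^-1 Cxx)) / q` and
#' `sigma2_e <- (y'y - mu 1'y - x' Z'y) / (n - 1)`,
#' with `Cxx` the random-effect block of the inverse of the
#' lambda-scaled MME coefficient matrix. Iteration stops when the maximum
#' relative change of both components falls below `rel_tol`.
#'
#' @param y an [expression_vector()] (or named numeric) aligned with the
#'   rows of `Z`.
#' @param Z an [incidence_map()][build_incidence] whose levels match
#'   `V$labels` (same order).
#' @param V a [cov_spec()]; pass Jaccard term matrices through
#'   [ensure_psd()] first.
#' @param max_iter maximum EM iterations (default 5000).
#' @param rel_tol relative convergence tolerance on both components
#'   (default 1e-8).
#' @param start optional numeric of length 2 `(sigma2_x, sigma2_e)`;
#'   defaults to half the sample variance of `y` each.
#' @param ridge diagonal ridge for near-singular `V` blocks (default 1e-8,
#'   applied only when a block's condition number exceeds 1e12).
#' @return object of class `variance_estimates`: `sigma2_x`, `sigma2_e`,
#'   `n_iter`, `converged`, `loglik_trace` (REML log-likelihood after each
#'   update), `ridge_applied`.
#' @export
em_reml <- function(y, Z, V, max_iter = 5000L, rel_tol = 1e-8,
                    start = NULL, ridge = 1e-8) {
  stopifnot(inherits(Z, "incidence_map"), inherits(V, "cov_spec"))
  yv <- as.numeric(y)
  n <- length(yv)
  if (n < 2L) stop("em_reml: need at least 2 observations")
  if (n != nrow(Z$Z)) stop("em_reml: y and Z are not conformable")
  if (!identical(Z$levels, V$labels))
    stop("em_reml: incidence levels and covariance labels differ")
  s2y <- stats::var(yv)
  if (s2y < 1e-300) {
    return(structure(list(sigma2_x = 0, sigma2_e = 0, n_iter = 0L,
                          converged = TRUE, loglik_trace = numeric(0),
                          ridge_applied = FALSE),
                     class = "variance_estimates"))
  }
  pre <- .mme_precompute(Z$Z, V, ridge = ridge)
  sy <- .y_stats(pre, Z$Z, yv)
  if (is.null(start)) start <- c(s2y / 2, s2y / 2)
  stopifnot(length(start) == 2L, all(start > 0))
  s2x <- start[1]
  s2e <- start[2]
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  floor_x <- s2y * 1e-12
  while (it < max_iter) {
    it <- it + 1L
    sol <- .mme_solve_at(pre, sy, s2x, s2e)
    s2x_new <- (sol$xVx + s2e * sol$tr_VC) / pre$q
    s2e_new <- sol$quad / (n - 1)
    if (!is.finite(s2x_new) || !is.finite(s2e_new) || s2e_new <= 0)
      stop("em_reml: update produced a non-finite or non-positive variance")
    delta <- max(abs(s2x_new - s2x) / max(s2x, floor_x),
                 abs(s2e_new - s2e) / s2e)
    s2x <- s2x_new
    s2e <- s2e_new
    trace <- c(trace, .reml_loglik_mme(pre, .mme_solve_at(pre, sy, s2x, s2e),
                                       s2x, s2e))
    if (delta < rel_tol) {
      converged <- TRUE
      break
    }
    if (s2x < floor_x) {
      # boundary: the random-effect variance is collapsing to zero
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("em_reml: not converged after ", max_iter, " iterations")
  structure(list(sigma2_x = s2x, sigma2_e = s2e, n_iter = it,
                 converged = converged, loglik_trace = trace,
                 ridge_applied = pre$ridge_applied),
            class = "variance_estimates")
}

#' @exportS3Method base::print
print.variance_estimates <- function(x, ...) {
  cat(sprintf(
    "variance_estimates: sigma2_x = %.6g, sigma2_e = %.6g (%d iter, %s)\n",
    x$sigma2_x, x$sigma2_e, x$n_iter,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' REML log-likelihood of the single random-effect model
#'
#' Dense evaluation through the marginal covariance
#' `Vy = Z V Z' sigma2_x + I sigma2_e`; intended for small instances and as
#' an independent check on [em_reml()]'s internal trace.
#'
#' @inheritParams em_reml
#' @param sigma2_x,sigma2_e variance components (`sigma2_e > 0`,
#'   `sigma2_x >= 0`).
#' @return REML log-likelihood (scalar), including the `-((n-1)/2) log 2 pi`
#'   constant.
#' @export
reml_loglik <- function(y, Z, V, sigma2_x, sigma2_e) {
  stopifnot(sigma2_e > 0, sigma2_x >= 0)
  yv <- as.numeric(y)
  n <- length(yv)
  Zm <- as.matrix(Z$Z)
  Vm <- as.matrix(V$matrix)
  Vy <- sigma2_x * (Zm %*% Vm %*% t(Zm)) + diag(sigma2_e, n)
  ch <- chol(Vy)
  ones <- rep(1, n)
  a1 <- backsolve(ch, forwardsolve(t(ch), ones))
  ay <- backsolve(ch, forwardsolve(t(ch), yv))
  xvx <- sum(ones * a1)
  mu <- sum(ones * ay) / xvx
  r <- yv - mu
  ar <- backsolve(ch, forwardsolve(t(ch), r))
  ll <- -0.5 * (2 * sum(log(diag(ch))) + log(xvx) + sum(r * ar)) -
    ((n - 1) / 2) * log(2 * pi)
  if (!is.finite(ll)) stop("reml_loglik: non-finite log-likelihood")
  ll
}

#' Solve the mixed model equations for effect solutions
#'
#' Solves Henderson's block system at the supplied variance estimates for
#' the intercept `mu` and the random-effect solutions (BLUPs), and returns
#' the per-level prediction-error variance from the diagonal of the inverse
#' coefficient matrix. Block-diagonal structure in `V` is exploited when
#' present and when `Z'Z` is conformable with the blocks; the result is
#' algebraically identical to the dense solve.
#'
#' @inheritParams em_reml
#' @param est a [em_reml()] result (or list with positive `sigma2_x`,
#'   `sigma2_e`).
#' @return object of class `effect_results`: `mu_hat`, `labels`, `blup`,
#'   `z`, `p` (filled by [standardize_and_test()]), `pev`.
#' @export
solve_mme <- function(y, Z, V, est, ridge = 1e-8) {
  stopifnot(inherits(Z, "incidence_map"), inherits(V, "cov_spec"))
  if (!(est$sigma2_x > 0)) stop("solve_mme: sigma2_x must be > 0")
  if (!(est$sigma2_e > 0)) stop("solve_mme: sigma2_e must be > 0")
  yv <- as.numeric(y)
  if (length(yv) != nrow(Z$Z)) stop("solve_mme: y and Z are not conformable")
  if (!identical(Z$levels, V$labels))
    stop("solve_mme: incidence levels and covariance labels differ")
  pre <- .mme_precompute(Z$Z, V, ridge = ridge)
  sy <- .y_stats(pre, Z$Z, yv)
  sol <- .mme_solve_at(pre, sy, est$sigma2_x, est$sigma2_e)
  blup <- as.vector(pre$T %*% sol$x_tilde)
  # PEV_k = sigma2_e * (C^-1)_kk = sigma2_e * [diag(T w T') + (T(w b))_k^2 / s]
  Tsq <- pre$T * pre$T
  diag_W <- as.vector(Tsq %*% sol$w)
  u <- as.vector(pre$T %*% (sol$w * pre$b_tilde))
  pev <- est$sigma2_e * (diag_W + u^2 / sol$s)
  structure(list(mu_hat = sol$mu, labels = V$labels, blup = blup,
                 z = rep(NA_real_, length(blup)),
                 p = rep(NA_real_, length(blup)), pev = pev),
            class = "effect_results")
}

#' @exportS3Method base::print
print.effect_results <- function(x, ...) {
  cat(sprintf("effect_results: mu_hat = %.6g, %d levels\n",
              x$mu_hat, length(x$labels)))
  if (!anyNA(x$z)) {
    top <- order(x$p)[seq_len(min(5L, length(x$p)))]
    print(as.data.frame(x)[top, ], row.names = FALSE)
  }
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.effect_results <- function(x, ...) {
  data.frame(level_id = x$labels, effect = x$blup, z = x$z, p = x$p,
             pev = x$pev, stringsAsFactors = FALSE)
}

#' Standardize effect solutions and test against the standard normal
#'
#' Each solution element is transformed to a z-score with the empirical mean
#' and standard deviation of the solution vector of that model,
#' `z_k = (x_k - mean(x)) / sd(x)`, and tested two-sided against N(0, 1):
#' `p_k = 2 (1 - Phi(|z_k|))`. Because a single common SD is used, the ratio
#' effect/z is constant across levels of one fit.
#'
#' @param res an [solve_mme()] result.
#' @return the same `effect_results` with `z` and `p` filled in, plus a
#'   `rank` component (1 = smallest p).
#' @export
standardize_and_test <- function(res) {
  stopifnot(inherits(res, "effect_results"))
  if (length(res$blup) < 2L) stop("standardize_and_test: need >= 2 levels")
  s <- stats::sd(res$blup)
  if (s == 0) stop("standardize_and_test: zero spread among solutions")
  res$z <- (res$blup - mean(res$blup)) / s
  res$p <- 2 * stats::pnorm(abs(res$z), lower.tail = FALSE)
  res$p[res$p == 0] <- .Machine$double.xmin   # keep p in (0, 1]
  res$rank <- rank(res$p, ties.method = "first")
  res
}

#' Random-effect variance as a percentage of the total variance of y
#'
#' Reported as `100 * sigma2_x / s2_y`, where `s2_y` is the unbiased sample
#' variance of the response. An alternative denominator
#' `sigma2_x + sigma2_e` is available via `denominator`.
#'
#' @param est a [em_reml()] result.
#' @param y the fitted [expression_vector()].
#' @param denominator `"sample_variance"` (default) or `"component_sum"`.
#' @return percentage (numeric scalar).
#' @export
variance_proportions <- function(est, y,
                                 denominator = c("sample_variance",
                                                 "component_sum")) {
  denominator <- match.arg(denominator)
  yv <- as.numeric(y)
  if (length(yv) < 2L) stop("variance_proportions: need >= 2 observations")
  den <- switch(denominator,
                sample_variance = stats::var(yv),
                component_sum = est$sigma2_x + est$sigma2_e)
  if (den == 0) stop("variance_proportions: zero total variance")
  100 * est$sigma2_x / den
}

#' Fit one similarity-aware mixed model end to end
#'
#' Orchestrates [build_incidence()] -> [em_reml()] -> [solve_mme()] ->
#' [standardize_and_test()]. The covariance spec is aligned with (and if
#' necessary subset to) the levels actually present in the incidence map;
#' deterministic given inputs and options.
#'
#' @inheritParams em_reml
#' @param mapping a [term_mapping()] assigning transcripts to levels, or
#'   `NULL` for the transcript-based model (every observation its own level).
#' @param weighted passed to [build_incidence()].
#' @param ... further options passed to [em_reml()] (`max_iter`, `rel_tol`,
#'   `start`, `ridge`).
#' @return list with `estimates` ([em_reml()] result), `effects`
#'   (standardized [solve_mme()] result), `incidence`, `pct_of_total`
#'   ([variance_proportions()]), and `y_used` (observations retained).
#' @export
fit_model <- function(y, mapping = NULL, V, weighted = FALSE, ...) {
  stopifnot(inherits(V, "cov_spec"))
  Z <- build_incidence(y, mapping, weighted = weighted)
  yv <- as.numeric(y)[match(Z$observations, names(y))]
  missing_lv <- setdiff(Z$levels, V$labels)
  if (length(missing_lv) > 0L)
    stop("fit_model: levels absent from covariance: ",
         paste(missing_lv[1:min(3, length(missing_lv))], collapse = ", "))
  if (length(V$labels) > length(Z$levels)) {
    message("fit_model: dropping ", length(V$labels) - length(Z$levels),
            " unused covariance level(s)")
    V <- subset_cov_spec(V, Z$levels)
  }
  # reorder incidence columns to covariance label order
  ord <- match(V$labels, Z$levels)
  Z$Z <- Z$Z[, ord, drop = FALSE]
  Z$levels <- V$labels
  est <- em_reml(yv, Z, V, ...)
  if (est$sigma2_x <= 0 || est$sigma2_e <= 0)
    stop("fit_model: degenerate variance estimates; cannot solve the MME")
  eff <- standardize_and_test(solve_mme(yv, Z, V, est))
  list(estimates = est, effects = eff, incidence = Z,
       pct_of_total = variance_proportions(est, yv),
       y_used = stats::setNames(yv, Z$observations))
}
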