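# Polygenic variance-components engine.
#
# Model: y = X beta + g + e with Var(g) = sigma2_a * K, Var(e) = sigma2_e * I,
# K the additive relationship matrix 2*Phi. Estimation profiles the total
# variance out and searches the heritability ratio h = sigma2_a / (sigma2_a +
# sigma2_e) on [0, 1). A one-off spectral rotation by the eigenvectors of K
# diagonalizes the covariance, so each likelihood evaluation is O(n p^2).

#' Eigendecomposition of a relationship matrix, reusable across fits
#'
#' Screening loops fit thousands of models against the same kinship
#' structure; precomputing the (expensive) symmetric eigendecomposition once
#' and passing it via the `eig` argument amortizes it.
#'
#' @param K symmetric PSD relationship matrix (2*Phi).
#' @return list with eigenvalues `d`, eigenvectors `U`, and `n`.
#' @export
relationship_eigen <- function(K) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8) stopf("K must be symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    stopf("K is not positive semidefinite (min eigenvalue %.3g)",
          min(e$values))
  }
  list(d = pmax(e$values, 0), U = e$vectors, n = nrow(K))
}

# Profile log-likelihood (REML or ML) at heritability ratio h, on rotated
# data. Returns the loglik and, on request, the GLS solution at h.
vc_profile <- function(h, ys, Xs, d, reml = TRUE, details = FALSE) {
  n <- length(ys)
  p <- ncol(Xs)
  v <- h * d + (1 - h)
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  XtWy <- crossprod(Xs, ys * w)
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta)) return(if (details) NULL else -Inf)
  r <- ys - Xs %*% beta
  rss <- sum(w * r^2)
  if (rss <= 0) return(if (details) NULL else -Inf)
  if (reml) {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(v)) +
                    determinant(XtWX, logarithm = TRUE)$modulus[1])
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi * s2) + 1) + sum(log(v)))
  }
  if (!details) return(as.numeric(ll))
  cov_beta <- s2 * solve(XtWX)
  list(loglik = as.numeric(ll), beta = drop(beta),
       se_beta = sqrt(diag(cov_beta)), cov_beta = cov_beta, s2 = s2)
}

#' Fit a polygenic variance-components model
#'
#' Maximizes the (restricted) likelihood over the heritability ratio by
#' Brent search on [0, 1), with the profile evaluated through the spectral
#' rotation of `K`. Fixed effects come from GLS at the optimum; the
#' standard error of h^2 is a delta-method value from the numerically
#' observed information of the profile likelihood (reported `NA` at the
#' boundary, where the information matrix is degenerate).
#'
#' @param y numeric trait vector (a binary trait is analyzed as 0/1 on the
#'   observed scale).
#' @param X fixed-effects design matrix including the intercept; default
#'   intercept only. Must be full column rank.
#' @param K additive relationship matrix (2*Phi), aligned with `y`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param eig optional [relationship_eigen()] of `K`.
#' @param h2_fixed if non-NULL, skip optimization and evaluate at this
#'   heritability ratio (e.g. 0 for the no-polygenic-variance null).
#' @param tol Brent tolerance on h^2 (default 1e-8).
#' @return object of class `"varcomp_fit"`: `sigma2_a`, `sigma2_e`, `h2`,
#'   `se_h2`, `beta`, `se_beta`, `loglik`, `converged`, `n_iter`, `method`,
#'   `n`, `p`.
#' @export
fit_polygenic <- function(y, X = NULL, K, method = c("REML", "ML"),
                          eig = NULL, h2_fixed = NULL, tol = 1e-8) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (nrow(X) != n) stopf("y and X row counts differ")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]] %||% "?"
    stopf("X is rank deficient; collinear column(s): %s",
          paste(drop_cols, collapse = ", "))
  }
  if (n < 2L * ncol(X)) stopf("need n >= 2 * rank(X)")
  if (is.null(eig)) eig <- relationship_eigen(K)
  if (eig$n != n) stopf("K dimension does not match y")
  d <- eig$d
  if (max(d) - min(d) < 1e-8 * max(1, max(d))) {
    stopf("K is proportional to the identity; h2 is not identifiable")
  }
  ys <- drop(crossprod(eig$U, y))
  Xs <- crossprod(eig$U, X)
  reml <- method == "REML"

  hmax <- 1 - 1e-6
  n_eval <- 0L
  f <- function(h) {
    n_eval <<- n_eval + 1L
    vc_profile(h, ys, Xs, d, reml = reml)
  }
  if (!is.null(h2_fixed)) {
    h_hat <- min(max(h2_fixed, 0), hmax)
    converged <- TRUE
  } else {
    opt <- stats::optimize(f, interval = c(0, hmax), maximum = TRUE,
                           tol = tol)
    cand <- c(0, opt$maximum, hmax)
    lls <- vapply(cand, f, numeric(1))
    h_hat <- cand[which.max(lls)]
    converged <- is.finite(max(lls))
  }
  det <- vc_profile(h_hat, ys, Xs, d, reml = reml, details = TRUE)
  if (is.null(det) || !is.finite(det$loglik)) {
    converged <- FALSE
    det <- list(loglik = NA_real_, beta = rep(NA_real_, ncol(X)),
                se_beta = rep(NA_real_, ncol(X)), s2 = NA_real_)
  }
  s2p <- det$s2
  se_h2 <- NA_real_
  if (converged && is.null(h2_fixed) && h_hat > 1e-5 && h_hat < hmax - 1e-5) {
    step <- min(1e-3, h_hat / 2, (hmax - h_hat) / 2)
    d2 <- (f(h_hat + step) - 2 * det$loglik + f(h_hat - step)) / step^2
    if (is.finite(d2) && d2 < 0) se_h2 <- sqrt(-1 / d2)
  }
  beta <- det$beta
  names(beta) <- colnames(X)
  fit <- list(sigma2_a = h_hat * s2p, sigma2_e = (1 - h_hat) * s2p,
              h2 = h_hat, se_h2 = se_h2, beta = beta,
              se_beta = stats::setNames(det$se_beta, colnames(X)),
              loglik = det$loglik, converged = converged, n_iter = n_eval,
              method = method, n = n, p = ncol(X))
  class(fit) <- "varcomp_fit"
  fit
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat(sprintf("polygenic %s fit: h2 = %.3f (SE %s), loglik = %.3f [%s]\n",
              x$method, x$h2,
              if (is.na(x$se_h2)) "NA" else sprintf("%.3f", x$se_h2),
              x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Raw (unrotated) polygenic log-likelihood at given variance components
#'
#' Evaluates the exact multivariate-normal (restricted) log-likelihood
#' through a Cholesky factorization of `V = sigma2_a K + sigma2_e I`,
#' without the spectral shortcut used by [fit_polygenic()]. Used as an
#' independent numerical route in verification, and to demonstrate the
#' per-family additivity of the likelihood for block-diagonal designs.
#'
#' @param y,X,K as in [fit_polygenic()].
#' @param sigma2_a,sigma2_e non-negative variance components (not both 0).
#' @param reml restricted likelihood when TRUE.
#' @return scalar log-likelihood.
#' @export
polygenic_loglik <- function(y, X, K, sigma2_a, sigma2_e, reml = TRUE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  V <- sigma2_a * K + diag(sigma2_e, n)
  cv <- chol(V)
  Vi_y <- backsolve(cv, forwardsolve(t(cv), y))
  Vi_X <- backsolve(cv, forwardsolve(t(cv), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(cv, forwardsolve(t(cv), r))
  quad <- sum(r * Vi_r)
  logdetV <- 2 * sum(log(diag(cv)))
  if (reml) {
    -0.5 * ((n - p) * log(2 * pi) + logdetV +
              determinant(XtViX, logarithm = TRUE)$modulus[1] + quad)
  } else {
    -0.5 * (n * log(2 * pi) + logdetV + quad)
  }
}

#' Likelihood-ratio test for heritability
#'
#' Compares a full REML polygenic fit against the no-polygenic-variance
#' null (`h2_fixed = 0`). Because the null pins sigma2_a at the boundary of
#' its parameter space, the statistic is referred to the boundary mixture
#' 0.5*chi2_0 + 0.5*chi2_1: p = 0.5 * P(chi2_1 >= Lambda), which equals 0.5
#' at Lambda = 0.
#'
#' @param fit_full,fit_null [fit_polygenic()] results on the same data; the
#'   null fitted with `h2_fixed = 0`.
#' @return list with `lambda`, `p`.
#' @export
lrt_heritability <- function(fit_full, fit_null) {
  stopifnot(inherits(fit_full, "varcomp_fit"),
            inherits(fit_null, "varcomp_fit"))
  if (fit_full$n != fit_null$n || fit_full$p != fit_null$p ||
      fit_full$method != fit_null$method) {
    stopf("full and null fits must share data, design and method")
  }
  lambda <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  list(lambda = lambda,
       p = 0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE))
}

#' Test a covariate within the polygenic model
#'
#' Adds `covariate` (a vector, or a matrix for a joint multi-column test)
#' to the fixed effects and compares maximum-likelihood fits with and
#' without it by a chi-squared likelihood-ratio test with df = number of
#' added columns (REML likelihoods are not comparable across fixed-effect
#' designs, hence ML here). A Wald p-value from the full fit is also
#' reported. Heritability with/without the covariate is estimated by REML
#' when `compute_h2` is TRUE.
#'
#' @param y trait vector.
#' @param X base fixed-effects design (with intercept).
#' @param covariate numeric vector or matrix to be tested.
#' @param K relationship matrix 2*Phi.
#' @param eig optional [relationship_eigen()] of `K`.
#' @param compute_h2 also run the two REML fits for h2 bookkeeping.
#' @return list: `beta`, `se`, `p` (LRT), `p_wald`, `df`, `lambda`,
#'   `h2_with`, `h2_without`, `converged`.
#' @export
covariate_test <- function(y, X, covariate, K, eig = NULL,
                           compute_h2 = TRUE) {
  C <- as.matrix(covariate)
  if (is.null(colnames(C))) {
    colnames(C) <- paste0("cov", seq_len(ncol(C)))
  }
  if (any(apply(C, 2, stats::sd) == 0)) {
    stopf("covariate is constant")
  }
  XC <- cbind(X, C)
  if (qr(XC)$rank < ncol(XC)) {
    stopf("covariate is collinear with the base design")
  }
  if (is.null(eig)) eig <- relationship_eigen(K)
  fit0 <- fit_polygenic(y, X, K, method = "ML", eig = eig)
  fit1 <- fit_polygenic(y, XC, K, method = "ML", eig = eig)
  q <- ncol(C)
  lambda <- max(0, 2 * (fit1$loglik - fit0$loglik))
  p_lrt <- stats::pchisq(lambda, df = q, lower.tail = FALSE)
  idx <- ncol(X) + seq_len(q)
  bc <- fit1$beta[idx]
  sec <- fit1$se_beta[idx]
  p_wald <- if (q == 1L) {
    2 * stats::pnorm(-abs(bc / sec))
  } else {
    stats::pchisq(sum((bc / sec)^2), df = q, lower.tail = FALSE)
  }
  h2_with <- h2_without <- NA_real_
  conv <- fit0$converged && fit1$converged
  if (compute_h2) {
    r0 <- fit_polygenic(y, X, K, method = "REML", eig = eig)
    r1 <- fit_polygenic(y, XC, K, method = "REML", eig = eig)
    h2_without <- r0$h2
    h2_with <- r1$h2
    conv <- conv && r0$converged && r1$converged
  }
  list(beta = bc, se = sec, p = p_lrt, p_wald = p_wald, df = q,
       lambda = lambda, h2_with = h2_with, h2_without = h2_without,
       converged = conv)
}

#' Export variance-component fits as a one-row-per-model table
#'
#' @param fits named list of [fit_polygenic()] results (names = model
#'   labels, e.g. covariate sets).
#' @param trait trait label recycled across rows.
#' @return data frame: trait, model, h2, se_h2, loglik, converged.
#' @export
varcomp_table <- function(fits, trait = "trait") {
  data.frame(trait = trait, model = names(fits),
             h2 = vapply(fits, function(f) f$h2, numeric(1)),
             se_h2 = vapply(fits, function(f) f$se_h2, numeric(1)),
             loglik = vapply(fits, function(f) f$loglik, numeric(1)),
             converged = vapply(fits, function(f) f$converged, logical(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
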