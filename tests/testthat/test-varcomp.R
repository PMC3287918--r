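# Small instances with analytically awkward but numerically checkable
# structure: the REML engine's spectral-rotation path is verified against
# the raw-likelihood route of polygenic_loglik().

make_instance <- function(seed, n_target = 24, h2 = 0.5, p_cov = 1) {
  ped <- random_pedigree(target = n_target, seed = seed)
  K <- 2 * kinship_matrix(ped)
  set.seed(seed * 13)
  n <- nrow(K)
  L <- chol(K)
  X <- cbind(intercept = 1,
             matrix(rnorm(n * p_cov), n,
                    dimnames = list(NULL, paste0("x", seq_len(p_cov)))))
  y <- drop(X %*% runif(ncol(X), -1, 1)) +
    sqrt(h2) * drop(crossprod(L, rnorm(n))) +
    rnorm(n, sd = sqrt(1 - h2))
  list(y = y, X = X, K = K)
}

test_that("REML estimates agree with a raw-likelihood brute-force oracle", {
  for (seed in c(2, 5, 9)) {
    inst <- make_instance(seed)
    fit <- fit_polygenic(inst$y, inst$X, inst$K)
    # oracle: profile the raw (unrotated, Cholesky-based) REML likelihood
    # over h2 at unit total variance scale, maximizing the scale
    # analytically via a nested 1-D search
    raw_profile <- function(h) {
      stats::optimize(function(s2) {
        polygenic_loglik(inst$y, inst$X, inst$K, s2 * h, s2 * (1 - h))
      }, interval = c(1e-4, 20), maximum = TRUE, tol = 1e-12)$objective
    }
    opt <- stats::optimize(raw_profile, c(0, 1 - 1e-6), maximum = TRUE,
                           tol = 1e-10)
    cand_h <- c(0, opt$maximum)
    oracle_h <- cand_h[which.max(vapply(cand_h, raw_profile, numeric(1)))]
    expect_equal(fit$h2, oracle_h, tolerance = 1e-5)
    expect_equal(fit$loglik, raw_profile(oracle_h), tolerance = 1e-6)
    # and the fitted variances reproduce the raw likelihood value exactly
    expect_equal(fit$loglik,
                 polygenic_loglik(inst$y, inst$X, inst$K, fit$sigma2_a,
                                  fit$sigma2_e),
                 tolerance = 1e-8)
  }
})

test_that("REML loglik is invariant to translation by fixed-effect columns", {
  inst <- make_instance(4)
  f1 <- fit_polygenic(inst$y, inst$X, inst$K)
  f2 <- fit_polygenic(inst$y + 5 * inst$X[, 1], inst$X, inst$K)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
  expect_equal(f1$sigma2_a, f2$sigma2_a, tolerance = 1e-6)
})

test_that("likelihood is additive over families for block designs", {
  st <- small_study()
  ped <- st$pedigree
  K <- 2 * st$kinship
  phen <- st$phenotypes[match(ped$iid, st$phenotypes$IID), ]
  y <- phen$Q1
  fams <- unique(ped$fid)
  # family-specific intercepts make the whole design block-diagonal
  X <- sapply(fams, function(f) as.numeric(ped$fid == f))
  ll_joint <- polygenic_loglik(y, X, K, sigma2_a = 0.5, sigma2_e = 0.7)
  ll_fam <- sum(vapply(fams, function(f) {
    i <- ped$fid == f
    polygenic_loglik(y[i], matrix(1, sum(i), 1), K[i, i], 0.5, 0.7)
  }, numeric(1)))
  expect_equal(ll_joint, ll_fam, tolerance = 1e-8)
})

test_that("identifiability and design-rank errors are raised", {
  inst <- make_instance(3)
  n <- length(inst$y)
  expect_error(fit_polygenic(inst$y, inst$X, diag(n)), "identity")
  Xbad <- cbind(inst$X, dup = inst$X[, 2])
  expect_error(fit_polygenic(inst$y, Xbad, inst$K), "collinear")
  expect_error(covariate_test(inst$y, inst$X, rep(1, n), inst$K),
               "constant")
  expect_error(covariate_test(inst$y, inst$X, inst$X[, 2], inst$K),
               "collinear")
})

test_that("boundary LRT gives p = 0.5 at zero statistic and detects real h2", {
  inst <- make_instance(6, n_target = 30, h2 = 0)
  # identical fits -> lambda 0 -> boundary mixture p = 1/2
  f <- fit_polygenic(inst$y, inst$X, inst$K)
  expect_equal(lrt_heritability(f, f)$p, 0.5)

  st <- med_study()
  phen <- st$phenotypes[match(st$pedigree$iid, st$phenotypes$IID), ]
  K <- 2 * st$kinship
  eig <- relationship_eigen(K)
  full <- fit_polygenic(phen$Q4, K = K, eig = eig)
  null <- fit_polygenic(phen$Q4, K = K, eig = eig, h2_fixed = 0)
  lrt <- lrt_heritability(full, null)
  expect_gte(lrt$lambda, 0)
  expect_lt(lrt$p, 0.01)  # h2 = 0.6 at n ~ 280 is easily detected
  expect_error(lrt_heritability(full, fit_polygenic(phen$Q4[-1],
                                                    K = K[-1, -1])),
               "share")
})

test_that("permuting the trait destroys heritability", {
  st <- med_study()
  phen <- st$phenotypes[match(st$pedigree$iid, st$phenotypes$IID), ]
  K <- 2 * st$kinship
  eig <- relationship_eigen(K)
  orig <- fit_polygenic(phen$Q4, K = K, eig = eig)$h2
  set.seed(8)
  perm <- vapply(1:5, function(i) {
    fit_polygenic(sample(phen$Q4), K = K, eig = eig)$h2
  }, numeric(1))
  expect_gt(orig, max(perm))
  expect_lt(mean(perm), 0.15)
})

test_that("covariate_test finds a self-covariate and reports sane output", {
  inst <- make_instance(12, n_target = 30)
  ct <- covariate_test(inst$y, inst$X[, 1, drop = FALSE],
                       inst$y, inst$K)
  expect_lt(ct$p, 1e-6)
  set.seed(2)
  z <- rnorm(length(inst$y))
  ct2 <- covariate_test(inst$y, inst$X, z, inst$K)
  expect_true(ct2$p >= 0 && ct2$p <= 1)
  expect_equal(ct2$df, 1L)
  expect_true(is.finite(ct2$h2_with) && is.finite(ct2$h2_without))
  # Wald and LRT agree to first order
  expect_lt(abs(ct2$p - ct2$p_wald), 0.1)
})

test_that("fit table export has the one-row-per-model layout", {
  st <- small_study()
  phen <- st$phenotypes[match(st$pedigree$iid, st$phenotypes$IID), ]
  K <- 2 * st$kinship
  eig <- relationship_eigen(K)
  fits <- list(
    none = fit_polygenic(phen$Affected, K = K, eig = eig),
    age_q4 = fit_polygenic(phen$Affected,
                           cbind(1, phen$Age, phen$Q4), K, eig = eig))
  tab <- varcomp_table(fits, trait = "Affected")
  expect_equal(dim(tab), c(2L, 6L))
  expect_equal(tab$model, c("none", "age_q4"))
  expect_true(all(tab$h2 >= 0 & tab$h2 <= 1))
})
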