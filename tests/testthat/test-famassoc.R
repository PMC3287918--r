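test_that("orthogonal decomposition follows the expected-genotype rules", {
  ped <- pedigree("A", c("f", "m", "c1", "c2", "solo"),
                  c(NA, NA, "f", "f", NA), c(NA, NA, "m", "m", NA),
                  c(1, 2, 1, 2, 1))
  G <- rbind(f = c(1L, 0L), m = c(1L, 2L), c1 = c(2L, 1L),
             c2 = c(1L, 1L), solo = c(2L, 0L))
  colnames(G) <- c("v1", "v2")
  d <- orthogonal_decompose(ped, G)
  expect_equal(d$b["c1", "v1"], 1)    # parental mean (1+1)/2
  expect_equal(d$w["c1", "v1"], 1)    # g - b = 2 - 1
  expect_equal(d$w["c2", "v2"], 0)    # g equals parental mean (0+2)/2
  # isolated founder: b = g, w = 0 (between-family information only)
  expect_equal(d$b["solo", "v1"], 2)
  expect_equal(d$w["solo", "v1"], 0)
  # conservation b + w = g everywhere (rows come back in pedigree order)
  Gord <- G[rownames(d$b), ]
  expect_equal(d$b + d$w,
               matrix(as.numeric(Gord), nrow(G), dimnames = dimnames(Gord)))

  # untyped parents -> sibship mean
  G2 <- G; G2["f", "v1"] <- NA; G2["m", "v1"] <- NA
  d2 <- orthogonal_decompose(ped, G2)
  expect_equal(d2$b["c1", "v1"], 1.5)  # mean of sibs c1, c2
  expect_equal(d2$w["c1", "v1"], 0.5)
})

test_that("decomposition conserves genotypes on simulated studies", {
  st <- small_study()
  sub <- st$genotypes[, 1:50]
  d <- orthogonal_decompose(st$pedigree, sub)
  obs <- !is.na(sub)
  expect_equal((d$b + d$w)[obs],
               as.numeric(sub[st$pedigree$iid, ][obs]))
})

test_that("assoc_linear matches the ordinary least-squares oracle", {
  set.seed(21)
  n <- 20
  b <- rnorm(n); w <- rnorm(n); cov1 <- rnorm(n)
  y <- 0.3 * b + 0.5 * w + 0.2 * cov1 + rnorm(n)
  r <- assoc_linear(y, b, w, covariates = cbind(cov1))
  full <- lm(y ~ cov1 + b + w)
  red <- lm(y ~ cov1)
  an <- anova(red, full)
  expect_equal(r$beta_b, unname(coef(full)["b"]), tolerance = 1e-10)
  expect_equal(r$beta_w, unname(coef(full)["w"]), tolerance = 1e-10)
  expect_equal(r$p_total, an$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(r$p_within,
               summary(full)$coefficients["w", 4], tolerance = 1e-10)
  expect_equal(r$df, 2L)
})

test_that("within-family estimator ignores confounding through expected genotype", {
  # stratification acting through the between component (the canonical
  # family-confounding direction) leaves the within coefficient exactly
  # unchanged; an arbitrary per-family shift is immune only in
  # expectation, which the calibration test below measures
  st <- small_study()
  ped <- st$pedigree
  v <- st$variants$variant_id[st$variants$rarity == "common"][1]
  d <- orthogonal_decompose(ped, st$genotypes[, v, drop = FALSE])
  phen <- st$phenotypes[match(ped$iid, st$phenotypes$IID), ]
  y <- phen$Q1
  r1 <- assoc_linear(y, d$b[, v], d$w[, v])
  r2 <- assoc_linear(y + 3 + 2 * d$b[, v], d$b[, v], d$w[, v])
  expect_equal(r1$beta_w, r2$beta_w, tolerance = 1e-8)
  expect_equal(r2$beta_b, r1$beta_b + 2, tolerance = 1e-8)
})

test_that("within test stays calibrated under population stratification", {
  # two families with different trait means and different allele
  # frequencies, no genotype effect: the naive total test inflates, the
  # within-family test does not
  set.seed(33)
  n_fam <- 40L
  reps <- 500L
  p_tot <- p_win <- numeric(reps)
  for (r in seq_len(reps)) {
    g1 <- rbinom(n_fam, 2, 0.4)   # family 1 (children's genotypes)
    g2 <- rbinom(n_fam, 2, 0.1)   # family 2
    g <- c(g1, g2)
    b <- c(rep(mean(g1), n_fam), rep(mean(g2), n_fam))
    w <- g - b
    y <- c(rnorm(n_fam, mean = 1), rnorm(n_fam, mean = -1))
    naive <- summary(lm(y ~ g))$coefficients
    p_tot[r] <- naive["g", 4]
    fit <- summary(lm(y ~ b + w))$coefficients
    p_win[r] <- if ("w" %in% rownames(fit)) fit["w", 4] else NA
  }
  rate_naive <- mean(p_tot < 0.05)
  rate_within <- mean(p_win < 0.05, na.rm = TRUE)
  expect_gt(rate_naive, 0.2)                  # strong inflation
  expect_gt(rate_within, 0.02)
  expect_lt(rate_within, 0.09)                # ~ nominal 5%
})

test_that("variance-components association reduces to the linear test without polygenic variance", {
  st <- med_study()
  ped <- st$pedigree
  phen <- st$phenotypes[match(ped$iid, st$phenotypes$IID), ]
  K <- 2 * st$kinship
  eig <- relationship_eigen(K)
  set.seed(5)
  y <- rnorm(nrow(ped))  # no polygenic variance at all
  covs <- cbind(Age = phen$Age, Q4 = phen$Q4)
  vids <- st$variants$variant_id[st$variants$rarity == "common"][1:5]
  d <- orthogonal_decompose(ped, st$genotypes[, vids, drop = FALSE])
  for (v in vids) {
    rl <- assoc_linear(y, d$b[, v], d$w[, v], covariates = covs)
    rv <- assoc_varcomp(y, d$b[, v], d$w[, v], covariates = covs,
                        K = K, eig = eig, compute_h2 = TRUE)
    if (rv$status != "tested") next
    expect_equal(rv$beta_b, rl$beta_b, tolerance = 1e-4)
    expect_lt(rv$h2_with, 0.05)
    # chi-squared LRT vs exact F differ only by the asymptotic
    # approximation at this n
    expect_lt(abs(rv$p_total - rl$p_total), 0.01)
  }
})

test_that("monomorphic variants get NCV status in both association models", {
  y <- rnorm(10)
  z <- rep(0, 10)
  expect_equal(assoc_linear(y, z, z)$status, "NCV")
  expect_equal(assoc_varcomp(y, z, z, K = diag(10) + 0.1)$status, "NCV")
})

test_that("gene-based combiner matches its closed-form limits", {
  # k = 1: the gene p-value is the marker p-value
  g1 <- gene_based_p(0.1, n_sims = 4e4, seed = 2)
  se <- sqrt(0.1 * 0.9 / 4e4)
  expect_lt(abs(g1$p_gene - 0.1), 3 * se)

  # independent markers: chi-squared_k survival function of T_obs
  set.seed(4)
  p <- runif(5, 0.01, 0.9)
  gk <- gene_based_p(p, diag(5), n_sims = 4e4, seed = 3)
  p_exact <- pchisq(gk$t_obs, df = 5, lower.tail = FALSE)
  expect_lt(abs(gk$p_gene - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 4e4) + 1e-4)

  # perfect LD: duplicated markers behave as one
  sig <- matrix(1, 3, 3)
  gd <- gene_based_p(rep(0.05, 3), sig, n_sims = 4e4, seed = 5)
  g1b <- gene_based_p(0.05, n_sims = 4e4, seed = 5)
  expect_lt(abs(gd$p_gene - g1b$p_gene),
            3 * sqrt(0.05 * 0.95 / 4e4) + 1e-3)
})

test_that("gene-based combiner is monotone under common random numbers", {
  sig <- diag(4) * 0.5 + 0.5
  p0 <- c(0.5, 0.2, 0.8, 0.4)
  base <- gene_based_p(p0, sig, n_sims = 2e4, seed = 9)$p_gene
  for (j in 1:4) {
    p1 <- p0; p1[j] <- p0[j] / 4
    expect_lte(gene_based_p(p1, sig, n_sims = 2e4, seed = 9)$p_gene, base)
  }
})

test_that("combiner validates and repairs the correlation matrix", {
  expect_error(gene_based_p(c(0.5, 0), diag(2)), "0, 1")
  expect_error(gene_based_p(c(0.5, 0.5), matrix(c(2, 0, 0, 1), 2)),
               "diagonal")
  bad <- matrix(c(1, 1.2, 1.2, 1), 2)  # indefinite beyond tolerance
  expect_error(gene_based_p(c(0.5, 0.5), bad), "positive semidefinite")
  mild <- matrix(c(1, 1 + 1e-8, 1 + 1e-8, 1), 2)
  expect_warning(gene_based_p(c(0.5, 0.5), mild, n_sims = 100, seed = 1),
                 "repaired")
})

test_that("association screens produce per-variant rows and gene scores", {
  st <- small_study()
  det <- assoc_screen(st, "common", "linear")
  expect_equal(nrow(det),
               sum(st$variants$rarity == "common"))
  expect_true(all(det$approach == "E"))
  ok <- det$status == "tested"
  expect_true(all(det$p[ok] >= 0 & det$p[ok] <= 1))
  gs <- gene_scores(det[ok, ][1:10, ], st, n_sims = 2000, seed = 4)
  expect_true(all(gs$p_gene > 0 & gs$p_gene <= 1))
  expect_true(all(gs$k_markers >= 1))
})
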