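test_that("configuration validation catches impossible settings", {
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(rare_fraction = 1.2), "proportions")
  expect_error(sim_config(n_genes = 0), "counts")
  expect_error(sim_config(causal_genes = 50, n_genes = 10), "causal_genes")
  # 3 generations cannot fit in a max size of 3 (needs 2g - 1 = 5)
  expect_error(sim_config(n_generations = 3, family_size_range = c(1, 3)),
               "generations")
  expect_error(sim_config(variants_per_gene_range = c(4, 2)), "ranges")
})

test_that("smallest configuration yields a trio with correct pointers", {
  cfg <- sim_config(n_families = 1, family_size_range = c(3, 3),
                    n_generations = 2, children_range = c(1, 1),
                    n_genes = 2, variants_per_gene_range = c(1, 2),
                    causal_genes = 1, seed = 5)
  ped <- simulate_pedigrees(cfg)
  expect_equal(nrow(ped), 3L)
  kid <- ped[!ped$founder, ]
  expect_equal(nrow(kid), 1L)
  expect_equal(ped$sex[match(kid$father, ped$iid)], 1L)
  expect_equal(ped$sex[match(kid$mother, ped$iid)], 2L)
})

test_that("simulation is deterministic for a fixed config", {
  cfg <- small_cfg(seed = 31)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(small_cfg(seed = 32))
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("founder allele draws hit their nominal MAF within binomial error", {
  st <- med_study()
  founders <- st$pedigree$iid[st$pedigree$founder]
  nf <- length(founders)
  Gf <- st$genotypes[founders, , drop = FALSE]
  f_obs <- colMeans(Gf) / 2
  maf <- st$variants$maf
  z <- (f_obs - maf) / sqrt(maf * (1 - maf) / (2 * nf))
  # per-variant binomial z-scores: essentially all within 3 SE
  expect_gt(mean(abs(z) <= 3), 0.98)
  expect_lt(abs(mean(z)), 0.1)
})

test_that("gene-dropped genotypes are Mendelian-consistent and gene-mapped", {
  st <- small_study()
  expect_identical(nrow(validate_mendelian(st$pedigree, st$genotypes)), 0L)
  expect_true(all(table(st$variants$variant_id) == 1))
  expect_equal(colnames(st$genotypes), st$variants$variant_id)
  # columns with zero realized MAF are all-zero
  mono <- st$variants$variant_id[st$variants$maf_sample == 0]
  expect_true(all(st$genotypes[, mono] == 0))
})

test_that("affection prevalence tracks the configured target", {
  st <- small_study()
  expect_lt(abs(mean(st$phenotypes$Affected) - 0.30), 0.03)
  st2 <- simulate_study(small_cfg(seed = 9, prevalence = 0.15))
  expect_lt(abs(mean(st2$phenotypes$Affected) - 0.15), 0.03)
})

test_that("null effect size leaves affection independent of causal burden", {
  # under effect_size = 0 the causal-gene burden should associate with
  # affection at chance level across seeds
  ps <- vapply(1:8, function(s) {
    st <- simulate_study(small_cfg(seed = 100 + s, effect_size = 0))
    tv <- st$truth$variant_id
    burden <- rowSums(st$genotypes[, tv, drop = FALSE])
    phen <- st$phenotypes[match(rownames(st$genotypes), st$phenotypes$IID), ]
    if (sd(burden) == 0) return(NA_real_)
    summary(stats::lm(phen$Affected ~ burden))$coefficients["burden", 4]
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 4)
  expect_gt(min(ps), 0.001)        # no systematic association
  expect_gt(mean(ps > 0.2), 0.3)   # p-values spread over (0, 1)
})

test_that("causal burden is higher among affected individuals", {
  diffs <- vapply(1:3, function(s) {
    st <- simulate_study(med_cfg(seed = 200 + s, effect_size = 1))
    tv <- st$truth$variant_id
    sc <- drop(st$genotypes[, tv, drop = FALSE] %*% st$truth$effect)
    phen <- st$phenotypes[match(rownames(st$genotypes), st$phenotypes$IID), ]
    mean(sc[phen$Affected == 1]) - mean(sc[phen$Affected == 0])
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("polygenic heritability is recoverable from simulated traits", {
  # Q4 carries no causal-gene effects, so its true polygenic h2 equals the
  # configured value exactly
  st <- med_study()
  phen <- st$phenotypes[match(st$pedigree$iid, st$phenotypes$IID), ]
  fit <- fit_polygenic(phen$Q4, K = 2 * st$kinship)
  expect_lt(abs(fit$h2 - 0.6), 0.2)  # desk-scale n; tighter bound at n~700
                                     # in the acceptance suite
})

test_that("a written study round-trips through the readers", {
  st <- simulate_study(small_cfg(seed = 77, missing_rate = 0.05))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  expect_identical(back$genotypes[rownames(st$genotypes), ],
                   st$genotypes)
  expect_equal(back$variants$maf, st$variants$maf, tolerance = 1e-12)
  expect_equal(back$variants$rarity, st$variants$rarity)
  expect_equal(back$phenotypes$Affected,
               st$phenotypes$Affected[match(back$phenotypes$IID,
                                            st$phenotypes$IID)])
  expect_equal(back$phenotypes$Q1,
               st$phenotypes$Q1[match(back$phenotypes$IID,
                                      st$phenotypes$IID)],
               tolerance = 1e-10)
  expect_identical(back$pedigree$father, st$pedigree$father)
  # truth file lists exactly the configured number of causal genes
  expect_equal(length(unique(back$truth$gene)), 5L)
  # missing genotypes survive the 0-allele sentinel
  expect_identical(which(is.na(back$genotypes[rownames(st$genotypes), ])),
                   which(is.na(st$genotypes)))
  expect_gt(sum(is.na(back$genotypes)), 0)
})
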