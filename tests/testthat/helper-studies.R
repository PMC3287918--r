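# Shared fixtures, built in code and cached per test run.

# Desk-scale configuration: 2 families x ~40 individuals, 100 genes,
# 5 causal.
small_cfg <- function(seed = 1L, ...) {
  sim_config(n_families = 2L, family_size_range = c(25L, 60L),
             n_generations = 4L, children_range = c(2L, 5L),
             marry_prob = 0.7, n_genes = 100L,
             variants_per_gene_range = c(2L, 6L), causal_genes = 5L,
             seed = seed, ...)
}

# Medium scale (~280 individuals in 4 families) for power-style checks
# where rare variants need room to segregate.
med_cfg <- function(seed = 1L, ...) {
  sim_config(n_families = 4L, family_size_range = c(50L, 90L),
             n_genes = 60L, variants_per_gene_range = c(2L, 6L),
             causal_genes = 5L, seed = seed, ...)
}

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(key, cfg) {
  if (is.null(.study_cache[[key]])) .study_cache[[key]] <- simulate_study(cfg)
  .study_cache[[key]]
}

small_study <- function() cached_study("small", small_cfg())
med_study <- function() cached_study("med", med_cfg())

# The full-scale default study (8 extended pedigrees, ~700 individuals),
# used by the acceptance checks.
full_study <- function() cached_study("full", sim_config(seed = 1L))

# Null world for calibration experiments: no causal effects, no polygenic
# variance, full-size pedigrees, 200 genes.
null_cfg <- function(seed) {
  sim_config(seed = seed, n_genes = 200L,
             variants_per_gene_range = c(2L, 4L), effect_size = 0)
}

# A hand-built three-generation pedigree with known kinship values:
# founder couple p1 x p2 -> full sibs s1, s2; s1 x spouse q1 -> child c1;
# p1 x second mate q2 -> h1 (half sib of s1/s2).
demo_pedigree <- function() {
  pedigree(fid = rep("A", 7),
           iid = c("p1", "p2", "q1", "q2", "s1", "s2", "h1"),
           father = c(NA, NA, NA, NA, "p1", "p1", "p1"),
           mother = c(NA, NA, NA, NA, "p2", "p2", "q2"),
           sex = c(1, 2, 2, 2, 1, 2, 1))
}

# Monte-Carlo gene-dropping estimate of pairwise kinship: founders carry
# unique allele labels, alleles drop independently per replicate, and the
# kinship of (i, j) is the average probability that one random allele from
# each is identical by descent.
drop_kinship_mc <- function(ped, n_drops, seed = 1) {
  n <- nrow(ped)
  fi <- match(ped$father, ped$iid)
  mi <- match(ped$mother, ped$iid)
  set.seed(seed)
  {
    A1 <- matrix(0L, n_drops, n)
    A2 <- matrix(0L, n_drops, n)
    lab <- 0L
    for (i in seq_len(n)) {
      if (ped$founder[i]) {
        A1[, i] <- lab + 1L
        A2[, i] <- lab + 2L
        lab <- lab + 2L
      } else {
        pf <- stats::runif(n_drops) < 0.5
        A1[, i] <- ifelse(pf, A1[, fi[i]], A2[, fi[i]])
        pm <- stats::runif(n_drops) < 0.5
        A2[, i] <- ifelse(pm, A1[, mi[i]], A2[, mi[i]])
      }
    }
    est <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
    se <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
    for (i in seq_len(n)) {
      for (j in i:n) {
        share <- ((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
                    (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])) / 4
        est[i, j] <- est[j, i] <- mean(share)
        se[i, j] <- se[j, i] <- stats::sd(share) / sqrt(n_drops)
      }
    }
    list(phi = est, se = se)
  }
}

# Random pedigree for oracle sweeps: a single family drawn from the
# simulator with size close to `target`.
random_pedigree <- function(target = 30L, seed = 1L) {
  cfg <- sim_config(n_families = 1L,
                    family_size_range = c(target - 10L, target + 10L),
                    n_generations = 4L, children_range = c(2L, 4L),
                    marry_prob = 0.6, n_genes = 1L,
                    variants_per_gene_range = c(1L, 1L),
                    causal_genes = 1L, seed = seed)
  simulate_pedigrees(cfg)
}
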