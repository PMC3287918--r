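#' Configuration for a synthetic family mini-exome study
#'
#' Defaults describe the full-scale study the package emulates: 8 extended
#' pedigrees totalling about 700 individuals, roughly 24,500 biallelic
#' variants in 3,204 genes of which about 74% are rare (founder MAF < 0.01),
#' 15 causal genes, and a binary affection status with 30% prevalence driven
#' through a liability-threshold model. Counts may be scaled down for tests;
#' proportions keep their meaning.
#'
#' @param n_families number of disjoint pedigrees.
#' @param family_size_range accepted (min, max) individuals per family; a
#'   family is re-drawn until its size falls inside.
#' @param n_generations generations per pedigree.
#' @param children_range (min, max) children per mating.
#' @param marry_prob probability a child of a non-terminal generation gains
#'   a married-in founder spouse and reproduces.
#' @param n_genes number of genes.
#' @param variants_per_gene_range (min, max) variants per gene.
#' @param rare_fraction fraction of variants with founder MAF drawn below
#'   0.01 (default 18131/24487).
#' @param nonsyn_fraction fraction of variants annotated nonsynonymous.
#' @param causal_genes number of causal genes (default 15).
#' @param effect_size per-minor-allele shift (trait SD units) each causal
#'   nonsynonymous variant adds to its assigned quantitative trait.
#' @param h2_polygenic residual polygenic heritability of Q1, Q2 and Q4.
#' @param prevalence target affection prevalence (default 0.30).
#' @param covariate_effects named liability coefficients for Age (per SD of
#'   age), Sex, Smoking (0/1 presence) and the raw traits Q1, Q2, Q4; signs
#'   default to the risk directions of the emulated study (Q4 protective).
#' @param missing_rate fraction of genotype calls set missing.
#' @param seed RNG seed; per-stage streams are derived from it.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_families = 8L,
                       family_size_range = c(60L, 120L),
                       n_generations = 4L,
                       children_range = c(3L, 6L),
                       marry_prob = 0.75,
                       n_genes = 3204L,
                       variants_per_gene_range = c(2L, 13L),
                       rare_fraction = 18131 / 24487,
                       nonsyn_fraction = 0.7,
                       causal_genes = 15L,
                       effect_size = 0.5,
                       h2_polygenic = 0.6,
                       prevalence = 0.30,
                       covariate_effects = c(Age = 0.3, Sex = 0,
                                             Smoking = 0.4, Q1 = 1.0,
                                             Q2 = 0.5, Q4 = -0.8),
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              family_size_range = as.integer(family_size_range),
              n_generations = as.integer(n_generations),
              children_range = as.integer(children_range),
              marry_prob = marry_prob,
              n_genes = as.integer(n_genes),
              variants_per_gene_range = as.integer(variants_per_gene_range),
              rare_fraction = rare_fraction,
              nonsyn_fraction = nonsyn_fraction,
              causal_genes = as.integer(causal_genes),
              effect_size = effect_size,
              h2_polygenic = h2_polygenic,
              prevalence = prevalence,
              covariate_effects = covariate_effects,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  counts <- c(cfg$n_families, cfg$n_generations, cfg$n_genes,
              cfg$causal_genes)
  if (any(counts < 1L)) stopf("all counts must be >= 1")
  props <- c(cfg$rare_fraction, cfg$nonsyn_fraction, cfg$marry_prob,
             cfg$missing_rate)
  if (any(props < 0 | props > 1)) stopf("proportions must lie in [0, 1]")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1) {
    stopf("prevalence must lie in (0, 1)")
  }
  if (cfg$h2_polygenic < 0 || cfg$h2_polygenic >= 1) {
    stopf("h2_polygenic must lie in [0, 1)")
  }
  rng_ok <- function(r) length(r) == 2L && r[1L] >= 1L && r[1L] <= r[2L]
  if (!rng_ok(cfg$family_size_range) || !rng_ok(cfg$children_range) ||
      !rng_ok(cfg$variants_per_gene_range)) {
    stopf("ranges must be (min, max) with 1 <= min <= max")
  }
  if (cfg$causal_genes > cfg$n_genes) {
    stopf("causal_genes cannot exceed n_genes")
  }
  # a single descent line through g generations needs 2g - 1 individuals
  if (cfg$family_size_range[2L] < 2L * cfg$n_generations - 1L) {
    stopf("family_size_range max %d cannot hold %d generations (needs >= %d)",
          cfg$family_size_range[2L], cfg$n_generations,
          2L * cfg$n_generations - 1L)
  }
  required <- c("Age", "Sex", "Smoking", "Q1", "Q2", "Q4")
  if (!all(required %in% names(cfg$covariate_effects))) {
    stopf("covariate_effects must name all of: %s",
          paste(required, collapse = ", "))
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate multi-generation pedigrees
#'
#' Each family starts from one founder couple; every mating draws a number
#' of children from `children_range`, and children of non-terminal
#' generations marry in a founder spouse with probability `marry_prob`.
#' A family is re-drawn (up to 200 attempts) until its size falls within
#' `family_size_range`.
#'
#' @param config a [sim_config()].
#' @return a [pedigree()] with `n_families` connected components.
#' @export
simulate_pedigrees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    fams <- lapply(seq_len(config$n_families), function(f) {
      sim_one_family(config, paste0("F", f))
    })
  })
  do.call(rbind_ped, fams)
}

rbind_ped <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  pedigree(df$fid, df$iid, df$father, df$mother, df$sex)
}

sim_one_family <- function(config, fid) {
  lo <- config$family_size_range[1L]
  hi <- config$family_size_range[2L]
  for (attempt in seq_len(200L)) {
    rec <- new.env()
    rec$iid <- character(0)
    rec$father <- character(0)
    rec$mother <- character(0)
    rec$sex <- integer(0)
    counter <- 0L
    add <- function(sex, father = NA_character_, mother = NA_character_) {
      counter <<- counter + 1L
      id <- paste0(fid, "_", counter)
      rec$iid <- c(rec$iid, id)
      rec$father <- c(rec$father, father)
      rec$mother <- c(rec$mother, mother)
      rec$sex <- c(rec$sex, sex)
      id
    }
    pa <- add(1L)
    ma <- add(2L)
    couples <- list(c(pa, ma))
    for (g in seq_len(config$n_generations - 1L)) {
      nxt <- list()
      last <- g == config$n_generations - 1L
      for (cp in couples) {
        nk <- sample(seq(config$children_range[1L],
                         config$children_range[2L]), 1L)
        for (k in seq_len(nk)) {
          sex <- sample(1:2, 1L)
          kid <- add(sex, father = cp[1L], mother = cp[2L])
          if (!last && stats::runif(1) < config$marry_prob) {
            sp <- add(if (sex == 1L) 2L else 1L)
            nxt[[length(nxt) + 1L]] <-
              if (sex == 1L) c(kid, sp) else c(sp, kid)
          }
        }
      }
      couples <- nxt
      if (!length(couples)) break
    }
    n <- length(rec$iid)
    if (n >= lo && n <= hi) {
      return(pedigree(rep(fid, n), rec$iid, rec$father, rec$mother, rec$sex))
    }
  }
  stopf("could not draw a family of size in [%d, %d] in 200 attempts; %s",
        lo, hi, "relax family_size_range or adjust children_range/marry_prob")
}

#' Simulate gene-structured genotypes by founder sampling + gene dropping
#'
#' Founder alleles are drawn Bernoulli(MAF) independently per variant (no
#' linkage disequilibrium); each non-founder inherits one uniformly chosen
#' allele from each parent, so Mendelian consistency holds by construction.
#' Genotypes are recoded so that counts refer to the allele that is minor
#' in the realized sample (all individuals; ties keep the founder-draw
#' minor allele), matching how [read_ped()] recodes alleles. The variant
#' table records both the population MAF the founder draws used (`maf`,
#' the analogue of a supplied annotation file, and the basis for
#' rare/common classification) and the realized sample MAF (`maf_sample`).
#' Within extended families rare founder alleles are amplified by descent,
#' so `maf_sample` typically exceeds `maf` for rare variants.
#'
#' @param ped a [pedigree()].
#' @param config a [sim_config()].
#' @return list with `genotypes` (individuals x variants integer matrix)
#'   and `variants` (variant_id, gene, chrom, pos, maf, class, rarity).
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 2L), {
    vr <- config$variants_per_gene_range
    n_per_gene <- sample(seq(vr[1L], vr[2L]), config$n_genes, replace = TRUE)
    m <- sum(n_per_gene)
    gene <- rep(sprintf("GENE%04d", seq_len(config$n_genes)), n_per_gene)
    variant_id <- paste0(gene, "_V", unlist(lapply(n_per_gene, seq_len)))
    chrom <- rep(rep_len(1:22, config$n_genes), n_per_gene)
    pos <- unlist(lapply(seq_len(config$n_genes), function(g) {
      g * 10000L + seq_len(n_per_gene[g]) * 100L
    }))
    is_rare <- stats::runif(m) < config$rare_fraction
    maf0 <- ifelse(is_rare, stats::runif(m, 0.0005, 0.0099),
                   stats::runif(m, 0.01, 0.5))
    cls <- ifelse(stats::runif(m) < config$nonsyn_fraction,
                  "nonsynonymous", "synonymous")

    n <- nrow(ped)
    iid <- ped$iid
    founder <- ped$founder
    nf <- sum(founder)
    A1 <- matrix(0L, n, m)
    A2 <- matrix(0L, n, m)
    A1[founder, ] <- matrix(stats::rbinom(nf * m, 1L, rep(maf0, each = nf)),
                            nrow = nf)
    A2[founder, ] <- matrix(stats::rbinom(nf * m, 1L, rep(maf0, each = nf)),
                            nrow = nf)
    fi <- match(ped$father, iid)
    mi <- match(ped$mother, iid)
    for (i in which(!founder)) {
      pickf <- stats::runif(m) < 0.5
      A1[i, ] <- ifelse(pickf, A1[fi[i], ], A2[fi[i], ])
      pickm <- stats::runif(m) < 0.5
      A2[i, ] <- ifelse(pickm, A1[mi[i], ], A2[mi[i], ])
    }
    G <- A1 + A2
    dimnames(G) <- list(iid, variant_id)

    f_real <- colMeans(G) / 2
    flip <- f_real > 0.5
    if (any(flip)) {
      G[, flip] <- 2L - G[, flip]
      f_real[flip] <- 1 - f_real[flip]
      # the counted allele changed; its population frequency is 1 - maf0
      # (clipped to the [0, 0.5] MAF scale; flips only occur near 0.5)
      maf0[flip] <- pmin(1 - maf0[flip], 0.5)
    }
    if (config$missing_rate > 0) {
      G[matrix(stats::runif(n * m) < config$missing_rate, n, m)] <-
        NA_integer_
    }
    variants <- classify_variants(data.frame(
      variant_id = variant_id, gene = gene, chrom = chrom, pos = pos,
      maf = maf0, maf_sample = f_real, class = cls,
      stringsAsFactors = FALSE))
    list(genotypes = G, variants = variants)
  })
}

#' Simulate phenotypes from a liability-threshold model
#'
#' Q1 and Q2 each receive additive effects from the nonsynonymous variants
#' of their assigned causal genes, plus a polygenic component with
#' covariance `h2 * 2*Phi` and residual noise of variance `1 - h2`; Q4 is
#' polygenic + noise only, independent of causal genes. Liability is a
#' linear combination of standardized Age, Sex, Smoking, Q1, Q2 and
#' (negatively) Q4 plus standard normal noise; affection is liability above
#' the empirical quantile giving the configured prevalence.
#'
#' @param ped a [pedigree()].
#' @param genotypes,variants output of [simulate_genotypes()].
#' @param config a [sim_config()].
#' @param kinship optional precomputed [kinship_matrix()] for `ped`.
#' @return list with `phenotypes` (IID, Affected, Q1, Q2, Q4, Age, Sex,
#'   Smoking) and `truth` (gene, variant_id, effect, trait).
#' @export
simulate_phenotypes <- function(ped, genotypes, variants, config,
                                kinship = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  if (!all(ped$iid %in% rownames(genotypes))) {
    stopf("genotypes must cover all pedigree members")
  }
  phi <- kinship %||% kinship_matrix(ped)
  K <- 2 * phi[ped$iid, ped$iid]
  L <- tryCatch(chol(K), error = function(e) {
    stopf("kinship decomposition failed (singular 2*Phi): %s",
          conditionMessage(e))
  })
  with_seed(derive_seed(config$seed, 3L), {
    n <- nrow(ped)
    h2 <- config$h2_polygenic
    draw_trait <- function() {
      a <- drop(crossprod(L, stats::rnorm(n))) * sqrt(h2)
      a + stats::rnorm(n, sd = sqrt(1 - h2))
    }
    q1 <- draw_trait()
    q2 <- draw_trait()
    q4 <- draw_trait()

    # causal genes: sampled among genes with a polymorphic nonsynonymous
    # variant, alternately assigned to Q1 and Q2. Per-variant effects are
    # frequency dependent: effect_size is the per-allele shift of a
    # MAF = 0.005 variant, rarer variants get proportionally larger
    # effects and common ones attenuated (beta ~ log10 MAF), so the causal
    # contribution does not swamp the polygenic variance.
    eligible <- unique(variants$gene[variants$class == "nonsynonymous" &
                                       variants$maf_sample > 0])
    if (length(eligible) < config$causal_genes) {
      stopf("only %d genes have polymorphic nonsynonymous variants; %d causal requested",
            length(eligible), config$causal_genes)
    }
    causal <- sample(eligible, config$causal_genes)
    truth_rows <- variants[variants$gene %in% causal &
                             variants$class == "nonsynonymous" &
                             variants$maf_sample > 0, , drop = FALSE]
    trait_of_gene <- stats::setNames(
      rep(c("Q1", "Q2"), length.out = length(causal)), sort(causal))
    truth <- data.frame(gene = truth_rows$gene,
                        variant_id = truth_rows$variant_id,
                        effect = config$effect_size *
                          log10(truth_rows$maf) / log10(0.005),
                        trait = trait_of_gene[truth_rows$gene],
                        stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    Gc <- genotypes[ped$iid, truth$variant_id, drop = FALSE]
    Gc[is.na(Gc)] <- 0L
    if (nrow(truth)) {
      q1 <- q1 + drop(Gc %*% (truth$effect * (truth$trait == "Q1")))
      q2 <- q2 + drop(Gc %*% (truth$effect * (truth$trait == "Q2")))
    }

    age <- stats::runif(n, 20, 80)
    sex01 <- as.integer(ped$sex == 2L)
    smoking <- stats::rbinom(n, 1L, 0.2)
    ce <- config$covariate_effects
    liability <- ce[["Age"]] * (age - 50) / (60 / sqrt(12)) +
      ce[["Sex"]] * sex01 + ce[["Smoking"]] * smoking +
      ce[["Q1"]] * q1 + ce[["Q2"]] * q2 + ce[["Q4"]] * q4 +
      stats::rnorm(n)
    thr <- stats::quantile(liability, 1 - config$prevalence, names = FALSE)
    affected <- as.integer(liability > thr)

    phen <- data.frame(IID = ped$iid, Affected = affected,
                       Q1 = q1, Q2 = q2, Q4 = q4, Age = age, Sex = sex01,
                       Smoking = smoking, stringsAsFactors = FALSE)
    list(phenotypes = phen, truth = truth)
  })
}

#' Simulate a complete family study with ground truth
#'
#' Convenience wrapper running [simulate_pedigrees()],
#' [simulate_genotypes()] and [simulate_phenotypes()] and bundling the
#' results (plus the kinship matrix) into one object. Identical
#' configurations (including seed) give identical studies.
#'
#' @param config a [sim_config()].
#' @return list of class `"sim_study"`: `pedigree`, `genotypes`,
#'   `variants`, `phenotypes`, `truth`, `kinship` (the matrix of kinship
#'   coefficients Phi), `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  ped <- simulate_pedigrees(config)
  gv <- simulate_genotypes(ped, config)
  phi <- kinship_matrix(ped)
  pt <- simulate_phenotypes(ped, gv$genotypes, gv$variants, config,
                            kinship = phi)
  study <- list(pedigree = ped, genotypes = gv$genotypes,
                variants = gv$variants, phenotypes = pt$phenotypes,
                truth = pt$truth, kinship = phi, config = config)
  class(study) <- "sim_study"
  study
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "sim_study: %d individuals in %d families; %d variants in %d genes\n",
    nrow(x$pedigree), length(unique(x$pedigree$fid)),
    ncol(x$genotypes), length(unique(x$variants$gene))))
  cat(sprintf("  causal genes: %d; affected: %.1f%%\n",
              length(unique(x$truth$gene)),
              100 * mean(x$phenotypes$Affected)))
  invisible(x)
}
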