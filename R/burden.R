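# Gene-level burden covariates. Missing genotypes contribute 0 to every
# burden; genes where more than 20% of individuals have a missing call
# across the used variants are flagged (status "flagged_missing") but still
# tested.

burden_core <- function(genotypes, vids, indicator = FALSE) {
  G <- genotypes[, vids, drop = FALSE]
  miss_frac <- mean(rowSums(is.na(G)) > 0)
  G[is.na(G)] <- 0L
  vals <- if (indicator) {
    as.integer(rowSums(G) > 0)
  } else {
    as.integer(rowSums(G))
  }
  list(values = stats::setNames(vals, rownames(genotypes)),
       n_variants_used = length(vids), missing_frac = miss_frac)
}

new_burden <- function(gene, approach, core) {
  status <- if (is.null(core)) {
    "NCV"
  } else if (core$missing_frac > 0.2) {
    "flagged_missing"
  } else {
    "ok"
  }
  structure(list(gene = gene, approach = approach,
                 values = if (is.null(core)) NULL else core$values,
                 n_variants_used = if (is.null(core)) 0L
                                   else core$n_variants_used,
                 status = status),
            class = "burden_vector")
}

#' Burden covariates for the four polygenic screening approaches
#'
#' * Approach A (`burden_rare_sum`): per-individual sum of minor-allele
#'   counts over all rare variants of the gene, synonymous and
#'   nonsynonymous alike.
#' * Approach B (`burden_nonsyn_carrier`): 0/1 indicator of carrying at
#'   least one rare nonsynonymous allele anywhere in the gene.
#' * Approach C (`burden_common_count`): per-individual sum of minor-allele
#'   counts over the gene's common variants.
#'
#' A gene with no qualifying variants for an approach gets status `"NCV"`
#' (no covariate value) rather than an error, matching how untestable genes
#' are reported downstream.
#'
#' @param gene gene identifier.
#' @param genotypes individuals x variants minor-allele count matrix.
#' @param variants classified variant table (see [classify_variants()]).
#' @return object of class `"burden_vector"`: `gene`, `approach`, `values`
#'   (named per-individual), `n_variants_used`, `status`.
#' @export
burden_rare_sum <- function(gene, genotypes, variants) {
  vids <- variants$variant_id[variants$gene == gene &
                                variants$rarity == "rare"]
  core <- if (length(vids)) burden_core(genotypes, vids) else NULL
  new_burden(gene, "A_rare_sum", core)
}

#' @rdname burden_rare_sum
#' @export
burden_nonsyn_carrier <- function(gene, genotypes, variants) {
  vids <- variants$variant_id[variants$gene == gene &
                                variants$rarity == "rare" &
                                variants$class == "nonsynonymous"]
  core <- if (length(vids)) burden_core(genotypes, vids, indicator = TRUE)
          else NULL
  new_burden(gene, "B_nonsyn_carrier", core)
}

#' @rdname burden_rare_sum
#' @export
burden_common_count <- function(gene, genotypes, variants) {
  vids <- variants$variant_id[variants$gene == gene &
                                variants$rarity == "common"]
  core <- if (length(vids)) burden_core(genotypes, vids) else NULL
  new_burden(gene, "C_common_count", core)
}

burden_for <- function(approach, gene, genotypes, variants) {
  switch(approach,
         A = burden_rare_sum(gene, genotypes, variants),
         B = burden_nonsyn_carrier(gene, genotypes, variants),
         C = burden_common_count(gene, genotypes, variants),
         stopf("unknown burden approach '%s'", approach))
}

detection_row <- function(approach, gene, variant_id = NA_character_,
                          family_id = NA_character_, p = NA_real_,
                          effect = NA_real_, h2_with = NA_real_,
                          h2_without = NA_real_, status = "tested",
                          detected = FALSE, beta_b = NA_real_,
                          p_within = NA_real_) {
  data.frame(approach = approach, gene = gene, variant_id = variant_id,
             family_id = family_id, p = p, p_within = p_within,
             effect = effect, beta_b = beta_b, h2_with = h2_with,
             h2_without = h2_without, status = status,
             detected = detected, stringsAsFactors = FALSE)
}

#' Gene-by-gene polygenic burden screening (approaches A, B, C)
#'
#' For each gene, the approach's burden covariate is added to the polygenic
#' model of affection status with the base covariates (default Age and Q4),
#' and tested with [covariate_test()]. A gene is detected when the burden
#' p-value falls below `alpha` (no multiple-testing correction). Genes
#' without qualifying variants (`NCV`) or with a constant burden are
#' reported with a status, never dropped silently; per-gene failures are
#' recorded as `nonconverged` and the scan continues.
#'
#' @param study a [simulate_study()]-shaped list (`pedigree`, `genotypes`,
#'   `variants`, `phenotypes`, `kinship`).
#' @param approach one of `"A"`, `"B"`, `"C"`.
#' @param base_covariates phenotype columns used as fixed effects.
#' @param alpha detection threshold (default 0.05).
#' @param genes optional subset of genes to screen.
#' @param compute_h2 record REML heritability with/without each burden
#'   (two extra fits per gene; disable in large calibration runs).
#' @return data frame of detection results, one row per gene.
#' @export
screen_genes <- function(study, approach = c("A", "B", "C"),
                         base_covariates = c("Age", "Q4"), alpha = 0.05,
                         genes = NULL, compute_h2 = TRUE) {
  approach <- match.arg(approach)
  dat <- screen_data(study, base_covariates)
  eig <- relationship_eigen(dat$K)
  genes <- genes %||% unique(study$variants$gene)
  rows <- lapply(genes, function(g) {
    bv <- burden_for(approach, g, dat$G, study$variants)
    if (bv$status == "NCV") {
      return(detection_row(approach, g, status = "NCV"))
    }
    vals <- bv$values[dat$iid]
    if (stats::sd(vals) == 0) {
      return(detection_row(approach, g, status = "NCV"))
    }
    ct <- tryCatch(
      covariate_test(dat$y, dat$X, vals, K = dat$K, eig = eig,
                     compute_h2 = compute_h2),
      error = function(e) NULL)
    if (is.null(ct) || !ct$converged) {
      return(detection_row(approach, g, status = "nonconverged"))
    }
    detection_row(approach, g, p = ct$p, effect = unname(ct$beta),
                  h2_with = ct$h2_with, h2_without = ct$h2_without,
                  status = if (bv$status == "flagged_missing")
                             "flagged_missing" else "tested",
                  detected = ct$p < alpha)
  })
  do.call(rbind, rows)
}

# Shared per-screen extraction: aligned y, X, K, genotypes.
screen_data <- function(study, base_covariates) {
  phen <- study$phenotypes
  ped <- study$pedigree
  iid <- ped$iid
  pidx <- match(iid, phen$IID)
  y <- phen$Affected[pidx]
  X <- cbind(intercept = 1,
             as.matrix(phen[pidx, base_covariates, drop = FALSE]))
  K <- 2 * study$kinship[iid, iid]
  list(iid = iid, y = y, X = X, K = K,
       G = study$genotypes[iid, , drop = FALSE], ped = ped)
}

#' Per-family single-SNP polygenic screening (approach D)
#'
#' Considers each pedigree separately: every variant polymorphic within the
#' family enters the family's polygenic model of affection (base covariates
#' Age and Q4) as a covariate. A variant is selected in a family when its
#' covariate is significant (p < `alpha`) and the family's heritability
#' estimate with the covariate is lower than without it; a gene is detected
#' when at least one of its variants is selected in at least one family.
#' The conjunction with significance is deliberate: "reduces heritability"
#' alone would select about half of all null variants.
#'
#' Per-family nonconvergence is recorded per variant and never aborts the
#' scan (small families and a binary trait make failures common).
#'
#' @inheritParams screen_genes
#' @param variants optional subset of variant ids to test.
#' @return data frame with one row per (family, variant) tested, plus NCV
#'   rows for variants monomorphic everywhere.
#' @export
screen_per_family <- function(study, base_covariates = c("Age", "Q4"),
                              alpha = 0.05, variants = NULL) {
  phen <- study$phenotypes
  ped <- study$pedigree
  vt <- study$variants
  vids <- variants %||% vt$variant_id[vt$rarity != "monomorphic"]
  fams <- unique(ped$fid)
  out <- list()
  for (f in fams) {
    sub <- ped[ped$fid == f, , drop = FALSE]
    iid <- sub$iid
    pidx <- match(iid, phen$IID)
    y <- phen$Affected[pidx]
    X <- cbind(intercept = 1,
               as.matrix(phen[pidx, base_covariates, drop = FALSE]))
    K <- 2 * study$kinship[iid, iid]
    eig <- relationship_eigen(K)
    base_ml <- tryCatch(fit_polygenic(y, X, K, method = "ML", eig = eig),
                        error = function(e) NULL)
    base_reml <- tryCatch(fit_polygenic(y, X, K, method = "REML",
                                        eig = eig),
                          error = function(e) NULL)
    if (is.null(base_ml) || is.null(base_reml)) next
    G <- study$genotypes[iid, vids, drop = FALSE]
    G[is.na(G)] <- 0L
    for (v in vids) {
      g <- G[, v]
      if (stats::sd(g) == 0) next  # monomorphic within this family
      row <- tryCatch({
        XC <- cbind(X, snp = g)
        if (qr(XC)$rank < ncol(XC)) stop("collinear")
        fit1 <- fit_polygenic(y, XC, K, method = "ML", eig = eig)
        fit1r <- fit_polygenic(y, XC, K, method = "REML", eig = eig)
        lambda <- max(0, 2 * (fit1$loglik - base_ml$loglik))
        p <- stats::pchisq(lambda, df = 1, lower.tail = FALSE)
        sel <- p < alpha && fit1r$h2 < base_reml$h2
        detection_row("D", vt$gene[match(v, vt$variant_id)], v, f, p,
                      unname(fit1$beta["snp"]), fit1r$h2, base_reml$h2,
                      status = "tested", detected = sel)
      }, error = function(e) {
        detection_row("D", vt$gene[match(v, vt$variant_id)], v, f,
                      status = "nonconverged")
      })
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) {
    return(detection_row("D", character(0)))
  }
  do.call(rbind, out)
}

#' Genes detected by a screening or association result
#' @param detections a detection data frame from [screen_genes()],
#'   [screen_per_family()] or [assoc_screen()].
#' @return character vector of unique detected genes.
#' @export
detected_genes <- function(detections) {
  unique(detections$gene[detections$detected %in% TRUE])
}
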