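# Family-based single-variant association in the QTDT style: the genotype
# is split into an expected (between-family) component b and a transmission
# deviation (within-family) component w = g - b, which are orthogonal
# sources of association. b carries population structure; w is immune to
# between-family confounding.

#' Orthogonal between/within decomposition of genotypes
#'
#' For each individual and variant, the expected genotype `b` is the mean
#' of the available parental genotypes; when neither parent is genotyped it
#' falls back to the sibship mean (full sibs, self included); an isolated
#' founder keeps its own genotype (so it contributes only between-family
#' information, w = 0). Always `b + w = g` exactly where `g` is observed.
#'
#' @param ped a [pedigree()].
#' @param genotypes individuals x variants minor-allele count matrix with
#'   iid rownames.
#' @return list of matrices `b` and `w`, same shape as `genotypes`.
#' @export
orthogonal_decompose <- function(ped, genotypes) {
  stopifnot(inherits(ped, "pedigree"))
  G <- genotypes[ped$iid, , drop = FALSE]
  n <- nrow(G)
  B <- matrix(NA_real_, n, ncol(G), dimnames = dimnames(G))
  fi <- match(ped$father, ped$iid)
  mi <- match(ped$mother, ped$iid)

  # sibship means (children grouped by parent couple), used as fallback
  sib_key <- ifelse(ped$founder, NA_character_,
                    paste(ped$father, ped$mother, sep = "|"))
  for (i in seq_len(n)) {
    g <- G[i, ]
    if (ped$founder[i]) {
      B[i, ] <- as.numeric(g)
      next
    }
    gf <- G[fi[i], ]
    gm <- G[mi[i], ]
    both <- !is.na(gf) & !is.na(gm)
    b <- ifelse(both, (as.numeric(gf) + as.numeric(gm)) / 2,
                ifelse(!is.na(gf), as.numeric(gf),
                       ifelse(!is.na(gm), as.numeric(gm), NA_real_)))
    if (anyNA(b)) {
      sibs <- which(sib_key == sib_key[i])
      sib_mean <- colMeans(G[sibs, , drop = FALSE], na.rm = TRUE)
      b[is.na(b)] <- sib_mean[is.na(b)]
    }
    B[i, ] <- b
  }
  B[is.na(G)] <- NA_real_
  W <- ifelse(is.na(G), NA_real_, G - B)
  list(b = B, w = W)
}

#' Linear family-based association test (approaches E and G)
#'
#' Least-squares fit of the trait on [intercept, covariates, b, w]. The
#' primary p-value tests total association (b and w jointly, 2 df F-test);
#' the within-family p-value (t-test of the w coefficient) is also emitted
#' so the structure-robust reading is available. When there is no
#' within-family variation the test degrades to 1 df on b alone and the
#' status records it.
#'
#' @param trait numeric response (binary affection analyzed as 0/1).
#' @param b,w between/within components for one variant
#'   (see [orthogonal_decompose()]).
#' @param covariates numeric matrix of covariates (no intercept), or NULL.
#' @return list: `beta_b`, `beta_w`, `p_total`, `p_within`, `df`, `status`.
#' @export
assoc_linear <- function(trait, b, w, covariates = NULL) {
  keep <- !(is.na(trait) | is.na(b) | is.na(w))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
  }
  y <- trait[keep]
  b <- b[keep]
  w <- w[keep]
  X0 <- cbind(intercept = rep(1, length(y)),
              if (!is.null(covariates)) covariates[keep, , drop = FALSE])
  if (stats::sd(b + w) == 0) {
    return(list(beta_b = NA_real_, beta_w = NA_real_, p_total = NA_real_,
                p_within = NA_real_, df = 0L, status = "NCV"))
  }
  fit0 <- stats::lm.fit(X0, y)
  rss0 <- sum(fit0$residuals^2)
  no_within <- stats::sd(w) == 0
  X1 <- if (no_within) cbind(X0, b = b) else cbind(X0, b = b, w = w)
  fit1 <- stats::lm.fit(X1, y)
  q <- fit1$rank - fit0$rank
  if (q < 1L) {
    return(list(beta_b = NA_real_, beta_w = NA_real_, p_total = NA_real_,
                p_within = NA_real_, df = 0L, status = "collinear"))
  }
  rss1 <- sum(fit1$residuals^2)
  df2 <- length(y) - fit1$rank
  Fstat <- ((rss0 - rss1) / q) / (rss1 / df2)
  p_total <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
  cf <- fit1$coefficients
  p_within <- NA_real_
  if (!no_within && !is.na(cf["w"])) {
    XtXi <- chol2inv(fit1$qr$qr[seq_len(fit1$rank), seq_len(fit1$rank),
                                drop = FALSE])
    piv <- fit1$qr$pivot[seq_len(fit1$rank)]
    se <- sqrt(diag(XtXi) * rss1 / df2)
    names(se) <- colnames(X1)[piv]
    if ("w" %in% names(se)) {
      tw <- cf["w"] / se["w"]
      p_within <- unname(2 * stats::pt(-abs(tw), df2))
    }
  }
  list(beta_b = unname(cf["b"]), beta_w = unname(cf["w"]),
       p_total = p_total, p_within = p_within, df = q,
       status = if (no_within) "between_only" else "tested")
}

#' Variance-components family-based association test (approaches F and H)
#'
#' Joint 2-df [covariate_test()] of [b, w] added to the polygenic model of
#' the trait with the base covariates; the pedigree additive relationship
#' 2*Phi stands in for marker-specific IBD sharing.
#'
#' @inheritParams assoc_linear
#' @param K relationship matrix (2*Phi) aligned with `trait`.
#' @param eig optional [relationship_eigen()] of `K`.
#' @param compute_h2 also run the REML fits recording heritability with and
#'   without the variant (skippable in large calibration loops).
#' @return list: `beta_b`, `beta_w`, `p_total`, `df`, `h2_with`,
#'   `h2_without`, `status`.
#' @export
assoc_varcomp <- function(trait, b, w, covariates = NULL, K, eig = NULL,
                          compute_h2 = TRUE) {
  if (stats::sd(b + w, na.rm = TRUE) == 0) {
    return(list(beta_b = NA_real_, beta_w = NA_real_, p_total = NA_real_,
                df = 0L, h2_with = NA_real_, h2_without = NA_real_,
                status = "NCV"))
  }
  X <- cbind(intercept = rep(1, length(trait)),
             if (!is.null(covariates)) as.matrix(covariates))
  C <- if (stats::sd(w, na.rm = TRUE) == 0) {
    cbind(b = b)
  } else {
    cbind(b = b, w = w)
  }
  res <- tryCatch(
    covariate_test(trait, X, C, K = K, eig = eig, compute_h2 = compute_h2),
    error = function(e) NULL)
  if (is.null(res) || !res$converged) {
    return(list(beta_b = NA_real_, beta_w = NA_real_, p_total = NA_real_,
                df = ncol(C), h2_with = NA_real_, h2_without = NA_real_,
                status = "nonconverged"))
  }
  list(beta_b = unname(res$beta["b"]),
       beta_w = if ("w" %in% colnames(C)) unname(res$beta["w"])
                else NA_real_,
       p_total = res$p, df = res$df, h2_with = res$h2_with,
       h2_without = res$h2_without,
       status = if (ncol(C) == 1L) "between_only" else "tested")
}

#' Family-based association screen over a variant panel (approaches E-H)
#'
#' Runs [assoc_linear()] (`model = "linear"`) or [assoc_varcomp()]
#' (`model = "varcomp"`) for every rare or common variant, on affection
#' status with the base covariates. Approach letters: E = common/linear,
#' F = common/varcomp, G = rare/linear, H = rare/varcomp. A gene is
#' detected when at least one of its variants has p < `alpha`.
#'
#' @inheritParams screen_genes
#' @param panel `"common"` or `"rare"` (monomorphic variants are skipped
#'   with NCV status).
#' @param model `"linear"` or `"varcomp"`.
#' @return detection data frame, one row per variant.
#' @export
assoc_screen <- function(study, panel = c("common", "rare"),
                         model = c("linear", "varcomp"),
                         base_covariates = c("Age", "Q4"), alpha = 0.05,
                         compute_h2 = TRUE) {
  panel <- match.arg(panel)
  model <- match.arg(model)
  approach <- if (panel == "common") {
    if (model == "linear") "E" else "F"
  } else {
    if (model == "linear") "G" else "H"
  }
  dat <- screen_data(study, base_covariates)
  vt <- study$variants
  vids <- vt$variant_id[vt$rarity == panel]
  dec <- orthogonal_decompose(study$pedigree, dat$G[, vids, drop = FALSE])
  eig <- if (model == "varcomp") relationship_eigen(dat$K) else NULL
  covs <- dat$X[, -1, drop = FALSE]
  rows <- lapply(vids, function(v) {
    gene <- vt$gene[match(v, vt$variant_id)]
    b <- dec$b[, v]
    w <- dec$w[, v]
    if (model == "linear") {
      r <- assoc_linear(dat$y, b, w, covariates = covs)
      detection_row(approach, gene, v, p = r$p_total, effect = r$beta_w,
                    status = r$status, beta_b = r$beta_b,
                    p_within = r$p_within,
                    detected = !is.na(r$p_total) && r$p_total < alpha)
    } else {
      r <- assoc_varcomp(dat$y, b, w, covariates = covs, K = dat$K,
                         eig = eig, compute_h2 = compute_h2)
      detection_row(approach, gene, v, p = r$p_total, effect = r$beta_w,
                    h2_with = r$h2_with, h2_without = r$h2_without,
                    status = r$status, beta_b = r$beta_b,
                    detected = !is.na(r$p_total) && r$p_total < alpha)
    }
  })
  do.call(rbind, rows)
}

#' Monte-Carlo gene-based p-value from marker p-values and their
#' correlation (VEGAS style)
#'
#' The observed statistic is the sum of 1-df chi-squared quantiles of the
#' marker p-values, T = sum_j qchisq(1 - p_j, 1). Null draws take
#' z ~ MVN(0, Sigma) with Sigma the marker correlation matrix and compare
#' T_sim = sum z^2; the gene p-value is (1 + #{T_sim >= T_obs}) /
#' (n_sims + 1). Mildly indefinite Sigma (eigenvalues above -1e-6) is
#' repaired to its nearest PSD version with a warning; worse is an error.
#'
#' @param p marker p-values in (0, 1].
#' @param sigma marker correlation matrix (unit diagonal); defaults to
#'   identity (independent markers).
#' @param n_sims Monte-Carlo draws (default 1e4; use 1e5 for publication
#'   precision).
#' @param seed RNG seed for the draws.
#' @return list: `p_gene`, `t_obs`, `k`, `n_sims`.
#' @export
gene_based_p <- function(p, sigma = NULL, n_sims = 1e4, seed = NULL) {
  k <- length(p)
  stopifnot(k >= 1L)
  if (any(p <= 0 | p > 1)) stopf("marker p-values must lie in (0, 1]")
  if (is.null(sigma)) sigma <- diag(k)
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != k || ncol(sigma) != k) {
    stopf("sigma must be %d x %d", k, k)
  }
  if (max(abs(diag(sigma) - 1)) > 1e-8) {
    stopf("sigma must have unit diagonal")
  }
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6) {
    stopf("sigma is not positive semidefinite (min eigenvalue %.3g)",
          min(e$values))
  }
  if (min(e$values) < -1e-12) {
    warning("sigma repaired to nearest PSD (negative eigenvalues clipped)")
  }
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
  t_obs <- sum(stats::qchisq(p, df = 1, lower.tail = FALSE))
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_sims * k), n_sims, k) %*% t(A)
    t_sim <- rowSums(Z^2)
    p_gene <- (1 + sum(t_sim >= t_obs)) / (n_sims + 1)
  })
  list(p_gene = p_gene, t_obs = t_obs, k = k, n_sims = n_sims)
}

#' Gene-based scores for every gene in an association result
#'
#' Combines the per-variant p-values of each gene with [gene_based_p()],
#' using the sample genotype correlation among the gene's markers as the
#' default correlation matrix.
#'
#' @param detections variant-level detection data frame from
#'   [assoc_screen()].
#' @param study the study the detections came from (for genotype
#'   correlations).
#' @param n_sims,seed passed to [gene_based_p()].
#' @return data frame: gene, k_markers, t_obs, p_gene, n_sims.
#' @export
gene_scores <- function(detections, study, n_sims = 1e4, seed = NULL) {
  det <- detections[!is.na(detections$p), , drop = FALSE]
  genes <- unique(det$gene)
  rows <- lapply(seq_along(genes), function(gi) {
    g <- genes[gi]
    d <- det[det$gene == g, , drop = FALSE]
    vids <- d$variant_id
    sig <- if (length(vids) > 1L) {
      G <- study$genotypes[, vids, drop = FALSE]
      cg <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))
      cg[!is.finite(cg)] <- 0
      diag(cg) <- 1
      cg
    } else {
      diag(1)
    }
    gp <- gene_based_p(pmin(d$p, 1), sig, n_sims = n_sims,
                       seed = if (is.null(seed)) NULL
                              else derive_seed(seed, gi))
    data.frame(gene = g, k_markers = gp$k, t_obs = gp$t_obs,
               p_gene = gp$p_gene, n_sims = n_sims,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
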