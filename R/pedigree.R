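#' Construct and validate a pedigree
#'
#' A pedigree is a data frame of individual records linked by parent
#' pointers. Validation enforces the conventions the rest of the package
#' relies on: globally unique individual ids, both parents present or both
#' absent (half-founders are rejected; add a dummy founder upstream),
#' father male / mother female, parents in the same family, and an acyclic
#' ancestry graph.
#'
#' @param fid family identifier (character or coercible).
#' @param iid individual identifier, unique across the whole pedigree.
#' @param father,mother parental iids; `NA` (or `"0"`) for founders.
#' @param sex 1 = male, 2 = female (PED convention).
#' @return A `data.frame` of class `"pedigree"` with columns
#'   `fid, iid, father, mother, sex`, ordered so that every parent precedes
#'   its children (ancestors-first), plus a logical `founder` column.
#' @examples
#' trio <- pedigree(fid = c(1, 1, 1), iid = c("p1", "p2", "c1"),
#'                  father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"),
#'                  sex = c(1, 2, 1))
#' kinship_matrix(trio)["p1", "c1"]  # 0.25
#' @export
pedigree <- function(fid, iid, father, mother, sex) {
  iid <- as.character(iid)
  fid <- as.character(fid)
  if (length(fid) == 1L) fid <- rep(fid, length(iid))
  father <- as.character(father)
  mother <- as.character(mother)
  father[father %in% c("0", "")] <- NA_character_
  mother[mother %in% c("0", "")] <- NA_character_
  sex <- as.integer(sex)

  n <- length(iid)
  if (any(lengths(list(fid, father, mother, sex)) != n)) {
    stopf("pedigree columns must have equal length")
  }
  if (anyDuplicated(iid)) {
    stopf("duplicated individual id(s): %s",
          paste(unique(iid[duplicated(iid)]), collapse = ", "))
  }
  if (!all(sex %in% c(1L, 2L))) {
    stopf("sex must be coded 1 (male) / 2 (female)")
  }
  half <- xor(is.na(father), is.na(mother))
  if (any(half)) {
    stopf("half-founders not supported (one parent known): %s",
          paste(iid[half], collapse = ", "))
  }
  known <- !is.na(father)
  missing_parent <- setdiff(c(father[known], mother[known]), iid)
  if (length(missing_parent)) {
    stopf("unknown parent id(s): %s", paste(missing_parent, collapse = ", "))
  }
  idx <- match(iid, iid)  # identity; used via match below
  fi <- match(father, iid)
  mi <- match(mother, iid)
  if (any(sex[fi[known]] != 1L)) {
    stopf("father of %s is not male",
          paste(iid[known][sex[fi[known]] != 1L], collapse = ", "))
  }
  if (any(sex[mi[known]] != 2L)) {
    stopf("mother of %s is not female",
          paste(iid[known][sex[mi[known]] != 2L], collapse = ", "))
  }
  same_fam <- fid[fi[known]] == fid[known] & fid[mi[known]] == fid[known]
  if (!all(same_fam)) {
    stopf("parents in a different family than child: %s",
          paste(iid[known][!same_fam], collapse = ", "))
  }

  ord <- ped_topo_order(iid, fi, mi)
  ped <- data.frame(fid = fid, iid = iid, father = father, mother = mother,
                    sex = sex, stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(ped) <- NULL
  ped$founder <- is.na(ped$father)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort over the parent -> child graph; errors on cycles,
# naming the individuals involved.
ped_topo_order <- function(iid, fi, mi) {
  n <- length(iid)
  indeg <- integer(n)
  indeg[!is.na(fi)] <- indeg[!is.na(fi)] + 1L
  indeg[!is.na(mi)] <- indeg[!is.na(mi)] + 1L
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(fi[i])) children[[fi[i]]] <- c(children[[fi[i]]], i)
    if (!is.na(mi[i])) children[[mi[i]]] <- c(children[[mi[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stopf("pedigree contains an ancestry cycle involving: %s",
          paste(iid[setdiff(seq_len(n), ord)], collapse = ", "))
  }
  ord
}

#' Pedigree kinship matrix
#'
#' Exact kinship coefficients by the standard tabular recursion processed
#' ancestors-first: founders are mutually unrelated with phi(i,i) = 1/2;
#' for a non-founder i with parents f, m, phi(i,j) = (phi(f,j) + phi(m,j))/2
#' for any earlier j and phi(i,i) = (1 + phi(f,m))/2. Individuals in
#' different families have kinship exactly 0. The additive (numerator)
#' relationship matrix used by the variance-components engine is `2 * phi`.
#'
#' @param ped a [pedigree()].
#' @return symmetric numeric matrix with iid dimnames.
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  iid <- ped$iid
  fi <- match(ped$father, iid)
  mi <- match(ped$mother, iid)
  phi <- matrix(0, n, n, dimnames = list(iid, iid))
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      j <- seq_len(i - 1L)
      v <- (phi[fi[i], j] + phi[mi[i], j]) / 2
      phi[i, j] <- v
      phi[j, i] <- v
      phi[i, i] <- (1 + phi[fi[i], mi[i]]) / 2
    }
  }
  phi
}

#' Classify variants by minor allele frequency
#'
#' Appends/overwrites the `rarity` column: `rare` when 0 < maf < threshold,
#' `common` when maf >= threshold, `monomorphic` when maf = 0. Monomorphic
#' variants are excluded from burden and association computations downstream
#' and surface as `NCV` statuses.
#'
#' @param variants data frame with at least `variant_id` and `maf`.
#' @param threshold MAF threshold separating rare from common (default 0.01).
#' @return the variant table with a `rarity` factor-free character column.
#' @export
classify_variants <- function(variants, threshold = 0.01) {
  stopifnot(is.data.frame(variants), "maf" %in% names(variants))
  maf <- variants$maf
  if (any(is.na(maf)) || any(maf < 0 | maf > 0.5)) {
    stopf("maf must lie in [0, 0.5]")
  }
  variants$rarity <- ifelse(maf == 0, "monomorphic",
                            ifelse(maf < threshold, "rare", "common"))
  variants
}

#' Mendelian consistency check
#'
#' For each non-founder genotyped together with both parents, a minor-allele
#' count is possible iff it lies between the number of parents homozygous
#' for the minor allele and the number of parents carrying at least one
#' minor allele. Variants or trio members with missing genotypes are
#' skipped.
#'
#' @param ped a [pedigree()].
#' @param genotypes individuals x variants integer matrix of minor-allele
#'   counts (0/1/2, `NA` missing) with iid rownames.
#' @return data frame of violations with columns `iid`, `variant_id`;
#'   zero rows when consistent.
#' @export
validate_mendelian <- function(ped, genotypes) {
  stopifnot(inherits(ped, "pedigree"), is.matrix(genotypes))
  kids <- ped[!ped$founder, , drop = FALSE]
  kids <- kids[kids$iid %in% rownames(genotypes) &
                 kids$father %in% rownames(genotypes) &
                 kids$mother %in% rownames(genotypes), , drop = FALSE]
  out_iid <- character(0)
  out_var <- character(0)
  vids <- colnames(genotypes) %||% as.character(seq_len(ncol(genotypes)))
  for (r in seq_len(nrow(kids))) {
    gc <- genotypes[kids$iid[r], ]
    gf <- genotypes[kids$father[r], ]
    gm <- genotypes[kids$mother[r], ]
    ok <- !(is.na(gc) | is.na(gf) | is.na(gm))
    cmin <- (gf == 2L) + (gm == 2L)
    cmax <- (gf >= 1L) + (gm >= 1L)
    bad <- ok & (gc < cmin | gc > cmax)
    if (any(bad)) {
      out_iid <- c(out_iid, rep(kids$iid[r], sum(bad)))
      out_var <- c(out_var, vids[bad])
    }
  }
  data.frame(iid = out_iid, variant_id = out_var, stringsAsFactors = FALSE)
}
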