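#' Read a PED-like pedigree + genotype file
#'
#' Whitespace-delimited rows: `FID IID FATHER MOTHER SEX PHENO` followed by
#' two allele columns per variant. `0` denotes a missing parent or a missing
#' allele. Alleles are recoded to minor-allele counts: the minor allele of
#' a variant is the less frequent allele label over all genotyped
#' individuals in the file at hand; at a 0.5/0.5 tie the lexicographically
#' smaller label is kept as the reference (major) allele, so the larger
#' label is counted.
#'
#' @param path PED file path.
#' @param variants optional variant table supplying `variant_id` column
#'   names (in file order); defaults to `V1..Vk`.
#' @return list with elements `pedigree` (a [pedigree()]) and `genotypes`
#'   (individuals x variants integer matrix, `NA` = missing).
#' @export
read_ped <- function(path, variants = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1L])[1L]
    stopf("ragged PED file: line %d has %d fields, expected %d",
          bad, ncols[bad], ncols[1L])
  }
  nc <- ncols[1L]
  if (nc < 6L || (nc - 6L) %% 2L != 0L) {
    stopf("PED file must have 6 + 2*n_variants columns; found %d", nc)
  }
  m <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  n_var <- (nc - 6L) / 2L
  ped <- pedigree(fid = m[, 1L], iid = m[, 2L], father = m[, 3L],
                  mother = m[, 4L], sex = m[, 5L])

  vids <- if (!is.null(variants)) {
    stopifnot(nrow(variants) == n_var)
    variants$variant_id
  } else {
    paste0("V", seq_len(n_var))
  }
  geno <- matrix(NA_integer_, nrow(m), n_var,
                 dimnames = list(m[, 2L], vids))
  if (n_var > 0L) {
    for (v in seq_len(n_var)) {
      a1 <- m[, 6L + 2L * v - 1L]
      a2 <- m[, 6L + 2L * v]
      miss <- a1 == "0" | a2 == "0"
      alleles <- c(a1, a2)
      alleles <- alleles[alleles != "0"]
      tab <- sort(table(alleles))
      minor <- if (length(tab) == 0L) {
        NA_character_
      } else if (length(tab) == 1L) {
        # only one allele observed in founders: any other label is minor
        other <- setdiff(unique(c(a1, a2)), c("0", names(tab)))
        if (length(other)) other[1L] else NA_character_
      } else if (tab[1L] == tab[2L]) {
        # tie: lexicographically smaller label stays the reference
        max(names(tab)[1:2])
      } else {
        names(tab)[1L]
      }
      cnt <- if (is.na(minor)) {
        integer(nrow(m))
      } else {
        (a1 == minor) + (a2 == minor)
      }
      cnt[miss] <- NA_integer_
      geno[, v] <- cnt
    }
  }
  geno <- geno[ped$iid, , drop = FALSE]
  list(pedigree = ped, genotypes = geno)
}

#' Write a simulated study to disk
#'
#' Emits the four plain-text files the readers consume: `study.ped`
#' (pedigree + two allele columns per variant, major = 1, minor = 2,
#' missing = 0), `variants.tsv`, `phenotypes.tsv` and `truth.tsv`. The PED
#' phenotype column carries affection status coded 1 = unaffected,
#' 2 = affected.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, a named character vector of file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create directory '%s'", dir)
  }
  ped <- study$pedigree
  G <- study$genotypes[ped$iid, , drop = FALSE]
  phen <- study$phenotypes
  aff <- phen$Affected[match(ped$iid, phen$IID)] + 1L

  a1 <- ifelse(is.na(G), "0", ifelse(G >= 1L, "2", "1"))
  a2 <- ifelse(is.na(G), "0", ifelse(G == 2L, "2", "1"))
  allele_cols <- matrix("", nrow(G), 2L * ncol(G))
  allele_cols[, seq(1L, 2L * ncol(G), by = 2L)] <- a1
  allele_cols[, seq(2L, 2L * ncol(G), by = 2L)] <- a2
  ped_mat <- cbind(ped$fid, ped$iid,
                   ifelse(is.na(ped$father), "0", ped$father),
                   ifelse(is.na(ped$mother), "0", ped$mother),
                   ped$sex, aff, allele_cols)
  paths <- c(ped = file.path(dir, "study.ped"),
             variants = file.path(dir, "variants.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeLines(apply(ped_mat, 1L, paste, collapse = " "), paths["ped"])
  utils::write.table(study$variants, paths["variants"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(phen, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read the companion TSV tables of a written study
#'
#' @param dir directory produced by [write_study()].
#' @return list with `pedigree`, `genotypes`, `variants`, `phenotypes`,
#'   `truth` mirroring the in-memory study.
#' @export
read_study <- function(dir) {
  variants <- utils::read.table(file.path(dir, "variants.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE,
                                colClasses = c(variant_id = "character",
                                               gene = "character"))
  pg <- read_ped(file.path(dir, "study.ped"), variants = variants)
  phen <- utils::read.table(file.path(dir, "phenotypes.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c(IID = "character"))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = c(gene = "character",
                                            variant_id = "character"))
  list(pedigree = pg$pedigree, genotypes = pg$genotypes,
       variants = variants, phenotypes = phen, truth = truth)
}

#' Export a kinship matrix as square TSV with an IID header row/column
#' @param phi kinship matrix from [kinship_matrix()].
#' @param path output file.
#' @export
write_kinship <- function(phi, path) {
  df <- data.frame(IID = rownames(phi), phi, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
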