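# Pathway over-representation and confusion-matrix evaluation against the
# causal-gene truth set.

#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `x` annotated-pathway genes when `n`
#' genes are sampled without replacement from a universe of `N` genes of
#' which `K` belong to the pathway:
#' p = sum_{k = x}^{min(K, n)} C(K,k) C(N-K, n-k) / C(N, n),
#' accumulated in log space for stability at genome-scale counts.
#'
#' @param x overlap count (detected genes in the pathway).
#' @param K pathway size within the universe.
#' @param n number of detected genes within the universe.
#' @param N universe size (genes annotated in at least one pathway).
#' @return upper-tail p-value; `x = 0` gives exactly 1.
#' @export
hypergeom_p <- function(x, K, n, N) {
  if (any(c(x, K, n, N) < 0) || K > N || n > N || x > min(K, n)) {
    stopf("inconsistent counts: need 0 <= x <= min(K, n) <= N")
  }
  if (x == 0) return(1)
  k <- seq(x, min(K, n))
  logp <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  mx <- max(logp)
  min(1, exp(mx) * sum(exp(logp - mx)))
}

#' Read pathways from a GMT file
#'
#' One pathway per line: id, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors (pathway id -> genes), with the
#'   descriptions as a `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stopf("GMT line %d has fewer than 3 fields", which(short)[1L])
  }
  pw <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(pw) <- vapply(fields, `[`, character(1), 1L)
  attr(pw, "description") <- vapply(fields, `[`, character(1), 2L)
  pw
}

#' Hypergeometric pathway over-representation
#'
#' The universe is restricted to genes annotated in at least one pathway
#' (only about a third of genes typically are); detected genes outside the
#' annotation are excluded from both `n` and `N`. No multiple-testing
#' correction is applied: a pathway is enriched when its raw p-value falls
#' below `alpha`.
#'
#' @param detected character vector of detected genes.
#' @param pathways named list of gene sets (see [read_gmt()]).
#' @param alpha enrichment threshold (default 0.05).
#' @return data frame: pathway, size, overlap, p, enriched; plus
#'   attributes `n_annotated_detected` and `universe_size`.
#' @export
enrich_pathways <- function(detected, pathways, alpha = 0.05) {
  if (!length(pathways)) stopf("empty pathway table")
  universe <- unique(unlist(pathways, use.names = FALSE))
  N <- length(universe)
  det <- intersect(unique(detected), universe)
  n <- length(det)
  res <- data.frame(
    pathway = names(pathways),
    size = vapply(pathways, length, integer(1)),
    overlap = vapply(pathways, function(g) length(intersect(g, det)),
                     integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  res$p <- mapply(hypergeom_p, res$overlap, res$size,
                  MoreArgs = list(n = n, N = N))
  res$enriched <- res$p < alpha
  attr(res, "n_annotated_detected") <- n
  attr(res, "universe_size") <- N
  res
}

#' Confusion-matrix evaluation of detected genes against the causal set
#'
#' Exact set arithmetic over the gene universe: TP = detected causal,
#' FP = detected non-causal, FN = missed causal, TN the rest.
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), ppv = TP/(TP+FP),
#' npv = TN/(TN+FN); a zero denominator yields `NA`, never 0.
#'
#' @param detected detected genes (subset of `universe`).
#' @param causal causal genes (must be a subset of `universe`).
#' @param universe all evaluable genes (e.g. every gene in the variant
#'   table, NCV genes included as non-detected).
#' @return list of class `"confusion_metrics"`: counts TP, FP, TN, FN and
#'   rates sensitivity, specificity, ppv, npv.
#' @export
confusion <- function(detected, causal, universe) {
  universe <- unique(universe)
  causal <- unique(causal)
  detected <- unique(detected)
  if (!all(causal %in% universe)) {
    stopf("causal genes outside the universe: %s",
          paste(setdiff(causal, universe), collapse = ", "))
  }
  if (!all(detected %in% universe)) {
    stopf("detected genes outside the universe: %s",
          paste(setdiff(detected, universe), collapse = ", "))
  }
  tp <- length(intersect(detected, causal))
  fp <- length(setdiff(detected, causal))
  fn <- length(setdiff(causal, detected))
  tn <- length(universe) - tp - fp - fn
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 ppv = rate(tp, tp + fp),
                 npv = rate(tn, tn + fn)),
            class = "confusion_metrics")
}

#' Confusion metrics from printed counts
#'
#' Convenience constructor when only the headline counts are known:
#' universe size, number of causal genes, total detected, and how many of
#' the detected are causal.
#'
#' @param n_universe,n_causal,n_detected,n_detected_causal integer counts.
#' @return a `"confusion_metrics"` object (see [confusion()]).
#' @export
confusion_from_counts <- function(n_universe, n_causal, n_detected,
                                  n_detected_causal) {
  stopifnot(n_detected_causal <= n_causal, n_detected_causal <= n_detected,
            n_detected <= n_universe, n_causal <= n_universe)
  universe <- paste0("g", seq_len(n_universe))
  causal <- universe[seq_len(n_causal)]
  detected <- c(causal[seq_len(n_detected_causal)],
                universe[n_causal + seq_len(n_detected - n_detected_causal)])
  confusion(detected, causal, universe)
}

#' Truncate a rate to a fixed number of decimals
#'
#' Truncation toward zero (floor on the scaled value), not rounding:
#' 1/15 = 0.0666... prints as "0.066" and 1/19 = 0.0526... as "0.052",
#' matching the reporting style this package reproduces.
#'
#' @param x numeric rate(s) in [0, 1] (NA passed through as "NA").
#' @param digits decimals kept (default 3).
#' @return character vector.
#' @export
format_rate <- function(x, digits = 3) {
  out <- ifelse(is.na(x), "NA",
                formatC(trunc(x * 10^digits) / 10^digits,
                        format = "f", digits = digits))
  as.character(out)
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("sens %s  spec %s  ppv %s  npv %s\n",
              format_rate(x$sensitivity), format_rate(x$specificity),
              format_rate(x$ppv), format_rate(x$npv)))
  invisible(x)
}
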