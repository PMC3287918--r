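#' Run the eight detection approaches end-to-end
#'
#' Simulates (or takes) a family study, runs the selected approaches,
#' evaluates each detected-gene set against the causal truth set over the
#' whole gene universe, and optionally scores pathway enrichment and
#' VEGAS-style gene-based p-values. Everything is deterministic given the
#' study/config seed.
#'
#' Approaches: A = rare-allele sum burden, B = rare nonsynonymous carrier
#' indicator, C = common minor-allele count (all three as covariates in the
#' polygenic model of affection), D = per-family single-SNP polygenic
#' screen; E/F = common-variant family-based association (linear /
#' variance-components), G/H = the same on the rare panel.
#'
#' @param study a [simulate_study()] result (or compatible list); if NULL,
#'   one is simulated from `config`.
#' @param config a [sim_config()] used when `study` is NULL.
#' @param approaches subset of LETTERS[1:8].
#' @param base_covariates fixed-effect phenotype columns (default Age, Q4).
#' @param alpha detection threshold (default 0.05, uncorrected).
#' @param pathways optional named list of gene sets for enrichment.
#' @param gene_based also compute gene-based scores for the association
#'   approaches E-H present in `approaches`.
#' @param n_sims Monte-Carlo draws for gene-based scores.
#' @param out_dir if non-NULL, write `detections.tsv`, `metrics.tsv`,
#'   `causal_p.tsv` (and `enrichment.tsv`, `genescores.tsv` when computed)
#'   there.
#' @param seed seed for the gene-based Monte Carlo (simulation randomness
#'   is governed by the study's own config seed).
#' @return list of class `"pedscreen_run"`: `detections` (per-approach
#'   list), `metrics` (data frame, approaches x rates), `causal_p`
#'   (causal gene x approach character matrix with NCV/nonconverged
#'   sentinels), `enrichment`, `genescores`, `alpha`, `universe`.
#' @export
run_all <- function(study = NULL, config = NULL,
                    approaches = LETTERS[1:8],
                    base_covariates = c("Age", "Q4"), alpha = 0.05,
                    pathways = NULL, gene_based = FALSE, n_sims = 1e4,
                    out_dir = NULL, seed = 1L) {
  stopifnot(length(approaches) >= 1L, all(approaches %in% LETTERS[1:8]),
            alpha > 0, alpha < 1)
  if (is.null(study)) {
    study <- simulate_study(config %||% sim_config())
  }
  universe <- unique(study$variants$gene)
  causal <- unique(study$truth$gene)

  runners <- list(
    A = function() screen_genes(study, "A", base_covariates, alpha),
    B = function() screen_genes(study, "B", base_covariates, alpha),
    C = function() screen_genes(study, "C", base_covariates, alpha),
    D = function() screen_per_family(study, base_covariates, alpha),
    E = function() assoc_screen(study, "common", "linear",
                                base_covariates, alpha),
    F = function() assoc_screen(study, "common", "varcomp",
                                base_covariates, alpha),
    G = function() assoc_screen(study, "rare", "linear",
                                base_covariates, alpha),
    H = function() assoc_screen(study, "rare", "varcomp",
                                base_covariates, alpha))
  detections <- lapply(approaches, function(a) runners[[a]]())
  names(detections) <- approaches

  metrics <- do.call(rbind, lapply(approaches, function(a) {
    cm <- confusion(detected_genes(detections[[a]]), causal, universe)
    data.frame(approach = a, TP = cm$TP, FP = cm$FP, TN = cm$TN,
               FN = cm$FN, sensitivity = cm$sensitivity,
               specificity = cm$specificity, ppv = cm$ppv, npv = cm$npv,
               stringsAsFactors = FALSE)
  }))

  causal_p <- causal_p_table(detections, causal)

  enrichment <- NULL
  if (!is.null(pathways)) {
    enrichment <- lapply(detections, function(d) {
      enrich_pathways(detected_genes(d), pathways, alpha)
    })
  }
  genescores <- NULL
  gb <- intersect(approaches, c("E", "F", "G", "H"))
  if (gene_based && length(gb)) {
    genescores <- lapply(stats::setNames(gb, gb), function(a) {
      gene_scores(detections[[a]], study, n_sims = n_sims, seed = seed)
    })
  }

  run <- structure(list(detections = detections, metrics = metrics,
                        causal_p = causal_p, enrichment = enrichment,
                        genescores = genescores, alpha = alpha,
                        universe = universe, causal = causal),
                   class = "pedscreen_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Per-causal-gene best p-value per approach, with sentinels for genes that
# were untestable (NCV) or whose models failed (nonconverged).
causal_p_table <- function(detections, causal) {
  causal <- sort(causal)
  out <- matrix("NCV", length(causal), length(detections),
                dimnames = list(causal, names(detections)))
  for (a in names(detections)) {
    d <- detections[[a]]
    for (g in causal) {
      rows <- d[d$gene == g, , drop = FALSE]
      if (!nrow(rows)) next
      if (all(is.na(rows$p))) {
        out[g, a] <- if (any(rows$status == "nonconverged"))
          "nonconverged" else "NCV"
      } else {
        out[g, a] <- formatC(min(rows$p, na.rm = TRUE), format = "g",
                             digits = 3)
      }
    }
  }
  out
}

write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  det <- do.call(rbind, run$detections)
  utils::write.table(det, file.path(dir, "detections.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cp <- data.frame(gene = rownames(run$causal_p), run$causal_p,
                   check.names = FALSE)
  utils::write.table(cp, file.path(dir, "causal_p.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(run$enrichment)) {
    en <- do.call(rbind, lapply(names(run$enrichment), function(a) {
      cbind(approach = a, run$enrichment[[a]])
    }))
    utils::write.table(en, file.path(dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$genescores)) {
    gs <- do.call(rbind, lapply(names(run$genescores), function(a) {
      cbind(approach = a, run$genescores[[a]])
    }))
    utils::write.table(gs, file.path(dir, "genescores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Markdown summary of a pipeline run
#'
#' @param run a [run_all()] result.
#' @param path optional file to write the report to.
#' @return the report as a character vector of lines (invisibly when
#'   written to `path`).
#' @export
make_report <- function(run, path = NULL) {
  stopifnot(inherits(run, "pedscreen_run"))
  m <- run$metrics
  lines <- c(
    "# Gene-detection comparison report", "",
    sprintf("Universe: %d genes; causal: %d; alpha = %g (uncorrected).",
            length(run$universe), length(run$causal), run$alpha), "",
    "## Detection metrics", "",
    "| approach | detected | TP | sensitivity | specificity | PPV | NPV |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %d | %d | %s | %s | %s | %s |", m$approach,
            m$TP + m$FP, m$TP, format_rate(m$sensitivity),
            format_rate(m$specificity), format_rate(m$ppv),
            format_rate(m$npv)),
    "", "## Best p-value per causal gene", "",
    paste0("| gene | ", paste(colnames(run$causal_p), collapse = " | "),
           " |"),
    paste0("|", paste(rep("---", ncol(run$causal_p) + 1L), collapse = "|"),
           "|"),
    sprintf("| %s | %s |", rownames(run$causal_p),
            apply(run$causal_p, 1L, paste, collapse = " | ")))
  if (!is.null(run$enrichment)) {
    lines <- c(lines, "", "## Enriched pathways", "")
    for (a in names(run$enrichment)) {
      en <- run$enrichment[[a]]
      hits <- en$pathway[en$enriched]
      lines <- c(lines, sprintf("- %s: %d enriched (%s)", a, length(hits),
                                if (length(hits))
                                  paste(hits, collapse = ", ")
                                else "none"))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
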