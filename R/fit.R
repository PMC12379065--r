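#' Fit the cell-specific causal network entropy model
#'
#' The main entry point: builds every cell's causal network over the
#' background edges, computes the gene-by-cell local entropy matrix,
#' the per-cell and per-stage scores, tests each stage against its
#' predecessor, and (when a pre-transition stage is found) extracts
#' signaling genes, their largest connected subgraph, and dark genes.
#'
#' @param dataset A [ccne_dataset] (or a gene-by-cell matrix together
#'   with `stages`).
#' @param network A [ccne_network] background (e.g. a PPI network).
#' @param stages,stage_order Only used when `dataset` is a bare matrix.
#' @param top_fraction Fraction of genes summed into each cell's score
#'   (default 0.05).
#' @param signaling_fraction Fraction of genes selected as signaling
#'   genes at the detected stage (default = `top_fraction`).
#' @param alpha Family-wise significance level for stage detection
#'   (default 0.05).
#' @param plan A [neighbor_plan()].
#' @param reference,test_side,correction,calibrate_reference Passed to
#'   [detect_critical_stage()].
#' @param dark_genes Logical; test the signaling genes for dark-gene
#'   status when a stage is detected (default `TRUE`).
#' @param dark_test `"wilcoxon"` (default) or `"t"`.
#' @return An object of class `ccne_fit` with components `lh` (local
#'   entropy matrix), `scores` ([ccne_scores]), `report`
#'   ([detect_critical_stage()] output), `signaling`, `dark`
#'   (or `NULL` when nothing was detected), `config`, and `call`.
#' @examples
#' circ <- build_default_circuit()
#' set.seed(7)
#' ds <- generate_sweep(circ, sim_config(n_cells_per_s = 20))
#' fit <- ccne(ds, complete_network(rownames(ds$values)))
#' fit
#' summary(fit)
#' @export
ccne <- function(dataset, network, stages = NULL, stage_order = NULL,
                 top_fraction = 0.05, signaling_fraction = top_fraction,
                 alpha = 0.05, plan = neighbor_plan(),
                 reference = "previous", test_side = "reference_cells",
                 correction = "sidak", calibrate_reference = TRUE,
                 dark_genes = TRUE, dark_test = "wilcoxon") {
  cl <- match.call()
  if (!inherits(dataset, "ccne_dataset")) {
    if (is.null(stages))
      stop("'stages' is required when 'dataset' is a bare matrix")
    dataset <- ccne_dataset(dataset, stages, stage_order)
  }
  stopifnot(inherits(network, "ccne_network"))
  lh <- local_entropy_matrix(dataset, network, plan)
  scores <- ccne_scores(lh, top_fraction)
  report <- detect_critical_stage(scores, alpha = alpha,
                                  reference = reference,
                                  test_side = test_side,
                                  correction = correction,
                                  calibrate_reference = calibrate_reference)
  signaling <- dark <- NULL
  if (!is.na(report$detected)) {
    signaling <- select_signaling_genes(lh, network, report$detected,
                                        signaling_fraction)
    t_idx <- match(report$detected, scores$stage_order)
    before <- scores$stage_order[t_idx - 1L]
    if (dark_genes &&
        sum(dataset$stages == before) >= 3L &&
        sum(dataset$stages == report$detected) >= 3L)
      dark <- identify_dark_genes(dataset, lh, signaling$genes, before,
                                  report$detected, test = dark_test)
  }
  structure(list(lh = lh, scores = scores, report = report,
                 signaling = signaling, dark = dark,
                 n_genes = nrow(dataset$values),
                 n_analyzed = nrow(lh), n_cells = ncol(dataset$values),
                 stage_order = dataset$stage_order,
                 config = list(top_fraction = top_fraction,
                               signaling_fraction = signaling_fraction,
                               alpha = alpha, plan = unclass(plan),
                               reference = reference,
                               test_side = test_side,
                               correction = correction,
                               calibrate_reference = calibrate_reference,
                               log_base = "natural",
                               version = as.character(packageVersion("ccne"))),
                 call = cl),
            class = "ccne_fit")
}

#' @export
print.ccne_fit <- function(x, ...) {
  cat("Cell-specific causal network entropy fit\n")
  cat(sprintf("  %d cells, %d/%d genes analyzed, %d stages\n",
              x$n_cells, x$n_analyzed, x$n_genes, length(x$stage_order)))
  cat("  H_t:", paste(sprintf("%s=%.4g", names(x$scores$H_t), x$scores$H_t),
                      collapse = "  "), "\n")
  if (is.na(x$report$detected))
    cat("  No pre-transition stage detected.\n")
  else
    cat("  Detected pre-transition stage:", x$report$detected, "\n")
  invisible(x)
}

#' @export
summary.ccne_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ccne_fit")
}

#' @export
print.summary.ccne_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\n")
  print(f$report)
  if (!is.null(f$signaling)) { cat("\n"); print(f$signaling) }
  if (!is.null(f$dark)) {
    cat("\nDark-gene calls (before vs pre-transition):\n")
    print(f$dark, row.names = FALSE)
  }
  invisible(x)
}

#' Plot the stage score series of a fit
#'
#' Draws `H_t` against stage order and marks the detected
#' pre-transition stage, the sharp rise of which is the early-warning
#' signal.
#'
#' @param x A `ccne_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ccne_fit <- function(x, ...) {
  Ht <- x$scores$H_t
  n <- length(Ht)
  plot(seq_len(n), Ht, type = "b", xaxt = "n", xlab = "stage",
       ylab = expression(H[t]), pch = 16, ...)
  axis(1, at = seq_len(n), labels = names(Ht))
  if (!is.na(x$report$detected)) {
    i <- match(x$report$detected, names(Ht))
    points(i, Ht[i], col = "red", pch = 16, cex = 1.6)
    abline(v = i, col = "red", lty = 2)
    mtext(paste("detected:", x$report$detected), col = "red", cex = 0.8)
  }
  invisible(x)
}
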