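#' Leave-one-out standard-deviation term
#'
#' The fluctuation contribution of one cell to one gene: the absolute
#' difference between the sample SD of the gene over all `M` cells of
#' the group and the sample SD with cell `l` removed.  Cells lying far
#' from the bulk of the distribution contribute large terms; for a
#' constant gene the term is 0.  Sample SDs use the `M - 1` (and
#' `M - 2`) denominator.
#'
#' @param gene_values Numeric vector of one gene's expression across
#'   the `M >= 3` cells of a group.
#' @param l Cell index within the group.
#' @return Scalar `|SD(E) - SD(E without cell l)| >= 0`.
#' @examples
#' loo_sd_term(c(1, 2, 3, 4), 4)  # == abs(sd(1:4) - sd(1:3))
#' @export
loo_sd_term <- function(gene_values, l) {
  loo_sd_terms(gene_values)[l]
}

#' @rdname loo_sd_term
#' @return `loo_sd_terms()`: the vector of terms for all `M` cells.
#' @export
loo_sd_terms <- function(gene_values) {
  M <- length(gene_values)
  if (M < 3L)
    stop("stage group too small for leave-one-out SD (M = ", M,
         ", need M >= 3)")
  s1 <- sum(gene_values)
  s2 <- sum(gene_values^2)
  sd_all <- sqrt(max(0, (s2 - s1^2 / M) / (M - 1)))
  s1l <- s1 - gene_values
  s2l <- s2 - gene_values^2
  var_loo <- (s2l - s1l^2 / (M - 1)) / (M - 2)
  abs(sd_all - sqrt(pmax(0, var_loo)))
}

#' Local entropy of a localized causal network
#'
#' The entropy of the normalized outgoing weights of one gene's
#' localized network, averaged over its `Q` outgoing edges and scaled
#' by the cell's leave-one-out SD term:
#' `LH = -(1/Q) * sum_j P_j log P_j * SD_l`, with
#' `P_j = w_j / sum_i w_i`.  `Q <= 1` gives `LH = 0` (a single-outcome
#' distribution has zero entropy; no outgoing causality scores zero).
#'
#' @param weights Positive outgoing edge weights (may be empty), or a
#'   localized-network record from [localized_networks()].
#' @param sd_term Non-negative scalar from [loo_sd_term()].
#' @return Scalar `LH >= 0`.
#' @examples
#' local_ccne(c(3, 1), sd_term = 2)   # -(1/2) sum(p log p) * 2
#' local_ccne(rep(1, 4), sd_term = 1) # log(4)/4
#' @export
local_ccne <- function(weights, sd_term) {
  if (is.list(weights)) weights <- weights$weights
  stopifnot(sd_term >= 0)
  Q <- length(weights)
  if (Q <= 1L || sd_term == 0) return(0)
  if (any(weights <= 0)) stop("localized-network weights must be positive")
  p <- weights / sum(weights)
  -(1 / Q) * sum(p * log(p)) * sd_term
}

#' Gene-by-cell matrix of local causal-network entropies
#'
#' Runs the whole per-cell pipeline: per stage group, nearest-neighbour
#' sets for every analyzed gene, cross-map weights for every background
#' edge, localized networks, leave-one-out SD terms, and the local
#' entropy for every (gene, cell).  Genes absent from the background
#' network are excluded (recorded in the `excluded_genes` attribute).
#'
#' @param dataset A [ccne_dataset].
#' @param background A [ccne_network].
#' @param plan A [neighbor_plan()].
#' @return Numeric matrix (analyzed genes x all cells) of local CCNE
#'   values, with attributes `plan`, `k_of_stage`, `excluded_genes`,
#'   `stages` (the dataset's stage factor) and `stage_order`.
#' @export
local_entropy_matrix <- function(dataset, background,
                                 plan = neighbor_plan()) {
  stopifnot(inherits(dataset, "ccne_dataset"),
            inherits(background, "ccne_network"))
  genes <- match_genes(dataset, background)
  excluded <- setdiff(rownames(dataset$values), genes)
  n_cells <- ncol(dataset$values)
  lh <- matrix(0, length(genes), n_cells,
               dimnames = list(genes, colnames(dataset$values)))
  ed <- background$edges
  ed <- ed[ed[, 1] %in% genes & ed[, 2] %in% genes, , drop = FALSE]
  pairs <- cbind(match(ed[, 1], genes), match(ed[, 2], genes))
  groups <- if (plan$scope == "stage")
    split(seq_len(n_cells), dataset$stages)
  else list(all = seq_len(n_cells))
  k_of_stage <- integer(0)
  for (gi in seq_along(groups)) {
    cells <- groups[[gi]]
    M <- length(cells)
    if (M < 3L)
      stop("stage group '", names(groups)[gi], "' too small (M = ", M,
           ", need M >= 3)")
    mat <- dataset$values[genes, cells, drop = FALSE]
    sdt <- t(apply(mat, 1, loo_sd_terms))
    if (nrow(pairs)) {
      gw <- group_weights(mat, pairs, plan)
      k_of_stage[names(groups)[gi]] <- gw$ks[1]
      for (g in seq_along(genes)) {
        rows <- which(pairs[, 1] == g | pairs[, 2] == g)
        if (!length(rows)) next
        W <- gw$w[rows, , drop = FALSE]      # |adj| x M
        for (l in seq_len(M)) {
          wv <- W[, l]
          wv <- wv[wv > 0]
          lh[g, cells[l]] <- local_ccne(wv, sdt[g, l])
        }
      }
    }
  }
  structure(lh, plan = plan, k_of_stage = k_of_stage,
            excluded_genes = excluded, stages = dataset$stages,
            stage_order = dataset$stage_order)
}

#' Cell-specific score from one cell's local entropies
#'
#' The cell score is the sum of the `S` largest local entropies in the
#' cell's column, `S = max(1, ceiling(top_fraction * G))` with `G` the
#' analyzed gene count.  Ties at the cutoff are broken by gene ID.
#'
#' @param lh_column Named numeric vector: one cell's local entropies.
#' @param top_fraction Fraction of genes summed (default 0.05, "top 5%").
#' @return List with `H` (the score) and `top_genes` (character).
#' @export
cell_ccne <- function(lh_column, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  G <- length(lh_column)
  if (G == 0L) stop("empty local-entropy column")
  if (is.null(names(lh_column))) names(lh_column) <- seq_len(G)
  S <- max(1L, ceiling(top_fraction * G))
  ord <- order(-lh_column, names(lh_column))[seq_len(S)]
  list(H = sum(lh_column[ord]), top_genes = names(lh_column)[ord])
}

#' Stage-level score series
#'
#' Arithmetic mean of the per-cell scores over the cells of each stage,
#' in stage order.
#'
#' @param H Numeric vector of per-cell scores.
#' @param stages Factor/character stage of each cell.
#' @param stage_order Stage labels in temporal order.
#' @return Named numeric vector `H_t` aligned to `stage_order`.
#' @export
stage_ccne <- function(H, stages, stage_order = levels(factor(stages))) {
  stages <- factor(as.character(stages), levels = stage_order)
  if (anyNA(stages)) stop("stage labels outside 'stage_order'")
  out <- tapply(H, stages, mean)[stage_order]
  setNames(as.vector(out), stage_order)
}

#' Per-cell and per-stage scores from a local-entropy matrix
#'
#' @param lh A matrix from [local_entropy_matrix()].
#' @param top_fraction Fraction of genes summed per cell (default 0.05).
#' @return An object of class `ccne_scores`: list with `H` (per-cell),
#'   `H_t` (per-stage means), `S`, `top_genes` (list per cell),
#'   `stages`, `stage_order`, `top_fraction`.
#' @export
ccne_scores <- function(lh, top_fraction = 0.05) {
  stages <- attr(lh, "stages")
  stage_order <- attr(lh, "stage_order")
  if (is.null(stages) || is.null(stage_order))
    stop("'lh' must come from local_entropy_matrix()")
  per_cell <- apply(lh, 2, cell_ccne, top_fraction = top_fraction,
                    simplify = FALSE)
  H <- vapply(per_cell, `[[`, 0, "H")
  structure(list(H = H,
                 H_t = stage_ccne(H, stages, stage_order),
                 S = max(1L, ceiling(top_fraction * nrow(lh))),
                 top_genes = lapply(per_cell, `[[`, "top_genes"),
                 stages = stages, stage_order = stage_order,
                 top_fraction = top_fraction),
            class = "ccne_scores")
}

#' @export
print.ccne_scores <- function(x, ...) {
  cat(sprintf("ccne_scores: %d cells, %d stages, S = %d (top %.0f%%)\n",
              length(x$H), length(x$stage_order), x$S,
              100 * x$top_fraction))
  print(round(x$H_t, 6))
  invisible(x)
}
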