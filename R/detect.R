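#' One-sample t statistic and two-sided P value
#'
#' `SC = sqrt(m) * (mean(X) - x) / SD(X)`, with the two-sided P value
#' from the t distribution with `m - 1` degrees of freedom.  If
#' `SD(X) = 0` the statistic is degenerate: by convention P is 1 when
#' `mean(X) == x` and 0 otherwise, with a warning.
#'
#' @param X Numeric vector, `m >= 2`.
#' @param x Reference constant.
#' @return List with `SC`, `p`, `m`.
#' @examples
#' one_sample_t(c(1, 2, 3), 0)  # SC = 2*sqrt(3)
#' @export
one_sample_t <- function(X, x) {
  m <- length(X)
  if (m < 2L) stop("need m >= 2 observations")
  stopifnot(is.finite(x))
  s <- sd(X)
  if (s == 0) {
    warning("SD(X) = 0: degenerate one-sample t test")
    return(list(SC = if (mean(X) == x) 0 else sign(mean(X) - x) * Inf,
                p = if (mean(X) == x) 1 else 0, m = m))
  }
  SC <- sqrt(m) * (mean(X) - x) / s
  list(SC = SC, p = 2 * pt(-abs(SC), df = m - 1), m = m)
}

#' Detect the pre-transition stage from a score series
#'
#' Scans the stages in temporal order.  A candidate stage `t >= 2` is
#' flagged when (a) its mean score exceeds the previous stage's,
#' `H_t > H_{t-1}`, and (b) the one-sample t test of the reference
#' cells' per-cell scores against `H_t` is significant.  Because
#' `T - 1` candidate stages are scanned, the per-stage significance
#' threshold is Sidak-corrected by default
#' (`1 - (1 - alpha)^(1/(T-1))`), which preserves the endpoint
#' behaviour: `alpha = 0` never detects, `alpha = 1` reduces detection
#' to criterion (a).  The detected stage is the earliest flagged one
#' (an early warning must precede the transition); all candidates are
#' reported.
#'
#' @param scores A [ccne_scores] object.
#' @param alpha Family-wise significance level (default 0.05).
#' @param reference `"previous"` (default): the reference is the
#'   immediately preceding stage.  `"baseline"`: all earlier stages
#'   pooled.
#' @param test_side `"reference_cells"` (default): `X` = per-cell
#'   scores of the reference stage, `x = H_t`.  `"candidate_cells"`:
#'   `X` = per-cell scores of the candidate stage, `x` = reference
#'   mean.
#' @param correction `"sidak"` (default) or `"none"` (raw per-stage
#'   `alpha`; anticonservative when several stages are scanned).
#' @param calibrate_reference Logical (default `TRUE`).  The reference
#'   "constant" of the one-sample test is itself a stage mean with
#'   sampling error, which inflates the raw statistic's null spread by
#'   `sqrt(1 + m_X / m_other)` (= `sqrt(2)` for equal stage sizes).
#'   When `TRUE`, the flagging decision uses the statistic divided by
#'   this factor (`p_cal` in the table); the raw `SC` and `p` are
#'   always reported unchanged.
#' @return An object of class `ccne_report`: list with `table` (one row
#'   per candidate stage: `stage`, `H`, `SC`, `p`, `flagged`),
#'   `detected` (stage label or `NA`), `alpha`, `alpha_per_stage`,
#'   settings, and `H_t`.
#' @export
detect_critical_stage <- function(scores, alpha = 0.05,
                                  reference = c("previous", "baseline"),
                                  test_side = c("reference_cells",
                                                "candidate_cells"),
                                  correction = c("sidak", "none"),
                                  calibrate_reference = TRUE) {
  stopifnot(inherits(scores, "ccne_scores"), alpha >= 0, alpha <= 1)
  reference <- match.arg(reference)
  test_side <- match.arg(test_side)
  correction <- match.arg(correction)
  so <- scores$stage_order
  Tn <- length(so)
  if (Tn < 2L) stop("need at least 2 stages")
  if (any(table(scores$stages) < 2L)) stop("every stage needs >= 2 cells")
  n_cand <- Tn - 1L
  alpha_stage <- if (correction == "sidak") 1 - (1 - alpha)^(1 / n_cand)
                 else alpha
  Ht <- scores$H_t
  rows <- vector("list", n_cand)
  for (t in 2:Tn) {
    ref_cells <- if (reference == "previous")
      scores$H[scores$stages == so[t - 1]]
    else scores$H[as.integer(scores$stages) < t]
    cand_cells <- scores$H[scores$stages == so[t]]
    if (test_side == "reference_cells") {
      tt <- one_sample_t(ref_cells, Ht[[t]])
      m_other <- length(cand_cells)
    } else {
      tt <- one_sample_t(cand_cells, mean(ref_cells))
      m_other <- length(ref_cells)
    }
    infl <- sqrt(1 + tt$m / m_other)
    p_cal <- if (is.finite(tt$SC)) 2 * pt(-abs(tt$SC) / infl, df = tt$m - 1)
             else tt$p
    p_flag <- if (calibrate_reference) p_cal else tt$p
    rows[[t - 1]] <- data.frame(
      stage = so[t], H = Ht[[t]], SC = tt$SC, p = tt$p, p_cal = p_cal,
      m = tt$m, rising = Ht[[t]] > Ht[[t - 1]],
      flagged = Ht[[t]] > Ht[[t - 1]] && p_flag < alpha_stage,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  detected <- if (any(tab$flagged)) tab$stage[which(tab$flagged)[1]]
              else NA_character_
  structure(list(table = tab, detected = detected, H_t = Ht,
                 alpha = alpha, alpha_per_stage = alpha_stage,
                 reference = reference, test_side = test_side,
                 correction = correction,
                 calibrate_reference = calibrate_reference),
            class = "ccne_report")
}

#' @export
print.ccne_report <- function(x, digits = 4, ...) {
  cat("Pre-transition stage detection (one-sample t over stage scores)\n")
  cat(sprintf("  alpha = %g (%s-corrected per stage: %.4g), reference = %s\n",
              x$alpha, x$correction, x$alpha_per_stage, x$reference))
  tab <- x$table
  for (cc in c("H", "SC", "p", "p_cal")) tab[[cc]] <- signif(tab[[cc]], digits)
  print(tab, row.names = FALSE)
  if (is.na(x$detected)) cat("No pre-transition stage detected.\n")
  else cat("Detected pre-transition stage:", x$detected, "\n")
  invisible(x)
}

#' Signaling genes at the detected stage and their largest subgraph
#'
#' Ranks analyzed genes by their mean local entropy over the cells of
#' the given stage, selects the top fraction (ties at the cutoff broken
#' by gene ID), and extracts the largest connected component of the
#' background network induced by the selection (ties by edge count,
#' then by lexicographically smallest member).
#'
#' @param lh A matrix from [local_entropy_matrix()].
#' @param background The [ccne_network] used to build `lh`.
#' @param stage Stage label (usually the detected stage).
#' @param fraction Fraction of genes selected (default 0.05).
#' @return An object of class `ccne_signaling`: list with `stage`,
#'   `ranking` (data frame `gene`, `mean_lh`, `selected`), `genes`
#'   (selected set), `subgraph_genes`, `subgraph_edges`.
#' @export
select_signaling_genes <- function(lh, background, stage,
                                   fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  stages <- attr(lh, "stages")
  if (!stage %in% as.character(stages)) stop("unknown stage: ", stage)
  mean_lh <- rowMeans(lh[, stages == stage, drop = FALSE])
  ord <- order(-mean_lh, rownames(lh))
  n_sel <- max(1L, ceiling(fraction * nrow(lh)))
  sel <- rownames(lh)[ord[seq_len(n_sel)]]
  ranking <- data.frame(gene = rownames(lh)[ord],
                        mean_lh = mean_lh[ord],
                        selected = rownames(lh)[ord] %in% sel,
                        stringsAsFactors = FALSE)
  g <- as_igraph(background, genes = sel)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {   # tie: edge count, then smallest member
    ecount <- vapply(best, function(ci) {
      sub <- igraph::induced_subgraph(g, which(comp$membership == ci))
      as.numeric(igraph::ecount(sub))
    }, 0)
    best <- best[ecount == max(ecount)]
    if (length(best) > 1L) {
      first_member <- vapply(best, function(ci)
        min(igraph::V(g)$name[comp$membership == ci]), "")
      best <- best[order(first_member)[1]]
    }
  }
  members <- igraph::V(g)$name[comp$membership == best[1]]
  sub <- igraph::induced_subgraph(g, igraph::V(g)$name %in% members)
  se <- igraph::as_edgelist(sub)
  colnames(se) <- c("from", "to")
  structure(list(stage = stage, ranking = ranking, genes = sel,
                 fraction = fraction,
                 subgraph_genes = sort(members), subgraph_edges = se),
            class = "ccne_signaling")
}

#' @export
print.ccne_signaling <- function(x, ...) {
  cat(sprintf("Signaling genes at stage '%s' (top %.0f%%): %s\n",
              x$stage, 100 * x$fraction, paste(x$genes, collapse = ", ")))
  cat(sprintf("Largest connected subgraph: %d genes, %d edges\n",
              length(x$subgraph_genes), nrow(x$subgraph_edges)))
  invisible(x)
}

# rank-sum (or t) test between two groups, safe for constant input
two_group_p <- function(a, b, test) {
  if (length(unique(c(a, b))) == 1L) return(1)
  if (test == "wilcoxon")
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  else t.test(a, b)$p.value
}

#' Identify dark genes among the signaling genes
#'
#' A signaling gene is "dark" when (a) its expression does not differ
#' significantly between the before-transition and pre-transition
#' stages, yet (b) its local entropy does.  Criterion (a) uses the raw
#' P value of a two-sided rank-sum test (Welch t available); criterion
#' (b) uses Benjamini-Hochberg-adjusted P values across the candidate
#' genes.
#'
#' @param dataset The [ccne_dataset].
#' @param lh The matching [local_entropy_matrix()].
#' @param genes Candidate genes (usually the signaling set).
#' @param before_stage,critical_stage Stage labels to compare
#'   (each needs >= 3 cells).
#' @param alpha_expr Expression-difference level for criterion (a)
#'   (default 0.05; dark requires P >= alpha_expr).
#' @param alpha_ccne Entropy-difference level for criterion (b)
#'   (default 0.05; dark requires adjusted P < alpha_ccne).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return Data frame with one row per candidate gene: `gene`,
#'   `p_expression`, `p_ccne`, `p_ccne_adj`, `dark`.
#' @export
identify_dark_genes <- function(dataset, lh, genes, before_stage,
                                critical_stage, alpha_expr = 0.05,
                                alpha_ccne = 0.05,
                                test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  stopifnot(inherits(dataset, "ccne_dataset"))
  st <- as.character(dataset$stages)
  for (sg in c(before_stage, critical_stage))
    if (sum(st == sg) < 3L)
      stop("stage '", sg, "' needs at least 3 cells")
  if (!all(genes %in% rownames(lh)))
    stop("genes not in the entropy matrix: ",
         paste(setdiff(genes, rownames(lh)), collapse = ", "))
  b <- st == before_stage; k <- st == critical_stage
  p_expr <- vapply(genes, function(g)
    two_group_p(dataset$values[g, b], dataset$values[g, k], test), 0)
  p_ccne <- vapply(genes, function(g)
    two_group_p(lh[g, b], lh[g, k], test), 0)
  p_adj <- p.adjust(p_ccne, method = "BH")
  data.frame(gene = genes, p_expression = p_expr, p_ccne = p_ccne,
             p_ccne_adj = p_adj,
             dark = p_expr >= alpha_expr & p_adj < alpha_ccne,
             row.names = NULL, stringsAsFactors = FALSE)
}
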