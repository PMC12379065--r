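#' Neighbourhood plan for cross-map causal inference
#'
#' Controls how per-gene nearest-neighbour cell sets are formed, the
#' scale(s) of the neighbourhood, and how ties are broken.
#'
#' @param k Neighbour count.  `NULL` (default) uses `ceiling(sqrt(M))`
#'   per stage group of size `M`, a standard bias/variance compromise
#'   for neighbourhood statistics.
#' @param k_fraction Alternative to `k`: neighbour count as a fraction
#'   of the group size, `max(1, ceiling(k_fraction * M))`.
#' @param tie_policy `"index_order"` (default): ties in expression
#'   distance are broken by cell index, deterministically.
#'   `"seeded_jitter"`: a fixed-seed uniform jitter of magnitude
#'   `1e-9 * data range` is added before ranking, removing systematic
#'   index bias while staying reproducible.
#' @param exclude_self Logical; a cell is never its own neighbour
#'   (default `TRUE`).
#' @param multi_scale Logical; if `TRUE`, weights are aggregated over a
#'   ladder of neighbourhood sizes `{ceiling(sqrt(M))/2, ceiling(sqrt(M)),
#'   2*ceiling(sqrt(M))}` (clamped to `[1, M-1]`), the "varying neighbour
#'   size" view of continuity scaling.
#' @param aggregation `"mean"` (default) or `"max"` across the ladder.
#' @param scope `"stage"` (default): neighbourhoods, group size `M` and
#'   SD terms are computed within each cell's stage group.  `"global"`:
#'   the whole dataset is one group.
#' @param jitter_seed Seed for `"seeded_jitter"` (default 1).
#' @return A list of class `ccne_neighbor_plan`.
#' @export
neighbor_plan <- function(k = NULL, k_fraction = NULL,
                          tie_policy = c("index_order", "seeded_jitter"),
                          exclude_self = TRUE, multi_scale = FALSE,
                          aggregation = c("mean", "max"),
                          scope = c("stage", "global"), jitter_seed = 1L) {
  tie_policy <- match.arg(tie_policy)
  aggregation <- match.arg(aggregation)
  scope <- match.arg(scope)
  if (!is.null(k) && !is.null(k_fraction))
    stop("give either 'k' or 'k_fraction', not both")
  if (!is.null(k)) stopifnot(k >= 1)
  if (!is.null(k_fraction)) stopifnot(k_fraction > 0, k_fraction <= 1)
  structure(list(k = if (is.null(k)) NULL else as.integer(k),
                 k_fraction = k_fraction, tie_policy = tie_policy,
                 exclude_self = exclude_self, multi_scale = multi_scale,
                 aggregation = aggregation, scope = scope,
                 jitter_seed = as.integer(jitter_seed)),
            class = "ccne_neighbor_plan")
}

# neighbour counts for a group of size M under a plan
plan_ks <- function(plan, M) {
  k0 <- if (!is.null(plan$k)) plan$k
        else if (!is.null(plan$k_fraction)) max(1, ceiling(plan$k_fraction * M))
        else ceiling(sqrt(M))
  if (k0 >= M)
    stop("neighbour count k = ", k0, " must be smaller than group size M = ", M)
  if (!plan$multi_scale) return(k0)
  ks <- unique(pmax(1L, pmin(M - 1L,
                             as.integer(c(ceiling(k0 / 2), k0, 2L * k0)))))
  sort(ks)
}

# deterministic jitter for tie breaking (internal)
apply_jitter <- function(x, seed) {
  rng <- diff(range(x))
  if (rng == 0) rng <- 1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x + runif(length(x), -1, 1) * 1e-9 * rng
}

#' Per-cell nearest-neighbour sets for one gene
#'
#' For each cell, the `k` cells whose expression of this gene is
#' nearest in absolute difference.  Ties are broken deterministically
#' according to the plan's tie policy.
#'
#' @param x Numeric vector of one gene's expression across the cells of
#'   one group.
#' @param k Number of neighbours, `1 <= k < length(x)`.
#' @param exclude_self Logical; drop the cell itself (default `TRUE`).
#' @param tie_policy,jitter_seed See [neighbor_plan()].
#' @return `M x M` logical matrix; row `l` flags the `k` neighbours of
#'   cell `l` (every row sums to `k`).
#' @examples
#' neighbor_sets(c(0, 1, 2, 3, 4), k = 2)[3, ]  # cell with value 2 -> {1, 3}
#' @export
neighbor_sets <- function(x, k, exclude_self = TRUE,
                          tie_policy = c("index_order", "seeded_jitter"),
                          jitter_seed = 1L) {
  tie_policy <- match.arg(tie_policy)
  M <- length(x)
  if (M < 2L) stop("group size M = ", M, " is too small (need M >= 2)")
  if (k < 1L || k >= M)
    stop("neighbour count k = ", k, " must satisfy 1 <= k < M = ", M)
  if (tie_policy == "seeded_jitter") x <- apply_jitter(x, jitter_seed)
  out <- matrix(FALSE, M, M)
  idx <- seq_len(M)
  for (l in idx) {
    d <- abs(x - x[l])
    if (exclude_self) d[l] <- Inf
    out[l, idx[order(d, idx)][seq_len(k)]] <- TRUE
  }
  out
}

#' Cross-map mutual-information weight between two genes in one cell
#'
#' The causal criterion: with `p_xy` the fraction of cells shared by
#' the two genes' neighbour sets of cell `l`, and `p_x`, `p_y` the
#' individual fractions, the weight is
#' `w = p_xy * log(p_xy / (p_x * p_y))` (natural log, `0 log 0 := 0`).
#' A positive value indicates excess overlap over independence -- a
#' functional dependency between the genes in this cell.  With equal
#' neighbour counts the criterion is symmetric in its arguments, so the
#' two directions of a background edge receive the same weight.
#'
#' @param gx_neighbors,gy_neighbors Neighbour sets of cell `l` for the
#'   two genes: integer index vectors or logical membership vectors.
#' @param M Total number of cells in the group.
#' @return Scalar weight (positive, zero, or negative; only positive
#'   weights become network edges).
#' @examples
#' cross_map_weight(1:5, 1:5, M = 25)      # identical sets: 0.2 * log(5)
#' cross_map_weight(1:4, 5:8, M = 20)      # disjoint: 0
#' @export
cross_map_weight <- function(gx_neighbors, gy_neighbors, M) {
  if (is.logical(gx_neighbors)) gx_neighbors <- which(gx_neighbors)
  if (is.logical(gy_neighbors)) gy_neighbors <- which(gy_neighbors)
  kx <- length(gx_neighbors); ky <- length(gy_neighbors)
  if (kx == 0L || ky == 0L) stop("empty neighbour set")
  if (kx >= M || ky >= M) stop("neighbour set size must be < M")
  n_xy <- length(intersect(gx_neighbors, gy_neighbors))
  if (n_xy == 0L) return(0)
  p_xy <- n_xy / M
  p_xy * log(p_xy / ((kx / M) * (ky / M)))
}

# Stage-group weight engine (internal).
#
# mat: genes x cells for ONE group; pairs: 2-column integer matrix of
# gene-row pairs to evaluate.  Returns a list with `w`: matrix
# (npairs x M) of aggregated cross-map weights per cell, plus the ks
# used.  Weights are symmetric (equal k both genes).
group_weights <- function(mat, pairs, plan) {
  M <- ncol(mat)
  ks <- plan_ks(plan, M)
  nb <- vector("list", length(ks))
  genes_used <- sort(unique(as.vector(pairs)))
  for (ki in seq_along(ks)) {
    nb[[ki]] <- setNames(vector("list", length(genes_used)),
                         as.character(genes_used))
    for (g in genes_used)
      nb[[ki]][[as.character(g)]] <-
        neighbor_sets(mat[g, ], ks[ki], plan$exclude_self, plan$tie_policy,
                      plan$jitter_seed)
  }
  np <- nrow(pairs)
  w <- matrix(0, np, M)
  for (p in seq_len(np)) {
    wk <- matrix(0, length(ks), M)
    for (ki in seq_along(ks)) {
      Na <- nb[[ki]][[as.character(pairs[p, 1])]]
      Nb <- nb[[ki]][[as.character(pairs[p, 2])]]
      n_xy <- rowSums(Na & Nb)
      p_xy <- n_xy / M
      pk <- ks[ki] / M
      wv <- ifelse(n_xy > 0, p_xy * log(p_xy / (pk * pk)), 0)
      wk[ki, ] <- wv
    }
    w[p, ] <- if (plan$aggregation == "mean") colMeans(wk)
              else apply(wk, 2, max)
  }
  list(w = w, ks = ks)
}

# match analyzed genes between dataset and background (internal)
match_genes <- function(dataset, background) {
  bg_genes <- background$genes
  present <- bg_genes %in% rownames(dataset$values)
  if (length(bg_genes) == 0L)
    stop("background network has no edges")
  if (mean(present) < 0.5)
    stop(sum(!present), " of ", length(bg_genes),
         " background genes are absent from the dataset; ",
         "likely a gene ID namespace mismatch")
  if (any(!present))
    warning(sum(!present), " background gene(s) not in the dataset; skipped: ",
            paste(head(bg_genes[!present], 5), collapse = ", "),
            if (sum(!present) > 5) ", ...")
  bg_genes[present]
}

#' Cell-specific causal network for one cell
#'
#' Evaluates the cross-map weight for both directions of every
#' background edge whose genes are present in the dataset, using the
#' cells of this cell's stage group (or all cells under
#' `scope = "global"`), and keeps directed edges with positive weight.
#'
#' @param dataset A [ccne_dataset].
#' @param background A [ccne_network].
#' @param cell_id Cell ID (column name) to build the network for.
#' @param plan A [neighbor_plan()].
#' @return An object of class `ccne_cell_network`: list with `cell_id`,
#'   `genes` (the analyzed gene universe) and `edges` (data frame
#'   `source`, `target`, `weight`; all weights > 0).
#' @export
build_cell_network <- function(dataset, background, cell_id,
                               plan = neighbor_plan()) {
  stopifnot(inherits(dataset, "ccne_dataset"),
            inherits(background, "ccne_network"))
  l_all <- match(cell_id, colnames(dataset$values))
  if (is.na(l_all)) stop("unknown cell ID: ", cell_id)
  genes <- if (nrow(background$edges)) match_genes(dataset, background)
           else character(0)
  if (length(genes) == 0L)
    return(structure(list(cell_id = cell_id, genes = genes,
                          edges = data.frame(source = character(0),
                                             target = character(0),
                                             weight = numeric(0))),
                     class = "ccne_cell_network"))
  cells <- if (plan$scope == "stage")
    which(dataset$stages == dataset$stages[l_all]) else seq_len(ncol(dataset$values))
  mat <- dataset$values[genes, cells, drop = FALSE]
  rownames(mat) <- genes
  ed <- background$edges
  keep <- ed[, 1] %in% genes & ed[, 2] %in% genes
  ed <- ed[keep, , drop = FALSE]
  l <- match(cell_id, colnames(dataset$values)[cells])
  if (nrow(ed) == 0L)
    edges <- data.frame(source = character(0), target = character(0),
                        weight = numeric(0))
  else {
    pairs <- cbind(match(ed[, 1], genes), match(ed[, 2], genes))
    gw <- group_weights(mat, pairs, plan)
    wl <- gw$w[, l]
    pos <- wl > 0
    edges <- data.frame(
      source = c(ed[pos, 1], ed[pos, 2]),
      target = c(ed[pos, 2], ed[pos, 1]),
      weight = c(wl[pos], wl[pos]),
      stringsAsFactors = FALSE)
  }
  structure(list(cell_id = cell_id, genes = genes, edges = edges),
            class = "ccne_cell_network")
}

#' @export
print.ccne_cell_network <- function(x, ...) {
  cat(sprintf("ccne_cell_network for cell '%s': %d genes, %d directed edges\n",
              x$cell_id, length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Localized causal networks of a cell-specific network
#'
#' Decomposes a cell's causal network into one star-shaped subnetwork
#' per analyzed gene: the gene and its outgoing neighbours.  Genes with
#' no outgoing edges yield records with zero neighbours.
#'
#' @param net A `ccne_cell_network` from [build_cell_network()].
#' @return Named list (one entry per analyzed gene) of lists with
#'   elements `center`, `neighbors` (character) and `weights` (numeric,
#'   all > 0, same length).
#' @export
localized_networks <- function(net) {
  stopifnot(inherits(net, "ccne_cell_network"))
  out <- setNames(vector("list", length(net$genes)), net$genes)
  for (g in net$genes) {
    sel <- net$edges$source == g
    out[[g]] <- list(center = g,
                     neighbors = net$edges$target[sel],
                     weights = net$edges$weight[sel])
  }
  out
}
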