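#' Staged single-cell expression dataset
#'
#' Bundles a gene-by-cell expression matrix with an ordered stage (time
#' point) assignment for every cell.  This is the object all downstream
#' scoring operates on: nearest-neighbour sets, leave-one-out standard
#' deviations and entropies are always computed within one stage group.
#'
#' @param values Numeric gene-by-cell matrix.  Row names are gene IDs,
#'   column names are cell IDs; both must be unique.  Entries must be
#'   finite and non-negative (expression levels).
#' @param stages Character or factor vector of length `ncol(values)`
#'   giving the stage label of each cell.
#' @param stage_order Character vector of the stage labels in temporal
#'   order.  Defaults to the order of first appearance in `stages`.
#'
#' @return An object of class `ccne_dataset`: a list with elements
#'   `values` (the matrix), `stages` (factor with levels in temporal
#'   order) and `stage_order`.
#' @examples
#' m <- matrix(rexp(30), 3, 10,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:10)))
#' ds <- ccne_dataset(m, rep(c("t0", "t1"), each = 5))
#' ds
#' @export
ccne_dataset <- function(values, stages, stage_order = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(values) == 0L)
    stop("'values' must be a non-empty numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene IDs as row names and cell IDs as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite entries")
  if (any(values < 0))
    stop("expression matrix contains negative entries")
  stages <- as.character(stages)
  if (length(stages) != ncol(values))
    stop("'stages' must have one entry per cell")
  if (is.null(stage_order)) stage_order <- unique(stages)
  stage_order <- as.character(stage_order)
  if (anyDuplicated(stage_order)) stop("'stage_order' has duplicates")
  if (!all(stages %in% stage_order))
    stop("stage labels not in 'stage_order': ",
         paste(setdiff(stages, stage_order), collapse = ", "))
  stage_order <- stage_order[stage_order %in% stages]
  f <- factor(stages, levels = stage_order)
  if (any(table(f) < 2L))
    stop("every stage needs at least 2 cells")
  structure(list(values = values, stages = f, stage_order = stage_order),
            class = "ccne_dataset")
}

#' @export
print.ccne_dataset <- function(x, ...) {
  cat(sprintf("ccne_dataset: %d genes x %d cells, %d stages\n",
              nrow(x$values), ncol(x$values), length(x$stage_order)))
  tb <- table(x$stages)
  cat("  stages:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ccne_dataset <- function(x) dim(x$values)

#' Background interaction network
#'
#' An undirected gene-gene graph (typically a protein-protein
#' interaction network) that constrains which directed causal edges are
#' evaluated per cell.  Self-loops and duplicate edges (in either
#' orientation) are removed.
#'
#' @param edges Two-column character matrix or data frame of gene IDs,
#'   one undirected edge per row.  Extra columns are ignored.
#' @return An object of class `ccne_network`: list with `edges` (a
#'   deduplicated two-column character matrix) and `genes`.
#' @examples
#' bg <- ccne_network(cbind(c("a", "b", "a"), c("b", "c", "b")))
#' bg
#' @export
ccne_network <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2, drop = FALSE])
  if (length(edges) == 0L) {
    em <- matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
    return(structure(list(edges = em, genes = character(0)),
                     class = "ccne_network"))
  }
  if (ncol(edges) < 2L) stop("edge list needs at least 2 columns")
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2)
  keep <- edges[, 1] != edges[, 2]
  n_self <- sum(!keep)
  if (n_self) message(n_self, " self-loop(s) dropped")
  edges <- edges[keep, , drop = FALSE]
  # canonical orientation, then dedupe
  flip <- edges[, 1] > edges[, 2]
  edges[flip, ] <- edges[flip, 2:1]
  edges <- unique(edges)
  colnames(edges) <- c("from", "to")
  structure(list(edges = edges, genes = sort(unique(as.vector(edges)))),
            class = "ccne_network")
}

#' @export
print.ccne_network <- function(x, ...) {
  cat(sprintf("ccne_network: %d genes, %d undirected edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Fully connected background network over a gene set
#'
#' Convenience constructor used with small simulated circuits, where
#' every gene pair is a candidate interaction.
#'
#' @param gene_ids Character vector of gene IDs.
#' @return A [ccne_network] with all `choose(n, 2)` edges.
#' @export
complete_network <- function(gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) < 2L) stop("need at least 2 genes")
  ccne_network(t(utils::combn(gene_ids, 2L)))
}

# igraph view of a background network (internal)
as_igraph <- function(net, genes = net$genes) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes)
  e <- net$edges[net$edges[, 1] %in% genes & net$edges[, 2] %in% genes, ,
                 drop = FALSE]
  igraph::add_edges(g, as.vector(t(e)))
}
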