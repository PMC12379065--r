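# Exhaustive O(M^2) reference implementations, kept deliberately naive
# and independent of the package internals.

oracle_neighbors <- function(x, k, exclude_self = TRUE) {
  M <- length(x)
  out <- matrix(FALSE, M, M)
  for (l in seq_len(M)) {
    cand <- data.frame(i = seq_len(M), d = abs(x - x[l]))
    if (exclude_self) cand <- cand[cand$i != l, ]
    cand <- cand[order(cand$d, cand$i), ]
    out[l, cand$i[seq_len(k)]] <- TRUE
  }
  out
}

oracle_weight <- function(set_a, set_b, M) {
  n_xy <- length(intersect(set_a, set_b))
  if (n_xy == 0) return(0)
  p_xy <- n_xy / M
  p_x <- length(set_a) / M
  p_y <- length(set_b) / M
  p_xy * log(p_xy / (p_x * p_y))
}

# all positive-weight directed edges for every cell of one group
oracle_group_network <- function(mat, edge_names, k) {
  M <- ncol(mat)
  nb_of <- lapply(setNames(rownames(mat), rownames(mat)),
                  function(g) oracle_neighbors(mat[g, ], k))
  lapply(seq_len(M), function(l) {
    rows <- list()
    for (e in seq_len(nrow(edge_names))) {
      a <- edge_names[e, 1]; b <- edge_names[e, 2]
      na <- which(nb_of[[a]][l, ])
      nb <- which(nb_of[[b]][l, ])
      w <- oracle_weight(na, nb, M)
      if (w > 0)
        rows[[length(rows) + 1]] <-
          data.frame(source = c(a, b), target = c(b, a), weight = w)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(source = character(0), target = character(0),
                    weight = numeric(0))
  })
}

oracle_loo_sd <- function(v) {
  vapply(seq_along(v), function(l) abs(sd(v) - sd(v[-l])), 0)
}

oracle_local_ccne <- function(w, sdt) {
  Q <- length(w)
  if (Q <= 1) return(0)
  p <- w / sum(w)
  -(1 / Q) * sum(p * log(p)) * sdt
}

# full local-entropy matrix by composition of the naive pieces,
# stage scope, single k = ceiling(sqrt(M))
oracle_entropy_matrix <- function(values, stages, edge_names) {
  genes <- sort(unique(as.vector(edge_names)))
  lh <- matrix(0, length(genes), ncol(values),
               dimnames = list(genes, colnames(values)))
  for (sg in unique(stages)) {
    cells <- which(stages == sg)
    mat <- values[, cells, drop = FALSE]
    M <- length(cells)
    k <- ceiling(sqrt(M))
    nets <- oracle_group_network(mat, edge_names, k)
    for (l in seq_len(M)) {
      for (g in genes) {
        ed <- nets[[l]]
        w <- ed$weight[ed$source == g]
        lh[g, cells[l]] <- oracle_local_ccne(w, oracle_loo_sd(mat[g, ])[l])
      }
    }
  }
  lh
}

oracle_cell_score <- function(lh_col, frac) {
  S <- max(1, ceiling(frac * length(lh_col)))
  ord <- order(-lh_col, names(lh_col))
  sum(lh_col[ord[seq_len(S)]])
}
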