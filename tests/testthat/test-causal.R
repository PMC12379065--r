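test_that("neighbour sets match hand-worked examples", {
  nb <- neighbor_sets(c(0, 1, 2, 3, 4), k = 2)
  expect_equal(which(nb[3, ]), c(2L, 4L))        # value 2 -> values {1, 3}
  expect_true(all(rowSums(nb) == 2))
  # constant vector: index-order tie policy gives the lowest-index others
  nbc <- neighbor_sets(rep(1, 5), k = 2, tie_policy = "index_order")
  expect_equal(which(nbc[5, ]), c(1L, 2L))
  # self-inclusion when exclude_self = FALSE
  nbs <- neighbor_sets(c(0, 10, 20), k = 1, exclude_self = FALSE)
  expect_equal(which(nbs[1, ]), 1L)
  expect_error(neighbor_sets(1:4, k = 4), "k < M|k =")
  expect_error(neighbor_sets(1, k = 1), "too small")
})

test_that("neighbour search equals the exhaustive sort-everything oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rexp(50)
    expect_identical(neighbor_sets(x, 7), oracle_neighbors(x, 7))
  }
  # with heavy ties (scRNA-like zeros)
  set.seed(9)
  x <- ifelse(runif(40) < 0.6, 0, rexp(40))
  expect_identical(neighbor_sets(x, 6), oracle_neighbors(x, 6))
})

test_that("seeded jitter is deterministic and leaves the RNG state alone", {
  x <- rep(c(0, 1), 10)
  a <- neighbor_sets(x, 3, tie_policy = "seeded_jitter", jitter_seed = 5)
  b <- neighbor_sets(x, 3, tie_policy = "seeded_jitter", jitter_seed = 5)
  expect_identical(a, b)
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(neighbor_sets(x, 3, tie_policy = "seeded_jitter"))
  expect_identical(runif(1), r1)
})

test_that("cross-map weight matches the closed forms", {
  expect_equal(cross_map_weight(1:5, 1:5, 25), 0.2 * log(5))
  expect_equal(cross_map_weight(1:4, 5:8, 20), 0)
  expect_equal(cross_map_weight(1:4, 3:6, 20), 0.1 * log(0.1 / 0.04))
  expect_error(cross_map_weight(integer(0), 1:2, 10), "empty")
})

test_that("weight is symmetric, bounded, and attains its ceiling only on equal sets", {
  set.seed(2)
  M <- 30; k <- 5
  for (i in 1:50) {
    a <- sample(M, k); b <- sample(M, k)
    w_ab <- cross_map_weight(a, b, M)
    expect_equal(w_ab, cross_map_weight(b, a, M))
    expect_true(is.finite(w_ab))
    ceiling_w <- (k / M) * log(M / k)
    expect_lte(w_ab, ceiling_w + 1e-12)
    if (setequal(a, b)) expect_equal(w_ab, ceiling_w)
    else expect_lt(w_ab, ceiling_w)
  }
  expect_equal(cross_map_weight(2:9, 2:9, 40), (8 / 40) * log(40 / 8))
})

test_that("cell networks match an all-pairs brute-force recomputation", {
  ds <- random_dataset(8, c(25, 30), seed = 4)
  bg <- complete_network(rownames(ds$values))
  en <- bg$edges
  for (cell in c("c3", "c40")) {
    net <- build_cell_network(ds, bg, cell)
    l_global <- match(cell, colnames(ds$values))
    cells <- which(ds$stages == ds$stages[l_global])
    mat <- ds$values[, cells, drop = FALSE]
    k <- ceiling(sqrt(length(cells)))
    oracle <- oracle_group_network(mat, en, k)[[match(cell, colnames(mat))]]
    got <- net$edges[order(net$edges$source, net$edges$target), ]
    want <- oracle[order(oracle$source, oracle$target), ]
    expect_equal(got$source, want$source)
    expect_equal(got$weight, want$weight, tolerance = 1e-12)
  }
})

test_that("degenerate networks behave as defined", {
  ds <- random_dataset(4, c(10, 10), seed = 5)
  empty_bg <- ccne_network(matrix(character(0), 0, 2))
  net <- build_cell_network(ds, empty_bg, "c1")
  expect_equal(nrow(net$edges), 0L)
  # duplicated genes: identical neighbour sets, both directions at the ceiling
  vals <- ds$values
  vals["g2", ] <- vals["g1", ]
  ds2 <- ccne_dataset(vals, as.character(ds$stages), ds$stage_order)
  bg <- ccne_network(rbind(c("g1", "g2")))
  net2 <- build_cell_network(ds2, bg, "c1")
  M <- sum(ds2$stages == ds2$stages[1]); k <- ceiling(sqrt(M))
  expect_equal(nrow(net2$edges), 2L)
  expect_equal(net2$edges$weight, rep((k / M) * log(M / k), 2))
})

test_that("gene-ID mismatches warn, then fail hard past 50%", {
  ds <- random_dataset(4, c(10, 10), seed = 6)
  bg1 <- ccne_network(rbind(c("g1", "g2"), c("g3", "zz")))
  expect_warning(build_cell_network(ds, bg1, "c1"), "skipped")
  bg2 <- ccne_network(rbind(c("xx", "yy"), c("yy", "zz"), c("g1", "qq")))
  expect_error(build_cell_network(ds, bg2, "c1"), "namespace")
})

test_that("localized networks partition the directed edges", {
  # star A -> {B, C, D}
  star <- structure(list(cell_id = "c", genes = c("A", "B", "C", "D"),
                         edges = data.frame(source = "A",
                                            target = c("B", "C", "D"),
                                            weight = c(1, 2, 3))),
                    class = "ccne_cell_network")
  ln <- localized_networks(star)
  expect_length(ln, 4L)
  expect_length(ln[["A"]]$neighbors, 3L)
  expect_length(ln[["B"]]$neighbors, 0L)
  # conservation on a simulated network
  ds <- random_dataset(6, c(12, 14), seed = 7)
  net <- build_cell_network(ds, complete_network(rownames(ds$values)), "c5")
  ln2 <- localized_networks(net)
  expect_equal(sum(lengths(lapply(ln2, `[[`, "neighbors"))), nrow(net$edges))
})

test_that("cell order permutation only relabels the networks", {
  ds <- random_dataset(5, c(14, 12), seed = 8)
  set.seed(11)
  perm <- sample(ncol(ds$values))
  ds_p <- ccne_dataset(ds$values[, perm], as.character(ds$stages)[perm],
                       ds$stage_order)
  bg <- complete_network(rownames(ds$values))
  for (cell in c("c2", "c20")) {
    a <- build_cell_network(ds, bg, cell)$edges
    b <- build_cell_network(ds_p, bg, cell)$edges
    expect_equal(a[order(a$source, a$target), ],
                 b[order(b$source, b$target), ],
                 ignore_attr = TRUE)
  }
})

test_that("probability bounds hold across random inputs", {
  set.seed(3)
  for (i in 1:30) {
    M <- sample(5:40, 1)
    k <- sample(seq_len(M - 1), 1)
    a <- sample(M, k); b <- sample(M, k)
    n_xy <- length(intersect(a, b))
    expect_lte(n_xy / M, min(k / M, 1))
    expect_true(is.finite(cross_map_weight(a, b, M)))
  }
})

test_that("multi-scale aggregation averages the single-k weights", {
  ds <- random_dataset(4, c(16, 16), seed = 10)
  bg <- ccne_network(rbind(c("g1", "g2")))
  plan_ms <- neighbor_plan(multi_scale = TRUE)
  net <- build_cell_network(ds, bg, "c1", plan_ms)
  M <- 16
  ks <- c(ceiling(ceiling(sqrt(M)) / 2), ceiling(sqrt(M)), 2 * ceiling(sqrt(M)))
  w_by_k <- vapply(ks, function(k) {
    na <- which(oracle_neighbors(ds$values["g1", 1:16], k)[1, ])
    nb <- which(oracle_neighbors(ds$values["g2", 1:16], k)[1, ])
    oracle_weight(na, nb, M)
  }, 0)
  w_mean <- mean(w_by_k)
  if (w_mean > 0) {
    expect_equal(net$edges$weight[1], w_mean, tolerance = 1e-12)
  } else {
    expect_equal(nrow(net$edges), 0L)
  }
})
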