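test_that("leave-one-out SD term matches the two-pass oracle", {
  expect_equal(loo_sd_term(c(1, 2, 3, 4), 4), abs(sd(1:4) - sd(1:3)))
  expect_equal(loo_sd_terms(rep(2.5, 6)), rep(0, 6))
  set.seed(1)
  for (i in 1:10) {
    v <- rexp(sample(3:30, 1))
    expect_equal(loo_sd_terms(v), oracle_loo_sd(v), tolerance = 1e-12)
  }
  # duplicating a value changes the leave-one-out multiset and the term
  v <- c(1, 5, 9, 2)
  v2 <- c(v, v[2])
  expect_false(isTRUE(all.equal(loo_sd_term(v, 2), loo_sd_term(v2, 2))))
  expect_equal(loo_sd_terms(v2), oracle_loo_sd(v2))
  expect_error(loo_sd_terms(c(1, 2)), "M >= 3")
})

test_that("local entropy matches closed forms and the hand oracle", {
  expect_equal(local_ccne(5, sd_term = 3), 0)            # Q = 1
  expect_equal(local_ccne(numeric(0), sd_term = 3), 0)   # Q = 0
  for (Q in 2:6)
    expect_equal(local_ccne(rep(0.7, Q), sd_term = 2), 2 * log(Q) / Q)
  p <- c(0.75, 0.25)
  expect_equal(local_ccne(c(3, 1), sd_term = 2),
               -(1 / 2) * sum(p * log(p)) * 2)
  expect_equal(local_ccne(c(3, 1), sd_term = 0), 0)
  set.seed(2)
  for (i in 1:20) {
    w <- rexp(sample(2:8, 1)); s <- rexp(1)
    expect_equal(local_ccne(w, s), oracle_local_ccne(w, s), tolerance = 1e-12)
    # normalized weights sum to one
    expect_equal(sum(w / sum(w)), 1, tolerance = 1e-12)
    # uniform maximizes: LH <= log(Q)/Q * sd
    expect_lte(local_ccne(w, s), log(length(w)) / length(w) * s + 1e-12)
  }
  expect_error(local_ccne(c(1, -1), 1), "positive")
})

test_that("entropy matrix equals the composition-of-pieces oracle", {
  ds <- random_dataset(7, c(9, 11), seed = 3)
  bg <- ccne_network(rbind(c("g1", "g2"), c("g1", "g3"), c("g2", "g4"),
                           c("g4", "g5"), c("g5", "g6"), c("g3", "g6"),
                           c("g2", "g6")))
  lh <- local_entropy_matrix(ds, bg)
  want <- oracle_entropy_matrix(ds$values, as.character(ds$stages), bg$edges)
  expect_equal(lh[rownames(want), ], want, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(lh >= 0))
})

test_that("identical cells give an all-zero matrix; non-background genes are excluded", {
  vals <- matrix(rep(c(1, 2, 3), 6), 3, 6,
                 dimnames = list(paste0("g", 1:3), paste0("c", 1:6)))
  ds <- ccne_dataset(vals, rep("t1", 6))
  bg <- ccne_network(rbind(c("g1", "g2")))
  suppressWarnings(lh <- local_entropy_matrix(ds, bg))
  expect_true(all(lh == 0))
  expect_equal(rownames(lh), c("g1", "g2"))
  expect_equal(attr(lh, "excluded_genes"), "g3")
})

test_that("cell scores take the top-S genes with deterministic ties", {
  col <- setNames(c(3, 1, 4, 1, 5), paste0("g", 1:5))
  expect_equal(cell_ccne(col, top_fraction = 1)$H, sum(col))
  expect_equal(cell_ccne(setNames(rep(0, 4), letters[1:4]), 0.05)$H, 0)
  set.seed(4)
  col40 <- setNames(rexp(40), sprintf("g%02d", 1:40))
  cc <- cell_ccne(col40, 0.05)
  expect_length(cc$top_genes, 2L)       # ceiling(0.05 * 40) = 2
  expect_equal(cc$H, sum(sort(col40, decreasing = TRUE)[1:2]))
  expect_equal(cc$H, oracle_cell_score(col40, 0.05))
  # tie at the cutoff: lexicographically smaller gene wins
  tie <- setNames(c(5, 2, 2, 1), c("d", "c", "a", "b"))
  expect_equal(cell_ccne(tie, top_fraction = 0.5)$top_genes, c("d", "a"))
})

test_that("stage scores are means in stage order, invariant to cell order", {
  H <- c(1, 3, 2, 8, 4, 6)
  st <- c("a", "a", "a", "b", "b", "b")
  expect_equal(unname(stage_ccne(H, st, c("a", "b"))), c(2, 6))
  expect_equal(unname(stage_ccne(H, st, c("b", "a"))), c(6, 2))
  set.seed(5)
  perm <- sample(6)
  expect_equal(stage_ccne(H[perm], st[perm], c("a", "b")),
               stage_ccne(H, st, c("a", "b")))
  # one cell per stage: H_t is that cell's score
  expect_equal(unname(stage_ccne(c(7, 9), c("a", "b"), c("a", "b"))), c(7, 9))
})

test_that("scores object recomputes per stage from scratch", {
  sw <- sweep_fit()
  sc <- sw$fit$scores
  for (sg in sc$stage_order[c(1, 5, 8)])
    expect_equal(sc$H_t[[sg]], mean(sc$H[sc$stages == sg]))
  expect_true(all(sc$H >= 0))
  expect_equal(sc$S, 1L)  # ceiling(0.05 * 8)
})

test_that("rescaling one gene rescales its local entropy linearly", {
  ds <- random_dataset(5, c(12, 12), seed = 6)
  bg <- complete_network(rownames(ds$values))
  lh1 <- local_entropy_matrix(ds, bg)
  vals <- ds$values
  vals["g2", ] <- 3 * vals["g2", ]
  ds2 <- ccne_dataset(vals, as.character(ds$stages), ds$stage_order)
  lh2 <- local_entropy_matrix(ds2, bg)
  expect_equal(lh2["g2", ], 3 * lh1["g2", ], tolerance = 1e-12)
  for (g in c("g1", "g3", "g4", "g5"))
    expect_equal(lh2[g, ], lh1[g, ], tolerance = 1e-12)
})
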