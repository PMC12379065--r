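# hand-built scores object for detection-rule tests
make_scores <- function(H_by_stage) {
  stages <- rep(names(H_by_stage), lengths(H_by_stage))
  H <- unlist(H_by_stage, use.names = FALSE)
  structure(list(H = H,
                 H_t = stage_ccne(H, stages, names(H_by_stage)),
                 S = 1L, top_genes = NULL,
                 stages = factor(stages, levels = names(H_by_stage)),
                 stage_order = names(H_by_stage), top_fraction = 0.05),
            class = "ccne_scores")
}

test_that("one-sample t statistic matches hand algebra and stats::t.test", {
  r <- one_sample_t(c(1, 2, 3), 0)
  expect_equal(r$SC, 2 * sqrt(3))
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), df = 2))
  tt <- t.test(c(1, 2, 3), mu = 0)
  expect_equal(r$SC, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)
  # centered case
  r0 <- one_sample_t(c(4, 5, 6), 5)
  expect_equal(r0$SC, 0)
  expect_equal(r0$p, 1)
  # translation invariance
  set.seed(1)
  X <- rnorm(10)
  a <- one_sample_t(X, 0.3)
  b <- one_sample_t(X + 17, 0.3 + 17)
  expect_equal(a$SC, b$SC)
  expect_equal(a$p, b$p)
  # degenerate variance conventions
  expect_warning(rd <- one_sample_t(c(2, 2, 2), 2), "degenerate")
  expect_equal(rd$p, 1)
  expect_warning(rd2 <- one_sample_t(c(2, 2, 2), 3), "degenerate")
  expect_equal(rd2$p, 0)
})

test_that("detection needs both a rising score and significance", {
  set.seed(2)
  flat <- make_scores(list(a = rnorm(20, 5, 1e-3), b = rnorm(20, 5, 1e-3),
                           cc = rnorm(20, 5, 1e-3)))
  flat$H_t[] <- 5                                     # exactly constant
  rep_flat <- detect_critical_stage(flat)
  expect_true(is.na(rep_flat$detected))
  expect_false(any(rep_flat$table$rising))
  # clear jump at the last stage
  set.seed(3)
  jump <- make_scores(list(a = rnorm(30, 1, 0.1), b = rnorm(30, 1, 0.1),
                           cc = rnorm(30, 5, 0.1)))
  expect_equal(detect_critical_stage(jump)$detected, "cc")
  # alpha = 0 never detects
  expect_true(is.na(detect_critical_stage(jump, alpha = 0)$detected))
  # alpha = 1 reduces to the rising criterion alone
  rep1 <- detect_critical_stage(jump, alpha = 1)
  expect_identical(rep1$table$flagged, rep1$table$rising)
  expect_error(detect_critical_stage(make_scores(list(a = c(1, 2)))),
               "2 stages")
})

test_that("earliest flagged stage wins but all candidates are reported", {
  set.seed(4)
  sc <- make_scores(list(a = rnorm(40, 1, 0.05), b = rnorm(40, 3, 0.05),
                         cc = rnorm(40, 1, 0.05), d = rnorm(40, 6, 0.05)))
  rep_ <- detect_critical_stage(sc)
  expect_equal(rep_$detected, "b")
  expect_equal(rep_$table$flagged, c(TRUE, FALSE, TRUE))
  expect_equal(nrow(rep_$table), 3L)
})

test_that("reference calibration divides the flagging statistic by sqrt(2)", {
  set.seed(5)
  sc <- make_scores(list(a = rnorm(25, 1, 0.3), b = rnorm(25, 1.2, 0.3)))
  r <- detect_critical_stage(sc)
  i <- 1
  expect_equal(r$table$p_cal[i],
               2 * pt(-abs(r$table$SC[i]) / sqrt(2), df = r$table$m[i] - 1))
  raw <- detect_critical_stage(sc, calibrate_reference = FALSE)
  expect_equal(raw$table$SC, r$table$SC)  # statistic itself unchanged
})

test_that("baseline reference pools all earlier stages", {
  set.seed(6)
  sc <- make_scores(list(a = rnorm(20, 1, 0.2), b = rnorm(20, 1.1, 0.2),
                         cc = rnorm(20, 4, 0.2)))
  r <- detect_critical_stage(sc, reference = "baseline")
  expect_equal(r$table$m, c(20L, 40L))
  X <- sc$H[as.integer(sc$stages) < 3]
  want <- one_sample_t(X, sc$H_t[["cc"]])
  expect_equal(r$table$SC[2], want$SC)
})

test_that("signaling-gene selection and largest subgraph follow the rules", {
  sw <- sweep_fit()
  fit <- sw$fit
  lh <- fit$lh
  bg <- complete_network(rownames(sw$dataset$values))
  st <- fit$report$detected
  # fraction = 1: everything, largest component of the whole background
  all_sel <- select_signaling_genes(lh, bg, st, fraction = 1)
  expect_setequal(all_sel$genes, rownames(lh))
  expect_setequal(all_sel$subgraph_genes, rownames(lh))
  # top fraction ranks by mean local entropy over the detected stage
  sel <- select_signaling_genes(lh, bg, st, fraction = 5 / 8)
  stages <- attr(lh, "stages")
  mlh <- rowMeans(lh[, stages == st])
  expect_setequal(sel$genes,
                  names(sort(mlh, decreasing = TRUE))[1:5])
  # with no edges among the selected genes the subgraph is one node
  empty_bg <- ccne_network(rbind(c("g1", "zz_not_present")))
  sel1 <- suppressWarnings(select_signaling_genes(lh, empty_bg, st, 5 / 8))
  expect_length(sel1$subgraph_genes, 1L)
  expect_equal(nrow(sel1$subgraph_edges), 0L)
})

test_that("subgraph ties resolve by edges then smallest member", {
  lh <- matrix(c(4, 3, 2, 1), 4, 2,
               dimnames = list(c("b", "a", "d", "cc"), c("x", "y")))
  attr(lh, "stages") <- factor(c("s1", "s1"))
  attr(lh, "stage_order") <- "s1"
  # two 2-node components among the selected 4 genes
  bg <- ccne_network(rbind(c("a", "b"), c("cc", "d")))
  sel <- select_signaling_genes(lh, bg, "s1", fraction = 1)
  expect_setequal(sel$subgraph_genes, c("a", "b"))  # smallest member 'a'
})

test_that("dark genes need invariant expression but shifted entropy", {
  set.seed(7)
  syn <- simulate_dark_gene_dataset()
  lh <- local_entropy_matrix(syn$dataset, syn$background)
  dg <- identify_dark_genes(syn$dataset, lh,
                            c("dark1", "de1", "h1", "h2", "h3"),
                            "before", "critical")
  expect_true(dg$dark[dg$gene == "dark1"])
  expect_false(dg$dark[dg$gene == "de1"])       # strongly differential
  expect_lt(dg$p_expression[dg$gene == "de1"], 0.05)
  # a gene identical in both stages in both signals is never dark
  ds <- syn$dataset
  vals <- ds$values
  vals["f1", ] <- rep(vals["f1", 1:40], 2)
  ds2 <- ccne_dataset(vals, as.character(ds$stages), ds$stage_order)
  lh2 <- local_entropy_matrix(ds2, syn$background)
  dg2 <- identify_dark_genes(ds2, lh2, "f1", "before", "critical")
  expect_false(dg2$dark)
  expect_error(identify_dark_genes(syn$dataset, lh, "nope", "before",
                                   "critical"), "not in the entropy matrix")
})

test_that("detection is invariant to a global positive rescaling", {
  sw <- sweep_fit()
  ds <- sw$dataset
  bg <- complete_network(rownames(ds$values))
  ds_scaled <- ccne_dataset(2.7 * ds$values, as.character(ds$stages),
                            ds$stage_order)
  fit2 <- ccne(ds_scaled, bg)
  expect_equal(fit2$report$detected, sw$fit$report$detected)
  expect_equal(fit2$scores$H_t, 2.7 * sw$fit$scores$H_t, tolerance = 1e-10)
  expect_equal(fit2$report$table$SC, sw$fit$report$table$SC,
               tolerance = 1e-8)
})
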