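#' Synthetic two-stage dataset with a planted dark gene
#'
#' Builds a ground-truth construction for validating dark-gene calls:
#' a "before" and a "critical" stage with identical marginal expression
#' for the planted gene, whose causal coupling nonetheless switches on
#' in the critical stage.
#'
#' Three hub genes are independent in the before stage and strongly
#' correlated (shared latent factor) in the critical stage.  The
#' planted dark gene draws its expression values from the same
#' distribution in both stages, but in the critical stage the values
#' are reordered to follow the ranks of hub `h1` -- the marginal
#' distribution is untouched while the cross-map neighbour overlap with
#' the hubs becomes maximal.  A control gene is strongly differentially
#' expressed instead.  Filler genes are independent noise.
#'
#' @param n_cells_per_stage Cells per stage (default 40).
#' @param n_filler Independent filler genes (default 4).
#' @return List with `dataset` ([ccne_dataset]), `background`
#'   ([ccne_network]), `dark_gene`, `control_gene`, `before_stage`,
#'   `critical_stage`.
#' @examples
#' set.seed(1)
#' syn <- simulate_dark_gene_dataset()
#' syn$dataset
#' @export
simulate_dark_gene_dataset <- function(n_cells_per_stage = 40,
                                       n_filler = 4) {
  n <- n_cells_per_stage
  stopifnot(n >= 10)
  hub <- function(latent) {
    if (is.null(latent)) 5 + rnorm(n)
    else 5 + 0.95 * latent + sqrt(1 - 0.95^2) * rnorm(n)
  }
  z <- rnorm(n)
  h_b <- replicate(3, hub(NULL))                 # before: independent
  h_c <- replicate(3, hub(z))                    # critical: correlated
  # one value pool for both stages: the marginal is literally identical,
  # only the coupling to the hubs changes
  pool <- 1 + stats::rlnorm(n, 0, 0.5)
  dark_b <- sample(pool)
  dark_c <- sort(pool)[rank(h_c[, 1], ties.method = "first")]
  ctrl_b <- 5 + rnorm(n)
  ctrl_c <- 10 + rnorm(n)
  fill <- function() stats::rlnorm(n, 1, 0.4)
  f_b <- replicate(n_filler, fill())
  f_c <- replicate(n_filler, fill())
  genes <- c("dark1", "de1", paste0("h", 1:3), paste0("f", seq_len(n_filler)))
  vals <- cbind(rbind(dark_b, ctrl_b, t(h_b), t(f_b)),
                rbind(dark_c, ctrl_c, t(h_c), t(f_c)))
  vals <- pmax(vals, 0)
  dimnames(vals) <- list(genes,
                         sprintf("%s_c%03d", rep(c("before", "critical"), each = n),
                                 seq_len(n)))
  ds <- ccne_dataset(vals, rep(c("before", "critical"), each = n),
                     stage_order = c("before", "critical"))
  ed <- rbind(c("dark1", "h1"), c("dark1", "h2"),
              c("de1", "h1"), c("de1", "h2"),
              c("h1", "h2"), c("h1", "h3"), c("h2", "h3"),
              cbind(paste0("f", seq_len(n_filler)),
                    c(paste0("f", seq_len(n_filler))[-1], "h3")))
  list(dataset = ds, background = ccne_network(ed),
       dark_gene = "dark1", control_gene = "de1",
       before_stage = "before", critical_stage = "critical")
}
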