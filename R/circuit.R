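#' Default 8-node regulatory circuit with a bifurcation at s = 0
#'
#' Constructs the stochastic Hill-kinetics gene circuit used as ground
#' truth throughout the package.  Genes `g1`-`g5` form a mutually
#' activating module of dynamic network biomarkers (DNBs); genes
#' `g6`-`g8` are stable downstream readouts (`g1 -> g6` activating,
#' `g3 -| g7` inhibiting, `g6 -> g8` activating).  Each node obeys
#'
#' \deqn{dx_i = [a_i(s) + \sum_e b_e h_e(x_{src}) - x_i]\,dt + \sigma\,dW_i}
#'
#' with Hill terms \eqn{h(x) = x^n/(K^n + x^n)} (activation) or
#' \eqn{K^n/(K^n + x^n)} (inhibition).  The control parameter `s` feeds
#' the basal production of the DNB module,
#' \eqn{a(s) = a_{base} + (a_0 - a_{base}) e^{\kappa s^3}}, where
#' \eqn{a_0} is computed at construction time as the exact fold (saddle-
#' node) value of the symmetric DNB subsystem, so the module's stable
#' low state collides with the saddle exactly at `s = 0`.  For `s < 0`
#' the low state exists and its leading Jacobian eigenvalue approaches 0
#' as `s` approaches 0 from below (critical slowing down); for `s > 0`
#' the module jumps to its high state.
#'
#' @param kappa Steepness of the s-coupling (default 7).  Larger values
#'   confine critical slowing down closer to the bifurcation.
#' @param a_base Basal DNB production far below the bifurcation
#'   (default 0.3, keeps the low state well away from zero expression).
#' @return An object of class `ccne_circuit`: node ids, `dnb_nodes`,
#'   an edge table (`src`, `tgt`, `sign`, `b`, `K`, `n`), per-node
#'   `basal_fun(s)`, `deg`, and the fold constants `a0`, `x_fold`
#'   (synchronized-coordinate fold location, in expression units).
#' @examples
#' circ <- build_default_circuit()
#' circ$dnb_nodes
#' leading_eigenvalue(circ, s = -0.5)  # strongly negative: stable
#' leading_eigenvalue(circ, s = 0)    # ~0: the bifurcation point
#' @export
build_default_circuit <- function(kappa = 7, a_base = 0.3) {
  stopifnot(kappa > 0, a_base > 0)
  K_dnb <- 6; n_dnb <- 2; b_total <- 12; deg <- 1
  # fold of the synchronized scalar reduction du = a/K + (b/K) h(u) - u,
  # back in x units: maximize phi(x) = x - b_total * h(x/K) over the
  # rising branch
  phi <- function(u) u - 2 * u^2 / (1 + u^2)   # scaled units, b/K = 2
  opt <- optimize(phi, c(1e-9, 1), maximum = TRUE, tol = 1e-12)
  a0 <- K_dnb * opt$objective
  x_fold <- K_dnb * opt$maximum
  if (a_base >= a0) stop("'a_base' must lie below the fold value ", signif(a0, 6))
  dnb <- paste0("g", 1:5)
  nodes <- paste0("g", 1:8)
  e <- expand.grid(src = 1:5, tgt = 1:5)
  e <- e[e$src != e$tgt, ]
  edges <- data.frame(
    src   = c(nodes[e$src], "g1", "g3", "g6"),
    tgt   = c(nodes[e$tgt], "g6", "g7", "g8"),
    sign  = c(rep(1L, nrow(e)), 1L, -1L, 1L),
    b     = c(rep(b_total / 4, nrow(e)), 1, 1, 1),
    K     = c(rep(K_dnb, nrow(e)), 1.5, 1.5, 1),
    n     = c(rep(n_dnb, nrow(e)), 2, 2, 2),
    stringsAsFactors = FALSE)
  basal_fun <- function(s) {
    a_dnb <- a_base + (a0 - a_base) * exp(kappa * s^3)
    c(rep(a_dnb, 5), 0.2, 0.2, 0.2)
  }
  structure(list(node_ids = nodes, dnb_nodes = dnb, edges = edges,
                 deg = rep(deg, 8), basal_fun = basal_fun,
                 a0 = a0, a_base = a_base, kappa = kappa,
                 K = K_dnb, n = n_dnb, b_total = b_total,
                 x_fold = x_fold),
            class = "ccne_circuit")
}

#' @export
print.ccne_circuit <- function(x, ...) {
  cat(sprintf("ccne_circuit: %d nodes (%d DNB), %d edges, fold at s = 0 (a0 = %.6f)\n",
              length(x$node_ids), length(x$dnb_nodes), nrow(x$edges), x$a0))
  invisible(x)
}

#' Simulation settings for the regulatory circuit
#'
#' @param s_values Strictly increasing numeric vector of control
#'   parameter values, one stage per value.
#' @param n_cells_per_s Cells sampled per stage (>= 2).
#' @param sigma Additive noise strength (default 0.05).
#' @param dt Euler-Maruyama step, in units of the degradation time
#'   (default 0.01).
#' @param burn_in Relaxation time before the first sample (default 200;
#'   tens of degradation times, enough to equilibrate the fluctuations
#'   and expose each cell to the stage's full metastable dynamics).
#' @param sampling_interval Time between consecutive samples in
#'   `"trajectory"` mode (default 20, several autocorrelation times
#'   except very close to the bifurcation).
#' @param cells_mode `"restart"` (default): every cell is an independent
#'   realization started at the deterministic fixed point and burned in
#'   separately.  `"trajectory"`: cells are snapshots of one long
#'   stationary trajectory, `sampling_interval` apart; cheaper, but
#'   samples share slow fluctuation modes near the bifurcation.
#' @param state_cap Divergence guard: integration aborts if any state
#'   exceeds this magnitude (default 1e3).
#' @return A list of class `ccne_sim_config`.
#' @export
sim_config <- function(s_values = round(seq(-0.5, 0.2, by = 0.1), 10),
                       n_cells_per_s = 50, sigma = 0.05, dt = 0.01,
                       burn_in = 200, sampling_interval = 20,
                       cells_mode = c("restart", "trajectory"),
                       state_cap = 1e3) {
  cells_mode <- match.arg(cells_mode)
  stopifnot(is.numeric(s_values), length(s_values) >= 1,
            !is.unsorted(s_values, strictly = TRUE),
            n_cells_per_s >= 2, sigma >= 0, dt > 0,
            dt < sampling_interval, burn_in > 0, sampling_interval > 0,
            state_cap > 0)
  structure(list(s_values = s_values, n_cells_per_s = as.integer(n_cells_per_s),
                 sigma = sigma, dt = dt, burn_in = burn_in,
                 sampling_interval = sampling_interval,
                 cells_mode = cells_mode, state_cap = state_cap),
            class = "ccne_sim_config")
}

#' Deterministic drift of a circuit
#'
#' @param circuit A [build_default_circuit()] object.
#' @param x Numeric state vector (one entry per node).
#' @param s Control parameter.
#' @return Numeric vector dx/dt.
#' @export
circuit_drift <- function(circuit, x, s) {
  basal <- circuit$basal_fun(s)
  d <- basal - circuit$deg * x
  ed <- circuit$edges
  si <- match(ed$src, circuit$node_ids)
  ti <- match(ed$tgt, circuit$node_ids)
  h <- ifelse(x[si] <= 0, 0, x[si]^ed$n / (ed$K^ed$n + x[si]^ed$n))
  contrib <- ed$b * ifelse(ed$sign > 0, h, 1 - h)
  d + as.vector(tapply(c(contrib, rep(0, length(x))),
                       c(ti, seq_along(x)), sum))
}

#' Analytic Jacobian of the circuit drift
#'
#' @inheritParams circuit_drift
#' @return Square numeric matrix (nodes x nodes).
#' @export
circuit_jacobian <- function(circuit, x, s) {
  G <- length(circuit$node_ids)
  J <- diag(-circuit$deg, G)
  ed <- circuit$edges
  si <- match(ed$src, circuit$node_ids)
  ti <- match(ed$tgt, circuit$node_ids)
  for (e in seq_len(nrow(ed))) {
    xv <- x[si[e]]; K <- ed$K[e]; n <- ed$n[e]
    dh <- if (xv <= 0) 0 else n * K^n * xv^(n - 1) / (K^n + xv^n)^2
    J[ti[e], si[e]] <- J[ti[e], si[e]] + ed$b[e] * ed$sign[e] * dh
  }
  dimnames(J) <- list(circuit$node_ids, circuit$node_ids)
  J
}

#' Tracked (low-branch) fixed point of the circuit
#'
#' Solves the symmetric DNB subsystem on its synchronized manifold for
#' the stable low state (the state the system occupies for `s <= 0`
#' before the transition), then propagates it through the downstream
#' nodes.  At `s = 0` this returns the degenerate fold point itself.
#'
#' @inheritParams circuit_drift
#' @return Named numeric state vector.
#' @export
circuit_fixed_point <- function(circuit, s) {
  a <- circuit$basal_fun(s)[1]
  if (a > circuit$a0 + 1e-12)
    stop("no low-branch fixed point: s = ", s, " is past the bifurcation")
  K <- circuit$K
  phi <- function(u) u - 2 * u^2 / (1 + u^2)
  u_fold <- circuit$x_fold / K
  target <- a / K
  f <- function(u) phi(u) - target
  x_dnb <- if (f(u_fold) <= 1e-12) {
    circuit$x_fold                      # at (or numerically at) the fold
  } else K * uniroot(f, c(0, u_fold), tol = 1e-14)$root
  x <- setNames(numeric(8), circuit$node_ids)
  x[circuit$dnb_nodes] <- x_dnb
  basal <- circuit$basal_fun(s)
  ed <- circuit$edges
  down <- setdiff(circuit$node_ids, circuit$dnb_nodes)
  for (nd in down) {                    # downstream chain is feed-forward
    inc <- ed[ed$tgt == nd, ]
    hv <- vapply(seq_len(nrow(inc)), function(i) {
      xv <- x[inc$src[i]]
      h <- if (xv <= 0) 0 else xv^inc$n[i] / (inc$K[i]^inc$n[i] + xv^inc$n[i])
      inc$b[i] * if (inc$sign[i] > 0) h else 1 - h
    }, 0)
    x[nd] <- (basal[match(nd, circuit$node_ids)] + sum(hv)) /
      circuit$deg[match(nd, circuit$node_ids)]
  }
  x
}

#' Leading Jacobian eigenvalue at the tracked fixed point
#'
#' The real part of the dominant eigenvalue of the drift Jacobian
#' restricted to the DNB module, evaluated at the low-branch fixed
#' point.  It is negative for `s < 0` and reaches 0 at the bifurcation
#' `s = 0`; its magnitude is the relaxation rate whose vanishing causes
#' critical slowing down.
#'
#' @inheritParams circuit_drift
#' @return Scalar real part of the dominant eigenvalue.
#' @export
leading_eigenvalue <- function(circuit, s) {
  x <- circuit_fixed_point(circuit, s)
  idx <- match(circuit$dnb_nodes, circuit$node_ids)
  J <- circuit_jacobian(circuit, x, s)[idx, idx]
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' Simulate cells at a single value of the control parameter
#'
#' Integrates the circuit SDE by Euler-Maruyama and samples
#' `n_cells_per_s` cells.  Sampled expression values are clipped at 0;
#' the integration state itself is not clipped.  Fully reproducible
#' under [set.seed()].
#'
#' @param circuit A [build_default_circuit()] object.
#' @param s Control parameter value (a stage label is derived from it).
#' @param config A [sim_config()].
#' @return A [ccne_dataset] with a single stage labelled
#'   `format(s)`.
#' @examples
#' circ <- build_default_circuit()
#' set.seed(1)
#' ds <- simulate_cells(circ, s = -0.3, sim_config(n_cells_per_s = 10))
#' ds
#' @export
simulate_cells <- function(circuit, s, config = sim_config()) {
  stopifnot(inherits(circuit, "ccne_circuit"),
            inherits(config, "ccne_sim_config"))
  x0 <- tryCatch(circuit_fixed_point(circuit, s),
                 error = function(e) NULL)
  if (is.null(x0)) {  # past the fold: start from the last pre-fold state
    x0 <- circuit_fixed_point(circuit, 0)
  }
  ed <- circuit$edges
  vals <- .em_simulate(
    unname(x0), circuit$basal_fun(s), circuit$deg,
    match(ed$src, circuit$node_ids) - 1L,
    match(ed$tgt, circuit$node_ids) - 1L,
    ed$b, ed$K, ed$n, as.integer(ed$sign),
    config$dt, config$sigma,
    as.integer(round(config$burn_in / config$dt)),
    config$n_cells_per_s,
    as.integer(round(config$sampling_interval / config$dt)),
    config$cells_mode == "restart", config$state_cap)
  lab <- format(s)
  dimnames(vals) <- list(circuit$node_ids,
                         sprintf("s%s_c%03d", lab, seq_len(ncol(vals))))
  ccne_dataset(vals, rep(lab, ncol(vals)))
}

#' Simulate a sweep of the control parameter
#'
#' Concatenates [simulate_cells()] over `config$s_values`, one ordered
#' stage per value.  The ground-truth critical (pre-transition) stage is
#' the largest `s < 0`: the last stage approaching the bifurcation from
#' below.
#'
#' @inheritParams simulate_cells
#' @return A [ccne_dataset] with attributes `truth` (list with
#'   `critical_stage`, `dnb_genes`, `s_of_stage`) describing the ground
#'   truth.
#' @export
generate_sweep <- function(circuit, config = sim_config()) {
  parts <- lapply(config$s_values, function(s)
    simulate_cells(circuit, s, config))
  vals <- do.call(cbind, lapply(parts, function(p) p$values))
  stages <- unlist(lapply(parts, function(p) as.character(p$stages)))
  ds <- ccne_dataset(vals, stages,
                     stage_order = vapply(config$s_values, format, ""))
  pre <- config$s_values[config$s_values < 0]
  attr(ds, "truth") <- list(
    critical_stage = if (length(pre)) format(max(pre)) else NA_character_,
    dnb_genes = circuit$dnb_nodes,
    s_of_stage = setNames(config$s_values, ds$stage_order))
  ds
}

#' Simulate a null sweep (negative control)
#'
#' Same number of stages and cells as [generate_sweep()], but the
#' control parameter is held at a deeply stable value for every stage,
#' so no stage is critical.  Used to measure false-detection rates.
#'
#' @inheritParams simulate_cells
#' @param s_fixed Value at which `s` is held (default -0.5).
#' @return A [ccne_dataset]; stage labels keep the nominal sweep grid so
#'   the result is interchangeable with a true sweep downstream.
#' @export
generate_null_sweep <- function(circuit, config = sim_config(),
                                s_fixed = -0.5) {
  parts <- lapply(seq_along(config$s_values), function(i)
    simulate_cells(circuit, s_fixed, config))
  labs <- vapply(config$s_values, format, "")
  vals <- do.call(cbind, lapply(parts, function(p) p$values))
  colnames(vals) <- sprintf("s%s_c%03d",
                            rep(labs, each = config$n_cells_per_s),
                            seq_len(config$n_cells_per_s))
  ds <- ccne_dataset(vals, rep(labs, each = config$n_cells_per_s),
                     stage_order = labs)
  attr(ds, "truth") <- list(critical_stage = NA_character_,
                            dnb_genes = circuit$dnb_nodes,
                            s_of_stage = setNames(rep(s_fixed, length(labs)),
                                                  labs))
  ds
}
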