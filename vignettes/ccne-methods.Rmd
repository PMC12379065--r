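---
title: "Cell-specific causal network entropy: model, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-specific causal network entropy: model, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many biological processes — differentiation, disease onset, cell-fate
decisions — proceed through an abrupt qualitative shift from one stable
state to another.  Dynamical-systems theory describes such shifts as
critical transitions at a bifurcation point: just before the shift the
system passes through a highly sensitive *pre-transition* state in
which a small group of molecules (dynamic network biomarkers, DNBs)
shows collectively increased fluctuation and mutual coupling, the
statistical shadow of a vanishing relaxation rate ("critical slowing
down").  Detecting that state from staged single-cell expression data
is hard: the data are noisy, sparse and heterogeneous, and expression
means often change smoothly right through the transition.

This package scores each cell by an entropy over *cell-specific causal
networks* and flags the stage at which the aggregate score rises
sharply.  The premise is that gene–gene dependency structure reacts to
approaching criticality earlier and more robustly than per-gene
expression summaries.

## The model

### Cross-map weight

For two genes $g_x, g_y$ observed in the $M$ cells of one stage group,
let $NN_k(g_x, l)$ be the $k$ cells whose expression of $g_x$ is
closest (absolute difference) to cell $l$'s, excluding $l$ itself.
With

$$p_x = \frac{|NN_k(g_x,l)|}{M},\quad
  p_y = \frac{|NN_k(g_y,l)|}{M},\quad
  p_{xy} = \frac{|NN_k(g_x,l)\cap NN_k(g_y,l)|}{M},$$

the cross-map mutual-information weight in cell $l$ is

$$w_l(g_x, g_y) \;=\; p_{xy}\,\log\frac{p_{xy}}{p_x\,p_y},
  \qquad 0\log 0 := 0 .$$

A positive weight means the two genes' neighbourhoods overlap more
than independence predicts — a functional dependency in that cell.
Only pairs joined in a user-supplied undirected background network
(typically a PPI network) are evaluated, and only positive weights
become directed edges (both directions of a background edge; with
equal neighbour counts the criterion is symmetric in its arguments, so
both directions carry the same weight — the package reports both and
does not claim to orient edges).  The weight is bounded by
$(k/M)\log(M/k)$, attained exactly when the two neighbour sets
coincide.

### Localized networks and the local entropy

The cell's directed network decomposes into one star per gene: the
gene $g_k$ and its $Q$ outgoing neighbours.  Normalizing the outgoing
weights to $P_j = w_j / \sum_i w_i$, the local entropy of gene $g_k$
in cell $l$ is

$$LH_k^l \;=\; -\frac{1}{Q}\sum_{j=1}^{Q} P_j \log P_j
  \;\times\; SD_l(g_k),$$

where the scale factor is the cell's leave-one-out contribution to the
gene's expression dispersion,

$$SD_l(g_k) \;=\; \bigl|\,\mathrm{SD}(E(g_k)) -
  \mathrm{SD}(E(g_k)\setminus l)\,\bigr| .$$

Cells in the tail of a gene's distribution get large terms; a constant
gene gets zero.  Near a critical point DNB genes both fluctuate more
(larger $SD$ terms) and couple more strongly (richer, more even
outgoing weights), so their local entropies rise jointly.

### Per-cell, per-stage scores and stage detection

The cell score is the sum of the $S$ largest local entropies in the
cell's column, $S = \max(1, \lceil f\,G\rceil)$ with $f = 0.05$ by
default ("top 5 %"), and the stage score $H_t$ is the mean cell score
over the stage.  Each stage $t \ge 2$ is then tested against its
predecessor with the one-sample statistic

$$SC \;=\; \sqrt{m}\,\frac{\overline{X} - x}{\mathrm{SD}(X)},$$

with $X$ the per-cell scores of the reference stage and $x = H_t$; a
stage is flagged when $H_t > H_{t-1}$ and the test is significant, and
the *earliest* flagged stage is reported (an early warning must
precede the transition).

## Detection calibration

Two aspects of the scan needed explicit calibration choices:

* **Multiplicity.**  $T-1$ candidate stages are scanned; the per-stage
  threshold is Šidák-corrected, $\alpha_\text{stage} = 1 - (1 -
  \alpha)^{1/(T-1)}$.  Šidák (rather than Bonferroni) preserves two
  exact endpoint properties: $\alpha = 0$ never detects, and $\alpha =
  1$ reduces detection to the rising criterion alone.
* **Reference uncertainty.**  The "constant" $x$ is itself a stage
  mean estimated from $m'$ cells.  Under the null with equal stage
  sizes, $SC$ is therefore approximately $N(0, 2)$, not $t_{m-1}$;
  flagging on the raw $P$ value roughly doubles the per-stage type-I
  rate, and across seven candidate stages pushes family-wise false
  positives towards 40 % — no threshold choice can rescue that while
  pretending $x$ is fixed.  By default the *flagging decision* uses
  the statistic divided by $\sqrt{1 + m/m'}$ (`p_cal` in the report);
  the uncorrected $SC$ and its $P$ value are always computed and
  reported too, so both views are available
  (`calibrate_reference = FALSE` restores raw-P flagging).

With both choices active, the family-wise false-detection rate on null
sweeps of the built-in simulator sits near the nominal $\alpha$; the
package's acceptance script measures it directly.

## Numerical conventions

* Natural logarithms throughout; the base only rescales all entropies
  uniformly (recorded in the fit configuration).
* $0\log 0 := 0$; zero neighbour-set overlap gives $w = 0$, hence no
  edge.
* $Q = 0$ (no outgoing causality) and $Q = 1$ (single outcome, zero
  entropy) both give $LH = 0$.
* Sample standard deviations (denominator $M-1$, and $M-2$ after
  leave-one-out) are used everywhere; stages need $M \ge 3$.
* Neighbour count defaults to $k = \lceil\sqrt{M}\rceil$ per stage
  group, the usual bias/variance compromise for neighbourhood
  statistics.  `k`, `k_fraction` and a multi-scale ladder
  $\{\lceil k/2\rceil, k, 2k\}$ (weights averaged, or maximized, across
  the ladder — the "varying neighbour size" view) are available.
* Neighbourhoods, $M$, and SD terms are computed within the cell's
  stage group by default (`scope = "stage"`); mixing stages would let
  between-stage shifts masquerade as within-stage structure.  A
  `"global"` scope is available.
* Ties in expression distance (ubiquitous with zero-inflated data) are
  broken by cell index by default — fully deterministic; a fixed-seed
  jitter policy (`"seeded_jitter"`, magnitude $10^{-9}\times$ data
  range) removes systematic index bias while staying reproducible.
* The top-$S$ gene set is chosen per cell (ties at the cutoff broken
  by gene ID).  Choosing one global set is a defensible alternative;
  the per-cell reading matches the per-cell score definition and is
  what the package implements.
* A degenerate reference ($\mathrm{SD}(X) = 0$) yields $P = 1$ when
  $\overline{X} = x$ and $P = 0$ otherwise, with a warning.
* Gene IDs are matched exactly and case-sensitively against the
  background network; unmatched background genes are skipped with a
  warning, and more than 50 % unmatched aborts (that is almost always
  an identifier-namespace mismatch, not biology).

## The built-in simulator

`build_default_circuit()` defines an 8-gene stochastic circuit whose
low state loses stability in a saddle-node bifurcation at the control
parameter $s = 0$; it is the package's ground truth for validation.

* Genes `g1`–`g5` (the DNB module) activate one another through Hill
  terms ($n = 2$, $K = 6$, total feedback strength 12, unit
  degradation).  On the module's symmetric manifold the drift reduces
  to a scalar fold problem; the fold value $a_0$ of the basal input is
  computed at construction time, so the bifurcation sits at $s = 0$
  exactly (machine precision), and the module's leading Jacobian
  eigenvalue — computed by `leading_eigenvalue()` and cross-checked in
  the tests by an independent ODE-relaxation/finite-difference oracle
  — rises monotonically to zero as $s \to 0^-$.
* The control parameter enters through the DNB basal input
  $a(s) = a_\text{base} + (a_0 - a_\text{base})\,e^{\kappa s^3}$ with
  $\kappa = 7$: a steep, saturating coupling that keeps the module
  deeply stable over most of the sweep ($\lambda_1 \approx -0.6$ at
  $s = -0.5$) and concentrates critical slowing down near the
  bifurcation ($\lambda_1 \approx -0.06$ at $s = -0.1$).  The state
  scale $K = 6$ keeps the potential barrier at the last
  pre-bifurcation stage a few times $\sigma^2/2$ at the default noise
  $\sigma = 0.05$, so cells there show large collective fluctuations —
  including occasional noise-induced early jumps, the hallmark of a
  pre-transition state — while earlier stages stay quiet.
* Genes `g6`–`g8` are downstream readouts (`g1 → g6` activating,
  `g3 ⊣ g7` inhibiting, `g6 → g8`), stable throughout; they provide
  the non-DNB contrast.
* Integration is Euler–Maruyama with additive noise, default
  $dt = 0.01$ in units of the degradation time.  Sampled expression
  values are clipped at zero; the integration state is not, so the
  clipping does not distort the dynamics.
* **Cells are independent realizations by default** (`cells_mode =
  "restart"`): each cell is its own trajectory started at the
  deterministic fixed point and burned in for 200 time units.
  Sampling one long trajectory (`"trajectory"` mode, kept as an
  option) is cheaper but makes cells share slow fluctuation modes —
  near criticality an entire stage then rides the same excursion,
  inflating stage-level score variance far beyond what any
  cells-as-replicates test assumes.  The restart default is what makes
  per-stage testing coherent.
* A sweep's ground-truth critical stage is the largest grid value
  below 0 — the last stage approaching the bifurcation from below;
  `generate_null_sweep()` holds $s$ at a deeply stable value as a
  negative control.

### What the simulator does and does not emulate

It reproduces the dynamical essence of the problem: a small coupled
module with a genuine bifurcation, critical slowing down, collective
fluctuation, and downstream bystander genes, under tunable additive
noise.  It does **not** emulate sequencing artefacts: there is no
dropout model beyond clipping, no library-size or capture-efficiency
variation, no discrete counts, and only 8 genes against a complete
background network.  Passing the validation suite therefore
demonstrates that the estimator recovers critical states from
dynamics of this kind — not that it is immune to scRNA-seq technical
noise; on real data the background network quality and the stage
annotation are the dominant practical risks.

### Problem sizes used in validation

The packaged tests and the acceptance script run the sweep
$s = -0.5, -0.4, \dots, 0.2$ with 50 cells per stage and
$\sigma = 0.05$ (20 seeds for detection and DNB identification, 40
null-sweep seeds for specificity, 10 seeds per noise level for the
noise comparison at $\sigma \in \{0.02, 0.05, 0.1\}$), and 20 seeds of
the planted dark-gene construction.  These sizes make every stochastic
check a stable Monte-Carlo estimate while keeping the whole suite
comfortably fast on one CPU.

## Signaling and dark genes

At the detected stage, genes are ranked by mean local entropy over the
stage's cells; the top fraction (default 5 %) are the candidate
signaling genes, and the largest connected component they induce in
the background network (ties: node count, then edge count, then
lexicographically smallest member) is reported for network-evolution
analysis.

A signaling gene is called **dark** when its expression does *not*
differ between the before-transition and pre-transition stages (raw
two-sided rank-sum $P \ge \alpha$) while its local entropy *does*
(Benjamini–Hochberg-adjusted rank-sum $P < \alpha$ across the
candidate set).  Such genes are invisible to differential-expression
analysis yet responsive to the causal-network reorganization.
`simulate_dark_gene_dataset()` plants exactly this structure — a gene
whose value multiset is identical in both stages but whose coupling to
a hub module switches on in the critical stage, next to a strongly
differential control gene — and the validation suite checks that the
planted gene, and not the control, is called.

## Limitations

* The background network is required; genes absent from it are not
  scored.  Edge quality directly limits what the method can see.
* With equal neighbour counts the cross-map weight is symmetric, so
  edge direction carries no information beyond the undirected support.
* Stage labels are taken as given and orderable; pseudotime inference
  for unordered data is out of scope.
* The per-stage groups must be large enough for neighbourhood
  statistics ($M \gtrsim 10$ in practice; $M \ge 3$ is the hard
  minimum).
* The Step-5 scan tests mean shifts between consecutive stages; slow
  monotone drifts spread over many stages can produce early flags, and
  the earliest-flag convention then reports the first of them.

## A minimal session

```{r example}
library(ccne)
circ <- build_default_circuit()
set.seed(1)
ds <- generate_sweep(circ, sim_config())       # 8 genes x 400 cells
fit <- ccne(ds, complete_network(rownames(ds$values)),
            signaling_fraction = 5 / 8)
summary(fit)
plot(fit)
```
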