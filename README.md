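# ccne — cell-specific causal network entropy

`ccne` detects **pre-transition (critical) states** in staged or
time-resolved single-cell expression data.  Processes such as
differentiation or disease onset often pass through a short,
high-sensitivity regime just before an abrupt state shift; a small
module of genes (dynamic network biomarkers, DNBs) then fluctuates and
couples collectively.  `ccne` scores each cell by an entropy over a
*cell-specific causal network* and flags the stage at which the
aggregate score rises sharply — an early-warning signal grounded in
the gene-dependency structure rather than in expression means.

It is aimed at computational biologists who have (a) a gene × cell
expression matrix, (b) an ordered stage/time label per cell, and (c)
an undirected background interaction network (e.g. a PPI network).

## Method in brief

For each cell `l` within its stage group of `M` cells, and each
background edge `(g_x, g_y)`, the cross-map mutual-information weight

    w_l(g_x, g_y) = p_xy * log( p_xy / (p_x * p_y) ),   0 log 0 := 0

is computed from the overlap of the genes' k-nearest-neighbour cell
sets (`p_x = p_y = k/M`, `p_xy` = overlap fraction; `k = ceiling(sqrt(M))`
by default).  Positive weights form the cell's directed network, which
decomposes into one star ("localized network") per gene.  Gene `g_k`'s
local entropy in cell `l` is

    LH_k^l = -(1/Q) * sum_j P_j log P_j  *  | SD(E(g_k)) - SD(E(g_k) \ l) |

with `P_j` the normalized outgoing weights and `Q` the out-degree.
The cell score `H^l` sums the top-5 % local entropies of the cell, the
stage score `H_t` averages `H^l` over the stage, and stage `t` is
flagged as the pre-transition state when `H_t > H_{t-1}` and the
one-sample statistic `SC = sqrt(m) (mean(X) - H_t) / SD(X)` (X = the
previous stage's per-cell scores) is significant, with Šidák
correction across the scanned stages and calibration for the sampling
error of the reference mean.  At the detected stage the top-ranked
genes become *signaling genes*; signaling genes whose expression does
not change while their entropy does are *dark genes*.

A stochastic 8-gene Hill-kinetics circuit with an exact saddle-node
bifurcation at control parameter `s = 0` (genes `g1`–`g5` form the DNB
module) ships with the package as ground truth; see the methods
vignette (`vignettes/ccne-methods.Rmd`) for the model, design
decisions and validation design.

## Worked example

```r
library(ccne)

circ <- build_default_circuit()          # 8 genes, DNB = g1..g5, fold at s = 0
set.seed(1)
ds  <- generate_sweep(circ, sim_config())            # s = -0.5 ... 0.2, 50 cells/stage
fit <- ccne(ds, complete_network(rownames(ds$values)),
            signaling_fraction = 5/8)
summary(fit)
```

```
Cell-specific causal network entropy fit
  400 cells, 8/8 genes analyzed, 8 stages
  H_t: -0.5=0.0002831  -0.4=0.0002774  -0.3=0.0003534  -0.2=0.0003422  -0.1=0.01015  0=0.01007  0.1=0.01043  0.2=0.0002924
  Detected pre-transition stage: -0.1

Pre-transition stage detection (one-sample t over stage scores)
  alpha = 0.05 (sidak-corrected per stage: 0.007301), reference = previous
 stage         H         SC         p     p_cal  m rising flagged
  -0.4 0.0002774    0.20950 8.349e-01 8.829e-01 50  FALSE   FALSE
  -0.3 0.0003534   -2.62800 1.143e-02 6.913e-02 50   TRUE   FALSE
  -0.2 0.0003422    0.29520 7.691e-01 8.355e-01 50  FALSE   FALSE
  -0.1 0.0101500 -305.10000 5.222e-82 1.223e-74 50   TRUE    TRUE
     0 0.0100700    0.02853 9.774e-01 9.840e-01 50  FALSE   FALSE
   0.1 0.0104300   -0.46760 6.422e-01 7.424e-01 50   TRUE   FALSE
   0.2 0.0002924    1.49900 1.404e-01 2.945e-01 50  FALSE   FALSE
Detected pre-transition stage: -0.1

Signaling genes at stage '-0.1' (top 62%): g4, g3, g2, g5, g1
Largest connected subgraph: 5 genes, 10 edges
```

Reading the output: the stage score stays flat while the system is far
from the bifurcation (`s ≤ -0.2`), then jumps by ~30× at `s = -0.1`,
the last stage before the fold — the detected pre-transition state
(`p_cal` is the multiplicity- and reference-calibrated P value that
drives flagging; `SC`/`p` are the raw statistic and P).  The five
signaling genes at that stage are exactly the DNB module `g1`–`g5`.
`plot(fit)` draws the `H_t` series with the detected stage marked.

File-based runs (`read_expression()`, `read_metadata()`,
`read_network()`, `run_pipeline()`) accept dense TSV/CSV or
MatrixMarket expression, a `cell_id/stage/stage_order` metadata table
and a two-column edge list, and write the entropy ("CCNE") matrix,
per-cell scores, a JSON report, and signaling/dark-gene tables, all
stamped with a configuration hash.  A thin command-line wrapper lives
at `inst/cli/ccne.R`:

```sh
Rscript inst/cli/ccne.R simulate --out sim --seed 3
Rscript inst/cli/ccne.R run --expr sim/expression.tsv --meta sim/metadata.tsv \
        --network sim/network.tsv --out results
```

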