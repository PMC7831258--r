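---
title: "Methods: coevolution features, multi-task distance networks, and the synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coevolution features, multi-task distance networks, and the synthetic test world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coevdist)
```

This vignette documents the model behind `coevdist`, the conventions and
numerical choices the implementation had to fix where the underlying design
left them open, and what the synthetic-data generator does and does not
establish.

## 1. The model

The pipeline predicts the matrix of Cβ–Cβ distances (Cα for glycine) of a
protein of length $L$ from one or two multiple sequence alignments of its
homologs. It has four stages.

**Alignment statistics.** Sequences are reweighted by identity clustering:
the weight of sequence $s$ is $1/|\{t : \mathrm{id}(s,t) \ge 0.8\}|$
(including $s$ itself), and $N_{\mathrm{eff}} = \sum_s w_s$. Positions where
either sequence is gapped count as mismatches; a sequence always belongs to
its own cluster, which keeps weights in $(0,1]$ even for heavily gapped
rows. Weighted, pseudocount-regularized marginal and pair frequencies
$f_i(a)$, $f_{ij}(a,b)$ over the 21-state alphabet (20 amino acids,
alphabetical, gap last) feed everything downstream. The diagonal pair
tables are set to $\mathrm{diag}(f_i)$ exactly so the consistency identity
$f_{ii}(a,a) = f_i(a)$ holds for any pseudocount.

**Coevolution tensors.** Three $L \times L \times 441$ tensors are computed:
the covariance $C_{ij}(a,b) = f_{ij}(a,b) - f_i(a) f_j(b)$; the precision
matrix, i.e. the inverse of the $(21L) \times (21L)$ covariance shrunk
toward its diagonal, $(1-\lambda) C + \lambda\,\mathrm{diag}(C)$; and the
couplings of a 21-state Potts model
$P(x) \propto \exp\!\big(\sum_i h_i(x_i) + \sum_{i<j} J_{ij}(x_i, x_j)\big)$
estimated by maximizing the weighted, $L_2$-regularized pseudolikelihood
with L-BFGS on analytic gradients (the gradient is validated against
central finite differences in the test suite to $10^{-5}$ relative). A
scalar contact score per pair is the Frobenius norm of $J_{ij}$ over the 20
non-gap states, with the average-product correction
$S_{ij} - S_{i\cdot} S_{\cdot j} / S_{\cdot\cdot}$, which exactly
annihilates rank-1 background.

**Networks.** Each of four feature stacks feeds its own residual
convolutional trunk with two heads: a ReLU head regressing real distances
(masked to true distances $< 16$ Å — larger distances are neither useful
nor learnable) and a 25-way softmax head classifying the distance into one
bin below 4.5 Å, 23 half-open 0.5 Å bins on $[4.5, 16)$, and one bin at
$\ge 16$ Å. The stacks are: COV (441 + 40 pairwise-expanded profile + 1
coupling contact score + 1 Pearson = 483 channels), PLM (441 + 40 + 1 =
482), PRE (441 + 40 + 1 joint entropy + 2 expanded column entropy = 484),
and OTHER (sequence-only: profile, secondary structure, accessibility and
entropy/MI statistics, 53 channels by default). Trunks are 64 channels wide
with 16 (COV), 20 (PLM), 16 (PRE) and 22 (OTHER) residual blocks built
from RCIN normalization, Maxout reduction, squeeze-and-excitation gates and
(PLM/PRE) dropout 0.2.

**Training and outputs.** Batch-of-1 multi-task training minimizes
$w_{\mathrm{reg}} \cdot \mathrm{MSE}_{<16\text{Å}} + w_{\mathrm{cls}} \cdot
\mathrm{CE}$, He-normal initialized, Adam (lr 0.001) through epoch 30 then
momentum SGD (lr 0.01, momentum 0.9) with fresh optimizer state at the
switch. The per-epoch validation metric is top-$L/2$ long-range
(separation $\ge 24$) contact precision of the average of the two
head-derived contact maps, each min–max rescaled to $[0,1]$ first. At
prediction time, per-network maps are symmetrized by transpose averaging
and ensemble-averaged across networks and alignments (up to $4 \times 2 =
8$ maps per output type).

## 2. Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| identity threshold | 0.8 | fraction | standard DCA reweighting convention |
| pseudocount | 0.5 | counts | mild regularization; oracle-tested at 0, 0.5, 1, 2 |
| PRE shrinkage $\lambda$ | 0.1 | — | guarantees invertibility; $\lambda = 0$ raises an actionable error on singular input |
| PLM $\lambda_J$ | $0.2 (L-1)$ | — | CCMpred-family scaling of the coupling penalty |
| PLM $\lambda_h$ | 0.01 | — | weak field penalty |
| regression mask | 16 | Å | distances beyond carry no signal |
| contact threshold | 8 | Å | field-standard contact definition (Cβ–Cβ) |
| long-range separation | 24 | residues | field-standard long-range definition |
| restraint window | ±0.1 | Å | bound half-width for distance-geometry input |
| restraint filter | ≤15 Å, sep ≥3; subsets at 11–15 Å | — | folding protocol constants |
| 1/d score floor ε | 0.1 | Å | bounds relative contact scores; only ranking is contract-bound |

## 3. Design choices where the design was open

- **RCIN wiring.** The normalization block is specified by its ingredients
  (instance, row, column normalization, ReLU) but not their composition.
  We compute the three normalized views, concatenate them channelwise
  ($3C$), fuse with a learned 1×1 convolution back to $C$, then ReLU. This
  preserves all three signals, keeps residual shapes, and is swappable
  behind the `nn_rcin()` constructor. Row/column normalization standardize
  each (row, channel) resp. (column, channel) slice to mean 0, variance 1
  with an $\varepsilon = 10^{-5}$ variance floor (degenerate $L = 1$ maps
  stay finite); instance normalization carries a learned per-channel affine.
- **PLM block internals.** The published block is "bottleneck-like" with the
  middle convolution decomposed into 3×3, 7×1, 1×7. We realize it as
  RCIN → 3×3, RCIN → (3×3, 7×1, 1×7), RCIN → SE → dropout, with the
  shortcut spanning the whole block; PRE/OTHER blocks stack two
  (3×3, RCIN, dropout, SE) sub-blocks under one full-block shortcut.
- **Output symmetry.** Raw heads need not be symmetric; predictions are
  symmetrized by transpose-averaging (distograms by averaging the $(i,j)$
  and $(j,i)$ bin vectors, which stays on the simplex).
- **Distogram→distance conversion.** Per pair, mean
  $\sum_b p_b r_b$ and standard deviation over bin representatives $r_b$:
  interior bins use midpoints; the open bins use 4.25 Å (physical Cβ–Cβ
  floor near 4 Å) and 16.25 Å. By default the $\ge 16$ Å bin is excluded
  and the remaining mass renormalized (`include_last = TRUE` switches the
  behavior); pairs with essentially all mass at $\ge 16$ Å are flagged
  `NA` and skipped by restraint generation.
- **MSE filter side.** The evaluation default filters on *predicted*
  distance ≥ 16 Å while the training mask filters on *true* distance; both
  modes are exposed (`filter_on`) because the two conventions coexist in
  the protocol this package implements.
- **Pearson column encoding.** The correlation statistic needs a numeric
  residue encoding; we use Kyte–Doolittle hydropathy (gap = 0), computed
  analytically under the joint pair distribution.
- **Contact potential.** The mean-contact-potential channel requires a
  20×20 pairwise preference table. To avoid shipping unverifiable
  third-party constants, the bundled table is *synthetic*:
  $U(a,b) = -h_a h_b / 10$ from Kyte–Doolittle hydropathies, so
  hydrophobic–hydrophobic pairs score favorably. It plays the structural
  role of a statistical potential, not its empirical content.
- **One model per branch.** Whether separate weights are trained per MSA
  source is ambiguous in the protocol; here one model per branch is applied
  to the feature sets of every alignment, and the ensemble denominator
  adapts (8 maps with two alignments, 4 with one).
- **Model selection.** When a validation set is supplied, the checkpoint
  with the best top-$L/2$ validation precision is retained; the final-epoch
  model is also returned.
- **Loss weights** default to $w_{\mathrm{reg}} = w_{\mathrm{cls}} = 1$;
  setting either to 0 reproduces the single-task ablations exactly (tested
  as an identity, not approximately).
- **Numerical conventions.** $0 \log 0 = 0$ throughout; distogram
  cross-entropy clips probabilities at $10^{-10}$; contact ranking breaks
  ties by lexicographic $(i, j)$ so all rankings are deterministic;
  ensemble averaging sums each element over maps in sorted-value order, so
  it is bit-identical under permutation of the map list.

## 4. The synthetic world

`generate_structure(L, seed)` grows a self-avoiding chain with virtual-bond
steps in [3.3, 4.2] Å (consecutive-residue distances within [3.0, 4.5] Å),
non-adjacent clearance ≥ 3.0 Å, and a mild centroid pull that makes folds
compact enough to show long-range contacts. `simulate_msa()` plants Potts
couplings on up to 10 of the structure's longest-separation contacts
(greedily residue-disjoint, separation ≥ 6 where available), using a
low-rank favored-pair pattern — two 4-residue amino-acid groups attract
within-group pairings with strength 1.5 by default — and samples
$n$ sequences as $n$ independent Gibbs chains with 200 burn-in sweeps
(gap fields set low so gaps are rare). Because chains are independent, the
nominal thinning interval is a no-op and retained only for interface
compatibility. Fields-only sampling is exact, which the marginal
convergence test exploits.

What a green test establishes: that the estimators recover planted
covariation (top-$L/5$ APC precision is seeded-tested at $\ge 0.6$ against
an expected random precision an order of magnitude lower), and that the
full feature→training→evaluation loop learns signal that generalizes to
held-out synthetic targets. What it does not establish: performance on real
proteins — the generator has no real energetics, no phylogenetic
correlation between sequences (sequences are i.i.d. given the model), no
alignment errors, and toy folds are far more regular than native ones.
Desk-scale trained networks (width 16, 2 blocks, 20 epochs, 10 targets)
demonstrate the training machinery, not predictive power.

## 5. Known limitations

- The pseudolikelihood fit is dense pure-R linear algebra: fine to
  $L \approx 50$, slow beyond; no GPU path.
- The OTHER branch's secondary-structure and accessibility channels fall
  back to uninformative constants unless external feature tables are
  provided.
- Checkpoints serialize parameters as decimal JSON: round-trips are exact
  to the decimal representation (~1 ulp), not bitwise.
- Restraint output covers distance bounds only; hydrogen-bond and torsion
  restraints from secondary structure are out of scope (an external merge
  hook is the supported route).
- The evaluation module reports `NA` with a message (rather than a value)
  whenever a metric is undefined: no long-range pairs ($L < 26$), empty
  filtered sets, or zero variance.
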