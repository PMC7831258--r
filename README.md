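# coevdist

Inter-residue distance prediction for proteins from multiple sequence
alignments, in R.

Residues that are close in a protein's 3D structure co-evolve: a mutation at
one position is compensated at its spatial neighbors, leaving a statistical
fingerprint in the columns of a deep multiple sequence alignment (MSA).
`coevdist` turns that fingerprint into quantitative distance predictions.
It is aimed at structural bioinformaticians who want a self-contained,
inspectable implementation of the full pipeline — coevolution features →
deep residual networks → distance maps → folding restraints — that runs and
trains on a laptop, with a synthetic-data module that makes every stage
testable without external databases or binaries.

## What it computes

**Features.** From a weighted alignment (sequence weights by 80% identity
clustering; `Neff` = sum of weights) the package derives the three classic
direct-coupling-analysis pair tensors over the 21-letter alphabet
(20 amino acids + gap):

- `COV`: the covariance tensor `C_ij(a,b) = f_ij(a,b) − f_i(a) f_j(b)`;
- `PRE`: the inverse of the shrunk covariance matrix (precision matrix);
- `PLM`: couplings `J_ij(a,b)` of a 21-state Potts model
  `P(x) ∝ exp(Σ h_i(x_i) + Σ J_ij(x_i,x_j))` fit by L2-regularized
  pseudolikelihood maximization (L-BFGS, analytic gradients);

plus scalar statistics (mutual information, normalized MI, joint entropy,
column-entropy sum, hydropathy-encoded Pearson correlation, mean contact
potential) and an APC-corrected coupling contact score
`S_ij − S_i· S_·j / S_··`.

**Networks.** Four multi-task residual convolutional networks — one per
feature stack (COV 483, PLM 482, PRE 484, OTHER 53 input channels) — share
a 64-channel trunk of 16/20/16/22 residual blocks built from RCIN
normalization (instance + row + column normalization fused by a 1×1
convolution, then ReLU), Maxout channel reduction, squeeze-and-excitation
gating and dropout. Each network emits **both** a real-value distance map
(ReLU head, supervised by masked MSE on true distances < 16 Å) and a
25-bin distogram (softmax head, supervised by cross-entropy over bins
{<4.5 Å, [4.5,16) in 0.5 Å steps, ≥16 Å}). Training is batch-of-1 with
He-normal init, Adam (lr 0.001) for 30 epochs then momentum SGD (lr 0.01,
momentum 0.9), with top-L/2 long-range contact precision as the validation
metric. The whole layer library, including backprop, is implemented in the
package and verified against finite differences.

**Outputs.** Per-network maps are ensemble-averaged (4 networks × up to 2
MSAs = 8 maps), converted to contact maps (`1/d` for real maps; summed
probability of bins ≤ 8 Å for distograms), scored by top-L/5, L/2, L
long-range precision (separation ≥ 24, contacts at Cβ–Cβ ≤ 8 Å), filtered
MSE and Pearson correlation, and exported as CASP RR contact lists and
CNS-dialect distance restraints (target ± 0.1 Å, separation ≥ 3, distance
≤ 15 Å, in five nested subsets at 11–15 Å cutoffs) with a
restraint-violation score for candidate models.

## Worked example

Recover planted contacts from a simulated alignment and emit restraints:

```r
library(coevdist)

st  <- generate_structure(30, seed = 11)          # toy fold, L = 30
msa <- simulate_msa(st, n_sequences = 500, coupling_strength = 1.5,
                    n_planted = 10, seed = 11)    # covariation on 10 contacts
msa <- compute_weights(msa)
msa
#> MSA: 500 sequences x 30 columns, Neff = 500.00

plm   <- plm_tensor(msa, optimizer_budget = 60)   # Potts fit (~5 s)
score <- coupling_contact_score(plm)              # APC-corrected couplings
contact_precision(score$values[, , 1], st$distmap,
                  k = floor(30 / 5), min_sep = 6)
#> [1] 1
```

All six top-L/5 coupling-score pairs are true contacts (the sampler planted
its couplings on spatial contacts, and the Potts fit recovers them). Convert
a distance map into folding restraints:

```r
rs <- make_restraints(st$distmap)
head(as.data.frame(rs), 3)
#>   i j    target     lower     upper
#> 1 1 4  6.797458  6.697458  6.897458
#> 2 1 5 10.215350 10.115350 10.315350
#> 3 1 6 13.340319 13.240319 13.440319
```

232 pairs pass the ≤ 15 Å / separation ≥ 3 filter; each restraint carries
±0.1 Å bounds for a distance-geometry engine, and `make_subsets()` produces
the five nested subsets (11–15 Å). Desk-scale end-to-end training is shown
in `?cmd_train` and the vignette.

## Command line

```sh
coevdist synthesize --out fixtures --n-targets 3 --seed 7
coevdist train --out run1 --branches COV --epochs 20 --seed 1
coevdist predict --msa aln1.fasta,aln2.fasta \
  --checkpoints COV=run1/COV.checkpoint.json --out pred
coevdist evaluate --pred pred/target.realdist.txt --pdb native.pdb --out eval
coevdist restraints --pred pred/target.realdist.txt --out rst
```

## Scope

The package deliberately does **not** run MSA database searches
(HHblits/Jackhmmer), PSI-BLAST/PSIPRED (external 1D features are read from
whitespace tables, or substituted by MSA-derived profiles), CNS/DFOLD 3D
model building (it emits restraint files and scores violations of given
coordinates), or full-scale benchmark training.
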