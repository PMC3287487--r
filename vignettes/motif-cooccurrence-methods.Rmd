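---
title: "Methods: conserved-motif discovery and log-linear co-occurrence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved-motif discovery and log-linear co-occurrence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comotif)
```

# The analysis

`comotif` implements a three-stage analysis of transcription-factor
binding motifs in promoters of co-regulated genes, motivated by the
regulatory program of MafB in macrophages:

1. **Conservation masking.** Promoters (a window around the
   transcription start site, by default −2000/+300, so 2300 nt) of
   orthologous genes from several mammals are aligned; positions of the
   reference (mouse) promoter that are not conserved across species are
   replaced by `N`, on the phylogenetic-footprinting premise that
   purifying selection retains functional cis-elements.
2. **Motif discovery and over-representation.** Motifs are discovered
   de novo in the masked promoters of the down-regulated gene set and
   scored by an Over-Representation Index (ORI) contrasting them with a
   non-regulated control set; the top candidates become "functional
   motif candidates".
3. **Co-occurrence inference.** The candidates' presence/absence across
   all promoters forms a binary gene × motif table; a hierarchical
   log-linear graphical model is selected by backward edge elimination,
   and its conditional-independence graph is read as the set of
   co-occurring motif pairs.

A synthetic-data generator replaces the study's microarray and promoter
databases, so every stage is testable offline against a known truth.

# Stage models and parameters

## Gene classification

A gene is *down-regulated* when its knockout/wild-type signal ratio is
below `down_threshold = 0.5` (less than half the wild-type level), and
*non-regulated* when the ratio equals 1 within `nonreg_tol` (default 0,
as in the source expression table; real data needs a positive
tolerance). A `force_down` hook admits genes missed by the array, the
way *Emr1* was restored by qRT-PCR evidence.

## Alignment and masking

Pairwise alignment is Smith-Waterman-Gotoh local alignment with affine
gaps, delegated to `Biostrings::pairwiseAlignment` behind
`sw_gotoh()`. The original pipeline's "default parameters" are not
recoverable; we adopt the common nucleotide scheme `match = +5`,
`mismatch = −4`, `gap_open = −10` (first gap position), `gap_extend =
−0.5`, all configurable. `N` mismatches everything, including `N`.

Species enter the multiple alignment when their local alignment to the
reference scores **strictly above 200** and spans **500–1000 alignment
columns inclusive** — the two thresholds the original analysis states.
The multiple alignment is a reference-centred star alignment (each
species globally aligned to the reference, gaps merged under
"once a gap, always a gap"); with at most a handful of mammalian
orthologues per gene, a guide-tree progressive scheme adds nothing. A
leave-one-out refinement pass then realigns each row against the
majority consensus of the others, keeping a candidate only if the
sum-of-pairs (SP) score improves, so SP is non-decreasing by
construction; the SP score uses linear gap costs (`gap_extend` per
gapped position, double gaps free), which keeps the exact
three-sequence oracle used in the tests tractable.

The masking rule is necessarily our own, since "non-conserved" was
never defined operationally: a reference position is kept when at least
`min_agree_frac = 0.5` of the non-gap orthologous bases in its column
match it (`N` never counts as agreement, nor does a column where every
other row is gapped), and kept runs shorter than `min_run = 6`
positions — below the span of any motif considered — are masked too.
Both knobs are exposed; masking is provably monotone in
`min_agree_frac`.

## ZOOPS motif discovery

`discover_motif_zoops()` is an EM motif finder under the
zero-or-one-occurrence-per-sequence model with optional reverse-strand
sites, the model used by the original MEME runs. Each sequence's
likelihood is a mixture of "no site" and "one site at position *j*,
strand σ" components; the M-step re-estimates the PWM with a
pseudocount of 0.25 per letter and the site prior γ. Background letter
frequencies are estimated from the input unless supplied. Convergence
is declared at a relative log-likelihood change below 1e-6 or 200
iterations. Because the M-step maximizes a Dirichlet-penalized
likelihood, monotonicity is asserted on the penalized objective at
every iteration.

Initialization is deterministic: every distinct clean width-mer of the
input defines a candidate seed; seeds are screened with a single EM
step and the best `n_keep = 10` are run to convergence, the winner
chosen by the ZOOPS log-likelihood-ratio score with lexicographic
tie-breaking. On inputs with more than `n_screen = 200` distinct
width-mers, screening is restricted to the words present in the most
sequences (again with lexicographic tie-breaking); this keeps discovery
quadratic-free on full-length promoters while remaining exhaustive on
small inputs such as the nine MafB binding sequences. When both strands
are modelled, the final model is oriented to the lexicographically
smaller of its consensus and reverse-complement consensus, which is
what makes the width-8 MafB consensus come out as `CTGCTGAC`
deterministically.

`discover_motif_set()` repeats discovery per width (defaults 6, 8, …,
18, ten motifs per width, at most 70 models), masking the called sites
between rounds so successive models describe different signal. How the
original "ten most significant" ranking interacted with site masking is
unknowable; we rank the per-width models by their log-likelihood-ratio
score after the masking loop, which makes rank/score monotonicity hold
by construction. The degenerate (bracketed) consensus lists letters
with column probability ≥ 0.2, in decreasing order — the threshold that
reproduces the 1–3-letter bracket style of the published MafB motif
table.

## Scanning and the E-value filter

`pwm_scan_evalue()` reports, per sequence, the best log-odds score over
all positions and strands, its p-value under the **exact** null score
distribution (dynamic programming over a discretized score lattice,
bins of 1e-3 of the log-odds scale), corrected for the *m* scanned
windows as 1 − (1 − p₁)^m, and an E-value = p × number of sequences.
Windows containing `N` are skipped; an unscannable sequence gets
p-value 1. Genes pass the MafB filter when their best MafB-motif
E-value is **strictly below 21** in the reference species *and* the
motif is present (same criterion) in every required species — mouse and
human by default. The threshold 21 is taken at face value as a plain
numeric cut on our E-value; the multi-motif QFAST combination of the
original MAST program is deliberately not reproduced, since the filter
involves a single motif family.

`locate_with_substitutions()` is the string-matching locator: a hit is
any offset, on either strand, where at most `budget` motif positions
mismatch (brackets match any listed letter; `N` in the sequence matches
nothing). The width-dependent budget follows the stated schedule — 1
substitution for widths 6 and 8, 2 for 10 and 12, 3 for 14 and 16, 4
for 18 — with unlisted widths inheriting the nearest lower listed
width. The GUI's companion "90% minimum match" setting contradicts this
schedule at short widths (10% of 8 is less than one substitution); the
explicit schedule is binding.

## ORI

The printed equation of the ORI did not survive in the source text —
only the definitions of its four quantities did. The implemented score,

$$\mathrm{ORI} = \frac{\mathrm{Patt}_p / S_p}
 {\max(\mathrm{Patt}_{np},1) / S_{np}} \cdot \frac{N_p}{N_{promoter}},$$

is a reconstruction: a group-size-normalized occurrence-rate ratio
times the fraction of target promoters carrying the motif. It is
consistent with every property stated of the score — values above 1
are meaningful, high values mean even presence across the
down-regulated promoters, low values mean concentration in a few — and
with the 18-versus-211 group sizes. It is strictly increasing in
$\mathrm{Patt}_p$ and $N_p$ and non-increasing in
$\mathrm{Patt}_{np}$. The formula is isolated in `compute_ori()` and an
additive (+1) smoothing variant is selectable, so a corrected formula
can be swapped in without touching the pipeline.

## The log-linear graphical model

Presence/absence of the candidate motifs over all genes is coded 2/1
(kept in all files for fidelity to the original input format) and
tabulated into a 2^k contingency table (k ≤ 16). `ipf_fit()` fits any
hierarchical log-linear model by iterative proportional fitting,
cycling over the generating class until the largest margin discrepancy
is below 1e-8 (at most 2000 cycles; non-convergence is flagged, and
non-convergent candidates are skipped with a warning during
elimination). Deviance is G² = 2Σ obs·ln(obs/fitted) over non-empty
cells; cells with zero observations contribute zero, and structural
zeros are not modelled. Degrees of freedom are (2^k − 1) minus the
model's parameter count; with effects (±1) coding over the full 2^k
grid the indicator columns of distinct interaction subsets are
orthogonal, so the design-matrix rank equals the size of the downward
closure of the generating class and can be counted exactly rather than
decomposed numerically.

`backward_eliminate()` starts from the saturated model (the complete
graph; an all-two-way start is selectable) and, at each step, tests
every current edge by fitting the graphical model of the graph without
that edge (generators = maximal cliques, Bron–Kerbosch) against the
*current* model, removing the edge with the largest p-value while that
p-value is ≥ `alpha = 0.001`. The published account is ambiguous about
whether the p < 0.001 rule applies to the single-edge test or the
cumulative reduced-vs-full test; the stepwise rule is binding here, and
the trace records both the per-step test and the cumulative deviance
against the full model, which is non-decreasing along the trace. The
choice of the saturated full model matches the published degrees of
freedom: with 10 binary variables the saturated model has 2^10 − 1 =
1023 parameters, consistent with a final model reported at 1001 df
against the full model. The fit is an S3 object (`lgm_fit`) with
`print`, `summary`, `fitted`, `residuals`, `coef` (effects-coded
u-terms) and `simulate` methods; the selection (`lgm_selection`) has
`print`, `summary` and an igraph-based `plot`.

Edges of the final graph are the motif "combinations"; the star table
marks a down-regulated gene for a combination when **both** motifs of
the pair are present in its promoter. When a printed star matrix groups
a motif with two or three "linked" motifs per column, this pairwise
both-present reading reproduces the published count of 15 genes
carrying GATA-1-bearing combinations, which is why it was adopted over
an all-linked-present reading.

Two published headline numbers are *not* reproduction targets: the
final deviance 122.806 itself and the exact elimination order depend on
the unpublished 229-gene occurrence matrix. The package checks instead
that the chi-square machinery reproduces p = 1.000 at that
deviance/df, and that model selection recovers planted structure on
synthetic data (below). The "directional" language of the original
interpretation is rendered as undirected conditional-dependence edges;
an undirected graphical model cannot orient them.

## Synthetic data

`simulation_config()` fixes the study conditions: 18 down-regulated
and 211 non-regulated genes, 4 species, 2300-nt promoters. Defaults
chosen where the study is silent: a 600-nt conserved core (inside the
500–1000 consensus band used by the species filter), background GC
0.5, planted motif width 10, per-site mutation rate 0.05 inside the
core of orthologue copies, substitution rate 0.3 outside it (far
enough above the masking threshold to make unmasked background rare),
and independent Bernoulli(0.3) motif presence in the non-regulated
group so the group contrast is controllable.

Presence patterns of the down-regulated group are drawn **exactly**
from the log-linear model P(x) ∝ exp(Σ mainᵢxᵢ + Σ coefᵢⱼxᵢxⱼ) by
enumerating all 2^k states (k ≤ 12) — no Gibbs sampling, hence no
convergence questions inside tests. One site per present motif per
gene (ZOOPS-consistent) is placed at a non-overlapping offset in the
conserved core, on a random strand. Everything is reproducible
bit-for-bit per seed.

What the generator does *not* emulate: tree-structured evolution
(substitutions are i.i.d. per species, not phylogenetic), microarray
noise, promoter GC heterogeneity and repeats, motif positional
preferences relative to the TSS, and multi-copy motifs (available only
behind the planting interface by passing presence counts separately).
Passing tests therefore demonstrate correctness of the algorithms
under the stated generative model, not performance on real promoters.

# Numerical choices

- Score lattice for exact scan p-values: 1e-3 bins of the log-odds
  range; agreement with full word enumeration is exact up to words
  whose score lies within width × bin of the threshold.
- EM: pseudocount 0.25, convergence 1e-6 relative, ≤ 200 iterations;
  ties between converged seeds broken lexicographically by consensus.
- IPF: margin tolerance 1e-8, ≤ 2000 cycles.
- Ranking ties (equal ORI): ascending width, then lexicographic motif
  id, with a message.
- Degenerate inputs: empty FASTA → empty list; all-`N` promoters scan
  to p = 1 and all-absent occurrence rows; a single-row alignment masks
  nothing (with a warning); `wt_signal = 0` genes are excluded with a
  warning.

# Problem sizes in the tests and acceptance script

The packaged checks run on deliberately scaled inputs chosen to
exercise every code path at interactive speed: alignments of up to 30
nt against the exhaustive affine-gap oracle (200 random pairs),
three-sequence MSAs of ≤ 12 nt against the cubic SP oracle, scan nulls
at widths ≤ 8 against 4^W enumeration, motif recovery at 20–50
sequences of 50–60 nt, pipeline runs at 12 + 30 genes with 300-nt
promoters, and model selection at k = 6, n = 400 with 20 replicates.
The structure-recovery simulation sets main effects to −coef/2 so each
planted pair is balanced around presence probability one half. These
sizes are the package's own test design; the functions themselves
accept full-scale inputs.

# Known limitations

- The ORI formula is a reconstruction (see above); ranked candidates
  should be read with that caveat.
- The refinement step realigns against a majority consensus, not a
  full profile, and cannot reorder alignment columns; it repairs local
  gap misplacements only.
- E-values follow the single-motif best-hit definition, not the MAST
  QFAST product over motif families.
- `N`-heavy masked promoters shrink the effective scan space, which the
  1 − (1 − p₁)^m correction accounts for, but extremely short unmasked
  stretches make best-hit p-values conservative.
- The independence graph is undirected; "directional" regulation
  claims require external evidence, as in the original validation by
  luciferase assays.
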