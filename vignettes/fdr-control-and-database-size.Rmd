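---
title: "FDR control, database size, and transcriptome-informed filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FDR control, database size, and transcriptome-informed filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoval)
```

## The problem

In bottom-up proteomics, MS/MS spectra are matched against the peptides of
a protein sequence database and each peptide-spectrum match (PSM) receives
a search score. Because most spectra can match something by chance, the
list of PSMs must be validated at a controlled false discovery rate (FDR).
Proteogenomics adds a twist: the database itself becomes a variable. A
popular strategy builds a *reduced transcriptome-informed database* - the
subset of the reference proteome whose transcripts are expressed in the
sample-matched transcriptome (FPKM above a threshold) - and reports more
identifications at the same nominal FDR. `proteoval` implements the
machinery needed to study, and correctly interpret, that observation:

* PSM validation prefilters and score-cutoff estimation by **target-decoy
  competition (TDC)** and by the **Benjamini-Hochberg (BH)** procedure;
* reduced-database construction and **post hoc transcriptome-informed
  filtering** of full-database identifications;
* **bipartite peptide-protein graphs** and their connected components as a
  measure of protein-inference ambiguity;
* spectrum-level **comparison of paired searches** (reallocations,
  additional identifications, decoy loss);
* a **ground-truth simulator** that reproduces the interplay between
  database size and FDR control.

## Validation model

### Prefilters

Search engines emit several candidate PSMs per spectrum.
`apply_prefilters()` reproduces the standard validation sequence:
candidates within 0.1 score units of a spectrum's best share "pretty
rank" 1 (strict `< 0.1`); exactly one rank-1 PSM is retained per
spectrum; retained peptides shorter than 7 residues are dropped. The
retained PSM among rank-1 ties is drawn uniformly at random under a
caller-supplied seed. A deterministic target-preferring rule may look
attractive, but it would break the equal-chance reasoning underlying TDC
(decoys must have the same opportunity to win a spectrum as incorrect
targets), so the seeded uniform draw is used instead.

### Target-decoy competition

Decoys are full sequence reversals (`generate_decoys()`), appended one
per target. After competition, an acceptance set at score cutoff $c$
holds $t$ targets and $d$ decoys, and its nominal FDR is estimated as

$$\widehat{\mathrm{FDR}}(c) = \frac{d + 1}{t}.$$

`tdc_cutoff()` returns the most lenient cutoff maximising $t$ subject to
$\widehat{\mathrm{FDR}} \le \alpha$; acceptance is inclusive
(`score >= cutoff`). The $+1$ guards the estimate when few decoys pass;
it also makes the procedure slightly conservative (its expected empirical
FDR sits just below $\alpha$), which is the designed behaviour and is
visible in the package's own calibration tests.

### Benjamini-Hochberg validation

For target-only searches, `bh_cutoff()` converts scores to p-values and
applies the step-up rule: with $p_{(1)} \le \dots \le p_{(m)}$, reject
the $k$ smallest where $k = \max\{i : p_{(i)} \le i\alpha/m\}$. Two
score-to-p-value conventions are provided, because search engines do not
agree on one: `"mascot"` reads scores as $-10\log_{10}P$ (so
$p = 10^{-s/10}$), and `"empirical"` estimates
$p = (1 + \#\{\text{decoys} \ge s\})/(1 + \#\text{decoys})$ from an
observed decoy distribution. Which convention matches a given engine's
score semantics is the user's responsibility; the BH guarantee requires
p-values that are valid (uniform or super-uniform) for incorrect
matches. For BH to be meaningful across database sizes, the p-value must
already account for the number of candidates per spectrum - that is what
makes BH stable where TDC is not.

## Transcriptome-informed reduction and filtering

`reduce_database()` retains reference proteins with at least one
transcript expressed strictly above the FPKM threshold (default 1, the
conventional noise floor for RNA-seq expression calls). Proteins mapping
to several transcripts are kept if *any* is expressed; proteins missing
from the mapping are dropped (with a reported count), since nothing
supports them. Identifier versions (`ENST...\.2`) are stripped before
matching because Ensembl dumps are inconsistent across releases.

`posthoc_filter()` offers the three filtering rules applied after a
full-database search, on the peptide-protein incidence matrix:

1. remove proteins with no expressed transcript, then peptides left
   mapping only to removed proteins;
2. additionally require that a removed protein has **no specific
   peptide** (a specific peptide rescues its protein regardless of
   expression), then remove peptides only shared between removed
   proteins;
3. as option 2, but a protein may only be removed if *every* one of its
   peptides is shared with a retained protein, so no peptide
   identification is ever lost.

Option 2 is the default: option 1 discards observed specific peptides
and gives transcript evidence excessive weight (proteins can outlive
their mRNA, and polyA-selected libraries miss some transcripts).

Option 3's "retained" is self-referential. It is resolved as a
deterministic fixed point: all no-transcript/no-specific candidates
start marked for removal; any marked protein owning a peptide whose
other parents are all marked is unmarked; the pass repeats until stable.
Because each pass unmarks every violator simultaneously, the result does
not depend on protein order; when two candidates share a peptide only
with each other, both are retained. Specificity is always evaluated on
the unfiltered matrix, so a peptide that becomes specific mid-filtering
does not change the candidate set; this choice also makes all three
options idempotent.

## Graphs, components, groups

`build_incidence()` encodes peptide-to-protein mappings as a sparse 0/1
matrix (peptides x proteins); its cross-product (`Matrix::crossprod`)
gives the protein adjacency matrix whose off-diagonal entries count
shared peptides. Connected components (CCs) are computed by union-find
over the nonzero off-diagonal entries; a single-protein CC is an
unambiguous identification, a multi-protein CC bundles proteins linked -
possibly transitively - by shared peptides. For large matrices
`reduced_cc()` first prunes proteins that share no peptide (and their
specific peptides) and provably returns exactly the multi-protein CCs of
the full computation. `protein_groups()` partitions proteins by *exact*
equality of peptide sets; subset relationships are deliberately not
merged (that would be a parsimony decision, not a grouping one), so
group counts may differ from tools that subsume. `ambiguity_metrics()`
reports the percentage of single-protein CCs, the percentage of specific
peptides, and per multi-protein CC the ratio of proteins to their
encoding genes; proteins without gene annotation count as their own
gene.

All orderings are first-appearance, so exports (`export_cc()`, GraphML
or DOT) and metrics are reproducible byte for byte.

## The simulator

### Score model

Each candidate match carries a latent per-candidate p-value
$u \sim U(0,1)$ with score $s = -10\log_{10} u$; the best incorrect
match in a database offering $k$ candidates scores
$-10\log_{10}(\min\text{ of }k\text{ uniforms})$. This max-of-$k$
construction is the standard abstraction of a search engine: database
size enters purely as candidate count. A fraction `pi1` of spectra has a
correct match whose score is drawn once from
$\mathcal{N}(\mu_{\text{correct}}, \sigma^2_{\text{correct}})$ (defaults
75 and 10 on the $-10\log_{10}p$ scale, placing typical correct matches
above the extreme-value range of $2000 \times 1000$ null draws) and
reused in both searches. Competition retains the best of {correct
target, best incorrect target, best decoy}.

### What reduction does - and the equal-chance assumption

The reduced database never loses a spectrum's correct sequence (that is
the point of transcriptome-informed reduction: expressed proteins stay).
Decoys are random sequences, so their candidate count shrinks by the
full reduction rate $r$: $k_d = \lceil (1-r)k \rceil$. For incorrect
*target* matches the situation is subtler, and this is the package's key
modelling decision: if incorrect-candidate capacity shrank by exactly
the same factor for targets and decoys, the equal-chance assumption
would continue to hold inside the reduced search, and TDC with the
$(d+1)/t$ estimator would remain a valid FDR-controlling procedure at
*any* database size - no artifact could appear. The anti-conservative
behaviour of TDC on excessively small databases arises precisely because
decoys become worse models of incorrect target matches: mis-assignments
concentrate on sequences similar to what is actually in the sample
(homologs, isoforms, near-miss modified forms of present peptides), and
a transcriptome-informed reduction retains exactly those sequences. The
`mismatch_retention` parameter $m$ (default 0.5) is the fraction of
incorrect-target matching capacity that survives reduction for this
reason: $k_t = \lceil ((1-r) + mr)k \rceil$. Setting $m = 0$ restores
exactly-equal reduction and TDC remains calibrated - a useful negative
control.

Reduced candidates are drawn as an exact subset of the full search's
candidates (the surviving-subset minimum and the removed-part minimum
jointly compose the full-pool minimum), so a spectrum's reduced-search
score never exceeds its full-search score, and reallocations onto
targets with a score gain cannot occur - the behaviour expected when one
database is a subset of the other.

### The BH track

BH operates on target-only searches. The simulator emits these on a
*database-size-calibrated* score scale: the score is $-10\log_{10}$ of
the spectrum-level p-value of the best candidate,
$p = 1 - (1-u_{\text{best}})^{k}$, which is exactly uniform for spectra
with no correct match, whatever $k$. Under the `"mascot"` convention
these scores decode back to valid p-values, so BH controls the FDR in
both regimes and its cutoffs barely move with database size. The raw
competition scores and the calibrated target-only scores cannot be one
column: a per-candidate score is identical for the correct match across
searches but decodes to a size-dependent p-value, while a calibrated
score is size-stable as a p-value but shifts for the correct match. The
simulator therefore carries both, which mirrors practice - engines
report match-level scores, and statistically valid spectrum-level
p-values require a size-aware calibration.

### Default study conditions

| parameter | default | meaning |
|---|---|---|
| `n_spectra` | 2000 | spectra per search (desk-scale; real runs have 10-100x more) |
| `pi1` | 0.6 | fraction of spectra with a correct match present |
| `k_full` | 1000 | incorrect-candidate count, full database |
| `reduction_rate` | 0.9 | fraction of sequences absent from the reduced database |
| `mismatch_retention` | 0.5 | incorrect-target capacity surviving reduction |
| `mu_correct`, `sd_correct` | 75, 10 | correct-match score distribution |

Calibration experiments use 200 replicates at $\alpha$ = 0.5%, 1%, 5%;
property tests run on 200-500 random instances of at most 100 PSMs or 60
graph vertices. These sizes give Monte-Carlo standard errors a factor
of about 30 below the effects being measured while keeping a full test
run in the order of a minute or two per module.

### What the simulator does not emulate

The generator targets the *mechanism*, not any dataset. It does not
reproduce engine-specific score scales or their dataset-dependent
cutoffs, correlated spectra from co-eluting peptides, chimeric spectra,
shared peptides at the scoring stage (sharing only enters the graph
module), contaminants, modified peptides, or the specific percentages
reported on real samples (those depend on raw data and a commercial
engine). Passing tests therefore demonstrate the statistical behaviour
of the validation procedures under a clean generative model - not that
any particular real dataset will show effects of a given size.

The identification-structure generator (`simulate_identifications()`)
draws specific peptides at a reduced rate (default 20%) for proteins
without transcript support: a protein absent from the sample is rarely
identified by a peptide of its own, whereas unsupported homologs are
routinely dragged in through shared peptides. The rate is deliberately
non-zero - proteins do outlive their transcripts.

## Numerical choices

* Acceptance is always inclusive (`score >= cutoff`); among equal-$t$
  feasible TDC sets the lowest cutoff is reported.
* Pretty-rank ties use strict `< 0.1`; the retained PSM among ties is a
  seeded uniform draw.
* A PSM mapping to both target and decoy accessions is classified target
  and its decoy accessions dropped (reversed tryptic peptides
  occasionally coincide with targets; counting them as decoys inflates
  $d$).
* Latent uniforms and spectrum-level p-values are floored at `1e-300`
  before taking logs.
* Infeasible validation (no acceptance set meets $\alpha$) yields an
  empty set with `cutoff = Inf`.
* All randomness flows from a single seed; replicate seeds are derived
  from the master seed, and seeded code restores the caller's RNG state.

## Known limitations

* No q-values, posterior error probabilities, or TDC refinements
  (mix-max, entrapment); the two implemented estimators are the point of
  comparison, not a complete validation toolbox.
* BH is applied per table; class-separated FDR (e.g. variant versus
  canonical peptides) is out of scope.
* Protein grouping is strict set-equality; counts are not comparable
  with parsimony-based groupers.
* The expression interface is transcript-level; gene-level expression
  tables must be mapped to transcripts upstream.
* I/L distinction is taken as given in peptide sequences; the package
  does not collapse isobaric residues.

## A worked example

```{r example, eval = FALSE}
library(proteoval)

sim <- simulate_pair(sim_config(n_spectra = 2000, seed = 7))

tdc_full <- tdc_cutoff(sim$full, alpha = 0.01)
tdc_red  <- tdc_cutoff(sim$reduced, alpha = 0.01)
empirical_fdp(valid_psms(sim$reduced, tdc_red)$spectrum_id,
              sim$truth, "reduced")

bh_full <- bh_cutoff(sim$full_target_only, 0.01)
bh_red  <- bh_cutoff(sim$reduced_target_only, 0.01)

pairs <- pair_searches(sim$full, sim$reduced)
decompose_additional(pairs, tdc_full$cutoff, tdc_red$cutoff)
decoy_loss_analysis(pairs, tdc_full$cutoff)
```
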