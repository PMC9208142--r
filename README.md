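# proteoval

FDR control and transcriptome-informed filtering for bottom-up
proteomics.

`proteoval` is an R toolkit for researchers who validate
peptide-spectrum matches (PSMs) and who use sample-matched
transcriptomes to refine proteomic identifications — in particular for
studying what happens to FDR control when the protein database searched
is made smaller, as proteogenomic "reduced transcriptome-informed
database" workflows do.

## What it does

* **PSM validation.** Prefilters (pretty-rank ties at score difference
  < 0.1, single best PSM per spectrum, minimum peptide length 7), then
  score-cutoff estimation either by **target-decoy competition** (TDC),
  with the nominal FDR of an acceptance set holding *t* valid targets
  and *d* valid decoys estimated as

  FDR&#770; = (d + 1) / t,

  or by the **Benjamini–Hochberg** (BH) step-up procedure on p-values
  derived from target-only search scores
  (p(i) ≤ i·α/m). Decoy databases are generated by full sequence
  reversal.
* **Database reduction and post hoc filtering.** Build a reduced
  database as the subset of a reference FASTA whose transcripts are
  expressed (FPKM > threshold), or search the full database and filter
  afterwards, with three rules differing in how shared peptides and
  specific peptides rescue proteins.
* **Ambiguity analysis.** Bipartite peptide–protein graphs, sparse
  incidence/adjacency matrices, connected components (with a fast
  pruned-matrix strategy for the multi-protein components), protein
  groups by identical peptide sets, and summary metrics (% single-protein
  components, % specific peptides, protein-to-gene ratios). GraphML/DOT
  export for inspection.
* **Paired-search comparison.** Spectrum-level pairing of full versus
  reduced searches: reallocation accounting, decomposition of additional
  identifications into lower-cutoff effects versus *pure reallocations*,
  and valid-decoy loss under a transferred cutoff.
* **Ground-truth simulation.** A generative model in which database size
  is a candidate count (best incorrect match = max of *k* null draws),
  with per-spectrum correctness labels, used to measure empirical false
  discovery proportions (FDP) against nominal estimates for TDC and BH
  across database sizes.

## A worked example

Simulate a paired full/reduced database search (2000 spectra, 90% of
sequences absent from the reduced database, correct sequences always
retained), then validate both at a nominal 1% FDR:

```r
library(proteoval)
sim <- simulate_pair(sim_config(n_spectra = 2000, seed = 7))

tdc_cutoff(sim$full, 0.01)
#> TDC validation at alpha = 0.01
#>   cutoff = 47.9313, t = 1220, d = 11, nominal FDR = 0.00983607
tdc_red <- tdc_cutoff(sim$reduced, 0.01)
tdc_red
#> TDC validation at alpha = 0.01
#>   cutoff = 36.3731, t = 1309, d = 12, nominal FDR = 0.00993125
empirical_fdp(valid_psms(sim$reduced, tdc_red)$spectrum_id,
              sim$truth, "reduced")
#> [1] 0.07792208
```

The reduced search looks better (1309 valid targets instead of 1220) at
the same nominal 1% FDR — but the ground truth shows its actual false
discovery proportion is 7.8%. The smaller decoy set no longer models
incorrect target matches, TDC's score cutoff drops from 47.9 to 36.4,
and the "additional identifications" are bought with uncontrolled
errors. BH validation of the corresponding target-only searches is
stable across the two database sizes:

```r
bh_cutoff(sim$full_target_only, 0.01)
#> BH validation at alpha = 0.01
#>   cutoff = 22.2101, t = 1205, d = 0, nominal FDR = 0.01
bh_cutoff(sim$reduced_target_only, 0.01)
#> BH validation at alpha = 0.01
#>   cutoff = 23.2405, t = 1210, d = 0, nominal FDR = 0.01
```

Where do the extra identifications come from? Pair the searches spectrum
by spectrum and decompose:

```r
pairs <- pair_searches(sim$full, sim$reduced)
decompose_additional(pairs, cutoff_full = 47.9313,
                     cutoff_reduced = tdc_red$cutoff)
#> additional identifications in the reduced search: 97 spectra, 97 peptides
#>          lower_cutoff_no_realloc lower_cutoff_realloc_from_target
#> spectra                       83                                7
#> ...
#>   99.0% of additional spectra due to the lower cutoff

decoy_loss_analysis(pairs, cutoff_full = 47.9313)
#> net loss: targets 0.6%, decoys 100.0%
```

Almost every additional identification is explained by the lower score
cutoff, not by spectra finding better matches; and under the full-search
cutoff the reduced search keeps nearly all valid targets while losing
the valid decoys — which is exactly why TDC lowers the cutoff.

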