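---
title: "Methods: codon optimality, preferred non-optimal codons, and protein surface exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon optimality, preferred non-optimal codons, and protein surface exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonopt)
library(dplyr)
```

This vignette documents the statistical procedures implemented in
`codonopt`, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical conventions adopted where the underlying methodology
leaves a choice open.

## The analysis in outline

The package operationalises a question about synonymous codon *choice*:
when a gene class lowers its use of the optimal codon of an amino acid,
does it spread the slack uniformly over the sister codons (as a neutral
model would predict), or concentrate it on one specific non-optimal
codon? The pipeline proceeds in five stages.

1. **A priori codon classification.** Codon counts of a designated
   highly expressed reference set (typically ribosomal-protein genes)
   and of the whole gene catalogue are pooled, converted to RSCU, and
   differenced. Per degenerate amino acid, the codon with the largest
   positive difference is the optimal codon; the remaining 41 codons are
   non-optimal. Using ribosomal genes against *all* genes (rather than
   highest vs lowest expression deciles) is the conservative variant of
   the classical reference-set approach: the background includes the
   reference, which shrinks the deltas but cannot flip their sign.
2. **tRNA stratification.** Codons are crossed with exact-match tRNA
   gene copy numbers: above-median counts are "high", the rest "low",
   and an *optimal* codon with zero exact matches is a wobble codon.
   Only optimal codons can be wobble — a zero-count non-optimal codon
   folds into `Non-opt_low-tRNAs` — because the four-way scheme
   (`Opt_high-tRNAs`, `Opt_wobble`, `Non-opt_low-tRNAs`,
   `Non-opt_high-tRNAs`) treats wobble as a property of codons that are
   *preferred despite* lacking a dedicated tRNA.
3. **Expression classes.** Genes are classified from an RPKM matrix
   over a focal gonad pair: testis-biased (fold ≥ 5 and testis ≥ 100
   RPKM), ovary-biased (symmetric), unbiased (fold < 5, either gonad
   ≥ 100 RPKM), otherwise excluded. Tissue specificity is summarised by
   tau over the full tissue panel.
4. **Gene-set contrasts.** Per-gene RSCU matrices for the three classes
   are contrasted codon-by-codon (mean difference, Welch t-test). Among
   each amino acid's non-optimal codons, the one ranking first on the
   testis-vs-unbiased delta is called the **primary non-optimal codon**,
   gated on both deltas (testis-vs-ovary and testis-vs-unbiased) being
   positive.
5. **Structure linkage.** Per-residue RSA/disorder/secondary-structure
   records are joined codon-wise to the CDS. Genes are binned by
   Percent-Non-opt; bin-wise RSA is compared by Mann-Whitney U tests;
   and per amino acid the mean RSA under the primary non-optimal codon
   is compared with the mean under the optimal codon, aggregated by an
   exact sign test across the 18 degenerate amino acids.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_rpkm` | 100 | RPKM | inclusion floor for "highly expressed" |
| `fold` | 5 | ratio | sex-bias threshold, inclusive (`>= 5`) |
| `pseudocount` | 0.01 | RPKM | added to both focal values before the ratio so a zero gonad yields a finite, ordered fold |
| `sex_specific_floor` | 1 | RPKM | a biased gene is "sex-specific" when the minor gonad is below this |
| `expr_cutoff` | 200 | RPKM | extreme vs high expression subclass |
| `length_cutoff` | 272 | codons | long vs short CDS subclass |
| `extreme_rscu` | 1.5 | RSCU | per-gene "extreme use" of a codon, inclusive |
| `bin_breaks` | 50, 60 | % | Percent-Non-opt bins: low ≤ 50 < moderate ≤ 60 < high |
| `cai_floor` | 0.01 | weight | weight for reference-absent codons, keeping `log` defined (the classical reference-set practice) |
| `secondary_frac` | 0.8 | ratio | a runner-up non-optimal codon is reported as secondary when its delta reaches this fraction of the primary's |

All printed thresholds are inclusive as written (≥ 100, ≥ 5-fold,
≥ 200, ≥ 272 codons, RSCU ≥ 1.5, bin edges ≤ 50 and ≤ 60).

## Numerical conventions and degenerate inputs

* **Met, Trp and stops** are excluded from every optimality statistic:
  they have no synonymous alternative, so they carry no information
  about codon *choice*. This exclusion applies uniformly to the CAI
  geometric mean, the Fop denominator, Percent-Non-opt, and the
  classification domain (59 codons, 18 amino acids).
* **RSCU of an absent amino acid** is `NA`, not zero: a gene that never
  uses Cys says nothing about its Cys codon preference. Contrasts use
  pairwise NA deletion per codon; the per-codon `n` columns report the
  effective sample sizes.
* **Argmax ties** in optimal-codon assignment go to the alphabetically
  first codon and are flagged (`tie = TRUE`) rather than hidden. An
  amino acid whose maximum delta is not positive is still assigned its
  argmax, with a warning and a `no_positive_optimal` flag.
* **Median demarcation** for tRNA status: counts strictly greater than
  the median are "high"; equal-to-median is "low". The boundary side is
  a convention; it is fixed, documented, and computed over the 59
  degenerate-amino-acid codons (the classification domain), not all 61.
* **t-tests** default to Welch (unequal variances); Student's pooled
  test is available via `var_equal = TRUE`. Per-codon p-values are
  reported raw by default — 59 parallel descriptive tests, not a
  discovery screen — with `p_adjust = "BH"` etc. available.
* **The sign test** is an exact binomial with two-sided p from doubling
  the smaller tail, capped at 1. With n = 18 paired amino acids a
  normal approximation would be inappropriate; the all-one-direction
  case gives exactly `2 * 0.5^18 ≈ 7.6e-06`.
* **Dunn's post-hoc z** after Kruskal-Wallis is computed from pooled
  ranks with the standard tie correction; no installed package provides
  it, so it is implemented here and checked in the test suite against a
  brute-force oracle and against `kruskal.test`'s tie-corrected H.
* **"Ranked ANOVA"** is read as Kruskal-Wallis with Dunn's pairwise
  comparisons, the standard pairing; Dunn p-values are unadjusted by
  default with Bonferroni/BH flags.
* **Per-gene "average RSA"** is the mean over residues (with standard
  errors where reported); medians are available via `center =
  "median"`. Means match the per-residue aggregation used in the
  per-amino-acid comparison.
* **tau** is computed on untransformed RPKM; a `log2_tau` option
  compresses the scale first. All-zero rows give `NA`.
* **Invalid CDS records** (length not divisible by 3, internal stop,
  ambiguous bases) are hard errors by default; batch entry points
  accept `skip_invalid = TRUE` to warn and drop the gene. A terminal
  stop codon is stripped before counting.
* Secondary-structure vocabularies are normalised to
  helix/strand/coil; DSSP-style 8-class codes fold as H,G,I → helix;
  E,B → strand; everything else → coil.

## What the generator emulates — and what it does not

`simulate_codon_study()` produces every pipeline input with known ground
truth. Its defaults are the study conditions the package targets:

* **Gene sets**: 916 testis-like, 258 ovary-like, 605 unbiased genes,
  a 90-gene ribosomal-like reference and a 1,000-gene background;
  log-normal CDS lengths with medians 273, 498, 269, 170 and 350
  codons (`sdlog = 0.45`). The background set stands in for the gene
  catalogue at desk scale.
* **Codon preferences**: per amino acid, a probability vector starting
  from uniform synonymous use; the reference moves 0.5 of its mass onto
  the designated optimal codon (unbiased 0.10, ovary 0.05 — producing
  the stepwise CAI decline from unbiased to ovary to testis), and the
  testis set moves `delta = 0.15` onto the designated primary
  non-optimal codon. Designated optimal codons are C3/G3-ending and
  designated primary non-optimal codons A3/T3-ending, mirroring the
  endings observed in fly genomes. Each gene draws its own preference
  from a Dirichlet centred on the set vector (concentration 40), which
  creates the between-gene variance the per-codon t-tests rely on;
  codons are then i.i.d. per occurrence.
* **Expression**: 59 tissues. Testis-like genes pair high testis
  expression (log-normal around 400 RPKM) with a ~70-fold lower ovary
  value and low off-target expression, yielding tau medians near 0.95;
  ovary-like genes land near 0.83 and unbiased genes near 0.75.
* **tRNA counts**: 12 of the 18 designated optimal codons are
  tRNA-rich, 6 have zero exact matches (wobble); 15 non-optimal codons
  are tRNA-rich and the rest low, with the median near 5.
* **Structure**: secondary-structure classes arrive in geometric-length
  blocks (means: coil 8, helix 10, strand 5 residues; weights tuned for
  residue fractions near 0.6/0.3/0.1); RSA is Beta-distributed with
  class means 0.53/0.34/0.13 (concentration 8), *raised by
  `mu_shift = 0.10`* for residues encoded by the designated primary
  non-optimal codon, clipped to [0, 1]; disorder is RSA plus N(0, 0.2)
  noise, clipped — which reproduces an RSA-disorder Spearman
  correlation around 0.7.

Deliberate simplifications: codons are sampled i.i.d. per occurrence
(no positional autocorrelation, no 5' ramp — occurrence-level statistics
are the target); amino-acid frequencies are uniform over the 18
degenerate amino acids (real proteomes are skewed, which changes power
per amino acid but not the estimators); the RSA-codon coupling is a
constant additive offset (real coupling is regional, via disordered
segments, not per-codon); and no sequence evolution or phylogeny is
modelled. Consequently, passing recovery tests demonstrates that the
estimators detect the statistical structure they target at realistic
sample sizes — not that real genomes contain that structure, and not
robustness to genomic confounders such as GC-content gradients or
mutational bias. One visible artefact of the uniform baseline: roughly
two thirds of baseline codon use is non-optimal, so synthetic
Percent-Non-opt distributions sit far higher than in a real genome where
optimal codons dominate; the bin machinery is exercised, but bin
*occupancies* are not comparable to real data.

## Problem sizes used by the checks

The test suite validates estimator behaviour at deliberately small
scales (tens of genes, hundreds of residues) and uses three larger
seeded experiments: primary-codon recovery at 300 genes per set with
`delta = 0.15` (expected recovery at least 17/18), RSA-direction
recovery at 500 residues per codon class per amino acid with
`mu_shift = 0.10` over 20 replicates (18/18 in at least 19 of 20), and a
null calibration of 2,006 per-codon t-tests in `delta = 0` worlds
(rejection within three binomial standard errors of 5%). The acceptance
script runs the full default-size study once. These sizes were chosen so
each check has clear statistical resolution while the whole suite stays
comfortably re-runnable on a laptop.

## Known limitations

* The primary-call rule (rank on the testis-vs-unbiased delta, gate on
  both deltas positive) is one reasonable formalisation of "the most
  preferred non-optimal codon, robust to both comparison sets"; with
  near-tied non-optimal codons the ranking can flip between datasets,
  which is why close runners-up are surfaced as `secondary`.
* CAI reference adequacy is enforced strictly: a reference set missing
  an entire amino acid is an error rather than silently imputed.
* The per-amino-acid RSA comparison conditions on the *a priori*
  classification and the primary calls; amino acids without a primary
  call (gate not met) drop out of the sign test, and the output reports
  which.
* `classify_sex_bias()` applies the fold rule to pseudocounted values;
  at the exact printed boundary (e.g. 100 vs 20 RPKM) the pseudocount
  nudges the ratio fractionally below the threshold. With the default
  0.01 pseudocount the effect is negligible except exactly at the
  boundary; set `pseudocount = 0` for strict printed-ratio behaviour
  when no zeros are present.
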