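---
title: "Methods: tumour-exclusive peptide discovery and warehouse selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumour-exclusive peptide discovery and warehouse selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepwarehouse)
```

## Scope and model

`tepwarehouse` implements the downstream, post-identification part of an
immunopeptidomics vaccine-design workflow. Its inputs are per-sample tables
of HLA-presented peptides with spectral confidence metrics (PSM count,
Xcorr, deltaCn, Percolator-style q-values), a pooled benign reference
ligandome, cohort HLA typing, and HPV oncogene RNA read counts. Everything
upstream — spectral search, FDR estimation, read alignment — is out of
scope and consumed as tabular output.

The pipeline has seven stages:

1. **Identification filtering.** Records are kept at `q <= 0.05` and
   peptide length 8–25 amino acids, both boundaries inclusive. The filter is
   order-preserving and idempotent.
2. **Binder annotation (class I).** A peptide is an *HLA ligand* when it
   carries a binding motif of an allotype its donor carries. Dedicated
   predictors are deliberately not re-implemented; the package scores
   peptides with additive position-specific weight matrices
   (`motif_matrix()`, one per allele and length, per-allele threshold) and
   combines calls across a patient's alleles with OR. Externally produced
   binder calls can be imported verbatim (`apply_binder_calls()`), and
   record tables that already carry per-peptide allele assignments are used
   directly (`annotate_from_assignments()`). *Purity* is the fraction of
   class I peptides flagged as binders.
3. **HPV calling.** A patient is HPV-positive when any single HPV type has
   ≥500 reads for E6, ≥500 for E7, or ≥500 summed over E1, E2, E4, E5, E6,
   E7, L1, L2. The sum rule is evaluated per type: summing reads across
   types has no biological reading. The called type is the one with the
   most total reads; ties break by E6+E7, then type name, so output is
   deterministic.
4. **Comparative profiling.** A tumour-exclusive peptide (TEP) is present
   in ≥1 tumour ligandome and absent from the benign reference of the same
   HLA class. Class I TEP are computed over binder-annotated ligands, class
   II over all presented peptides, mirroring the distinction between
   "ligands" and "presented peptides". Matching is exact, case-insensitive
   string equality at the peptide level (also for class II, where a
   9-mer-core comparison would be an alternative); isoleucine/leucine are
   kept distinct by default because mass spectrometry cannot separate them
   and exact matching is the conservative choice — `collapse_il = TRUE`
   merges them. Prevalence is the percentage of cohort samples presenting
   the peptide; the conventional candidate filter is ≥3 of 40 samples
   (7.5%).
5. **Cohort statistics.** Allele enrichment builds a 2×2 allele-count table
   (two copies per individual; reference counts reconstructed as
   `round(freq × 2N)`), with Woolf's log-OR confidence interval by default
   (the CI method is configurable because published reports rarely state
   it) and a chi-square p-value, replaced by Fisher's exact test when an
   expected cell is below 5 — both are always reported. Zero cells get the
   Haldane–Anscombe 0.5 correction and are flagged. Population coverage
   uses the standard Hardy–Weinberg/locus-independence formula
   `1 − Π_l (1 − Σ f_covered)²`. Mass–yield association is a Pearson
   correlation with Fisher-z interval via `stats::cor.test()`.
6. **Warehouse optimisation.** For each frequent class I allotype (top 5
   per isotype by carrier count), candidate TEP assigned to that allotype
   and presented by ≥2 carriers form a peptide × carrier incidence matrix.
   The optimiser minimises selection size while maximising carrier
   coverage; the reported selection is the smallest set attaining the
   maximal attainable coverage (which is always the coverage of the whole
   pool, since coverage is monotone), with ties broken by the
   lexicographically smallest peptide list. Spectral QC (PSM ≥2,
   Xcorr ≥1.5, deltaCn ≥0.2, best value across samples, inclusive) is
   applied *after* selection: failing peptides are removed from the pool
   and the optimisation re-runs, up to 3 runs, recording every peptide that
   ever entered a selection as a warehouse candidate. Class II selection is
   allotype-agnostic over the whole cohort (candidates: TEP in ≥3
   ligandomes passing QC), because a single cohort-level class II set is
   the reported design. Allotypes whose pool attains coverage of ≤1 carrier
   are skipped as negligible.
7. **Compositions.** A patient's semi-personalised composition is the union
   of selections for the allotypes they carry; the realised fraction is the
   share of those peptides present in their own ligandome.

## Numerical choices in the optimiser

Instances with ≤20 candidate peptides are solved exactly: subset coverage
is computed for all `2^n` subsets by a doubling dynamic programme over
two 31-bit patient masks (cohorts of up to 62 carriers per allotype), and
the Pareto front is read off as the best coverage per size, keeping
strictly improving points. Larger instances use greedy seeding (maximum
marginal coverage, first-index tie-break) followed by seeded local search:
each proposal either perturbs the incumbent minimal full-coverage set
(drop one, greedily repair, prune redundant members, largest index first)
or samples a random subset to improve the best-coverage-per-size table.
The iteration budget counts proposals; a seed is mandatory on this path
and makes results bit-for-bit reproducible. On small instances the
stochastic path is tested never to exceed the exhaustive optimum. When QC
re-runs are exhausted and the final selection still contains failing
peptides, the QC-clean subset is reported with its recomputed coverage, so
selections never contain QC failures.

Saturation of source proteins is estimated from the permutation-averaged
accumulation curve (all orderings when ≤7 samples, otherwise 100 seeded
random orderings) fitted with `S(n) = S_max (1 − e^{−kn})` by least
squares (`nls`, with a Levenberg–Marquardt fallback). The exponential form
is a stand-in — the estimator behind published saturation percentages is
typically unnamed — and is labelled as such in the output
(`fit_method`). A flat curve short-circuits to 100% attained; a failed fit
returns the curve with `NA` estimates and a warning rather than an error.

## The synthetic cohort generator

`simulate_cohort()` emulates the joint structure the analysis assumes, and
its defaults are the study conditions: 40 patients, 55% HPV-positive
(positive count fixed at `round(n × frac)`), genotypes drawn under
Hardy–Weinberg from a compact European-style frequency table in which
HLA-B*51:01 carries the enriched cohort frequency (16.2%), mean class I
ligandome of 1338 peptides with 70% 9-mers, mean class II ligandome of 702
peptides with modal length 15 (17%), and a target mass–yield correlation
of 0.4645 implemented as a bivariate normal on (log mass, log yield) — the
simplest generator achieving a prescribed Pearson r. Where the study
conditions do not pin a value, one realistic choice was made once: a
shared (allotype-attached) class I pool of 400 peptides and class II pool
of 300, presented by an eligible carrier with probability 0.35 so that
shared peptides typically appear in the low single digits of patients; a
benign-overlap fraction of 0.77, leaving roughly a quarter of cohort
peptides tumour-exclusive as in the measured data; 1000 benign-only
background peptides; and a QC pass fraction of 0.6. HPV-positive patients
receive one type (HPV-16 weighted 19:1:1:1 against HPV-35/-58/-59) with E6
and E7 planted above the 500-read threshold; negatives draw ~8 background
reads per type, far below it.

Each generated table draws from its own named random stream derived from
the master seed, so adding a table never perturbs the others, and the
whole simulation is byte-identical for a fixed seed. Q-values are drawn in
(0, 0.05] and lengths within 8–25, i.e. simulated records already satisfy
the identification filters; this keeps the planted truth — TEP are exactly
the planted non-benign peptides, incidence matrices are exactly the
planted allotype attachments — recoverable by construction, which is what
the planted-truth suites assert. The filters themselves are exercised on
hand-built fixtures instead.

What the generator does not emulate, and what passing tests therefore do
not show about measured data: real binding-motif sequence composition
(peptides are uniform random over the alphabet apart from planted motif
anchors), source-protein structure (no protein annotations are planted, so
saturation is exercised on separate fixtures), retention-time or abundance
structure, shared peptides between patients outside the designed pools,
and any correlation between QC quality and peptide identity.

## Problem sizes in the checked examples

The test suite solves the optimiser against brute-force subset enumeration
on 200 random incidence matrices of up to 12 peptides × 10 patients, runs
planted-truth recovery on a full 40-patient cohort at the default
ligandome sizes, and checks frequency convergence on a 5000-patient
genotype-only simulation. The acceptance script runs the complete pipeline
on the default 40-patient configuration with a 2000-proposal local-search
budget for the (few) allotypes whose candidate pools exceed the exhaustive
limit of 20.

## Known limitations

* The motif scorer is a pluggable stand-in, not a trained predictor;
  absolute purity values on real data require imported predictor calls.
* Exclusivity is exact sequence matching; substring (nested-peptide)
  relationships between class II peptides are not collapsed.
* The per-type reading of the HPV sum rule and the OR-combination of motif
  calls are package decisions where the conventions are unstated; both are
  recorded in the run manifest's assumption list.
* Reference allele counts are reconstructed from rounded published
  frequencies, so odds ratios can differ in the last digit from those
  computed on raw counts.
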