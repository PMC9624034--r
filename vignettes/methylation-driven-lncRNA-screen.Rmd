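---
title: "Screening for methylation-driven lncRNAs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for methylation-driven lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmeth)
```

# The problem

Promoter hypermethylation is a classic route to transcriptional silencing,
and long noncoding RNAs are increasingly nominated as tumor suppressors or
oncogenes on methylation grounds. The screen implemented here asks, for a
tumor/normal cohort profiled on a 450K-style methylation array and by
RNA-seq: *which lncRNAs are both differentially expressed and carry a
differentially methylated CpG in their promoter?* The surviving (CpG,
lncRNA) pairs — "methylation-driven" lncRNAs — are then candidates for
single-gene validation: clone-level bisulfite sequencing of the promoter,
a diagnostic cut-off on the methylation rate, and survival stratification.

This vignette explains each model, its parameters and defaults, the
numerical conventions, and the design decisions that were genuinely open.

# Coordinates and promoter annotation

All internal coordinates are **0-based half-open**. GTF input is 1-based
inclusive and converted on ingest (`start - 1`); the 4-column manifest
extract is declared 0-based, with `one_based = TRUE` available for 1-based
extracts. One convention internally eliminates off-by-one drift between
the probe, transcript and window arithmetic.

The promoter of a transcript spans strand-relative offsets
`[-upstream, +downstream)` around the TSS (defaults 2500 and 1000 bp, so
3500 bp when unclipped). For a plus-strand transcript the TSS is `start`;
for a minus-strand transcript we take the **last transcribed base**
(`end - 1`) — the standard antisense convention; nothing in the screen's
definition forces another choice. Windows are clipped at the chromosome
origin. Probes are joined to windows by half-open containment of the CpG
cytosine position, ignoring probe strand: a CpG is strand-symmetric, and
450K probes interrogate one CpG regardless of design strand. Pairs are
deduplicated at gene level by default, so multi-TSS genes union their
promoters (`by = "transcript"` keeps per-transcript rows); gene-level is
the most inclusive, deterministic reading of "the promoter of a lncRNA".

CpG islands use the Gardiner–Garden criteria: 200-bp windows sliding 1 bp,
GC fraction ≥ 0.5 and observed/expected CpG = `#CG * L / (#C * #G)` ≥ 0.6.
Passing windows whose intervals overlap or touch are merged and the merged
island is revalidated against the same thresholds; `N` bases count toward
window length but not composition. The merge-then-revalidate scheme is our
choice — island predictors differ in their internals, and the published
criteria themselves are the stable part.

# Differential screens

**Expression.** Counts are normalized to CPM with a pseudocount
(`(c + 0.5) / (lib + 2 * 0.5 * n_genes) * 1e6`), keeping values strictly
positive so log2 fold changes are always defined. Per gene we use a
two-sided Mann–Whitney U test: exact null when the combined sample size is
at most 12 with no ties (small pilot designs), normal approximation with
tie correction otherwise — the switch balances exactness and speed.
Benjamini–Hochberg controls the FDR across genes, and a gene is `up`/`down`
when `fdr < 0.05` and `|log2fc| >= 1` (fold change ≥ 2). The rank test is
deliberately the built-in engine: it is assumption-light and invariant to
monotone transforms. Externally produced tables from count-model packages
can be imported with `read_de_table()` and intersected via
`consensus_de()`, which requires every method to call the gene significant
and (by default) to agree on direction; whether a consensus should demand
direction agreement is not a settled convention, so it is a flag.

**Methylation.** Per probe, Δβ = mean tumor β − mean normal β over
non-missing entries, the same rank test, and BH across tested probes.
Probes with fewer than 2 observed values per group are skipped and
reported, not silently dropped.

# DMR detection

Region calling follows the bump-hunting scheme whose vocabulary matches
the stated parameters (resamples, cut-off, minimum probe count): probes
are clustered per chromosome with inter-probe gaps ≤ 500 bp (`max_gap`,
exposed as an argument — array spacing varies and no single value is
canonical); a candidate region is a maximal run of consecutive probes with
`|Δβ| ≥ 0.2` and a common sign; candidates with fewer than 2 probes are
discarded. Significance is empirical: sample group labels are permuted 100
times, the maximum candidate area (Σ|Δβ|) per permutation forms the null,
and `p = (1 + #{null ≥ observed}) / (resamples + 1)` — add-one smoothing
keeps p strictly positive, standard permutation practice. Two documented
simplifications relative to smoothing-based region callers: no loess
smoothing of the Δβ profile, and area is the unweighted sum of |Δβ|.
Missing betas are imputed as the group mean **only inside permutation
rounds**, keeping the permutation null exchangeable while the reported Δβ
uses observed values.

# Integration

A pair is called when the probe is significantly differentially methylated,
the gene significantly differentially expressed, and the (probe, gene)
edge is in the promoter join. Direction concordance (hyper+down or
hypo+up) is annotated but **not required by default**: a screen of this
shape legitimately reports both hyper- and hypomethylated lncRNAs, and the
concordance filter is a biological prior, so it is a flag
(`require_concordance`). Pairs are annotated with Spearman's ρ between the
probe's beta values and the gene's normalized expression (average-rank
ties; exact permutation p at n ≤ 8, t approximation otherwise). For
"top-k" style rankings each gene is represented by its max-|Δβ| promoter
probe, ties broken lexicographically — some per-gene representative rule
is needed and the maximum is the least surprising.

# BSP clone analysis

A clone is compared with the untreated reference position by position; at
each CpG cytosine C reads as methylated, T as unmethylated, and anything
else (including an alignment gap) as ambiguous. Ambiguous calls are
excluded from both numerator and denominator of the methylation rate, so
sequencing errors do not bias it. The bisulfite conversion rate — the
fraction of **non-CpG** reference cytosines read as T — is the per-clone
QC; the threshold of 0.95 is the conventional acceptance class for
clone-based bisulfite work. Clones with indels are pre-aligned with
Needleman–Wunsch (match +1, mismatch −1, gap −2, C/T and G/A scored as
matches, since only the bisulfite top strand is modelled). Per-sample
rates pool passing clones; the protocol expectation of 10 clones per
sample is enforced as a warning, not an error. Group comparison is the
Mann–Whitney test, or the Wilcoxon signed-rank variant for declared
tumor/normal pairs.

# ROC and survival

ROC thresholds sit at midpoints between consecutive distinct marker
values, plus infinite sentinels; a sample is positive when its value is
≥ the threshold (methylation high = tumor, reversible by flag). Midpoints
make cut-offs independent of sample order and handle ties exactly — the
trapezoid AUC equals the pairwise U-statistic with half-credit for ties.
The Youden cut-off maximizes J = sens + spec − 1; ties are broken toward
higher sensitivity, then the lower cut-off (a screening-friendly rule,
stated because the optimum is frequently non-unique on small cohorts).

Survival uses the product-limit estimator and the two-group log-rank test
(hypergeometric variance, 1-df chi-square), with markers dichotomized at
the median using a strict `>` for the high group — the split rule is not
universal, so the quantile is configurable. Truncation at 60 months is not
applied by default.

# The synthetic-data model

The generators emulate the statistical structure the analysis assumes,
with effect sizes chosen to echo the regimes such screens report:

* **Methylation**: null probes i.i.d. Beta(2, 2) in both groups; driver
  promoter probes Beta with mean 0.15 (normal) shifted by the planted
  Δβ = 0.5 in tumors (hypo drivers mirror around 0.85); moment
  parameterization with precision 30.
* **Expression**: gene baselines log-normal (median 300 counts); planted
  log2 fold change 2 for drivers (hyper → down, hypo → up); negative
  binomial counts with dispersion 0.2; in linkage mode each driver's
  per-sample mean is scaled by `2^(-k * centered promoter beta)`, inducing
  the negative methylation–expression correlation the integration stage
  looks for.
* **BSP**: per-sample methylation probabilities drawn from a
  mean-preserving Beta (precision 10) around group means 0.361 (tumor) and
  0.055 (normal); per-CpG Bernoulli methylation; C→T conversion with
  efficiency 0.99 at unmethylated CpG and non-CpG cytosines.
* **Survival**: exponential event times, baseline hazard log(2)/24 per
  month (24-month median), hazard ratio 3 for the high-marker group;
  each subject censored with probability 0.3 at a uniform fraction of its
  event time.
* **Sample sizes**: 20 vs 20 arrays, 300 genes, 2000 probes, 18 BSP tissue
  pairs with 10 clones each — small enough for the full pipeline and test
  suite to run in seconds to a couple of minutes, large enough for the
  planted effects to be recovered with high power.

Each generator draws from its own stream derived from the master seed by a
fixed offset, so identical seeds give byte-identical fixtures even when
only part of the pipeline is rerun.

What the simulation does **not** model: Infinium I/II probe chemistry and
its beta-value compression, batch and cell-composition effects,
read-level RNA-seq (isoform structure, GC bias), chromatogram noise in
Sanger clones, and informative censoring. Passing tests therefore show the
algorithms are correct under the assumed data model, not that the screen
is robust to every artifact of real cohorts.

# Numerical conventions and degenerate inputs

* All-constant features: p = 1, log2fc/Δβ = 0, never significant.
* Zero-total-count samples are an error naming the sample.
* Youden maximization tolerates division round-off of 1e-9 when
  collecting the tie set.
* Empty candidate sets (no probe over the DMR cutoff, empty pair tables)
  are valid empty results, not errors; an empty pair table is a warning at
  the pipeline level.
* An amplicon with no non-CpG cytosine has an undefined conversion rate;
  such clones conservatively fail QC.

# Interfaces

The exported functions and persisted TSV intermediates are the package's
interface; `run_screen()`, `run_validation()` and `run_demo()` orchestrate
the arms file-to-file with a JSON run manifest (config hash, input
checksums, per-stage counts), and `inst/scripts/lncmeth-pipeline.R` is a
thin shell entry point over those three calls.

# Known limitations

No IDAT parsing or array normalization, no dispersion-model count testing
(import such tables instead), no liftover, no Cox regression, no primer
design, and no NGS bisulfite alignment. The DMR caller is a documented
simplification of smoothing-based bump hunting and is not claimed to match
any specific array package bit-for-bit.
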