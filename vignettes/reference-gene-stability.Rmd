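---
title: "Reference-gene selection: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene selection: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkgselect)
```

`hkgselect` selects reference (housekeeping) genes for relative expression
studies under a two-condition contrast, typically hypoxia (Hx) versus
normoxia (Nx) across several donor cell lines. This vignette describes the
statistics the package implements, the defaults and why they were chosen,
what the synthetic-data generator does and does not emulate, and the places
where the design was genuinely open.

## Stage 1: the RNA-seq screen

### Normalization

Two normalizations feed the screen, because a gene that looks stable under
one but not the other is suspect:

* **TPM** (`tpm_normalize()`). The default `standard` mode computes
  length-normalized rates `count / (length/1000)` and rescales each sample so
  its rates sum to one million; columns sum to 1e6 exactly. The `literal`
  mode instead divides the rate by the library size in millions, which is
  the classic three-term formula read verbatim with "sequencing depth" as
  library size. The two differ by a per-sample constant, so CVs computed
  within a sample set are very close but not identical; both modes are
  provided because printed results at two-decimal precision cannot
  distinguish them. `standard` is the default because it is the definition
  in common use.
* **Median-of-ratios size factors** (`size_factor_normalize()`). The size
  factor of a sample is the median, over genes with all-positive counts, of
  that sample's count divided by the gene's geometric mean across samples.
  The median is taken on the log scale, so an even number of reference genes
  interpolates geometrically — this is the canonical estimator, and the
  implementation is cross-checked against DESeq2's
  `estimateSizeFactorsForMatrix` in the test suite. There is no
  pseudo-reference fallback: if no gene is positive everywhere the function
  stops, since a screen on such data would be meaningless.

### The screening statistic

For each candidate gene, cell line and normalization method, the test and
control samples of that line are **pooled together** and

\[ CV = \frac{SD_{Hx\,and\,Nx}}{mean_{Hx\,and\,Nx}} \]

is computed (a pooled record across all lines is reported as `cell_line =
"ALL"` but does not enter the qualifying grid). The SD is the sample
((n-1)-denominator) SD by default — per-line sample counts are small — and
is switchable to the population SD via `screen_config(sd_type =
"population")`.

Per gene, the **mean qualifying CV** averages the per-line x per-method CVs
at or below `cv_threshold` (default 0.15, the conventional "stable
expression" cutoff on normalized counts). A gene with no qualifying CV is
ineligible — a value, not an error — and the number of qualifying CVs is
reported so users can require consistency across lines if they wish; the
package deliberately does not enforce a minimum beyond one.

Eligible genes are then scored:

\[ score = \frac{\overline{CV}}{\min \overline{CV}}
         + \frac{|L2FC|}{\min |L2FC|} \]

Both terms have minimum exactly 1, so the best possible score is 2. The
fold-change term uses the **absolute** log2 fold change — "smallest" means
closest to zero, so a gene at -0.02 beats one at +0.05. If the minimal
|L2FC| is exactly zero that gene takes the value 1 and the others divide by
a configurable floor (default 1e-3) with a warning, since the published
procedure never encounters an exact zero. Ties in the summed score are
broken by smaller mean CV, then gene symbol, and flagged in the output; the
procedure as published never exhibits ties.

The log2 fold change itself is a first-class **input**: the screen is
designed to consume an externally produced, shrunken differential-expression
table (`read_l2fc_table()`, columns `gene`, `l2fc`, `adj_p`). Dispersion
estimation, shrinkage and variance-stabilizing transforms are deliberately
out of scope. When no table is supplied, `naive_l2fc()` provides
`log2((mean_test + pc)/(mean_control + pc))` on size-factor-normalized
values with pseudocount 0.5 (configurable; keeps zero means finite).

`filter_low_counts()` (total count < 10 removed) matches the usual
pre-filter applied before differential expression; `de_filter()` implements
the |L2FC| >= 2 at adjusted-P <= 0.05 convention for extracting regulated
genes. `apply_exclusion()` flags or drops candidates present on a
hypoxia-inducible list; the bundled list
(`builtin_file("hypoxia_inducible")`) is a labelled synthetic stand-in built
from canonical HIF-1 targets, not a complete curated resource, and the
policy defaults to `warn` because exclusion lists are never exhaustive.

### Fold-change reporting

`l2fc_to_fold()` and `signed_fold()` use the negative-reciprocal convention
common in qPCR reporting: `2^l2fc` when positive, `-2^(-l2fc)` when
negative, so a halving prints as -2.0 rather than 0.5 and `|fold| >= 1`
always. The function is odd-symmetric on the log scale.

## Stage 2: qRT-PCR stability validation

### Preprocessing and the detection limit

`preprocess_ct()` removes observations flagged below detection or at/above
the limit of detection (default Ct 35, where single-copy noise dominates),
then averages technical replicates per (gene, line, condition, run). Runs
stay separate samples: qPCR plates shift globally between runs, and the
pairwise/ratio structure of all downstream statistics absorbs per-sample
shifts, whereas averaging across runs would not. QC notes are emitted for
replicate means outside the 14-32 raw-Ct working range typical of
high-copy-number reference genes, and when a line's gene means span more
than 10 cycles (reference and target genes far apart in Ct amplify
efficiency errors).

### The estimators

All methods operate per cell line on the genes x samples matrix of mean Ct.

* **GeNorm** (`genorm()`). Ct is converted to relative quantities
  `q = 2^(minCt - Ct)` (efficiency exactly 2); for each gene pair the SD
  over samples of the pairwise log2 ratio is computed, and `M` is a gene's
  mean over its pairs. Pairs are evaluated pairwise-complete; pairs with
  fewer than two common samples are skipped with a warning. The stepwise
  exclusion order and the pairwise variation `V(n/n+1)` of geometric-mean
  normalization factors are returned, but gene *ranks* come from the
  full-panel M values: the stepwise procedure cannot separate its final
  pair, while the full-panel M is defined for every gene.
* **Comparative delta-Ct** (`delta_ct_method()`). The mean over partner
  genes of the SD of the pairwise Ct difference. On two-gene inputs this is
  identical to GeNorm's M, a relationship the test suite asserts.
* **BestKeeper** (`bestkeeper()`). Arithmetic mean, SD and CV% of raw Ct per
  gene, plus the Pearson correlation of each gene with the BestKeeper index
  (per-sample geometric mean of candidate Cts). With missing entries the
  index uses the genes available in each sample — a documented deviation
  from the original complete-case tool. Stability orders by SD ascending,
  ties by larger correlation; correlations are undefined (NA) with fewer
  than three complete samples or zero variance.
* **NormFinder** (`normfinder()`). On log-scale expression (negated Ct) the
  additive model *expression = gene effect + sample effect + error* is
  fitted per condition group by two-way centering. With k genes and group
  size n, the centered per-gene sample variance `s2_ig` satisfies
  `E[s2] = (1 - 2/k) sigma2_ig + sum_l sigma2_lg / k^2`, giving the
  closed-form estimate `sigma2_ig = max(0, (s2_ig - S_g/(k(k-1))) k/(k-2))`
  with `S_g = sum_i s2_ig`. The intergroup variance `gamma2` is estimated by
  method of moments from the gene-centered group differences, which are then
  shrunk by `gamma2 / (gamma2 + sigma2_ig/n_g)`. The stability value is
  `mean_g |shrunken difference| + sqrt(mean_g sigma2_ig/n_g)`; lower is more
  stable. When a group has fewer than two samples the ungrouped variant
  (`sqrt(sigma2_i)` from a single-group fit) is used. Missing entries can be
  mean-imputed within (gene, group) (`na_action = "impute"`); a gene missing
  an entire group must be excluded by the caller. At least three genes are
  required (the k-2 denominator).
* **RefFinder aggregation** (`reffinder_aggregate()`). Geometric mean of the
  four method ranks, re-ranked ascending, ties broken by the delta-Ct rank.
  The published web tool's exact weighting is not public; this package
  implements the four constituent estimators from their primary definitions
  and aggregates with an unweighted geometric mean, so numeric agreement
  with the web tool is not guaranteed (the orderings are what the combined
  ranking consumes).
* **Livak 2^-ddCt** (`livak_fold()`). Within each (line, run), the reference
  Ct is the arithmetic mean of the reference genes' Cts — equivalent to the
  geometric mean of their linear quantities, the recommended multi-reference
  normalization. `ddCt = (Ct_target - Ct_ref)_test - (Ct_target -
  Ct_ref)_control`; per-line values average ddCt over runs *on the log
  scale* before converting to a signed fold. Runs with the target or a
  reference below detection are skipped with a warning. Amplification
  efficiency is assumed to be exactly 2 throughout; no efficiency-corrected
  variant is provided.

### The Livak-based stability rank

The step-wise relative-expression comparison is summarized as: for gene g,
with every other candidate h serving as reference in turn, score
`mean |ddCt(g | h)|` over references and runs. Because the ddCt grid is
additive (`ddCt(g|h) = D_g - D_h` with `D_g` the gene's own condition
response), the SD over references is the same for every gene, so a
magnitude-based spread is the only informative reading of "variation across
references"; the per-gene fold grid remains available through
`livak_fold()` for alternative summaries. A gene with no run in which both
it and a partner are measured in both conditions gets NA and the worst rank.

### Combining methods, lines and the drop policy

`combined_ranking()` ranks each line by the four stability methods, the
RefFinder aggregate and the Livak-based score, takes the mean of the six
ranks (default; `variant = "reffinder"` uses the RefFinder rank alone — the
published description of which ranks enter the overall average is ambiguous,
so both are emitted and the six-method mean, which uses all computed
evidence, is the default), and re-ranks. Overall ranks average the per-line
final ranks and re-rank ascending.

A gene whose measurements hit the detection limit anywhere in a line is
excluded from that line's model fits and assigned the line's worst ranks
(`drop_policy = "any_below_detection"`, the default). The rationale: removal
of below-detection values silently *hides* instability — the gene's worst
samples are exactly the ones deleted — so a candidate that drops out of the
detectable range under treatment cannot be assessed as a reference and
should be penalized, not laundered. `drop_policy = "all_missing"` retains
such genes (pairwise-complete) and only drops genes with no retained
observation in the line. Lines with fewer than two analyzable candidates are
excluded from the overall average with a note.

## The synthetic-data generator

`sim_config()` defaults encode the study design the package targets: 5 donor
lines x 2 conditions x 2 replicates for RNA-seq, and 4 lines x 2 biological
runs x 3 technical replicates for qPCR. Counts are negative binomial with
`Var = mu + a mu^2`: 10 designated stable genes at dispersion 0.01,
20 regulated genes at dispersion 0.05 with log2 effects recycled from
(±1, ±2, ±3), and background genes at dispersion 0.1 — conventional bulk
RNA-seq values. Donor effects are multiplicative log2-normal offsets
(SD 0.25) shared by a line's samples, mimicking donor-to-donor spread; mean
depth is 1e6 reads over the simulated gene set; gene lengths are log-uniform
on 500-10000 bp. Ct tables follow
`Ct = intercept - log2(relative expression) + N(0, 0.3)` per
(gene, line, condition, run) plus `N(0, 0.2)` per technical replicate, with
efficiency exactly 2 and the detection limit at Ct 35; the intercept (25)
puts median-abundance genes mid-range so the usual 14-32 window is mostly
respected.

What the generator does **not** emulate: sequencing batch effects (real
multi-donor datasets are often sequenced in batches, and batch is not
modelled here beyond the donor offset), library-preparation and length
biases, amplification-efficiency
differences between assays, inter-plate calibration drift, and rRNA species
invisible to poly-A selection. Passing the recovery tests therefore shows
the estimators separate designed stable from designed regulated genes under
idealized noise — not that any particular real gene is stable.

The recovery properties asserted in the tests use the generator defaults: on
50 seeded runs the screen places at least 9 of the 10 designed stable genes
above every regulated gene, and a designed-unstable gene (l2fc 2) among five
stable candidates ranks last in the combined validation, each in at least
95% of runs. Problem sizes (100 genes x 20 samples; 6 genes x 4 lines) were
chosen as the smallest instances at which those frequencies are stable.

## Numerical choices and degenerate inputs

* Sample SD everywhere unless configured otherwise; documented above.
* Rankings are deterministic: ties break by the stated secondary statistic,
  then gene symbol; no random tie-breaking anywhere.
* `genorm` with two genes returns equal M for both (the pair SD) without a
  stepwise phase; `V` requires at least three genes.
* Zero-mean expression blocks make a CV undefined: the record is flagged and
  never qualifies, rather than erroring.
* Below-detection tokens accepted in Ct files are `">NN"` and
  `"Undetermined"` (configurable regexes), per the usual instrument exports.
* All tabular outputs are TSV with one header row and four-decimal floats.

## Known limitations

* The screen's qualifying-CV average is sensitive to the CV threshold near
  0.15; genes hovering at the cutoff can change eligibility between
  normalizations. The per-line CV grid is exposed so users can inspect this.
* TPM underestimates stability for very low-expressed genes (tiny absolute
  SDs produce large CVs); candidates should be screened at expression levels
  comparable to the genes of interest.
* NormFinder's variance estimates can clip to zero with few genes (k = 3)
  and small samples; ranks remain defined but closely separated genes should
  not be over-interpreted.
* The RefFinder aggregation here is unweighted; the public web tool may
  weight ranks differently.
* rRNA references (e.g. 18S) cannot be screened from poly-A RNA-seq at all —
  stage 1 and stage 2 are complementary, not redundant.
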