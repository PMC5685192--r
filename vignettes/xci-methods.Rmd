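---
title: "Calling XCI status from allele-specific expression: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling XCI status from allele-specific expression: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciase)
```

## The problem

X-chromosome inactivation (XCI) silences one X in female cells, but
silencing is incomplete: many X-linked genes escape and keep expressing from
the inactive X (Xi), usually at a fraction of the active-X (Xa) level.
Bulk RNA-seq of a typical female tissue mixes two cell populations (maternal
X active / paternal X active), which cancels the allelic signal. `xciase`
implements the two designs that sidestep the mixture:

1. **A donor with fully skewed XCI**: every cell silences the same X, so
   bulk allelic counts at heterozygous sites read out Xi expression
   directly, in as many tissues as were sampled.
2. **Single cells**: each cell is internally pure. Allelic counts per cell
   reveal which haplotype is active, and aggregating across cells of the
   same population reads out Xi expression.

## The Xi-expression test and its error bound

Both callers reduce to the same primitive. For a gene with $k$ reads from
the putative Xi allele out of $n$ total, Xi expression is declared when a
one-sided exact binomial test rejects

$$H_0: k \sim \mathrm{Bin}(n, p_0), \qquad p_0 = 0.025,$$

with FDR correction (Benjamini–Hochberg by default; a Storey-type
$\pi_0$-scaled variant is available) applied within each tissue or each
sample separately, and significance at $q < 0.01$. The null is *not* zero:
$p_0$ is an empirical upper bound on the allele-miscall rate — the rate at
which reads report the wrong allele through sequencing error or residual
mapping bias. The natural calibrator is *XIST*, which is expressed from Xi
only, so in a fully skewed sample any Xa-allele reads at *XIST* are
miscalls; 2.5% is the upper end of what such calibration yields, and using
it as $H_0$ makes the caller conservative whenever the true miscall rate is
lower. The same bound absorbs the single-cell setting's allelic dropout:
dropout deletes reads but does not manufacture wrong-allele reads, so
aggregate tests stay valid (at some cost in sensitivity).

Binomial machinery details: the two-sided test (used for the X/Y dosage and
direction-bias analyses) follows the minimum-likelihood convention, which
coincides with tail-doubling at $p_0 = 0.5$. The exact Wilcoxon signed-rank
test enumerates the sign-flip null by convolution over realized (mid)ranks
for $n \le 30$ — ties and zero-differences are handled explicitly, which is
why the package carries its own implementation — and switches to a
continuity-corrected normal approximation above. Binomial proportions are
interval-estimated with Jeffreys intervals, $\mathrm{Beta}(k + \tfrac12,
n - k + \tfrac12)$ central quantiles, with the conventional endpoint forcing
at $k = 0$ and $k = n$.

## Skewed-donor calling

Sites are filtered (blacklist, coverage floor), mapped to genes, and reduced
to **one site per gene** — the site covered by more than 7 reads in the most
tissues, ties broken to the smaller coordinate so the choice is
order-invariant. Allele orientation: the Xi allele is the allele with the
lower mean per-tissue expression fraction pooled across tissues (per-tissue
fractions, not pooled reads, so deep tissues do not dominate); at *XIST* the
orientation is inverted. An exactly balanced site is unresolvable and is
excluded rather than guessed.

Per-gene classification across tissues:

- `full` — no significant tissue;
- `incomplete_single_context` — exactly one significant tissue among at
  least two *powered* tissues;
- `incomplete_shared` — several significant tissues with max/min Xi
  fraction at most $H = 3$ (configurable);
- `incomplete_heterogeneous` — otherwise.

A tissue is *powered* when its coverage gives at least 80% power to detect
an Xi fraction of 0.10 at the nominal $q$ threshold. This makes
"escape in exactly one tissue" a falsifiable claim: it is only asserted when
the silent tissues had the coverage to show escape if it were there. (At
100 reads the power for a 0.10 Xi fraction is 79%, i.e. just under the bar —
single-context claims effectively require somewhat deeper coverage, which is
intended.) The across-tissue classifier is a deterministic replacement for
hierarchical Bayesian tissue models used in some analyses; the per-tissue
binomial machinery beneath it is preserved exactly, and $H$ trades off
shared-versus-heterogeneous granularity without affecting which genes are
called incompletely inactivated at all.

Skew screening (`estimate_skew`) summarizes candidate donors by the
read-weighted mean major-allele fraction over catalogued-inactive nonPAR
sites, folded to $[0.5, 1]$ because parental labels are unknown without
phasing: 0.5 is balanced XCI, 1.0 fully skewed.

## Single-cell calling

Per-cell biallelic detection assesses only cell-site observations with at
least 8 reads and flags those with minor-allele fraction above 0.05 *and* a
nominally significant ($p < 0.05$) one-sided binomial excess over $p_0$; a
gene needs two such observations to be called biallelic within a sample.
Sites that are biallelic in more than 10% of their covered cells, plus all
PAR1 sites (PAR1 genes escape by construction), are excluded from phase
inference so escape genes do not blur the partition.

With trio phasing, each cell is assigned to the parental population whose
haplotype matches the majority of its expressed alleles (each site votes by
its within-cell majority allele). Without trio data, the partition is
inferred: a cell–cell agreement matrix (matches minus mismatches of
majority alleles over shared, non-excluded sites) is split by the sign of
the leading eigenvector of the centered matrix, then refined by alternating
(i) re-estimating each site's population-1 allele from *read-weighted*
population sums and (ii) re-assigning cells by agreement, to a fixpoint.
Read weighting in step (i) matters: a per-cell majority vote becomes nearly
uninformative at sites whose Xi fraction approaches 0.5 under heavy
dropout, while expected read differences keep the sign of $1 - 2f$ for any
$f < 0.5$. The partition is identifiable only up to a global label swap;
cells with agreement below 0.8 are demoted to uninformative (a doublet /
contamination guard), and cells whose only observations sit at excluded
sites are reported uninformative rather than dropped. After assignment the
phase is extended to all sites (including excluded ones) from read-weighted
population sums, and *XIST*'s site phase is flipped — it expresses the
inactive haplotype, so its inferred orientation is systematically inverted,
and anchoring it restores the convention that its reads aggregate to Xi.

Aggregation maps, per cell, the active-haplotype allele to Xa and the other
to Xi, then sums over cells and sites per gene. Genes with fewer than 5
contributing cells or fewer than 8 aggregate reads are `not_assayed`
(distinct from `inactive`). The binomial test against $p_0$ with per-sample
FDR correction yields `escape` at $q < 0.01$.

## The synthetic-data generator

The generator is first-class, tested code; its defaults encode the study
conditions the callers target:

| parameter | default | meaning |
|---|---|---|
| `escape_fraction` | 0.23 | nonPAR genes escaping XCI |
| `tissue_specific_escape_fraction` | 0.058 | subset escaping in exactly one tissue |
| `xi_to_xa_mean` | 0.33 | mean Xi/Xa expression ratio at escape genes |
| `par1_xi_to_xa_mean` | 0.80 | Xi/Xa ratio at PAR1 genes |
| `miscall_rate` | 0.025 | per-read wrong-allele probability |
| `n_tissues`, `depth_mean` | 16, 100 | bulk design and negative-binomial site depth |
| `n_cells`, `sc_depth_mean` | 200, 20 | single-cell design |
| `dropout_rate` | 0.7 | per-allele transcript-pool dropout per cell-site |
| `skew` | 0.5 | probability a cell's active X is haplotype 1 |

Modeling choices worth stating:

- Per-gene Xi/Xa ratios are drawn from a Beta distribution **on the ratio
  scale** (mean `xi_to_xa_mean`, concentration 10), so Xi expression never
  exceeds Xa. This matches the phenomenon being emulated — escape
  expression rarely reaches Xa levels — and keeps the phasing problem
  well-posed (a gene expressing Xi *more* than Xa is indistinguishable from
  a phase flip by any expression-based method).
- Read depths are negative-binomial (overdispersed coverage); sites per
  gene are Poisson(2) truncated at $\ge 1$, exercising the site-to-gene
  collapse.
- Single-cell dropout acts on the **transcript pool before sequencing**:
  each allele's transcripts are removed with probability `dropout_rate`,
  read depth scales with the surviving pool, and per-read miscalls are
  applied to the sampled reads. Dropout therefore thins coverage without
  biasing aggregate allele fractions, and — critically — a dropped-out
  active allele cannot leave behind a majority of phantom miscall reads.
- The sex-expression simulator adds unbiased autosomal background genes
  (1000 by default). Without them, escape-driven female excess on chrX
  would shift the library-size normalization and masquerade as male bias at
  every unbiased gene — in real data the rest of the transcriptome anchors
  normalization, and the background genes play that role here. Expected
  female:male ratios are $(1 + r)$ at nonPAR escape genes and $(1 + r)/2$
  at PAR1 genes (male X+Y output in the denominator), with negative-binomial
  counts around log-normal baselines.
- Chromatin coverage rows are Dirichlet draws over the 15 Roadmap-style
  states (rows sum to one exactly); escape genes have configurable states'
  concentrations multiplied by a shift factor.

What the generator does *not* emulate: reference-mapping bias, positional
correlation of escape along the chromosome, cell-type structure, batch
effects, and covariate-driven expression variation. Passing tests therefore
demonstrate correctness of the inference machinery under the stated
generative model, not robustness to every artifact of real data — the
miscall bound and the site blacklist are the hooks real-data artifacts are
meant to flow through.

## Downstream statistics

Sex-bias analyses reduce per-tissue differential-expression summaries to
category statistics: per-tissue proportions of significantly biased genes by
catalogue status (undefined, not zero, when a category has no assessed
genes); paired exact Wilcoxon comparisons between categories across
tissues; a two-sided exact binomial test on per-gene bias directions (a
gene's direction is the majority over its significant tissues, falling back
to all expressed tissues — the reduction is configurable since conventions
differ); concordance of direction across tissues with ties scoring 0.5; and
flagging of escape-like genes (concordance > 0.9 plus at least one
significant tissue, outside the catalogued escape set). The default
differential-expression backend is an ordinary gene-wise linear model on
log2-CPM with sex plus supplied covariates, fitted with `limma`
(`lmFit`/`eBayes(trend = TRUE)`); precision weights and surrogate-variable
adjustment are deliberately out of scope, and externally computed summaries
can be substituted. The X–Y homolog re-test replaces each X member's counts
with the X+Y pair sum and re-runs the fit, asking whether female bias
survives accounting for the male-specific Y output.

The catalogue module encodes the standard merge rules for prior XCI status
lists: equal or one-sided-absent statuses carry over; escape+variable gives
escape, escape+inactive gives variable, inactive+variable gives inactive.
Cell-hybrid expression counts are categorized with configurable thresholds
defaulting to 2/9 and 7/9 of Xi-expressing lines — values chosen to keep
three non-empty classes on a nine-line panel, since published surveys state
no numeric cutoffs.

Chromatin-state enrichment compares per-gene state coverage between escape
and inactive genes with one-sided Wilcoxon rank-sum tests in both
directions (normal approximation with tie and continuity correction), and
calibrates them by label permutation preserving set sizes, with the
one-sided p-value itself as the permutation statistic and the add-one
estimator $(1 + \#\mathrm{extreme})/(1 + N)$. Both analytic and permutation
p-values are Bonferroni-flagged at $0.05/30$, since which of the two should
carry the correction is ambiguous in common practice; both are emitted.

## Numerical conventions and degenerate inputs

Coordinates are 1-based throughout; BED input is converted on read. PAR
boundaries default to the GRCh37 intervals shipped as a YAML config.
Indels are always excluded (mapping bias); unknown count-table dialects are
rejected rather than sniffed, because silently misparsing count columns is
the worst failure mode. All Monte-Carlo procedures require a seed; equal
pooled allele fractions, all-zero difference vectors, single-class labels,
zero-coverage observations, and categories with no assessed genes each have
a defined, tested behavior (exclusion, error, or NA — never a silent 0).

## Problem sizes and known limitations

The shipped tests and the acceptance script run at reduced but structurally
faithful sizes — 500 genes x 16 tissues at 100x for the donor design, 200
cells x 50 sites at 70% dropout for the single-cell design — which complete
in seconds and give the recovery estimates useful working precision (e.g.
escape-fraction recovery inside its binomial CI; phasing accuracy at or
near 100%).

Known limitations: gene-level false-positive control in the donor design is
the union of 16 per-tissue FDR procedures, so when the true miscall rate
sits exactly at the bound $p_0$ the realized gene-level false-positive rate
among inactive genes runs slightly above the per-tissue $q$ threshold
(about 1.5–2% at the default operating point); with real miscall rates
below the bound the test is conservative. Reference-free phasing assumes
two populations (one donor); it does not model XCI mosaicism beyond the
two-haplotype structure, and genes with Xi expression at or above Xa are
unidentifiable by expression-based phasing. The X/Y dosage analysis assumes
the maternal PAR1 allele is X-borne in males, i.e. no recombination between
the assayed site and the sex-determining region.
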