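---
title: "Directional concordance of cancer omics changes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional concordance of cancer omics changes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordia)
```

## The question

Population-level case-control studies routinely interpret a gene's bulk
expression, methylation or copy-number change in tumors as evidence for its
"activation" (oncogene) or "inactivation" (tumor suppressor). concordia
implements the analysis needed to interrogate that practice: it measures
whether differential calls even agree in *direction* across independent
cohorts of the same cancer, and whether candidate oncogenes/TSGs show the
direction their label predicts. The package also ships the
mutation-state-stratified test that separates the behaviour of a gene's
mutant and wild-type copies, and a synthetic-data generator so the full
workflow runs offline with known ground truth.

## The binomial consistency model

The central statistic: among $N$ genes whose change direction is determined
in two independent cohorts, let $m$ be the number with the same direction in
both. If agreement were chance alone, each gene would agree with probability
$P_r = 0.5$ (up and down exchangeable), so the significance of observing at
least $m$ agreements is the upper binomial tail

$$p = \sum_{k=m}^{N} \binom{N}{k} P_r^{\,k} (1-P_r)^{N-k}.$$

`binomial_consistency_pvalue()` evaluates this sum in a numerically careful
way:

* for $P_r = 0.5$ and $N \le 50$, the binomial coefficients are summed
  exactly in double precision (they are exact integers there and every term
  is an exact multiple of $2^{-N}$), so symmetric cases such as
  $N = 27, m = 14$ return $0.5$ *exactly*;
* otherwise the terms are accumulated in log space with log-sum-exp, which
  keeps tails finite for $N$ well beyond $10^4$. With thousands of shared
  genes at >99% agreement the tail underflows the smallest double
  ($\approx 10^{-308}$); `log10 = TRUE` exposes the exact log-tail (of order
  $10^{-1261}$ for 4247 agreements of 4253), which is why such results are
  reported against a $2.2\times10^{-16}$ floor rather than as a number.

The test suite checks the implementation against `stats::pbinom` and, for
every $N \le 20$, against exhaustive enumeration of all $2^N$ equally likely
agreement patterns.

### Agreement-rate variants

Four variants cover the ways two call lists can be compared; all reuse the
same tail test.

* **shared** — genes called in both cohorts; $m/N$ is the headline agreement
  rate.
* **union** — genes called in at least one cohort; a singly-called gene is
  scored against the sign of its (possibly non-significant) effect in the
  other cohort. Rationale: a truly differential gene that narrowly misses
  significance in one cohort still has an informative direction there.
* **marginal** — calls of cohort A restricted to genes at least marginally
  significant (two-sided $p < 0.1$, Welch t-test) in cohort B. This is the
  stricter reading of the union idea: directions of genes with *no* signal
  in the reference cohort fluctuate randomly and are excluded.
* **third_dataset** — genes called in exactly one of the two cohorts,
  validated against an independent third cohort's calls.

Two conservative tie rules were genuinely open and are fixed as package
policy: a zero effect in the reference cohort counts as *inconsistent*, and
an empty comparison ($N = 0$) carries no p-value rather than $p = 1$.

`merge_consistent()` builds the downstream gene lists: the union of both
cohorts' calls minus genes called in both with opposite directions.

## Differential callers

**Expression (SAM-style).** Per gene, the relative difference
$d = (\bar x_\text{cancer} - \bar x_\text{normal}) / (s + s_0)$ with $s$ the
pooled standard error and $s_0$ a fudge constant stabilizing small
variances. $s_0$ defaults to a percentile search: candidates are the 5%
quantiles of $s$, and the winner minimizes the coefficient of variation of
the median absolute deviation of $d$ across 20 $s$-quantile bins; a flat
profile falls back to $\mathrm{median}(s)$. The null distribution of $d$
comes from group-label permutations (all distinct ones when fewer than
requested, a seeded rejection draw of distinct label sets otherwise). Genes
are called at the smallest symmetric threshold $\Delta$ on $|d|$ whose
estimated FDR — median permutation count of $|d^*| \ge \Delta$ over the
observed count, with the true-null proportion fixed conservatively at 1 —
stays at or below the target (default 5%). Calling up and down jointly via
$|d|$, rather than SAM's asymmetric option, is a deliberate simplification;
with $s_0 = 0$ and equal group sizes $d$ is exactly proportional to the
pooled t statistic (verified numerically in the tests).

**Methylation.** Probe beta-values $\beta = M/(U+M+100)$ from unmethylated
(U) and methylated (M) intensities; the +100 regularizer bounds $\beta < 1$
and stabilizes dim probes. Probes aggregate to genes by mean beta.
Calling is a per-gene two-sample Student t-test (pooled variance; Welch
behind a flag) with Benjamini–Hochberg correction at 5%. Gene-level testing
after aggregation — rather than probe-level testing before mapping — is the
documented choice where the original procedure was ambiguous.

**Copy number.** A simplified GISTIC-style score per marker:
$G = f \cdot a$, the fraction $f$ of samples whose log2 ratio exceeds a
noise threshold (default $\pm 0.1$, the conventional value) times the mean
exceeding amplitude $a$; deletions are scored on negated values so $G \ge 0$
always, and amplification analysis of $X$ equals deletion analysis of $-X$
exactly. The null permutes marker values *within each sample*, preserving
per-sample amplitude distributions, and pools all markers and permutations
into one empirical null; BH-adjusted empirical p-values at or below the
target FDR define significant markers, and maximal contiguous runs of them
are the reported regions. This is deliberately far simpler than full GISTIC
(no segmentation, no arm-level peel-off, no focal/broad split) and no score
parity is claimed; the recovery guarantees tested are of the planted-signal
kind. A gene overlapping both an amplification and a deletion region in one
dataset is ambiguous and excluded from events, with a logged count.

## Candidate-gene analysis

An **event** is one candidate gene with a retained (consistency-merged)
call of one modality in its own cancer type; each (gene, cancer, modality)
counts once, so a gene altered in two cancers contributes two events.
`direction_bias_test()` asks whether a class (oncogenes; stability or
non-stability TSGs) shows its label-predicted direction more often than a
fair coin: frequency = favored/total events, p = the binomial tail above.
The "average frequency" of a class admits two readings — events pooled over
cancers before dividing, or the unweighted mean of per-cancer frequencies —
so `average_frequency()` reports both, with pooled as the headline.
`background_frequency()` supplies the comparison point: the direction
frequency among *all* retained differential genes, not just candidates.

## Mutation-state stratification

`stratify_and_test()` splits a gene's cancer samples by mutation class
(activating / inactivating / undetermined / wild type; unannotated samples
are excluded, never defaulted) and tests each stratum against the normal
controls with a two-tailed t-test (pooled variance by default). Strata with
fewer than two samples are reported untested. Raw p-values are reported
without cross-strata correction — the case-study design reports per-stratum
evidence, and the output notes this. `reversal_report()` flags the
situation the analysis is designed to expose: two strata significant in
opposite directions, meaning the bulk direction misrepresents at least one
mutant state.

## What the generator emulates — and what it does not

`generate_expression_pair()` plants exactly `round(frac_de * n_genes)`
differential genes with mean shift $\pm$`effect_size` on Gaussian noise;
each planted gene keeps its sign in the second cohort with probability
`consistency`, flipping *independently* otherwise — exactly the Bernoulli
model the concordance test assumes. Methylation shifts are planted on the
beta scale and realized through scaled M intensities at fixed total signal;
copy-number alterations are contiguous marker segments present in
`carrier_frac` of samples, so a planted segment's expected marker score is
simply frequency × amplitude (0.4 × 0.8 = 0.32 under the default recovery
scenario). Truth tables are always emitted as sidecar TSVs; recovery tests
recount planted signs from them, never from the data.

Defaults represent a well-powered two-cohort design: 2000 genes, 20+20
samples per cohort, 10% differential at 2 log2-units effect over 0.5 noise,
95% cross-cohort consistency; methylation shifts of 0.2 beta over 0.05
noise at 30+30; copy-number segments of 10 markers at ±0.8 log2 in 40% of
samples over 0.1 marker noise. These sizes make planted effects clearly
recoverable while the full workflow stays in the minutes range on one core.

The generator deliberately omits probe-level artifacts, batch effects,
correlated genes, realistic genome coordinates and sample contamination.
Passing recovery tests therefore demonstrate the *statistical machinery* is
correct under its own assumptions — not that real cohorts, with their
correlation structure and technical noise, would reach the same agreement
rates.

## Numerical and design notes

* All randomness is seeded: generators take a `seed` field, permutation
  routines a `seed` argument, and `run_full_analysis()` derives one named
  seed stream per stage from a single master seed, so identical
  configurations give byte-identical report bundles (no timestamps in any
  output).
* Empirical p-values use the add-one rule $(1 + \#\{G^* \ge G\})/(1 + n)$,
  never exactly zero.
* Degenerate genes (zero variance in both groups with $s_0 = 0$, or
  undefined t) are excluded from calling, with warnings, rather than being
  assigned arbitrary statistics.
* Percentages in the run reports are rendered to two decimals.
* Problem sizes in the shipped analysis scripts (2000 genes, 300 markers,
  two simulated cancers) are the package's default study conditions chosen
  for clear planted-signal recovery at interactive runtimes.

## Limitations

The SAM and GISTIC reimplementations are intentionally minimal and are not
drop-in replacements for `samr` or GISTIC2; the concordance machinery is
agnostic to which caller produced the input tables, so calls from external
tools can be supplied as TSVs with `gene` and `direction` columns. The
binomial model treats genes as independent; co-regulated gene sets violate
that assumption and make the reported tails anti-conservative on real data.
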