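---
title: "Models and methods behind somamosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind somamosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somamosaic)
```

`somamosaic` analyses low variant-allele-fraction (VAF) somatic mosaic SNVs
from deep exome allele-count data. This vignette documents the statistical
models, the defaults and why they were chosen, the numerical choices, and
what the synthetic-cohort generator does and does not emulate.

## The beta-binomial error model

At a given genomic site, unrelated control samples (a *panel of normals*)
share a site-specific error process: some sites are clean, others are
systematically error-prone through alignment ambiguity or context-specific
chemistry. We model the error VAF of sample $j$ as $p_j \sim
\mathrm{Beta}(\alpha, \beta)$ and its alt count as $a_j \sim
\mathrm{Binomial}(d_j, p_j)$, i.e. a beta-binomial with site-specific
overdispersion. `fit_site_error_model()` maximises the likelihood

$$\ell(\alpha,\beta) = \sum_j \left[ \log\binom{d_j}{a_j} +
\log B(a_j+\alpha,\, d_j-a_j+\beta) - \log B(\alpha,\beta) \right]$$

over $(\log\alpha, \log\beta)$ by Nelder–Mead from a method-of-moments
start. Everything is evaluated through `lchoose`/`lbeta` in log space:
depths of several hundred make naive binomial coefficients overflow.
When the sample variance of the panel fractions does not exceed the
binomial floor, the moment estimate of overdispersion is undefined and the
optimiser is started near-binomial; the MLE then runs toward the binomial
boundary ($\alpha, \beta \to \infty$ at fixed mean), which is the correct
limit and numerically harmless.

A panel with zero alt reads everywhere carries no information about
overdispersion and an unpenalised MLE would degenerate to zero error. We
return a *floor model* instead: $\alpha =$ `pseudocount` (default 0.5) and
$\beta = \bar d$, giving mean error `pseudocount / (pseudocount + mean
depth)` — about $8.6\times10^{-4}$ at 584×. This keeps scores finite and
conservative at pristine sites.

The **EB score** of a case observation is $-\log_{10} P(X \ge a)$ for $X
\sim \mathrm{BetaBinomial}(d, \alpha, \beta)$. `compute_eb_score()` builds
the full log-pmf vector and accumulates the upper tail by a
reverse-cumulative log-sum-exp, so all $d+1$ tail probabilities come out of
one $O(d)$ pass with no underflow until far beyond double precision. The
panel counts are strand-pooled: strand is not represented in the count
tables, so a strand-split score variant is deliberately out of scope.

## Cutoff calibration

`calibrate_cutoff()` scans candidate thresholds placed at midpoints between
consecutive distinct scores (plus $\pm\infty$) under the rule "score
strictly greater than threshold passes", and returns the smallest threshold
maximising sensitivity + specificity (the Youden point); AUC is the
trapezoid area under the ROC. Midpoint thresholds were chosen over raw
observed scores so that the returned cutoff can be plugged directly into
the filter stack, which excludes calls with score $\le$ cutoff — with
thresholds at observed scores, the boundary case would flip depending on
which convention downstream code assumed. The default operating point,
`eb_cutoff = 2.396`, is the package's calibrated default when no labelled
set is supplied.

## The post-filter stack

`apply_post_filters()` applies six independent rules, each contributing a
reason code; a call fails iff it collects at least one code, which makes
the operation idempotent and order-free:

| rule | matched mode | brain-only mode |
|---|---|---|
| `min_depth` | depth < 35 | depth < 100 |
| `germline_vaf` | VAF ≥ 0.40 | VAF ≥ 0.20 |
| `eb_score` | score ≤ cutoff | same |
| `read_position` | all alt reads within terminal 10 bp | same |
| `min_support` | < 3 alt reads or ≤ 50% retained | same |
| `mappability` | flag set | same |

Brain-only mode exists because without a matched normal, accidental
germline contamination must be excluded by harder quantitative bounds.
Two interpretive choices: the support rule is read as *both* "at least 3
quality-filtered alt reads" *and* "more than half of the raw alt reads
survive MQ20/BQ30 filtering", which covers both numbers in the rule's
usual phrasing; and the read-position rule uses a 10 bp terminal window, a
common artifact signature of misalignment at read ends. Both flags are
computed upstream of this package (they need read-level data) and arrive
as columns; absent columns default to passing.

## Amplicon validation

A re-sequenced candidate is validated when its amplicon alt count is
incompatible with the platform's background error for its substitution
class: a one-sided exact binomial upper tail $P(X \ge a \mid
\mathrm{Bin}(d, r_c))$ with the six pyrimidine-centred class rates $r_c$
(`default_background_errors()`; calls on the purine strand are normalised
first). The default $\alpha = 0.05$, one-sided and uncorrected across
sites: validation asks per-candidate "is this distinguishable from noise",
not a family-wise discovery question, and no correction is applied unless
the caller does so. Precision is reported as a percentage to one decimal.

## Burden and the somatic clock

`summarize_burden()` gives per-subject×tissue counts, mean/median VAF, the
fraction below 5% VAF, and the six-way consequence-category counts (which
partition the call set). `fit_accumulation_rate()` regresses per-subject
SNV count on age by OLS — the clock is phrased as a linear rate in
SNVs/exome/year, and OLS estimates exactly that slope; a Poisson log-link
GLM is available (`family = "poisson"`) as a count-aware alternative but
its slope lives on the log scale. Genome extrapolation multiplies the
exome slope by `genome_bp/exome_bp` (defaults 3 Gb / 75 Mb = 40) without
intermediate rounding; tissue fold ratios are rounded to one decimal only
at the reporting step.

## Mutational signatures

Spectra live on the 96 channels (6 pyrimidine-centred substitutions × 16
flanking contexts) in the fixed order: substitution class slowest, then 5'
base, then 3' base (`channel_labels()`). Exposure fitting maximises the
multinomial likelihood of the *counts* under the mixture $\sum_i e_i s_i$,
$e_i \ge 0$, $\sum e_i = 1$. We use counts, not fractions: a 500-mutation
spectrum carries much less information than a 10,000-mutation one, and
only the count likelihood lets BIC weigh that. The optimiser is the
closed-form EM update for mixture proportions ($e_i \leftarrow \frac1N
\sum_c n_c\, e_i s_{ic} / p_c$), run to a $10^{-10}$ relative tolerance:
monotone, exactly simplex-constrained, and fast enough for exhaustive
subset search. An NNLS-on-fractions mode is kept for cross-checking.

Model selection is exhaustive over subsets of size $\le$ `max_k` (default
5) of a user-chosen candidate list, scored by $\mathrm{BIC} = k\ln N -
2\ell$ with $k$ the subset size and $N$ the mutation total; ties break
first to higher cosine similarity between reconstruction and observed
spectrum, then to the smaller subset. BIC-primary with cosine tie-break is
this package's documented choice; a search over a full 65-signature power
set is combinatorially infeasible and guarded by an explicit model budget.
`exome_adjust_catalog()` rescales genome-derived catalogs by
exome/genome trinucleotide frequency ratios and renormalises.

`synthetic_signature_catalog()` is a deterministic, synthetic stand-in
catalog (flat clock-like, CpG-deamination-like and oxidative-damage-like
shapes plus fillers) used by the simulator and tests; real analyses should
load a published catalog via `read_signature_catalog()`.

## Prioritisation and enrichment

Consequence terms map to six categories (Non-synonymous, Synonymous, UTR,
Intronic, Splicing, Intergenic) by an exact term table; unknown terms
become `"unclassified"` rather than erroring. The pathogenic filter keeps
Non-synonymous variants with CADD strictly above 20 that are population-
novel or have MAF strictly below $10^{-4}$; both boundaries are exclusive
(a CADD of exactly 20, or a MAF of exactly 0.01%, is removed).

`permutation_enrichment()` draws `draw_size` genes from the pool without
replacement `n_perm` times and reports $p = (1 + \#\{\text{overlap} \ge
\text{observed}\})/(n_{perm}+1)$ — the +1 correction keeps p-values off
zero. For the unadjusted test this null is exactly hypergeometric, and the
exact tail `phyper` value is emitted alongside as an oracle; the two must
agree within Monte-Carlo error, which the test suite checks on a grid of
instances. The gene-length adjustment stratifies null draws by length
quintile of the pool, preserving the query's length-bin composition — a
resampling surrogate for length-aware enrichment tools whose exact schemes
are unpublished. The 5% significance column is a report flag, never a
filter.

## Carriers

Germline genotypes at risk sites come from deep count VAFs: below 0.40 is
hom-ref, 0.40 (inclusive) to 0.90 is het, at or above 0.90 is hom-alt. The
0.40 bound is the germline threshold used throughout the pipeline; the
0.90 hom-alt boundary is this package's addition, needed to count two ε4
copies from unphased counts — at 584× the binomial spread of a true het is
±6%, so 0.90 separates the genotype clouds with large margin. APOE ε
haplotypes resolve from rs429358/rs7412 dosages (ε4 = C/C, ε3 = T/C, ε2 =
T/T, ε1 = C/T); the double heterozygote is ε2/ε4 vs ε1/ε3, unresolvable
without phasing, and is flagged ambiguous and excluded from ε4 copy counts
with a warning. A subject is a pathogenic-germline carrier with two ε4
copies or any risk-modifier catalog hit; a pathogenic-somatic carrier with
at least one retained putatively-pathogenic somatic SNV in the designated
pathway gene union. The four categories partition every cohort.

## The synthetic-cohort generator

The generator emulates the *derived count structure* of a deep-WES
mosaicism study, with defaults set to that study design:

* cohort of 52 AD / 11 non-AD subjects, ages uniform on the study range
  (57–96); group-specific APOE allele frequencies (rs429358-C 0.39 in AD
  vs 0.14 in controls, rs7412-T 0.06) chosen to reproduce realistic ε4
  carrier fractions under Hardy–Weinberg; Braak stages high (4–6) in AD
  and low (0–1) otherwise; onset trailing age by 5–15 years.
* truth burdens Poisson with mean $2 + 0.53 \times \text{age}$
  (SNVs/exome/year slope 0.53; the intercept admits developmental
  mutations).
* channels drawn from a configurable signature mixture (default half
  clock-like flat, quarter CpG-deamination, quarter oxidative); contexts
  are generated directly and are self-consistent with ref/alt by
  construction — an abstract contig stands in for a genome, and no
  reference sequence is shipped.
* VAFs from Beta(1.2, 40) truncated to (0.005, 0.40): median ≈ 2.3% and
  ~87% of mass below 5%, matching the observed low-VAF mosaic regime.
* depths Poisson around 584; case alt counts Binomial(depth, VAF + class
  error), panel/normal counts Binomial(depth, class error) with the
  amplicon-derived per-class background table as the noise floor; a
  21-sample panel of normals; optional error-only decoy sites.

It does **not** emulate read-level artifacts (strand bias, read-position
clustering, mappability — those arrive as upstream flags), indels, CNVs,
contamination, or overdispersed per-site depth (Poisson depth is a
stand-in; real WES depth is wider-tailed). Passing tests therefore show
the statistical machinery is correct under the declared generating model,
not that real-data artifact modes are handled — those are exactly what
the upstream flags and manual-inspection steps of a production pipeline
cover.

## Problem sizes and determinism

The test suite and the acceptance script exercise: the full filter stack
on a 5,000-site cohort at 584× with a 21-sample panel; clock recovery on
200-subject cohorts over 50 seeds; signature recovery on 10,000-mutation
spectra over 100 seeds; permutation nulls at 10,000 draws; and exact
EB-score agreement with brute-force tail summation at depths up to 1,000
over 100 random models (to $10^{-9}$, using a linear-space oracle where
the tail is representable and a sequential log-space oracle in the deep
tail). Every stochastic step takes an explicit integer seed, and fixed
seeds give bit-identical outputs.

## Known limitations

* Strand-pooled EB scores (no strand-split variant).
* OLS clock on counts; no mixed or segmented models.
* The built-in signature catalog is synthetic; published exposures can
  only be reproduced with a published catalog supplied by the user.
* Germline carrier calling assumes diploid autosomal sites and does not
  phase; indels in risk genes are out of scope.
* Candidate generation (raw calling from reads) is upstream of this
  package: inputs are allele-count tables, not BAMs.
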