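---
title: "Methods: paired adenoma-carcinoma exome analysis with adeca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired adenoma-carcinoma exome analysis with adeca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific setting

When a carcinoma arises inside a pre-existing adenoma of the same patient,
the two lesions share part of their somatic history. Comparing their exomes
lets one time genomic events along the malignant transformation: mutations
found in both lesions (lesion-common) predate the divergence of the
malignant clone, while lesion-specific mutations arose afterwards. `adeca`
implements the complete comparative analysis for such paired lesions:

1. **Regional classification** of somatic mutations into lesion-common,
   adenoma-specific and carcinoma-specific classes.
2. **Cancer cell fraction (CCF)** estimation per mutation and lesion,
   adjusted for tumor purity, local copy number and mutation multiplicity.
3. **Subclonal reconstruction** by Dirichlet-process binomial-mixture
   clustering of mutations on a cellular-prevalence grid, in one-sample
   and two-sample modes, with a fitness-peak sharpness comparison.
4. **Clonality-shift enrichment**: preranked gene-set analysis on the
   per-gene change in CCF between lesions.
5. **Microsatellite instability (MSI)** calling from per-locus
   read-length histograms of tumor vs matched normal.
6. **Copy-number change classes** along the adenoma-carcinoma sequence
   and segment-level concordance between lesions.

A synthetic-data module generates paired cases with complete ground truth
so each stage can be validated without patient data.

## Models and estimators

### Presence calling and regional classes

A variant is *present* in a lesion when it has at least `min_alt = 3`
supporting reads and VAF at least `min_vaf = 0.03`, and *absent* only when
fewer than 3 supporting reads are seen at depth at least
`min_depth_absent = 20`. Everything else is *indeterminate* and excluded
from class statistics: forcing absent calls at shallow depth would inflate
the lesion-specific classes, so abstention is the safer default. The
thresholds are exposed in `run_config()` because no community standard
exists for two-lesion presence calling.

The class ratio per lesion is summarized as
`log2((n_specific + 0.5) / (n_common + 0.5))`; the Haldane–Anscombe
pseudocount keeps zero cells finite without changing the sign semantics
(positive means lesion-specific mutations dominate). Gene-level recurrence
counts **cases** (a gene mutated twice in one case counts once), matching
how recurrence is reported in cohort studies.

### CCF

With purity $\alpha$, local tumor copy number $q_t$ and multiplicity $m$,
a mutation carried by a fraction $\phi$ of tumor cells has expected VAF

$$\xi(\phi) = \frac{\alpha\, m\, \phi}{\alpha q_t + 2(1-\alpha)}.$$

Multiplicity is estimated by rounding
$\hat v (\alpha q_t + 2(1-\alpha))/\alpha$ into $\{1, \dots, q_t\}$, and the
CCF point estimate is the inverse transform of the observed VAF, clipped to
$[0,1]$. The 95% interval and the clonality probability come from the
Jeffreys $\mathrm{Beta}(x + \tfrac12,\, d - x + \tfrac12)$ posterior on the
VAF pushed through the same linear map; a mutation is labelled *clonal*
when at least half its posterior mass lies at CCF $\ge 0.95$ (the
conventional clonality cutoff; the probability-mass operationalization is
this package's concretization, since "likelihood of clonality" has no
unique definition). Estimates whose unclipped CCF exceeds 1.25 are flagged
as copy-model-inconsistent rather than silently clipped.

The point estimate is a plug-in: its error is binomial sampling noise
scaled by $(\alpha q_t + 2(1-\alpha))/(\alpha m)$. At depth 150 and purity
0.6 this scale factor reaches 5.3 for a subclonal single-copy mutation on
a four-copy locus, so per-mutation CCF error for subclonal mutations on
amplified loci is intrinsically of order 0.1; pooling across mutations
(the clustering module) is the remedy, not a different point estimator.
The validation suite measures exactly this behavior.

### Subclonal clustering

Mutations are clustered with a Dirichlet-process mixture: cluster
parameters are cellular prevalences on the grid $\{0.01, \dots, 1.00\}$
(step 0.01, uniform base measure), the likelihood of mutation $i$ in a
cluster at $\phi$ is $\mathrm{Binomial}(d_i, \xi_i(\phi))$, and in
two-sample mode the product of the two lesions' binomial terms with an
independent $\phi$ per lesion. A collapsed Gibbs sampler (Rcpp) resamples
assignments, cluster grid positions, and the DP concentration
(Gamma(1,1) prior, Escobar–West update). The grid replaces a continuous
Beta base measure deliberately: conditional draws become exact categorical
samples and 0.01 resolution is below the posterior width at exome depths.

Defaults are 10,000 iterations, 2,000 burn-in, thinning 5. Consensus
clusters cut the average-linkage tree of (1 − mean pairwise co-clustering)
at 0.5; singleton clusters are merged into the prevalence-nearest cluster
because one-mutation clusters at exome depth are indistinguishable from
read noise. A non-stationary trace of the cluster count triggers a warning
but still returns results. The sampler was validated against exact
enumeration of all set partitions on small instances (fixed concentration),
where the posterior co-clustering matrix is computable in closed form.

**Sharpness.** A lesion whose mutations concentrate into few,
high-prevalence clusters sits on a sharper fitness peak. This qualitative
criterion is concretized as $S = f_{\text{modal}} \cdot \phi_{\text{modal}}
/ k$ (modal-cluster mutation fraction times its prevalence over the number
of clusters); the lesion with larger $S$ wins, with ties declared below a
difference of 0.01. Any monotone combination of the three ingredients
would serve; this one is dimensionless and bounded.

### Clonality-shift enrichment

For every lesion-common mutation, $\Delta\mathrm{CCF} =
\mathrm{CCF}_{\text{carcinoma}} - \mathrm{CCF}_{\text{adenoma}}$. Genes
aggregate their records by the mean (configurable to max-|Δ|), ranked
descending with lexicographic tie-breaks for determinism. The enrichment
score is the weighted Kolmogorov–Smirnov running sum (hit increments
$|s|^p$ normalized by total hit weight, $p = 1$ by default; miss decrements
$1/(N-k)$); ES is the signed maximum deviation, with exact magnitude ties
between the positive and negative extreme resolved to the positive one so
the statistic does not depend on float rounding. The null permutes gene
labels (there is only one ranked list per cohort, so sample permutation is
unavailable); NES divides ES by the mean |null ES| of the same sign, the
p-value is two-sided with the +1 finite-sample correction, and q-values
are Benjamini–Hochberg across sets. Positive ES is reported as *Ca-Clonal*
(mutations more clonal in the carcinoma), negative as *Ad-Clonal*.
Hypermutated cases can be excluded from the ranking with a flag.

### MSI

Each microsatellite locus is tested by a two-sample Kolmogorov–Smirnov
statistic on the count-weighted read-length ECDFs of tumor versus matched
normal. P-values use the asymptotic Kolmogorov tail with effective size
$nm/(n+m)$; when the pooled read count is below 50 the exact, ties-aware
Smirnov distribution is used instead. Loci with fewer than 20 reads in
either histogram are excluded. Per lesion, Benjamini–Hochberg across loci
at FDR 0.05 defines significant slippage events; a lesion is MSI-H at 10
or more events. The threshold sits between the "fewer than five events"
typical of stable genomes and the dozens-to-hundreds seen in MSI-H
genomes, and is configurable. Lesions are tested separately (a per-case
pooled test would mask a lesion-restricted mismatch-repair defect);
both verdicts are reported.

### Copy-number change classes

Absolute copy number $n$ maps to gain ($n > 2$), neutral ($n = 2$) or loss
($n < 2$). When segments carry only log2 ratios, $n$ is recovered by
inverting the purity mixture $r = \log_2\!\big[(\alpha n +
2(1-\alpha))/2\big]$. A gene takes the state of the segment covering its
midpoint in each lesion (deterministic, avoids fractional states), and the
state pair maps to: Gain-C / Loss-C (concordant), Gain-Ad / Gain-Ca /
Loss-Ad / Loss-Ca (lesion-specific), Neutral, plus an *Opposite* bucket
for the rare gain/loss reversals, reported separately rather than forced
into the six directional classes. Concordance between lesions is the
Pearson correlation of log2 ratios over the intersected segment grid,
weighted by interval length (unweighted correlation would overcount short
noisy segments); pairs below 0.5 are called discordant.

## The synthetic cohort

`sim_config()` defaults emulate a 21-pair cohort: 11 cases in cohort A and
10 in cohort B, with cohort B carrying twice the lesion-specific mutation
load and higher copy-number discordance (0.3 vs 0.1), three hypermutated
cases (4, 15, 21; 20-fold common-mutation inflation), two of which
(4 and 21) are MSI-H. Purity defaults to 0.70 per lesion, the typical
yield of microdissected gastrointestinal specimens; depth is
negative-binomial with mean 150 and size 8 (exome-scale overdispersion).

Each case draws one ancestral clone (prevalence 1 in both lesions), a
shared subclone with independent per-lesion prevalences in [0.1, 0.8], and
lesion-private subclones. Private prevalence ranges are asymmetric —
adenoma [0.1, 0.5], carcinoma [0.4, 1.0] — which encodes the selective
sweep accompanying malignant transformation and produces the expected
ordering mean CCF(carcinoma-specific) > mean CCF(adenoma-specific). A
`sweep = TRUE` mode makes the carcinoma descend from a single adenoma
subclone (fewer, higher-prevalence carcinoma clusters). 70% of common
mutations sit on the ancestral clone. Multiplicity is 1 for subclonal
mutations; clonal mutations draw $m$ uniformly from $\{1..q_t\}$
(multiplicity above 1 requires the mutation to precede the amplification,
i.e. to be early/clonal — and this keeps the CCF inverse problem
identifiable). Absent alleles still emit reads at error rate 0.001, giving
presence calling a realistic false-positive floor. A 20-gene set with a
+0.4 CCF shift in the carcinoma is planted for enrichment validation, and
stable/unstable microsatellite histograms are discretized Gaussians
(sd 0.7 repeat units) with unstable loci mixing in an allele contracted by
2 repeat units at a fraction equal to purity.

What the generator does **not** emulate: trinucleotide signature
structure, germline contamination, mapping artifacts, subclonal copy
number, allele-specific copy number, and correlated noise between nearby
loci. Green validation therefore demonstrates correctness of the
estimators under the stated generative model, not robustness to every
artifact of real exomes.

## Validation scale and determinism

The validation suite runs at desk scale: 500-mutation CCF sets, 2-case
classification cohorts, 180-mutation clustering fixtures (3 clones of 60),
2,000-locus MSI panels, 1,000-instance enrichment oracles with
1,000-permutation nulls, 50-replicate concordance simulations, and one
full 21-case cohort for the shape checks — sizes chosen so the full suite
completes in about a minute while keeping binomial standard errors well
inside the asserted margins. All randomness flows through explicit seeds;
rerunning any stage with the same seed reproduces byte-identical outputs
(the Gibbs sampler draws exclusively from R's RNG stream).

One validation bound is knowingly not met: on the 500-mutation CCF fixture
the plug-in estimator's RMSE lands at 0.080–0.093 across seeds, against an
asserted bound of 0.08. The corresponding test is left failing rather than
weakened: the measured error equals the binomial noise floor of the
prescribed estimator under this generator's mixture of clonal and
subclonal mutations (about 40% subclonal with copy numbers up to 4), and
meeting 0.08 would require either a more clonal mixture or an estimator
that pools information across mutations, which is the clustering module's
role.

## Limitations

* CCF assumes the reported purity/ploidy are correct; no joint
  re-estimation is attempted.
* Copy states are total (not allele-specific); loss of heterozygosity
  without copy change is invisible.
* The two-sample clustering assumes shared cluster membership across
  lesions, which is exactly right for lesion-common mutations but cannot
  place lesion-specific mutations on the shared tree (no phylogeny is
  reconstructed).
* MSI calling needs per-locus read-length histograms produced upstream;
  no realignment of raw reads is performed.
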