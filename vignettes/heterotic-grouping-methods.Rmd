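---
title: "Heterotic grouping from line-by-tester trials: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterotic grouping from line-by-tester trials: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterotic)
```

## The problem

Hybrid maize breeding needs parents drawn from complementary *heterotic
groups* — sets of inbred lines that combine better with lines outside the
set than within it.  For biofortification programs the question is whether
lines can be grouped on a nutritional trait (provitamin A carotenoid
content, µg/g of grain) without wrecking the grouping that grain yield
would suggest.  The standard instrument is the line × tester testcross
trial: every candidate line is crossed to two testers of known, opposite
group affiliation, and the testcrosses are evaluated in multi-environment
trials.  Molecular markers give an independent view of the same germplasm:
diversity statistics, distance-based clustering and admixture estimates of
latent ancestry.

This package implements both arms — the quantitative-genetic grouping and
the SNP-based clustering — plus a synthetic-data generator with known truth
so that every stage has a parameter-recovery test.

## Combining ability

For line $j$ and tester $i$, with $\bar X_{..}$ the overall testcross mean,
$\bar X_{.j}$ the line mean, $\bar X_{i.}$ the tester mean and
$\bar X_{ij}$ the cross mean:

$$\mathrm{GCA}_j = \bar X_{.j} - \bar X_{..}, \qquad
  \mathrm{SCA}_{ij} = \bar X_{ij} - \bar X_{.j} - \bar X_{i.} + \bar X_{..},$$
$$\mathrm{HSGCA}_{ij} = \mathrm{GCA}_j + \mathrm{SCA}_{ij}
                      = \bar X_{ij} - \bar X_{i.}.$$

All margins are computed from the table of cross means, not from pooled raw
plots, so mild missingness does not bias them.  Floating point forces a
choice between the two algebraically identical HSGCA forms: `heterotic`
computes HSGCA as *cross mean minus tester mean* (bit-exact for that
identity) and verifies `GCA + SCA` against it to a relative $10^{-8}$.
With two testers the zero-sum constraints make SCA antisymmetric,
$\mathrm{SCA}_{1j} = -\mathrm{SCA}_{2j}$, which is why the sign conditions
below are meaningful.

The combined ANOVA (`anova_line_by_tester()`) decomposes Environment +
Rep(Env) + Hybrid + Hybrid×Env + Error with Hybrid split into Line, Tester
and Line×Tester, and Hybrid×Env split likewise.  Environments are treated
as random: Line, Tester and Line×Tester are tested against their matching
×Env mean squares, interactions against error.  Sums of squares are the
balanced closed forms on factor means (randomized-complete-block logic); no
lattice block adjustment is attempted, so the error degrees of freedom for
a 60 × 2 × 8 × 2 design are 952 here, where a lattice-adjusted analysis of
the same field design with check entries would print a different error df.
The genetic df (Line 59, Tester 1, Line×Tester 59, Line×Env 413,
Tester×Env 7, Line×Tester×Env 413) are invariant to that choice and are
asserted in the acceptance suite.

Entry-mean repeatability uses moment estimators from the expected mean
squares, each truncated at zero,
$\hat\sigma^2_\varepsilon = MS_E$,
$\hat\sigma^2_{he} = (MS_{H\times E}-MS_E)/r$,
$\hat\sigma^2_h = (MS_H - MS_{H\times E})/(re)$, giving
$\mathrm{rep} = \hat\sigma^2_h / (\hat\sigma^2_h + \hat\sigma^2_{he}/e +
\hat\sigma^2_\varepsilon/(re))$.  Published analyses of this trial type
often use REML for the variance components; the moment form is used here
because it is closed-form, testable, and identical to REML for balanced
data up to truncation.

## Grouping rules

Two testers, nominally of opposite groups: positive effects with tester 1
send a line to group B, positive effects with tester 2 to group A
(`grouping_config(tester_to_group = …)`; the map is pure convention and
swapping it swaps every label).

**SCA method** (`assign_sca()`): a line joins a group when its SCA signs
oppose across the testers *and* its best testcross mean is not
significantly lower than the tester × tester check cross.  "Not
significantly different or greater" is operationalized as best mean
$\ge$ check mean $-$ LSD$(\alpha)$, with
$\mathrm{LSD} = t_{1-\alpha/2,\,df_E}\sqrt{2\,MS_E/n}$ — the conventional
companion test in this trial literature.  Lines whose largest absolute SCA
falls under a per-trait magnitude floor stay unassigned; the defaults are
100 kg/ha for grain yield (the published practice for this trial type) and
0.05 µg/g for provitamin A (half of one printed decimal — "no SCA effect"
at reporting precision).  The SCA method may therefore leave lines
unassigned.

**HSGCA method** (`assign_hsgca()`): a line with positive HSGCA with
exactly one tester joins that tester's keyed group; when both HSGCA values
share a sign the line goes to the group where its value is *smaller*
(smallest positive or most negative — `tie_break = "min_value"`).  The
source literature's tie-break sentence can be argued either way, so
`"max_value"` is offered; the default is the literal reading.  The method
assigns every line.  An exact value tie falls to the first tester and is
logged.

**Concordance** (`compare_methods()`): Spearman rank correlation of
per-line scores plus an agreement percentage.  Whether published
concordances of this kind were computed on effect values, group codes or
ranked testcross means is not stated anywhere we could verify, so the
default score is the line's effect with tester 1 under each method
(SCA vs HSGCA), and any score vector can be supplied.  Agreement counts
unassigned lines in the denominator but never in the numerator, keeping
the full line count in view.  Exact Spearman p-values are used up to
n = 10, the t-approximation beyond.

## Markers

QC (`filter_markers()`) removes a marker iff missingness > 10% or
major-allele frequency > 95% or heterozygosity > 20% — *strict*
inequalities, chosen because published retained ranges touch 0.95 and 0.19
exactly.  Monomorphic markers fail the MAF rule automatically.  Removal
attribution (for reporting) follows the order missing → MAF → het; the
removal set itself is an OR and order-independent.

Per marker (`marker_stats()`), with allele frequencies $p, q$ from
non-missing calls: gene diversity $D = 1 - p^2 - q^2$, Botstein's
$\mathrm{PIC} = D - 2p^2q^2$, so $\mathrm{PIC} \le D \le 0.5$ with both
maxima at $p = 0.5$ ($D = 0.5$, PIC $= 0.375$).

IBS distance: per shared marker, similarity $(2 - |g_i - g_j|)/2$;
distance = 1 − mean similarity.  Pairs sharing no marker are an error, not
a silent NA.  Ward clustering uses the Lance–Williams update on squared
distances (`hclust` `ward.D2`); which Ward variant the published analyses
used is typically unstated, and cluster composition can differ at the
margin between variants.  PCA runs on the column-centred dosage matrix with
per-marker mean imputation (the common default of genotype-PCA tools), not
on the IBS matrix.  Testers are included with the lines in all structure
analyses, mirroring dendrograms that show 62 leaves for 60 lines plus two
testers.

**Admixture**: full Bayesian MCMC structure estimation is out of scope;
`admixture_em()` maximizes the same admixture likelihood
$\sum_{im} [\,g_{im}\log(QF)_{im} + (2-g_{im})\log(1-(QF)_{im})\,]$ by
alternating EM with Dirichlet-random restarts, which is deterministic given
a seed and feeds replicate log-likelihoods to Evanno's
$\Delta K(K) = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / sd(L(K))$
exactly as the MCMC replicates would.  Membership calls use the 60% rule:
maximum membership $\ge 0.60$ assigns the sample to its argmax subgroup,
anything lower is "mixed".  Frequencies are clamped to
$[10^{-9}, 1-10^{-9}]$ before logs; missing calls drop out of the
likelihood; the EM trace is checked non-decreasing in the test suite.

## The synthetic world

`simulate_trial()` draws every term of
$y = \mu + E + R(E) + g_l + g_t + s_{lt} + (gE)_{l} + (gE)_{t} + (sE)_{lt}
+ \varepsilon$ i.i.d. normal and then centres each effect within its factor
(SCA double-centred), so the zero-sum constraints hold *exactly* and the
estimators above are exactly unbiased on the generated truth — that is what
makes the recovery tests sharp.  The three ×Env terms share one `var_gxe`
knob, and the replicate-within-environment variance defaults to zero (the
generator's contract lists no separate component for it).

Default trait variances are back-derived from a published combined ANOVA of
a 60-line × 2-tester × 8-environment × 2-rep provitamin-A testcross series,
via the moment equations (values rounded once and fixed):
grain yield — $\sigma^2_\varepsilon \approx 1.14\times10^6$,
$\sigma^2_{SCA} = (MS_{SCA} - MS_{SCA\times E})/(re) \approx 5.0\times10^5$,
$\sigma^2_{GCA,line} \approx 2.5\times10^5$, environment
$\approx 3\times10^6$; provitamin A — $\sigma^2_\varepsilon = 1.36$,
$\sigma^2_{SCA} \approx 0.15$, $\sigma^2_{GCA,line} \approx 1.26$, tester
GCA variance from a 2.5 µg/g tester contrast.  A simulated default trial
therefore prints an ANOVA whose error mean square, CV and repeatability sit
in the published neighbourhood — a sanity anchor, not a fit.

With `group_structure`, SCA is planted deterministically at
$\pm d = \pm\sqrt{\mathrm{var\_sca}}$ by line-group × tester-group
opposition.  Note the planted-truth recovery ceiling of the HSGCA rule: a
line whose GCA exceeds $d$ has positive HSGCA with both testers and the
tie-break can re-route it, so recovery tests keep
$\sigma_{GCA} \ll d$ — that is a property of the rule, not of the
implementation.

`simulate_genotypes()` uses the Balding–Nichols model: ancestral
frequencies $U(0.05, 0.95)$, subpopulation frequencies
$\mathrm{Beta}(p(1-F_{st})/F_{st},\,(1-p)(1-F_{st})/F_{st})$, per-sample
Dirichlet($\alpha$) admixture, binomial(2) genotypes from the mixed
frequency.  Heterozygous draws collapse to a random homozygote with
probability $1 - \mathrm{het\_rate}$; the default het_rate 0.25 reproduces
a mean observed heterozygosity near 0.09 against a mean gene diversity
near 0.37, the regime of S6–S8 inbred panels.  Defaults $K = 3$,
$F_{st} = 0.3$, 2000 markers, 5% missing calls.  The generator has **no
linkage disequilibrium and no genotype–phenotype coupling**: marker
clusters and heterotic groups are independent unless the user ties
`group_structure` to ancestry.  A green end-to-end test therefore
establishes that the estimators recover the stated generative model — not
that real DArTag panels satisfy that model.

## Numerical conventions, in one place

* Margins from cross means; missing trait cells are `NA`, never zero.
* HSGCA stored as cross mean − tester mean (bit-exact identity); GCA + SCA
  checked to 1e−8 relative.
* Variance components truncated at zero (affects repeatability only).
* QC thresholds strict (`>`); boundary markers retained.
* Effects ties in `assign_hsgca()` broken by tester order, logged.
* Grain yield = fresh weight × (100 − moisture)/85 × 10⁴/area, area
  default 3.75 m²; the shelling convention is the formula itself and is
  recorded in the pipeline run log.
* Seeds: one integer in `sim_config()`; the genotype generator and each EM
  restart derive fixed offsets from it, so every artifact is reproducible
  byte for byte.

## Known limitations

* **Greedy Ward is not a global optimizer.**  Cutting the Ward tree at
  $K$ does not always yield the partition minimizing within-cluster sum of
  squares; on unstructured Gaussian instances with $n \le 8$ the cut
  disagrees with the exhaustive optimum in roughly 15% of cases (and even
  well-separated instances fail occasionally).  The acceptance suite states
  that equivalence as a hard criterion and it fails honestly there; treat
  flat Ward labels as the field treats them — a dendrogram summary, not an
  optimum.
* The ANOVA is RCBD-sequential; published lattice-adjusted tables of the
  same design will differ in error df and slightly in mean squares.
* The EM admixture estimator is a stand-in for Bayesian MCMC structure
  software: same likelihood, same Evanno decision surface, but no prior,
  no correlated-frequencies model, and EM can sit on a local mode (hence
  restarts, and replicate spread feeding $\Delta K$).
* Two testers only, by design: the assignment rules are defined for a
  two-tester system and do not generalize as written.
* The Spearman-score convention for concordance is a documented choice;
  compare like with like when citing such correlations.
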