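---
title: "Testing for meiotic drive in hybrid backcross pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for meiotic drive in hybrid backcross pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiodrive)
```

## The scientific problem

Mendelian segregation gives each allele of a heterozygous parent a 50%
chance of reaching the next generation. Meiotic drivers break this symmetry:
in females, meiosis is asymmetric (one oocyte, three polar bodies), so a
chromosome variant that preferentially attaches to the egg-side spindle at
meiosis I — typically through centromere strength — can be transmitted to
more than half of the offspring ("chromosomal meiotic drive"). Neocentromere
systems achieve the same at meiosis II, provided a single crossover between
the centromere and the driving distal element has made the secondary oocyte
heterozygous there. Drivers that have fixed within a population become
cryptic: only a cross between long-isolated populations re-exposes them in
heterozygous hybrids.

`meiodrive` implements the full analysis pipeline for such a cross: two
subspecies (labelled Australian, AUS, and Timor, TIM, after the zebra finch
system that motivates the design) are hybridized, the F1 is backcrossed to
the AUS side, and the BC1 again, while every egg — including apparently
infertile ones and dead embryos — is genotyped at microsatellite markers
tightly linked to centromeres (median 0 cM) or to distal chromosome ends
(median 50 cM). The drive parameter

$$k = \Pr(\text{transmitted allele is of AUS origin})$$

is estimated per marker and pooled over markers, separately by parent sex,
generation (F1, BC1) and marker class (centromeric, distal). A chromosomal
driver predicts distortion *only in females*, at centromeric markers (MI
drive) or distal markers (MII drive); male transmissions act as the control
that absorbs shared confounds (genotyping artefacts, viability selection).

## Tracing allele origins and counting informative transmissions

The subspecies origin of each allele length is fixed by the founder pools:
an allele length seen only in AUS founders is AUS, only in TIM founders is
TIM, and one seen in both pools is ambiguous (`AMBIG`). Transmissions
involving ambiguous alleles are excluded and tallied in the ledger; this is
deliberately more conservative than trusting founder-pool labels for shared
lengths, and a registry can be supplied explicitly where identity-by-descent
information justifies it.

For every breeding pair, marker and focal parent (the AUS/TIM heterozygous
hybrid), `classify_pair()` enumerates every offspring genotype the pair can
produce — including single-peak genotypes caused by null alleles and the
maternal W at Z-linked markers — and checks whether each one uniquely
determines the origin of the focal parent's transmitted allele:

* **fully informative** pairs contribute every offspring;
* the **AB×AB** constellation (both parents carry the same two lengths)
  contributes only homozygous offspring — a heterozygous offspring could
  carry either parent's A;
* all other pairs are excluded wholesale.

A focal parent heterozygous with an inferred null allele is never counted,
and at Z-linked markers the hemizygous ZW female cannot be focal, so
Z-linked transmission is effectively tested in males only (the W is treated
as a null allele; this is justified only in the absence of a sex-ratio bias,
which `sex_ratio_test()` checks).

Null alleles (allelic dropout) are inferred from the pedigree by
`infer_null_alleles()`: an apparent homozygote that is Mendelian-
inconsistent in some genotyped trio, but consistent once one slot is
rewritten to NULL, is rewritten — only when it is the unique candidate that
restores consistency. This conservative rule has precision 1 against
simulated truth; its recall is below 1, which mirrors the real situation
(undetected dropouts remain and are handled by the `heterozygous_parents`
robustness subset). Deduction then takes genotypes at face value; an
explicit NULL slot in an offspring genotype acts as a wildcard for the
dropped allele. A fully permissive dropout model was rejected because it
would make AB×AB homozygotes ambiguous, contradicting the constellation
rules above.

## Statistics

For a pooled count of $s$ AUS transmissions among $n$, `estimate_k()`
reports $\hat k = s/n$ with a Wilson interval, a central (doubled-tail)
exact binomial p-value against the background rate $p_0$, and the Wald test
of the equivalent intercept-only binomial GLM with offset
$\operatorname{logit} p_0$, whose MLE is analytic:
$\hat\beta_0 = \operatorname{logit}\hat k - \operatorname{logit} p_0$. The
central two-sided definition was chosen because it matches the symmetry of
the Wald test; the minimum-likelihood definition is available via
`binom_exact_p(..., method = "minlik")`.

The background rate is the pooled male estimate — by default the
population-level intercept of a binomial GLMM with marker identity as a
random intercept (`background_rate(..., method = "glmm")`), with the raw
pooled proportion as an alternative; the two differ only when marker sample
sizes are unbalanced and between-marker variance is positive. $p_0$ enters
all downstream tests as a plug-in offset constant; its own sampling error is
not propagated, mirroring standard offset usage, and is small (the male pool
is about half of all informative transmissions).

`glmm_fit()` maximizes the logit-normal binomial marginal likelihood

$$\ell(\beta,\sigma)=\sum_g \log \int
\prod_{i\in g}\binom{n_i}{y_i} p_i(u)^{y_i}(1-p_i(u))^{n_i-y_i}
\,\varphi(u;0,\sigma^2)\,du, \qquad
\operatorname{logit} p_i(u)=\operatorname{logit}p_0 + x_i^\top\beta + u,$$

by adaptive Gauss–Hermite quadrature (20 nodes by default; nodes from the
Golub–Welsch eigendecomposition). Each group's integrand is centred at its
conditional mode and scaled by the local curvature, so 20 nodes give
likelihoods that agree with brute-force numerical integration to well below
1e-6 on test instances. Fixed effects are either an intercept or a
cell-means parameterization of the eight generation × position × sex
levels; `contrast_level()` tests one cell against the transmission-weighted
mean of the other seven (the weighting is a declared choice — the contrast
behind a published "one level differs from the rest" statement is rarely
fully specified). Among-individual heterogeneity (the signature of a driver
active only in some genetic backgrounds) is tested by
`lrt_random_effect()`, which reports both the nominal $\chi^2_1$ p-value
(the convention of common GLMM software) and the boundary-corrected
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ p-value, since $\sigma=0$ lies on the
boundary and the nominal test is conservative.

Power calculations use the arcsine-transform approximation
($h = 2\arcsin\sqrt{k} - 2\arcsin\sqrt{0.5}$, both rejection tails
included), cross-checked against exact binomial power enumeration; the two
agree in the detectable $k$ to within 0.003 for $n \ge 500$. Effects are
symmetric in $k \leftrightarrow 1-k$. p-values are reported nominally
throughout; `bonferroni_ledger()` provides the family-wise accounting
(markers × generations × sexes × analysis variants) on demand.

## The synthetic cross: what it emulates

`simulate_cross()` reproduces the study design structurally, so that every
stage of the pipeline can be checked against a truth log. Defaults are the
study's own numbers: 2 contributing Timor founders (of 4), 11 F1 (7 m, 4 f),
443 BC1-generation eggs with 51 adults (26 m, 25 f) of which 41 (18 m, 23 f)
breed, 905 BC2-generation eggs with 79 adults, 56 markers on 29 chromosomes
(29 centromeric at most 27 cM from the centromere, median 0; 27 distal at
least 18 cM away, median 50; minimum inter-marker distance 17 cM; one
chromosome is the Z), ~12% apparently infertile eggs, and a 4.78% admixed
diploid fraction for the introgression screen. Where the study does not fix
a value we chose once: 6 AUS and 2 TIM allele lengths per locus (low Timor
diversity follows from the two contributing founders), a 2% allelic dropout
rate, abnormality rates totalling ~2.9% (39/1,359 in the study) split
across tetraploidy, triploidy, haploidy, trisomy and monosomy, and an
85:15 embryo:chick split among dead samples.

**Meiosis model.** Each chromosome carries a centromere (position 0), a
centromeric marker at $p_c$ cM and optionally a distal marker at $p_d$ cM.
Female meiosis I retains the AUS-origin centromere of an origin-heterozygous
bivalent with probability $d_{MI}$ (0.5 = fair; male meiosis is always
symmetric — requesting a male bias is a configuration error because
chromosomal drive exploits the asymmetric female meiosis). The default
crossover model, `obligate_one`, places exactly one crossover per bivalent
uniformly on a 50 cM bundle and exchanges one chromatid per homolog — i.e.
complete interference, for which the correct map function is Morgan's
$r = d/100$ ($d \le 50$). The alternative `poisson` model draws
per-chromatid crossover counts as thinned Poisson processes, which
reproduces Haldane's map function exactly. (A single obligate crossover and
Haldane mapping are mutually inconsistent, so the package pairs each
crossover regime with its own map function; under `obligate_one` a 50 cM
distal marker is exactly unlinked, $r = 0.5$.) Meiosis II retains the
AUS-origin chromatid with probability $d_{MII}$ only when the retained
secondary oocyte is origin-heterozygous at the distal locus — i.e. when a
crossover fell between centromere and locus, the condition a neocentromere
mechanism requires; otherwise segregation is fair. W vs Z transmission is
fair, and offspring sex follows the maternal Z/W gamete (F1 sexes are set
by quota, since the 11 F1 are defined as the birds that reached maturity).

**Nuisance processes.** Infertile eggs are drawn per egg and remain in the
pedigree as records without genotypes; survival to adulthood is realized by
sampling the configured number of adults among fertile eggs, with an
optional inbreeding penalty that multiplies an egg's survival weight by
$(1-\text{penalty})$ per marker homozygous identical-by-descent for an AUS
allele — with the penalty on and drive off, survivor-only counts show a
spurious deficit of AUS alleles while the truth log stays fair, which is
exactly the confound the male-derived background rate absorbs. Null alleles
mask one allele per affected genotype. Chromosomal abnormalities are
constructed mechanistically: MI nondisjunction contributes both parental
homologs (visible as a third allele at centromere-linked markers of a
heterozygous parent), MII nondisjunction contributes two copies of one
chromatid (invisible without dosage — the screen cannot and does not detect
it), polyspermy contributes a second, independently segregating paternal
gamete. Infertility and survivorship are applied inside the breeding loop
(they shape who breeds next); genotype-level nuisances live in
`inject_nuisance()`.

**Seeding.** One root seed; every stage and every parent's gamete batch
derives its own stream via `derive_seed()`, so a run is bit-reproducible
and single meioses can be replayed in isolation with `simulate_meiosis()`.

**What the simulator does not emulate.** Mutation, genotyping plate effects,
linkage between marker chromosomes, assortative pairing, heritable
(segregating) null alleles, and BDM-incompatibility viability surfaces are
all absent. Passing the recovery and calibration tests therefore shows the
pipeline is correct under the stated generative model, not that real data
meet its assumptions.

## Anomaly screen and exclusion rule

Length genotypes carry no dosage, so the screen keys on the set of distinct
alleles: three at a marker imply at least three chromosome copies. Defaults
(all configurable): triploidy when at least two chromosomes show three
alleles, tetraploidy when two show four, trisomy when exactly one shows
three, haploidy when every marker is single-allele and attributable to one
parent, monosomy when every marker of one chromosome is single-allele and
inconsistent with the other parent (a one-marker signal is never called —
it is indistinguishable from a single dropout). These thresholds are
artifact choices validated against the simulator's truth log; the published
study reports outcomes, not rules. Transmission records are dropped, per
affected chromosome, only when the contributing parent is a hybrid or
backcross individual; an anomaly contributed by the pure partner leaves the
hybrid parent's transmissions intact.

## Robustness subsets

Two record subsets mirror the study's sensitivity analyses:
`heterozygous_parents` (both parents heterozygous without an inferred null
at the marker — removes any effect of undetected nulls) and `no_inbreeding`
(pairs that cannot produce offspring homozygous for any AUS allele —
removes inbreeding-depression effects that mimic drive against AUS).

## Numerical and degenerate-input choices

* Exact two-sided binomial p: central (doubled-tail), capped at 1.
* $s \in \{0, n\}$: the offset GLM reports a boundary estimate with a
  profile-likelihood interval instead of a Wald interval.
* $\sigma \to 0$: the quadrature collapses analytically to the plain GLM
  likelihood below $\sigma = 10^{-8}$; the optimizer works on the bounded
  scale $\sigma \ge 0$.
* Non-convergence of a GLMM is flagged on the returned object, never
  silent; the pipeline logs and skips failed fits.
* Ambiguous deductions, Mendelian-inconsistent offspring, non-diploid
  genotypes, uninformative pairs and anomaly exclusions each land in
  exactly one ledger category; missing offspring genotypes are reported
  separately (an absent genotype is an infertile or lost egg, never an
  ambiguity).
* Offspring of unknown sex at Z-linked markers are counted only when the
  deduction does not depend on sex; otherwise they are ambiguous.

## Problem sizes used in the tests

The packaged test-suite runs the full study-scale design (1,348 eggs x 56
markers) for the recovery experiment — 100 replicates with female
centromeric $d = 0.475$, checking the median pooled estimates — a 10,000
marker calibration of the exact test at $n = 350$ transmissions per marker,
an exhaustive classifier-vs-enumeration check over all parental genotype
pairs from a four-allele registry including NULL and W placeholders, and
Monte-Carlo checks of the meiosis engine at $10^5$–$2\times10^5$ gametes.
Smaller down-scaled configurations (see `tests/testthat/helper-oracles.R`)
exercise the design logic where full scale adds nothing. The recovery
replicates run the registry and counting engine directly; the anomaly
screen and null inference, whose correctness is established in their own
tests, contribute only sub-0.1% perturbations to pooled estimates at the
default rates.

## A worked example

```{r, eval = FALSE}
library(meiodrive)
cfg <- cross_config(seed = 1,
                    drive = drive_spec("all", "F", "MI_centromere", d = 0.475))
sim <- simulate_cross(cfg)
calls <- classify_mechanism(detect_anomalies(sim$dataset), sim$dataset)
ds <- infer_null_alleles(sim$dataset, exclude_individuals = calls$offspring_id)$dataset
ct <- count_transmissions(ds, anomaly_calls = calls)
p0 <- background_rate(ct$records)
fem_cen <- subset(ct$records, parent_sex == "F" & position_class == "centromeric")
estimate_k(sum(fem_cen$transmitted), nrow(fem_cen), p0 = as.numeric(p0))
```

The same analysis, end to end with all outputs on disk, is
`run_pipeline(system.file("extdata", "toy_config.yaml", package = "meiodrive"),
"out")`.

## Known limitations

* Origin assignment is by allele length against founder pools; identity-by-
  descent through the pedigree is not tracked for shared lengths (they are
  excluded as AMBIG). This loses information relative to a full pedigree
  phasing but cannot create false signal.
* The anomaly screen's mechanism calls are validated only against the
  simulator's generative rules; real nondisjunction biology is richer.
* MII-mechanism triploidy and isodisomic errors through homozygous parents
  are undetectable from fragment lengths.
* The background-rate offset is treated as a known constant.
* The power bounds depend on the arcsine approximation away from very small
  $n$; use `power_exact_binom()` where exactness matters.
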