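---
title: "Methods: kinship structure of residential camps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship structure of residential camps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campkin)
```

# The model

## Kinship, inbreeding, relatedness

A genealogy is a directed acyclic graph of parent links. The kinship
coefficient φ(i,j) is the probability that one allele drawn at random from
i and one from j at the same autosomal locus are identical by descent. It
satisfies the classic recursion

φ(i,j) = ½ [ φ(f_i, j) + φ(m_i, j) ]   (i not an ancestor of j),

with φ(i,i) = ½(1 + F_i) where the inbreeding coefficient F_i is the
kinship of i's parents. `kinship_matrix()` evaluates the recursion by
dynamic programming over a topological order of the pedigree (ancestors
first), so each of the ~n²/2 entries is computed exactly once; naive
recursion would be exponential in pedigree depth. Missing parents are
treated as unique, unrelated founders — individuals with one known parent
are allowed, and no imputation is attempted.

Wright's coefficient of relatedness is taken as r = 2φ off the diagonal.
The inbreeding-normalised form 2φ/√((1+F_i)(1+F_j)) is available via
`relatedness_matrix(k, inbreeding_adjust = TRUE)` but is not the default:
the populations this package targets are essentially outbred (in the
motivating setting 78 of 80 marriages were between spouses with no known
shared ancestry), the plain doubling matches the convention of standard
pedigree software, and keeping the default simple makes the textbook
values (parent–offspring and full siblings 0.5, half siblings 0.25, first
cousins 0.125, a cousin's child 0.0625, second cousins 0.03125) exact.
Whether field estimates should carry the inbreeding correction for the
rare consanguineous couples' offspring is genuinely open; we document the
assumption rather than hide it.

The diagonal of the relatedness matrix is set to `NA`, not 1: no analysis
in this package ever uses self-relatedness in an aggregation, and a
sentinel that propagates loudly is safer than a value that would be
silently absorbed into a mean. The single place self-relatedness is needed
(the s statistic between spouses, below) substitutes 1 explicitly.

## The gene-dropping oracle

`gene_drop_ibd()` estimates φ by simulation: founders receive unique
allele pairs, each non-founder inherits one uniformly random allele from
each parent per replicate, and the estimate is the frequency with which
one random allele from each pair member is identical by descent. This is
a binomial estimator with standard error √(φ(1−φ)/n), entirely
independent of the recursion — it shares no code path — and the test-suite
requires the two to agree within 3 standard errors on random pedigrees.
Phantom (missing) parents contribute private alleles that can never be
identical by descent with anything else, matching the unique-founder
convention of the recursion.

## Shared reproductive interest

s(i,j) = (r_B + r_D) / (1 + r_C), with r_B = r(i,j), r_D = r(i,
spouse(j)) and r_C = r(i, spouse(i)). It measures how related ego expects
to be to the alter's future offspring, relative to ego's own, and so
captures the stake one has in affines as well as consanguines. Absent
spouses contribute nothing: r_D = 0 when the alter is unmarried, r_C = 0
when ego is unmarried, which makes s collapse exactly to r in a population
with no marriages. When the alter is ego's own spouse, r_D is ego's
relatedness to self, taken as 1 under the outbred convention. The matrix
is asymmetric: your stake in me need not equal mine in you. Widowed and
divorced statuses are not modelled; the spouse map reflects current
marriages.

## Aggregating relatedness within groups

Three summaries of "how related is a camp" coexist and differ as soon as
group sizes differ: the mean of per-camp mean pairwise relatedness
(`r_group`), the mean over individuals of mean relatedness to campmates
(`r_individual`), and the mean over all co-resident dyads (`r_dyads`).
With two communities — 20 members pairwise related at 0.1, 100 at 0.02 —
they give 0.06, 1/30 ≈ 0.033 and 118/5140 ≈ 0.023 respectively
(`worked_example_fixture()`; the dyad count is C(20,2) + C(100,2) =
5140). `r_individual` is the most behaviourally salient — it is the
average indirect-fitness stake an individual has in its group — and it is
what the headline "mean relatedness to campmates" figures use. Singleton
camps have no within-camp dyad and are excluded from `r_group`, their
members from `r_individual`. The `subset` argument selects adult–adult,
all, adult-to-child or child-to-child dyads; the adult/child split comes
from the data's adult flag, not an age cutoff, because field genealogies
can contain individuals with known status but no age estimate.

## Camp statistics

**Stability.** Field descriptions pin only the endpoints: 1 means no
change in camp composition between visits, 0 complete turnover.
`camp_stability()` operationalises the index as the mean Jaccard
similarity |A∩B|/|A∪B| of consecutive visit rosters, which meets both
endpoints, is symmetric, and is invariant to roster ordering and
relabeling. The choice is recorded in the run manifest of every analysis.

**Kin-network dispersion.** `kin_camp_count()` counts camps holding at
least one individual related to ego at or above a threshold (default
0.0625, a cousin's child). Ego's own camp is counted when it contains such
kin — "camps where I have kin" naturally includes home — and an
`include_own_camp = FALSE` flag exposes the exclusive variant.
`household_residence_options()` counts camps where either spouse has kin
at the threshold, always including each spouse's current camp: the
minimum is therefore 1, the couple's own camp. Whether residence options
should require kin of a specific closeness, or whether affinal kin of kin
also grant access, is not settled; the union-of-kin-camps rule is the
package's assumption and is flagged in the manifest.

**Distance.** Camp distances use the haversine great-circle formula on a
sphere of radius 6371.0088 km (through the geosphere package). At the
tens-of-kilometres scale of a single municipality the difference from an
ellipsoidal geodesic is far below any quantity of interest here.
`camp_pair_analysis()` builds the C(k,2) table of mean cross-camp adult
relatedness against distance and reports the Spearman correlation.

# Inference

Correlations are ordinary Pearson or Spearman coefficients with two-sided
p-values (`stats::cor.test`); the first-order partial correlation
r_xy·z = (r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²)) is tested on n−3
degrees of freedom and verified in the suite against the
residual-regression construction.

## Permutation tests and the married-couple problem

Sex differences in per-individual summaries (mean relatedness to
campmates, kin-camp counts) are tested by a two-tailed permutation test
with the add-one correction p = (b+1)/(m+1); the default is 10,000
permutations.

The naive scheme shuffles sex labels freely across individuals. Building
the package revealed that this scheme is invalid for spousal data, and
measurably so. Spouses co-reside, and under bilocal residence each couple
typically contains one member living among natal kin and one who married
in: their relatedness-to-campmates values are strongly negatively
correlated (about −0.45 in synthetic bilocal populations), while their
sex labels are perfectly anti-aligned — every couple contributes exactly
one male and one female. A free shuffle breaks that pairing and
understates the null variance of the sex difference: in a 200-replicate
calibration experiment on sex-symmetric bilocal populations the global
shuffle rejected a true null about 11–12% of the time at the nominal 5%
level (the observed-difference SD was 1.23× the permutation SD).

The default randomization therefore respects the couple structure: labels
are swapped within each married couple with probability ½, and shuffled
freely among the unmarried. This is the exchangeable null for data in
which sex is tied to couple membership; under it the same calibration
experiment rejects at 5.0% (10/200). Free-shuffle and camp-stratified
schemes remain available through the `pairs` and `strata` arguments, and
the scheme in force is recorded in the manifest. Note the camp-stratified
variant does not fix the problem — the couple pairing operates within
camps.

# The synthetic population generator

`generate_population()` exists so that every pipeline stage is testable
without field data, and so that post-marital dispersal rules can be
manipulated experimentally. It forward-simulates:

1. founder couples seeded across camps (the founder count is solved from
   the geometric growth factor mean_offspring/2 so the expected number of
   adults per camp hits the configured target);
2. per generation, Poisson(mean_offspring) children per couple, cohort
   sexes balanced; children inherit the couple's camp;
3. monogamous marriages between opposite-sex members of the same
   generation in *different* camps, prohibited between anyone with known
   shared ancestry except with a small exception probability (default
   2/80); the couple settles on the husband's side with probability 1
   (patrilocal), 0 (matrilocal) or ½ (bilocal, the default);
4. ages assigned top-down by generation with a 25-year mean
   inter-generation interval (SD 3 y), the spousal gap
   N(4.29, 5.31²) years applied to husbands;
5. camp coordinates uniform in a 40 km box centred on 17.06° N, 122.43° E
   (coastal northeastern Luzon, the kind of landscape the defaults
   emulate); an optional exponential distance kernel on the marriage
   market (off by default) produces kin networks that decay with
   distance;
6. visit rosters in which whole households (couple plus dependent
   children) relocate to a random camp with probability 0.25 per visit —
   households, not individuals, are the mobile unit;
7. a per-camp foraging-proportion covariate drawn uniformly on
   [0.195, 1], the range observed in the motivating fieldwork.

Defaults: 15 camps, 18.1 expected adults per camp, 4 generations (the
last being children). `mean_offspring = 4` gives a generation growth
factor of 2, hence a mean genealogical depth of ≈3.3 over four
generations and a child share of roughly half the population — jointly
consistent with a high-fertility forager demography. Fertility and the
inter-generation interval are conventional choices, not field estimates;
only their scale matters for any property the suite tests.

**What the generator does and does not emulate.** It reproduces the
descriptive scales — camp sizes, genealogy depth, age gaps, rare
consanguinity, cross-camp marriage, household turnover — and the
qualitative signature of each dispersal regime (no sex asymmetry in
campmate relatedness under bilocal; male philopatry under patrilocal, the
mirror under matrilocal; both verified over seeds in the suite). It does
not model mortality, divorce, remarriage, polygyny, age-structured
fertility, or kin-directed (rather than random) household moves, and
camp membership at census is the lineage outcome of settlement decisions
alone. Tests passing on these populations therefore validate the
*computations*; they cannot certify behaviour on demographic structures
the generator lacks.

# Numerical and design notes

* Determinism: every stochastic routine takes an explicit seed;
  identical inputs and seed give identical output bits.
* The kinship table is dense; at the few-hundred-individual scale of
  camp studies (~190k pairs at n = 615) this is a trivial allocation and
  far faster than sparse bookkeeping.
* `aggregate_relatedness()` and friends accept any symmetric matrix with
  id dimnames and an `NA` diagonal, so the same aggregation code serves r
  and s.
* Degenerate inputs fail early with named offenders: parent cycles
  (including self-parenthood), sex-inconsistent or dangling parent ids,
  non-mutual spouse links, empty dyad subsets, fewer than two visits for
  stability, zero-variance correlations.
* Problem sizes in the test-suite were chosen to keep the full run at
  roughly half a minute — default-scale populations (~500 individuals)
  where a claim concerns the defaults, 5-camp populations (~90
  individuals) for oracle equalities, 100,000-replicate gene drops where
  Monte Carlo precision is the point, and a 200-seed calibration for the
  permutation null.
* The two worked-example dyad aggregations are exact rationals (1/30,
  118/5140); reports round to 3 decimals for display but keep raw values.

# Known limitations

* Genealogical r is a pedigree expectation, not realised genome sharing;
  no marker-based estimation is provided.
* The kin-marriage prohibition in the generator tests *known* shared
  ancestry; deep cryptic consanguinity among founders is, by
  construction, invisible — as it is in field genealogies.
* The couple-exchangeable permutation null assumes sex is exchangeable
  *within* couples and among the unmarried; residual dependencies (e.g.
  sibling-set co-residence) are not represented in the randomization,
  though calibration shows no measurable effect at the default scales.
* Camp stability from two or three visits is a noisy index; it is passed
  through, not smoothed.
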