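---
title: "Exclusion paternity and mating-system inference for sequential clutches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exclusion paternity and mating-system inference for sequential clutches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirepart)
```

## The problem

Female sea turtles mate near the start of the nesting season, store sperm,
and lay several clutches weeks apart. When the mother of every clutch is
known and a sample of hatchlings is genotyped at a panel of microsatellite
loci, the paternal contribution to each hatchling can be recovered by
*exclusion*: every hatchling carries one maternal and one paternal allele
per locus, so subtracting the maternal genotype leaves the paternal one.
From the paternal residues one can ask the questions this package answers:

* How many males sired each clutch (minimum-father count), and is the
  clutch multiply sired?
* Do the same males reappear across a female's sequential clutches (sperm
  storage), or do new males enter between nesting events (remating)?
* What breeding sex ratio (BSR) — males actually siring offspring per
  nesting female — does the assemblage show, and what does that imply for
  the unsampled population?

The package implements the full chain as plain R functions plus two classed
fits: `clutch_paternity()` (one clutch) and `mating_system()` (one season),
and a seeded synthetic-data generator (`sim_study()` and friends) so that
every stage can be exercised and validated without field data.

## Exclusion analysis and the minimum-father partition

For hatchling genotype $\{h_1, h_2\}$ and maternal genotype $\{m_1, m_2\}$,
the candidate paternal set at a locus is: the non-maternal allele when
exactly one allele matches the mother (certain); both alleles when both
match (the maternal copy is ambiguous); and a *mismatch flag* when neither
matches. Mismatches are never dropped silently — a hatchling mismatching at
more than two loci is reported as a candidate foreign hatchling and set
aside with a warning, because a true offspring can only mismatch through
rare mutation or genotyping error.

A set of hatchlings can share one father only if, at every locus, a single
genotype (at most two alleles) covers every member's candidate set. The
minimum number of fathers is therefore a constrained set-partition problem.
`min_father_partition(method = "exact")` solves it by iterative deepening:
starting from the pigeonhole lower bound it searches depth-first for a
feasible assignment of hatchlings into exactly `k` groups, raising `k`
until one exists — the first feasible `k` is the minimum. Maternal/paternal
ambiguity is resolved *inside* the search — group feasibility admits every
interpretation of an ambiguous pair — rather than fixed greedily
beforehand. This is the central engineering decision:
likelihood-based sibship software makes the same choice implicitly, and a
greedy pre-resolution demonstrably overcounts fathers on ambiguous
instances. The exact search:

* processes hatchlings in sorted-id order and breaks ties among equally
  minimal partitions by a canonical key (group count, then sorted group
  sizes, then member ids), so the result is invariant to input order;
* is bounded below by the pigeonhole bound
  $\max_\ell \lceil a_\ell / 2 \rceil$, where $a_\ell$ is the number of
  distinct certain paternal alleles at locus $\ell$;
* is validated in the test suite against exhaustive enumeration of all set
  partitions on hundreds of small random instances.

With seven loci of 14–25 alleles the constraints are strong and the search
is effectively linear in practice; `method = "greedy"` (each hatchling
joins the first compatible group) is available as a fast upper bound and is
never below the exact count — note it can be far above it, because any
*two* hatchlings are pairwise compatible and early groups absorb a mixture
of sibships.

**Multiple paternity** is called conservatively: at least three certain
paternal alleles at *two or more* loci. A single locus with three or more
paternal alleles is attributed to mutation, the clutch is treated as singly
sired at that locus, and — provided other loci remain to carry the
constraints — the locus is excluded from the partition. On a one-locus
panel nothing can be excluded and the pigeonhole bound stands.

**Mutation model.** Microsatellites mutate predominantly by one repeat
unit, so the generator's mutation model is single-step (±1 size class,
reflecting at the ladder ends). No mutation or dropout rate is asserted for
real data; the generator defaults both to zero, and non-zero rates exist to
probe robustness.

## Matching fathers and classifying transitions

Reconstructed fathers are *partial* genotypes: a locus may carry two
attributed alleles (complete), one (the second never segregated into the
sample, or the sire is homozygous), or none. Two reconstructions match when
they are non-contradictory at every locus (`max_mismatch_loci = 0` by
default): two complete loci must be equal, a complete locus must contain a
half-known allele, and two half-known alleles can always coexist. Within a
female, consecutive clutches are chained through `match_fathers()` to build
a season-level sire register; across females the register entries are
compared the same way, and compatible sires collapse to a single male for
the BSR count.

For a male siring proportion $f$ of the sperm store, the chance that none
of $n$ sampled hatchlings are his is

$$p_f = (1 - f)^n .$$

`classify_transitions()` applies this both ways: a sire of the first clutch
absent from the second is "chance or sperm depletion" when $p_f \ge \alpha$
and "unlikely due to chance" otherwise; a sire newly appearing in the
second clutch is tested with his combined-clutch proportion against the
first clutch's sample size, and an improbably large newcomer is
"remating-consistent". $\alpha$ defaults to 0.05. The `f_mode` switch
chooses between the first clutch (stored sperm assumed well mixed) and the
pooled clutches as the proportion estimate for disappearing sires; both are
defensible and the package reports the mode used. The test is per father:
no joint test over the simultaneous disappearance of several sires is
attempted, because the joint event's null distribution depends on the
unknown correlation structure of the sperm store.

Detection power for a sample of $n$ hatchlings under proportions
$f_1..f_k$ is $1 - \sum_i f_i^n$ (the all-one-sire events are disjoint);
with two equal sires and $n = 20$ this is $1 - 2^{-19} \approx 0.999998$,
which is why a 20-hatchling sample is the conventional design point.

## Locus quality

`popgen_summary()` reports, per locus and combined: observed and expected
heterozygosity, a Monte-Carlo exact Hardy–Weinberg test (alleles permuted
among individuals; chosen over the asymptotic chi-square because genotype
tables with 14–25 alleles are extremely sparse; default 10,000 replicates,
seeded and reported), the probability of identity

$$PI_\ell = 2\left(\sum_i p_i^2\right)^2 - \sum_i p_i^4,$$

and exclusion probabilities for one known parent ($PE_2$) and for a random
parent pair ($PE_3$), using the classical polynomial identities in the
allele-frequency power sums. The closed forms are *not trusted*: the test
suite re-derives both by brute-force enumeration over all genotype trios
weighted by Hardy–Weinberg frequencies and requires agreement to 1e-12 —
the enumeration, not the polynomial, is the ground truth. Loci combine as
$PI = \prod_\ell PI_\ell$ and $PE = 1 - \prod_\ell (1 - PE_\ell)$.

The duplicate-genotyping error rate is the plain concordance estimator:
mismatched allele calls over calls compared, with unordered pairs aligned
to minimise mismatches and missing calls skipped. Under the
uniform-replacement error model with per-call rate $\varepsilon$ and $k$
alleles, its expectation is $\varepsilon (1 - 1/k)$ (a replacement can
collide with the true allele), which the tests verify.

## Clutch metrics

Emergence success is $E = (H - (L + D)) / T$ — hatched eggs minus the
hatchlings that never left the nest, over total eggs. The carapace is
modelled as a half-ellipsoid: $a = SCL/2$, $b = SCW/2$, and the depth
semi-axis $c$ is recovered by treating CCL as half the perimeter of the
$(a, c)$ ellipse — the curve a measuring tape follows along the shell —
inverted via Ramanujan's perimeter approximation with a bisection tolerance
of 1e-9. The area uses the Thomsen approximation with exponent 1.6, halved
for the dorsal surface only, and is validated against a numeric surface
integral to within 1.2% relative error. The pairing of $c$ with $a$ in the
perimeter is a modelling choice (the tape runs along the length axis); it
is isolated in one internal function and swappable. Units are cm and cm².
Note the area is *not* monotone in SCL at fixed CCL: lengthening the shell
under a fixed curved length flattens it.

The comparison layer (`group_comparisons()`, `linear_fit()`) delegates to
the standard R tests (pooled t, F variance ratio, chi-square on quantile
bins, OLS with the overall F) and reports one- and two-tailed p-values,
because published analyses of this kind are often ambiguous about
tailedness.

## The synthetic-data generator

`sim_study()` emulates the study conditions the analysis assumes:

| Parameter | Default | Rationale |
|---|---|---|
| loci | 7, with 14–25 alleles each | the marker panel's published diversity range |
| adult genotypes | Hardy–Weinberg draws | panmictic population, no inbreeding |
| females | 16, laying 1–3 clutches (weights 0.10/0.65/0.25) | renesting females, occasional tertiary clutches |
| clutch size | ~100 eggs, 20 sampled | one-fifth sampling; detection power ≈ 1 for two sires |
| fathers per female | 1–5, weights (0.72, 0.12, 0.08, 0.04, 0.04) | single paternity dominant, rare high polyandry |
| siring proportions | normalised Gamma(3) weights | moderately uneven shares |
| remating | off by default; per-transition probability, fresh share ~ Beta(2, 2) | remating is the rare event under study |
| mutation / genotyping error | 0 / 0 | no rates are asserted for real data |
| emergence | Binomial(clutch size, 0.6) | a hot-season emergence rate |
| internesting interval | 11 days | species-typical mode |
| incubation | Normal(55, 3) days, rounded | typical range |

All draws flow from one root seed (`with_seed()` restores the caller's RNG
state), so runs are bit-reproducible; truth labels (which male sired each
sampled hatchling) ride along for recovery scoring and round-trip through
the CSV writers.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: null alleles, allelic dropout and stutter
(the real pipeline screens these upstream), linkage between loci,
within-clutch sperm stratification (draws are i.i.d. within a clutch),
temperature effects on emergence, and any spatial or temporal nesting
structure. Recovery rates measured on generator output are therefore an
upper bound on field performance.

## Experiment designs used by the validation suite

*Sire-count recovery.* Clutches are simulated under the study conditions
(7 loci, 14–25 alleles, 20 sampled hatchlings, no error) with 1–4 sires;
recovery is scored only where every sire has at least two sampled
offspring, since a single-offspring sibship is indistinguishable from a
mutation under the conservative MP rule. The suite requires ≥95% exact
father-count recovery on 120 such clutches; in practice recovery failures
come from two sires drawing Mendelian-compatible allele sets by chance.

*Remating flagging.* A planted remating replicate is the displacement
pattern actually observed in the field: clutch 1 sired by two males with
shares $(1-f, f)$, clutch 2 by the first male and a *new* male with the
same shares, $f \in [0.3, 0.7)$ spread over replicates by a deterministic
low-discrepancy sequence. A replicate is flagged when any transition has
$p_f < 0.05$. Storage-only replicates keep both sires at stable shares.
The suite requires ≥99% of 1,000 remating replicates flagged and ≤5% of
storage-only replicates falsely flagged; analytically the remating power is
≈0.998 (the disappearance side needs only 3 of 20 hatchlings from the
displaced sire) and the storage-only false-flag rate is at most
$(1-0.3)^{20} \approx 8\times10^{-4}$ per sire.

*Problem sizes.* The exact-partition oracle comparison uses 200 instances
of up to 8 hatchlings (Bell-number enumeration is exact there); the
recovery and flagging experiments use 120 and 1,000 replicates; the HWE
size check uses 120 panels of 60 adults. These sizes give Monte-Carlo
standard errors comfortably inside the asserted margins while keeping the
default test run to a few minutes.

## Numerical and degenerate-input conventions

* Frequencies are renormalised on construction and must sum to 1 within
  1e-9; monomorphic loci are rejected (no parentage information).
* Allele pairs are stored sorted (missing last), making equality
  order-insensitive; 0 is the missing-call code throughout, and a
  single-allele call is kept — it is treated as paternal evidence only when
  it cannot be maternal.
* `T = 0` inventories, constant predictors, zero-variance groups,
  zero-call loci and one-sire detection power all return flagged `NA`/zero
  results rather than errors, matching how analysts meet them in practice;
  invalid *parameters* (negative rates, impossible shared-father counts,
  inconsistent inventories) error immediately.
* Population extrapolation rounds to the nearest integer at each step —
  the convention that reproduces all four published bounds from the census
  inputs; floor or ceiling conventions reproduce at most three of the four.
* BSR from per-female counts assumes no male is shared between females
  (the observed situation); the assignment interface drops that assumption
  by cross-female matching.

## Known limitations

* Exclusion with exact partition replaces full-likelihood sibship
  reconstruction; it does not use population allele frequencies to weigh
  ambiguous cases, and with fewer or less diverse loci it will undercount
  sires more readily than a likelihood model.
* A sire who skips the sample of one clutch and reappears later is
  registered as two males by the chain matcher (season-level identity is
  only propagated through consecutive clutches).
* The error model in matching is all-or-nothing (`max_mismatch_loci`); no
  per-locus error likelihood is computed.
* The half-ellipse inversion for the depth axis requires
  CCL strictly above the flat-shell limit; measurements violating that
  (tape shorter than the shell is long) are rejected as geometry errors.
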