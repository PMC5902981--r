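---
title: "Simulating genomic selection with zygote genome editing of a monogenic locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic selection with zygote genome editing of a monogenic locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Many economically or welfare-relevant traits in livestock are monogenic:
polledness (hornlessness) in cattle is the canonical example. When the
desired allele segregates at very low frequency, driving it to fixation by
selection alone is slow, diverts selection pressure away from the polygenic
breeding goal, and can raise inbreeding. Genome editing of zygotes offers a
shortcut: convert undesired alleles directly in the embryos of selected
matings. `edsim` simulates a closed nucleus breeding program that combines
truncation genomic selection with zygote editing, so that the two routes to
fixation — index weight versus editing — can be compared on equal terms:
time to fixation, polygenic response given up, inbreeding, number of editing
procedures, and a simple cost–benefit balance.

## The simulation model

**Population and polygenic trait.** Generations are discrete. Each
generation, `n_sires` males (default 100) and `n_dams` females (2000) are
selected from the candidate cohort and each dam is mated once to a sire
drawn uniformly at random with replacement; every mating produces
`n_off_per_mating` zygotes (10), giving 20,000 candidates per generation at
the defaults. An animal's true breeding value (TBV) for the polygenic trait
is simulated directly: founders draw TBV from N(0, 1) — the founder additive
variance defines the unit — and offspring receive the midparent average plus
a Mendelian sampling deviation from
N(0, 0.5 (1 − 0.5 (F_sire + F_dam))), so that within-family variance shrinks
as parents become inbred.

**Pseudo-genomic evaluation.** No markers are simulated. A genomic EBV with
reliability r² (default 0.5) is emulated as EBV = r² (TBV + PE) with
PE ~ N(0, (1 − r²)/r²). On a base population this gives
cor(TBV, EBV) = r and Var(EBV) = r² σ²_A, the defining properties of an EBV
of that reliability. The prediction-error variance is kept on the founder
scale (σ²_A = 1) in every generation rather than rescaled to the current
genetic variance; the printed model formula is used literally, and the
consequence — realized accuracy drifting slightly below r at the Bulmer
equilibrium — is shared by design with the program being emulated.

**Monogenic locus.** Each animal carries `g` ∈ {0, 1, 2} copies of the
desired allele of a single biallelic locus, unlinked to and with no effect
on the polygenic trait. Founder genotypes are Hardy–Weinberg draws at
frequency 0.01; transmission is Mendelian.

**Selection.** Phase 1 (burn-in): five generations of truncation selection
on EBV alone, which carries genetic variance and response to their Bulmer
equilibrium — at the defaults, variance ≈ 0.73 and per-generation response
≈ 1.13, the package's generation-0 reference quantities. Phase 2: twenty
generations of truncation selection on the index I = b1·EBV + b2·G with
b1 = 1. `b2 = 0` ignores the locus, `b2 = 0.5` gives it moderate emphasis,
and `b2 = 1000` dominates any realistic EBV (all three are ordinary numeric
weights, not lexicographic rules). Ties in the index are broken by lower
animal id so a run is a pure function of (scenario, seed).

**Genome editing.** When enabled, `round(edit_fraction × n_dams)` matings
(200 at the defaults) are targeted per generation in phase 2. Eligibility is
decided at the family level: only matings whose parents jointly carry at
least one undesired allele qualify. Eligible matings are ranked by fewest
parental desired alleles, then best parent-average index, then lowest dam
id. Every zygote of a targeted mating is subjected to the procedure: each of
its undesired alleles converts independently with probability `k`, and the
zygote survives with probability `s` regardless of conversion success —
mortality attaches to the procedure itself and aggregates mosaicism and
off-target losses, which are not modelled as distinct states. Each subjected
zygote counts as one editing procedure. The combination k = s = 0.2
(`low_efficiency` scenario) yields one live fully edited offspring per 25
subjected heterozygous zygotes, matching currently realistic efficiency.
An `edit_carriers_only` switch restricts subjection (and counting) to
carrier zygotes within targeted families; it is off by default because the
family-level convention is what reproduces the published per-generation
procedure ceilings (2000 zygotes per generation while all targeted families
segregate).

**Inbreeding.** Pedigree inbreeding is exact. Because generations are
discrete and parents always come from the previous generation's selected
parents, the additive relationship matrix among each generation's ~2100
selected parents can be propagated recursively
(a(x,y) = 0.25 [a(sx,sy) + a(sx,dy) + a(dx,sy) + a(dx,dy)],
a(x,x) = 1 + 0.5 a(sx,dx)); a candidate's F is half the relationship of its
parents. This is algebraically identical to the classic tabular method run
over the full ~500,000-animal pedigree — the test suite verifies exact
agreement against an independent whole-pedigree implementation — at a cost
that stays quadratic in the number of parents. Founders are unrelated and
non-inbred.

## Evaluation metrics

Per generation and replicate the package records allele frequency, mean and
variance of TBV, selection response (Δ mean TBV), mean F and ΔF, counts of
animals with the desired phenotype under dominant (g ≥ 1) and recessive
(g = 2) gene action, and the editing log (eligible, targeted, subjected,
survived, fully edited). Scenario comparisons against the b2 = 0 baseline
convert the TBV difference at a horizon into months
(ΔTBV / R_eq × 24 by default) and into "genetic standard deviations". For
the latter the reported tables divide by the equilibrium genetic variance
(≈ 0.73) as such: the published month and sigma columns are mutually
consistent only under that divisor, so `scenario_summary()` reports it as
`sd_loss` and additionally provides the conventional √variance version as
`sd_loss_sqrt`. Time to fixation is the first generation whose cohort
frequency is 1.0, averaged over replicates in which the allele was not lost
to drift; a replicate's `allele_lost` flag records whether frequency ever
hit zero (under editing the allele can be lost and re-introduced). The
breakeven editing cost per zygote is
(extra desired-phenotype percentage × population × horizon × unit cost) /
procedures.

## What the generator emulates — and what it does not

The simulator reproduces the stochastic machinery of a nucleus program under
pseudo-genomic selection: Bulmer-equilibrated variance, intensity-driven
response, family co-selection, drift at a low-frequency locus, and the
throughput arithmetic of zygote editing. It does not simulate marker data,
linkage, or genomic relationships (the locus is unlinked and evaluation is
emulated through the reliability parameter); generations do not overlap;
contributions are not optimized; there is no inbreeding depression; and
mosaicism/off-target events exist only as extra mortality. Passing tests
therefore validate the selection-editing-drift arithmetic, not the
behaviour of any marker-based evaluation on real data.

## Numerical and design choices

* **Rounding.** The number of targeted matings uses half-up rounding
  (`floor(x + 0.5)`), fixed so that 10% of 2000 matings is exactly 200.
* **Mate assignment.** Uniform with replacement (a sire can go unused), per
  the literal design; `balanced_mating = TRUE` divides dams evenly across
  sires for sensitivity checks.
* **Sexes.** Bernoulli(0.5) per animal with no balancing. A cohort with
  fewer live candidates of a sex than parent slots aborts the replicate
  with an error; at the design sizes this is vanishingly unlikely.
* **Draw order.** Within a generation: sire assignment, Mendelian sampling
  deviations, sire then dam transmitted alleles, sexes, editing
  conversions, editing survival, EBV prediction errors of survivors. One
  seed per replicate (`base_seed + i`) makes runs bit-reproducible.
* **Dead zygotes** stay in the cohort with `alive = FALSE`, are never
  candidates, and are excluded from all statistics.
* **Degenerate inputs.** Founder frequencies 0 and 1 are legal (the locus
  starts absent or fixed); `r² = 0` is rejected (a zero-information EBV has
  no defined scale); editing a zygote without an undesired allele is a
  contract error unless the family-level convention explicitly allows it.

## Replicate counts and problem sizes

Published summaries use 50 replicates of the 20,000-candidate program. The
package's own acceptance checks run 20–25 replicates per scenario and a
19-scenario drift grid at 8 replicates, sizes chosen so the whole suite
runs on a laptop in minutes while keeping Monte-Carlo standard errors a
small fraction of the quantities checked; tolerances are the larger of
three Monte-Carlo standard errors (estimated from the replicates) and 10%
of the published value.

## Known limitations

* With `b2 = 0` and no editing the desired allele drifts freely from
  frequency 0.01; most such replicates lose it within 20 generations. This
  makes the "fraction of replicates losing the allele" statistic extremely
  sensitive to which scenarios enter the denominator.
* Simulated allele-frequency dynamics reach fixation about one generation
  earlier than the published trajectories in the editing scenarios (and
  several generations earlier for moderate-weight selection without
  editing), while everything upstream — equilibrium variance and response,
  gen-5 frequencies, response dips and their timing, procedure counts —
  agrees closely. The source implementation is not available to reconcile
  the residual difference; affected comparisons are reported as computed.
* The cost–benefit layer is deliberately linear: no discounting, no
  gene-flow weighting, no market structure.
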