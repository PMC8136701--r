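---
title: "AED coverage analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AED coverage analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedcover)
```

## The problem

When a cardiac arrest happens outside a hospital, survival depends on
defibrillation within 3–5 minutes. A bystander can deliver it only if an
automated external defibrillator (AED) is close enough: the conventional
threshold is 100 m straight-line distance, walkable briskly in roughly
90 s. Because historical OHCA locations cluster and those clusters are
stable over time, a registry of past events is a usable proxy for future
demand. This package operationalises that idea as four questions:

1. How far is each historical OHCA from its nearest 24/7 AED, and what
   fraction is *covered* (distance strictly < 100 m)?
2. How does coverage split across municipality strata (urban /
   intermediate / rural) and location types (home / public)?
3. Where are the *hotspots* — dense pockets of uncovered events with no
   AED nearby — and how much would one AED per hotspot gain?
4. Which AEDs are *redundant* — removable (relocatable) with zero loss of
   historical coverage?

## Distance model

Straight-line distance only. In geographic mode (WGS84 lon/lat) we use the
haversine great-circle distance with mean Earth radius 6 371 000 m; at a
100 m decision threshold the sub-metre differences against an ellipsoidal
model are irrelevant, and no projection machinery is needed. Planar mode
(x/y in metres, Euclidean) exists for simulation and exact worked
examples. The geodata tool used in the original workflow does not document
its Earth model, so the haversine choice is a stated convention, not a
reproduction guarantee. Vertical distance (floors of a building) is
ignored: the analysis is strictly 2-D. Road-network or walking-time
distances are out of scope.

Nearest-neighbour queries are defined by the brute-force pairwise scan;
the implementation simply vectorises that scan, and the test suite asserts
equivalence against independently coded exhaustive oracles on random
instances in both metrics.

## Conventions that change numbers

* **Boundary is strict.** Covered means distance < 100 m; an event at
  exactly 100.0 m is uncovered. Both disk counts (hotspot and overlay
  densities) use the same strict inequality.
* **Ties.** Nearest-AED ties break to the lowest index; greedy placement
  ties break by smallest mean member distance, then lowest candidate
  index; greedy deletion orders by most redundantly-covered first, ties by
  ascending id. All three make results deterministic for a fixed input
  order.
* **Quantiles.** Median and IQR use linear interpolation between order
  statistics (R's default type 7, the spreadsheet family convention).
  Published IQR bounds computed under an unknown other convention may
  differ slightly; exact reproduction of third-party IQRs is not promised.
* **Rounding.** Rates and distances print to 1 decimal; decimal commas in
  source tables are normalised to decimal points everywhere.
* **24/7 filter.** Only AEDs available around the clock participate in
  coverage. Private AEDs count toward coverage but are not relocatable by
  default.

## Hotspot detection and placement

The defining predicate — at least *k* = 5 uncovered OHCAs within 100 m and
no AED within 100 m — is evaluated by exact disk counting, which is a
uniform-kernel density estimate up to normalisation. Site selection is
greedy maximal coverage: candidates default to the uncovered OHCA
locations themselves (finite, canonical, and anchored to "areas with ≥ 5
historical OHCAs"; a grid mode exists for sensitivity checks), candidates
within 100 m of any existing or placed AED are suppressed, and the best
candidate is placed repeatedly until the best remaining one would newly
cover fewer than *k* events. One AED per hotspot: a placement immediately
suppresses candidates within 100 m, so no two proposals overlap.

Greedy is not guaranteed optimal for maximal covering location problems.
On small instances (≤ 20 candidates) the suite compares the greedy total
against exhaustive enumeration and reports any gap rather than hiding it;
exact integer programming at registry scale is a non-goal. Because the
original hotspot centres were read off a map by hand, the *count* of
hotspots in any given dataset is procedure-dependent; only the mechanics
(predicate, threshold, impact accounting) are reproducible, and only they
are tested.

## Relocation (overlays)

"Relocatable without significant loss of coverage" is tightened to **zero
loss**: a plan is valid only if removing all listed AEDs jointly leaves
the covered-OHCA *set* (not merely the rate) identical. This is stricter
than the published phrasing but objective and testable. Deletion is
iterative greedy: remove the most-redundant eligible AED whose disk is
fully backed up by survivors, recompute, repeat. The iteration handles
mutual-backup pairs correctly (one of the two is kept), and a final joint
verification guards the set-equality invariant. On instances with ≤ 12
AEDs the suite compares the greedy removable count against exhaustive
subset search; equality held on every sampled instance, and any future gap
would be printed, not suppressed. Whether removable AEDs were identified
jointly or one-at-a-time in the original workflow is unstated; joint
validity is the stricter reading and is what this package guarantees.
Overlay density (> 1 AED per 100 m disk) is reported for mapping, but the
relocation decision is purely coverage-based.

## Synthetic scenarios: what they emulate, and what not

`generate_scenario()` draws OHCAs from a per-stratum parent–offspring
cluster process (parents uniform within a stratum band, offspring
isotropic Gaussian, resampled — not clamped — at band boundaries to avoid
artificial edge mass), plus optional planted hotspot clusters; AEDs are
uniform background plus planted overlay groups. Defaults are the study's
stated world: 2 971 eligible events, 79.3 % at home, strata mix
1399 : 486 : 340, 633 background AEDs, and a 60 × 60 km region matching
the territory's ~3 200 km² extent. Exclusion rates are not published per
rule; the defaults (traumatic 0.14, highway 0.02, healthcare 0.09,
incomplete 0.02, independent draws) were chosen once so the expected
included fraction ≈ 75 % matches 2 225 / 2 971 and are not revisited.
Cause mix among non-traumatic events (cardiac 0.85 / respiratory 0.09 /
other 0.06) is likewise a one-time realistic choice, as is the 0.4
private-AED share.

Planted structures are constructed to satisfy their predicates: hotspot
members sit within a spread < *r* of a centre that is ≥ 2*r* + 10 m from
every AED and every other planted centre, so they are uncovered and
detectable by construction; overlay groups put ≥ 2 AEDs in one disk.

Two deliberate non-realisms matter for interpreting green tests. First,
background AEDs are uniform, not demand-following, so synthetic baseline
coverage (≈ 1–2 %) is well below the observed 7.5 %, and many synthetic
AEDs cover nothing — relocation counts are accordingly large. A green
pipeline run on synthetic data therefore establishes correctness of the
mechanics, not realism of any particular coverage figure. Second, planted
recovery tests use a sparse, weakly clustered background (chosen a priori:
60 events over 400 km², dispersion 3 km) so that the only hotspots are the
planted ones and "exactly *m* placements" is a well-posed expectation;
with the realistic clustered defaults, accidental background hotspots are
expected and legitimate.

## Acceptance targets

The registry coordinates behind the published analysis are not deposited,
so data-dependent headline results (40 hotspots, 17 relocatable AEDs, the
median distances) cannot be recomputed and are not targets. What is
reproducible is the rate arithmetic: `scripts/acceptance.R` rebuilds each
published coverage percentage from its published numerator/denominator by
constructing a world with exactly that many covered/uncovered events and
running the real pipeline — including, for the post-placement rate, greedy
placement over 45 planted five-member hotspots adding 225 newly covered
events (167 → 392 of 2 225, i.e. 7.5 % → 17.6 %, +10.1 points).

## Known limitations

* Greedy placement and deletion are heuristics; optimality is checked only
  on small instances.
* Geographic-mode grids and the planar→geographic mapping use local
  equirectangular scaling, adequate at tens of km but not continental
  scale.
* No temporal modelling: AED availability is binary 24/7, and incidence
  has no time-of-day structure.
* Geocoding is out of scope; coordinates are trusted inputs, with only
  range/finite validation at the readers.
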