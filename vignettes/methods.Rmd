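---
title: "Models and methods behind sibmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sibmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibmap)
```

## The problem

In an outcrossing species, an F1 full-sib family segregates for markers
that are heterozygous in one parent (lm x ll maternal, nn x np paternal)
or in both (hk x hk, ef x eg, ab x cd). The pseudo-testcross strategy
treats each parent's transmissions as an independent backcross: every
progeny carries one maternal and one paternal gamete, so each parent
gets its own linkage map, built from the markers informative for it.
Several interrelated families can then be combined into a composite
(consensus) map, and the phased gamete data support genome
characterisation: segregation-distortion regions (SDRs), centromere
placement from recombination-frequency profiles, and maternal versus
paternal recombination-rate comparisons.

`sibmap` implements that entire chain, plus a truth-annotated meiosis
simulator, so every stage can be validated end to end without any
external data.

## The simulator's world

`sim_config()` fixes the stated world: 12 linkage groups of roughly
85--116 cM (uniformly spaced defaults over that range), a full-sib
family of 168 progeny by default (realistic for a medium breeding
population; the emulated study spans 67--352), a marker panel of mixed
CP types (defaults 30% lm x ll, 30% nn x np, 20% hk x hk, 10% ef x eg,
10% ab x cd -- GBS SNP panels are dominated by uniparental and hk
configurations, multi-allelic SSR-like types are the minority), 5%
missing calls and 1% genotyping errors i.i.d. per call (under the 20%
missing ceiling the emulated study filtered at).

Meiosis follows the classical count--location model:

* chiasma count per bivalent is Poisson with mean `2 L_eff / 100`,
  where `L_eff` is the intensity-weighted genetic length, so each
  gamete carries `L_eff / 100` crossovers in expectation;
* chiasma positions are drawn from the normalised intensity profile;
  a pericentromeric window (default 20 cM at mid-LG) multiplies the
  intensity by `suppression_factor` (default 0.2), creating the
  recombination cold spot the centromere method relies on;
* each chiasma involves exactly two of the four chromatids, one chosen
  uniformly from each homolog -- no chromatid interference, no obligate
  chiasma, and no positional interference (interference proper is out
  of scope). Gametes are traced along chromatid axes, so every chiasma
  a gamete participates in toggles its grandparental phase.

Because positions are drawn on the intensity-scaled axis, the *true
genetic coordinate* of a marker is the intensity integral of its
simulation coordinate; truth maps and the centromere truth are reported
in that coordinate, which is what any mapper can estimate.

Maternal gametes come one per independent meiosis (one surviving
megaspore). Paternal gametes optionally come from a finite pool of
pollen tetrads: sampling is uniform over tetrads with unused
microspores and without replacement within a tetrad, reflecting pollen
shed as intact tetrads. Viability selection at configured loci is
applied to zygotes before genotyping noise, so truth annotations are
never perturbed. The tetrad-pool size and the per-sex rate multipliers
are independent knobs: the emulated study's tetrad hypothesis concerns
shared paternal meioses, but whether sharing alone lowers the
per-progeny mean event count is left open, so neither mechanism is
hard-wired.

What a green simulator-based test does *not* establish: behaviour under
crossover interference (real data are closer to Kosambi's assumptions
than to Haldane's), locus-specific error processes (errors here are
i.i.d.), population structure, or segregation patterns of multi-locus
SSRs.

## Two-point estimation, grouping, ordering

For one parent, coded calls become transmitted-allele indicators;
`twopoint_matrix()` computes, per marker pair, the recombinant fraction
minimised over the two phase assignments (capped at 0.5) and the LOD
`R log10(r) + (n-R) log10(1-r) + n log10 2`.

Two deliberate guards:

* **hk x hk pairs are excluded from grouping, ordering and distance
  fitting.** The transmitted allele of an hk marker is observable only
  in homozygous progeny, i.e. when the *other* parent transmitted the
  same allele; between two linked hk markers that censoring is
  correlated through the other parent, biasing the pairwise estimate --
  severely enough to fold a map. hk markers are instead inserted into
  the fully-informative framework by triangulation
  (`insert_marker()`), and phased against framework anchors only.
* **Grouping uses LOD > 5 plus a recombination cap `max_rf = 0.30`.**
  With hundreds of markers there are on the order of 10^5 unlinked
  pairs; at n = 200 a pure LOD > 5 rule admits a fraction ~2e-6 of them
  (binomial tail at r-hat < 0.33), i.e. an expected ~0.4+ spurious
  edges that would fuse linkage groups. The cap is standard two-point
  practice and was fixed a priori.

Ordering minimises the sum of adjacent recombination fractions (SARF):
a minimum-spanning-tree diameter path seeds the order, cheapest
insertion adds stragglers, and a delta-evaluated local search (2-opt
reversals plus relocation of blocks of up to three markers in either
orientation) polishes it. The search is deterministic; orientation is
canonicalised lexicographically. With noiseless, fully informative
data the realized discordance counts are locally additive, so the true
bin order is the SARF optimum; ties occur exactly where two orders are
supported by identical counts, which is why order-recovery checks are
made at the bin level and at the printed precision of typical map
tables.

## Distances, cleaning, phasing, imputation

Positions come from weighted least squares over the Kosambi distances
(`d = 25 ln((1+2r)/(1-2r))`) of pairs within `window` ranks (default
5), weights LOD^2, first marker at 0, negative increments clamped, and
zero-recombination adjacent pairs snapped to identical positions so
bins are exact. One caveat documented for simulation work: the
simulator is interference-free, so true fractions are Haldane's, and
Kosambi under-converts by roughly `g/100` per gap of `g` cM; length
validations therefore target the Kosambi-consistent truth length and
use `window = 1`, which is the consistent estimator for that target.

Nearest-neighbour cleaning re-implements the classical iterative
pruning: `nn_fit` (triangle distance inflation), `nn_stress` (mean
absolute r discrepancy to flanks) and its cM analogue, with thresholds
2 cM / 0.035 / 3.5 cM. These statistics are two-point quantities with
binomial standard errors of 1--2 cM at realistic n, so a marker is
removed only when it exceeds a threshold by more than `noise_z = 3`
standard errors; without that allowance the literal rule strips
20--30% of *noiseless* markers through a removal cascade. A truly bad
marker (e.g. 15% call errors) exceeds the allowance by an order of
magnitude and is still removed first.

Phase assignment anchors the first framework marker at "A" and chains
by majority coupling; hk markers are phased against the nearest
framework anchor (never against each other -- the same censoring bias
that affects their pairwise r would otherwise invert flips when the
other parent's phases are in repulsion). Imputation is first-order
Markov: the nearest non-missing flanks give a posterior through
Kosambi-converted interval fractions; entries are filled only at
posterior >= 0.95 (`posterior_min`, exposed), observed entries are
never overwritten. hk genotypes are resolved to parental origin the
same way, requiring the threshold in each parent independently;
partially resolved transmissions yield one split marker and a missing
call in the other, and each biparental marker splits into `_m`
(lm x ll) and `_p` (nn x np) markers under the fixed dictionary
first allele -> `lm`/`nn`.

Error detection flags singleton phase flips (double phase change
within a 2-marker window on both sides), sets them missing and
re-imputes; bins are then maximal runs of map-ordered markers whose
phase vectors are compatible with the bin consensus (missing entries
wildcard), with the lexicographically smallest member as
representative. Recombination events are phase changes between
consecutive non-missing entries per progeny.

## The composite map

Component maps are merged position-wise. Component LGs join a
consensus LG when they share markers (connected components of the
shared-marker graph; bridging conflicts resolved by majority shared
count). Each component contributes order constraints for consecutive
distinct positions and interval data for pairs up to `k` positions
apart; order conflicts are broken by deleting the cheapest arcs on
cycles (fewest supporting maps, then smallest summed distance support,
then lexicographic), so unanimous orders always survive. The consensus
order is a deterministic Kahn topological sort keyed by mean
normalised component position.

Positions minimise the mean absolute difference between consensus and
component intervals subject to the order (an L1 linear program).
Small instances are solved exactly by the simplex method; large ones
by iteratively-reweighted least squares (the objective is convex, so
IRLS approaches the global optimum where plain coordinate descent can
stall on non-smooth points) followed by per-gap median descent.
Degenerate L1 optima are canonicalised by moving every gap to the
midpoint of its one-dimensional optimal interval -- the two-component
toy (0/5/10 vs 0/6/12) lands on 0/5.5/11 reproducibly. `k` runs from 1
to `k_max` (default 10) and the `k` minimising the mean per-component
RMSE wins, ties to the smaller `k`.

A variance note recorded here because it bounds what merging can do:
six component maps of n = 150 gametes over ~90 cM have position errors
that accumulate like random walks (var ~ 100 x/n cM^2); an L1 consensus
is close to a per-interval median of six walks, so its RMSE against
truth has a floor of ~2.5--2.9 cM. Validation thresholds tighter than
that floor cannot be met by any position-based merge of such inputs.

## Genome characterisation

* **Distortion**: per marker, an allele-level 1:1 chi-square with 1 df
  on the focal transmissions (hk calls contribute one h and one k);
  the genotype-class 1:2:1 test is available behind a flag. Markers
  with P < 0.1 are distorted; SDRs are maximal runs of >= 5 distorted
  markers with gaps <= 5 cM (the run rule formalises what the emulated
  study judged visually). Under the null ~10% of markers flag, but
  whole LGs drift together under linkage, so calibration checks use a
  block bootstrap over LGs.
* **Centromeres**: RF_M profiles record, per marker, the fraction of
  progeny whose phase differs from each terminal marker (two-point
  phase difference, not cumulative change -- the 0.45 saturation
  threshold only makes sense for a quantity approaching 0.5). The
  centromere estimate is the first crossing of the linearly
  interpolated curves; the span runs outward to the first marker with
  directional RF >= 0.45 each way. If neither side reaches the bound
  the LG is `undetermined`; otherwise `metacentric` when the crossing
  lies in the central 60% of the LG (this package's numeric rule for a
  distinction the source method leaves qualitative), else
  `acrocentric`.
* **Recombination-rate comparison**: paired t-test on per-LG mean
  events per progeny across maternal/paternal map pairs, with the
  fraction of pairs where the maternal rate is at least the paternal;
  a zero-variance nonzero shift reports t = Inf, P = 0.
* **Coancestry**: the textbook recursive kinship with memoisation;
  founders unrelated and non-inbred, missing parents unknown founders,
  self-kinship 0.5 without inbreeding.

## Numerical and interface choices

* Map positions are 0-based per LG, closed intervals, written at
  1/10000 cM so our own files round-trip byte-identically.
* The canonical missing token is `--`; phases are two digits
  (maternal, paternal), `-` unknown.
* Configuration files are JSON (`jsonlite` is available everywhere the
  package runs; no YAML parser is assumed).
* All randomness flows from one integer seed; identical seeds give
  byte-identical simulator output.
* The CLI (`sibmap_cli()`) wires the stages: `simulate`, `filter`,
  `map`, `phase`, `bin`, `merge`, `characterize`, `report`; exit
  status 2 flags usage errors, 1 validation failures.

## Known limitations

No crossover interference model (and hence a documented Kosambi/Haldane
mismatch in simulation-based validation); no multipoint hidden-phase
likelihood over all five CP types simultaneously (biparental markers
enter through phasing and splitting, mirroring the two-stage design of
the mapping studies this follows); marker order inside a
zero-recombination bin is undefined by construction; the composite
stage merges positions, never re-estimates recombination across
populations.
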