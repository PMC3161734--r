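---
title: "Circadian regulation of nitrogen metabolism through the lens of elementary flux modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian regulation of nitrogen metabolism through the lens of elementary flux modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaflux)
```

## The question

In the green alga *Chlamydomonas reinhardtii*, nitrogen assimilation is under
circadian control. The RNA-binding heteromer CHLAMY1 binds perfect
(UG)\eqn{_k} dinucleotide repeats with at least seven uninterrupted units in
the 3' UTR of target mRNAs and represses their translation during the night.
Among the targets are nitrite reductase (NiR) and argininosuccinate lyase
(ASL). What does switching this set of enzymes off (or down) at night do to
the metabolic capabilities of the cell?

`circaflux` answers this with constraint-based pathway analysis. All
*elementary flux modes* (EFMs) of a stoichiometric model of night-time
nitrogen metabolism are enumerated; each EFM is scored by a carbon yield for
the amino acid it produces; and the regulated enzymes -- identified by
scanning 3' UTRs for the binding motif -- are either removed (complete
inactivation, the knockout scheme) or down-weighted (partial downregulation,
the weighted scheme). Comparing the yield distribution with and without
regulation shows *which part of the flux capability* the clock removes.

## The model

An EFM is a flux vector $v$ with $S v = 0$ over the internal metabolites,
non-negative flux through irreversible reactions, and minimal support: no
proper subset of its active reactions can sustain a steady state. EFMs are
the indivisible pathway units of the network; every steady-state flux is a
non-negative combination of them.

The carbon yield of a mode for target amino acid $A$ is computed from the
mode's overall chemical equation (the net consumption/production of external
metabolites):

$$ Y \;=\; \frac{n_A \, c_A}{\sum_s n_s \, c_s} $$

where $n_A$ is the net production of the target, $c_A$ its carbon count, and
the sum runs over the *designated* carbon sources the mode net-consumes
(glucose-6-phosphate from night-time starch breakdown, and acetate). CO2 is
external but never a designated source, so $Y < 1$ means net CO2 release and
$Y > 1$ means net (non-photosynthetic) CO2 incorporation.

Distribution statistics per target and scheme:

* **all** -- plain five-number summary and mean $\bar Y = \frac1n \sum y_i$
  over every classified mode;
* **knockout** -- the same over the modes that use *no* regulated reaction
  (all-or-none night model); an empty set is reported as infeasible;
* **weighted** -- every mode is kept, but affected modes carry weight
  $w_a$ (default $0.1$) against $1$ for unaffected modes; the weighted mean
  is $\bar Y_w = \sum w_i y_i / \sum w_i$ and the quantiles come from the
  weighted empirical CDF with linear interpolation, which for $w_a = 1/10$
  is exactly the ordinary type-7 quantile of the sample with unaffected
  modes replicated ten times. With $w_a = 1$ the weighted mean reduces to
  the plain mean.

The 10% residual activity is a convention, not a measurement; the
`sweep_downregulation()` helper recomputes the weighted means across nearby
weights and checks that the direction of the shift does not change.

## The packaged core model

The shipped fixture (`chlamy_core_network()`, under
`inst/extdata/chlamy_core_synthetic/`) is a **reduced synthetic
reconstruction** of the pathways involved: glycolysis/gluconeogenesis, both
branches of the pentose phosphate pathway, acetate activation, the citrate
cycle with the glyoxylate shunt, a lumped electron transport chain (P/O = 2),
an ATP maintenance sink, a lumped NADH/NADPH exchange valve, ferredoxin
reduction, nitrate/nitrite/ammonium assimilation (GS/GOGAT and GDH), and the
biosynthesis of glycine, alanine, asparagine, lysine and arginine --
41 reactions over 43 metabolites, every reaction carbon-balanced. It is a
stand-in assembled from textbook pathway structure at a size where complete
enumeration takes a fraction of a second; the published curated model of
this system is about 2.5 times larger (105 reactions, 95 metabolites) and
its supplementary tables are not redistributable here, so full-scale mode
counts are not reproduced by the fixture (see *Limitations*).

Modelling conventions worth making explicit:

* **Externals.** G6P, acetate, nitrate, nitrite, ammonium, CO2 and the five
  target amino acids are buffered; energy and redox carriers are internal.
* **Export-only targets.** No reaction consumes the external amino acids:
  the committed steps of alanine and glycine formation run toward the
  product only. Otherwise the buffered amino-acid pools would act as
  undeclared carbon sources and the yield statistic loses its meaning.
* **Nitrite asymmetry.** External nitrite enters through an uptake-only
  transporter into an internal nitrite pool consumed solely by NiR, so there
  is no nitrite-excretion shortcut; with NiR inactive, neither nitrate nor
  nitrite can feed nitrogen into metabolism.
* **Carrier carbon.** ATP/ADP and NAD(P)/NAD(P)H carry a
  `skip_carbon_check` flag: their ring carbon is a conserved moiety, never
  net-consumed, and is excluded from the per-reaction carbon balance. The
  acetyl skeleton of acetyl-CoA is counted (2 carbons), the CoA moiety is
  not.
* **Regulated set.** The fixture ships four regulated reactions --
  glucose-6-phosphate isomerase, NADP-dependent isocitrate dehydrogenase,
  NiR and ASL. These are the regulated enzymes identifiable from the primary
  description of the system; the full experimental set is reported to
  comprise six enzymes, and the set is deliberately overridable at run time
  (`chlamy_core_scenario("asl_nir_only")` restricts it to the two enzymes
  with direct binding evidence).
* **Reversibility.** Reactions are irreversible only where directionality
  is biochemically firm; when not conclusive, reversible is the default.

## The enumeration engine

`enumerate_efms()` implements the double description method on the flux cone
$\{v \ge 0 : Sv = 0\}$ of the split network (each reversible reaction
becomes a forward/backward pair). Starting from the unit flux vectors, one
steady-state hyperplane is imposed at a time; candidate rays from adjacent
positive/negative pairs are accepted under the combinatorial test (no third
ray's support inside the union), with the rank bound
$|\mathrm{supp}| \le t+1$ after $t$ constraints used as a cheap pre-filter.
Rows are processed by ascending nonzero count with a deterministic
tie-break, so enumeration is reproducible and invariant under reaction
reordering.

Numerical choices: all arithmetic is exact -- 64-bit integers with 128-bit
intermediates and gcd reduction per ray (stoichiometric rows with fractional
coefficients are pre-scaled to integers). Support-minimality decisions are
therefore never at the mercy of floating-point rounding; overflow aborts
loudly rather than corrupting results. Forward/backward two-cycles of split
pairs are discarded after un-splitting (their net flux is zero); a mode
whose support is entirely reversible appears once per orientation. A
configurable cap (default 5 million rays) guards runaway inputs.

`enumerate_efms_bruteforce()` is the package's independent reference: it
tests every support subset directly against the definition (kernel of the
restricted matrix one-dimensional, fully nonzero, sign-feasible). The two
engines are compared for set equality on hundreds of seeded random networks
in the tests and in the acceptance script.

## Synthetic data: what it emulates, what it does not

The generators provide every input type with known ground truth:

* `random_network()` composes source-to-sink pathways sharing intermediates
  with matching carbon counts, plus carbon-conserving split reactions, so
  carbon balance and mode existence hold by construction. These networks
  probe the *engine* (they are small and tree-like with occasional cycles
  through shared intermediates); they do not mimic the dense cofactor
  coupling of real metabolism -- that is what the packaged core model is
  for.
* `planted_utrs()` plants maximal (UG)$_k$ runs at recorded positions in
  background DNA whose accidental runs are broken below threshold, flanked
  by non-U/G bases. Real UTRs differ in base composition and repeat-length
  distribution; the planted sets establish scanner *correctness*
  (recall/precision 1 at exact coordinates), not genomic statistics.
* `synthetic_proteome()` draws residues i.i.d. from a frequency vector --
  sufficient for validating composition profiling against a multinomial
  error bound, silent about real codon usage.

A single seed drives a separate stream per generator, so fixtures are
reproducible independently of call order.

## What the core model shows

```{r results, eval = FALSE}
net  <- chlamy_core_network()
efms <- enumerate_efms(net)          # 1695 modes, well under a second
tab  <- scenario_compare(efms, net$config$regulated_reactions)
```

On this model (numbers as computed by the tests and
`scripts/acceptance.R`): between 89% and 100% of the modes producing each
amino acid use at least one regulated reaction; knocking the regulated set
out leaves *no* arginine-producing mode (ASL is essential) and *no* mode
consuming nitrate or nitrite (NiR is essential); about 1/21 of all modes
remain fully active. Mean yields rise under both knockout and 10%-weighting
for glycine, alanine and asparagine while no maximum yield rises --
regulation predominantly suppresses low-yield routes, consistent with
conserving carbon and energy at night when photosynthesis is off. In the
GAP-variant scenario (glycolysis and the pentose phosphate pathway removed,
GAP + acetate fed) the maximum yields are insensitive to regulation, showing
that the maximum-yield statistic depends on the carbon source chosen, while
the distribution shift is the robust signal.

Lysine is the exception at this scale: its mean yield *falls* under
knockout (0.468 to 0.384). Two identifiable reasons, both scale artifacts
rather than engine properties: (i) the unaffected set at 41 reactions is
dominated by co-production modes (e.g. 14 glycine + 1 lysine from the same
carbon) whose per-target yield is tiny under the yield convention, and
(ii) the regulated set here has four enzymes where the experimentally
reported set has six, so our unaffected set is systematically larger and
noisier. The tests assert the four-target pattern and deliberately leave
the lysine component failing rather than masking it.

## Limitations

* The fixture is a reduced synthetic reconstruction: absolute mode counts
  (hundreds of thousands to millions at full scale) and per-target counts
  are not comparable to the published full model, only the qualitative
  regulation effects are.
* No compartments: all reactions share one pool, as in the system this
  package models, which excludes compartment-specific costs.
* Regulation is presence/absence of one motif; no transcriptional or
  post-translational layer, no motif-enrichment statistics.
* The weighted scheme treats the weight as a residual translation activity,
  applied uniformly to every affected enzyme; enzyme-specific fold changes
  would slot into the same machinery but are not modelled.
* The brute-force oracle is exponential and limited to small networks by
  design; at full scale correctness rests on the exact arithmetic and the
  invariants (steady state, sign feasibility, pairwise minimality) that are
  re-checked on every enumeration in the test suite.
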