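---
title: "Models and design of virtual2DE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of virtual2DE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtual2DE)
```

virtual2DE reconstructs quantitative two-dimensional electrophoresis (2DE)
patterns from per-section peptide identification tables. This vignette is
the package's own account of the models it implements, the parameters that
matter, the numerical choices behind them, and what the synthetic-data
tests do and do not demonstrate.

## Charge model and isoelectric point

A polypeptide's net charge at pH $p$ is the Henderson–Hasselbalch sum over
its ionizable groups,

$$Q(p) \;=\; \sum_{\text{basic } i} \frac{n_i}{1 + 10^{\,p - pK_{a,i}}}
\;-\; \sum_{\text{acidic } j} \frac{n_j}{1 + 10^{\,pK_{a,j} - p}},$$

with both termini included. $Q$ is strictly decreasing in pH, so whenever
the molecule has at least one acidic and one basic group there is a unique
root on $[0, 14]$ — the isoelectric point — which `isoelectricPoint()`
locates by bisection to a tolerance of $10^{-4}$ pH units (the property
suite checks this against a brute-force grid-scan argmin at the same
resolution). Values are reported to two decimals, the precision used in
reference tables.

**pKa sets.** Three tables ship with the package (`pkaSet()`). The default
is the Bjellqvist set: side-chain pKas D 4.05, E 4.45, C 9.0, Y 10.0,
H 5.98, K 10.0, R 12.0; residue-specific N-terminal amine pKas (e.g. V
7.44, G 7.50, default 7.50) and a uniform C-terminal carboxyl pKa of 3.55.
Implementations of the Bjellqvist model differ in one detail — whether a
C-terminal Asp/Glu gets an adjusted pKa (side chain or terminal group). We
validated the variants against the published reference pI values of the
ten packaged mature chains: only the *position-independent* side-chain
convention reproduces all ten exactly (the discriminating case is
transthyretin, the one fixture chain ending in Glu: 5.31 under this
convention versus 5.33–5.35 under the adjusted ones). That convention is
therefore the package default. EMBOSS and Lehninger sets are included for
sensitivity analysis; they shift absolute pI by up to ~0.5 pH but preserve
orderings.

**Modifications as charge edits.** A proteoform's modifications edit the
group inventory: each phosphate contributes two acidic groups (pKa 1.2 and
6.5 — the second ionization is what moves spots near neutral pH), each
sialic acid (NeuAc) one acidic group (pKa 2.6), and each lysine acetylation
removes one lysine amine. Neutral sugars and methionine oxidation change
mass only. This is deliberately the simplest model that yields the acidic
spot trains observed for heavily modified plasma proteins; it ignores
electrostatic coupling between sites and local-environment pKa shifts.

## Mass model

`proteinMass()` sums residue masses plus one water plus modification
deltas. Average masses (ExPASy residue table) are the package's gel
coordinate scale — they reproduce the published reference chain masses of
the packaged fixtures to the dalton — while monoisotopic masses serve
peptide bookkeeping. Glycan deltas come from monomer composition (average:
Hex 162.14, HexNAc 203.20, NeuAc 291.26, Fuc 146.14 Da), since annotations
give compositions, not masses. Residues B, Z, X, U, O are rejected rather
than approximated: a silent average-mass substitution would corrupt the Mw
axis by tens of daltons on a large chain.

## Digestion and the emPAI denominator

`digestTryptic()` cleaves after K/R except before proline (the Keil rule,
as applied by the common search engines; a flag disables it) and
enumerates peptides with up to `maxMissed` internal missed cleavages
(default 2). The "theoretically observable" count $N_{obsbl}$ — the emPAI
denominator — counts *distinct fully cleaved* peptides inside an
observability window, by default 500–4500 Da and 6–50 residues, a typical
Orbitrap acquisition range. Two choices here are genuinely open and are
therefore config-exposed:

* counting missed-cleavage variants would double-cover sequence and
  inflate $N_{obsbl}$, so the default excludes them
  (`includeMissed = TRUE` for sensitivity checks);
* the acquisition window used in any given study is rarely stated, so the
  window is an explicit argument and recorded by callers. Absolute emPAI
  values are only comparable under a fixed window; the package's validation
  consequently rests on formula-level identities and simulator recovery,
  never on reproducing someone else's absolute emPAI magnitudes.

`emPAI(n_obs, n_obsbl)` implements $PAI = N_{obs}/N_{obsbl}$,
$emPAI = 10^{PAI} - 1$; $N_{obsbl} = 0$ is an explicit error, not a silent
zero. Identified peptides are counted as distinct sequences with
modification state collapsed (a flag counts modified forms separately),
because counting an oxidized and unoxidized observation of one peptide
twice would inflate precisely the heavily modified proteoforms the method
is trying to map.

**Acceptance filter.** `acceptProteins()` keeps proteins with at least two
distinct *unique* peptides above the score threshold. "100% confidence" is
an engine-specific phrase; it is operationalized as the score threshold,
which the caller sets to whatever their engine's certainty level maps to.
The rule is evaluated per section by default — each section is a separate
LC-MS/MS experiment — with `per = "run"` pooling evidence across sections
for the semi-virtual use case where a protein's identity is established
once across the strip.

## Axes and sectioning

The pI axis is a monotone piecewise-linear interpolant through anchor
points (`piAxis()`); extrapolation is refused. `nl311Anchors()` provides a
documented 5-point approximation of an 18 cm pH 3–11 nonlinear gradient
(steep ends, shallow middle); it is adequate for simulation and teaching,
and users supply the manufacturer's curve for accurate work. The Mw axis
(`mwAxis()`) is the standard log-linear SDS-PAGE calibration: least-squares
fit of $\log_{10} Mw$ on relative migration, slope necessarily negative.

Sectioning schemes partition the plane with half-open intervals
$[low, high)$, the final interval closed — an exact partition with no
double assignment, verified by an exhaustive grid audit in the tests.
`strip36` is one row of 36 equal 0.5 cm sections (18 cm strip); `grid96`
is 8 Mw-rows × 12 pI-columns (the published grid geometry is not public,
so the 8×12 default is overridable by custom boundaries). Off-range
coordinates raise an explicit off-gel signal rather than disappearing.

In `buildPattern()`, semi-virtual (single-row) patterns place each spot at
the supplied *theoretical* chain mass — per chain, not per canonical entry,
so e.g. haptoglobin's alpha and beta chains form separate spot rows — while
grid patterns use the section's migration-midpoint Mw. Total emPAI is
conserved from quantification to map.

## Pattern comparison and rendering

`comparePatterns()` matches spots per accession greedily (closest
pI-midpoint first) within pI and relative-Mw tolerances and reports log2
emPAI ratios with a pseudocount (default 0.01 emPAI units) so zeros stay
finite. Greedy matching, not optimal assignment, is a documented
limitation: per-protein spot sets are small and tolerance windows rarely
overlap, and identical patterns always match completely with ratio 0.
`renderPattern()` writes deterministic SVG with circle *area* proportional
to emPAI — the perceptually honest reading of "ball size proportional to
abundance" — with a radius-proportional mode available since that phrase
is ambiguous.

## The simulator: what it emulates, and what it does not

`simulateTrain()` builds a proteoform ensemble: $n$ phosphosites occupied
independently with probability $\theta$ (binomial weights over the
phosphate count) crossed with a discrete glycoform set; weights multiply
and sum to 1. `simulateSectionTable()` is the stochastic forward model:
each species' pI receives Gaussian focusing jitter (default sd 0.05 pH),
is located to a section, and yields
$\min(N_{obsbl}, \mathrm{Poisson}(depth \times weight \times N_{obsbl}))$
distinct peptides sampled without replacement from the chain's observable
set. Poisson-thinned sampling is the simplest model with emPAI-like
saturation: as depth grows, observed peptides saturate at $N_{obsbl}$ and
emPAI at 9.

All randomness flows from one explicit seed through a local RNG that never
touches global state; fixed seeds give byte-identical tables. Defaults
used by the validation suite: depth 5 (a section near the middle of the
dynamic range — far from both dropout and saturation for weights around
0.1–0.4), jitter 0 for recovery tests (isolating the reconstruction from
focusing noise) and 0.05 otherwise, 50 replicates.

What the simulator does **not** model: spectrum-level noise, retention
time, chimeric identifications, inter-section carry-over (a protein
smearing into neighbouring sections — visible in real section data — is
represented only through pI jitter), Mw jitter (meaningless in semi-virtual
mode, where Mw is theoretical by construction), and any correlation
between modification state and peptide detectability. Passing recovery
tests therefore demonstrates that the *reconstruction pipeline* is
faithful to its own forward model at realistic depths, not that real gels
are free of these effects.

## Validation summary

The test suite checks, at tolerances stated in the tests themselves:
exact reproduction of the published pI (2 decimals) and average Mw
(nearest Da) for the ten packaged mature plasma chains; digestion against
brute-force enumeration on 200 random sequences; bisection pI against a
$10^{-4}$-step grid scan on 100 random peptides; emPAI worked identities;
emPAI conservation through map building; byte-identical seeded reruns; and
recovery of a simulated 3-phospho, 2-glycoform haptoglobin beta-chain
train (eight species, five contiguous acidic-shifted sections) in at least
90% of 50 replicates at depth 5 with zero jitter, with the emPAI-weighted
centroid within one section width of truth. Problem sizes were chosen so
the whole suite runs in about a minute.

## Known limitations

* The charge model treats sites as independent; dense phosphorylation on a
  short chain will be less acidic in reality than predicted.
* The Bjellqvist table is calibrated for denatured proteins in IPG
  systems; folded-state pIs differ.
* $N_{obsbl}$ depends on the observability window; absolute emPAI values
  are comparable only within one configuration.
* The nonlinear gradient approximation is 5-point; section pH windows near
  the steep ends inherit its error.
* Greedy spot matching can mispair when two proteoform spots of one
  protein fall within one tolerance window of each other.
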