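---
title: "Methods: library enumeration and screening analytics in clickscreen"
author: "clickscreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: library enumeration and screening analytics in clickscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clickscreen)
```

`clickscreen` models a two-step combinatorial campaign against zinc
metalloenzymes such as the human carbonic anhydrases: CuAAC click
assembly of a triazole scaffold, sulfonamide *N*-acylation, parallel
synthesis bookkeeping, thermal-shift triage, and enzymatic confirmation.
This vignette records the scientific and numerical choices behind each
stage — what is assumed, what is tunable, and what the synthetic-data
generators do and do not emulate.

## Chemistry model

### Building-block validation

A building block is admitted only if its SMILES parses to a single
connected molecule containing **exactly one** reactive group of its
declared role: a carbon-bound azide (either charge convention,
`C–N=N⁺=N⁻` or the hypervalent `C–N=N≡N` form some toolkits emit), a
terminal alkyne `C≡CH`, or a carboxylic acid `–C(=O)OH`. We additionally
reject blocks carrying reactive groups of the *other* two roles, and
blocks with more than one primary sulfonamide or a pre-formed *N*-acyl
sulfonamide. The rationale is operational: parallel synthesis presumes a
single unambiguous reaction site per step, and a polyfunctional block
would silently multiply products. Multi-fragment SMILES (salts,
solvates) are rejected rather than stripped — desalting policy belongs
to input curation, not to the enumerator.

A primary sulfonamide `–S(=O)₂NH₂` on carbon is the handle for the
second step. It is recorded per block (`carries_sulfonamide`), and the
design layer enforces the campaign topology: exactly one of the
azide/alkyne sets carries it on *every* member (alkynyl sulfonamides or
azido sulfonamides), the other click partner and the acids never do.

### The two transforms

Both transforms are explicit edits of the Kekulé graph, after which Open
Babel re-perceives aromaticity and emits canonical SMILES:

* **CuAAC** joins the azide triple N(α)–N(β)–N(γ) and the alkyne carbons
  C(i)≡C(t) into the aromatic ring N1–N2–N3–C4–C5, with the azide's
  carbon substituent on N1 and the alkyne substituent on C4. Only the
  1,4-regioisomer is emitted, reflecting the copper(I) selectivity of the
  reaction; no 1,5 option exists. The edit conserves every heavy atom of
  both parents.
* ***N*-acylation** condenses the sulfonamide nitrogen with the acid's
  carboxyl carbon and deletes the hydroxyl oxygen (water loss): the
  product has exactly `N(substrate) + N(acid) − 1` heavy atoms. Only the
  primary sulfonamide nitrogen is ever acylated; amide N–H elsewhere in a
  block is untouched, and a 1,4-disubstituted triazole has no ring N–H to
  compete.

Structure equality is always decided on canonical SMILES
(`canonical_smiles()`, Open Babel's `can` writer); raw strings are never
compared. Canonicalization is idempotent, which the test suite asserts.

One implementation note: we serialize edited graphs with explicit
`M CHG` property lines rather than the legacy molfile atom-line charge
field, because elastic column widths in regenerated molfiles can
misalign the legacy field and silently neutralize azide or nitro
charges. SMARTS counting likewise operates on molecule objects built
directly from SMILES, never on re-written molfiles.

### Enumeration semantics

Members are addressed by 1-based label triples {i,j,k} into the azide,
alkyne and acid sets; labels may be non-contiguous (a curated acid subset
keeps its original numbering), so planned-combination lists reference
labels, not positions. A failed transform marks that member `failed` and
enumeration continues — one bad combination must not abort a campaign.
Distinct triples collapsing to one canonical product (e.g. duplicated
reagents under different labels) are emitted but flagged `duplicate`.
The theoretical space is simply |azides|·|alkynes|·|acids|, independent
of what was planned; an empty set yields zero with a warning rather than
an error, so an in-progress design can still be reported.

## Synthesis tracking

SSR is the percentage of planned experiments that isolated the target;
the mean isolated yield averages only isolated members *with a reported
yield* (isolated-but-unquantified members count toward SSR alone, an
assumption the report states explicitly in its `yield_basis` field).
Printed percentages are rounded half away from zero — with counts like
186/247 (75.30%) and 76/89 (85.39%) banker's rounding would agree, but
half-away-from-zero matches how screening reports conventionally print
and makes e.g. 74.5 → 75 predictable. Pooling reports sums counts and
recomputes SSR from the sums, so pooled results are invariant under
input permutation and never an average of averages.

## Thermal-shift analysis

### Tm extraction

Two extractors are provided. The **derivative** method smooths the
fluorescence with a Savitzky–Golay filter and takes the temperature of
the maximum first derivative, computed with the filter's own derivative
kernel and refined by parabolic interpolation around the peak. The
default window is 11 points (5.5 °C on the standard 0.5 °C grid), cubic
order: on simulated two-state melts with 2% multiplicative noise this
window keeps the mean |error| near 0.09 °C, whereas a 7-point window
lets occasional peak misses exceed 0.45 °C; the window is a user
parameter for sharper or noisier transitions. The **boltzmann** method
fits the two-state sigmoid F(T) = base + amp/(1 + exp((Tm − T)/slope))
by Levenberg–Marquardt and is the more accurate extractor (max |error|
≈ 0.07 °C under the same noise), at the cost of assuming the two-state
shape. The derivative default exists because it is assumption-free about
baselines and is what plate-reader software conventionally reports.

A curve is `usable = FALSE` when its transition amplitude is
indistinguishable from noise (signal-to-noise of the 5–95% amplitude
range below 10), when the derivative peak sits on the grid boundary, or
when the sigmoid fit fails or returns a Tm outside the scanned range.
Unusable wells are excluded from shift tables with a logged reason.

### Shifts and hit calling

Per plate, the reference Tm is the **median of usable control wells** —
no cross-plate pooling, so plate-to-plate protein or dye drift cannot
leak between plates. Sample shifts are ΔTm = Tm − reference. The hit
rule is

> hit ⇔ |ΔTm| ≥ MED(ΔTm) + 3·RSD(ΔTm) **and** |ΔTm| ≥ 0.5 °C

with MED the median and RSD a robust standard deviation of the plate's
*sample* shifts (controls never contribute). We take RSD = 1.4826·MAD,
the standard consistency-scaled median absolute deviation; the constant
is a parameter (`rsd_constant`) because "robust SD" admits several
estimators and a laboratory may prefer, e.g., Qn. The statistics are
computed on signed shifts; an `on_absolute` option repeats the call on
|shifts| for sensitivity analysis. The 0.5 °C floor is applied as an
AND: on a very tight plate (RSD → 0) the adaptive threshold alone would
flag negligible shifts, and the floor encodes the smallest shift worth
calling a meaningful interaction. Hits are signed: positive shifters
stabilize, negative destabilize; both directions are reported because
destabilizers can still be genuine binders. When wells carry a
screening-concentration column, plates are called per concentration and
a compound is a primary hit if flagged at any concentration.

A plate needs at least 4 sample shifts for MED/RSD — below that the
robust scale is meaningless and the plate errors out as too sparse.

## Dose–response confirmation

Esterase kinetics reduce to least-squares initial-rate slopes over a
configurable early window. Percent inhibition anchors each rate between
the no-inhibitor control and the no-enzyme background, clamped to
[−20, 120] with a flag (values outside that range indicate assay
artifacts, not biology). The 4PL y = bottom + (top − bottom)/(1 +
(IC50/x)^hill) is fitted to pooled replicate points (a mean-fit option
exists) with IC50 parameterized as log10(IC50) for conditioning, using
Levenberg–Marquardt from multistarts at Hill ∈ {0.5, 1, 2}. A fit is
reported non-converged when the response spans less than 15 inhibition
points (no dose dependence), the optimizer fails, the fitted IC50 falls
outside the tested ladder by more than 10-fold (guard band), the
plateaus invert, or the Hill slope leaves (0.2, 5) — slopes outside that
range on a 10-point 3-fold ladder are fit pathologies, not pharmacology.
Non-inhibitors are reported qualitatively as "IC50 > top concentration".
The Wald 95% interval on log10(IC50) is transformed back to
concentration units. IC50 is exactly equivariant under concentration
rescaling (µM → nM multiplies it by 1000), which the tests assert.

The default titration design is the campaign's: 10-point 3-fold serial
dilution from 200 µM (lowest point 200/3⁹ ≈ 0.01 µM), n = 4. Enzyme
concentrations are metadata carried through reports, not model inputs.

## Synthetic data: what it emulates, and what not

The generators exist so that every stage has inputs with known ground
truth:

* `smiles_pool()` decorates ~10 aromatic/aliphatic scaffolds into >100
  azides, >100 acids and >60 sulfonamide-bearing terminal alkynes —
  entirely programmatic, no database export. Every entry passes
  validation for its role.
* `gen_outcomes()` draws isolation as Bernoulli(SSR/100) and yields from
  a normal truncated to (0, 100]. Defaults (SSR 75%, yield 56 ± 15%)
  match a realistic parallel-synthesis regime.
* `gen_melt_plate()` builds two-state sigmoid melts (default Tm₀ 55 °C,
  transition width 1 °C, 25–95 °C grid at 0.5 °C) with planted shifter
  deltas, null jitter (sd 0.15 °C), exact-Tm₀ controls and multiplicative
  2% noise. The default plate — 5 compounds at +3 °C, 10 at −2 °C, 85
  nulls, 8 controls — mirrors a primary screen that advances 5 positive
  and 10 negative shifters. An optional post-transition decay term
  stress-tests Tm extraction against aggregation-like signal loss, which
  real DSF data show and the default model omits.
* `gen_dose_kinetics()` emits linear traces whose slopes encode a planted
  4PL (defaults: control 2×10⁻³ AU/s, background 2×10⁻⁴ AU/s, 0–300 s at
  15 s); noise is applied on the inhibition scale so "5% noise" means 5
  inhibition points regardless of rate units. Planted potencies for
  pipeline demos (0.2, 1.1, 6.07, 8.74 µM) sit in the low-micromolar
  regime a confirmed carbonic-anhydrase hit set occupies.

All generators require an explicit seed, use a fixed RNG kind, and
restore the caller's RNG state, so identical seeds give byte-identical
outputs and no test depends on ambient randomness.

What passing on these generators does **not** show: real DSF artifacts
(aggregation decay, dye-compound interactions, edge effects), non-linear
kinetics (substrate depletion, slow-binding inhibitors), synthesis
failures correlated with specific building blocks, or purity effects.
The generators validate the *analysis machinery*, not the assays.

## Problem sizes used in the checks

The routine test suite and the acceptance script run deliberately
moderate simulation sizes — 100-seed Tm recovery, 4 × 50-seed IC50
recovery, a 100-compound screening plate, 150–500 random enumeration
triples — chosen so the full validation battery completes in a few
minutes while keeping Monte-Carlo error well below the asserted bands.

## Known limitations

* Regiochemistry is fixed to 1,4; genuinely thermal (uncatalyzed)
  cycloadditions producing 1,5-mixtures are out of scope.
* Stereochemistry passes through from input SMILES but the transforms
  neither create nor check stereocenters.
* The derivative Tm extractor's error distribution has a heavier tail
  than the Boltzmann fit's; for sub-0.3 °C per-well guarantees use
  `method = "boltzmann"`.
* Hit calling treats wells as independent; no spatial (edge-effect)
  model.
* No Ki conversion from IC50 (no Michaelis constant is modelled), and no
  selectivity statistics beyond comparing per-isoform IC50s.
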