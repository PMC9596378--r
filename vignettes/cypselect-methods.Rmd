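---
title: "Models and procedures behind cypselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and procedures behind cypselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypselect)
```

cypselect implements the computational spine of a subtype-selective
cyclophilin-inhibitor campaign: decoding an affinity selection of a
DNA-encoded macrocycle library, fitting coupled prolyl-isomerase kinetics
into absolute IC50s, modelling fluorescence-polarization (FP) and SPR
binding equilibria, and assembling panel-wide selectivity, mutant-rescue
and mitochondrial calcium-retention summaries. Every assay has a matching
synthetic generator with known ground truth, so the whole pipeline is
testable end to end. This vignette records the models, the parameters that
matter, and the design decisions where more than one reasonable choice
existed.

## 1. Encoded-library selection and enrichment

### The library model

A DNA-encoded macrocycle library attaches a DNA barcode to each compound;
an affinity selection against an immobilized cyclophilin followed by
sequencing reveals binders as enriched barcodes. `design_library()` models
a four-position combinatorial library, by default 20 x 20 x 20 x 32 =
256,000 members. The true building-block counts of such libraries are not
derivable from the assembled compound set, so the factorization is a
configurable default; every downstream computation works for any
factorization.

Each position carries its own codon table: fixed-length DNA codons
(default 8 nt) generated greedily from a seeded shuffle of the full
$4^L$ enumeration, accepting a codon only if it is at Hamming distance
$\ge 3$ from every codon already accepted at that position. Distance 3 is
the minimum that makes single-substitution correction sound: a read codon
with one error is within distance 1 of exactly one table entry. If the
shuffled pool is exhausted before the requested table size, a capacity
error is raised rather than silently weakening the code. The simulated
read layout is a 12-nt 5' constant region, the four codons separated by
4-nt constant spacers, and a 12-nt 3' constant region; the error model is
uniform substitutions only (no indels or chimeras), which is the dominant
short-read error mode and keeps codon offsets fixed.

### The enrichment statistic

`simulate_selection()` draws pre-selection reads from a uniform member
distribution and post-selection reads from the baseline multiplied by the
configured enrichment factors, renormalized. Factors of overlapping
patterns compose multiplicatively, so a family-wide factor (e.g. `"JO**"`
at 50x) can be combined with an extra factor on one member; this is how
recovery tests plant a known rank-1 member inside a known rank-1 family.
(With a flat family factor all family members are exchangeable in
expectation and no single member could be asserted as rank 1.)

`decode_reads()` locates codons at fixed offsets and assigns each observed
codon to the unique table entry within `max_mismatch` (0 or 1)
substitutions; reads failing any slot are rejected with a structured
reason (`truncated`, `unmatched`, `ambiguous`). Percent abundances are
computed over *decoded* reads only, since the statistic quantifies library
barcodes, not sequencing throughput. The enrichment statistic is the
change in percentage abundance,

$$\Delta\% = \mathrm{post\%} - \mathrm{pre\%},$$

which sums to zero over the full member universe — a useful audit
invariant. Because a difference of percentages says nothing about ratio
for rare members, a pseudocounted fold
$((\mathrm{post}+\alpha)/(\mathrm{post_{tot}}+\alpha N)) /
((\mathrm{pre}+\alpha)/(\mathrm{pre_{tot}}+\alpha N))$ with Jeffreys-style
$\alpha = 0.5$ is reported alongside; rankings order by $\Delta\%$, then
fold, then member id, making output deterministic. `aggregate_families()`
sums $\Delta\%$ over wildcard patterns (all single- and double-wildcard
patterns under `"auto"`), which is how conserved hit families such as
`JO**` surface from member-level noise.

Default scenario conditions: read depth $10^5$ per round and substitution
rate 0.005/base (a typical short-read error magnitude). At that depth the
per-member binomial noise on $\Delta\%$ for a 256,000-member library is
far below the planted signals used in the recovery tests.

## 2. Coupled prolyl-isomerase kinetics

### Signal model

In the chymotrypsin-coupled assay, *cis*→*trans* isomerization of the
Suc-AAPF-AMC substrate is rate-limiting for protease cleavage, so released
fluorescence follows one-phase association,

$$F(t) = F_0 + (F_\mathrm{plateau} - F_0)\,(1 - e^{-k_\mathrm{obs} t}),$$

with $k_\mathrm{obs} = k_\mathrm{thermal} + k_\mathrm{enzyme} f_\mathrm{free}$:
the uncatalyzed thermal isomerization plus the enzymatic contribution
scaled by the free-enzyme fraction. Defaults: sampling every 1 s for
330 s, enzyme at 5 nM, $k_\mathrm{thermal} = 0.005$ s⁻¹,
$k_\mathrm{enzyme} = 0.025$ s⁻¹, amplitude 100→600 AU, Gaussian noise
2 AU. The amplitude is a free parameter of the generator rather than being
derived from substrate cis-content, which the signal model does not need.

Because the enzyme concentration (5 nM) overlaps the potency range of the
best inhibitors (low nM), free-ligand approximations fail and the bound
fraction follows the Morrison tight-binding quadratic:

$$[EI] = \frac{(E + I + K_i^\mathrm{app}) -
  \sqrt{(E + I + K_i^\mathrm{app})^2 - 4 E I}}{2},
\qquad f_\mathrm{free} = 1 - [EI]/E.$$

A direct consequence is the *stoichiometric floor*: the dose at which
activity is halved equals $K_i^\mathrm{app} + E/2 \ge E/2$ (2.5 nM at 5 nM
enzyme), no matter how potent the compound. Recovery scenarios therefore
set the generator's $K_i^\mathrm{app}$ to the target IC50 minus $E/2$, so
the planted compound truly has the stated absolute IC50.

### Fitting procedure

1. **Bleach truncation** (`truncate_at_max()`): after the substrate's cis
   pool is exhausted the signal plateaus and then declines through
   photobleaching (modelled in the generator as post-plateau exponential
   decay, 0.1%/s by default, starting where the curve reaches 99% of its
   amplitude). Each trace is smoothed with a centred moving average
   (window 5, odd by construction) and cut at the **last** index attaining
   the smoothed maximum — the tie-break that leaves constant and
   monotonically rising traces untouched. Traces with fewer than 10 points
   after truncation are excluded, never imputed.
2. **One-phase fit** (`fit_one_phase()`): unweighted Levenberg–Marquardt
   on the residual function with $k > 0$, initialized from the first
   point, the maximum, and the half-rise time. $F_0$ is fitted free with
   that initialization. The residual-function interface (rather than a
   model-formula wrapper) keeps noiseless, zero-residual fits
   well-defined; these recover $(F_0, F_\mathrm{plateau}, k)$ to 1e-6
   relative.
3. **Control normalization** (`normalize_rates()`): percent activity is
   anchored on plate controls,
   $100 (k - \bar k_\mathrm{substrate}) /
   (\bar k_\mathrm{enzyme} - \bar k_\mathrm{substrate})$, and inhibition is
   its complement. Values are deliberately not clamped: inhibition below
   0% or above 100% is informative scatter. A plate whose control means
   are separated by less than 3 pooled control SDs fails outright — a
   dynamic-range guard.
4. **Dose–response** (`fit_dose_response()`): four-parameter logistic in
   $\log_{10}$ dose with bounds Bottom ∈ [−10, 40], Top ∈ [60, 110],
   Hill ∈ [0.3, 5]. The bounds are this package's choice: they prevent
   asymptote degeneracy on sparse dose ranges while leaving realistic
   curves unconstrained. The reported IC50 is the **absolute** one — the
   dose where the fitted curve crosses 50% inhibition, root-solved on
   $[\min\mathrm{dose}/10, \max\mathrm{dose}\times 10]$ — not the curve
   midpoint; both are reported. A crossing beyond the top tested dose is
   censored as `"> max dose"`: with Top bounded away from 50 the fitted
   curve always crosses *somewhere*, and a crossing outside the tested
   range is an extrapolation of the asymptote bounds, not a measured
   potency. This censoring rule is what makes "inhibitor too weak for the
   dose range" produce a bound instead of a fabricated number.

**Known limitation.** The symmetric 4PL cannot represent the
stoichiometric-titration shape that appears when
$K_i^\mathrm{app} \ll E$: the true inhibition curve rises essentially
linearly in dose and clips abruptly at 100%. The 50% crossing of the
best-fitting 4PL then sits ~8% below the true crossing (for example
2.40 nM fitted vs 2.60 nM true at $K_i^\mathrm{app}$ = 0.1 nM, E = 5 nM).
Tests therefore assert the exact stoichiometric floor on the simulated
system for any $K_i^\mathrm{app}$, and assert the fitted floor on
scenarios whose true IC50 clears $E/2$ by more than that crossing bias.
Concentrations are handled in µM end to end (nM inputs converted once at
the boundary): a single working unit removes a conversion layer, and all
log-scale fits are translation-invariant, so the unit cannot affect any
estimate.

## 3. Equilibrium binding models

`fit_fp_saturation()` fits the one-site total-binding model
$A(X) = \mathrm{background} + B_\mathrm{max} X/(K_D + X) + \mathrm{NS}\,X$
to anisotropy titrations (NS optional, default off). The generator computes
the bound-probe fraction from the exact two-component quadratic, so probe
depletion is in the synthetic truth even though the fitted hyperbola
ignores it; input is taken as anisotropy and never converted to
polarization, and the quantum-yield change on binding is neglected
(anisotropy-additive mixing).

`fit_fp_competition()` fits the one-site competitive model — a logistic in
$\log_{10}$ competitor with unit Hill slope, asymptotes bounded in
[−10, 20] and [80, 110] on the normalized 0–100% scale — and converts IC50
to an inhibition constant by the hot-probe (Cheng–Prusoff) correction
$K_i = \mathrm{IC50}/(1 + L_\mathrm{hot}/K_{D,\mathrm{hot}})$, importing
the probe's KD from its saturation fit. The correction only lowers the
IC50, so $K_i \le \mathrm{IC50}$ always.

`solve_ternary_equilibrium()` is the exact oracle behind the shortcut: it
solves the coupled equilibria $P + L \rightleftharpoons PL$,
$P + I \rightleftharpoons PI$ by root-finding on free protein — the scalar
function $P(1 + L/(K_D+P) + I/(K_i+P)) - P_\mathrm{tot}$ is strictly
increasing with a unique root on $[0, P_\mathrm{tot}]$ — followed by
Newton polishing to hold all mass balances to 1e-9 relative. Competition
generators sample from this oracle, never from the shortcut being tested.

The closed-form correction is valid only in the dilute regime. Probe
occupancy below 10% and $L_\mathrm{hot}/K_{D,\mathrm{hot}} < 0.1$ are
necessary but not sufficient: the protein itself must be dilute relative
to both $K_D$ and $K_i$, with relative bias approximately
$P/K_D + P/(2K_i)$ (at $P$ = 10 nM, $K_D$ = 100 nM, $K_i$ = 72 nM the
shortcut is ~17% high despite only 9% probe occupancy). The
oracle-equivalence Monte-Carlo draws
$P = \min(K_D, K_i)/50$, inside the regime where the one-site competitive
model is the right tool; `fit_fp_competition()` refuses the closed form
outright when $L_\mathrm{hot}/K_{D,\mathrm{hot}} > 10$ and directs the
user to the exact solver. `fit_spr()` fits the one-site specific-binding
isotherm $RU(C) = B_\mathrm{max} C/(K_D + C)$; the KD is invariant to any
multiplicative normalization of the response. Equilibrium only — on/off
kinetics are out of scope.

## 4. Panel profiling

`selectivity_matrix()` holds compound x variant IC50/Ki cells in µM, each
optionally censored (`">"`/`"<"` bounds). The censoring algebra is closed:
`fold_selectivity()` and `mutant_shift()` return
`censored_qty` objects whose bound direction is propagated through ratios
(a `> 100` µM off-target over a 0.010 µM target is `> 10,000`-fold; both
operands censored gives `indeterminate`, never a bare number). Folds are
computed within one assay family only — an IC50 is never divided by a Ki.
`round_fold()` rounds to 1 or 2 significant figures, the conventions used
for published fold claims (2/0.013 → "150-fold" at 2 s.f.; 3.1/0.072 →
"40-fold" at 1 s.f.).

`simulate_crc()` emulates a calcium-retention-capacity recording: each
CaCl₂ pulse produces an instantaneous fluorescence jump of the
extramitochondrial calcium dye followed by exponential return toward
baseline (uptake, default rate 0.08 s⁻¹, pulses every 120 s); after the
capacity-th resorbed pulse the next injection triggers permeability-pore
opening, modelled as an abrupt sustained rise toward the level of all
released calcium. `count_crc_pulses()` counts a pulse as taken up when the
trace returns below baseline + $f\,(\mathrm{peak}-\mathrm{baseline})$
(default $f = 0.3$) within a window (default 0.8 x the injection interval)
**after** the post-injection peak — the after-the-peak condition is what
distinguishes the release injection, whose trace only rises. The first
failing pulse marks release; a trace with no release yields a flagged
lower-bound count, which propagates into `crc_ratio()` (treated/control
pulses) as a censored bound. The uptake criterion $(f, w)$ is this
package's quantitative reading of a qualitative "abrupt release" call.

`species_fractions()` normalizes diester/monoester/diacid total-ion counts
to fractions of their sum, and `build_report()` assembles all stages into
a deterministic machine-readable report (byte-identical across re-runs on
equal inputs).

## 5. What the synthetic generators do and do not emulate

The generators reproduce the *structure* of each assay's data — encoded
reads with substitution errors, association kinetics with bleach and
noise, exact-equilibrium isotherms, pulsed CRC traces — under known ground
truth, which is exactly what recovery tests need. They deliberately omit:
PCR/sequencing indels and chimeras, bead/background binding beyond the
enrichment factors, substrate consumption and coupled-protease saturation,
fluorophore quantum-yield shifts, SPR mass-transport and kinetics, and
biological variance between mitochondrial preparations. Passing recovery
tests therefore demonstrates that the *analysis* is correct and unbiased
under the stated noise models, not that any particular wet-lab number is
reproduced; published potencies enter only as scenario ground truths or as
printed inputs to fold arithmetic.

Problem sizes used by the test-suite and the acceptance script — the full
256,000-member library at depth $10^5$, 51 stochastic plates of
10 doses x 3 replicates, 100-draw binding and CRC Monte-Carlos — were
chosen to give comfortable statistical margins for every claim while
keeping a complete run in the minutes range on a single core.
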