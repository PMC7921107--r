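---
title: "Modeling DNA stability and the density-reliability tradeoff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling DNA stability and the density-reliability tradeoff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnastability)
```

## The problem

A DNA storage system keeps data in pools of short synthesized strands
(~150-1000 nt). Each strand carries an address (PCR primer target), an
index (its position within a file), and payload. Strands break, acquire
base lesions, and accumulate sequencing/synthesis errors; every one of
these failure modes consumes error-correction overhead that would
otherwise have been payload. This package provides the quantitative
machinery to reason about that tradeoff: kinetic models for how fast DNA
degrades under different handling regimes, a channel model for what the
decoder ultimately sees, exact reliability mathematics for the standard
concatenated Reed-Solomon architecture, and an optimizer that finds the
densest code meeting a reliability target.

## Degradation kinetics

**Backbone scission** is modeled as a homogeneous Poisson process: a
strand of $L$ nt stored $t$ years under per-nt scission rate $r$ stays
intact with probability $e^{-rLt}$. Published fossil-DNA estimates
combine a ~500-year half-life with a per-nt rate of $5.5\times10^{-6}$
/nt/yr for ~242-nt sequences; the product $rLt = 0.67$ is often read
linearly as "~50% fragmented". We deliberately use the exponential form
rather than the linear product: it is the first-order kinetics such
rates describe, it stays in $[0,1]$, and at these argument sizes it
gives 48.6% fragmented — the same answer to within a couple of points.
`rate_from_half_life()` inverts the model exactly
($r = \ln 2 / (L\,t_{1/2})$, giving $5.7\times10^{-6}$ for the same
anchors; the small gap to the published $5.5\times10^{-6}$ is that
linearized reading).

```{r}
fossil <- first_order_breakage(5.5e-6)
intact_fraction_breakage(fossil, length = 242, time = 500)
```

**Freeze-thaw cycling** follows the published exponential fit for lambda
DNA, $\text{intact} = 0.9484\, e^{-0.068 n}$ after $n$ cycles (defaults
of `freeze_thaw_model()`): ~11% degraded after one cycle, ~76% after
twenty. `fit_exponential_decay()` recovers such models from data by
least squares on $\log(\text{intact})$ — deterministic, no starting
values, exact through two points. A negative fitted decay (possible on
noisy, nearly-flat data) is clamped to zero so the returned model always
satisfies its invariants.

**Temperature extrapolation** uses the Arrhenius form
$r(T_2) = r(T_1)\,e^{-(E_a/R)(1/T_2 - 1/T_1)}$ with
$R = 8.314$ J/(mol K). The activation energy is a *required* argument
with no default: accelerated-aging studies of stored DNA invoke the
exponential-in-$1/T$ assumption without agreeing on a single $E_a$, and
an invented default would silently dominate any multi-decade
extrapolation. Temperatures are Kelvin internally; the command-line
interface accepts Celsius.

**Base lesions** (depurination and 8-oxo-dG, pooled into one rate since
measurements report them jointly) accumulate as
$1 - e^{-r_\ell L t}$. The default rate is calibrated to the reported
anchor of a 6%/yr lesion probability for 200-nt strands:
$r_\ell = -\ln(0.94)/200 \approx 3.1\times10^{-4}$/nt/yr. We interpret
the 6% figure as the probability of at least one lesion per strand per
year (the natural reading of "develop a lesion"), not as an expected
lesion count; at these magnitudes the two differ by under 2% relative.

Qualitative effects that are reported without numbers — e.g. that a pH
drop from 6 to 5 can accelerate degradation by roughly an order of
magnitude — are deliberately *not* modeled as operations; they appear
only as notes like this one.

## The channel

The decoder sees two failure modes. A strand is **erased** when all of
its $c$ physical copies are lost; the per-copy loss probability is
modeled as linear in length, giving
$p_{\text{erasure}} = (\min(1, L\,b))^c$. The published default for the
breakage coefficient $b$ is $5\times10^{-3}$ per nt. Two remarks:

* the linear form exceeds 1 for $L > 1/b$, so we clamp before raising to
  the $c$-th power — the minimal repair that preserves monotonicity;
* the same source that prints $5\times10^{-3}$ also describes the
  calibration "1000-nt strands erase with probability 50% or less",
  which corresponds to $5\times10^{-4}$. We keep the printed constant as
  the default and expose the coefficient as a free parameter rather than
  silently resolving the contradiction. Note that at $5\times10^{-3}$
  every strand of 200 nt or more saturates the clamp, so
  reliability curves under the printed default are flat at failure
  probability 1 for most practical lengths; the calibrated
  $5\times10^{-4}$ reading produces the graded curves one expects.

A present symbol is **erroneous** if any of its `nt_per_symbol`
nucleotides is corrupted: $1-(1-p_{\text{nt}})^{s}$, with $s = 4$ nt per
8-bit symbol (2 bits/nt) as the natural GF(256) mapping. Substitutions,
insertions and deletions are pooled into one per-nt rate. Copies improve
only the erasure exponent, not the within-strand error rate — no
consensus-calling across copies is modeled, matching how the channel is
usually analyzed.

## Reliability of the concatenated code

The architecture interleaves an inner RS code within each strand with an
outer RS code across 255 strands, one outer symbol per strand. An RS
code with minimum distance $d$ decodes iff $2t + e \le d-1$ for $t$
errors and $e$ erasures.

* Inner failure: $P[\mathrm{Binom}(n_{\text{in}}, p_{\text{sym}}) >
  \lfloor (d_{\text{in}}-1)/2 \rfloor]$.
* An outer symbol is erased if the strand is lost *or* survives but its
  inner decode fails (failures are detected and passed to the outer
  decoder as erasures). Silent inner miscorrections are set to zero by
  default — they are genuinely rare for random overload patterns, as the
  codec simulations confirm — but the outer analysis accepts a nonzero
  symbol-error probability, so the model is fully general.
* Outer failure: the exact trinomial sum
  $P[2T + E > d_{\text{out}} - 1]$ over each symbol independently being
  erroneous / erased / clean. This is $O(n^2)$ terms, accumulated in the
  log domain so that probabilities far below double underflow (the
  $10^{-14}$ regime and deeper) keep full relative accuracy;
  `log10_outer_decoding_error()` reports the exponent directly.

`system_error_curve()` re-evaluates the whole chain across strand
lengths, recomputing the inner block length from the fixed address
overhead and symbol size while keeping the template's inner *redundancy*
$n_{\text{in}}-k_{\text{in}}$ fixed (the published curve construction
does not state a rule for the inner message length; holding redundancy
fixed isolates the length effect and keeps the correction radius
constant). Reliability is compared against a hard-drive-class reference
of $10^{-14}$ — we use the rate itself rather than the sometimes-quoted
"log error probability of $-15$", which differs by an order of
magnitude; the threshold is a parameter everywhere it appears.

## Density optimization

`optimize_design()` maximizes
$$\rho = \frac{k_{\text{out}}}{n_{\text{out}}}\cdot
\frac{8\,(k_{\text{in}} - \text{index})}{L_{\text{nt}}}
\quad\text{bits/nt},\qquad
L_{\text{nt}} = \text{address} + 4\,n_{\text{in}},$$
subject to the residual outer failure probability staying below the
target (default $10^{-14}$). The search enumerates every inner message
length; for each one, the failure probability of *every* outer message
length is read off a single shared log-domain binomial tail (with
detected-erasure inner failures and no silent symbol errors the outer
failure event is exactly the binomial erasure tail), and ties are broken
toward larger outer $k$, then larger inner $k$. The winner is then
re-verified through the general trinomial tail rather than trusted from
the search loop. Conventions fixed by the published analysis: outer
block 255, index 4 symbols, single copy. The address overhead defaults
to 40 nt (a 20-nt primer target at each end, consistent with the usual
<25-nt limit); it is configurable, and whether one counts it in the
denominator is likewise a convention — both are supported via
`address_nt`.

Sweeping breakage from $10^{-3}$ to $10^{-8}$ across lengths 100-1000 nt
reproduces the expected structure: short strands win at high breakage
(less likely to break, so the outer code spends less on parity), long
strands win at low breakage (less relative address/index overhead), and
at intermediate rates an interior optimal length balances the two.

```{r, eval = FALSE}
sweep <- density_sweep(seq(100, 1000, by = 50), 10^-(3:8),
                       p_error_per_nt = 1e-3)
density_optima(sweep)
plot_density_sweep(sweep, by = "length")
```

## Monte-Carlo validation

`simulate_decode()` samples the channel and applies the decode
predicate $2T + E \le d-1$ — deliberately the *same event* the analytic
model computes, so the two paths must agree. Implementation choices:

* Strand erasure is sampled at strand level with probability $q^c$;
  this is distributionally identical to sampling the $c$ copies
  individually.
* Trials are drawn in fixed blocks of $10^4$; each block's seed comes
  from a Lehmer LCG stream derived from the user seed, and a block is
  always drawn in full then truncated. Consequently a fixed seed is
  bit-reproducible *and* extending the trial count never changes
  earlier trials.
* Simulation cannot certify $10^{-14}$ events. The analytic/simulation
  agreement gate runs on a fixed 12-point grid whose failure
  probabilities lie between $\sim 2\times10^{-3}$ and $\sim 0.95$, i.e.
  where $10^5$ trials observe hundreds of failures; extreme-tail claims
  are analytic-only, which is precisely why the trinomial tail is
  computed exactly rather than sampled.

`simulate_codec_roundtrip()` is the deeper oracle: a complete GF(256)
systematic Reed-Solomon codec (Berlekamp-Massey with Forney syndromes
for erasures, Chien search, Forney magnitudes) encodes a random
payload, the sampled channel corrupts it, and the concatenated decode
is performed algebraically — index placement, inner errors-and-erasures
decoding, outer erasure decoding. It exercises what the predicate
abstracts away (actual correction, index integrity, miscorrection), at
the price of speed; the test suite checks per-trial agreement between
predicate and codec in regimes where miscorrection does not occur.

## What the synthetic conditions do and do not show

All validation inputs are generated in code: decay curves with
log-normal multiplicative noise (σ = 0.02 on the log scale, 10 points —
typical of gel/qPCR quantification replicates), i.i.d. channel draws,
uniform random payloads. Real systems violate several of these
idealizations: breakage is sequence- and position-biased, errors
cluster (homopolymers), strand dropout correlates with GC content and
synthesis yield, and copy counts are highly dispersed after PCR. The
tests therefore demonstrate internal consistency (analytics vs two
independent oracles) and faithfulness to the published anchors — not
that the i.i.d. channel is an adequate description of any particular
wet system. Problem sizes used by the test suite (12×10^5 Monte-Carlo
trials, $3^{12}$ exhaustive enumeration, 19×6 design sweep) were chosen
as the smallest that make the statistical gates sharp.

## Known limitations

* No insertion/deletion-aware decoding at nucleotide resolution; indels
  are folded into the per-symbol error rate.
* No joint optimization over address length or symbol size.
* No sequence constraints (GC content, homopolymers) in the density
  accounting.
* The Arrhenius module extrapolates; it inherits every caveat of
  accelerated-aging inference, including mechanisms that do not follow
  an exponential temperature dependence.
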