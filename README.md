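# dnastability

Quantitative design tools for DNA data-storage systems: how fast stored
DNA degrades, what the decoder sees as a result, and how much
information density must be sacrificed to hit a reliability target.

DNA storage keeps data on pools of short synthesized strands, each
carrying an address, an index, and payload. Strands break (hydrolysis,
freeze-thaw mechanics, shear), acquire base lesions, and pick up
synthesis/sequencing errors. The standard defense is a concatenated
Reed-Solomon architecture — an inner RS code correcting symbol errors
within each strand, an outer RS code across 255 strands correcting
whole-strand losses — and every parity symbol spent is payload lost.
This package is for system designers who want those tradeoffs as
numbers rather than intuitions.

## What it computes

**Kinetics** — closed-form degradation models with calibration helpers:

- Poisson backbone scission: `intact = exp(-r L t)`;
  `rate_from_half_life()` inverts it.
- Freeze-thaw decay `intact = A exp(-k n)` with the published lambda-DNA
  fit (A = 0.9484, k = 0.068/cycle) as default, plus a deterministic
  log-linear fitter `fit_exponential_decay()`.
- Arrhenius temperature scaling (`arrhenius_scale()`), activation energy
  supplied by the user.
- Base-lesion accumulation (depurination + 8-oxo-dG pooled), anchored at
  6%/yr for a 200-nt strand.

**Channel** — strand erasure `(min(1, L b))^c` (all `c` copies lost) and
per-symbol error `1 - (1 - p)^4`.

**Reliability** — exact analytic decoder-failure probabilities for the
concatenated scheme: binomial inner-failure tails, and the exact
trinomial outer tail `P[2T + E > d - 1]`, all in the log domain so the
1e-14 regime and far beyond stay accurate (`outer_decoding_error_prob()`,
`log10_outer_decoding_error()`, `system_error_curve()`).

**Density optimization** — `optimize_design()` / `density_sweep()` find
the densest inner/outer code pair (bits per synthesized nt) whose
residual decoder error stays below a target (default 1e-14,
hard-drive-class), with outer block 255, 4 index symbols, and 40 nt of
address overhead as conventions.

**Monte-Carlo validation** — `simulate_decode()` is a seeded,
bit-reproducible channel simulator of the same decode predicate the
analytics compute; `simulate_codec_roundtrip()` goes deeper, running a
full GF(256) Reed-Solomon errors-and-erasures codec
(encode → corrupt → algebraically decode) implemented in the package.

## Worked example

```r
library(dnastability)

# Fossil-grade kinetics: 242-nt strands, 5.5e-6 scissions/nt/yr, 500 years
intact_fraction_breakage(first_order_breakage(5.5e-6), 242, 500)
#> [1] 0.5140165        # ~49% of strands fragmented

# Twenty freeze-thaw cycles under the published fit
freeze_thaw_intact(freeze_thaw_model(), 20)
#> [1] 0.2434171        # ~76% degraded

# Densest design for 200-nt strands at 1e-4 breakage/nt, target 1e-14
optimize_design(density_query(strand_length = 200,
                              breakage_prob_per_nt = 1e-4))
#> Tradeoff point: L = 200 nt, breakage 0.0001/nt -> 1.1627 bits/nt
#>   outer RS[255,218], inner RS[40,38], residual error 1.86e-15

# Validate an analytic failure probability by simulation
design <- concatenated_design(outer = rs_code(255, 223),
                              inner = rs_code(40, 36))
channel <- channel_params(strand_length_nt(design),
                          p_error_per_nt = 1e-3, breakage_factor = 5e-4)
sym <- outer_symbol_channel(design, channel)
outer_decoding_error_prob(design$outer, sym$p_symbol_erasure, 0)
#> [1] 0.07980954
simulate_decode(simulation_spec(design, channel, trials = 1e5, seed = 1))
#> Monte-Carlo decode: 7924/100000 failures, estimate 0.07924 (SE 0.00085), seed 1
```

The tradeoff point reads: at that breakage rate the best 200-nt design
spends 37 of 255 outer symbols and 2 of 40 inner symbols on parity plus
4 symbols on the index and 40 nt on addresses, leaving 1.16 payload bits
per synthesized nucleotide while keeping the chance of losing the block
below 1e-14.

A shell entry point wrapping the same functions is installed as
`exec/dnastability` (subcommands `kinetics`, `reliability sweep`,
`density sweep`, `simulate`).

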