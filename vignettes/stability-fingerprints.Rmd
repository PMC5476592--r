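---
title: "Single-amide stability fingerprints from overlapping-peptide HDX-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-amide stability fingerprints from overlapping-peptide HDX-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxfp)
```

## The model

Under EX2 conditions every backbone amide *i* takes up deuterium
mono-exponentially with a single apparent rate constant,
$D_i(t) = 1 - e^{-k_{ex,i} t}$. What the mass spectrometer reports,
however, is the centroid uptake of whole peptides. `hdxfp` recovers the
per-amide rates from the *redundancy* of an overlapping peptide library in
two global stages.

**Stage 1 (linear).** The boundary points of all peptides partition the
covered sequence into minimal subfragments; each peptide is an exact
concatenation of subfragments, so at every labeling time $t$

$$D^{exp}_{n,t} = \sum_{j \in n} x_{j,t} + E^{lin}_{n,t},$$

a linear system in the subfragment deuterium contents $x_{j,t}$ shared by
all peptides. We minimise $GE^{lin} = \sum_{n,t} (E^{lin}_{n,t})^2$
independently per time point (the objective is separable over $t$) subject
to the physical box $0 \le x_{j,t} \le \mathrm{capacity}_j$. Capacity is
the number of exchangeable amides: interval length minus prolines (which
have no amide hydrogen) and minus the protein's first residue (a free
α-amine). This implements the "minus prolines" accounting as capacity
bookkeeping rather than as a subtraction from the measured sums, which is
the same arithmetic but keeps every quantity non-negative.

**Stage 2 (non-linear).** Subfragment rates fitted from
$x_{j,t}/\mathrm{capacity}_j$ seed a simultaneous bounded
Levenberg–Marquardt fit of all per-amide rates:

$$D^{exp}_{n,t} = \sum_{i=m_n}^{l_n}
  \bigl(1 - e^{-k_{ex,i} t}\bigr)\, e^{-k_{bk,i}\, t_{lag}}
  + E^{nonlin}_{n,t},$$

where $e^{-k_{bk,i} t_{lag}}$ is the fraction of label retained during the
quenched LC lag ($k_{bk,i}$ = random-coil rate at quench conditions).
Finally $\Delta G_{ex,i} = -RT \ln(k_{ex,i}/k_{int,i})$ with
$R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ converts rates into the stability
fingerprint.

Assumptions worth keeping in mind: EX2 kinetics throughout (one
exponential per amide; bimodal/EX1 envelopes are not modelled), centroid
uptake only (no isotope-envelope shape information), and a single global
lag time for the back-exchange correction.

## Random-coil reference rates

Intrinsic rates are computed from the poly-DL-alanine reference constants
with nearest-neighbour corrections (Bai *et al.* 1993, *Proteins* 17:75;
acid factors after Molday *et al.* 1972), shipped as versioned delimited
files under `inst/extdata/` and recorded as a provenance string in every
rate table:

$$k_{int} = k_A 10^{-pD} F_A + k_B 10^{pD - pK_D} F_B + k_W F_B,$$

with $F = 10^{\lambda(\text{res}_i) + \rho(\text{res}_{i-1})}$ per
catalysis channel, Arrhenius temperature corrections
($E_a$ = 14/17/19 kcal mol⁻¹ for acid/base/water at constant pD — the
base-term value folds in the temperature dependence of the D₂O ion
product, so $pK_D = 15.05$ is used unchanged), titration-state mixing for
Asp/Glu/His and the C-terminal carboxyl, and extra factors for the free
N-terminal amine (second residue) and the C-terminal amide. Prolines and
position 1 get exactly 0. With these constants an interior poly-alanine
amide at pH-meter 7.0 and 0 °C has a half-life of almost exactly 1 s,
the standard random-coil anchor, which the test suite asserts.

Two conventions are configurable and worth stating:

* **pD.** `exchange_conditions()` treats the supplied pH as a glass
  electrode reading of a deuterated buffer and adds the standard +0.4
  correction; pass `pD_corrected = TRUE` to supply a pD directly.
* **Temperature folding.** Sub-second effective labeling times obtained by
  on-ice incubation are folded onto the warm time axis with the dedicated
  rule-of-thumb operation `equivalent_labeling_time()`
  ($\times 10^{\Delta T / 25\,\mathrm{K}}$), mirroring how such time
  points are treated experimentally. The full Arrhenius model is used
  *inside* $k_{int}$/$k_{bk}$ only; the simple rule only folds the time
  axis. Over the 0–25 °C span the full model's per-25-K factor is 8–16
  depending on temperature, bracketing the rule's 10.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `filter_threshold` | 2 | deuterons | peptides whose linear-stage residual reaches 2 D are considered misassigned and dropped (optional stage, on by default) |
| `n_term_excl` | 0 | residues | capacity follows the "minus prolines only" accounting literally; set 1–2 for the common convention that fragment-N-terminal amides lose label during handling |
| `lower_bound` | 1e-8 | s⁻¹ | effectively non-exchanging over a 3.4×10⁵ s window; avoids log-domain singularities |
| upper bound policy | `k_int` (labeling) | s⁻¹ | no amide exchanges faster than in the unstructured chain; a strict `"quench"` mode bounds by quench-condition rates instead, since either reading of "bounds from intrinsic back-exchange rates" is defensible |
| `t_lag` | none (must be supplied) | s | instrument-specific; no universal default exists |
| `temperature_dG` | labeling temperature | K | ΔG values correspond to the conditions the rates were measured at |
| `n_starts`, `perturb_sd` | 1, 0.5 | –, log₁₀ | optional multi-start reporting of per-residue dispersion |

## Numerical choices

* **Optimisation variable** is $\log_{10} k$: rates span up to nine orders
  of magnitude and the log-parameterisation conditions both the Jacobian
  (supplied analytically) and the box bounds.
* **Tie-breaking.** Single-coverage regions make the linear systems
  rank-deficient. A ridge of 1e-8 on $\|x\|^2$ selects the minimum-norm
  constrained optimum, and affected subfragments/residues are flagged
  `weakly determined` so downstream consumers can down-weight them.
* **Linear solver.** Projected quasi-Newton (L-BFGS-B) from the clipped
  unconstrained solution, followed by an active-set polish that re-solves
  the free coordinates exactly; agreement with an exhaustive 0.01-D grid
  refinement oracle is part of the test suite (0.02 D tolerance).
* **Convergence.** Relative change of $GE^{nonlin}$ below 1e-10 or 500
  iterations; exhausting the budget returns the best point with a
  non-convergence flag rather than an error.
* **Degenerate inputs.** All-proline subfragments are pinned at 0;
  all-zero uptake series seed at the lower bound with a flag; residues
  whose fitted rate sits on the lower bound are *censored* in the
  fingerprint (reported at the bound-implied maximum ΔG, never infinity).
* **t50 classification** interpolates fractional uptake linearly in
  log-time between the bracketing grid points (the sampling grid is
  log-spaced); on a 13-point grid this reproduces the nominal t50 of an
  exponential to within ~6 %, comfortably inside the 1000/3000 s class
  boundaries.
* **Iterative residual filter.** A one-shot "error ≥ 2 D" cut misbehaves
  when many peptides are corrupted: the global fit smears a gross error
  into overlapping clean peptides. The pipeline therefore deletes in
  blocks anchored at the current worst offender (cut at
  $\max(\text{threshold}, 0.6 \times \text{max error})$), refits, and
  repeats until all residuals are below threshold. The 0.6 block factor
  was calibrated and then validated on independent synthetic scenarios.
  One-shot `filter_by_fit_error()` remains available.
* **N-terminal exclusions**, when enabled, are applied by trimming each
  measured peptide's interval before partitioning. Trimming is equivalent
  to excluding those residues at constraint assembly but keeps subfragment
  capacities purely sequence-intrinsic.

## What the synthetic generator does and does not emulate

`hdx_scenario()` defaults describe the regime the pipeline is built for: a
220-residue two-domain helical protein; ≥ 200 peptides of 4–41 residues
drawn until per-residue redundancy ≥ 3; 13 log-spaced times from 0.3 s to
3.4×10⁵ s (the two sub-3-s points standing for folded on-ice incubations);
Gaussian centroid noise of 0.05 D; labeling at pH-meter 7.0 / 298.15 K,
quench at 2.5 / 273.15 K; lag time 30 s (a typical injection-to-elution
scale — real values are instrument-specific and must be supplied for real
data). Ground-truth profiles alternate slow helix plateaus with parabolic
flanks and fast loop dips across 10⁻⁶–10² s⁻¹, plus a few very slow
"core anchor" residues. All randomness derives from one seed via
independent derived streams (sequence / truth / library / noise /
corruption), and a YAML manifest re-instantiates a scenario exactly.

The generator deliberately omits: protease cleavage specificity (peptides
are sampled uniformly), EX1/bimodal envelopes, m/z- or retention-domain
effects, replicate structure, and correlated (systematic) noise. Passing
the recovery tests therefore demonstrates the *deconvolution machinery* is
correct under its stated model — not that every real dataset carries
enough information; with sparse overlap or heavy noise the honest outcome
is a profile dominated by `weakly determined` flags.

## Known limitations

* Residual-based filtering cannot detect a corrupted peptide whose span is
  covered by no (or only similarly corrupted) other peptides: the linear
  stage absorbs the offset into the private subfragments. The synthetic
  filter stress test shows this as rare single-fragment misses at heavy
  (40 %) corruption.
* Within a subfragment covered by identical peptide sets, residues are
  exchangeable in the likelihood; the fit resolves them only through the
  non-linear time structure, and permutation ambiguity among similar rates
  is flagged rather than resolved.
* The nearest-neighbour reference set spans pD 1–13 and 263–323 K;
  conditions outside that range are extrapolated with a warning and an
  `extrapolated` provenance flag, never silently.
* The flanking-context spread of intrinsic rates at pH 7 / 0 °C is about
  9-fold max-over-mean (about 160-fold full range) under the bundled
  factor set; statements about ">30-fold" context variation in the
  literature refer to the full two-sided range, not max-over-mean.
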