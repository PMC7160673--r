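---
title: "Models and methods behind kmeopl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kmeopl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmeopl)
```

# The assay and its combinatorial structure

A Kme-OPL (methyllysine oriented peptide library) experiment measures how a
reader domain binds seven-mer peptides centered on a methylated lysine. Each
*set* fixes one residue at one flanking position (P−3…P+3) while the other
five flanks are an equimolar degenerate mix over 19 amino acids (no
cysteine); each *pool* combines all 114 sets of one methyl order (Kme0–Kme3).
`enumerate_sets()` encodes this grid with a canonical ordering —
position-major, residues sorted by one-letter code — so matrices and file
exports are reproducible across runs. Set identifiers serialize as
`Kme{m}_P{±k}_{residue}`.

A lysine-centered seven-mer is a member of exactly six sets of its methyl
order (one per flank), unless a flank contains cysteine, in which case the
library never synthesized it and it belongs to no set. The seven-mer is
treated as the complete informative unit: the physical library frames
peptides with residues beyond P±3, but no position outside the window is
modeled because no position outside it is varied.

# Signal pipeline

**Background subtraction.** Reader wells are measured alongside GST-only
control wells; per set, the replicate mean of the control is subtracted from
the replicate mean of the reader signal and the difference is clamped at
zero. The clamp reflects the floor of the measurement (deposited scores on
this assay are reported on a non-negative RFU scale) and guarantees the
minimum rule downstream never propagates negative "binding".

**Inferred background.** When a plate lacks simultaneous GST wells, the
Kme0-pool signal decides between a user-supplied low and high background
reference: for a methyl-dependent reader the unmodified pool is background
only, so the nearer reference is the right one. The distance rule and its
tie-break (exact ties go to the *high* reference) are this package's
choices; subtracting more on a tie is conservative, trading sensitivity for
fewer false positives.

**Methyl-order call.** The preferred order is the argmax of the four
GST-subtracted pool signals. Readers that bind two orders nearly equally are
common (me2/me3 dual readers), so every order within 10% of the maximum is
co-reported. The 10% band is a package default (`tol` in
`call_methyl_order()`); the underlying biology offers no sharp threshold.

**Specificity.** The per-set normalized signals (profile divided by its
maximum) are binned over [0, 1]. The *specificity index* is the fraction of
sets at normalized signal ≥ 0.5: a sequence-specific reader tolerates few
residues, so few sets score high and the index is small, while a promiscuous
reader pushes most sets toward 1. Labels use index ≤ 0.15 ("specific") and
≥ 0.5 ("promiscuous"); these cutoffs are package conventions chosen so that
a reader favoring one residue per position (6 high sets of 114, index 0.053)
is firmly "specific" and a reader tolerating most residues at most positions
is firmly "promiscuous". The label never feeds back into computation; it is
a reporting aid.

# Lowest-Bin proteome scoring

Every lysine in a proteome with at least three residues on each side yields
a candidate seven-mer. Its LoB score is the *minimum* of the six profile
lookups (position, residue): one disfavored flank vetoes the motif. Despite
the historical "Bin" name the computation is continuous — no discretization
is applied, because the profile is itself continuous and binning would only
discard resolution.

Exclusions are explicit rather than silent, so motif totals reconcile:

- `near_terminus` — a K within 3 residues of an end cannot be evaluated at
  all six positions, and padding would fabricate signal;
- `contains_C` — the library never measures cysteine, so any score would be
  imputation;
- `ambiguous_residue` — non-standard codes (X, B, Z, U…) have no profile
  column.

Scores stay on the raw GST-subtracted RFU scale; the normalized score
(divide by the scan maximum) exists for cross-reader comparison and, because
normalization is a positive rescaling of a minimum, raw and normalized
profiles induce identical rankings. Ties share the minimum rank and rows
order by (rank, protein id, position) so output is invariant to input record
order.

Optimal and poor binding sequences come from the per-position argmax/argmin
of the profile; ties are reported exhaustively with the lexicographically
smallest residue as the primary answer, and all-zero (or constant) columns
are flagged unconstrained instead of pretending a preference.

`annotate_with_abundance()` joins per-cell copy numbers and reports how many
times more abundant a reference protein (typically histone H3) is than each
hit. This contextualizes LoB ranks: a motif on a protein four orders of
magnitude rarer than histones may bind as tightly yet never dominate
detection in cells.

# Fluorescence polarization fitting

Polarization readings (mP) are converted to anisotropy, *A* = 2*P*/(3 − *P*)
with *P* in fraction units, and fit with specific binding with Hill slope:

$$A(x) = \mathrm{baseline} + (A_{\max} - \mathrm{baseline})
          \frac{x^{h}}{K_d^{h} + x^{h}}$$

with protein concentration *x* in μM. Choices worth stating:

- **Scaling.** "Scale to the last dilution at a requested 20 mP" is read as
  proportional rescaling anchored at the *lowest* protein concentration (the
  last point of a serial dilution); the anchor point maps exactly to the
  request and the operation is idempotent. Both the request and the anchor
  rule are overridable.
- **Baseline.** A fitted baseline term absorbs the instrument offset at zero
  binding implied by the scaling procedure. `constrain_baseline = TRUE`
  fixes it at 0 for the stricter model.
- **Optimizer.** Bounded Levenberg–Marquardt (`minpack.lm::nlsLM`),
  initialized at *K*d = geometric mid-concentration, *h* = 1,
  *A*max = max *A*, baseline = min *A*; on failure, three seeded
  log-uniform restarts of the start values. Bounds keep *h* in [0.1, 10] and
  *K*d positive.
- **Reliability.** A converged fit is still flagged unreliable when *K*d
  falls outside the measured range × [0.01, 100] — the "too weak to be
  determined" regime — and a warning fires when *K*d approaches 10× the
  ligand concentration (default 10 nM), where the free≈total approximation
  (ligand depletion ignored) breaks down. All reported reader *K*d values in
  this assay family are ≥ 0.1 μM, an order of magnitude above that line.

# The synthetic generator

`latent_reader_model()` formalizes the simplest binding model consistent
with positional scanning: independent multiplicative occupancy. A peptide
with flank residues *r(q)* binds proportionally to
∏ᵩ *w*(*q*, *r*(*q*)) with weights in (0, 1], times an order weight (1 at
the preferred methyl order), times a maximum signal *S*₀. Averaging over the
equimolar mixture gives closed forms:

- set (fix residue *a* at position *p*):
  *S*₀ · *ow* · *w*(*p*, *a*) · ∏_{q≠p} mean_r *w*(*q*, *r*);
- pool: *S*₀ · *ow* · ∏_q mean_r *w*(*q*, *r*).

Two exact consequences are tested: the mean of the 19 set expectations at
any position equals the pool expectation (mixture identity), and sharpening
the weights drives both the pool expectation and the specificity index down
together — the computable form of the observation that sequence-specific
readers give low pool signals while promiscuous readers give high ones. The
package asserts this link qualitatively (monotonicity along the sweep), not
as particular RFU values.

**Calibration.** The mixture dilutes sharply tuned readers by the fifth
power of the mean position weight, so one latent *S*₀ cannot put both a
promiscuous and a near one-hot reader at realistic signal levels. The
defaults resolve this once:

- the default model is moderately promiscuous (hot residues at weight 1,
  others at ε = 0.8) so that with *S*₀ = 2000 RFU, GST background 150 RFU,
  well noise SD 50 RFU and 4 replicates — magnitudes typical of the plate
  assay — set and pool signals land in the hundreds of RFU;
- for sequence-specific study conditions (one-hot weights, ε = 0.05),
  `s0_for_best_set()` rescales *S*₀ so the best set expectation sits at
  1000 RFU, again with 50 RFU noise. This is a statement about units, not
  noise: fluorescence units are arbitrary, and what is physically meaningful
  is the signal-to-noise of the measured sets.

Noise is Gaussian truncated at zero — no noise model is implied by the
assay itself, and truncation respects the detector floor. All generators
(plates, proteomes with planted motifs, FP titrations) are bit-reproducible
from their seed, and proteome generation emits a ground-truth manifest of
planted positions.

**What the generator does not emulate.** Cooperative effects between
positions (e.g. β-hairpin induction that couples P−2 and P+1 preferences),
bead-binding kinetics, antibody sandwich amplification, washing losses,
plate-position effects, and heavy-tailed or signal-proportional noise.
Passing the end-to-end tests therefore shows the pipeline is correct under
independent-position binding with homoscedastic noise; it does not certify
recovery for readers whose recognition is strongly cooperative.

# Problem sizes and numerics

The test suite and acceptance script run: 100 seeded plate simulations
(114 sets × 4 replicates each) with a 100-protein synthetic proteome per
seed for planted-motif recovery; 100 noisy FP titrations of 4 replicate
12-point serial dilutions (0.01–100 μM) for *K*d recovery; 1,000 random
motifs against random profiles for the brute-force LoB oracle; and the full
4⁶ enumeration on a 4-letter alphabet for argmax optimality. These sizes
give stable Monte-Carlo summaries (recovery rates, median errors) while
keeping a full run in the tens of seconds.

Floating-point conventions: the mixture identity is asserted to ~1e−13
relative; profile normalization divides by the maximum only when it is
positive (all-zero profiles are flagged "no binding" instead); exact
signal ties in ranking are broken by identifiers, never by memory order.

# Known limitations

- The seven-mer window is the assay's footprint, not every reader's;
  preferences outside P±3 are invisible by construction.
- LoB is a false-positive-averse lower bound: a motif strong at five
  positions and untested at the sixth (C, terminus) is excluded, not
  approximated.
- Specificity labels depend on the 0.5 normalized-signal cut; profiles with
  near-bimodal distributions straddling 0.5 can flip label with small
  normalization changes, which is why the continuous index is always
  reported alongside.
- The FP model assumes free ≈ total protein; very tight binders (*K*d near
  the ligand concentration) need a depletion-aware model that is out of
  scope here and is flagged by a warning instead.
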