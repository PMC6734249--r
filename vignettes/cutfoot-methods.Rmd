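---
title: "Methods: cut matrices, footprint mixtures, and symmetry scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cut matrices, footprint mixtures, and symmetry scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutfoot)
```

## The measurement model

CUT&RUN tethers a protein A–micrococcal nuclease fusion to an antibody
bound in situ. The nuclease cleaves the accessible DNA around each binding
site and the released fragments are sequenced in paired-end mode. Unlike
Tn5-based assays, the cleavage is blunt: each fragment-end boundary *is* a
cut site, with no enzymatic overhang to correct for. Two consequences
shape everything in this package:

* **Both fragment ends are informative.** For a read pair, the cut sites
  are the 5′ boundaries of mate R1 (`s1`) and mate R2 (`e2`) — for a
  proper FR pair, the two outer boundaries of the fragment. The two ends
  of a single *mate*, by contrast, do not both mark cuts, which is why
  generic coverage-style tools mis-estimate cut profiles on this assay.
* **Fragments are short.** Factor-protected fragments run ~25–120 bp, so
  mates overlap (dovetail) routinely, and inserts shorter than the read
  length produce 3′ adapter read-through.

## Coordinates: inter-base boundaries

All intervals are 0-based half-open (BED convention) and cut sites are
*inter-base boundary indices*: the boundary `b` sits between base `b − 1`
and base `b`. With fragments stored as `[start, end)`, the forward cut
boundary is `start` and the reverse cut boundary is `end` — no
strand-dependent ±1 correction is ever applied, which is exactly the 1-bp
reverse-strand adjustment that ATAC-seq-derived cut-matrix tools need to
make explicitly. Offsets remain available (`forward_offset`,
`reverse_offset`, default `(0, 0)`) so ATAC-style data (Tn5's 4-bp
overhang, conventionally `(4, −5)`) can be processed by the same code.

Cut-matrix columns: column `i` (1-based in R) counts cuts situated just
before oriented nucleotide `i` of the `W = motif + 2·flank` window. For a
minus-strand motif the column index is flipped (`W + 1 − i`) and the
forward/reverse labels swap, so all rows share one orientation. One
fencepost subtlety is worth recording: flipping column indices reverses
the window's *nucleotide* columns, i.e. it reflects the window about base
centers, not about inter-base boundaries. A mirror-image of the genome
therefore reproduces the oriented matrix exactly when boundaries are
reflected as `b → C − 1 − b` (base-center reflection); reflecting
boundaries as `b → C − b` instead would demand a flip rule with a
different fencepost (`W − i`, window `(ws, we]`). We follow the
column-reversal convention, and the mirror-invariance test in the suite
uses the matching reflection.

The window is `[start − flank, end + flank)` with `flank = 100` by
default; a 150-bp variant is a flag away, and neither choice affects any
other module because `W` is carried in the `CutMatrix`.

## The footprint mixture

Let `X_i` be site `i`'s count vector over `S = 2W` positions (forward
columns then reverse columns — the model sees strand-specific structure)
and `R_i = Σ_s X_is`. The two-component model is

* bound (weight π): `R ~ NB(μ₁, r₁)`, `X | R ~ Multinomial(R, λ)`;
* unbound (weight 1 − π): `R ~ NB(μ₀, r₀)`, `X | R ~ Multinomial(R, 1/S)`.

The multinomial coefficient cancels in every likelihood *ratio*, so it is
never materialised; the per-site binding log-odds is

```
log_odds_i = logit(π) + [log NB(R_i; μ₁, r₁) − log NB(R_i; μ₀, r₀)]
             + Σ_s X_is log(λ_s S)
```

clipped to ±700 before the logistic transform. This is the two-component
core of the classic digital-footprinting mixture; the hierarchical layer
that regresses π on motif score/conservation is deliberately out of scope
(the binding-call criteria here use peak membership and motif identity
directly instead).

**Fitting.** Plain EM. E-step responsibilities are computed in log space
(`logsumexp`); the M-step updates `λ_s = (Σ z_i X_is + α) / (Σ z_i R_i +
Sα)` with pseudocount `α = 1`, `π = mean(z)` clamped to `[1e−4, 1−1e−4]`,
and the NB components by responsibility-weighted method of moments with
the size parameter floored at 0.05; a component whose weighted variance
does not exceed its mean falls back to Poisson. Convergence is
`|Δ loglik| < 1e−6` or 200 iterations.

**Numerical choices worth knowing.**

* Initialisation is deterministic and seed-free: λ from the aggregate
  profile of the upper half of sites by read total (pseudocounted), π =
  0.1, both NB components from global moments. Two runs on the same matrix
  are bit-identical.
* The moments-based NB update is not an exact M-step, so EM's monotonicity
  guarantee does not formally apply. The fitter guards this: if an
  iteration ever lowers the observed-data log-likelihood it keeps the
  previous parameters and stops, so the reported trace is monotone by
  construction. On all test fixtures the guard never fires.
* λ is floored at 1e−8 and renormalised, keeping every log finite.
* On pure-null data the two components are structurally identical, π is
  unidentifiable, and the bound component's λ absorbs sampling structure:
  its deviation from uniform shrinks with depth (≈ the multinomial
  sampling scale `0.4·√(S/N)`, inflated ~2× by responsibility selection)
  but is not zero at finite N. The null-data test asserts exactly this
  large-sample behaviour and does not assert a value for π.
* Model JSON is written with 17 significant digits, which round-trips IEEE
  doubles exactly; a stage re-run from a saved model reproduces the
  original run byte-for-byte.

## Footprint symmetry

The profile handed to the symmetry analysis is the model's λ summed over
strands (length W); raw aggregate counts work too, since the score is
scale-free in amplitude. The profile is split at the middle — an odd
middle point goes to the left half (configurable) — and each half is
fitted with `y = A·exp(B·x)`, `x = 0, 1, …` left-to-right on *both*
halves, so an ascending left arm has `B_left > 0` and a descending right
arm `B_right < 0`. Whether `x` should instead count from the motif center
is not determined by the field's usage; the left-to-right convention is a
documented choice and only flips signs coherently. Nonlinear least
squares is initialised from a log-linear regression on values floored at
1e−12 (a pure log-linear fit is available as a flag); `R² = 1 −
SS_res/SS_tot` on the original scale, defined as 0 for numerically
constant halves, which also marks the fit degenerate.

`FSS = B_left·R²_left − B_right·R²_right`, and a motif is **primary** when
`FSS > 0.3` and the arms are mirrored: `|B_left + B_right| ≤ 0.2 ·
max(|B_left|, |B_right|)`. The "small difference between the rates"
condition is unquantified in the field's usage; 0.2 relative is this
package's default, reported alongside the components so users can
re-threshold.

**Scale caveat.** `B` is a *per-position* rate, so FSS depends on the
window length. Over a 103-point half-window, a probability-normalised
profile that rises smoothly across the whole flank cannot have `B` much
above ~0.05 — e.g. the default simulator template (rise 0.03/bp) yields a
nearly perfectly mirrored profile with FSS ≈ 0.031, classified secondary
at the 0.3 cutoff. Cutoff-clearing FSS values arise from profiles whose
rise is concentrated near the motif (large `B`, moderate `R²`) or from
fits over shorter windows. We kept both the generator's template (chosen
for a realistic-looking footprint, before any test was run) and the
published 0.3 cutoff rather than tuning either; the classification logic
is exercised in tests with exact exponential profiles where the
arithmetic is unambiguous.

## Direct binding sites

Three criteria, applied in two steps: `filter_sites()` removes peaks on
excluded chromosomes (chrM/MT) or overlapping the blacklist and keeps
motif sites with ≥ 1 bp overlap of a retained peak (full containment is a
flag); `call_direct_binding()` then requires the primary flag and
`log_odds > 5`, strictly — 5.00 is not called. Output is rank-ordered by
descending log-odds with coordinate tie-breaks for determinism.

## Trimming

The second-pass trimmer removes the longest read suffix of length `k ∈
[1, 6]` exactly equal to the adapter's first `k` bases (longest-first, one
trim per read). Matching is exact by design: mismatch-tolerant matching at
these lengths would fire constantly by chance (a random 1-mer matches 25%
of the time already), and the template trimmer upstream owns ≥ 7-bp
overhangs. After trimming, pairs with either mate < 25 bp are dropped
(boundary inclusive: 25 bp is kept; the pair policy exists because the
aligner needs both mates). The FASTQ simulator constructs inserts from the
three bases other than the adapter's first base, which guarantees the true
overhang is exactly recoverable — the caveat being that on real data an
insert whose last bases coincidentally extend the adapter match is
over-trimmed by those bases; this is inherent to exact suffix matching,
not an implementation artifact.

## What the simulator does and does not emulate

`simulate_fragments()` states this world: motif sites alternate strands on
a synthetic contig, 2 kb apart; bound sites draw `R ~ NB(mean 40, size
5)` cut positions from the template profile over the oriented window,
unbound sites draw `R ~ NB(8, 2)` from uniform; each drawn cut becomes one
end of a stranded fragment (forward/reverse with probability ½, mirrored
on minus-strand sites); a `duplicate_fraction` (default 0.1) of each
site's fragments are exact `(s1, e2)` copies; fragment lengths are drawn
from 250–400 bp and *extended when necessary so the partner end lands
outside the site window*. That last rule is a deliberate unrealism: it
makes the number of in-window ends per site exactly equal the drawn `R`
(the generator's conservation invariant, which the round-trip tests rely
on). Real data violates it — neighbouring sites share fragments and both
ends of short fragments often fall in one window — so a green round-trip
test establishes coordinate bookkeeping and model identifiability, not
biological realism. Likewise there is no sequence realism (no reference
genome, no quality-error model, FASTQ mates generated independently), no
chromatin-state covariates, and peak intervals are simply site windows
plus 20 bp slack.

Default means 40/8 give a clear but not caricatured separation
(overlapping tails: ~9% of bound sites draw ≤ 15 ends); 500 sites keep
every test under seconds. The FASTQ defaults (42-bp reads, the common
CUT&RUN read length; TruSeq read-through adapter) are overridable.

## Degenerate inputs and edge conventions

* Cut matrix: boundary exactly on the window end is excluded (half-open
  window); overlapping sites each get independent rows; a fragment end in
  two windows counts in both.
* Size fractionation: the 120-bp boundary value goes to the small (factor)
  fraction; `Inf` disables fractionation.
* Duplicate key is `(chrom, s1, e2, R1-strand)`; strand is included to
  keep mirrored fragments distinct even though the field's verbal
  definition names only the positions. Default is to *retain* duplicates.
* Model fitting refuses all-zero matrices and < 20 sites with reads.
* QC: missing inputs produce `not-available` flags, never errors; warn
  thresholds sit at the strict end of the accepted ranges (adapter loss
  15%, library 1e7 pairs, duplication 15%, alignment 90% with the boundary
  passing); there is deliberately no single overall verdict.

## Known limitations

* The mixture omits covariate priors (motif score, conservation) on π;
  numeric parity with hierarchical footprinting packages is not claimed —
  structural parity with the NB/multinomial/logit core is.
* FSS values are window-length dependent (above); compare scores only
  across motifs analysed with the same window.
* The trimmer cannot distinguish a true adapter base from an insert base
  that happens to equal it; exact-match behaviour is the documented
  contract.
* `load_fragments()` trusts the aligner's proper-pair flags and takes
  alignment boundaries as-is (no dovetail re-clipping).
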