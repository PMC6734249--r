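# cutfoot

Cut-matrix estimation and motif footprinting for CUT&RUN data.

CUT&RUN maps chromatin-associated proteins by tethering a protein
A–micrococcal nuclease fusion to an antibody bound in situ; the nuclease
cleaves the DNA flanking each binding site and releases short fragments for
paired-end sequencing. Every fragment end is therefore a nuclease **cut
site**, and the genome-wide pattern of cut sites around a transcription
factor's motif occurrences carries single-nucleotide-resolution evidence of
direct binding: a bound motif shows a **footprint** — depleted cuts over the
protected motif core, elevated cuts in the flanks. `cutfoot` is for
computational biologists who have aligned CUT&RUN data (or fragment BED
files) plus motif occurrences and want to go from fragments to a
rank-ordered list of direct binding sites without a cluster pipeline.

## What it computes

1. **Cut matrix** — for motif sites *m* and oriented window positions
   *i* ∈ 1..W (W = motif length + 2·flank), strand-specific counts of
   fragment-end boundaries, where a count at position *i* means a cut just
   before oriented nucleotide *i*. Minus-strand motifs are column-flipped
   and strand-swapped; CUT&RUN needs no cut-site offset (offset = 0), and
   the inter-base boundary convention absorbs the 1-bp reverse-strand shift
   that ATAC-seq-style tools require.
2. **Footprint mixture model** — sites are a two-component mixture. For
   site counts X over S = 2W strand-specific positions with total
   R = Σ X_s:

   - bound: R ~ NB(μ₁, r₁), X | R ~ Multinomial(R, λ), λ the footprint
     profile;
   - unbound: R ~ NB(μ₀, r₀), X | R ~ Multinomial(R, 1/S).

   EM estimates λ, the NB components and the mixing weight π; the per-site
   **binding log-odds** is
   `logit(π) + log NB-ratio + Σ_s X_s log(λ_s·S)`, and the posterior
   binding probability is its logistic transform.
3. **Footprint symmetry score (FSS)** — each half of the footprint profile
   is fitted by `A·exp(B·x)`; `FSS = B_left·R²_left − B_right·R²_right`.
   A symmetric, steep footprint (high FSS, `B_left ≈ −B_right`) marks a
   **primary** motif (the assayed factor's own); asymmetry marks a
   co-factor (secondary) motif.
4. **Direct binding sites** — sites with a primary motif, inside a
   blacklist/chrM-filtered peak, with log-odds > 5 (strict).
5. **Trimming and QC** — an exact-match trimmer for 1–6-bp 3′ adapter
   read-through overhangs that template trimmers miss (with the 25-bp
   minimum-length filter), and the standard QC metrics (fragment size
   distribution, adapter content, library size, duplication rate, alignment
   percentage, peak count, motif enrichment) with pass/warn flags.

A synthetic-data module simulates stranded fragments around bound/unbound
motif sites (negative-binomial read totals, configurable footprint profile,
PCR duplicates) and read-through FASTQ with known overhangs, so the entire
pipeline is testable offline with known ground truth.

## Worked example

```r
library(cutfoot)

params <- simulation_params(seed = 7)        # 300 bound + 200 unbound sites
sim    <- simulate_fragments(params)

cm <- build_cut_matrix(sim$fragments, sim$sites, flank = 100)
cm
#> CutMatrix: 500 sites x 206 positions (motif 6 bp, flank 100 bp)
#>   forward ends: 7047, reverse ends: 7144

model <- fit_footprint_model(cm)
model
#> FootprintModel: S = 412 positions, pi = 0.609, NB bound mean 41.6 /
#>   null mean 7.8, 4 EM iterations (converged)

scores   <- score_sites(model, cm)
filtered <- filter_sites(sim$sites, sim$peaks)
calls    <- call_direct_binding(scores, filtered, primary = TRUE,
                                threshold = 5)
sum(calls$called)                            # 283 of 500 sites called
head(calls[, c("site_id", "strand", "log_odds", "posterior", "called")], 3)
#>     site_id strand log_odds posterior called
#> 1 site_0381      + 81.24033         1   TRUE
#> 2 site_0411      + 63.82830         1   TRUE
#> 3 site_0163      + 60.07187         1   TRUE
```

The fitted mixing weight (0.609) recovers the simulated bound fraction
(0.6); the NB means (41.6 / 7.8) recover the simulated 40 / 8 reads per
site; every one of the 283 called sites is truly bound in the simulation
(precision 1.0). The symmetry score of the fitted profile:

```r
footprint_symmetry_score(model_profile(model))
#> FSS = 0.0310 (B_left 0.0228, r2 0.698; B_right -0.0219, r2 0.687;
#>   rate gap 0.0009) -> secondary motif
```

The arms are almost perfectly mirrored (rate gap 0.0009) but per-position
rates over a 103-point half-window are shallow, so the whole-window FSS
sits far below the 0.3 primary cutoff — see the methods vignette for why
the cutoff corresponds to steeper fitted profiles and how to rescale.
Because the primary flag is an explicit input to `call_direct_binding()`,
this does not affect the calls above.

The one-command pipeline (`run_pipeline(config)` or the CLI
`inst/cli/cutfoot run --config config.json`) chains
trim → fragments → fractionate → cut matrix → model → FSS → calls → QC and
writes each stage's artifact (TSV/BED/bedGraph/JSON) plus the resolved
configuration to the output directory; each stage is also available as a
subcommand (`simulate`, `trim`, `fragments`, `cutmatrix`, `footprint`,
`fss`, `call`, `qc`).

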