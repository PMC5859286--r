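# cpfsca

Statistical coupling analysis (SCA) and sector mapping for protein
families, built around the cryptochrome/photolyase family (CPF) — the
homologous family spanning light-driven DNA-repair enzymes (photolyases)
and the circadian transcriptional repressors (cryptochromes). The package
is for computational biologists who want to identify networks of
conserved, co-evolving positions ("sectors") in a multiple sequence
alignment, relate them to ligand-binding pockets on a structure (the FAD
active site and the secondary antenna-cofactor pocket of CPF proteins),
and quantify the circadian bioluminescence recordings used to validate
such positions functionally.

## The method

Given an aligned protein family, the pipeline:

1. **Preprocesses the alignment** — removes sequences with ungapped length
   outside [400, 800] residues, highly gapped positions (> 40% gaps) and
   then highly gapped sequences (> 20%), and sequences too similar or too
   dissimilar to a chosen reference; each surviving sequence *s* gets a
   redundancy-correcting weight `w_s = 1 / n_s`, where `n_s` counts
   sequences with > 80% identity to *s*, giving the effective sequence
   count `M' = Σ_s w_s`.
2. **Measures positional conservation** as the Kullback–Leibler relative
   entropy of the weighted amino-acid frequencies against a background
   distribution, `D_i = Σ_a f_i^a ln(f_i^a / q^a)` (nats).
3. **Builds the conservation-weighted covariance tensor**

   ```
   C̃_ij^ab = (∂D_i^a/∂f_i^a) (∂D_j^b/∂f_j^b) (f_ij^ab − f_i^a f_j^b)
   ```

   with the conservation weight
   `∂D_i^a/∂f_i^a = ln[ f(1−q) / (q(1−f)) ]`, and reduces it to the
   positional SCA matrix `C̃_ij = sqrt(Σ_ab (C̃_ij^ab)²)`.
4. **Identifies the sector** by spectral decomposition of the SCA matrix:
   positions with a top-eigenmode loading above 0.03 (after sign
   orientation) form a single sector of co-evolving positions.
5. **Projects sequences** into the space of positional correlations (via
   the SVD duality of the conservation-weighted, centered alignment), so
   subfamilies — e.g. CRYs vs photolyases — that diverge at sector
   positions separate along the top modes.
6. **Maps sector positions onto a structure**: pockets are defined as all
   residues with at least one atom within 4 Å of a named ligand, alignment
   columns are matched to structure residues by pairwise alignment of the
   reference sequence, and sector/pocket overlap is scored
   hypergeometrically.
7. **Quantifies luminescence traces** the way circadian rescue and
   degradation assays are analysed: background correction, discarding the
   first 10 h, running-average baseline subtraction, damped-sine fitting
   (`A e^{−dt} sin(2πt/T + φ)`) with an arrhythmicity call at < 80%
   goodness of fit, one-phase-decay half-life fitting
   (`t½ = ln 2 / k`), and −1..1 heat-map scaling.

Because the published CPF alignment was never deposited, the package ships
a first-class synthetic-alignment generator with a planted co-evolving
sector driven by a latent per-sequence state, independently conserved
columns, gap injection, near-duplicate clusters and subfamily labels —
with full ground truth, so every stage is benchmarked against known
answers.

## Worked example

```r
library(cpfsca)

sim  <- generate_msa(seed = 42)            # 500 x 100, 15 planted sector columns
paln <- as_processed_alignment(sim$alignment)
paln
#> <processed_alignment> 500 sequences (M' = 500) x 100 positions

res    <- sca_matrix(paln)                 # tensor + Frobenius-reduced matrix
spec   <- eigendecompose(res$matrix, k = 4)
spec
#> <spectral_result> top 4 of 100 modes; eigenvalues: 58.96, 7.496, 3.131, 2.965

sector <- define_sector(spec, threshold = 0.03, paln = paln)
sector
#> <sector_definition> 16 positions with mode-1 loading > 0.03
sector_recovery_metrics(sector$members, sim$truth$sector_columns)
#> # A tibble: 1 x 6
#>   n_predicted n_truth n_overlap precision recall    f1
#> 1          16      15        15     0.938      1 0.968

coords <- project_sequences(reduce_alignment(paln, res$freq, res$phi), paln)
ann    <- annotate_projection(coords, sim$truth$labels)
mode_separation_auc(ann$coordinates)       # CRY vs PHL along mode 1
#> [1] 0.996
```

The top eigenvalue (59.0) stands far above the bulk (7.5, 3.1, ...): the
planted co-evolving network dominates the spectrum. The sector recovers
all 15 planted columns plus one false positive (F1 = 0.97), and the two
subfamilies separate almost perfectly in sequence space (AUC = 0.996).

A rhythm-analysis example:

```r
tr  <- generate_trace(period_h = 26.9, amplitude = 100, damping_per_h = 0.01,
                      baseline = 300, drift_per_h = -1, noise_sd = 5, seed = 42)
det <- baseline_subtract(trim_initial(background_correct(tr, 0), 10), 24)
fit_damped_sine(det)
#> <damped_sine_fit> T = 26.951 h, goodness = 98.45% (rhythmic)
```

The 26.9-h simulated rescue trace is recovered to 0.05 h despite 5% noise,
a declining baseline and exponential damping.

Fitted objects have `tidy()` / `glance()` methods and `autoplot()` /
`plot_*()` figures; `run_pipeline("run.yaml")` executes the whole chain
(preprocess → conservation → SCA → sector → projection → structure
overlap) reproducibly into a run directory with a JSON manifest.

Real-structure workflows (e.g. the photolyase structure 1TEZ with its
8-HDF antenna cofactor, or the CRY2 structures 4I6G/4I6E) are supported by
pointing `parse_structure()` at a local PDB file, choosing a chain, and
naming the ligands; the packaged tests use constructed toy structures so
they run offline.

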