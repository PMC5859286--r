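---
title: "Methods: conservation-weighted coupling analysis and rhythm quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation-weighted coupling analysis and rhythm quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the statistics it implements:
the model behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic benchmark does and does not emulate,
and the numerical decisions a maintainer would want written down.

## The statistical model

Statistical coupling analysis treats a multiple sequence alignment as a
sample from the evolutionary ensemble of a protein family and asks which
positions co-vary beyond what independent drift would produce, weighting
that covariance by positional conservation. The premise is biological:
positions under a joint functional constraint — an allosteric network, a
binding surface — are both conserved and correlated, while phylogenetic
noise is spread over weakly conserved positions. In the
cryptochrome/photolyase family this machinery is pointed at a concrete
question: does the network of co-evolving positions around the essential
FAD pocket extend to the secondary (antenna-cofactor) pocket that
repressor cryptochromes appear to have repurposed as a protein-interaction
surface?

### Sequence weighting and frequencies

Alignments over-represent well-sequenced clades. Each sequence therefore
receives weight $w_s = 1/n_s$, with $n_s$ the number of sequences
(including $s$) at fractional identity strictly above 0.8 to $s$; the
effective sequence count is $M' = \sum_s w_s$. Two properties motivate
counting the sequence itself: weights stay in $(0,1]$, and replicating
every sequence $d$ times leaves $M'$ — and everything downstream — exactly
unchanged, a property the test suite asserts to $10^{-10}$.

Identity between two aligned rows is defined as matching non-gap letters
divided by columns where at least one of the pair is non-gap. Columns
gapped in both sequences say nothing about divergence, so they are
excluded from the denominator; the definition is configurable because the
field uses several conventions.

Weighted frequencies are regularized toward a background distribution
$q$ with a pseudocount fraction $\lambda$:
$f_i^a = (1-\lambda)\,\hat f_i^a + \lambda q^a$ and
$f_{ij}^{ab} = (1-\lambda)\,\hat f_{ij}^{ab} + \lambda q^a q^b$. Gaps and
unknown letters carry no amino-acid mass, so frequencies at gapped columns
sum to less than one; this is deliberate — a gap is absence of evidence,
not a 21st residue type.

### Conservation and its weight

Positional conservation is the Kullback–Leibler relative entropy
$D_i = \sum_a f_i^a \ln (f_i^a / q^a)$, in nats. It is zero exactly when a
column matches the background and grows as the column concentrates on any
letter, fastest for letters rare in the background. The coupling weight is
the derivative of the *binarized* per-letter entropy
$D_i^a = f\ln\frac{f}{q} + (1-f)\ln\frac{1-f}{1-q}$:

$$\phi_i^a = \frac{\partial D_i^a}{\partial f_i^a}
           = \ln\frac{f_i^a\,(1-q^a)}{q^a\,(1-f_i^a)},$$

zero at background frequency, strictly increasing in $f$, and infinite at
$f \in \{0, 1\}$ — which the pseudocount precludes ($\lambda > 0$ is
required before $\phi$ is computed).

A note on interpretation: a conservation value of 3 nats corresponds to a
column identity that depends on the letter's background frequency — about
0.8 for the rarest letters, above 0.9 for moderately common ones, and
unreachable for the most common letters (full conservation of leucine
yields only $\ln(1/q_L) \approx 2.4$ nats). `identity_for_conservation()`
reports the solved identity per letter; the package asserts nothing about
a single "identity at $D = 3$" because no single value exists.

### The coupling tensor and the SCA matrix

The conservation-weighted covariance tensor is

$$\tilde C_{ij}^{ab} = \phi_i^a\,\phi_j^b\,(f_{ij}^{ab} - f_i^a f_j^b),$$

stored as a $(20L)\times(20L)$ symmetric matrix of $20\times 20$ blocks,
and reduced per position pair by the Frobenius norm over letters,
$\tilde C_{ij} = \sqrt{\sum_{ab}(\tilde C_{ij}^{ab})^2}$. Both operations
are checked against independent loop-based recomputation to $10^{-12}$ on
random alignments. The tensor is identically zero when joints factorize
exactly, and for sampled independent columns the off-diagonal of
$\tilde C$ shrinks as alignment depth grows (checked at $M = 200$ vs
$2000$).

### Sector definition

The SCA matrix is eigendecomposed (dense symmetric solver; eigenvalues
descending; each eigenvector oriented so its largest-magnitude loading is
positive, ties broken by first index — the positive orientation is needed
because a one-sided loading threshold is meaningless on an unoriented
eigenvector). The sector is the set of positions with top-mode loading
strictly greater than 0.03, the printed operating point of the CPF
analysis; the threshold and mode index are configuration. No
independent-component rotation and no randomization-based eigenvalue
significance test are applied: the sector here is defined purely by the
EV1 threshold, and those extensions are out of scope. Splitting the sector
by the second eigenmode is supported descriptively (the loadings table
carries all requested modes) without a hard subgroup assignment, since no
quantitative rule is defined for one.

### Sequence-space projection

To see which sequences drive the positional correlations, the binarized
alignment (sequence × position × letter) is reduced to sequence × position
by projecting each position's letter axis onto its conservation pattern:

$$r_{si} = \sum_a \phi_i^a\,(x_{sia} - \hat f_i^a),$$

with centering at the *empirical* weighted frequencies so a fully constant
column reduces to exact zeros. The projection vector is $\phi_i$ itself,
with no further per-position normalization — the choice is an
implementation constant; any per-position rescaling leaves the direction
of each position's contribution unchanged.

Sequence coordinates come from the spectral decomposition of the
weight-aware positional correlation of the reduced alignment,
$P = R^\top \mathrm{diag}(w) R / M'$: the coordinate of sequence $s$ along
mode $m$ is $r_s \cdot v_m / \sqrt{M' \lambda_m}$. This is the SVD duality
route — with unit weights the coordinates *are* the left singular vectors
of $R$ (asserted to $10^{-8}$) — and it makes coordinates invariant to
sequence duplication and reordering. The Frobenius-reduced SCA matrix has
similar but not identical eigenvectors; it defines the sector, while $P$
defines the sequence-space geometry. This separation is a deliberate
design choice: a projection onto the Frobenius-matrix eigenvectors cannot
satisfy the SVD duality exactly, because the two matrices differ.

### Structure mapping

Pockets follow the 4 Å rule: a residue belongs to a ligand's pocket if any
of its atoms lies within 4.0 Å (inclusive — "within" is read as $\le$) of
any ligand atom, by Euclidean distance. Hydrogens are used when present
(crystal structures typically lack them, so the default effect is nil);
waters are ignored; alternate locations resolve to the highest-occupancy
record. Alignment columns map to structure residues through a global
pairwise alignment (BLOSUM62, affine gaps, opening 10 / extension 0.5) of
the alignment's reference sequence against the structure-derived sequence;
identities below 30% raise a warning since a poor alignment produces
unreliable maps. Sector/pocket overlap is scored with a hypergeometric
tail over the mapped positions. Tests use constructed toy structures whose
pocket membership is known by construction; runs against real CPF
structures (1TEZ, 4I6G, 4I6E) are an optional workflow on user-supplied
files.

### Rhythm and decay quantification

Luminescence recordings (counts every 10 minutes) are background-corrected
by a constant per-channel level, trimmed of their first 10 h (the
synchronization transient; the boundary point at exactly 10 h is kept and
time is not re-zeroed), and detrended by a centered running average with a
24 h window — one circadian period, so the oscillation itself averages
out of the baseline. At the trace edges the window shrinks symmetrically
to the available span.

The rhythm model is $A e^{-dt}\sin(2\pi t/T + \varphi)$. A subtlety the
package handles explicitly: running-average detrending is a linear filter
that distorts the oscillation near the edges, and fitting a clean damped
sine to filtered data biases the period by several tenths of an hour when
the window is close to the period. The fit therefore passes the *model*
through the same running-mean operator as the data, so data and model are
filtered identically and the filter cannot bias the parameters. The
operator is built once per fit as an $n \times n$ averaging matrix.

Starting values are deterministic: the period seed is the periodogram peak
within 15–40 h, the amplitude seed is $\sqrt 2$ times the detrended
standard deviation, the damping seed is 0.01 h$^{-1}$, and the phase seed
is the best of a coarse 8-point grid. The optimizer is
Levenberg–Marquardt with tight tolerances (`ftol = ptol = 1e-12`,
200 iterations) and box constraints keeping $T$ in the seed window and
$A \ge 0$. Goodness of fit is percent variance explained,
$100\,(1 - SS_{res}/SS_{tot})$, on the detrended trace; recordings under
80% — including any fit that fails to converge, and constant traces,
which short-circuit — are called arrhythmic. The commercial analysis
software that popularized the 80% rule does not publish its goodness
definition; percent variance explained of the damped sine on detrended
data is this package's documented reading.

Half-lives come from a one-phase decay $y = (y_0 - p)e^{-kt} + p$ fitted
to traces normalized to their first reading, seeded by a log-linear
regression above a provisional plateau, reporting $t_{1/2} = \ln 2 / k$.
Heat-map display scales each detrended trace to a z-score and then
linearly so its largest absolute value is 1; zero-variance traces map to
zero rather than dividing by zero.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| length bounds | 400, 800 | residues | CPF domain size band; inclusive, since only strictly smaller/larger sequences are discarded |
| max gap per position | 0.4 | fraction | toolbox convention; exposed in config |
| max gap per sequence | 0.2 | fraction | toolbox convention; exposed in config |
| reference identity band | [0.2, 0.8] | fraction | removes near-duplicates of the reference and non-homologous outliers |
| weighting identity | 0.8 | fraction | neighbors are > 80% identical |
| pseudocount λ | 0.03 | fraction | standard toolbox default; keeps φ finite |
| background q | database table | fractions | amino-acid frequencies of a large nonredundant protein set; `uniform = TRUE` for closed-form checks |
| sector threshold | 0.03 | loading | printed operating point; strict inequality |
| pocket cutoff | 4.0 | Å | "within 4 Å", inclusive |
| trim | 10 | h | synchronization transient |
| detrend window | 24 | h | one circadian period |
| rhythmicity threshold | 80 | % variance explained | the arrhythmicity rule |

## The synthetic benchmark

`generate_msa()` emulates exactly the statistical structure SCA assumes: a
latent two-state variable per sequence drives a planted set of sector
columns (each state prefers one letter with probability 0.9, background
otherwise), other columns are independent background draws, a handful of
columns are independently conserved, gaps are injected at a low rate, and
optional near-duplicate clusters exercise the weighting. Defaults — 500
sequences, 100 positions, 15 sector columns, coupling 0.9, two equal
states, 1% gaps — are the package's benchmark conditions throughout the
tests and the acceptance script.

The default state letters alternate rare- and common-background residues
(W, L). Both choices matter: rarity makes φ large, amplifying the planted
coupling for sector recovery, while the *contrast* in background frequency
between the two states' letters is what allows the one-dimensional
φ-weighted reduction to tell the states apart in sequence space. With two
equally rare letters the reduction is nearly symmetric between the states
and subfamily separation collapses toward chance — a genuine property of
the 1D reduction, not a failure of the planted signal, and the reason the
default is not two rare letters.

What the generator does *not* emulate: phylogenetic correlation along a
tree (its redundancy is cluster-based), heterogeneous column-specific
substitution processes, alignment errors, and the long-tailed subfamily
structure of real retrievals. Passing benchmarks therefore demonstrate
correctness of the machinery and sensible power under idealized
co-evolution, not performance guarantees on real families — on real data,
phylogenetic confounding is the dominant hazard and is exactly what the
conservation weighting and sequence weights mitigate but cannot remove.

Trace generation covers the observed rescue-period range (21.8–26.9 h)
with configurable damping, drift and Gaussian noise; decay traces cover
plateaued exponentials. Benchmarks run at 70 h recordings, 10-min
sampling, 5% noise.

## Numerical choices and degenerate inputs

- Exact symmetry of the pair-frequency matrix and the tensor is enforced
  by averaging with the transpose; the eigensolver rejects asymmetry
  beyond $10^{-8}$ relative.
- Eigenvalue ties break deterministically (first index); eigenvector sign
  is fixed by the largest-|loading| rule, so identical inputs give
  identical sectors across platforms.
- Modes with nonpositive eigenvalues are excluded from sequence
  coordinates (their scale $\lambda_m^{-1/2}$ is undefined).
- Empty results fail loudly: filters that remove everything, traces
  shorter than the trim, and missing references/ligands raise typed
  errors rather than returning empty objects.
- The pipeline writes no timestamps, so identical config + seed
  reproduces byte-identical run directories (asserted via checksums).
- Problem sizes in the shipped tests and acceptance script — alignments up
  to 2000 × 20 for the independence null and 500 × 100 for benchmarks,
  10 replicate seeds per stochastic claim — were chosen as the smallest
  sizes at which the benchmarked properties are stable.

## Known limitations

- The headline counts of the original CPF analysis (9719 → 5385 sequences,
  2447 effective, 459 positions, a 260-position sector) depend on a 2016
  database retrieval and an alignment that were never deposited; they are
  not reproducible from first principles and the package does not attempt
  them. Everything it claims is recomputed on synthetic or user-supplied
  inputs.
- `parse_structure()` reads PDB format only (via bio3d); mmCIF is out of
  scope.
- The sector is a single EV1 thresholding; families whose co-evolution is
  spread across several comparable eigenmodes need the multi-mode loadings
  table and judgment, not this package's single-sector rule.
- Goodness-of-fit of the damped sine is R² on detrended data; other
  readings of the 80% rule would shift rhythmicity calls near the
  boundary.
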