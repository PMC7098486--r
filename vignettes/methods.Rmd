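---
title: "Models and methods behind ubiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ubiquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ubiquant)
```

# Scope

`ubiquant` re-implements, as a tested and reusable pipeline, the
quantitative machinery used to study Parkin/PINK1/USP30-dependent
mitochondrial ubiquitylation in induced neurons: intact-mass
quantification of phosphorylated and diGLY-branched Ub^dGG proteoforms,
TMT-MS3 quantification with its quality filters and normalizations,
moderated Welch statistics with permutation-based FDR control, and
mitophagic-flux / PRM stoichiometry quantification. Because the raw mass
spectrometry data behind the original study are not publicly deposited,
every input the pipeline consumes can be simulated with known ground
truth; what the tests establish is therefore round-trip correctness of
the computational stages, not re-discovery of biological results.

# The Ub^dGG proteoform model

LbPro*-type proteases cleave ubiquitin after R74, releasing a Ub monomer
lacking the C-terminal Gly-Gly (Ub^dGG, residues 1-74 of UniProt P0CG48)
while leaving a Gly-Gly dipeptide (+114.0429 Da) on each lysine that
carried a chain branch. A proteoform is identified by its diGLY branch
count (0-3 is the quantified range; seven lysines exist) and S65
phosphorylation state (+79.966 Da):

mass = mass(Ub^dGG) + n_branches * 114.0429 + phospho * 79.966.

Branch lysine positions are deliberately not modeled: intact mass cannot
resolve positional isomers, so proteoform identity is (branch count,
phospho state) only. Reported deltas use the conventional rounded values;
internally all arithmetic uses full-precision monoisotopic masses (IUPAC
atomic masses, proton = 1.007276 Da, consistent with the MH+ mass
convention of vendor deconvolution software).

Isotope envelopes are computed by exact aggregated convolution of
per-element isotope distributions (repeated squaring, direct non-FFT
convolution so far-tail centroid masses stay exact), with peak masses as
abundance-weighted centroids per nucleon offset. An independent
atom-by-atom expansion oracle in the test suite pins this to 1e-9.

# Spectrum simulation (the stated world)

The simulator renders each proteoform's exact-composition isotope
cluster as Gaussian profiles at resolving power 60,000 at 200 Th scaling
as 1/sqrt(m/z), inside the 625-925 m/z acquisition window, across a
charge envelope and a Gaussian chromatographic elution profile:

* **Charge envelope.** Discretized Gaussian centered at z = 12 (sd 1).
  The default support is z = 10-13 — the charge states at which all
  eight Ub^dGG candidates fall entirely inside the 625-925 window (z = 14
  of unmodified Ub^dGG would sit at ~604 m/z, outside it) — and is never
  allowed above the acquisition cap of z = 17. Restricting the envelope
  to in-window charges keeps the round trip unbiased: otherwise heavier
  species would expose more charge states than lighter ones and inherit
  a systematic abundance advantage.
* **Chromatography.** 5 scans across a Gaussian elution peak (sd 1.2
  scans): minimal but sufficient to exercise XIC integration.
* **Noise.** Additive Gaussian per profile point, scaled to a fraction
  of the tallest peak (default 1%; acceptance round trips run at 0).
  TMT channel noise is multiplicative log-normal — the standard MS error
  structure — which keeps recovery tests well-posed.
* **Mixture compositions.** The bundled HeLa 1 h and iNeuron 6 h
  mixtures carry the published phospho-proteoform percentages (12 / 1.42
  / 0.05% and 5.5 / 0.27%). The non-phospho complement is not published
  as percentages; it is apportioned once with the same roughly 10-fold
  decay per added branch seen in the phospho series (e.g. 76.53 / 9.0 /
  0.9 / 0.1% for HeLa). The acceptance targets concern only the phospho
  species, but the complement determines the spectral background they
  must be quantified against.

What the simulator does **not** emulate: chimeric spectra, co-isolation
interference mechanics (only a scalar isolation-specificity attribute),
retention-time structure, or detector saturation. A green round-trip
test therefore establishes correctness of deconvolution and bookkeeping,
not robustness to every artifact of real data.

# Deconvolution and targeted quantification

Peak picking takes local maxima at S/N >= 3 over a noise floor estimated
by the median absolute deviation of the profile (with a tiny relative
floor so noise-free spectra behave); apexes are refined by a log-parabola
(exact for Gaussians) and areas are trapezoidal integrals between
bracketing local minima.

Deisotoping is greedy highest-intensity-first. For each seed centroid,
every charge z <= 17 and every plausible isotopologue index of the seed
is scored by the normalized dot product between observed centroid areas
and the sulfur-free averagine envelope at the implied neutral mass
(cached at 1 Da granularity); the vendor semantics are kept: accept at
fit >= 0.80, re-queue residual centroids above 25% of their original
area, neutral-mass search range 189-2000 Da by default (overridden to
8,000-9,200 Da for Ub^dGG work). Scoring all seed alignments and keeping
the best resolves the classic off-by-one monoisotopic assignment
problem: a one-isotopologue shift still passes the 0.80 threshold but
always scores below the true alignment on noise-free data. The reported
cluster area is the sum of observed areas over matched isotopologues
plus the fitted envelope tail for unmatched ones — using the fitted
scale alone would inherit the ~0.5% shape mismatch between averagine and
the true Ub composition, which the tests for intensity conservation
would catch. The monoisotopic mass is the abundance-weighted mean over
matched isotopologues; species are merged across charges (descending
intensity, ties to lower charge) within 0.25 Da, matched across scans
within the 0.5 Da XIC tolerance, and assigned to the nearest of the
eight candidates within 0.5 Da (candidates are > 34 Da apart, so ties
cannot occur).

"Fit factor" and "remainder" are proprietary vendor notions; only their
threshold semantics (accept at >= 0.80 on a normalized fit metric,
re-queue above 25% residual) are reproduced here, on the normalized dot
product. Percentages are normalized to all Ub^dGG species including
unmodified, plus any unassigned signal, so assigned and unassigned
fractions always sum to 1.

# TMT quantification

The PSM filters follow the stated exclusions literally: isolation
specificity < 0.7, summed reporter S/N < 150, or no MS3 spectrum are
excluded, hence the boundary values 0.7 and 150 are retained. Reporter
centroids match the closest peak within 0.003 Da. Rollup sums S/N across
matching PSMs; site keys are (protein, 1-based residue, modification
type) so diGLY and phospho layers never merge, and only PSMs with
AScore >= 13 (95% localization confidence, threshold = -10 log10 of the
complementary probability) contribute to site rows. Missing channels are
explicit `NA`s excluded from sums, not zeros.

Equal-loading normalization (each channel scaled so column sums equal
the mean column sum) is estimated on the **proteome** layer, and diGLY
sites are then divided by their protein's relative abundance profile.
Normalizing the site matrix by its own column sums would push every null
site negative whenever a subset of sites is genuinely elevated — the
planted-effect simulations make this bias visible — whereas the
proteome, with thousands of unchanged proteins, is a stable loading
reference. Sites whose protein is not quantified pass through flagged
`normalized = FALSE`. Time courses divide each channel by the mean of
the same genotype's untreated channels.

# Differential statistics

The moderated statistic is Tusher-style: d = (meanA - meanB) /
(s0 + sqrt(varA/nA + varB/nB)). The legend naming the procedure gives no
formula, so the additive fudge-constant formulation is the documented
departure point from any vendor-specific variant. p values are classical
two-sided Welch (unmodified denominator, Welch-Satterthwaite df), so
s0 = 0 reduces exactly to `t.test`; s0 only moderates the ranking used
for FDR control, mirroring how volcano p-value thresholds and FDR
significance are reported side by side.

Permutation FDR is SAM-style: the null |d| distribution pools all
distinct two-group label assignments (exhaustive whenever at most
min(n_permutations, 1000) exist — identity excluded, complements
deduplicated for equal arms — otherwise a seeded sample of 250); for a
cutoff, estimated FDR = median permuted exceedance count / observed
count (the robust median variant, standard SAM practice), and the
significant set is the largest set with estimated FDR <= the level.
Features are analyzed complete-case. On all-null data the estimator is
conservative, so the empirical false-positive proportion sits at or
below the nominal level.

The organelle-shift summary tests each annotated class's mean log2 ratio
against zero with a two-sided one-sample t test and Benjamini-Hochberg
correction across classes; the exact test behind the original
"statistically distinct" claim is unstated, so this choice is a
documented assumption. Classes with fewer than two proteins are
untestable and report `NA`.

# Flux and PRM quantification

The immunoblot flux readout is (processed - background) /
(post-import - background), with per-lane constant background (standard
quantitative-immunoblot practice; the original text does not specify).
The imaging equation is applied literally: red minus green (clipped at
zero), binary mask of positive pixels, value = area x percent area x
0.01 x mean masked intensity; "percent area" is the masked fraction of
the analyzed field in percent, which is what makes the x 0.01 dimension
bookkeeping work. Per-soma values divide by the untreated-condition mean
(division per value, before cohort averaging — the unstated alternative,
dividing cohort means, differs only by Jensen-type second-order terms at
the simulated noise levels). Somata under 30% of the cohort's mean
dual-channel intensity are excluded first.

PRM abundance per peptide is spike_fmol x light/heavy area; the protein
value is the peptide mean divided by the mitochondrial input, with SEM
across peptides, and stoichiometries propagate error to first order. The
default reference world has the translocon receptors at 2.0 fmol/ug and
the deubiquitylase at 0.6 fmol/ug (2, 6 and 2 peptides), i.e. a 0.3
stoichiometry of USP30 to TOMM20 and TOMM70.

# TMT effect model defaults

The default 11-plex mirrors the genotype x treatment x time design (WT
and S65A, untreated / 2 h / 6 h, duplicates). Planted elevated diGLY
sites number 134 among 2,400 features, concentrated on ~84 proteins
(~1.6 sites per protein); 6 h log2 effects are uniform on [1, 3] (at
least 2-fold by construction, with the bulk of real hits spanning 2- to
8-fold), 2 h effects are 75% of the 6 h log2 effect, and S65A channels
attenuate effects by 0.5 (the ~2-fold reduced signature of the
phospho-dead UBL). Channel noise is log-normal with sd 0.2 on the log2
scale (typical TMT-MS3 replicate precision); 5% of PSMs violate each of
the isolation-specificity and summed-S/N filters, 2% lack MS3, 3% are
unlocalized. The optional phospho layer plants exactly one responsive
feature with a log2 effect of 2.5 — the pS65-Ub peptide analogue, the
single depolarization-responsive phosphopeptide.

# Numerical choices and degenerate inputs

* Compositions never go negative; unknown element symbols error.
* Isotope distributions are pruned below 1e-14 relative abundance and
  renormalized to sum to 1 (1e-9 guaranteed).
* Flat or empty spectra yield empty centroid lists; empty centroid lists
  yield empty species tables; both carry zero unassigned area.
* Candidate lists whose masses are closer than twice the assignment
  tolerance are rejected outright rather than silently tie-broken.
* Zero protein channels make the corresponding normalized site channel
  missing; zero-variance features with s0 = 0 report `NA` statistics;
  genotypes without untreated channels error.
* Permutation tests error when fewer than two distinct label
  permutations exist.
* All generators are reproducible from (parameters, seed); the pipeline
  orchestrator derives per-stage seeds from the global seed and records
  a configuration hash.

# Known limitations

Discovery-scale results of the original study (numbers of sites,
fold-reductions of specific proteins, chain-linkage fold changes) depend
on undeposited raw data and are outside what this package can or tries
to reproduce. The deisotoper is tuned for well-resolved high-mass
proteoform spectra; heavily overlapping envelopes at low resolving power
would need a joint-fitting approach. MS2-level localization scoring,
search-engine PSM assignment and protein-assembly parsimony are modeled
only through their downstream attributes (AScore, quality flags, a
most-quantified-protein tie-break), not re-implemented.
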