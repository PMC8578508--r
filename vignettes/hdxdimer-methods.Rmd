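---
title: "Models and methods behind hdxdimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hdxdimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxdimer)
```

## Scope

`hdxdimer` implements the quantitative analyses used to characterise
phosphorylation-driven dimerization of multidomain proteins, with the
BET-family epigenetic reader BRD4 as the packaged worked case. Casein
kinase 2 (CK2) phosphorylates serine clusters flanking BRD4's second
bromodomain; the phosphorylated protein dimerizes through a coiled-coil
"motif B" (residues 506–530) and the basic-residue-enriched interaction
domain (BID). The package covers the five measurement modalities such a
study leans on:

1. **Differential HDX-MS** at peptide and residue level, with the combined
   absolute/statistical significance rule and the overlapping-peptide
   projection.
2. **EX1/EX2 kinetic classification** from isotopic-envelope time series by
   binomial-mixture deconvolution.
3. **Cross-linking MS set logic** for monomer- versus dimer-enriched
   fractions, contact matrices and HDX concordance.
4. **Construct-level sequence utilities**: intact masses, CK2
   consensus-motif scanning, heptad-repeat annotation, mutant construction.
5. **NanoBRET quantification** (milliBRET, one-site-total and 4PL fits) and
   **hydrodynamic conversions** (s20,w, Svedberg/frictional-ratio
   relations).

A built-in Linderstrøm–Lang simulator generates peptide maps, uptake tables
and envelopes, so every stage is testable without instrument data.

## The exchange model

Amide hydrogens exchange with solvent deuterium. For residue $j$ the
intrinsic (unprotected) rate is $k^{int}_j$ (min$^{-1}$); structure slows
exchange by a protection factor $P_j \ge 1$, so the observed EX2 rate is
$k^{int}_j / P_j$. The expected uptake of peptide $p$ at exposure $t$ is

$$
u_p(t) = (1-b)\, f_D \Big[ \sum_{j \in p,\ \mathrm{EX2}}
   \big(1 - e^{-(k^{int}_j/P_j)\,t}\big)
 + \sum_{s \cap p \neq \emptyset} n_s \big(1 - e^{-k^{op}_s t}\big) \Big]
$$

where $f_D$ is the deuterium fraction of the labelling mix, $b$ the
back-exchange fraction, and the second sum runs over EX1 segments $s$:
intervals that open cooperatively at rate $k^{op}_s$ and exchange all
$n_s$ of their amides at once (the regime in which refolding is slower
than intrinsic exchange, producing bimodal envelopes). The first residue
of each peptide and all prolines carry no observable amide and never
exchange — the standard convention.

Choices and defaults:

* **$f_D = 0.862$** — derived from the labelling protocol the simulator
  emulates: 5 µl protein diluted into 50 µl of 94.8 % D₂O buffer gives
  $50/55 \times 0.948$. Configurable in `labeling_protocol()`.
* **Exposure times** default to 3 s (0.05 min), 0.5, 50 and 180 min, in
  triplicate, with Gaussian centroid noise of SD 0.05 Da per replicate —
  a typical between-replicate spread for well-behaved peptides on a
  quadrupole-TOF platform.
* **Intrinsic rates** are drawn once per model from a seeded lognormal
  (geometric mean 10 min$^{-1}$, sdlog 1) rather than from the full
  sequence-dependent intrinsic-rate tables. This is a documented
  simplification: the pipeline only ever consumes *differences* between
  states sharing the same $k^{int}$, so the sequence dependence of the
  intrinsic rate cancels from everything downstream.
* **Back-exchange** defaults to 0 and no correction is ever applied:
  results are relative deuterium levels, the convention when all states
  are measured under identical quench/LC conditions. A nonzero `b` exists
  to test robustness.
* **EX1 opening is modelled as irreversible**: once a segment opens it
  exchanges completely. This is the cleanest bimodality generator; partial
  reclosing and EX1/EX2 crossover regimes are out of scope.

Envelopes are built on a 1-Da isotope grid as the convolution of an
averagine-style Poisson natural envelope (rate $5.34\times10^{-4}$ per Da
of peptide mass) with the deuteration distribution: a single binomial
$\mathrm{Bin}(n, \bar p(t))$ under EX2, and under EX1 a two-component
mixture whose closed-population weight is $e^{-k^{op} t}$. Because the
binomial mean is $n\bar p$, envelope centroids agree with the uptake
formula to machine precision — a cross-generator identity the test-suite
asserts at $10^{-6}$ Da.

## Differential analysis and the significance rule

Uptake is the centroid at exposure $t$ minus the mean time-0 centroid of
the same peptide and state; records without a time-0 reference are
flagged, never imputed. For each peptide and timepoint,
$\Delta = \bar u_A - \bar u_B$ with
$\mathrm{sd}_{diff} = \sqrt{sd_A^2 + sd_B^2}$ propagated from replicate
SDs. A difference is **significant** only when
$|\Delta| > 0.5\ \mathrm{Da}$ *and* $|\Delta| > 2.3 \times \mathrm{sd}$ —
the absolute gate suppresses small-but-precise differences, the relative
gate suppresses large-but-noisy ones.

Two deliberate interpretation choices (both exposed as options):

* The SD in the relative gate is the **per-peptide, per-timepoint**
  propagated SD by default (`sd_mode = "per_peptide"`); a pooled mode
  (root-mean-square of all per-peptide SDs used as one global SD) is
  provided because with $n = 3$ replicates per state the per-peptide SD
  estimate is noisy and some laboratories prefer pooling.
* The per-peptide summary is the **mean over all timepoints** of the
  per-timepoint $\Delta$, with non-significant timepoints contributing 0.
  Zeroing (rather than dropping) non-significant peptides means covered
  but unaffected regions read 0 instead of turning into coverage gaps —
  the same convention by which EX1-flagged peptides are treated as "no
  difference" (their centroid shift conflates population transfer with
  uptake, so an EX2-style $\Delta$ is not meaningful).

## Residue projection

Peptide-level differences are projected to residues by averaging over
overlapping peptides:

$$
\mathrm{res}_j = \frac{1}{N}\sum_{i=1}^{N} \frac{\mathrm{pep}_i}{\mathrm{amide}_i}
$$

where the $N$ peptides are those in which residue $j$ is an *exchanging*
position (first residue and prolines excluded), $\mathrm{pep}_i$ is the
peptide summary difference and $\mathrm{amide}_i$ its exchanging-amide
count. Uncovered residues are reported as gaps, never zero. The projection
is linear in the peptide deltas and is verified against an independent
brute-force loop over (residue, peptide) pairs on a thousand random maps.

Because each peptide spreads its difference uniformly over its amides, a
sharply protected segment produces a trapezoidal per-residue profile whose
shoulders extend one peptide length beyond the true boundaries.
`call_protected_regions()` therefore defaults to a **half-maximum
threshold** (`min_abs = max|res_j| / 2`), the FWHM-style boundary rule
that undoes this spreading for an isolated feature; maximal runs of at
least `min_run = 5` consecutive covered residues of uniform sign are
reported. An absolute `min_abs` (Da/residue) can be supplied instead when
several features of very different magnitude coexist — a known limitation
of the relative rule.

## EX1 classification

`fit_envelope()` fits, by least squares against the observed envelope,
a single binomial and a two-binomial mixture (each convolved with the
natural envelope), selecting between them with the BIC-like criterion
$K\log(\mathrm{RSS}/K) + n_{par}\log K$ over the $K$ isotope channels.
Optimisation is deterministic: Brent for the single mode (initialised
from the centroid), L-BFGS-B from a small fixed grid of starts for the
mixture, with the canonical ordering $p_{low} < p_{high}$.

`classify_kinetics()` calls a peptide EX1 only when three signatures
co-occur: the mixture is preferred at $\ge 2$ consecutive exposures, the
mode separation $n(p_{high}-p_{low})$ is at least `delta_min = 2` Da
(below which two binomials are statistically indistinguishable from one
at realistic noise), and the low-mass weight $w_{low}$ is non-increasing
in time — the monotone population transfer that defines correlated
whole-segment exchange. Gradual centroid drift (EX2) fails the first two;
flat envelopes are ambiguous. This classifier is an analogue, not a
reimplementation, of interactive bimodal-analysis tools; its false-EX1
rate on pure-EX2 simulations is held at or below 5 %.

## Cross-link logic

Link identity is the canonical position pair (positions ordered, scores
ignored), because presence across fractions is what carries information.
Links unique to the monomer-enriched fraction are putative
intra-molecular contacts, links unique to the dimer-enriched fraction
putative inter-molecular ones. The admissible chemistry for
amine-reactive (BS3-style) cross-linkers is K–K, K–S, K–Y, K–T,
order-insensitive. A link between the same position on both peptides is
logically possible only between two protein copies, so self-links are
annotated inter-molecular wherever they occur, and a self-link landing in
the monomer-unique set is surfaced as an inconsistency report rather than
silently reassigned. Links present in both fractions are kept as an
explicit `shared` set — an extension beyond the usual unique-set
reporting, so the three sets always partition the union.
`hdx_concordance()` scores the fraction of inter-links with an endpoint
within `window` residues of a protected region; it is monotone
non-decreasing in the window by construction. No 3-D distance filtering
is attempted: no structure enters this analysis.

## Construct toolkit and the packaged BRD4 sequence

Intact masses are residue sums plus one water, on the average scale by
default (the scale of intact-mass tables; the monoisotopic table is
included), with UniMod shifts for phospho (+79.98 average) and acetyl
(+42.04). Heptad content of an interval is `floor(length/7)`;
`heptad_register_score()` scores the fraction of a/d core positions
occupied by hydrophobic residues (A, I, L, M, F, V, W, Y), maximised over
the seven register phases with ties to the smallest phase. Coordinates
are 1-based inclusive throughout. The CK2 consensus is S/T-x-x-E/D; the
scanner reports both serine and threonine sites, while the packaged
mutant helpers act on serines (the phospho-deficient constructs of
interest are serine-to-alanine mutants).

The packaged file `O60885_1-722_reconstructed.fasta` carries the
N-terminal 722 residues of human BRD4 (the isoform-C span). It is a
**reconstruction**, prepared without database access, and is validated by
every independent anchor available: lysine 519 falls mid-coiled-coil;
the BD2 WPF shelf sits at 374–376; the NPS cluster contains exactly 7
consensus serines and the CPS cluster exactly 6 (the 7A/6A mutant sites);
the inter-construct segment masses (531–579: 5,863.8 Da; 580–722:
16,038.8 Da) and the coiled-coil-deletion mass difference close on the
published construct tables to 0.1 Da. The low-complexity BD1–BD2 linker
(roughly residues 169–330) has no such anchor and is the region least
certain in this reconstruction.

One empirical caveat is worth stating plainly: published "theoretical"
masses of expression constructs routinely include an uncleaved
purification tag. For the construct family modelled here, the bare
1–N chain masses computed by `intact_mass()` sit a *constant*
1,845.9 Da below the published theoretical values of all three
constructs — consistent with one shared N-terminal His/TEV-site tag that
was never removed (and with the insect-cell rows sitting exactly one
glycine, +57.0 Da, higher still). Since the tag's sequence is not
published, `hdxdimer` reports bare-chain masses and exposes
`mass_options(adduct = )` for users who know their construct's tag mass;
all *differences* between constructs (segment masses, mutant shifts,
deletion masses) are tag-free and reproduce the published tables.

## NanoBRET and hydrodynamics

milliBRET is $1000 \times A_{610}/D_{450}$, invariant under common
scaling of the two channels. The titration model is the one-site-total
form $Y = B_{max}X/(K_d+X) + N_S X$; dose–response curves use the
four-parameter logistic
$Y = Bottom + (Top-Bottom)/(1+10^{(LogX_{mid}-X)\,h})$ with the midpoint
labelled EC50 or IC50 purely by curve direction. Fits use
Levenberg–Marquardt least squares with data-driven initialisation (extrema
for the asymptotes, half-range crossing for the midpoint) and a positivity
bound on $K_d$; the 4PL canonical form keeps $Top > Bottom$ with the
direction in the Hill slope's sign, resolving the swap degeneracy.

Sedimentation utilities implement
$s_{20,w} = s_{obs}\,(\eta_b/\eta_{20,w})
\,(1-\bar v\rho_{20,w})/(1-\bar v\rho_b)$ and the Svedberg/frictional
relations $f = M(1-\bar v\rho)/(N_A s)$,
$f_0 = 6\pi\eta r_0$, $r_0 = (3M\bar v/4\pi N_A)^{1/3}$ with
$\bar v = 0.73$ cm³/g by default and hydration ignored (the
anhydrous-sphere convention of common c(s) software). These are
consistency utilities: inverting experimentally fitted c(s) distributions
is out of scope, so measured sedimentation tables are not reproduction
targets.

## What the simulator does and does not establish

The generator reproduces the *structure* of a differential HDX study —
overlapping peptic coverage, triplicate centroids with Gaussian noise,
state-dependent protection, EX1 bimodality, saturating kinetics — under
the study conditions wired into its defaults (triplicates; exposures
0.05/0.5/50/180 min; $f_D = 0.862$; 0.05 Da centroid noise; a 22-residue
segment protected 20-fold against a 50-fold baseline in a 150-residue
construct for the recovery benchmarks). It does **not** emulate
peptide-identification errors, chromatographic carry-over, intensity-
dependent centroid bias, proline-rich coverage holes, or correlated
replicate drift. Passing recovery tests therefore demonstrates the
correctness and statistical behaviour of the analysis chain, not the
instrument-level robustness of any laboratory pipeline.

Problem sizes used by the test-suite and the acceptance script —
150-residue constructs, ~50-peptide maps, 20-seed recovery panels,
100 + 100 peptides for the kinetic classifier — were chosen as the
smallest sizes at which the benchmarked proportions are statistically
meaningful.

## Reproducibility contract

Every stochastic entry point takes an explicit seed and restores the
caller's RNG state. `hdx_report()` stamps outputs with the seed and an
MD5 hash of the full configuration; re-running with identical inputs is
byte-identical, and the test-suite asserts this.
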