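---
title: "Grid-based 3D-QSAR for phthalate ester toxicity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based 3D-QSAR for phthalate ester toxicity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Phthalate esters (PAEs) — dialkyl and diaryl esters of
benzene-1,2-dicarboxylic acid — are ubiquitous plasticizers whose acute
and cellular toxicity varies strongly with the length and branching of
the two ester chains. `paeqsar` implements a comparative molecular field
workflow over a small PAE panel with three endpoints: rat acute oral
LD50 (mg/kg, modeled as lgLD50 = log10), the 72-h HepG2 IC50 (µM,
modeled as lgIC50), and relative Nrf2 protein content (a dimensionless
ratio near 1, modeled untransformed).

The modeling chain is the classical CoMFA/CoMSIA one:

1. one minimized 3D conformer per compound, with Gasteiger partial
   charges, Crippen atomic logP contributions as hydrophobicity weights,
   and rule-based H-bond donor/acceptor flags;
2. rigid least-squares superposition of every compound onto the dimethyl
   phthalate (DMP) template over the shared 12-atom
   benzene-1,2-dicarboxylate core, with the two symmetry-equivalent arm
   mappings resolved by minimum core RMSD;
3. molecular interaction fields on a rectangular grid enclosing the
   aligned ensemble. CoMFA: Lennard-Jones 6–12 steric energy of an sp³
   carbon probe and a Coulomb electrostatic term
   $332\,q_p q_i/(\varepsilon(r)\,r)$ with the distance-dependent
   dielectric $\varepsilon(r) = r$, both truncated at ±30 kcal/mol, the
   electrostatic value replaced by its across-compound column mean at
   sterically excluded points. CoMSIA: Gaussian similarity indices
   $A_F(q) = -\sum_i w_{p}\,w_i\,e^{-\alpha r_{iq}^2}$ for steric
   (vdW-volume weights $r_{vdW}^3$), electrostatic (charges),
   hydrophobic (atomic logP), donor and acceptor (0/1 flags)
   properties — smooth and cutoff-free;
4. low-variance column filtering, block scaling (each field divided by
   the overall standard deviation of its retained entries), PLS1
   regression (NIPALS), leave-one-out q², and the training statistics
   r², SEE = √(SSE/(n−c−1)) and F = [(SST−SSE)/c]/[SSE/(n−c−1)];
5. Tropsha's seven external-validation conditions, a leverage-based
   applicability domain with Williams-plot classification, and
   StDev·Coefficient contour fields.

The central scientific assumption is the usual one for field-based
QSAR of a homologous series: after core alignment, the biological
response is a linear function of a few latent directions of the
(many, collinear) grid descriptors.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| grid spacing | 2.0 | Å | the standard CoMFA region default; halving it quadruples runtime with little change in PLS fits |
| grid margin | 4.0 | Å | standard padding so fields decay inside the box |
| steric probe | sp³ C, R 1.70 Å, ε 0.107 kcal/mol | — | conventional CoMFA probe |
| probe charge / weights | +1 | e / — | conventional |
| CoMFA cutoff | 30 | kcal/mol | conventional truncation; also applied to the Coulomb term |
| CoMSIA α | 0.3 | Å⁻² | the literature default attenuation |
| min-sigma filter | 2.0 (CoMFA), 0.1 (CoMSIA) | field units | drops columns whose cross-compound SD is noise-level |
| max components | 5 | — | training sets here are as small as 5 compounds |
| parsimony margin | 0.05 | relative q² | see *Component selection* |
| h\* | 3k/n | — | leverage warning threshold, k = latent variables |
| Y-outlier bound | 2.5 | SD | standardized-residual threshold |

## Conformers: why "extended sketch", not global minimum

Two observations drove the default conformer strategy
(`embed_compounds(mode = "extended")`):

* A global lowest-energy search (kept as `mode = "ensemble"`) lets every
  flexible ester coil its chains differently. The resulting steric
  fields vary idiosyncratically across the homologous series, which is
  conformational noise, not signal. The original workflow minimized
  *sketched* structures with a local optimizer, which keeps chains
  extended; we emulate exactly that: one start with every acyclic
  torsion at 180°, then local MMFF94 minimization (gradient tolerance
  0.005 kcal/(mol·Å), ≤1000 iterations).
* The two ring–carboxylate torsions each relax out of plane with an
  arbitrary sign, producing four near-degenerate, non-superposable twist
  states. The backend therefore minimizes all four sign combinations as
  deterministic starts, and the aligner keeps whichever minimized twist
  superposes best on the template core. With this, the 13-compound core
  RMSD stays ≤ ~0.05 Å across embedding seeds instead of splitting into
  ~1 Å clusters.

Gasteiger charges stand in for Gasteiger–Hückel (the π correction is
proprietary) and MMFF94 for the Tripos force field; both substitutions
follow the stated optimization settings.

## Component selection

`select_components()` scans 1..5 latent variables by LOO q² and picks
the smallest count within 5% (relative) of the best q². The strict
argmax variant (`parsimony = 0`) systematically buys an extra component
or two on ~15% of small-n replicates for q² gains of order 0.02 —
smaller than LOO resampling noise. The 5% margin is the long-standing
CoMFA practice.

On the packaged endpoints, automatic selection is deliberately
conservative (1–2 latent variables). The published models used k = 3
(their applicability-domain threshold 3k/n = 0.692 for n = 13 says so),
and `build_qsar_model(..., n_components = 3)` reproduces that model
size; its q² is then reported as computed, whatever it is. Published
q²/SEE/F and field-contribution percentages depend on the original
software's internals (grid placement, charge scheme, defaults) and are
*not* reproduction targets; the test suite checks properties (oracle
equivalence with least squares at full rank, exact naive-loop LOO
equality, leverage against brute-force inversion, and so on) instead.

## The applicability domain

Leverage is computed in the PLS latent-score space,
$h_i = t_i (T^\top T)^{-1} t_i^\top$, because the raw descriptor matrix
has far more columns than compounds (XᵀX singular); this also makes
k in h\* = 3k/n equal the number of latent variables, consistent with
the printed thresholds. Leverages for the Williams plot are computed
over the combined train+test score matrix; standardized residuals use
the population (n-denominator) SD. Classification is strict: a compound
at exactly h\* is in-domain. (Note the printed threshold 1.28 for n = 7
disagrees with 3k/n = 1.2857 at the second decimal; the formula is
implemented as stated, not as printed.)

## What the synthetic generator does and does not establish

`gen_latent_pls_data()` draws X = T Pᵀ + E, y = T c + e with orthonormal
factor scores, a geometric variance ladder across factor loadings
(amplitudes 2^(f−1)..1) and response coefficients scaled inversely to
the ladder. The ladder matters: with equal-variance factors a single
PLS component can blend all of them and the factor count is
unidentifiable *in principle* — no selection rule could recover it. The
ladder + inverse coefficients make every factor contribute comparably
to y while forcing later latent components to reach the low-variance
ones, so "f planted factors" genuinely means f recoverable components.
Noise is i.i.d. Gaussian with the response noise parameterized as
SNR = var(signal)/var(noise).

`gen_homologous_series()` emits linear di-n-alkyl phthalates (chain 1 =
DMP) with a synthetic endpoint a + b·k rising with chain length k,
matching the direction of the measured lgLD50 series; defaults a = 3.5,
b = 0.1 put values in the observed range. `gen_ad_fixture()` plants
leverage/residual outliers exceeding their thresholds by ≥20% and tames
chance background outliers so the planted set is exactly the flagged
set.

None of these emulate real assay noise (CCK-8 variance, densitometry),
inter-lab LD50 heterogeneity, or conformational uncertainty — a green
test on synthetic data establishes the statistical machinery, not the
chemistry.

## Numerical choices and degenerate inputs

* NIPALS PLS1 is direct per component (no inner iteration is needed for
  a single response); extraction stops with an error if X is exhausted,
  and `select_components()` treats that as the end of the scan.
* LOO folds refit everything, including column centering; q² uses
  SS about the retained (n−1) training mean of each fold.
* `fit_pls()` refuses zero-variance responses, n < 3, and
  n_components > min(n−1, p); `model_stats()` refuses n−c−1 ≤ 0.
* Kabsch superposition uses SVD with the determinant correction, so
  reflections are never introduced; symmetry-equivalent core matches
  are scanned in lexicographic order and ties broken toward the first,
  making alignment deterministic.
* Grid points are enumerated x-fastest, and a grid box is snapped
  *outward* to spacing multiples, so enlarging the margin can only add
  points.
* The Coulomb term floors r at 0.1 Å and both CoMFA fields truncate at
  ±30 kcal/mol; nothing is ever infinite.
* Contour region extraction takes percentiles of the *signed nonzero*
  StDev·Coefficient distribution (favorable above the 80th, unfavorable
  below the 20th) and groups points by 6-neighborhood; a constant field
  warns and returns no regions.

## Known limitations

* Absolute reproduction of the published model statistics (q² 0.522
  etc.) is out of reach without the original software; the package
  reproduces the printed *data* exactly and the printed *model size*,
  and reports its own statistics honestly.
* The electrostatic field contributes little here because Gasteiger
  charges make the homologous series' core charge distributions nearly
  identical; published contribution percentages (e.g. E = 41.6%) are
  not reproduced.
* The IC50 CoMSIA reference-prediction column is internally
  inconsistent for five compounds (DNP, DIDP, DHXP, DNOP, DPHP:
  Exp − Pred ≠ printed Res, values appear row-shifted);
  `flag_residual_anomalies()` records, and nothing corrects, this.
* With 5-compound training sets (IC50, Nrf2) every statistic is fragile;
  the Tropsha battery on 2-compound test sets is reported but close to
  meaningless, which is a property of the data, not the implementation.
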