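---
title: "Models and methods: enzymatic-fingerprint annotation and cell-wall omics integration"
author: "glycowall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycowall)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the design choices that were
genuinely open, and what the synthetic-data validation does and does not
show.

## The ion model

Neutral oligosaccharides ionize in positive-mode MALDI from a
DHB-type matrix almost exclusively as sodium adducts. The package
therefore models every annotated peak as the [M+Na]+ ion of the
unreduced oligomer:

$$ m/z = \sum_i n_i M_i + M_{\mathrm{H_2O}} + M_{\mathrm{Na}} $$

over anhydro residue masses (Hex 162.0528, Pen 132.0423, dHex 146.0579,
HexA 176.0321 Da) and ester group masses (acetyl 42.0106, methyl
14.0157 Da). No other adducts (K+, H+) are modelled by default; the mass
table is overridable (`residue_masses(override_file)`), so a potassium
adduct series is one substitution away.

Two points deserve emphasis:

* **Nominal m/z is a truncation.** Comparing the model against every
  annotated ion shows that the reported integer m/z values drop the
  decimal part of the monoisotopic mass rather than rounding it: XLFGa1
  computes to 1597.51 and is reported as 1597, XLFGa2 to 1639.52 and is
  reported as 1639, while all ions with decimal parts below 0.5 agree
  under either convention. `nominal_mz()` therefore truncates toward
  zero.
* **One annotation is internally inconsistent.** The letter grammar puts
  XLGa1 at 995.31 (nominal 995), yet the ion list reports it at 1451 —
  which is exactly XLLGa1 (1451.45). The package does not force-fit
  this: `sodiated_mass("XLGa1")` answers 995, and the discrepancy is
  treated as a naming slip in the source material.

## Composition search and its ceilings

`enumerate_compositions()` inverts the mass model by exhaustive search.
Unbounded, the inverse problem is ill-posed, so the search space is
limited by structural ceilings: at most 12 glycosyl residues (the
annotated space spans DP 4–8 hexo-oligomers and up to 5 pentoses),
acetyl ≤ backbone (Hex+Pen) residues, methyl ≤ uronic acids (methyl
esters ride on uronic acids), and uronic acids ≤ backbone residues. The
last ceiling encodes that uronic acids occur here as glucuronoxylan-type
substituents, never as free uronic homo-oligomers; without it, a
hypothetical HexA trimer at 569.10 would shadow the real isobaric pair
at m/z 569. That pair — Hex3a1 and Pen4, identical elemental formulae —
is a genuine chemical ambiguity and is always reported as such.

Digest-default annotation libraries additionally cap acetylation at 2,
matching the observed annotation space; the `"unconstrained"` mode lifts
that cap for exploratory matching.

## Annotation tolerance and reference normalization

The default matching tolerance is ±0.3 Da. A reflectron TOF externally
calibrated with galactomannan oligomers (DP 3–9) holds peak positions
well within ±0.5 Da over m/z 500–3000, and the closest spacing between
library compositions that must be distinguished is about 1 Da, so 0.3 Da
separates neighbours while tolerating realistic jitter (the synthetic
generator's default jitter of 0.05 Da is far inside it). The tolerance
is an explicit argument everywhere.

Intensities are normalized per spectrum to a digest-specific reference
ion (glucanase 1085 = XXXG, mannanase 731 = Hex4a1, xylanase 655 =
Pen3U1a1). When several peaks fall within the matching window of the
reference m/z, the most intense is taken — reference ions are major
fragments, so the rule is stable. Only intensities are normalized; a
"normalization of masses" is not a defined operation and is not
implemented. Replicate spectra (three spots per hydrolysate) are kept as
separate rows of the intensity matrix; averaging before PCA is left as
an explicit downstream choice because the sample axis of the original
fingerprint PCA (replicates vs replicate means) is not documented.

## Composition accounting

NSP is total AIM sugar minus starch glucose, floored at zero. Unit
discipline is enforced mechanically: every analyte column of a
`composition_table` carries a `%AIM`, `%NSP` or `DM` tag and
`check_same_unit()` refuses arithmetic across tags.

The degree of methylesterification converts weight percentages to a
molar ratio with methanol at 32.042 g/mol and galacturonic acid as the
**anhydro residue**, 176.126 g/mol. The free-acid mass (194.14) is
rejected because only the anhydro convention reproduces the published DM
values from the published methanol and uronic-acid contents (68.7
recomputed vs 69.2 published at 60DAF; 51.2 vs 52.2 at 2M, both within
the rounding of two-significant-figure inputs).

Release fractions divide a treatment's released sugar by that sugar's
initial content, both in %NSP. A zero initial content is reported as an
error, not as zero — a zero release is a measurement, an undefined
fraction is not. Reconstruction of the published fraction panel from the
published release panel succeeds to ±0.3 wherever the inputs are well
measured; for trace sugars printed with one decimal (e.g. 0.1 %NSP) the
attainable agreement is bounded by input rounding, and the package's
tests propagate that bound rather than pretending to more precision than
the inputs carry.

Stage effects on chemical data use classical one-way ANOVA at the
study's severe p < 1e-4 gate, plus the three named contrasts (60DAF vs
H, H vs 2M, 60DAF vs 2M) reported as letter flags.

## The moderated t-test

The differential engine is a two-group empirical-Bayes moderated t.
Gene-wise residual variances $s_g^2$ (df $d_g$) are modelled as draws
from a scaled inverse-chi-square prior with scale $s_0^2$ and df $d_0$,
estimated by moment matching on $e_g = \log s_g^2 - \psi(d_g/2) +
\log(d_g/2)$: the mean of $e_g$ identifies $s_0$, the excess of its
variance over $\psi'(d_g/2)$ identifies $d_0$ through the trigamma
inverse (Newton iteration on the $1/x$ scale). The posterior variance
$(d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)$ — always between $s_g^2$ and
$s_0^2$ — replaces $s_g^2$ in the t-statistic, referred to
$d_0 + d_g$ df. The limiting cases are exact: $d_0 = 0$ reproduces the
ordinary pooled t-test, $d_0 = \infty$ (estimated when variances are
exchangeable) uses the common $s_0$. The test suite verifies both
limits, calibration (type-I error 0.01 ± 0.003 at α = 0.01 over 10,000
null genes; null p-values uniform by Kolmogorov–Smirnov), and agreement
with the independent reference implementation in `limma`.

Background correction of two-colour arrays is modelled as simple
subtraction floored at a small positive constant — a stand-in, since no
estimator is documented for the original arrays; headline counts that
depend on it (expressed-probe fractions, total differential transcripts,
manually curated profile selections) are deliberately not asserted
anywhere. Probe cross-hybridization classes and antisense probes are out
of scope; the synthetic design has neither.

Quantile normalization maps each within-column rank to the cross-column
mean of that rank's values; ties share the average of the reference
values their ranks span. It is idempotent and rank-preserving, both
tested. Lowess detrending of M against A uses span 0.15: narrow enough
to track bias varying over a fraction of the intensity range, wide
enough to average hundreds of probes per window on a full-size array.

## Clustering, networks, integration

Expression profiles are clustered with distance $1 - r$ (Pearson) and
average linkage, making the result invariant to per-gene scaling and
shifting; merge ties follow the deterministic lowest-index convention of
`hclust`. Correlation networks admit an edge when p < 0.01 and r > 0.7
(gene networks, positive mode — co-expression is the object of
interest) or |r| > 0.7 (biochemistry integration, absolute mode —
negative correlations between early genes and late-rising sugars are
exactly the signal). No multiple-testing adjustment is applied to edges
by default, matching the study's raw thresholds; a Benjamini–Hochberg
switch exists but defaults off. Gene–gene correlations are computed
across all per-genotype stage series jointly (the 8 genotypes × 2 plots
design read as 16 series over 5 stages), which puts enough observations
behind each edge that the r > 0.7 gate is conservative.

For integration, the eight genotypes are averaged into three fixed pools
(V034/I062/V083, W029/I095/H097, H074/I016) so the expression axis
matches the three biochemical replicates per stage; pairing is by stage
and replicate/pool index. PCA is centred (optionally scaled) and is
tested to 1e-8 against an eigendecomposition of the covariance matrix.

## The synthetic study and what it shows

The generators emulate the study conditions: five stages × eight
genotypes × two plots; digest spectra planted from the annotated ion
rosters with lognormal intensity noise (CV 0.2), Gaussian m/z jitter
(0.05 Da) and optional uniform decoys kept ≥ 1 Da from planted masses;
composition tables interpolating the published stage endpoints (Gal
18.7→7.2, UA 22.4→29.0, Xyl 4.8→7.6, Man 4.4→3.1, Fuc 0.8→1.2 %NSP)
with replicate noise on the order of the published standard deviations;
expression matrices with cluster A elevated at 60/110DAF and cluster B
elevated at H/1M/2M (default shift 2 log2 units, residual sd 0.5).
Negative composition draws are resampled, never clipped. Every
generator is a pure function of (scenario, seed) and restores the global
RNG state.

Problem sizes in the shipped tests — hundreds to a few thousand genes, a
ten-gene module among 100, three replicate spectra per digest — are
chosen so the whole validation runs in seconds while keeping every
statistical check well-powered; the generators scale to the full 135k
probe design by changing one argument.

What passing means: the pipeline recovers planted compositions at 100%
under realistic jitter, recovers planted co-expression clusters exactly
at low residual noise, admits ≤ 2 false network edges around a planted
module, and reproduces the qualitative sign structure of the integration
(early genes positively correlated with declining galactose and
mannose, negatively with rising xylose and fucose; late genes opposite)
in ≥ 95% of seeded replicate runs. What it does not show: performance
under features real data have and the generators lack — correlated
probe effects, dye-specific bias beyond a smooth trend, isotopic
envelopes and in-source fragments in spectra, compositional closure of
percentage data, or the manual curation steps of the original gene
selection. Dataset-dependent headline numbers can therefore not be
reproduced from synthetic data and are not claimed.

## Degenerate inputs and numerical conventions

Empty compositions have a defined mass (water + sodium, 41.00 Da) but no
code. Constant profiles are rejected by correlation and clustering
functions with the offending gene named. Zero-variance columns stop
scaled PCA by name. A missing reference ion aborts normalization naming
the digest and expected m/z. The trigamma inverse converges in a few
Newton steps for any positive argument; `d0` overflows cleanly to
infinity when gene variances are exchangeable. Peak lists are read in a
closed acquisition window [500, 3000] — boundary peaks are kept.
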