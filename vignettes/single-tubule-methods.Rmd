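---
title: "Methods: phenotype-guided single-tubule proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-guided single-tubule proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubulomics)
```

The cortical collecting duct (CCD) is a short epithelial tube built from
principal cells (PCs: Na$^+$ reabsorption through ENaC, water transport
through AQP2/3/4) and type A/B intercalated cells (ICs: proton and
bicarbonate handling through the vH$^+$-ATPase, AE1, and pendrin). A single
microperfused CCD can be phenotyped electrophysiologically and then
processed for mass spectrometry, so that each tubule contributes both a
functional readout and a proteome. `tubulomics` implements that analysis
chain end to end, together with a ground-truth simulator that makes every
stage testable without any external data.

## Electrophysiology

**Cable analysis.** A perfused tubule is modelled as a finite, sealed-end
cable: the luminal fluid (resistivity $\rho$, default 60 $\Omega\,$cm for
physiological saline at 37$^\circ$C) is the core conductor and the
epithelium a distributed membrane of specific resistance $R_{te}$
($\Omega\,$cm$^2$). With core resistance per length
$r_c = 4\rho/(\pi d^2)$ and membrane resistance per length
$r_m = R_{te}/(\pi d)$, a constant current $I_0$ (default 13 nA) injected
at the perfusion end produces end deflections

$$\Delta V_0 = I_0\, r_c \lambda \coth(L/\lambda), \qquad
  \Delta V_L = \Delta V_0 / \cosh(L/\lambda), \qquad
  \lambda = \sqrt{r_m/r_c}.$$

`invert_cable()` solves this in closed form:
$\lambda = L/\operatorname{acosh}(\Delta V_0/\Delta V_L)$, then the input
resistance gives $r_c$, the diameter $d = \sqrt{4\rho/(\pi r_c)}$, and
$R_{te} = r_m \pi d$. The two-deflection sealed-end variant is a design
choice: it is the closed-form member of the cable-analysis family and the
natural counterpart of a double-barreled perfusion setup that records at
both ends. The inversion requires $|\Delta V_0| > |\Delta V_L|$; equal
deflections are rejected as non-invertible rather than silently producing
an infinite length constant.

**Ohm's law and amiloride.** The equivalent short-circuit current is
$I'_{sc} = V_{te}/R_{te}$ (mV over $\Omega\,$cm$^2$ mapped to
$\mu$A/cm$^2$), reported signed: all voltages in the package are lumen
minus bath, so a lumen-negative tubule has a negative $I'_{sc}$ and a
negative amiloride-sensitive voltage
$\Delta V_{te}(\mathrm{amil}) = V_{te,\mathrm{basal}} - V_{te,\mathrm{amil}}$.
Magnitudes are available trivially; the signed convention is kept
throughout because it makes the sign structure of all downstream
correlations explicit (for example, water-channel expression correlates
*positively* with basal $V_{te}$ precisely because $V_{te}$ is negative).

**Dilution potentials.** Replacing the bath with dilute NaCl (145 mM
lumen against 30 mM bath by default) generates a bi-ionic
Goldman–Hodgkin–Katz potential

$$V_{dp} = \frac{RT}{F}
  \ln\frac{\beta\,[\mathrm{Na}]_b + [\mathrm{Cl}]_l}
          {\beta\,[\mathrm{Na}]_l + [\mathrm{Cl}]_b},
  \qquad \beta = P_{Na}/P_{Cl},$$

which `pnapcl_from_dp()` inverts in closed form. A purely Cl$^-$-selective
shunt gives $+42.1$ mV at 310.15 K; $\beta = 1$ gives exactly zero. The
attainable interval is $\pm(RT/F)\ln(c_{ctrl}/c_{low})$; measured
potentials at the bounds return the boundary solutions 0 or $\infty$
flagged as such, and values outside the interval are errors
("permeability not representable"). Concentrations are used directly —
activity coefficients are ignored and liquid-junction correction is
assumed to have been applied upstream, both deliberate simplifications.

## Targeted (PRM) quantification

Transition-level quality control applies three requirements: mass error
strictly below 10 ppm, elution inside the scheduled acquisition window,
and coelution of a peptide's transitions. Coelution needs an operational
definition; the package uses median-anchored trimming: within each
(peptide, sample) group the transition whose apex is farthest from the
group median is discarded until the apex spread is at most 0.2 min
(default), and groups left with fewer than two transitions are dropped
because coelution is undefined for a singleton. Every rejected transition
carries exactly one reason code with precedence
`ppm` > `window` > `coelution` > `singleton`, which makes the filter
idempotent and its decisions auditable. Manual peak-shape validation of
the original workflow has no algorithmic equivalent; it is *not*
emulated.

Quantification is MS2-level summation — transition areas to peptides,
peptides to proteins — with empty cells left missing, never zero.
Normalisation is log$_2$ double-centering: subtract each sample mean, then
each protein mean, over observed entries (`double_center()`). One pass of
each zeroes both margins of a complete matrix exactly; sample loading and
protein ionisation efficiency are removed, leaving relative regulation.
No imputation is applied in targeted mode.

## Untargeted quantification

LFQ-like matrices are log$_2$-transformed and per-sample mean-centered
(`log_center()`). Remaining missing values are drawn from a downshifted
normal per sample, $N(\mu_s - 1.8\sigma_s, (0.3\sigma_s)^2)$ — the
standard left-censored imputation convention, reflecting that missingness
in nano-scale proteomics is dominated by low-abundance dropout. The
two-group comparison is a per-protein two-tailed Student (pooled
variance) $t$-test — the common default of the upstream analysis
environment, with Welch available by flag — vectorised over the matrix
and cross-checked against `stats::t.test()` in the unit tests.
Benjamini–Hochberg $q$-values are attached, and `hit_flag` requires both
$|{\log_2 \mathrm{fc}}| \ge 1$ and $p < 0.05$ by default (the cutoffs are
figure-level choices in such studies, so both are configurable).
Zero-variance proteins are flagged degenerate rather than assigned a
p-value.

iBAQ copy-number surrogates divide summed intensity by the count of
theoretically observable tryptic peptides: cleavage C-terminal to K/R
except before P, zero missed cleavages, peptide length 6–30 residues —
a documented convention, not a universal constant. Proteins with no
observable peptide get a missing iBAQ value, not a division error.

## Integration

Pearson correlation over pairwise-complete observations with a floor of
three shared observations per reported coefficient; zero-variance series
give missing coefficients. Marker heatmap order comes from agglomerative
clustering of the correlation-profile rows (Euclidean distance, average
linkage; the linkage is a design choice — Ward and complete linkage were
evaluated and recover planted marker blocks no better). PCA is
mean-centered SVD (`stats::prcomp`), run on normalised
(double-centered) intensities when the question is compositional.
Chord-diagram statistics summarise a protein-by-phenotype correlation
grid into per (cell class, phenotype) masses of positive and negative
coefficients separately, normalised to width 1 within each sign —
positive and negative contributions are deliberately not netted against
each other.

`covariation_vs_regulation()` pairs each protein's tubule-to-tubule
correlation with an anchor protein (pendrin) in wild-type data against
its knockout log$_2$ fold change, returning the scatter, the overall
Pearson $r$, quadrant counts, and permutation p-values (shuffling fold
changes over proteins) for both the correlation and the
$(x>0, y<0)$ count. In the canonical analysis the candidate set is the
transport-relevant markers on the normalised wild-type matrix;
housekeeping proteins act as normalisation references and are not
pendrin-covariation candidates — including them only injects fold-change
noise into the permutation null.

## The synthetic cohort generator

The simulator is a first-class, tested component whose defaults *are*
the study conditions: 12 wild-type tubules of 400–600 µm length and
15–30 µm diameter, knockout cohorts of 5 samples per genotype each
pooling 5 dissected tubules, a 46-protein marker panel plus 362
background proteins (a deliberate scale-down of a ~3,600-protein
proteome), true abundances spanning more than five orders of magnitude,
and intensity-dependent missingness calibrated to a 30% overall rate
with a steep detection-limit slope (logistic, 2 per log$_2$ unit).

Per tubule the generator draws an intercalated-cell fraction
(Beta(3.5, 5) on top of a negative logit-scale coupling to length — longer,
more medullary tubules carry fewer ICs), and four latent axes: a
water-versus-salt adaptation axis $z$ (vasopressin-type programs versus
ENaC activity; mildly coupled, $\rho = 0.4$, to the IC fraction so that
PC-poor tubules run each PC at higher Na$^+$-transport activity), a PC
program factor, a housekeeping/metabolic factor, and a type-B IC activity
factor shared by the pendrin module. Protein abundance multiplies a
baseline (defined at the reference composition) by a composition response
— class weight raised to a per-protein exponent, above 1 for most
markers to encode that cell-type programs covary supra-linearly with
cell-type mass, which is what makes same-class markers correlate strongly
with each other and composition dominate the first principal component —
a tubule-size factor (length × circumference), the latent loadings, and
log-normal noise (0.3 log$_2$ total, split into biological and
measurement parts). A per-tubule recovery/yield factor (0.4 log$_2$)
multiplies all measured intensities of a sample, mimicking single-tubule
processing losses; it is exactly removed by per-sample centering.

Phenotypes come from a two-conductance equivalent circuit,
$V_{te} = E\,g_t/(g_t + g_p)$, with the transcellular conductance
following ENaC membrane *density* (abundance per tubule surface) times
the latent activity, amiloride blocking 98% of $g_t$, and
$R_{te} = 1/(g_t+g_p)$. The defaults ($E = -140$ mV,
$g_{t0} = 0.9$, $g_{p0} = 5.5$ mS/cm$^2$) put simulated cohorts inside
the physiological ranges reported for mouse CCD (basal $V_{te}$ around
$-10$ to $-30$ mV, $|I'_{sc}|$ of order $10^2$ µA/cm$^2$, $R_{te}$
around 160 $\Omega\,$cm$^2$) while keeping the voltage divider in its
quasi-linear regime. Recordings are completed by forward-cable
deflections at 13 nA and GHK dilution potentials from log-normal planted
$P_{Na}/P_{Cl}$ ratios, each with small measurement noise. Running the
electrophysiology module on noise-free recordings recovers the true
$R_{te}$, diameter, and length constant to within 0.1%.

The knockout generator reduces the anchor (pendrin) to a noise-floor
signal, decreases an explicit four-protein module (CLCNKB, BSND,
ATP6V1G3, ATP6V1B1) by $-1.5$ log$_2$, applies a secondary profile of
moderate decreases across the vH$^+$-ATPase machinery and other IC
markers with AE1 unchanged and mild PC increases, and shifts the
knockout composition by $-0.5$ logit units toward fewer intercalated
cells — the remodeling direction reported for this model. Pooling five
tubules per sample is essential: at single-tubule composition variance a
$-1.5$ effect is statistically invisible at five samples per genotype.

**What the simulator does not emulate.** Raw spectra, retention-time
drift, isotope envelopes, peptide-level inference, shared peptides,
batch effects between acquisition blocks, and mouse-level random effects
beyond pooling. Passing recovery tests on this generator therefore shows
that the analysis chain is correct and well calibrated on data with the
study's statistical geometry — not that it is robust to every artefact of
real acquisitions.

## Numerical and design notes

- All generators are pure functions of (config, seed); seeded helpers
  restore the caller's RNG stream.
- Tables are TSV (UTF-8, one header, empty fields for missing values);
  sequences are FASTA; configs are YAML with unknown keys rejected.
- Problem sizes used by the test-and-acceptance battery: 125-point cable
  grid; 100-point GHK ladder; 50 random matrices for centering; 2,000
  null proteins × 50 repeats for t-test calibration; 200 replicate
  cohorts (n = 12) for coupling recovery against a 1,000-replicate
  Monte-Carlo oracle written directly from the generative equations; 100
  knockout cohorts (5 vs 5, 1,000 permutations each) for module and
  covariation recovery.
- Known limitations: the amiloride protocol also contains a thiazide
  component that is not modelled separately; absolute permeabilities
  ($P_{Na}$, $P_{Cl}$ individually) are out of scope; chord outputs are
  numeric only (rendering is left to dedicated circular-layout
  packages); marker-class block contiguity in clustered heatmaps holds
  for the default configuration and in roughly nine of ten random
  cohorts — at twelve tubules the sampling noise of a correlation
  estimate is large enough that single weakly-coupled markers
  occasionally stray.

## A minimal session

```{r example}
cohort <- generate_cohort(cohort_config(n_tubules = 12, seed = 1))
phen <- derive_phenotypes(cohort$recordings)
summary(phen[, c("Rte", "Isc", "dVte_amil", "pna_pcl")])

m <- log2(cohort$targeted)
round(cor(m["Scnn1b", ], phen$dVte_amil), 2)   # ENaC vs amiloride voltage

pc <- pca_matrix(double_center(cohort$targeted)$values, axis = "tubules")
round(abs(cor(pc$scores, cohort$truth$tubules$ic_fraction))[1], 2)
```
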