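---
title: "Partitioning photosynthetic electron flow: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning photosynthetic electron flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafflow)
```

## The measurement model

A pulse-amplitude-modulated fluorometer mounted on a gas-exchange cuvette
measures, for the same patch of leaf, net CO2 assimilation $A$ and the
light-adapted PSII operating efficiency

$$\Phi_{PSII} = \frac{F_m' - F_s}{F_m'},$$

where $F_s$ is steady-state fluorescence and $F_m'$ the maximum during a
saturating pulse. Electron transport rate follows as
$ETR = \Phi_{PSII}\, f\, I\, \alpha_{leaf}$ with $f$ the fraction of
absorbed photons reaching PSII and $\alpha_{leaf}$ the leaf absorptance.
The package defaults, $f = 0.5$ and $\alpha_{leaf} = 0.88$, are the values
conventionally assumed for healthy C3 leaves under red/blue actinic light;
both live in `fluoro_constants()` and are never hard-coded at call sites,
because $\alpha_{leaf}$ in particular varies with chlorophyll content and
any serious absorptance measurement should replace it.

Day respiration is taken as $R_l = R_d/2$, the standard allowance for
partial light suppression of mitochondrial respiration; $R_d$ is measured
once per leaf after >5 min darkness and ingested as a positive magnitude
(instruments log dark CO2 efflux as negative $A$; `dark_respiration()`
negates it). The factor 0.5 is an assumption, exposed as `rl_factor`.

## Calibration under 2% O2 and the partition

At 2% O2, Rubisco oxygenation is nearly abolished and linear electron flow
serves carboxylation almost exclusively, making $\Phi_{PSII}$ a linear
function of the quantum efficiency of CO2 fixation:

$$\Phi_{PSII} = k\,\Phi_{CO2} + b = \tfrac{k}{4}\,\Phi_{e^-} + b,$$

with 4 electrons per CO2. The method assumes this relation, fitted per
leaf over a stepwise light decrease (1000, 750, 500, 300, 200, 100, 50
µmol m⁻² s⁻¹), continues to hold in ambient air, and that linear electron
flow is devoted entirely to carboxylation plus oxygenation. Inverting it
gives $\Phi_{e^-} = 4(\Phi_{PSII} - b)/k$ and
$J_T = I\,\alpha_{leaf}\,\Phi_{e^-}$, and the stoichiometry (4 e⁻ per
carboxylation; 4 e⁻ per oxygenation with one CO2 released per two
oxygenations) closes the budget:

$$J_C = \tfrac13[J_T + 8(A+R_l)],\quad
  J_O = \tfrac23[J_T - 4(A+R_l)],\quad
  Pr = \tfrac1{12}[J_T - 4(A+R_l)].$$

These three outputs are algebraically dependent — `partition_flows()`
satisfies $J_C + J_O = J_T$, $J_O = 8\,Pr$ and $J_C = 4(A + R_l + Pr)$
identically, which the test suite checks on random inputs to $10^{-9}$
relative.

### The sign of respiration in $\Phi_{CO2}$

Two conventions for $\Phi_{CO2}$ circulate. The *net* form
$(A - R_l)/(I\alpha_{leaf})$ treats respiration as a debit; the *gross*
form $(A + R_l)/(I\alpha_{leaf})$ adds it back so the numerator equals
carboxylation minus photorespiratory release. Both are provided in
`phi_co2()` (`mode = "as_printed"` is the net form and the default there).
For the **calibration regression**, however, `run_leaf()` and
`pipeline_partition()` default to the gross form, and we consider this a
substantive choice rather than a preference: at low O2,
$A + R_l = V_c - \tfrac12 V_o \approx J/4$ is proportional to
$\Phi_{e^-}$, so the calibration points lie exactly on the assumed line,
whereas the net form subtracts a further $R_d/(I\alpha_{leaf})$ term that
varies as $1/I$ across the light steps and visibly bends the low-light end
of the line (at $I = 50$ it is of the same order as $\Phi_{CO2}$ itself).
The partition equations above add $R_l$ to $A$, so the gross form is also
the internally consistent one. The mode used is recorded in every
`phi_calibration` object.

### Other estimation choices

- **Per-leaf calibration** is the default (`partition_leaves()` splits by
  `plant_id`): the protocol measures calibration and ambient phases on the
  same leaf, and pooling across leaves would confound leaf-to-leaf
  absorptance differences into $k$.
- **Regression direction**: OLS of $\Phi_{PSII}$ on $\Phi_{CO2}$, exactly
  the form of the calibration equation; no errors-in-variables correction
  is attempted. Under instrument noise on $A$ this attenuates $k$
  slightly; averaging the readings taken at each light step before the fit
  (`average_per_light = TRUE`, default) reduces that bias to well under 1%
  at the default noise levels.
- **Negative $Pr$** (possible under noise when $J_T < 4(A+R_l)$) is
  reported as-is with a `negative_oxygenation` flag, never clipped:
  clipping would bias genotype means upward in exactly the comparisons the
  method exists for.
- **$R_l$ at 2% O2** reuses the single $R_d$ measured in darkness at
  ambient O2, as the protocol measures respiration once per leaf.
- **Steady states**: the instrument practice of waiting for "stable"
  readings is operationalized in `steady_state_average()` as a window of
  `window = 3` consecutive readings whose $A$ and $g_s$ each spread less
  than `rel_tol = 0.02` around the window mean — a reproducible stand-in
  for an operator judgment, and deliberately configurable since no
  numerical criterion is canonical.

## What the simulator emulates

`simulate_leaf()` generates the full two-phase protocol with known ground
truth. Potential electron flow follows a non-rectangular hyperbola — the
smaller root of
$\theta J^2 - (\phi_{e,0} I + J_{max})J + \phi_{e,0} I J_{max} = 0$ —
with defaults $J_{max} = 120$ µmol e⁻ m⁻² s⁻¹, initial slope
$\phi_{e,0} = 0.3$ e⁻ per incident photon and curvature $\theta = 0.7$,
typical of a well-watered Arabidopsis rosette (giving $A \approx 18$
µmol m⁻² s⁻¹ at saturating light, 400 ppm CO2). Flow is split by a fixed
oxygenation fraction $\phi = V_o/V_c$ (0.25 in ambient air, matching the
roughly 20–30% of C3 carbon gain lost to photorespiration at moderate
temperature; 0.01 at 2% O2, reflecting small residual oxygenation — a
strict-zero mode exists for exact tests). Then $V_c = J/(4(1+\phi))$,
$V_o = \phi V_c$, $A = V_c - \tfrac12 V_o - R_d/2$, so by construction
$Pr = V_o/2$, $A_{gross} = V_c$, $J_C = 4V_c$, $J_O = 4V_o$ and
$J_C/J_O = 1/\phi$.

Fluorescence is emulated *through the calibration relation itself*:
$\Phi_{PSII} = b_{true} + (k_{true}/4)\,J/(I\alpha_{leaf})$ with defaults
$k_{true} = 9$, $b_{true} = 0.05$, then $F_m' = 1000$ and
$F_s = F_m'(1-\Phi_{PSII})$. This is deliberate: the estimation method
*assumes* that linearity, and the simulator instantiates the assumption so
that forward simulation followed by the full pipeline returns the
configured $(k, b)$ and ground-truth $Pr$, $J_C$, $J_O$ to numerical
precision at zero noise — an exactness the tests rely on. The
corresponding limitation is that the simulator cannot reveal how the
method degrades when the linearity itself fails (variable absorptance,
alternative electron sinks such as nitrate reduction or the Mehler
reaction, state transitions): passing round-trip tests certify the
estimation chain, not the physiological assumption. Likewise there is no
temperature or $C_i$ dependence, no stomatal dynamics, and no
within-curve drift; observation noise is independent Gaussian
($\sigma_{\Phi_{PSII}} = 0.01$, $\sigma_A = 0.3$ µmol m⁻² s⁻¹ by default,
the magnitudes a stable cuvette delivers), with $\Phi_{PSII}$ truncated to
$[0, 0.999]$.

Under those noise defaults, 200 simulated leaves at $\phi = 0.25$ recover
$Pr/A_{gross}$ with a median absolute relative error of about 7% (the
acceptance script recomputes this), and seed-averaged estimates increase
strictly with $\phi$ over 0.1–0.4.

## The trait study layer

`simulate_study()` draws a genotype × replicate trait table as
baseline × effect × $(1 + \mathcal N(0, cv))$ — six biological replicates
and $cv = 0.05$ by default, with wild-type baselines chosen as typical
8-week Arabidopsis rosette values (`default_trait_baselines()`).
`study_report()` then mirrors how such studies are reported: per-trait
percent change against the reference genotype with two-sided t-tests
(pooled by default; Welch available), normality (Shapiro–Wilk) and
variance-homogeneity (Levene) checks that are *reported but never gate*
the test, and no multiple-testing correction by default (per-trait testing
at $P < 0.05$ is the field's reporting convention; `p_adjust = "holm"` is
available and off by default).

PCA (`pca_traits()`) standardizes traits and decomposes the correlation
matrix, so eigenvalues sum to the trait count and the variance explained
is invariant to units. The observation unit is a genuine choice:
replicate-level rows (default) measure within-genotype structure too,
while genotype means — four points for four genotypes — force almost all
variance into two components and match reports where PC1+PC2 explain
nearly everything; both modes are provided because published loadings
tables rarely state which was used. Eigenvector signs are arbitrary, so
each component is flipped to make its largest-magnitude loading positive,
and any comparison with published loadings should be made on absolute
values.

The germination stress-tolerance index has no single canonical formula;
the default is the transparent ratio
$100 \cdot \text{final}_{stress}/\text{final}_{control}$, with a
time-weighted promptness variant (`method = "timed"`, weights $1/t$) for
assays where earliness matters.

## Numerical and degenerate-input behavior

Calibration requires ≥ 3 points and nonzero variance in $\Phi_{CO2}$;
non-positive slopes are flagged, not rejected. $J_O = 0$ yields an
infinite $J_C/J_O$ with a flag rather than an error, and $A_{gross} = 0$
marks the ratio undefined. File ingest flags physically impossible rows
($F_s > F_m'$, $F_m' \le 0$, negative conductance) instead of dropping
them. All problem sizes used by the tests and the acceptance script —
10,000 random triples for the algebra, 200 noisy leaves, 500 simulated
studies, 40 seeds per oxygenation level — were chosen to make the checks
statistically stable while keeping the default suite fast on a laptop.
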