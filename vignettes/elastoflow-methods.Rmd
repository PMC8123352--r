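---
title: "Quantitative quasi-static elastography with elastoflow: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative quasi-static elastography with elastoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

`elastoflow` reconstructs the spatial distribution of the Young's modulus of
a soft specimen from two inputs only: a B-mode CINE sequence recorded while a
rectangular ultrasound transducer slowly compresses the specimen, and a
load-cell log of the compressing force. No radio-frequency data are needed.

The material is modelled as isotropic, nearly incompressible and locally
homogeneous linear elastic. Under a purely axial compressive stress
$\sigma_0$ with all other stress components zero, Hooke's law collapses to
$\varepsilon_{zz} = \sigma_0 / E$, so the modulus follows pixel-wise from

$$E(x, z) = \frac{\sigma_0(x, z)}{\varepsilon_0(x, z)},$$

with the stress taken from an analytic model of the loading and the strain
measured from the images. Mild strain stiffening can be absorbed by an
exponential (Veronda–Westmann-type) apparent modulus
$E_{NL} = E\,e^{3\gamma\varepsilon_0^2}$; with `gamma > 0` the pipeline
divides this factor out and reports the linear modulus. The in-plane
(two-dimensional) Poisson's ratio $\nu' = -\varepsilon_{xx}/\varepsilon_{zz}$
is converted to the physical three-dimensional ratio by
$\nu = \nu'/(1-\nu')$, and moduli convert to the clinically familiar
shear-wave speed through $c_t = \sqrt{E / (2\rho(1+\nu))}$.

Note on the strain ratio: the 2D Poisson's ratio is the ratio of the
*lateral* to the *axial* strain magnitude. Writing it with the indices the
other way round (axial over lateral) would give its reciprocal; the package
consistently uses $\nu' = -\varepsilon_{xx}/\varepsilon_{zz}$ for axial
compression along $z$.

## The four pipeline stages

**1. Displacement.** A dense optical-flow estimator tracks the speckle
pattern from the unloaded reference frame to every later frame. Because the
accumulated deformation eventually decorrelates the images, each new field is
scored by the 2D Pearson correlation $\rho$ between the reference and the
back-warped target; when $\rho$ drops below `rhoMin` (default 0.9) the
current frame becomes the new reference and the accumulated displacement is
composed with all further fields. Composition is proper warp composition
$u_{tot}(x) = u_{acc}(x) + u_{new}(x + u_{acc}(x))$ with bilinear sampling —
naive pixel-wise addition is wrong in Eulerian coordinates for large motion
and is kept only as a debug mode (`compose = "add"`). The package ships two
backends behind one interface (`flowBackends()`): a pyramidal iterative
Lucas–Kanade estimator (default) and a pyramidal Horn–Schunck estimator.
Frames are Gaussian-blurred (`blurSigma`, default 1 px) before tracking.
If even directly consecutive frames fall below
`min(rhoMin, abortFloor)` (`abortFloor` = 0.5) the sequence is declared
untrackable and the run aborts: redefining the reference can never do better
than consecutive-frame tracking. The 0.5 floor separates "switch the
reference often" (a legitimate regime, e.g. `rhoMin = 1`) from "the image
content is gone" (pure decorrelation), which a threshold at `rhoMin` itself
could not, since `rhoMin = 1` must still complete.

**2. Strain.** The displacement gradients are estimated with a 2D
Savitzky–Golay first-derivative filter: each row of the $(2M{+}1)\times(2M{+}1)$
kernel is $h(x) = 3x / ((2M{+}1)^2 M (M{+}1)\,GS)$, the least-squares slope
estimator over the window, averaged across the $2M{+}1$ perpendicular lines.
The normalisation (in particular that the grid step $GS$ *divides*) is fixed
by the requirement that linear displacement fields differentiate exactly —
a property the test suite enforces for $M \in \{1,2,3\}$. All four gradient
components are computed without symmetrisation; the axial component
$\varepsilon_{zz}$ drives the modulus. The default half-width `M = 5`
(about 0.5 mm at 0.045 mm/px) balances noise suppression against edge blur;
at the fine pixel pitch of the imaging setup this is a mild filter. An `M`-pixel border is
invalid by construction and masked.

**3. Stress.** The axial stress inside a semi-infinite elastic half-space
under a uniformly loaded rectangle has a closed form (Love's solution) built
from the solid angle $\Omega$ subtended by the loaded rectangle and a
corner-distance term:
$\sigma_{zz} = \frac{1}{2\pi}\left(\partial_z V - z\,\partial^2_z V\right)$
with $\partial_z V = -p\,\Omega$. The pressure is $p = F/A_1$ with $F$ the
logged force resampled linearly to the frame times and $A_1$ the footprint
area. The specimen rests on a finite base plate, which acts as a second
(mirrored) compressor; both fields superpose as
$\sigma_{total} = \sigma_{top} + (A_1/A_2)\,\sigma_{bottom}$. The bottom
field is evaluated with the same pressure $p = F/A_1$ on the base-sized
rectangle and then scaled by $A_1/A_2$, so the bottom compressor carries the
total force $F$. Arccos arguments are clamped to $[-1, 1]$ and depth is
floored at $10^{-9}$ m so surface pixels evaluate finitely. The
implementation is verified against an independent adaptive-quadrature
integration of the Boussinesq point-load kernel $3pz^3/(2\pi R^5)$ to
better than 0.5 % on an interior grid. A uniform plane-stress baseline
($\sigma_{zz} = F/A_1$ everywhere) is provided for comparison; on
simulated homogeneous data it produces visibly less homogeneous elastograms
than the Love field, which the test suite asserts as an inequality of
spatial coefficients of variation.

**4. Gating and maps.** Each tracked frame gets trustability descriptors
built from 2D correlations of consecutive data: $\rho_i$ (images),
$\rho_s$ (strain maps) and $\rho_e$ (modulus maps), combined as
$p_S = \rho_i \rho_s$ and $p_E = \rho_i \rho_s \rho_e$ and gated
sequentially at `pMin` (default 0.9): frames failing the strain gate $p_S$
are discarded before the elastogram descriptor is even computed. Pairings
are dynamic: each frame is compared with the last accepted frame, with the
immediately preceding frame as a fallback partner, so one corrupted frame
rejects exactly itself and a noisy early frame cannot become a permanent,
blocking comparison base. In practice this gate removes the early
low-compression frames, whose strain (and hence modulus) maps are noise
dominated — exactly the frames one would not want in the average. The
accepted per-frame modulus maps, which all live on the reference pixel grid
(cumulative fields are sampled at reference pixels), are averaged pixel-wise
with a per-pixel frame count; ROI statistics report the median as the
headline value, plus mean and standard deviation.

## Mechanical reference estimators

Two classical contact estimators serve as the package's mechanical
cross-checks. The bonded-block compression relation
$E = 3\sigma / ((\lambda^{-2} - \lambda)\,Z)$, $Z = 1 + 2S^2$, is fitted by
ordinary least squares through the contact point over all post-contact
points up to 15 % strain ($S$ is the bonded-to-free surface ratio;
0.139 for the 25 mm × 25 mm face of a 45 mm block, exposed as an argument).
The indentation estimator inverts the Bulychev–Alekhin–Shorshorov contact
stiffness $dF/d\delta = (2/\sqrt{\pi})\,\phi_c \sqrt{A}\,M_3'$ with
$E = M_3'(1-\nu^2)$ and the rectangular-indenter shape factor
$\phi_c = 1.016$. Contact is declared at the first sample reaching 0.1 N.
Both estimators are validated by round trips: data simulated from each model
are recovered exactly without noise, and with < 1 % bias under 1 % force
noise across 1000 replicates.

## What the phantom simulator emulates — and what it does not

The simulator builds a speckle texture from random point scatterers with
log-normal amplitudes convolved with a Gaussian point-spread function,
deforms it frame by frame with an analytic compression field (inverse
mapping, bilinear interpolation), and adds Gaussian intensity noise. The
default conditions reproduce the phantom study: 25 mm × 25 mm field of view,
3 mm compression at 1 mm/s recorded at 43 frames/s under the 38 mm × 8 mm
footprint, with homogeneous soft/hard bodies and an 8 mm cylindrical
inclusion. The "full" preset renders 556 × 556 px at 0.045 mm/px; the
"fast" preset renders the same field of view at 256 × 256 px and is what the
shipped validation uses, keeping a full study run in tens of seconds.

Two forward deformation models are available. The default, `"love"`,
derives the per-pixel strain from the same two-compressor Love stress field
the pipeline assumes, calibrated so the centre-column surface displacement
equals the applied compression; it represents a specimen that actually obeys
the half-space stress model, and makes the inverse problem well-posed so
that the residual reconstruction error is attributable to the tracking and
differentiation stages. It is also the only forward model under which the
Love-vs-plane-stress homogeneity comparison is meaningful: a generator that
imposed uniform stress would make the plane-stress inversion trivially exact.
The `"uniform"` model implements the rigid-compressor series-spring
idealisation (every column compresses by the same amount, stress uniform
with depth per column); its column strain integral equals the applied
compression exactly, which the tests exploit. For inclusion phantoms the
strain field is laterally smoothed over ~1 mm (Gaussian, σ = 0.5 mm) to
avoid the unphysical jump at the inclusion boundary of a purely columnar
model.

The rendering frame moves with the transducer face, as a real probe-mounted
image does: material appears to move toward the probe, and a dark band grows
at the bottom of the image where the field of view descends below the
specimen. Force curves follow $F = p\,A_1$ with the pressure implied by the
phantom's modulus field (through the exponential stress-strain law when
$\gamma > 0$), sampled at 100 Hz so that force-to-frame resampling is
exercised.

Deliberately not modelled: coherent RF speckle statistics (phase,
interference), attenuation, shadowing and reverberation artifacts,
out-of-plane motion, and viscoelastic creep. Passing the synthetic suite
therefore demonstrates the correctness and numerical stability of the
algorithmic chain under realistic speckle, motion and noise — not robustness
to every acoustic artifact of real tissue data.

## Numerical choices and degenerate inputs

* **Strain floor**: moduli are masked (NA), never infinite, where
  $|\varepsilon_{zz}| <$ `strainFloor` (default $10^{-4}$).
* **Flow backend defaults** (Lucas–Kanade): 5 pyramid levels down to a
  minimum of ~24 px, 5 warp iterations per level, an aggregation window of
  two 8-px box passes, Tikhonov regularisation scaled to the mean gradient
  energy, and a 1-px smoothing of the flow between iterations. The window
  and iteration counts were chosen by benchmarking displacement accuracy on
  rigid-shift and analytic-compression fixtures (sub-0.1 px median error);
  wider windows also stabilise the per-frame modulus maps that feed the
  $\rho_e$ descriptor.
* **Warping**: bilinear inverse mapping; pixels sampling outside the domain
  are NA and excluded from correlations and averages.
* **Correlation degeneracy**: zero-variance inputs raise an error in
  `frameCorrelation()`; inside the descriptor stage they yield NA and the
  frame is rejected rather than aborting the run.
* **Reporting range**: Poisson maps are clipped to $[0, 0.5]$; values with
  $\nu' \ge 1$ are masked.
* **Determinism**: all stochastic steps (speckle, noise, synthetic curves)
  are seeded; two runs of the pipeline on the same inputs are bit-identical.

## Validation scale

The shipped validation runs the fast-preset suite (256 × 256 px, 130 frames
per sequence) with body moduli at the reference medians of the phantom
study's mechanical measurements: hard 18.9 kPa, soft 6.92 kPa, inclusion
phantom combining both with an 8 mm inclusion. ROI layouts follow the study:
one central region for homogeneous specimens; the inclusion disc (shrunk to
60 % radius against edge blur) plus two lateral body rectangles otherwise.
Linear materials ($\gamma = 0$) are used for these runs, matching the
default of the modulus stage; the $\gamma$-path is validated separately by
exact round trips.

## Known limitations

* Love's solution assumes a homogeneous half-space; strong modulus
  contrasts or specimens of the same size as the footprint violate it, and
  the reconstruction inherits that bias (the real-data error budget is
  dominated by it).
* The descriptor $\rho_e$ compares mean-removed elastograms; on perfectly
  homogeneous media its information content is low and the gate then leans
  on the shared systematic structure of consecutive maps.
* Displacements are two-dimensional; out-of-plane motion is invisible and
  will degrade $\rho$ without being separable from axial decorrelation.
* The compression estimator's shape factor $S$ and the indenter's effective
  contact area are geometry approximations; both enter linearly and should
  be calibrated for other specimen shapes.
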