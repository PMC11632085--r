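---
title: "Relativistic transmission circular dichroism from dipolar T-matrices: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relativistic transmission circular dichroism from dipolar T-matrices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A chiral molecule between a distant light source and an observer moves
towards the observer along the optical axis at a substantial fraction of the
speed of light. The observable is the *transmission circular dichroism*
(TCD): the normalized difference between the forward transmissions for
incident circularly polarized plane waves of negative and positive helicity,

$$\mathrm{TCD} = \frac{T^- - T^+}{T^- + T^+},$$

rotationally averaged over molecular orientations and studied as a function
of the speed fraction $\beta = v/c$ and the lab-frame wavelength $L = 2\pi/k$.
`chiroboost` implements the full frame-hopping pipeline for this quantity,
from tabulated dynamic polarizability tensors to the $(\beta, L)$ TCD grid,
with a synthetic polarizability generator standing in for the
quantum-chemistry stage.

## Model

### From polarizabilities to the T-matrix

The optical response of a deep-subwavelength molecule is captured at dipolar
order by four complex $3\times 3$ dynamic polarizability tensors
$\alpha_{ee}, \alpha_{em}, \alpha_{me}, \alpha_{mm}$ coupling the induced
electric/magnetic dipoles to the incident electric/magnetic fields.
`build_tmatrix()` maps them to the $6\times 6$ parity-basis transition
matrix

$$\mathbf T = \frac{i c_h Z_h k_h^3}{6\pi}
\begin{pmatrix}
\mathbf C\,\alpha_{ee}\,\mathbf C^{-1} &
\mathbf C\,(-i\,\alpha_{em}/Z_h)\,\mathbf C^{-1}\\
\mathbf C\,(i\,\alpha_{me}/c_h)\,\mathbf C^{-1} &
\mathbf C\,(\alpha_{mm}/(c_h Z_h))\,\mathbf C^{-1}
\end{pmatrix},$$

where $c_h, Z_h$ are the host-medium wave speed and impedance (defaults
$c_0, Z_0$: solvation effects are assumed to be contained in the tensors
themselves) and $\mathbf C$ translates Cartesian into spherical components.
Because observables sandwich $\mathbf C \cdots \mathbf C^{-1}$, any unitary
$\mathbf C$ consistent with one fixed component order is admissible; the
package uses rows $e_m^\dagger$ with the Condon–Shortley spherical basis
vectors and the global order $m = (-1, 0, +1)$.

**Units.** Reciprocity ($\alpha_{me} = -\alpha_{em}^{\mathsf T}$) is literal
in atomic units but picks up a factor $1/\mu_0$ in raw SI. Internally all
four tensors are stored in *reduced SI* form — $\alpha_{ee}$,
$\alpha_{em}/Z_0$, $\alpha_{me}/c_0$, $\alpha_{mm}/(c_0 Z_0)$, all in
C·m²/V — where $\mu_0 c_0 = Z_0$ makes the reciprocity relation literal
again and the T-matrix prefactors reduce to host/vacuum ratios. Atomic-unit
import applies the CODATA conversion factors once, at read time.

### Helicity basis, rotation, and the orientation average

Helicity (the photon spin projection on the propagation direction) is
invariant under Lorentz boosts, so the scattering is organized in the
helicity basis: `parity_to_helicity()` conjugates by the unitary that maps
the electric/magnetic channels $N, M$ to $(N \pm M)/\sqrt 2$, with the $+$
combination labelled helicity $+1$. Which sign carries which label is a
convention; the package pins it together with all other phase choices (see
*Normalization and phases* below) and uses it consistently everywhere.

A molecular orientation is applied as a rotated T-matrix
$T_R = R\,T\,R^{-1}$, with $R$ block-diagonal over the two helicity
channels and each block an $l = 1$ Wigner-D matrix. The package
parameterizes orientations by zyz Euler angles $(0, \theta, \Phi)$, i.e.
$R = R_y(\theta) R_z(\Phi)$, *omitting the leftmost (lab-frame) z-rotation*:
rotating the molecule about the axis of a circularly polarized beam only
multiplies the forward amplitudes by a phase that cancels in every
$|\cdot|^2$. This choice matters: with the dropped angle on the *other*
side, the per-orientation TCD would depend on $\theta$ alone and the
two-angle average would not be a rotational average at all. With
$(0, \theta, \Phi)$, sampling $(\theta, \Phi)$ uniformly on the sphere with
the $\sin\theta$ measure reproduces the exact SO(3) average of any axial
observable; the suite verifies this by checking that the averaged TCD is
invariant (to sampling accuracy) under an arbitrary fixed pre-rotation of
the whole T-matrix stack.

Orientations are generated by `sample_orientations()`: a seeded random
start followed by projected gradient descent on the Thomson-style
inverse-chord repulsion energy $\sum_{i<j} 1/\|x_i - x_j\|$, with
backtracking line search and a tangential-gradient stopping rule. The exact
objective of the sampler is not critical — any uniformly dispersed set
works, and the functional acceptance is the rotational-invariance test —
but the small-$n$ optima are sharp and testable: $n = 2$ converges to an
antipodal pair and $n = 6$ to the octahedron (minimum pairwise angle
$90^\circ$) from any tested seed. The average uses uniform $1/N$ weights,
with $N = 50$ as the default study condition.

### Frame hopping

The incident wave propagates along $-z$ towards the observer; the molecule
moves along $-z$ as well (away from the source). Active boosts are used
throughout (the passive picture is $\beta \to -\beta$). The pipeline per
lab wavelength is:

1. **Boost in.** The incident wavenumber is redshifted into the molecule
   frame, $k' = k\,e^{-\xi}$ with rapidity $\xi = \mathrm{artanh}\,\beta$;
   helicity and direction are unchanged (`boost_incident()`).
2. **Scatter.** The plane wave is expanded in $l = 1$ spherical waves —
   only the $(\lambda, m = -\lambda)$ channel survives on axis, with
   coefficient $\sqrt{3/4\pi}$ — the rotated helicity T-matrix is applied,
   and the forward ($\theta_s = \pi$) far-field amplitudes are formed for
   both outgoing helicities (`expand_plane_wave()`, `apply_tmatrix()`,
   `farfield_forward()`).
3. **Boost out.** The forward amplitudes are plane-wave coefficients, so
   the inverse boost only rescales the wavenumber, $k_{lab} = k' e^{+\xi}$,
   times one common helicity-independent amplitude factor $s(\beta)$. The
   package sets $s(\beta) \equiv 1$: TCD is a ratio of intensity sums with
   the same factor in every term, so it cancels identically (asserted by
   test). Boosting is done in the plane-wave basis deliberately — boosting
   spherical-wave coefficients would mix in ever higher multipole orders.
4. **Detect.** Transmissions add the incoming amplitude to the co-helical
   scattered channel only, $T^+ = |E^+_{s,+} + E_{in}|^2 + |E^+_{s,-}|^2$
   and mirrored for $T^-$, and the TCD is their normalized difference.

Two consequences follow exactly, and both are acceptance properties: the
boosted spectrum is the rest spectrum remapped by
$L \to L\sqrt{(1-\beta)/(1+\beta)}$ (features shift to *shorter* lab
wavelengths as the molecule approaches), and the TCD magnitude is
independent of $\beta$. Because the T-matrices exist only on the imported
energy grid, each speed is evaluated at the lab wavelengths that map
exactly onto that grid (`grid_lab_wavelengths()`); the admissible lab
window therefore contracts as $\beta$ grows, exactly like the plotted
wavelength range of a boosted-spectrum sweep. A linear-in-$k$ interpolator
exists (`interpolate = TRUE`) but is off by default.

### Normalization and phases

All radial delta weights and envelope factors of a monochromatic plane wave
collapse into two documented constants: the plane-wave expansion amplitude
$\sqrt{3/4\pi}$ and the forward far-field normalization $\sqrt{12\pi}$. The
latter is the stationary-phase constant of the $l = 1$ spherical waves with
the $e^{ikr}/(kr)$ envelope dropped and the common $-i$ phase factored out
of scattered and incoming channels alike, so the incoming amplitude can be
taken real. These are not free parameters: the test suite pins them against
a brute-force evaluation of the actual vector spherical wavefunctions
(explicit spherical harmonics, closed-form spherical Hankel functions,
numerical curl) at $kr = 10^6$, and the overall interference phase is
checked physically — an isotropic *lossy* dipole must dim the forward
transmission below the empty-space value, while a lossless one may change
it only at second order. With these conventions the forward scattered
amplitude of an isotropic electric dipole reproduces the Rayleigh result
$k^3\alpha/(4\pi\varepsilon_0)$ exactly.

## Synthetic polarizability sets

The generator emulates what a linear-response quantum-chemistry calculation
hands over, without claiming its accuracy: each electronic transition is a
damped single-pole resonance

$$\Lambda(E) = \frac{\gamma}{E_0 - E - i\gamma},$$

dimensionless, $|\Lambda(E_0)| = 1$, with positive imaginary part
(absorptive in the $e^{-i\omega t}$ convention) whose HWHM is exactly the
damping parameter $\gamma$ in eV. Oscillator $n$ with electric moment
$p_n$, magnetic moment $m_n$ and chirality coupling $\kappa_n$ contributes

$$\alpha_{ee} \mathrel{+}= \alpha_0\, p_n p_n^{\mathsf T} \Lambda_n,\quad
\alpha_{mm} \mathrel{+}= \alpha_0\, m_n m_n^{\mathsf T} \Lambda_n,\quad
\alpha_{em} \mathrel{+}= i \kappa_n \alpha_0\, p_n m_n^{\mathsf T} \Lambda_n,\quad
\alpha_{me} = -\alpha_{em}^{\mathsf T},$$

so reciprocity is exact by construction, mirroring the set equals negating
$\kappa$, and for $|\kappa| \le 1$ the $6\times 6$ bianisotropic imaginary
part is positive semidefinite, which makes the induced T-matrices passive.

**Parameters and defaults.** The overall scale $\alpha_0 = 4\times10^{-39}$
C·m²/V (about 240 atomic units) is a typical small-biomolecule electric
polarizability; at 3.1 eV it yields T-matrix entries of order $10^{-8}$ to
$10^{-7}$ — the physically realistic weak-scattering regime. Magnetic
moments are set an order of magnitude below electric ones. The shipped
presets mirror the two damping regimes of the motivating systems:
`chiral-dna-like` uses $\gamma = 0.15$ eV on a UV grid (3.6–6.0 eV),
`chiral-chl-like` uses $\gamma = 0.03$ eV near 3.1 eV (400 nm, the region
of the strong chlorophyll-a ACD band), `chiral-single` is the minimal
one-band chiral model at 3.1 eV, and `achiral-iso` is an isotropic achiral
reference. Grid steps (0.02 eV broad / 0.005 eV narrow) resolve the
narrowest line with several points per HWHM.

**What the generator does not emulate.** Real molecular tensors carry many
overlapping transitions, vibronic structure, and anisotropies fixed by the
actual geometry; the presets are smooth few-band caricatures. Passing tests
therefore demonstrate the correctness of the *scattering and boosting
machinery* on physically sensible inputs, not agreement with any measured
spectrum. Fitting the presets to real B-DNA or chlorophyll data is
explicitly out of scope.

## Numerical choices and degenerate inputs

* **Exact small cases first.** Wigner functions are evaluated by the
  factorial series and tested against the $l = 1$ closed forms and the
  Cartesian rotation oracle $D^1 = \mathbf C R_z R_y R_z \mathbf C^\dagger$
  to $10^{-12}$; composition and unitarity are property-tested.
* **Poles.** The helical polarization vector at $\theta_k \in \{0, \pi\}$
  uses the continuous limits of $\hat\theta, \hat\phi$ with $\phi_k$ as
  given (the pipeline fixes $\phi_i = 0$).
* **Grid matching.** A lab wavelength is accepted as on-grid when its
  boosted wavenumber is within $10^{-9}$ relative of a grid point;
  otherwise it is an error (or linear interpolation, if enabled).
  Out-of-window wavelengths are excluded and reported; an empty admissible
  set is an error that prints the admissible window.
* **Degenerate TCD.** `tcd(0, 0)` is an explicit undefined-ratio error;
  the bound $|TCD| \le 1$ holds structurally (ratio of non-negative sums).
* **Passivity.** Every preset T-matrix satisfies
  $-(T + T^\dagger)/2 - T^\dagger T \succeq -10^{-12}$; this is the
  validity check applied to synthetic inputs.
* **Second-order caveat on the achiral null.** For an *anisotropic* achiral
  reciprocal scatterer the two cross-helicity forward intensities differ at
  second order in the scattering strength (the classic interference of
  linear dichroism and birefringence), so the per-orientation TCD vanishes
  exactly only for isotropic scatterers and to $O(|T|^2)$ otherwise. In the
  weak-scattering molecular regime ($|T| \sim 10^{-7}$) this is below
  $10^{-13}$ and far below every stated tolerance; the shipped achiral
  preset is isotropic, for which the null is exact to machine precision.
* **Determinism.** The orientation sampler is a pure function of
  $(n, \mathrm{seed})$ and restores the caller's RNG state; CSV/JSON
  writers emit full-precision (`%.17g` / 17 significant digits) numbers so
  identical configurations reproduce identical bytes and write/read round
  trips are exact.

## Problem sizes

The shipped study conditions are 50 orientations, 91–241 grid energies per
preset, and speed sets such as $\{0, 0.2, 0.4, 0.6, 0.8, 0.99\}$ or an
equally spaced $[0, 1)$ grid; the rotational-invariance check uses 200
orientations on a thinned wavelength grid. A full
50-orientation × 91-wavelength × 6-speed sweep runs in seconds on one core.

## Known limitations

* Dipolar order only ($l = 1$, 6×6 T-matrices); no quadrupoles or
  multipole mixing under the boost (avoided by boosting plane-wave, not
  spherical-wave, coefficients).
* Axial geometry only: incidence and detection along $-z$; oblique
  incidence and off-forward TCD angular distributions are out of scope.
* T-matrices are evaluated on the imported energy grid; interpolation is
  linear in $k$ and off by default.
* The common inverse-boost amplitude factor $s(\beta)$ is not modelled
  (set to 1); only ratio observables such as TCD are therefore meaningful
  downstream, and spectra carry arbitrary overall magnitude scaling.
* The quantum-chemistry stage is out of scope: real molecular tensors
  enter only through the polarizability CSV interface.
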