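# chiroboost

Transmission circular dichroism (TCD) of chiral molecules moving at
relativistic speed, computed from dipolar T-matrices.

## What it does, and for whom

Circular dichroism — the differential response to left- vs right-circularly
polarized light — is the standard optical fingerprint of molecular
chirality, and a candidate biosignature for molecules in space. When the
molecule moves towards the observer at a substantial fraction of the speed
of light, its chiroptical spectrum is Doppler-remapped, and predicting the
observable signal requires solving the scattering problem across reference
frames. `chiroboost` is for computational (bio)physicists who have — or
want to emulate — spectrally resolved bianisotropic polarizability tensors
of a molecule and need the rotationally averaged, Lorentz-boosted TCD seen
by a stationary observer.

The pipeline is the frame-hopping method: the incident circularly
polarized plane wave (propagating along −z) is actively boosted into the
molecule's rest frame; the scattering is solved there with a 6×6 dipolar
transition matrix built from the polarizability tensors

```
T = (i c_h Z_h k³ / 6π) · [ C α_ee C⁻¹        C (−i α_em/Z_h) C⁻¹ ]
                          [ C (i α_me/c_h) C⁻¹  C (α_mm/(c_h Z_h)) C⁻¹ ]
```

converted to the helicity basis (helicity is boost-invariant) and rotated
with l = 1 Wigner-D matrices over uniformly dispersed molecular
orientations; the forward far-field amplitudes are inverse-boosted back to
the lab frame, where the transmissions for the two incident helicities

```
T⁺ = |E⁺(s,+) + E_in|² + |E⁺(s,−)|²,   T⁻ = |E⁻(s,+)|² + |E⁻(s,−) + E_in|²
```

give the headline observable `TCD = (T⁻ − T⁺)/(T⁻ + T⁺)`. Two exact
consequences structure every result: the boosted spectrum is the rest
spectrum remapped by `L → L·sqrt((1−β)/(1+β))`, and the TCD magnitude is
independent of β.

A synthetic generator of damped-Lorentzian chiral polarizability sets
(resonance energies, HWHM damping in eV, electric/magnetic transition
moments, chirality coupling κ) replaces the quantum-chemistry stage, so
the whole pipeline runs and is tested without external data; real tensors
can be supplied through a documented CSV interface (atomic units or SI).

## Worked example

```r
library(chiroboost)

## synthetic chiral molecule: one 3.1 eV (400 nm) band, HWHM 0.15 eV
pol   <- preset_polarizabilities("chiral-single")
stack <- parity_to_helicity(build_tmatrix_stack(pol))

## 50 uniformly dispersed orientations, deterministic under the seed
ors  <- sample_orientations(50, seed = 1)
grid <- tcd_beta_sweep(stack, c(0, 0.2, 0.6), ors, verbose = FALSE)

do.call(rbind, lapply(split(grid, grid$beta), function(g)
  data.frame(beta = g$beta[1],
             L_peak_nm   = g$wavelength_nm_lab[which.max(abs(g$tcd))],
             max_abs_tcd = max(abs(g$tcd)),
             window_nm   = sprintf("%.0f-%.0f", min(g$wavelength_nm_lab),
                                   max(g$wavelength_nm_lab)))))
```

```
 beta L_peak_nm  max_abs_tcd window_nm
  0.0  397.3853 1.116747e-08   310-564
  0.2  324.4637 1.116747e-08   253-460
  0.6  198.6926 1.116747e-08   155-282
```

Reading the output: at rest the TCD peaks at 397 nm, next to the 400 nm
resonance. At β = 0.2 the whole spectrum (peak *and* admissible window) is
contracted by `sqrt(0.8/1.2) ≈ 0.8165` — the peak moves to 324 nm — and at
β = 0.6 by exactly 1/2 (199 nm). The peak magnitude (≈ 1.1e−8 for this
weak, physically scaled scatterer) is identical at every speed: motion
remaps the wavelength axis but does not change the strength of the chiral
signature. The absorption-side reference spectrum comes from the same
T-matrices:

```r
sp <- absorption_acd_spectra(stack)
sp$wavelength_nm[which.max(abs(sp$acd))]   # 399.9 nm ACD band
```

Mirroring the molecule (`mirror_enantiomer(pol)`) flips the sign of both
ACD and TCD exactly; the isotropic achiral preset gives an identically
zero TCD.

The same pipeline is scriptable from a shell via
`inst/cli/chiroboost.R {build|tcd|spectra}`, which wraps `cmd_build()`
(polarizability CSV → T-matrix JSON store), `cmd_tcd()` (β sweep → TCD
CSV) and `cmd_spectra()` (absorption/ACD CSV).

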