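# mubafire

Multistage background field removal for MR field maps.

## The problem

Gradient-echo MRI phase measures the local magnetic field. The field shifts
generated by tissue microstructure — the signal of interest for quantitative
susceptibility mapping (QSM) and phase-contrast analysis — are roughly an
order of magnitude weaker than the background: static-field inhomogeneity the
shim cannot remove, and dipole fields from air/tissue interfaces and other
susceptibility sources outside the brain. Background field removal (BFR)
subtracts those external contributions from a field map (Hz) inside a binary
region-of-interest mask while preserving internal contrast.

`mubafire` implements a sequential multistage filter chain:

1. **POLF** — first-order polynomial fit `a + b·x + c·y + d·z` over the mask:
   removes the constant frequency offset and linear shim-like gradients.
2. **SPHINX** — projection onto real regular solid spherical harmonics
   `v_lm = N_lm · r^l · Y_lm(θ, φ)` orthonormalized on the masked domain by
   Gram–Schmidt (fields from any source outside the mask satisfy the Laplace
   equation inside it, so this captures the smooth harmonic background;
   order 4 in the chain, order 10 standalone).
3. **DIPF** — projection onto dipole fields: a conjugate-gradient fit of an
   exterior pseudo-susceptibility `χ_ext` minimizing
   `‖m·(b − c·(χ_ext ∗ d))‖² + λ‖χ_ext‖²` with the spectral dipole kernel
   `D(k) = 1/3 − k_z²/|k|²`, removing fields of discrete sources near the
   mask (λ = 500, 50 iterations, 1/8 zero padding by default).
4. **Local stage** (optional) — thresholding at `ξ = n_σ·σ(b)`,
   diagonal-connection + six-neighbor exclusion refinement, and a final DIPF
   whose sources are restricted to the excluded pockets: removes air-bubble
   spikes and the spurious dipole halo they radiate into surrounding tissue.

A mask-aware (normalized-convolution) Gaussian filter is included as the
conventional homodyne reference method, along with a Monte Carlo brain-phantom
simulator, evaluation metrics, parameter sweeps, plotting helpers, NIfTI I/O
and a command-line interface (`exec/mubafire`).

## Worked example

```r
library(mubafire)

# synthetic brain-like sample: 72 x 80 x 56 voxels, 9.4 T
study <- simulate_study(n = 1, seed = 1, preset = "desk-small")
s <- study$samples[[1]]
masked_summary(s$b_obs, s$mask)$std   # observed field sd: 96.2 Hz
masked_summary(s$b_ref, s$mask)$std   # internal reference sd: 6.22 Hz

res <- run_chain(s$b_obs, s$mask, s$grid, chain_config())
print(res)
#> <chain_result> stages: polf -> sphinx -> dipf
#>   masked sd (Hz): input 96.2, polf 94.1, sphinx 60.1, dipf 5.51
#>   excluded voxels: 0

l1_metric(res$corrected, s$b_ref, s$mask)  # 1.50 Hz mean deviation
```

The chain reduces the masked field standard deviation from 96.2 Hz to
5.51 Hz, close to the 6.22 Hz of the true internal contrast, and the mean
absolute deviation from the reference is 1.50 Hz — background removed,
contrast preserved. (`sigma_log` values above are from this exact call; your
numbers are identical for the same seed.)

From the shell:

```sh
mubafire simulate --preset desk-small --n 2 --seed 7 --out sim/
mubafire correct --in sim/sample001/b_obs.nii.gz --mask sim/mask.nii.gz \
    --out corrected.nii.gz --method mubafire --save-stages
mubafire study --preset desk-small --n 10 --seed 1 --out report/
```

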