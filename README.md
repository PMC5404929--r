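# snarepore

Energetics and electrophysiology of SNARE-crowded fusion pores.

Exocytotic fusion pores — the nanometre-scale channels that open when a
vesicle fuses with the plasma membrane — flicker between open and closed
states and either reseal ("kiss and run") or dilate irreversibly (full
fusion). In the nanodisc–cell single-pore assay, a ~24 nm discoidal
bilayer particle (an ApoE-scaffolded nanolipoprotein particle carrying
v-SNAREs) fuses with a cell expressing flipped t-SNAREs, and the
current through the voltage-clamped pore reports its geometry with
sub-millisecond resolution. `snarepore` is for researchers analysing
such recordings and modelling what they imply: it implements both the
measurement chain and an equilibrium statistical-mechanical model that
explains why pore dilation needs many more SNAREs than pore nucleation.

## What it computes

**Model.** The pore is a toroid of waist radius $r_{po}$ and rim
separation $h$ between the disc and the target membrane. Its free
energy combines Helfrich bending ($\kappa \oint C^2 dA$, $\kappa = 20\,kT$),
membrane tension ($\gamma\,\Delta A$), short-range steric-hydration
repulsion ($P_0 e^{-d/\lambda}$), and a torque $\tau$ resisting twisting
of the scaffold belt once the pore outgrows the disc. Of the $N$
v-SNAREs on the disc face, $N_z$ zipper fully and crowd into a ring of
rods (footprint $b$) at the pore waist; summing the Boltzmann factors of
all $(h, N_z)$ states,

$$e^{-U(r_{po},N)/kT} = \sum_{N_z=0}^{N} \binom{N}{N_z}
\int_b^{h_{max}} e^{-U_{tot}(r_{po},h,N_z)/kT}\,dh ,$$

gives the free-energy landscape $U(r_{po}, N)$. Crowding of the
zippered ring generates an entropic expansion force that offsets the
~22 pN of intrinsic membrane resistance, down to ~5 pN at 15 SNAREs per
face.

**Pipeline.** Zero-phase 280 Hz filtering and 80-point block averaging;
burst detection ($|I| > 2$ pA, ≥ 250 ms); flicker idealization
($I < -0.25$ pA for ≥ 15 points); point-by-point open-pore conductances
$G = |I|/V$ and radii $r_{po} = \sqrt{\rho \lambda_c G/\pi}$;
equal-weight averaged distributions across pores; Boltzmann inversion
$U/kT = -\ln P + A$; geometric/exponential dwell fits; two-component
conductance mixtures; and the dilation sigmoid
$P_{dil}(N) = e^{(N-N_0)/b}/(1+e^{(N-N_0)/b})$.

**Synthetic data.** `synth_trace()` generates patch recordings with
exact ground truth (renewal bursts, geometric flicker counts,
exponential dwells, Boltzmann-sampled open-state conductances, white
noise), so the entire chain is testable offline.

## Worked example

```r
library(snarepore)

p <- model_params()                      # default parameter set
prof0  <- free_energy_profile(N = 0,  params = p)
prof15 <- free_energy_profile(N = 15, params = p)
prof0
#> free-energy profile: N = 0 SNAREs, 271 radii in [0.25, 7] nm
#>   minimum at r_po = 0.471 nm; U range 157.02 kT
net_inward_force(prof0)                  # 21.5 pN resists expansion
net_inward_force(prof15)                 # 4.6 pN with 15 SNAREs/face

# a synthetic 5-minute recording, analysed end to end
sp <- synth_spec(seed = 1, duration = 300, burst_rate = 1, noise_sd = 1.6,
                 conductance = list(type = "fixed", G = 450))
st  <- synth_trace(sp)
out <- run_pipeline(list(st$trace))
out$table[, c("T0", "n_flickers", "P_o", "G_po", "r_po_mean")]
#>       T0 n_flickers       P_o     G_po r_po_mean
#> 1 14.128         20 0.9394111 447.1255  1.129329
#> 2 13.344         19 0.9109712 446.0089  1.127456
#> 3 14.316         33 0.8851635 443.2029  1.121947
```

The model says a SNARE-free pore prefers a ~0.5 nm radius and is pushed
shut with ~21.5 pN averaged over radii beyond 1.5 nm; adding 15 SNAREs
per face cancels ~17 pN of that entropically. The pipeline recovers the
generator's ground truth: three bursts with ~450 pS mean open
conductance (1.13 nm radii), lifetimes of 13–14 s, tens of flickers, and
open probabilities near 0.9.

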