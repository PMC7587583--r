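# capstim

Quantitative models of **capacitively coupled electrical stimulation (ES)**
chambers for cartilage tissue engineering, with a focus on cells seeded on
or embedded in **electrically conductive hydrogel scaffolds**.

In the classic capacitive-coupling set-up, two glass cover slips insulate
the electrodes from a thin layer of cell culture medium, so the sample is
driven purely through displacement currents. Experimenters need to know,
before running a study: what field actually reaches the medium, how a
conductive scaffold redistributes that field, how strongly a single cell's
transmembrane potential (TMP) is modulated, and whether dielectrophoretic
forces could move or deform the cells. `capstim` answers these questions
with three complementary models plus uncertainty quantification:

* **Equivalent circuit** — each layer is a lossy dielectric with complex
  permittivity ε\* = ε_r ε₀ − iσ/ω and impedance Z = d/(iω ε\* πr²); the
  chamber is the series sum Z_total = 2 Z_cs + Z_buf and the field in the
  medium follows from the voltage divider, E_s = (V₀/d_buf) · Z_buf/Z_total.
* **Axisymmetric electro-quasistatic finite elements** — ∇·(ε\*∇φ) = 0 on
  a triangular (r, z) mesh with the applied potential on the outer
  cover-slip faces. The nm-thick cell membrane is a thin-layer interface:
  duplicated node pairs coupled by the surface admittance
  Y_m = (σ_m + iω ε_m ε₀)/d_m, so the potential jump across a pair *is*
  the TMP.
* **Multi-shell cell dielectrics** — nucleated spherical cells are reduced
  to an equivalent homogeneous permittivity ε₂\* (membrane, cytoplasm,
  nuclear envelope, nucleoplasm), feeding the Clausius–Mossotti factor
  CM = (ε₂\* − ε₁\*)/(ε₂\* + 2ε₁\*) whose real part sets the sign of the
  dielectrophoretic force.
* **Uncertainty quantification** — Monte Carlo (Saltelli design) and
  point-collocation polynomial chaos over any of these models, yielding
  per-frequency means, 90% prediction intervals and first-order Sobol
  sensitivity indices.

## Worked example

The reference chamber (cover slips 0.15 mm thick, radius 16.5 mm,
ε_r = 4; medium 1.415 mm, σ = 1.5 S/m, ε_r = 80; applied amplitude
44.81 V) at the most common stimulation frequency, 60 kHz:

```r
library(capstim)

st <- default_chamber()
Mod(chamber_impedance(st, 60e3))      # 26270.22  ohm
Arg(chamber_impedance(st, 60e3)) * 180 / pi   # -89.99759 degrees
Mod(buffer_field(st, 60e3))           # 1.329543  V/m
dissipated_power(st, 60e3)            # 3.209e-06 W
```

The chamber behaves as an almost ideal capacitor (phase −90°), the field
that reaches the medium is **1.33 V/m** — 1.5× smaller than the 2 V/m
value traditionally quoted for this device — and the dissipated power of
~3 µW rules out any thermal effect.

The same chamber solved by finite elements, with a spherical cell
embedded in a 1 mm × 1 mm conductive hydrogel block:

```r
sc   <- preset("spherical_centred_in_hydrogel")
sys  <- fem_system(build_geometry(sc))
mem  <- list(material = material("m", 0, 11.3), thickness = 7e-9)
mats <- scenario_materials(sc, sigma_hydro = 0.5)
sol  <- solve_eqs(sys, mats, frequency = 1e6, V0 = 44.81, membrane = mem)
Mod(probe_tmp(sol, "top"))   # 3.60e-04 V  (sigma_hydro = 0.5 S/m)
sol60 <- solve_eqs(sys, mats, frequency = 6e4, V0 = 44.81, membrane = mem)
field_in_out(sol60)          # Ei = 2.67, Eo = 1.33 V/m
```

A gel less conductive than the medium concentrates the field inside the
scaffold (E_i > E_o) and raises the cell's TMP; raising the gel
conductivity to 10 S/m reverses both effects. Uncertainty studies wrap
any such model:

```r
r <- run_study(uq_study(circuit_uq_model("abs_impedance"),
                        circuit_distributions(), method = "pc", seed = 1))
sobol_first_order(r, average = TRUE)
#      d_cs      r_cs    eps_cs     d_buf sigma_buf   eps_buf
#     0.163     0.665     0.165     0.000     0.002     0.000
```

— the cover-slip radius, thickness and permittivity control the chamber
impedance; the medium's properties are almost irrelevant, which is why
impedance spectroscopy alone cannot monitor a hydrogel in situ.

A command-line front end (`inst/cli/capstim.R`) exposes the same
functionality as `circuit-sweep`, `fem-solve`, `cm-factor`, `uq-run` and
`presets` subcommands with CSV/JSON outputs and per-run manifests.

## Further reading

The methods vignette (`vignettes/capacitive-stimulation-model.Rmd`)
documents the model assumptions, the thin-layer membrane treatment, the
meshing and numerical choices, the uncertainty-quantification designs and
the known limitations.
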