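# endoqc

Software re-creation of an opto-electronic quality-assurance bench for
**rigid surgical endoscopes**, for medical-physics and clinical-engineering
teams who want to prototype, test or teach objective endoscope QA without
the hardware.

Rigid endoscopes degrade through sterilization, radiation and mechanical
stress. A QA bench summarises each instrument per session by two numbers:

* **Transmission** of the illumination fibres, in calibrated units:
  `100 · S_endo / S_cal`, where the calibration signal `S_cal` (light
  source directly on the photocell) defines full scale (100 units).
* **Contrast** of the lens train, in grey levels: black/white line
  patterns at seven spatial frequencies are captured through the
  endoscope; for each capture, with `N` pixels in a circular region of
  interest and ascending cumulative histogram `F`, contrast is
  `g75 − g25` with `g_q = min{ g : F(g) ≥ ⌈qN/100⌉ }`, averaged over the
  seven frequencies.

Decisions are relative to the **best-of-type** value stored in the
measurement database (the 100% reference level): new/repaired endoscopes
are **accepted at ≥ 40%** of best-of-type on *both* metrics, clinical
endoscopes are **rejected below 20%** on *either*, and changes **larger
than 5%** between measurements count as significant. `endoqc` implements
the pattern generator, a parameterised virtual endoscope (blur, veiling
glare, vignetting, dust, fibre transmission, moisture), both metrics, the
registry, the decision rules, and longitudinal stability/trend/repair
reports. See `vignettes/endoqc-methods.Rmd` for the model details.

## Worked example

```r
library(endoqc)

reg <- endo_registry()

# a factory-fresh endoscope measured on an empty database
new <- endoscope_state("KS-1001", "storz-10320A")
out <- run_session(new, reg, context = "NEW",
                   timestamp = as.POSIXct("2011-07-07 09:00", tz = "UTC"),
                   seed = 1)
out$record$transmission   # 100      (units: full fibre transmission)
out$record$contrast       # 255      (grey levels: perfect line contrast)
out$decision
#> <decision ACCEPT: T=100.0% C=100.0%>

# the same type after 400 sterilization cycles of wear
worn <- age_endoscope(
  endoscope_state("KS-1002", "storz-10320A", blur_sigma = 0.6,
                  fibre_transmission = 0.9,
                  degradation_rates = list(transmission = 0.004,
                                           blur = 0.01)),
  n_cycles = 400)
out2 <- run_session(worn, reg, context = "CLINICAL",
                    timestamp = as.POSIXct("2012-03-06 09:00", tz = "UTC"),
                    seed = 2)
out2$decision
#> <decision REJECT: T=18.1% C=17.4% [transmission-below-rejection,
#>                                    contrast-below-rejection]>
```

The worn instrument measures 18.1% of the best stored transmission and
17.4% of the best contrast of its type — both below the 20% rejection
level, so it is withdrawn for repair.

The full synthetic study — a fleet with a stable reference endoscope,
slowly degrading clinical instruments, a rejection-triggered repair with
post-repair burn-in — runs with:

```r
endoqc_demo(seed = 7, out_dir = "demo")   # records.csv, decisions.csv,
                                          # reports.json
```

or from the shell via the installed CLI script:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","endoqc",package="endoqc"))')" \
    demo --seed 7 --out demo
```

Other subcommands: `patterns`, `simulate`, `measure`, `db`, `decide`,
`report` (see `?endoqc_cli`). Images travel as ASCII PGM with JSON
sidecars; the registry round-trips through a documented CSV dialect.

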