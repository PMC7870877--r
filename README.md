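# pvload

Pressure-volume (PV) loop analysis of the left ventricle under acute
load interventions, plus a closed-loop time-varying-elastance simulator
that generates ground-truth-annotated recordings for validating every
analysis stage.

## The problem

The end-systolic pressure-volume relationship (ESPVR) — the regression
through per-beat end-systolic points (V_es, P_es) collected while the
ventricular load changes — indexes contractility through its slope
E_es (mmHg/mL) and volume intercept V_0 (mL). Under *rapid afterload
increases* the end-systolic points run a biphasic course, so a single
line fits poorly. `pvload` fits both

* a linear ESPVR: `P_es = E_es (V_es − V_0)`, and
* a bilinear ESPVR: two lines over a contiguous time-ordered split of
  the points, the split chosen to maximize the geometric mean of the
  two r² values, with the breakpoint at the analytic intersection,

together with the iterative slack-volume estimate V_d entering the
maximal-elastance end-systole detector `E_max(t) = P(t)/(V(t) − V_d)`,
preload-recruitable stroke work (slope M_w, intercept V_w), and the
per-beat indices P_ed, V_ed, P_es, V_es, SV, SW, E_a = P_es/SV,
dP/dt_max.

The companion simulator embeds the two mechanisms thought to produce
the biphasic course — shortening deactivation, as an
afterload-dependent shift of the effective V_0
(`V0_eff = a·E_a + b`, default `−24.2·E_a + 23`), and the
Frank-Starling mechanism, as beat-to-beat preload adaptation through a
venous-backup compartment — so the pipeline can be checked against
known truth under preload reduction (vena-cava occlusion), afterload
increase (1–2 s resistance ramp), and preload reduction at elevated
afterload. It is aimed at cardiovascular physiologists and modelers
working with conductance-catheter recordings or lumped-parameter heart
models.

## Worked example

Simulate a noisy afterload intervention with shortening deactivation
enabled and analyze it:

```r
library(pvload)
cfg <- sim_config(sda_enabled = TRUE, seed = 42)
rec <- distort_and_noise(simulate_run(cfg, make_protocol("pload", cfg)))
analyze_run(rec)
```

```
<pv_analysis> pload: 25 beats (0 excluded), window of 8 beats
<pv_vd> Vd = 28.69 mL after 3 iterations (converged)
  linear:   <pv_linfit> Ees = 2.923 mmHg/mL, V0 = 28.7 mL, r2 = 0.8805 (n = 8)
  bilinear:
<pv_bilinfit> split after point 4, gm_r2 = 0.8982
  phase 1: <pv_linfit> Ees = 3.054 mmHg/mL, V0 = 30.6 mL, r2 = 0.8121 (n = 4)
  phase 2: <pv_linfit> Ees = 1.078 mmHg/mL, V0 = -41.7 mL, r2 = 0.9935 (n = 4)
  breakpoint: V* = 70.1 mL, P* = 120.5 mmHg
  PRSW:     <pv_prsw> Mw = -241.2 mmHg, Vw = 136.6 mL, r2 = 0.2452 (n = 8) [not meaningful]
  model used: bilin
```

Reading the output: the 8-beat intervention window splits into a steep
first phase (slope 3.05 — the shortening-deactivation limb, where the
leftward V_0 shift piles pressure on nearly constant end-diastolic
volume) and a second phase whose slope 1.08 is close to the
generator's true E_es of 1.2 — the Frank-Starling limb ascending the
shifted ESPVR line. The strongly negative phase-2 V_0 (−41.7 mL)
reflects the afterload-shifted intercept. PRSW is flagged "not
meaningful", as expected under pure afterload loading. A preload run
analyzed the same way returns a single line recovering E_es within a
few percent.

Cohort-level work uses `simulate_cohort()` /
`aggregate_fit_table()` / `v0_ea_analysis()`, which emulate a
multi-animal study (three protocols, repeats, between-animal parameter
dispersion) and report mean ± SD fit tables and the pooled
V_0-versus-E_a relation.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/pvload-cli.R simulate --protocol pload --sda --seed 1 --out run1
Rscript inst/scripts/pvload-cli.R analyze --in run1
Rscript inst/scripts/pvload-cli.R cohort --animals 10 --repeats 3 --seed 1 --out cohort/
```

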