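# liftzone

Estimating where a worker's hands are at the origin of a two-handed
lift — and how risky that lift is — from five body-worn inertial
measurement units (IMUs).

## The problem

The ACGIH Threshold Limit Values (TLV) for lifting grade a lift by the
hand location at its origin: the vertical height **V** of the hand
centre above the ground, and the horizontal distance **H** from the
mid-point between the ankles to the mid-point between the hands.  The
(V, H) plane divides into 12 zones (4 vertical bands V1–V4 × 3
horizontal bands H1–H3), commonly simplified to three risk levels
(low: zones 4–5; medium: 6–9; high: 1–3 and 10–12).  Taping V and H in
the field interrupts work; `liftzone` estimates them instead from IMUs
on the forearm, upper arm, back, thigh and calf (tri-axial gyroscope +
accelerometer, 25 Hz).

The core is a sagittal-plane link chain.  With segment lengths
\(L_s\) and inclination-from-vertical angles \(\theta_s\):

```
V = L_back·cos θ_back + L_thigh·cos θ_thigh + L_calf
    − L_UA·cos θ_UA − L_FA·cos θ_FA
H = L_UA·sin θ_UA + L_FA·sin θ_FA + L_back·sin θ_back − L_thigh·sin θ_thigh
```

Angles come from a drift-correcting complementary filter
(θ_k = α(θ_{k−1} + ω_k Δt) + (1−α)·atan2(a_x, a_z), default α = 0.98);
lifts are found by a hysteresis detector on the smoothed forearm
angular speed and scored at the lift origin.  Segment lengths come
either from a single forearm measurement scaled by population ratios
(the *ratio* model) or from five individual measurements (the
*ratio + length* model).

Because the original 10-subject laboratory data set is not publicly
available, the package includes a seeded synthetic-trial simulator
(`simulate_experiment()`) that emulates the 10 × 3 × 12 = 360-trial
design with motion-capture-style ground truth, so the whole pipeline is
testable by parameter recovery.  See the vignette
(`vignettes/lifting-zone-estimation.Rmd`) for the model, assumptions
and design choices.

## Worked example

Simulate a 3-subject experiment with realistic sensor noise, estimate
hand locations with the forearm-ratio model, and score against the
simulator's ground truth:

```r
library(liftzone)

exp <- simulate_experiment(n_subjects = 3, reps = 3, zones = 1:12, seed = 42)
res <- estimate_hand_locations(exp, model = "ratio")
evaluate_results(res)
```

```
Trials scored: 108 (missing predictions: 0)
12-zone accuracy: 82% (89/108)
V-band accuracy: 82%, H-band accuracy: 100%

Grouped lifting-risk confusion (rows = ground truth, cols = model)

Row-normalized rates:
        low medium high Sums
low    0.78   0.00 0.22    1
medium 0.06   0.86 0.08    1
high   0.11   0.06 0.83    1

             low medium high  Avg
Precision p 0.64   0.91 0.87 0.80
Recall r    0.78   0.86 0.83 0.82
F-score     0.70   0.89 0.85 0.81

Weighted recall (trace/total): 0.83  [n = 108]

Mean V error: 0.5 cm, mean H error: -1.8 cm
```

Reading this: 82 % of trials landed in exactly the right zone out of
twelve; collapsing to the three risk levels, each row of the confusion
table shows where true low/medium/high lifts were classified (rows sum
to 1), and precision/recall/F summarize each class from the raw
counts.  The population-ratio anthropometry is what limits this model —
rerunning with `model = "ratio_length"` (individually measured segment
lengths) classifies the same 108 trials perfectly, and the gap between
the two models is exactly what the method's evaluation is about.

The same pipeline runs from the shell over on-disk CSV streams:

```sh
Rscript inst/cli/liftzone.R simulate --out runs/demo --subjects 3 --seed 42
Rscript inst/cli/liftzone.R estimate --data runs/demo --model ratio
Rscript inst/cli/liftzone.R evaluate --results runs/demo/results_ratio.csv
```

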