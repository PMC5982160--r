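# skelmatch

Single-exemplar activity recognition from skeletal tracking streams
(Kinect-v1 class: 20 named joints with 3-D positions per frame), for
people building movement-monitoring tools — ambient-assisted living,
rehabilitation exercises, dual-task cognitive screening — who cannot
collect a training corpus per user and per activity.

## The method

Each activity is registered with a **single key sample** (one frame for a
posture, one sequence for a movement) and a set of **relevant joints**.
The relevant joints induce a set of bones $B$ from the skeleton topology;
for each bone the observation's direction $u_b$ is compared with the key
sample's $v_b$ through the angle $\theta_b$ between them,

$$ s_b = 100\,(1 - \theta_b/180^\circ), \qquad
   S = \frac{1}{|B|} \sum_{b\in B} s_b , $$

and movements average $S$ over a trailing window uniformly resampled to
the template (matched speed, no time warping). The predicted activity is
the argmax of $S$ over templates, subject to two guards:

* **Minimum limits of prediction** — easily detected "sink" activities
  (Stand, Stay Seated, Walk, Walk Backwards) tend to absorb other
  activities' samples; a per-activity limit gates a sink out of the
  decision whenever its score does not surpass the limit, even if it
  scored highest. Packaged defaults: Stand 85.4, Stay Seated 78.0,
  Walk \[D\] 78.0, Walk Backwards \[D\] 79.0. Limits are calibrated from
  pre-evaluation score samples via a max/min selection interval with a
  mean fallback (`calibration_interval()`, `calibrate_all()`).
* **Joint-set variants** — per activity, relevant joints can be the bare
  extremity chain plus shoulder/hip girdles (`vB`), that set plus the
  trunk (`vT`), or the whole body minus hands, feet and head (`vC`).

A seeded synthetic motion generator (`generate_sequence()`, eight study
activities, per-joint sensor noise, execution variability, compensatory
arm sway on leg activities) and an evaluation harness (`run_protocol()`,
`compare_strategies()`; Suc/Vic/Rate tables and confusion matrices)
reproduce the full strategy-comparison workflow end to end.

## Worked example

```r
library(skelmatch)

# a reference recorder registers the 8 study templates (trunk variant)
recorder  <- generate_participant(seed = 42)
templates <- build_study_templates("vT", recorder, fps = 15)

# another body performs a noisy left-leg flexion with compensatory sway
performer <- generate_participant(seed = 7)
script    <- with_balance_sway(activity_scripts()[["Leg Flexion [I]"]], 0.15)
obs       <- generate_sequence(script, performer, fps = 15,
                               noise = noise_params(seed = 99))

predict_activity(obs, templates, limits = default_limits())
#> <activity_prediction> Leg Flexion [I]
#>   Leg Flexion [I]           98.55%
#>   Grab Object [D]           97.34%
#>   Stand                     95.26%
#>   Walk Backwards [D]        95.15%
#>   Leg Circular Swing [I]    95.08%
#>   Walk [D]                  94.14%
#>   Drink [D]                 93.99%
#>   Stay Seated               91.07%
```

The sway arm makes Grab Object the runner-up at 97.3% — the
characteristic confusion channel for leg activities — while the trunk
bones of `vT` keep the true activity on top. Under `vB` (no trunk) the
same margins shrink and occasionally invert, which is what the evaluation
harness quantifies.

A thin CLI wraps the same functions (`exec/skelmatch`):

```sh
skelmatch generate  --activity "Leg Flexion [I]" --participant-seed 3 \
                    --noise default --reps 25 --out seqs/
skelmatch classify  --templates templates/ --input seqs/some.csv \
                    --limits limits.json --explain
skelmatch calibrate --scores scores.csv --out limits.json
skelmatch evaluate  --config protocol.json --out results/
```

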