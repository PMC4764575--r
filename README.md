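# kinetoswitch

Analysis of sister kinetochore directional switching during metaphase.

During metaphase, the two kinetochores of each chromosome attach to
microtubule bundles (K-fibres) from opposite spindle poles and are coupled
through centromeric chromatin. Each K-fibre is net polymerising (`+`) or
depolymerising (`-`), and the adaptive switching of these hidden states
drives the saw-tooth, quasi-periodic oscillation of the pair along the
normal to the metaphase plate. Because positions are sampled every ~2 s
with noise, switch times cannot be read directly off the tracks. This
package is for researchers who need to infer them: it fits an explicit
switching time-series model to paired trajectories by MCMC, calls each
directional switch as lead-initiated (LIDS), trail-initiated (TIDS) or
joint (JDS), and computes the mechanical signatures (inter-sister
distance, percent stretch, twist angle) around those events.

## The model

Positions `X1`, `X2` (nm, plate-normal coordinates) of the two sisters
evolve per frame as a Markov-switching linear autoregression:

    dX1 =  c0 + c(s1) - a X1 + b X2 + N(0, s^2)
    dX2 = -c0 - c(s2) - a X2 + b X1 + N(0, s^2)

with hidden per-sister states `s1, s2 in {+, -}` selecting the drive
(`c(+) = c_+ > 0`, `c(-) = c_- < 0`), relaxation `a`, sister coupling `b`,
and a baseline `c0 > 0` that maintains the equilibrium separation
`2 c0 / (b + a)`. Exactly one sister may flip per frame, with probability
`p_incoherent` when the sisters move incoherently and `p_coherent` when
coherent. The posterior `pi(a, b, c0, c_+/-, s^2, p, states | X)` is
sampled by Gibbs/Metropolis-Hastings updates with a
forward-filter/backward-sample pass for the state path (C++ under the
hood), under a normal prior on the rest length `2 c0 / (b + a)` and flat
constrained priors elsewhere. Coherent runs (>= 5 frames of unchanged
coherent state) are extracted from the modal path, and each reversal is
classified by which sister's switch frame comes first.

## Worked example

Simulate one paired trajectory at the default parameter set, fit it, and
call its switches:

```r
library(kinetoswitch)

params <- switch_model_params()   # model defaults; see ?switch_model_params
sim <- simulate_trajectory(params, n_frames = 150, seed = 23)

priors <- ks_priors(rest_length_mean = equilibrium_separation(params),
                    rest_length_sd = 1e4)   # wide prior for synthetic data
fit <- run_chain(sim$trajectory, priors, config = list(seed = 1))
fit
#> Switching AR model fit: 150 frames, 3 chains
#>   converged: TRUE (max R-hat 1.000, state agreement 1.00)
#>      parameter      mean        sd      lower    median      upper
#> 1            a   0.05597  0.001034    0.05424   0.05596    0.05764
#> 2            b   0.03979  0.001031    0.03808   0.03980    0.04147
#> 3           c0 628.00571 38.419188  568.05831 627.46831  688.12308
#> 4       c_plus  64.00457 36.919723    6.54929  64.39195  120.82241
#> 5      c_minus -63.06601 36.967846 -120.30068 -62.92788   -6.03882
#> 6           s2 920.98111 76.278178  803.58755 916.80721 1050.53421
#> 7 p_incoherent   0.36298  0.097223    0.20840   0.35858    0.52894
#> 8   p_coherent   0.07442  0.023698    0.03976   0.07195    0.11731

runs <- detect_coherent_runs(fit$point_path)
events <- match_directional_events(runs, fit$point_path)$events
events[, c("event_type", "first_switch_frame", "lead_sister",
           "completion_time_s")]
#>   event_type first_switch_frame lead_sister completion_time_s
#> 1       TIDS                 12           2                 4
#> 2       LIDS                124           1                18

score_against_truth(events, sim$truth)$accuracy
#> [1] 1
```

Reading the fit: `a`, `b`, `s2` and the switch probabilities recover the
generating values (0.056, 0.04, 1000 nm², 0.39, 0.063) within their
posterior spread. `c0` and the individual drives are deliberately wide:
the likelihood only identifies the *net* drives `c0 + c_+` and `c0 + c_-`,
so `c0` is pinned jointly by the sign constraints and the rest-length
prior — the vignette explains this flat direction. The two detected
reversals are called correctly against the simulation truth (accuracy 1);
the three true events bounded by runs shorter than five frames are, by
design, not called.

For a whole cohort, `switch_accuracy_study()` wraps
simulate → fit → detect → score, and `run_pipeline()` drives the CSV-based
stage pipeline (simulate, infer, detect, profile) with a manifest.

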