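test_that("modal state path uses persistence to break ties", {
  marg <- rbind(c(0, 1, 0, 0),
                c(0, 0.5, 0.5, 0),   # tie with previous state 2: keep 2
                c(0, 0.2, 0.8, 0),
                c(0, 0.5, 0.5, 0))   # tie with previous state 3: keep 3
  expect_equal(point_state_estimate(marg), c(2L, 2L, 3L, 3L))
  # degenerate marginals reproduce the path exactly
  path <- c(2L, 2L, 1L, 3L, 3L)
  m <- matrix(0, 5, 4)
  m[cbind(1:5, path)] <- 1
  expect_equal(point_state_estimate(m), path)
})

test_that("modal path matches the enumeration oracle on the toy posterior", {
  p <- base_params(s2 = 2000, p_incoherent = 0.35, p_coherent = 0.1)
  sim <- simulate_trajectory(p, n_frames = 6, seed = 17)
  exact <- exact_path_posterior(sim$trajectory, p)
  modal <- apply(exact$marginals, 1, which.max)
  # no near-ties in this fixture, so persistence cannot kick in
  expect_true(all(apply(exact$marginals, 1, function(r)
    diff(sort(r, decreasing = TRUE)[2:1]) > 1e-6)))
  expect_equal(point_state_estimate(exact$marginals), unname(modal))
})

test_that("coherent-run detection matches a brute-force scan", {
  brute_runs <- function(path, min_len = 5) {
    out <- list()
    t <- 1
    while (t <= length(path)) {
      if (is_coherent(path[t])) {
        e <- t
        while (e < length(path) && path[e + 1] == path[t]) e <- e + 1
        if (e - t + 1 >= min_len) {
          out[[length(out) + 1]] <- c(start = t, end = e)
        }
        t <- e + 1
      } else {
        t <- t + 1
      }
    }
    do.call(rbind, out)
  }
  expect_equal(nrow(detect_coherent_runs(rep(2L, 150))), 1L)
  expect_equal(detect_coherent_runs(rep(2L, 150))$end_frame, 150L)
  expect_equal(nrow(detect_coherent_runs(c(1L, rep(2L, 4), 1L))), 0L)
  set.seed(66)
  for (i in 1:25) {
    path <- sample(1:4, 30, replace = TRUE,
                   prob = c(0.1, 0.4, 0.4, 0.1))
    runs <- detect_coherent_runs(path)
    bf <- brute_runs(path)
    if (is.null(bf)) {
      expect_equal(nrow(runs), 0L)
    } else {
      expect_equal(runs$start_frame, unname(bf[, "start"]))
      expect_equal(runs$end_frame, unname(bf[, "end"]))
    }
  }
})

test_that("event classification follows the switching-order rule", {
  expect_equal(classify_event(40, 42), "LIDS")
  expect_equal(classify_event(41, 40), "TIDS")
  expect_equal(classify_event(40, 40), "JDS")
})

test_that("directional events are matched across gaps; reverts are not events", {
  # runs of opposite direction with a two-flip gap: sister flip frames exact
  path <- c(rep(2L, 8), 4L, 4L, rep(3L, 8))
  # state 2 = "+-": sister1 '+', flips at frame 9 ('+-' -> '--');
  # sister2 flips at frame 11 ('--' -> '-+')
  runs <- detect_coherent_runs(path)
  me <- match_directional_events(runs, path)
  expect_equal(nrow(me$events), 1L)
  ev <- me$events
  expect_equal(ev$switch_frame_sister1, 9L)
  expect_equal(ev$switch_frame_sister2, 11L)
  expect_equal(ev$lead_sister, 1L)  # the sigma='+' sister of the '+-' run
  expect_equal(ev$event_type, "LIDS")
  expect_equal(ev$completion_time_s, 4)
  # trail-first gap through '++': lead of '+-' is sister 1, switching last
  path2 <- c(rep(2L, 8), 1L, 1L, rep(3L, 8))
  me2 <- match_directional_events(detect_coherent_runs(path2), path2)
  expect_equal(me2$events$event_type, "TIDS")
  # adjacent opposite runs: both flips in the same frame, a JDS
  path3 <- c(rep(2L, 8), rep(3L, 8))
  me3 <- match_directional_events(detect_coherent_runs(path3), path3)
  expect_equal(me3$events$event_type, "JDS")
  expect_equal(me3$events$completion_time_s, 0)
  # a transient single-sister excursion between same-direction runs: revert
  path4 <- c(rep(2L, 8), 1L, 1L, rep(2L, 8))
  me4 <- match_directional_events(detect_coherent_runs(path4), path4)
  expect_equal(nrow(me4$events), 0L)
  expect_equal(me4$n_reverts, 1L)
  # a sister flipping twice inside the gap: the persisting flip is taken
  path5 <- c(rep(2L, 8), 4L, 2L, 4L, 4L, rep(3L, 8))
  me5 <- match_directional_events(detect_coherent_runs(path5), path5)
  expect_equal(me5$events$switch_frame_sister1, 11L)
  expect_equal(me5$events$switch_frame_sister2, 13L)
})

test_that("the detector recovers every saw-tooth switch exactly", {
  saw <- make_idealized_sawtooth(150, half_period = 17, amplitude = 1000,
                                 separation = 900)
  path <- states_from_displacements(saw$trajectory, smooth_window = 1)
  expect_equal(path, saw$truth$states)
  runs <- detect_coherent_runs(path)
  me <- match_directional_events(runs, path)
  truth_ev <- saw$truth$events
  expect_equal(nrow(me$events), nrow(truth_ev))
  expect_equal(me$events$first_switch_frame, truth_ev$first_switch_frame)
  expect_equal(me$events$event_type, truth_ev$event_type)
  sc <- score_against_truth(me$events, saw$truth)
  expect_equal(sc$accuracy, 1)
  expect_equal(sc$n_matched, sc$n_true)
})

test_that("feeding the detector the truth path gives perfect accuracy", {
  p <- base_params()
  co <- simulate_cohort(p, 12, seed = 33, forced_variant = TRUE)
  for (sim in co$sims) {
    runs <- detect_coherent_runs(sim$truth$states, min_length = 1)
    me <- match_directional_events(runs, sim$truth$states)
    sc <- score_against_truth(me$events, sim$truth)
    expect_equal(sc$accuracy, 1)
    expect_equal(nrow(me$events), nrow(sim$truth$events))
  }
})

test_that("randomly permuted labels score at the binary-call chance level", {
  p <- base_params()
  co <- simulate_cohort(p, 120, seed = 44)
  correct <- 0L
  total <- 0L
  set.seed(9)
  for (sim in co$sims) {
    ev <- sim$truth$events
    lt <- ev[ev$event_type %in% c("LIDS", "TIDS"), ]
    if (nrow(lt) == 0) next
    shuffled <- lt
    shuffled$event_type <- sample(c("LIDS", "TIDS"), nrow(lt),
                                  replace = TRUE)
    sc <- score_against_truth(shuffled, sim$truth)
    correct <- correct + sc$n_correct
    total <- total + sc$n_matched
  }
  expect_lt(abs(correct / total - 0.5), 3 * sqrt(0.25 / total))
})

test_that("event statistics: fractions, bias and degenerate cases", {
  ev <- data.frame(event_type = c(rep("LIDS", 5), rep("TIDS", 3),
                                  rep("JDS", 2)),
                   completion_time_s = c(rep(4, 5), rep(2, 3), 0, 0))
  runs <- data.frame(length = c(10, 20, 30))
  st <- event_statistics(ev, runs, dt = 2)
  expect_equal(unname(st$fractions), c(0.5, 0.3, 0.2))
  expect_equal(sum(st$fractions), 1)
  expect_equal(st$lead_trail_bias, 5 / 3, tolerance = 1e-12)
  expect_false(st$bias_undefined)
  expect_equal(unname(st$run_duration_s["mean"]), 40)
  expect_equal(unname(st$median_completion_s["LIDS"]), 4)
  # all-LIDS: bias undefined, reported as infinite with a flag
  st2 <- event_statistics(ev[ev$event_type == "LIDS", ], runs)
  expect_true(is.infinite(st2$lead_trail_bias))
  expect_true(st2$bias_undefined)
  expect_error(event_statistics(ev[0, ], runs), "at least one event")
})

test_that("call accuracy does not improve as displacement noise grows", {
  accs <- vapply(c(250, 2000, 8000), function(s2) {
    p <- base_params(s2 = s2)
    st <- switch_accuracy_study(n_traj = 6, params = p, seed = 71,
                                mcmc = quick_mcmc())
    st$accuracy
  }, numeric(1))
  # pooled events per level are few; allow ~3 binomial MC standard errors
  se <- sqrt(0.1 * 0.9 / 15)
  expect_gte(accs[1], accs[2] - 3 * se)
  expect_gte(accs[2], accs[3] - 3 * se)
  expect_gte(accs[1], accs[3] - 3 * se)
})
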