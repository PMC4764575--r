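test_that("log-likelihood matches the Gaussian closed form and peaks at truth", {
  p <- base_params(s2 = 400)
  sim <- simulate_trajectory(base_params(s2 = 0), n_frames = 11, seed = 3)
  traj <- sim$trajectory
  path <- sim$truth$states
  # zero residuals: only the Gaussian normalisation remains
  p_eval <- base_params(s2 = 400)
  expect_equal(loglik_trajectory(traj, path, p_eval),
               -2 * 10 * 0.5 * log(2 * pi * 400))
  # true path beats every single-flip perturbation (noise-free data)
  ll_true <- loglik_trajectory(traj, path, p_eval)
  for (t in seq_along(path)) {
    for (s in setdiff(1:4, path[t])) {
      alt <- path
      alt[t] <- s
      expect_lt(loglik_trajectory(traj, alt, p_eval), ll_true)
    }
  }
  # degenerate s2 = 0
  p0 <- base_params(s2 = 0)
  expect_identical(loglik_trajectory(traj, path, p0), Inf)
  alt <- path
  alt[3] <- setdiff(1:4, path[3])[1]
  expect_identical(loglik_trajectory(traj, alt, p0), -Inf)
  expect_error(loglik_trajectory(traj, path[-1], p_eval), "path length")
})

test_that("linear-block conditional mean equals the least-squares solution", {
  p <- base_params()
  sim <- simulate_trajectory(p, n_frames = 51, seed = 8)
  pp <- kinetoswitch:::prep_trajectory(sim$trajectory)
  path <- sim$truth$states
  d <- kinetoswitch:::linear_design(pp, path)
  ols <- coef(lm(d$y ~ 0 + d$X))
  set.seed(1)
  upd <- update_linear_params(sim$trajectory, path, p, wide_priors(p))
  expect_equal(unname(attr(upd, "conditional_mean")), unname(ols),
               tolerance = 1e-8)
  expect_length(attr(upd, "held"), 0)
  # sign structure of the returned draw
  expect_gt(upd$a, 0)
  expect_gt(upd$b, 0)
  expect_gt(upd$c_plus, 0)
  expect_lt(upd$c_minus, 0)
  expect_gt(upd$c0, 0)
})

test_that("a drive state never visited by the path is held, not invented", {
  p <- base_params()
  sim <- simulate_trajectory(switch_model_params(p_incoherent = 1e-9,
                                                 p_coherent = 1e-9),
                             n_frames = 40, seed = 2)
  path <- sim$truth$states  # constant coherent state: '+-' or '-+' only
  expect_equal(length(unique(path)), 1L)
  upd <- update_linear_params(sim$trajectory, path, p, wide_priors(p))
  expect_length(attr(upd, "held"), 0)  # both drives visited across sisters
  # force an unvisited drive: an all-'++' path never uses c_minus
  upd2 <- update_linear_params(sim$trajectory, rep(1L, length(path)), p,
                               wide_priors(p))
  expect_true("d_minus" %in% attr(upd2, "held"))
  expect_equal(upd2$c0 + upd2$c_minus, p$c0 + p$c_minus, tolerance = 1e-6)
})

test_that("noise-variance update is conjugate", {
  p <- base_params(s2 = 0)
  sim <- simulate_trajectory(p, n_frames = 26, seed = 4)
  path <- sim$truth$states
  pr <- ks_priors(s2_shape = 3, s2_rate = 50)
  n <- 2 * length(path)
  # zero residuals: posterior IG(shape + n/2, rate); check the draw mean
  set.seed(9)
  draws <- replicate(4000, update_noise_var(sim$trajectory, path, p, pr))
  expect_equal(mean(draws), 50 / (3 + n / 2 - 1), tolerance = 0.05)
  # known residual sum of squares: shift c0 by delta adds delta^2 per row
  delta <- 5
  p_off <- base_params(c0 = p$c0 + delta, s2 = 0)
  rss <- n * delta^2
  set.seed(10)
  draws2 <- replicate(4000, update_noise_var(sim$trajectory, path, p_off, pr))
  expect_equal(mean(draws2), (50 + rss / 2) / (3 + n / 2 - 1),
               tolerance = 0.05)
})

test_that("switch-probability updates are Beta-conjugate per coherence class", {
  pr <- ks_priors()
  # path: coherent block with one exit, incoherent block with one exit
  path <- c(rep(2L, 10), rep(1L, 5), rep(3L, 6))
  # opportunities: coherent n=15 (frames in states 2,3 before the last),
  # switches k=1 (2->1); incoherent n=5, switches k=1 (1->3)
  set.seed(3)
  draws <- replicate(4000, update_switch_probs(path, pr))
  expect_equal(mean(draws["p_coherent", ]), (1 + 1) / (2 + 15),
               tolerance = 0.02)
  expect_equal(mean(draws["p_incoherent", ]), (1 + 1) / (2 + 5),
               tolerance = 0.03)
  # no incoherent frames: prior draw (Beta(1,1) mean 1/2)
  set.seed(4)
  draws2 <- replicate(4000, update_switch_probs(rep(2L, 30), pr))
  expect_equal(mean(draws2["p_incoherent", ]), 0.5, tolerance = 0.03)
})

test_that("state samplers match brute-force path enumeration on a toy case", {
  p <- base_params(s2 = 2000, p_incoherent = 0.35, p_coherent = 0.1)
  sim <- simulate_trajectory(p, n_frames = 6, seed = 17)
  traj <- sim$trajectory
  exact <- exact_path_posterior(traj, p)
  n <- 4000
  set.seed(30)
  ffbs <- replicate(n, sample_state_path(traj, p, method = "ffbs"))
  set.seed(31)
  path <- sim$truth$states
  gibbs <- matrix(NA_integer_, 5, 6000)
  for (i in seq_len(ncol(gibbs))) {
    path <- sample_state_path(traj, p, current_path = path, method = "gibbs")
    gibbs[, i] <- path
  }
  for (t in 1:5) {
    for (s in 1:4) {
      pe <- exact$marginals[t, s]
      mc_se <- sqrt(pe * (1 - pe) / n)
      expect_lt(abs(mean(ffbs[t, ] == s) - pe), 4 * mc_se + 0.005)
      # single-site sweep chain: same target, autocorrelated draws
      expect_lt(abs(mean(gibbs[t, ] == s) - pe), 0.05)
    }
  }
})

test_that("the path sampler recovers a known path when noise is small", {
  p <- base_params(s2 = 25)
  sim <- simulate_trajectory(p, n_frames = 150, seed = 12)
  set.seed(1)
  path <- sample_state_path(sim$trajectory, p)
  expect_gt(mean(path == sim$truth$states), 0.99)
})

test_that("with the likelihood flattened the paths follow the prior chain", {
  p <- base_params(s2 = 1e12)
  sim <- simulate_trajectory(base_params(), n_frames = 150, seed = 14)
  set.seed(2)
  draws <- replicate(200, sample_state_path(sim$trajectory, p))
  # stationary coherent-class mass is p_inc / (p_inc + p_coh)
  target <- p$p_incoherent / (p$p_incoherent + p$p_coherent)
  frac <- mean(is_coherent(as.vector(draws[-(1:10), ])))
  expect_lt(abs(frac - target), 0.03)
})

test_that("a tight rest-length prior pins the sampled equilibrium separation", {
  p <- base_params()
  sim <- simulate_trajectory(p, n_frames = 150, seed = 6)
  rl <- equilibrium_separation(p)
  fit <- run_chain(sim$trajectory,
                   ks_priors(rest_length_mean = rl, rest_length_sd = 10),
                   config = quick_mcmc())
  pooled <- do.call(rbind, lapply(fit$chains, `[[`, "samples"))
  rl_draws <- 2 * pooled[, "c0"] / (pooled[, "a"] + pooled[, "b"])
  expect_lt(abs(mean(rl_draws) - rl), 30)
  expect_lt(sd(rl_draws), 50)
})

test_that("chains are reproducible, constrained, and summarised coherently", {
  p <- base_params()
  sim <- simulate_trajectory(p, n_frames = 140, seed = 18)
  f1 <- run_chain(sim$trajectory, wide_priors(p), quick_mcmc(seed = 77))
  f2 <- run_chain(sim$trajectory, wide_priors(p), quick_mcmc(seed = 77))
  expect_identical(f1$chains[[1]]$samples, f2$chains[[1]]$samples)
  expect_identical(f1$point_path, f2$point_path)
  pooled <- do.call(rbind, lapply(f1$chains, `[[`, "samples"))
  expect_true(all(pooled[, "a"] > 0))
  expect_true(all(pooled[, "b"] > 0))
  expect_true(all(pooled[, "c0"] > 0))
  expect_true(all(pooled[, "c_plus"] > 0))
  expect_true(all(pooled[, "c_minus"] < 0))
  expect_true(all(pooled[, c("p_incoherent", "p_coherent")] >= 0 &
                    pooled[, c("p_incoherent", "p_coherent")] <= 1))
  # state marginals normalise per frame
  expect_equal(rowSums(f1$state_marginals),
               rep(1, nrow(f1$state_marginals)))
  # a 2-frame trajectory runs but cannot be declared converged
  tiny <- sim$trajectory[1:2, ]
  expect_warning(ft <- run_chain(tiny, wide_priors(p),
                                 quick_mcmc(min_frames = 112)),
                 "fewer than")
  expect_false(ft$convergence$converged)
})

test_that("the convergence report flags disagreeing chains", {
  cfg <- kinetoswitch:::mcmc_defaults()
  fake_chain <- function(shift, modal_state) {
    m <- matrix(0.02, 30, 4)
    m[, modal_state] <- 0.94
    set.seed(modal_state + 10 * shift)
    list(samples = matrix(rnorm(400 * 8, mean = shift), 400, 8,
                          dimnames = list(NULL,
                                          kinetoswitch:::PARAM_NAMES)),
         state_marginals = m)
  }
  good <- kinetoswitch:::convergence_report(
    list(fake_chain(0, 2), fake_chain(0, 2), fake_chain(0, 2)), cfg)
  expect_true(good$converged)
  expect_true(all(good$rhat < 1.1))
  # a chain stuck in a different parameter mode
  bad <- kinetoswitch:::convergence_report(
    list(fake_chain(0, 2), fake_chain(5, 2)), cfg)
  expect_true(bad$excluded)
  expect_gt(max(bad$rhat), 1.1)
  # chains whose modal state paths disagree
  split <- kinetoswitch:::convergence_report(
    list(fake_chain(0, 2), fake_chain(0, 3)), cfg)
  expect_true(split$excluded)
  expect_lt(split$state_agreement, 0.9)
})

test_that("pure-noise input is flagged as non-converged, not estimated", {
  set.seed(56)
  wn <- data.frame(frame = 1:150, time_s = (0:149) * 2,
                   x1 = rnorm(150, 500, 100), x2 = rnorm(150, -500, 100))
  fit <- run_chain(wn, ks_priors(rest_length_mean = 1000,
                                 rest_length_sd = 1e4),
                   quick_mcmc(n_chains = 3, seed = 21))
  expect_true(fit$convergence$excluded)
})

test_that("short-chain recovery: posterior covers the generating values", {
  p <- base_params()
  sims <- lapply(1:2, function(i) simulate_trajectory(p, 150, seed = 100 + i))
  for (sim in sims) {
    fit <- run_chain(sim$trajectory, wide_priors(p), quick_mcmc(seed = 41))
    sm <- fit$summary$params
    rownames(sm) <- sm$parameter
    for (par in c("a", "b", "s2", "p_incoherent", "p_coherent")) {
      truth <- p[[par]]
      expect_lt(abs(sm[par, "mean"] - truth), 4 * sm[par, "sd"] + 1e-12)
    }
  }
})

test_that("credible intervals approximately cover at the nominal rate", {
  p <- base_params()
  covered <- 0L
  n_rep <- 12L
  for (i in seq_len(n_rep)) {
    sim <- simulate_trajectory(p, 150, seed = 200 + i)
    fit <- run_chain(sim$trajectory, wide_priors(p),
                     quick_mcmc(n_chains = 1, seed = 300 + i))
    sm <- fit$summary$params
    a_row <- sm[sm$parameter == "a", ]
    if (a_row$lower <= p$a && p$a <= a_row$upper) covered <- covered + 1L
  }
  # 90% nominal; with 12 replicates allow the binomial spread
  expect_gte(covered, 8L)
})
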