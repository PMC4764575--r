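#' Priors for the switching autoregressive model
#'
#' All priors are uninformative (flat, subject to the sign constraints of
#' [switch_model_params()]) except for: a normal prior on the relaxed
#' inter-sister separation evaluated on the derived quantity
#' `2 * c0 / (b + a)` (its mean is the rest length measured on
#' microtubule-depolymerised cells, 788 nm by default; its SD is
#' configurable), a Beta prior on each per-frame switch probability, and a
#' weakly-informative inverse-gamma prior on the noise variance `s2`.
#'
#' @param rest_length_mean Mean of the rest-length prior (nm).
#' @param rest_length_sd SD of the rest-length prior (nm). No population SD
#'   accompanies the 788 nm mean; the default 100 nm is a plausible
#'   biological scale. Use a large value (e.g. `1e4`) for an effectively
#'   flat prior.
#' @param s2_shape,s2_rate Inverse-gamma shape and rate for `s2` (nm^2).
#' @param switch_alpha,switch_beta Beta prior parameters shared by
#'   `p_incoherent` and `p_coherent` (default Beta(1, 1), flat).
#' @return An object of class `ks_priors`.
#' @export
ks_priors <- function(rest_length_mean = 788, rest_length_sd = 100,
                      s2_shape = 2, s2_rate = 100,
                      switch_alpha = 1, switch_beta = 1) {
  if (rest_length_mean <= 0 || rest_length_sd <= 0) {
    stop("rest-length prior mean and sd must be positive")
  }
  if (s2_shape <= 0 || s2_rate <= 0 || switch_alpha <= 0 || switch_beta <= 0) {
    stop("prior hyperparameters must be positive")
  }
  structure(list(rest_length_mean = rest_length_mean,
                 rest_length_sd = rest_length_sd,
                 s2_shape = s2_shape, s2_rate = s2_rate,
                 switch_alpha = switch_alpha, switch_beta = switch_beta),
            class = "ks_priors")
}

# Per-trajectory quantities reused across every MCMC update.
prep_trajectory <- function(traj) {
  x1 <- traj$x1
  x2 <- traj$x2
  if (!all(is.finite(x1)) || !all(is.finite(x2))) {
    stop("trajectory positions must be finite on a contiguous frame range")
  }
  n <- length(x1)
  L <- n - 1L
  list(n = n, L = L,
       x1h = x1[seq_len(L)], x2h = x2[seq_len(L)],
       dx1 = diff(x1), dx2 = diff(x2))
}

#' Log-likelihood of a trajectory given a state path and parameters
#'
#' Sum over frames and sisters of the Gaussian log-density of the observed
#' frame-to-frame displacement about its model mean.
#'
#' @param traj Trajectory data frame with `x1`, `x2`.
#' @param path Integer state path of length `nrow(traj) - 1`.
#' @param params A [switch_model_params()] object.
#' @return Scalar log-likelihood. With `s2 = 0` the value is `-Inf` unless
#'   every residual is exactly zero (degenerate noise-free case).
#' @export
loglik_trajectory <- function(traj, path, params) {
  pp <- prep_trajectory(traj)
  path <- as_state_index(path)
  if (length(path) != pp$L) {
    stop("path length must equal the number of displacement steps (",
         pp$L, ")")
  }
  d1 <- ifelse(SIG1[path] > 0, params$c_plus, params$c_minus)
  d2 <- ifelse(SIG2[path] > 0, params$c_plus, params$c_minus)
  r1 <- pp$dx1 - (params$c0 + d1 - params$a * pp$x1h + params$b * pp$x2h)
  r2 <- pp$dx2 - (-params$c0 - d2 - params$a * pp$x2h + params$b * pp$x1h)
  if (params$s2 == 0) {
    # degenerate noise-free model: +Inf only if every residual vanishes
    # (up to floating-point roundoff of the position recursion)
    tol <- 1e-8 * max(1, max(abs(c(pp$x1h, pp$x2h))))
    return(if (any(abs(c(r1, r2)) > tol)) -Inf else Inf)
  }
  sum(dnorm(c(r1, r2), 0, sqrt(params$s2), log = TRUE))
}

# Design matrix of the identified linear parameterisation. Conditional on the
# state path, the displacement model is linear in (a, b, d_plus, d_minus)
# with net drives d_plus = c0 + c_plus and d_minus = c0 + c_minus; the
# original (c0, c_plus, c_minus) triple is collinear in the design (the c0
# column equals the sum of the two drive-indicator columns), so c0 is
# identified only through the rest-length prior and the sign constraints
# d_minus < c0 < d_plus (with c0 > 0).
linear_design <- function(pp, path) {
  s1 <- SIG1[path]
  s2 <- SIG2[path]
  X <- cbind(a = c(-pp$x1h, -pp$x2h),
             b = c(pp$x2h, pp$x1h),
             d_plus = c(as.numeric(s1 > 0), -as.numeric(s2 > 0)),
             d_minus = c(as.numeric(s1 < 0), -as.numeric(s2 < 0)))
  list(X = X, y = c(pp$dx1, pp$dx2))
}

# Least-squares solution of the stacked linear system for the identified
# block; used for initialisation and as the conditional posterior mean.
linear_mle <- function(pp, path) {
  d <- linear_design(pp, path)
  active <- colSums(abs(d$X)) > 0
  XtX <- crossprod(d$X[, active, drop = FALSE])
  Xty <- crossprod(d$X[, active, drop = FALSE], d$y)
  beta <- rep(NA_real_, 4)
  names(beta) <- colnames(d$X)
  fit <- try(solve(XtX, Xty), silent = TRUE)
  if (!inherits(fit, "try-error")) beta[active] <- drop(fit)
  beta
}

params_to_theta <- function(params) {
  c(a = params$a, b = params$b,
    d_plus = params$c0 + params$c_plus,
    d_minus = params$c0 + params$c_minus)
}

theta_to_params <- function(theta, c0, s2, p_inc, p_coh, dt) {
  list(a = theta[["a"]], b = theta[["b"]], c0 = c0,
       c_plus = theta[["d_plus"]] - c0, c_minus = theta[["d_minus"]] - c0,
       s2 = s2, p_incoherent = p_inc, p_coherent = p_coh, dt = dt)
}

rest_length_logprior <- function(c0, a, b, priors) {
  dnorm(2 * c0 / (a + b), priors$rest_length_mean, priors$rest_length_sd,
        log = TRUE)
}

# Gibbs/MH update of (a, b, d_plus, d_minus) and c0. The identified block is
# proposed from its conjugate multivariate-normal conditional (an
# independence proposal); sign constraints are enforced by rejection and the
# rest-length prior by a Metropolis-Hastings correction. c0 is then drawn
# exactly from its truncated-normal conditional on (max(0, d_minus), d_plus).
update_linear_core <- function(pp, path, current, priors) {
  d <- linear_design(pp, path)
  active <- colSums(abs(d$X)) > 0
  theta <- params_to_theta(current)
  c0 <- current$c0
  held <- names(theta)[!active]
  accepted <- FALSE
  Xa <- d$X[, active, drop = FALSE]
  XtX <- crossprod(Xa)
  U <- try(chol(XtX), silent = TRUE)
  if (!inherits(U, "try-error")) {
    mu <- backsolve(U, backsolve(U, crossprod(Xa, d$y), transpose = TRUE))
    prop <- theta
    prop[active] <- drop(mu) +
      sqrt(current$s2) * backsolve(U, rnorm(sum(active)))
    ok <- prop[["a"]] > 0 && prop[["b"]] > 0 &&
      prop[["d_plus"]] > c0 && prop[["d_minus"]] < c0
    if (ok) {
      log_ratio <- rest_length_logprior(c0, prop[["a"]], prop[["b"]], priors) -
        rest_length_logprior(c0, theta[["a"]], theta[["b"]], priors)
      if (is.finite(log_ratio) && log(runif(1)) < log_ratio) {
        theta <- prop
        accepted <- TRUE
      }
    }
  } else {
    held <- names(theta)
  }
  lo <- max(0, theta[["d_minus"]])
  hi <- theta[["d_plus"]]
  scale <- (theta[["a"]] + theta[["b"]]) / 2
  c0 <- rtruncnorm1(priors$rest_length_mean * scale,
                    priors$rest_length_sd * scale, lo, hi)
  out <- list(a = theta[["a"]], b = theta[["b"]], c0 = c0,
              c_plus = theta[["d_plus"]] - c0,
              c_minus = theta[["d_minus"]] - c0)
  attr(out, "accepted") <- accepted
  attr(out, "held") <- held
  attr(out, "conditional_mean") <- if (!inherits(U, "try-error"))
    setNames(drop(mu), colnames(Xa)) else NULL
  out
}

#' One MCMC update of the linear model parameters
#'
#' Draws `(a, b, c0, c_plus, c_minus)` from their conditional posterior given
#' the state path and noise variance: a conjugate multivariate-normal step on
#' the identified linear block (the net drives `c0 + c_plus` and
#' `c0 + c_minus` together with `a`, `b`), subject to the sign constraints,
#' Metropolis-Hastings-corrected for the rest-length prior on
#' `2 * c0 / (b + a)`, followed by an exact truncated-normal draw of `c0`
#' from that prior. A drive state never visited by the path is not
#' identified; its coefficient is held at the current value and flagged.
#'
#' @inheritParams loglik_trajectory
#' @param current Current parameter values (a `ks_params` object or list).
#' @param priors A [ks_priors()] object.
#' @return List `(a, b, c0, c_plus, c_minus)` with attributes `accepted`
#'   (logical, MH outcome for the linear block) and `held` (names of
#'   unidentified coefficients kept at their current values).
#' @export
update_linear_params <- function(traj, path, current, priors) {
  pp <- prep_trajectory(traj)
  update_linear_core(pp, as_state_index(path), current, priors)
}

#' Conjugate update of the noise variance
#'
#' Inverse-gamma draw with shape `s2_shape + n/2` and rate
#' `s2_rate + RSS/2`, where `RSS` pools the squared displacement residuals
#' of both sisters (the variance is shared between sisters).
#'
#' @inheritParams update_linear_params
#' @param linear_params Current values of `(a, b, c0, c_plus, c_minus)`.
#' @return Scalar draw of `s2` (nm^2).
#' @export
update_noise_var <- function(traj, path, linear_params, priors) {
  pp <- prep_trajectory(traj)
  path <- as_state_index(path)
  update_noise_core(pp, path, linear_params, priors)
}

update_noise_core <- function(pp, path, lp, priors) {
  d1 <- ifelse(SIG1[path] > 0, lp$c_plus, lp$c_minus)
  d2 <- ifelse(SIG2[path] > 0, lp$c_plus, lp$c_minus)
  r1 <- pp$dx1 - (lp$c0 + d1 - lp$a * pp$x1h + lp$b * pp$x2h)
  r2 <- pp$dx2 - (-lp$c0 - d2 - lp$a * pp$x2h + lp$b * pp$x1h)
  rss <- sum(r1^2) + sum(r2^2)
  n <- 2 * pp$L
  1 / rgamma(1, shape = priors$s2_shape + n / 2,
             rate = priors$s2_rate + rss / 2)
}

#' Beta-conjugate update of the switch probabilities
#'
#' Counts switch/no-switch opportunities separately over coherent and
#' incoherent frames of the path and draws each probability from its
#' Beta conditional. A class with no opportunities yields a prior draw.
#'
#' @param path Integer state path.
#' @param priors A [ks_priors()] object.
#' @return Named numeric `c(p_incoherent, p_coherent)`.
#' @export
update_switch_probs <- function(path, priors) {
  path <- as_state_index(path)
  L <- length(path)
  a0 <- priors$switch_alpha
  b0 <- priors$switch_beta
  if (L < 2) {
    return(c(p_incoherent = rbeta(1, a0, b0), p_coherent = rbeta(1, a0, b0)))
  }
  changed <- path[-1] != path[-L]
  coh <- COHERENT_STATE[path[-L]]
  k_c <- sum(changed & coh)
  n_c <- sum(coh)
  k_i <- sum(changed & !coh)
  n_i <- sum(!coh)
  c(p_incoherent = rbeta(1, a0 + k_i, b0 + n_i - k_i),
    p_coherent = rbeta(1, a0 + k_c, b0 + n_c - k_c))
}

#' Sample the hidden state path
#'
#' Draws a new pair-state path given the parameters, either by a blocked
#' forward-filter/backward-sample pass (`"ffbs"`, an exact draw from the
#' path's full conditional) or by one single-site Gibbs sweep over frames
#' (`"gibbs"`). Both target the same posterior; FFBS mixes better per unit
#' work and is the default.
#'
#' @inheritParams loglik_trajectory
#' @param current_path Current path (required for `"gibbs"`).
#' @param method `"ffbs"` or `"gibbs"`.
#' @return Integer state path.
#' @export
sample_state_path <- function(traj, params, current_path = NULL,
                              method = c("ffbs", "gibbs")) {
  method <- match.arg(method)
  pp <- prep_trajectory(traj)
  sample_path_core(pp, params, current_path, method)
}

sample_path_core <- function(pp, params, current_path, method) {
  if (params$s2 <= 0) stop("state sampling requires s2 > 0")
  if (method == "ffbs") {
    .ks_ffbs_cpp(pp$dx1, pp$dx2, pp$x1h, pp$x2h,
                 params$a, params$b, params$c0, params$c_plus,
                 params$c_minus, params$s2,
                 params$p_incoherent, params$p_coherent)
  } else {
    if (is.null(current_path)) stop("gibbs sweep needs a current path")
    .ks_gibbs_sweep_cpp(pp$dx1, pp$dx2, pp$x1h, pp$x2h,
                        params$a, params$b, params$c0, params$c_plus,
                        params$c_minus, params$s2,
                        params$p_incoherent, params$p_coherent,
                        as.integer(current_path))
  }
}

mcmc_defaults <- function() {
  list(n_burn = 2000, n_draws = 4000, n_chains = 3, seed = 1,
       state_sampler = "ffbs", min_frames = 112,
       rhat_threshold = 1.1, state_agreement_threshold = 0.9,
       init_jitter = 0.1)
}

chain_init <- function(pp, traj, priors, dt, jitter) {
  path <- states_from_displacements(traj)
  beta <- linear_mle(pp, path)
  a <- max(beta[["a"]], 1e-4, na.rm = TRUE)
  b <- max(beta[["b"]], 1e-4, na.rm = TRUE)
  dp <- if (is.finite(beta[["d_plus"]])) beta[["d_plus"]] else 100
  dm <- if (is.finite(beta[["d_minus"]])) beta[["d_minus"]] else -100
  if (!(dp > dm)) { tmp <- dp; dp <- max(dm, 1) + 1; dm <- min(tmp, 0) }
  if (dp <= 0) dp <- abs(dp) + 1
  # dispersed starts: jitter multiplicatively, keep ordering dp > dm
  a <- a * exp(rnorm(1, 0, jitter))
  b <- b * exp(rnorm(1, 0, jitter))
  dp <- dp * exp(rnorm(1, 0, jitter))
  lo <- max(0, dm)
  if (dp <= lo) dp <- lo + 1  # keep the c0 interval (max(0, dm), dp) open
  c0 <- lo + (dp - lo) * runif(1, 0.25, 0.75)
  d <- linear_design(pp, path)
  resid <- d$y - d$X %*% c(a, b, dp, dm)
  s2 <- max(stats::var(drop(resid)), 1e-6) * exp(rnorm(1, 0, jitter))
  list(path = path,
       params = list(a = a, b = b, c0 = c0, c_plus = dp - c0,
                     c_minus = dm - c0, s2 = s2,
                     p_incoherent = runif(1, 0.2, 0.6),
                     p_coherent = runif(1, 0.03, 0.15), dt = dt))
}

PARAM_NAMES <- c("a", "b", "c0", "c_plus", "c_minus", "s2",
                 "p_incoherent", "p_coherent")

run_one_chain <- function(pp, traj, priors, cfg, chain_seed, dt) {
  set.seed(chain_seed)
  st <- chain_init(pp, traj, priors, dt, cfg$init_jitter)
  cur <- st$params
  path <- st$path
  n_iter <- cfg$n_burn + cfg$n_draws
  samples <- matrix(NA_real_, cfg$n_draws, length(PARAM_NAMES),
                    dimnames = list(NULL, PARAM_NAMES))
  state_counts <- matrix(0, pp$L, 4)
  switch_counts <- c(k_incoherent = 0, n_incoherent = 0,
                     k_coherent = 0, n_coherent = 0)
  n_accept <- 0L
  held_any <- character(0)
  for (it in seq_len(n_iter)) {
    path <- sample_path_core(pp, cur, path, cfg$state_sampler)
    sp <- update_switch_probs(path, priors)
    cur$p_incoherent <- sp[["p_incoherent"]]
    cur$p_coherent <- sp[["p_coherent"]]
    lin <- update_linear_core(pp, path, cur, priors)
    cur[c("a", "b", "c0", "c_plus", "c_minus")] <-
      lin[c("a", "b", "c0", "c_plus", "c_minus")]
    held_any <- union(held_any, attr(lin, "held"))
    cur$s2 <- update_noise_core(pp, path, cur, priors)
    if (it > cfg$n_burn) {
      n_accept <- n_accept + attr(lin, "accepted")
      j <- it - cfg$n_burn
      samples[j, ] <- unlist(cur[PARAM_NAMES])
      state_counts[cbind(seq_len(pp$L), path)] <-
        state_counts[cbind(seq_len(pp$L), path)] + 1
      # posterior expected switch/opportunity counts per coherence class
      chg <- path[-1] != path[-pp$L]
      coh <- COHERENT_STATE[path[-pp$L]]
      switch_counts <- switch_counts +
        c(sum(chg & !coh), sum(!coh), sum(chg & coh), sum(coh))
    }
  }
  list(samples = samples,
       state_marginals = state_counts / cfg$n_draws,
       switch_counts = switch_counts / cfg$n_draws,
       accept_rate = n_accept / cfg$n_draws,
       seed = chain_seed,
       log = if (length(held_any))
         paste("unidentified coefficients held:",
               paste(held_any, collapse = ", ")) else character(0))
}

#' Fit the switching autoregressive model to one trajectory by MCMC
#'
#' Runs several independent chains from dispersed initialisations, each
#' cycling four update blocks (state path; switch probabilities; linear
#' parameters with the rest-length prior; noise variance), and assesses
#' convergence by the split-chain potential scale reduction factor on every
#' continuous parameter together with cross-chain agreement of the per-frame
#' modal states. Non-convergence is not an error: the fit is marked
#' `excluded`, mirroring the analysis rule that trajectories whose chains
#' fail to converge are dropped.
#'
#' @inheritParams loglik_trajectory
#' @param priors A [ks_priors()] object.
#' @param config Named list overriding any of: `n_burn` (2000), `n_draws`
#'   (4000), `n_chains` (3), `seed`, `state_sampler` (`"ffbs"` or
#'   `"gibbs"`), `min_frames` (112; shorter trajectories run with a
#'   warning), `rhat_threshold` (1.1), `state_agreement_threshold` (0.9),
#'   `init_jitter` (0.1).
#' @return Object of class `ks_fit`: `chains` (per-chain sample matrices,
#'   state marginals, acceptance rates, logs), `convergence` (R-hat per
#'   parameter, state agreement, `converged`, `excluded`), pooled
#'   `state_marginals`, the modal `point_path`, `summary` (from
#'   [summarize_posterior()]) and the configuration used.
#' @export
run_chain <- function(traj, priors = ks_priors(), config = list()) {
  cfg <- utils::modifyList(mcmc_defaults(), config)
  pp <- prep_trajectory(traj)
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- 2
  if (pp$n < cfg$min_frames) {
    warning("trajectory has ", pp$n, " frames, fewer than the ",
            cfg$min_frames, "-frame admission filter; fitting anyway")
  }
  chains <- lapply(seq_len(cfg$n_chains), function(k) {
    run_one_chain(pp, traj, priors, cfg, derive_seed(cfg$seed, k), dt)
  })
  conv <- convergence_report(chains, cfg)
  marg <- Reduce(`+`, lapply(chains, `[[`, "state_marginals")) /
    length(chains)
  fit <- structure(list(chains = chains, convergence = conv,
                        state_marginals = marg,
                        switch_counts = Reduce(`+`, lapply(
                          chains, `[[`, "switch_counts")) / length(chains),
                        point_path = point_state_estimate(marg),
                        priors = priors, config = cfg, dt = dt,
                        n_frames = pp$n),
                   class = "ks_fit")
  fit$summary <- summarize_posterior(fit)
  fit
}

convergence_report <- function(chains, cfg) {
  draws <- lapply(chains, `[[`, "samples")
  rhat <- vapply(PARAM_NAMES, function(p) {
    split_rhat(sapply(draws, function(d) d[, p]))
  }, numeric(1))
  modal <- vapply(chains, function(ch) point_state_estimate(ch$state_marginals),
                  integer(nrow(chains[[1]]$state_marginals)))
  modal <- matrix(modal, ncol = length(chains))
  agreement <- if (length(chains) == 1) 1 else
    mean(apply(modal, 1, function(r) all(r == r[1])))
  converged <- all(is.finite(rhat)) &&
    all(rhat < cfg$rhat_threshold) &&
    agreement >= cfg$state_agreement_threshold
  list(rhat = rhat, state_agreement = agreement,
       rhat_threshold = cfg$rhat_threshold,
       state_agreement_threshold = cfg$state_agreement_threshold,
       converged = converged, excluded = !converged)
}

#' Posterior summaries of a fitted trajectory
#'
#' Pools the post-burn-in draws of all chains and returns per-parameter
#' means, SDs and central credible intervals, plus the per-frame marginal
#' probability of each pair state.
#'
#' @param fit A `ks_fit` from [run_chain()], or a list of chain results.
#' @param prob Credible interval mass (default 0.9).
#' @return List with `params` (data frame: mean, sd, median, lower, upper),
#'   `state_marginals` (frames x 4, rows summing to 1) and `modal_path`.
#' @export
summarize_posterior <- function(fit, prob = 0.9) {
  chains <- if (inherits(fit, "ks_fit")) fit$chains else fit
  pooled <- do.call(rbind, lapply(chains, `[[`, "samples"))
  qs <- c((1 - prob) / 2, 0.5, 1 - (1 - prob) / 2)
  pars <- data.frame(
    parameter = colnames(pooled),
    mean = colMeans(pooled),
    sd = apply(pooled, 2, sd),
    lower = apply(pooled, 2, quantile, qs[1]),
    median = apply(pooled, 2, quantile, qs[2]),
    upper = apply(pooled, 2, quantile, qs[3]),
    row.names = NULL)
  marg <- Reduce(`+`, lapply(chains, `[[`, "state_marginals")) /
    length(chains)
  list(params = pars, state_marginals = marg,
       modal_path = point_state_estimate(marg))
}

#' @export
print.ks_fit <- function(x, ...) {
  cat("Switching AR model fit:", x$n_frames, "frames,",
      length(x$chains), "chains\n")
  cat("  converged:", x$convergence$converged,
      sprintf("(max R-hat %.3f, state agreement %.2f)\n",
              max(x$convergence$rhat), x$convergence$state_agreement))
  print(x$summary$params, digits = 4)
  invisible(x)
}
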