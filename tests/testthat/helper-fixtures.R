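# Shared fixtures: everything is generated in code at test time.

base_params <- function(...) switch_model_params(...)

# Wide rest-length prior centred on the generating model's implied
# equilibrium, so recovery tests measure the likelihood, not the prior.
wide_priors <- function(params = base_params()) {
  ks_priors(rest_length_mean = equilibrium_separation(params),
            rest_length_sd = 1e4)
}

# Short-chain MCMC settings for unit tests (not the analysis defaults).
quick_mcmc <- function(...) {
  utils::modifyList(list(n_burn = 300, n_draws = 600, n_chains = 2,
                         min_frames = 10, seed = 1), list(...))
}

# Exact posterior over all 4^L state paths of a short trajectory, by brute
# force; the independent oracle for the state samplers.
exact_path_posterior <- function(traj, params) {
  L <- nrow(traj) - 1L
  M <- kinetoswitch:::transition_matrix(params$p_incoherent,
                                        params$p_coherent)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  logp <- apply(grid, 1, function(path) {
    lp <- log(0.25)
    if (L > 1) {
      tr <- M[cbind(path[-L], path[-1])]
      if (any(tr == 0)) return(-Inf)
      lp <- lp + sum(log(tr))
    }
    lp + loglik_trajectory(traj, path, params)
  })
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  marg <- sapply(1:4, function(s) {
    vapply(seq_len(L), function(t) sum(w[grid[, t] == s]), numeric(1))
  })
  list(paths = grid, prob = w, marginals = marg)
}

# Random 3D rigid transform (rotation + translation) for invariance tests.
random_rigid_transform <- function() {
  A <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 2000))
}

apply_rigid <- function(P, tf) {
  sweep(as.matrix(P) %*% t(tf$R), 2, tf$t, "+")
}
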