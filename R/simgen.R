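#' One-frame displacement of a sister pair
#'
#' Evaluates the deterministic part of the switching autoregressive update
#' (plus optional supplied noise): `dx1 = c0 + c(sigma1) - a*x1 + b*x2` and
#' `dx2 = -c0 - c(sigma2) - a*x2 + b*x1`, where `c(+) = c_plus` and
#' `c(-) = c_minus`.
#'
#' @param x1,x2 Current sister positions along the plate normal (nm).
#' @param state Pair state (integer code or label, see [pair_states()]).
#' @param params A [switch_model_params()] object.
#' @param noise Length-2 numeric, the Gaussian noise added to each sister's
#'   displacement (default `c(0, 0)`, i.e. noise off).
#' @return Named numeric `c(dx1, dx2)` in nm.
#' @examples
#' p <- switch_model_params()
#' step_displacements(500, -500, "+-", p)  # c(649, -519)
#' @export
step_displacements <- function(x1, x2, state, params, noise = c(0, 0)) {
  if (!all(is.finite(c(x1, x2, noise)))) {
    stop("step_displacements: non-finite position or noise input")
  }
  s <- as_state_index(state)
  drive <- function(sig) if (sig > 0) params$c_plus else params$c_minus
  dx1 <- params$c0 + drive(SIG1[s]) - params$a * x1 + params$b * x2 + noise[1]
  dx2 <- -params$c0 - drive(SIG2[s]) - params$a * x2 + params$b * x1 + noise[2]
  c(dx1 = dx1, dx2 = dx2)
}

#' Advance the hidden pair state by one frame
#'
#' With probability `p_coherent` (current state coherent) or `p_incoherent`
#' (incoherent) exactly one sister flips its polymerisation state, the
#' flipping sister chosen uniformly at random; otherwise the state is
#' unchanged. Under `forced_variant`, when the pair is incoherent the sister
#' who switched last cannot switch again, so every excursion out of coherence
#' resolves as a directional switch of the pair.
#'
#' @inheritParams step_displacements
#' @param forced_variant Logical; forbid the last switcher from flipping while
#'   incoherent.
#' @param last_switcher `1`, `2` or `NA`; the sister that flipped most
#'   recently (required bookkeeping for `forced_variant`).
#' @return List with `state` (integer code) and `switcher` (`1`, `2` or `NA`
#'   if no flip occurred).
#' @export
advance_state <- function(state, params, forced_variant = FALSE,
                          last_switcher = NA_integer_) {
  s <- as_state_index(state)
  p <- if (COHERENT_STATE[s]) params$p_coherent else params$p_incoherent
  if (runif(1) >= p) {
    return(list(state = s, switcher = NA_integer_))
  }
  if (forced_variant && !COHERENT_STATE[s] && !is.na(last_switcher)) {
    sister <- 3L - as.integer(last_switcher)
  } else {
    sister <- if (runif(1) < 0.5) 1L else 2L
  }
  list(state = flip_sister(s, sister), switcher = sister)
}

#' Simulate one paired sister trajectory
#'
#' Generates a paired trajectory from the switching autoregressive model,
#' iterating [advance_state()] then [step_displacements()] per frame, and
#' records the complete truth: the hidden state path, every sister flip, and
#' the directional switch events with their true LIDS/TIDS/JDS labels.
#'
#' @inheritParams advance_state
#' @param n_frames Number of frames (default 150, i.e. 5 min at 2 s/frame).
#' @param init Optional list with elements `x1`, `x2` (nm) and `state`
#'   (initial pair state). Defaults: `x1 = 450`, `x2 = -450` nm and a state
#'   drawn uniformly from the two coherent states.
#' @param seed Optional integer seed for exact reproducibility.
#' @param pair_id,cell_id Identifiers carried into the trajectory table.
#' @return A list of class `ks_sim` with elements
#'   \describe{
#'     \item{trajectory}{data frame `frame`, `time_s`, `x1`, `x2` (nm).}
#'     \item{truth}{list with `states` (integer path of length
#'       `n_frames - 1`; state `t` drives the displacement from frame `t` to
#'       `t + 1`), `switches` (data frame `frame`, `sister`, `from`, `to`),
#'       `events` (data frame of true directional switch events, see
#'       [match_directional_events()]), `n_reverts`, and `notes`.}
#'   }
#' @examples
#' sim <- simulate_trajectory(switch_model_params(), n_frames = 150, seed = 1)
#' head(sim$trajectory)
#' table(sim$truth$events$event_type)
#' @export
simulate_trajectory <- function(params, n_frames = 150, init = NULL,
                                forced_variant = FALSE, seed = NULL,
                                pair_id = 1L, cell_id = 1L) {
  if (n_frames < 2) stop("n_frames must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    init <- list(x1 = 450, x2 = -450,
                 state = if (runif(1) < 0.5) 2L else 3L)
  }
  L <- n_frames - 1L
  x1 <- x2 <- numeric(n_frames)
  x1[1] <- init$x1
  x2[1] <- init$x2
  states <- integer(L)
  switches <- vector("list", L)
  state <- as_state_index(init$state)
  last_switcher <- NA_integer_
  noise_sd <- sqrt(params$s2)
  for (t in seq_len(L)) {
    if (t > 1L) {
      adv <- advance_state(state, params, forced_variant, last_switcher)
      if (!is.na(adv$switcher)) {
        switches[[t]] <- data.frame(frame = t, sister = adv$switcher,
                                    from = state_label(state),
                                    to = state_label(adv$state))
        last_switcher <- adv$switcher
      }
      state <- adv$state
    }
    states[t] <- state
    noise <- if (noise_sd > 0) rnorm(2, 0, noise_sd) else c(0, 0)
    dx <- step_displacements(x1[t], x2[t], state, params, noise)
    x1[t + 1] <- x1[t] + dx[1]
    x2[t + 1] <- x2[t] + dx[2]
  }
  notes <- character(0)
  if (!is_oscillatory(params)) {
    notes <- "parameters outside the oscillatory regime (need a > b and p_incoherent > p_coherent)"
  }
  traj <- data.frame(frame = seq_len(n_frames),
                     time_s = (seq_len(n_frames) - 1) * params$dt,
                     x1 = x1, x2 = x2)
  attr(traj, "dt") <- params$dt
  attr(traj, "pair_id") <- pair_id
  attr(traj, "cell_id") <- cell_id
  sw <- do.call(rbind, switches[!vapply(switches, is.null, logical(1))])
  if (is.null(sw)) {
    sw <- data.frame(frame = integer(0), sister = integer(0),
                     from = character(0), to = character(0))
  }
  ev <- true_events(states, dt = params$dt)
  structure(list(trajectory = traj,
                 truth = list(states = states, switches = sw,
                              events = ev$events, n_reverts = ev$n_reverts,
                              notes = notes)),
            class = "ks_sim")
}

#' Simulate a cohort of independent trajectories
#'
#' @inheritParams simulate_trajectory
#' @param n_traj Number of independent trajectories; per-trajectory seeds are
#'   derived deterministically from `seed`.
#' @return A list of class `ks_cohort`: `sims` (list of [simulate_trajectory()]
#'   results), `params`, and `truth_summary` (true event count, LIDS/TIDS/JDS
#'   counts and the true lead:trail ratio pooled over the cohort).
#' @export
simulate_cohort <- function(params, n_traj, n_frames = 150,
                            forced_variant = FALSE, seed = NULL) {
  if (n_traj < 1) stop("n_traj must be at least 1")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  sims <- lapply(seq_len(n_traj), function(i) {
    simulate_trajectory(params, n_frames = n_frames,
                        forced_variant = forced_variant,
                        seed = derive_seed(seed, i), pair_id = i)
  })
  ev <- do.call(rbind, lapply(sims, function(s) s$truth$events))
  counts <- c(LIDS = sum(ev$event_type == "LIDS"),
              TIDS = sum(ev$event_type == "TIDS"),
              JDS = sum(ev$event_type == "JDS"))
  structure(list(sims = sims, params = params, seed = seed,
                 truth_summary = list(
                   n_events = nrow(ev), counts = counts,
                   lead_trail_ratio = unname(counts["LIDS"] / counts["TIDS"]),
                   n_reverts = sum(vapply(sims, function(s) s$truth$n_reverts,
                                          numeric(1))))),
            class = "ks_cohort")
}

#' Idealised saw-tooth pair trajectory
#'
#' Noise-free triangle-wave motion of two sisters at constant separation with
#' exactly periodic directional switches (both sisters reverse within the
#' same frame, so the true events are all JDS). Used to verify that the
#' detector recovers every switch frame exactly.
#'
#' @param n_frames Number of frames.
#' @param half_period Frames per half period (>= 5, so each leg is a valid
#'   coherent run).
#' @param amplitude Peak centre excursion from the plate (nm); `0` yields a
#'   static pair with no switches.
#' @param separation Constant inter-sister separation (nm).
#' @param dt Frame interval (s).
#' @return A `ks_sim` object (see [simulate_trajectory()]).
#' @export
make_idealized_sawtooth <- function(n_frames = 150, half_period = 17,
                                    amplitude = 1000, separation = 900,
                                    dt = 2) {
  if (half_period < 5) stop("half_period must be at least 5 frames")
  L <- n_frames - 1L
  if (amplitude == 0) {
    states <- rep(2L, L)
    m <- numeric(n_frames)
  } else {
    # direction of motion for displacement step t: +1 for the first
    # half-period, then alternating
    dirs <- rep(rep(c(1, -1), length.out = ceiling(L / half_period)),
                each = half_period)[seq_len(L)]
    states <- ifelse(dirs > 0, 2L, 3L)
    step <- 2 * amplitude / half_period
    m <- cumsum(c(-amplitude, dirs * step))[seq_len(n_frames)]
  }
  traj <- data.frame(frame = seq_len(n_frames),
                     time_s = (seq_len(n_frames) - 1) * dt,
                     x1 = m + separation / 2, x2 = m - separation / 2)
  attr(traj, "dt") <- dt
  attr(traj, "pair_id") <- 1L
  attr(traj, "cell_id") <- 1L
  sw_at <- which(diff(states) != 0) + 1L
  sw <- data.frame(frame = rep(sw_at, each = 2),
                   sister = rep(c(1L, 2L), length(sw_at)),
                   from = rep(state_label(states[sw_at - 1L]), each = 2),
                   to = rep(state_label(states[sw_at]), each = 2))
  ev <- true_events(states, dt = dt)
  structure(list(trajectory = traj,
                 truth = list(states = states, switches = sw,
                              events = ev$events, n_reverts = ev$n_reverts,
                              notes = character(0))),
            class = "ks_sim")
}

#' Crude state path from displacement signs
#'
#' Maps the sign of a centred moving average of each sister's frame-to-frame
#' displacement onto a polymerisation state (sister 1 moving in +x is driven
#' by `+`; sister 2 moving in +x by `-`). Used to initialise the MCMC and to
#' run the event detector on noise-free input without inference.
#'
#' @param traj A trajectory data frame with columns `x1`, `x2`.
#' @param smooth_window Odd moving-average width in frames (default 3).
#' @return Integer state path of length `nrow(traj) - 1`.
#' @export
states_from_displacements <- function(traj, smooth_window = 3) {
  dx1 <- diff(traj$x1)
  dx2 <- diff(traj$x2)
  smooth <- function(v) {
    if (smooth_window <= 1 || length(v) < smooth_window) return(v)
    f <- as.numeric(stats::filter(v, rep(1 / smooth_window, smooth_window),
                                  sides = 2))
    f[is.na(f)] <- v[is.na(f)]
    f
  }
  s1 <- ifelse(smooth(dx1) > 0, 1L, -1L)
  s2 <- ifelse(smooth(dx2) > 0, -1L, 1L)
  ifelse(s1 > 0, ifelse(s2 > 0, 1L, 2L), ifelse(s2 > 0, 3L, 4L))
}
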