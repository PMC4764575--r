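#' Modal state path from per-frame marginals
#'
#' Collapses a frames x 4 matrix of posterior pair-state probabilities to a
#' single path by taking the per-frame mode; ties are broken toward the
#' previous frame's chosen state (persistence), and toward the lowest state
#' code at the first frame.
#'
#' @param state_marginals Numeric matrix (frames x 4), rows summing to 1.
#' @param tol Tie tolerance on probabilities.
#' @return Integer state path.
#' @export
point_state_estimate <- function(state_marginals, tol = 1e-9) {
  m <- as.matrix(state_marginals)
  if (ncol(m) != 4) stop("state_marginals must have 4 columns")
  path <- integer(nrow(m))
  for (t in seq_len(nrow(m))) {
    top <- which(m[t, ] >= max(m[t, ]) - tol)
    if (t > 1 && path[t - 1] %in% top) {
      path[t] <- path[t - 1]
    } else {
      path[t] <- top[1]
    }
  }
  path
}

#' Coherent runs in a state path
#'
#' A coherent run is a maximal interval over which the pair state is constant
#' and coherent (`+-` or `-+`) for at least `min_length` frames. Shorter
#' coherent stretches and incoherent frames are not runs.
#'
#' @param path Integer or label state path.
#' @param min_length Minimum run length in frames (default 5).
#' @return Data frame with `start_frame`, `end_frame`, `length`, `state`
#'   (label) and `direction` (+1 / -1), in frame order.
#' @export
detect_coherent_runs <- function(path, min_length = 5) {
  path <- as_state_index(path)
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- COHERENT_STATE[r$values] & r$lengths >= min_length
  data.frame(start_frame = starts[keep], end_frame = ends[keep],
             length = r$lengths[keep], state = state_label(r$values[keep]),
             direction = STATE_DIRECTION[r$values[keep]])
}

# Shared event-matching engine. `runs` must be an ordered run table as
# produced by detect_coherent_runs(); consecutive runs of opposite direction
# yield a directional switch event, same-direction neighbours are reverts.
match_events_engine <- function(runs, path, dt = 2) {
  path <- as_state_index(path)
  events <- list()
  n_reverts <- 0L
  if (nrow(runs) >= 2) {
    for (i in seq_len(nrow(runs) - 1L)) {
      before <- runs[i, ]
      after <- runs[i + 1L, ]
      if (after$direction == before$direction) {
        n_reverts <- n_reverts + 1L
        next
      }
      gap <- seq.int(before$end_frame + 1L, after$start_frame)
      # per sister, the flip that persists into run_after: the last frame in
      # the gap at which that sister's state changes
      frames <- vapply(1:2, function(k) {
        sig <- if (k == 1) SIG1[path] else SIG2[path]
        ch <- gap[sig[gap] != sig[gap - 1L]]
        if (length(ch) == 0) NA_integer_ else ch[length(ch)]
      }, integer(1))
      if (anyNA(frames)) next  # not a full pair reversal; skip defensively
      # the lead sister of run_before is the one driven poleward: in this
      # model's sign convention the sigma = '+' sister of the coherent state
      # (its flip sends the pair into the separation-shrinking '--' state)
      lead <- if (before$state == "+-") 1L else 2L
      f_lead <- frames[lead]
      f_trail <- frames[3L - lead]
      type <- classify_event(f_lead, f_trail)
      events[[length(events) + 1L]] <- data.frame(
        before_index = i, after_index = i + 1L,
        before_start = before$start_frame, before_end = before$end_frame,
        after_start = after$start_frame, after_end = after$end_frame,
        direction_before = before$direction,
        lead_sister = lead,
        switch_frame_sister1 = frames[1], switch_frame_sister2 = frames[2],
        switch_frame_lead = f_lead, switch_frame_trail = f_trail,
        first_switch_frame = min(frames),
        first_switcher = switch(type, LIDS = "lead", TIDS = "trail",
                                JDS = "joint"),
        event_type = type,
        completion_time_s = abs(f_lead - f_trail) * dt)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_events()
  if (nrow(ev)) ev$event_index <- seq_len(nrow(ev))
  list(events = ev, n_reverts = n_reverts)
}

empty_events <- function() {
  data.frame(before_index = integer(0), after_index = integer(0),
             before_start = integer(0), before_end = integer(0),
             after_start = integer(0), after_end = integer(0),
             direction_before = numeric(0), lead_sister = integer(0),
             switch_frame_sister1 = integer(0),
             switch_frame_sister2 = integer(0),
             switch_frame_lead = integer(0), switch_frame_trail = integer(0),
             first_switch_frame = integer(0), first_switcher = character(0),
             event_type = character(0), completion_time_s = numeric(0))
}

#' Match switch points into directional switching events
#'
#' Pairs each coherent run with the next run of opposite direction, locates
#' each sister's switch frame inside the intervening gap (the flip that
#' persists into the following run), and classifies the event by switching
#' order. Consecutive runs of the same direction (a transient single-sister
#' excursion, a "revert") produce no directional event and are tallied
#' separately.
#'
#' @param runs Run table from [detect_coherent_runs()].
#' @param path The state path the runs were computed from.
#' @param dt Frame interval (s), for completion times.
#' @return List with `events` (one row per directional switch; includes both
#'   sisters' switch frames, the lead sister of the preceding run, the event
#'   type and the completion time) and `n_reverts`.
#' @export
match_directional_events <- function(runs, path, dt = 2) {
  match_events_engine(runs, path, dt = dt)
}

# True directional events of a generative state path: same engine, but every
# maximal coherent block counts (no minimum run length).
true_events <- function(states, dt = 2) {
  runs <- detect_coherent_runs(states, min_length = 1)
  match_events_engine(runs, states, dt = dt)
}

#' Classify a directional switch by switching order
#'
#' A lead-initiated directional switch (LIDS) has the lead sister switching
#' at least one frame before the trailing sister, a trail-initiated switch
#' (TIDS) the reverse; sisters switching within the same frame give a joint
#' directional switch (JDS).
#'
#' @param switch_frame_lead,switch_frame_trail Switch frames of the lead and
#'   trailing sister of the preceding coherent run.
#' @return `"LIDS"`, `"TIDS"` or `"JDS"`.
#' @export
classify_event <- function(switch_frame_lead, switch_frame_trail) {
  if (switch_frame_lead < switch_frame_trail) "LIDS"
  else if (switch_frame_lead > switch_frame_trail) "TIDS"
  else "JDS"
}

#' Score detected events against simulation truth
#'
#' Greedily matches detected directional switch events to true ones by
#' nearest first-switch frame within a window (default: half the median true
#' run length). Accuracy is the fraction of correct event-type calls among
#' matched true events, with unmatched detections counting against it.
#'
#' @param events Detected event table ([match_directional_events()]).
#' @param truth Truth record of a `ks_sim` (list with `states` and `events`).
#' @param window Matching half-window in frames; `NULL` for the default rule.
#' @return List with `accuracy`, `n_true`, `n_detected`, `n_matched`,
#'   `n_correct`, `n_unmatched_detected` and the `matches` table.
#' @export
score_against_truth <- function(events, truth, window = NULL) {
  true_ev <- truth$events
  if (is.null(window)) {
    blocks <- detect_coherent_runs(truth$states, min_length = 1)
    window <- max(1, stats::median(blocks$length) / 2)
  }
  n_det <- nrow(events)
  n_true <- nrow(true_ev)
  if (n_true == 0) {
    return(list(accuracy = if (n_det == 0) 1 else 0, n_true = 0,
                n_detected = n_det, n_matched = 0, n_correct = 0,
                n_unmatched_detected = n_det,
                matches = data.frame()))
  }
  taken <- rep(FALSE, n_true)
  matches <- list()
  unmatched <- 0L
  if (n_det > 0) {
    # visit detections in order of their best match distance so close pairs
    # claim each other first
    dist <- abs(outer(events$first_switch_frame, true_ev$first_switch_frame,
                      "-"))
    ord <- order(apply(dist, 1, min))
    for (d in ord) {
      cand <- which(!taken & dist[d, ] <= window)
      if (length(cand) == 0) {
        unmatched <- unmatched + 1L
        next
      }
      j <- cand[which.min(dist[d, cand])]
      taken[j] <- TRUE
      matches[[length(matches) + 1L]] <- data.frame(
        detected = d, true = j, frame_error = dist[d, j],
        detected_type = events$event_type[d],
        true_type = true_ev$event_type[j],
        correct = events$event_type[d] == true_ev$event_type[j])
    }
  }
  m <- if (length(matches)) do.call(rbind, matches) else
    data.frame(correct = logical(0))
  n_matched <- nrow(m)
  n_correct <- sum(m$correct)
  denom <- n_matched + unmatched
  list(accuracy = if (denom > 0) n_correct / denom else NA_real_,
       n_true = n_true, n_detected = n_det, n_matched = n_matched,
       n_correct = n_correct, n_unmatched_detected = unmatched,
       matches = m)
}

#' Summary statistics of directional switching events
#'
#' @param events Event table ([match_directional_events()]).
#' @param runs Run table ([detect_coherent_runs()]).
#' @param dt Frame interval (s).
#' @return List with event count, LIDS/TIDS/JDS fractions, the lead:trail
#'   bias `fraction(LIDS)/fraction(TIDS)` (`Inf` with `bias_undefined = TRUE`
#'   when no TIDS occurred), coherent-run duration summaries (mean, SD,
#'   median, CV, in seconds) and median completion times by event type.
#' @export
event_statistics <- function(events, runs, dt = 2) {
  if (nrow(events) == 0) stop("event_statistics requires at least one event")
  n <- nrow(events)
  counts <- c(LIDS = sum(events$event_type == "LIDS"),
              TIDS = sum(events$event_type == "TIDS"),
              JDS = sum(events$event_type == "JDS"))
  fractions <- counts / n
  bias <- unname(if (counts["TIDS"] == 0) Inf else
    counts["LIDS"] / counts["TIDS"])
  dur <- runs$length * dt
  completion <- vapply(c("LIDS", "TIDS", "JDS"), function(tp) {
    x <- events$completion_time_s[events$event_type == tp]
    if (length(x)) stats::median(x) else NA_real_
  }, numeric(1))
  list(n_events = n, counts = counts, fractions = fractions,
       lead_trail_bias = bias, bias_undefined = !is.finite(bias),
       run_duration_s = c(mean = mean(dur), sd = sd(dur),
                          median = stats::median(dur),
                          cv = sd(dur) / mean(dur)),
       median_completion_s = completion)
}
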