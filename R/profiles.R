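#' Event-aligned averaging of a scalar signal
#'
#' Stacks windows of a per-frame signal centred on each event's first-switch
#' frame (the modal switching time of the first switching sister) and
#' averages per lag, optionally split by conditioning labels such as the
#' event type or the prior event type. Windows truncated by trajectory ends
#' contribute to the lags they cover.
#'
#' @param signal Data frame with `pair_id`, `frame` and a `value` column.
#' @param events Event table with `pair_id`, an alignment frame column and
#'   any conditioning columns.
#' @param dt Frame interval (s).
#' @param window_s Half-window in seconds (default 40).
#' @param align_col Column of `events` giving the alignment frame
#'   (default `"first_switch_frame"`).
#' @param condition_cols Character vector of `events` columns to condition
#'   on (default `"event_type"`); may be empty.
#' @return Data frame of class `ks_profile`: conditioning columns, `lag_s`,
#'   `mean`, `sem`, `n`; lags with no coverage are absent.
#' @export
align_event_windows <- function(signal, events, dt = 2, window_s = 40,
                                align_col = "first_switch_frame",
                                condition_cols = "event_type") {
  stopifnot(all(c("pair_id", "frame", "value") %in% names(signal)))
  if (!align_col %in% names(events)) {
    stop("events lacks alignment column ", align_col)
  }
  if (nrow(events) == 0) stop("no events to align")
  w <- round(window_s / dt)
  lags <- -w:w
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    sig <- signal[signal$pair_id == ev$pair_id, ]
    at <- match(ev[[align_col]] + lags, sig$frame)
    ok <- !is.na(at)
    if (!any(ok)) next
    rows[[i]] <- data.frame(event = i, lag_s = lags[ok] * dt,
                            value = sig$value[at[ok]])
    for (cc in condition_cols) rows[[i]][[cc]] <- ev[[cc]]
  }
  long <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(long)) stop("no signal coverage for any event window")
  grp <- long[, c(condition_cols, "lag_s"), drop = FALSE]
  agg <- stats::aggregate(long$value, grp, function(v) {
    c(mean = mean(v), sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA,
      n = length(v))
  })
  out <- cbind(agg[, c(condition_cols, "lag_s"), drop = FALSE],
               as.data.frame(agg$x))
  out <- out[do.call(order, out[, c(condition_cols, "lag_s"), drop = FALSE]), ]
  rownames(out) <- NULL
  class(out) <- c("ks_profile", class(out))
  out
}

#' Run-rescaled averaging of a scalar signal
#'
#' Linearly rescales each admitted coherent run onto a common `[0, 1]` grid
#' (proportion of run) and averages the interpolated signal per grid point,
#' optionally split by conditioning labels carried on the run table (e.g.
#' prior/next event type). Only runs of `min_frames` to `max_frames`
#' inclusive are admitted.
#'
#' @param signal Data frame `pair_id`, `frame`, `value`.
#' @param runs Run table with `pair_id`, `start_frame`, `end_frame` and any
#'   conditioning columns (see [label_runs()]).
#' @param min_frames,max_frames Admission window in frames (defaults 6, 20).
#' @param grid_size Number of grid points on `[0, 1]` (default 101).
#' @param condition_cols Conditioning columns of `runs`; may be empty.
#' @return Data frame: conditioning columns, `fraction`, `mean`, `sem`, `n`.
#' @export
rescale_runs <- function(signal, runs, min_frames = 6, max_frames = 20,
                         grid_size = 101, condition_cols = character(0)) {
  stopifnot(all(c("pair_id", "frame", "value") %in% names(signal)))
  admit <- runs$length >= min_frames & runs$length <= max_frames
  runs <- runs[admit, , drop = FALSE]
  if (nrow(runs) == 0) stop("no runs admitted by the length window")
  grid <- seq(0, 1, length.out = grid_size)
  rows <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    rn <- runs[i, ]
    sig <- signal[signal$pair_id == rn$pair_id, ]
    at <- match(rn$start_frame:rn$end_frame, sig$frame)
    if (anyNA(at)) next
    v <- sig$value[at]
    frac <- seq(0, 1, length.out = length(v))
    rows[[i]] <- data.frame(run = i, fraction = grid,
                            value = approx(frac, v, xout = grid)$y)
    for (cc in condition_cols) rows[[i]][[cc]] <- rn[[cc]]
  }
  long <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(long)) stop("no signal coverage for any admitted run")
  grp <- long[, c(condition_cols, "fraction"), drop = FALSE]
  agg <- stats::aggregate(long$value, grp, function(v) {
    c(mean = mean(v), sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA,
      n = length(v))
  })
  out <- cbind(agg[, c(condition_cols, "fraction"), drop = FALSE],
               as.data.frame(agg$x))
  out <- out[do.call(order, out[, c(condition_cols, "fraction"),
                                drop = FALSE]), ]
  rownames(out) <- NULL
  out
}

#' Label runs with their bounding event types
#'
#' Attaches to each coherent run the type of the directional switch that
#' started it (`prior_event_type`) and the one that ended it
#' (`next_event_type`), using the run indices carried on the event table.
#'
#' @param runs Run table ([detect_coherent_runs()]).
#' @param events Event table ([match_directional_events()]).
#' @return `runs` with the two label columns added (`NA` where no event
#'   bounds the run).
#' @export
label_runs <- function(runs, events) {
  runs$prior_event_type <- NA_character_
  runs$next_event_type <- NA_character_
  if (nrow(events)) {
    runs$prior_event_type[events$after_index] <- events$event_type
    runs$next_event_type[events$before_index] <- events$event_type
  }
  runs
}

#' Autocorrelation of sister-centre displacements
#'
#' Computes overlapping `lag_frames`-frame displacements of the sister-pair
#' centre along the plate normal, pools their autocorrelation over lags
#' across trajectories, and estimates the oscillation half-period as the lag
#' of the global minimum.
#'
#' @param centres List of numeric vectors (or a single vector), each a
#'   trajectory of the sister-centre position (nm).
#' @param lag_frames Displacement span in frames (default 4, i.e. 8 s).
#' @param max_lag_s Largest lag examined, in seconds.
#' @param dt Frame interval (s).
#' @return List with `curve` (data frame `lag_s`, `r`, `n`) and
#'   `half_period_s` (lag of the global minimum over positive lags).
#' @export
displacement_autocorrelation <- function(centres, lag_frames = 4,
                                         max_lag_s = 60, dt = 2) {
  if (is.numeric(centres)) centres <- list(centres)
  disp <- lapply(centres, function(x) {
    if (length(x) <= lag_frames) return(numeric(0))
    x[-seq_len(lag_frames)] - x[seq_len(length(x) - lag_frames)]
  })
  disp <- disp[vapply(disp, length, integer(1)) > 1]
  if (!length(disp)) stop("series too short for the displacement lag")
  if (all(vapply(disp, function(d) var(d) == 0, logical(1)))) {
    stop("constant position series: displacement autocorrelation undefined")
  }
  max_lag <- floor(max_lag_s / dt)
  curve <- lapply(0:max_lag, function(l) {
    a <- unlist(lapply(disp, function(d) {
      if (length(d) > l) d[seq_len(length(d) - l)] else numeric(0)
    }))
    b <- unlist(lapply(disp, function(d) {
      if (length(d) > l) d[(l + 1):length(d)] else numeric(0)
    }))
    if (length(a) < 3) return(NULL)
    data.frame(lag_s = l * dt, r = stats::cor(a, b), n = length(a))
  })
  curve <- do.call(rbind, curve[!vapply(curve, is.null, logical(1))])
  pos <- curve[curve$lag_s > 0, ]
  list(curve = curve,
       half_period_s = pos$lag_s[which.min(pos$r)])
}

#' Rank-based comparison of groups
#'
#' Two-sided Mann-Whitney rank-sum test for two groups, or Kruskal-Wallis
#' homogeneity test for two or more.
#'
#' @param groups Named list of numeric vectors (each non-empty).
#' @param test `"rank-sum"` (exactly 2 groups) or `"rank-homogeneity"`.
#' @return List `statistic`, `p_value`, `test`, `n` (group sizes).
#' @export
compare_distributions <- function(groups,
                                  test = c("rank-sum", "rank-homogeneity")) {
  test <- match.arg(test)
  if (length(groups) < 2 || any(vapply(groups, length, integer(1)) == 0)) {
    stop("need at least two non-empty groups")
  }
  if (test == "rank-sum") {
    if (length(groups) != 2) stop("rank-sum test needs exactly two groups")
    ht <- wilcox.test(groups[[1]], groups[[2]])
  } else {
    ht <- kruskal.test(groups)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test,
       n = vapply(groups, length, integer(1)))
}

#' Pooled twist-distance correlation
#'
#' Pearson correlation between twist angle and inter-sister distance over
#' all pooled frames.
#'
#' @param twist,distance Paired numeric vectors (frames pooled over
#'   trajectories).
#' @return List `r`, `p_value`, `n`.
#' @export
twist_distance_correlation <- function(twist, distance) {
  ok <- is.finite(twist) & is.finite(distance)
  ht <- cor.test(twist[ok], distance[ok], method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = sum(ok))
}

#' Median separation of two groups in component-SD units
#'
#' Reports `|median(A) - median(B)|` as a fraction of the pooled
#' within-group SD, and whether it clears the 2-SD separation that a mixture
#' of two Gaussians needs for its density to be bimodal.
#'
#' @param values_a,values_b Non-empty numeric vectors (the two putative
#'   mixture components, e.g. a quantity at LIDS vs TIDS events).
#' @return List `separation_sd`, `bimodal` (separation >= 2).
#' @export
bimodality_separation <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be non-empty")
  na <- length(values_a)
  nb <- length(values_b)
  pooled_sd <- if (na + nb > 2) {
    sqrt(((na - 1) * var(values_a) + (nb - 1) * var(values_b)) /
           (na + nb - 2))
  } else 0
  sep <- if (is.finite(pooled_sd) && pooled_sd > 0) {
    abs(median(values_a) - median(values_b)) / pooled_sd
  } else 0
  list(separation_sd = sep, bimodal = sep >= 2)
}
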