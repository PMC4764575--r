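#' Fit the metaphase plate through kinetochore positions
#'
#' Fits, per frame, a least-squares plane through the cloud of kinetochore
#' positions: the plate point is the centroid and the plate normal the
#' direction of minimal variance of the cloud. Normal orientation is made
#' temporally consistent (each frame's normal has non-negative dot product
#' with the previous frame's; the first frame's normal has its largest
#' component positive).
#'
#' @param points Data frame with columns `frame`, `x`, `y`, `z` (nm), the
#'   pooled kinetochore positions per frame (>= 3 non-collinear points).
#' @return Data frame of class `ks_plate`: `frame`, plate point `px, py, pz`
#'   and unit normal `nx, ny, nz`.
#' @export
fit_plate <- function(points) {
  need <- c("frame", "x", "y", "z")
  if (!all(need %in% names(points))) {
    stop("points must have columns frame, x, y, z")
  }
  frames <- sort(unique(points$frame))
  out <- vector("list", length(frames))
  prev_n <- NULL
  for (i in seq_along(frames)) {
    f <- frames[i]
    P <- as.matrix(points[points$frame == f, c("x", "y", "z")])
    if (nrow(P) < 3) stop("frame ", f, ": need at least 3 points")
    ctr <- colMeans(P)
    Pc <- sweep(P, 2, ctr)
    sv <- svd(Pc, nu = 0)
    if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
      stop("frame ", f, ": degenerate (collinear) kinetochore cloud")
    }
    nrm <- sv$v[, 3]
    if (is.null(prev_n)) {
      if (nrm[which.max(abs(nrm))] < 0) nrm <- -nrm
    } else if (sum(nrm * prev_n) < 0) {
      nrm <- -nrm
    }
    prev_n <- nrm
    out[[i]] <- data.frame(frame = f, px = ctr[1], py = ctr[2], pz = ctr[3],
                           nx = nrm[1], ny = nrm[2], nz = nrm[3])
  }
  res <- do.call(rbind, out)
  class(res) <- c("ks_plate", class(res))
  res
}

#' Signed plate-normal coordinates of a 3D track
#'
#' Projects positions onto the plate normal: the signed distance of each
#' point from the metaphase plate.
#'
#' @param track Data frame with `frame`, `x`, `y`, `z` (nm).
#' @param plate A [fit_plate()] result covering the track's frames.
#' @return Numeric vector of signed normal distances (nm), one per track row.
#' @export
to_plate_coords <- function(track, plate) {
  idx <- match(track$frame, plate$frame)
  if (anyNA(idx)) stop("plate fit missing frames: ",
                       paste(unique(track$frame[is.na(idx)]), collapse = ", "))
  (track$x - plate$px[idx]) * plate$nx[idx] +
    (track$y - plate$py[idx]) * plate$ny[idx] +
    (track$z - plate$pz[idx]) * plate$nz[idx]
}

#' Twist angle of the sister axis
#'
#' Angle between the (undirected) sister-sister axis and the plate normal:
#' `acos(|unit(p1 - p2) . normal|)` in degrees, in `[0, 90]`.
#'
#' @param p1,p2 Sister positions: length-3 vectors or n x 3 matrices (nm).
#' @param normal Unit plate normal: length-3 vector or n x 3 matrix.
#' @return Twist angle(s) in degrees.
#' @export
twist_angle <- function(p1, p2, normal) {
  p1 <- rbind_vec(p1)
  p2 <- rbind_vec(p2)
  normal <- rbind_vec(normal)
  axis <- p1 - p2
  len <- sqrt(rowSums(axis^2))
  if (any(len == 0)) stop("twist_angle: coincident sister positions")
  cosang <- abs(rowSums(axis * normal)) / len
  drop(acos(pmin(1, cosang)) * 180 / pi)
}

rbind_vec <- function(v) {
  if (is.null(dim(v))) matrix(v, nrow = 1) else as.matrix(v)
}

#' Plate-frame observables of one paired 3D track
#'
#' Converts a paired sister track into the model's observables: signed
#' plate-normal positions of both sisters, the 3D inter-sister distance,
#' percent stretch relative to the rest length, and the twist angle.
#'
#' @param pair_track Data frame with `frame` and sister coordinates
#'   `x1_x, x1_y, x1_z, x2_x, x2_y, x2_z` (nm).
#' @param plate A [fit_plate()] result.
#' @param rest_length Relaxed inter-sister spring length L0 (nm; default 788,
#'   the value measured on microtubule-depolymerised cells).
#' @param dt Frame interval (s).
#' @return Data frame `frame`, `time_s`, `x1`, `x2` (signed normal distances,
#'   nm), `d` (3D inter-sister distance, nm), `stretch_pct`
#'   (`100 * (d - L0) / L0`) and `twist_deg`.
#' @export
geometry_series <- function(pair_track, plate, rest_length = 788, dt = 2) {
  need <- c("frame", "x1_x", "x1_y", "x1_z", "x2_x", "x2_y", "x2_z")
  if (!all(need %in% names(pair_track))) {
    stop("pair_track must have columns ", paste(need, collapse = ", "))
  }
  idx <- match(pair_track$frame, plate$frame)
  if (anyNA(idx)) stop("plate fit missing frames for this track")
  p1 <- as.matrix(pair_track[, c("x1_x", "x1_y", "x1_z")])
  p2 <- as.matrix(pair_track[, c("x2_x", "x2_y", "x2_z")])
  nrm <- as.matrix(plate[idx, c("nx", "ny", "nz")])
  t1 <- data.frame(frame = pair_track$frame, x = p1[, 1], y = p1[, 2],
                   z = p1[, 3])
  t2 <- data.frame(frame = pair_track$frame, x = p2[, 1], y = p2[, 2],
                   z = p2[, 3])
  d <- sqrt(rowSums((p1 - p2)^2))
  data.frame(frame = pair_track$frame,
             time_s = (pair_track$frame - 1) * dt,
             x1 = to_plate_coords(t1, plate),
             x2 = to_plate_coords(t2, plate),
             d = d,
             stretch_pct = 100 * (d - rest_length) / rest_length,
             twist_deg = twist_angle(p1, p2, nrm))
}

#' Admission filter for paired tracks
#'
#' Keeps tracks whose longest gap-free stretch of consecutive frames (all
#' coordinates finite) spans at least `min_frames` frames, trimmed to that
#' stretch; everything else is excluded with a reason.
#'
#' @param tracks Data frame with `cell_id`, `pair_id`, `frame` and coordinate
#'   columns (any set of numeric columns beyond the identifiers).
#' @param min_frames Minimum number of consecutive complete frames
#'   (default 112).
#' @return List with `tracks` (retained rows, trimmed) and `log` (one row per
#'   input track: `cell_id`, `pair_id`, `retained`, `n_frames`, `reason`).
#' @export
filter_tracks <- function(tracks, min_frames = 112) {
  if (!all(c("cell_id", "pair_id", "frame") %in% names(tracks))) {
    stop("tracks must have cell_id, pair_id and frame columns")
  }
  coord_cols <- setdiff(names(tracks), c("cell_id", "pair_id", "frame"))
  key <- interaction(tracks$cell_id, tracks$pair_id, drop = TRUE)
  kept <- list()
  logs <- list()
  for (k in levels(key)) {
    tr <- tracks[key == k, ]
    tr <- tr[order(tr$frame), ]
    complete <- rowSums(!is.finite(as.matrix(tr[, coord_cols]))) == 0
    frames <- tr$frame[complete]
    seg <- longest_consecutive(frames)
    if (length(seg) >= min_frames) {
      kept[[k]] <- tr[tr$frame %in% seg, ]
      logs[[k]] <- data.frame(cell_id = tr$cell_id[1], pair_id = tr$pair_id[1],
                              retained = TRUE, n_frames = length(seg),
                              reason = "")
    } else {
      logs[[k]] <- data.frame(cell_id = tr$cell_id[1], pair_id = tr$pair_id[1],
                              retained = FALSE, n_frames = length(seg),
                              reason = sprintf(
                                "longest gap-free segment %d < %d frames",
                                length(seg), min_frames))
    }
  }
  list(tracks = if (length(kept)) do.call(rbind, c(kept, make.row.names = FALSE))
       else tracks[0, ],
       log = do.call(rbind, c(logs, make.row.names = FALSE)))
}

longest_consecutive <- function(frames) {
  if (length(frames) == 0) return(integer(0))
  breaks <- c(0, which(diff(frames) != 1), length(frames))
  lens <- diff(breaks)
  i <- which.max(lens)
  frames[(breaks[i] + 1):breaks[i + 1]]
}
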