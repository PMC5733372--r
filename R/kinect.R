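# Motion-capture skeleton I/O, Fourier resampling, segment-length scaling and
# planar joint-angle extraction.
#
# The interchange format is a long CSV with header time_s,joint,x_m,y_m,z_m:
# one row per joint per frame, joints named shoulder/elbow/wrist/hand,
# coordinates in metres. The capture frame's +y axis is vertical (up); the
# horizontal motion axis is found from the data.

.required_joints <- c("shoulder", "elbow", "wrist", "hand")

#' Construct a skeleton recording
#'
#' @param time frame timestamps (s), nondecreasing.
#' @param joints named list of n x 3 coordinate matrices (columns x, y, z in
#'   metres) for `shoulder`, `elbow`, `wrist`, `hand`.
#' @param fps nominal frame rate; by default inferred from the timestamps.
#' @param subject optional subject identifier.
#' @return an object of class `"skeleton_recording"`.
#' @export
skeleton_recording <- function(time, joints, fps = NULL, subject = NA_character_) {
  time <- as.numeric(time)
  if (any(diff(time) < 0)) stop("timestamps must be nondecreasing", call. = FALSE)
  missing <- setdiff(.required_joints, names(joints))
  if (length(missing))
    stop("missing required joint(s): ", paste(missing, collapse = ", "), call. = FALSE)
  joints <- lapply(joints[.required_joints], function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L || nrow(m) != length(time))
      stop("each joint needs one (x, y, z) row per frame", call. = FALSE)
    if (any(!is.finite(m))) stop("joint positions must be finite", call. = FALSE)
    colnames(m) <- c("x", "y", "z")
    m
  })
  if (is.null(fps)) fps <- 1 / stats::median(diff(time))
  structure(list(time = time, joints = joints, fps = fps, subject = subject),
            class = "skeleton_recording")
}

#' @export
print.skeleton_recording <- function(x, ...) {
  cat(sprintf("Skeleton recording: %d frames at %.4g fps (%.2f s)%s\n",
              length(x$time), x$fps, diff(range(x$time)),
              if (is.na(x$subject)) "" else paste0(", subject ", x$subject)))
  invisible(x)
}

#' Read a skeleton recording from CSV
#'
#' Expects the long format `time_s,joint,x_m,y_m,z_m` (one row per joint per
#' frame). Rows with unknown joint names are ignored with a warning; frames
#' missing any of the required joints (shoulder, elbow, wrist, hand) are an
#' error.
#'
#' @param path CSV file path.
#' @param subject optional subject id stored on the recording.
#' @return a [skeleton_recording()].
#' @export
read_skeleton <- function(path, subject = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "joint", "x_m", "y_m", "z_m")
  if (!all(need %in% names(df)))
    stop("expected CSV header time_s,joint,x_m,y_m,z_m", call. = FALSE)
  bad <- !is.finite(df$time_s) | !is.finite(df$x_m) | !is.finite(df$y_m) | !is.finite(df$z_m)
  if (any(bad))
    stop("unparseable rows (non-numeric fields) at lines: ",
         paste(utils::head(which(bad) + 1L, 10), collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(df$joint), .required_joints)
  if (length(unknown)) {
    warning("ignoring unknown joint name(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    df <- df[df$joint %in% .required_joints, ]
  }
  for (j in .required_joints) {
    if (!any(df$joint == j))
      stop(sprintf("recording is missing required joint '%s'", j), call. = FALSE)
  }
  tgrid <- sort(unique(df$time_s))
  joints <- lapply(.required_joints, function(j) {
    sub <- df[df$joint == j, ]
    if (nrow(sub) != length(tgrid) || any(sort(sub$time_s) != tgrid))
      stop(sprintf("joint '%s' is not present in every frame", j), call. = FALSE)
    sub <- sub[order(sub$time_s), ]
    cbind(x = sub$x_m, y = sub$y_m, z = sub$z_m)
  })
  names(joints) <- .required_joints
  skeleton_recording(tgrid, joints, subject = subject)
}

#' Write a skeleton recording to CSV
#'
#' Inverse of [read_skeleton()]; coordinates are written in full double
#' precision so a round trip is exact to ~1e-15.
#'
#' @param rec a [skeleton_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(rec, path) {
  stopifnot(inherits(rec, "skeleton_recording"))
  rows <- do.call(rbind, lapply(.required_joints, function(j) {
    data.frame(time_s = rec$time, joint = j,
               x_m = rec$joints[[j]][, "x"],
               y_m = rec$joints[[j]][, "y"],
               z_m = rec$joints[[j]][, "z"])
  }))
  rows <- rows[order(rows$time_s), ]
  utils::write.csv(format(rows, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Fourier (FFT zero-padding) resampling of one uniformly sampled channel by an
# integer factor. A linear trend with slope estimated from head/tail means is
# removed first and re-added analytically on the fine grid: this cancels the
# periodic-extension wrap jump of transient signals (e.g. a flexion ramp from
# rest level to plateau) that would otherwise ring, while vanishing
# identically for signals that are already periodic in the window (the means
# of matching head/tail segments agree), so band-limited periodic inputs are
# reproduced exactly.
.fourier_resample <- function(x, factor = 2L) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 samples to resample", call. = FALSE)
  m <- n * factor
  k <- max(2L, min(n %/% 5L, 30L))
  # slope of the line carrying the head level to the tail level over one full
  # period (n samples), so the periodic extension of the residual is
  # value-continuous for recordings that start and end settled
  slope <- (mean(x[(n - k + 1L):n]) - mean(x[1:k])) / n
  r <- x - slope * (0:(n - 1L))
  X <- stats::fft(r)
  Y <- complex(length.out = m)
  h <- n %/% 2L
  Y[1:(h + 1L)] <- X[1:(h + 1L)]
  if (n %% 2L == 0L) {
    # split the Nyquist bin between its positive and negative images
    Y[h + 1L] <- X[h + 1L] / 2
    Y[m - h + 1L] <- X[h + 1L] / 2
    if (h > 1L) Y[(m - h + 2L):m] <- X[(h + 2L):n]
  } else {
    Y[(m - h + 1L):m] <- X[(h + 2L):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n + slope * (0:(m - 1L)) / factor
}

#' Resample a recording to double its frame rate
#'
#' Spectral (FFT zero-padding) resampling of every coordinate channel,
#' doubling the number of frames; a 30 fps capture becomes the 60 fps series
#' used by the analysis. The input must be uniformly sampled; fill gaps
#' beforehand (see `Details`).
#'
#' @details Dropped frames must be interpolated before calling this function,
#'   e.g. with `stats::approx` on each channel, because the FFT method
#'   requires a uniform grid; a non-uniform recording is an error.
#'
#' @param rec a [skeleton_recording()].
#' @param factor integer upsampling factor (default 2: 30 to 60 fps).
#' @return a [skeleton_recording()] with `factor` times as many frames.
#' @export
resample_recording <- function(rec, factor = 2L) {
  stopifnot(inherits(rec, "skeleton_recording"))
  dt <- tryCatch(.uniform_dt(rec$time, "recording timestamps"),
                 error = function(e)
                   stop(paste0(conditionMessage(e),
                               "; interpolate dropped frames before resampling"),
                        call. = FALSE))
  n <- length(rec$time)
  joints <- lapply(rec$joints, function(m)
    apply(m, 2, .fourier_resample, factor = factor))
  time <- rec$time[1] + (0:(n * factor - 1L)) * dt / factor
  skeleton_recording(time, joints, fps = rec$fps * factor, subject = rec$subject)
}

#' Fill dropped frames by linear interpolation
#'
#' Depth cameras drop frames; the Fourier resampler requires a uniform grid.
#' This reconstructs the nominal frame grid from the recording's frame rate
#' and linearly interpolates every coordinate channel at the missing frames,
#' reporting how many were filled.
#'
#' @param rec a [skeleton_recording()] with possibly missing frames.
#' @param tol fraction of the frame interval within which a timestamp is
#'   matched to the nominal grid.
#' @return a uniform [skeleton_recording()]; a message reports the gap count.
#' @export
fill_gaps <- function(rec, tol = 0.25) {
  stopifnot(inherits(rec, "skeleton_recording"))
  dt <- 1 / rec$fps
  grid <- seq(rec$time[1], rec$time[length(rec$time)] + tol * dt, by = dt)
  # map observed frames to nominal slots
  slot <- round((rec$time - rec$time[1]) / dt) + 1L
  ok <- abs(rec$time - (rec$time[1] + (slot - 1L) * dt)) < tol * dt &
    !duplicated(slot)
  n_fill <- length(grid) - sum(ok)
  if (n_fill == 0L && length(grid) == length(rec$time)) return(rec)
  joints <- lapply(rec$joints, function(m) {
    out <- matrix(NA_real_, length(grid), 3, dimnames = list(NULL, c("x", "y", "z")))
    for (j in 1:3)
      out[, j] <- stats::approx(rec$time[ok], m[ok, j], xout = grid,
                                rule = 2)$y
    out
  })
  message(sprintf("filled %d dropped frame(s) of %d by linear interpolation",
                  n_fill, length(grid)))
  skeleton_recording(grid, joints, fps = rec$fps, subject = rec$subject)
}

#' Segment lengths from the static window
#'
#' Average Euclidean distances shoulder-elbow, elbow-wrist and wrist-hand over
#' the initial static window of the recording (the subject holds the rest
#' posture before the movement starts). Averaging over the window suppresses
#' marker noise.
#'
#' @param rec a [skeleton_recording()].
#' @param static_window window length in seconds (default 5 s).
#' @return numeric(3): upper-arm, forearm and hand lengths (m).
#' @export
segment_lengths <- function(rec, static_window = 5) {
  stopifnot(inherits(rec, "skeleton_recording"))
  idx <- which(rec$time < rec$time[1] + static_window)
  # the recording must cover the window (its frames span window - 1/fps)
  covered <- rec$time[length(rec$time)] + 1 / rec$fps + 1e-9
  if (length(idx) < 1L || covered < rec$time[1] + static_window)
    stop("recording is shorter than the static window", call. = FALSE)
  d <- function(a, b) sqrt(rowSums((rec$joints[[a]][idx, , drop = FALSE] -
                                      rec$joints[[b]][idx, , drop = FALSE])^2))
  c(upper_arm = mean(d("shoulder", "elbow")),
    forearm = mean(d("elbow", "wrist")),
    hand = mean(d("wrist", "hand")))
}

#' Extract planar joint angles and the wrist height series
#'
#' Projects the joints onto the sagittal plane spanned by the vertical axis
#' and the dominant horizontal motion axis (the direction of largest
#' horizontal wrist displacement, found by principal components of the
#' shoulder-centred wrist track), then computes the package's joint angles:
#' `theta1` from the downward vertical to the upper-arm vector, `theta2` and
#' `theta3` as relative segment angles. The horizontal axis is oriented so
#' that flexion is positive regardless of the recorded side. Angles are
#' unwrapped so multi-revolution excursions stay continuous.
#'
#' @param rec a [skeleton_recording()], typically already resampled to 60 fps.
#' @param vertical name of the vertical capture axis (default `"y"`).
#' @return an object of class `"arm_input"`: list with `time`, `fps`,
#'   `theta` (n x 3 angle matrix, rad), `wrist_y` (wrist height relative to
#'   the shoulder, m), `wrist_y_disp` (displacement from the initial height),
#'   `lengths` (per-frame mean segment lengths), `subject`.
#' @export
extract_planar_angles <- function(rec, vertical = "y") {
  stopifnot(inherits(rec, "skeleton_recording"))
  axes <- c("x", "y", "z")
  if (!vertical %in% axes) stop("'vertical' must be one of x, y, z", call. = FALSE)
  horiz <- setdiff(axes, vertical)
  sh <- rec$joints$shoulder
  rel <- function(j) rec$joints[[j]] - sh
  wr <- rel("wrist")
  # dominant horizontal axis from the wrist track
  H <- wr[, horiz, drop = FALSE]
  H <- sweep(H, 2, colMeans(H))
  u <- eigen(crossprod(H), symmetric = TRUE)$vectors[, 1]
  planar <- function(j) {
    m <- rel(j)
    cbind(h = m[, horiz, drop = FALSE] %*% u, v = m[, vertical])
  }
  el <- planar("elbow"); wrp <- planar("wrist"); ha <- planar("hand")
  # orient the horizontal axis so the wrist moves into +h (flexion positive)
  ref <- wrp[which.max(abs(wrp[, 1] - wrp[1, 1])), 1] - wrp[1, 1]
  if (is.finite(ref) && ref < 0) {
    el[, 1] <- -el[, 1]; wrp[, 1] <- -wrp[, 1]; ha[, 1] <- -ha[, 1]
  }
  seg_angle <- function(p_prox, p_dist) {
    d <- p_dist - p_prox
    small <- sqrt(rowSums(d^2)) < 1e-6
    ang <- atan2(d[, 1], -d[, 2])
    if (any(small)) {
      # degenerate frames: interpolate the angle from the neighbours
      ok <- which(!small)
      if (!length(ok)) stop("all segment vectors are degenerate", call. = FALSE)
      ang[small] <- stats::approx(ok, ang[ok], xout = which(small), rule = 2)$y
    }
    ang
  }
  org <- matrix(0, nrow(el), 2)
  phi1 <- .unwrap(seg_angle(org, el))
  phi2 <- .unwrap(seg_angle(el, wrp))
  phi3 <- .unwrap(seg_angle(wrp, ha))
  theta <- cbind(theta1 = phi1, theta2 = phi2 - phi1, theta3 = phi3 - phi2)
  wy <- wr[, vertical]
  structure(list(time = rec$time, fps = rec$fps, theta = theta,
                 wrist_y = wy, wrist_y_disp = wy - wy[1],
                 lengths = c(upper_arm = mean(sqrt(rowSums(rel("elbow")^2))),
                             forearm = mean(sqrt(rowSums((rec$joints$wrist - rec$joints$elbow)^2))),
                             hand = mean(sqrt(rowSums((rec$joints$hand - rec$joints$wrist)^2)))),
                 subject = rec$subject),
            class = "arm_input")
}

#' @export
print.arm_input <- function(x, ...) {
  cat(sprintf("Arm input: %d frames at %.4g fps; segment lengths %.3f/%.3f/%.3f m\n",
              length(x$time), x$fps, x$lengths[1], x$lengths[2], x$lengths[3]))
  cat(sprintf("theta1 range %.1f..%.1f deg, wrist rise %.3f m\n",
              min(x$theta[, 1]) * 180 / pi, max(x$theta[, 1]) * 180 / pi,
              max(x$wrist_y_disp)))
  invisible(x)
}

.unwrap <- function(a) {
  d <- diff(a)
  a + c(0, cumsum(ifelse(d > pi, -2 * pi, ifelse(d < -pi, 2 * pi, 0))))
}

#' Ingest a raw recording for fitting
#'
#' Full preprocessing pipeline: Fourier-resample the capture to double rate
#' (30 to 60 fps), measure segment lengths over the static window, and
#' extract planar joint angles and the wrist height series. The static window
#' is retained in the output (its extent is stored), so the movement onset is
#' known to the estimator.
#'
#' @param rec a [skeleton_recording()] at the native capture rate, beginning
#'   with a static rest window.
#' @param static_window static window length (s).
#' @param vertical vertical capture axis name.
#' @return an `"arm_input"` with the measured `lengths` replaced by the
#'   static-window estimate and a `static_window` element added.
#' @export
prepare_input <- function(rec, static_window = 5, vertical = "y") {
  stopifnot(inherits(rec, "skeleton_recording"))
  lens <- segment_lengths(rec, static_window)
  up <- resample_recording(rec)
  input <- extract_planar_angles(up, vertical = vertical)
  input$lengths <- lens
  input$static_window <- static_window
  input
}
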