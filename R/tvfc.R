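#' Parcel timeseries container
#'
#' Bundles per-subject frames x parcels matrices with the repetition time
#' and group labels. All downstream stages consume this container.
#'
#' @param subjects named list of numeric matrices (frames x parcels); all
#'   matrices must share the parcel dimension
#' @param tr repetition time in seconds
#' @param group character vector ("control" or "patient"), one per subject;
#'   recycled if length 1
#' @param parcel_ids optional parcel names; defaults to column names of the
#'   first matrix or "p001", ...
#' @return object of class `parcel_ts_set`
#' @export
parcel_ts_set <- function(subjects, tr, group = "patient", parcel_ids = NULL) {
  stopifnot(is.list(subjects), length(subjects) >= 1, tr > 0)
  p <- ncol(subjects[[1]])
  if (p < 2) stop("need at least 2 parcels")
  if (!all(vapply(subjects, ncol, 1L) == p))
    stop("all subjects must have the same number of parcels")
  if (any(vapply(subjects, function(m) anyNA(m), TRUE)))
    stop("missing frames are not allowed")
  if (is.null(parcel_ids)) {
    parcel_ids <- colnames(subjects[[1]])
    if (is.null(parcel_ids)) parcel_ids <- sprintf("p%03d", seq_len(p))
  }
  if (is.null(names(subjects)))
    names(subjects) <- sprintf("sub%03d", seq_along(subjects))
  group <- rep_len(group, length(subjects))
  stopifnot(all(group %in% c("control", "patient")))
  structure(list(subjects = subjects, tr = tr,
                 group = setNames(group, names(subjects)),
                 parcel_ids = parcel_ids),
            class = "parcel_ts_set")
}

#' @export
print.parcel_ts_set <- function(x, ...) {
  cat(sprintf("parcel_ts_set: %d subjects (%d control, %d patient), %d parcels, TR = %g s\n",
              length(x$subjects), sum(x$group == "control"),
              sum(x$group == "patient"), length(x$parcel_ids), x$tr))
  invisible(x)
}

#' Preprocess parcel timeseries
#'
#' Applies, in order: zero-phase 4th-order Butterworth bandpass, regression
#' of the cross-parcel mean signal from every parcel (a version of
#' global-signal regression; OLS residuals are kept), and removal of `trim`
#' frames from each end to absorb boundary effects.
#'
#' @param ts a [parcel_ts_set]
#' @param band numeric length-2, bandpass edges in Hz; must lie strictly
#'   inside (0, Nyquist) where Nyquist = 1/(2 TR). Default 0.017-0.1 Hz.
#' @param trim frames removed from each end (default 10)
#' @return a [parcel_ts_set] with frames reduced by `2 * trim`
#' @export
preprocess_timeseries <- function(ts, band = c(0.017, 0.1), trim = 10L) {
  stopifnot(inherits(ts, "parcel_ts_set"), length(band) == 2, band[1] < band[2])
  nyq <- 1 / (2 * ts$tr)
  if (band[2] >= nyq || band[1] <= 0)
    stop(sprintf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz (Nyquist)",
                 band[1], band[2], nyq))
  nf <- nrow(ts$subjects[[1]])
  if (2 * trim >= nf) stop("2 * trim must be smaller than the frame count")
  bf <- signal::butter(4, band / nyq, type = "pass")
  out <- lapply(ts$subjects, function(m) {
    filt <- apply(m, 2, function(col) signal::filtfilt(bf, col))
    g <- rowMeans(filt)
    gm <- cbind(1, g)
    beta <- qr.solve(gm, filt)
    res <- filt - gm %*% beta
    if (trim > 0) res <- res[(trim + 1):(nrow(res) - trim), , drop = FALSE]
    res
  })
  parcel_ts_set(out, tr = ts$tr, group = ts$group, parcel_ids = ts$parcel_ids)
}

#' Sliding-window edge dynamics
#'
#' Slides a rectangular window across each subject's timeseries, computes
#' the Pearson correlation of every parcel pair within each window, and
#' Fisher-transforms the correlations (r clipped to +-(1 - 1e-12) first so
#' that degenerate perfectly correlated inputs stay finite).
#'
#' @param ts a [parcel_ts_set]
#' @param window_seconds window width in seconds; the window length in
#'   frames is `round(window_seconds / tr)` (60 s at TR 0.8 s -> 75 frames)
#' @param step_frames step between consecutive windows in frames (default 1)
#' @return object of class `edge_dynamics`: per-subject windows x edges
#'   matrices of Fisher-z values, the canonical [edge_index], and the
#'   window/step geometry
#' @export
sliding_window_correlation <- function(ts, window_seconds = 60, step_frames = 1L) {
  stopifnot(inherits(ts, "parcel_ts_set"), step_frames >= 1)
  w <- as.integer(round(window_seconds / ts$tr))
  if (w < 3) stop("window length must be at least 3 frames")
  nf <- nrow(ts$subjects[[1]])
  if (nf < w) stop("timeseries shorter than one window")
  starts <- seq.int(1L, nf - w + 1L, by = as.integer(step_frames))
  eidx <- edge_index(length(ts$parcel_ids), ts$parcel_ids)
  sel <- cbind(eidx$i, eidx$j)
  mats <- lapply(names(ts$subjects), function(sid) {
    m <- ts$subjects[[sid]]
    z <- matrix(NA_real_, length(starts), nrow(eidx))
    for (k in seq_along(starts)) {
      win <- m[starts[k]:(starts[k] + w - 1L), , drop = FALSE]
      sds <- apply(win, 2, stats::sd)
      if (any(sds == 0))
        stop(sprintf("zero-variance parcel in subject %s, window %d, parcel %s",
                     sid, k, ts$parcel_ids[which(sds == 0)[1]]))
      r <- cor(win)
      z[k, ] <- fisher_z(r[sel])
    }
    colnames(z) <- eidx$name
    z
  })
  names(mats) <- names(ts$subjects)
  structure(list(subjects = mats, edge_index = eidx,
                 window_frames = w, step_frames = as.integer(step_frames),
                 tr = ts$tr, group = ts$group, parcel_ids = ts$parcel_ids),
            class = "edge_dynamics")
}

#' @export
print.edge_dynamics <- function(x, ...) {
  cat(sprintf("edge_dynamics: %d subjects, %d windows x %d edges (window %d frames, step %d)\n",
              length(x$subjects), nrow(x$subjects[[1]]), nrow(x$edge_index),
              x$window_frames, x$step_frames))
  invisible(x)
}
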