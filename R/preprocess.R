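## Preprocessing: zero-phase Butterworth low-pass denoising, sliding-window
## segmentation, and sensor-major feature stacking, plus an optional reader
## for a documented per-subject/per-trial CSV layout.

#' Window / filter configuration
#'
#' @param window_len window length in samples (>= 2).
#' @param overlap_fraction fractional overlap between consecutive windows,
#'   in \code{[0, 1)}.
#' @param sampling_rate sampling rate in Hz.
#' @param filter_order Butterworth order.
#' @param filter_cutoff low-pass cutoff in Hz.  If the cutoff reaches the
#'   Nyquist frequency the filter is unrealizable and filtering becomes a
#'   warned pass-through (see \code{\link{lowpass_filter}}).
#' @return Object of class \code{"window_config"}.
#' @export
window_config <- function(window_len = 200, overlap_fraction = 0.5,
                          sampling_rate = 20, filter_order = 5,
                          filter_cutoff = 30) {
  window_len <- check_count(window_len, "window_len", min = 2L)
  overlap_fraction <- check_scalar(overlap_fraction, "overlap_fraction", min = 0)
  if (overlap_fraction >= 1)
    stop("`overlap_fraction` must be < 1", call. = FALSE)
  structure(list(window_len = window_len,
                 overlap_fraction = overlap_fraction,
                 sampling_rate = check_scalar(sampling_rate, "sampling_rate",
                                              min = 0, strict = TRUE),
                 filter_order = check_count(filter_order, "filter_order"),
                 filter_cutoff = check_scalar(filter_cutoff, "filter_cutoff",
                                              min = 0, strict = TRUE)),
            class = "window_config")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies the configured Butterworth low-pass forward and backward
#' (\code{signal::filtfilt}) so the output is phase-free.  If the cutoff is
#' at or above the Nyquist frequency the requested filter is unrealizable:
#' the signal is returned unchanged with a warning, so a nominal
#' configuration whose cutoff exceeds half the sampling rate degrades to a
#' documented pass-through instead of an error.
#'
#' @param x numeric vector (one channel) or channels-by-time matrix.
#' @param config a \code{\link{window_config}}.
#' @return Filtered data with the same shape as \code{x}.
#' @export
lowpass_filter <- function(x, config = window_config()) {
  stopifnot(inherits(config, "window_config"))
  if (!all(is.finite(x))) stop("non-finite values in input signal", call. = FALSE)
  nyq <- config$sampling_rate / 2
  if (config$filter_cutoff >= nyq) {
    warning(sprintf(
      "cutoff %.3g Hz >= Nyquist %.3g Hz: filter unrealizable, returning input unchanged",
      config$filter_cutoff, nyq))
    return(x)
  }
  bf <- signal::butter(config$filter_order, config$filter_cutoff / nyq,
                       type = "low")
  nf <- max(length(bf$a), length(bf$b)) - 1L
  # one pass started from the DC steady state of its first sample (the
  # Butterworth low-pass has unit DC gain)
  pass <- function(x) {
    as.numeric(signal::filter(bf$b, bf$a, x,
                              init.x = rep(x[1], nf),
                              init.y = rep(x[1], nf)))
  }
  # mirror padding keeps the extension free of spurious low-frequency
  # content at the joints, so startup transients stay inside the trimmed
  # region; exact for constants, small kink artefacts for strong trends
  apply_fun <- function(v) {
    n <- length(v)
    if (n < 3 * config$filter_order)
      stop("signal shorter than 3 x filter order", call. = FALSE)
    p <- min(n - 1L, 30L * nf)
    ext <- c(v[(p + 1L):2], v, v[(n - 1L):(n - p)])
    y <- rev(pass(rev(pass(ext))))
    y[(p + 1L):(p + n)]
  }
  if (is.matrix(x)) t(apply(x, 1L, apply_fun)) else apply_fun(x)
}

#' Sliding-window segmentation
#'
#' Cuts a channels-by-time recording into fixed-length windows at stride
#' \code{round(window_len * (1 - overlap_fraction))}.  Window starts are
#' \code{0, s, 2s, ...} while a full window fits; a recording shorter than
#' one window yields an empty list with a warning.
#'
#' @param x numeric matrix, channels x T (a vector is treated as one channel).
#' @param config a \code{\link{window_config}}.
#' @return List of channels x \code{window_len} matrices, in temporal order.
#' @examples
#' w <- segment_windows(matrix(rnorm(400), 1), window_config(200, 0.5))
#' length(w) # 3 windows at starts 0, 100, 200
#' @export
segment_windows <- function(x, config = window_config()) {
  stopifnot(inherits(config, "window_config"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  h <- config$window_len
  T_len <- ncol(x)
  if (T_len < h) {
    warning(sprintf("recording length %d < window length %d: no windows", T_len, h))
    return(list())
  }
  s <- max(1L, as.integer(round(h * (1 - config$overlap_fraction))))
  starts <- seq.int(0L, T_len - h, by = s)
  lapply(starts, function(st) x[, (st + 1L):(st + h), drop = FALSE])
}

#' Stack per-sensor channel blocks into one sample matrix
#'
#' Concatenates the \code{J} per-sensor 5 x h channel blocks row-wise in
#' sensor order, giving the \code{(5J) x h} multi-sensor sample matrix: row
#' \code{5(j-1)+c} is channel \code{c} of sensor \code{j}.
#'
#' @param per_sensor_windows list of \code{J} numeric matrices, each
#'   \code{5 x h}.
#' @return A \code{(5J) x h} matrix.
#' @export
stack_features <- function(per_sensor_windows) {
  stopifnot(is.list(per_sensor_windows), length(per_sensor_windows) >= 1L)
  hs <- vapply(per_sensor_windows, ncol, integer(1))
  rs <- vapply(per_sensor_windows, nrow, integer(1))
  if (length(unique(hs)) != 1L || any(rs != 5L))
    stop("all sensor blocks must be 5 x h with a common h", call. = FALSE)
  do.call(rbind, per_sensor_windows)
}

#' Read a WARD-style directory of per-subject trial recordings
#'
#' Expects the documented plain-text layout
#' \preformatted{
#'   <path>/Subject<s>/a<class>t<trial>.csv
#' }
#' where each CSV has \code{5*J} columns (sensor-major: sensor 1 channels
#' x,y,z,theta,rho, then sensor 2, ...) and one row per time sample.  Every
#' trial is low-pass filtered, segmented with \code{config}, stacked, and
#' collected into a labelled dataset.  By default the first
#' \code{windows_per_class} windows per subject/class are kept; set
#' \code{random_subset = TRUE} for a seeded random subset instead.
#'
#' @param path directory containing \code{Subject*} subdirectories.
#' @param config a \code{\link{window_config}}.
#' @param J sensors per recording.
#' @param windows_per_class windows retained per subject/class
#'   (\code{Inf} keeps all).
#' @param random_subset take a seeded random subset instead of the first
#'   windows.
#' @param seed seed for \code{random_subset}.
#' @return A \code{"gait_dataset"} (without ground-truth templates).
#' @export
read_ward_layout <- function(path, config = window_config(), J = 5,
                             windows_per_class = 10, random_subset = FALSE,
                             seed = 0) {
  if (!dir.exists(path)) stop(sprintf("directory not found: %s", path), call. = FALSE)
  subj_dirs <- sort(list.dirs(path, recursive = FALSE))
  subj_dirs <- subj_dirs[grepl("Subject[0-9]+$", basename(subj_dirs))]
  if (length(subj_dirs) == 0L)
    stop(sprintf("no Subject<N> subdirectories under %s", path), call. = FALSE)
  J <- check_count(J, "J")
  C <- 5L * J

  samples <- list(); labels <- integer(0); subjects <- integer(0)
  pick <- function(k, avail) {
    k <- min(k, avail)
    if (random_subset) with_seed(seed, sort(sample.int(avail, k))) else seq_len(k)
  }
  for (sd in subj_dirs) {
    sid <- as.integer(sub("Subject", "", basename(sd)))
    files <- sort(list.files(sd, pattern = "^a[0-9]+t[0-9]+\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L)
      stop(sprintf("no trial files (a<class>t<trial>.csv) in %s", sd), call. = FALSE)
    cls <- as.integer(sub("^a([0-9]+)t[0-9]+\\.csv$", "\\1", basename(files)))
    for (cl in sort(unique(cls))) {
      wins <- list()
      for (f in files[cls == cl]) {
        rec <- as.matrix(utils::read.csv(f, header = FALSE))
        if (ncol(rec) != C)
          stop(sprintf("%s: expected %d columns (5 x J), found %d",
                       f, C, ncol(rec)), call. = FALSE)
        x <- lowpass_filter(t(rec), config)
        wins <- c(wins, segment_windows(x, config))
      }
      keep <- pick(windows_per_class, length(wins))
      for (w in wins[keep]) {
        samples[[length(samples) + 1L]] <- w
        labels <- c(labels, cl); subjects <- c(subjects, sid)
      }
    }
  }
  n <- length(samples)
  arr <- array(0, dim = c(C, config$window_len, n))
  for (i in seq_len(n)) arr[, , i] <- samples[[i]]
  # labels are re-indexed to consecutive 1..L preserving order
  labels <- as.integer(factor(labels))
  structure(list(samples = arr, labels = labels, subjects = subjects,
                 J = J, window_len = config$window_len, n_channels = 5L,
                 L = length(unique(labels)), n = n,
                 sampling_rate = config$sampling_rate,
                 templates = NULL, seed = NA_integer_),
            class = "gait_dataset")
}
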