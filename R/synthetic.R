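## Synthetic generators: JSM-2 jointly sparse ensembles with known ground
## truth, and labelled multi-subject gait-like datasets, so the whole
## compression + classification pipeline is testable without external data.

#' Orthonormal sparsifying basis
#'
#' Builds the square orthonormal matrix used as the sparsifying dictionary of
#' the JSM-2 signal model.  \code{"identity"} means signals are sparse in the
#' sample domain; \code{"dct"} gives the orthonormal type-II discrete cosine
#' basis, the conventional choice for smooth quasi-periodic signals.
#'
#' @param N basis side (signal length), positive integer.
#' @param kind \code{"identity"} or \code{"dct"}.
#' @return An \code{N x N} matrix with orthonormal columns.
#' @examples
#' B <- make_dictionary_basis(8, "dct")
#' max(abs(crossprod(B) - diag(8))) < 1e-10
#' @export
make_dictionary_basis <- function(N, kind = c("identity", "dct")) {
  N <- check_count(N, "N")
  kind <- match.arg(kind)
  if (kind == "identity") return(diag(N))
  # orthonormal DCT-II: row k (0-based) is c_k * cos(pi*(2t+1)*k/(2N))
  t0 <- seq_len(N) - 1L
  B <- sqrt(2 / N) * cos(pi * outer(t0, 2 * t0 + 1) / (2 * N))
  B[1L, ] <- 1 / sqrt(N)
  t(B) # columns are the basis atoms
}

#' Simulate a JSM-2 jointly sparse sensor ensemble
#'
#' Draws \code{J} signals \eqn{x_j = \Psi \theta_j + \epsilon_j} sharing one
#' sparse support of size \code{k} (the JSM-2 joint sparsity model: common
#' support, per-sensor coefficient values).  Nonzero coefficients are i.i.d.
#' standard normal, independently per sensor; noise is i.i.d. Gaussian.
#'
#' @param J number of sensors (signals), >= 1.
#' @param N signal length.
#' @param k shared sparsity, \code{0 <= k <= N}.
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed RNG seed; identical arguments give bit-identical output.
#' @param basis orthonormal \code{N x N} sparsifying matrix
#'   (default identity); see \code{\link{make_dictionary_basis}}.
#' @return A list with components
#'   \item{ensemble}{object of class \code{"sensor_ensemble"}: \code{signals}
#'     (\code{N x J} matrix, one column per sensor), \code{J}, \code{N}.}
#'   \item{model}{object of class \code{"sparse_model"} carrying the ground
#'     truth: \code{basis}, \code{coefficients} (\code{N x J}),
#'     \code{support} (sorted index set), \code{k}.}
#' @examples
#' sim <- simulate_jsm2_ensemble(J = 3, N = 64, k = 4, seed = 1)
#' sim$model$support
#' @export
simulate_jsm2_ensemble <- function(J, N, k, noise_sd = 0, seed = 0,
                                   basis = NULL) {
  J <- check_count(J, "J"); N <- check_count(N, "N")
  k <- check_count(k, "k", min = 0L)
  noise_sd <- check_scalar(noise_sd, "noise_sd", min = 0)
  if (k > N) stop("`k` must not exceed `N`", call. = FALSE)
  if (is.null(basis)) basis <- diag(N)
  stopifnot(is.matrix(basis), nrow(basis) == N, ncol(basis) == N)

  with_seed(seed, {
    support <- sort(sample.int(N, k))
    theta <- matrix(0, N, J)
    if (k > 0) theta[support, ] <- rnorm(k * J)
    X <- basis %*% theta
    if (noise_sd > 0) X <- X + matrix(rnorm(N * J, sd = noise_sd), N, J)
    list(
      ensemble = structure(list(signals = X, J = J, N = N),
                           class = "sensor_ensemble"),
      model = structure(list(basis = basis, coefficients = theta,
                             support = support, k = k),
                        class = "sparse_model")
    )
  })
}

#' Simulate a labelled multi-subject gait-like dataset
#'
#' Emulates the shape of a multi-sensor wearable activity database:
#' \code{J} body-worn sensors, each with 5 channels (3-axis accelerometer +
#' 2-axis gyroscope), fixed-length windows, multiple subjects and activity
#' classes.  Each class owns one smooth band-limited template per channel
#' (a sum of 2--4 random-phase sinusoids below a class-specific cutoff,
#' scaled by \code{class_sep}); each subject perturbs the class template
#' with a small random amplitude and phase shift; each window adds i.i.d.
#' Gaussian noise.
#'
#' @param n_subjects,n_classes,windows_per_class positive integers; the
#'   dataset has \code{n_subjects * n_classes * windows_per_class} windows.
#' @param J sensors per subject (default 5).
#' @param window_len samples per window (default 200).
#' @param class_sep positive scale of the class templates relative to unit
#'   noise; larger values separate the classes more.
#' @param noise_sd per-sample Gaussian noise standard deviation.
#' @param sampling_rate Hz, used to place template harmonics (default 20).
#' @param seed RNG seed.
#' @return Object of class \code{"gait_dataset"}: \code{samples}
#'   (\code{(5J) x window_len x n} array, sensor-major channel rows),
#'   \code{labels} (integer 1..L), \code{subjects} (integer ids), \code{J},
#'   \code{window_len}, \code{n_channels = 5}, \code{L}, \code{n}, and the
#'   ground-truth class \code{templates} (\code{(5J) x window_len x L}) for
#'   oracle checks.
#' @examples
#' d <- simulate_gait_dataset(2, 3, 4, J = 2, window_len = 50, seed = 1)
#' d$n # 24
#' @export
simulate_gait_dataset <- function(n_subjects, n_classes, windows_per_class,
                                  J = 5, window_len = 200, class_sep = 1,
                                  noise_sd = 0.1, sampling_rate = 20,
                                  seed = 0) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_classes <- check_count(n_classes, "n_classes")
  windows_per_class <- check_count(windows_per_class, "windows_per_class")
  J <- check_count(J, "J")
  window_len <- check_count(window_len, "window_len", min = 2L)
  class_sep <- check_scalar(class_sep, "class_sep", min = 0, strict = TRUE)
  noise_sd <- check_scalar(noise_sd, "noise_sd", min = 0)

  C <- 5L * J
  h <- window_len
  n <- n_subjects * n_classes * windows_per_class
  tt <- (seq_len(h) - 1L) / sampling_rate
  nyq <- sampling_rate / 2

  with_seed(seed, {
    # class templates: per channel a sum of 2-4 sinusoids with frequencies
    # below a class-specific cutoff in (0.5, 0.8*nyquist]
    templates <- array(0, dim = c(C, h, n_classes))
    for (cl in seq_len(n_classes)) {
      cutoff <- 0.5 + (0.8 * nyq - 0.5) * cl / n_classes
      for (ch in seq_len(C)) {
        n_harm <- sample(2:4, 1L)
        freq <- runif(n_harm, 0.25, cutoff)
        phase <- runif(n_harm, 0, 2 * pi)
        amp <- runif(n_harm, 0.5, 1.5)
        templates[ch, , cl] <- class_sep *
          colSums(amp * sin(outer(2 * pi * freq, tt) + phase))
      }
    }

    samples <- array(0, dim = c(C, h, n))
    labels <- integer(n); subjects <- integer(n)
    idx <- 0L
    for (s in seq_len(n_subjects)) {
      for (cl in seq_len(n_classes)) {
        # subject-specific perturbation of the class template
        gain <- 1 + rnorm(C, sd = 0.05)
        shift <- sample.int(max(1L, h %/% 20L), 1L) - 1L
        base <- templates[, , cl] * gain
        if (shift > 0)
          base <- base[, c((shift + 1L):h, seq_len(shift)), drop = FALSE]
        for (w in seq_len(windows_per_class)) {
          idx <- idx + 1L
          samples[, , idx] <- base +
            if (noise_sd > 0) matrix(rnorm(C * h, sd = noise_sd), C, h) else 0
          labels[idx] <- cl
          subjects[idx] <- s
        }
      }
    }

    structure(list(samples = samples, labels = labels, subjects = subjects,
                   J = J, window_len = h, n_channels = 5L, L = n_classes,
                   n = n, sampling_rate = sampling_rate,
                   templates = templates, seed = as.integer(seed)),
              class = "gait_dataset")
  })
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf(
    "Gait dataset: %d windows (%d x %d each), %d sensors x %d channels,\n  %d classes, %d subjects\n",
    x$n, dim(x$samples)[1], x$window_len, x$J, x$n_channels, x$L,
    length(unique(x$subjects))))
  invisible(x)
}

#' @export
print.sensor_ensemble <- function(x, ...) {
  cat(sprintf("Sensor ensemble: J = %d signals of length N = %d\n", x$J, x$N))
  invisible(x)
}
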