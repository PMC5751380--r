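## Distributed compressed sensing under the JSM-2 joint sparsity model:
## per-sensor random measurement blocks forming a block-diagonal operator,
## simultaneous compression, compression-ratio bookkeeping, and joint
## reconstruction by SOMP or the one-step greedy algorithm (OSGA).

#' Compression ratio
#'
#' \code{CR = (N - M) / N * 100}: the percentage of samples removed by
#' compressing a length-\code{N} vector to \code{M} measurements.
#'
#' @param N original per-channel length.
#' @param M compressed length, \code{1 <= M <= N}.
#' @return CR in percent.
#' @export
compression_ratio <- function(N, M) {
  N <- check_count(N, "N"); M <- check_count(M, "M")
  if (M > N) stop("`M` must not exceed `N`", call. = FALSE)
  (N - M) / N * 100
}

#' Measurements needed for a target compression ratio
#'
#' Inverts \code{\link{compression_ratio}}: \code{M = round(N (1 - CR/100))},
#' clamped to at least 1.
#'
#' @param cr compression ratio in percent, \code{[0, 100)}.
#' @param N original per-channel length.
#' @export
cr_to_measurements <- function(cr, N) {
  cr <- check_scalar(cr, "cr", min = 0)
  if (cr >= 100) stop("`cr` must be < 100", call. = FALSE)
  N <- check_count(N, "N")
  max(1L, as.integer(round(N * (1 - cr / 100))))
}

#' Block-diagonal random measurement scheme
#'
#' Draws \code{J} independent per-sensor measurement blocks
#' \eqn{\Phi_j \in R^{M \times N}}; the implied full operator is
#' block-diagonal, so each sensor compresses its own data independently.
#' \code{"sparse_binary"} blocks put exactly two ones in each column at
#' distinct uniformly chosen rows (requires \code{M >= 2}); \code{"gaussian"}
#' blocks have i.i.d. \code{N(0, 1/M)} entries.
#'
#' @param J number of sensors.
#' @param N signal (or channel) length.
#' @param M measurements per sensor block, \code{1 <= M <= N}.
#' @param kind \code{"sparse_binary"} (default) or \code{"gaussian"}.
#' @param seed RNG seed; the scheme is reproducible from (args, seed).
#' @return Object of class \code{"measurement_scheme"}: \code{blocks} (list
#'   of \code{J} matrices), \code{J}, \code{N}, \code{M}, \code{kind},
#'   \code{seed}, \code{compression_ratio}.
#' @export
make_measurement_scheme <- function(J, N, M, kind = c("sparse_binary", "gaussian"),
                                    seed = 0) {
  J <- check_count(J, "J"); N <- check_count(N, "N")
  M <- check_count(M, "M")
  if (M > N) stop("`M` must not exceed `N`", call. = FALSE)
  kind <- match.arg(kind)
  if (kind == "sparse_binary" && M < 2L)
    stop("sparse_binary blocks need M >= 2 (two nonzeros per column)", call. = FALSE)
  blocks <- with_seed(seed, lapply(seq_len(J), function(j) {
    if (kind == "gaussian") {
      matrix(rnorm(M * N, sd = 1 / sqrt(M)), M, N)
    } else {
      B <- matrix(0, M, N)
      for (col in seq_len(N)) B[sample.int(M, 2L), col] <- 1
      B
    }
  }))
  structure(list(blocks = blocks, J = J, N = N, M = M, kind = kind,
                 seed = as.integer(seed),
                 compression_ratio = compression_ratio(N, M)),
            class = "measurement_scheme")
}

#' @export
print.measurement_scheme <- function(x, ...) {
  cat(sprintf("Block-diagonal measurement scheme: J = %d blocks of %d x %d (%s), CR = %.1f%%, seed %d\n",
              x$J, x$M, x$N, x$kind, x$compression_ratio, x$seed))
  invisible(x)
}

#' Simultaneously compress multi-sensor data
#'
#' Applies the block-diagonal scheme: sensor \code{j}'s data are multiplied
#' by its own block \eqn{\Phi_j}, independently of the other sensors.
#' Methods exist for a \code{"sensor_ensemble"} (one length-\code{N} vector
#' per sensor), a single \code{(5J) x h} gait window matrix (each of the 5
#' channel rows of sensor \code{j} is compressed by \eqn{\Phi_j} and the
#' sensor's channels are concatenated channel-major, giving \code{y_j} of
#' length \code{5M}), and a whole \code{"gait_dataset"}.
#'
#' @param x data to compress.
#' @param scheme a \code{\link{make_measurement_scheme}} result with
#'   matching \code{J} and \code{N}.
#' @param ... unused.
#' @return For an ensemble, an object of class \code{"compressed_ensemble"}
#'   with \code{measurements} (\code{M x J}), \code{Y} (stacked vector) and
#'   the scheme; for a window, the stacked numeric vector of length
#'   \code{5*J*M}; for a dataset, a \code{(5*J*M) x n} matrix with
#'   attributes \code{"row_partition"} (list mapping sensors to rows) and
#'   \code{"labels"}/\code{"subjects"}.
#' @export
compress <- function(x, scheme, ...) UseMethod("compress")

#' @rdname compress
#' @export
compress.sensor_ensemble <- function(x, scheme, ...) {
  stopifnot(inherits(scheme, "measurement_scheme"))
  if (scheme$J != x$J || scheme$N != x$N)
    stop(sprintf("scheme (J=%d, N=%d) does not match ensemble (J=%d, N=%d)",
                 scheme$J, scheme$N, x$J, x$N), call. = FALSE)
  meas <- vapply(seq_len(x$J),
                 function(j) as.numeric(scheme$blocks[[j]] %*% x$signals[, j]),
                 numeric(scheme$M))
  meas <- matrix(meas, scheme$M, x$J)
  structure(list(measurements = meas, Y = as.numeric(meas), scheme = scheme),
            class = "compressed_ensemble")
}

#' @rdname compress
#' @export
compress.matrix <- function(x, scheme, ...) {
  stopifnot(inherits(scheme, "measurement_scheme"))
  C <- nrow(x)
  if (C != 5L * scheme$J)
    stop(sprintf("window has %d rows but scheme implies %d (= 5 x J)",
                 C, 5L * scheme$J), call. = FALSE)
  if (ncol(x) != scheme$N)
    stop(sprintf("window length %d does not match scheme N = %d",
                 ncol(x), scheme$N), call. = FALSE)
  unlist(lapply(seq_len(scheme$J), function(j) {
    rows <- (5L * (j - 1L) + 1L):(5L * j)
    # Phi_j applied to each of the 5 channel rows; channel-major stacking
    as.numeric(scheme$blocks[[j]] %*% t(x[rows, , drop = FALSE]))
  }), use.names = FALSE)
}

#' @rdname compress
#' @export
compress.gait_dataset <- function(x, scheme, ...) {
  stopifnot(inherits(scheme, "measurement_scheme"))
  if (scheme$J != x$J)
    stop(sprintf("scheme J = %d but dataset J = %d", scheme$J, x$J), call. = FALSE)
  if (scheme$N != x$window_len)
    stop(sprintf("scheme N = %d but dataset window length = %d",
                 scheme$N, x$window_len), call. = FALSE)
  M <- scheme$M; J <- x$J; n <- x$n
  d_sensor <- 5L * M
  out <- matrix(0, d_sensor * J, n)
  for (j in seq_len(J)) {
    rows <- (5L * (j - 1L) + 1L):(5L * j)
    # flatten sensor j's 5 x h x n slab to h x (5n), compress in one product
    slab <- aperm(x$samples[rows, , , drop = FALSE], c(2L, 1L, 3L))
    dim(slab) <- c(x$window_len, 5L * n)
    z <- scheme$blocks[[j]] %*% slab        # M x (5n), channel-major per sample
    dim(z) <- c(d_sensor, n)
    out[(d_sensor * (j - 1L) + 1L):(d_sensor * j), ] <- z
  }
  attr(out, "row_partition") <- lapply(seq_len(J), function(j)
    (d_sensor * (j - 1L) + 1L):(d_sensor * j))
  attr(out, "labels") <- x$labels
  attr(out, "subjects") <- x$subjects
  out
}

## Shared greedy MMV engine.  tasks: Ylist[[j]] is the measurement vector and
## Alist[[j]] the task-j design (same column count across tasks).  Selects up
## to k shared atoms; per-task least-squares refit after every selection.
somp_engine <- function(Ylist, Alist, k, one_pass = FALSE) {
  J <- length(Ylist)
  n_atoms <- ncol(Alist[[1L]])
  norms <- lapply(Alist, function(A) pmax(col_norms(A), .Machine$double.eps))
  support <- integer(0)
  resid <- Ylist
  if (k > 0 && one_pass) {
    score <- rowSums(vapply(seq_len(J), function(j)
      as.numeric(crossprod(Alist[[j]], Ylist[[j]]) / norms[[j]])^2,
      numeric(n_atoms)))
    support <- sort(order(-score)[seq_len(min(k, n_atoms))])
  } else if (k > 0) {
    for (it in seq_len(min(k, n_atoms))) {
      score <- rowSums(vapply(seq_len(J), function(j)
        as.numeric(crossprod(Alist[[j]], resid[[j]]) / norms[[j]])^2,
        numeric(n_atoms)))
      score[support] <- -Inf
      support <- c(support, which_max_first(score))
      for (j in seq_len(J)) {
        cf <- qr.coef(qr(Alist[[j]][, support, drop = FALSE]), Ylist[[j]])
        cf[is.na(cf)] <- 0
        resid[[j]] <- Ylist[[j]] -
          Alist[[j]][, support, drop = FALSE] %*% cf
      }
    }
    support <- sort(support)
  }
  W <- matrix(0, n_atoms, J)
  if (length(support) > 0) {
    for (j in seq_len(J)) {
      cf <- qr.coef(qr(Alist[[j]][, support, drop = FALSE]), Ylist[[j]])
      cf[is.na(cf)] <- 0
      W[support, j] <- cf
    }
  }
  list(W = W, support = support)
}

#' Joint reconstruction of a compressed JSM-2 ensemble
#'
#' Recovers the shared support and per-sensor coefficients from jointly
#' compressed measurements.  \code{"somp"} (simultaneous orthogonal matching
#' pursuit) iterates \code{k} times, each time selecting the atom maximizing
#' the sum over sensors of squared normalized correlations between the
#' current residual and the effective column \eqn{(\Phi_j \Psi)_{idx}}, then
#' refitting per-sensor least squares on the selected set.  \code{"osga"}
#' (one-step greedy algorithm) ranks all atoms by the same score once and
#' keeps the top \code{k} — a weaker single-pass baseline.
#'
#' @param Y a \code{"compressed_ensemble"} from \code{\link{compress}}.
#' @param basis orthonormal \code{N x N} sparsifying matrix.
#' @param k number of atoms to select (>= 0); must not exceed the per-sensor
#'   measurement count.
#' @param method \code{"somp"} or \code{"osga"}.
#' @return A list with \code{model} (estimated \code{"sparse_model"}:
#'   coefficients \code{N x J} and shared support) and \code{X_hat}
#'   (\code{N x J} reconstruction \eqn{\Psi \hat\theta}).
#' @export
joint_reconstruct <- function(Y, basis, k, method = c("somp", "osga")) {
  stopifnot(inherits(Y, "compressed_ensemble"))
  method <- match.arg(method)
  k <- check_count(k, "k", min = 0L)
  scheme <- Y$scheme
  stopifnot(is.matrix(basis), nrow(basis) == scheme$N, ncol(basis) == scheme$N)
  if (k > scheme$M)
    stop(sprintf("k = %d exceeds per-sensor measurements M = %d", k, scheme$M),
         call. = FALSE)
  Alist <- lapply(scheme$blocks, function(B) B %*% basis)
  Ylist <- lapply(seq_len(scheme$J), function(j) Y$measurements[, j])
  fit <- somp_engine(Ylist, Alist, k, one_pass = (method == "osga"))
  theta <- fit$W
  structure(list(
    model = structure(list(basis = basis, coefficients = theta,
                           support = fit$support, k = length(fit$support)),
                      class = "sparse_model"),
    X_hat = basis %*% theta,
    method = method), class = "joint_reconstruction")
}
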