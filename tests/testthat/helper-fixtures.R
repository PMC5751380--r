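# Shared fixture builders; everything is generated in code at test time.

# Multitask instance with known row-sparse truth: J sensor blocks of d rows,
# n_atoms dictionary columns, `active` rows carrying the signal.
make_mmv_instance <- function(n_atoms = 40, J = 5, d = 30, active = c(3, 17, 25),
                              amplitude = 10, labels = NULL, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(d * J * n_atoms), d * J, n_atoms)
  rp <- lapply(seq_len(J), function(j) ((j - 1) * d + 1):(j * d))
  if (is.null(labels)) labels <- rep(seq_len(4), length.out = n_atoms)
  dict <- build_dictionary(X, labels = labels, row_partition = rp)
  W <- matrix(0, n_atoms, J)
  W[active, ] <- amplitude * matrix(rnorm(length(active) * J), length(active), J)
  y <- numeric(d * J)
  for (j in seq_len(J)) y[rp[[j]]] <- dict$atoms[rp[[j]], ] %*% W[, j]
  list(dict = dict, W = W, y = y, rp = rp, active = sort(active))
}

# Small well-separated labelled dataset for pipeline tests.
make_small_dataset <- function(n_subjects = 4, n_classes = 3, windows = 4,
                               J = 2, window_len = 60, class_sep = 5,
                               noise_sd = 0.1, seed = 7) {
  simulate_gait_dataset(n_subjects, n_classes, windows, J = J,
                        window_len = window_len, class_sep = class_sep,
                        noise_sd = noise_sd, seed = seed)
}

# Support-restricted per-task least squares: the reconstruction oracle.
ls_on_support <- function(y, dict, support) {
  J <- length(dict$row_partition)
  W <- matrix(0, dict$n, J)
  for (j in seq_len(J)) {
    rows <- dict$row_partition[[j]]
    W[support, j] <- qr.coef(qr(dict$atoms[rows, support, drop = FALSE]),
                             y[rows])
  }
  W
}
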