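test_that("sparse binary blocks have exactly two ones per column; schemes are seeded", {
  sch <- make_measurement_scheme(J = 2, N = 10, M = 4, "sparse_binary", seed = 5)
  for (B in sch$blocks) {
    expect_equal(dim(B), c(4, 10))
    expect_true(all(colSums(B != 0) == 2))
    expect_true(all(B %in% c(0, 1)))
  }
  sch2 <- make_measurement_scheme(J = 2, N = 10, M = 4, "sparse_binary", seed = 5)
  expect_identical(sch$blocks, sch2$blocks)
  # blocks are drawn independently per sensor
  expect_false(identical(sch$blocks[[1]], sch$blocks[[2]]))
  expect_error(make_measurement_scheme(1, 10, 11), "M")
  expect_error(make_measurement_scheme(1, 10, 0), "M")
})

test_that("compression equals the full block-diagonal operator applied to the stack", {
  sim <- simulate_jsm2_ensemble(J = 3, N = 20, k = 5, noise_sd = 0.2, seed = 6)
  sch <- make_measurement_scheme(3, 20, 8, "gaussian", seed = 7)
  Y <- compress(sim$ensemble, sch)
  # brute-force oracle: assemble the JM x JN block-diagonal matrix
  full <- matrix(0, 3 * 8, 3 * 20)
  for (j in 1:3)
    full[(8 * (j - 1) + 1):(8 * j), (20 * (j - 1) + 1):(20 * j)] <- sch$blocks[[j]]
  expect_lt(max(abs(Y$Y - full %*% as.numeric(sim$ensemble$signals))), 1e-12)
  # off-diagonal blocks of the full operator are zero by construction
  expect_equal(sum(full != 0), sum(vapply(sch$blocks, function(B) sum(B != 0), numeric(1))))

  zero <- sim$ensemble; zero$signals[] <- 0
  expect_equal(compress(zero, sch)$Y, numeric(24))

  sch5 <- make_measurement_scheme(5, 200, 60, "gaussian", seed = 1)
  ens5 <- simulate_jsm2_ensemble(5, 200, 5, seed = 1)$ensemble
  expect_length(compress(ens5, sch5)$Y, 300)
  expect_error(compress(ens5, sch), "does not match")
})

test_that("compression is linear", {
  sch <- make_measurement_scheme(2, 15, 6, "gaussian", seed = 3)
  e1 <- simulate_jsm2_ensemble(2, 15, 4, noise_sd = 1, seed = 1)$ensemble
  e2 <- simulate_jsm2_ensemble(2, 15, 4, noise_sd = 1, seed = 2)$ensemble
  comb <- e1; comb$signals <- 2.5 * e1$signals - 1.3 * e2$signals
  expect_lt(max(abs(compress(comb, sch)$Y -
                    (2.5 * compress(e1, sch)$Y - 1.3 * compress(e2, sch)$Y))), 1e-12)
})

test_that("compression ratio arithmetic", {
  expect_equal(compression_ratio(200, 60), 70)
  expect_equal(compression_ratio(100, 100), 0)
  expect_equal(compression_ratio(100, 25), 75)
  expect_error(compression_ratio(100, 101), "M")
  expect_equal(cr_to_measurements(70, 200), 60L)
  # CR strictly decreasing in M at fixed N
  crs <- vapply(1:50, function(M) compression_ratio(50, M), numeric(1))
  expect_true(all(diff(crs) < 0))
})

test_that("gait-window compression flattens channels per sensor with the shared block", {
  d <- make_small_dataset(n_subjects = 1, n_classes = 1, windows = 2,
                          J = 2, window_len = 30)
  sch <- make_measurement_scheme(2, 30, 10, "gaussian", seed = 2)
  comp <- compress(d, sch)
  expect_equal(dim(comp), c(2 * 5 * 10, 2))
  expect_equal(attr(comp, "row_partition"), list(1:50, 51:100))
  # single-window method agrees with the dataset method
  y1 <- compress(d$samples[, , 1], sch)
  expect_equal(y1, comp[, 1])
  # sensor 2, channel 3 occupies rows 50 + (21:30): Phi_2 x channel row 8
  expect_equal(comp[50 + 21:30, 1],
               as.numeric(sch$blocks[[2]] %*% d$samples[8, , 1]))
})

test_that("SOMP recovers noiseless JSM-2 ensembles exactly and matches the LS oracle", {
  sim <- simulate_jsm2_ensemble(J = 5, N = 64, k = 4, noise_sd = 0, seed = 21)
  sch <- make_measurement_scheme(5, 64, 32, "gaussian", seed = 22)
  Y <- compress(sim$ensemble, sch)
  rec <- joint_reconstruct(Y, diag(64), k = 4, method = "somp")
  expect_identical(rec$model$support, sim$model$support)
  # least squares restricted to the true support, per sensor
  for (j in 1:5) {
    A <- sch$blocks[[j]][, sim$model$support, drop = FALSE]
    ls <- qr.coef(qr(A), Y$measurements[, j])
    expect_lt(max(abs(rec$model$coefficients[sim$model$support, j] - ls)), 1e-8)
  }
  expect_lt(max(abs(rec$X_hat - sim$ensemble$signals)), 1e-8)
  expect_error(joint_reconstruct(Y, diag(64), k = 33), "exceeds")
})

test_that("SOMP's first atom equals the exhaustive summed-squared-correlation argmax", {
  sim <- simulate_jsm2_ensemble(J = 4, N = 48, k = 6, noise_sd = 0.05, seed = 31)
  B <- make_dictionary_basis(48, "dct")
  sch <- make_measurement_scheme(4, 48, 24, "gaussian", seed = 32)
  # signals sparse in the DCT basis
  X <- B %*% sim$model$coefficients
  ens <- structure(list(signals = X, J = 4, N = 48), class = "sensor_ensemble")
  Y <- compress(ens, sch)
  rec1 <- joint_reconstruct(Y, B, k = 1, method = "somp")
  # brute-force scan over all atoms
  score <- vapply(seq_len(48), function(idx) {
    sum(vapply(1:4, function(j) {
      a <- (sch$blocks[[j]] %*% B)[, idx]
      (sum(a * Y$measurements[, j]) / sqrt(sum(a^2)))^2
    }, numeric(1)))
  }, numeric(1))
  expect_equal(rec1$model$support, which.max(score))
})

test_that("k = 0 reconstruction is identically zero", {
  sim <- simulate_jsm2_ensemble(J = 2, N = 16, k = 3, seed = 2)
  sch <- make_measurement_scheme(2, 16, 8, "gaussian", seed = 2)
  rec <- joint_reconstruct(compress(sim$ensemble, sch), diag(16), k = 0)
  expect_equal(rec$X_hat, matrix(0, 16, 2))
  expect_length(rec$model$support, 0)
})

test_that("greedy residuals are non-increasing in the selected-atom budget", {
  sim <- simulate_jsm2_ensemble(J = 3, N = 40, k = 10, noise_sd = 0.3, seed = 41)
  sch <- make_measurement_scheme(3, 40, 20, "gaussian", seed = 42)
  Y <- compress(sim$ensemble, sch)
  # greedy selection is nested, so residuals at budget k trace the iterations
  res_norm <- vapply(0:10, function(k) {
    rec <- joint_reconstruct(Y, diag(40), k = k, method = "somp")
    sum(vapply(1:3, function(j)
      sum((Y$measurements[, j] -
             sch$blocks[[j]] %*% rec$X_hat[, j])^2), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(res_norm) <= 1e-10))
})

test_that("SOMP beats the one-pass OSGA on support recovery over seeded trials", {
  n_trials <- 60
  hit_somp <- hit_osga <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    sim <- simulate_jsm2_ensemble(J = 5, N = 128, k = 8, noise_sd = 0, seed = 1000 + t)
    sch <- make_measurement_scheme(5, 128, 32, "gaussian", seed = 2000 + t)
    Y <- compress(sim$ensemble, sch)
    hit_somp[t] <- identical(
      joint_reconstruct(Y, diag(128), 8, "somp")$model$support, sim$model$support)
    hit_osga[t] <- identical(
      joint_reconstruct(Y, diag(128), 8, "osga")$model$support, sim$model$support)
  }
  expect_gte(mean(hit_somp), 0.95)
  expect_lte(mean(hit_osga), mean(hit_somp))
})
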