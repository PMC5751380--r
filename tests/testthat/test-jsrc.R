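test_that("dictionary columns are unit-norm, class-contiguous and label-mapped", {
  set.seed(1)
  X <- matrix(rnorm(12 * 6), 12, 6) * 5
  dict <- build_dictionary(X, labels = c(3, 1, 2, 1, 3, 2),
                           row_partition = list(1:6, 7:12))
  expect_equal(dict$n, 6L)
  expect_equal(unname(vapply(dict$class_cols, length, integer(1))), c(2L, 2L, 2L))
  expect_true(all(abs(colSums(dict$atoms^2) - 1) < 1e-12))
  expect_true(!is.unsorted(as.integer(dict$labels)))
  # column for original sample 2 (class 1, first occurrence) is first
  expect_equal(dict$atoms[, 1], X[, 2] / sqrt(sum(X[, 2]^2)))
  expect_error(build_dictionary(X, labels = 1:5), "labels")
  expect_error(build_dictionary(X, 1:6, row_partition = list(1:5)), "cover")
})

test_that("ridge SRCC matches the normal-equations oracle and orthonormal shortcut", {
  set.seed(2)
  d <- 30; n <- 12; lambda <- 0.37
  X <- matrix(rnorm(d * n), d, n)
  dict <- build_dictionary(X, rep(1:3, each = 4),
                           row_partition = list(1:15, 16:30))
  y <- rnorm(d)
  nb <- srcc_neighbors(y, dict, lambda = lambda, m = 2)
  # brute-force: per sensor solve (A'A + lambda I) w = A'y, average |w|
  score <- numeric(n)
  for (rows in dict$row_partition) {
    A <- dict$atoms[rows, ]
    w <- solve(crossprod(A) + lambda * diag(n), crossprod(A, y[rows]))
    score <- score + abs(as.numeric(w)) / 2
  }
  expect_lt(max(abs(nb$scores - score[nb$indices])), 1e-8)
  sel_oracle <- unlist(lapply(split(seq_len(n), dict$labels), function(cols)
    cols[order(-score[cols], cols)][1:2]))
  expect_equal(nb$indices, sort(unname(sel_oracle)))

  # orthonormal atoms, one sensor block: ridge = correlation / (1 + lambda)
  Q <- qr.Q(qr(matrix(rnorm(20 * 8), 20, 8)))
  od <- build_dictionary(Q, rep(1:2, each = 4), row_partition = list(1:20))
  nbo <- srcc_neighbors(y[1:20], od, lambda = 0.5, m = 4)
  expect_lt(max(abs(nbo$scores -
                    (abs(crossprod(od$atoms, y[1:20])) / 1.5)[nbo$indices])), 1e-10)
  # a test equal to one atom scores that atom top of its class
  nb1 <- srcc_neighbors(od$atoms[, 3], od, lambda = 1e-6, m = 1)
  expect_true(3 %in% nb1$indices)
})

test_that("SRCC selection is invariant to positive rescaling of the test vector", {
  set.seed(3)
  X <- matrix(rnorm(24 * 9), 24, 9)
  dict <- build_dictionary(X, rep(1:3, 3), row_partition = list(1:12, 13:24))
  y <- rnorm(24)
  a <- srcc_neighbors(y, dict, m = 2)
  b <- srcc_neighbors(7.3 * y, dict, m = 2)
  expect_identical(a$indices, b$indices)
  expect_equal(b$scores, 7.3 * a$scores)
})

test_that("m at least the largest class returns the whole dictionary", {
  set.seed(4)
  X <- matrix(rnorm(10 * 7), 10, 7)
  dict <- build_dictionary(X, c(1, 1, 1, 2, 2, 3, 3))
  nb <- srcc_neighbors(rnorm(10), dict, m = 3)
  expect_equal(nb$indices, 1:7)
  expect_equal(nb$n, dict$n)
})

test_that("KNN pruning equals the brute-force sorted distance list", {
  set.seed(5)
  X <- matrix(rnorm(16 * 10), 16, 10)
  dict <- build_dictionary(X, rep(1:2, each = 5))
  y <- rnorm(16)
  nb <- knn_neighbors(y, dict, m = 2)
  yn <- y / sqrt(sum(y^2))
  d2 <- colSums((dict$atoms - yn)^2)
  oracle <- unlist(lapply(split(seq_len(10), dict$labels), function(cols)
    cols[order(d2[cols], cols)][1:2]))
  expect_equal(nb$indices, sort(unname(oracle)))
  # a test equal to a training atom picks it first in its class
  nb1 <- knn_neighbors(X[, 7], dict, m = 1)
  expect_true(7 %in% nb1$indices)
  expect_equal(nb1$n, 2L)  # m = 1 per class, 2 classes
  expect_error(knn_neighbors(y, dict, m = 0), "m")
})

test_that("greedy joint solver interpolates with a full square dictionary", {
  set.seed(6)
  inst <- make_mmv_instance(n_atoms = 20, J = 2, d = 20, active = c(2, 9),
                            seed = 16)
  W <- solve_joint(inst$y, inst$dict, k = 20, method = "greedy")
  expect_lt(sqrt(sum(W$residual^2)), 1e-8)
  # row-sparsity bound honoured on random instances
  for (k in c(1, 3, 7)) {
    Wk <- solve_joint(rnorm(length(inst$y)), inst$dict, k = k)
    expect_lte(length(Wk$support), k)
    expect_lte(sum(rowSums(Wk$W != 0) > 0), k)
  }
  expect_error(solve_joint(inst$y, inst$dict, k = 21), "exceeds")
})

test_that("greedy per-task residual norms are non-increasing in the budget", {
  inst <- make_mmv_instance(n_atoms = 30, J = 3, d = 25, active = c(1, 8, 20),
                            amplitude = 2, seed = 17)
  y_noisy <- inst$y + rnorm(length(inst$y), sd = 0.3)
  prev <- rep(Inf, 3)
  for (k in 1:8) {
    W <- solve_joint(y_noisy, inst$dict, k = k)
    rn <- vapply(seq_along(inst$rp), function(j)
      sqrt(sum(W$residual[inst$rp[[j]]]^2)), numeric(1))
    expect_true(all(rn <= prev + 1e-10))
    prev <- rn
  }
})

test_that("MBCS recovers a noiseless multitask instance to the LS oracle", {
  inst <- make_mmv_instance(n_atoms = 40, J = 5, d = 30, active = c(3, 17, 25),
                            amplitude = 10, seed = 9)
  fit <- solve_joint(inst$y, inst$dict, method = "mbcs")
  expect_equal(fit$support, inst$active)
  W_ls <- ls_on_support(inst$y, inst$dict, inst$active)
  expect_lt(max(abs(fit$W - W_ls)), 1e-3)
  expect_true(all(fit$beta > 0))
  expect_true(fit$converged)
  # stored residual identity E = y - A W
  recon <- numeric(length(inst$y))
  for (j in seq_along(inst$rp))
    recon[inst$rp[[j]]] <- inst$dict$atoms[inst$rp[[j]], ] %*% fit$W[, j]
  expect_lt(max(abs(fit$residual - (inst$y - recon))), 1e-10)
})

test_that("single-task MBCS matches greedy support on well-separated amplitudes", {
  set.seed(10)
  inst <- make_mmv_instance(n_atoms = 30, J = 1, d = 40, active = c(4, 12, 27),
                            amplitude = 1, seed = 18)
  # amplitudes 5, 8, 12: distinct and well separated from zero
  W <- matrix(0, 30, 1); W[c(4, 12, 27), 1] <- c(5, 8, 12)
  y <- as.numeric(inst$dict$atoms %*% W[, 1])
  mb <- solve_joint(y, inst$dict, method = "mbcs")
  gr <- solve_joint(y, inst$dict, k = 3, method = "greedy")
  expect_equal(mb$support, gr$support)
  expect_equal(mb$support, c(4L, 12L, 27L))
})

test_that("residual rule: exact class reconstruction wins; masks partition W", {
  inst <- make_mmv_instance(n_atoms = 40, J = 3, d = 25,
                            active = c(11, 14, 17), # all class 2 under labels below
                            labels = rep(1:4, each = 10), seed = 19)
  W <- solve_joint(inst$y, inst$dict, k = 5)
  res <- residual_classify(inst$y, inst$dict, W)
  expect_equal(res$label, 2L)
  expect_lt(res$residuals[["2"]], 1e-8)
  # masks sum exactly to W
  expect_identical(Reduce(`+`, res$masked), W$W)
  # brute-force per-class recomputation
  for (i in seq_len(inst$dict$L)) {
    e2 <- 0
    for (j in seq_along(inst$rp)) {
      rows <- inst$rp[[j]]
      e2 <- e2 + sum((inst$y[rows] -
                        inst$dict$atoms[rows, ] %*% res$masked[[i]][, j])^2)
    }
    expect_equal(unname(res$residuals[i]), sqrt(e2))
  }
})

test_that("a class absent from the pruned dictionary gets residual ||y||", {
  set.seed(11)
  X <- matrix(rnorm(12 * 4), 12, 4)
  dict <- build_dictionary(X, c(1, 1, 3, 3))  # class 2 never present
  full <- build_dictionary(cbind(X, rnorm(12)), c(1, 1, 3, 3, 2))
  y <- rnorm(12)
  W <- solve_joint(y, dict, k = 2)
  # evaluate against a dictionary object that lists class 2 with no columns
  dict3 <- dict
  dict3$classes <- c("1", "2", "3")
  dict3$class_cols <- list(`1` = 1:2, `2` = integer(0), `3` = 3:4)
  dict3$L <- 3L
  res <- residual_classify(y, dict3, W)
  expect_equal(unname(res$residuals[["2"]]), sqrt(sum(y^2)))
})

test_that("classification is invariant to permuting class identities", {
  d <- make_small_dataset(seed = 23)
  sch <- make_measurement_scheme(d$J, d$window_len, 30, seed = 3)
  comp <- compress(d, sch)
  dict <- build_dictionary(comp[, -(1:3)], d$labels[-(1:3)],
                           row_partition = attr(comp, "row_partition"))
  perm <- c(2L, 3L, 1L)
  dictp <- build_dictionary(comp[, -(1:3)], perm[d$labels[-(1:3)]],
                            row_partition = attr(comp, "row_partition"))
  for (i in 1:3) {
    y <- comp[, i]
    ra <- residual_classify(y, dict, solve_joint(y, dict, k = 5))
    rb <- residual_classify(y, dictp, solve_joint(y, dictp, k = 5))
    expect_equal(rb$label, perm[ra$label])
  }
})

test_that("fitted model classifies training samples and unseen subjects", {
  d <- make_small_dataset(n_subjects = 5, seed = 29)
  train_idx <- d$subjects <= 4
  dtr <- d
  dtr$samples <- d$samples[, , train_idx, drop = FALSE]
  dtr$labels <- d$labels[train_idx]; dtr$subjects <- d$subjects[train_idx]
  dtr$n <- sum(train_idx)
  fit <- jsrc(dtr, cr = 50, m = 4, k = 4, seed = 5)
  # one-sample pipeline agrees with batch predict
  p1 <- classify_pipeline(d$samples[, , 1], fit)
  expect_equal(p1$label, predict(fit, d$samples[, , 1, drop = FALSE])[1])
  # held-out subject, well-separated classes: all correct
  pred <- predict(fit, d$samples[, , !train_idx, drop = FALSE])
  expect_equal(pred, d$labels[!train_idx])
  # neighbour dictionary is strictly smaller than the full dictionary
  y <- compress(d$samples[, , 1], fit$scheme)
  nb <- srcc_neighbors(y, fit$dictionary, m = 4)
  expect_equal(nb$n, 3L * 4L)
  expect_lt(nb$n, fit$dictionary$n)
})

test_that("one training sample per class still identifies an exact repeat", {
  d <- make_small_dataset(n_subjects = 1, n_classes = 3, windows = 1, seed = 31)
  fit <- jsrc(d, cr = 50, m = 1, k = 1, seed = 2)
  for (i in 1:3)
    expect_equal(predict(fit, d$samples[, , i, drop = FALSE])[1], d$labels[i])
})

test_that("mbcs solver plugs into the end-to-end pipeline", {
  d <- make_small_dataset(n_subjects = 2, n_classes = 2, windows = 2,
                          window_len = 40, seed = 37)
  fit <- jsrc(d, cr = 50, m = 2, k = 2, solver = "mbcs", seed = 4)
  pred <- predict(fit, d)
  expect_equal(pred, d$labels)
})
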