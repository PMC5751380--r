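## Evaluation: confusion tables and percent metrics, subject-wise nested
## cross-validation, traditional baselines (SRC / KNN / NBC), and the
## compression-ratio x neighbour-count sweep driver.

#' Confusion table
#'
#' Builds an L x L count table with entry (i, j) = number of samples of true
#' class i predicted as class j.  \code{as_confusion_table} wraps an
#' existing count matrix (e.g. a published table) in the same class.
#'
#' @param true,pred true and predicted labels (same length).
#' @param classes optional class level set; defaults to the union of both.
#' @return Object of class \code{"confusion_table"} (a named integer matrix).
#' @export
confusion_table <- function(true, pred, classes = NULL) {
  if (length(true) != length(pred))
    stop("`true` and `pred` must have equal length", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(as.character(true),
                                                 as.character(pred))))
  f1 <- factor(as.character(true), levels = as.character(classes))
  f2 <- factor(as.character(pred), levels = as.character(classes))
  tab <- table(true = f1, predicted = f2)
  as_confusion_table(unclass(as.matrix(tab)))
}

#' @rdname confusion_table
#' @param counts square nonnegative count matrix.
#' @export
as_confusion_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("confusion counts must be square", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- colnames(counts) <- as.character(seq_len(nrow(counts)))
  structure(counts, class = c("confusion_table", class(counts)))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("Confusion table (rows = true, columns = predicted):\n")
  print(unclass(x))
  m <- confusion_metrics(x)
  cat(sprintf("Overall accuracy: %.1f%%\n", m$accuracy))
  invisible(x)
}

#' Accuracy, precision and recall from a confusion table
#'
#' Accuracy is the diagonal sum over the grand total, in percent.  Per-class
#' recall is the diagonal entry over its row total (how much of class i is
#' found) and per-class precision the diagonal entry over its column total
#' (how much of what is called class i really is).  Classes with a zero
#' denominator report \code{NA}, not zero.
#'
#' @param tab a \code{\link{confusion_table}} (or square count matrix).
#' @return List with \code{accuracy} (percent), \code{precision} and
#'   \code{recall} (named percent vectors), \code{N_A} (correct count) and
#'   \code{N_T} (total count).
#' @export
confusion_metrics <- function(tab) {
  counts <- unclass(as.matrix(tab))
  if (nrow(counts) != ncol(counts)) stop("counts must be square", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  N_T <- sum(counts)
  if (N_T <= 0) stop("empty confusion table", call. = FALSE)
  N_A <- sum(diag(counts))
  rs <- rowSums(counts); cs <- colSums(counts)
  recall <- ifelse(rs > 0, diag(counts) / rs * 100, NA_real_)
  precision <- ifelse(cs > 0, diag(counts) / cs * 100, NA_real_)
  names(recall) <- names(precision) <- rownames(counts)
  list(accuracy = N_A / N_T * 100, precision = precision, recall = recall,
       N_A = N_A, N_T = N_T)
}

#' Subject-wise nested cross-validation plan
#'
#' Randomly partitions the subjects into \code{outer_folds} groups of (as
#' near as possible) equal size; each subject is held out for testing in
#' exactly one outer fold.  Within each outer training set a nested
#' \code{inner_folds}-way partition is also drawn, available for tuning.
#'
#' @param subjects subject id per sample, or a vector of unique subject ids.
#' @param outer_folds,inner_folds fold counts (inner folds are capped at the
#'   number of training subjects).
#' @param seed RNG seed; plans are deterministic per seed.
#' @return Object of class \code{"cv_plan"}: \code{outer} (list of held-out
#'   subject sets), \code{inner} (per outer fold, a list of nested held-out
#'   sets), \code{subjects}, \code{seed}.
#' @export
make_cv_plan <- function(subjects, outer_folds = 10, inner_folds = 9,
                         seed = 0) {
  subj <- sort(unique(subjects))
  outer_folds <- check_count(outer_folds, "outer_folds")
  inner_folds <- check_count(inner_folds, "inner_folds")
  if (outer_folds > length(subj))
    stop(sprintf("%d folds for %d subjects", outer_folds, length(subj)),
         call. = FALSE)
  with_seed(seed, {
    shuffled <- sample(subj)
    outer <- split(shuffled, rep_len(seq_len(outer_folds), length(subj)))
    outer <- lapply(unname(outer), sort)
    inner <- lapply(outer, function(test_set) {
      tr <- setdiff(subj, test_set)
      nf <- min(inner_folds, length(tr))
      sh <- sample(tr)
      lapply(unname(split(sh, rep_len(seq_len(nf), length(tr)))), sort)
    })
    structure(list(outer = outer, inner = inner, subjects = subj,
                   seed = as.integer(seed)), class = "cv_plan")
  })
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("Subject-wise CV plan: %d subjects, %d outer folds (nested %d-way), seed %d\n",
              length(x$subjects), length(x$outer), length(x$inner[[1L]]),
              x$seed))
  invisible(x)
}

#' Run subject-wise cross-validation of the compressed-domain classifier
#'
#' One measurement scheme is drawn (seed-deterministically) and shared by
#' every fold, so training and test atoms live in the same measurement
#' space.  For each outer fold the model is trained on the training
#' subjects' compressed windows only and evaluated on the held-out
#' subjects'; predictions are pooled into one confusion table.  Any overlap
#' between train and test subjects is an internal error.
#'
#' @param dataset a \code{"gait_dataset"}.
#' @param plan a \code{\link{make_cv_plan}}; built from
#'   \code{outer_folds}/\code{inner_folds}/\code{seed} when \code{NULL}.
#' @param cr compression ratio in percent.
#' @param m,k,lambda,solver,neighbor,scheme_kind classifier settings, as in
#'   \code{\link{jsrc}}.
#' @param outer_folds,inner_folds used when \code{plan} is \code{NULL}.
#' @param seed seed for the scheme (and plan, when drawn here).
#' @param verbose print per-fold progress.
#' @return List with pooled \code{confusion} and \code{metrics},
#'   \code{per_fold} data frame (fold, n_test, accuracy, mean per-sample
#'   classification time in ms — informational only), the \code{plan} and
#'   \code{scheme}.
#' @export
run_cv <- function(dataset, plan = NULL, cr = 50, m = 40, k = 20,
                   lambda = 1e-3, solver = c("greedy", "mbcs"),
                   neighbor = c("srcc", "knn", "none"),
                   scheme_kind = c("sparse_binary", "gaussian"),
                   outer_folds = 10, inner_folds = 9, seed = 0,
                   verbose = FALSE) {
  stopifnot(inherits(dataset, "gait_dataset"))
  solver <- match.arg(solver); neighbor <- match.arg(neighbor)
  scheme_kind <- match.arg(scheme_kind)
  if (is.null(plan))
    plan <- make_cv_plan(dataset$subjects, outer_folds, inner_folds, seed)
  M <- cr_to_measurements(cr, dataset$window_len)
  scheme <- make_measurement_scheme(dataset$J, dataset$window_len, M,
                                    kind = scheme_kind, seed = seed)
  comp <- compress(dataset, scheme)
  rp <- attr(comp, "row_partition")
  classes <- sort(unique(as.character(dataset$labels)))
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  per_fold <- data.frame()

  for (f in seq_along(plan$outer)) {
    test_subj <- plan$outer[[f]]
    train_idx <- which(!(dataset$subjects %in% test_subj))
    test_idx <- which(dataset$subjects %in% test_subj)
    if (length(intersect(dataset$subjects[train_idx],
                         dataset$subjects[test_idx])) > 0L)
      stop("internal error: subject leakage between train and test", call. = FALSE)
    if (length(test_idx) == 0L) next
    train <- comp[, train_idx, drop = FALSE]
    attr(train, "row_partition") <- rp
    dict <- build_dictionary(train, dataset$labels[train_idx])
    factors <- scores <- NULL
    if (neighbor == "srcc") {
      factors <- srcc_factorize(dict, lambda)
      scores <- srcc_score_matrix(comp[, test_idx, drop = FALSE], dict,
                                  lambda, factors)
    }
    t0 <- proc.time()[["elapsed"]]
    pred <- character(length(test_idx))
    for (i in seq_along(test_idx)) {
      out <- classify_one(comp[, test_idx[i]], dict, lambda, m, k, solver,
                          neighbor,
                          score = if (is.null(scores)) NULL else scores[, i])
      pred[i] <- out$label
    }
    elapsed <- proc.time()[["elapsed"]] - t0
    truth <- as.character(dataset$labels[test_idx])
    pooled <- pooled + unclass(confusion_table(truth, pred, classes))
    acc_f <- mean(pred == truth) * 100
    per_fold <- rbind(per_fold, data.frame(
      fold = f, n_test = length(test_idx), accuracy = acc_f,
      mean_time_ms = elapsed / length(test_idx) * 1000))
    if (verbose)
      message(sprintf("fold %d/%d: n_test = %d, accuracy = %.1f%%",
                      f, length(plan$outer), length(test_idx), acc_f))
  }
  pooled <- as_confusion_table(pooled)
  list(confusion = pooled, metrics = confusion_metrics(pooled),
       per_fold = per_fold, plan = plan, scheme = scheme)
}

#' Traditional single-task baselines: SRC, KNN, NBC
#'
#' Operates on concatenated compressed vectors (columns).  \code{"src"}:
#' greedy orthogonal matching pursuit with \code{params$k} atoms over the
#' unit-normalized training dictionary, labelled by the minimal
#' class-restricted residual.  \code{"knn"}: majority vote of the
#' \code{params$k} nearest training columns (Euclidean), ties towards the
#' smaller class.  \code{"nbc"}: Gaussian naive Bayes per vector entry with
#' empirical class priors.
#'
#' @param test vector or d x n_test matrix of test columns.
#' @param train d x n_train matrix of training columns.
#' @param labels training labels.
#' @param method \code{"src"}, \code{"knn"} or \code{"nbc"}.
#' @param params list; \code{k} for src/knn (defaults 20 and 1),
#'   \code{var_floor} for nbc (default 1e-9).
#' @return Predicted label(s), same type as \code{labels} where possible.
#' @export
baseline_classify <- function(test, train, labels,
                              method = c("src", "knn", "nbc"),
                              params = list()) {
  method <- match.arg(method)
  if (!is.matrix(train) || ncol(train) < 1L)
    stop("`train` must be a non-empty matrix", call. = FALSE)
  if (length(labels) != ncol(train))
    stop("one label per training column required", call. = FALSE)
  test <- if (is.matrix(test)) test else matrix(as.numeric(test), ncol = 1L)
  if (nrow(test) != nrow(train))
    stop("test and train dimension mismatch", call. = FALSE)
  f <- factor(labels)
  classes <- levels(f)

  pred <- switch(method,
    src = {
      dict <- build_dictionary(train, labels,
                               row_partition = list(seq_len(nrow(train))))
      k <- if (is.null(params$k)) 20L else check_count(params$k, "k")
      vapply(seq_len(ncol(test)), function(i) {
        y <- test[, i]
        W <- solve_joint(y, dict, k = min(k, nrow(train), dict$n),
                         method = "greedy")
        r <- class_residuals(y, dict, W$W)
        dict$classes[which(r == min(r))[1L]]
      }, character(1))
    },
    knn = {
      k <- if (is.null(params$k)) 1L else check_count(params$k, "k")
      k <- min(k, ncol(train))
      tn2 <- colSums(train^2)
      vapply(seq_len(ncol(test)), function(i) {
        d2 <- tn2 - 2 * as.numeric(crossprod(train, test[, i])) +
          sum(test[, i]^2)
        nb <- order(d2, seq_along(d2))[seq_len(k)]
        votes <- table(factor(as.character(f[nb]), levels = classes))
        classes[which_max_first(as.numeric(votes))]
      }, character(1))
    },
    nbc = {
      vf <- if (is.null(params$var_floor)) 1e-9 else params$var_floor
      mu <- sapply(classes, function(cl)
        rowMeans(train[, f == cl, drop = FALSE]))
      v <- sapply(classes, function(cl) {
        Xc <- train[, f == cl, drop = FALSE]
        pmax(rowMeans((Xc - rowMeans(Xc))^2), vf)
      })
      logprior <- log(as.numeric(table(f)) / ncol(train))
      vapply(seq_len(ncol(test)), function(i) {
        ll <- vapply(seq_along(classes), function(ci)
          -0.5 * sum(log(2 * pi * v[, ci]) + (test[, i] - mu[, ci])^2 / v[, ci]),
          numeric(1)) + logprior
        classes[which_max_first(ll)]
      }, character(1))
    })
  if (!anyNA(suppressWarnings(as.integer(classes))) && is.numeric(labels))
    pred <- as.integer(pred)
  pred
}

#' Sweep compression ratio and neighbour count
#'
#' Runs one identically seeded cross-validation per grid point and collects
#' pooled accuracy and mean per-sample classification time (informational
#' only; never asserted) into a tidy table.
#'
#' @param dataset a \code{"gait_dataset"}.
#' @param cr_grid compression ratios in percent, each in \code{[0, 100)}.
#' @param m_grid neighbour counts per class.
#' @param solvers character vector of joint solvers.
#' @param neighbor neighbour criterion, as in \code{\link{run_cv}}.
#' @param seed seed shared by every run.
#' @param csv optional path; when given the table is also written as CSV.
#' @param ... further arguments passed to \code{\link{run_cv}}.
#' @return Data frame with columns cr, m, solver, accuracy, mean_time_ms.
#' @export
cr_sweep <- function(dataset, cr_grid, m_grid, solvers = "greedy",
                     neighbor = "srcc", seed = 0, csv = NULL, ...) {
  if (length(cr_grid) == 0L || length(m_grid) == 0L)
    stop("grids must be nonempty", call. = FALSE)
  if (any(cr_grid < 0 | cr_grid >= 100))
    stop("compression ratios must be in [0, 100)", call. = FALSE)
  rows <- list()
  for (solver in solvers) for (cr in cr_grid) for (m in m_grid) {
    res <- run_cv(dataset, cr = cr, m = m, solver = solver,
                  neighbor = neighbor, seed = seed, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      cr = cr, m = m, solver = solver,
      accuracy = res$metrics$accuracy,
      mean_time_ms = mean(res$per_fold$mean_time_ms))
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
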