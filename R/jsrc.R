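## Joint sparse representation classification in the compressed domain:
## over-complete dictionary of compressed training windows, per-test-sample
## neighbour pruning (ridge-coefficient SRCC criterion or KNN), joint
## row-sparse coefficient solvers (greedy SOMP over sensor tasks, or
## multitask Bayesian compressive sensing), and the minimal-residual rule.

#' Build an over-complete training dictionary
#'
#' Stacks compressed training samples as columns, grouped contiguously by
#' ascending class, each column scaled to unit Euclidean norm.  The
#' per-sensor row partition (which rows of a compressed vector belong to
#' which sensor) is carried along for the joint solvers.
#'
#' @param x numeric matrix of compressed training samples, one column per
#'   sample (e.g. the output of \code{\link{compress}} on a dataset), or any
#'   d x n matrix.
#' @param labels class label per column (integer, character or factor).
#' @param row_partition list of row-index vectors, one per sensor; defaults
#'   to \code{attr(x, "row_partition")}, or a single block covering all rows.
#' @return Object of class \code{"training_dictionary"}: \code{atoms} (unit
#'   columns, class-major), \code{labels} (per column), \code{classes}
#'   (level set), \code{class_cols} (list of column indices per class),
#'   \code{row_partition}, \code{L}, \code{n}.
#' @export
build_dictionary <- function(x, labels, row_partition = NULL) {
  if (!is.matrix(x) || ncol(x) < 1L) stop("`x` must be a d x n matrix", call. = FALSE)
  if (length(labels) != ncol(x))
    stop(sprintf("%d labels for %d columns", length(labels), ncol(x)), call. = FALSE)
  if (is.null(row_partition)) row_partition <- attr(x, "row_partition")
  if (is.null(row_partition)) row_partition <- list(seq_len(nrow(x)))
  covered <- sort(unlist(row_partition))
  if (!identical(covered, seq_len(nrow(x))))
    stop("row_partition must cover every row exactly once", call. = FALSE)

  f <- factor(labels)
  ord <- order(as.integer(f))           # stable: class-major, original order within
  atoms <- x[, ord, drop = FALSE]
  nrm <- col_norms(atoms)
  nrm[nrm == 0] <- 1
  atoms <- sweep(atoms, 2L, nrm, "/")
  lab <- f[ord]
  classes <- levels(f)
  class_cols <- lapply(classes, function(cl) which(lab == cl))
  names(class_cols) <- classes
  structure(list(atoms = atoms, labels = lab, classes = classes,
                 class_cols = class_cols, row_partition = row_partition,
                 L = length(classes), n = ncol(atoms)),
            class = c("training_dictionary", "jsrc_dictionary"))
}

#' @export
print.training_dictionary <- function(x, ...) {
  cat(sprintf("Over-complete dictionary: %d atoms of dim %d, %d classes, %d sensors\n",
              x$n, nrow(x$atoms), x$L, length(x$row_partition)))
  invisible(x)
}

## Per-sensor ridge factorizations reused across test samples.  For each
## sensor block A_j (d_j x n) the ridge solution
##   w = (A_j' A_j + lambda I)^{-1} A_j' y
## is computed through whichever of the primal (n x n) or dual (d_j x d_j)
## normal system is smaller; the two are algebraically identical.
srcc_factorize <- function(dict, lambda) {
  lapply(dict$row_partition, function(rows) {
    A <- dict$atoms[rows, , drop = FALSE]
    d <- nrow(A); n <- ncol(A)
    if (d <= n) {
      list(dual = TRUE, A = A,
           R = chol(tcrossprod(A) + diag(lambda, d)))
    } else {
      list(dual = FALSE, A = A,
           R = chol(crossprod(A) + diag(lambda, n)))
    }
  })
}

## Mean over sensors of |ridge coefficient|: returns an n_atoms x n_test
## score matrix for a d x n_test matrix of test vectors.
srcc_score_matrix <- function(Ytest, dict, lambda, factors = NULL) {
  if (is.null(factors)) factors <- srcc_factorize(dict, lambda)
  J <- length(factors)
  acc <- 0
  for (j in seq_len(J)) {
    f <- factors[[j]]
    Yj <- Ytest[dict$row_partition[[j]], , drop = FALSE]
    W <- if (f$dual) {
      crossprod(f$A, backsolve(f$R, forwardsolve(t(f$R), Yj)))
    } else {
      backsolve(f$R, forwardsolve(t(f$R), crossprod(f$A, Yj)))
    }
    acc <- acc + abs(W)
  }
  acc / J
}

## Per-class top-m selection by score (descending), deterministic
## lower-index tie-break; returns sorted column indices.
select_per_class <- function(score, dict, m) {
  sel <- unlist(lapply(dict$class_cols, function(cols) {
    keep <- min(m, length(cols))
    cols[order(-score[cols], cols)[seq_len(keep)]]
  }), use.names = FALSE)
  sort(sel)
}

make_neighbor_dictionary <- function(dict, sel, score, m, lambda = NA_real_,
                                     criterion = "srcc") {
  lab <- dict$labels[sel]
  classes <- dict$classes
  class_cols <- lapply(classes, function(cl) which(lab == cl))
  names(class_cols) <- classes
  structure(list(atoms = dict$atoms[, sel, drop = FALSE], labels = lab,
                 classes = classes, class_cols = class_cols,
                 row_partition = dict$row_partition, L = dict$L,
                 n = length(sel), indices = sel, scores = score[sel],
                 m = m, lambda = lambda, criterion = criterion),
            class = c("neighbor_dictionary", "jsrc_dictionary"))
}

#' SRCC neighbour selection: prune the dictionary with ridge coefficients
#'
#' The sparse representation coefficients-inducing criterion: for each
#' sensor the test block is ridge-regressed on the corresponding rows of
#' every training atom (closed form \eqn{(A'A + \lambda I)^{-1} A' y}); each
#' atom is scored by the mean absolute ridge coefficient across sensors, and
#' within each class the \code{min(m, n_i)} highest-scoring atoms are kept,
#' ties broken towards the lower column index.  The pruned dictionary
#' (\code{L * m} atoms at most) is what the joint solver then works on.
#'
#' @param y compressed test vector (length = rows of the dictionary).
#' @param dict a \code{\link{build_dictionary}} result.
#' @param lambda ridge penalty, > 0 (default \code{1e-3}).
#' @param m neighbours kept per class.
#' @param pooled solve one ridge problem on the full stacked vector instead
#'   of per-sensor problems averaged (non-default variant).
#' @return Object of class \code{"neighbor_dictionary"}; see
#'   \code{\link{build_dictionary}} for shared fields, plus \code{indices}
#'   (columns kept from the parent), \code{scores}, \code{m}, \code{lambda}.
#' @export
srcc_neighbors <- function(y, dict, lambda = 1e-3, m = 40, pooled = FALSE) {
  stopifnot(inherits(dict, "training_dictionary"))
  lambda <- check_scalar(lambda, "lambda", min = 0, strict = TRUE)
  m <- check_count(m, "m")
  y <- matrix(as.numeric(y), ncol = 1L)
  if (nrow(y) != nrow(dict$atoms))
    stop("test vector length does not match dictionary rows", call. = FALSE)
  score <- if (pooled) {
    pooled_dict <- dict
    pooled_dict$row_partition <- list(seq_len(nrow(dict$atoms)))
    as.numeric(srcc_score_matrix(y, pooled_dict, lambda))
  } else {
    as.numeric(srcc_score_matrix(y, dict, lambda))
  }
  sel <- select_per_class(score, dict, m)
  make_neighbor_dictionary(dict, sel, score, m, lambda, "srcc")
}

#' KNN neighbour selection
#'
#' Comparison criterion: within each class keep the \code{min(m, n_i)} atoms
#' closest in Euclidean distance to the (unit-normalized) test vector, ties
#' broken towards the lower column index.
#'
#' @inheritParams srcc_neighbors
#' @return A \code{"neighbor_dictionary"}.
#' @export
knn_neighbors <- function(y, dict, m = 40) {
  stopifnot(inherits(dict, "training_dictionary"))
  m <- check_count(m, "m")
  y <- as.numeric(y)
  if (length(y) != nrow(dict$atoms))
    stop("test vector length does not match dictionary rows", call. = FALSE)
  ny <- sqrt(sum(y^2)); if (ny > 0) y <- y / ny
  d2 <- colSums((dict$atoms - y)^2)
  sel <- select_per_class(-d2, dict, m)
  make_neighbor_dictionary(dict, sel, -d2, m, criterion = "knn")
}

## Multitask Bayesian CS: hierarchical Gaussian model with per-atom prior
## precisions alpha shared across the J sensor tasks and a common noise
## precision beta0, fit by evidence maximization (multitask RVM updates);
## atoms whose precision diverges are pruned.  Returns posterior means.
mbcs_engine <- function(Ylist, Alist, tol = 1e-6, max_iter = 200,
                        prune_alpha = 1e8) {
  J <- length(Ylist)
  n_atoms <- ncol(Alist[[1L]])
  d <- vapply(Ylist, length, integer(1))
  alpha <- rep(1, n_atoms)
  vy <- mean(vapply(Ylist, function(y) mean(y^2), numeric(1)))
  beta0 <- if (vy > 0) 100 / vy else 1
  active <- rep(TRUE, n_atoms)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    act <- which(active)
    if (length(act) == 0L) { converged <- TRUE; break }
    musq <- gam <- numeric(length(act))
    rss <- 0; gam_tot <- 0
    for (j in seq_len(J)) {
      Aj <- Alist[[j]][, act, drop = FALSE]
      H <- beta0 * crossprod(Aj) + diag(alpha[act], length(act))
      R <- chol(H)
      Sigma_diag <- colSums(backsolve(R, diag(length(act)))^2)
      mu <- beta0 * backsolve(R, forwardsolve(t(R), crossprod(Aj, Ylist[[j]])))
      g <- 1 - alpha[act] * Sigma_diag
      musq <- musq + as.numeric(mu)^2
      gam <- gam + g
      gam_tot <- gam_tot + sum(g)
      rss <- rss + sum((Ylist[[j]] - Aj %*% mu)^2)
    }
    alpha_new <- gam / pmax(musq, .Machine$double.eps)
    alpha_new <- pmin(pmax(alpha_new, 1e-12), 1e12)
    beta0 <- min(max((sum(d) - gam_tot) / max(rss, 1e-300), 1e-6), 1e12)
    delta <- max(abs(log(alpha_new) - log(alpha[act])))
    alpha[act] <- alpha_new
    active[act] <- alpha_new < prune_alpha
    if (delta < tol) { converged <- TRUE; break }
  }

  act <- which(active)
  W <- matrix(0, n_atoms, J)
  if (length(act) > 0L) {
    for (j in seq_len(J)) {
      Aj <- Alist[[j]][, act, drop = FALSE]
      H <- beta0 * crossprod(Aj) + diag(alpha[act], length(act))
      R <- chol(H)
      W[act, j] <- beta0 *
        backsolve(R, forwardsolve(t(R), crossprod(Aj, Ylist[[j]])))
    }
  }
  list(W = W, support = act, alpha = alpha, beta0 = beta0,
       converged = converged)
}

#' Solve the joint row-sparse coefficient problem
#'
#' Estimates the coefficient matrix \code{W} (one column per sensor task)
#' representing the test vector over the dictionary atoms under a shared row
#' support.  \code{"greedy"} runs simultaneous orthogonal matching pursuit
#' over the sensor tasks, selecting at most \code{k} shared atoms with a
#' per-task least-squares refit each iteration (the mixed l2/l0 program).
#' \code{"mbcs"} fits the multitask Bayesian compressive sensing model:
#' Gaussian noise with unknown precision and zero-mean Gaussian priors on
#' each coefficient row with per-atom precisions shared across tasks,
#' estimated by evidence maximization; non-convergence within
#' \code{max_iter} is flagged, not an error.
#'
#' @param y compressed test vector (stacked over sensors).
#' @param A a \code{"jsrc_dictionary"} (training or neighbour dictionary).
#' @param k row-sparsity bound for the greedy solver (>= 1, at most the
#'   smallest per-sensor row count).
#' @param method \code{"greedy"} or \code{"mbcs"}.
#' @param tol relative convergence tolerance for \code{"mbcs"}.
#' @param max_iter iteration cap for \code{"mbcs"}.
#' @return Object of class \code{"joint_coefficients"}: \code{W}
#'   (atoms x tasks), \code{support} (active rows), \code{solver},
#'   \code{residual} (stacked \code{y - A W}), \code{beta} (per-atom prior
#'   precisions, mbcs only), \code{beta0} (noise precision, mbcs only),
#'   \code{converged}.
#' @export
solve_joint <- function(y, A, k = 20, method = c("greedy", "mbcs"),
                        tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(A, "jsrc_dictionary"))
  method <- match.arg(method)
  y <- as.numeric(y)
  if (length(y) != nrow(A$atoms))
    stop("test vector length does not match dictionary rows", call. = FALSE)
  Ylist <- lapply(A$row_partition, function(rows) y[rows])
  Alist <- lapply(A$row_partition, function(rows) A$atoms[rows, , drop = FALSE])
  if (method == "greedy") {
    k <- check_count(k, "k")
    dmin <- min(vapply(Ylist, length, integer(1)))
    if (k > dmin)
      stop(sprintf("k = %d exceeds the smallest per-sensor row count (%d)", k, dmin),
           call. = FALSE)
    fit <- somp_engine(Ylist, Alist, min(k, A$n))
    fit$beta <- NULL; fit$beta0 <- NULL; fit$converged <- TRUE
  } else {
    tol <- check_scalar(tol, "tol", min = 0, strict = TRUE)
    fit <- mbcs_engine(Ylist, Alist, tol = tol, max_iter = max_iter)
    if (!fit$converged)
      warning("mbcs solver did not converge within max_iter", call. = FALSE)
    fit$beta <- fit$alpha
  }
  E <- numeric(length(y))
  J <- length(Ylist)
  for (j in seq_len(J))
    E[A$row_partition[[j]]] <- Ylist[[j]] - Alist[[j]] %*% fit$W[, j]
  structure(list(W = fit$W, support = fit$support, solver = method,
                 k = if (method == "greedy") k else NA_integer_,
                 residual = E, beta = fit$beta, beta0 = fit$beta0,
                 converged = fit$converged),
            class = "joint_coefficients")
}

## Per-class residuals ||y - A delta_i(W)||_2 on the full stacked vector.
class_residuals <- function(y, A, W) {
  r <- numeric(A$L)
  names(r) <- A$classes
  ny <- sqrt(sum(y^2))
  J <- length(A$row_partition)
  for (i in seq_len(A$L)) {
    cols <- A$class_cols[[i]]
    if (length(cols) == 0L) { r[i] <- ny; next }
    e2 <- 0
    for (j in seq_len(J)) {
      rows <- A$row_partition[[j]]
      approx <- A$atoms[rows, cols, drop = FALSE] %*% W[cols, j]
      e2 <- e2 + sum((y[rows] - approx)^2)
    }
    r[i] <- sqrt(e2)
  }
  r
}

#' Classify by the minimal residual rule
#'
#' For each class \code{i} the coefficient matrix is masked to the rows of
#' that class's atoms (\eqn{\delta_i(W)}) and the class residual
#' \eqn{r_i = \|y - A\,\delta_i(W)\|_2} is computed over the full stacked
#' vector; the predicted class minimizes \code{r_i}, ties broken towards the
#' smaller class index.  A class with no atoms in \code{A} gets
#' \eqn{r_i = \|y\|_2} (all-zero mask).
#'
#' @param y compressed test vector.
#' @param A a \code{"jsrc_dictionary"}.
#' @param W a \code{"joint_coefficients"} object (or bare atoms x tasks
#'   matrix) dimensioned to \code{A}.
#' @return Object of class \code{"jsrc_classification"}: \code{label}
#'   (predicted class, as the dictionary's label type), \code{residuals}
#'   (named per-class), \code{masked} (list of per-class
#'   \eqn{\delta_i(W)} matrices, which sum to \code{W}).
#' @export
residual_classify <- function(y, A, W) {
  stopifnot(inherits(A, "jsrc_dictionary"))
  Wm <- if (inherits(W, "joint_coefficients")) W$W else as.matrix(W)
  if (nrow(Wm) != A$n)
    stop("coefficient rows do not match dictionary atoms", call. = FALSE)
  y <- as.numeric(y)
  r <- class_residuals(y, A, Wm)
  best <- which(r == min(r))[1L]
  masked <- lapply(seq_len(A$L), function(i) {
    Mi <- matrix(0, nrow(Wm), ncol(Wm))
    cols <- A$class_cols[[i]]
    if (length(cols)) Mi[cols, ] <- Wm[cols, , drop = FALSE]
    Mi
  })
  names(masked) <- A$classes
  label <- A$classes[best]
  if (is.factor(A$labels) && !anyNA(suppressWarnings(as.integer(A$classes))))
    label <- as.integer(label)
  structure(list(label = label, residuals = r, masked = masked),
            class = "jsrc_classification")
}

#' @export
print.jsrc_classification <- function(x, ...) {
  cat("Predicted class:", x$label, "\n")
  cat("Per-class residuals:\n")
  print(round(x$residuals, 4))
  invisible(x)
}

## Fast path used by predict/run_cv: label + residuals only, with
## precomputed SRCC factors and a compressed test vector.
classify_one <- function(y, dict, lambda, m, k, solver, neighbor,
                         factors = NULL, score = NULL) {
  A <- switch(neighbor,
    srcc = {
      if (is.null(score))
        score <- as.numeric(srcc_score_matrix(matrix(y, ncol = 1L), dict,
                                              lambda, factors))
      sel <- select_per_class(score, dict, m)
      make_neighbor_dictionary(dict, sel, score, m, lambda, "srcc")
    },
    knn = knn_neighbors(y, dict, m),
    none = dict)
  W <- solve_joint(y, A, k = min(k, A$n), method = solver)
  r <- class_residuals(y, A, W$W)
  list(label = A$classes[which(r == min(r))[1L]], residuals = r,
       n_atoms = A$n)
}

#' Fit a compressed-domain joint sparse representation classifier
#'
#' The end-to-end model: raw multi-sensor windows are jointly compressed by
#' a block-diagonal random measurement scheme (drawn once and shared by
#' training and test data), the compressed training windows form an
#' over-complete dictionary, and prediction prunes the dictionary per test
#' sample (SRCC ridge criterion by default), solves the joint row-sparse
#' coefficient problem across sensors, and labels by the minimal residual
#' rule.
#'
#' @param x training data: a \code{"gait_dataset"}, a \code{(5J) x h x n}
#'   array of raw windows, or an already-compressed d x n matrix carrying a
#'   \code{"row_partition"} attribute.
#' @param labels class labels per sample (taken from the dataset if absent).
#' @param scheme a \code{"measurement_scheme"}; built from \code{cr} /
#'   \code{scheme_kind} / \code{seed} when \code{NULL} and \code{x} is raw.
#' @param cr compression ratio in percent used when drawing a scheme.
#' @param scheme_kind \code{"sparse_binary"} or \code{"gaussian"}.
#' @param lambda SRCC ridge penalty (> 0).
#' @param m neighbours kept per class.
#' @param k row-sparsity bound of the greedy joint solver.
#' @param solver \code{"greedy"} or \code{"mbcs"}.
#' @param neighbor \code{"srcc"} (default), \code{"knn"}, or \code{"none"}
#'   (use the full dictionary, the plain JSRC baseline).
#' @param seed seed for the measurement scheme when one is drawn here.
#' @return Object of class \code{"jsrc_model"} with \code{print},
#'   \code{summary} and \code{predict} methods.
#' @seealso \code{\link{predict.jsrc_model}}, \code{\link{run_cv}}
#' @examples
#' d <- simulate_gait_dataset(3, 3, 4, J = 2, window_len = 40,
#'                            class_sep = 5, noise_sd = 0.05, seed = 1)
#' fit <- jsrc(d, cr = 50, m = 4, k = 3, seed = 1)
#' pred <- predict(fit, d)
#' mean(pred == d$labels)
#' @export
jsrc <- function(x, labels = NULL, scheme = NULL, cr = 50,
                 scheme_kind = c("sparse_binary", "gaussian"),
                 lambda = 1e-3, m = 40, k = 20,
                 solver = c("greedy", "mbcs"),
                 neighbor = c("srcc", "knn", "none"), seed = 0) {
  scheme_kind <- match.arg(scheme_kind)
  solver <- match.arg(solver)
  neighbor <- match.arg(neighbor)
  cl <- match.call()

  if (inherits(x, "gait_dataset")) {
    if (is.null(labels)) labels <- x$labels
    if (is.null(scheme)) {
      M <- cr_to_measurements(cr, x$window_len)
      scheme <- make_measurement_scheme(x$J, x$window_len, M,
                                        kind = scheme_kind, seed = seed)
    }
    comp <- compress(x, scheme)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (is.null(scheme))
      stop("supply a `scheme` (or a gait_dataset) so windows can be compressed",
           call. = FALSE)
    ds <- structure(list(samples = x, labels = labels,
                         subjects = rep(NA_integer_, dim(x)[3L]),
                         J = scheme$J, window_len = dim(x)[2L],
                         n_channels = 5L, n = dim(x)[3L]),
                    class = "gait_dataset")
    comp <- compress(ds, scheme)
  } else if (is.matrix(x)) {
    if (is.null(attr(x, "row_partition")))
      stop("compressed input must carry a 'row_partition' attribute", call. = FALSE)
    comp <- x
  } else stop("unsupported training input", call. = FALSE)
  if (is.null(labels)) stop("training labels are required", call. = FALSE)

  dict <- build_dictionary(comp, labels)
  structure(list(scheme = scheme, dictionary = dict, lambda = lambda,
                 m = check_count(m, "m"), k = check_count(k, "k"),
                 solver = solver, neighbor = neighbor, call = cl),
            class = "jsrc_model")
}

#' @export
print.jsrc_model <- function(x, ...) {
  cat("Compressed-domain joint sparse representation classifier\n")
  if (!is.null(x$scheme))
    cat(sprintf("  measurement scheme: %s, CR = %.1f%% (M = %d of N = %d), J = %d\n",
                x$scheme$kind, x$scheme$compression_ratio, x$scheme$M,
                x$scheme$N, x$scheme$J))
  cat(sprintf("  dictionary: %d atoms x dim %d, %d classes\n",
              x$dictionary$n, nrow(x$dictionary$atoms), x$dictionary$L))
  cat(sprintf("  neighbour criterion: %s (m = %d, lambda = %g); solver: %s (k = %d)\n",
              x$neighbor, x$m, x$lambda, x$solver, x$k))
  invisible(x)
}

#' @export
summary.jsrc_model <- function(object, ...) {
  print(object)
  tab <- table(object$dictionary$labels)
  cat("  training atoms per class:\n")
  print(tab)
  invisible(object)
}

#' Predict classes for new multi-sensor windows
#'
#' @param object a fitted \code{\link{jsrc}} model.
#' @param newdata a \code{"gait_dataset"}, a \code{(5J) x h x n} array, one
#'   \code{(5J) x h} window matrix, or an already-compressed d x n matrix.
#' @param type \code{"class"} for a label vector, \code{"residuals"} for the
#'   n x L matrix of per-class residuals (with predicted labels as an
#'   attribute).
#' @param ... unused.
#' @export
predict.jsrc_model <- function(object, newdata,
                               type = c("class", "residuals"), ...) {
  type <- match.arg(type)
  comp <- if (inherits(newdata, "gait_dataset")) {
    compress(newdata, object$scheme)
  } else if (is.array(newdata) && length(dim(newdata)) == 3L) {
    ds <- structure(list(samples = newdata, labels = NULL,
                         subjects = rep(NA_integer_, dim(newdata)[3L]),
                         J = object$scheme$J, window_len = dim(newdata)[2L],
                         n_channels = 5L, n = dim(newdata)[3L]),
                    class = "gait_dataset")
    compress(ds, object$scheme)
  } else if (is.matrix(newdata) && !is.null(object$scheme) &&
             nrow(newdata) == 5L * object$scheme$J &&
             ncol(newdata) == object$scheme$N) {
    matrix(compress(newdata, object$scheme), ncol = 1L)
  } else if (is.matrix(newdata)) {
    if (nrow(newdata) != nrow(object$dictionary$atoms))
      stop(sprintf("newdata rows (%d) do not match model dimension (%d)",
                   nrow(newdata), nrow(object$dictionary$atoms)), call. = FALSE)
    newdata
  } else stop("unsupported newdata", call. = FALSE)

  dict <- object$dictionary
  n_test <- ncol(comp)
  factors <- NULL; scores <- NULL
  if (object$neighbor == "srcc") {
    factors <- srcc_factorize(dict, object$lambda)
    scores <- srcc_score_matrix(comp, dict, object$lambda, factors)
  }
  labels <- character(n_test)
  res <- matrix(NA_real_, n_test, dict$L, dimnames = list(NULL, dict$classes))
  for (i in seq_len(n_test)) {
    out <- classify_one(comp[, i], dict, object$lambda, object$m, object$k,
                        object$solver, object$neighbor,
                        score = if (is.null(scores)) NULL else scores[, i])
    labels[i] <- out$label
    res[i, names(out$residuals)] <- out$residuals
  }
  if (is.factor(dict$labels) && !anyNA(suppressWarnings(as.integer(dict$classes))))
    labels <- as.integer(labels)
  if (type == "class") return(labels)
  attr(res, "labels") <- labels
  res
}

#' One-call pipeline: compress, prune, solve, classify a single window
#'
#' Convenience wrapper running the full per-sample path of a fitted model on
#' one raw \code{(5J) x h} window: compression with the stored scheme, SRCC
#' (or KNN) neighbour pruning, the joint solver, and the minimal residual
#' rule.  Returns the full classification object rather than just a label.
#'
#' @param sample raw window matrix, or an already-compressed vector.
#' @param model a \code{"jsrc_model"}.
#' @return A \code{"jsrc_classification"} (see \code{\link{residual_classify}}).
#' @export
classify_pipeline <- function(sample, model) {
  stopifnot(inherits(model, "jsrc_model"))
  y <- if (is.matrix(sample)) compress(sample, model$scheme) else as.numeric(sample)
  dict <- model$dictionary
  A <- switch(model$neighbor,
              srcc = srcc_neighbors(y, dict, model$lambda, model$m),
              knn = knn_neighbors(y, dict, model$m),
              none = dict)
  W <- solve_joint(y, A, k = min(model$k, A$n), method = model$solver)
  residual_classify(y, A, W)
}
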