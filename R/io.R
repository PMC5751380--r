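## Serialization glue, run configuration, the bundled reference confusion
## table, and the command-line dispatcher.

#' Reference nine-class gait confusion table
#'
#' The published confusion counts of a nine-activity wearable-sensor gait
#' classification experiment (1800 windows, 200 per class), bundled as a
#' worked example for \code{\link{confusion_metrics}}.  Two rows of the
#' original table ("upstairs" and "jog") sum to more than their nominal 200
#' windows as printed; they are included verbatim, and their derived
#' per-class recalls should be read with that inconsistency in mind.
#'
#' @return A \code{\link{confusion_table}}.
#' @examples
#' m <- confusion_metrics(gait9_confusion())
#' round(m$recall["standing"]) # 93
#' @export
gait9_confusion <- function() {
  path <- system.file("extdata", "gait9_confusion.csv", package = "gaitcs",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  counts <- as.matrix(df[, -1L])
  rownames(counts) <- df[[1L]]
  as_confusion_table(counts)
}

#' Save / load a gait dataset as plain-text files
#'
#' \code{save_dataset} writes one CSV per window (rows = sensor-major
#' channels, columns = time) plus \code{manifest.csv} (file, label, subject)
#' and \code{meta.json} (layout, seed, content hash); \code{load_dataset}
#' reconstructs the dataset losslessly (up to ground-truth templates, which
#' are not serialized).  \code{save_dataset_archive} /
#' \code{load_dataset_archive} do the same through one binary archive file.
#'
#' @param dataset a \code{"gait_dataset"}.
#' @param dir directory to create/fill.
#' @return \code{save_dataset} returns \code{dir} invisibly;
#'   \code{load_dataset} a \code{"gait_dataset"}.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gait_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("sample%05d.csv", seq_len(dataset$n))
  for (i in seq_len(dataset$n))
    utils::write.table(dataset$samples[, , i], file.path(dir, files[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(file = files, label = dataset$labels,
                              subject = dataset$subjects),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  meta <- list(J = dataset$J, window_len = dataset$window_len,
               n_channels = dataset$n_channels, L = dataset$L,
               n = dataset$n, sampling_rate = dataset$sampling_rate,
               seed = dataset$seed,
               content_md5 = unname(tools::md5sum(file.path(dir, "manifest.csv"))))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n <- nrow(man)
  arr <- array(0, dim = c(5L * meta$J, meta$window_len, n))
  for (i in seq_len(n))
    arr[, , i] <- as.matrix(utils::read.csv(file.path(dir, man$file[i]),
                                            header = FALSE))
  structure(list(samples = arr, labels = man$label, subjects = man$subject,
                 J = meta$J, window_len = meta$window_len,
                 n_channels = meta$n_channels, L = meta$L, n = n,
                 sampling_rate = meta$sampling_rate, templates = NULL,
                 seed = if (is.null(meta$seed)) NA_integer_ else meta$seed),
            class = "gait_dataset")
}

#' @rdname save_dataset
#' @param file archive path.
#' @export
save_dataset_archive <- function(dataset, file) {
  stopifnot(inherits(dataset, "gait_dataset"))
  saveRDS(dataset, file)
  invisible(file)
}

#' @rdname save_dataset
#' @export
load_dataset_archive <- function(file) {
  x <- readRDS(file)
  stopifnot(inherits(x, "gait_dataset"))
  x
}

#' Save / load a fitted model or measurement scheme
#'
#' One archive holds the scheme, dictionary and hyperparameters, so an
#' experiment is exactly replayable.
#'
#' @param object a \code{"jsrc_model"} or \code{"measurement_scheme"}.
#' @param file archive path.
#' @export
save_model <- function(object, file) {
  stopifnot(inherits(object, "jsrc_model") ||
              inherits(object, "measurement_scheme"))
  saveRDS(object, file)
  invisible(file)
}

#' @rdname save_model
#' @export
load_model <- function(file) readRDS(file)

#' Run configuration
#'
#' The full set of tunables of a pipeline run, round-tripping losslessly
#' through a \code{key = value} text file.
#'
#' @param ... overrides of the defaults listed below.
#' @return Object of class \code{"run_config"} (a named list): window
#'   settings (\code{window_len} 200, \code{overlap_fraction} 0.5,
#'   \code{sampling_rate} 20, \code{filter_order} 5, \code{filter_cutoff}
#'   30), scheme settings (\code{scheme_kind} sparse_binary, \code{cr} 50),
#'   classifier settings (\code{lambda} 1e-3, \code{m} 40, \code{k} 20,
#'   \code{solver} greedy, \code{neighbor} srcc), CV settings
#'   (\code{outer_folds} 10, \code{inner_folds} 9) and \code{seed} 0.
#' @export
run_config <- function(...) {
  cfg <- list(window_len = 200L, overlap_fraction = 0.5, sampling_rate = 20,
              filter_order = 5L, filter_cutoff = 30,
              scheme_kind = "sparse_binary", cr = 50,
              lambda = 1e-3, m = 40L, k = 20L,
              solver = "greedy", neighbor = "srcc",
              outer_folds = 10L, inner_folds = 9L, seed = 0L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path text file of \code{key = value} lines (\code{#} comments
#'   allowed).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) { if (num == round(num)) as.integer(num) else num } else v
  })
  names(parsed) <- keys
  do.call(run_config, parsed)
}

#' @rdname run_config
#' @param config a \code{"run_config"}.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, digits = 15), "")),
             path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

write_artifact_meta <- function(path, config) {
  jsonlite::write_json(list(seed = config$seed, config_md5 = config_hash(config)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
}

cli_usage <- function() {
  cat("usage: gaitcs <command> [--config FILE] [--key value ...]\n",
      "commands:\n",
      "  simulate --out DIR [--n-subjects N --n-classes L --windows W]\n",
      "  compress --data DIR --out FILE.csv\n",
      "  train    --data DIR --out MODEL.rds\n",
      "  classify --data DIR --model MODEL.rds --out FILE.csv\n",
      "  evaluate --data DIR --out FILE.csv\n",
      "  sweep    --data DIR --out FILE.csv [--cr-grid 10,30,50 --m-grid 20,40]\n",
      sep = "")
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args)) stop("missing value for --", key, call. = FALSE)
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line dispatcher
#'
#' Thin shell entry point over the package functions; see
#' \code{inst/cli/gaitcs.R} for the executable wrapper.  Commands:
#' \code{simulate} (write a synthetic dataset), \code{compress} (write
#' compressed columns as CSV), \code{train} (fit and archive a model),
#' \code{classify} (label a dataset with a stored model), \code{evaluate}
#' (subject-wise CV, confusion table to CSV), \code{sweep} (CR x m grid to
#' CSV).  Every artifact gets a sidecar \code{.meta.json} naming the seed
#' and config hash that produced it.  Settings come from \code{--config}
#' (a \code{key = value} file) overridden by individual flags.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args) {
  if (length(args) == 0L || args[1L] %in% c("-h", "--help", "help")) {
    cli_usage(); return(invisible(0L))
  }
  cmd <- args[1L]
  status <- tryCatch({
    opts <- parse_cli_args(args[-1L])
    cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else run_config()
    for (key in intersect(names(opts), names(cfg))) {
      v <- opts[[key]]
      num <- suppressWarnings(as.numeric(v))
      cfg[[key]] <- if (!is.na(num)) num else v
    }
    seed <- as.integer(cfg$seed)

    get_data <- function() {
      if (is.null(opts$data)) stop("--data is required", call. = FALSE)
      if (dir.exists(opts$data)) load_dataset(opts$data)
      else load_dataset_archive(opts$data)
    }
    need_out <- function() {
      if (is.null(opts$out)) stop("--out is required", call. = FALSE)
      opts$out
    }
    num_list <- function(v, default) {
      if (is.null(v)) default else as.numeric(strsplit(v, ",")[[1L]])
    }

    switch(cmd,
      simulate = {
        out <- need_out()
        d <- simulate_gait_dataset(
          n_subjects = as.integer(num_list(opts$n_subjects, 20)),
          n_classes = as.integer(num_list(opts$n_classes, 9)),
          windows_per_class = as.integer(num_list(opts$windows, 10)),
          J = 5, window_len = as.integer(cfg$window_len), seed = seed)
        save_dataset(d, out)
        write_artifact_meta(file.path(out, "manifest.csv"), cfg)
        message(sprintf("wrote %d windows to %s", d$n, out))
      },
      compress = {
        d <- get_data(); out <- need_out()
        M <- cr_to_measurements(cfg$cr, d$window_len)
        scheme <- make_measurement_scheme(d$J, d$window_len, M,
                                          kind = cfg$scheme_kind, seed = seed)
        comp <- compress(d, scheme)
        utils::write.table(comp, out, sep = ",", row.names = FALSE,
                           col.names = FALSE)
        write_artifact_meta(out, cfg)
        message(sprintf("compressed %d windows at CR = %.1f%% to %s",
                        ncol(comp), scheme$compression_ratio, out))
      },
      train = {
        d <- get_data(); out <- need_out()
        fit <- jsrc(d, cr = cfg$cr, scheme_kind = cfg$scheme_kind,
                    lambda = cfg$lambda, m = as.integer(cfg$m),
                    k = as.integer(cfg$k), solver = cfg$solver,
                    neighbor = cfg$neighbor, seed = seed)
        save_model(fit, out)
        write_artifact_meta(out, cfg)
        message("model written to ", out)
      },
      classify = {
        d <- get_data(); out <- need_out()
        if (is.null(opts$model)) stop("--model is required", call. = FALSE)
        fit <- load_model(opts$model)
        if (fit$scheme$N != d$window_len)
          stop(sprintf("model window length %d does not match data window length %d",
                       fit$scheme$N, d$window_len), call. = FALSE)
        pred <- predict(fit, d)
        utils::write.csv(data.frame(sample = seq_len(d$n), label = pred),
                         out, row.names = FALSE)
        write_artifact_meta(out, cfg)
        message("predictions written to ", out)
      },
      evaluate = {
        d <- get_data(); out <- need_out()
        res <- run_cv(d, cr = cfg$cr, m = as.integer(cfg$m),
                      k = as.integer(cfg$k), lambda = cfg$lambda,
                      solver = cfg$solver, neighbor = cfg$neighbor,
                      scheme_kind = cfg$scheme_kind,
                      outer_folds = as.integer(cfg$outer_folds),
                      inner_folds = as.integer(cfg$inner_folds), seed = seed)
        utils::write.csv(as.data.frame(unclass(res$confusion)), out)
        write_artifact_meta(out, cfg)
        message(sprintf("pooled accuracy %.2f%% over %d windows; confusion table in %s",
                        res$metrics$accuracy, res$metrics$N_T, out))
      },
      sweep = {
        d <- get_data(); out <- need_out()
        tab <- cr_sweep(d, cr_grid = num_list(opts$cr_grid, c(10, 50, 90)),
                        m_grid = num_list(opts$m_grid, c(20, 40)),
                        solvers = cfg$solver, neighbor = cfg$neighbor,
                        seed = seed, k = as.integer(cfg$k),
                        lambda = cfg$lambda, scheme_kind = cfg$scheme_kind,
                        outer_folds = as.integer(cfg$outer_folds),
                        inner_folds = as.integer(cfg$inner_folds), csv = out)
        write_artifact_meta(out, cfg)
        message(sprintf("%d sweep rows written to %s", nrow(tab), out))
      },
      { cli_usage(); stop("unknown command: ", cmd, call. = FALSE) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
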