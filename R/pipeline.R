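# Pipeline orchestration: staged commands over a single run configuration.
# Each stage reads its inputs from and writes its outputs to files under the
# configured output directory, so stages are independently testable and
# resumable; rerunning a stage with the same config and seed reproduces its
# outputs. A shell entry point wrapping these functions ships in
# inst/exec/eegentropy.

#' Pipeline run configuration
#'
#' @param out_dir Directory for all stage outputs.
#' @param seed Global integer seed; stage and subject seeds derive from it.
#' @param synth List of [synth_config()] arguments (less the seed).
#' @param bandpass_low,bandpass_high Band edges in Hz for cleaning.
#' @param window_s,overlap Segmentation window and overlap.
#' @param measures Entropy measure tags to extract.
#' @param alpha Electrode-selection significance level.
#' @param classifiers Which classifiers to evaluate
#'   (`"svm"`, `"mlp"`, `"cnn1d"`).
#' @param scheme Evaluation scheme(s): `"5fold"`, `"loso"`.
#' @param epochs,batch_size,patience Network training settings.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, synth = list(),
                       bandpass_low = 1, bandpass_high = 50,
                       window_s = 0.5, overlap = 0.5,
                       measures = "SAE", alpha = 0.05,
                       classifiers = c("svm", "mlp", "cnn1d"),
                       scheme = "5fold",
                       epochs = 30, batch_size = 64, patience = 5) {
  # keep named vectors as named lists so YAML round-trips preserve names
  if (!is.null(synth$class_complexity)) {
    synth$class_complexity <- as.list(unlist(synth$class_complexity))
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
              bandpass_low = bandpass_low, bandpass_high = bandpass_high,
              window_s = window_s, overlap = overlap,
              measures = toupper(measures), alpha = alpha,
              classifiers = classifiers, scheme = scheme,
              epochs = epochs, batch_size = batch_size, patience = patience)
  class(cfg) <- "run_config"
  cfg
}

#' Read/write a run configuration as YAML
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_synth <- function(config) {
  do.call(synth_config, c(config$synth, list(seed = config$seed)))
}

config_subjects <- function(config) {
  sprintf("S%02d", seq_len(config_synth(config)$n_subjects))
}

# cheap structural hash so logs can show whether two runs shared a config
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

log_stage <- function(config, stage, note = "") {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  line <- sprintf("%s | stage=%s | config=%s | seed=%d | eegentropy=%s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  config_hash(config), config$seed,
                  as.character(utils::packageVersion("eegentropy")), note)
  cat(line, "\n", file = file.path(config$out_dir, "run.log"),
      append = TRUE, sep = "")
  invisible(line)
}

require_stage <- function(path, stage, needed_by) {
  if (!file.exists(path) && !dir.exists(path)) {
    abort(sprintf("Missing artifact '%s': run the %s stage before %s.",
                  path, stage, needed_by))
  }
}

#' Pipeline stages
#'
#' `run_synth()` writes one delimited recording per subject.
#' `run_features()` band-pass filters, segments and extracts every configured
#' entropy measure to per-subject CSV feature tables. `run_select()` runs the
#' electrode selection per subject and measure and writes per-decision
#' reports plus an adoption-frequency summary. `run_train_eval()` evaluates
#' the configured classifiers (SVM on adopted channels; MLP/1D-CNN on all
#' channels) under the configured scheme(s). `run_report()` consolidates the
#' per-measure accuracy table and the selection frequencies.
#'
#' @param config A [run_config()].
#' @return Invisibly, the paths written (or for `run_report` the summary
#'   tibbles).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_synth <- function(config) {
  sc <- config_synth(config)
  log_stage(config, "synth")
  paths <- vapply(config_subjects(config), function(sid) {
    rec <- generate_session(sc, sid)
    p <- file.path(config$out_dir, "recordings", sid)
    write_recording(rec, p, format = "delimited")
    p
  }, "")
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_features <- function(config) {
  log_stage(config, "features")
  paths <- c()
  for (sid in config_subjects(config)) {
    rp <- file.path(config$out_dir, "recordings", sid)
    require_stage(rp, "synth", "features")
    rec <- read_recording(rp)
    rec <- bandpass(rec, config$bandpass_low, config$bandpass_high)
    segs <- segment(rec, config$window_s, config$overlap)
    for (ms in config$measures) {
      ft <- extract_features(segs, entropy_config(ms))
      p <- file.path(config$out_dir, "features",
                     sprintf("%s_%s.csv", sid, ms))
      dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
      write_feature_table(ft, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

feature_path <- function(config, sid, ms) {
  file.path(config$out_dir, "features", sprintf("%s_%s.csv", sid, ms))
}

selection_path <- function(config, sid, ms) {
  file.path(config$out_dir, "selection", sprintf("%s_%s.csv", sid, ms))
}

#' @rdname pipeline
#' @export
run_select <- function(config) {
  log_stage(config, "select")
  decisions <- list()
  for (sid in config_subjects(config)) {
    for (ms in config$measures) {
      fp <- feature_path(config, sid, ms)
      require_stage(fp, "features", "select")
      sel <- select_electrodes(read_feature_table(fp), config$alpha)
      p <- selection_path(config, sid, ms)
      dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(as.data.frame(sel), p, row.names = FALSE)
      decisions <- c(decisions, list(sel))
    }
  }
  freq <- selection_frequency(decisions)
  utils::write.csv(freq, file.path(config$out_dir, "selection",
                                   "selection_frequency.csv"),
                   row.names = FALSE)
  invisible(freq)
}

read_selection <- function(config, sid, ms) {
  p <- selection_path(config, sid, ms)
  require_stage(p, "select", "train")
  tibble::as_tibble(utils::read.csv(p, check.names = FALSE))
}

config_trainers <- function(config, input_width = NULL) {
  trainers <- list()
  if ("svm" %in% config$classifiers) {
    trainers$svm <- function(d) train_svm_rbf(d)
  }
  if ("mlp" %in% config$classifiers) {
    trainers$mlp <- function(d) train_net(d, net_spec(
      "mlp", epochs = config$epochs, batch_size = config$batch_size,
      patience = config$patience, seed = config$seed))
  }
  if ("cnn1d" %in% config$classifiers) {
    trainers$cnn1d <- function(d) train_net(d, net_spec(
      "cnn1d", epochs = config$epochs, batch_size = config$batch_size,
      patience = config$patience, seed = config$seed))
  }
  trainers
}

#' @rdname pipeline
#' @export
run_train_eval <- function(config) {
  log_stage(config, "train")
  trainers <- config_trainers(config)
  subjects <- config_subjects(config)
  rows <- list()
  for (ms in config$measures) {
    tables <- lapply(subjects, function(sid) {
      fp <- feature_path(config, sid, ms)
      require_stage(fp, "features", "train")
      read_feature_table(fp)
    })
    names(tables) <- subjects
    for (clf in names(trainers)) {
      use_selection <- clf == "svm"
      if ("5fold" %in% config$scheme) {
        for (sid in subjects) {
          sel <- if (use_selection) read_selection(config, sid, ms) else NULL
          if (use_selection && !any(sel$verdict == "adopt")) next
          ds <- assemble_dataset(tables[[sid]], sel, seed = config$seed)
          rep5 <- crossval_5fold(ds, trainers[[clf]], seed = config$seed)
          rows <- c(rows, list(tibble::tibble(
            measure = ms, classifier = clf, scheme = "5fold",
            subject_id = sid, accuracy = rep5$accuracy)))
        }
      }
      if ("loso" %in% config$scheme && length(subjects) >= 2) {
        dss <- lapply(subjects, function(sid)
          assemble_dataset(tables[[sid]], NULL, seed = config$seed))
        repl <- loso(dss, trainers[[clf]])
        rows <- c(rows, list(tibble::tibble(
          measure = ms, classifier = clf, scheme = "loso",
          subject_id = repl$folds$subject_id,
          accuracy = repl$folds$accuracy)))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  p <- file.path(config$out_dir, "metrics.csv")
  utils::write.csv(out, p, row.names = FALSE)
  invisible(out)
}

#' @rdname pipeline
#' @export
run_report <- function(config) {
  log_stage(config, "report")
  mp <- file.path(config$out_dir, "metrics.csv")
  require_stage(mp, "train", "report")
  metrics <- tibble::as_tibble(utils::read.csv(mp))
  summary <- metrics |>
    dplyr::group_by(.data$measure, .data$classifier, .data$scheme) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = stats::sd(.data$accuracy),
                     n_subjects = dplyr::n(), .groups = "drop")
  utils::write.csv(summary, file.path(config$out_dir, "accuracy_summary.csv"),
                   row.names = FALSE)
  fp <- file.path(config$out_dir, "selection", "selection_frequency.csv")
  freq <- if (file.exists(fp)) tibble::as_tibble(utils::read.csv(fp)) else NULL
  invisible(list(accuracy = summary, selection_frequency = freq))
}
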