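#' Write sessions to the documented CSV schema
#'
#' One row per trial: `subject_id`, `task_kind`, `trial_index` (0-based),
#' `game_index` (0-based), `target_image`, `col0_images`, `col1_images`,
#' `col2_images` (semicolon-joined labels in category-row order), `choice`
#' (0..2, empty for a non-response) and `reward`.
#'
#' @param sessions list of `session_log`s (a single log is accepted).
#' @param path output CSV path.
#' @export
write_sessions <- function(sessions, path) {
  if (inherits(sessions, "session_log")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    tr <- s$trials
    cols <- vapply(1:3, function(c) {
      apply(s$layouts[, (0:2) * 3L + c, drop = FALSE], 1,
            function(imgs) paste(image_label(imgs), collapse = ";"))
    }, character(nrow(tr)))
    data.frame(
      subject_id = s$subject_id,
      task_kind = s$config$task_kind,
      trial_index = tr$trial,
      game_index = tr$game - 1L,
      target_image = image_label(tr$target),
      col0_images = cols[, 1], col1_images = cols[, 2], col2_images = cols[, 3],
      choice = tr$choice - 1L,
      reward = tr$reward
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Read sessions from the documented CSV schema
#'
#' Inverse of [write_sessions()]. Layouts are validated (each column must
#' hold one image per category; every image exactly once per trial) and
#' schema violations are reported with their row numbers. Reward
#' probabilities are not stored in the CSV, so the returned configs carry
#' the task-kind defaults unless `config` is supplied.
#'
#' @param path CSV path.
#' @param config optional [task_config()] overriding the inferred one.
#' @return list of `session_log`s, in file order of first appearance.
#' @export
read_sessions <- function(path, config = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "task_kind", "trial_index", "game_index",
                "target_image", "col0_images", "col1_images", "col2_images",
                "choice", "reward")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0)
    stop("missing columns: ", paste(missing, collapse = ", "))
  split_rows <- split(seq_len(nrow(d)), factor(d$subject_id,
                                               levels = unique(d$subject_id)))
  lapply(names(split_rows), function(sid) {
    i <- split_rows[[sid]]
    s <- d[i, ]
    n <- nrow(s)
    layouts <- matrix(0L, n, 9L)
    for (t in seq_len(n)) {
      lay <- matrix(0L, 3, 3)
      for (c in 1:3) {
        parts <- strsplit(s[[paste0("col", c - 1, "_images")]][t], ";")[[1]]
        if (length(parts) != 3)
          stop("row ", i[t], ": column ", c - 1, " does not list 3 images")
        lay[, c] <- image_id(parts)
      }
      tryCatch(validate_layout(lay),
               error = function(e) stop("row ", i[t], ": ",
                                        conditionMessage(e), call. = FALSE))
      layouts[t, ] <- as.integer(t(lay))
    }
    kind <- s$task_kind[1]
    cfg <- config %||% task_config(kind,
                                   n_games = length(unique(s$game_index)),
                                   trials_per_game = n / length(unique(s$game_index)))
    target <- image_id(s$target_image)
    choice <- suppressWarnings(as.integer(s$choice)) + 1L
    structure(list(
      config = cfg, subject_id = sid,
      trials = data.frame(trial = s$trial_index, game = s$game_index + 1L,
                          target = target, choice = choice,
                          reward = as.integer(s$reward)),
      layouts = layouts
    ), class = "session_log")
  })
}

#' Import externally deposited sessions via an explicit column mapping
#'
#' Reads a third-party CSV whose column names differ from the package
#' schema, renaming via a user-supplied mapping (names = package schema
#' columns, values = columns in the file). Unmapped schema columns are
#' listed in the error rather than guessed. Non-response trials may be
#' encoded as an empty `choice`; they are preserved as NA choices, which
#' are excluded from model likelihoods and scored as errors in accuracy.
#'
#' @param path CSV path.
#' @param mapping named character vector mapping schema names to file
#'   column names.
#' @param config optional [task_config()].
#' @return list of `session_log`s.
#' @export
import_sessions <- function(path, mapping, config = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "task_kind", "trial_index", "game_index",
                "target_image", "col0_images", "col1_images", "col2_images",
                "choice", "reward")
  unmapped <- setdiff(required, names(mapping))
  if (length(unmapped) > 0)
    stop("unmapped schema columns (supply them in `mapping`): ",
         paste(unmapped, collapse = ", "))
  absent <- setdiff(unname(mapping[required]), names(d))
  if (length(absent) > 0)
    stop("mapped columns not present in file: ", paste(absent, collapse = ", "))
  out <- d[, unname(mapping[required])]
  names(out) <- required
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write.csv(out, tmp, row.names = FALSE, quote = FALSE, na = "")
  read_sessions(tmp, config = config)
}

#' Write / read the fitted-parameter table
#'
#' Long CSV: `subject_id`, `model`, `parameter`, `value` (natural scale),
#' `transformed` (fitting scale), `log_evidence`, `convergence`.
#'
#' @param fits list of `subject_fit`s.
#' @param path CSV path.
#' @export
write_fits <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    data.frame(subject_id = f$subject_id, model = f$model,
               parameter = names(f$estimate),
               value = unname(f$estimate),
               transformed = unname(f$theta),
               log_evidence = f$log_evidence,
               convergence = f$convergence)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Run configuration files
#'
#' A flat YAML document with `task`, `cohort`, `fit` and `stats` sections
#' plus `seed` and `out_dir`; unknown keys are rejected before any stage
#' runs.
#'
#' @param path YAML path.
#' @return validated nested list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("task", "cohort", "fit", "stats", "seed", "out_dir", "log_level")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$task)) {
    tkeys <- c("task_kind", "n_games", "trials_per_game", "p_reward_target",
               "p_reward_nontarget", "reversal_interval")
    unknown <- setdiff(names(cfg$task), tkeys)
    if (length(unknown) > 0)
      stop("unknown task keys: ", paste(unknown, collapse = ", "))
    cfg$task <- do.call(task_config, cfg$task)
  }
  if (!is.null(cfg$cohort)) {
    ckeys <- setdiff(names(formals(cohort_config)), c("task"))
    unknown <- setdiff(names(cfg$cohort), ckeys)
    if (length(unknown) > 0)
      stop("unknown cohort keys: ", paste(unknown, collapse = ", "))
    args <- cfg$cohort
    if (!is.null(cfg$task)) args$task <- cfg$task
    cfg$cohort <- do.call(cohort_config, args)
  }
  cfg
}

# Polynomial rolling hash of an R object's serialized bytes, for provenance.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b + 1) %% 2147483629
  sprintf("%08x", h)
}

#' Provenance stamp for output files
#'
#' @param config any configuration object.
#' @param seed master seed of the run.
#' @return list with `seed`, `package_version` and a stable `config_hash`.
#' @export
provenance <- function(config, seed) {
  list(seed = seed,
       package_version = as.character(utils::packageVersion("volbandit")),
       config_hash = config_hash(config))
}
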