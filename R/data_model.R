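# Behavioral dataset container and its line-oriented text format.
#
# A dataset holds trial-level logs for a pool of individuals, each of whom
# performed blocks of one or more task conditions, plus (for the value-guided
# task) the per-episode environment trace: the full transition/terminal-reward
# table in force at episode 0 and the drift events applied before later
# episodes.  Internally everything is flat data.frames; `get_blocks()` builds
# per-block views.

ALLOWED_P1 <- c(0.2, 0.8, 0.4, 0.6)

#' Construct a behavioral dataset
#'
#' @param trials data.frame of trial records. For the MDP task the columns are
#'   `participant, condition, block, episode, step, cue, action, reward, rt`;
#'   for the perceptual task `participant, condition, block, trial,
#'   stimulus_id, true_label, action, rt`.  Episodes and blocks are 0-based,
#'   `step` is 1-based, `cue` and `action` are 0-based codes (action 0 = C1).
#' @param envs data.frame of environment-trace rows (MDP only): columns
#'   `participant, condition, block, episode, kind, step, node, action, p1`.
#'   Episode-0 rows give the full table after the first drift; rows with
#'   episode e > 0 are drift reassignments applied before episode e.
#' @param task `"mdp"` or `"perceptual"`.
#' @param steps named integer vector mapping condition labels to the number of
#'   decision steps M (MDP only).
#' @param metadata named character vector (seed, generator provenance, ...).
#' @return An object of class `behavioral_dataset`.
#' @export
new_behavioral_dataset <- function(trials, envs = NULL, task = "mdp",
                                   steps = NULL, metadata = character()) {
  task <- match.arg(task, c("mdp", "perceptual"))
  ds <- structure(
    list(task = task,
         steps = if (!is.null(steps)) setNames(as.integer(steps), names(steps)),
         trials = as.data.frame(trials),
         envs = if (!is.null(envs)) as.data.frame(envs),
         metadata = if (length(metadata)) setNames(as.character(metadata), names(metadata)) else character()),
    class = "behavioral_dataset")
  validate_dataset(ds)
  ds
}

mdp_trial_cols <- c("participant", "condition", "block", "episode", "step",
                    "cue", "action", "reward", "rt")
perc_trial_cols <- c("participant", "condition", "block", "trial",
                     "stimulus_id", "true_label", "action", "rt")
env_cols <- c("participant", "condition", "block", "episode", "kind", "step",
              "node", "action", "p1")

# Number of state-action entries in an M-step environment: one transition
# entry per non-final tree node x action, one terminal-reward entry per
# final node x action (6 at M=2, 14 at M=3).
n_env_entries <- function(M) {
  trans <- if (M > 1) sum(2^(0:(M - 2))) * 2 else 0
  trans + 2^(M - 1) * 2
}

#' Validate a behavioral dataset against its invariants
#'
#' Checks column layout, value ranges, the reward-only-at-final-step rule,
#' contiguous complete episodes, and the environment-trace coverage.
#'
#' @param ds a `behavioral_dataset`.
#' @return `ds`, invisibly; errors describe the first violated invariant.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "behavioral_dataset"))
  tr <- ds$trials
  if (ds$task == "mdp") {
    if (!identical(names(tr), mdp_trial_cols))
      stop_eidt("trials must have columns: ", paste(mdp_trial_cols, collapse = ", "))
    if (is.null(ds$steps) || length(ds$steps) == 0)
      stop_eidt("an MDP dataset must declare its conditions and steps")
    if (nrow(tr) == 0) return(invisible(ds))
    if (!all(tr$condition %in% names(ds$steps)))
      stop_eidt("unknown condition label in trials: ",
                paste(setdiff(unique(tr$condition), names(ds$steps)), collapse = ", "))
    M <- ds$steps[tr$condition]
    if (!all(tr$step >= 1 & tr$step <= M))
      stop_eidt("step index outside 1..M")
    if (!all(tr$cue %in% c(0L, 1L))) stop_eidt("state cue must be 0 or 1")
    if (!all(tr$action %in% c(0L, 1L))) stop_eidt("action must be 0 (C1) or 1 (C2)")
    final <- tr$step == M
    if (any(is.na(tr$reward[final])))
      stop_eidt("reward missing at the final step of an episode")
    if (any(!is.na(tr$reward[!final])))
      stop_eidt("reward present on a non-final step")
    if (!all(tr$reward[final] %in% c(0L, 1L))) stop_eidt("reward must be 0 or 1")
    # episodes contiguous and complete within each block
    key <- paste(tr$participant, tr$condition, tr$block)
    for (k in unique(key)) {
      b <- tr[key == k, ]
      M1 <- ds$steps[[b$condition[1]]]
      n_ep <- nrow(b) / M1
      if (n_ep != round(n_ep) ||
          !identical(b$episode, rep(0:(n_ep - 1), each = M1)) ||
          !identical(b$step, rep(1:M1, n_ep)))
        stop_eidt("episodes not contiguous/complete in block ", k)
    }
    # environment trace coverage
    ev <- ds$envs
    if (is.null(ev) || !identical(names(ev), env_cols))
      stop_eidt("an MDP dataset requires an environment trace with columns: ",
                paste(env_cols, collapse = ", "))
    if (!all(ev$p1 %in% ALLOWED_P1))
      stop_eidt("environment probabilities must come from the allowed pair set")
    if (!all(ev$kind %in% c("trans", "reward"))) stop_eidt("bad environment entry kind")
    ekey <- paste(ev$participant, ev$condition, ev$block)
    for (k in unique(key)) {
      b0 <- ev[ekey == k & ev$episode == 0, ]
      M1 <- ds$steps[[ds$trials$condition[key == k][1]]]
      if (nrow(b0) != n_env_entries(M1))
        stop_eidt("environment trace does not cover block ", k)
    }
  } else {
    if (!identical(names(tr), perc_trial_cols))
      stop_eidt("trials must have columns: ", paste(perc_trial_cols, collapse = ", "))
    if (nrow(tr) > 0) {
      if (!all(tr$action >= 0 & tr$action <= 9)) stop_eidt("action must be a digit 0-9")
      if (!all(tr$rt >= 0)) stop_eidt("response times must be non-negative")
    }
  }
  invisible(ds)
}

#' @export
print.behavioral_dataset <- function(x, ...) {
  cat(sprintf("<behavioral_dataset> task=%s, %d individuals, %d trials\n",
              x$task, length(individual_ids(x)), nrow(x$trials)))
  if (!is.null(x$steps))
    cat("  conditions:", paste(sprintf("%s (M=%d)", names(x$steps), x$steps),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Participant identifiers of a dataset
#' @param ds a `behavioral_dataset`.
#' @return character vector of unique ids, in first-appearance order.
#' @export
individual_ids <- function(ds) unique(ds$trials$participant)

#' Extract one individual's record
#'
#' @param ds a `behavioral_dataset`.
#' @param id participant identifier.
#' @return An `individual_record`: list with `participant_id` and `blocks`
#'   (a list of `block_record` objects across all conditions).
#' @export
get_individual <- function(ds, id) {
  if (!id %in% ds$trials$participant) stop_eidt("unknown participant: ", id)
  blocks <- list()
  for (cond in names(ds$steps) %||% unique(ds$trials$condition))
    blocks <- c(blocks, get_blocks(ds, id, cond))
  structure(list(participant_id = id, blocks = blocks),
            class = "individual_record")
}

#' Extract an individual's blocks for one condition
#' @inheritParams get_individual
#' @param condition condition label.
#' @return list of `block_record` objects (possibly empty).
#' @export
get_blocks <- function(ds, id, condition) {
  tr <- ds$trials[ds$trials$participant == id & ds$trials$condition == condition, ]
  if (nrow(tr) == 0) return(list())
  lapply(sort(unique(tr$block)), function(b) {
    bt <- tr[tr$block == b, setdiff(names(tr), c("participant", "condition", "block"))]
    rownames(bt) <- NULL
    ev <- ds$envs[ds$envs$participant == id & ds$envs$condition == condition &
                    ds$envs$block == b, ]
    structure(list(condition = condition,
                   M = if (ds$task == "mdp") ds$steps[[condition]],
                   trials = bt,
                   env_init = {
                     e0 <- ev[ev$episode == 0, c("kind", "step", "node", "action", "p1")]
                     rownames(e0) <- NULL; e0
                   },
                   env_events = {
                     e1 <- ev[ev$episode > 0, c("episode", "kind", "step", "node", "action", "p1")]
                     rownames(e1) <- NULL; e1
                   }),
              class = "block_record")
  })
}

#' Assemble a dataset from per-individual records
#'
#' @param records list of `individual_record` objects (distinct ids).
#' @inheritParams new_behavioral_dataset
#' @return a `behavioral_dataset`.
#' @export
dataset_from_records <- function(records, steps, task = "mdp",
                                 metadata = character()) {
  ids <- vapply(records, `[[`, "", "participant_id")
  if (anyDuplicated(ids)) stop_eidt("duplicate participant ids")
  trs <- list(); evs <- list()
  for (rec in records) {
    bi <- stats::setNames(integer(length(steps)), names(steps))
    for (blk in rec$blocks) {
      if (task == "mdp" && !blk$condition %in% names(steps))
        stop_eidt("unknown condition label: ", blk$condition)
      b <- bi[[blk$condition]]
      bi[[blk$condition]] <- b + 1L
      t1 <- cbind(participant = rec$participant_id, condition = blk$condition,
                  block = b, blk$trials)
      trs[[length(trs) + 1L]] <- t1
      if (task == "mdp") {
        e0 <- cbind(episode = 0L, blk$env_init)
        e1 <- blk$env_events
        ee <- rbind(e0[, c("episode", "kind", "step", "node", "action", "p1")],
                    if (nrow(e1)) e1[, c("episode", "kind", "step", "node", "action", "p1")])
        evs[[length(evs) + 1L]] <- cbind(participant = rec$participant_id,
                                         condition = blk$condition, block = b, ee)
      }
    }
  }
  new_behavioral_dataset(do.call(rbind, trs),
                         if (task == "mdp") do.call(rbind, evs),
                         task = task, steps = steps, metadata = metadata)
}

# ---- text serialization ----------------------------------------------------

# Shortest decimal representation that parses back to the identical double.
fmt_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "NA"
  ok <- !is.na(x)
  s <- sprintf("%.12g", x[ok])
  bad <- as.numeric(s) != x[ok]
  s[bad] <- sprintf("%.17g", x[ok][bad])
  out[ok] <- s
  out
}

fmt_col <- function(x) {
  if (is.numeric(x) && !is.integer(x)) fmt_num(x)
  else { o <- as.character(x); o[is.na(x)] <- "NA"; o }
}

#' Write a dataset to its line-oriented text format
#'
#' The format is a tab-separated file with `#`-prefixed header lines (format
#' version, task kind, condition declarations, metadata) followed by one or
#' two column sections (`trials`, and `environments` for the MDP task).
#' Output is byte-stable: writing the same dataset twice yields identical
#' files.
#'
#' @param ds a valid `behavioral_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  con <- file(path, "wb")  # binary mode for byte-stable newlines
  on.exit(close(con))
  wl <- function(s) writeLines(s, con, sep = "\n")
  wl("#eidt-dataset v1")
  wl(paste("#task", ds$task))
  if (!is.null(ds$steps))
    for (i in seq_along(ds$steps))
      wl(paste("#condition", names(ds$steps)[i], ds$steps[[i]]))
  for (k in names(ds$metadata)) wl(paste("#meta", k, ds$metadata[[k]]))
  sect <- function(name, df) {
    wl(paste("#columns", name, paste(names(df), collapse = " ")))
    if (nrow(df)) wl(do.call(paste, c(lapply(df, fmt_col), sep = "\t")))
  }
  sect("trials", ds$trials)
  if (ds$task == "mdp") sect("environments", ds$envs)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path file path.
#' @return a validated `behavioral_dataset`; malformed records raise a parse
#'   error naming the offending line.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_eidt("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "#eidt-dataset v1")
    stop_eidt("line 1: not an eidt dataset file")
  task <- NULL; steps <- integer(); meta <- character()
  sections <- list(); cur <- NULL; cur_cols <- NULL; cur_rows <- integer()
  flush_sect <- function() {
    if (!is.null(cur)) sections[[cur]] <<- list(cols = cur_cols, rows = cur_rows)
  }
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (startsWith(ln, "#")) {
      parts <- strsplit(sub("^#", "", ln), " ", fixed = TRUE)[[1]]
      key <- parts[1]
      if (key == "task") task <- parts[2]
      else if (key == "condition") steps[parts[2]] <- suppressWarnings(as.integer(parts[3]))
      else if (key == "meta") meta[parts[2]] <- paste(parts[-(1:2)], collapse = " ")
      else if (key == "columns") {
        flush_sect()
        cur <- parts[2]; cur_cols <- parts[-(1:2)]; cur_rows <- integer()
      } else stop_eidt("line ", i, ": unknown header directive '", key, "'")
    } else {
      if (is.null(cur)) stop_eidt("line ", i, ": data before any #columns section")
      nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
      if (nf != length(cur_cols))
        stop_eidt("line ", i, ": expected ", length(cur_cols), " fields, found ", nf)
      cur_rows <- c(cur_rows, i)
    }
  }
  flush_sect()
  if (is.null(task)) stop_eidt("missing #task header")
  parse_sect <- function(name, int_cols, num_cols, chr_cols) {
    s <- sections[[name]]
    if (is.null(s)) stop_eidt("missing #columns ", name, " section")
    df <- if (length(s$rows) == 0) {
      empty <- lapply(s$cols, function(cn) character(0))
      as.data.frame(setNames(empty, s$cols))
    } else {
      utils::read.table(text = lines[s$rows], sep = "\t", col.names = s$cols,
                        colClasses = "character", na.strings = "NA",
                        quote = "", comment.char = "")
    }
    for (cn in intersect(int_cols, names(df))) df[[cn]] <- as.integer(df[[cn]])
    for (cn in intersect(num_cols, names(df))) df[[cn]] <- as.numeric(df[[cn]])
    df
  }
  if (task == "mdp") {
    trials <- parse_sect("trials",
                         c("block", "episode", "step", "cue", "action", "reward"),
                         "rt", c("participant", "condition"))
    envs <- parse_sect("environments",
                       c("block", "episode", "step", "node", "action"),
                       "p1", c("participant", "condition", "kind"))
    new_behavioral_dataset(trials, envs, task = "mdp", steps = steps,
                           metadata = meta)
  } else {
    trials <- parse_sect("trials", c("block", "trial", "true_label", "action"),
                         "rt", c("participant", "condition", "stimulus_id"))
    new_behavioral_dataset(trials, task = "perceptual",
                           steps = NULL, metadata = meta)
  }
}

# ---- data-quality exclusion -------------------------------------------------

#' Per-block summary statistics for one individual
#'
#' For each block: mean terminal reward, action bias (percentage of trials
#' choosing C1), and a response-time summary.
#'
#' @param record an `individual_record` with at least one block.
#' @param rt_stat `"mean"` (default) or `"median"`; the per-block summary of
#'   trial response times.
#' @return data.frame with one row per block: `condition, block, mean_reward,
#'   bias_pct, rt`.
#' @export
participant_stats <- function(record, rt_stat = c("mean", "median")) {
  rt_stat <- match.arg(rt_stat)
  if (!length(record$blocks)) stop_eidt("record has no blocks")
  rows <- lapply(seq_along(record$blocks), function(i) {
    blk <- record$blocks[[i]]
    if (!nrow(blk$trials)) stop_eidt("block with no trials")
    tr <- blk$trials
    data.frame(condition = blk$condition, block = i - 1L,
               mean_reward = mean(tr$reward[!is.na(tr$reward)]),
               bias_pct = 100 * mean(tr$action == 0L),
               rt = if (all(is.na(tr$rt))) NA_real_
                    else match.fun(rt_stat)(tr$rt, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Tukey-style outlier bounds by the interquartile-range method
#'
#' Quartiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`); the range is `(Q1 - k*IQR, Q3 + k*IQR)`.
#'
#' @param values non-empty numeric vector.
#' @param k IQR multiplier (default 1.5).
#' @return numeric `c(low, high)`.
#' @export
iqr_ranges <- function(values, k = 1.5) {
  if (length(values) == 0 || all(is.na(values))) stop_eidt("empty values")
  if (k <= 0) stop_eidt("k must be positive")
  q <- quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(low = q[1] - k * iqr, high = q[2] + k * iqr)
}

#' Data-driven exclusion thresholds for a dataset
#'
#' Applies [iqr_ranges()] to the pool of per-block statistics: mean reward
#' separately per condition (reward scales differ across conditions), action
#' bias and response time pooled across all blocks.
#'
#' @param ds a `behavioral_dataset` (MDP task).
#' @param k IQR multiplier.
#' @inheritParams participant_stats
#' @return list with elements `reward` (named list of `c(low, high)` per
#'   condition), `bias`, and `rt` (`NULL` when the dataset has no response
#'   times).
#' @export
compute_exclusion_thresholds <- function(ds, k = 1.5, rt_stat = "mean") {
  st <- do.call(rbind, lapply(individual_ids(ds), function(id)
    participant_stats(get_individual(ds, id), rt_stat)))
  list(reward = lapply(split(st$mean_reward, st$condition), iqr_ranges, k = k),
       bias = iqr_ranges(st$bias_pct, k = k),
       rt = if (!all(is.na(st$rt))) iqr_ranges(st$rt, k = k))
}

#' Apply data-quality exclusion criteria
#'
#' An individual is removed when any single block falls outside any bound.
#' The reported reason is the first violated metric in the fixed order
#' reward, bias, response time.
#'
#' @param ds a `behavioral_dataset`.
#' @param thresholds bounds as returned by [compute_exclusion_thresholds()].
#' @inheritParams participant_stats
#' @return list with `dataset` (retained individuals) and `report` (an
#'   `exclusion_report`: thresholds, the per-block statistics, and the
#'   excluded ids with reasons).
#' @export
apply_exclusion <- function(ds, thresholds, rt_stat = "mean") {
  ids <- individual_ids(ds)
  stats_all <- list(); excluded <- list()
  outside <- function(x, b) !is.na(x) & (x < b[1] | x > b[2])
  for (id in ids) {
    st <- participant_stats(get_individual(ds, id), rt_stat)
    stats_all[[id]] <- cbind(participant = id, st)
    reason <- NULL
    rb <- thresholds$reward[st$condition]
    bad_reward <- mapply(function(x, b) outside(x, b), st$mean_reward, rb)
    if (any(bad_reward)) reason <- "reward"
    else if (any(outside(st$bias_pct, thresholds$bias))) reason <- "bias"
    else if (!is.null(thresholds$rt) && any(outside(st$rt, thresholds$rt)))
      reason <- "response_time"
    if (!is.null(reason))
      excluded[[id]] <- data.frame(participant = id, reason = reason)
  }
  excl <- if (length(excluded)) do.call(rbind, excluded)
          else data.frame(participant = character(), reason = character())
  rownames(excl) <- NULL
  keep <- setdiff(ids, excl$participant)
  out <- ds
  out$trials <- ds$trials[ds$trials$participant %in% keep, ]
  rownames(out$trials) <- NULL
  if (!is.null(ds$envs)) {
    out$envs <- ds$envs[ds$envs$participant %in% keep, ]
    rownames(out$envs) <- NULL
  }
  report <- structure(list(thresholds = thresholds,
                           per_participant_stats = do.call(rbind, c(stats_all,
                             list(make.row.names = FALSE))),
                           excluded = excl),
                      class = "exclusion_report")
  list(dataset = out, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d excluded (%s)\n", nrow(x$excluded),
              paste(sprintf("%s: %d", names(table(x$excluded$reason)),
                            table(x$excluded$reason)), collapse = ", ")))
  invisible(x)
}
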