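#' Task configuration for an expanded judgment experiment
#'
#' Describes the cue statistics and timing of a sequential sampling
#' ("expanded judgment") task: discrete left/right cues arrive at a fixed
#' stimulus onset asynchrony and each cue points at the correct response with
#' probability `validity`. The observer samples a self-chosen number of cues
#' before committing to a choice.
#'
#' @param validity Probability in (0.5, 1) that a cue matches the true
#'   direction. Default 0.7.
#' @param cue_duration Cue on-screen duration in seconds. Default 0.2.
#' @param isi Inter-stimulus interval in seconds. Default 0.6.
#' @param max_cues Maximum number of cues available per trial. Default 10.
#'
#' @return An object of class `task_config` with fields `validity`,
#'   `cue_duration`, `isi`, `soa` (= `cue_duration + isi`) and `max_cues`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$soa  # 0.8 s between cue onsets
task_config <- function(validity = 0.7, cue_duration = 0.2, isi = 0.6,
                        max_cues = 10L) {
  if (!is.numeric(validity) || length(validity) != 1 ||
      validity <= 0.5 || validity >= 1)
    stop("`validity` must be a single probability in (0.5, 1)")
  if (cue_duration <= 0 || isi < 0) stop("invalid cue timing")
  if (max_cues < 2) stop("`max_cues` must be at least 2")
  structure(list(validity = validity, cue_duration = cue_duration,
                 isi = isi, soa = cue_duration + isi,
                 max_cues = as.integer(max_cues)),
            class = "task_config")
}

#' Analytic probability that two consecutive cues are identical
#'
#' With independent cues of validity `v`, two consecutive cues agree either
#' because both are valid or both invalid, so the probability of a "same"
#' pair is `v^2 + (1 - v)^2`. At `v = 0.7` this equals 0.58, the chance rate
#' against which an observed excess of responses after "same" pairs is
#' judged.
#'
#' @param validity Cue validity, a probability in \[0, 1\].
#' @return The probability of a "same" pair.
#' @export
#' @examples
#' analytic_same_pair_prob(0.7)  # 0.58
analytic_same_pair_prob <- function(validity) {
  if (!is.numeric(validity) || any(validity < 0 | validity > 1) ||
      any(!is.finite(validity)))
    stop("`validity` must lie in [0, 1]")
  validity^2 + (1 - validity)^2
}

#' Ideal-observer choice given a sampled cue sequence
#'
#' Majority vote over the cues seen: respond toward whichever direction
#' received more cues; exact ties are resolved by a fair coin.
#'
#' @param cues Character vector of `"L"`/`"R"`, or a numeric vector coded
#'   -1 (left) / +1 (right).
#' @return `"L"` or `"R"`.
#' @export
ideal_observer_choice <- function(cues) {
  s <- encode_cues(cues)
  if (length(s) == 0) stop("`cues` must be non-empty")
  tot <- sum(s)
  if (tot > 0) "R" else if (tot < 0) "L" else if (stats::runif(1) < 0.5) "L" else "R"
}

# map "L"/"R" (or -1/+1) to the signed coding S_t: L -> -1, R -> +1
encode_cues <- function(cues) {
  if (is.numeric(cues)) {
    if (!all(cues %in% c(-1, 1))) stop("numeric cues must be -1 or +1")
    return(as.numeric(cues))
  }
  if (!all(cues %in% c("L", "R"))) stop("cues must be 'L' or 'R'")
  ifelse(cues == "R", 1, -1)
}

decode_cues <- function(s) ifelse(s > 0, "R", "L")

#' Construct a single trial record
#'
#' @param trial_id Integer identifier.
#' @param true_direction `"L"` or `"R"`.
#' @param cues Cue sequence actually presented (characters or -1/+1).
#' @param choice `"L"`, `"R"` or `"none"` (no commitment by `max_cues`).
#' @param rt Response latency in seconds from the final cue onset.
#' @return A `trial_record` list; `n_sampled` is the number of cues seen.
#' @export
trial_record <- function(trial_id, true_direction, cues, choice,
                         rt = NA_real_) {
  s <- encode_cues(cues)
  if (!true_direction %in% c("L", "R")) stop("bad true_direction")
  if (!choice %in% c("L", "R", "none")) stop("bad choice")
  structure(list(trial_id = as.integer(trial_id),
                 true_direction = true_direction,
                 cues = decode_cues(s), s = s,
                 choice = choice, n_sampled = length(s),
                 rt = rt),
            class = "trial_record")
}

#' Summarize behaviour on a set of trials
#'
#' Computes accuracy, mean number of cues sampled, mean response latency,
#' the fraction of responses given after a "same" pair (last two cues
#' identical; single-cue trials are excluded from that denominator), and the
#' accuracy an ideal observer would have achieved on the same sampled cues.
#' Ideal-observer ties contribute 0.5 in expectation, which keeps the
#' summary deterministic; a strict coin-flip convention is available via
#' `tie = "random"`.
#'
#' Trials with `choice == "none"` are excluded from all averages (and
#' counted in `n_no_choice`).
#'
#' @param trials List of [trial_record()] objects.
#' @param cfg A [task_config()].
#' @param tie How ideal-observer ties are credited: `"expected"` (0.5 each)
#'   or `"random"` (fair coin).
#' @return A `behavior_summary` list with fields `accuracy`,
#'   `mean_n_sampled`, `mean_rt`, `frac_same_end`, `ideal_accuracy`,
#'   `n_trials`, `n_no_choice`.
#' @export
summarize_behavior <- function(trials, cfg = task_config(),
                               tie = c("expected", "random")) {
  tie <- match.arg(tie)
  done <- Filter(function(tr) tr$choice != "none", trials)
  if (length(done) == 0) stop("no completed trials to summarize")
  correct <- vapply(done, function(tr) tr$choice == tr$true_direction, logical(1))
  ns <- vapply(done, function(tr) tr$n_sampled, numeric(1))
  rts <- vapply(done, function(tr) tr$rt, numeric(1))
  same_end <- vapply(done, function(tr) {
    n <- tr$n_sampled
    if (n < 2) NA else tr$s[n] == tr$s[n - 1]
  }, logical(1))
  ideal <- vapply(done, function(tr) {
    tot <- sum(tr$s)
    truth <- if (tr$true_direction == "R") 1 else -1
    if (tot == 0) {
      if (tie == "expected") 0.5
      else as.numeric((if (stats::runif(1) < 0.5) -1 else 1) == truth)
    } else as.numeric(sign(tot) == truth)
  }, numeric(1))
  structure(list(
    accuracy = mean(correct),
    mean_n_sampled = mean(ns),
    mean_rt = mean(rts, na.rm = TRUE),
    frac_same_end = mean(same_end, na.rm = TRUE),
    ideal_accuracy = mean(ideal),
    n_trials = length(done),
    n_no_choice = length(trials) - length(done)
  ), class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Behaviour over %d trials (%d without commitment):\n",
           "  accuracy        %.3f (ideal observer %.3f)\n",
           "  cues sampled    %.2f\n",
           "  mean RT         %.0f ms\n",
           "  responses after a 'same' pair: %.3f\n"),
    x$n_trials, x$n_no_choice, x$accuracy, x$ideal_accuracy,
    x$mean_n_sampled, 1000 * x$mean_rt, x$frac_same_end))
  invisible(x)
}

#' Write / read trial tables as CSV
#'
#' Long format, one row per presented cue: columns `trial_id`,
#' `true_direction`, `cue_index` (1-based), `cue`, `chosen`, `rt_ms`;
#' `chosen` and `rt_ms` are filled only on the final row of each trial.
#'
#' @param trials List of [trial_record()] objects.
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns a
#'   list of `trial_record` objects.
#' @export
write_trials <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    n <- tr$n_sampled
    data.frame(trial_id = tr$trial_id,
               true_direction = tr$true_direction,
               cue_index = seq_len(n),
               cue = tr$cues,
               chosen = c(rep(NA_character_, n - 1), tr$choice),
               rt_ms = c(rep(NA_real_, n - 1), round(1000 * tr$rt, 3)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  lapply(split(df, df$trial_id), function(d) {
    d <- d[order(d$cue_index), ]
    n <- nrow(d)
    trial_record(d$trial_id[1], d$true_direction[1], d$cue,
                 choice = d$chosen[n],
                 rt = d$rt_ms[n] / 1000)
  })
}
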