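#' Reject trials with out-of-range response times
#'
#' Removes trials whose RT falls below `low` or above `high` (both in
#' seconds). The fraction removed is attached as attribute
#' `"rejection_rate"`. The operation is idempotent.
#'
#' @param trials trial table with an `rt` column (seconds).
#' @param low,high RT bounds in seconds; trials with `rt < low` or
#'   `rt > high` are dropped.
#' @return The filtered trial table.
#' @export
filter_rts <- function(trials, low = 0.2, high = 4) {
  if (low >= high) stop("low must be smaller than high")
  if (!"rt" %in% names(trials) || anyNA(trials$rt))
    stop("rt must be present on all trials")
  keep <- trials$rt >= low & trials$rt <= high
  out <- trials[keep, , drop = FALSE]
  attr(out, "rejection_rate") <- 1 - mean(keep)
  out
}

#' Label trials by condition and perceptual report
#'
#' Test trials reported as intermediate are illusion trials (`ILL`); test
#' trials reported veridically are `no-ILL`. Control trials (whose second
#' flash really is intermediate) are `CTRL-correct` when reported as
#' intermediate and `CTRL-incorrect` otherwise; only correct control trials
#' enter subsequent electrophysiological analyses.
#'
#' @param trials trial table with `condition` and `response` columns.
#' @return `trials` with a `label` column and a logical `excluded` column
#'   marking incorrect control trials.
#' @export
classify_trials <- function(trials) {
  if (nrow(trials) == 0L) {
    trials$label <- character(0)
    trials$excluded <- logical(0)
    return(trials)
  }
  ok_cond <- trials$condition %in% c("test", "control")
  ok_resp <- trials$response %in% c("intermediate", "not-intermediate")
  if (!all(ok_cond)) stop("unknown condition code")
  if (!all(ok_resp)) stop("unknown response code")
  lab <- ifelse(trials$condition == "test",
                ifelse(trials$response == "intermediate", "ILL", "no-ILL"),
                ifelse(trials$response == "intermediate",
                       "CTRL-correct", "CTRL-incorrect"))
  trials$label <- lab
  trials$excluded <- lab == "CTRL-incorrect"
  trials
}

#' Signal-detection criterion from hit and false-alarm rates
#'
#' The response bias (criterion) is `c = -(z(H) + z(FA)) / 2` with `z` the
#' standard-normal quantile function; here `H` is the proportion of control
#' trials correctly reported as intermediate and `FA` the proportion of test
#' trials reported as illusory. Negative values indicate a liberal bias
#' toward reporting the illusion.
#'
#' Rates of exactly 0 or 1 make `z` infinite; when trial counts are supplied
#' they are edge-corrected, either by replacing 0 with `1/(2N)` and 1 with
#' `1 - 1/(2N)` (`"half_count"`, the default) or by the log-linear rule
#' `(count + 0.5) / (N + 1)` applied to all rates (`"loglinear"`).
#'
#' @param H hit rate in `[0, 1]`.
#' @param FA false-alarm rate in `[0, 1]`.
#' @param n_h,n_fa trial counts behind `H` and `FA`; required when a rate is
#'   exactly 0 or 1.
#' @param edge_correction `"half_count"`, `"loglinear"` or `"none"`.
#' @return The criterion `c` (dimensionless scalar).
#' @export
compute_criterion <- function(H, FA, n_h = NULL, n_fa = NULL,
                              edge_correction = c("half_count", "loglinear",
                                                  "none")) {
  edge_correction <- match.arg(edge_correction)
  if (!(H >= 0 && H <= 1 && FA >= 0 && FA <= 1))
    stop("H and FA must lie in [0, 1]")
  fix <- function(p, n) {
    if (edge_correction == "loglinear") {
      if (is.null(n)) stop("loglinear correction needs the trial count")
      return((p * n + 0.5) / (n + 1))
    }
    if (p > 0 && p < 1) return(p)
    if (edge_correction == "none" || is.null(n))
      stop("rate of exactly 0 or 1 needs trial counts for edge correction")
    if (p == 0) 1 / (2 * n) else 1 - 1 / (2 * n)
  }
  H <- fix(H, n_h)
  FA <- fix(FA, n_fa)
  -(stats::qnorm(H) + stats::qnorm(FA)) / 2
}

#' Summarise behaviour of one subject
#'
#' Computes, per sequence direction and pooled, the illusion rate among test
#' trials, control accuracy, the signal-detection summary (`H`, `FA`,
#' criterion `c`), mean RTs and trial counts per label. Trials must be
#' labelled (see [classify_trials()]).
#'
#' @param trials labelled trial table.
#' @param edge_correction passed to [compute_criterion()].
#' @return An object of class `behavior_summary`: a list with one entry per
#'   direction plus `"pooled"`, each holding `illusion_rate`,
#'   `control_accuracy`, `H`, `FA`, `c`, `mean_rt` (named by label) and
#'   `n_trials` (named by label).
#' @export
summarize_behavior <- function(trials, edge_correction = "half_count") {
  if (!"label" %in% names(trials)) stop("trials must be labelled first")
  scopes <- c(as.list(unique(trials$direction)), list(NULL))
  names(scopes) <- c(unique(trials$direction), "pooled")
  out <- lapply(scopes, function(dir) {
    tt <- if (is.null(dir)) trials else trials[trials$direction == dir, ,
                                               drop = FALSE]
    n_test <- sum(tt$condition == "test")
    n_ctrl <- sum(tt$condition == "control")
    if (n_test == 0L) stop("no test trials for a direction")
    fa <- mean(tt$label[tt$condition == "test"] == "ILL")
    h <- if (n_ctrl > 0L)
      mean(tt$label[tt$condition == "control"] == "CTRL-correct") else NA_real_
    crit <- if (n_ctrl > 0L)
      compute_criterion(h, fa, n_h = n_ctrl, n_fa = n_test,
                        edge_correction = edge_correction) else NA_real_
    labs <- c("ILL", "no-ILL", "CTRL-correct", "CTRL-incorrect")
    list(
      illusion_rate = fa,
      control_accuracy = h,
      H = h, FA = fa, c = crit,
      mean_rt = vapply(labs, function(l)
        if (any(tt$label == l)) mean(tt$rt[tt$label == l]) else NA_real_, 0),
      n_trials = vapply(labs, function(l) sum(tt$label == l), 0L)
    )
  })
  structure(out, class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("Behavioural summary\n")
  for (nm in names(x)) {
    s <- x[[nm]]
    cat(sprintf("  %-8s illusion %.1f%%  ctrl acc %s  c = %s  (n: %s)\n",
                nm, 100 * s$illusion_rate,
                ifelse(is.na(s$control_accuracy), "NA",
                       sprintf("%.1f%%", 100 * s$control_accuracy)),
                ifelse(is.na(s$c), "NA", sprintf("%+.3f", s$c)),
                paste(names(s$n_trials), s$n_trials, collapse = ", ")))
  }
  invisible(x)
}
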