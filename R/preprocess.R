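#' Preprocessing configuration
#'
#' Thresholds for beat-level artifact elimination, record-level missing-data
#' exclusion, and smoothing. Defaults follow the standard elimination rules
#' for finger-cuff beat-to-beat pressure: a beat is unrealistic when pulse
#' pressure is below 10 mmHg, when SAP jumps more than 20 mmHg between
#' consecutive beats, when DAP deviates more than 25 mmHg from its 10
#' enclosing beats, or when the heart-reference-system height has drifted
#' more than 35 cm from its starting position. A record is excluded when
#' more than 4 of the 5 minutes before or after induction, or more than 8 of
#' the last 10 minutes, are missing.
#'
#' @param pp_min minimum plausible pulse pressure, mmHg.
#' @param sap_step_max maximum plausible SAP change between consecutive
#'   beats, mmHg; the later beat of an offending pair is flagged.
#' @param dap_context_n number of enclosing beats (split evenly before and
#'   after) against which DAP is compared.
#' @param dap_context_max maximum plausible deviation of DAP from the
#'   summary of its enclosing beats, mmHg.
#' @param dap_context_stat summary of the enclosing DAP values: `"median"`
#'   (robust to runs of artifacts, the default) or `"mean"`.
#' @param hrs_drift_max maximum plausible HRS height drift from the start of
#'   the record, cm.
#' @param miss_peri_max maximum tolerated missing seconds in each of the
#'   windows \[-300, 0) and \[0, +300) s around induction.
#' @param miss_tail_max maximum tolerated missing seconds in \[+300, +900\] s.
#' @param coverage_cap_s seconds of coverage credited to a valid beat before
#'   the next valid beat (caps the credit so sparse beats cannot fake
#'   coverage).
#' @param smooth_window moving-average window, seconds (and samples, at
#'   1 Hz).
#' @param smooth_align `"center"` (default) or `"trailing"` window alignment.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(pp_min = 10, sap_step_max = 20,
                              dap_context_n = 10, dap_context_max = 25,
                              dap_context_stat = c("median", "mean"),
                              hrs_drift_max = 35,
                              miss_peri_max = 240, miss_tail_max = 480,
                              coverage_cap_s = 3,
                              smooth_window = 45,
                              smooth_align = c("center", "trailing")) {
  cfg <- list(pp_min = pp_min, sap_step_max = sap_step_max,
              dap_context_n = dap_context_n, dap_context_max = dap_context_max,
              dap_context_stat = match.arg(dap_context_stat),
              hrs_drift_max = hrs_drift_max,
              miss_peri_max = miss_peri_max, miss_tail_max = miss_tail_max,
              coverage_cap_s = coverage_cap_s,
              smooth_window = smooth_window,
              smooth_align = match.arg(smooth_align))
  thr <- unlist(cfg[c("pp_min", "sap_step_max", "dap_context_n",
                      "dap_context_max", "hrs_drift_max", "miss_peri_max",
                      "miss_tail_max", "coverage_cap_s", "smooth_window")])
  if (any(thr <= 0)) stop("all preprocessing thresholds must be > 0", call. = FALSE)
  class(cfg) <- "preprocess_config"
  cfg
}

#' Flag artifact beats
#'
#' Marks beats as invalid when any elimination rule fires. Every rule is
#' evaluated against the raw series (not sequentially against
#' already-filtered data), so the result is idempotent and independent of
#' rule order. The DAP-context rule needs at least `dap_context_n + 1` beats
#' and is skipped (with the other rules still applied) on shorter series;
#' near the record edges it uses the enclosing beats that exist. The HRS
#' rule applies only when the channel is present.
#'
#' @param beats a [beat_series()].
#' @param cfg a [preprocess_config()].
#' @return The series with `valid = FALSE` on flagged beats and an
#'   `elim_counts` attribute counting beats failing each rule (a beat
#'   failing several rules is counted under each).
#' @export
flag_artifacts <- function(beats, cfg = preprocess_config()) {
  stopifnot(inherits(beats, "beat_series"))
  n <- length(beats)
  counts <- c(pp = 0L, sap_step = 0L, dap_context = 0L, hrs = 0L)
  if (n == 0) {
    attr(beats, "elim_counts") <- counts
    return(beats)
  }
  bad <- matrix(FALSE, n, 4, dimnames = list(NULL, names(counts)))

  bad[, "pp"] <- (beats$sap - beats$dap) < cfg$pp_min

  if (n > 1) {
    step <- abs(diff(beats$sap)) > cfg$sap_step_max
    bad[, "sap_step"] <- c(FALSE, step)     # later beat of the pair
  }

  if (n >= cfg$dap_context_n + 1) {
    half <- cfg$dap_context_n %/% 2
    stat <- if (cfg$dap_context_stat == "median") stats::median else mean
    dev <- vapply(seq_len(n), function(i) {
      ctx <- c(seq(max(1, i - half), i - 1), seq(i + 1, min(n, i + half)))
      ctx <- ctx[ctx >= 1 & ctx <= n & ctx != i]
      abs(beats$dap[i] - stat(beats$dap[ctx]))
    }, numeric(1))
    bad[, "dap_context"] <- dev > cfg$dap_context_max
  }

  if (!is.null(beats$hrs))
    bad[, "hrs"] <- abs(beats$hrs - beats$hrs[1]) > cfg$hrs_drift_max

  beats$valid <- beats$valid & !apply(bad, 1, any)
  attr(beats, "elim_counts") <- colSums(bad)
  beats
}

# Seconds of valid-beat coverage inside [lo, hi): each valid beat covers the
# interval to the next valid beat, capped at cap seconds.
coverage_seconds <- function(t_valid, lo, hi, cap) {
  if (length(t_valid) == 0) return(0)
  t_valid <- sort(t_valid)
  ends <- c(pmin(t_valid[-length(t_valid)] + cap, t_valid[-1]),
            t_valid[length(t_valid)] + cap)
  a <- pmax(t_valid, lo)
  b <- pmin(ends, hi)
  sum(pmax(b - a, 0))
}

#' Record-level missing-data check
#'
#' Computes valid-beat coverage in the three assessment windows around
#' induction — \[-300, 0), \[0, +300), and \[+300, +900\] seconds — and
#' excludes the record when more than `miss_peri_max` seconds (default 240,
#' i.e. >4 of 5 minutes) are missing in either peri-induction window, or
#' more than `miss_tail_max` seconds (default 480, >8 of the last 10
#' minutes) in the tail window. A valid beat covers the time up to the next
#' valid beat, capped at `coverage_cap_s`.
#'
#' @param beats a [beat_series()] with artifact flags applied.
#' @param t_induction induction time, seconds since record start.
#' @param cfg a [preprocess_config()].
#' @return A list of class `exclusion_report` with fields `included`,
#'   `reasons` (data frame: window, missing seconds, limit), `coverage`
#'   (per-window missing seconds), and `eliminated_beats`.
#' @export
check_missingness <- function(beats, t_induction, cfg = preprocess_config()) {
  stopifnot(inherits(beats, "beat_series"))
  tv <- beats$t[beats$valid] - t_induction
  windows <- data.frame(
    window = c("pre_induction", "peri_induction", "tail"),
    lo = c(-300, 0, 300), hi = c(0, 300, 900),
    limit_s = c(cfg$miss_peri_max, cfg$miss_peri_max, cfg$miss_tail_max))
  covered <- vapply(seq_len(nrow(windows)), function(i)
    coverage_seconds(tv, windows$lo[i], windows$hi[i], cfg$coverage_cap_s),
    numeric(1))
  windows$missing_s <- (windows$hi - windows$lo) - covered
  reasons <- windows[windows$missing_s > windows$limit_s,
                     c("window", "missing_s", "limit_s")]
  counts <- attr(beats, "elim_counts")
  structure(list(included = nrow(reasons) == 0,
                 reasons = reasons,
                 coverage = windows,
                 eliminated_beats = counts,
                 n_beats = length(beats),
                 n_eliminated = sum(!beats$valid),
                 frac_eliminated = if (length(beats)) mean(!beats$valid) else NA_real_),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %s; %d/%d beats eliminated (%.1f%%)\n",
              if (x$included) "included" else "EXCLUDED",
              x$n_eliminated, x$n_beats, 100 * x$frac_eliminated))
  if (nrow(x$reasons)) print(x$reasons)
  invisible(x)
}

grid_rel <- -300:900   # induction-relative 1-Hz grid, 1201 samples

#' Resample valid beats onto the 1-Hz induction-relative grid
#'
#' Linearly interpolates the remaining (valid) beat values onto a 1-second
#' grid spanning -300 to +900 s around induction. Samples before the first
#' or after the last valid beat are masked; internal gaps are bridged (bad
#' records have already been excluded by [check_missingness()]).
#'
#' @param beats a [beat_series()] with artifact flags applied.
#' @param t_induction induction time, seconds since record start.
#' @return A list of class `clean_signal` with fields `t` (the grid,
#'   induction-relative seconds), `sap`, `map`, `dap`, `pp` (mmHg, `NA`
#'   where masked) and logical `mask` (TRUE = sample available).
#' @export
resample_1hz <- function(beats, t_induction) {
  stopifnot(inherits(beats, "beat_series"))
  keep <- beats$valid
  if (sum(keep) < 2) stop("insufficient data: < 2 valid beats", call. = FALSE)
  tv <- beats$t[keep] - t_induction
  grid <- grid_rel
  mask <- grid >= tv[1] & grid <= tv[length(tv)]
  interp <- function(y) {
    out <- rep(NA_real_, length(grid))
    out[mask] <- stats::approx(tv, y[keep], xout = grid[mask], ties = "ordered")$y
    out
  }
  sap <- interp(beats$sap); map <- interp(beats$map); dap <- interp(beats$dap)
  structure(list(t = grid, sap = sap, map = map, dap = dap,
                 pp = sap - dap, mask = mask),
            class = "clean_signal")
}

#' @export
print.clean_signal <- function(x, ...) {
  cat(sprintf("<clean_signal> 1 Hz on [-300, +900] s; %d/%d samples available\n",
              sum(x$mask), length(x$mask)))
  invisible(x)
}

moving_average_masked <- function(x, mask, window, align) {
  n <- length(x)
  if (align == "center") {
    before <- (window - 1) %/% 2
    after <- window - 1 - before
  } else {                     # trailing
    before <- window - 1
    after <- 0
  }
  vals <- ifelse(mask, x, 0)
  cnt <- as.numeric(mask)
  cs <- c(0, cumsum(vals)); cc <- c(0, cumsum(cnt))
  i <- seq_len(n)
  lo <- pmax(1L, i - before); hi <- pmin(n, i + after)
  s <- cs[hi + 1] - cs[lo]
  k <- cc[hi + 1] - cc[lo]
  ifelse(mask & k > 0, s / k, NA_real_)
}

#' Moving-average smoothing of a 1-Hz signal
#'
#' Applies a 45-sample (45-second) moving average to each pressure channel,
#' computed over available samples only; the window is truncated at the
#' record edges and the availability mask is unchanged. The window is
#' centered by default (set `smooth_align = "trailing"` in the config for a
#' causal filter).
#'
#' @param signal a [resample_1hz()] output.
#' @param cfg a [preprocess_config()].
#' @return A `clean_signal` with smoothed channels.
#' @export
smooth_signal <- function(signal, cfg = preprocess_config()) {
  stopifnot(inherits(signal, "clean_signal"))
  for (ch in c("sap", "map", "dap", "pp"))
    signal[[ch]] <- moving_average_masked(signal[[ch]], signal$mask,
                                          cfg$smooth_window, cfg$smooth_align)
  signal
}

#' Full preprocessing pipeline for one record
#'
#' Runs artifact flagging, the missing-data exclusion check, 1-Hz
#' resampling, and 45-s smoothing, in that order. Excluded records return a
#' report with `included = FALSE` and no signal.
#'
#' @param record an [induction_record()].
#' @param cfg a [preprocess_config()].
#' @return A list with elements `signal` (a `clean_signal`, or `NULL` when
#'   excluded) and `report` (an `exclusion_report`).
#' @export
preprocess_record <- function(record, cfg = preprocess_config()) {
  stopifnot(inherits(record, "induction_record"))
  beats <- flag_artifacts(record$beats, cfg)
  report <- check_missingness(beats, record$t_induction, cfg)
  if (!report$included) return(list(signal = NULL, report = report))
  signal <- smooth_signal(resample_1hz(beats, record$t_induction), cfg)
  list(signal = signal, report = report)
}
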