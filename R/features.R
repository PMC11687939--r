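#' Analysis section windows
#'
#' The induction recording is analysed over three partly overlapping
#' windows, all in induction-relative seconds: A = \[-300, 0) (the 5 min
#' before the first induction agent), B = \[0, +300) (the first 5 min
#' after), and C = \[0, +900\] (the full 15 min after). B is contained in C;
#' A is disjoint from both.
#'
#' @return Named list of `c(lo, hi)` bounds; the upper bound is exclusive
#'   for A and B and inclusive for C.
#' @export
section_windows <- function() {
  list(A = c(-300, 0), B = c(0, 300), C = c(0, 900))
}

section_index <- function(signal, section) {
  w <- section_windows()[[section]]
  if (section == "C") signal$t >= w[1] & signal$t <= w[2]
  else signal$t >= w[1] & signal$t < w[2]
}

#' Per-section summary statistics of one pressure channel
#'
#' Minimum and maximum with their times of occurrence, mean, and sample
#' variance over the unmasked samples of a section. Ties for the extrema are
#' broken toward the earliest sample; times are induction-relative seconds.
#'
#' @param signal a `clean_signal`.
#' @param which channel: `"sap"`, `"map"`, `"dap"` or `"pp"`.
#' @param section `"A"`, `"B"` or `"C"`.
#' @return Named list: `min`, `t_min`, `max`, `t_max`, `mean`, `var`.
#' @export
section_stats <- function(signal, which = c("sap", "map", "dap", "pp"),
                          section = c("A", "B", "C")) {
  which <- match.arg(which); section <- match.arg(section)
  idx <- section_index(signal, section) & signal$mask
  x <- signal[[which]][idx]
  t <- signal$t[idx]
  if (length(x) < 2)
    stop(sprintf("empty section: %s has < 2 unmasked samples in section %s",
                 which, section), call. = FALSE)
  i_min <- which.min(x); i_max <- which.max(x)   # which.min: earliest on ties
  list(min = x[i_min], t_min = t[i_min],
       max = x[i_max], t_max = t[i_max],
       mean = mean(x), var = stats::var(x))
}

#' Per-sample slope of a smoothed channel
#'
#' Central-difference slope in mmHg/min: `slope[i] = (x[i+1] - x[i-1]) / 2 *
#' 60` on interior samples whose full triple is unmasked; `NA` elsewhere.
#'
#' @param signal a `clean_signal` (smoothed).
#' @param which channel name.
#' @return Numeric vector aligned with `signal$t`.
#' @export
slope_series <- function(signal, which = c("sap", "map", "dap", "pp")) {
  which <- match.arg(which)
  x <- signal[[which]]; m <- signal$mask
  n <- length(x)
  out <- rep(NA_real_, n)
  i <- 2:(n - 1)
  ok <- m[i - 1] & m[i] & m[i + 1]
  out[i][ok] <- (x[i + 1][ok] - x[i - 1][ok]) / 2 * 60
  out
}

#' Mean negative slope around induction
#'
#' Arithmetic mean of the strictly negative slope samples within the 2.5
#' minutes before and after induction (\[-150, +150\] s). When no slope in
#' the window is negative the value is 0 and the result carries attribute
#' `no_negative_slope = TRUE`.
#'
#' @param signal a smoothed `clean_signal`.
#' @param which channel name.
#' @param window `c(lo, hi)` in induction-relative seconds.
#' @return Scalar mmHg/min (<= 0).
#' @export
mean_negative_slope <- function(signal, which = c("sap", "map", "dap"),
                                window = c(-150, 150)) {
  which <- match.arg(which)
  s <- slope_series(signal, which)
  inw <- signal$t >= window[1] & signal$t <= window[2]
  neg <- s[inw & !is.na(s) & s < 0]
  if (length(neg) == 0) return(structure(0, no_negative_slope = TRUE))
  mean(neg)
}

#' Steepest downward slopes and their deciles
#'
#' Over the unmasked slope samples of a section (default C), returns the
#' single steepest (most negative) slope and the first and second deciles of
#' the slope distribution — its 10th and 20th percentiles, i.e. the
#' most-negative tail — under the linear-interpolation percentile
#' definition. When the section contains no downward slope at all, the
#' result carries attribute `no_downward_slope = TRUE`.
#'
#' @param signal a smoothed `clean_signal`.
#' @param which channel name.
#' @param section section id, default `"C"`.
#' @param negative_only if `TRUE`, deciles are taken over the negative-slope
#'   subset instead of all slopes.
#' @return Named list: `steepest`, `d1`, `d2` (mmHg/min).
#' @export
steepest_slopes <- function(signal, which = c("sap", "map", "dap"),
                            section = "C", negative_only = FALSE) {
  which <- match.arg(which)
  s <- slope_series(signal, which)
  s <- s[section_index(signal, section) & !is.na(s)]
  if (length(s) < 10)
    stop("too few slope samples in section ", section, call. = FALSE)
  pool <- if (negative_only) s[s < 0] else s
  if (length(pool) == 0) pool <- s
  q <- stats::quantile(pool, c(0.10, 0.20), names = FALSE, type = 7)
  out <- list(steepest = min(s), d1 = q[1], d2 = q[2])
  if (all(s >= 0)) attr(out, "no_downward_slope") <- TRUE
  out
}

#' Cross-section change statistics
#'
#' Changes of a per-section statistic from the pre-induction baseline
#' (section A) to each post-induction section: `delta = value(later) -
#' value(A)`, for B and C.
#'
#' @param statsA,statsB,statsC outputs of [section_stats()] for one channel.
#' @param stats which statistics to difference.
#' @return Named list `A_to_B`, `A_to_C`, each a named numeric vector.
#' @export
cross_section_deltas <- function(statsA, statsB, statsC,
                                 stats = c("min", "max", "mean", "var")) {
  delta <- function(later) vapply(stats, function(s) later[[s]] - statsA[[s]],
                                  numeric(1))
  list(A_to_B = delta(statsB), A_to_C = delta(statsC))
}

#' The default feature registry
#'
#' Ordered enumeration of the 98 features extracted from one preprocessed
#' induction record:
#' \itemize{
#'   \item 54 per-section statistics: 3 pressure channels (SAP, MAP, DAP)
#'     x 3 sections (A, B, C) x \{min, t_min, max, t_max, mean, var\};
#'   \item 6 pulse-pressure statistics: 3 sections x \{mean, var\};
#'   \item 3 mean negative slopes (per channel, 2.5 min around induction);
#'   \item 3 steepest downward slopes (per channel, section C);
#'   \item 6 slope deciles (d1, d2 per channel, section C);
#'   \item 24 cross-section deltas: \{min, max, mean, var\} x 3 channels x
#'     \{A to B, A to C\};
#'   \item 2 pulse-pressure mean deltas (A to B, A to C).
#' }
#' The authoritative feature list of the original study is not public; this
#' registry is the package's constructed enumeration, consistent with every
#' feature family described for the method and totalling exactly 98. A user
#' holding the authoritative list can pass a replacement registry to
#' [featurize()].
#'
#' @return Data frame with columns `name`, `family`, `signal`, `section`,
#'   `stat`, of class `feature_registry`; 98 rows.
#' @export
feature_registry <- function() {
  sigs <- c("sap", "map", "dap")
  secs <- c("A", "B", "C")
  stats6 <- c("min", "t_min", "max", "t_max", "mean", "var")
  rows <- list()
  for (sg in sigs) for (sc in secs) for (st in stats6)
    rows[[length(rows) + 1]] <- c(paste(sg, sc, st, sep = "_"),
                                  "section_stat", sg, sc, st)
  for (sc in secs) for (st in c("mean", "var"))
    rows[[length(rows) + 1]] <- c(paste("pp", sc, st, sep = "_"),
                                  "section_stat", "pp", sc, st)
  for (sg in sigs)
    rows[[length(rows) + 1]] <- c(paste0(sg, "_mean_neg_slope"),
                                  "mean_neg_slope", sg, "", "")
  for (sg in sigs)
    rows[[length(rows) + 1]] <- c(paste0(sg, "_steepest_slope"),
                                  "steepest_slope", sg, "C", "steepest")
  for (sg in sigs) for (d in c("d1", "d2"))
    rows[[length(rows) + 1]] <- c(paste0(sg, "_slope_", d),
                                  "steepest_slope", sg, "C", d)
  for (sg in sigs) for (st in c("min", "max", "mean", "var"))
    for (pair in c("A_to_B", "A_to_C"))
      rows[[length(rows) + 1]] <- c(paste("d", sg, st, pair, sep = "_"),
                                    "delta", sg, pair, st)
  for (pair in c("A_to_B", "A_to_C"))
    rows[[length(rows) + 1]] <- c(paste("d", "pp", "mean", pair, sep = "_"),
                                  "delta", "pp", pair, "mean")
  reg <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(reg) <- c("name", "family", "signal", "section", "stat")
  stopifnot(nrow(reg) == 98, !anyDuplicated(reg$name))
  class(reg) <- c("feature_registry", class(reg))
  reg
}

#' Extract the feature vector of one preprocessed record
#'
#' Computes every feature in the registry (default: the 98-feature registry
#' of [feature_registry()]) from a smoothed, masked 1-Hz signal. The
#' computation is deterministic and pure; any feature that cannot be
#' computed raises an error naming it.
#'
#' @param signal a smoothed `clean_signal` from [preprocess_record()].
#' @param registry a [feature_registry()].
#' @return Named numeric vector in registry order, all values finite.
#' @export
featurize <- function(signal, registry = feature_registry()) {
  stopifnot(inherits(signal, "clean_signal"))
  sec_stats <- list()
  for (sg in c("sap", "map", "dap", "pp")) for (sc in c("A", "B", "C")) {
    st <- tryCatch(section_stats(signal, sg, sc), error = function(e) e)
    sec_stats[[paste(sg, sc)]] <- st
  }
  get_stats <- function(sg, sc) {
    st <- sec_stats[[paste(sg, sc)]]
    if (inherits(st, "error"))
      stop("uncomputable feature for ", sg, " section ", sc, ": ",
           conditionMessage(st), call. = FALSE)
    st
  }
  slopes <- lapply(stats::setNames(nm = c("sap", "map", "dap")), function(sg)
    list(mns = mean_negative_slope(signal, sg),
         steep = steepest_slopes(signal, sg)))
  vals <- vapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    v <- switch(r$family,
      section_stat = get_stats(r$signal, r$section)[[r$stat]],
      mean_neg_slope = as.numeric(slopes[[r$signal]]$mns),
      steepest_slope = slopes[[r$signal]]$steep[[r$stat]],
      delta = get_stats(r$signal, substr(r$section, 6, 6))[[r$stat]] -
              get_stats(r$signal, "A")[[r$stat]],
      stop("unknown feature family: ", r$family, call. = FALSE))
    as.numeric(v)
  }, numeric(1))
  names(vals) <- registry$name
  if (any(!is.finite(vals)))
    stop("uncomputable feature: ", names(vals)[!is.finite(vals)][1], call. = FALSE)
  vals
}

#' Featurize a cohort of records
#'
#' Preprocesses and featurizes each record, dropping those the exclusion
#' rules remove.
#'
#' @param records list of [induction_record()]s.
#' @param cfg a [preprocess_config()].
#' @param registry a [feature_registry()].
#' @return List with `features` (data frame: `id` + one column per feature),
#'   `included` (logical per record), `reports` (exclusion reports), and
#'   `signals` (the included records' clean signals, for downstream
#'   threshold rules).
#' @export
featurize_cohort <- function(records, cfg = preprocess_config(),
                             registry = feature_registry()) {
  pre <- lapply(records, preprocess_record, cfg = cfg)
  included <- vapply(pre, function(p) p$report$included, logical(1))
  feats <- lapply(pre[included], function(p) featurize(p$signal, registry))
  ids <- vapply(records, function(r) r$patient_id, character(1))
  tab <- as.data.frame(do.call(rbind, feats))
  features <- cbind(data.frame(id = ids[included], stringsAsFactors = FALSE), tab)
  rownames(features) <- NULL
  list(features = features, included = included,
       reports = lapply(pre, `[[`, "report"),
       signals = lapply(pre[included], `[[`, "signal"))
}
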