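#' Consensus labels from an expert panel
#'
#' A subject is classified hemodynamically unstable when at least 75% of the
#' panel voted unstable, operationalized as `votes_unstable >=
#' ceiling(0.75 * k)`; with a 4-expert panel this means 3/4 or 4/4 votes.
#' An exact-75% count (e.g. 12 of 16) counts as agreement.
#'
#' @param ratings a [rating_matrix()].
#' @param agreement required agreement proportion (default 0.75).
#' @return Data frame with columns `subject`, `votes_unstable`, `k`,
#'   `label` (`"unstable"`/`"stable"`).
#' @export
aggregate_votes <- function(ratings, agreement = 0.75) {
  stopifnot(inherits(ratings, "rating_matrix"))
  k <- ncol(ratings$votes)
  if (k == 0) stop("no raters", call. = FALSE)
  votes <- rowSums(ratings$votes)
  need <- ceiling(agreement * k)
  data.frame(subject = ratings$subjects,
             votes_unstable = as.integer(votes), k = k,
             label = ifelse(votes >= need, "unstable", "stable"),
             stringsAsFactors = FALSE)
}

icc_from_ms <- function(MSR, MSC, MSE, n, k, unit, definition) {
  num <- MSR - MSE
  den <- switch(definition,
    consistency = switch(unit,
      single  = MSR + (k - 1) * MSE,
      average = MSR),
    agreement = switch(unit,
      single  = MSR + (k - 1) * MSE + (k / n) * (MSC - MSE),
      average = MSR + (MSC - MSE) / n))
  if (den == 0) {
    warning("ICC denominator is zero; estimate undefined", call. = FALSE)
    return(NaN)
  }
  num / den
}

#' Intraclass correlation from two-way ANOVA mean squares
#'
#' Estimates the ICC of an n-subject x k-rater matrix from the two-way
#' ANOVA decomposition (MSR between subjects, MSC between raters, MSE
#' residual), for the two-way random and two-way mixed models, with single
#' or average measurement units, under the consistency or absolute-agreement
#' definition. The point estimates of the random and mixed models coincide;
#' the model label records the intended inference. Negative estimates are
#' reported as computed. A matrix with zero total variance yields an
#' estimate of 1 with a warning (perfectly reproduced constants).
#'
#' @param x numeric matrix, subjects in rows, raters in columns (binary 0/1
#'   votes are fed in as numerics).
#' @param model `"two_way_random"` or `"two_way_mixed"`.
#' @param unit `"single"` or `"average"`.
#' @param definition `"consistency"` or `"agreement"`.
#' @param conf.level confidence level for the optional F-based interval
#'   (consistency definition only; `NULL` to skip).
#' @return List of class `icc_result`: `estimate`, `model`, `unit`,
#'   `definition`, `n`, `k`, mean squares `MSR`, `MSC`, `MSE`, and `ci` when
#'   requested.
#' @export
icc <- function(x, model = c("two_way_random", "two_way_mixed"),
                unit = c("single", "average"),
                definition = c("consistency", "agreement"),
                conf.level = NULL) {
  model <- match.arg(model); unit <- match.arg(unit)
  definition <- match.arg(definition)
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("icc needs n >= 2 subjects and k >= 2 raters", call. = FALSE)
  if (anyNA(x)) stop("icc needs a complete matrix", call. = FALSE)
  grand <- mean(x)
  rm <- rowMeans(x); cm <- colMeans(x)
  SSR <- k * sum((rm - grand)^2)
  SSC <- n * sum((cm - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST < .Machine$double.eps * length(x)) {
    warning("zero total variance; ICC defined as 1", call. = FALSE)
    est <- 1
  } else {
    est <- icc_from_ms(MSR, MSC, MSE, n, k, unit, definition)
  }
  res <- list(estimate = est, model = model, unit = unit,
              definition = definition, n = n, k = k,
              MSR = MSR, MSC = MSC, MSE = MSE)
  if (!is.null(conf.level) && definition == "consistency" && MSE > 0) {
    # F-based interval on MSR/MSE (exact for the consistency definition)
    Fobs <- MSR / MSE
    alpha <- 1 - conf.level
    FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    FU <- Fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    bounds <- if (unit == "single")
      c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    else c(1 - 1 / FL, 1 - 1 / FU)
    res$ci <- sort(bounds)
  }
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(%s, %s, %s) = %.4f  [n=%d, k=%d]\n",
              x$model, x$unit, x$definition, x$estimate, x$n, x$k))
  if (!is.null(x$ci))
    cat(sprintf("  CI: (%.4f, %.4f)\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Intra-rater consistency over repeat labelling sessions
#'
#' For each rater with a repeat session, forms the n x 2 (session) matrix of
#' their votes and estimates ICC(two-way mixed, single measures,
#' consistency). Raters whose votes are constant across both sessions have
#' an undefined ICC and are excluded from the pooled value with a warning.
#' The pooled value is the unweighted mean of the per-rater estimates.
#'
#' @param ratings a [rating_matrix()] with a `repeats` block.
#' @return List: `per_rater` (named numeric, `NA` where undefined),
#'   `pooled`, `results` (per-rater `icc_result`s).
#' @export
intra_rater <- function(ratings) {
  stopifnot(inherits(ratings, "rating_matrix"))
  if (is.null(ratings$repeats))
    stop("intra_rater needs a repeats block", call. = FALSE)
  per <- vapply(seq_along(ratings$raters), function(j) {
    m <- cbind(ratings$votes[, j], ratings$repeats[, j])
    if (stats::var(as.vector(m)) == 0) return(NA_real_)
    icc(m, "two_way_mixed", "single", "consistency")$estimate
  }, numeric(1))
  names(per) <- ratings$raters
  if (anyNA(per))
    warning("rater(s) with constant votes excluded from pooled intra-rater ICC: ",
            paste(names(per)[is.na(per)], collapse = ", "), call. = FALSE)
  list(per_rater = per, pooled = mean(per, na.rm = TRUE))
}

#' Inter-rater agreement of the full panel
#'
#' Agreement between the experts, estimated as ICC(two-way random, average
#' measures, absolute agreement) on the subjects x raters vote matrix.
#'
#' @param ratings a [rating_matrix()].
#' @param conf.level optional confidence level passed to [icc()].
#' @return An `icc_result`.
#' @export
inter_rater <- function(ratings, conf.level = NULL) {
  stopifnot(inherits(ratings, "rating_matrix"))
  icc(ratings$votes, "two_way_random", "average", "agreement",
      conf.level = conf.level)
}

#' Consistency between a rater subpanel and the rest of the panel
#'
#' Averages the votes within each group per subject and estimates
#' ICC(two-way random, average measures) on the resulting n x 2 matrix —
#' used to decide whether a small subpanel (e.g. 4 experts) can stand in
#' for the full panel when labelling further cases.
#'
#' @param ratings a [rating_matrix()].
#' @param group1,group2 disjoint character vectors of rater ids covering the
#'   panel.
#' @return An `icc_result`.
#' @export
subpanel_consistency <- function(ratings, group1, group2) {
  stopifnot(inherits(ratings, "rating_matrix"))
  if (length(intersect(group1, group2)) > 0)
    stop("rater groups overlap: ",
         paste(intersect(group1, group2), collapse = ", "), call. = FALSE)
  missing <- setdiff(c(group1, group2), ratings$raters)
  if (length(missing) > 0)
    stop("unknown rater id: ", missing[1], call. = FALSE)
  m <- cbind(rowMeans(ratings$votes[, group1, drop = FALSE]),
             rowMeans(ratings$votes[, group2, drop = FALSE]))
  icc(m, "two_way_random", "average", "agreement")
}
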