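#' Synthetic cohort configuration
#'
#' Parameters of the induction-waveform simulator. The defaults emulate the
#' cohort the pipeline is designed for: about 21% of patients
#' hemodynamically unstable, unstable patients starting from a somewhat
#' higher systolic baseline (161 vs 150 mmHg) and undergoing a large, fast
#' exponential pressure decline after the first induction agent, stable
#' patients a small or slow one, with an optional vasopressor-like rebound
#' bump a couple of minutes after induction, beat-level Gaussian noise, and
#' artifact beats injected per elimination rule.
#'
#' Ground-truth class drives the generating parameters (rather than
#' thresholding the generated trace), so label noise and trace noise can be
#' controlled independently. MAP and DAP are generated as fixed fractions
#' of SAP plus independent noise — sufficient for every pipeline rule,
#' without claiming pulse-contour realism.
#'
#' @param n cohort size.
#' @param prevalence_unstable proportion of unstable patients (default
#'   0.21).
#' @param seed integer RNG seed.
#' @param regime `"separable"` (default; large fast drops vs small ones) or
#'   `"overlap"` (class parameter distributions overlap, a harder
#'   problem).
#' @param heart_rate mean and sd of per-patient heart rate, bpm.
#' @param baseline_sap named list of per-class `c(mean, sd)` baseline SAP,
#'   mmHg.
#' @param drop named list of per-class `c(mean, sd)` post-induction decline
#'   magnitude, mmHg.
#' @param tau named list of per-class `c(lo, hi)` uniform range of the
#'   decline time constant, seconds (small = fast drop).
#' @param rebound_prob named list of per-class probability of a
#'   vasopressor-like rebound.
#' @param rebound_delay `c(lo, hi)` seconds after induction before the
#'   rebound starts.
#' @param rebound_gain `c(lo, hi)` rebound magnitude as a fraction of the
#'   decline.
#' @param noise_sd per-beat Gaussian noise sd, mmHg.
#' @param drift_sd sd of the pre-induction linear drift, mmHg/min.
#' @param map_frac,dap_frac MAP and DAP as fractions of SAP.
#' @param artifact_rates named list of per-beat (or per-record, for `hrs`
#'   and `gap`) artifact injection probabilities: `pp`, `sap_step`, `dap`,
#'   `hrs`, `gap`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 100, prevalence_unstable = 0.21, seed = 1,
                          regime = c("separable", "overlap"),
                          heart_rate = c(70, 10),
                          baseline_sap = list(stable = c(150, 20),
                                              unstable = c(161, 20)),
                          drop = NULL, tau = NULL,
                          rebound_prob = list(stable = 0.10, unstable = 0.50),
                          rebound_delay = c(90, 180),
                          rebound_gain = c(0.3, 0.6),
                          noise_sd = 2, drift_sd = 1,
                          map_frac = 0.75, dap_frac = 0.60,
                          artifact_rates = list(pp = 0.03, sap_step = 0.02,
                                                dap = 0.015, hrs = 0.05,
                                                gap = 0.3)) {
  regime <- match.arg(regime)
  if (is.null(drop))
    drop <- if (regime == "separable")
      list(stable = c(10, 4), unstable = c(65, 10))
    else list(stable = c(25, 12), unstable = c(45, 15))
  if (is.null(tau))
    tau <- if (regime == "separable")
      list(stable = c(180, 360), unstable = c(20, 60))
    else list(stable = c(60, 240), unstable = c(40, 150))
  if (prevalence_unstable < 0 || prevalence_unstable > 1)
    stop("prevalence must be in [0, 1]", call. = FALSE)
  stopifnot(heart_rate[2] >= 0, noise_sd >= 0, all(unlist(tau) > 0))
  structure(list(n = n, prevalence_unstable = prevalence_unstable,
                 seed = seed, regime = regime, heart_rate = heart_rate,
                 baseline_sap = baseline_sap, drop = drop, tau = tau,
                 rebound_prob = rebound_prob, rebound_delay = rebound_delay,
                 rebound_gain = rebound_gain, noise_sd = noise_sd,
                 drift_sd = drift_sd, map_frac = map_frac,
                 dap_frac = dap_frac, artifact_rates = artifact_rates),
            class = "cohort_config")
}

#' Generate one synthetic induction record
#'
#' Beat times come from a per-patient heart-rate draw; the systolic
#' trajectory is `baseline + drift * t` before induction and `baseline -
#' drop * (1 - exp(-t / tau))` after, plus an optional delayed rebound
#' (logged as a phenylephrine event) and per-beat noise. Artifact beats are
#' injected per elimination rule and their positions recorded in the
#' ground truth for recovery checks.
#'
#' @param cfg a [cohort_config()].
#' @param class `"stable"` or `"unstable"`.
#' @param seed integer RNG seed for this record.
#' @param patient_id identifier.
#' @param artifacts inject artifacts (set `FALSE` for clean traces).
#' @return An [induction_record()]; its `ground_truth` holds the class and
#'   attribute `truth` on the record carries the generating parameters and
#'   injected-artifact beat index.
#' @export
generate_record <- function(cfg, class = c("stable", "unstable"), seed = 1,
                            patient_id = sprintf("sim-%06d", seed),
                            artifacts = TRUE) {
  class <- match.arg(class)
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  t_ind <- 305
  dur <- t_ind + 905
  hr <- max(stats::rnorm(1, cfg$heart_rate[1], cfg$heart_rate[2]), 40)
  period <- 60 / hr
  n_max <- ceiling(dur / period * 1.3) + 10
  intervals <- pmax(stats::rnorm(n_max, period, period * 0.03), 0.25)
  t <- cumsum(intervals)
  t <- t[t <= dur]
  tr <- t - t_ind

  baseline <- stats::rnorm(1, cfg$baseline_sap[[class]][1],
                           cfg$baseline_sap[[class]][2])
  drift <- stats::rnorm(1, 0, cfg$drift_sd) / 60       # mmHg/s
  delta <- max(stats::rnorm(1, cfg$drop[[class]][1], cfg$drop[[class]][2]), 0)
  tau <- stats::runif(1, cfg$tau[[class]][1], cfg$tau[[class]][2])

  sap <- baseline + drift * pmin(tr, 0)
  post <- tr > 0
  sap[post] <- sap[post] - delta * (1 - exp(-tr[post] / tau))

  events <- data.frame(drug = "propofol", dose = 2, units = "mg/kg",
                       time = t_ind)
  if (stats::runif(1) < cfg$rebound_prob[[class]]) {
    d <- stats::runif(1, cfg$rebound_delay[1], cfg$rebound_delay[2])
    g <- stats::runif(1, cfg$rebound_gain[1], cfg$rebound_gain[2]) * delta
    reb <- tr > d
    sap[reb] <- sap[reb] + g * (1 - exp(-(tr[reb] - d) / 30))
    events <- rbind(events, data.frame(drug = "phenylephrine", dose = 100,
                                       units = "ug", time = t_ind + d))
  }

  n <- length(t)
  sap <- sap + stats::rnorm(n, 0, cfg$noise_sd)
  map <- cfg$map_frac * sap + stats::rnorm(n, 0, cfg$noise_sd / 2)
  dap <- cfg$dap_frac * sap + stats::rnorm(n, 0, cfg$noise_sd / 2)
  hrs <- stats::rnorm(n, 0, 1)
  if (any(c(sap, map, dap) <= 0))
    stop("infeasible parameters: nonpositive pressure generated", call. = FALSE)

  injected <- rep(FALSE, n)
  if (artifacts) {
    ar <- cfg$artifact_rates
    # a short dropout (gap) somewhere outside the peri-induction windows
    if (stats::runif(1) < ar$gap) {
      gap_start <- stats::runif(1, t_ind + 320, t_ind + 800)
      drop_idx <- which(t >= gap_start & t <= gap_start + 30)
      if (length(drop_idx) > 0 && length(drop_idx) < n - 20) {
        keep <- setdiff(seq_len(n), drop_idx)
        t <- t[keep]; tr <- tr[keep]; sap <- sap[keep]; map <- map[keep]
        dap <- dap[keep]; hrs <- hrs[keep]
        n <- length(t); injected <- rep(FALSE, n)
      }
    }
    low_pp <- stats::runif(n) < ar$pp
    dap[low_pp] <- sap[low_pp] - stats::runif(sum(low_pp), 5, 9)
    step <- stats::runif(n) < ar$sap_step
    step[1] <- FALSE
    sap[step] <- sap[step] +
      sample(c(-1, 1), sum(step), replace = TRUE) * stats::runif(sum(step), 28, 45)
    dap_out <- stats::runif(n) < ar$dap & !low_pp
    dap[dap_out] <- dap[dap_out] +
      sample(c(-1, 1), sum(dap_out), replace = TRUE) * stats::runif(sum(dap_out), 30, 45)
    hrs_seg <- rep(FALSE, n)
    if (stats::runif(1) < ar$hrs) {
      start <- sample.int(n - 40, 1) + 10L  # keep beat 1 as the HRS anchor
      hrs_seg[start:(start + 29)] <- TRUE
      hrs[hrs_seg] <- 40 + stats::rnorm(sum(hrs_seg), 0, 1)
    }
    injected <- low_pp | step | dap_out | hrs_seg
    sap <- pmax(sap, 20); dap <- pmax(dap, 5); map <- pmax(map, 10)
  }

  rec <- suppressWarnings(induction_record(
    patient_id = patient_id,
    beats = beat_series(t, sap, map, dap, hrs = hrs),
    t_induction = t_ind, events = events, ground_truth = class))
  attr(rec, "truth") <- list(class = class, baseline = baseline,
                             delta = delta, tau = tau,
                             injected_artifacts = injected)
  rec
}

# Per-subject class draw; uses the current RNG stream (callers seed it).
draw_classes <- function(cfg) {
  ifelse(stats::runif(cfg$n) < cfg$prevalence_unstable, "unstable", "stable")
}

#' Generate a labelled synthetic cohort
#'
#' Draws each subject's class from `Bernoulli(prevalence_unstable)` and a
#' per-record sub-seed, then simulates the records; fully reproducible
#' under the cohort seed.
#'
#' @param cfg a [cohort_config()].
#' @param artifacts inject artifact beats (default `TRUE`).
#' @return List with `records` (list of [induction_record()]s) and `truth`
#'   (data frame: `id`, `class`, `delta`, `tau`, `baseline`).
#' @export
generate_cohort <- function(cfg, artifacts = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"), cfg$n >= 2)
  set.seed(cfg$seed)
  classes <- draw_classes(cfg)
  seeds <- sample.int(.Machine$integer.max - 1, cfg$n)
  records <- lapply(seq_len(cfg$n), function(i)
    generate_record(cfg, classes[i], seed = seeds[i],
                    patient_id = sprintf("sim-%04d", i),
                    artifacts = artifacts))
  truth <- do.call(rbind, lapply(records, function(r) {
    tt <- attr(r, "truth")
    data.frame(id = r$patient_id, class = tt$class, delta = tt$delta,
               tau = tt$tau, baseline = tt$baseline,
               stringsAsFactors = FALSE)
  }))
  list(records = records, truth = truth)
}

#' Simulate an expert panel's votes
#'
#' Each rater's vote is the ground-truth class flipped independently with
#' probability `flip_prob` — a simple noisy-rater model for exercising the
#' consensus and reliability machinery.
#'
#' @param truth character vector of `"stable"`/`"unstable"` classes (or a
#'   0/1 vector).
#' @param k number of raters (default 15).
#' @param flip_prob per-vote flip probability in \[0, 0.5).
#' @param seed integer RNG seed.
#' @param repeats also draw a second, independent session per rater.
#' @return A [rating_matrix()].
#' @export
generate_votes <- function(truth, k = 15, flip_prob = 0.1, seed = 1,
                           repeats = FALSE) {
  if (flip_prob < 0 || flip_prob >= 0.5)
    stop("flip_prob must be in [0, 0.5)", call. = FALSE)
  y <- if (is.character(truth)) as.integer(truth == "unstable") else as.integer(truth)
  n <- length(y)
  set.seed(seed)
  draw <- function() {
    flips <- matrix(stats::rbinom(n * k, 1, flip_prob), n, k)
    m <- (matrix(y, n, k) + flips) %% 2
    rownames(m) <- sprintf("s%04d", seq_len(n))
    colnames(m) <- sprintf("r%02d", seq_len(k))
    m
  }
  votes <- draw()
  rating_matrix(votes, repeats = if (repeats) draw() else NULL)
}

#' Archetype traces where threshold-based PIH definitions disagree with
#' hemodynamic instability
#'
#' Two discordant morphologies: `"slow_drift"` — a low-baseline patient
#' drifting slowly below the 65 mmHg MAP threshold, hypotensive by the
#' MAP < 65 rule but hemodynamically stable by construction; and
#' `"fast_drop"` — a hypertensive patient with a deep, fast decline that
#' never crosses 65 mmHg MAP, negative by the MAP < 65 rule yet unstable by
#' construction.
#'
#' @param type `"slow_drift"` or `"fast_drop"`.
#' @param seed integer RNG seed.
#' @return An [induction_record()] (no artifact beats).
#' @export
generate_archetype <- function(type = c("slow_drift", "fast_drop"), seed = 1) {
  type <- match.arg(type)
  if (type == "slow_drift") {
    cfg <- cohort_config(seed = seed, noise_sd = 1, drift_sd = 0,
                         baseline_sap = list(stable = c(105, 0),
                                             unstable = c(105, 0)),
                         drop = list(stable = c(30, 0), unstable = c(30, 0)),
                         tau = list(stable = c(300, 300),
                                    unstable = c(300, 300)),
                         rebound_prob = list(stable = 0, unstable = 0))
    generate_record(cfg, "stable", seed = seed,
                    patient_id = paste0("archetype-slow-drift-", seed),
                    artifacts = FALSE)
  } else {
    cfg <- cohort_config(seed = seed, noise_sd = 1, drift_sd = 0,
                         baseline_sap = list(stable = c(185, 0),
                                             unstable = c(185, 0)),
                         drop = list(stable = c(60, 0), unstable = c(60, 0)),
                         tau = list(stable = c(25, 25), unstable = c(25, 25)),
                         rebound_prob = list(stable = 0, unstable = 0))
    generate_record(cfg, "unstable", seed = seed,
                    patient_id = paste0("archetype-fast-drop-", seed),
                    artifacts = FALSE)
  }
}
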