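# Fixture builders and independent oracles used across the suite.

# A compliant record with regular beats every `dt` seconds around induction
# at t = 305 s, with constant or supplied pressures.
make_record <- function(sap = 120, map = 90, dap = 70, dt = 1,
                        hrs = NULL, id = "fix-1") {
  t <- seq(0.5, 1210, by = dt)
  n <- length(t)
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else x
  induction_record(id,
                   beat_series(t, rep_n(sap), rep_n(map), rep_n(dap),
                               hrs = if (is.null(hrs)) NULL else rep_n(hrs)),
                   t_induction = 305)
}

# A clean_signal built directly: values on the [-300, 900] grid; everything
# outside `t_keep` masked.
make_signal <- function(sap, map = 0.75 * sap, dap = 0.6 * sap,
                        t_keep = -300:900) {
  grid <- -300:900
  pick <- grid %in% t_keep
  expand <- function(x) {
    v <- rep(NA_real_, length(grid))
    v[pick] <- x
    v
  }
  structure(list(t = grid, sap = expand(sap), map = expand(map),
                 dap = expand(dap), pp = expand(sap - dap), mask = pick),
            class = "clean_signal")
}

# Brute-force ICC oracle: two-way ANOVA mean squares via stats::aov, then the
# McGraw-Wong estimator written out directly.
icc_oracle <- function(x, unit, definition) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  num <- MSR - MSE
  if (definition == "consistency") {
    if (unit == "single") num / (MSR + (k - 1) * MSE) else num / MSR
  } else {
    if (unit == "single") num / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
    else num / (MSR + (MSC - MSE) / n)
  }
}

# Pairwise-comparison AUROC oracle.
auroc_oracle <- function(scores, y01) {
  pos <- scores[y01 == 1]; neg <- scores[y01 == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
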