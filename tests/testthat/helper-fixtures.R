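# Fixtures built in code: tiny stacks and oracle (brute-force) statistics.

# stack whose intensity is `base` except `high` on the given frame indices;
# with the frame range chosen against the window edges this gives exact
# hand-computable windowed dF/F
step_stack <- function(h = 4, w = 5, n_frames = 40, frame_rate = 1.8,
                       base = 100, high = 110, high_frames = 22:30) {
  vals <- rep(base, n_frames)
  vals[high_frames] <- high
  fr <- array(rep(vals, each = h * w), c(h, w, n_frames))
  imaging_stack(fr, frame_rate_hz = frame_rate)
}

# O(n^2) transcription of the Fisher-Lee pairwise-sine formula on doubled
# angles; the independent oracle for circ_corr_axial
oracle_circ_corr <- function(a_deg, b_deg) {
  al <- 2 * a_deg * pi / 180
  be <- 2 * b_deg * pi / 180
  n <- length(al)
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      num <- num + sin(al[i] - al[j]) * sin(be[i] - be[j])
      da <- da + sin(al[i] - al[j])^2
      db <- db + sin(be[i] - be[j])^2
    }
  }
  num / sqrt(da * db)
}

# direct complex-sum oracles for the axial mean and variance
oracle_circ_mean <- function(a_deg, w = rep(1, length(a_deg))) {
  s <- sum(w * cos(2 * a_deg * pi / 180)) + 1i * sum(w * sin(2 * a_deg * pi / 180))
  ((Arg(s) / 2) * 180 / pi) %% 180
}
oracle_circ_var <- function(a_deg) {
  s <- sum(exp(2i * a_deg * pi / 180))
  1 - Mod(s) / length(a_deg)
}

# one-way ANOVA F and p via lm/anova, the reference route for the
# vectorised per-pixel computation
oracle_anova_p <- function(y, g) {
  stats::anova(stats::lm(y ~ factor(g)))[["Pr(>F)"]][1]
}

expect_angle_equal <- function(a, b, tol = 1e-9) {
  d <- abs(collimap::circ_diff_axial(a, b))
  expect_lt(max(d), tol)
}
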