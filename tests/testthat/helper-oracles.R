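# Independent oracles, deliberately coded differently from the package
# implementations they check.

# direct, loop-based evaluation of the per-cycle irregularity formula
oracle_is <- function(periods) {
  out <- numeric(length(periods) - 1L)
  for (n in 2:length(periods))
    out[n - 1L] <- 100 * abs(periods[n] - periods[n - 1L]) / periods[n - 1L]
  out
}

# two-sided signed-rank p by explicit expansion of every sign vector
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  mu <- sum(r) / 2
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# two-sided Mann-Whitney p by explicit enumeration of group labelings,
# with U computed from its pair-count definition
oracle_mwu_p <- function(a, b) {
  count_u <- function(g1, g2) sum(outer(g1, g2, ">"))
  u_obs <- count_u(a, b)
  pool <- c(a, b)
  n1 <- length(a)
  labelings <- combn(length(pool), n1)
  u_all <- apply(labelings, 2, function(ix) count_u(pool[ix], pool[-ix]))
  mu <- n1 * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# sensitivity / precision of detected peak times against truth
match_stats <- function(truth, detected, tol = 0.002) {
  d <- outer(detected, truth, function(a, b) abs(a - b))
  list(tp = sum(apply(d, 2, min) <= tol),
       fn = sum(apply(d, 2, min) > tol),
       fp = sum(apply(d, 1, min) > tol))
}

# fresh scratch directory for fixture files
withr_local_tempdir <- function() {
  d <- tempfile("ecgait_test_")
  dir.create(d)
  d
}

# straight-line trajectory fixture: `dist_cm` covered at constant speed
# over `dur_s`, sampled at `fps`
line_trajectory <- function(dist_cm, dur_s, fps = 100) {
  n_steps <- as.integer(dur_s * fps)
  s <- seq(0, dist_cm, length.out = n_steps + 1L)
  trajectory(0:n_steps, s, rep(0, n_steps + 1L), frame_rate = fps)
}
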