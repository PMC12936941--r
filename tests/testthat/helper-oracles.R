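# Independent oracles and fixture builders used across the suite. Every
# oracle is coded independently of the implementation path it checks.

# OLS by normal equations on the raw design matrix (independent of the
# package's centered-sums fit and of stats::lm).
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  fitted <- X %*% beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1L], slope = beta[2L],
       r2 = 1 - ss_res / ss_tot)
}

# textbook paired t-test
paired_t_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t_stat = t_stat, p_value = 2 * pt(-abs(t_stat), df = n - 1))
}

# Kruskal-Wallis with explicit rank sums and tie correction
kruskal_oracle <- function(groups) {
  v <- unlist(groups, use.names = FALSE)
  n <- length(v)
  r <- rank(v)
  idx <- rep(seq_along(groups), vapply(groups, length, 0L))
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / tapply(r, idx, length)) - 3 * (n + 1)
  ties <- table(v)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / correction
  list(H = H, p_value = pchisq(H, df = length(groups) - 1, lower.tail = FALSE))
}

# non-negative root of the steady-state quadratic in i_hat (units of K_M):
#   4 (A + lt)^2 i^2 - 4 (A + lt) (eps L - lt) i - 4 eps L (lt + A) = 0
# solved by a bracketed root-finder, independent of the closed form.
ihat_root_oracle <- function(L, lt, s, eps = 1, K_M = 1) {
  A <- 1 + s
  q <- function(i) {
    4 * (A + lt)^2 * i^2 - 4 * (A + lt) * (eps * L - lt) * i -
      4 * eps * L * (lt + A)
  }
  if (L == 0) return(0)
  hi <- 1
  while (q(hi) < 0) hi <- hi * 2
  K_M * uniroot(q, lower = 0, upper = hi, tol = 1e-14)$root
}

# closed-form critical relative leakage flux at fixed l_tilde: setting
# r = 1 gives i = K_M/s, and squaring the defining relation reduces to a
# linear equation in L.
critical_fixed_oracle <- function(s, lt, eps = 1) {
  A <- 1 + s
  cc <- (2 / s) * (A + lt)
  cc * (cc + 2 * lt) / (eps * (4 * A + 4 * lt + 2 * cc))
}

# exhaustive pixel enumeration over a bounding box (rasterization oracle)
raster_oracle <- function(cells, focal, radius_um, um_per_pixel) {
  fx <- cells$x_um[focal]; fy <- cells$y_um[focal]
  n_aux <- 0; n_all <- 0
  lo_x <- floor(min(cells$x_um) - 10); hi_x <- ceiling(max(cells$x_um) + 10)
  lo_y <- floor(min(cells$y_um) - 10); hi_y <- ceiling(max(cells$y_um) + 10)
  gx <- (seq(floor(lo_x / um_per_pixel),
             ceiling(hi_x / um_per_pixel)) + 0.5) * um_per_pixel
  gy <- (seq(floor(lo_y / um_per_pixel),
             ceiling(hi_y / um_per_pixel)) + 0.5) * um_per_pixel
  for (i in seq_len(nrow(cells))) {
    if (i == focal) next
    if (cells$shape[i] == "rect") {
      in_x <- gx >= cells$x_um[i] - cells$width_um[i] / 2 &
        gx <= cells$x_um[i] + cells$width_um[i] / 2
      in_y <- gy >= cells$y_um[i] - cells$height_um[i] / 2 &
        gy <= cells$y_um[i] + cells$height_um[i] / 2
      px <- rep(gx[in_x], times = sum(in_y))
      py <- rep(gy[in_y], each = sum(in_x))
    } else {
      px0 <- rep(gx, times = length(gy))
      py0 <- rep(gy, each = length(gx))
      keep <- (px0 - cells$x_um[i])^2 + (py0 - cells$y_um[i])^2 <=
        cells$radius_um[i]^2
      px <- px0[keep]; py <- py0[keep]
    }
    k <- sum((px - fx)^2 + (py - fy)^2 <= radius_um^2)
    n_all <- n_all + k
    if (cells$cell_type[i] == "AUX") n_aux <- n_aux + k
  }
  if (n_all == 0) return(NA_real_)
  n_aux / n_all
}

# build a minimal valid track-table data frame from per-track specs:
# each element of `specs` is list(track_id, cell_type, lengths, x, y)
make_tracks <- function(specs, replicate_id = "R1", chamber_id = "C1",
                        dt_h = 5 / 60) {
  rows <- lapply(specs, function(sp) {
    nf <- length(sp$lengths)
    data.frame(
      replicate_id = replicate_id, chamber_id = chamber_id,
      frame = seq_len(nf) - 1L, time_h = (seq_len(nf) - 1L) * dt_h,
      track_id = sp$track_id, cell_type = sp$cell_type,
      x_um = rep_len(sp$x %||% 20, nf), y_um = rep_len(sp$y %||% 20, nf),
      length_um = sp$lengths, area_um2 = sp$lengths * 1,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exponential-length track, optionally with multiplicative noise factors
exp_lengths <- function(mu, n_frames, l0 = 2, dt_h = 5 / 60,
                        noise = rep(1, n_frames)) {
  l0 * exp(mu * (seq_len(n_frames) - 1L) * dt_h) * noise
}

# single-frame cell layout for neighborhood tests
make_frame <- function(x, y, area, cell_type, replicate_id = "R1",
                       chamber_id = "C1") {
  n <- length(x)
  data.frame(replicate_id = replicate_id, chamber_id = chamber_id,
             frame = 0L, time_h = 0, track_id = seq_len(n),
             cell_type = cell_type, x_um = x, y_um = y,
             length_um = sqrt(area), area_um2 = area,
             stringsAsFactors = FALSE)
}
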