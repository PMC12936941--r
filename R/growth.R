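# Single-cell specific growth rates: track quality filters, log-linear
# fits of ln(length) vs time, and strain/replicate summaries.

#' Filter tracks before growth-rate fitting
#'
#' Applies, in order: (a) the jump filter -- a track is discarded entirely
#' if any consecutive-frame pair changes observed length by more than
#' `max_rel_length_change` relative to the earlier frame; (b) the
#' minimum-frames filter -- tracks with fewer than `min_frames` frames are
#' discarded. A track failing both rules is counted under (a).
#'
#' @param table a track table.
#' @param max_rel_length_change maximum |relative length change| between
#'   consecutive frames (default 0.15).
#' @param min_frames minimum number of consecutive frames (default 5).
#' @return list with `tracks` (the retained table) and `exclusions`
#'   (data frame counting tracks removed per rule).
#' @export
filter_tracks <- function(table, max_rel_length_change = 0.15,
                          min_frames = 5) {
  check_number(max_rel_length_change, "max_rel_length_change", positive = TRUE)
  check_number(min_frames, "min_frames", positive = TRUE)
  n <- nrow(table)
  log <- function(kept, n_jump, n_short) {
    list(tracks = kept,
         exclusions = data.frame(
           rule = c("length_jump", "min_frames"),
           n_tracks = c(n_jump, n_short),
           stringsAsFactors = FALSE))
  }
  if (n == 0L) return(log(table, 0L, 0L))
  trk <- .track_key(table)
  ord <- order(trk, table$frame)
  table <- table[ord, , drop = FALSE]
  trk <- trk[ord]
  new_track <- c(TRUE, trk[-1L] != trk[-n])
  grp <- cumsum(new_track)
  len <- table$length_um
  rel <- c(NA_real_, len[-1L] / len[-n] - 1)
  rel[new_track] <- NA_real_
  jump_row <- !is.na(rel) & abs(rel) > max_rel_length_change
  n_per_track <- tabulate(grp)
  jump_track <- tabulate(grp[jump_row], nbins = max(grp)) > 0L
  short_track <- n_per_track < min_frames
  drop_jump <- jump_track
  drop_short <- short_track & !jump_track
  keep_track <- !(drop_jump | drop_short)
  kept <- table[keep_track[grp], , drop = FALSE]
  rownames(kept) <- NULL
  log(kept, sum(drop_jump), sum(drop_short))
}

#' Fit a specific growth rate to one track
#'
#' Ordinary least-squares regression of `ln(length_um)` on `time_h` over
#' the full lifetime of the cell. The slope is the specific growth rate
#' (per hour, length as biomass proxy). `r2` is the coefficient of
#' determination; if the log-lengths have zero variance it is defined as 0
#' (such records then fail the downstream R^2 filter), and it is exactly 1
#' when the residuals vanish.
#'
#' @param time_h numeric vector of times (hours), or a single-track data
#'   frame with `time_h` and `length_um`.
#' @param length_um cell lengths (um), all > 0.
#' @return list with `mu_h`, `r2` and `n_frames`.
#' @export
fit_track_growth <- function(time_h, length_um = NULL) {
  if (is.data.frame(time_h)) {
    length_um <- time_h$length_um
    time_h <- time_h$time_h
  }
  n <- length(time_h)
  if (n < 2L) stop("growth fit needs at least 2 frames", call. = FALSE)
  if (any(!is.finite(length_um)) || any(length_um <= 0)) {
    stop("all lengths must be positive and finite", call. = FALSE)
  }
  y <- log(length_um)
  tc <- time_h - mean(time_h)
  yc <- y - mean(y)
  sxx <- sum(tc^2)
  syy <- sum(yc^2)
  sxy <- sum(tc * yc)
  if (sxx == 0) stop("times must not be constant", call. = FALSE)
  mu <- sxy / sxx
  if (syy == 0) {
    r2 <- 0
  } else {
    ss_res <- syy - sxy^2 / sxx
    r2 <- if (ss_res <= 1e-14 * syy) 1 else min(1, sxy^2 / (sxx * syy))
  }
  list(mu_h = mu, r2 = r2, n_frames = n)
}

# Vectorized grouped OLS over all tracks of a (pre-filtered) table.
.fit_all_tracks <- function(table) {
  trk <- .track_key(table)
  ord <- order(trk, table$frame)
  table <- table[ord, , drop = FALSE]
  trk <- trk[ord]
  grp <- match(trk, unique(trk))
  t_ <- table$time_h
  y <- log(table$length_um)
  n <- tabulate(grp)
  # two-pass centered sums: numerically equivalent to per-track OLS
  tc <- t_ - (as.numeric(rowsum(t_, grp)) / n)[grp]
  yc <- y - (as.numeric(rowsum(y, grp)) / n)[grp]
  sxx <- as.numeric(rowsum(tc * tc, grp))
  syy_c <- as.numeric(rowsum(yc * yc, grp))
  sxy <- as.numeric(rowsum(tc * yc, grp))
  mu <- sxy / sxx
  r2 <- ifelse(syy_c <= 0, 0, pmin(1, sxy^2 / (sxx * syy_c)))
  ss_res <- syy_c - sxy^2 / sxx
  r2[syy_c > 0 & ss_res <= 1e-14 * syy_c] <- 1
  first <- which(c(TRUE, trk[-1L] != trk[-length(trk)]))
  data.frame(
    replicate_id = table$replicate_id[first],
    chamber_id = table$chamber_id[first],
    track_id = table$track_id[first],
    cell_type = table$cell_type[first],
    mu_h = mu,
    r2 = r2,
    n_frames = n,
    mean_x_um = as.numeric(rowsum(table$x_um, grp)) / n,
    mean_y_um = as.numeric(rowsum(table$y_um, grp)) / n,
    stringsAsFactors = FALSE
  )
}

#' Apply the goodness-of-fit filter
#'
#' Keeps growth records with `r2` strictly greater than the threshold
#' (a record at exactly the threshold is removed).
#'
#' @param records growth-record data frame with an `r2` column.
#' @param min_r2 threshold (default 0.8).
#' @return the filtered records.
#' @export
apply_r2_filter <- function(records, min_r2 = 0.8) {
  stopifnot(is.data.frame(records), "r2" %in% names(records))
  out <- records[records$r2 > min_r2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate growth rates for every track in a table
#'
#' Full estimation stage: jump filter, minimum-frames filter, per-track
#' log-linear fit, then the strict R^2 filter. The exclusion log counts
#' tracks removed by each rule in application order.
#'
#' @param table a track table.
#' @param config a run configuration ([default_config()]); its `filters`
#'   block supplies the thresholds.
#' @return list with `records` (one row per retained track: `mu_h`, `r2`,
#'   `n_frames`, lifetime-mean centroid) and `exclusions`.
#' @export
estimate_growth_rates <- function(table, config = default_config()) {
  f <- config$filters
  flt <- filter_tracks(table, f$max_rel_length_change, f$min_frames)
  if (nrow(flt$tracks) == 0L) {
    rec <- data.frame(replicate_id = character(0), chamber_id = character(0),
                      track_id = integer(0), cell_type = character(0),
                      mu_h = numeric(0), r2 = numeric(0),
                      n_frames = integer(0), mean_x_um = numeric(0),
                      mean_y_um = numeric(0), stringsAsFactors = FALSE)
  } else {
    rec <- .fit_all_tracks(flt$tracks)
  }
  n_before <- nrow(rec)
  rec2 <- apply_r2_filter(rec, f$min_r2)
  excl <- rbind(flt$exclusions,
                data.frame(rule = "r2", n_tracks = n_before - nrow(rec2),
                           stringsAsFactors = FALSE))
  list(records = rec2, exclusions = excl)
}

#' Doubling time in minutes
#'
#' Converts a specific growth rate (/h) to a doubling time,
#' `60 * ln(2) / mu_h` minutes.
#'
#' @param mu_h specific growth rate(s), all > 0.
#' @return doubling time(s) in minutes.
#' @export
doubling_time_min <- function(mu_h) {
  if (!is.numeric(mu_h) || any(!is.finite(mu_h)) || any(mu_h <= 0)) {
    stop("mu_h must be > 0", call. = FALSE)
  }
  60 * log(2) / mu_h
}

#' Summarize growth rates by replicate and strain
#'
#' Arithmetic mean, SEM (`sd/sqrt(n)`; reported as `NA` with a warning for
#' single-record groups) and count per (replicate, cell type), plus pooled
#' rows over all cells per cell type (`replicate_id = "pooled"`).
#'
#' @param records growth-record data frame.
#' @return data frame with `replicate_id`, `cell_type`, `mean_mu_h`,
#'   `sem_mu_h`, `n`.
#' @export
summarize_growth <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("replicate_id", "cell_type", "mu_h") %in% names(records)))
  if (nrow(records) == 0L) {
    warning("no growth records to summarize")
    return(data.frame(replicate_id = character(0), cell_type = character(0),
                      mean_mu_h = numeric(0), sem_mu_h = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE))
  }
  one <- function(df, label) {
    n <- nrow(df)
    sem <- if (n < 2L) NA_real_ else stats::sd(df$mu_h) / sqrt(n)
    data.frame(replicate_id = label, cell_type = df$cell_type[1L],
               mean_mu_h = mean(df$mu_h), sem_mu_h = sem, n = n,
               stringsAsFactors = FALSE)
  }
  parts <- list()
  for (ct in sort(unique(records$cell_type))) {
    sub <- records[records$cell_type == ct, , drop = FALSE]
    for (r in sort(unique(sub$replicate_id))) {
      g <- sub[sub$replicate_id == r, , drop = FALSE]
      if (nrow(g) == 1L) {
        warning(sprintf("group (%s, %s) has a single record; SEM undefined",
                        r, ct))
      }
      parts[[length(parts) + 1L]] <- one(g, r)
    }
    parts[[length(parts) + 1L]] <- one(sub, "pooled")
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
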