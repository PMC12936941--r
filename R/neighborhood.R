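# Local neighborhood composition: auxotroph area fraction within a
# circular neighborhood around each focal cell, and the rank-correlation /
# permutation statistics linking composition to growth.

# Area-weighted auxotroph fraction for focal cells of one frame.
# Centroid rule: a neighbor contributes its full area iff its centroid
# lies within `radius_um` of the focal centroid; the focal cell itself is
# excluded. NA where no neighbor qualifies. `focal` restricts the focal
# cells (all cells remain neighbors); results align with `focal`.
.frame_aux_fraction <- function(x, y, area, is_aux, radius_um,
                                focal = NULL) {
  n <- length(x)
  if (is.null(focal)) focal <- seq_len(n)
  m <- length(focal)
  if (m == 0L) {
    return(list(fraction = numeric(0), n_neighbors = integer(0)))
  }
  if (n <= 1L) {
    return(list(fraction = rep(NA_real_, m), n_neighbors = rep(0L, m)))
  }
  # pairwise squared distances via the Gram matrix:
  # |p_i - p_j|^2 = sq_i + sq_j - 2 <p_i, p_j>
  P <- cbind(x, y)
  G <- P[focal, , drop = FALSE] %*% t(P)       # m x n inner products
  sq <- x * x + y * y
  A <- (sq[focal] - radius_um^2) - 2 * G       # adds sq_i along rows
  inside <- t(t(A) + sq) <= 0                  # adds sq_j per column
  inside[cbind(seq_len(m), focal)] <- FALSE    # exclude the focal cell
  storage.mode(inside) <- "double"
  S <- inside %*% cbind(area, area * is_aux, 1)
  frac <- ifelse(S[, 1L] > 0, S[, 2L] / S[, 1L], NA_real_)
  list(fraction = frac, n_neighbors = as.integer(S[, 3L]))
}

#' Local auxotroph area fraction of one focal cell
#'
#' Fraction of neighbor cell area belonging to auxotrophs within a
#' circular neighborhood centered on the focal cell's centroid at one
#' frame, excluding the focal cell itself. A neighbor counts (with its
#' full area) iff its centroid lies within the radius.
#'
#' @param table a track table.
#' @param frame frame number.
#' @param track_id focal track id.
#' @param radius_um neighborhood radius (default 5).
#' @param replicate_id,chamber_id restrict to one chamber; may be omitted
#'   if the table holds a single chamber.
#' @return the fraction in \[0, 1\], or `NA` if no neighbor qualifies.
#' @export
local_aux_fraction <- function(table, frame, track_id, radius_um = 5,
                               replicate_id = NULL, chamber_id = NULL) {
  check_number(radius_um, "radius_um", positive = TRUE)
  sub <- table
  if (!is.null(replicate_id)) sub <- sub[sub$replicate_id == replicate_id, ]
  if (!is.null(chamber_id)) sub <- sub[sub$chamber_id == chamber_id, ]
  if (length(unique(paste(sub$replicate_id, sub$chamber_id))) > 1L) {
    stop("table spans several chambers; supply replicate_id/chamber_id",
         call. = FALSE)
  }
  sub <- sub[sub$frame == frame, , drop = FALSE]
  focal <- which(sub$track_id == track_id)
  if (length(focal) != 1L) {
    stop(sprintf("focal track %s not present at frame %s", track_id, frame),
         call. = FALSE)
  }
  res <- .frame_aux_fraction(sub$x_um, sub$y_um, sub$area_um2,
                             sub$cell_type == "AUX", radius_um)
  res$fraction[focal]
}

#' Rasterized auxotroph area fraction
#'
#' Pixel-area variant of the neighborhood rule for cells given as simple
#' shapes on a pixel grid: neighbor pixels whose centers fall inside the
#' circular neighborhood are counted, and the fraction is auxotroph pixels
#' over all neighbor pixels. Shapes are axis-aligned rectangles
#' (`shape = "rect"`, `width_um` x `height_um`) or discs
#' (`shape = "disc"`, `radius_um` column), centered on (`x_um`, `y_um`).
#'
#' @param cells data frame with `x_um`, `y_um`, `cell_type`, `shape` and
#'   the shape-size columns described above.
#' @param focal row index of the focal cell (excluded from the count).
#' @param radius_um neighborhood radius around the focal centroid.
#' @param um_per_pixel pixel size (default 0.065 um).
#' @return fraction in \[0, 1\], or `NA` if no neighbor pixel qualifies.
#' @export
rasterized_aux_fraction <- function(cells, focal, radius_um,
                                    um_per_pixel = 0.065) {
  check_number(radius_um, "radius_um", positive = TRUE)
  check_number(um_per_pixel, "um_per_pixel", positive = TRUE)
  stopifnot(is.data.frame(cells), focal >= 1, focal <= nrow(cells))
  fx <- cells$x_um[focal]
  fy <- cells$y_um[focal]
  n_aux <- 0; n_all <- 0
  for (i in seq_len(nrow(cells))) {
    if (i == focal) next
    if (cells$shape[i] == "rect") {
      hw <- cells$width_um[i] / 2
      hh <- cells$height_um[i] / 2
      if (hw <= 0 || hh <= 0) stop("zero-area shape", call. = FALSE)
      xs <- .pixel_centers(cells$x_um[i] - hw, cells$x_um[i] + hw, um_per_pixel)
      ys <- .pixel_centers(cells$y_um[i] - hh, cells$y_um[i] + hh, um_per_pixel)
      px <- rep(xs, times = length(ys))
      py <- rep(ys, each = length(xs))
    } else if (cells$shape[i] == "disc") {
      r <- cells$radius_um[i]
      if (r <= 0) stop("zero-area shape", call. = FALSE)
      xs <- .pixel_centers(cells$x_um[i] - r, cells$x_um[i] + r, um_per_pixel)
      ys <- .pixel_centers(cells$y_um[i] - r, cells$y_um[i] + r, um_per_pixel)
      px <- rep(xs, times = length(ys))
      py <- rep(ys, each = length(xs))
      inside_shape <- (px - cells$x_um[i])^2 + (py - cells$y_um[i])^2 <= r^2
      px <- px[inside_shape]; py <- py[inside_shape]
    } else {
      stop(sprintf("unknown shape '%s'", cells$shape[i]), call. = FALSE)
    }
    if (length(px) == 0L) stop("zero-area shape at pixel resolution",
                               call. = FALSE)
    k <- sum((px - fx)^2 + (py - fy)^2 <= radius_um^2)
    n_all <- n_all + k
    if (cells$cell_type[i] == "AUX") n_aux <- n_aux + k
  }
  if (n_all == 0) return(NA_real_)
  n_aux / n_all
}

# centers of grid pixels overlapping [lo, hi] on a global grid anchored at 0
.pixel_centers <- function(lo, hi, um_per_pixel) {
  i0 <- floor(lo / um_per_pixel)
  i1 <- ceiling(hi / um_per_pixel) - 1
  if (i1 < i0) i1 <- i0
  centers <- (seq.int(i0, i1) + 0.5) * um_per_pixel
  centers[centers >= lo & centers <= hi]
}

#' Lifetime-mean neighborhood composition per track
#'
#' For every track, the per-frame local auxotroph area fraction (centroid
#' rule, see [local_aux_fraction()]) averaged over the track's frames;
#' frames with no qualifying neighbor are skipped. Growth rate is a
#' track-level quantity, so this lifetime mean is the default covariate
#' paired with it.
#'
#' @param table a track table.
#' @param radius_um neighborhood radius (default 5).
#' @param cell_types restrict focal cells to these types (e.g. `"AUX"`);
#'   all cells still count as neighbors. Default: records for all tracks.
#' @return data frame with one row per (focal) track: `replicate_id`,
#'   `chamber_id`, `track_id`, `cell_type`, `radius_um`, `aux_fraction`
#'   (`NA` if undefined at every frame), `n_neighbor_cells` (lifetime-mean
#'   neighbor count) and `n_frames_defined`.
#' @export
lifetime_fraction <- function(table, radius_um = 5, cell_types = NULL) {
  check_number(radius_um, "radius_um", positive = TRUE)
  chamber <- paste(table$replicate_id, table$chamber_id, sep = "\r")
  focal_row <- if (is.null(cell_types)) rep(TRUE, nrow(table)) else
    table$cell_type %in% cell_types
  frac <- rep(NA_real_, nrow(table))
  nn <- rep(NA_integer_, nrow(table))
  for (ch in unique(chamber)) {
    rows_ch <- which(chamber == ch)
    by_frame <- split(rows_ch, table$frame[rows_ch])
    for (rows in by_frame) {
      focal <- which(focal_row[rows])
      if (length(focal) == 0L) next
      res <- .frame_aux_fraction(table$x_um[rows], table$y_um[rows],
                                 table$area_um2[rows],
                                 table$cell_type[rows] == "AUX", radius_um,
                                 focal = focal)
      frac[rows[focal]] <- res$fraction
      nn[rows[focal]] <- res$n_neighbors
    }
  }
  table <- table[focal_row, , drop = FALSE]
  frac <- frac[focal_row]
  nn <- nn[focal_row]
  trk <- .track_key(table)
  grp <- match(trk, unique(trk))
  first <- which(!duplicated(grp))
  def <- !is.na(frac)
  n_def <- as.numeric(rowsum((def) * 1, grp))
  sum_f <- as.numeric(rowsum(ifelse(def, frac, 0), grp))
  mean_nn <- as.numeric(rowsum(as.numeric(nn), grp)) / tabulate(grp)
  out <- data.frame(
    replicate_id = table$replicate_id[first],
    chamber_id = table$chamber_id[first],
    track_id = table$track_id[first],
    cell_type = table$cell_type[first],
    radius_um = radius_um,
    aux_fraction = ifelse(n_def > 0, sum_f / pmax(n_def, 1), NA_real_),
    n_neighbor_cells = mean_nn,
    n_frames_defined = as.integer(n_def),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation (tie-corrected)
#'
#' Pearson correlation of mid-ranks, the tie-corrected form of Spearman's
#' rho.
#'
#' @param x,y paired numeric vectors, at least 3 finite pairs.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need at least 3 finite pairs", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  rx <- rank(x); ry <- rank(y)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  vx <- sum(rxc^2); vy <- sum(ryc^2)
  if (vx == 0 || vy == 0) {
    stop("rank variance is zero; correlation undefined", call. = FALSE)
  }
  sum(rxc * ryc) / sqrt(vx * vy)
}

#' Permutation test for Spearman's rho
#'
#' Shuffles `y` against `x` `n_perm` times under the given seed and
#' reports the fraction of permutations whose correlation is equal to or
#' more extreme than the observed one (two-sided via |rho| by default).
#' The plain fraction is reported, so the resolution floor is
#' `1/n_perm` (a p of 0 means "less than 1/n_perm").
#'
#' @param x,y paired numeric vectors.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed (mandatory; the test is deterministic given it).
#' @param sided `"two"` (|rho|, default), `"less"` or `"greater"`.
#' @return list with `rho_obs`, `p_value`, `n`, `n_perm`.
#' @export
permutation_pvalue <- function(x, y, n_perm = 10000, seed,
                               sided = c("two", "less", "greater")) {
  sided <- match.arg(sided)
  check_number(n_perm, "n_perm", positive = TRUE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  rho_obs <- spearman_rho(x, y)
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(rxc * ryc[sample.int(n)]),
           numeric(1))
  }) / denom
  eps <- 1e-12   # count fp-equal permutations as "equal or more extreme"
  p <- switch(sided,
              two = mean(abs(perm) >= abs(rho_obs) - eps),
              less = mean(perm <= rho_obs + eps),
              greater = mean(perm >= rho_obs - eps))
  list(rho_obs = rho_obs, p_value = p, n = n, n_perm = as.integer(n_perm))
}

#' Correlation between growth and neighborhood composition across radii
#'
#' For each radius and cell type: Spearman's rho between the fitted growth
#' rates and the lifetime-mean local auxotroph fraction, with a
#' permutation p-value. Cells are pooled across replicates by default
#' (per-replicate correlations can be obtained by subsetting the inputs).
#' Records whose fraction is undefined (no neighbors at any frame) are
#' dropped, with counts reported.
#'
#' @param records growth-record data frame (see [estimate_growth_rates()]).
#' @param table the track table the records were fitted from.
#' @param radii_um distinct neighborhood radii (default `c(5, 9, 13)`).
#' @param n_perm permutations per test (default 10000).
#' @param seed integer seed.
#' @return data frame with `radius_um`, `cell_type`, `rho`, `p_value`,
#'   `n`, `n_dropped`.
#' @export
radius_sweep <- function(records, table, radii_um = c(5, 9, 13),
                         n_perm = 10000, seed = 1L) {
  if (anyDuplicated(radii_um)) stop("radii must be distinct", call. = FALSE)
  if (any(radii_um <= 0)) stop("radii must be positive", call. = FALSE)
  out <- list()
  seed_i <- 0L
  for (r in radii_um) {
    nf <- lifetime_fraction(table, radius_um = r)
    m <- merge(records,
               nf[c("replicate_id", "chamber_id", "track_id", "aux_fraction")],
               by = c("replicate_id", "chamber_id", "track_id"))
    for (ct in sort(unique(m$cell_type))) {
      sub <- m[m$cell_type == ct, , drop = FALSE]
      defined <- is.finite(sub$aux_fraction)
      seed_i <- seed_i + 1L
      if (sum(defined) < 3L) next
      pt <- tryCatch(
        permutation_pvalue(sub$aux_fraction[defined], sub$mu_h[defined],
                           n_perm = n_perm, seed = seed + seed_i),
        error = function(e) NULL)
      if (is.null(pt)) next
      out[[length(out) + 1L]] <- data.frame(
        radius_um = r, cell_type = ct, rho = pt$rho_obs,
        p_value = pt$p_value, n = pt$n, n_dropped = sum(!defined),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(radius_um = numeric(0), cell_type = character(0),
               rho = numeric(0), p_value = numeric(0), n = integer(0),
               n_dropped = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Bin growth rates by local auxotroph fraction
#'
#' Visualization summary only (inference always uses the continuous data):
#' growth-rate median and IQR per bin of the local fraction, with either
#' `k` equal-width bins on \[0, 1\] or bins at the empirical quartiles.
#'
#' @param fraction local auxotroph fractions.
#' @param mu_h paired growth rates.
#' @param mode `"fixed_width"` or `"quartile"`.
#' @param k number of bins (default 4).
#' @return data frame with bin edges, `n`, `median`, `q1`, `q3`.
#' @export
bin_growth_by_fraction <- function(fraction, mu_h,
                                   mode = c("fixed_width", "quartile"),
                                   k = 4) {
  mode <- match.arg(mode)
  check_number(k, "k", positive = TRUE)
  ok <- is.finite(fraction) & is.finite(mu_h)
  fraction <- fraction[ok]; mu_h <- mu_h[ok]
  if (mode == "quartile") {
    if (length(fraction) < k) stop("need at least k records", call. = FALSE)
    if (length(unique(fraction)) == 1L) {
      stop("all fractions identical; quartile bins undefined", call. = FALSE)
    }
    edges <- unique(stats::quantile(fraction, probs = seq(0, 1, length.out = k + 1),
                                    names = FALSE, type = 7))
  } else {
    edges <- seq(0, 1, length.out = k + 1)
  }
  bin <- cut(fraction, breaks = edges, include.lowest = TRUE)
  out <- do.call(rbind, lapply(seq_along(levels(bin)), function(b) {
    v <- mu_h[as.integer(bin) == b]
    data.frame(bin = levels(bin)[b],
               lo = edges[b], hi = edges[b + 1L], n = length(v),
               median = if (length(v)) stats::median(v) else NA_real_,
               q1 = if (length(v)) stats::quantile(v, 0.25, names = FALSE) else NA_real_,
               q3 = if (length(v)) stats::quantile(v, 0.75, names = FALSE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
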