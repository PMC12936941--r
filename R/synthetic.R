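# Synthetic chamber generator: emulates time-lapse tracking tables from
# monolayer growth chambers seeded with ~90% wildtype / ~10% auxotroph
# cells, so every downstream stage is testable without imaging data.
#
# Geometry: the chamber is a 2D monolayer discretized into vertical lanes
# of one cell width. Cells in a lane are stacked from the closed back wall
# (y = side) toward the open side (y = 0) that faces the main feeding
# channel. As cells grow and divide the stack lengthens and cells are
# pushed toward the open side, where they are washed out -- a simple
# shoving rule (an explicit invention; it reproduces boundary retention
# qualitatively, not cell mechanics).

#' Synthetic-generator configuration
#'
#' Defaults mirror the experimental conditions the analysis assumes:
#' 40 um chambers, ~10% auxotroph seeding, 5-minute frames over 12 h,
#' wildtype rate 0.70 /h, five replicates, and an 8 um exclusion strip
#' next to the open side. The growth-coupling rule for auxotrophs is
#' either `"linear"` -- relative rate `g(f) = max(0, r0 + beta * f)` in
#' the local auxotroph area fraction `f`, with `r0 = 0.23/0.70` so the
#' zero-cluster rate echoes the observed regime -- or `"model"`, where
#' `g(f)` is the leakage/uptake model's relative growth rate with the
#' wildtype leakage flux scaled by the local wildtype fraction `(1 - f)`.
#'
#' @param chamber_side_um chamber side length (um).
#' @param aux_seed_fraction probability a seeded cell is an auxotroph.
#' @param n_initial_cells number of seeded cells.
#' @param mu_wt_h wildtype specific growth rate (/h).
#' @param coupling_mode `"linear"` or `"model"`.
#' @param r0 linear mode: auxotroph relative rate at `f = 0`.
#' @param beta linear mode: change in relative rate per unit `f`
#'   (negative in the amino-acid-limited regime).
#' @param model model mode: list with shared leakage rate `l` (/h),
#'   `mu_max_aux`, `epsilon`, `K_M`, `I_C_factor`.
#' @param division_length_um length at which a cell divides.
#' @param birth_length_um minimum seeded cell length.
#' @param length_noise_cv coefficient of variation of multiplicative
#'   (lognormal) length measurement noise.
#' @param jump_probability per-frame probability of a spurious observed
#'   length jump; the jump factor is drawn uniformly from [1.16, 1.5]
#'   with a random sign of the exponent, i.e. always outside +/-15%.
#' @param washout remove cells pushed beyond the open boundary.
#' @param duration_h experiment duration (h).
#' @param frame_interval_min imaging interval (min).
#' @param n_replicates number of biological replicates.
#' @param n_chambers chambers generated per replicate.
#' @param replicate_sd_h between-replicate SD of the wildtype rate (/h).
#' @param exclusion_margin_um strip next to the open side dropped from the
#'   output, as in the image analysis.
#' @param cell_width_um rod width; area = length x width.
#' @param lateral_slip_prob probability that the front daughter of a
#'   division slips into an adjacent lane, letting lineage clusters
#'   spread sideways.
#' @param neighborhood_radius_um radius of the local-composition rule used
#'   by the growth coupling (the analyzer's 5 um centroid rule, so
#'   generator and analyzer agree by construction).
#' @return a validated list with class `synthetic_config`.
#' @export
synthetic_config <- function(chamber_side_um = 40,
                             aux_seed_fraction = 0.10,
                             n_initial_cells = 60L,
                             mu_wt_h = 0.70,
                             coupling_mode = c("linear", "model"),
                             r0 = 0.23 / 0.70,
                             beta = -0.3,
                             model = list(l = 0.004, mu_max_aux = 0.90,
                                          epsilon = 1, K_M = 1,
                                          I_C_factor = 20),
                             division_length_um = 4.0,
                             birth_length_um = 2.0,
                             length_noise_cv = 0.02,
                             jump_probability = 0.005,
                             washout = TRUE,
                             duration_h = 12,
                             frame_interval_min = 5,
                             n_replicates = 5L,
                             n_chambers = 5L,
                             replicate_sd_h = 0.01,
                             exclusion_margin_um = 8,
                             cell_width_um = 1,
                             lateral_slip_prob = 0.2,
                             neighborhood_radius_um = 5) {
  cfg <- list(
    chamber_side_um = chamber_side_um,
    aux_seed_fraction = aux_seed_fraction,
    n_initial_cells = as.integer(n_initial_cells),
    mu_wt_h = mu_wt_h,
    coupling_mode = match.arg(coupling_mode),
    r0 = r0,
    beta = beta,
    model = model,
    division_length_um = division_length_um,
    birth_length_um = birth_length_um,
    length_noise_cv = length_noise_cv,
    jump_probability = jump_probability,
    washout = isTRUE(washout),
    duration_h = duration_h,
    frame_interval_min = frame_interval_min,
    n_replicates = as.integer(n_replicates),
    n_chambers = as.integer(n_chambers),
    replicate_sd_h = replicate_sd_h,
    exclusion_margin_um = exclusion_margin_um,
    cell_width_um = cell_width_um,
    lateral_slip_prob = lateral_slip_prob,
    neighborhood_radius_um = neighborhood_radius_um
  )
  validate_synthetic_config(cfg)
}

#' @rdname synthetic_config
#' @param cfg a synthetic configuration list to validate.
#' @export
validate_synthetic_config <- function(cfg) {
  if (inherits(cfg, "synthetic_config")) return(cfg)
  check_number(cfg$chamber_side_um, "chamber_side_um", positive = TRUE)
  check_number(cfg$aux_seed_fraction, "aux_seed_fraction", nonneg = TRUE)
  if (cfg$aux_seed_fraction > 1) {
    stop("config error: aux_seed_fraction must be in [0, 1]", call. = FALSE)
  }
  check_number(cfg$n_initial_cells, "n_initial_cells", positive = TRUE)
  check_number(cfg$mu_wt_h, "mu_wt_h", nonneg = TRUE)
  if (!cfg$coupling_mode %in% c("linear", "model")) {
    stop("config error: coupling_mode must be 'linear' or 'model'", call. = FALSE)
  }
  if (!(cfg$division_length_um > cfg$birth_length_um &&
          cfg$birth_length_um > 0)) {
    stop("config error: need division_length_um > birth_length_um > 0",
         call. = FALSE)
  }
  check_number(cfg$length_noise_cv, "length_noise_cv", nonneg = TRUE)
  check_number(cfg$jump_probability, "jump_probability", nonneg = TRUE)
  check_number(cfg$duration_h, "duration_h", positive = TRUE)
  check_number(cfg$frame_interval_min, "frame_interval_min", positive = TRUE)
  check_number(cfg$n_replicates, "n_replicates", positive = TRUE)
  check_number(cfg$n_chambers, "n_chambers", positive = TRUE)
  check_number(cfg$replicate_sd_h, "replicate_sd_h", nonneg = TRUE)
  check_number(cfg$exclusion_margin_um, "exclusion_margin_um", nonneg = TRUE)
  check_number(cfg$cell_width_um, "cell_width_um", positive = TRUE)
  check_number(cfg$lateral_slip_prob, "lateral_slip_prob", nonneg = TRUE)
  check_number(cfg$neighborhood_radius_um, "neighborhood_radius_um",
               positive = TRUE)
  if (cfg$coupling_mode == "model") {
    m <- cfg$model
    check_number(m$l, "model$l", nonneg = TRUE)
    check_number(m$mu_max_aux, "model$mu_max_aux", positive = TRUE)
  }
  class(cfg) <- c("synthetic_config", "list")
  cfg
}

# Core engine; consumes the *current* RNG stream (callers seed it).
# Returns list(tracks = per-frame rows, truth = per-track true mean rates).
.simulate_chamber <- function(cfg, replicate_id, chamber_id, mu_offset = 0) {
  dt_h <- cfg$frame_interval_min / 60
  n_frames <- as.integer(round(cfg$duration_h * 60 / cfg$frame_interval_min)) + 1L
  side <- cfg$chamber_side_um
  width <- cfg$cell_width_um
  n_lanes <- max(1L, as.integer(floor(side / width)))
  mu_wt <- cfg$mu_wt_h + mu_offset
  sdlog <- if (cfg$length_noise_cv > 0) {
    sqrt(log(1 + cfg$length_noise_cv^2))
  } else 0
  radius <- cfg$neighborhood_radius_um

  if (cfg$coupling_mode == "model") {
    m <- cfg$model
    s <- fitness_benefit(m$mu_max_aux, mu_wt)
    l_tilde <- m$l / m$mu_max_aux
    L0 <- m$l * m$I_C_factor / mu_wt
    aux_rate <- function(f) {
      i_hat <- internal_concentration(L0 * (1 - f), l_tilde, s,
                                      epsilon = m$epsilon, K_M = m$K_M)
      mu_wt * (1 + s) * i_hat / (m$K_M + i_hat)
    }
  } else {
    aux_rate <- function(f) mu_wt * pmax(0, cfg$r0 + cfg$beta * f)
  }

  # seed cells: random lanes, stacked insertion order, Bernoulli types
  n0 <- cfg$n_initial_cells
  is_aux0 <- stats::runif(n0) < cfg$aux_seed_fraction
  len0 <- stats::runif(n0, cfg$birth_length_um, cfg$division_length_um)
  lane0 <- sample.int(n_lanes, n0, replace = TRUE)
  lanes <- vector("list", n_lanes)
  for (k in seq_len(n_lanes)) {
    in_k <- which(lane0 == k)
    lanes[[k]] <- list(id = in_k, aux = is_aux0[in_k], len = len0[in_k])
  }
  next_id <- n0 + 1L

  rec <- vector("list", n_frames)
  for (fr in seq_len(n_frames) - 1L) {
    sizes <- vapply(lanes, function(l) length(l$id), 0L)
    if (sum(sizes) == 0L) break
    lane_idx <- rep.int(seq_len(n_lanes), sizes)
    len <- unlist(lapply(lanes, `[[`, "len"), use.names = FALSE)
    id <- unlist(lapply(lanes, `[[`, "id"), use.names = FALSE)
    aux <- unlist(lapply(lanes, `[[`, "aux"), use.names = FALSE)
    cum <- unlist(lapply(lanes, function(l) cumsum(l$len)), use.names = FALSE)
    y <- side - (cum - len / 2)
    x <- (lane_idx - 0.5) * width

    if (cfg$washout && any(y < 0)) {
      keep <- y >= 0
      for (k in unique(lane_idx[!keep])) {
        m_k <- keep[lane_idx == k]
        lanes[[k]] <- list(id = lanes[[k]]$id[m_k], aux = lanes[[k]]$aux[m_k],
                           len = lanes[[k]]$len[m_k])
      }
      lane_idx <- lane_idx[keep]; len <- len[keep]; id <- id[keep]
      aux <- aux[keep]; y <- y[keep]; x <- x[keep]
      if (length(id) == 0L) break
    }
    n <- length(id)

    # local auxotroph area fraction (analyzer's centroid rule), needed
    # only for auxotroph cells; an isolated cell sees no auxotrophs (f=0)
    mu <- rep.int(mu_wt, n)
    aux_idx <- which(aux)
    if (length(aux_idx) > 0L) {
      f <- .frame_aux_fraction(x, y, len * width, aux, radius,
                               focal = aux_idx)$fraction
      f[is.na(f)] <- 0
      mu[aux_idx] <- aux_rate(f)
    }

    obs <- len * if (sdlog > 0) exp(stats::rnorm(n, 0, sdlog)) else 1
    if (cfg$jump_probability > 0) {
      j <- which(stats::runif(n) < cfg$jump_probability)
      if (length(j) > 0L) {
        fac <- stats::runif(length(j), 1.16, 1.5)
        expo <- sample(c(-1, 1), length(j), replace = TRUE)
        obs[j] <- obs[j] * fac^expo
      }
    }
    rec[[fr + 1L]] <- list(frame = rep.int(fr, n), id = id, aux = aux,
                           x = x, y = y, obs = obs, mu = mu)
    if (fr == n_frames - 1L) break

    len_new <- len * exp(mu * dt_h)

    # write back grown lengths and process divisions lane by lane
    pending <- list()   # slipped daughters to insert into adjacent lanes
    offset <- 0L
    for (k in seq_len(n_lanes)) {
      nk <- sum(lane_idx == k)
      if (nk == 0L) next
      idx <- which(lane_idx == k)
      lens_k <- len_new[idx]
      ids_k <- id[idx]
      aux_k <- aux[idx]
      div <- lens_k >= cfg$division_length_um
      if (!any(div)) {
        lanes[[k]] <- list(id = ids_k, aux = aux_k, len = lens_k)
        next
      }
      new_id <- integer(0); new_aux <- logical(0); new_len <- numeric(0)
      for (i in seq_len(nk)) {
        if (!div[i]) {
          new_id <- c(new_id, ids_k[i])
          new_aux <- c(new_aux, aux_k[i])
          new_len <- c(new_len, lens_k[i])
        } else {
          half <- lens_k[i] / 2
          d1 <- next_id; d2 <- next_id + 1L; next_id <- next_id + 2L
          new_id <- c(new_id, d1); new_aux <- c(new_aux, aux_k[i])
          new_len <- c(new_len, half)
          if (cfg$lateral_slip_prob > 0 &&
                stats::runif(1) < cfg$lateral_slip_prob && n_lanes > 1L) {
            k2 <- k + sample(c(-1L, 1L), 1L)
            k2 <- min(max(k2, 1L), n_lanes)
            if (k2 == k) k2 <- if (k == 1L) 2L else k - 1L
            pending[[length(pending) + 1L]] <-
              list(lane = k2, pos = i, id = d2, aux = aux_k[i], len = half)
          } else {
            new_id <- c(new_id, d2); new_aux <- c(new_aux, aux_k[i])
            new_len <- c(new_len, half)
          }
        }
      }
      lanes[[k]] <- list(id = new_id, aux = new_aux, len = new_len)
    }
    for (p in pending) {
      tgt <- lanes[[p$lane]]
      at <- min(p$pos, length(tgt$id) + 1L)
      lanes[[p$lane]] <- list(
        id = append(tgt$id, p$id, after = at - 1L),
        aux = append(tgt$aux, p$aux, after = at - 1L),
        len = append(tgt$len, p$len, after = at - 1L))
    }
  }

  rec <- rec[!vapply(rec, is.null, TRUE)]
  if (length(rec) == 0L) {
    empty <- data.frame(replicate_id = character(0), chamber_id = character(0),
                        frame = integer(0), time_h = numeric(0),
                        track_id = integer(0), cell_type = character(0),
                        x_um = numeric(0), y_um = numeric(0),
                        length_um = numeric(0), area_um2 = numeric(0))
    return(list(tracks = empty,
                truth = data.frame(replicate_id = character(0),
                                   chamber_id = character(0),
                                   track_id = integer(0),
                                   cell_type = character(0),
                                   mu_true_h = numeric(0),
                                   n_frames = integer(0))))
  }
  frame_v <- unlist(lapply(rec, `[[`, "frame"), use.names = FALSE)
  id_v <- unlist(lapply(rec, `[[`, "id"), use.names = FALSE)
  aux_v <- unlist(lapply(rec, `[[`, "aux"), use.names = FALSE)
  x_v <- unlist(lapply(rec, `[[`, "x"), use.names = FALSE)
  y_v <- unlist(lapply(rec, `[[`, "y"), use.names = FALSE)
  obs_v <- unlist(lapply(rec, `[[`, "obs"), use.names = FALSE)
  mu_v <- unlist(lapply(rec, `[[`, "mu"), use.names = FALSE)

  keep <- y_v >= cfg$exclusion_margin_um
  frame_v <- frame_v[keep]; id_v <- id_v[keep]; aux_v <- aux_v[keep]
  x_v <- x_v[keep]; y_v <- y_v[keep]; obs_v <- obs_v[keep]; mu_v <- mu_v[keep]

  tracks <- data.frame(
    replicate_id = replicate_id,
    chamber_id = chamber_id,
    frame = frame_v,
    time_h = frame_v * dt_h,
    track_id = id_v,
    cell_type = ifelse(aux_v, "AUX", "WT"),
    x_um = x_v,
    y_um = y_v,
    length_um = obs_v,
    area_um2 = obs_v * width,
    mu_true_h = mu_v,
    stringsAsFactors = FALSE
  )
  # dropping the margin strip can interrupt a track (shoving may push a
  # cell back across the margin); split such tracks into consecutive runs
  tracks <- split_track_gaps(tracks)
  mu_sum <- rowsum(tracks$mu_true_h, tracks$track_id)
  n_fr <- rowsum(rep(1L, nrow(tracks)), tracks$track_id)
  tid <- as.integer(rownames(mu_sum))
  truth <- data.frame(
    replicate_id = replicate_id,
    chamber_id = chamber_id,
    track_id = tid,
    cell_type = tracks$cell_type[match(tid, tracks$track_id)],
    mu_true_h = as.numeric(mu_sum) / as.numeric(n_fr),
    n_frames = as.integer(n_fr),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$track_id), , drop = FALSE]
  rownames(truth) <- NULL
  tracks$mu_true_h <- NULL
  list(tracks = tracks, truth = truth)
}

#' Generate a synthetic chamber track table
#'
#' Deterministic given `(config, seed)`: cells are seeded at non-overlapping
#' stacked positions with Bernoulli(`aux_seed_fraction`) type labels; true
#' lengths grow exponentially at the current rate (wildtype at `mu_wt_h`,
#' auxotrophs at `mu_wt_h * g(f)` with `f` the local auxotroph area fraction
#' under the analyzer's centroid rule); cells split into two half-length
#' daughters at the division length; observed lengths carry lognormal
#' measurement noise and occasional spurious jumps; cells pushed beyond the
#' open boundary are washed out; rows inside the exclusion margin are
#' dropped from the output.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (mandatory).
#' @param replicate_id,chamber_id labels stamped on the output.
#' @param mu_offset additive replicate offset on the wildtype rate (/h).
#' @return a validated [track_table()].
#' @seealso [ground_truth()] for the matching true rates.
#' @export
generate_chamber <- function(config, seed, replicate_id = "R1",
                             chamber_id = "C1", mu_offset = 0) {
  config <- validate_synthetic_config(config)
  sim <- with_seed(seed, .simulate_chamber(config, replicate_id, chamber_id,
                                           mu_offset))
  track_table(sim$tracks, chamber_side_um = config$chamber_side_um)
}

#' Generate a multi-replicate synthetic experiment
#'
#' One chamber set per biological replicate (`n_chambers` chambers each),
#' with replicate-specific wildtype-rate offsets drawn from
#' Normal(0, `replicate_sd_h`). Replicates are labelled `"R1" ... "Rn"`,
#' chambers `"C1" ... "Cm"`.
#'
#' @inheritParams generate_chamber
#' @return a validated [track_table()] spanning all replicates.
#' @export
generate_replicates <- function(config, seed) {
  config <- validate_synthetic_config(config)
  sims <- with_seed(seed, .simulate_replicates(config))
  tab <- do.call(rbind, lapply(sims, `[[`, "tracks"))
  track_table(tab, chamber_side_um = config$chamber_side_um)
}

.simulate_replicates <- function(config) {
  offsets <- stats::rnorm(config$n_replicates, 0, config$replicate_sd_h)
  sims <- vector("list", config$n_replicates * config$n_chambers)
  i <- 0L
  for (r in seq_len(config$n_replicates)) {
    for (ch in seq_len(config$n_chambers)) {
      i <- i + 1L
      sims[[i]] <- .simulate_chamber(config, sprintf("R%d", r),
                                     sprintf("C%d", ch), offsets[r])
    }
  }
  sims
}

#' True per-track growth rates for a generated table
#'
#' Re-runs the generator at the same `(config, seed)` and returns the true
#' instantaneous rate averaged over each track's recorded lifetime,
#' joinable on (`replicate_id`, `chamber_id`, `track_id`).
#'
#' @inheritParams generate_chamber
#' @param replicates if `TRUE`, match [generate_replicates()]; otherwise
#'   match [generate_chamber()] (with the same `replicate_id`,
#'   `chamber_id`, `mu_offset`).
#' @return data frame with `mu_true_h` and `n_frames` per track.
#' @export
ground_truth <- function(config, seed, replicates = FALSE,
                         replicate_id = "R1", chamber_id = "C1",
                         mu_offset = 0) {
  config <- validate_synthetic_config(config)
  if (replicates) {
    sims <- with_seed(seed, .simulate_replicates(config))
    out <- do.call(rbind, lapply(sims, `[[`, "truth"))
    rownames(out) <- NULL
    return(out)
  }
  sim <- with_seed(seed, .simulate_chamber(config, replicate_id, chamber_id,
                                           mu_offset))
  sim$truth
}
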