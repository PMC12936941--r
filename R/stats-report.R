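# Replicate-level hypothesis tests and the end-to-end pipeline driver.
# Strain comparisons run at the replicate level (n = replicates), never at
# the cell level; no multiple-testing correction is applied and raw
# p-values are reported.

#' Paired t-test on replicate means
#'
#' Classical paired t-test on the per-replicate mean growth rates of two
#' strains, two-sided p from the t distribution with n - 1 df. A zero
#' variance of the differences is flagged as degenerate: with zero mean
#' difference the result is reported as t = 0, p = 1; with a nonzero mean
#' difference the t statistic is infinite and p = 0.
#'
#' @param x,y paired per-replicate values (equal length >= 2).
#' @return list with `t_stat`, `p_value`, `df`, `n_pairs`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)",
                                   call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t_stat = 0, p_value = 1, df = n - 1L, n_pairs = n,
                  mean_diff = 0, degenerate = TRUE))
    }
    return(list(t_stat = sign(mean(d)) * Inf, p_value = 0, df = n - 1L,
                n_pairs = n, mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t_stat = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), n_pairs = n, mean_diff = mean(d),
       degenerate = FALSE)
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected Kruskal-Wallis H with p from the chi-squared distribution
#' on k - 1 df; used for overall differences in growth-rate distributions.
#' If every value across all groups is identical the statistic is defined
#' as H = 0, p = 1.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 0L) == 0L)) {
    stop("groups must be non-empty", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) stop("need at least 3 values in total",
                                call. = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p_value = 1, df = length(groups) - 1L))
  }
  g <- factor(rep.int(seq_along(groups), vapply(groups, length, 0L)))
  ht <- stats::kruskal.test(values, g)
  list(H = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise.
#'
#' @param p p-value(s).
#' @return character vector of labels.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Run the full analysis pipeline
#'
#' Chains every stage on synthetic (or supplied) data: generate
#' replicates, estimate growth rates, neighborhood statistics across the
#' configured radii, replicate-level paired t-test (WT vs AUX) and a
#' Kruskal-Wallis test on the pooled rate distributions, the relative
#' growth heatmap with its equal-growth contour, and the leakage
#' inference. All stage outputs are written as CSV/JSON to `out_dir`
#' together with the resolved configuration and seed, so every stage can
#' be re-loaded and re-run independently; re-running with the same seed
#' reproduces every output byte-identically.
#'
#' @param config run configuration ([default_config()]).
#' @param seed integer seed governing all randomness.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param tracks optionally, an existing track table to analyze instead of
#'   generating one (the synthetic stage is then skipped).
#' @return a list (invisible) with `tracks`, `growth`, `exclusions`,
#'   `summary`, `neighborhood`, `sweep`, `tests`, `heatmap`, `contour`,
#'   `inference`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = NULL, tracks = NULL) {
  config <- validate_config(config)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(tracks)) {
      tracks <- generate_replicates(config$synthetic, seed)
    }
    stage <- "growth"
    gr <- estimate_growth_rates(tracks, config)
    summ <- summarize_growth(gr$records)

    stage <- "neighborhood"
    nb <- config$neighborhood
    neigh <- lifetime_fraction(tracks, radius_um = nb$radius_um)
    sweep <- radius_sweep(gr$records, tracks, radii_um = nb$radii_um,
                          n_perm = nb$n_permutations, seed = seed + 1000L)

    stage <- "stats"
    rep_means <- summ[summ$replicate_id != "pooled", , drop = FALSE]
    wt <- rep_means[rep_means$cell_type == "WT", ]
    aux <- rep_means[rep_means$cell_type == "AUX", ]
    common <- intersect(wt$replicate_id, aux$replicate_id)
    tests <- list()
    if (length(common) >= 2L) {
      tt <- paired_t_test(wt$mean_mu_h[match(common, wt$replicate_id)],
                          aux$mean_mu_h[match(common, aux$replicate_id)])
      tests$paired_t_wt_vs_aux <- c(tt, stars = significance_stars(tt$p_value))
    }
    if (all(c("WT", "AUX") %in% gr$records$cell_type)) {
      kw <- kruskal_wallis(split(gr$records$mu_h, gr$records$cell_type))
      tests$kruskal_wallis_by_type <- kw
    }

    stage <- "heatmap"
    m <- config$model
    leak_grid <- 10^seq(-4, 0, length.out = 60)
    benefit_grid <- seq(1.02, 1.6, length.out = 30)
    hm <- growth_heatmap(leak_grid, benefit_grid, mu_wt = m$mu_wt,
                         epsilon = m$epsilon, K_M = m$K_M,
                         I_C_factor = m$I_C_factor)
    contour <- data.frame(
      benefit = benefit_grid,
      l_star = vapply(benefit_grid - 1, function(s) {
        # NA where the equal-growth contour leaves the parameter space
        tryCatch(critical_leakage(s, epsilon = m$epsilon, mu_wt = m$mu_wt,
                                  K_M = m$K_M,
                                  I_C_factor = m$I_C_factor)$l_star,
                 error = function(e) NA_real_)
      }, numeric(1)))

    stage <- "infer"
    inference <- infer_leakage(gr$records, neigh, config)

    list(tracks = tracks, growth = gr$records, exclusions = gr$exclusions,
         summary = summ, neighborhood = neigh, sweep = sweep, tests = tests,
         heatmap = hm, contour = contour, inference = inference)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    write_tracks(res$tracks, file.path(out_dir, "tracks.csv"))
    w(res$growth, "growth.csv")
    w(res$exclusions, "exclusions.csv")
    w(res$summary, "growth_summary.csv")
    w(res$neighborhood, "neighborhood.csv")
    w(res$sweep, "neighborhood_stats.csv")
    hm_long <- expand.grid(benefit = as.numeric(rownames(res$heatmap)),
                           leakage = as.numeric(colnames(res$heatmap)))
    hm_long$r <- as.vector(res$heatmap)
    w(hm_long, "heatmap.csv")
    w(res$contour, "contour.csv")
    jsonlite::write_json(unclass(res$inference),
                         file.path(out_dir, "inference.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(res$tests, file.path(out_dir, "tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log <- list(seed = as.integer(seed),
                config = .config_as_plain_list(config))
    yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  }
  invisible(res)
}

.config_as_plain_list <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .config_as_plain_list)
    attributes(x) <- list(names = names(x))
  }
  x
}
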