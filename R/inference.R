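# Leakage-rate inference: extrapolate the auxotroph growth rate to a
# fully-wildtype neighborhood, invert the exchange model for the shared
# leakage rate, and report the fold-change to the critical threshold.

#' Extrapolated maximum auxotroph growth rate
#'
#' Linear regression of auxotroph growth rate on the local wildtype
#' fraction, evaluated at a wildtype fraction of 1 -- the growth rate an
#' auxotroph would reach when fully surrounded by producers.
#'
#' @param mu_h auxotroph specific growth rates (/h).
#' @param wt_fraction local wildtype fraction per record (= 1 minus the
#'   local auxotroph fraction), at least 3 records with distinct values.
#' @return list with `mu_max_obs`, `stderr` (standard error of the
#'   regression mean at fraction 1), `intercept`, `slope`, `n`.
#' @export
extrapolate_max_growth <- function(mu_h, wt_fraction) {
  ok <- is.finite(mu_h) & is.finite(wt_fraction)
  mu_h <- mu_h[ok]; wt_fraction <- wt_fraction[ok]
  if (length(mu_h) < 3L) stop("need at least 3 records", call. = FALSE)
  if (length(unique(wt_fraction)) < 2L) {
    stop("wildtype fraction is constant; extrapolation undefined",
         call. = FALSE)
  }
  fit <- stats::lm(mu_h ~ wt_fraction)
  pr <- stats::predict(fit, newdata = data.frame(wt_fraction = 1),
                       se.fit = TRUE)
  list(mu_max_obs = unname(pr$fit), stderr = unname(pr$se.fit),
       intercept = unname(stats::coef(fit)[1L]),
       slope = unname(stats::coef(fit)[2L]), n = length(mu_h))
}

#' Infer the shared leakage rate from an observed maximum growth rate
#'
#' Finds the shared leakage rate `l` (`l_aux = l_wt = l`) at which the
#' exchange model's relative growth rate equals `mu_max_obs / mu_wt`.
#' The model is strictly increasing in `l`, so the inverse is found by
#' bracketing and Brent root-finding to 1e-10 relative tolerance.
#'
#' @param mu_max_obs observed (extrapolated) maximum auxotroph rate (/h);
#'   must satisfy `0 < mu_max_obs / mu_wt < 1 + s`, where
#'   `s = fitness_benefit(mu_max_aux, mu_wt)` -- no finite leakage can
#'   explain a rate at or above the saturation bound.
#' @param mu_wt wildtype rate (/h).
#' @param mu_max_aux auxotroph maximum rate with the amino acid supplied.
#' @param epsilon,K_M,I_C_factor model constants.
#' @return list with `l_fit` (/h), `L_fit` (relative leakage flux),
#'   `r_obs` and `s`.
#' @export
infer_leakage_rate <- function(mu_max_obs, mu_wt = 0.70, mu_max_aux = 0.90,
                               epsilon = 1, K_M = 1, I_C_factor = 20) {
  check_number(mu_max_obs, "mu_max_obs")
  check_number(mu_wt, "mu_wt", positive = TRUE)
  s <- fitness_benefit(mu_max_aux, mu_wt)
  r_obs <- mu_max_obs / mu_wt
  if (r_obs <= 0) stop("mu_max_obs must be positive", call. = FALSE)
  r_sup <- .shared_l_supremum(s, epsilon, K_M, I_C_factor)
  if (r_obs >= min(1 + s, r_sup)) {
    stop(sprintf(paste0("unattainable: relative rate %.4f is at or above the ",
                        "saturation bound %.4f of the shared-leakage model; ",
                        "no finite leakage explains it"),
                 r_obs, min(1 + s, r_sup)), call. = FALSE)
  }
  fn <- function(l) {
    .relative_growth_shared_l(l, s, mu_wt, epsilon, K_M, I_C_factor) - r_obs
  }
  l_fit <- .bracketed_root(fn, upper0 = max(1, mu_wt))
  list(l_fit = l_fit, L_fit = l_fit * I_C_factor / mu_wt,
       r_obs = r_obs, s = s)
}

#' Fold-change in leakage needed to reach the equal-growth threshold
#'
#' Ratio of the critical relative leakage flux (where auxotroph and
#' wildtype grow equally, same `s` and shared-rate coupling) to the
#' fitted flux: how much higher wildtype leakage would have to be for
#' auxotrophs to stop being disadvantaged. Greater than 1 exactly when
#' the observed relative growth is below parity.
#'
#' @param L_fit fitted relative leakage flux (> 0; a zero flux is
#'   reported as an infinite fold with a flag).
#' @param s fitness benefit (> 0).
#' @param epsilon,mu_wt,K_M,I_C_factor model constants.
#' @return list with `fold`, `L_star` and `infinite` flag.
#' @export
fold_to_threshold <- function(L_fit, s, epsilon = 1, mu_wt = 0.70,
                              K_M = 1, I_C_factor = 20) {
  check_number(L_fit, "L_fit", nonneg = TRUE)
  crit <- critical_leakage(s, epsilon = epsilon, mu_wt = mu_wt, K_M = K_M,
                           I_C_factor = I_C_factor)
  if (L_fit == 0) {
    return(list(fold = Inf, L_star = crit$L_star, infinite = TRUE))
  }
  list(fold = crit$L_star / L_fit, L_star = crit$L_star, infinite = FALSE)
}

#' Full leakage inference from growth records and neighborhood data
#'
#' Chains the stages: joins auxotroph growth records with their
#' lifetime-mean wildtype fraction (1 - local auxotroph fraction at the
#' configured radius), extrapolates to a fully-wildtype neighborhood,
#' inverts the model for the shared leakage rate, and reports the
#' fold-change to the critical threshold. Uncertainty on the leakage rate
#' is propagated by inverting the model at `mu_max_obs +/- 1 stderr`.
#'
#' @param records growth-record data frame.
#' @param neigh lifetime neighborhood records ([lifetime_fraction()]) at
#'   the radius of interest.
#' @param config run configuration supplying the model constants.
#' @return list of class `leakage_inference` with fields `mu_max_obs`,
#'   `stderr`, `r_obs`, `s`, `l_fit`, `L_fit`, `l_lo`, `l_hi`, `L_star`,
#'   `fold_to_threshold`, `n_records`.
#' @export
infer_leakage <- function(records, neigh, config = default_config()) {
  m <- config$model
  dat <- merge(records[records$cell_type == "AUX", , drop = FALSE],
               neigh[c("replicate_id", "chamber_id", "track_id",
                       "aux_fraction")],
               by = c("replicate_id", "chamber_id", "track_id"))
  dat <- dat[is.finite(dat$aux_fraction), , drop = FALSE]
  ext <- extrapolate_max_growth(dat$mu_h, 1 - dat$aux_fraction)
  inv <- infer_leakage_rate(ext$mu_max_obs, mu_wt = m$mu_wt,
                            mu_max_aux = m$mu_max_aux, epsilon = m$epsilon,
                            K_M = m$K_M, I_C_factor = m$I_C_factor)
  r_sup <- .shared_l_supremum(inv$s, m$epsilon, m$K_M, m$I_C_factor)
  band <- vapply(c(ext$mu_max_obs - ext$stderr, ext$mu_max_obs + ext$stderr),
                 function(mu) {
                   if (mu <= 0) return(0)
                   if (mu / m$mu_wt >= min(1 + inv$s, r_sup)) return(Inf)
                   infer_leakage_rate(mu, mu_wt = m$mu_wt,
                                      mu_max_aux = m$mu_max_aux,
                                      epsilon = m$epsilon, K_M = m$K_M,
                                      I_C_factor = m$I_C_factor)$l_fit
                 }, numeric(1))
  fold <- fold_to_threshold(inv$L_fit, inv$s, epsilon = m$epsilon,
                            mu_wt = m$mu_wt, K_M = m$K_M,
                            I_C_factor = m$I_C_factor)
  out <- list(mu_max_obs = ext$mu_max_obs, stderr = ext$stderr,
              r_obs = inv$r_obs, s = inv$s, l_fit = inv$l_fit,
              L_fit = inv$L_fit, l_lo = band[1L], l_hi = band[2L],
              L_star = fold$L_star, fold_to_threshold = fold$fold,
              n_records = ext$n)
  class(out) <- "leakage_inference"
  out
}
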