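# Leakage/uptake growth model for an auxotroph surrounded by producing
# wildtype cells. All concentrations are expressed in units of the Monod
# constant K_M (the relative growth rate depends only on i_hat / K_M).
#
# Symbols: s       fitness benefit of auxotrophy (dimensionless)
#          epsilon uptake+leakage ratio auxotroph/wildtype (default 1)
#          l_wt, l_aux  leakage rates (/h, fraction of internal pool)
#          L       relative leakage flux  l_wt * I_C / (mu_wt * K_M)
#          l_tilde relative auxotroph leakage  l_aux / mu_max_aux
#          i_hat   steady-state internal amino-acid concentration
#          r       auxotroph growth rate relative to wildtype

#' Model parameter set
#'
#' Bundles all exchange-model parameters. The internal concentration of
#' producers is `I_C = I_C_factor * K_M` (default 20, i.e. producers grow
#' near their maximum rate).
#'
#' @param mu_wt wildtype rate in minimal medium (/h; default 0.70).
#' @param mu_max_aux auxotroph maximum rate with the amino acid supplied
#'   (/h; default 0.90).
#' @param l_wt,l_aux leakage rates (/h; `l_aux` defaults to `l_wt`).
#' @param epsilon uptake+leakage ratio auxotroph/wildtype (default 1:
#'   identical transporters).
#' @param K_M half-saturation constant; concentrations are expressed in
#'   its units (default 1).
#' @param I_C_factor producer internal concentration in units of `K_M`
#'   (default 20).
#' @return a list with class `model_params`; includes the derived fitness
#'   benefit `s`.
#' @export
model_params <- function(mu_wt = 0.70, mu_max_aux = 0.90, l_wt = 0.004,
                         l_aux = l_wt, epsilon = 1, K_M = 1,
                         I_C_factor = 20) {
  check_number(mu_wt, "mu_wt", positive = TRUE)
  check_number(mu_max_aux, "mu_max_aux", positive = TRUE)
  check_number(l_wt, "l_wt", nonneg = TRUE)
  check_number(l_aux, "l_aux", nonneg = TRUE)
  check_number(epsilon, "epsilon", positive = TRUE)
  check_number(K_M, "K_M", positive = TRUE)
  check_number(I_C_factor, "I_C_factor", positive = TRUE)
  p <- list(mu_wt = mu_wt, mu_max_aux = mu_max_aux, l_wt = l_wt,
            l_aux = l_aux, epsilon = epsilon, K_M = K_M,
            I_C_factor = I_C_factor,
            s = fitness_benefit(mu_max_aux, mu_wt))
  class(p) <- "model_params"
  p
}

#' Fitness benefit of auxotrophy
#'
#' Proportional growth-rate gain of the auxotroph over the wildtype when
#' the amino acid is not limiting: `s = (mu_max_aux - mu_wt) / mu_wt`.
#'
#' @param mu_max_aux auxotroph maximum rate (/h).
#' @param mu_wt wildtype rate in minimal medium (/h).
#' @return `s` (dimensionless).
#' @export
fitness_benefit <- function(mu_max_aux, mu_wt) {
  if (any(mu_max_aux <= 0) || any(mu_wt <= 0)) {
    stop("growth rates must be positive", call. = FALSE)
  }
  (mu_max_aux - mu_wt) / mu_wt
}

#' Derived leakage ratios
#'
#' The dimensionless ratios the model runs on: the relative leakage flux
#' `L = l_wt * I_C_factor / mu_wt` (leaked vs growth-used amino acid of
#' producers) and the relative auxotroph leakage rate
#' `l_tilde = l_aux / mu_max_aux`.
#'
#' @param params a [model_params()].
#' @return list with `L` and `l_tilde`.
#' @export
derived_ratios <- function(params) {
  stopifnot(inherits(params, "model_params"))
  list(L = params$l_wt * params$I_C_factor / params$mu_wt,
       l_tilde = params$l_aux / params$mu_max_aux)
}

#' Steady-state internal amino-acid concentration of the auxotroph
#'
#' Non-negative root of the uptake/leakage balance:
#' `i_hat = K_M * (eps*L - lt + sqrt((eps*L + lt)^2 + 4*eps*L*(1+s))) /
#'  (2*((1+s) + lt))`.
#'
#' Vectorized over `L`.
#'
#' @param L relative leakage flux(es), >= 0.
#' @param l_tilde relative auxotroph leakage rate, >= 0.
#' @param s fitness benefit.
#' @param epsilon uptake+leakage ratio (default 1).
#' @param K_M Monod constant (default 1).
#' @return `i_hat` in units of concentration (same units as `K_M`).
#' @export
internal_concentration <- function(L, l_tilde, s, epsilon = 1, K_M = 1) {
  if (any(!is.finite(L)) || any(L < 0)) stop("L must be >= 0", call. = FALSE)
  check_number(l_tilde, "l_tilde", nonneg = TRUE)
  check_number(s, "s")
  check_number(epsilon, "epsilon", positive = TRUE)
  check_number(K_M, "K_M", positive = TRUE)
  disc <- (epsilon * L + l_tilde)^2 + 4 * epsilon * L * (1 + s)
  if (any(disc < 0)) stop("negative discriminant; invalid parameters",
                          call. = FALSE)
  K_M * (epsilon * L - l_tilde + sqrt(disc)) / (2 * ((1 + s) + l_tilde))
}

#' Relative growth rate of the auxotroph
#'
#' Highest growth rate an auxotroph can reach relative to the wildtype
#' when fully surrounded by producers:
#' `r = (1 + s) * i_hat / (K_M + i_hat)`, with `i_hat` from
#' [internal_concentration()]. Bounded by `0 <= r <= 1 + s`; `r = 1` means
#' parity with the wildtype.
#'
#' @param params a [model_params()].
#' @return `r` (dimensionless).
#' @export
relative_growth_rate <- function(params) {
  stopifnot(inherits(params, "model_params"))
  ratios <- derived_ratios(params)
  i_hat <- internal_concentration(ratios$L, ratios$l_tilde, params$s,
                                  epsilon = params$epsilon, K_M = params$K_M)
  (1 + params$s) * i_hat / (params$K_M + i_hat)
}

# r as a function of a single shared leakage rate l (= l_wt = l_aux), the
# coupling used by the heatmap, the inference and the generator's model
# mode. Vectorized over l.
.relative_growth_shared_l <- function(l, s, mu_wt, epsilon = 1, K_M = 1,
                                      I_C_factor = 20) {
  mu_max_aux <- (1 + s) * mu_wt
  L <- l * I_C_factor / mu_wt
  i_hat <- vapply(seq_along(l), function(i) {
    internal_concentration(L[i], l[i] / mu_max_aux, s, epsilon, K_M)
  }, numeric(1))
  (1 + s) * i_hat / (K_M + i_hat)
}

#' Relative growth rate over a leakage x benefit grid
#'
#' Evaluates the auxotroph's relative growth rate for every combination
#' of leakage rate (shared `l_aux = l_wt = l`, in /h) and growth benefit
#' `1 + s`, coupling `mu_max_aux = (1 + s) * mu_wt`. This is the heatmap
#' over which the equal-growth contour (see [critical_leakage()]) marks
#' where auxotrophs match wildtype growth.
#'
#' @param leakage_grid leakage rates (/h), positive.
#' @param benefit_grid growth benefits `1 + s`, positive.
#' @param mu_wt wildtype rate (/h; default 0.70).
#' @param epsilon,K_M,I_C_factor model constants.
#' @return matrix of `r` with rows = benefits, columns = leakage rates
#'   (dimnames carry the grid values).
#' @export
growth_heatmap <- function(leakage_grid, benefit_grid, mu_wt = 0.70,
                           epsilon = 1, K_M = 1, I_C_factor = 20) {
  if (length(leakage_grid) == 0L || length(benefit_grid) == 0L) {
    stop("grids must be non-empty", call. = FALSE)
  }
  if (any(leakage_grid <= 0) || any(benefit_grid <= 0)) {
    stop("grid values must be positive", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow = length(benefit_grid),
                ncol = length(leakage_grid),
                dimnames = list(benefit = format(benefit_grid, trim = TRUE),
                                leakage = format(leakage_grid, trim = TRUE)))
  for (i in seq_along(benefit_grid)) {
    s <- benefit_grid[i] - 1
    out[i, ] <- .relative_growth_shared_l(leakage_grid, s, mu_wt,
                                          epsilon, K_M, I_C_factor)
  }
  out
}

#' Critical leakage: the equal-growth threshold
#'
#' Solves `r(L*) = 1` -- the leakage above which the auxotroph outgrows
#' the wildtype. `r` is strictly increasing in the leakage, so the root is
#' unique; it is found by bracketing (geometric expansion until the sign
#' changes) and Brent root-finding to 1e-10 relative tolerance. At the
#' root the internal concentration satisfies `i_hat = K_M / s`.
#'
#' Two couplings are supported: a fixed relative auxotroph leakage
#' `l_tilde` (solve for `L` alone), or the shared-rate coupling
#' `l_aux = l_wt = l` (default when `l_tilde` is `NULL`), where both `L`
#' and `l_tilde` derive from `l`.
#'
#' @param s fitness benefit; must be > 0 (for `s <= 0` the auxotroph can
#'   never reach parity: `r < 1` for all finite leakage). Under the
#'   shared-rate coupling `r` additionally saturates below `1 + s` as the
#'   leakage grows, so parity also has no solution for small positive `s`
#'   (below about `1/(epsilon * I_C_factor)`); this is reported as a
#'   no-solution error.
#' @param epsilon uptake+leakage ratio (default 1).
#' @param l_tilde fixed relative auxotroph leakage rate, or `NULL` for the
#'   shared-rate coupling.
#' @param mu_wt,K_M,I_C_factor constants for the shared-rate coupling.
#' @return list with `L_star` (critical relative leakage flux), `l_star`
#'   (critical leakage rate in /h; `NA` in fixed-`l_tilde` mode) and
#'   `i_hat_star = K_M / s`.
#' @export
critical_leakage <- function(s, epsilon = 1, l_tilde = NULL, mu_wt = 0.70,
                             K_M = 1, I_C_factor = 20) {
  check_number(s, "s")
  if (s <= 0) {
    stop("no solution: for s <= 0 the auxotroph cannot reach wildtype growth",
         call. = FALSE)
  }
  if (!is.null(l_tilde)) {
    check_number(l_tilde, "l_tilde", nonneg = TRUE)
    fn <- function(L) {
      i <- internal_concentration(L, l_tilde, s, epsilon, K_M)
      (1 + s) * i / (K_M + i) - 1
    }
    L_star <- .bracketed_root(fn, upper0 = 10 * max(1, K_M / s * I_C_factor))
    return(list(L_star = L_star, l_star = NA_real_, i_hat_star = K_M / s))
  }
  r_sup <- .shared_l_supremum(s, epsilon, K_M, I_C_factor)
  if (r_sup <= 1) {
    stop(sprintf(paste0("no solution: under the shared-rate coupling the ",
                        "relative growth rate saturates at %.4f < 1; the ",
                        "auxotroph cannot reach parity at this s"), r_sup),
         call. = FALSE)
  }
  fn <- function(l) {
    .relative_growth_shared_l(l, s, mu_wt, epsilon, K_M, I_C_factor) - 1
  }
  l_star <- .bracketed_root(fn, upper0 = max(1, mu_wt))
  list(L_star = l_star * I_C_factor / mu_wt, l_star = l_star,
       i_hat_star = K_M / s)
}

# supremum of r over l under the shared-rate coupling: as l grows, both L
# and l_tilde diverge and i_hat saturates at epsilon*(1+s)*I_C_factor*K_M
.shared_l_supremum <- function(s, epsilon, K_M, I_C_factor) {
  i_inf <- K_M * epsilon * (1 + s) * I_C_factor
  (1 + s) * i_inf / (K_M + i_inf)
}

# root of a strictly increasing fn on (0, inf) with fn(0) < 0
.bracketed_root <- function(fn, upper0 = 1, tol_rel = 1e-10) {
  lo <- 0
  hi <- upper0
  it <- 0L
  while (fn(hi) < 0) {
    lo <- hi
    hi <- hi * 4
    it <- it + 1L
    if (it > 200L) stop("failed to bracket root", call. = FALSE)
  }
  u <- stats::uniroot(fn, lower = lo, upper = hi,
                      tol = tol_rel * max(1, hi))
  # polish: a couple of bisection steps at machine precision scale
  stats::uniroot(fn, lower = max(0, u$root * (1 - 1e-6)),
                 upper = u$root * (1 + 1e-6) + 1e-300,
                 tol = .Machine$double.eps^0.75,
                 extendInt = "upX")$root
}
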