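# Leakage/uptake growth model: closed forms against independent
# root-finding oracles, limits, monotonicity, critical leakage.

test_that("fitness benefit and derived ratios are the defining ratios", {
  expect_equal(fitness_benefit(0.90, 0.70), 2 / 7, tolerance = 1e-12)
  expect_equal(round(fitness_benefit(0.90, 0.70), 4), 0.2857)
  expect_equal(fitness_benefit(0.84, 0.84), 0)
  expect_equal(round(fitness_benefit(0.90, 0.84), 4), 0.0714)
  expect_error(fitness_benefit(0.9, 0), "positive")

  p <- model_params(mu_wt = 0.70, mu_max_aux = 0.90, l_wt = 0.01)
  r <- derived_ratios(p)
  expect_equal(r$L, 0.01 * 20 / 0.70, tolerance = 1e-12)
  expect_equal(round(r$L, 6), 0.285714)
  expect_equal(round(r$l_tilde, 6), 0.011111)
  expect_equal(derived_ratios(model_params(l_wt = 0))$L, 0)
  expect_equal(derived_ratios(model_params(mu_wt = 1, mu_max_aux = 1,
                                           l_wt = 0.3))$L, 20 * 0.3)
})

test_that("internal concentration matches the quadratic-root oracle", {
  # no leakage, no amino acid
  expect_equal(internal_concentration(0, 0.1, 0.2), 0)
  # worked cases
  expect_equal(internal_concentration(1, 0.1, 0.2),
               (0.9 + sqrt(6.01)) / 2.6, tolerance = 1e-12)
  expect_equal(internal_concentration(1, 0.1, 0.2), 1.2890, tolerance = 1e-4)
  i2 <- internal_concentration(2 / 7, 1 / 90, 2 / 7)
  expect_equal(round(i2, 5), 0.58705)
  expect_equal(i2, ihat_root_oracle(2 / 7, 1 / 90, 2 / 7), tolerance = 1e-9)

  # randomized sweep against the independent bracketed root-finder
  set.seed(12)
  for (i in 1:200) {
    L <- 10^runif(1, -3, 2)
    lt <- 10^runif(1, -4, 0)
    s <- runif(1, 0.01, 1)
    eps <- runif(1, 0.5, 2)
    got <- internal_concentration(L, lt, s, epsilon = eps)
    want <- ihat_root_oracle(L, lt, s, eps = eps)
    expect_equal(got, want, tolerance = 1e-9,
                 label = sprintf("L=%g lt=%g s=%g eps=%g", L, lt, s, eps))
  }
})

test_that("relative growth rate obeys its limits and worked example", {
  p0 <- model_params(l_wt = 0)
  expect_equal(relative_growth_rate(p0), 0)
  # saturation: i_hat -> inf when L -> inf at fixed l_tilde
  s <- 0.3
  i_big <- internal_concentration(1e9, 0.1, s)
  r_big <- (1 + s) * i_big / (1 + i_big)
  expect_equal(r_big, 1 + s, tolerance = 1e-6)
  # worked case: shared l = 0.01 with the measured rates
  p <- model_params(mu_wt = 0.70, mu_max_aux = 0.90, l_wt = 0.01)
  expect_equal(relative_growth_rate(p), 0.47558, tolerance = 1e-4)
  # bounds 0 <= r <= 1 + s on a random sweep
  set.seed(8)
  for (i in 1:100) {
    p_i <- model_params(mu_wt = 0.7, mu_max_aux = 0.7 * (1 + runif(1, 0.01, 1)),
                        l_wt = 10^runif(1, -4, 1))
    r_i <- relative_growth_rate(p_i)
    expect_gte(r_i, 0)
    expect_lte(r_i, 1 + p_i$s + 1e-12)
  }
})

test_that("the heatmap is monotone in leakage and hits the parity point", {
  hm <- growth_heatmap(10^seq(-4, 0, length.out = 25),
                       seq(1.05, 1.5, length.out = 8))
  expect_identical(dim(hm), c(8L, 25L))
  # strictly increasing along every leakage row; vanishing at low leakage
  for (i in seq_len(nrow(hm))) expect_true(all(diff(hm[i, ]) > 0))
  # r falls off like sqrt(L) toward zero leakage
  expect_lt(max(growth_heatmap(1e-9, seq(1.05, 1.5, length.out = 8))), 1e-3)
  expect_lt(max(growth_heatmap(1e-13, seq(1.05, 1.5, length.out = 8))), 1e-5)
  expect_error(growth_heatmap(c(-1, 1), 1.2), "positive")
  expect_error(growth_heatmap(numeric(0), 1.2), "non-empty")

  # the algebraic parity point: L = 5.5, l_tilde = 0.1 at s = 0.2 gives r = 1
  p_star <- model_params(mu_wt = 0.70, mu_max_aux = 1.2 * 0.70,
                         l_wt = 5.5 * 0.70 / 20, l_aux = 0.1 * 1.2 * 0.70)
  expect_equal(relative_growth_rate(p_star), 1, tolerance = 1e-12)
})

test_that("critical leakage solves r = 1 and matches the algebraic reduction", {
  # fixed l_tilde: the squared system is linear in L and gives exactly 5.5
  crit <- critical_leakage(0.2, l_tilde = 0.1)
  expect_equal(crit$L_star, 5.5, tolerance = 1e-9)
  expect_equal(crit$L_star, critical_fixed_oracle(0.2, 0.1), tolerance = 1e-9)
  expect_equal(crit$i_hat_star, 1 / 0.2)

  # r(L*) = 1 to 1e-9 across random valid parameters, both couplings
  set.seed(21)
  for (i in 1:25) {
    s <- runif(1, 0.1, 0.8)
    lt <- 10^runif(1, -3, -0.5)
    cf <- critical_leakage(s, l_tilde = lt)
    i_star <- internal_concentration(cf$L_star, lt, s)
    expect_equal((1 + s) * i_star / (1 + i_star), 1, tolerance = 1e-9)
    # algebraic identity at parity: i_hat * s = K_M
    expect_equal(i_star * s, 1, tolerance = 1e-9)
    cs <- critical_leakage(s)
    p_c <- model_params(mu_wt = 0.70, mu_max_aux = (1 + s) * 0.70,
                        l_wt = cs$l_star)
    expect_equal(relative_growth_rate(p_c), 1, tolerance = 1e-9)
  }

  expect_error(critical_leakage(0), "s <= 0")
  expect_error(critical_leakage(-0.1), "s <= 0")
  # shared-rate coupling saturates below parity for small s
  expect_error(critical_leakage(0.02), "no solution")
})

test_that("r increases strictly in both leakage and benefit", {
  lt <- 0.05
  Ls <- 10^seq(-3, 2, length.out = 40)
  for (s in c(0.1, 0.3, 0.6)) {
    i <- internal_concentration(Ls, lt, s)
    r <- (1 + s) * i / (1 + i)
    expect_true(all(diff(r) > 0))
  }
  ss <- seq(0.05, 1, length.out = 30)
  for (L in c(0.1, 1, 10)) {
    r <- vapply(ss, function(s) {
      i <- internal_concentration(L, lt, s)
      (1 + s) * i / (1 + i)
    }, numeric(1))
    expect_true(all(diff(r) > 0))
  }
})
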