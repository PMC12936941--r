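# Synthetic chamber generator: determinism, seeding statistics, growth
# and division invariants, ground-truth consistency.

test_that("generation is deterministic under a seed and varies across seeds", {
  cfg <- synthetic_config(duration_h = 2, n_initial_cells = 30)
  a <- generate_chamber(cfg, seed = 7)
  b <- generate_chamber(cfg, seed = 7)
  expect_identical(a, b)
  c_ <- generate_chamber(cfg, seed = 8)
  expect_false(identical(a, c_))
  expect_error(generate_chamber(cfg, seed = NULL), "seed")
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- .Random.seed
  invisible(generate_chamber(cfg, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("seeded auxotroph fraction is binomially consistent with 10%", {
  cfg <- synthetic_config(n_initial_cells = 200, duration_h = 1)
  bounds <- qbinom(c(0.005, 0.995), 200, 0.10) / 200
  for (seed in 1:5) {
    tab <- generate_chamber(cfg, seed = seed)
    first <- tab[tab$frame == 0, ]
    frac <- mean(first$cell_type == "AUX")
    expect_gte(frac, bounds[1])
    expect_lte(frac, bounds[2])
  }
})

test_that("noiseless uncoupled growth is recovered exactly by the fit", {
  cfg <- synthetic_config(length_noise_cv = 0, jump_probability = 0,
                          r0 = 1, beta = 0, duration_h = 3,
                          n_initial_cells = 30)
  tab <- generate_chamber(cfg, seed = 21)
  gr <- estimate_growth_rates(tab)
  expect_gt(nrow(gr$records), 0)
  expect_lt(max(abs(gr$records$mu_h - 0.70) / 0.70), 1e-9)
  expect_true(all(gr$records$r2 == 1))
  # fitted rates equal the ground truth
  truth <- ground_truth(cfg, seed = 21)
  m <- merge(gr$records, truth, by = c("replicate_id", "chamber_id", "track_id"))
  expect_equal(m$mu_h, m$mu_true_h, tolerance = 1e-9)
})

test_that("division conserves length: total biomass grows exponentially", {
  # noiseless all-wildtype chamber far from carrying capacity: the summed
  # observed length must grow by exp(mu dt) every frame, divisions included
  cfg <- synthetic_config(length_noise_cv = 0, jump_probability = 0,
                          aux_seed_fraction = 0, n_initial_cells = 5,
                          duration_h = 2, exclusion_margin_um = 0)
  tab <- generate_chamber(cfg, seed = 5)
  total <- tapply(tab$length_um, tab$frame, sum)
  ratios <- as.numeric(total[-1] / total[-length(total)])
  expect_equal(ratios, rep(exp(0.70 * 5 / 60), length(ratios)),
               tolerance = 1e-9)
})

test_that("linear coupling produces rates that fall with local clustering", {
  cfg <- synthetic_config(beta = -0.5, duration_h = 4, n_initial_cells = 120)
  truth <- ground_truth(cfg, seed = 31)
  tab <- generate_chamber(cfg, seed = 31)
  nf <- lifetime_fraction(tab, radius_um = 5, cell_types = "AUX")
  m <- merge(truth[truth$cell_type == "AUX", ], nf,
             by = c("replicate_id", "chamber_id", "track_id"))
  m <- m[is.finite(m$aux_fraction) & m$n_frames >= 3, ]
  expect_gt(nrow(m), 10)
  expect_lt(spearman_rho(m$aux_fraction, m$mu_true_h), 0)
})

test_that("model coupling matches the exchange model where f = 0", {
  cfg <- synthetic_config(coupling_mode = "model", length_noise_cv = 0,
                          jump_probability = 0, duration_h = 3,
                          n_initial_cells = 60, aux_seed_fraction = 0.05)
  tab <- generate_chamber(cfg, seed = 13)
  truth <- ground_truth(cfg, seed = 13)
  nf <- lifetime_fraction(tab, radius_um = 5, cell_types = "AUX")
  m <- merge(truth, nf, by = c("replicate_id", "chamber_id", "track_id"))
  solo <- m[is.finite(m$aux_fraction) & m$aux_fraction == 0, ]
  expect_gt(nrow(solo), 0)
  p <- model_params(mu_wt = 0.70, mu_max_aux = 0.90, l_wt = 0.004)
  expected <- 0.70 * relative_growth_rate(p)
  expect_equal(solo$mu_true_h, rep(expected, nrow(solo)), tolerance = 1e-9)
  # and no auxotroph can exceed the f = 0 prediction
  aux_truth <- m[m$cell_type.x == "AUX", ]
  expect_lte(max(aux_truth$mu_true_h), expected + 1e-9)
})

test_that("replicate structure: labels, offsets and ground-truth join", {
  cfg <- synthetic_config(duration_h = 2, n_initial_cells = 30,
                          n_replicates = 5, n_chambers = 2)
  tab <- generate_replicates(cfg, seed = 17)
  expect_setequal(unique(tab$replicate_id), paste0("R", 1:5))
  expect_setequal(unique(tab$chamber_id), paste0("C", 1:2))
  truth <- ground_truth(cfg, seed = 17, replicates = TRUE)
  key_tab <- unique(paste(tab$replicate_id, tab$chamber_id, tab$track_id))
  key_tr <- paste(truth$replicate_id, truth$chamber_id, truth$track_id)
  expect_setequal(key_tab, key_tr)

  # zero replicate-SD: noiseless wildtype rates agree across replicates
  cfg0 <- synthetic_config(duration_h = 2, n_initial_cells = 30,
                           n_replicates = 3, n_chambers = 1,
                           replicate_sd_h = 0, length_noise_cv = 0,
                           jump_probability = 0, aux_seed_fraction = 0)
  tr0 <- ground_truth(cfg0, seed = 3, replicates = TRUE)
  expect_equal(tr0$mu_true_h, rep(0.70, nrow(tr0)), tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(aux_seed_fraction = 1.5), "aux_seed_fraction")
  expect_error(synthetic_config(birth_length_um = 5), "division_length")
  expect_error(synthetic_config(duration_h = -1), "duration_h")
  expect_error(synthetic_config(coupling_mode = "nonsense"))
})
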