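# Neighborhood composition (centroid and rasterized rules), Spearman
# correlation, permutation test, radius sweep and binning.

test_that("centroid rule: area-weighted fraction excluding the focal cell", {
  # one AUX neighbor inside (area 1.5), one WT outside -> 1.0
  tab <- make_frame(x = c(10, 12, 18), y = c(10, 10, 10),
                    area = c(2, 1.5, 3), cell_type = c("WT", "AUX", "WT"))
  expect_equal(local_aux_fraction(tab, frame = 0, track_id = 1, radius_um = 5), 1.0)

  # AUX area 2 and WT area 6 inside -> 0.25
  tab2 <- make_frame(x = c(10, 12, 13), y = c(10, 10, 10),
                     area = c(2, 2, 6), cell_type = c("WT", "AUX", "WT"))
  expect_equal(local_aux_fraction(tab2, frame = 0, track_id = 1, radius_um = 5), 0.25)

  # no neighbor within the radius -> missing
  tab3 <- make_frame(x = c(10, 30), y = c(10, 30), area = c(2, 2),
                     cell_type = c("WT", "AUX"))
  expect_true(is.na(local_aux_fraction(tab3, frame = 0, track_id = 1,
                                       radius_um = 5)))
  # absent focal track errors
  expect_error(local_aux_fraction(tab3, frame = 0, track_id = 9,
                                  radius_um = 5), "not present")
  # all-WT and all-AUX neighborhoods hit the bounds
  tab4 <- make_frame(x = c(10, 11, 12), y = rep(10, 3), area = rep(2, 3),
                     cell_type = c("AUX", "WT", "WT"))
  expect_equal(local_aux_fraction(tab4, frame = 0, track_id = 1, radius_um = 5), 0)
  tab5 <- make_frame(x = c(10, 11, 12), y = rep(10, 3), area = rep(2, 3),
                     cell_type = c("WT", "AUX", "AUX"))
  expect_equal(local_aux_fraction(tab5, frame = 0, track_id = 1, radius_um = 5), 1)
})

test_that("rasterized rule counts pixel centers and matches exhaustive enumeration", {
  cells <- data.frame(
    x_um = c(10, 12, 10), y_um = c(10, 10, 13.5),
    cell_type = c("WT", "AUX", "WT"),
    shape = c("disc", "disc", "rect"),
    radius_um = c(0.5, 1, NA), width_um = c(NA, NA, 2),
    height_um = c(NA, NA, 1), stringsAsFactors = FALSE)

  # single AUX disc fully inside, WT rect fully outside a 3 um circle
  expect_equal(rasterized_aux_fraction(cells, focal = 1, radius_um = 3), 1.0)

  # equal-pixel-count AUX and WT rectangles -> 0.5 (grid-aligned so both
  # rasterize to the same pixel count)
  eq <- data.frame(x_um = c(10, 8, 12), y_um = c(10, 10, 10),
                   cell_type = c("WT", "AUX", "WT"), shape = "rect",
                   width_um = 1, height_um = 2, stringsAsFactors = FALSE)
  expect_equal(rasterized_aux_fraction(eq, focal = 1, radius_um = 5,
                                       um_per_pixel = 0.1), 0.5)

  # rectangle straddling the circle boundary: agree with the brute-force
  # pixel enumeration oracle at the 0.065 um grid
  strad <- data.frame(x_um = c(10, 14.5, 11), y_um = c(10, 10, 11),
                      cell_type = c("WT", "AUX", "WT"), shape = "rect",
                      width_um = c(1, 3, 1), height_um = c(1, 1.4, 2),
                      stringsAsFactors = FALSE)
  got <- rasterized_aux_fraction(strad, focal = 1, radius_um = 5)
  expect_equal(got, raster_oracle(strad, 1, 5, 0.065), tolerance = 1e-12)

  expect_error(rasterized_aux_fraction(
    data.frame(x_um = c(0, 1), y_um = c(0, 0), cell_type = c("WT", "AUX"),
               shape = "rect", width_um = 0, height_um = 1,
               stringsAsFactors = FALSE), focal = 1, radius_um = 5),
    "zero-area")

  # centroid and rasterized rules agree on a well-separated layout where
  # every cell is entirely inside or outside the circle
  far <- data.frame(x_um = c(20, 22, 19, 35), y_um = c(20, 20, 22, 20),
                    cell_type = c("WT", "AUX", "WT", "AUX"), shape = "disc",
                    radius_um = 0.5, stringsAsFactors = FALSE)
  ras <- rasterized_aux_fraction(far, focal = 1, radius_um = 5)
  tabf <- make_frame(x = far$x_um, y = far$y_um,
                     area = rep(pi * 0.25, 4), cell_type = far$cell_type)
  cen <- local_aux_fraction(tabf, frame = 0, track_id = 1, radius_um = 5)
  expect_equal(ras, cen, tolerance = 0.01)
})

test_that("lifetime fraction averages defined frames and matches recomputation", {
  # two frames with changing composition around the focal cell
  f0 <- make_frame(x = c(10, 12, 14), y = rep(10, 3), area = c(2, 2, 2),
                   cell_type = c("AUX", "WT", "WT"))
  f1 <- f0; f1$frame <- 1L; f1$time_h <- 5 / 60
  f1$cell_type <- c("AUX", "AUX", "WT")   # track 2 relabeled to vary composition
  tab <- track_table(rbind(f0, f1), validate = FALSE)
  lf <- lifetime_fraction(tab, radius_um = 5)
  # track 3: frame 0 sees AUX (d=4) + WT (d=2) -> 0.5; frame 1 both AUX -> 1
  expect_equal(lf$aux_fraction[lf$track_id == 3], 0.75)
  # track 2: constant 0.5 composition -> lifetime mean equals the frame value
  expect_equal(lf$aux_fraction[lf$track_id == 2],
               local_aux_fraction(tab, 0, 2, 5))

  # synthetic chamber: records match an independent per-frame recomputation
  cfg <- synthetic_config(duration_h = 1.5, n_initial_cells = 25)
  chamber <- generate_chamber(cfg, seed = 9)
  lf2 <- lifetime_fraction(chamber, radius_um = 5)
  ids <- sample(unique(chamber$track_id), 10)
  for (id in ids) {
    frames <- chamber$frame[chamber$track_id == id]
    per_frame <- vapply(frames, function(fr) {
      local_aux_fraction(chamber, fr, id, 5)
    }, numeric(1))
    want <- if (all(is.na(per_frame))) NA_real_ else mean(per_frame, na.rm = TRUE)
    expect_equal(lf2$aux_fraction[lf2$track_id == id], want, label = id)
  }
})

test_that("Spearman's rho handles ties and monotone invariance", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:5, -(1:5)), -1)
  # hand-computed mid-rank example with a tie
  x <- c(1, 2, 3, 4); y <- c(2, 2, 3, 1)
  expect_equal(spearman_rho(x, y), -1.5 / sqrt(22.5))
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  # invariance under strictly monotone transforms
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b))
  expect_equal(spearman_rho(a, qlogis(plogis(b))), spearman_rho(a, b))
  expect_error(spearman_rho(rep(1, 5), 1:5), "variance")
  expect_error(spearman_rho(1:2, 2:1), "3 finite")
})

test_that("permutation p-values are deterministic, bounded and powerful", {
  x <- 1:20; y <- x + 0.5
  pt <- permutation_pvalue(x, y, n_perm = 10000, seed = 42)
  expect_equal(pt$rho_obs, 1)
  expect_lt(pt$p_value, 0.001)
  pt2 <- permutation_pvalue(x, y, n_perm = 10000, seed = 42)
  expect_identical(pt, pt2)

  # resolution limit at a single permutation
  set.seed(1); xr <- rnorm(15); yr <- rnorm(15)
  p1 <- permutation_pvalue(xr, yr, n_perm = 1, seed = 5)$p_value
  expect_true(p1 %in% c(0, 1))

  # p-values live on the 1/n_perm grid
  p <- permutation_pvalue(xr, yr, n_perm = 200, seed = 6)$p_value
  expect_equal(p * 200, round(p * 200))
})

test_that("radius sweep reports per-radius statistics and rejects duplicates", {
  cfg <- synthetic_config(beta = -0.5, duration_h = 4, n_initial_cells = 120)
  tab <- generate_chamber(cfg, seed = 19)
  gr <- estimate_growth_rates(tab)
  sw <- radius_sweep(gr$records, tab, radii_um = c(5, 13), n_perm = 200,
                     seed = 4)
  aux5 <- sw[sw$radius_um == 5 & sw$cell_type == "AUX", ]
  aux13 <- sw[sw$radius_um == 13 & sw$cell_type == "AUX", ]
  expect_identical(nrow(aux5), 1L)
  # coupling is generated at 5 um, so the signal is at least as strong there
  expect_gte(abs(aux5$rho), abs(aux13$rho))
  expect_lt(aux5$rho, 0)
  expect_error(radius_sweep(gr$records, tab, radii_um = c(5, 5)), "distinct")
})

test_that("binning is a faithful visualization summary", {
  expect_equal(bin_growth_by_fraction(seq(0, 1, 0.01), seq(0, 1, 0.01),
                                      "fixed_width", k = 4)$lo,
               c(0, 0.25, 0.5, 0.75))
  q <- bin_growth_by_fraction(c(1:8) / 10, rnorm(8), "quartile", k = 4)
  expect_equal(q$n, rep(2L, 4))
  # monotone decreasing relation -> non-increasing bin medians
  set.seed(11)
  f <- runif(200); mu <- 0.33 - 0.5 * 0.23 * f + rnorm(200, 0, 0.005)
  b <- bin_growth_by_fraction(f, mu, "fixed_width", k = 4)
  expect_true(all(diff(b$median) <= 0))
  expect_error(bin_growth_by_fraction(rep(0.5, 10), rnorm(10), "quartile"),
               "identical")
})
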