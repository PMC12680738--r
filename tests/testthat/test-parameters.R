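# Per-station habitat parameter measurements.

test_that("shortest-chord width is exact on simple channels", {
  banks <- rect_channel(L = 60, W = 5)
  cl <- extract_centerline(banks, spacing_m = 2)
  for (i in c(5L, 15L, 25L))
    expect_equal(width_at(cl$nodes[i, ], banks)$W, 5, tolerance = 1e-6)
  # node outside the channel is refused
  expect_error(width_at(c(30, 80), banks), "outside")
})

test_that("width follows a linear taper", {
  xs <- seq(0, 100, by = 0.5)
  w <- 8 - 6 * xs / 100       # 8 m at inlet to 2 m at outlet
  banks <- bank_geometry(left_bank = cbind(xs, w / 2),
                         right_bank = cbind(xs, -w / 2),
                         inlet = c(0, 0), outlet = c(100, 0))
  W_mid <- width_at(c(50, 0), banks)$W
  # taper makes the minimal chord slightly oblique; analytic minimum is
  # W(50) * cos(atan(dw/dx / 2)) with dw/dx = -0.06
  expect_equal(W_mid, 5, tolerance = 0.01)
})

test_that("islands are excluded from the wetted width and fraction", {
  banks <- rect_channel(L = 40, W = 6)
  island <- rbind(c(18, 2), c(22, 2), c(22, 4), c(18, 4))
  banks$islands <- list(island)
  res <- width_at(c(20, 3), banks)
  expect_equal(res$chord$length, 6, tolerance = 1e-6)
  expect_equal(res$chord$island_overlap_m, 2, tolerance = 1e-6)
  expect_equal(res$W, 4, tolerance = 1e-6)
  expect_equal(wet_fraction_at(res$chord, banks), 4 / 6, tolerance = 1e-6)
  # no islands: fully wet
  banks$islands <- list()
  res2 <- width_at(c(20, 3), banks)
  expect_equal(wet_fraction_at(res2$chord, banks), 1)
})

test_that("side widths accumulate layer crossings along the lateral ray", {
  banks <- rect_channel(L = 40, W = 5)
  chord <- width_at(c(20, 2.5), banks)$chord
  strip <- function(y0, y1) rbind(c(10, y0), c(30, y0), c(30, y1), c(10, y1))
  # 12 m buffer flanking the left bank (y in [5, 17])
  expect_equal(side_width(chord, list(strip(5, 17)), "left"), 12, tolerance = 1e-6)
  # nothing on the right
  expect_equal(side_width(chord, list(), "right"), 0)
  # two disjoint patches on the left ray: 0.3 + 0.2
  expect_equal(side_width(chord, list(strip(4.0, 4.3), strip(4.5, 4.7)), "left"),
               0.5, tolerance = 1e-6)
  # a detached layer beyond the reach limit is ignored
  expect_equal(side_width(chord, list(strip(200, 260)), "left", max_m = 100), 0)
})

test_that("bank-top width brackets the wetted width and flags missing tops", {
  banks <- rect_channel(L = 40, W = 5, top_offset = 2)
  chord <- width_at(c(20, 2.5), banks)$chord
  expect_equal(bank_top_width(chord, banks), 9, tolerance = 1e-6)
  # coincident bank tops degenerate to the wetted width
  banks2 <- banks
  banks2$left_bank_top <- banks$left_bank
  banks2$right_bank_top <- banks$right_bank
  expect_equal(bank_top_width(chord, banks2), 5, tolerance = 1e-6)
  # one side missing: flagged NA, not zero
  banks3 <- banks
  banks3$right_bank_top <- NULL
  bt <- bank_top_width(chord, banks3)
  expect_true(is.na(bt))
  expect_equal(attr(bt, "missing_side"), "right")
})

test_that("depth interpolation honours bed points and clips negatives", {
  cl <- as_centerline(cbind(seq(0, 100, by = 1), 0))
  bed <- data.frame(x = c(0, 100), y = 0, elev = c(263.0, 262.0))
  d <- depth_series(cl, 263.5, bed)
  expect_equal(d$D[cl$s == 50], 1.0, tolerance = 1e-9)
  expect_equal(d$n_clipped, 0L)
  # flat bed 1 m below flat surface
  bed2 <- data.frame(x = c(0, 50, 100), y = 0, elev = 262.5)
  expect_true(all(abs(depth_series(cl, 263.5, bed2)$D - 1) < 1e-9))
  # surface below bed: clipped with a warning count
  bed3 <- data.frame(x = c(0, 100), y = 0, elev = c(264, 262))
  expect_warning(d3 <- depth_series(cl, 263.5, bed3), "clipped")
  expect_gt(d3$n_clipped, 0L)
  expect_true(all(d3$D >= 0))
  expect_error(depth_series(cl, 263.5, bed[1, ]), "two bed points")
})

test_that("depth reproduces bed points exactly at their stations", {
  cl <- as_centerline(cbind(seq(0, 100, by = 1), 0))
  bed <- data.frame(x = c(10, 40, 80), y = 0, elev = c(262.8, 262.3, 262.6))
  d <- depth_series(cl, 263.5, bed)
  expect_equal(d$D[cl$s %in% bed$x], 263.5 - bed$elev, tolerance = 1e-9)
})

test_that("velocity proxy follows continuity scaling", {
  expect_equal(velocity_proxy(4, 1) / velocity_proxy(2, 0.5), 0.25)
  expect_equal(velocity_proxy(6, 0.5), velocity_proxy(6, 0.5))
  expect_true(is.na(velocity_proxy(0, 1)))
  expect_equal(velocity_proxy(2, 1), 4 * velocity_proxy(4, 2))
})

test_that("pool detection recovers seeded deep-slow reaches", {
  fx <- generate_site(small_meander())
  cl <- extract_centerline(fx$banks, spacing_m = 1)
  st <- extract_stations(fx$banks, fx$layers, cl)
  pools <- detect_pools(st)
  expect_equal(nrow(pools), 1L)
  expect_equal(pools$s_start, 30, tolerance = 2)
  expect_equal(pools$s_end, 50, tolerance = 2)
  # two separated reaches give two intervals
  fx2 <- generate_site(meander_spec(axis_length = 200, amplitude = 6,
                                    wavelength = 100, width = 5,
                                    pool_reaches = list(c(40, 60), c(130, 145)),
                                    seed = 11))
  cl2 <- extract_centerline(fx2$banks, spacing_m = 1)
  st2 <- extract_stations(fx2$banks, fx2$layers, cl2)
  pools2 <- detect_pools(st2)
  expect_equal(nrow(pools2), 2L)
  # uniform depth: strict percentile comparison yields no pools
  stu <- st; stu$D <- 0.5; stu$v_proxy <- velocity_proxy(stu$W, stu$D)
  expect_equal(nrow(detect_pools(stu)), 0L)
  expect_error(detect_pools(st[1:5, ]), "at least 10")
})

test_that("coverage fraction measures the covered share of a bank", {
  bank <- cbind(seq(0, 100, by = 1), 0)
  # strip touching the bank along its first half; a tight reach keeps the
  # spillover past the strip end below the sampling step
  strip <- rbind(c(0, 0), c(50, 0), c(50, 1), c(0, 1))
  expect_equal(coverage_fraction(bank, list(strip), max_dist_m = 0.3), 0.5,
               tolerance = 0.02)
  expect_equal(coverage_fraction(bank, list(), max_dist_m = 2), 0)
  full <- rbind(c(0, 0.5), c(100, 0.5), c(100, 1.5), c(0, 1.5))
  expect_equal(coverage_fraction(bank, list(full), max_dist_m = 2), 1)
  # a strip farther than the reach does not count
  far <- rbind(c(0, 5), c(100, 5), c(100, 6), c(0, 6))
  expect_equal(coverage_fraction(bank, list(far), max_dist_m = 2), 0)
})

test_that("widths are invariant under rigid motion of all inputs", {
  fx <- generate_site(small_meander())
  cl <- extract_centerline(fx$banks, spacing_m = 4)
  i <- 10L
  w0 <- width_at(cl$nodes[i, ], fx$banks)
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(500, -200)
  mv <- function(m) sweep(m %*% R, 2, shift, "+")
  banks2 <- fx$banks
  banks2$left_bank <- mv(banks2$left_bank); banks2$right_bank <- mv(banks2$right_bank)
  banks2$left_bank_top <- mv(banks2$left_bank_top)
  banks2$right_bank_top <- mv(banks2$right_bank_top)
  banks2$islands <- lapply(banks2$islands, mv)
  banks2$inlet <- as.numeric(mv(rbind(banks2$inlet)))
  banks2$outlet <- as.numeric(mv(rbind(banks2$outlet)))
  w1 <- width_at(as.numeric(mv(rbind(cl$nodes[i, ]))), banks2)
  expect_equal(w1$W, w0$W, tolerance = 1e-4)
  bt0 <- bank_top_width(w0$chord, fx$banks)
  bt1 <- bank_top_width(w1$chord, banks2)
  expect_equal(bt1, bt0, tolerance = 1e-4)
  expect_gte(bt0, w0$W)
})
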