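# Metric categorisation, aggregation, assessment modes.

test_that("gradient classification follows the strict 0.02 threshold", {
  expect_equal(classify_gradient(0.0023), "M")
  expect_equal(classify_gradient(0.02), "M")
  expect_equal(classify_gradient(0.021), "H")
  expect_warning(g <- classify_gradient(-0.03), "absolute")
  expect_equal(g, "H")
})

test_that("every published bin boundary categorises exactly as printed", {
  for (cs in mmi_bin_cases()) {
    res <- score_value(cs[[1]], cs[[3]], cs[[2]])
    expect_equal(res$label, cs[[4]],
                 label = sprintf("%s(%s) value %.6g -> %s", cs[[1]], cs[[2]],
                                 cs[[3]], res$label))
    expect_equal(res$score, unname(c(excellent = 10, good = 7.5,
                                     fair = 5, poor = 2.5)[cs[[4]]]))
  }
  expect_error(score_value("M9", 101), "outside")
  expect_error(score_value("M9", -1), "outside")
})

test_that("the published per-metric categories reproduce both totals", {
  transect_cats <- list(
    M2 = c(left = "good", right = "excellent"), M3 = "fair", M4 = "good",
    M5 = "fair", M6 = "good", M7 = "poor", M8 = "fair", M9 = "poor")
  tr <- aggregate_categories(transect_cats)
  expect_identical(tr$total, 43.75)
  expect_identical(tr$overall, "fair")
  continuous_cats <- list(
    M2 = c(left = "excellent", right = "excellent"),
    M3 = c(left = "fair", right = "fair"), M4 = "good", M5 = "fair",
    M6 = "good", M7 = "poor", M8 = "fair", M9 = "fair")
  co <- aggregate_categories(continuous_cats)
  expect_identical(co$total, 47.5)
  expect_identical(co$overall, "good")
})

test_that("aggregation is permutation-invariant and quantised to 1.25", {
  cats <- list(M2 = c(left = "good", right = "poor"), M3 = "fair", M4 = "good",
               M5 = "excellent", M6 = "poor", M7 = "fair", M8 = "good",
               M9 = "excellent")
  base <- aggregate_categories(cats)
  perm <- aggregate_categories(cats[sample(names(cats))])
  expect_equal(perm$total, base$total)
  expect_equal(base$total %% 1.25, 0)
  expect_error(aggregate_categories(cats[-2]), "M3")
  expect_equal(total_class(60), "excellent")
  expect_equal(total_class(60 - 1e-9), "good")
  expect_equal(total_class(45), "good")
  expect_equal(total_class(30), "fair")
  expect_equal(total_class(29.99), "poor")
})

test_that("station scoring weights categories by length", {
  # half the length stable (0.1 m erosion), half severely eroded (1.2 m)
  res <- score_stations("M3", c(0.1, 1.2), weights = c(50, 50))
  expect_equal(unname(res$pct_by_category[c("excellent", "poor")]), c(0.5, 0.5))
  expect_equal(res$site_value, 0.65)
  expect_equal(res$label, "fair")  # 0.65 in [0.5, 1)
  # all excellent
  res2 <- score_stations("M2", rep(11, 5), weights = rep(1, 5))
  expect_equal(unname(res2$pct_by_category["excellent"]), 1)
  # single station is a unit mass
  res3 <- score_stations("M6", 80)
  expect_equal(sum(res3$pct_by_category), 1)
  expect_equal(unname(res3$pct_by_category["good"]), 1)
  # alternative site rules
  resw <- score_stations("M3", c(0.1, 1.2), weights = c(99, 1), site_rule = "worst")
  expect_equal(resw$label, "poor")
  resm <- score_stations("M3", c(0.1, 0.1, 1.2), site_rule = "majority")
  expect_equal(resm$label, "excellent")
  expect_error(score_stations("M3", numeric(0)), "empty")
})

test_that("degrading a station never improves any category or the total", {
  fx <- generate_site(small_meander())
  cl <- extract_centerline(fx$banks, spacing_m = 2)
  st <- extract_stations(fx$banks, fx$layers, cl)
  pools <- detect_pools(st)
  base <- assess_continuous(st, pools, cl, slope = 0.002)
  worse <- st
  worse$B_left[10] <- 0          # strip the buffer at one station
  worse$E_right[12] <- 2.0       # widen erosion at another
  rep2 <- assess_continuous(worse, pools, cl, slope = 0.002)
  expect_lte(rep2$total, base$total)
  lv <- c(poor = 1, fair = 2, good = 3, excellent = 4)
  expect_lte(lv[rep2$metrics$M2$left$label], lv[base$metrics$M2$left$label])
  expect_lte(lv[rep2$metrics$M3$right$label], lv[base$metrics$M3$right$label])
  expect_lte(rep2$metrics$M2$left$pct_by_category["excellent"],
             base$metrics$M2$left$pct_by_category["excellent"])
})

test_that("constant-parameter sites score identically in all modes", {
  fx <- generate_site(meander_spec(axis_length = 150, amplitude = 6,
                                   wavelength = 100, width = 5, seed = 5))
  cl <- extract_centerline(fx$banks, spacing_m = 1)
  st <- extract_stations(fx$banks, fx$layers, cl)
  pools <- detect_pools(st)   # none seeded
  cont <- assess_continuous(st, pools, cl, slope = 0.002)
  tran <- assess_transects(st, 14, pools, cl, slope = 0.002)
  expect_equal(tran$total, cont$total)
  for (code in paste0("M", 2:9)) {
    mc <- cont$metrics[[code]]; mt <- tran$metrics[[code]]
    if (!is.null(mc$left)) {
      expect_equal(mt$left$label, mc$left$label)
      expect_equal(mt$right$label, mc$right$label)
    } else expect_equal(mt$label, mc$label)
  }
  # vicinity mode agrees with the per-station categories on a uniform site
  vic <- assess_vicinity(st, 14)
  expect_true(all(vic$M2_left == cont$metrics$M2$left$station_labels[1]))
  # endpoint-only sampling uses exactly the first and last stations
  idx <- streamhab:::transect_indices(st$s, 2)
  expect_equal(idx, c(1L, nrow(st)))
  expect_error(assess_transects(st, nrow(st) + 10, pools, cl, slope = 0.002),
               "more transects")
})

test_that("vicinity categories are never better than transect categories", {
  fx <- generate_site(small_meander())
  fx <- degrade(fx, c(44, 48), "M2", side = "left")
  cl <- extract_centerline(fx$banks, spacing_m = 1)
  st <- extract_stations(fx$banks, fx$layers, cl)
  vic <- assess_vicinity(st, 14)
  tran <- assess_transects(st, 14, detect_pools(st), cl, slope = 0.002)
  lv <- c(poor = 1, fair = 2, good = 3, excellent = 4)
  expect_true(all(lv[vic$M2_left] <= lv[tran$metrics$M2$left$label]))
  expect_true(all(lv[vic$M6] <= lv[tran$metrics$M6$label]))
})
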