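test_that("percentages round half away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -2.5, 22.4, 22.5)),
               c(1, 2, 3, -3, 22, 23))
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("kappa matches hand-worked and degenerate cases", {
  # perfect agreement on any diagonal table
  k <- cohens_kappa(diag(c(7, 11, 2)))
  expect_equal(k$kappa, 1)
  expect_equal(k$p_o, 1)
  # hand-worked 2x2: p_o = 0.70, p_e = 0.50, kappa = 0.40
  tab <- matrix(c(20, 10, 5, 15), 2)
  k2 <- cohens_kappa(tab)
  expect_equal(k2$p_o, 0.70)
  expect_equal(k2$p_e, 0.50)
  expect_equal(k2$kappa, 0.40)
  # rows proportional to column margins: chance-level agreement
  k3 <- cohens_kappa(matrix(c(9, 9, 21, 21), 2))
  expect_equal(k3$kappa, 0)
  # degenerate margins: everything in one cell
  k4 <- cohens_kappa(matrix(c(5, 0, 0, 0), 2))
  expect_equal(k4$kappa, 1)   # p_o = 1 despite p_e = 1
  # all mass off-diagonal: margins disjoint, chance agreement zero
  k5 <- cohens_kappa(matrix(c(0, 4, 0, 0), 2))
  expect_equal(k5$kappa, 0)
  expect_error(cohens_kappa(matrix(0, 2, 2)), "all-zero")
  expect_error(cohens_kappa(matrix(1, 2, 3)), "square")
})

test_that("kappa and chi-square match brute-force recomputation", {
  set.seed(501)
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    tab <- matrix(rpois(k * k, 6) + 1, k)
    expect_equal(cohens_kappa(tab)$kappa, oracle_kappa(tab),
                 tolerance = 1e-10)
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    obs <- matrix(rpois(r * c, 8) + 1, r)
    got <- chisq_independence(obs)
    want <- oracle_chisq(obs)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
})

test_that("kappa agrees with an independent library implementation", {
  set.seed(502)
  for (i in 1:50) {
    tab <- matrix(rpois(9, 10) + 1, 3)
    expect_equal(cohens_kappa(tab)$kappa,
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
  }
})

test_that("chi-square handles independence, 2x2 closed form and validity", {
  flat <- matrix(rep(c(12, 9, 30, 14, 9), 2), 2, byrow = TRUE)
  r <- chisq_independence(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # closed-form 2x2: n(ad-bc)^2 / (r1 r2 c1 c2) = 60*300^2/30^4
  r2 <- chisq_independence(matrix(c(10, 20, 20, 10), 2))
  expect_equal(r2$statistic, 60 * (10 * 10 - 20 * 20)^2 / 30^4)
  expect_equal(round(r2$statistic, 3), 6.667)
  expect_equal(r2$df, 1)
  # expected counts and residuals are consistent
  expect_equal(sum(r2$expected), sum(r2$observed))
  expect_equal(r2$std_residuals,
               (r2$observed - r2$expected) / sqrt(r2$expected))
  # Cochran's rule: six of ten expected cells below 5
  small <- rbind(c(2, 2, 2, 30, 30), c(8, 8, 8, 30, 30))
  rs <- chisq_independence(small)
  expect_false(rs$valid)
  # exactly 80 % of expected cells at 5 or above is still valid
  edge <- rbind(c(5, 20, 20, 20, 20), c(5, 20, 20, 20, 20))
  expect_true(chisq_independence(edge)$valid)
  # any expected cell below 1 invalidates regardless
  tiny <- rbind(c(1, 30, 30, 30, 30), c(1, 30, 30, 30, 30))
  expect_false(chisq_independence(tiny * c(0.5, 1))$valid)
  expect_true(chisq_independence(flat * 2)$valid)
  expect_error(chisq_independence(matrix(c(0, 0, 1, 2), 2, byrow = TRUE)),
               "zero row margin")
  expect_error(chisq_independence(matrix(5, 1, 2)), "2x2")
})

test_that("goodness-of-fit matches the textbook statistic", {
  obs <- c(50, 30, 20)
  r <- chisq_gof(obs)
  e <- rep(100 / 3, 3)
  expect_equal(r$statistic, sum((obs - e)^2 / e))
  expect_equal(r$df, 2)
  expect_true(r$valid)
  expect_error(chisq_gof(c(0)), "at least 2")
})

test_that("exposure tables reproduce printed-share arithmetic on fixtures", {
  # 68 of 295 assets are bus shelters -> 23 %
  types <- rep(c("bus_shelter", "other"), c(68, 227))
  ds <- fixture_dataset(assets = data.frame(
    asset_type = types,
    imd_quintile = rep(c(1, 2, 3, 4, 5), length.out = 295)))
  tb <- exposure_tables(ds)
  row <- tb$asset_type_counts
  expect_equal(row$n_assets[row$asset_type == "bus_shelter"], 68)
  expect_equal(row$pct_assets[row$asset_type == "bus_shelter"], 23)

  # quintile split 74/73/50/72/26: Q5 holds 9 % of assets
  ds2 <- fixture_dataset(assets = data.frame(
    asset_type = "other",
    imd_quintile = rep(1:5, c(74, 73, 50, 72, 26))))
  tb2 <- exposure_tables(ds2)
  expect_equal(tb2$assets_by_quintile$n_assets, c(74, 73, 50, 72, 26))
  expect_equal(tb2$assets_by_quintile$pct_assets[5], 9)

  # 156 of 295 assets medium -> 53 %
  ds3 <- fixture_dataset(assets = data.frame(
    asset_type = "other",
    size_class = rep(c("medium", "small"), c(156, 139)),
    imd_quintile = rep(1:5, length.out = 295)))
  tb3 <- exposure_tables(ds3)
  expect_equal(
    tb3$size_overall$pct_assets[tb3$size_overall$size_class == "medium"],
    53)
})

test_that("table margins are mutually consistent on generated data", {
  ds <- generate_audit(generator_config(seed = 8))
  sc <- score_products(ds)
  v <- classify_adverts(ds, sc)
  tb <- exposure_tables(ds, scores = sc, verdicts = v)
  n <- count_hierarchy(ds)
  expect_equal(sum(tb$assets_by_quintile$n_assets), n$n_assets)
  expect_equal(sum(tb$adverts_by_quintile$n_adverts), n$n_adverts)
  expect_equal(sum(tb$size_by_quintile), n$n_assets)
  expect_equal(sum(tb$asset_type_counts$n_assets), n$n_assets)
  expect_equal(tb$food_drink_by_quintile$n_food_drink +
                 tb$food_drink_by_quintile$n_other,
               tb$adverts_by_quintile$n_adverts)
  # advert-level HFSS statuses partition the food/drink adverts
  expect_equal(sum(tb$hfss_by_quintile), sum(is_food_drink_advert(ds)))
  expect_equal(unname(colSums(tb$hfss_by_quintile)),
               tb$food_drink_by_quintile$n_food_drink)
  # Fig-6-style matrix: column sums equal deduplicated type counts
  expect_equal(unname(colSums(tb$asset_product_matrix)),
               tb$product_type_counts$n_adverts)
  # compliance partition
  expect_equal(tb$compliance_by_quintile$n_food_drink,
               tb$food_drink_by_quintile$n_food_drink)
})

test_that("standardised residuals recover the deprivation gradient shape", {
  # per-quintile advert totals and food/drink counts shaped like the
  # audited gradient: elevated in Q1/Q2, depressed in Q4/Q5
  ds <- fixture_from_quintile_counts(
    total_adverts = c(100, 96, 80, 112, 49),
    food_drink = c(19, 23, 16, 8, 6))
  tests <- run_exposure_tests(ds)
  res <- tests$food_drink$std_residuals["food_drink", ]
  expect_gt(res[["Q1"]], 0)
  expect_gt(res[["Q2"]], 0)
  expect_lt(res[["Q4"]], 0)
  expect_lt(res[["Q5"]], 0)
})

test_that("sparse compliance tables are flagged invalid, mirroring small samples", {
  ds <- fixture_from_quintile_counts(
    total_adverts = c(30, 30, 30, 30, 30),
    food_drink = c(3, 2, 2, 1, 2))
  # make one food advert HFSS so both compliance rows are populated
  fd_products <- ds$products$product_id[ds$products$product_type == "food"]
  hf <- hfss_nutrients()
  for (f in names(hf)) ds$products[[f]][1] <- hf[[f]]
  tests <- run_exposure_tests(ds)
  expect_false(tests$compliance$valid)
  expect_true(tests$total$valid)
})
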