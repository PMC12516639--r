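profile_row <- function(energy = 0, satfat = 0, sugars = 0, sodium = 0,
                        fibre = 0, basis = "NSP", protein = 0, fvn = 0) {
  data.frame(energy_kj_per_100 = energy, satfat_g_per_100 = satfat,
             total_sugars_g_per_100 = sugars, sodium_mg_per_100 = sodium,
             fibre_g_per_100 = fibre, fibre_basis = basis,
             protein_g_per_100 = protein, fvn_percent = fvn)
}

test_that("A points band correctly, cap at 10, zero profile scores zero", {
  expect_equal(a_points(profile_row())$a_total, 0)
  a <- a_points(profile_row(energy = 1046, satfat = 2.0, sugars = 26,
                            sodium = 100))
  expect_equal(unlist(a[, c("energy", "satfat", "sugars", "sodium")]),
               c(energy = 3, satfat = 1, sugars = 5, sodium = 1))
  expect_equal(a$a_total, 10)
  expect_equal(a_points(profile_row(energy = 10000))$energy, 10)
  expect_error(a_points(profile_row(energy = -1)), "negative")
})

test_that("C points band on the declared fibre basis with strict edges", {
  expect_equal(c_points(profile_row(fvn = 100))$fvn, 5)
  cc <- c_points(profile_row(fvn = 50, fibre = 0.8, basis = "NSP",
                             protein = 3.0))
  expect_equal(unlist(cc[, c("fvn", "fibre", "protein")]),
               c(fvn = 1, fibre = 1, protein = 1))
  expect_equal(cc$c_total, 3)
  # a value exactly at a threshold scores in the lower band
  expect_equal(c_points(profile_row(fvn = 40))$fvn, 0)
  # 0.8 g fibre: 1 NSP point but 0 AOAC points
  expect_equal(c_points(profile_row(fibre = 0.8, basis = "AOAC"))$fibre, 0)
  expect_error(c_points(profile_row(basis = "banana")), "fibre_basis")
})

test_that("npm_score composes A and C with the protein cap and HFSS rule", {
  expect_false(npm_score(profile_row(), "drink")$is_hfss)
  expect_equal(npm_score(profile_row(), "drink")$total_score, 0)
  # the worked example: A = 10, C = (fvn 0, fibre 1, protein 1)
  r <- npm_score(profile_row(energy = 1046, satfat = 2.0, sugars = 26,
                             sodium = 100, fibre = 0.8, basis = "NSP",
                             protein = 3.0), "food")
  expect_equal(r$total_score, 8)
  expect_true(r$is_hfss)
  expect_false(r$protein_capped)
  # A >= 11 with full FVN points: protein still counted
  r2 <- npm_score(profile_row(energy = 2500, satfat = 1.5, sugars = 15,
                              sodium = 95, fibre = 1.5, basis = "NSP",
                              protein = 7, fvn = 85), "food")
  expect_equal(r2$a_total, 12)
  expect_equal(unlist(r2[, c("c_fvn", "c_fibre", "c_protein")]),
               c(c_fvn = 5, c_fibre = 2, c_protein = 4))
  expect_false(r2$protein_capped)
  expect_equal(r2$total_score, 1)
  # same A but low FVN: protein dropped
  r3 <- npm_score(profile_row(energy = 2500, satfat = 1.5, sugars = 15,
                              sodium = 95, fibre = 1.5, basis = "NSP",
                              protein = 7, fvn = 0), "food")
  expect_true(r3$protein_capped)
  expect_equal(r3$total_score, 12 - 0 - 2)
  # drinks fail at a total of 1
  expect_true(npm_score(profile_row(sugars = 5), "drink")$is_hfss)
})

test_that("scorer agrees with the brute-force band oracle", {
  set.seed(401)
  prof <- random_profiles(600)
  cls <- sample(c("food", "drink"), 600, replace = TRUE)
  got <- npm_score(prof, cls)
  for (i in seq_len(600)) {
    want <- oracle_npm(prof$energy_kj_per_100[i], prof$satfat_g_per_100[i],
                       prof$total_sugars_g_per_100[i],
                       prof$sodium_mg_per_100[i], prof$fibre_g_per_100[i],
                       prof$fibre_basis[i], prof$protein_g_per_100[i],
                       prof$fvn_percent[i], cls[i])
    expect_equal(got$total_score[i], want$total_score,
                 label = sprintf("profile %d total", i))
    expect_equal(got$is_hfss[i], want$is_hfss,
                 label = sprintf("profile %d verdict", i))
  }
})

test_that("every band edge is strict and components are monotone", {
  tabs <- npm_thresholds()
  for (comp in names(tabs)) {
    thr <- sort(tabs[[comp]]$threshold)
    below <- adaudit:::band_points(thr, comp)
    above <- adaudit:::band_points(thr + 1e-9, comp)
    expect_true(all(below < above), label = comp)
    expect_true(all(diff(adaudit:::band_points(
      seq(0, max(thr) * 1.2, length.out = 200), comp)) >= 0),
      label = comp)
  }
})

test_that("raising A nutrients never lowers the score; raising FVN never raises it", {
  set.seed(402)
  prof <- random_profiles(200)
  cls <- rep("food", 200)
  base <- npm_score(prof, cls)$total_score
  for (field in c("energy_kj_per_100", "satfat_g_per_100",
                  "total_sugars_g_per_100", "sodium_mg_per_100")) {
    up <- prof
    up[[field]] <- up[[field]] * 1.5 + 1
    expect_true(all(npm_score(up, cls)$total_score >= base), label = field)
  }
  up <- prof
  up$fvn_percent <- pmin(up$fvn_percent + 30, 100)
  expect_true(all(npm_score(up, cls)$total_score <= base))
})

test_that("FVN derivation follows the ingredients/reference/zero hierarchy", {
  ing <- data.frame(name = c("tomato", "water"),
                    declared_percent = c(60, 30),
                    is_fvn = c(TRUE, FALSE))
  expect_equal(derive_fvn_percent(ing),
               list(fvn_percent = 60, provenance = "ingredients_sum"))
  over <- data.frame(name = c("apple", "hazelnut"),
                     declared_percent = c(70, 40), is_fvn = TRUE)
  expect_equal(derive_fvn_percent(over)$fvn_percent, 100)
  expect_equal(derive_fvn_percent(NULL),
               list(fvn_percent = 0, provenance = "assumed_zero"))
  lk <- data.frame(name = "Orange Juice", fvn_percent = 95)
  expect_equal(derive_fvn_percent(NULL, name = "orange juice", lookup = lk),
               list(fvn_percent = 95, provenance = "reference_match"))
  expect_equal(derive_fvn_percent(NULL, name = "cola", lookup = lk),
               list(fvn_percent = 0, provenance = "assumed_zero"))
  bad <- data.frame(name = "x", declared_percent = 130, is_fvn = TRUE)
  expect_error(derive_fvn_percent(bad), "percent")
})

test_that("per-portion nutrition converts by weight or is not assessable", {
  r <- per_portion_to_per_100(list(total_sugars_g_per_100 = 10), 50,
                              "measured")
  expect_true(r$assessable)
  expect_equal(r$profile$total_sugars_g_per_100, 20)
  r2 <- per_portion_to_per_100(list(energy_kj_per_100 = 500), 250,
                               "handbook")
  expect_equal(r2$profile$energy_kj_per_100, 200)
  expect_false(per_portion_to_per_100(list(energy_kj_per_100 = 500), NA,
                                      "none")$assessable)
  expect_error(per_portion_to_per_100(list(energy_kj_per_100 = 1), 0,
                                      "measured"), "positive")
})

test_that("batch scoring respects NPM scope and missing nutrition", {
  prods <- fixture_products(
    c("food", "non_alcoholic_beverage", "alcoholic_beverage", "other",
      "food"),
    c("hfss", "pass", "hfss", NA, NA))
  sc <- score_products(prods)
  expect_equal(sc$in_npm_scope, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(sc$assessable, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(sc$is_hfss[1])
  expect_false(sc$is_hfss[2])
  expect_true(is.na(sc$is_hfss[3]))   # alcohol out of scope
  expect_true(is.na(sc$is_hfss[5]))   # missing nutrition
  expect_equal(sc$product_class[1:2], c("food", "drink"))
})

test_that("the shipped threshold table is checksum-pinned", {
  tabs <- npm_thresholds()
  expect_named(tabs, c("energy_kj", "fibre_aoac_g", "fibre_nsp_g",
                       "fvn_percent", "protein_g", "satfat_g",
                       "sodium_mg", "total_sugars_g"))
  expect_equal(max(tabs$fvn_percent$points), 5)
})
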