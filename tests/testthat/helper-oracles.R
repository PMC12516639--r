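# Independent brute-force oracles. Each re-derives its statistic from first
# principles (literal threshold lists, explicit double loops) without
# touching the package's implementation paths.

# NPM oracle: linear scan over literal band thresholds.
oracle_npm <- function(energy, satfat, sugars, sodium, fibre, fibre_basis,
                       protein, fvn, class) {
  band <- function(x, thr) sum(x > thr)
  a_energy <- band(energy, c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680,
                             3015, 3350))
  a_satfat <- band(satfat, 1:10)
  a_sugars <- band(sugars, c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45))
  a_sodium <- band(sodium, seq(90, 900, by = 90))
  a <- a_energy + a_satfat + a_sugars + a_sodium
  c_fvn <- if (fvn > 80) 5 else if (fvn > 60) 2 else if (fvn > 40) 1 else 0
  fib_thr <- if (toupper(fibre_basis) == "NSP")
    c(0.7, 1.4, 2.1, 2.8, 3.5) else c(0.9, 1.9, 2.9, 3.9, 4.7)
  c_fibre <- band(fibre, fib_thr)
  c_protein <- band(protein, c(1.6, 3.2, 4.8, 6.4, 8.0))
  capped <- a >= 11 && c_fvn < 5
  total <- if (capped) a - c_fvn - c_fibre else
    a - c_fvn - c_fibre - c_protein
  hfss <- if (class == "food") total >= 4 else total >= 1
  list(a_total = a, c_fvn = c_fvn, c_fibre = c_fibre,
       c_protein = c_protein, protein_capped = capped,
       total_score = total, is_hfss = hfss)
}

# Kappa oracle: explicit loops over the confusion table.
oracle_kappa <- function(tab) {
  n <- sum(tab)
  po <- 0
  for (i in seq_len(nrow(tab))) po <- po + tab[i, i]
  po <- po / n
  pe <- 0
  for (k in seq_len(nrow(tab))) {
    rk <- 0; ck <- 0
    for (j in seq_len(ncol(tab))) rk <- rk + tab[k, j]
    for (i in seq_len(nrow(tab))) ck <- ck + tab[i, k]
    pe <- pe + rk * ck
  }
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

# Pearson chi-square oracle: explicit loops for expected counts and the
# statistic.
oracle_chisq <- function(obs) {
  n <- sum(obs)
  rs <- rowSums(obs); cs <- colSums(obs)
  stat <- 0
  for (i in seq_len(nrow(obs))) {
    for (j in seq_len(ncol(obs))) {
      e <- rs[i] * cs[j] / n
      stat <- stat + (obs[i, j] - e)^2 / e
    }
  }
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  list(statistic = unname(stat), df = df,
       p_value = stats::pchisq(unname(stat), df, lower.tail = FALSE))
}

# Random nutrient profiles spanning the band tables (including exact
# threshold values with some probability).
random_profiles <- function(n) {
  pick <- function(max, thresholds) {
    x <- stats::runif(n, 0, max)
    hit <- stats::runif(n) < 0.1
    x[hit] <- sample(thresholds, sum(hit), replace = TRUE)
    x
  }
  data.frame(
    energy_kj_per_100 = pick(4000, seq(335, 3350, by = 335)),
    satfat_g_per_100 = pick(14, 1:10),
    total_sugars_g_per_100 = pick(55, c(4.5, 9, 13.5, 18, 22.5, 27, 31,
                                        36, 40, 45)),
    sodium_mg_per_100 = pick(1100, seq(90, 900, by = 90)),
    fibre_g_per_100 = pick(6, c(0.7, 1.4, 2.1, 2.8, 3.5, 0.9, 1.9, 2.9,
                                3.9, 4.7)),
    fibre_basis = sample(c("NSP", "AOAC"), n, replace = TRUE),
    protein_g_per_100 = pick(12, c(1.6, 3.2, 4.8, 6.4, 8.0)),
    fvn_percent = pick(100, c(40, 60, 80)))
}
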