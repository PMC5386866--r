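test_that("degenerate meiosis inputs behave as specified", {
  set.seed(1)
  t0 <- simulate_meiosis(0)
  expect_equal(length(t0$chiasmata), 0L)
  expect_true(all(vapply(t0$gametes, function(g) length(g$breaks) == 0,
                         logical(1))))
  expect_error(simulate_meiosis(-1), "nonnegative")
})

test_that("uniform meiosis matches the Poisson chiasma model", {
  set.seed(42)
  n <- 10000
  xo <- numeric(n); chi <- numeric(n); rec <- logical(n)
  for (i in seq_len(n)) {
    tet <- simulate_meiosis(100)
    chi[i] <- length(tet$chiasmata)
    g <- tet$gametes[[sample.int(4, 1)]]
    xo[i] <- length(g$breaks)
    rec[i] <- sibmap:::phase_at(g, 45) != sibmap:::phase_at(g, 55)
  }
  ## E chiasmata per bivalent = 2, E crossovers per gamete = 1
  expect_lt(abs(mean(chi) - 2), 4 * sqrt(2 / n))
  expect_lt(abs(mean(xo) - 1), 4 * sqrt(1 / n))
  ## two markers 10 cM apart: Haldane r = (1 - exp(-0.2)) / 2 = 0.0906
  r_true <- 0.5 * (1 - exp(-0.2))
  expect_lt(abs(mean(rec) - r_true), 4 * sqrt(r_true * (1 - r_true) / n))
  ## every chiasma marks exactly two of four chromatids
  set.seed(7)
  tet <- simulate_meiosis(300)
  expect_equal(sum(lengths(lapply(tet$gametes, `[[`, "breaks"))),
               2 * length(tet$chiasmata))
})

test_that("suppression window lowers crossover density inside it", {
  set.seed(11)
  prof <- sibmap:::intensity_profile(100, 50, 20, 0.2)
  n_in <- n_out <- 0
  for (i in 1:10000) {
    tet <- simulate_meiosis(100, prof)
    n_in <- n_in + sum(tet$chiasmata >= 40 & tet$chiasmata <= 60)
    n_out <- n_out + sum(tet$chiasmata < 40 | tet$chiasmata > 60)
  }
  expect_lt(n_in / 20, n_out / 80)           # density, per cM
  ratio <- (n_in / 20) / (n_out / 80)
  expect_lt(abs(ratio - 0.2), 0.05)
})

test_that("noiseless simulation round-trips to truth phases", {
  cfg <- sim_config(n_lg = 2, lg_lengths = c(60, 70), n_progeny = 50,
                    marker_density = 0.8, missing_rate = 0, error_rate = 0,
                    seed = 3)
  sim <- simulate_population(cfg)
  g <- sim$geno
  am <- transmitted_alleles(g, "mother")
  panel <- sim$truth$markers
  expect_true(all(g$calls != "--"))
  for (i in seq_len(nrow(panel))) {
    if (!sibmap:::seg_informative(panel$seg[i], "mother")) next
    truth_allele <- as.integer(
      sim$truth$phases_all$mother[, panel$marker_id[i]] == panel$phase_m[i])
    obs <- am[panel$marker_id[i], ]
    keep <- !is.na(obs)           # hk heterozygotes are unobservable
    expect_identical(unname(obs[keep]), truth_allele[keep])
    if (panel$seg[i] %in% c("lmxll", "efxeg", "abxcd")) {
      expect_true(all(keep))
    }
  }
})

test_that("a viability locus shifts the allele ratio to 1:(s)", {
  cfg <- sim_config(n_lg = 1, lg_lengths = 80, n_progeny = 1000,
                    marker_density = 0.4, type_mix = c(lmxll = 1),
                    missing_rate = 0, error_rate = 0,
                    sd_loci = data.frame(lg = "LG01", pos = 40,
                                         parent = "mother", allele = 0,
                                         s = 0.5),
                    seed = 9)
  sim <- simulate_population(cfg)
  ph <- sim$truth$phases_all$mother
  pos <- sim$truth$markers$pos
  nearest <- which.min(abs(pos - 40))
  freq_surv <- mean(ph[, nearest] == 0)
  ## expected favoured-allele frequency 1 / (1 + 0.5) = 2/3
  expect_lt(abs(freq_surv - 2 / 3), 4 * sqrt(2 / 9 / 1000))
})

test_that("finite tetrad pools bound paternal gamete diversity", {
  cfg <- sim_config(n_lg = 1, lg_lengths = 90, n_progeny = 18,
                    marker_density = 0.5, tetrad_pool_size = 5,
                    missing_rate = 0, error_rate = 0, seed = 13)
  sim <- simulate_population(cfg)
  expect_true(all(sim$truth$tetrads$tetrad <= 5))
  xo <- sim$truth$crossovers
  pat <- xo[xo$parent == "father", ]
  keysets <- tapply(pat$pos, pat$progeny, function(p)
    paste(sort(p), collapse = ","))
  n_zero <- sum(!unique(sim$truth$tetrads$progeny) %in% names(keysets))
  expect_lte(length(unique(keysets)) + min(n_zero, 1), 4 * 5)
  ## pool too small to supply the family
  expect_error(sim_config(n_lg = 1, lg_lengths = 50, n_progeny = 50,
                          tetrad_pool_size = 10), "tetrad pool")
})

test_that("identical seeds give byte-identical outputs", {
  cfg <- sim_config(n_lg = 2, lg_lengths = c(50, 60), n_progeny = 25,
                    marker_density = 0.5, seed = 77)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_genotypes(s1$geno, p1)
  write_genotypes(s2$geno, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(s1$truth$crossovers, s2$truth$crossovers)
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
  expect_error(sim_config(type_mix = c(lmxll = 0.5)), "sum to 1")
  expect_error(sim_config(n_lg = 1, lg_lengths = 50, centromere_pos = 60),
               "centromere")
  expect_error(sim_config(n_lg = 1, lg_lengths = 50, centromere_pos = 5,
                          suppression_width = 20), "window")
})
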