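lm_record <- function(n_lm, n_ll) {
  calls <- c(rep("lm", n_lm), rep("ll", n_ll))
  names(calls) <- paste0("P", seq_along(calls))
  calls
}

test_that("segregation chi-square matches hand arithmetic", {
  expect_equal(unname(sd_chi2("lmxll", lm_record(50, 50))[c("chi2", "p")]),
               c(0, 1))
  r4060 <- sd_chi2("lmxll", lm_record(40, 60))
  expect_equal(unname(r4060["chi2"]), 4)
  expect_equal(unname(r4060["p"]), pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(unname(r4060["p"]), 0.1)          # distorted at alpha = .1
  r5545 <- sd_chi2("lmxll", lm_record(55, 45))
  expect_equal(unname(r5545["chi2"]), 1)
  expect_gt(unname(r5545["p"]), 0.1)
  ## genotype-class variant for hk x hk
  hk <- c(rep("hh", 25), rep("hk", 50), rep("kk", 25))
  expect_equal(unname(sd_chi2("hkxhk", hk, genotype_classes = TRUE)["chi2"]),
               0)
})

test_that("SDR calling needs long enough, dense enough runs", {
  mkscan <- function(distorted, pos) {
    structure(data.frame(lg = "LG01", marker = paste0("M", seq_along(pos)),
                         position = pos, chi2 = 1,
                         p = ifelse(distorted, 0.01, 0.9),
                         distorted = distorted),
              class = c("sd_scan", "data.frame"))
  }
  expect_equal(nrow(find_sdrs(mkscan(rep(FALSE, 10), 1:10))), 0L)
  one <- find_sdrs(mkscan(rep(TRUE, 6), seq(0, 4, length.out = 6)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_markers, 6L)
  ## a 6 cM gap splits the run
  split_pos <- c(0, 1, 2, 9, 10, 11)
  expect_equal(nrow(find_sdrs(mkscan(rep(TRUE, 6), split_pos))), 0L)
  ## runs shorter than min_run are not regions
  expect_equal(nrow(find_sdrs(mkscan(c(rep(TRUE, 4), FALSE, TRUE), 1:6))),
               0L)
})

toy_profile <- function() {
  ph <- matrix(c(0L, 0L, 0L, 0L,
                 0L, 0L, 1L, 1L,
                 0L, 1L, 1L, 1L,
                 1L, 1L, 1L, 0L), 4, 4, byrow = TRUE,
               dimnames = list(paste0("P", 1:4), paste0("M", 1:4)))
  rf_profile(ph, c(0, 1, 2, 3))
}

test_that("RF profiles count phase differences from both terminals", {
  prof <- toy_profile()
  expect_equal(prof$rf_from_start, c(NA, 0.25, 0.5, 0.75))
  expect_equal(prof$rf_from_end, c(0.75, 0.5, 0.25, NA))
  ## same pairwise comparison seen from either anchor
  expect_equal(prof$rf_from_start[4], prof$rf_from_end[1])
  ## zero recombinants give a zero profile
  flat <- matrix(0L, 4, 3, dimnames = list(paste0("P", 1:4),
                                           paste0("M", 1:3)))
  pf <- rf_profile(flat, c(0, 1, 2))
  expect_true(all(pf$rf_from_start[-1] == 0))
})

test_that("the centromere span interpolates the curve crossing", {
  prof <- toy_profile()
  cs <- centromere_span(prof)
  ## curves cross midway between markers 2 and 3 (0.25/0.5 vs 0.5/0.25)
  expect_equal(cs$intersection, 1.5)
  ## both directional curves reach 0.45 one marker out: central span
  expect_equal(cs$classification, "metacentric")
  expect_equal(c(cs$span_start, cs$span_end), c(1, 2))
  ## mirrored map gives the mirrored intersection
  ph <- matrix(c(0L, 0L, 0L, 0L,
                 0L, 0L, 1L, 1L,
                 0L, 1L, 1L, 1L,
                 1L, 1L, 1L, 0L), 4, 4, byrow = TRUE)
  mir <- ph[, 4:1]
  colnames(mir) <- paste0("M", 1:4); rownames(mir) <- paste0("P", 1:4)
  cs2 <- centromere_span(rf_profile(mir, c(0, 1, 2, 3)))
  expect_equal(cs2$intersection, 3 - cs$intersection)
  ## curves that never cross -> undetermined, no span
  ph3 <- matrix(c(rep(0L, 4), 0L, 0L, 1L, 1L, rep(1L, 4)), 4, 3,
                dimnames = list(paste0("P", 1:4), paste0("M", 1:3)))
  prof3 <- rf_profile(ph3, c(0, 1, 2))
  prof3$rf_from_start <- c(NA, 0.4, 0.45)
  prof3$rf_from_end <- c(0.1, 0.05, NA)
  expect_true(is.na(centromere_span(prof3)$intersection))
})

test_that("a central suppression window is recovered as metacentric", {
  cfg <- sim_config(n_lg = 1, lg_lengths = 90, n_progeny = 250,
                    marker_density = 0.7, type_mix = c(lmxll = 1),
                    missing_rate = 0, error_rate = 0,
                    suppression_factor = 0.1, seed = 33)
  sim <- simulate_population(cfg)
  prof <- rf_profile(sim$truth$phases_all$mother,
                     sim$truth$maps$mother$position)
  cs <- centromere_span(prof)
  truth_g <- sim$truth$centromeres$gpos -
    min(sim$truth$markers$gpos)
  expect_lt(abs(cs$intersection - truth_g), 12)
})

test_that("collinearity pairs LGs and aligns orientation", {
  m1 <- genmap(data.frame(lg = "1", marker = LETTERS[1:10],
                          position = 0:9))
  expect_equal(collinearity(m1, m1)$rho, 1)
  ## one adjacent swap among 5 shared markers: rho = 1 - 6*2/(5*24) = 0.9
  m2 <- genmap(data.frame(lg = "1", marker = c("A", "C", "B", "D", "E"),
                          position = 0:4))
  m3 <- genmap(data.frame(lg = "1", marker = c("A", "B", "C", "D", "E"),
                          position = 0:4))
  expect_equal(collinearity(m2, m3)$rho, 0.9)
  ## a reversed map scores +1 after orientation alignment
  mr <- genmap(data.frame(lg = "1", marker = rev(LETTERS[1:10]),
                          position = 0:9))
  expect_equal(collinearity(m1, mr)$rho, 1)
  ## fewer than 2 shared markers -> NA
  ma <- genmap(data.frame(lg = "1", marker = c("A", "Z"), position = 0:1))
  mb <- genmap(data.frame(lg = "1", marker = c("A", "Q"), position = 0:1))
  expect_true(is.na(collinearity(ma, mb)$rho))
})

test_that("the paired maternal/paternal test behaves at its limits", {
  same <- rep(0.8, 12)
  res <- maternal_paternal_compare(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$mean_diff, 0)
  shift <- maternal_paternal_compare(same + 0.18, same)
  expect_equal(shift$mean_diff, 0.18)
  expect_equal(shift$t, Inf)
  expect_equal(shift$p, 0)
  expect_equal(shift$frac_maternal_ge, 1)
  set.seed(8)
  mat <- rnorm(36, 1.0, 0.05); pat <- mat - rnorm(36, 0.18, 0.05)
  res2 <- maternal_paternal_compare(mat, pat)
  expect_lt(res2$p, 1e-7)
  expect_error(maternal_paternal_compare(1, 1), "2 LG pairs")
})

test_that("coancestry recursion reproduces textbook kinship", {
  ped <- data.frame(
    id = c("F1", "F2", "F3", "X", "Y", "Z"),
    sire = c(NA, NA, NA, "F1", "F1", "X"),
    dam = c(NA, NA, NA, "F2", "F2", "F3"),
    stringsAsFactors = FALSE)
  expect_equal(coancestry(ped, "F1", "F1"), 0.5)   # non-inbred self
  expect_equal(coancestry(ped, "F1", "F2"), 0)
  expect_equal(coancestry(ped, "F1", "X"), 0.25)   # parent-offspring
  expect_equal(coancestry(ped, "X", "Y"), 0.25)    # full sibs
  expect_equal(coancestry(ped, "Y", "Z"), 0.125)   # avuncular
  ## symmetry and bounds on all pairs
  for (a in ped$id) for (b in ped$id) {
    f1 <- coancestry(ped, a, b)
    expect_equal(f1, coancestry(ped, b, a))
    expect_gte(f1, 0); expect_lte(f1, 1)
  }
  cyc <- data.frame(id = c("A", "B"), sire = c("B", "A"),
                    dam = c(NA, NA), stringsAsFactors = FALSE)
  expect_error(coancestry(cyc, "A", "B"), "cycle")
})

test_that("a null genome-wide scan is calibrated up to linkage blocks", {
  cfg <- sim_config(n_lg = 6, lg_lengths = rep(90, 6), n_progeny = 200,
                    marker_density = 0.4, type_mix = c(lmxll = 1),
                    missing_rate = 0, error_rate = 0, seed = 55)
  sim <- simulate_population(cfg)
  scan <- sd_scan(sim$geno, sim$truth$maps$mother)
  frac_lg <- tapply(scan$distorted, scan$lg, mean)
  set.seed(56)
  boot <- replicate(2000, mean(sample(frac_lg, replace = TRUE)))
  ci <- stats::quantile(boot, c(0.005, 0.995))
  expect_true(ci[1] <= 0.10 && 0.10 <= ci[2])
})
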