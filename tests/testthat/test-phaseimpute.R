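test_that("phase assignment couples adjacent markers and re-flips", {
  set.seed(5)
  truth <- matrix(rbinom(300, 1, 0.5), nrow = 100)  # 100 progeny x 3 markers
  truth[, 2] <- truth[, 1]; truth[, 3] <- truth[, 1]
  x <- t(truth)
  rownames(x) <- c("A", "B", "C")
  x["B", ] <- 1L - x["B", ]          # deliberately flipped marker
  ph <- assign_phase(x, c("A", "B", "C"))
  expect_equal(unname(ph$flip), c(0L, 1L, 0L))
  expect_identical(ph$phased[, "B"], ph$phased[, "A"])
  ## single marker: anchored to phase A
  single <- assign_phase(x, "A")
  expect_equal(unname(single$flip), 0L)
})

test_that("imputation follows the two-interval posterior", {
  ph <- matrix(c(0L, NA, 0L), 1, dimnames = list("P1", c("A", "B", "C")))
  res <- impute_missing(ph, c(0, 1, 2))
  ## posterior (1-r)^2 / ((1-r)^2 + r^2) ~ 0.9996 at r = kosambi_r(1)
  expect_equal(res$phased[1, "B"], 0L)
  expect_equal(res$n_imputed, 1L)
  ## disagreeing equidistant flanks stay missing
  ph2 <- matrix(c(0L, NA, 1L), 1, dimnames = list("P1", c("A", "B", "C")))
  expect_true(is.na(impute_missing(ph2, c(0, 1, 2))$phased[1, "B"]))
  ## terminal marker with a single close flank is imputed
  ph3 <- matrix(c(NA, 1L, 1L), 1, dimnames = list("P1", c("A", "B", "C")))
  r <- 0.01
  d <- kosambi_d(r)
  expect_equal(impute_missing(ph3, c(0, d, 10))$phased[1, "A"], 1L)
  ## both flanks missing -> left missing
  ph4 <- matrix(c(NA_integer_, NA, NA), 1,
                dimnames = list("P1", c("A", "B", "C")))
  expect_true(all(is.na(impute_missing(ph4, c(0, 1, 2))$phased)))
})

test_that("imputation is monotone and accurate on simulated data", {
  cfg <- sim_config(n_lg = 1, lg_lengths = 80, n_progeny = 120,
                    marker_density = 1, type_mix = c(lmxll = 1),
                    missing_rate = 0, error_rate = 0, seed = 15)
  sim <- simulate_population(cfg)
  truth <- sim$truth$phases_all$mother
  pos <- sim$truth$maps$mother$position
  set.seed(16)
  masked <- truth
  holes <- matrix(runif(length(truth)) < 0.1, nrow(truth))
  masked[holes] <- NA_integer_
  res <- impute_missing(masked, pos)
  ## observed entries untouched
  expect_identical(res$phased[!holes], truth[!holes])
  ## missingness only decreases
  expect_lte(sum(is.na(res$phased)), sum(holes))
  ## accuracy over imputed entries
  filled <- holes & !is.na(res$phased)
  expect_gte(mean(res$phased[filled] == truth[filled]), 0.99)
})

test_that("hk resolution follows per-parent flank posteriors", {
  calls <- c("hh", "kk", "hk", "hk", "--")
  mk_ctx <- function(sym) {
    ## 3-marker LG: flanks at 1 cM both sides, focal in the middle
    ph <- matrix(NA_integer_, 5, 3,
                 dimnames = list(paste0("P", 1:5), c("L", "X", "R")))
    ph[, "L"] <- sym; ph[, "R"] <- sym
    list(phased = ph, positions = c(0, 1, 2), col = 2L, flip = 0L)
  }
  ## progeny 3: both parents' flanks say phase A (symbol 0 = allele 0 = h)
  ## progeny 4: mother says A, father ambiguous (flanks NA)
  ctx_m <- mk_ctx(c(0L, 1L, 0L, 0L, 0L))
  ctx_f <- mk_ctx(c(1L, 0L, 1L, NA, 0L))
  ctx_f$phased[4, c("L", "R")] <- NA_integer_
  res <- resolve_hk(calls, ctx_m, ctx_f)
  expect_equal(res$am, c(0L, 1L, 0L, 0L, NA))
  expect_equal(res$ap, c(0L, 1L, 1L, NA, NA))
  ## no context at all: only homozygotes resolve
  res2 <- resolve_hk(calls, NULL, NULL)
  expect_equal(res2$am, c(0L, 1L, NA, NA, NA))
})

test_that("splitting biparental markers recodes deterministically", {
  g <- cp_geno(data.frame(marker_id = c("Q1", "Q2"),
                          seg = c("abxcd", "hkxhk"), phase = "--"),
               matrix(c("ac", "ad", "bc", "bd",
                        "hh", "hk", "kk", "hk"), 2, byrow = TRUE,
                      dimnames = list(NULL, paste0("P", 1:4))))
  resolved <- list(Q2 = list(am = c(0L, 0L, 1L, NA),
                             ap = c(0L, 1L, 1L, NA)))
  sp <- split_biparental(g, resolved)
  expect_setequal(sp$markers$marker_id, c("Q1_m", "Q1_p", "Q2_m", "Q2_p"))
  ## spec dictionary: first allele -> lm / nn
  expect_equal(unname(sp$calls["Q1_m", ]), c("lm", "lm", "ll", "ll"))
  expect_equal(unname(sp$calls["Q1_p", ]), c("nn", "np", "nn", "np"))
  expect_equal(unname(sp$calls["Q2_m", ]), c("lm", "lm", "ll", "--"))
  expect_equal(unname(sp$calls["Q2_p", ]), c("nn", "np", "np", "--"))
  ## cardinality: n calls per split marker
  expect_equal(ncol(sp$calls), 4L)
})
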