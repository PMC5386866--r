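test_that("two-point estimates match their closed forms", {
  a <- rep(0L, 20)
  expect_equal(twopoint(a, a), list(r = 0, lod = 20 * log10(2),
                                    n_informative = 20L))
  b <- a; b[1:2] <- 1L
  expect_equal(twopoint(a, b)$r, 0.1)
  half <- c(rep(1L, 10), rep(0L, 10))
  est <- twopoint(a, half)
  expect_equal(est$r, 0.5)
  expect_equal(est$lod, 0)
  ## zero informative progeny
  expect_true(is.na(twopoint(c(NA_integer_, NA), c(0L, 1L))$r))
})

test_that("r is symmetric and LOD invariant to allele relabelling", {
  set.seed(2)
  x <- matrix(rbinom(60, 1, 0.5), nrow = 3,
              dimnames = list(c("A", "B", "C"), NULL))
  x[sample(60, 6)] <- NA
  tp <- twopoint_matrix(x)
  expect_equal(tp$r, t(tp$r))
  x2 <- x; x2["B", ] <- 1L - x2["B", ]
  tp2 <- twopoint_matrix(x2)
  expect_equal(tp$r, tp2$r)
  expect_equal(tp$lod, tp2$lod)
})

test_that("grouping follows the LOD threshold", {
  set.seed(3)
  linked <- matrix(rbinom(40, 1, 0.5), nrow = 2)
  linked[2, ] <- linked[1, ]
  rownames(linked) <- c("A", "B")
  tp <- twopoint_matrix(linked)
  expect_equal(length(group_markers(tp)$groups), 1L)
  expect_equal(length(group_markers(tp, lod_threshold = Inf)$groups), 0L)
  expect_equal(sort(group_markers(tp, lod_threshold = Inf)$unplaced),
               c("A", "B"))
})

test_that("a simulated multi-LG panel groups into the true LGs", {
  cfg <- sim_config(n_lg = 3, lg_lengths = c(80, 90, 100), n_progeny = 150,
                    marker_density = 0.6, type_mix = c(lmxll = 1),
                    missing_rate = 0, error_rate = 0, seed = 21)
  sim <- simulate_population(cfg)
  x <- transmitted_alleles(sim$geno, "mother")
  grp <- group_markers(twopoint_matrix(x))
  expect_equal(length(grp$groups), 3L)
  truth_lg <- sim$truth$markers$lg
  names(truth_lg) <- sim$truth$markers$marker_id
  for (g in grp$groups) {
    expect_equal(length(unique(truth_lg[g])), 1L)
  }
})

test_that("Kosambi functions evaluate and invert exactly", {
  expect_equal(kosambi_d(0), 0)
  expect_equal(kosambi_d(0.25), 25 * log(3))
  expect_equal(kosambi_r(10), 0.5 * tanh(0.2))
  r <- seq(0, 0.49, by = 0.01)
  expect_lt(max(abs(kosambi_r(kosambi_d(r)) - r)), 1e-12)
  expect_error(kosambi_d(0.5), "infinite")
})

test_that("ordering minimises SARF and canonicalises orientation", {
  tp <- tp_from_positions(c(A = 0, B = 5, C = 10))
  expect_equal(order_markers(tp), c("A", "B", "C"))
  tp_rev <- tp_from_positions(c(C = 0, B = 5, A = 10))
  expect_equal(order_markers(tp_rev), c("A", "B", "C"))
  tp2 <- tp_from_positions(c(B = 0, A = 7))
  expect_equal(order_markers(tp2), c("A", "B"))
})

test_that("a noiseless simulated LG is ordered exactly", {
  cfg <- sim_config(n_lg = 1, lg_lengths = 90, n_progeny = 200,
                    marker_density = 0.5, type_mix = c(lmxll = 1),
                    missing_rate = 0, error_rate = 0, seed = 31)
  sim <- simulate_population(cfg)
  x <- transmitted_alleles(sim$geno, "mother")
  tp <- twopoint_matrix(x)
  ord <- order_markers(tp)
  pos <- regression_distances(ord, tp)
  ## order is defined at the bin level: cosegregating markers tie
  est <- genmap(data.frame(lg = "1", marker = ord, position = unname(pos)))
  reps <- vapply(split(est$marker, est$bin), `[[`, character(1), 1)
  est <- genmap(as.data.frame(est)[est$marker %in% reps, ])
  cc <- collinearity(est, sim$truth$maps$mother)
  expect_gte(cc$rho, 0.9995)
})

test_that("regression distances reproduce closed-form and additive cases", {
  x <- matrix(0L, 2, 20, dimnames = list(c("A", "B"), NULL))
  x[2, 1:2] <- 1L                      # r = 0.1
  tp <- twopoint_matrix(x)
  pos <- regression_distances(c("A", "B"), tp)
  expect_equal(unname(pos), c(0, kosambi_d(0.1)), tolerance = 1e-10)
  ## perfectly additive distances recovered to < 0.1 cM RMSE
  truth <- c(A = 0, B = 3, C = 9, D = 14, E = 22, F = 30)
  tpa <- tp_from_positions(truth)
  fit <- regression_distances(names(truth), tpa)
  expect_lt(sqrt(mean((fit - truth)^2)), 0.1)
  ## a cosegregating bin collapses to one position
  xb <- matrix(rep(c(0L, 1L), each = 10), 3, 20, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), NULL))
  tpb <- twopoint_matrix(xb)
  posb <- regression_distances(c("A", "B", "C"), tpb)
  expect_true(all(posb == 0))
})

test_that("iterative cleaning removes bad markers and only bad markers", {
  set.seed(41)
  cfg <- sim_config(n_lg = 1, lg_lengths = 80, n_progeny = 200,
                    marker_density = 0.4, type_mix = c(lmxll = 1),
                    missing_rate = 0, error_rate = 0, seed = 41)
  sim <- simulate_population(cfg)
  x <- transmitted_alleles(sim$geno, "mother")
  tp <- twopoint_matrix(x)
  ord <- order_markers(tp)
  clean0 <- clean_iterative(ord, tp)
  expect_equal(nrow(clean0$removed), 0L)
  ## inject a 15% error marker
  bad <- x
  mid <- ord[floor(length(ord) / 2)]
  flip <- sample(ncol(x), 30)
  bad[mid, flip] <- 1L - bad[mid, flip]
  tpb <- twopoint_matrix(bad)
  ordb <- order_markers(tpb)
  cleanb <- clean_iterative(ordb, tpb)
  expect_true(mid %in% cleanb$removed$marker)
  expect_equal(cleanb$removed$marker[1], mid)
  ## infinite thresholds are the identity
  ident <- clean_iterative(ordb, tpb, fit_max = Inf, stress_max = Inf,
                           stress_cm_max = Inf)
  expect_equal(nrow(ident$removed), 0L)
  ## cleaning never increases map length
  expect_lte(max(cleanb$pos), max(clean_iterative(
    ordb, tpb, fit_max = Inf, stress_max = Inf,
    stress_cm_max = Inf)$pos) + 1e-9)
})

test_that("framework insertion places a marker by triangulation", {
  truth <- c(A = 0, B = 10, C = 20, D = 30)
  tp <- tp_from_positions(c(truth, X = 14))
  p <- insert_marker(tp, "X", names(truth), truth)
  expect_equal(p, 14, tolerance = 0.2)
  ## beyond the terminal marker
  tp2 <- tp_from_positions(c(truth, Y = -4))
  expect_equal(insert_marker(tp2, "Y", names(truth), truth), -4,
               tolerance = 0.3)
})
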