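simple_map <- function(markers, pos, lg = "1") {
  genmap(data.frame(lg = lg, marker = markers, position = pos,
                    stringsAsFactors = FALSE))
}

test_that("constraint generation matches hand enumeration", {
  m1 <- simple_map(c("A", "B", "C", "D", "E"), c(0, 1, 2, 3, 4))
  m2 <- simple_map(c("C", "D", "E", "F", "G"), c(0, 1, 2, 3, 4))
  ## k = 2, two 5-position maps: per map 4 lag-1 + 3 lag-2 = 7 intervals
  cons <- build_constraints(list(a = m1, b = m2), k = 2)
  expect_equal(nrow(cons$intervals), 14L)
  ## 3 + 4 adjacent pairs; the shared C-D edge aggregates (weight 2)
  expect_equal(nrow(cons$order_edges), 6L)
  expect_equal(cons$order_edges$weight[cons$order_edges$from == "C" &
                                         cons$order_edges$to == "D"], 2)
  ## one map, k = 1: exactly its adjacent intervals
  c1 <- build_constraints(list(a = m1), k = 1)
  expect_equal(nrow(c1$intervals), 4L)
  expect_equal(c1$intervals$dist, rep(1, 4))
  ## identical duplicated maps double the (consistent) data
  c2 <- build_constraints(list(a = m1, b = m1), k = 1)
  expect_equal(nrow(c2$intervals), 8L)
  ## tied positions become zero-length data against the representative
  m3 <- simple_map(c("A", "B", "C"), c(0, 0, 5))
  c3 <- build_constraints(list(a = m3), k = 1)
  expect_true(any(c3$intervals$dist == 0))
})

test_that("conflict resolution deletes minority arcs deterministically", {
  m1 <- simple_map(c("A", "B", "C", "D"), c(0, 2, 4, 6))
  m2 <- simple_map(c("A", "C", "B", "D"), c(0, 2, 4, 6))
  ## collinear inputs: nothing deleted
  res0 <- resolve_conflicts(build_constraints(list(a = m1, b = m1),
                                              k = 1)$order_edges)
  expect_equal(nrow(res0$deleted), 0L)
  ## 1 vs 1 disagreement: exactly one arc goes, by the documented
  ## tie-break (equal weight and support -> lexicographic from/to)
  res1 <- resolve_conflicts(build_constraints(list(a = m1, b = m2),
                                              k = 1)$order_edges)
  expect_equal(nrow(res1$deleted), 1L)
  expect_equal(res1$deleted$from, "B")
  expect_equal(res1$deleted$to, "C")
  ## 2 vs 1: the minority arc is deleted
  res2 <- resolve_conflicts(build_constraints(list(a = m1, b = m2, c = m1),
                                              k = 1)$order_edges)
  expect_equal(nrow(res2$deleted), 1L)
  expect_equal(paste(res2$deleted$from, res2$deleted$to), "C B")
})

test_that("L1 consensus positions solve the documented examples", {
  ## single map: identity (zero objective attainable)
  m1 <- simple_map(c("A", "B", "C"), c(0, 5, 10))
  cm1 <- merge_maps(list(a = m1), k_max = 3)
  expect_equal(cm1$map$position, c(0, 5, 10))
  expect_equal(cm1$diagnostics[["1"]]$k, 1L)    # ties break small
  expect_equal(unname(cm1$diagnostics[["1"]]$rmse), 0)
  ## two maps A/B/C at 0/5/10 and 0/6/12: canonical B = 5.5, C = 11
  m2 <- simple_map(c("A", "B", "C"), c(0, 6, 12))
  cm2 <- merge_maps(list(a = m1, b = m2), k_max = 1)
  expect_equal(cm2$map$position, c(0, 5.5, 11))
  ## consensus length never exceeds the components plus disagreements
  expect_lte(max(cm2$map$position), 12)
})

test_that("exact LP and coordinate descent agree on small instances", {
  set.seed(77)
  for (rep in 1:5) {
    truth <- cumsum(c(0, runif(8, 0.5, 5)))
    names(truth) <- paste0("M", 1:9)
    maps <- lapply(1:3, function(i) {
      keep <- sort(sample(9, 7))
      simple_map(names(truth)[keep],
                 truth[keep] - truth[keep[1]] + rnorm(7, 0, 0.2))
    })
    maps <- lapply(maps, function(m) {
      m$position <- cummax(m$position); genmap(as.data.frame(m)) })
    names(maps) <- paste0("c", 1:3)
    cons <- build_constraints(maps, k = 2)
    res <- resolve_conflicts(cons$order_edges)
    ord <- sibmap:::consensus_order(
      sort(unique(unlist(lapply(maps, `[[`, "marker")))), res$kept, maps)
    pos_cd <- lp_positions(ord, cons$intervals, exact_max = 0)    # CD only
    pos_lp <- lp_positions(ord, cons$intervals, exact_max = 1e6)  # simplex
    obj <- function(p) {
      s <- 0
      for (i in seq_len(nrow(cons$intervals))) {
        s <- s + abs(abs(p[cons$intervals$to[i]] -
                           p[cons$intervals$from[i]]) -
                       cons$intervals$dist[i])
      }
      s
    }
    expect_lt(abs(obj(pos_cd) - obj(pos_lp)), 0.05)
  }
})

test_that("unanimous orders survive merging and merging is idempotent", {
  set.seed(78)
  truth <- cumsum(c(0, runif(11, 0.5, 4)))
  names(truth) <- sprintf("M%02d", 1:12)
  maps <- lapply(1:4, function(i) {
    keep <- sort(sample(12, 9))
    simple_map(names(truth)[keep], truth[keep] - truth[keep[1]])
  })
  names(maps) <- paste0("p", 1:4)
  cm <- merge_maps(maps, k_max = 3)
  ## all components agree on order, so the consensus preserves it
  expect_equal(cm$map$marker, names(truth))
  expect_equal(nrow(cm$diagnostics[["1"]]$deleted), 0L)
  ## consensus of the consensus returns the same map
  cm2 <- merge_maps(list(cons = cm$map), k_max = 3)
  expect_equal(cm2$map$marker, cm$map$marker)
  expect_equal(cm2$map$position, cm$map$position, tolerance = 1e-9)
})

test_that("consensus LG assignment joins component LGs by shared markers", {
  mA <- genmap(data.frame(lg = c("1", "1", "2", "2"),
                          marker = c("A", "B", "C", "D"),
                          position = c(0, 5, 0, 5)))
  mB <- genmap(data.frame(lg = c("7", "7", "9", "9"),
                          marker = c("A", "B", "C", "D"),
                          position = c(0, 4, 0, 6)))
  groups <- consensus_groups(list(x = mA, y = mB))
  expect_equal(length(unique(groups$consensus)), 2L)
  cm <- merge_maps(list(x = mA, y = mB), k_max = 1)
  expect_equal(length(unique(cm$map$lg)), 2L)
  ## zero shared markers cannot anchor a consensus group
  mC <- genmap(data.frame(lg = "1", marker = c("Q", "R"),
                          position = c(0, 3)))
  g2 <- consensus_groups(list(x = mA, z = mC))
  expect_equal(length(unique(g2$consensus)), 3L)
})

test_that("composite files carry provenance and diagnostics", {
  m1 <- simple_map(c("A", "B", "C"), c(0, 5, 10))
  m2 <- simple_map(c("B", "C", "D"), c(0, 5, 10))
  cm <- merge_maps(list(a = m1, b = m2), k_max = 2)
  p <- withr::local_tempfile(fileext = ".tsv")
  pj <- withr::local_tempfile(fileext = ".json")
  write_composite(cm, p, pj)
  tab <- utils::read.delim(p)
  expect_equal(tab$maps, c("a", "a,b", "a,b", "b"))
  dg <- jsonlite::read_json(pj)
  expect_true(!is.null(dg[["1"]]$k))
})
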