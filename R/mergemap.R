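#' Assign component linkage groups to consensus linkage groups
#'
#' Connected components of the shared-marker graph over all component LGs
#' become consensus LGs. A component LG bridging two consensus groups is
#' assigned by majority shared-marker count (ties lexicographic).
#'
#' @param maps named list of [genmap] component maps
#' @return data.frame with `map`, `lg`, `consensus` (consensus LG label:
#'   the most common component LG label in the group)
#' @export
consensus_groups <- function(maps) {
  stopifnot(length(maps) >= 1, !is.null(names(maps)))
  nodes <- unique(do.call(rbind, lapply(names(maps), function(m) {
    data.frame(map = m, lg = unique(maps[[m]]$lg), stringsAsFactors = FALSE)
  })))
  nodes$id <- paste(nodes$map, nodes$lg, sep = "::")
  marker_lg <- lapply(seq_len(nrow(nodes)), function(i) {
    mp <- maps[[nodes$map[i]]]
    mp$marker[mp$lg == nodes$lg[i]]
  })
  names(marker_lg) <- nodes$id
  edges <- NULL
  if (nrow(nodes) > 1) {
    for (i in 1:(nrow(nodes) - 1)) {
      for (j in (i + 1):nrow(nodes)) {
        if (nodes$map[i] == nodes$map[j]) next
        nsh <- length(intersect(marker_lg[[i]], marker_lg[[j]]))
        if (nsh > 0) edges <- rbind(edges, data.frame(
          a = nodes$id[i], b = nodes$id[j], w = nsh))
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(nodes$id)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
  }
  comp <- igraph::components(g)
  nodes$group <- comp$membership[nodes$id]
  ## consensus label: most frequent component-LG label, ties lexicographic
  lab <- vapply(split(nodes$lg, nodes$group), function(x) {
    tt <- sort(table(x), decreasing = TRUE)
    names(tt)[1]
  }, character(1))
  lab[] <- make.unique(unname(lab), sep = "#")  # keep labels distinct
  nodes$consensus <- unname(lab[as.character(nodes$group)])
  nodes[, c("map", "lg", "consensus")]
}

# Distinct-position (bin) structure of one component LG: representative
# marker per position plus the tied members.
component_bins <- function(map, lg) {
  d <- map[map$lg == lg, , drop = FALSE]
  pos <- unique(d$position)
  reps <- character(length(pos)); ties <- list()
  for (i in seq_along(pos)) {
    mem <- d$marker[d$position == pos[i]]
    reps[i] <- mem[1]
    ties[[i]] <- mem[-1]
  }
  list(pos = pos, reps = reps, ties = ties, markers = d)
}

#' Build interval data and order constraints for one consensus LG
#'
#' Every component contributes: an order constraint for each pair of
#' consecutive distinct positions, and an interval datum (pair of
#' representative markers, component distance) for each pair of distinct
#' positions separated by at most `k` position steps. Markers tied at one
#' position contribute a zero-length datum against their representative.
#'
#' @param comp_maps named list of [genmap]s restricted to one consensus LG
#' @param k maximum interval size (position steps)
#' @return list with `intervals` (data.frame from/to/dist/map) and
#'   `order_edges` (data.frame from/to/weight/support)
#' @export
build_constraints <- function(comp_maps, k) {
  stopifnot(k >= 1)
  ints <- list(); edges <- list()
  for (m in names(comp_maps)) {
    map <- comp_maps[[m]]
    for (lg in unique(map$lg)) {
      cb <- component_bins(map, lg)
      nb <- length(cb$pos)
      if (nb > 1) {
        for (i in 1:(nb - 1)) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = cb$reps[i], to = cb$reps[i + 1],
            dist = cb$pos[i + 1] - cb$pos[i], map = m,
            stringsAsFactors = FALSE)
          for (j in (i + 1):min(nb, i + k)) {
            ints[[length(ints) + 1L]] <- data.frame(
              from = cb$reps[i], to = cb$reps[j],
              dist = cb$pos[j] - cb$pos[i], map = m,
              stringsAsFactors = FALSE)
          }
        }
      }
      for (i in seq_len(nb)) {
        for (tied in cb$ties[[i]]) {
          ints[[length(ints) + 1L]] <- data.frame(
            from = cb$reps[i], to = tied, dist = 0, map = m,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  intervals <- if (length(ints)) do.call(rbind, ints) else
    data.frame(from = character(0), to = character(0), dist = numeric(0),
               map = character(0))
  oe <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), dist = numeric(0),
               map = character(0))
  ## aggregate parallel order edges: weight = #supporting maps
  if (nrow(oe)) {
    key <- paste(oe$from, oe$to, sep = "\r")
    agg <- tapply(seq_len(nrow(oe)), key, function(ix) {
      c(weight = length(unique(oe$map[ix])), support = sum(oe$dist[ix]))
    })
    uk <- names(agg)
    order_edges <- data.frame(
      from = sub("\r.*$", "", uk), to = sub("^.*\r", "", uk),
      weight = vapply(agg, `[[`, numeric(1), "weight"),
      support = vapply(agg, `[[`, numeric(1), "support"),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    order_edges <- data.frame(from = character(0), to = character(0),
                              weight = numeric(0), support = numeric(0))
  }
  list(intervals = intervals, order_edges = order_edges)
}

#' Break order-constraint cycles
#'
#' Conflicting component orders create directed cycles. Cycles are broken
#' by repeatedly deleting the cheapest edge lying on a cycle: smallest
#' number of supporting component maps, then smallest summed supporting
#' interval distance, then lexicographic (from, to). Edges supported by
#' every component can only be deleted if a single component is internally
#' inconsistent, which cannot happen for valid maps.
#'
#' @param order_edges data.frame from [build_constraints()]
#' @return list with `kept` and `deleted` edge data.frames
#' @export
resolve_conflicts <- function(order_edges) {
  kept <- order_edges
  deleted <- kept[0, ]
  repeat {
    if (!nrow(kept)) break
    g <- igraph::graph_from_data_frame(kept[, c("from", "to")])
    if (igraph::is_dag(g)) break
    ## edges on a cycle: target reaches source
    dmat <- igraph::distances(g, mode = "out")
    on_cycle <- which(is.finite(dmat[cbind(kept$to, kept$from)]))
    cand <- kept[on_cycle, ]
    pick <- on_cycle[order(cand$weight, cand$support, cand$from, cand$to)][1]
    deleted <- rbind(deleted, kept[pick, ])
    kept <- kept[-pick, ]
  }
  list(kept = kept, deleted = deleted)
}

# Deterministic consensus order: Kahn's topological sort over the kept
# order edges, choosing among ready vertices by mean normalised component
# position, then lexicographically. Markers without order edges (tied
# members) are keyed the same way.
consensus_order <- function(markers, kept_edges, comp_maps) {
  keys <- stats::setNames(numeric(length(markers)), markers)
  cnt <- stats::setNames(numeric(length(markers)), markers)
  for (m in names(comp_maps)) {
    map <- comp_maps[[m]]
    for (lg in unique(map$lg)) {
      d <- map[map$lg == lg, ]
      span <- max(d$position) - min(d$position)
      rel <- if (span > 0) (d$position - min(d$position)) / span else
        rep(0.5, nrow(d))
      keys[d$marker] <- keys[d$marker] + rel
      cnt[d$marker] <- cnt[d$marker] + 1
    }
  }
  keys <- ifelse(cnt > 0, keys / cnt, 0.5)
  succ <- split(kept_edges$to, factor(kept_edges$from, levels = markers))
  indeg <- stats::setNames(integer(length(markers)), markers)
  tt <- table(kept_edges$to)
  indeg[names(tt)] <- as.integer(tt)
  ready <- markers[indeg == 0]
  out <- character(0)
  while (length(ready)) {
    ready <- ready[order(keys[ready], ready)]
    v <- ready[1]
    ready <- ready[-1]
    out <- c(out, v)
    for (w in succ[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  if (length(out) != length(markers)) {
    stop("internal error: order constraints not acyclic after resolution")
  }
  out
}

#' Solve consensus positions by L1 interval fitting
#'
#' Positions minimise the mean absolute difference between consensus
#' marker intervals and the component interval data, subject to the
#' consensus order (nonnegative inter-marker gaps) with the first marker
#' at 0. Small problems are solved exactly as a linear program (slack
#' reformulation, [boot::simplex()]); larger ones by coordinate descent
#' on the piecewise-linear objective (each gap update is a weighted-median
#' step, never increasing the objective). Either solution is then
#' canonicalised by per-gap centring sweeps: every gap is moved to the
#' midpoint of its one-dimensional optimal interval, which resolves the
#' degeneracy of L1 optima deterministically.
#'
#' @param ord consensus marker order
#' @param intervals interval data from [build_constraints()]
#' @param exact_max maximum LP size (variables + constraints) solved by
#'   the exact simplex
#' @return named numeric vector of positions (cM)
#' @export
lp_positions <- function(ord, intervals, exact_max = 400) {
  n <- length(ord)
  pos_of <- stats::setNames(seq_len(n), ord)
  if (n == 1) return(stats::setNames(0, ord))
  ## each datum covers gaps lo..hi-1
  lo <- pmin(pos_of[intervals$from], pos_of[intervals$to])
  hi <- pmax(pos_of[intervals$from], pos_of[intervals$to])
  d <- intervals$dist
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]; d <- d[keep]
  m <- length(d)
  if (m == 0) return(stats::setNames(rep(0, n), ord))
  spans <- lapply(seq_len(m), function(c) lo[c]:(hi[c] - 1))
  cover <- vector("list", n - 1)   # data touching each gap
  for (c in seq_len(m)) for (t in spans[[c]]) {
    cover[[t]] <- c(cover[[t]], c)
  }
  g <- init_gaps(n, spans, d)
  use_exact <- (n - 1 + m) <= exact_max
  if (use_exact) {
    g_lp <- try(lp_exact(n, spans, d), silent = TRUE)
    if (!inherits(g_lp, "try-error") && !anyNA(g_lp)) g <- g_lp
  } else {
    ## large instances: IRLS approximation of the L1 objective (the
    ## problem is convex, so this approaches the global optimum where
    ## plain coordinate descent can stall on non-smooth points)
    g <- irls_gaps(g, n, spans, d)
  }
  g <- descend_gaps(g, spans, d, cover, center = FALSE)
  g <- descend_gaps(g, spans, d, cover, center = TRUE, max_sweeps = 5)
  stats::setNames(c(0, cumsum(g)), ord)
}

# Iteratively reweighted least squares on the span-incidence system:
# weights 1/max(|residual|, delta) approximate the L1 objective; gaps are
# projected to >= 0 each round.
irls_gaps <- function(g, n, spans, d, iters = 40, delta = 1e-4) {
  A <- matrix(0, length(d), n - 1)
  for (c in seq_along(spans)) A[c, spans[[c]]] <- 1
  for (it in seq_len(iters)) {
    res <- as.vector(A %*% g) - d
    w <- 1 / pmax(abs(res), delta)
    AtW <- t(A * w)
    M <- AtW %*% A
    diag(M) <- diag(M) + 1e-10
    g_new <- tryCatch(as.vector(solve(M, AtW %*% d)),
                      error = function(e) g)
    g_new <- pmax(g_new, 0)
    if (max(abs(g_new - g)) < 1e-8) { g <- g_new; break }
    g <- g_new
  }
  g
}

# Starting point: per-gap medians of single-gap data, remaining length of
# wider data spread uniformly.
init_gaps <- function(n, spans, d) {
  g <- rep(0, n - 1)
  w <- rep(0, n - 1)
  for (c in seq_along(spans)) {
    len <- length(spans[[c]])
    g[spans[[c]]] <- g[spans[[c]]] + d[c] / len
    w[spans[[c]]] <- w[spans[[c]]] + 1
  }
  ifelse(w > 0, g / w, 0)
}

obj_value <- function(g, spans, d) {
  s <- vapply(seq_along(spans), function(c) sum(g[spans[[c]]]), numeric(1))
  sum(abs(s - d))
}

# Coordinate descent; with center = TRUE each gap goes to the midpoint of
# its 1-D optimal interval provided the move keeps the objective equal.
descend_gaps <- function(g, spans, d, cover, center, max_sweeps = 60) {
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (t in seq_along(g)) {
      cs <- cover[[t]]
      if (is.null(cs)) next
      targ <- vapply(cs, function(c) d[c] - sum(g[spans[[c]]]) + g[t],
                     numeric(1))
      targ <- pmax(sort(targ), 0)
      mm <- length(targ)
      lo_opt <- targ[ceiling(mm / 2)]
      hi_opt <- targ[floor(mm / 2) + 1]
      new <- if (center) (lo_opt + hi_opt) / 2 else lo_opt
      if (center) {
        old_obj <- obj_value(g, spans, d)
        g_try <- g; g_try[t] <- new
        if (obj_value(g_try, spans, d) > old_obj + 1e-9) next
      }
      delta <- max(delta, abs(new - g[t]))
      g[t] <- new
    }
    if (delta < 1e-10) break
  }
  g
}

# Exact LP: min sum(e) s.t. span.g - e <= d, span.g + e >= d, g,e >= 0.
lp_exact <- function(n, spans, d) {
  m <- length(d)
  nv <- (n - 1) + m
  a <- c(rep(0, n - 1), rep(1, m))
  A1 <- matrix(0, m, nv); A2 <- matrix(0, m, nv)
  for (c in seq_len(m)) {
    A1[c, spans[[c]]] <- 1
    A1[c, (n - 1) + c] <- -1
    A2[c, spans[[c]]] <- 1
    A2[c, (n - 1) + c] <- 1
  }
  sol <- boot::simplex(a = a, A1 = A1, b1 = d, A2 = A2, b2 = d,
                       maxi = FALSE)
  if (sol$solved != 1) stop("simplex failed")
  unname(sol$soln[seq_len(n - 1)])
}

#' Merge component maps into a composite map
#'
#' For each consensus linkage group, order conflicts are resolved, and the
#' L1 consensus is solved for every maximum interval size `k = 1..k_max`;
#' the `k` minimising the mean per-component RMSE between consensus and
#' component positions of shared markers is retained (ties to the smaller
#' `k`).
#'
#' @param maps named list of [genmap] component maps
#' @param k_max largest interval size tried
#' @return object of class `composite_map`: list with `map` (a [genmap]
#'   over consensus LGs), and per-LG `diagnostics` (chosen `k`,
#'   per-component RMSE, deleted order constraints, marker provenance)
#' @export
merge_maps <- function(maps, k_max = 10) {
  stopifnot(length(maps) >= 1)
  if (is.null(names(maps))) names(maps) <- sprintf("map%d", seq_along(maps))
  groups <- consensus_groups(maps)
  out_rows <- list(); diags <- list()
  for (cons in sort(unique(groups$consensus))) {
    sel <- groups[groups$consensus == cons, ]
    comp_maps <- list()
    for (i in seq_len(nrow(sel))) {
      sub <- maps[[sel$map[i]]]
      sub <- sub[sub$lg == sel$lg[i], , drop = FALSE]
      sub$position <- sub$position - min(sub$position)
      if (is.null(comp_maps[[sel$map[i]]])) {
        comp_maps[[sel$map[i]]] <- sub
      } else {
        comp_maps[[sel$map[i]]] <- rbind(comp_maps[[sel$map[i]]], sub)
      }
    }
    markers <- sort(unique(unlist(lapply(comp_maps, function(m) m$marker))))
    base <- build_constraints(comp_maps, k = 1)
    res <- resolve_conflicts(base$order_edges)
    ord <- consensus_order(markers, res$kept, comp_maps)
    best <- NULL
    for (k in seq_len(k_max)) {
      cons_k <- build_constraints(comp_maps, k = k)
      pos <- lp_positions(ord, cons_k$intervals)
      rmse <- vapply(comp_maps, function(cm) {
        shared <- intersect(cm$marker, ord)
        sqrt(mean((pos[shared] - cm$position[match(shared, cm$marker)])^2))
      }, numeric(1))
      score <- mean(rmse)
      if (is.null(best) || score < best$score - 1e-12) {
        best <- list(k = k, pos = pos, rmse = rmse, score = score)
      }
    }
    provenance <- vapply(ord, function(mk) {
      paste(names(comp_maps)[vapply(comp_maps, function(cm)
        mk %in% cm$marker, logical(1))], collapse = ",")
    }, character(1))
    out_rows[[cons]] <- data.frame(lg = cons, marker = ord,
                                   position = unname(best$pos[ord]),
                                   stringsAsFactors = FALSE)
    diags[[cons]] <- list(k = best$k, rmse = best$rmse,
                          deleted = res$deleted, provenance = provenance)
  }
  structure(list(map = genmap(do.call(rbind, out_rows)),
                 diagnostics = diags),
            class = "composite_map")
}

#' @export
print.composite_map <- function(x, ...) {
  s <- summary.genmap(x$map)
  s$k <- vapply(s$lg, function(g) x$diagnostics[[g]]$k, numeric(1))
  s$mean_rmse <- vapply(s$lg, function(g) mean(x$diagnostics[[g]]$rmse),
                        numeric(1))
  print(s)
  invisible(x)
}

#' Write a composite map with provenance and diagnostics
#'
#' @param cm a `composite_map`
#' @param path map TSV path (map dialect plus a `maps` provenance column)
#' @param path_json optional diagnostics JSON (chosen k, RMSEs, deletions)
#' @return `path`, invisibly
#' @export
write_composite <- function(cm, path, path_json = NULL) {
  prov <- unlist(lapply(sort(unique(cm$map$lg)), function(g)
    cm$diagnostics[[g]]$provenance))
  lines <- c("lg\tmarker\tcM\tbin\tmaps",
             sprintf("%s\t%s\t%s\t%s\t%s", cm$map$lg, cm$map$marker,
                     format_cm(cm$map$position), cm$map$bin, prov))
  writeLines(lines, path)
  if (!is.null(path_json)) {
    jsonlite::write_json(lapply(cm$diagnostics, function(d)
      list(k = d$k, rmse = as.list(d$rmse),
           n_deleted = nrow(d$deleted))),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
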