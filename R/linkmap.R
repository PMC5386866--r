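#' Two-point linkage estimates for a set of uniparental markers
#'
#' Pseudo-testcross two-point analysis on the transmitted-allele matrix of
#' one parent. For each marker pair the recombination fraction is the
#' recombinant fraction minimised over the two phase assignments (so
#' `r <= 0.5` always), and the LOD is the base-10 likelihood ratio against
#' independence, `LOD = R log10(r) + (n - R) log10(1 - r) + n log10 2`
#' evaluated at the estimate (`r = 0` handled by its limit `n log10 2`).
#'
#' @param x integer matrix of transmitted alleles (markers x progeny,
#'   0/1/NA), e.g. from [transmitted_alleles()]
#' @return list of symmetric matrices `r`, `lod`, `n` (informative pairs);
#'   pairs with zero informative progeny get `r = NA`, `lod = 0`
#' @export
twopoint_matrix <- function(x) {
  stopifnot(is.matrix(x))
  obs <- !is.na(x)
  one <- !is.na(x) & x == 1L
  zero <- obs & !one
  storage.mode(one) <- "numeric"
  storage.mode(zero) <- "numeric"
  storage.mode(obs) <- "numeric"
  n <- tcrossprod(obs)
  agree <- tcrossprod(one) + tcrossprod(zero)
  disc <- n - agree
  R <- pmin(disc, agree)           # min over the two phase assignments
  r <- ifelse(n > 0, R / n, NA_real_)
  lod <- matrix(0, nrow(x), nrow(x), dimnames = dimnames(n))
  pos <- n > 0
  lod[pos] <- lod_score(R[pos], n[pos])
  diag(lod) <- 0
  dimnames(r) <- dimnames(n) <- dimnames(lod) <- list(rownames(x), rownames(x))
  list(r = r, lod = lod, n = n)
}

# LOD of linkage at the MLE r = R/n (R recombinants of n informative).
lod_score <- function(R, n) {
  r <- R / n
  term <- ifelse(R > 0, R * log10(r), 0) +
    ifelse(n - R > 0, (n - R) * log10(1 - r), 0)
  term + n * log10(2)
}

#' Two-point estimate for a single marker pair
#'
#' @param a,b integer vectors of transmitted alleles (0/1/NA) for the two
#'   markers over the same progeny
#' @return list with `r`, `lod`, `n_informative`
#' @export
twopoint <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  n <- sum(keep)
  if (n == 0) {
    return(list(r = NA_real_, lod = 0, n_informative = 0L))
  }
  disc <- sum(a[keep] != b[keep])
  R <- min(disc, n - disc)
  list(r = R / n, lod = lod_score(R, n), n_informative = n)
}

#' Group markers into linkage groups
#'
#' Markers are joined when their pairwise LOD strictly exceeds
#' `lod_threshold` and the recombination-fraction estimate is below
#' `max_rf`; linkage groups are the connected components of that graph.
#' The `max_rf` guard (standard two-point grouping practice) keeps rare
#' large-sample LOD excursions between truly unlinked markers from fusing
#' groups. Singletons are reported unplaced.
#'
#' @param tp output of [twopoint_matrix()]
#' @param lod_threshold minimum LOD for an edge (strict)
#' @param max_rf maximum recombination fraction for an edge
#' @return list with `groups` (list of marker-id vectors, largest first)
#'   and `unplaced` (singleton marker ids)
#' @export
group_markers <- function(tp, lod_threshold = 5.0, max_rf = 0.30) {
  adj <- !is.na(tp$r) & tp$lod > lod_threshold & tp$r < max_rf
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  ids <- rownames(tp$r)
  groups <- split(ids, comp$membership)
  sizes <- lengths(groups)
  unplaced <- unlist(groups[sizes == 1], use.names = FALSE)
  groups <- groups[sizes > 1]
  groups <- groups[order(-lengths(groups),
                         vapply(groups, min, character(1)))]
  names(groups) <- NULL
  list(groups = groups, unplaced = if (is.null(unplaced)) character(0)
       else unplaced)
}

#' Order the markers of one linkage group
#'
#' Minimises the sum of adjacent recombination fractions (SARF). The seed
#' order is the diameter path of the minimum spanning tree of the
#' two-point distance graph, with off-path markers added by cheapest
#' insertion; the seed is then polished by full 2-opt segment reversals
#' and single-marker relocations until no move improves the objective.
#' Deterministic given the input; the returned orientation is canonical
#' (first marker id lexicographically smaller than last).
#'
#' @param tp output of [twopoint_matrix()] for at least the group markers
#' @param members marker ids in the group (>= 2)
#' @return character vector of ordered marker ids
#' @export
order_markers <- function(tp, members = rownames(tp$r)) {
  stopifnot(length(members) >= 2)
  d <- tp$r[members, members, drop = FALSE]
  if (anyNA(d)) {
    # uninformative pairs get the maximum penalty so they are never adjacent
    d[is.na(d)] <- 0.5
  }
  if (length(members) == 2) return(canonical_orientation(members))
  ord <- mst_seed_order(d)
  ord <- polish_order(ord, d)
  canonical_orientation(members[ord])
}

sarf <- function(ord, d) {
  sum(d[cbind(ord[-length(ord)], ord[-1])])
}

# Seed order: MST diameter path, then cheapest insertion of leftovers
# (processed by increasing distance to the placed set, ties by index).
mst_seed_order <- function(d) {
  n <- nrow(d)
  # epsilon keeps zero-recombination pairs as (cheap) edges in the graph
  g <- igraph::graph_from_adjacency_matrix(d + 1e-6, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mt <- igraph::mst(g, algorithm = "prim")
  far <- igraph::farthest_vertices(mt)
  path <- as.integer(igraph::shortest_paths(
    mt, from = far$vertices[1], to = far$vertices[2])$vpath[[1]])
  rest <- setdiff(seq_len(n), path)
  ord <- path
  while (length(rest)) {
    near <- vapply(rest, function(i) min(d[i, ord]), numeric(1))
    pick <- rest[order(near, rest)][1]
    best_cost <- Inf; best_pos <- 1L
    for (pos in 0:length(ord)) {
      cand <- append(ord, pick, after = pos)
      cost <- sarf(cand, d)
      if (cost < best_cost - 1e-12) {
        best_cost <- cost; best_pos <- pos
      }
    }
    ord <- append(ord, pick, after = best_pos)
    rest <- setdiff(rest, pick)
  }
  ord
}

# Local search: delta-evaluated 2-opt (segment reversal) plus or-opt
# relocation of blocks of length 1-3 in either orientation.
polish_order <- function(ord, d) {
  n <- length(ord)
  if (n < 3) return(ord)
  edge <- function(a, b) {
    if (a < 1 || b > n) 0 else d[ord[a], ord[b]]
  }
  eps <- 1e-9                 # material improvement; ties never move
  improved <- TRUE
  rounds <- 0L
  while (improved && rounds < 50L * n) {
    improved <- FALSE
    rounds <- rounds + 1L
    ## 2-opt: reversing ord[i..j] only changes the two boundary edges
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        delta <- edge(i - 1, j) + edge(i, j + 1) -
          edge(i - 1, i) - edge(j, j + 1)
        if (delta < -eps) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
    ## block or-opt with delta evaluation
    for (len in 1:3) {
      if (n <= len + 1) next
      for (i in seq_len(n - len + 1)) {
        j <- i + len - 1
        gain_out <- edge(i - 1, i) + edge(j, j + 1) - edge(i - 1, j + 1)
        if (gain_out <= eps) next
        block <- ord[i:j]
        rest <- ord[-(i:j)]
        m <- length(rest)
        best <- NULL; best_delta <- eps
        for (p in 0:m) {
          if (p == i - 1) next   # original slot
          left <- if (p >= 1) rest[p] else NA
          right <- if (p < m) rest[p + 1] else NA
          gap <- if (p >= 1 && p < m) d[left, right] else 0
          for (rev_ in c(FALSE, TRUE)) {
            b <- if (rev_) rev(block) else block
            cost_in <- (if (p >= 1) d[left, b[1]] else 0) +
              (if (p < m) d[b[len], right] else 0) - gap
            delta <- gain_out - cost_in
            if (delta > best_delta) {
              best_delta <- delta
              best <- append(rest, b, after = p)
            }
          }
        }
        if (!is.null(best)) {
          ord <- best
          improved <- TRUE
          break
        }
      }
    }
  }
  ord
}

canonical_orientation <- function(ids) {
  if (ids[1] <= ids[length(ids)]) ids else rev(ids)
}

#' Insert a marker into a fixed framework by two-point triangulation
#'
#' Finds the map position for one marker given an ordered, positioned
#' framework: among the `n_nb` framework markers with the highest LOD to
#' the target, the position `p` minimising
#' `sum w_j (|p - pos_j| - d_j)^2` (weights `LOD^2`, `d_j` two-point
#' Kosambi distances) is computed segment-wise in closed form.
#'
#' @param tp two-point estimates covering the target and framework
#' @param mk target marker id
#' @param ord ordered framework marker ids
#' @param pos named framework positions (cM)
#' @param n_nb number of nearest (highest-LOD) anchors used
#' @return fitted position (cM), or `NA` if no informative anchor
#' @export
insert_marker <- function(tp, mk, ord, pos, n_nb = 8) {
  lods <- tp$lod[mk, ord]
  rs <- tp$r[mk, ord]
  usable <- which(!is.na(rs) & rs < 0.4999 & lods > 0)
  if (!length(usable)) return(NA_real_)
  anchors <- usable[order(-lods[usable])][seq_len(min(n_nb, length(usable)))]
  aj <- pos[ord[anchors]]
  dj <- kosambi_d(rs[anchors])
  wj <- lods[anchors]^2
  brk <- sort(unique(aj))
  cand <- c(-Inf, brk, Inf)
  best_p <- NA_real_; best_cost <- Inf
  for (s in seq_len(length(cand) - 1)) {
    lo <- cand[s]; hi <- cand[s + 1]
    mid <- if (is.infinite(lo)) hi - 1 else if (is.infinite(hi)) lo + 1
      else (lo + hi) / 2
    sgn <- ifelse(mid >= aj, 1, -1)       # sign of (p - a_j) in segment
    ## sum w (sgn*(p - a) - d)^2 -> quadratic in p
    p_hat <- sum(wj * (aj + sgn * dj)) / sum(wj)
    p_hat <- min(max(p_hat, lo), hi)
    cost <- sum(wj * (abs(p_hat - aj) - dj)^2)
    if (cost < best_cost - 1e-12) { best_cost <- cost; best_p <- p_hat }
  }
  unname(best_p)
}

#' Map positions by weighted regression on two-point distances
#'
#' With the marker order fixed, positions are fitted by weighted least
#' squares over the Kosambi distances of all marker pairs within `window`
#' rank steps (weights `LOD^2`), anchoring the first marker at 0.
#' Adjacent negative increments are clamped to zero so positions are
#' monotone. If exclusions (pairs at `r >= 0.5` or without data)
#' disconnect the window graph, the fit falls back to chaining adjacent
#' two-point distances.
#'
#' @param ord ordered marker ids
#' @param tp output of [twopoint_matrix()]
#' @param window maximum rank separation of pairs entering the fit
#' @return numeric vector of positions (cM) named by marker
#' @export
regression_distances <- function(ord, tp, window = 5) {
  n <- length(ord)
  if (n == 1) return(stats::setNames(0, ord))
  pairs <- NULL
  for (i in 1:(n - 1)) {
    for (j in (i + 1):min(n, i + window)) {
      r <- tp$r[ord[i], ord[j]]
      if (is.na(r) || r >= 0.5) next
      w <- tp$lod[ord[i], ord[j]]^2
      if (w <= 0) w <- 1e-6
      pairs <- rbind(pairs, c(i, j, kosambi_d(r), w))
    }
  }
  chain <- function() {
    inc <- numeric(n - 1)
    for (i in 1:(n - 1)) {
      r <- tp$r[ord[i], ord[i + 1]]
      inc[i] <- if (is.na(r)) 0 else kosambi_d(min(r, 0.4999))
    }
    stats::setNames(c(0, cumsum(inc)), ord)
  }
  if (is.null(pairs)) return(chain())
  ## connectivity check on the pair graph
  g <- igraph::graph_from_edgelist(cbind(pairs[, 1], pairs[, 2]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n || igraph::components(g)$no > 1) return(chain())
  ## WLS: minimise sum w (x_j - x_i - d)^2 with x_1 = 0
  A <- matrix(0, n - 1, n - 1)
  b <- numeric(n - 1)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    dd <- pairs[k, 3]; w <- pairs[k, 4]
    ii <- i - 1; jj <- j - 1     # x_1 fixed at 0
    if (jj > 0) { A[jj, jj] <- A[jj, jj] + w; b[jj] <- b[jj] + w * dd }
    if (ii > 0) { A[ii, ii] <- A[ii, ii] + w; b[ii] <- b[ii] - w * dd }
    if (ii > 0 && jj > 0) {
      A[ii, jj] <- A[ii, jj] - w
      A[jj, ii] <- A[jj, ii] - w
    }
  }
  x <- c(0, solve(A, b))
  inc <- pmax(diff(x), 0)          # clamp to monotone
  ## markers with no observed recombinant cosegregate: snap them to the
  ## same position so bins are exact (WLS would leave epsilon gaps)
  r_adj <- tp$r[cbind(ord[-n], ord[-1])]
  inc[!is.na(r_adj) & r_adj == 0] <- 0
  stats::setNames(c(0, cumsum(inc)), ord)
}

#' Nearest-neighbour diagnostics for mapped markers
#'
#' For marker `i` with mapped flanks `left`/`right`:
#' `nn_fit(i) = d2pt(left,i) + d2pt(i,right) - d2pt(left,right)` (two-point
#' Kosambi cM; distance inflation attributable to `i`);
#' `nn_stress(i)` is the mean over the immediate informative flanks of
#' `|r_hat - r_map|` where `r_map` is the Kosambi fraction implied by the
#' map distance; `nn_stress_cm(i)` is the same discrepancy in cM.
#'
#' Because all three statistics are built from two-point estimates they
#' carry binomial sampling noise; each is therefore returned with a
#' delta-method standard error (`*_se`) so callers can demand a
#' statistically material excess before declaring a marker bad.
#'
#' @param ord ordered marker ids
#' @param pos named positions (cM)
#' @param tp two-point estimates
#' @return data.frame with `marker`, `nn_fit`, `nn_stress`,
#'   `nn_stress_cm` and their standard errors
#' @export
nn_diagnostics <- function(ord, pos, tp) {
  n <- length(ord)
  d2 <- function(a, b) {
    r <- tp$r[a, b]
    if (is.na(r)) return(NA_real_)
    kosambi_d(min(r, 0.4999))
  }
  # variance of the two-point Kosambi distance (delta method)
  vd <- function(a, b) {
    r <- min(tp$r[a, b], 0.4999)
    nn <- tp$n[a, b]
    if (is.na(r) || nn <= 0) return(NA_real_)
    (100 / (1 - 4 * r^2))^2 * r * (1 - r) / nn
  }
  vr <- function(a, b) {
    r <- tp$r[a, b]; nn <- tp$n[a, b]
    if (is.na(r) || nn <= 0) return(NA_real_)
    max(r, 1 / (nn + 2)) * (1 - min(r, 1 - 1 / (nn + 2))) / nn
  }
  out <- data.frame(marker = ord, nn_fit = 0, nn_fit_se = 0,
                    nn_stress = 0, nn_stress_se = 0,
                    nn_stress_cm = 0, nn_stress_cm_se = 0,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    flanks <- c(if (k > 1) ord[k - 1], if (k < n) ord[k + 1])
    if (k > 1 && k < n) {
      f <- d2(ord[k - 1], ord[k]) + d2(ord[k], ord[k + 1]) -
        d2(ord[k - 1], ord[k + 1])
      v <- vd(ord[k - 1], ord[k]) + vd(ord[k], ord[k + 1]) +
        vd(ord[k - 1], ord[k + 1])
      out$nn_fit[k] <- if (is.na(f)) 0 else max(f, 0)
      out$nn_fit_se[k] <- if (is.na(v)) 0 else sqrt(v)
    }
    sr <- scm <- vsr <- vscm <- numeric(0)
    for (fl in flanks) {
      r_hat <- tp$r[ord[k], fl]
      if (is.na(r_hat)) next
      dmap <- abs(pos[ord[k]] - pos[fl])
      r_map <- kosambi_r(dmap)
      sr <- c(sr, abs(r_hat - r_map))
      scm <- c(scm, abs(kosambi_d(min(r_hat, 0.4999)) - dmap))
      vsr <- c(vsr, vr(ord[k], fl))
      vscm <- c(vscm, vd(ord[k], fl))
    }
    out$nn_stress[k] <- if (length(sr)) mean(sr) else 0
    out$nn_stress_se[k] <- if (length(vsr)) sqrt(sum(vsr)) / length(vsr)
      else 0
    out$nn_stress_cm[k] <- if (length(scm)) mean(scm) else 0
    out$nn_stress_cm_se[k] <- if (length(vscm)) sqrt(sum(vscm)) /
      length(vscm) else 0
  }
  out
}

#' Iterative nearest-neighbour cleaning of one linkage group
#'
#' Repeatedly removes the worst marker exceeding any of the three
#' diagnostic thresholds (nearest-neighbour fit > `fit_max` cM, stress >
#' `stress_max`, stress in cM > `stress_cm_max`), re-orders and re-fits
#' distances, until all survivors pass. Because the diagnostics are
#' two-point statistics with binomial sampling noise, a marker only
#' counts as exceeding a threshold when it does so by more than
#' `noise_z` standard errors of the statistic; otherwise clean data at
#' moderate population sizes would be eroded by a removal cascade. The
#' worst offender is the marker with the largest threshold-relative
#' excess (deterministic ties by marker id). Cleaning never increases
#' the total map length.
#'
#' @param ord ordered marker ids of the group
#' @param tp two-point estimates
#' @param fit_max,stress_max,stress_cm_max thresholds; `Inf` disables
#' @param window passed to [regression_distances()]
#' @param noise_z sampling-noise allowance (standard errors)
#' @return list with `ord`, `pos`, `removed` (data.frame of marker and the
#'   criterion that fired) and final `diagnostics`
#' @export
clean_iterative <- function(ord, tp, fit_max = 2.0, stress_max = 0.035,
                            stress_cm_max = 3.5, window = 5, noise_z = 3) {
  removed <- data.frame(marker = character(0), criterion = character(0),
                        stringsAsFactors = FALSE)
  repeat {
    pos <- regression_distances(ord, tp, window)
    diag_ <- nn_diagnostics(ord, pos, tp)
    excess <- pmax(
      diag_$nn_fit / (fit_max + noise_z * diag_$nn_fit_se),
      diag_$nn_stress / (stress_max + noise_z * diag_$nn_stress_se),
      diag_$nn_stress_cm / (stress_cm_max + noise_z *
                              diag_$nn_stress_cm_se))
    offenders <- which(excess > 1)
    if (!length(offenders) || length(ord) <= 2) {
      return(list(ord = ord, pos = pos, removed = removed,
                  diagnostics = diag_))
    }
    worst <- offenders[order(-excess[offenders], diag_$marker[offenders])][1]
    crit <- c("nn_fit", "nn_stress", "nn_stress_cm")[
      which.max(c(diag_$nn_fit[worst] /
                    (fit_max + noise_z * diag_$nn_fit_se[worst]),
                  diag_$nn_stress[worst] /
                    (stress_max + noise_z * diag_$nn_stress_se[worst]),
                  diag_$nn_stress_cm[worst] /
                    (stress_cm_max + noise_z *
                       diag_$nn_stress_cm_se[worst])))]
    removed <- rbind(removed, data.frame(marker = diag_$marker[worst],
                                         criterion = crit))
    ord <- setdiff(ord, diag_$marker[worst])
    if (length(ord) > 2) ord <- order_markers(tp, ord)
  }
}
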