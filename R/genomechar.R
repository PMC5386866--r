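# Allele-level 1:1 chi-square from a marker's coded calls: counts of the
# two transmitted alleles pooled over informative parents (an 'hk' call
# contributes one h and one k).
sd_chi2_counts <- function(seg, calls) {
  calls <- calls[calls != MISSING_CALL]
  if (!length(calls)) return(c(chi2 = NA_real_, p = NA_real_, n = 0))
  c0 <- c1 <- 0
  am <- MAT_ALLELE[[seg]][calls]
  ap <- PAT_ALLELE[[seg]][calls]
  c0 <- sum(am == 0L, na.rm = TRUE) + sum(ap == 0L, na.rm = TRUE)
  c1 <- sum(am == 1L, na.rm = TRUE) + sum(ap == 1L, na.rm = TRUE)
  if (seg == "hkxhk") {
    nhk <- sum(calls == "hk")
    c0 <- c0 + nhk; c1 <- c1 + nhk
  }
  n <- c0 + c1
  if (n == 0) return(c(chi2 = NA_real_, p = NA_real_, n = 0))
  chi2 <- (c0 - c1)^2 / n
  c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), n = n)
}

#' Segregation-distortion chi-square test for one marker
#'
#' Allele-level 1:1 test with one degree of freedom on the transmitted
#' allele counts (the convention used for codominant markers); with
#' `genotype_classes = TRUE`, `hk x hk` markers are instead tested against
#' the 1:2:1 genotype-class expectation (2 df).
#'
#' @param seg segregation type
#' @param calls coded progeny calls
#' @param genotype_classes use the genotype-class test where applicable
#' @return named vector `chi2`, `p`, `n`
#' @export
sd_chi2 <- function(seg, calls, genotype_classes = FALSE) {
  if (genotype_classes && seg == "hkxhk") {
    calls <- calls[calls != MISSING_CALL]
    if (!length(calls)) return(c(chi2 = NA_real_, p = NA_real_, n = 0))
    obs <- c(sum(calls == "hh"), sum(calls == "hk"), sum(calls == "kk"))
    expd <- sum(obs) * c(0.25, 0.5, 0.25)
    chi2 <- sum((obs - expd)^2 / expd)
    return(c(chi2 = chi2,
             p = stats::pchisq(chi2, df = 2, lower.tail = FALSE),
             n = sum(obs)))
  }
  sd_chi2_counts(seg, calls)
}

#' Genome-wide segregation-distortion scan
#'
#' Applies [sd_chi2()] to every mapped marker; markers with `P < alpha`
#' are flagged distorted (strict inequality). Markers without informative
#' calls are skipped (`NA`).
#'
#' @param geno a [cp_geno]
#' @param map a [genmap] of (a subset of) its markers
#' @param alpha distortion threshold on the P value
#' @return object of class `sd_scan`: data.frame `lg`, `marker`,
#'   `position`, `chi2`, `p`, `distorted`
#' @export
sd_scan <- function(geno, map, alpha = 0.1) {
  idx <- match(map$marker, geno$markers$marker_id)
  if (anyNA(idx)) stop("map contains markers absent from the genotype set")
  stat <- t(vapply(idx, function(i)
    sd_chi2(geno$markers$seg[i], geno$calls[i, ]), numeric(3)))
  out <- data.frame(lg = map$lg, marker = map$marker,
                    position = map$position,
                    chi2 = stat[, "chi2"], p = stat[, "p"],
                    distorted = !is.na(stat[, "p"]) & stat[, "p"] < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("sd_scan", "data.frame")
  out
}

#' Call segregation-distortion regions
#'
#' A region is a maximal run of at least `min_run` consecutive distorted
#' markers whose inter-marker gaps are at most `max_gap_cm`, reported as a
#' closed cM interval per LG.
#'
#' @param scan an `sd_scan`
#' @param min_run minimum run length (markers)
#' @param max_gap_cm maximum within-run gap (cM)
#' @return data.frame `lg`, `start`, `end`, `n_markers`
#' @export
find_sdrs <- function(scan, min_run = 5, max_gap_cm = 5) {
  out <- list()
  for (g in unique(scan$lg)) {
    d <- scan[scan$lg == g, ]
    d <- d[order(d$position), ]
    run <- integer(0)
    flush <- function(run) {
      if (length(run) >= min_run) {
        out[[length(out) + 1L]] <<- data.frame(
          lg = g, start = d$position[run[1]],
          end = d$position[run[length(run)]], n_markers = length(run))
      }
    }
    for (i in seq_len(nrow(d))) {
      if (!isTRUE(d$distorted[i])) { flush(run); run <- integer(0); next }
      if (length(run) && d$position[i] - d$position[run[length(run)]] >
          max_gap_cm) {
        flush(run); run <- integer(0)
      }
      run <- c(run, i)
    }
    flush(run)
  }
  if (!length(out)) {
    return(data.frame(lg = character(0), start = numeric(0),
                      end = numeric(0), n_markers = integer(0)))
  }
  do.call(rbind, out)
}

#' Bidirectional recombination-frequency profile of one linkage group
#'
#' From phased gamete data, `rf_from_start[n]` is the proportion of
#' progeny whose phase at marker `m_n` differs from the phase at the
#' first (terminal) marker `m_0`, over pairwise non-missing progeny;
#' `rf_from_end` anchors at the last marker. If a terminal marker has
#' more than 50% missing phases the next marker inward is used as the
#' anchor (recorded in `anchor_start`/`anchor_end`).
#'
#' @param phased progeny x markers phase matrix for one LG (map order)
#' @param positions marker positions (cM)
#' @return object of class `rf_profile`: list with `positions`,
#'   `rf_from_start`, `rf_from_end`, `n_start`, `n_end`, anchors
#' @export
rf_profile <- function(phased, positions) {
  stopifnot(ncol(phased) >= 3, ncol(phased) == length(positions))
  n_mk <- ncol(phased)
  pick_anchor <- function(idx_seq) {
    for (k in idx_seq) {
      if (mean(is.na(phased[, k])) <= 0.5) return(k)
    }
    idx_seq[1]
  }
  a0 <- pick_anchor(seq_len(n_mk))
  a1 <- pick_anchor(rev(seq_len(n_mk)))
  rf_vs <- function(anchor) {
    ref <- phased[, anchor]
    rf <- n <- rep(NA_real_, n_mk)
    for (k in seq_len(n_mk)) {
      if (k == anchor) next
      keep <- !is.na(ref) & !is.na(phased[, k])
      n[k] <- sum(keep)
      rf[k] <- if (n[k] > 0) mean(ref[keep] != phased[keep, k]) else NA
    }
    list(rf = rf, n = n)
  }
  s <- rf_vs(a0); e <- rf_vs(a1)
  structure(list(positions = positions, rf_from_start = s$rf,
                 rf_from_end = e$rf, n_start = s$n, n_end = e$n,
                 anchor_start = a0, anchor_end = a1),
            class = "rf_profile")
}

#' Locate a centromere span from an RF profile
#'
#' The centromere point estimate is the first crossing of the linearly
#' interpolated `rf_from_start` and `rf_from_end` curves. The span
#' extends outward from the intersection to the first marker with
#' directional RF at or above `rf_threshold` on each side (the
#' start-anchored curve rightward, the end-anchored curve leftward).
#' If either side never reaches the threshold the span is truncated at
#' the LG end and the LG is classified `undetermined`; otherwise it is
#' `metacentric` when the intersection lies in the central 60% of the LG
#' and `acrocentric` otherwise.
#'
#' @param prof an [rf_profile]
#' @param rf_threshold directional RF bound delimiting the span
#' @return data.frame `span_start`, `span_end`, `intersection`,
#'   `classification`
#' @export
centromere_span <- function(prof, rf_threshold = 0.45) {
  pos <- prof$positions
  ok <- !is.na(prof$rf_from_start) & !is.na(prof$rf_from_end)
  x <- pos[ok]
  fs <- prof$rf_from_start[ok]
  fe <- prof$rf_from_end[ok]
  if (length(x) < 2) {
    return(data.frame(span_start = NA_real_, span_end = NA_real_,
                      intersection = NA_real_,
                      classification = "undetermined"))
  }
  dd <- fs - fe
  cross <- NA_real_
  for (i in seq_len(length(x) - 1)) {
    if (dd[i] == 0) { cross <- x[i]; break }
    if (dd[i] * dd[i + 1] < 0) {
      cross <- x[i] + (0 - dd[i]) / (dd[i + 1] - dd[i]) * (x[i + 1] - x[i])
      break
    }
    if (i == length(x) - 1 && dd[i + 1] == 0) cross <- x[i + 1]
  }
  if (is.na(cross)) {
    return(data.frame(span_start = NA_real_, span_end = NA_real_,
                      intersection = NA_real_,
                      classification = "undetermined"))
  }
  right <- which(x > cross & fs >= rf_threshold)
  left <- which(x < cross & fe >= rf_threshold)
  trunc_r <- !length(right)
  trunc_l <- !length(left)
  span_end <- if (trunc_r) max(pos) else x[right[1]]
  span_start <- if (trunc_l) min(pos) else x[left[length(left)]]
  L0 <- min(pos); L1 <- max(pos)
  central <- cross >= L0 + 0.2 * (L1 - L0) & cross <= L0 + 0.8 * (L1 - L0)
  cls <- if (trunc_l && trunc_r) "undetermined" else
    if (central) "metacentric" else "acrocentric"
  data.frame(span_start = span_start, span_end = span_end,
             intersection = cross, classification = cls,
             stringsAsFactors = FALSE)
}

#' Marker-order collinearity between two maps
#'
#' LGs are paired by majority shared-marker count; for each pair with at
#' least two shared markers the Spearman rank correlation of the shared
#' markers' positions is reported. Orientation is auto-aligned: the
#' magnitude is reported with the sign convention that the majority
#' orientation is positive, so a fully reversed LG scores +1.
#'
#' @param map_a,map_b [genmap] objects
#' @return data.frame `lg_a`, `lg_b`, `n_shared`, `rho`
#' @export
collinearity <- function(map_a, map_b) {
  shared <- intersect(map_a$marker, map_b$marker)
  ia <- match(shared, map_a$marker); ib <- match(shared, map_b$marker)
  pairs <- data.frame(lg_a = map_a$lg[ia], lg_b = map_b$lg[ib],
                      pa = map_a$position[ia], pb = map_b$position[ib],
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) {
    return(data.frame(lg_a = character(0), lg_b = character(0),
                      n_shared = integer(0), rho = numeric(0)))
  }
  ## majority pairing of LGs
  tab <- as.data.frame(table(pairs$lg_a, pairs$lg_b),
                       stringsAsFactors = FALSE)
  names(tab) <- c("lg_a", "lg_b", "n")
  tab <- tab[tab$n > 0, ]
  tab <- tab[order(-tab$n, tab$lg_a, tab$lg_b), ]
  used_a <- used_b <- character(0)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    if (tab$lg_a[i] %in% used_a || tab$lg_b[i] %in% used_b) next
    used_a <- c(used_a, tab$lg_a[i]); used_b <- c(used_b, tab$lg_b[i])
    d <- pairs[pairs$lg_a == tab$lg_a[i] & pairs$lg_b == tab$lg_b[i], ]
    rho <- if (nrow(d) >= 2 && stats::sd(d$pa) > 0 && stats::sd(d$pb) > 0) {
      r <- suppressWarnings(stats::cor(d$pa, d$pb, method = "spearman"))
      abs(r)
    } else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      lg_a = tab$lg_a[i], lg_b = tab$lg_b[i], n_shared = nrow(d),
      rho = rho, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$lg_a), , drop = FALSE]
}

#' Compare maternal and paternal recombination rates
#'
#' Paired comparison of mean recombination events per progeny per LG
#' between maternal/paternal map pairs: mean difference, two-sided paired
#' t statistic with `n_pairs - 1` df, and the fraction of pairs where the
#' maternal rate is at least the paternal. A degenerate zero-variance
#' nonzero shift is reported as `t = +/-Inf`, `p = 0`.
#'
#' @param maternal,paternal numeric vectors of per-LG mean events per
#'   progeny, aligned pairwise
#' @return list with `mean_diff`, `t`, `df`, `p`, `frac_maternal_ge`
#' @export
maternal_paternal_compare <- function(maternal, paternal) {
  stopifnot(length(maternal) == length(paternal))
  if (length(maternal) < 2) stop("need at least 2 LG pairs")
  d <- maternal - paternal
  md <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  if (s == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t <- md / (s / sqrt(n))
    p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  }
  list(mean_diff = md, t = t, df = n - 1, p = p,
       frac_maternal_ge = mean(maternal >= paternal))
}

#' Kinship (coancestry) coefficient from a pedigree
#'
#' Standard recursive kinship: `f(x, x) = 0.5 * (1 + f(sire, dam))`,
#' `f(x, y) = 0.5 * (f(sire_x, y) + f(dam_x, y))` recursing on the
#' individual that is not an ancestor of the other; distinct founders are
#' unrelated and non-inbred, and missing parents are unknown founders.
#'
#' @param ped pedigree data.frame (`id`, `sire`, `dam`)
#' @param a,b individual ids
#' @return kinship coefficient in `[0, 1]`
#' @export
coancestry <- function(ped, a, b) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  if (!a %in% ped$id || !b %in% ped$id) stop("unknown individual")
  depth <- new.env(parent = emptyenv())
  gen <- function(x) {
    if (is.na(x) || !x %in% ped$id) return(0L)
    if (!is.null(depth[[x]])) {
      if (identical(depth[[x]], "visiting")) stop("pedigree cycle at ", x)
      return(depth[[x]])
    }
    depth[[x]] <- "visiting"
    i <- idx[[x]]
    d <- 1L + max(gen(ped$sire[i]), gen(ped$dam[i]))
    depth[[x]] <- d
    d
  }
  for (id in ped$id) gen(id)
  memo <- new.env(parent = emptyenv())
  f <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    ux <- if (x %in% ped$id) x else NA
    uy <- if (y %in% ped$id) y else NA
    if (is.na(ux) || is.na(uy)) return(if (identical(x, y)) 0.5 else 0)
    key <- paste(sort(c(x, y)), collapse = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (x == y) {
      i <- idx[[x]]
      0.5 * (1 + f(ped$sire[i], ped$dam[i]))
    } else {
      ## recurse on the later-generation individual
      if (gen(x) >= gen(y)) {
        i <- idx[[x]]
        0.5 * (f(ped$sire[i], y) + f(ped$dam[i], y))
      } else {
        i <- idx[[y]]
        0.5 * (f(x, ped$sire[i]) + f(x, ped$dam[i]))
      }
    }
    memo[[key]] <- val
    val
  }
  f(a, b)
}
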