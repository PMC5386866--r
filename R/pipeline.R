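#' Mapping options
#'
#' Collects the tunable thresholds of the mapping pipeline with the
#' defaults used throughout: LOD > 5 grouping with an `max_rf = 0.3`
#' recombination guard, regression window of 5 ranks, nearest-neighbour
#' cleaning thresholds (2 cM fit, 0.035 stress, 3.5 cM stress),
#' imputation posterior 0.95 and a 2-marker error-detection window.
#'
#' @param lod_threshold,max_rf grouping thresholds
#' @param window regression window (ranks)
#' @param fit_max,stress_max,stress_cm_max cleaning thresholds
#' @param posterior_min imputation / hk-resolution posterior
#' @param error_window singleton-detection window (markers)
#' @return list of options
#' @export
map_opts <- function(lod_threshold = 5.0, max_rf = 0.30, window = 5,
                     fit_max = 2.0, stress_max = 0.035,
                     stress_cm_max = 3.5, posterior_min = 0.95,
                     error_window = 2) {
  list(lod_threshold = lod_threshold, max_rf = max_rf, window = window,
       fit_max = fit_max, stress_max = stress_max,
       stress_cm_max = stress_cm_max, posterior_min = posterior_min,
       error_window = error_window)
}

#' Build one parent's linkage map
#'
#' Runs the pseudo-testcross chain for one parent: transmitted-allele
#' extraction, two-point estimation, LOD grouping, MST-seeded ordering,
#' regression distances, iterative nearest-neighbour cleaning, phasing,
#' linkage-informed imputation, singleton error correction and bin
#' mapping. By default only markers informative for the parent enter;
#' pass `markers` to restrict further (e.g. to uniparental markers only).
#'
#' @param geno a [cp_geno]
#' @param parent `"mother"` or `"father"`
#' @param markers optional marker ids to map
#' @param opts a [map_opts()] list
#' @return object of class `parent_map`: `map` (a [genmap]), per-LG
#'   `phased` matrices (error-corrected, imputed), `flips`, `bins`,
#'   `counts` (per-progeny matrix and per-LG means), `removed`,
#'   `ambiguous`, `unplaced`
#' @export
build_parent_map <- function(geno, parent = c("mother", "father"),
                             markers = NULL, opts = map_opts()) {
  parent <- match.arg(parent)
  if (is.null(markers)) {
    markers <- geno$markers$marker_id[
      seg_informative(geno$markers$seg, parent)]
  }
  sub <- subset_geno(geno, markers)
  x <- transmitted_alleles(sub, parent)
  usable <- rowSums(!is.na(x)) > 0
  x <- x[usable, , drop = FALSE]
  tp <- twopoint_matrix(x)
  ## hk x hk pairs: the transmitted allele is only observable when the
  ## other parent sent the same allele, and the parents' transmissions
  ## are correlated along the LG, so hk-hk two-point estimates are
  ## biased towards zero. They never enter grouping, ordering or
  ## distance fitting: the map framework is built from fully informative
  ## markers and hk markers are inserted by triangulation against it.
  ishk <- sub$markers$seg[match(rownames(x), sub$markers$marker_id)] ==
    "hkxhk"
  if (sum(ishk) > 1) {
    tp$r[ishk, ishk] <- NA_real_
    tp$lod[ishk, ishk] <- 0
  }
  grp <- group_markers(tp, opts$lod_threshold, opts$max_rf)
  groups <- grp$groups
  ## label LGs by decreasing size, then first member id
  lab <- sprintf("LG%02d", seq_along(groups))
  map_rows <- list(); phased <- list(); flips <- c()
  bins <- list(); counts_mat <- NULL; removed <- list(); ambiguous <- c()
  unplaced <- grp$unplaced
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    frame <- members[!ishk[match(members, rownames(x))]]
    hks <- setdiff(members, frame)
    if (length(frame) < 2) { unplaced <- c(unplaced, members); next }
    ord <- order_markers(tp, frame)
    cl <- clean_iterative(ord, tp, opts$fit_max, opts$stress_max,
                          opts$stress_cm_max, opts$window)
    removed[[lab[gi]]] <- cl$removed
    full_pos <- cl$pos[cl$ord]
    for (mk in hks) {
      p <- insert_marker(tp, mk, cl$ord, cl$pos)
      if (!is.na(p)) full_pos[mk] <- p
    }
    full_pos <- full_pos - min(full_pos)
    ## stable order: by position, framework-first at ties, then id
    full_ord <- names(full_pos)[order(full_pos,
                                      names(full_pos) %in% hks,
                                      names(full_pos))]
    pos <- unname(full_pos[full_ord])
    ph <- assign_phase(x, full_ord, biased = full_ord %in% hks)
    ambiguous <- c(ambiguous, ph$ambiguous)
    imp <- impute_missing(ph$phased, pos, opts$posterior_min)
    err <- detect_errors(imp$phased, opts$error_window)
    imp2 <- impute_missing(err$phased, pos, opts$posterior_min)
    phased[[lab[gi]]] <- imp2$phased
    flips <- c(flips, ph$flip)
    bins[[lab[gi]]] <- make_bins(imp2$phased, full_pos)
    cc <- count_recombinations(imp2$phased)
    counts_mat <- cbind(counts_mat, cc$counts)
    map_rows[[gi]] <- data.frame(lg = lab[gi], marker = full_ord,
                                 position = pos, stringsAsFactors = FALSE)
  }
  if (!length(map_rows)) stop("no linkage groups formed")
  colnames(counts_mat) <- names(phased)
  structure(list(parent = parent,
                 map = genmap(do.call(rbind, map_rows)),
                 phased = phased, flips = flips, bins = bins,
                 counts = list(matrix = counts_mat,
                               lg_mean = colMeans(counts_mat, na.rm = TRUE)),
                 removed = removed, ambiguous = unique(ambiguous),
                 unplaced = unplaced),
            class = "parent_map")
}

#' @export
print.parent_map <- function(x, ...) {
  cat(sprintf("parent_map (%s): %d LGs, %d markers, %.1f cM\n", x$parent,
              length(unique(x$map$lg)), nrow(x$map), map_length(x$map)))
  s <- summary.genmap(x$map)
  s$mean_xo <- x$counts$lg_mean[s$lg]
  print(s)
  invisible(x)
}

# Per-marker context used by resolve_hk for one parent.
hk_context <- function(pm, marker) {
  row <- which(pm$map$marker == marker)
  if (!length(row)) return(NULL)
  lg <- pm$map$lg[row]
  ph <- pm$phased[[lg]]
  col <- match(marker, colnames(ph))
  flip <- unname(pm$flips[marker])
  if (is.na(col) || !length(flip)) return(NULL)
  list(phased = ph, positions = pm$map$position[pm$map$lg == lg],
       col = col, flip = flip)
}

#' Resolve all hk x hk markers of a population
#'
#' @param geno a [cp_geno]
#' @param pm_mother,pm_father `parent_map`s that place the biparental
#'   markers
#' @param posterior_min per-parent resolution threshold
#' @return named list of `resolve_hk()` results by marker id
#' @export
resolve_population_hk <- function(geno, pm_mother, pm_father,
                                  posterior_min = 0.95) {
  hk <- geno$markers$marker_id[geno$markers$seg == "hkxhk"]
  out <- list()
  for (mk in hk) {
    out[[mk]] <- resolve_hk(geno$calls[mk, ],
                            hk_context(pm_mother, mk),
                            hk_context(pm_father, mk),
                            posterior_min)
  }
  out
}

#' Map a full-sib population end to end
#'
#' For each parent, builds an integrated map over its uniparental plus
#' all biparental markers, resolves the parental origin of `hk` calls
#' from both parents' phased data, splits the biparental markers into
#' uniparental transmissions, and re-runs error correction, imputation
#' and bin mapping on the completed marker set. The split markers keep
#' the integrated-map positions of their biparental source.
#'
#' @param geno a [cp_geno]
#' @param opts a [map_opts()] list
#' @return list with `mother` and `father` final `parent_map`s, the
#'   final per-parent [cp_geno] sets (`geno_mother`, `geno_father`) and
#'   the `resolved` hk assignments
#' @export
map_population <- function(geno, opts = map_opts()) {
  pm_m <- build_parent_map(geno, "mother", opts = opts)
  pm_f <- build_parent_map(geno, "father", opts = opts)
  has_bip <- any(geno$markers$seg %in% c("hkxhk", "efxeg", "abxcd"))
  if (!has_bip) {
    return(list(mother = pm_m, father = pm_f,
                geno_mother = geno, geno_father = geno, resolved = list()))
  }
  resolved <- resolve_population_hk(geno, pm_m, pm_f, opts$posterior_min)
  split <- split_biparental(geno, resolved)
  final_geno <- function(parent) {
    uni_seg <- if (parent == "mother") "lmxll" else "nnxnp"
    suffix <- if (parent == "mother") "_m" else "_p"
    keep_uni <- geno$markers$marker_id[geno$markers$seg == uni_seg]
    keep_split <- split$markers$marker_id[
      endsWith(split$markers$marker_id, suffix)]
    mk <- rbind(geno$markers[match(keep_uni, geno$markers$marker_id),
                             c("marker_id", "seg", "phase")],
                split$markers[match(keep_split, split$markers$marker_id),
                              c("marker_id", "seg", "phase")])
    cp_geno(mk, rbind(geno$calls[keep_uni, , drop = FALSE],
                      split$calls[keep_split, , drop = FALSE]))
  }
  g_m <- final_geno("mother")
  g_f <- final_geno("father")
  fin_m <- finalize_parent_map(pm_m, g_m, "mother", opts)
  fin_f <- finalize_parent_map(pm_f, g_f, "father", opts)
  list(mother = fin_m, father = fin_f,
       geno_mother = g_m, geno_father = g_f, resolved = resolved)
}

# Rebuild phased/bins/counts for a parent after hk resolution and
# splitting, keeping the integrated-map positions (biparental marker ids
# take their split suffix).
finalize_parent_map <- function(pm, geno_final, parent, opts) {
  suffix <- if (parent == "mother") "_m" else "_p"
  x <- transmitted_alleles(geno_final, parent)
  map <- pm$map
  new_id <- map$marker
  bip <- !map$marker %in% geno_final$markers$marker_id
  new_id[bip] <- paste0(map$marker[bip], suffix)
  keep <- new_id %in% geno_final$markers$marker_id
  map2 <- genmap(data.frame(lg = map$lg[keep], marker = new_id[keep],
                            position = map$position[keep],
                            stringsAsFactors = FALSE))
  flips <- pm$flips
  names(flips) <- ifelse(bip, new_id, map$marker)[
    match(names(pm$flips), map$marker)]
  phased <- list(); bins <- list(); counts_mat <- NULL
  for (lg in unique(map2$lg)) {
    ord <- lg_markers(map2, lg)
    pos <- map2$position[map2$lg == lg]
    ph <- matrix(NA_integer_, ncol(x), length(ord),
                 dimnames = list(colnames(x), ord))
    for (k in seq_along(ord)) {
      fl <- unname(flips[ord[k]])
      if (!length(fl) || is.na(fl)) next
      ## maternal split markers code the first allele as "lm", which
      ## decodes as allele 1: the allele axis is inverted relative to
      ## the stage map the flip was estimated on
      if (parent == "mother" && endsWith(ord[k], suffix) &&
          !ord[k] %in% pm$map$marker) {
        fl <- 1L - fl
      }
      ph[, k] <- as.integer(xor(x[ord[k], ], fl))
    }
    imp <- impute_missing(ph, pos, opts$posterior_min)
    err <- detect_errors(imp$phased, opts$error_window)
    imp2 <- impute_missing(err$phased, pos, opts$posterior_min)
    phased[[lg]] <- imp2$phased
    names(pos) <- ord
    bins[[lg]] <- make_bins(imp2$phased, pos)
    cc <- count_recombinations(imp2$phased)
    counts_mat <- cbind(counts_mat, cc$counts)
  }
  colnames(counts_mat) <- unique(map2$lg)
  structure(list(parent = parent, map = map2, phased = phased,
                 flips = flips, bins = bins,
                 counts = list(matrix = counts_mat,
                               lg_mean = colMeans(counts_mat, na.rm = TRUE)),
                 removed = pm$removed, ambiguous = pm$ambiguous,
                 unplaced = pm$unplaced),
            class = "parent_map")
}

#' Characterise a mapped parent
#'
#' Runs the segregation-distortion scan and region calling plus the
#' bidirectional RF profile and centromere span of every LG.
#'
#' @param pm a `parent_map`
#' @param geno the matching final [cp_geno]
#' @param sd_alpha distortion threshold
#' @param rf_threshold centromere-span RF bound
#' @param min_run,max_gap_cm SDR rule
#' @return list with `sd` (an `sd_scan`), `sdrs`, `centromeres`
#'   (data.frame per LG) and `profiles`
#' @export
characterize_parent <- function(pm, geno, sd_alpha = 0.1,
                                rf_threshold = 0.45, min_run = 5,
                                max_gap_cm = 5) {
  mapped <- pm$map[pm$map$marker %in% geno$markers$marker_id, ]
  scan <- sd_scan(geno, genmap(as.data.frame(mapped)), alpha = sd_alpha)
  sdrs <- find_sdrs(scan, min_run = min_run, max_gap_cm = max_gap_cm)
  cent <- list(); profs <- list()
  for (lg in unique(pm$map$lg)) {
    ph <- pm$phased[[lg]]
    pos <- pm$map$position[pm$map$lg == lg]
    if (ncol(ph) < 3) next
    prof <- rf_profile(ph, pos)
    profs[[lg]] <- prof
    cs <- centromere_span(prof, rf_threshold)
    cs$lg <- lg
    cent[[lg]] <- cs
  }
  list(sd = scan, sdrs = sdrs,
       centromeres = if (length(cent)) do.call(rbind, cent) else NULL,
       profiles = profs)
}
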