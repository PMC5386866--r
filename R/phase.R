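#' Assign linkage phase along one linkage group
#'
#' Given the transmitted-allele matrix of one parent and a fixed marker
#' order, chooses a flip `f_m` per marker so that adjacent markers are
#' predominantly coupling, anchored at the first phasable marker
#' (`f = 0`, homolog "A"). The phased symbol of progeny `p` at marker `m`
#' is `allele XOR f_m` (0 = "A", 1 = "B"). A marker exactly tied between
#' coupling and repulsion against its phased neighbour is flagged
#' ambiguous and excluded (its column stays `NA`, its flip is `NA`).
#'
#' Markers flagged `biased` (partially informative markers whose
#' observability is correlated with the other parent's transmissions,
#' i.e. `hk x hk`) are never compared against each other: the unbiased
#' framework is phased first along the chain, then each biased marker is
#' anchored to its nearest phased framework marker. Without this, a pair
#' of `hk` markers whose phases are in repulsion in the other parent
#' shows an inverted coupling signal and flips the rest of the chain.
#'
#' @param x integer matrix of transmitted alleles (markers x progeny)
#' @param ord ordered marker ids (rows of `x`)
#' @param biased optional logical (aligned with `ord`): markers excluded
#'   from anchoring each other
#' @return list with `phased` (progeny x markers, 0/1/NA in map order),
#'   `flip` (named 0/1/NA per marker), `ambiguous` (marker ids)
#' @export
assign_phase <- function(x, ord, biased = rep(FALSE, length(ord))) {
  stopifnot(all(ord %in% rownames(x)), length(biased) == length(ord))
  n_prog <- ncol(x)
  phased <- matrix(NA_integer_, n_prog, length(ord),
                   dimnames = list(colnames(x), ord))
  flip <- stats::setNames(rep(NA_integer_, length(ord)), ord)
  ambiguous <- character(0)
  majority_flip <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    same <- sum(a[keep] == b[keep])
    diff_ <- sum(keep) - same
    if (same == diff_) NA_integer_ else if (same > diff_) 0L else 1L
  }
  ## pass 1: unbiased framework, chained
  anchor <- NULL
  frame_idx <- which(!biased)
  if (!length(frame_idx)) frame_idx <- seq_along(ord)  # all biased: chain
  for (k in frame_idx) {
    a <- x[ord[k], ]
    if (all(is.na(a))) { ambiguous <- c(ambiguous, ord[k]); next }
    if (is.null(anchor)) {
      flip[k] <- 0L
    } else {
      f <- majority_flip(a, phased[, anchor])
      if (is.na(f)) { ambiguous <- c(ambiguous, ord[k]); next }
      flip[k] <- f
    }
    phased[, ord[k]] <- as.integer(xor(a, flip[k]))
    anchor <- ord[k]
  }
  ## pass 2: biased markers against the nearest phased framework marker
  placed <- which(!is.na(flip))
  for (k in setdiff(which(biased), frame_idx)) {
    a <- x[ord[k], ]
    if (all(is.na(a)) || !length(placed)) {
      ambiguous <- c(ambiguous, ord[k]); next
    }
    near <- placed[which.min(abs(placed - k))]
    f <- majority_flip(a, phased[, near])
    if (is.na(f)) { ambiguous <- c(ambiguous, ord[k]); next }
    flip[k] <- f
    phased[, ord[k]] <- as.integer(xor(a, f))
  }
  list(phased = phased, flip = flip, ambiguous = ambiguous)
}

# Posterior that the phase symbol at map position `pos` is 0 ("A"), given
# the nearest non-missing flanking symbols of one progeny row and Kosambi
# recombination fractions from the map distances. Returns NA when both
# flanks are missing.
flank_posterior <- function(row, positions, k) {
  n <- length(row)
  lft <- if (k > 1) { i <- max(which(!is.na(row[seq_len(k - 1)])), -Inf); i }
         else -Inf
  rgt_cand <- if (k < n) which(!is.na(row[(k + 1):n])) else integer(0)
  rgt <- if (length(rgt_cand)) k + min(rgt_cand) else Inf
  like0 <- 1; like1 <- 1
  found <- FALSE
  if (is.finite(lft) && lft >= 1) {
    r <- kosambi_r(abs(positions[k] - positions[lft]))
    if (row[lft] == 0L) { like0 <- like0 * (1 - r); like1 <- like1 * r }
    else { like0 <- like0 * r; like1 <- like1 * (1 - r) }
    found <- TRUE
  }
  if (is.finite(rgt)) {
    r <- kosambi_r(abs(positions[rgt] - positions[k]))
    if (row[rgt] == 0L) { like0 <- like0 * (1 - r); like1 <- like1 * r }
    else { like0 <- like0 * r; like1 <- like1 * (1 - r) }
    found <- TRUE
  }
  if (!found) return(NA_real_)
  like0 / (like0 + like1)
}

#' Linkage-informed imputation of missing phase calls
#'
#' Missing entries are imputed from the nearest non-missing flanking
#' markers through interval recombination probabilities (Kosambi fractions
#' of the map distances), first-order Markov along the LG. An entry is
#' filled only when the posterior for one phase reaches `posterior_min`;
#' observed entries are never touched, so missingness only decreases.
#'
#' @param phased progeny x markers phase matrix (0/1/NA)
#' @param positions marker positions (cM) aligned with the columns
#' @param posterior_min minimum posterior to impute
#' @return list with `phased` and `n_imputed`
#' @export
impute_missing <- function(phased, positions, posterior_min = 0.95) {
  stopifnot(ncol(phased) == length(positions))
  n_imp <- 0L
  for (p in seq_len(nrow(phased))) {
    row <- phased[p, ]
    nas <- which(is.na(row))
    for (k in nas) {
      post0 <- flank_posterior(row, positions, k)
      if (is.na(post0)) next
      if (post0 >= posterior_min) {
        phased[p, k] <- 0L; n_imp <- n_imp + 1L
      } else if (1 - post0 >= posterior_min) {
        phased[p, k] <- 1L; n_imp <- n_imp + 1L
      }
    }
  }
  list(phased = phased, n_imputed = n_imp)
}

#' Resolve the parental origin of hk calls
#'
#' An `hk` genotype received `h` from one parent and `k` from the other
#' but does not say which. For each parent with the marker placed on its
#' map, the transmitted allele is inferred from that parent's flanking
#' phased data: the flank posterior of the phase symbol is converted to an
#' allele through the marker's estimated flip. Each parent must reach
#' `posterior_min` independently; a parent that does not (or in whose map
#' the marker is unlinked) stays missing, so resolution may be partial.
#' `hh`/`kk` calls resolve trivially.
#'
#' @param calls character vector of `hh`/`hk`/`kk`/`--` progeny calls
#' @param ctx_m,ctx_f per-parent context: `NULL` if the marker is not
#'   placed for that parent, else a list with `phased` (progeny x markers
#'   of that LG, the focal marker's column included), `positions`, `col`
#'   (focal column index) and `flip` (the marker's estimated flip, 0/1)
#' @param posterior_min per-parent resolution threshold
#' @return list of integer vectors `am`, `ap` (transmitted allele, 0 = h,
#'   1 = k, `NA` unresolved)
#' @export
resolve_hk <- function(calls, ctx_m, ctx_f, posterior_min = 0.95) {
  n <- length(calls)
  am <- ap <- rep(NA_integer_, n)
  am[calls == "hh"] <- 0L; ap[calls == "hh"] <- 0L
  am[calls == "kk"] <- 1L; ap[calls == "kk"] <- 1L
  hk <- which(calls == "hk")
  infer <- function(ctx, p) {
    if (is.null(ctx) || is.na(ctx$flip)) return(NA_integer_)
    row <- ctx$phased[p, ]
    row[ctx$col] <- NA_integer_   # ignore the focal (ambiguous) marker
    post0 <- flank_posterior(row, ctx$positions, ctx$col)
    if (is.na(post0)) return(NA_integer_)
    sym <- if (post0 >= posterior_min) 0L
           else if (1 - post0 >= posterior_min) 1L else NA_integer_
    if (is.na(sym)) return(NA_integer_)
    as.integer(xor(sym, ctx$flip))  # symbol -> transmitted allele
  }
  for (p in hk) {
    am[p] <- infer(ctx_m, p)
    ap[p] <- infer(ctx_f, p)
  }
  list(am = am, ap = ap)
}

#' Split biparental markers into uniparental markers
#'
#' Each biparental marker with resolved parental origins yields an
#' `lm x ll` marker for the maternal transmission (id suffixed `_m`) and
#' an `nn x np` marker for the paternal transmission (suffix `_p`), under
#' the fixed dictionary first allele -> `lm` / `nn`, second allele ->
#' `ll` / `np`. Unresolved transmissions become missing calls.
#'
#' @param geno a [cp_geno] (only biparental markers are split)
#' @param resolved named list: for each biparental marker id a list with
#'   integer vectors `am`, `ap` (0/1/NA); for `ef x eg` and `ab x cd`
#'   markers this may be omitted (origins are read off the calls)
#' @return a [cp_geno] of the split uniparental markers
#' @export
split_biparental <- function(geno, resolved = list()) {
  bip <- which(geno$markers$seg %in% c("hkxhk", "efxeg", "abxcd"))
  if (!length(bip)) stop("no biparental markers to split")
  mk <- list(); cl <- list()
  for (i in bip) {
    id <- geno$markers$marker_id[i]
    seg <- geno$markers$seg[i]
    calls <- geno$calls[i, ]
    if (seg == "hkxhk") {
      if (is.null(resolved[[id]])) next
      am <- resolved[[id]]$am
      ap <- resolved[[id]]$ap
    } else {
      am <- unname(MAT_ALLELE[[seg]][calls])
      ap <- unname(PAT_ALLELE[[seg]][calls])
    }
    enc <- function(a, codes) {
      out <- rep(MISSING_CALL, length(a))
      out[!is.na(a) & a == 0L] <- codes[1]
      out[!is.na(a) & a == 1L] <- codes[2]
      out
    }
    mk[[length(mk) + 1L]] <- data.frame(
      marker_id = paste0(id, "_m"), seg = "lmxll", phase = "--",
      stringsAsFactors = FALSE)
    cl[[length(cl) + 1L]] <- enc(am, c("lm", "ll"))
    mk[[length(mk) + 1L]] <- data.frame(
      marker_id = paste0(id, "_p"), seg = "nnxnp", phase = "--",
      stringsAsFactors = FALSE)
    cl[[length(cl) + 1L]] <- enc(ap, c("nn", "np"))
  }
  if (!length(mk)) stop("no splittable biparental markers (hk unresolved?)")
  calls <- do.call(rbind, cl)
  colnames(calls) <- colnames(geno$calls)
  cp_geno(do.call(rbind, mk), calls)
}
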