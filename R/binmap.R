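#' Detect residual genotyping errors as singleton phase flips
#'
#' A call is flagged when it implies a double phase change within
#' `window` markers on both sides: its nearest non-missing neighbours on
#' each side agree with each other and disagree with it. Flagged calls
#' are set missing (to be re-imputed); terminal markers are never flagged.
#'
#' @param phased progeny x markers phase matrix (0/1/NA), map order
#' @param window maximum marker-index distance to each flank
#' @return list with `phased` and `flagged` (data.frame progeny/marker)
#' @export
detect_errors <- function(phased, window = 2) {
  flagged <- NULL
  n <- ncol(phased)
  for (p in seq_len(nrow(phased))) {
    row <- phased[p, ]
    obs <- which(!is.na(row))
    if (length(obs) < 3) next
    for (j in 2:(length(obs) - 1)) {
      k <- obs[j]; lft <- obs[j - 1]; rgt <- obs[j + 1]
      if (k - lft <= window && rgt - k <= window &&
          row[lft] == row[rgt] && row[k] != row[lft]) {
        flagged <- rbind(flagged, data.frame(
          progeny = rownames(phased)[p], marker = colnames(phased)[k],
          stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(flagged)) {
    phased[cbind(match(flagged$progeny, rownames(phased)),
                 match(flagged$marker, colnames(phased)))] <- NA_integer_
  }
  list(phased = phased,
       flagged = if (is.null(flagged))
         data.frame(progeny = character(0), marker = character(0)) else flagged)
}

#' Collapse cosegregating markers into recombination bins
#'
#' Markers are processed in map order; a marker joins the current bin when
#' its phase vector is compatible with the bin consensus (missing entries
#' wildcard-match), otherwise a new bin starts. The bin representative is
#' the lexicographically smallest member id and the bin position is the
#' representative's mapped position. The partition depends only on map
#' order, not input order.
#'
#' @param phased progeny x markers phase matrix (0/1/NA), columns in map
#'   order
#' @param positions named marker positions (cM)
#' @return list with `bins` (list of `members`, `representative`,
#'   `position`) and `bin_of` (named bin index per marker)
#' @export
make_bins <- function(phased, positions) {
  mk <- colnames(phased)
  stopifnot(all(mk %in% names(positions)))
  bins <- list()
  consensus <- NULL
  members <- character(0)
  flush <- function(bins, members) {
    if (!length(members)) return(bins)
    rep_ <- min(members)
    bins[[length(bins) + 1L]] <- list(members = members,
                                      representative = rep_,
                                      position = unname(positions[rep_]))
    bins
  }
  for (k in seq_along(mk)) {
    v <- phased[, k]
    if (is.null(consensus)) {
      consensus <- v; members <- mk[k]; next
    }
    both <- !is.na(consensus) & !is.na(v)
    if (all(consensus[both] == v[both])) {
      consensus[is.na(consensus)] <- v[is.na(consensus)]
      members <- c(members, mk[k])
    } else {
      bins <- flush(bins, members)
      consensus <- v; members <- mk[k]
    }
  }
  bins <- flush(bins, members)
  bin_of <- integer(0)
  for (b in seq_along(bins)) {
    bin_of[bins[[b]]$members] <- b
  }
  list(bins = bins, bin_of = bin_of)
}

#' Count recombination events (phase changes) per progeny
#'
#' Counts changes between consecutive non-missing phase entries in each
#' progeny row. Rows with fewer than two observed entries are undefined
#' (`NA`) and excluded from the mean.
#'
#' @param phased progeny x markers phase matrix (0/1/NA), map order
#' @return list with `counts` (integer per progeny, `NA` undefined) and
#'   `mean` (mean events per progeny over defined rows)
#' @export
count_recombinations <- function(phased) {
  counts <- apply(phased, 1, function(row) {
    obs <- row[!is.na(row)]
    if (length(obs) < 2) return(NA_integer_)
    sum(diff(obs) != 0)
  })
  list(counts = counts, mean = mean(counts, na.rm = TRUE))
}

#' Bin map of one linkage group as a [genmap]
#'
#' @param bins output of [make_bins()]
#' @param lg linkage-group label
#' @return [genmap] with one row per marker, positioned at its bin
#' @keywords internal
bins_to_map <- function(bins, lg) {
  ord <- order(vapply(bins$bins, `[[`, numeric(1), "position"),
               seq_along(bins$bins))
  rows <- do.call(rbind, lapply(bins$bins[ord], function(b) {
    data.frame(lg = lg, marker = b$members, position = b$position,
               stringsAsFactors = FALSE)
  }))
  rows$position <- rows$position - min(rows$position)
  genmap(rows)
}
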