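#' Construct a genetic map
#'
#' A genetic map is an ordered table of marker positions: columns `lg`,
#' `marker`, `position` (cM, 0-based from the first marker of each linkage
#' group) and `bin` (markers sharing a position share a bin). Positions must
#' be nondecreasing within each linkage group.
#'
#' @param df data.frame with columns `lg`, `marker`, `position` and
#'   optionally `bin` (recomputed from tied positions when absent)
#' @return object of class `genmap` (a data.frame)
#' @export
genmap <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("lg", "marker", "position")
  if (!all(need %in% names(df))) {
    stop("map needs columns: ", paste(need, collapse = ", "))
  }
  df$lg <- as.character(df$lg)
  df$marker <- as.character(df$marker)
  df$position <- as.numeric(df$position)
  if (anyNA(df$position)) stop("non-numeric map position")
  if (anyDuplicated(df$marker)) stop("duplicate marker in map")
  for (g in unique(df$lg)) {
    p <- df$position[df$lg == g]
    if (is.unsorted(p)) {
      stop("decreasing positions within LG ", g)
    }
  }
  df$bin <- assign_bins(df$lg, df$position)
  rownames(df) <- NULL
  class(df) <- c("genmap", "data.frame")
  df
}

# Bin id per row: markers with identical position within an LG share a bin.
assign_bins <- function(lg, position) {
  out <- character(length(lg))
  for (g in unique(lg)) {
    i <- which(lg == g)
    b <- cumsum(c(TRUE, diff(position[i]) > 0))
    out[i] <- sprintf("%s_b%03d", g, b)
  }
  out
}

#' Per-LG map summary
#'
#' @param object a [genmap]
#' @param ... unused
#' @return data.frame with LG, marker count, bin count and length (cM)
#' @export
summary.genmap <- function(object, ...) {
  do.call(rbind, lapply(split(object, object$lg), function(d) {
    data.frame(lg = d$lg[1], n_markers = nrow(d),
               n_bins = length(unique(d$bin)),
               length_cm = max(d$position) - min(d$position))
  }))
}

# Total map length (sum of per-LG spans).
map_length <- function(map) sum(summary.genmap(map)$length_cm)

# Markers of one LG in map order.
lg_markers <- function(map, lg) map$marker[map$lg == lg]
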