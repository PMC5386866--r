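#' @keywords internal
SEG_TYPES <- c("lmxll", "nnxnp", "hkxhk", "efxeg", "abxcd")

#' Missing-call token used in all genotype tables
#' @keywords internal
MISSING_CALL <- "--"

# Legal progeny calls for each outcross segregation type.
SEG_CALLS <- list(
  lmxll = c("ll", "lm"),
  nnxnp = c("nn", "np"),
  hkxhk = c("hh", "hk", "kk"),
  efxeg = c("ee", "ef", "eg", "fg"),
  abxcd = c("ac", "ad", "bc", "bd")
)

# Allele transmitted by the mother (0 = first allele, 1 = second allele,
# NA = uninformative or ambiguous) for each call of each segregation type.
MAT_ALLELE <- list(
  lmxll = c(ll = 0L, lm = 1L),
  nnxnp = c(nn = NA_integer_, np = NA_integer_),
  hkxhk = c(hh = 0L, hk = NA_integer_, kk = 1L),
  efxeg = c(ee = 0L, ef = 1L, eg = 0L, fg = 1L),
  abxcd = c(ac = 0L, ad = 0L, bc = 1L, bd = 1L)
)

# Allele transmitted by the father, same conventions.
PAT_ALLELE <- list(
  lmxll = c(ll = NA_integer_, lm = NA_integer_),
  nnxnp = c(nn = 0L, np = 1L),
  hkxhk = c(hh = 0L, hk = NA_integer_, kk = 1L),
  efxeg = c(ee = 0L, ef = 0L, eg = 1L, fg = 1L),
  abxcd = c(ac = 0L, ad = 1L, bc = 0L, bd = 1L)
)

# Call string from transmitted allele indices (mother, father).
call_from_alleles <- function(seg, am, ap) {
  switch(seg,
    lmxll = c("ll", "lm")[am + 1L],
    nnxnp = c("nn", "np")[ap + 1L],
    hkxhk = c("hh", "hk", "kk")[am + ap + 1L],
    efxeg = c("ee", "eg", "ef", "fg")[am * 2L + ap + 1L],
    abxcd = c("ac", "ad", "bc", "bd")[am * 2L + ap + 1L],
    stop("unknown segregation type: ", seg)
  )
}

seg_informative <- function(seg, parent) {
  if (parent == "mother") seg %in% c("lmxll", "hkxhk", "efxeg", "abxcd")
  else seg %in% c("nnxnp", "hkxhk", "efxeg", "abxcd")
}

#' Construct a CP-coded genotype set
#'
#' Bundles per-marker metadata (segregation type and linkage phase) with the
#' matrix of coded progeny calls for a full-sib outcross population. This is
#' the container every pipeline stage consumes. Calls follow the usual CP
#' dialect (`lm`/`ll`, `nn`/`np`, `hh`/`hk`/`kk`, `ee`/`ef`/`eg`/`fg`,
#' `ac`/`ad`/`bc`/`bd`) with `"--"` for missing.
#'
#' @param markers data.frame with columns `marker_id`, `seg` (one of
#'   `lmxll`, `nnxnp`, `hkxhk`, `efxeg`, `abxcd`) and optionally `phase`
#'   (per-parent coupling digits, `-` when unknown) and `lg`.
#' @param calls character matrix, one row per marker (rownames must equal
#'   `markers$marker_id`), one column per progeny.
#' @return An object of class `cp_geno`.
#' @export
cp_geno <- function(markers, calls) {
  stopifnot(is.data.frame(markers), is.matrix(calls))
  req <- c("marker_id", "seg")
  if (!all(req %in% names(markers))) {
    stop("markers must contain columns: ", paste(req, collapse = ", "))
  }
  markers$marker_id <- as.character(markers$marker_id)
  markers$seg <- as.character(markers$seg)
  if (anyDuplicated(markers$marker_id)) {
    stop("duplicate marker_id: ",
         paste(unique(markers$marker_id[duplicated(markers$marker_id)]),
               collapse = ", "))
  }
  bad <- !markers$seg %in% SEG_TYPES
  if (any(bad)) {
    stop("unknown segregation type for marker ",
         markers$marker_id[which(bad)[1]], ": ", markers$seg[which(bad)[1]])
  }
  if (is.null(markers$phase)) markers$phase <- "--"
  if (nrow(calls) != nrow(markers)) {
    stop("calls must have one row per marker")
  }
  if (ncol(calls) == 0) stop("no progeny columns")
  rownames(calls) <- markers$marker_id
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("P%03d", seq_len(ncol(calls)))
  }
  for (i in seq_len(nrow(markers))) {
    legal <- c(SEG_CALLS[[markers$seg[i]]], MISSING_CALL)
    bad <- which(!calls[i, ] %in% legal)
    if (length(bad)) {
      stop(sprintf("illegal call '%s' for %s marker '%s' (progeny column %d)",
                   calls[i, bad[1]], markers$seg[i], markers$marker_id[i],
                   bad[1]))
    }
  }
  structure(list(markers = markers, calls = calls),
            class = "cp_geno")
}

#' @export
print.cp_geno <- function(x, ...) {
  cat(sprintf("cp_geno: %d markers x %d progeny\n",
              nrow(x$markers), ncol(x$calls)))
  print(table(x$markers$seg))
  invisible(x)
}

#' Transmitted-allele matrix for one parent
#'
#' Converts coded calls to the allele index (0/1) transmitted by one parent;
#' `NA` marks missing or uninformative calls (including unresolved `hk`).
#'
#' @param geno a [cp_geno] object
#' @param parent `"mother"` or `"father"`
#' @return integer matrix, markers x progeny
#' @export
transmitted_alleles <- function(geno, parent = c("mother", "father")) {
  parent <- match.arg(parent)
  tab <- if (parent == "mother") MAT_ALLELE else PAT_ALLELE
  out <- matrix(NA_integer_, nrow(geno$calls), ncol(geno$calls),
                dimnames = dimnames(geno$calls))
  for (i in seq_len(nrow(geno$calls))) {
    lk <- tab[[geno$markers$seg[i]]]
    out[i, ] <- lk[geno$calls[i, ]]
  }
  out
}

# Subset a cp_geno by marker ids (keeps order given).
subset_geno <- function(geno, ids) {
  idx <- match(ids, geno$markers$marker_id)
  if (anyNA(idx)) stop("unknown marker ids in subset")
  cp_geno(geno$markers[idx, , drop = FALSE],
          geno$calls[idx, , drop = FALSE])
}
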