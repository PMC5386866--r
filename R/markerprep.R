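#' Classify a marker's segregation type from parental genotypes
#'
#' Parents are given as two-character diploid genotypes (e.g. `"AG"`).
#' Uniparental markers are heterozygous in a single parent (`lm x ll`
#' maternal, `nn x np` paternal); biparental markers are heterozygous in
#' both, split by shared-allele count: both alleles shared -> `hk x hk`,
#' one shared -> `ef x eg`, none shared -> `ab x cd`. A recode dictionary
#' mapping observed progeny genotypes to canonical CP calls is returned
#' alongside the code.
#'
#' @param mother,father diploid parental genotypes as two-character strings
#' @return list with `seg`, and `dict` (named map from sorted progeny
#'   genotype strings to CP calls)
#' @export
classify_segregation <- function(mother, father) {
  gm <- sort(strsplit(mother, "")[[1]])
  gf <- sort(strsplit(father, "")[[1]])
  if (length(gm) != 2 || length(gf) != 2 || anyNA(c(gm, gf)) ||
      any(c(gm, gf) == "-")) {
    stop("parental calls must both be present to classify")
  }
  het_m <- gm[1] != gm[2]
  het_f <- gf[1] != gf[2]
  key <- function(a, b) paste0(sort(c(a, b)), collapse = "")
  if (het_m && !het_f) {
    # mother l/m, father l/l: identify 'l' with the father's allele when
    # shared, otherwise the lexicographically first maternal allele
    l <- if (gf[1] %in% gm) gf[1] else gm[1]
    m <- setdiff(gm, l)[1]
    if (is.na(m)) m <- gm[2]
    dict <- stats::setNames(c("ll", "lm"),
                            c(key(l, gf[1]), key(m, gf[1])))
    list(seg = "lmxll", dict = dict)
  } else if (!het_m && het_f) {
    n <- if (gm[1] %in% gf) gm[1] else gf[1]
    p <- setdiff(gf, n)[1]
    if (is.na(p)) p <- gf[2]
    dict <- stats::setNames(c("nn", "np"),
                            c(key(gm[1], n), key(gm[1], p)))
    list(seg = "nnxnp", dict = dict)
  } else if (het_m && het_f) {
    shared <- intersect(gm, gf)
    if (length(shared) == 2) {
      h <- gm[1]; k <- gm[2]
      dict <- stats::setNames(c("hh", "hk", "kk"),
                              c(key(h, h), key(h, k), key(k, k)))
      list(seg = "hkxhk", dict = dict)
    } else if (length(shared) == 1) {
      e <- shared
      f <- setdiff(gm, e)
      g <- setdiff(gf, e)
      dict <- stats::setNames(c("ee", "ef", "eg", "fg"),
                              c(key(e, e), key(e, f), key(e, g), key(f, g)))
      list(seg = "efxeg", dict = dict)
    } else {
      a <- gm[1]; b <- gm[2]; c_ <- gf[1]; d <- gf[2]
      dict <- stats::setNames(c("ac", "ad", "bc", "bd"),
                              c(key(a, c_), key(a, d), key(b, c_), key(b, d)))
      list(seg = "abxcd", dict = dict)
    }
  } else {
    stop("marker homozygous in both parents is not segregating")
  }
}

# Recode raw progeny diploid genotypes through a classification dictionary.
# Non-Mendelian calls (absent from the dictionary) are counted and set
# missing rather than dropping the marker.
recode_progeny <- function(cls, raw_calls) {
  keys <- vapply(raw_calls, function(g) {
    if (is.na(g) || g %in% c(MISSING_CALL, "", "NN", "N")) return(MISSING_CALL)
    paste0(sort(strsplit(g, "")[[1]]), collapse = "")
  }, character(1))
  out <- unname(cls$dict[keys])
  bad <- is.na(out) & keys != MISSING_CALL
  out[is.na(out)] <- MISSING_CALL
  list(calls = out, n_bad = sum(bad))
}

new_filter_report <- function(geno) {
  structure(list(
    steps = data.frame(step = "input", n = nrow(geno$markers),
                       stringsAsFactors = FALSE),
    dropped = data.frame(marker_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  ), class = "filter_report")
}

record_step <- function(report, step, geno, dropped_ids) {
  report$steps <- rbind(report$steps,
                        data.frame(step = step, n = nrow(geno$markers)))
  if (length(dropped_ids)) {
    report$dropped <- rbind(report$dropped,
                            data.frame(marker_id = dropped_ids, reason = step))
  }
  report
}

#' @export
print.filter_report <- function(x, ...) {
  print(x$steps)
  invisible(x)
}

apply_drop <- function(geno, drop) {
  keep <- setdiff(geno$markers$marker_id, drop)
  subset_geno(geno, keep)
}

#' Pre-mapping marker filters
#'
#' Sequential filters applied before linkage analysis, with strict boundary
#' semantics: `filter_missing()` removes markers with a missing-call
#' fraction strictly above `max_missing` (default 20%); `filter_maf()`
#' removes markers whose minor-allele frequency, computed on progeny allele
#' counts (minor-allele count / (2 x non-missing progeny)), is strictly
#' below `min_maf` (default 10%); `filter_extreme_sd()` removes markers
#' whose 1-df allele-ratio chi-square P value is strictly below `alpha`
#' (default 1e-5). Each returns the filtered [cp_geno] plus an updated
#' `filter_report`, and re-running a filter on its own output changes
#' nothing.
#'
#' @param geno a [cp_geno]
#' @param max_missing,min_maf,alpha thresholds
#' @param report an existing `filter_report` to extend (optional)
#' @return list with `geno` and `report`
#' @export
filter_missing <- function(geno, max_missing = 0.20, report = NULL) {
  if (max_missing < 0 || max_missing > 1) stop("max_missing outside [0,1]")
  if (is.null(report)) report <- new_filter_report(geno)
  frac <- rowMeans(geno$calls == MISSING_CALL)
  drop <- geno$markers$marker_id[frac > max_missing]
  geno <- apply_drop(geno, drop)
  list(geno = geno, report = record_step(report, "missing", geno, drop))
}

#' @rdname filter_missing
#' @export
filter_maf <- function(geno, min_maf = 0.10, report = NULL) {
  if (min_maf < 0 || min_maf > 1) stop("min_maf outside [0,1]")
  if (is.null(report)) report <- new_filter_report(geno)
  maf <- marker_maf(geno)
  drop <- geno$markers$marker_id[is.na(maf) | maf < min_maf]
  geno <- apply_drop(geno, drop)
  list(geno = geno, report = record_step(report, "maf", geno, drop))
}

# Progeny-level minor allele frequency. Each call contributes two allele
# observations; alleles are the type's canonical letters.
marker_maf <- function(geno) {
  vapply(seq_len(nrow(geno$markers)), function(i) {
    calls <- geno$calls[i, ]
    calls <- calls[calls != MISSING_CALL]
    if (!length(calls)) return(NA_real_)
    alleles <- unlist(strsplit(calls, ""))
    cnt <- table(alleles)
    if (length(cnt) < 2) return(0)     # monomorphic: minor allele absent
    min(cnt) / length(alleles)
  }, numeric(1))
}

#' @rdname filter_missing
#' @export
filter_extreme_sd <- function(geno, alpha = 1e-5, report = NULL) {
  if (is.null(report)) report <- new_filter_report(geno)
  p <- vapply(seq_len(nrow(geno$markers)), function(i) {
    sd_chi2_counts(geno$markers$seg[i], geno$calls[i, ])["p"]
  }, numeric(1))
  drop <- geno$markers$marker_id[!is.na(p) & p < alpha]
  geno <- apply_drop(geno, drop)
  list(geno = geno, report = record_step(report, "extreme_sd", geno, drop))
}

#' Write a filter report
#'
#' @param report a `filter_report`
#' @param path_tsv,path_json output paths (either may be `NULL`)
#' @return `report`, invisibly
#' @export
write_filter_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(report$dropped, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(steps = report$steps, dropped = report$dropped),
                         path_json, dataframe = "columns", digits = NA)
  }
  invisible(report)
}
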