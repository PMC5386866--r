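#' Read a progeny genotype table
#'
#' Supported dialects:
#' \describe{
#'   \item{`cp-tsv`}{the package's canonical tab-separated dialect: header
#'     `marker seg phase <progeny ids>`, one row per marker with the
#'     segregation type in angle brackets (`<lmxll>`), the linkage phase in
#'     braces (`{0-}`: one digit per parent, `-` = unknown) and one coded
#'     call per progeny, `--` for missing.}
#'   \item{`hapmap-like`}{a plain TSV with columns `rs`, then two parental
#'     columns and the progeny, all as diploid allele pairs (`AG`, `--`);
#'     segregation types are derived from the parental genotypes via
#'     [classify_segregation()].}
#'   \item{`vcf`}{an uncompressed VCF with GT fields; biallelic SNPs only.
#'     Parental samples are named via `mother=`/`father=`.}
#' }
#' All dialects normalise to canonical CP tokens with `"--"` for missing.
#' `write_genotypes()` followed by `read_genotypes()` is byte-stable for
#' `cp-tsv`.
#'
#' @param path file path
#' @param dialect one of `"cp-tsv"`, `"hapmap-like"`, `"vcf"`
#' @param mother,father parental column/sample names (dialects that carry
#'   parental genotypes)
#' @return a [cp_geno]
#' @export
read_genotypes <- function(path, dialect = c("cp-tsv", "hapmap-like", "vcf"),
                           mother = NULL, father = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(dialect,
         "cp-tsv" = read_cp_tsv(path),
         "hapmap-like" = read_hapmap_like(path, mother, father),
         "vcf" = read_vcf_geno(path, mother, father))
}

read_cp_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty genotype file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 4 || !identical(header[1:3], c("marker", "seg", "phase"))) {
    stop("cp-tsv header must start with: marker seg phase; no progeny columns?")
  }
  progeny <- header[-(1:3)]
  if (!length(progeny)) stop("no progeny columns")
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- length(fields)
  mk <- character(n); seg <- character(n); ph <- character(n)
  calls <- matrix(NA_character_, n, length(progeny),
                  dimnames = list(NULL, progeny))
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) != 3 + length(progeny)) {
      stop(sprintf("line %d: expected %d fields, got %d", i + 1,
                   3 + length(progeny), length(f)))
    }
    mk[i] <- f[1]
    seg[i] <- gsub("^<|>$", "", f[2])
    ph[i] <- gsub("^\\{|\\}$", "", f[3])
    calls[i, ] <- f[-(1:3)]
  }
  ph <- normalize_phase(ph, seg)
  markers <- data.frame(marker_id = mk, seg = seg, phase = ph,
                        stringsAsFactors = FALSE)
  g <- try(cp_geno(markers, calls), silent = TRUE)
  if (inherits(g, "try-error")) {
    stop("parse error in ", path, ": ", attr(g, "condition")$message)
  }
  g
}

# Canonical phase is two characters (mother, father digit or '-'); accept a
# single digit for uniparental markers and pad the uninformative side.
normalize_phase <- function(ph, seg) {
  out <- ph
  for (i in seq_along(ph)) {
    p <- ph[i]
    if (nchar(p) == 1 && p %in% c("0", "1")) {
      out[i] <- if (seg[i] == "nnxnp") paste0("-", p) else paste0(p, "-")
    } else if (nchar(p) != 2 || grepl("[^01-]", p)) {
      out[i] <- "--"
    }
  }
  out
}

#' Write a genotype table in the canonical cp-tsv dialect
#'
#' @param geno a [cp_geno]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genotypes <- function(geno, path) {
  header <- paste(c("marker", "seg", "phase", colnames(geno$calls)),
                  collapse = "\t")
  ph <- normalize_phase(geno$markers$phase, geno$markers$seg)
  rows <- vapply(seq_len(nrow(geno$markers)), function(i) {
    paste(c(geno$markers$marker_id[i],
            paste0("<", geno$markers$seg[i], ">"),
            paste0("{", ph[i], "}"),
            geno$calls[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

read_hapmap_like <- function(path, mother, father) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (is.null(mother) || is.null(father)) {
    stop("hapmap-like dialect requires mother= and father= column names")
  }
  if (!all(c("rs", mother, father) %in% names(tab))) {
    stop("hapmap-like file must contain columns rs, ", mother, ", ", father)
  }
  prog_cols <- setdiff(names(tab), c("rs", "alleles", mother, father))
  if (!length(prog_cols)) stop("no progeny columns")
  recode_one <- function(rs, gm, gf, calls) {
    cls <- classify_segregation(gm, gf)
    recoded <- recode_progeny(cls, calls)
    list(seg = cls$seg, calls = recoded$calls, n_bad = recoded$n_bad)
  }
  segs <- character(nrow(tab))
  calls <- matrix(MISSING_CALL, nrow(tab), length(prog_cols),
                  dimnames = list(NULL, prog_cols))
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    res <- try(recode_one(tab$rs[i], tab[[mother]][i], tab[[father]][i],
                          as.character(tab[i, prog_cols])), silent = TRUE)
    if (inherits(res, "try-error")) next
    segs[i] <- res$seg
    calls[i, ] <- res$calls
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no informative markers in ", path)
  markers <- data.frame(marker_id = as.character(tab$rs)[keep],
                        seg = segs[keep], phase = "--",
                        stringsAsFactors = FALSE)
  cp_geno(markers, calls[keep, , drop = FALSE])
}

read_vcf_geno <- function(path, mother, father) {
  if (is.null(mother) || is.null(father)) {
    stop("vcf dialect requires mother= and father= sample names")
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#CHROM")) {
    stop("not a VCF file: ", path)
  }
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:9)]
  if (!all(c(mother, father) %in% samples)) {
    stop("VCF lacks parental samples ", mother, "/", father)
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  prog <- setdiff(samples, c(mother, father))
  gt_of <- function(f) sub(":.*$", "", f)
  dip <- function(gt, ref, alt) {
    a <- strsplit(gt, "[/|]")[[1]]
    if (length(a) != 2 || any(a == ".")) return(MISSING_CALL)
    paste0(c(ref, alt)[as.integer(a) + 1][order(as.integer(a))], collapse = "")
  }
  segs <- character(length(body)); keep <- logical(length(body))
  ids <- character(length(body))
  calls <- matrix(MISSING_CALL, length(body), length(prog),
                  dimnames = list(NULL, prog))
  for (i in seq_along(body)) {
    f <- body[[i]]
    ref <- f[4]; alt <- f[5]
    if (nchar(ref) != 1 || nchar(alt) != 1) next  # biallelic SNPs only
    ids[i] <- if (f[3] != ".") f[3] else paste0(f[1], "_", f[2])
    g <- vapply(f[-(1:9)], gt_of, character(1))
    names(g) <- samples
    gm <- dip(g[[mother]], ref, alt); gf <- dip(g[[father]], ref, alt)
    res <- try({
      cls <- classify_segregation(gm, gf)
      pc <- vapply(g[prog], dip, character(1), ref = ref, alt = alt)
      recode_progeny(cls, pc)$calls
    }, silent = TRUE)
    if (inherits(res, "try-error")) next
    segs[i] <- classify_segregation(gm, gf)$seg
    calls[i, ] <- res
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no informative biallelic SNPs in ", path)
  cp_geno(data.frame(marker_id = ids[keep], seg = segs[keep], phase = "--",
                     stringsAsFactors = FALSE),
          calls[keep, , drop = FALSE])
}

#' Export biallelic SNP markers as VCF
#'
#' Writes lm x ll, nn x np and hk x hk markers of a [cp_geno] as diploid GT
#' records (`./.` for missing); multi-allelic CP types are skipped. Alleles
#' are written as generic REF=A, ALT=T since CP codes carry no nucleotide
#' identity.
#'
#' @param geno a [cp_geno]
#' @param path output path
#' @param map optional [genmap]; mapped markers get CHROM = LG and POS =
#'   round(100 * position); unmapped markers go to CHROM "un"
#' @return `path`, invisibly
#' @export
write_vcf <- function(geno, path, map = NULL) {
  biallelic <- geno$markers$seg %in% c("lmxll", "nnxnp", "hkxhk")
  g <- subset_geno(geno, geno$markers$marker_id[biallelic])
  gt_tab <- list(
    lmxll = c(ll = "0/0", lm = "0/1"),
    nnxnp = c(nn = "0/0", np = "0/1"),
    hkxhk = c(hh = "0/0", hk = "0/1", kk = "1/1")
  )
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g$calls)), collapse = "\t"))
  chrom <- rep("un", nrow(g$markers)); pos <- seq_len(nrow(g$markers))
  if (!is.null(map)) {
    idx <- match(g$markers$marker_id, map$marker)
    hit <- !is.na(idx)
    chrom[hit] <- map$lg[idx[hit]]
    pos[hit] <- pmax(1L, round(100 * map$position[idx[hit]]))
  }
  rows <- vapply(seq_len(nrow(g$markers)), function(i) {
    lk <- gt_tab[[g$markers$seg[i]]]
    gt <- unname(lk[g$calls[i, ]])
    gt[is.na(gt)] <- "./."
    paste(c(chrom[i], pos[i], g$markers$marker_id[i], "A", "T", ".", ".",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read / write a genetic-map TSV
#'
#' The map dialect is a TSV with header `lg  marker  cM  bin`; positions are
#' decimal centimorgans and must be nondecreasing within each LG. Bins are
#' recomputed from tied positions on read, so a file written by
#' [write_map()] round-trips byte-identically.
#'
#' @param path file path
#' @return a [genmap]
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("lg", "marker", "cM") %in% names(tab))) {
    stop("map file needs header: lg marker cM bin")
  }
  genmap(data.frame(lg = tab$lg, marker = tab$marker,
                    position = as.numeric(tab$cM),
                    stringsAsFactors = FALSE))
}

#' @rdname read_map
#' @param map a [genmap]
#' @export
write_map <- function(map, path) {
  lines <- c("lg\tmarker\tcM\tbin",
             sprintf("%s\t%s\t%s\t%s", map$lg, map$marker,
                     format_cm(map$position), map$bin))
  writeLines(lines, path)
  invisible(path)
}

# Fixed-precision cM formatting (1/10000 cM); guarantees byte-stable
# round-trips of our own output.
format_cm <- function(x) {
  s <- sprintf("%.4f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", ".0", s)
}

#' Read / write a pedigree CSV
#'
#' Columns `id`, `sire`, `dam`; empty fields are unknown (founder) parents.
#'
#' @param path file path
#' @return data.frame with character columns `id`, `sire`, `dam`
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("id", "sire", "dam") %in% names(ped))) {
    stop("pedigree needs columns id, sire, dam")
  }
  ped$sire[is.na(ped$sire) | ped$sire == ""] <- NA_character_
  ped$dam[is.na(ped$dam) | ped$dam == ""] <- NA_character_
  ped
}

#' @rdname read_pedigree
#' @param ped pedigree data.frame
#' @export
write_pedigree <- function(ped, path) {
  out <- ped[, c("id", "sire", "dam")]
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phased-gamete matrix
#'
#' TSV grid with progeny rows and marker columns; entries `A`, `B` or `-`.
#' Internally phases are integer 0 (`A`) / 1 (`B`) with `NA` missing.
#'
#' @param path file path
#' @return integer matrix, progeny x markers
#' @export
read_phased <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  out[m == "A"] <- 0L
  out[m == "B"] <- 1L
  out
}

#' @rdname read_phased
#' @param phased integer matrix (0/1/NA), progeny x markers
#' @export
write_phased <- function(phased, path) {
  sym <- matrix("-", nrow(phased), ncol(phased))
  sym[!is.na(phased) & phased == 0L] <- "A"
  sym[!is.na(phased) & phased == 1L] <- "B"
  lines <- c(paste(c("progeny", colnames(phased)), collapse = "\t"),
             vapply(seq_len(nrow(phased)), function(i) {
               paste(c(rownames(phased)[i], sym[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
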