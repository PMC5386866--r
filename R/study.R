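#' Headline statistics of a multi-population composite-mapping study
#'
#' Recomputes the summary statistics of a composite-mapping study from a
#' directory of map files in this package's map dialect: six component
#' bin maps named `component_<parent>.tsv` (with `<parent>` tagged by
#' population so reciprocal uses of one parent stay distinct) and a
#' `composite.tsv`. A `populations.json` file maps each component to its
#' population and parental role, e.g.
#' `{"component_P1.tsv": {"population": "POP1", "role": "mother"}, ...}`.
#' Optionally, per-component genotype tables `geno_<parent>.tsv` enable
#' the distorted-marker fraction.
#'
#' The statistics mirror the quantities a multi-pedigree mapping study
#' reports: all pairwise component-LG Spearman correlations (with shared
#' marker counts), composite-versus-component correlations, composite
#' marker totals, cross-population marker sharing, and the fraction of
#' mapped markers with segregation-distortion P < 0.1.
#'
#' @param dir directory containing the study files
#' @return list of summary statistics
#' @export
composite_study_stats <- function(dir) {
  if (!dir.exists(dir)) {
    stop("supplementary-data directory not found: ", dir,
         " (the published component/composite map and genotype tables",
         " must be downloaded and converted once; see README)")
  }
  comp_files <- list.files(dir, pattern = "^component_.*\\.tsv$",
                           full.names = TRUE)
  if (!length(comp_files)) stop("no component_*.tsv maps in ", dir)
  comps <- lapply(comp_files, read_map)
  names(comps) <- sub("^component_(.*)\\.tsv$", "\\1", basename(comp_files))
  composite <- read_map(file.path(dir, "composite.tsv"))

  ## pairwise component collinearity
  pair_rows <- list()
  nm <- names(comps)
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j <= i) next
      cc <- collinearity(comps[[i]], comps[[j]])
      if (nrow(cc)) {
        cc$pair <- paste(nm[i], nm[j], sep = "x")
        pair_rows[[length(pair_rows) + 1L]] <- cc
      }
    }
  }
  pw <- do.call(rbind, pair_rows)
  ## composite vs component
  cvc <- do.call(rbind, lapply(nm, function(m) {
    cc <- collinearity(composite, comps[[m]])
    cc$pair <- m
    cc
  }))

  ## cross-population marker sharing
  pops <- NULL
  pop_file <- file.path(dir, "populations.json")
  if (file.exists(pop_file)) {
    meta <- jsonlite::read_json(pop_file, simplifyVector = FALSE)
    pops <- vapply(meta, function(x) x$population, character(1))
    names(pops) <- sub("^component_(.*)\\.tsv$", "\\1", names(meta))
  }
  shared2 <- shared3 <- NA_integer_
  if (!is.null(pops)) {
    marker_pops <- list()
    for (m in nm) {
      for (mk in unique(comps[[m]]$marker)) {
        marker_pops[[mk]] <- union(marker_pops[[mk]], pops[[m]])
      }
    }
    npop <- lengths(marker_pops[intersect(names(marker_pops),
                                          composite$marker)])
    shared2 <- sum(npop >= 2)
    shared3 <- sum(npop >= 3)
  }

  ## distortion fraction over component-map markers
  geno_files <- list.files(dir, pattern = "^geno_.*\\.tsv$",
                           full.names = TRUE)
  frac_dist <- NA_real_
  if (length(geno_files)) {
    tot <- dist <- 0
    for (gf in geno_files) {
      par <- sub("^geno_(.*)\\.tsv$", "\\1", basename(gf))
      if (!par %in% nm) next
      geno <- read_genotypes(gf)
      mp <- comps[[par]]
      mp <- genmap(as.data.frame(mp)[mp$marker %in%
                                       geno$markers$marker_id, ])
      scan <- sd_scan(geno, mp, alpha = 0.1)
      tot <- tot + sum(!is.na(scan$p))
      dist <- dist + sum(scan$distorted, na.rm = TRUE)
    }
    if (tot > 0) frac_dist <- dist / tot
  }

  list(
    n_pairwise = nrow(pw),
    mean_rho = mean(pw$rho, na.rm = TRUE),
    min_rho = min(pw$rho, na.rm = TRUE),
    mean_shared = mean(pw$n_shared),
    composite_n_comparisons = nrow(cvc),
    composite_mean_rho = mean(cvc$rho, na.rm = TRUE),
    composite_n_markers = nrow(composite),
    composite_length_cm = sum(summary.genmap(composite)$length_cm),
    snps_in_2plus_pops = shared2,
    snps_in_3_pops = shared3,
    frac_distorted = frac_dist
  )
}
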