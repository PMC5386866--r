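#' Simulation configuration for full-sib outcross populations
#'
#' Builds the stated world the generator emulates: 12 metacentric linkage
#' groups of roughly 85-116 cM, a full-sib family of realistic size, a
#' mixed marker panel of uniparental (lm x ll, nn x np) and biparental
#' (hk x hk, ef x eg, ab x cd) markers, bounded missing data, central
#' crossover suppression around each centromere, optional viability
#' (segregation-distortion) loci, sex-specific crossover-rate multipliers,
#' and a finite pollen-tetrad pool if desired.
#'
#' @param n_lg number of linkage groups
#' @param lg_lengths genetic length of each LG in cM
#' @param n_progeny full-sib family size
#' @param marker_density markers per cM (total panel, before per-parent
#'   informativeness)
#' @param type_mix named proportions over the five CP segregation types;
#'   must sum to 1
#' @param missing_rate,error_rate i.i.d. per-call missing and genotyping
#'   error probabilities applied to the observed table only
#' @param maternal_rate_scale,paternal_rate_scale multipliers on crossover
#'   intensity in maternal / paternal meioses
#' @param tetrad_pool_size number of paternal pollen tetrads progeny are
#'   drawn from (`Inf` = a fresh meiosis per progeny)
#' @param centromere_pos centromere position per LG (cM); default mid-LG
#' @param suppression_width,suppression_factor width (cM) of the
#'   pericentromeric crossover-suppression window and the multiplier
#'   (in `[0,1]`) applied to crossover intensity inside it
#' @param sd_loci data.frame of viability loci with columns `lg`, `pos`,
#'   `parent` (`"mother"`/`"father"`), `allele` (0 = grandparental homolog
#'   A survives, 1 = B survives) and `s` (survival probability of gametes
#'   carrying the other allele)
#' @param seed integer seed; all randomness flows from it
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_lg = 12,
                       lg_lengths = round(seq(85, 116, length.out = n_lg)),
                       n_progeny = 168,
                       marker_density = 1,
                       type_mix = c(lmxll = 0.3, nnxnp = 0.3, hkxhk = 0.2,
                                    efxeg = 0.1, abxcd = 0.1),
                       missing_rate = 0.05,
                       error_rate = 0.01,
                       maternal_rate_scale = 1,
                       paternal_rate_scale = 1,
                       tetrad_pool_size = Inf,
                       centromere_pos = lg_lengths / 2,
                       suppression_width = 20,
                       suppression_factor = 0.2,
                       sd_loci = NULL,
                       seed = 1) {
  stopifnot(n_lg >= 1, length(lg_lengths) == n_lg, all(lg_lengths > 0),
            n_progeny >= 1, marker_density > 0,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            maternal_rate_scale >= 0, paternal_rate_scale >= 0,
            suppression_factor >= 0, suppression_factor <= 1,
            suppression_width >= 0,
            length(centromere_pos) == n_lg)
  if (!all(names(type_mix) %in% SEG_TYPES) || abs(sum(type_mix) - 1) > 1e-8) {
    stop("type_mix must be named over the CP types and sum to 1")
  }
  if (any(centromere_pos < 0 | centromere_pos > lg_lengths)) {
    stop("centromere outside LG")
  }
  if (any(centromere_pos - suppression_width / 2 < 0) ||
      any(centromere_pos + suppression_width / 2 > lg_lengths)) {
    stop("suppression window extends beyond an LG")
  }
  if (is.finite(tetrad_pool_size) &&
      4 * tetrad_pool_size < n_progeny) {
    stop("tetrad pool too small: ", tetrad_pool_size,
         " tetrads supply at most ", 4 * tetrad_pool_size, " gametes")
  }
  if (!is.null(sd_loci)) {
    stopifnot(is.data.frame(sd_loci),
              all(c("lg", "pos", "parent", "allele", "s") %in% names(sd_loci)),
              all(sd_loci$s >= 0 & sd_loci$s <= 1),
              all(sd_loci$parent %in% c("mother", "father")),
              all(sd_loci$allele %in% c(0, 1)))
  }
  structure(list(n_lg = n_lg, lg_lengths = lg_lengths,
                 n_progeny = n_progeny, marker_density = marker_density,
                 type_mix = type_mix, missing_rate = missing_rate,
                 error_rate = error_rate,
                 maternal_rate_scale = maternal_rate_scale,
                 paternal_rate_scale = paternal_rate_scale,
                 tetrad_pool_size = tetrad_pool_size,
                 centromere_pos = centromere_pos,
                 suppression_width = suppression_width,
                 suppression_factor = suppression_factor,
                 sd_loci = sd_loci, seed = as.integer(seed)),
            class = "sim_config")
}

# Piecewise-constant crossover intensity over [0, L]: baseline 1 with the
# suppression window scaled by `factor`. Returned as segment table.
intensity_profile <- function(L, centromere = NULL, width = 0, factor = 1) {
  if (is.null(centromere) || width <= 0 || factor == 1) {
    return(data.frame(from = 0, to = L, f = 1))
  }
  a <- max(0, centromere - width / 2)
  b <- min(L, centromere + width / 2)
  seg <- data.frame(from = c(0, a, b), to = c(a, b, L), f = c(1, factor, 1))
  seg[seg$to > seg$from, , drop = FALSE]
}

#' Simulate one meiosis (a tetrad of four gametes)
#'
#' Chiasma counts per bivalent are Poisson with mean `2 * L_eff / 100`
#' where `L_eff` is the intensity-weighted genetic length, so each gamete
#' carries `L_eff / 100` crossovers in expectation. Chiasma positions are
#' drawn from the normalised intensity profile. Each chiasma exchanges the
#' distal segments of exactly two of the four chromatids -- one chosen
#' uniformly from each homolog (no chromatid interference); there is no
#' obligate chiasma and no positional interference.
#'
#' @param lg_length genetic length in cM (`0` gives four parental gametes)
#' @param intensity optional piecewise-constant intensity table with
#'   columns `from`, `to`, `f` (baseline 1); default uniform
#' @param rate_scale extra multiplier on chiasma intensity
#' @return list with `gametes` (four chromatids, each a list with segment
#'   `bounds`, per-segment homolog `hom` in `{0,1}`, and crossover
#'   positions `breaks`) and `chiasmata` (sorted chiasma positions, cM)
#' @export
simulate_meiosis <- function(lg_length, intensity = NULL, rate_scale = 1) {
  if (!is.numeric(lg_length) || length(lg_length) != 1 || lg_length < 0) {
    stop("lg_length must be a single nonnegative number")
  }
  L <- lg_length
  n_chi <- 0L
  pos <- numeric(0)
  if (L > 0) {
    if (is.null(intensity)) intensity <- data.frame(from = 0, to = L, f = 1)
    w <- (intensity$to - intensity$from) * intensity$f
    l_eff <- sum(w) * rate_scale
    n_chi <- stats::rpois(1, 2 * l_eff / 100)
    if (n_chi > 0) {
      seg <- sample.int(nrow(intensity), n_chi, replace = TRUE, prob = w)
      pos <- sort(intensity$from[seg] +
                    stats::runif(n_chi) * (intensity$to[seg] -
                                             intensity$from[seg]))
    }
  }
  ## one chromatid per homolog per chiasma (axes 1,2 = homolog A; 3,4 = B)
  pick1 <- if (n_chi) sample(1:2, n_chi, replace = TRUE) else integer(0)
  pick2 <- if (n_chi) sample(3:4, n_chi, replace = TRUE) else integer(0)
  gametes <- lapply(1:4, function(s) {
    cur <- s
    breaks <- numeric(0)
    for (k in seq_len(n_chi)) {
      if (cur == pick1[k]) {
        cur <- pick2[k]; breaks <- c(breaks, pos[k])
      } else if (cur == pick2[k]) {
        cur <- pick1[k]; breaks <- c(breaks, pos[k])
      }
    }
    h0 <- if (s <= 2) 0L else 1L
    hom <- as.integer((h0 + seq(0, length(breaks))) %% 2)
    list(bounds = c(breaks, max(L, 0)), hom = hom, breaks = breaks)
  })
  list(gametes = gametes, chiasmata = pos)
}

# Homolog (0/1) carried by a chromatid at genetic positions `pos`.
phase_at <- function(ch, pos) {
  ch$hom[findInterval(pos, ch$bounds, left.open = TRUE) + 1L]
}

#' Simulate a full-sib outcross population with truth annotations
#'
#' Maternal gametes are drawn one per independent meiosis (one surviving
#' megaspore); paternal gametes come from pollen tetrads -- a fresh meiosis
#' per progeny when `tetrad_pool_size` is infinite, otherwise sampled
#' across a finite tetrad pool (uniformly over tetrads with unused
#' microspores, without replacement within a tetrad). Viability selection
#' at the configured loci is applied to zygotes before genotyping noise;
#' missing data and errors perturb the observed table only, never the
#' truth.
#'
#' @param config a [sim_config]
#' @return list with `geno` (a [cp_geno]) and `truth` (class `sim_truth`):
#'   true marker table and per-parent maps, per-parent phased gamete
#'   matrices (progeny x markers, 0 = homolog A), per-progeny crossover
#'   positions, centromere truth, and paternal tetrad assignments
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  lgs <- sprintf("LG%02d", seq_len(cfg$n_lg))

  ## marker panel
  panel <- do.call(rbind, lapply(seq_len(cfg$n_lg), function(i) {
    L <- cfg$lg_lengths[i]
    m <- max(2L, round(cfg$marker_density * L))
    data.frame(lg = lgs[i],
               marker_id = sprintf("%s_M%04d", lgs[i], seq_len(m)),
               pos = sort(stats::runif(m, 0, L)),
               seg = sample(names(cfg$type_mix), m, replace = TRUE,
                            prob = cfg$type_mix),
               phase_m = stats::rbinom(m, 1, 0.5),
               phase_f = stats::rbinom(m, 1, 0.5),
               stringsAsFactors = FALSE)
  }))

  profiles <- lapply(seq_len(cfg$n_lg), function(i) {
    intensity_profile(cfg$lg_lengths[i], cfg$centromere_pos[i],
                      cfg$suppression_width, cfg$suppression_factor)
  })
  ## true genetic coordinate: crossover-intensity integral of the
  ## simulation coordinate (suppression windows compress map distance)
  gcoord <- function(p, prof) {
    vapply(p, function(q) sum(pmax(0, pmin(q, prof$to) - prof$from) *
                                prof$f), numeric(1))
  }
  panel$gpos <- NA_real_
  for (i in seq_len(cfg$n_lg)) {
    sel <- panel$lg == lgs[i]
    panel$gpos[sel] <- gcoord(panel$pos[sel], profiles[[i]])
  }

  ## paternal tetrad pool
  finite_pool <- is.finite(cfg$tetrad_pool_size)
  new_tetrad <- function() {
    per_lg <- lapply(seq_len(cfg$n_lg), function(i) {
      simulate_meiosis(cfg$lg_lengths[i], profiles[[i]],
                       cfg$paternal_rate_scale)
    })
    perms <- replicate(cfg$n_lg, sample.int(4), simplify = FALSE)
    list(meioses = per_lg, perms = perms, used = rep(FALSE, 4))
  }
  pool <- if (finite_pool) {
    lapply(seq_len(cfg$tetrad_pool_size), function(i) new_tetrad())
  }

  n <- cfg$n_progeny
  prog_ids <- sprintf("P%03d", seq_len(n))
  mat_phase <- lapply(seq_len(cfg$n_lg), function(i)
    matrix(NA_integer_, n, sum(panel$lg == lgs[i])))
  pat_phase <- lapply(seq_len(cfg$n_lg), function(i)
    matrix(NA_integer_, n, sum(panel$lg == lgs[i])))
  xo_rows <- list()
  tetrad_of <- integer(n)
  max_attempts <- 1000L * n

  gamete_phases <- function(gam, lg_i) {
    phase_at(gam, panel$pos[panel$lg == lgs[lg_i]])
  }
  survival_prob <- function(mg, pg) {
    if (is.null(cfg$sd_loci)) return(1)
    p <- 1
    for (j in seq_len(nrow(cfg$sd_loci))) {
      loc <- cfg$sd_loci[j, ]
      li <- match(as.character(loc$lg), lgs)
      gam <- if (loc$parent == "mother") mg[[li]] else pg[[li]]
      if (phase_at(gam, loc$pos) != loc$allele) p <- p * loc$s
    }
    p
  }

  accepted <- 0L
  attempts <- 0L
  next_tetrad_id <- 0L
  while (accepted < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("viability selection rejected too many zygotes; ",
           "check sd_loci survival probabilities")
    }
    ## maternal gamete: fresh meiosis per progeny, one megaspore survives
    m_gams <- lapply(seq_len(cfg$n_lg), function(i) {
      tet <- simulate_meiosis(cfg$lg_lengths[i], profiles[[i]],
                              cfg$maternal_rate_scale)
      tet$gametes[[sample.int(4, 1)]]
    })
    ## paternal gamete
    if (finite_pool) {
      open <- which(vapply(pool, function(t) any(!t$used), logical(1)))
      tid <- open[sample.int(length(open), 1)]
      slot_open <- which(!pool[[tid]]$used)
      slot <- slot_open[sample.int(length(slot_open), 1)]
    } else {
      tid <- next_tetrad_id + 1L
      tet <- new_tetrad()
      slot <- sample.int(4, 1)
    }
    tt <- if (finite_pool) pool[[tid]] else tet
    p_gams <- lapply(seq_len(cfg$n_lg), function(i) {
      tt$meioses[[i]]$gametes[[tt$perms[[i]][slot]]]
    })
    if (stats::runif(1) > survival_prob(m_gams, p_gams)) next
    accepted <- accepted + 1L
    if (finite_pool) pool[[tid]]$used[slot] <- TRUE else {
      next_tetrad_id <- tid
    }
    tetrad_of[accepted] <- tid
    for (i in seq_len(cfg$n_lg)) {
      mat_phase[[i]][accepted, ] <- gamete_phases(m_gams[[i]], i)
      pat_phase[[i]][accepted, ] <- gamete_phases(p_gams[[i]], i)
      for (par in c("mother", "father")) {
        gam <- if (par == "mother") m_gams[[i]] else p_gams[[i]]
        if (length(gam$breaks)) {
          xo_rows[[length(xo_rows) + 1L]] <-
            data.frame(progeny = prog_ids[accepted], parent = par,
                       lg = lgs[i], pos = gam$breaks,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }

  mat_phase <- do.call(cbind, mat_phase)
  pat_phase <- do.call(cbind, pat_phase)
  dimnames(mat_phase) <- list(prog_ids, panel$marker_id)
  dimnames(pat_phase) <- list(prog_ids, panel$marker_id)

  ## encode observed calls from transmitted alleles
  am <- t(mat_phase) == panel$phase_m   # allele index 1 iff homolog matches
  ap <- t(pat_phase) == panel$phase_f
  calls <- matrix(NA_character_, nrow(panel), n,
                  dimnames = list(panel$marker_id, prog_ids))
  for (i in seq_len(nrow(panel))) {
    calls[i, ] <- call_from_alleles(panel$seg[i], as.integer(am[i, ]),
                                    as.integer(ap[i, ]))
  }

  ## genotyping noise (observed table only)
  if (cfg$error_rate > 0) {
    err <- which(matrix(stats::runif(length(calls)) < cfg$error_rate,
                        nrow(calls)))
    for (j in err) {
      i <- (j - 1) %% nrow(calls) + 1
      alt <- setdiff(SEG_CALLS[[panel$seg[i]]], calls[j])
      calls[j] <- alt[sample.int(length(alt), 1)]
    }
  }
  if (cfg$missing_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- MISSING_CALL
  }

  phase_str <- paste0(ifelse(seg_informative(panel$seg, "mother"),
                             panel$phase_m, "-"),
                      ifelse(seg_informative(panel$seg, "father"),
                             panel$phase_f, "-"))
  geno <- cp_geno(data.frame(marker_id = panel$marker_id, seg = panel$seg,
                             phase = phase_str, stringsAsFactors = FALSE),
                  calls)

  truth_map <- function(parent) {
    keep <- seg_informative(panel$seg, parent)
    if (!any(keep)) {
      return(genmap(data.frame(lg = character(0), marker = character(0),
                               position = numeric(0))))
    }
    d <- panel[keep, ]
    d <- do.call(rbind, lapply(split(d, d$lg), function(x) {
      x$position <- x$gpos - min(x$gpos)
      x
    }))
    genmap(data.frame(lg = d$lg, marker = d$marker_id,
                      position = d$position, stringsAsFactors = FALSE))
  }
  mat_ph <- mat_phase
  mat_ph[, !seg_informative(panel$seg, "mother")] <- NA_integer_
  pat_ph <- pat_phase
  pat_ph[, !seg_informative(panel$seg, "father")] <- NA_integer_

  truth <- structure(list(
    config = cfg,
    markers = panel,
    maps = list(mother = truth_map("mother"), father = truth_map("father")),
    phases = list(mother = mat_ph, father = pat_ph),
    phases_all = list(mother = mat_phase, father = pat_phase),
    crossovers = if (length(xo_rows)) do.call(rbind, xo_rows) else
      data.frame(progeny = character(0), parent = character(0),
                 lg = character(0), pos = numeric(0)),
    centromeres = data.frame(
      lg = lgs, pos = cfg$centromere_pos,
      gpos = vapply(seq_len(cfg$n_lg), function(i)
        gcoord(cfg$centromere_pos[i], profiles[[i]]), numeric(1))),
    tetrads = data.frame(progeny = prog_ids, tetrad = tetrad_of)
  ), class = "sim_truth")

  list(geno = geno, truth = truth)
}

#' Write simulator truth files
#'
#' Centromeres and tetrad assignments go to JSON, crossover positions and
#' the true marker table to TSV, true phases to phased-matrix TSVs.
#'
#' @param truth a `sim_truth`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(centromeres = truth$centromeres, tetrads = truth$tetrads),
    file.path(dir, "truth.json"), dataframe = "columns", digits = NA)
  utils::write.table(truth$crossovers, file.path(dir, "crossovers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$markers, file.path(dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_map(truth$maps$mother, file.path(dir, "map_mother.tsv"))
  write_map(truth$maps$father, file.path(dir, "map_father.tsv"))
  write_phased(truth$phases$mother, file.path(dir, "phased_mother.tsv"))
  write_phased(truth$phases$father, file.path(dir, "phased_father.tsv"))
  invisible(dir)
}
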