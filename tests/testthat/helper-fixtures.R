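# Small in-code fixtures shared across test files.

# A tiny hand-coded cp_geno: 3 markers x 4 progeny.
toy_geno <- function() {
  cp_geno(
    data.frame(marker_id = c("M1", "M2", "M3"),
               seg = c("lmxll", "nnxnp", "hkxhk"),
               phase = c("0-", "-1", "00"),
               stringsAsFactors = FALSE),
    matrix(c("ll", "lm", "--", "lm",
             "nn", "np", "np", "nn",
             "hh", "hk", "kk", "hk"),
           nrow = 3, byrow = TRUE,
           dimnames = list(NULL, paste0("P", 1:4))))
}

# Random valid cp_geno for property tests.
random_geno <- function(n_mk = 20, n_prog = 15, seed = 1) {
  set.seed(seed)
  segs <- sample(c("lmxll", "nnxnp", "hkxhk", "efxeg", "abxcd"),
                 n_mk, replace = TRUE)
  calls <- t(vapply(segs, function(s) {
    v <- sample(sibmap:::SEG_CALLS[[s]], n_prog, replace = TRUE)
    v[stats::runif(n_prog) < 0.1] <- "--"
    v
  }, character(n_prog)))
  rownames(calls) <- NULL
  colnames(calls) <- sprintf("P%02d", seq_len(n_prog))
  cp_geno(data.frame(marker_id = sprintf("M%03d", seq_len(n_mk)),
                     seg = segs,
                     phase = sample(c("0-", "1-", "-0", "00", "--"),
                                    n_mk, replace = TRUE),
                     stringsAsFactors = FALSE),
          calls)
}

# Uniparental lm x ll geno built directly from a phase matrix
# (progeny x markers, 0/1) so tests control the data exactly.
geno_from_phases <- function(phases, phase_bits = rep(1L, ncol(phases))) {
  n_mk <- ncol(phases)
  calls <- t(vapply(seq_len(n_mk), function(i) {
    allele <- as.integer(phases[, i] == phase_bits[i])
    ifelse(is.na(allele), "--", c("ll", "lm")[allele + 1])
  }, character(nrow(phases))))
  colnames(calls) <- rownames(phases)
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("P%03d", seq_len(nrow(phases)))
  }
  ids <- colnames(phases)
  if (is.null(ids)) ids <- sprintf("M%03d", seq_len(n_mk))
  cp_geno(data.frame(marker_id = ids, seg = "lmxll", phase = "--",
                     stringsAsFactors = FALSE), calls)
}

# Synthetic two-point object from exact positions: r from Kosambi
# distances, LOD for a nominal n (noise-free oracle input).
tp_from_positions <- function(pos, n = 1000) {
  ids <- names(pos)
  m <- length(pos)
  r <- outer(pos, pos, function(a, b) kosambi_r(abs(a - b)))
  dimnames(r) <- list(ids, ids)
  R <- r * n
  lod <- matrix(0, m, m, dimnames = dimnames(r))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) lod[i, j] <- sibmap:::lod_score(R[i, j], n)
  }
  nmat <- matrix(n, m, m, dimnames = dimnames(r))
  list(r = r, lod = lod, n = nmat)
}

haldane_r_ <- function(d) 0.5 * (1 - exp(-2 * d / 100))
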