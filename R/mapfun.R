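#' Kosambi mapping function
#'
#' `kosambi_d()` converts a recombination fraction to map distance in
#' centimorgans, `d = 25 * log((1 + 2r) / (1 - 2r))`; `kosambi_r()` is its
#' inverse, `r = tanh(d / 50) / 2`. The two are mutual inverses to better
#' than 1e-12 over the valid domain.
#'
#' @param r recombination fraction in `[0, 0.5)`
#' @param d map distance in cM, `d >= 0`
#' @return distance in cM, or recombination fraction
#' @examples
#' kosambi_d(0.25)      # 25 * log(3) ~ 27.465
#' kosambi_r(10)        # ~ 0.0987
#' @export
kosambi_d <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) {
    stop("kosambi_d is defined for r in [0, 0.5); r >= 0.5 has infinite distance")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_d
#' @export
kosambi_r <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("map distance must be nonnegative")
  0.5 * tanh(d / 50)
}

# Haldane map function; used by the simulator's closed-form oracles
# (crossovers are Poisson along the genetic axis, so the true two-point
# recombination fraction between markers d cM apart is Haldane's).
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d / 100))
haldane_d <- function(r) -50 * log(1 - 2 * r)
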