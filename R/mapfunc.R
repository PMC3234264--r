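# Map-function algebra for intermated recombinant inbred lines (IRILs).
#
# Three coordinate systems are related here:
#   r — the meiotic recombination fraction between two loci (one meiosis);
#   R — the recombinant fraction observed between fixed inbred lines derived
#       by t generations of random intermating of an F2 followed by selfing
#       to fixation (line-level signal, inflated by the extra meioses);
#   d — genetic distance in centiMorgan on the meiotic scale (Haldane).
#
# For plain selfed RILs (t = 0) the line-level fraction is the classical
# Haldane-Waddington value R = 2r / (1 + 2r). Each round of random intermating
# decays the gametic linkage disequilibrium by a factor (1 - r), giving
#   R(r, t) = 1/2 * (1 - (1 - r)^t * (1 - 2r) / (1 + 2r)).
# The closed form is validated against a brute-force meiosis simulation in the
# test suite before anything downstream relies on it.

#' Haldane map distance from a recombination fraction
#'
#' @param r meiotic recombination fraction(s) in \[0, 0.5\]. `r = 0.5` maps to
#'   `Inf`.
#' @return Distance(s) in centiMorgan.
#' @seealso [haldane_r()] for the inverse.
#' @export
#' @examples
#' haldane_d(0.1648394) # ~ 20 cM
haldane_d <- function(r) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE)) {
    stop("recombination fraction must lie in [0, 0.5]", call. = FALSE)
  }
  -50 * log(1 - 2 * r)
}

#' Recombination fraction from a Haldane map distance
#'
#' @param d distance(s) in centiMorgan, non-negative.
#' @return Meiotic recombination fraction(s) in \[0, 0.5).
#' @export
haldane_r <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("distance must be non-negative", call. = FALSE)
  0.5 * (1 - exp(-2 * d / 100))
}

#' Line-level recombinant fraction for intermated RILs
#'
#' Forward map from the meiotic recombination fraction `r` to the recombinant
#' fraction `R` expected between inbred lines produced by `t` generations of
#' random intermating of an F2 followed by selfing to fixation. `t = 0`
#' reduces to the Haldane-Waddington formula `2r / (1 + 2r)`.
#'
#' @param r meiotic recombination fraction(s) in \[0, 0.5\].
#' @param t number of intermating generations (integer >= 0).
#' @return Expected line-level recombinant fraction(s) in \[0, 0.5\].
#' @export
#' @examples
#' iril_R(0.25, t = 0) # 1/3
iril_R <- function(r, t) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE)) {
    stop("recombination fraction must lie in [0, 0.5]", call. = FALSE)
  }
  if (length(t) != 1L || is.na(t) || t < 0 || t != round(t)) {
    stop("`t` must be a single non-negative integer", call. = FALSE)
  }
  0.5 * (1 - (1 - r)^t * (1 - 2 * r) / (1 + 2 * r))
}

#' Meiotic recombination fraction from a line-level recombinant fraction
#'
#' Inverse of [iril_R()]. For `t = 0` the closed form `r = R / (2 (1 - R))`
#' applies; for `t > 0` the strictly monotone forward map is inverted by a
#' safeguarded Newton iteration (vectorized, dimension-preserving).
#'
#' @param R line-level recombinant fraction(s) in \[0, 0.5\]. Values at or
#'   above 0.5 correspond to unlinked loci (infinite distance) and raise an
#'   error; truncate upstream if needed.
#' @param t number of intermating generations.
#' @return Meiotic recombination fraction(s), same shape as `R`.
#' @export
iril_r_inverse <- function(R, t) {
  if (any(R < 0 | R >= 0.5, na.rm = TRUE)) {
    stop("line-level recombinant fraction must lie in [0, 0.5); R >= 0.5 ",
         "implies infinite map distance", call. = FALSE)
  }
  if (t == 0) return(R / (2 * (1 - R)))
  out <- R
  r <- pmin(R / (2 * (1 - R)), 0.49)  # t = 0 inverse as starting point
  for (i in 1:50) {
    f <- 0.5 * (1 - (1 - r)^t * (1 - 2 * r) / (1 + 2 * r)) - R
    fp <- 0.5 * (t * (1 - r)^(t - 1) * (1 - 2 * r) / (1 + 2 * r) +
                   4 * (1 - r)^t / (1 + 2 * r)^2)
    r <- pmin(pmax(r - f / fp, 0), 0.5 - 1e-12)
  }
  out[] <- r
  out
}

#' Convert between r, R and cM for an intermated-RIL design
#'
#' One-stop conversion between the meiotic recombination fraction (`"r"`), the
#' line-level recombinant fraction (`"R"`) and Haldane centiMorgan (`"d"`)
#' under `t` generations of intermating. The pseudo-centiMorgan scale used for
#' uncorrected (plain-RIL) distances is obtained by passing `t = 0`.
#'
#' @param x numeric vector of input values.
#' @param t intermating generations (0 for the pseudo-cM scale).
#' @param from,to one of `"r"`, `"R"`, `"d"`.
#' @return Converted numeric vector. `R >= 0.5` converted towards distance
#'   signals an error (infinite distance) rather than returning a number.
#' @export
#' @examples
#' map_function(0.2479, t = 0, from = "R", to = "d") # ~ 20 cM
map_function <- function(x, t, from = c("r", "R", "d"), to = c("d", "r", "R")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(x)
  r <- switch(from,
    r = x,
    R = iril_r_inverse(x, t),
    d = haldane_r(x)
  )
  switch(to,
    r = r,
    R = iril_R(r, t),
    d = haldane_d(r)
  )
}
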