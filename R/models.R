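#' Minkowski combination of two channel responses
#'
#' Combines two response magnitudes with the Minkowski (p-norm) rule
#' \deqn{C = (E_1^m + E_2^m)^{1/m},}
#' the workhorse model of partial binocular summation. `m = 1` is additive
#' (city-block) combination, `m = 2` is Euclidean (quadratic) summation, and
#' as `m` grows the rule approaches a MAX operator that returns the stronger
#' channel alone.
#'
#' Computation is carried out as `hi * (1 + (lo/hi)^m)^(1/m)` on the log
#' scale, which is numerically stable for large `m` and tolerates a zero
#' weaker channel.
#'
#' @param strong,weak Response magnitudes (spikes/s or contrast-sensitivity
#'   units). `strong` must be positive; `weak` may be zero. The two are
#'   interchangeable: the function orders them internally.
#' @param m Minkowski exponent, a positive real (scalar or vector recycled
#'   against the responses).
#' @return Numeric vector of combined response magnitudes.
#' @examples
#' minkowski_combine(4, 3, m = 2)   # 5: the Euclidean 3-4-5 triple
#' minkowski_combine(1, 1, m = 2)   # sqrt(2): 41% enhancement
#' @seealso [enhancement_factor()], [solve_minkowski_exponent()]
#' @export
minkowski_combine <- function(strong, weak, m) {
  check_positive(m, "m")
  check_nonnegative(strong, "strong")
  check_nonnegative(weak, "weak")
  n <- max(length(strong), length(weak), length(m))
  strong <- rep_len(strong, n)
  weak <- rep_len(weak, n)
  m <- rep_len(m, n)
  hi <- pmax(strong, weak)
  lo <- pmin(strong, weak)
  out <- hi
  pos <- hi > 0 & lo > 0
  # hi * exp(log1p((lo/hi)^m) / m), stable even for m near 50
  out[pos] <- hi[pos] * exp(log1p((lo[pos] / hi[pos])^m[pos]) / m[pos])
  out
}

#' Binocular enhancement factor for equal monocular inputs
#'
#' When the two channels are equal, Minkowski combination predicts a
#' binocular-to-monocular ratio of exactly \eqn{2^{1/m}}: 2.0 for additive
#' combination, 1.414 (a 41\% enhancement) for quadratic summation, and 1 in
#' the MAX limit.
#'
#' @param m Minkowski exponent(s), positive.
#' @return `2^(1/m)`, the predicted binocular/monocular response ratio.
#' @examples
#' enhancement_factor(2)     # 1.414..., i.e. 41% enhancement
#' enhancement_factor(1.85)  # 1.45
#' @export
enhancement_factor <- function(m) {
  check_positive(m, "m")
  2^(1 / m)
}

#' Gated power-law amplification of a monocular response
#'
#' The gated-amplifier model: when the other channel is active (the "gate"),
#' the response to the driving channel is amplified as
#' \deqn{C = a \cdot M^n,}
#' with gain `a > 1` and a compressive exponent `n < 1` in the regimes of
#' interest. Only the magnitude of the driving (stronger) channel enters; the
#' gating channel's magnitude does not. With `a > 1`, `n < 1` the ratio
#' `C/M` falls as `M` grows -- the principle of inverse effectiveness
#' (weaker responses are proportionally more enhanced).
#'
#' @param mono Monocular (driving-channel) response magnitude, positive.
#' @param a Multiplicative gain, positive.
#' @param n Exponent, positive.
#' @return `a * mono^n`.
#' @examples
#' power_law_amplify(1, a = 2.2, n = 0.84)   # 2.2: mono = 1 isolates the gain
#' power_law_amplify(50, a = 2.14, n = 0.89)
#' @export
power_law_amplify <- function(mono, a, n) {
  check_positive(mono, "mono")
  check_positive(a, "a")
  check_positive(n, "n")
  a * mono^n
}

#' Schroedinger's magnitude-weighted binocular average
#'
#' The 1926 nonlinear weighted average proposed for suprathreshold binocular
#' brightness: each eye's response is weighted by its own share of the total,
#' \deqn{C = L\frac{L}{L+R} + R\frac{R}{L+R} = \frac{L^2 + R^2}{L + R}.}
#' The prediction always lies between the two monocular responses, so the
#' model is a candidate rule for mildly suppressive ("Between") binocular
#' neurons. The model has no free parameters.
#'
#' @param strong,weak The two monocular response magnitudes. At least one
#'   must be positive (the weights are undefined when both are zero).
#' @return A tibble with columns `predicted`, `weight_strong`, `weight_weak`
#'   and `model = "schrodinger"`. Weights sum to 1.
#' @examples
#' schrodinger_combine(2, 1)   # predicted 5/3
#' schrodinger_combine(2, 0)   # absent channel carries zero weight
#' @export
schrodinger_combine <- function(strong, weak) {
  check_nonnegative(strong, "strong")
  check_nonnegative(weak, "weak")
  n <- max(length(strong), length(weak))
  strong <- rep_len(strong, n)
  weak <- rep_len(weak, n)
  tot <- strong + weak
  if (any(tot <= 0)) {
    stop("schrodinger_combine(): both channels are zero; weights are undefined",
         call. = FALSE)
  }
  tibble::tibble(
    predicted = (strong^2 + weak^2) / tot,
    weight_strong = strong / tot,
    weight_weak = weak / tot,
    model = "schrodinger"
  )
}

#' Maximum-likelihood (inverse-variance) weighted binocular average
#'
#' Reliability-weighted cue combination: the binocular response is the
#' weighted average of the monocular responses with weights inversely
#' proportional to the channel variances,
#' \deqn{C = k_1 E_1 + k_2 E_2, \qquad
#'       k_1 = \frac{1/\sigma_1^2}{1/\sigma_1^2 + 1/\sigma_2^2},}
#' and \eqn{k_2 = 1 - k_1}. Because firing-rate variance grows with firing
#' rate, this rule tends to weight the *weaker* channel more than
#' magnitude-proportional weighting does. The model has no free parameters:
#' it is fully determined by the measured rates and variances.
#'
#' @param strong,weak Monocular response magnitudes.
#' @param var_strong,var_weak The corresponding response variances; both must
#'   be strictly positive (the weights are undefined at zero variance).
#' @return A tibble with columns `predicted`, `weight_strong`, `weight_weak`
#'   and `model = "mle"`. Weights sum to 1.
#' @examples
#' mle_combine(10, 6, 1, 1)    # equal variances: arithmetic mean, 8
#' mle_combine(10, 5, 10, 5)   # k1 = 1/3, predicted 20/3
#' @export
mle_combine <- function(strong, weak, var_strong, var_weak) {
  check_nonnegative(strong, "strong")
  check_nonnegative(weak, "weak")
  if (any(!is.finite(var_strong)) || any(!is.finite(var_weak)) ||
      any(var_strong <= 0) || any(var_weak <= 0)) {
    stop("mle_combine(): channel variances must be finite and strictly positive",
         call. = FALSE)
  }
  n <- max(length(strong), length(weak), length(var_strong), length(var_weak))
  strong <- rep_len(strong, n)
  weak <- rep_len(weak, n)
  var_strong <- rep_len(var_strong, n)
  var_weak <- rep_len(var_weak, n)
  k1 <- (1 / var_strong) / (1 / var_strong + 1 / var_weak)
  k2 <- 1 - k1
  tibble::tibble(
    predicted = k1 * strong + k2 * weak,
    weight_strong = k1,
    weight_weak = k2,
    model = "mle"
  )
}

# ---- input checks ----------------------------------------------------------

check_positive <- function(x, name) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  }
  invisible(x)
}
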