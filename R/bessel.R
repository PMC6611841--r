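# Bessel functions of the first kind for complex argument.
#
# Base R's besselJ is real-only and no installed package evaluates J0/J1 on
# the complex plane, so the two pieces the Womersley solution needs are
# implemented here:
#   * besselJ01c(): J0(z) and J1(z) by power series, accurate for |z| <= ~20
#     (beyond that the alternating series cancels catastrophically in doubles);
#   * besselJ_ratio10(): the ratio J1(z)/J0(z) by the standard backward
#     recurrence for h_nu = J_nu/J_{nu-1},  h_nu = 1 / (2 nu / z - h_{nu+1}),
#     which is stable for any |z| and is all the flow-amplitude formula needs.

#' Complex Bessel functions J0 and J1 (power series)
#'
#' Evaluates the Bessel functions of the first kind of order zero and one for
#' complex argument by their power series. Intended for moderate arguments
#' (|z| up to about 20); larger arguments are rejected because the series
#' loses all precision there.
#'
#' @param z complex (or numeric) vector, |z| <= 20.
#' @return list with complex vectors `J0` and `J1`.
#' @export
besselJ01c <- function(z) {
  z <- as.complex(z)
  if (any(Mod(z) > 20))
    stop("besselJ01c: power series is only reliable for |z| <= 20")
  q <- -(z * z) / 4            # series ratio factor
  term0 <- rep(1 + 0i, length(z))
  term1 <- z / 2
  J0 <- term0
  J1 <- term1
  for (k in 1:60) {
    term0 <- term0 * q / (k * k)
    term1 <- term1 * q / (k * (k + 1))
    J0 <- J0 + term0
    J1 <- J1 + term1
    if (all(Mod(term0) < 1e-18 * pmax(Mod(J0), 1e-300)) &&
        all(Mod(term1) < 1e-18 * pmax(Mod(J1), 1e-300)))
      break
  }
  list(J0 = J0, J1 = J1)
}

#' Ratio J1(z)/J0(z) for complex argument
#'
#' Computed by backward recurrence on h_nu = J_nu(z)/J_{nu-1}(z), started far
#' above the turning point nu ~ |z| where the recurrence is strongly damped.
#' Stable for arbitrarily large |z| (Womersley numbers up to at least 100),
#' where the direct series for J0 and J1 is unusable.
#'
#' @param z complex scalar or vector.
#' @return complex vector of the same length as `z`.
#' @export
besselJ_ratio10 <- function(z) {
  z <- as.complex(z)
  vapply(z, function(zz) {
    if (Mod(zz) == 0) return(0 + 0i)
    nmax <- ceiling(Mod(zz)) + 60L
    h <- 0 + 0i
    for (nu in seq(nmax, 1L)) h <- 1 / (2 * nu / zz - h)
    h
  }, complex(1))
}
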