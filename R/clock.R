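#' Per-year mutation rate from a per-generation rate
#'
#' @param muGen per-site per-generation rate.
#' @param generationsPerYear generations per year (use 365/generation-days
#'   for a species with a generation time in days; e.g. 365/40 for a 40-day
#'   generation, or 1/25 for a 25-year generation).
#' @return Per-site per-year rate.
#' @examples
#' perYearRate(0.41e-8, 365 / 40)   # ~3.74e-8 (silkworm)
#' perYearRate(1.2e-8, 1 / 25)      # ~0.048e-8 (human)
#' @export
perYearRate <- function(muGen, generationsPerYear) {
  if (any(muGen <= 0) || any(generationsPerYear <= 0))
    .stopf("inputs must be positive")
  muGen * generationsPerYear
}

#' Effective population size from the population mutation parameter
#'
#' Ne = theta / (4 mu), with mu on a per-year scale when divergence times in
#' years are wanted directly.
#'
#' @param theta population mutation parameter (theta = 4 Ne mu).
#' @param mu mutation rate on the chosen time scale.
#' @return Ne.
#' @examples
#' effectivePopulationSize(0.034, 3 * 0.41e-8)
#' @export
effectivePopulationSize <- function(theta, mu) {
  if (any(theta <= 0) || any(mu <= 0)) .stopf("inputs must be positive")
  theta / (4 * mu)
}

#' Divergence time from tau and Ne
#'
#' T = 4 tau Ne. When \code{Ne} was computed from a per-year mutation rate
#' (\code{neUnits = "year"}) the result is in years directly; when it came
#' from a per-generation rate (\code{neUnits = "generation"}) the
#' generation count is divided by \code{generationsPerYear}. The two
#' pathways agree algebraically: T = tau * theta / mu_year.
#'
#' @param tau divergence time in units of 4 Ne.
#' @param Ne effective population size.
#' @param generationsPerYear used only for \code{neUnits = "generation"}.
#' @param neUnits time scale of the mutation rate behind \code{Ne}.
#' @return Divergence time in years.
#' @export
divergenceTimeYears <- function(tau, Ne, generationsPerYear = 1,
                                neUnits = c("year", "generation")) {
  neUnits <- match.arg(neUnits)
  if (tau < 0 || Ne <= 0 || generationsPerYear <= 0)
    .stopf("tau must be >= 0 and Ne, generationsPerYear positive")
  t4 <- 4 * tau * Ne
  if (neUnits == "generation") t4 / generationsPerYear else t4
}

#' Molecular-clock report: per-year rate, Ne and divergence time
#'
#' Converts the per-generation rate into a per-year rate, derives Ne =
#' theta/(4 mu_year) and the divergence time T = 4 tau Ne (in years), and
#' reports T both raw and rounded to the nearest 100 years. When a
#' confidence interval on the per-generation rate is supplied, T is also
#' evaluated at both bounds; T decreases monotonically in mu, so the lower
#' rate bound yields the upper time bound.
#'
#' @param params a \linkS4class{ClockParams}.
#' @param muCi optional length-2 numeric (lower, upper) CI on the
#'   per-generation rate.
#' @return list(muYear, Ne, timeYears, timeRounded, timeCi).
#' @examples
#' clockReport(clockParams(0.034, 0.0035, 0.41e-8, 3))
#' @export
clockReport <- function(params, muCi = NULL) {
  validObject(params)
  tAt <- function(mu) {
    muYear <- perYearRate(mu, params@generationsPerYear)
    divergenceTimeYears(params@tau,
                        effectivePopulationSize(params@theta, muYear))
  }
  muYear <- perYearRate(params@muGen, params@generationsPerYear)
  Ne <- effectivePopulationSize(params@theta, muYear)
  T <- divergenceTimeYears(params@tau, Ne)
  out <- list(muYear = muYear, Ne = Ne, timeYears = T,
              timeRounded = round(T, -2), timeCi = NULL)
  if (!is.null(muCi)) {
    if (length(muCi) != 2L || any(muCi <= 0) || muCi[1] > muCi[2])
      .stopf("muCi must be a positive (lower, upper) pair")
    out$timeCi <- c(low = tAt(muCi[2]), high = tAt(muCi[1]))
  }
  out
}
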