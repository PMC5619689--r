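## Closed-form mutation-selection balance for a fully recessive deleterious
## allele, in infinite and finite constant-size populations.

.checkRates <- function(u, s) {
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u <= 0 || u >= 1)
    stop("u must be a single mutation rate in (0, 1)")
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0 || s > 1)
    stop("s must be a single selection coefficient in (0, 1]")
  invisible(NULL)
}

.checkRecessive <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || h != 0)
    stop("closed-form theory is available only for fully recessive alleles ",
         "(h = 0); use the simulator for h > 0")
  invisible(NULL)
}

.checkN <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0)
    stop("N must be a single positive diploid population size")
  invisible(NULL)
}

#' Equilibrium frequency in an infinite population
#'
#' Deterministic mutation-selection balance for a fully recessive deleterious
#' allele in an infinite population: q = sqrt(u / s).
#'
#' @param u mutation rate towards the deleterious allele, per generation.
#' @param s selection coefficient against the mutant homozygote, in (0, 1].
#' @param h dominance coefficient; must be 0 (no closed form is implemented
#'   for partial dominance).
#' @return The equilibrium allele frequency.
#' @examples
#' eqFreqInfinite(1e-8, s = 1)  # ~1e-4
#' @export
eqFreqInfinite <- function(u, s = 1, h = 0) {
  .checkRates(u, s)
  .checkRecessive(h)
  sqrt(u / s)
}

#' Mean frequency in a finite population (exact)
#'
#' Mean frequency of a fully recessive deleterious allele at
#' mutation-selection-drift equilibrium in a Wright-Fisher population of
#' constant diploid size N:
#' qbar = Gamma(2Nu + 1/2) / (sqrt(2Ns) * Gamma(2Nu)).
#' Evaluated in log-gamma space, since 2Nu spans many orders of magnitude.
#' Converges to \code{\link{eqFreqInfinite}} as 2Nu grows large and to
#' \code{\link{meanFreqLowMut}} as 2Nu approaches 0.
#'
#' @inheritParams eqFreqInfinite
#' @param N diploid effective population size.
#' @return The mean equilibrium allele frequency.
#' @examples
#' meanFreqFinite(1.5e-8, s = 1, N = 20000)  # ~5.3e-6
#' @export
meanFreqFinite <- function(u, s = 1, h = 0, N) {
  .checkRates(u, s)
  .checkRecessive(h)
  .checkN(N)
  theta <- 2 * N * u
  exp(lgamma(theta + 0.5) - lgamma(theta)) / sqrt(2 * N * s)
}

#' Variance of the frequency in a finite population
#'
#' Equilibrium variance of the frequency of a fully recessive deleterious
#' allele in a constant-size population: sigma_q^2 = u/s - qbar^2. For a
#' lethal allele (s = 1) at low population mutation rate this is approximately
#' u itself: drift makes the frequency distribution extremely dispersed
#' relative to its mean.
#'
#' @inheritParams meanFreqFinite
#' @return The variance of the equilibrium allele frequency.
#' @examples
#' varFreqFinite(1.5e-8, s = 1, N = 20000)
#' @export
varFreqFinite <- function(u, s = 1, h = 0, N) {
  qbar <- meanFreqFinite(u, s = s, h = h, N = N)
  u / s - qbar^2
}

#' Mean frequency in a finite population (low-mutation approximation)
#'
#' Low population mutation rate (2Nu << 1) approximation to
#' \code{\link{meanFreqFinite}}: qbar = u * sqrt(2 * pi * N / s). A warning is
#' issued when 2Nu > 0.1, where the approximation degrades.
#'
#' @inheritParams meanFreqFinite
#' @return The approximate mean equilibrium allele frequency.
#' @examples
#' meanFreqLowMut(1.5e-8, s = 1, N = 35651)  # ~7.1e-6
#' @export
meanFreqLowMut <- function(u, s = 1, h = 0, N) {
  .checkRates(u, s)
  .checkRecessive(h)
  .checkN(N)
  if (2 * N * u > 0.1)
    warning("2Nu = ", format(2 * N * u, digits = 3),
            " > 0.1: the low-mutation approximation may be inaccurate")
  u * sqrt(2 * pi * N / s)
}

#' Constant population size equivalent to a mean frequency
#'
#' Inverts the low-mutation-rate mean, qbar = u * sqrt(2 * pi * N / s), to
#' find the constant diploid size N = qbar^2 * s / (2 * pi * u^2) whose
#' equilibrium mean matches a given frequency (e.g. the mean of simulations
#' under a non-equilibrium demographic history).
#'
#' @param qbar mean allele frequency to match.
#' @param u mutation rate per generation.
#' @param s selection coefficient in (0, 1].
#' @return The equivalent diploid size, rounded to the nearest integer.
#' @examples
#' equivalentConstantN(7.10e-6, u = 1.5e-8, s = 1)  # ~35658
#' @export
equivalentConstantN <- function(qbar, u, s = 1) {
  .checkRates(u, s)
  if (!is.numeric(qbar) || length(qbar) != 1L || !is.finite(qbar) || qbar <= 0)
    stop("qbar must be a single positive frequency")
  if (qbar >= sqrt(u / s))
    stop("qbar >= sqrt(u/s): no finite population size attains this mean ",
         "under the low-mutation approximation")
  round(qbar^2 * s / (2 * pi * u^2))
}
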