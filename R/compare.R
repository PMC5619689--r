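## Sample-frequency generation and resampling comparison statistics between
## observed variant catalogs and simulated expectations.

#' Poisson sampling of allele counts
#'
#' Approximates the allele count of a rare variant among \code{chroms}
#' sampled chromosomes by Poisson(q * chroms), truncated at \code{chroms};
#' the corresponding sample frequency is count / chroms. This matches how
#' sample frequencies are generated from simulated population frequencies to
#' mimic an exome-aggregation sample.
#'
#' @param q population allele frequencies (vectorised).
#' @param chroms number of sampled chromosomes (2n; default 65762, i.e. an
#'   assumed mean of 32,881 sequenced individuals).
#' @return Integer allele counts.
#' @examples
#' set.seed(1)
#' mean(sampleAlleleCount(rep(7.1e-6, 1e4), 65762))  # ~0.467
#' @export
sampleAlleleCount <- function(q, chroms = 65762) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  if (length(chroms) != 1L || chroms < 2) stop("chroms must be >= 2")
  pmin(rpois(length(q), q * chroms), chroms)
}

.empiricalP <- function(r, R) min(1, 2 * (r + 1) / (R + 1))

#' Resampling test of an observed mean sample frequency against simulation
#'
#' Builds the null distribution of the mean sample frequency of K mutations
#' of one mutation class: R times, K population frequencies are drawn from
#' the simulated pool, Poisson-sampled at \code{chroms} chromosomes, and
#' averaged. The two-tailed empirical p-value is 2 (r + 1) / (R + 1), where r
#' is the number of null means greater than or equal to the observed mean
#' (ties count as extreme), capped at 1. \code{fold} is the observed mean
#' over the mean of the null means.
#'
#' @param observedFreqs the K observed sample frequencies of the class.
#' @param simPool simulated population frequencies for the class (should be
#'   much larger than K).
#' @param chroms chromosomes used for Poisson sampling (2n).
#' @param R number of resampled null means (>= 1000).
#' @param class optional class label carried through to the result.
#' @return A list with components \code{class}, \code{K},
#'   \code{observed_mean}, \code{expected_mean}, \code{fold},
#'   \code{p_two_tailed} and \code{sim_means} (the null distribution).
#' @examples
#' set.seed(1)
#' pool <- rexp(20000, 2e5)
#' obs <- sampleAlleleCount(sample(pool, 10), 65762) / 65762
#' meanFreqTest(obs, pool, R = 2000)$p_two_tailed
#' @export
meanFreqTest <- function(observedFreqs, simPool, chroms = 65762, R = 100000,
                         class = NA_character_) {
  K <- length(observedFreqs)
  if (K < 1L) stop("at least one observed frequency is required")
  if (R < 1000) stop("R must be >= 1000")
  if (length(simPool) < K)
    stop("simPool must be larger than the number of observed mutations")
  obs <- mean(observedFreqs)
  draws <- sample(simPool, K * R, replace = TRUE)
  counts <- sampleAlleleCount(draws, chroms)
  simMeans <- colMeans(matrix(counts / chroms, nrow = K, ncol = R))
  r <- sum(simMeans >= obs)
  list(class = class, K = K, observed_mean = obs,
       expected_mean = mean(simMeans),
       fold = if (mean(simMeans) > 0) obs / mean(simMeans) else NA_real_,
       p_two_tailed = .empiricalP(r, R), sim_means = simMeans)
}

#' Gene-level test of an observed combined allele frequency
#'
#' Compares the observed combined sample frequency of all known lethal
#' alleles in a gene with gene-level simulations (combined population
#' frequencies allowing compound heterozygosity, e.g. from
#' \code{\link{simulateGene}}). Each simulated frequency is Poisson-sampled
#' at \code{chroms} chromosomes; the two-tailed empirical p-value is defined
#' as in \code{\link{meanFreqTest}}. Also reports the fraction of simulations
#' in which no deleterious allele was observed in the sampled chromosomes.
#'
#' @param observedCombined observed combined sample frequency of the gene.
#' @param geneSims simulated combined population frequencies (typically 1000).
#' @param chroms chromosomes used for Poisson sampling (2n).
#' @param gene optional gene label carried through to the result.
#' @return A list with components \code{gene}, \code{observed_combined_freq},
#'   \code{p_two_tailed}, \code{zero_fraction} (fraction of simulations with
#'   sampled count 0) and \code{sim_sample_freqs}.
#' @examples
#' set.seed(1)
#' geneLevelTest(3e-5, rexp(1000, 1e5))$p_two_tailed
#' @export
geneLevelTest <- function(observedCombined, geneSims, chroms = 65762,
                          gene = NA_character_) {
  if (length(geneSims) < 1L) stop("at least one simulation is required")
  sampled <- sampleAlleleCount(geneSims, chroms) / chroms
  R <- length(sampled)
  r <- sum(sampled >= observedCombined)
  list(gene = gene, observed_combined_freq = observedCombined,
       p_two_tailed = .empiricalP(r, R),
       zero_fraction = mean(sampled == 0),
       sim_sample_freqs = sampled)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values: the statistic -2 sum(log p) is compared to
#' a chi-square distribution with 2k degrees of freedom.
#'
#' @param pValues p-values in (0, 1].
#' @return A list with components \code{statistic}, \code{df} and \code{p}.
#' @examples
#' fisherCombined(rep(0.5, 27))
#' @export
fisherCombined <- function(pValues) {
  if (length(pValues) < 1L) stop("at least one p-value is required")
  if (any(pValues <= 0 | pValues > 1))
    stop("p-values must lie in (0, 1]; cap empirical p-values upstream")
  stat <- -2 * sum(log(pValues))
  df <- 2 * length(pValues)
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE))
}
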