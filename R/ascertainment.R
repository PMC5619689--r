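## Ascertainment bias in disease-mutation discovery under inbreeding.

#' Genotype probabilities under inbreeding
#'
#' Probabilities of the three genotypes for a bi-allelic site at population
#' frequency q in an individual with inbreeding coefficient F:
#' P(AA) = F(1-q) + (1-F)(1-q)^2, P(Aa) = (1-F) 2q(1-q),
#' P(aa) = F q + (1-F) q^2. F = 0 recovers Hardy-Weinberg; inbreeding
#' inflates homozygote classes at the expense of heterozygotes.
#'
#' @param q population allele frequency in [0, 1] (vectorised).
#' @param F inbreeding coefficient in [0, 1].
#' @return A list with components \code{AA}, \code{Aa}, \code{aa}; the three
#'   sum to 1.
#' @examples
#' genotypeProbs(0.5, F = 0)    # Hardy-Weinberg: 0.25 / 0.5 / 0.25
#' genotypeProbs(7.1e-6, F = 1/16)$aa
#' @export
genotypeProbs <- function(q, F = 0) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  if (length(F) != 1L || F < 0 || F > 1) stop("F must lie in [0, 1]")
  list(AA = F * (1 - q) + (1 - F) * (1 - q)^2,
       Aa = (1 - F) * 2 * q * (1 - q),
       aa = F * q + (1 - F) * q^2)
}

#' Probability that a recessive mutation is ascertained
#'
#' A recessive lethal mutation can only be identified if at least one
#' affected homozygote is observed. Surveying n unrelated individuals with
#' inbreeding coefficient F, the probability of ascertainment is
#' P_asc = 1 - (1 - P(aa))^n = 1 - [(1 - q)(1 + q - F q)]^n,
#' strictly increasing in q, F and n. Evaluated in log space for numerical
#' stability at tiny q and large n.
#'
#' @param q population allele frequency in [0, 1] (vectorised).
#' @param F inbreeding coefficient of the surveyed population, in [0, 1].
#' @param n number of surveyed individuals (>= 1).
#' @return Ascertainment probabilities in [0, 1].
#' @examples
#' pAscertain(7.10e-6, F = 1/16, n = 1e4)
#' @export
pAscertain <- function(q, F, n) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  if (length(F) != 1L || F < 0 || F > 1) stop("F must lie in [0, 1]")
  if (length(n) != 1L || n < 1) stop("n must be >= 1")
  paa <- F * q + (1 - F) * q^2
  -expm1(n * log1p(-paa))
}

#' Simulated ascertainment experiment over a pool of population frequencies
#'
#' Given present-day population frequencies of disease mutations of one
#' mutation class (typically drawn from the demographic simulator), marks
#' each mutation as ascertained and compares the mean sample frequency of the
#' ascertained subset with that of all mutations. By default ascertainment is
#' a single Bernoulli draw with probability \code{\link{pAscertain}} (exactly
#' the distribution of "at least one homozygote among nA genotypes", but much
#' faster); \code{method = "genotypes"} samples the nA individual genotypes
#' explicitly, for validation. Sample frequencies for all mutations are then
#' generated by Poisson sampling at \code{sampleChromosomes} chromosomes, as
#' in \code{\link{sampleAlleleCount}}.
#'
#' @param freqs population allele frequencies, one per mutation.
#' @param cfg an \code{\link{AscertainmentConfig}}.
#' @param method \code{"bernoulli"} (default) or \code{"genotypes"}.
#' @return A list with components \code{P_asc} (fraction of mutations
#'   ascertained), \code{q_u} (mean sample frequency of all mutations),
#'   \code{q_a} (mean sample frequency of the ascertained subset), \code{fold}
#'   (q_a / q_u; \code{NA} if no mutation was ascertained or q_u = 0),
#'   \code{n_ascertained}, and \code{ascertained} (logical per mutation).
#' @examples
#' set.seed(1)
#' pool <- rexp(5000, rate = 2e5)  # toy frequency pool
#' ascertainmentExperiment(pool, AscertainmentConfig(nA = 1e4, FA = 1/16))
#' @export
ascertainmentExperiment <- function(freqs, cfg,
                                    method = c("bernoulli", "genotypes")) {
  stopifnot(is(cfg, "AscertainmentConfig"))
  method <- match.arg(method)
  if (length(freqs) < 1L) stop("freqs must contain at least one frequency")
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  asc <- if (method == "bernoulli") {
    runif(length(freqs)) < pAscertain(freqs, cfg@FA, cfg@nA)
  } else {
    paa <- genotypeProbs(freqs, cfg@FA)$aa
    rbinom(length(freqs), size = as.integer(cfg@nA), prob = paa) > 0L
  }
  sampled <- sampleAlleleCount(freqs, cfg@sampleChromosomes) /
    cfg@sampleChromosomes
  qU <- mean(sampled)
  qA <- if (any(asc)) mean(sampled[asc]) else NA_real_
  list(P_asc = mean(asc), q_u = qU, q_a = qA,
       fold = if (!is.na(qA) && qU > 0) qA / qU else NA_real_,
       n_ascertained = sum(asc), ascertained = asc)
}

#' Ascertainment summary across mutation classes and study designs
#'
#' Convenience wrapper reproducing the shape of a class-by-design summary
#' table: for each mutation-class frequency pool and each (nA, FA) design,
#' runs \code{\link{ascertainmentExperiment}} and reports the ascertainment
#' probability and the fold inflation of the ascertained mean.
#'
#' @param pools named list of frequency pools (one per mutation class).
#' @param designs data.frame with columns \code{nA} and \code{FA}.
#' @param sampleChromosomes chromosomes for sample-frequency estimation.
#' @return A data.frame with columns \code{class}, \code{nA}, \code{FA},
#'   \code{P_asc}, \code{q_u}, \code{q_a}, \code{fold}.
#' @export
ascertainmentTable <- function(pools, designs, sampleChromosomes = 65762) {
  stopifnot(is.list(pools), !is.null(names(pools)),
            all(c("nA", "FA") %in% names(designs)))
  rows <- list()
  for (cl in names(pools)) {
    for (i in seq_len(nrow(designs))) {
      cfg <- AscertainmentConfig(designs$nA[i], designs$FA[i],
                                 sampleChromosomes)
      ex <- ascertainmentExperiment(pools[[cl]], cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, nA = designs$nA[i], FA = designs$FA[i],
        P_asc = ex$P_asc, q_u = ex$q_u, q_a = ex$q_a, fold = ex$fold)
    }
  }
  do.call(rbind, rows)
}
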