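## User-facing simulation API over the Wright-Fisher engine.

#' Draw site mutation rates from the lognormal heterogeneity model
#'
#' Within a mutation class, per-site rates vary around the class mean u:
#' log10(M) ~ Normal(log10(u) - (sigma^2 / 2) * ln(10), sigma^2), an offset
#' chosen so that E[M] = u. With sigma = 0 the draw degenerates to u.
#'
#' @param u mean mutation rate (scalar).
#' @param sigma spread in log10 units (default 0.57).
#' @param n number of draws.
#' @return A vector of n positive rates with expectation u.
#' @examples
#' set.seed(1)
#' mean(drawMutationRate(1.5e-8, 0.57, 1e5))  # ~1.5e-8
#' @export
drawMutationRate <- function(u, sigma = 0.57, n = 1) {
  if (u <= 0) stop("u must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(rep(u, n))
  mu <- log10(u) - (sigma^2 / 2) * log(10)
  10^rnorm(n, mean = mu, sd = sigma)
}

#' One Wright-Fisher generation for a vector of sites
#'
#' Applies, in order: recurrent one-way mutation towards the deleterious
#' allele (q_m = q + (1 - q) M, no back mutation), viability selection on
#' random-union genotypes with fitnesses 1, 1 - h s, 1 - s, and binomial
#' drift in a population of \code{NNext} diploids. The corner where all
#' surviving genotypes are lethal homozygotes (q_m = 1, s = 1) resolves to
#' loss of the allele. Vectorised over \code{q} (and \code{M}).
#'
#' @param q current allele frequencies in [0, 1].
#' @param NNext diploid size of the next generation.
#' @param M mutation rate(s) per gamete per generation.
#' @param sel a \code{\link{SelectionParams}} object (its
#'   \code{treatmentGenerations} is ignored here).
#' @return Sampled next-generation frequencies.
#' @examples
#' set.seed(1)
#' wfStep(rep(1e-4, 5), NNext = 1e4, M = 1.5e-8, sel = SelectionParams())
#' @export
wfStep <- function(q, NNext, M, sel = SelectionParams()) {
  stopifnot(is(sel, "SelectionParams"))
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  if (length(NNext) != 1L || NNext < 1) stop("NNext must be a single size >= 1")
  NNext <- round(NNext)
  qm <- q + (1 - q) * M
  qs <- .selMap(qm, sel@s, sel@h)
  rbinom(length(qs), 2 * NNext, qs) / (2 * NNext)
}

#' Deterministic two-way migration between Africa and Europe
#'
#' Mixes the post-selection allele frequencies of the two populations once
#' per generation, before drift: each population retains fraction (1 - m) of
#' its own gene pool and receives fraction m from the other.
#'
#' @param qAFR,qEUR allele frequencies (vectorised).
#' @param mAFEU fraction of the African gene pool replaced by European
#'   migrants, in [0, 0.5] (0.5 is the full-mixing limit).
#' @param mEUAF fraction of the European gene pool replaced by African
#'   migrants, in [0, 0.5].
#' @return A list with elements \code{qAFR} and \code{qEUR}.
#' @examples
#' migrateFreqs(0.2, 0, 0.5, 0.5)  # full mixing: both 0.1
#' @export
migrateFreqs <- function(qAFR, qEUR, mAFEU, mEUAF) {
  if (any(mAFEU < 0 | mAFEU > 0.5 | mEUAF < 0 | mEUAF > 0.5))
    stop("migration rates must lie in [0, 0.5]")
  list(qAFR = (1 - mAFEU) * qAFR + mAFEU * qEUR,
       qEUR = (1 - mEUAF) * qEUR + mEUAF * qAFR)
}

#' Per-generation selection-coefficient schedule
#'
#' Expands a \code{\link{SelectionParams}} into the selection coefficient
#' applied at each simulated generation: \code{s} throughout, forced to 0 for
#' the final \code{treatmentGenerations} generations (fully effective modern
#' treatment).
#'
#' @param sel a \code{SelectionParams}.
#' @param totalGens total number of simulated generations.
#' @return Numeric vector of length \code{totalGens}.
#' @examples
#' table(selectionSchedule(SelectionParams(treatmentGenerations = 3), 10))
#' @export
selectionSchedule <- function(sel, totalGens) {
  stopifnot(is(sel, "SelectionParams"))
  totalGens <- as.integer(totalGens)
  treat <- as.integer(sel@treatmentGenerations)
  if (treat > totalGens)
    stop("treatmentGenerations exceeds totalGens")
  s <- rep(sel@s, totalGens)
  if (treat > 0) s[(totalGens - treat + 1L):totalGens] <- 0
  s
}

.resultFrame <- function(M, res) {
  data.frame(replicate = seq_along(M), drawn_rate = M,
             q_AFR = res$qA, q_EUR = res$qE,
             segregating = res$segregating)
}

#' Simulate the frequency of a deleterious allele at a single site
#'
#' Forward Wright-Fisher simulation of one bi-allelic site under recurrent
#' one-way mutation, (partially) recessive lethal selection, migration and
#' drift, through the demographic model: a burn-in era at constant size
#' (starting from the wild-type allele fixed, long enough to reach
#' mutation-selection-drift equilibrium) followed by the modeled history.
#' Replicates are independent; in \code{"lognormal"} rate mode each replicate
#' draws its own mutation rate via \code{\link{drawMutationRate}}.
#'
#' @param model a \code{\link{DemographicModel-class}}.
#' @param config a \code{\link{SiteConfig}}.
#' @param selection a \code{\link{SelectionParams}}.
#' @return A data.frame with one row per replicate and columns
#'   \code{replicate}, \code{drawn_rate}, \code{q_AFR}, \code{q_EUR}
#'   (present-day population frequencies; identical for single-population
#'   models) and \code{segregating} (\code{q_EUR > 0}).
#' @examples
#' res <- simulateSite(constantModel(500), SiteConfig(1e-5, replicates = 200,
#'                                                    seed = 1))
#' mean(res$q_EUR)
#' @export
simulateSite <- function(model, config, selection = SelectionParams()) {
  stopifnot(is(model, "DemographicModel"), is(config, "SiteConfig"),
            is(selection, "SelectionParams"))
  validObject(config)
  validObject(selection)
  if (!is.null(config@seed)) set.seed(config@seed)
  R <- as.integer(config@replicates)
  M <- if (config@rateMode == "lognormal")
    drawMutationRate(config@u, config@sigma, R)
  else rep(config@u, R)
  .resultFrame(M, .wfEngine(model, M, selection))
}

#' Simulate the combined frequency of all lethal alleles in a gene
#'
#' Gene-level model of compound heterozygosity: every pair of distinct lethal
#' alleles in the gene is assumed as unfit as a homozygote, so the combined
#' frequency of all lethal alleles behaves as a single bi-allelic site whose
#' mutation rate is the gene-wide total U. Per replicate, a rate u_j is drawn
#' for each contributing site from the lognormal heterogeneity model and
#' U = sum(u_j) drives the single-locus machinery.
#'
#' @param model a \code{\link{DemographicModel-class}}.
#' @param config a \code{\link{GeneConfig}}.
#' @param selection a \code{\link{SelectionParams}}.
#' @return As \code{\link{simulateSite}}; \code{drawn_rate} is the drawn
#'   gene-wide total rate U and the frequencies are combined frequencies of
#'   all lethal alleles in the gene.
#' @examples
#' cfg <- GeneConfig(rep(3.76e-9, 10), replicates = 100, seed = 1)
#' res <- simulateGene(constantModel(500), cfg)
#' @export
simulateGene <- function(model, config, selection = SelectionParams()) {
  stopifnot(is(model, "DemographicModel"), is(config, "GeneConfig"),
            is(selection, "SelectionParams"))
  validObject(config)
  validObject(selection)
  if (!is.null(config@seed)) set.seed(config@seed)
  R <- as.integer(config@replicates)
  J <- length(config@siteRates)
  U <- if (config@sigma > 0) {
    draws <- vapply(config@siteRates,
                    function(u) drawMutationRate(u, config@sigma, R),
                    numeric(R))
    if (R == 1L) sum(draws) else rowSums(draws)
  } else rep(sum(config@siteRates), R)
  .resultFrame(U, .wfEngine(model, U, selection))
}

#' Write or read simulation results as TSV with a JSON metadata sidecar
#'
#' The TSV holds one row per replicate (columns as returned by
#' \code{\link{simulateSite}}); \code{<path>.json} records the run metadata
#' (configuration, seed, package version) so results are reproducible.
#'
#' @param results data.frame of replicate results.
#' @param path output TSV path.
#' @param meta named list of run metadata to record in the sidecar.
#' @return \code{writeReplicateResults} returns \code{path} invisibly;
#'   \code{readReplicateResults} returns the data.frame with the sidecar
#'   metadata (if present) in \code{attr(, "meta")}.
#' @export
writeReplicateResults <- function(results, path, meta = list()) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  meta$package_version <- as.character(utils::packageVersion("reclethal"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeReplicateResults
#' @export
readReplicateResults <- function(path) {
  res <- read.delim(path, na.strings = ".")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(res, "meta") <- jsonlite::fromJSON(sidecar)
  res
}
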