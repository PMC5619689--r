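## S4 classes for the demographic model, simulation configuration and
## ascertainment model.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' DemographicModel: piecewise population-size history for one or two
#' populations
#'
#' Time is measured in discrete generations before present; epochs are
#' half-open intervals \code{[start, end)} with \code{start > end >= 0}
#' (\code{start} is the older boundary). Population sizes are diploid;
#' exponential epochs are parameterised by their boundary sizes
#' (\code{N_start} at the older boundary, \code{N_end} approached at the
#' younger boundary) and the per-generation size is rounded to the nearest
#' integer. A burn-in era of \code{burninGenerations} generations at constant
#' size \code{burninNe} precedes the oldest epoch. For two-population models
#' the \code{AFR} lineage carries the ancestral population until
#' \code{splitGen}, when the \code{EUR} lineage is founded with the ancestral
#' allele frequency; symmetric (possibly time-varying) migration applies after
#' the split.
#'
#' @slot epochs data.frame with columns \code{population} (\code{"AFR"} or
#'   \code{"EUR"}), \code{start}, \code{end} (generations before present),
#'   \code{size_model} (\code{"constant"} or \code{"exponential"}),
#'   \code{N_start}, \code{N_end} (diploid sizes).
#' @slot splitGen generation before present of the AFR/EUR split
#'   (\code{NA} for single-population models).
#' @slot migration data.frame with columns \code{start}, \code{end},
#'   \code{m_AFR_EUR}, \code{m_EUR_AFR}: per-generation migration rates active
#'   on \code{[start, end)}.
#' @slot burninNe diploid size of the burn-in era.
#' @slot burninGenerations length of the burn-in era (default
#'   \code{10 * burninNe}).
#' @slot name label for the model.
#'
#' @seealso \code{\link{rescaledTennessen}}, \code{\link{constantModel}},
#'   \code{\link{sizeAt}}
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(
    epochs = "data.frame",
    splitGen = "numeric",
    migration = "data.frame",
    burninNe = "numeric",
    burninGenerations = "numeric",
    name = "character"
  )
)

.checkTiling <- function(ep, pop, oldest) {
  ep <- ep[ep$population == pop, , drop = FALSE]
  if (nrow(ep) == 0L) return(sprintf("no epochs for population %s", pop))
  ep <- ep[order(-ep$start), , drop = FALSE]
  if (abs(ep$start[1L] - oldest) > 1e-9)
    return(sprintf("oldest %s epoch must start at %g generations", pop, oldest))
  if (abs(ep$end[nrow(ep)]) > 1e-9)
    return(sprintf("youngest %s epoch must end at 0", pop))
  if (nrow(ep) > 1L &&
      any(abs(ep$end[-nrow(ep)] - ep$start[-1L]) > 1e-9))
    return(sprintf("%s epochs must tile time without gaps or overlaps", pop))
  if (any(ep$start <= ep$end))
    return("each epoch must have start > end")
  NULL
}

setValidity("DemographicModel", function(object) {
  ep <- object@epochs
  msgs <- character()
  need <- c("population", "start", "end", "size_model", "N_start", "N_end")
  if (!all(need %in% names(ep)))
    return(paste("epochs must have columns:", paste(need, collapse = ", ")))
  if (!all(ep$population %in% c("AFR", "EUR")))
    msgs <- c(msgs, "epoch populations must be 'AFR' or 'EUR'")
  if (!all(ep$size_model %in% c("constant", "exponential")))
    msgs <- c(msgs, "size_model must be 'constant' or 'exponential'")
  if (any(round(ep$N_start) < 1) || any(round(ep$N_end) < 1))
    msgs <- c(msgs, "population sizes must round to >= 1")
  if (length(object@burninNe) != 1L || object@burninNe < 1)
    msgs <- c(msgs, "burninNe must be a single value >= 1")
  if (length(object@burninGenerations) != 1L || object@burninGenerations < 1)
    msgs <- c(msgs, "burninGenerations must be >= 1")
  hist <- max(ep$start)
  m <- .checkTiling(ep, "AFR", hist)
  if (!is.null(m)) msgs <- c(msgs, m)
  if (!is.na(object@splitGen)) {
    if (object@splitGen <= 0 || object@splitGen > hist)
      msgs <- c(msgs, "splitGen must lie within the modeled time span")
    m <- .checkTiling(ep, "EUR", object@splitGen)
    if (!is.null(m)) msgs <- c(msgs, m)
  } else if (any(ep$population == "EUR")) {
    msgs <- c(msgs, "EUR epochs given but splitGen is NA")
  }
  mig <- object@migration
  if (nrow(mig) > 0L) {
    if (any(mig$m_AFR_EUR < 0 | mig$m_AFR_EUR >= 0.5 |
            mig$m_EUR_AFR < 0 | mig$m_EUR_AFR >= 0.5))
      msgs <- c(msgs, "migration rates must lie in [0, 0.5)")
    if (is.na(object@splitGen) && any(mig$m_AFR_EUR > 0 | mig$m_EUR_AFR > 0))
      msgs <- c(msgs, "migration requires a two-population model")
    if (!is.na(object@splitGen) && any(mig$start > object@splitGen + 1e-9))
      msgs <- c(msgs, "migration epochs must postdate the split")
  }
  if (length(msgs)) msgs else TRUE
})

#' SelectionParams: genotype fitness scheme for a deleterious allele
#'
#' Relative fitnesses are 1, 1 - h*s and 1 - s for the wild-type homozygote,
#' heterozygote and mutant homozygote. \code{treatmentGenerations} forces
#' \code{s} to 0 in the final generations of a simulation, mimicking fully
#' effective modern treatment of the disease.
#'
#' @slot s selection coefficient against the mutant homozygote, in [0, 1]
#'   (1 = lethal).
#' @slot h dominance coefficient (0 = fully recessive).
#' @slot treatmentGenerations number of final generations with s forced to 0.
#' @exportClass SelectionParams
setClass("SelectionParams",
  representation(s = "numeric", h = "numeric",
                 treatmentGenerations = "numeric"))

setValidity("SelectionParams", function(object) {
  msgs <- character()
  if (length(object@s) != 1L || object@s < 0 || object@s > 1)
    msgs <- c(msgs, "s must be a single value in [0, 1]")
  if (length(object@h) != 1L || object@h < 0)
    msgs <- c(msgs, "h must be a single value >= 0")
  if (length(object@treatmentGenerations) != 1L ||
      object@treatmentGenerations < 0)
    msgs <- c(msgs, "treatmentGenerations must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @param s selection coefficient against the mutant homozygote.
#' @param h dominance coefficient.
#' @param treatmentGenerations final generations with selection switched off.
#' @rdname SelectionParams-class
#' @export
SelectionParams <- function(s = 1, h = 0, treatmentGenerations = 0) {
  new("SelectionParams", s = as.numeric(s), h = as.numeric(h),
      treatmentGenerations = as.numeric(treatmentGenerations))
}

#' SiteConfig: single-site simulation configuration
#'
#' @slot u mean per-generation mutation rate towards the deleterious allele.
#' @slot sigma lognormal spread of the mutation rate across simulations, in
#'   log10 units (0.57 by default; 0 disables heterogeneity).
#' @slot rateMode \code{"lognormal"} (draw a rate per replicate with mean u)
#'   or \code{"fixed"}.
#' @slot replicates number of independent replicates.
#' @slot seed optional RNG seed recorded with the run.
#' @exportClass SiteConfig
setClass("SiteConfig",
  representation(u = "numeric", sigma = "numeric", rateMode = "character",
                 replicates = "numeric", seed = "numericOrNULL"))

setValidity("SiteConfig", function(object) {
  msgs <- character()
  if (length(object@u) != 1L || object@u <= 0 || object@u >= 1)
    msgs <- c(msgs, "u must be a single rate in (0, 1)")
  if (length(object@sigma) != 1L || object@sigma < 0)
    msgs <- c(msgs, "sigma must be >= 0")
  if (!object@rateMode %in% c("lognormal", "fixed"))
    msgs <- c(msgs, "rateMode must be 'lognormal' or 'fixed'")
  if (length(object@replicates) != 1L || object@replicates < 1)
    msgs <- c(msgs, "replicates must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @param u mean mutation rate per generation.
#' @param sigma lognormal spread in log10 units.
#' @param rateMode \code{"lognormal"} or \code{"fixed"}.
#' @param replicates number of replicates.
#' @param seed optional RNG seed.
#' @rdname SiteConfig-class
#' @export
SiteConfig <- function(u, sigma = 0.57, rateMode = c("lognormal", "fixed"),
                       replicates = 1000, seed = NULL) {
  rateMode <- match.arg(rateMode)
  new("SiteConfig", u = as.numeric(u), sigma = as.numeric(sigma),
      rateMode = rateMode, replicates = as.numeric(replicates),
      seed = if (is.null(seed)) NULL else as.numeric(seed))
}

#' GeneConfig: gene-level simulation configuration
#'
#' A gene is modeled as a pooled class of lethal alleles: per replicate a rate
#' u_j is drawn for each contributing site and the gene-wide rate U = sum(u_j)
#' drives a single bi-allelic simulation, assuming compound heterozygotes are
#' as unfit as homozygotes.
#'
#' @slot siteRates mean mutation rates of the sites known to cause the severe
#'   disease form.
#' @slot sigma lognormal spread per site, in log10 units.
#' @slot replicates number of replicates.
#' @slot seed optional RNG seed.
#' @exportClass GeneConfig
setClass("GeneConfig",
  representation(siteRates = "numeric", sigma = "numeric",
                 replicates = "numeric", seed = "numericOrNULL"))

setValidity("GeneConfig", function(object) {
  msgs <- character()
  if (length(object@siteRates) < 1L)
    msgs <- c(msgs, "at least one site rate is required")
  if (any(object@siteRates <= 0))
    msgs <- c(msgs, "all site rates must be > 0")
  if (length(object@sigma) != 1L || object@sigma < 0)
    msgs <- c(msgs, "sigma must be >= 0")
  if (length(object@replicates) != 1L || object@replicates < 1)
    msgs <- c(msgs, "replicates must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @param siteRates per-site mean mutation rates.
#' @param sigma lognormal spread in log10 units.
#' @param replicates number of replicates.
#' @param seed optional RNG seed.
#' @rdname GeneConfig-class
#' @export
GeneConfig <- function(siteRates, sigma = 0.57, replicates = 1000,
                       seed = NULL) {
  if (length(siteRates) == 0L)
    stop("siteRates must contain at least one rate")
  new("GeneConfig", siteRates = as.numeric(siteRates),
      sigma = as.numeric(sigma), replicates = as.numeric(replicates),
      seed = if (is.null(seed)) NULL else as.numeric(seed))
}

#' AscertainmentConfig: parameters of a putative disease-discovery study
#'
#' Discovery of a recessive lethal mutation requires observing at least one
#' affected homozygote in a survey of \code{nA} individuals drawn from a
#' population with average inbreeding coefficient \code{FA}; sample
#' frequencies are afterwards estimated on \code{sampleChromosomes}
#' chromosomes.
#'
#' @slot nA sample size of the discovery study.
#' @slot FA average inbreeding coefficient in the discovery population
#'   (e.g. 1/16 for offspring of first-cousin marriages).
#' @slot sampleChromosomes number of chromosomes (2n) used for post-hoc
#'   sample-frequency estimation (default 65762).
#' @exportClass AscertainmentConfig
setClass("AscertainmentConfig",
  representation(nA = "numeric", FA = "numeric",
                 sampleChromosomes = "numeric"))

setValidity("AscertainmentConfig", function(object) {
  msgs <- character()
  if (length(object@nA) != 1L || object@nA < 1)
    msgs <- c(msgs, "nA must be >= 1")
  if (length(object@FA) != 1L || object@FA < 0 || object@FA > 1)
    msgs <- c(msgs, "FA must lie in [0, 1]")
  if (length(object@sampleChromosomes) != 1L || object@sampleChromosomes < 2)
    msgs <- c(msgs, "sampleChromosomes must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' @param nA discovery-study sample size.
#' @param FA average inbreeding coefficient.
#' @param sampleChromosomes chromosomes for sample-frequency estimation.
#' @rdname AscertainmentConfig-class
#' @export
AscertainmentConfig <- function(nA, FA, sampleChromosomes = 65762) {
  new("AscertainmentConfig", nA = as.numeric(nA), FA = as.numeric(FA),
      sampleChromosomes = as.numeric(sampleChromosomes))
}

## ---- accessors ----

#' @describeIn DemographicModel-class epoch table.
#' @param object,x a \code{DemographicModel}.
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))

#' @rdname DemographicModel-class
#' @export
setMethod("epochs", "DemographicModel", function(object) object@epochs)

#' @describeIn DemographicModel-class generation of the AFR/EUR split
#'   (NA for single-population models).
#' @export
setGeneric("splitGen", function(object) standardGeneric("splitGen"))

#' @rdname DemographicModel-class
#' @export
setMethod("splitGen", "DemographicModel", function(object) object@splitGen)

#' @describeIn DemographicModel-class burn-in diploid size.
#' @export
setGeneric("burninNe", function(object) standardGeneric("burninNe"))

#' @rdname DemographicModel-class
#' @export
setMethod("burninNe", "DemographicModel", function(object) object@burninNe)

#' @describeIn DemographicModel-class number of burn-in generations.
#' @export
setGeneric("burninGenerations",
           function(object) standardGeneric("burninGenerations"))

#' @rdname DemographicModel-class
#' @export
setMethod("burninGenerations", "DemographicModel",
          function(object) object@burninGenerations)

#' @describeIn DemographicModel-class migration-rate table.
#' @export
setGeneric("migrationRates",
           function(object) standardGeneric("migrationRates"))

#' @rdname DemographicModel-class
#' @export
setMethod("migrationRates", "DemographicModel",
          function(object) object@migration)

#' @describeIn DemographicModel-class span of the post-burn-in history in
#'   generations (age of the oldest epoch boundary).
#' @export
setGeneric("historyGenerations",
           function(object) standardGeneric("historyGenerations"))

#' @rdname DemographicModel-class
#' @export
setMethod("historyGenerations", "DemographicModel",
          function(object) max(object@epochs$start))

#' @describeIn DemographicModel-class total simulated generations
#'   (burn-in + history).
#' @export
setGeneric("totalGenerations",
           function(object) standardGeneric("totalGenerations"))

#' @rdname DemographicModel-class
#' @export
setMethod("totalGenerations", "DemographicModel",
          function(object) object@burninGenerations + max(object@epochs$start))

## ---- show methods ----

setMethod("show", "DemographicModel", function(object) {
  twoPop <- !is.na(object@splitGen)
  cat("DemographicModel:", object@name, "\n")
  cat(sprintf("  burn-in: %d generations at Ne = %s\n",
              as.integer(object@burninGenerations),
              format(object@burninNe, big.mark = ",")))
  cat(sprintf("  history: %s generations, %d epochs (%s)\n",
              format(max(object@epochs$start), big.mark = ","),
              nrow(object@epochs),
              if (twoPop) sprintf("AFR/EUR split %s generations ago",
                                  format(object@splitGen, big.mark = ","))
              else "single population"))
  for (i in seq_len(nrow(object@epochs))) {
    e <- object@epochs[i, ]
    cat(sprintf("    %s [%s, %s): %s\n", e$population,
                format(e$start, big.mark = ","),
                format(e$end, big.mark = ","),
                if (e$size_model == "constant")
                  sprintf("N = %s", format(round(e$N_start), big.mark = ","))
                else sprintf("N %s -> %s",
                             format(round(e$N_start), big.mark = ","),
                             format(round(e$N_end), big.mark = ","))))
  }
  if (nrow(object@migration) > 0L) {
    for (i in seq_len(nrow(object@migration))) {
      m <- object@migration[i, ]
      cat(sprintf("    migration [%s, %s): AFR<-EUR %.3g, EUR<-AFR %.3g\n",
                  format(m$start, big.mark = ","),
                  format(m$end, big.mark = ","),
                  m$m_AFR_EUR, m$m_EUR_AFR))
    }
  }
  invisible(object)
})

setMethod("show", "SelectionParams", function(object) {
  cat(sprintf(
    "SelectionParams: s = %g, h = %g%s\n", object@s, object@h,
    if (object@treatmentGenerations > 0)
      sprintf(", s = 0 in final %d generations",
              as.integer(object@treatmentGenerations)) else ""))
  invisible(object)
})

setMethod("show", "SiteConfig", function(object) {
  cat(sprintf("SiteConfig: u = %g (%s, sigma = %g), %d replicates%s\n",
              object@u, object@rateMode, object@sigma,
              as.integer(object@replicates),
              if (!is.null(object@seed))
                sprintf(", seed = %d", as.integer(object@seed)) else ""))
  invisible(object)
})

setMethod("show", "GeneConfig", function(object) {
  cat(sprintf(
    "GeneConfig: %d sites, U = %g (sigma = %g), %d replicates%s\n",
    length(object@siteRates), sum(object@siteRates), object@sigma,
    as.integer(object@replicates),
    if (!is.null(object@seed))
      sprintf(", seed = %d", as.integer(object@seed)) else ""))
  invisible(object)
})

setMethod("show", "AscertainmentConfig", function(object) {
  cat(sprintf(
    "AscertainmentConfig: nA = %s, FA = %.4g, 2n = %s chromosomes\n",
    format(object@nA, big.mark = ","), object@FA,
    format(object@sampleChromosomes, big.mark = ",")))
  invisible(object)
})
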