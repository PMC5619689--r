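## Mutation-type classification from sequence context, synthetic variant
## catalogs mimicking an exome-aggregation disease-mutation table, and the
## site-level QC filters.

.BASES <- c("A", "C", "G", "T")
.CLASSES <- c("CpGti", "CpGtv", "nonCpGti", "nonCpGtv")

#' Per-generation mutation rates of the four mutation classes
#'
#' Mean rates (per bp per generation) for transitions at methylated CpG
#' sites, CpG transversions, and non-CpG transitions and transversions, as
#' estimated from large human pedigree studies. CpG transitions are roughly
#' 17-fold more mutable than the average of the other three classes.
#'
#' @return Named numeric vector of rates for CpGti, CpGtv, nonCpGti,
#'   nonCpGtv.
#' @examples
#' mutationClassRates()
#' @export
mutationClassRates <- function() {
  c(CpGti = 1.12e-7, CpGtv = 9.59e-9, nonCpGti = 6.18e-9, nonCpGtv = 3.76e-9)
}

#' Classify a point mutation from its immediate sequence context
#'
#' A site is in CpG context if the reference base is a C immediately followed
#' by a G, or (on the reverse strand) a G immediately preceded by a C. A
#' change is a transition if it swaps within a purine or pyrimidine pair
#' ({A,G} or {C,T}), otherwise a transversion. The class is the cross of the
#' two: CpGti, CpGtv, nonCpGti or nonCpGtv. Classification is
#' strand-symmetric. Vectorised.
#'
#' @param prev,ref,alt,nxt single bases (A/C/G/T); \code{prev} and \code{nxt}
#'   flank the reference base, \code{ref != alt}.
#' @return Character vector of class names.
#' @examples
#' classifyMutationType("A", "C", "T", "G")  # CpGti
#' classifyMutationType("C", "G", "A", "T")  # CpGti on the reverse strand
#' @export
classifyMutationType <- function(prev, ref, alt, nxt) {
  n <- max(length(prev), length(ref), length(alt), length(nxt))
  prev <- rep_len(toupper(prev), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  nxt <- rep_len(toupper(nxt), n)
  if (!all(c(prev, ref, alt, nxt) %in% .BASES))
    stop("bases must be one of A, C, G, T")
  if (any(ref == alt)) stop("ref and alt must differ")
  cpg <- (ref == "C" & nxt == "G") | (ref == "G" & prev == "C")
  ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
        (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  paste0(ifelse(cpg, "CpG", "nonCpG"), ifelse(ti, "ti", "tv"))
}

## draw a random (prev, ref, alt, nxt) context consistent with a class
.contextForClass <- function(class, n) {
  prev <- sample(.BASES, n, replace = TRUE)
  nxt <- sample(.BASES, n, replace = TRUE)
  ref <- character(n)
  alt <- character(n)
  fwd <- runif(n) < 0.5  # which strand carries the C of the CpG / the change
  if (class %in% c("CpGti", "CpGtv")) {
    ref[fwd] <- "C"
    nxt[fwd] <- "G"
    ref[!fwd] <- "G"
    prev[!fwd] <- "C"
    if (class == "CpGti") {
      alt[fwd] <- "T"
      alt[!fwd] <- "A"
    } else {
      alt[fwd] <- sample(c("A", "G"), sum(fwd), replace = TRUE)
      alt[!fwd] <- sample(c("C", "T"), sum(!fwd), replace = TRUE)
    }
  } else {
    ## avoid CpG context: use A/T reference bases
    ref[fwd] <- "A"
    ref[!fwd] <- "T"
    if (class == "nonCpGti") {
      alt[fwd] <- "G"
      alt[!fwd] <- "C"
    } else {
      alt[fwd] <- sample(c("C", "T"), sum(fwd), replace = TRUE)
      alt[!fwd] <- sample(c("A", "G"), sum(!fwd), replace = TRUE)
    }
  }
  data.frame(prev_base = prev, ref = ref, alt = alt, next_base = nxt,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic disease-variant catalog
#'
#' Emulates the statistical structure of a curated table of mutations causing
#' recessive lethal diseases, with sample frequencies from an exome-style
#' aggregation sample: per mutation class, K population frequencies are drawn
#' from a simulated pool (\code{world = "null"}), or from the subset that a
#' discovery study with inbreeding would have ascertained
#' (\code{world = "ascertained"}, inflating frequencies most for the least
#' mutable classes); allele counts are Poisson-sampled at \code{AN}
#' chromosomes. Configurable fractions of records are injected with a
#' homozygote observation, with low coverage, or (for CpGti) with a
#' CpG-island flag, to exercise \code{\link{applySiteFilters}}. Sequence
#' contexts are generated to be consistent with each class label. The
#' catalog is synthetic: it reproduces class composition and frequency
#' structure, not real variants.
#'
#' @param freqPools named list of population-frequency pools, one per class
#'   in \code{classCounts}.
#' @param classCounts named integer vector: number of catalog records per
#'   mutation class. The default composition (417 records, 29.3% CpGti)
#'   mirrors a hand-curated recessive-lethal set.
#' @param world \code{"null"} (frequencies drawn directly from the pool) or
#'   \code{"ascertained"}.
#' @param ascCfg an \code{\link{AscertainmentConfig}}; required for the
#'   ascertained world.
#' @param AN number of genotyped chromosomes per record.
#' @param homFraction fraction of records with at least one homozygote.
#' @param lowCovFraction fraction of records with coverage fraction below
#'   0.8.
#' @param cgiCount number of CpGti records flagged as lying in a CpG island.
#' @param genes number of gene labels to spread records over.
#' @return A data.frame with columns \code{variant_id}, \code{gene},
#'   \code{prev_base}, \code{ref}, \code{alt}, \code{next_base},
#'   \code{cgi_flag}, \code{class}, \code{pop_freq}, \code{AC}, \code{AN},
#'   \code{n_hom}, \code{frac_cov15}.
#' @examples
#' set.seed(1)
#' pools <- list(CpGti = rexp(5000, 2e4), CpGtv = rexp(5000, 2e5),
#'               nonCpGti = rexp(5000, 3e5), nonCpGtv = rexp(5000, 4e5))
#' cat417 <- generateCatalog(pools)
#' table(cat417$class)
#' @export
generateCatalog <- function(freqPools,
                            classCounts = c(CpGti = 122, CpGtv = 32,
                                            nonCpGti = 104, nonCpGtv = 159),
                            world = c("null", "ascertained"), ascCfg = NULL,
                            AN = 65762, homFraction = 3 / 417,
                            lowCovFraction = 29 / 417, cgiCount = 12,
                            genes = 32) {
  world <- match.arg(world)
  if (!all(names(classCounts) %in% .CLASSES))
    stop("classCounts names must be among: ", paste(.CLASSES, collapse = ", "))
  if (!all(names(classCounts) %in% names(freqPools)))
    stop("freqPools must provide a pool for every class in classCounts")
  if (world == "ascertained" && !is(ascCfg, "AscertainmentConfig"))
    stop("the ascertained world requires an AscertainmentConfig")
  recs <- list()
  for (cl in names(classCounts)) {
    K <- as.integer(classCounts[[cl]])
    if (K < 1L) next
    pool <- freqPools[[cl]]
    if (length(pool) == 0L) stop("empty frequency pool for class ", cl)
    if (world == "ascertained") {
      keep <- runif(length(pool)) < pAscertain(pool, ascCfg@FA, ascCfg@nA)
      if (!any(keep))
        stop("no mutations of class ", cl,
             " were ascertained; enlarge the pool or the study")
      pool <- pool[keep]
    }
    q <- sample(pool, K, replace = TRUE)
    ctx <- .contextForClass(cl, K)
    recs[[cl]] <- data.frame(
      gene = sprintf("GENE%02d", sample.int(genes, K, replace = TRUE)),
      ctx,
      cgi_flag = FALSE,
      class = cl,
      pop_freq = q,
      AC = sampleAlleleCount(q, AN),
      AN = AN,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, recs)
  n <- nrow(tab)
  tab$variant_id <- sprintf("var%04d", seq_len(n))
  rownames(tab) <- NULL
  ## QC-artifact injection
  tab$n_hom <- 0L
  nHom <- round(homFraction * n)
  if (nHom > 0) tab$n_hom[sample.int(n, nHom)] <- 1L
  tab$frac_cov15 <- runif(n, 0.85, 1)
  nLow <- round(lowCovFraction * n)
  if (nLow > 0)
    tab$frac_cov15[sample.int(n, nLow)] <- runif(nLow, 0.3, 0.79)
  iCpGti <- which(tab$class == "CpGti")
  if (cgiCount > 0 && length(iCpGti))
    tab$cgi_flag[sample(iCpGti, min(cgiCount, length(iCpGti)))] <- TRUE
  tab[, c("variant_id", "gene", "prev_base", "ref", "alt", "next_base",
          "cgi_flag", "class", "pop_freq", "AC", "AN", "n_hom",
          "frac_cov15")]
}

#' Apply site-level quality and methylation filters to a variant catalog
#'
#' Removes, in order: records homozygous in at least one sampled individual
#' (likely misclassified pathogenicity or incomplete penetrance), records
#' where fewer than \code{minCovFrac} of individuals were sequenced to at
#' least 15x, and CpG-transition records inside CpG islands (which tend to be
#' unmethylated and so lack the elevated CpGti rate).
#'
#' @param records a catalog data.frame as from \code{\link{generateCatalog}}
#'   (or read with \code{\link{readVariantCatalog}}).
#' @param minCovFrac minimum fraction of individuals covered >= 15x.
#' @param excludeHomozygous drop records with \code{n_hom > 0}.
#' @param excludeCgiCpGti drop CpGti records with \code{cgi_flag}.
#' @return A list with \code{records} (the surviving rows) and \code{report}
#'   (named counts removed per rule: homozygous, coverage, cgi). The report
#'   counts always sum to the number of rows removed.
#' @examples
#' set.seed(1)
#' pools <- list(CpGti = rexp(1000, 2e4), CpGtv = rexp(1000, 2e5),
#'               nonCpGti = rexp(1000, 3e5), nonCpGtv = rexp(1000, 4e5))
#' flt <- applySiteFilters(generateCatalog(pools))
#' flt$report
#' @export
applySiteFilters <- function(records, minCovFrac = 0.8,
                             excludeHomozygous = TRUE,
                             excludeCgiCpGti = TRUE) {
  need <- c("class", "cgi_flag", "n_hom", "frac_cov15")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  report <- c(homozygous = 0L, coverage = 0L, cgi = 0L)
  if (excludeHomozygous) {
    drop <- records$n_hom > 0
    report[["homozygous"]] <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  drop <- records$frac_cov15 < minCovFrac
  report[["coverage"]] <- sum(drop)
  records <- records[!drop, , drop = FALSE]
  if (excludeCgiCpGti) {
    drop <- records$class == "CpGti" & records$cgi_flag
    report[["cgi"]] <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  list(records = records, report = report)
}

#' Read or write a variant catalog as TSV
#'
#' Tab-separated with a header line and \code{"."} for missing values.
#'
#' @param records catalog data.frame.
#' @param path file path.
#' @return \code{readVariantCatalog} returns the catalog data.frame;
#'   \code{writeVariantCatalog} returns \code{path} invisibly.
#' @export
writeVariantCatalog <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' @rdname writeVariantCatalog
#' @export
readVariantCatalog <- function(path) {
  tab <- read.delim(path, na.strings = ".", stringsAsFactors = FALSE)
  need <- c("variant_id", "class", "AC", "AN")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("malformed variant catalog ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  bad <- which(tab$AC > tab$AN | tab$AC < 0)
  if (length(bad))
    stop("malformed variant catalog ", path, ": AC outside [0, AN] at line ",
         bad[1L] + 1L, " (variant ", tab$variant_id[bad[1L]], ")")
  tab
}
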