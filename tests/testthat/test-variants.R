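revcomp <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

test_that("mutation types are classified from sequence context", {
  expect_equal(classifyMutationType("A", "C", "T", "G"), "CpGti")
  expect_equal(classifyMutationType("C", "G", "A", "T"), "CpGti")
  expect_equal(classifyMutationType("A", "T", "C", "A"), "nonCpGti")
  expect_equal(classifyMutationType("A", "C", "A", "G"), "CpGtv")
  expect_equal(classifyMutationType("T", "A", "T", "C"), "nonCpGtv")
  ## a C not followed by G is not CpG context
  expect_equal(classifyMutationType("A", "C", "T", "A"), "nonCpGti")
  expect_error(classifyMutationType("A", "N", "T", "G"), "bases")
  expect_error(classifyMutationType("A", "C", "C", "G"), "differ")
})

test_that("classification is strand-symmetric over every context", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(prev = bases, ref = bases, alt = bases, nxt = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  fwd <- classifyMutationType(grid$prev, grid$ref, grid$alt, grid$nxt)
  rev <- classifyMutationType(revcomp(grid$nxt), revcomp(grid$ref),
                              revcomp(grid$alt), revcomp(grid$prev))
  expect_equal(fwd, rev)
  ## transitions and transversions partition every change
  expect_equal(sort(unique(fwd)),
               c("CpGti", "CpGtv", "nonCpGti", "nonCpGtv"))
})

test_that("CpG transitions are ~17-fold more mutable than other classes", {
  r <- mutationClassRates()
  expect_equal(unname(r["CpGti"] / mean(r[c("CpGtv", "nonCpGti",
                                            "nonCpGtv")])),
               17, tolerance = 0.02)
})

.toyPools <- function(n = 3000) {
  list(CpGti = rexp(n, 2e4), CpGtv = rexp(n, 2e5),
       nonCpGti = rexp(n, 3e5), nonCpGtv = rexp(n, 4e5))
}

test_that("synthetic catalogs have the configured composition and structure", {
  set.seed(10)
  cat417 <- generateCatalog(.toyPools())
  expect_equal(nrow(cat417), 417)
  tabs <- table(cat417$class)
  expect_equal(unname(tabs["CpGti"]), 122L)  # 29.3% of 417
  expect_equal(sum(cat417$cgi_flag), 12)
  expect_true(all(cat417$cgi_flag[cat417$class != "CpGti"] == FALSE))
  ## every generated context is consistent with its class label
  expect_equal(classifyMutationType(cat417$prev_base, cat417$ref,
                                    cat417$alt, cat417$next_base),
               cat417$class)
  expect_true(all(cat417$AC >= 0 & cat417$AC <= cat417$AN))
  ## null world: allele counts reflect the pool means
  pools <- .toyPools(20000)
  set.seed(11)
  big <- generateCatalog(pools, classCounts = c(CpGti = 2000), AN = 65762)
  expect_equal(mean(big$AC), mean(pools$CpGti) * 65762, tolerance = 0.1)
})

test_that("the ascertained world inflates frequencies, most for rare classes", {
  set.seed(12)
  pools <- .toyPools(20000)
  cfg <- AscertainmentConfig(nA = 1e4, FA = 1 / 16)
  K <- c(CpGti = 500, CpGtv = 500, nonCpGti = 500, nonCpGtv = 500)
  nullCat <- generateCatalog(pools, classCounts = K)
  ascCat <- generateCatalog(pools, classCounts = K, world = "ascertained",
                            ascCfg = cfg)
  fold <- sapply(names(pools), function(cl)
    mean(ascCat$pop_freq[ascCat$class == cl]) /
      mean(nullCat$pop_freq[nullCat$class == cl]))
  expect_true(all(fold > 1))
  ## rarer classes (lower-frequency pools) are inflated more
  expect_gt(fold[["nonCpGtv"]], fold[["CpGti"]])
  expect_error(generateCatalog(pools, world = "ascertained"),
               "AscertainmentConfig")
})

test_that("site filters remove homozygous, low-coverage and CGI records", {
  toy <- data.frame(
    variant_id = sprintf("v%02d", 1:10),
    class = c(rep("CpGti", 4), rep("nonCpGtv", 6)),
    cgi_flag = FALSE,
    n_hom = c(1, 1, rep(0, 8)),
    frac_cov15 = c(0.9, 0.9, 0.5, 0.5, 0.5, rep(0.95, 5)))
  flt <- applySiteFilters(toy)
  expect_equal(nrow(flt$records), 5)
  expect_equal(flt$report, c(homozygous = 2L, coverage = 3L, cgi = 0L))
  ## a fully clean catalog passes unchanged
  clean <- toy; clean$n_hom <- 0L; clean$frac_cov15 <- 1
  fltClean <- applySiteFilters(clean)
  expect_equal(fltClean$records, clean)
  expect_equal(sum(fltClean$report), 0L)
  ## CGI filter hits only flagged CpG transitions
  cgi <- clean; cgi$cgi_flag[1:2] <- TRUE; cgi$cgi_flag[5] <- TRUE
  fltCgi <- applySiteFilters(cgi)
  expect_equal(unname(fltCgi$report["cgi"]), 2L)
  expect_false(any(fltCgi$records$class == "CpGti" &
                   fltCgi$records$cgi_flag))
})

test_that("filter report counts always sum to the rows removed", {
  set.seed(13)
  for (i in 1:5) {
    cat417 <- generateCatalog(.toyPools())
    flt <- applySiteFilters(cat417)
    expect_equal(sum(flt$report), nrow(cat417) - nrow(flt$records))
  }
  ## with 3 homozygous, 29 low-coverage and no CGI flags injected, a
  ## 417-record catalog leaves 385 (disjoint artifact sets under this seed)
  set.seed(21)
  cat417 <- generateCatalog(.toyPools(), cgiCount = 0)
  flt <- applySiteFilters(cat417)
  expect_equal(unname(flt$report["homozygous"]), 3L)
  expect_equal(unname(flt$report["coverage"]), 29L)
  expect_equal(nrow(flt$records), 385)
})

test_that("variant catalogs round-trip through TSV and are validated", {
  set.seed(14)
  cat417 <- generateCatalog(.toyPools())
  p <- tempfile(fileext = ".tsv")
  writeVariantCatalog(cat417, p)
  back <- readVariantCatalog(p)
  expect_equal(back$AC, cat417$AC)
  expect_equal(back$class, cat417$class)
  ## malformed files produce diagnostics naming the problem
  bad <- cat417; bad$AC[5] <- bad$AN[5] + 10
  writeVariantCatalog(bad, p)
  expect_error(readVariantCatalog(p), "line 6")
  nocol <- cat417[, setdiff(names(cat417), "AC")]
  writeVariantCatalog(nocol, p)
  expect_error(readVariantCatalog(p), "missing column")
})
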