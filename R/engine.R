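## Internal forward Wright-Fisher engine.
##
## Exact per-generation scheme for every replicate: mutation (deterministic
## gamete-frequency increment), viability selection on random-union
## genotypes, deterministic migration after the split, then binomial drift at
## the next generation's size. Replicates currently fixed for the wild type
## are not advanced generation by generation: within a stretch of constant
## (sizes, migration, selection) their waiting time to the next non-zero
## binomial draw is geometric, so it is sampled directly (calendar queue) and
## the conditional positive count is drawn from the truncated binomial via
## the inverse CDF. Waiting times are re-drawn at every stretch boundary,
## which is exact by memorylessness. The result is distributionally identical
## to the dense update but runs the ~155k-generation default history in
## seconds instead of minutes.

## post-selection gamete frequency; w_AA = 1, w_Aa = 1-hs, w_aa = 1-s;
## the all-lethal-homozygote corner (den = 0) resolves to loss.
.selMap <- function(qm, s, h) {
  whet <- 1 - h * s
  whom <- 1 - s
  num <- qm * (1 - qm) * whet + qm^2 * whom
  den <- (1 - qm)^2 + 2 * qm * (1 - qm) * whet + qm^2 * whom
  ifelse(den <= 0, 0, num / den)
}

## positive-truncated binomial draws; size scalar, prob vector
.rtruncbinom <- function(size, prob) {
  n <- length(prob)
  if (n == 0L) return(integer(0))
  p0 <- exp(size * log1p(-prob))
  u <- runif(n, p0, 1)
  pmax(1, qbinom(u, size, prob))
}

## waiting times (>= 1 generation) until the first success with per-element
## probability p; Inf where p == 0
.rwait <- function(p) {
  gn <- rep(Inf, length(p))
  pos <- p > 0
  if (any(pos)) gn[pos] <- 1 + rgeom(sum(pos), p[pos])
  gn
}

## Run the engine. model: DemographicModel; M: per-replicate mutation rate;
## selection: SelectionParams. Returns list(qA, qE, segregating).
.wfEngine <- function(model, M, selection) {
  R <- length(M)
  Tt <- as.integer(totalGenerations(model))
  treat <- as.integer(selection@treatmentGenerations)
  if (treat > Tt)
    stop("treatmentGenerations exceeds the total simulated generations")
  sFull <- selection@s
  h <- selection@h
  hist <- historyGenerations(model)
  hasSplit <- !is.na(model@splitGen)

  ## per-generation trajectories; generation g leaves the population at
  ## tvec[g] generations before present
  tvec <- Tt - seq_len(Tt)
  NAtraj <- sizeAt(model, "AFR", tvec)
  if (hasSplit) {
    NEtraj <- rep(NA_integer_, Tt)
    post <- tvec < model@splitGen
    NEtraj[post] <- sizeAt(model, "EUR", tvec[post])
    gSplit <- which(post)[1L]
    mig <- migrationAt(model, tvec)
    mAE <- mig$m_AFR_EUR
    mEA <- mig$m_EUR_AFR
  } else {
    NEtraj <- rep(NA_integer_, Tt)
    gSplit <- NA_integer_
    mAE <- mEA <- numeric(Tt)
  }
  sTraj <- rep(sFull, Tt)
  if (treat > 0) sTraj[(Tt - treat + 1L):Tt] <- 0

  ## stretch boundaries: any change in sizes, migration, selection or the
  ## existence of the European population
  keyChanged <- c(TRUE,
                  diff(NAtraj) != 0 |
                  diff(is.na(NEtraj)) != 0 |
                  (diff(ifelse(is.na(NEtraj), 0L, NEtraj)) != 0) |
                  diff(mAE) != 0 | diff(mEA) != 0 | diff(sTraj) != 0)
  sStarts <- which(keyChanged)
  sEnds <- c(sStarts[-1L] - 1L, Tt)

  ## zero-state post-selection frequency, cached per selection coefficient
  qs0Cache <- list()
  qs0For <- function(sg) {
    key <- format(sg, digits = 17)
    if (is.null(qs0Cache[[key]]))
      qs0Cache[[key]] <<- .selMap(M, sg, h)
    qs0Cache[[key]]
  }

  cA <- integer(R)
  cE <- integer(R)
  activeMask <- logical(R)
  act <- integer(0)
  NAprev <- NAtraj[1L]
  NEprev <- NA_integer_

  for (si in seq_along(sStarts)) {
    gs <- sStarts[si]
    ge <- sEnds[si]
    L <- ge - gs + 1L
    NAg <- NAtraj[gs]
    NEg <- NEtraj[gs]
    postsplit <- !is.na(NEg)
    sg <- sTraj[gs]
    mAEg <- mAE[gs]
    mEAg <- mEA[gs]
    qs0 <- qs0For(sg)

    ## seeding probabilities for zero replicates
    lA <- 2 * NAg * log1p(-qs0)
    if (postsplit) {
      lE <- 2 * NEg * log1p(-qs0)
      pA0 <- -expm1(lA)
      pE0 <- -expm1(lE)
      pU0 <- -expm1(lA + lE)
    } else {
      pA0 <- pE0 <- NULL
      pU0 <- -expm1(lA)
    }

    calendar <- L >= 30L
    if (calendar) {
      bucket <- vector("list", L)
      zeros <- which(!activeMask)
      if (length(zeros)) {
        gn <- .rwait(pU0[zeros])
        keep <- gn <= L
        if (any(keep)) {
          sp <- split(zeros[keep], gn[keep])
          for (nm in names(sp))
            bucket[[as.integer(nm)]] <- sp[[nm]]
        }
      }
    }

    for (l in seq_len(L)) {
      g <- gs + l - 1L

      ## advance segregating replicates
      if (length(act)) {
        Ma <- M[act]
        qA <- cA[act] / (2 * NAprev)
        qAm <- qA + (1 - qA) * Ma
        qAs <- .selMap(qAm, sg, h)
        if (postsplit) {
          qE <- if (g == gSplit) qA else cE[act] / (2 * NEprev)
          qEm <- qE + (1 - qE) * Ma
          qEs <- .selMap(qEm, sg, h)
          if (mAEg > 0 || mEAg > 0) {
            qAp <- (1 - mAEg) * qAs + mAEg * qEs
            qEp <- (1 - mEAg) * qEs + mEAg * qAs
          } else {
            qAp <- qAs
            qEp <- qEs
          }
          kA <- rbinom(length(act), 2 * NAg, qAp)
          kE <- rbinom(length(act), 2 * NEg, qEp)
          cE[act] <- kE
          dead <- kA == 0 & kE == 0
        } else {
          kA <- rbinom(length(act), 2 * NAg, qAs)
          dead <- kA == 0
        }
        cA[act] <- kA
        if (any(dead)) {
          dIds <- act[dead]
          activeMask[dIds] <- FALSE
          act <- act[!dead]
          if (calendar) {
            gn <- l + .rwait(pU0[dIds])
            keep <- gn <= L
            if (any(keep)) {
              sp <- split(dIds[keep], gn[keep])
              for (nm in names(sp)) {
                i <- as.integer(nm)
                bucket[[i]] <- c(bucket[[i]], sp[[nm]])
              }
            }
          }
        }
      }

      ## first non-zero draws of currently fixed replicates
      sIds <- if (calendar) bucket[[l]] else {
        zeros <- which(!activeMask)
        if (length(zeros)) zeros[runif(length(zeros)) < pU0[zeros]]
        else integer(0)
      }
      if (length(sIds)) {
        if (postsplit) {
          pA <- pA0[sIds]
          pE <- pE0[sIds]
          pU <- pU0[sIds]
          u1 <- runif(length(sIds)) * pU
          both <- u1 < pA * pE
          aOnly <- !both & u1 < pA * pE + pA * (1 - pE)
          drawA <- both | aOnly
          drawE <- both | !(both | aOnly)
          kA <- integer(length(sIds))
          kE <- integer(length(sIds))
          if (any(drawA))
            kA[drawA] <- .rtruncbinom(2 * NAg, qs0[sIds[drawA]])
          if (any(drawE))
            kE[drawE] <- .rtruncbinom(2 * NEg, qs0[sIds[drawE]])
          cA[sIds] <- kA
          cE[sIds] <- kE
        } else {
          cA[sIds] <- .rtruncbinom(2 * NAg, qs0[sIds])
        }
        activeMask[sIds] <- TRUE
        act <- c(act, sIds)
      }

      NAprev <- NAg
      if (postsplit) NEprev <- NEg
    }
  }

  qA <- cA / (2 * NAprev)
  qE <- if (hasSplit) cE / (2 * NEprev) else qA
  list(qA = qA, qE = qE, segregating = qE > 0)
}
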