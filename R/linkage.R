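## Nonparametric allele-sharing linkage scan. Per marker, the observed
## statistic S is the sum over affected pairs of the estimated number of
## alleles shared identical-by-descent through the parents the pair has in
## common. IBD is deduced from parental genotypes where the transmission is
## unambiguous and set to its conditional expectation (1/2 per shared
## parent) otherwise. The null distribution is a Monte-Carlo gene drop:
## founder alleles are dropped through the pedigree at the marker's founder
## allele frequency and the same estimator is applied to the simulated
## genotypes. This is a singlepoint S_pairs scan, not exact multipoint
## likelihood; region calling only consumes the sign of the standardized
## score.

## P(parent transmitted its reference-state copy | genotypes).
## parent hom or missing -> 1/2; parent het: child hom determines the
## transmitted allele; child het is resolved by the other parent when that
## parent is homozygous, otherwise expectation 1/2.
transProbRef <- function(pg, cg, og) {
  eq <- function(x, v) !is.na(x) & x == v
  p <- rep(0.5, length(pg))
  het <- eq(pg, 1L)
  p[het & eq(cg, 0L)] <- 1
  p[het & eq(cg, 2L)] <- 0
  hz <- het & eq(cg, 1L)
  p[hz & eq(og, 0L)] <- 0
  p[hz & eq(og, 2L)] <- 1
  p
}

## S and definedness for a set of affecteds, vectorized across "units"
## (markers or gene-drop replicates). geno: function(id) -> integer vector
## of genotypes across units (NA vector if ungenotyped). sires/dams: named
## parent ids per affected (NA allowed). A unit is "defined" only when at
## least one pair has both transmissions through a shared parent fully
## resolved (both posteriors 0 or 1): pairs with an ambiguous member
## contribute exactly their conditional expectation 1/2 and carry no
## evidence for or against sharing.
sharingS <- function(affecteds, sires, dams, geno, nUnits) {
  k <- length(affecteds)
  pS <- pD <- vector("list", k)
  for (i in seq_len(k)) {
    cg <- geno(affecteds[i])
    sg <- geno(sires[i]); dg <- geno(dams[i])
    pS[[i]] <- transProbRef(sg, cg, dg)
    pD[[i]] <- transProbRef(dg, cg, sg)
  }
  S <- rep(0, nUnits)
  defined <- rep(FALSE, nUnits)
  res <- function(p) p != 0.5
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!is.na(sires[i]) && !is.na(sires[j]) && sires[i] == sires[j]) {
      S <- S + pS[[i]] * pS[[j]] + (1 - pS[[i]]) * (1 - pS[[j]])
      defined <- defined | (res(pS[[i]]) & res(pS[[j]]))
    }
    if (!is.na(dams[i]) && !is.na(dams[j]) && dams[i] == dams[j]) {
      S <- S + pD[[i]] * pD[[j]] + (1 - pD[[i]]) * (1 - pD[[j]])
      defined <- defined | (res(pD[[i]]) & res(pD[[j]]))
    }
  }
  list(S = S, defined = defined)
}

parentVectors <- function(ped, affecteds) {
  tb <- pedTable(ped)
  row <- tb[match(affecteds, tb$id), ]
  list(sires = row$sire, dams = row$dam)
}

#' Pairwise allele-sharing statistic at one marker
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param ped a \linkS4class{Pedigree}.
#' @param marker marker id or column index.
#' @param affecteds ids of >= 2 affected individuals, each with at least one
#'   genotyped parent.
#' @return list with elements \code{S} (the statistic: summed IBD-shared
#'   alleles over affected pairs) and \code{defined} (FALSE when the marker
#'   is uninformative for every pair, in which case S is the constant
#'   prior expectation).
#' @export
pairwiseSharingStatistic <- function(gm, ped, marker, affecteds) {
  stopifnot(length(affecteds) >= 2)
  cl <- calls(gm)
  pv <- parentVectors(ped, affecteds)
  geno <- function(id) {
    if (!is.na(id) && id %in% rownames(cl)) cl[id, marker] else NA_integer_
  }
  r <- sharingS(affecteds, pv$sires, pv$dams, geno, 1L)
  list(S = r$S, defined = r$defined)
}

## topological order of a restricted pedigree (parents before children)
topoOrder <- function(tb) {
  placed <- character(); ids <- tb$id
  while (length(ids)) {
    ready <- vapply(seq_along(ids), function(i) {
      r <- tb[tb$id == ids[i], ]
      (is.na(r$sire) || r$sire %in% placed || !(r$sire %in% tb$id)) &&
      (is.na(r$dam)  || r$dam  %in% placed || !(r$dam  %in% tb$id))
    }, TRUE)
    if (!any(ready)) stop("pedigree cycle detected")
    placed <- c(placed, ids[ready]); ids <- ids[!ready]
  }
  placed
}

ancestorsClosure <- function(ped, ids) {
  tb <- pedTable(ped)
  out <- character(); stack <- ids
  while (length(stack)) {
    out <- union(out, stack)
    par <- tb[match(stack, tb$id), c("sire", "dam")]
    stack <- setdiff(unlist(par, use.names = FALSE), c(out, NA))
  }
  out
}

#' Monte-Carlo gene-drop null for the sharing statistic
#'
#' Drops founder alleles (Bernoulli with the supplied allele frequency)
#' through the pedigree restricted to the affecteds, their parents and all
#' their ancestors, applies the same sharing estimator to each replicate,
#' and returns the empirical mean and standard deviation of S over the
#' replicates in which the statistic is defined.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param affecteds affected ids (>= 2).
#' @param freq alternate-allele frequency (scalar in [0, 1]).
#' @param nReps number of gene drops (default 1000; < 100 warns).
#' @param seed integer seed (mandatory: the null must be reproducible).
#' @return list: nullMean, nullSd, fracDefined, nReps.
#' @export
geneDropNull <- function(ped, affecteds, freq, nReps = 1000, seed) {
  if (missing(seed)) stop("a seed is mandatory for the gene-drop null")
  if (nReps < 100) warning("nReps < 100: null standard deviation will be unstable")
  set.seed(seed)
  pv <- parentVectors(ped, affecteds)
  keep <- ancestorsClosure(ped, unique(c(affecteds,
                                         stats::na.omit(c(pv$sires, pv$dams)))))
  tb <- pedTable(ped)
  tb <- tb[tb$id %in% keep, ]
  ord <- topoOrder(tb)
  a1 <- a2 <- matrix(0L, nrow = length(ord), ncol = nReps,
                     dimnames = list(ord, NULL))
  for (id in ord) {
    r <- tb[tb$id == id, ]
    for (slot in 1:2) {
      par <- if (slot == 1) r$sire else r$dam
      m <- if (slot == 1) a1 else a2
      if (is.na(par) || !(par %in% ord)) {
        m[id, ] <- stats::rbinom(nReps, 1L, freq)
      } else {
        pick <- stats::runif(nReps) < 0.5
        m[id, ] <- ifelse(pick, a1[par, ], a2[par, ])
      }
      if (slot == 1) a1 <- m else a2 <- m
    }
  }
  g <- a1 + a2
  geno <- function(id) if (!is.na(id) && id %in% ord) g[id, ] else
    rep(NA_integer_, nReps)
  r <- sharingS(affecteds, pv$sires, pv$dams, geno, nReps)
  def <- r$defined
  if (sum(def) < 2)
    return(list(nullMean = NA_real_, nullSd = NA_real_,
                fracDefined = mean(def), nReps = nReps))
  list(nullMean = mean(r$S[def]), nullSd = stats::sd(r$S[def]),
       fracDefined = mean(def), nReps = nReps)
}

#' Genome-wide sharing scan with region merging
#'
#' Computes per-marker S, the gene-drop null (cached per distinct founder
#' allele frequency), the standardized score Z and the signed
#' LOD = sign(Z) * Z^2 / (2 ln 10), then merges maximal runs of consecutive
#' markers with Z > 0 into candidate linked regions, tolerating up to
#' \code{gapMarkers} consecutive undefined (uninformative) markers inside a
#' run; a defined marker with Z <= 0 always breaks a run.
#'
#' @param gm QC'd \linkS4class{GenotypeMatrix}.
#' @param ped a \linkS4class{Pedigree}.
#' @param affecteds affected ids (>= 2, each with a genotyped parent).
#' @param nReps gene drops per frequency (default 1000).
#' @param seed integer seed for the null.
#' @param gapMarkers tolerated consecutive undefined markers inside a
#'   region (default 20).
#' @param freqs optional per-marker alternate-allele frequencies; by
#'   default estimated from genotyped individuals with no genotyped parent
#'   (the flock founders: the sire and the dams), never from affected lambs.
#' @return list: \code{scan} (data.frame marker, chrom, pos, S, defined,
#'   nullMean, nullSd, Z, LOD) and \code{regions} (data.frame chrom, start,
#'   end, nMarkers, maxZ, maxLOD).
#' @export
linkageScan <- function(gm, ped, affecteds, nReps = 1000, seed,
                        gapMarkers = 20, freqs = NULL) {
  if (missing(seed)) stop("a seed is mandatory for the gene-drop null")
  cl <- calls(gm)
  mk <- markerRanges(gm)
  if (is.null(freqs)) {
    tb <- pedTable(ped)
    gt <- rownames(cl)
    gpar <- function(p) !is.na(p) & p %in% gt
    fnd <- tb$id[tb$id %in% gt &
                 !gpar(tb$sire) & !gpar(tb$dam)]
    if (length(fnd) < 2) stop("cannot estimate founder allele frequencies: fewer than 2 genotyped founders")
    freqs <- colMeans(cl[fnd, , drop = FALSE], na.rm = TRUE) / 2
    freqs[is.nan(freqs)] <- NA_real_
  }
  pv <- parentVectors(ped, affecteds)
  geno <- function(id) if (!is.na(id) && id %in% rownames(cl))
    cl[id, ] else rep(NA_integer_, ncol(cl))
  obs <- sharingS(affecteds, pv$sires, pv$dams, geno, ncol(cl))

  ## null cached per distinct founder frequency (few distinct values: the
  ## frequencies are multiples of 1/(2 x number of genotyped founders))
  fkey <- round(freqs, 6)
  uf <- unique(fkey[!is.na(fkey)])
  cache <- lapply(seq_along(uf), function(i)
    geneDropNull(ped, affecteds, uf[i], nReps = nReps, seed = seed + i))
  names(cache) <- format(uf, digits = 12)
  nullMean <- nullSd <- rep(NA_real_, ncol(cl))
  hit <- !is.na(fkey)
  nm <- vapply(cache, `[[`, 0, "nullMean")
  ns <- vapply(cache, `[[`, 0, "nullSd")
  idx <- match(format(fkey[hit], digits = 12), names(cache))
  nullMean[hit] <- nm[idx]; nullSd[hit] <- ns[idx]

  Z <- rep(NA_real_, ncol(cl))
  ok <- obs$defined & !is.na(nullSd) & nullSd > 1e-9
  Z[ok] <- (obs$S[ok] - nullMean[ok]) / nullSd[ok]
  LOD <- sign(Z) * Z^2 / (2 * log(10))

  scan <- data.frame(marker = markerIds(gm),
                     chrom = as.character(seqnames(mk)), pos = start(mk),
                     S = obs$S, defined = ok, nullMean = nullMean,
                     nullSd = nullSd, Z = Z, LOD = LOD,
                     stringsAsFactors = FALSE)
  list(scan = scan, regions = mergeLinkedRegions(scan, gapMarkers))
}

#' Merge positive-score markers into linked regions
#'
#' Constituent markers of a region all have Z > 0; undefined markers never
#' break a run (up to the gap tolerance) and a defined marker with Z <= 0
#' always does. Region bounds are extended through the flanking undefined
#' markers up to (but excluding) the nearest contradicting (Z <= 0) marker
#' or the end of the marker map: between the last positive and the first
#' negative marker the linked segment's true boundary is unobserved.
#'
#' @param scan the per-marker scan data.frame from \code{\link{linkageScan}}.
#' @param gapMarkers tolerated consecutive undefined markers inside a region.
#' @return data.frame of regions: chrom, start, end, nMarkers (positive
#'   constituent markers), maxZ, maxLOD.
#' @export
mergeLinkedRegions <- function(scan, gapMarkers = 20) {
  out <- list(); k <- 0L
  for (c1 in unique(scan$chrom)) {
    s <- scan[scan$chrom == c1, ]
    state <- ifelse(!s$defined, "U", ifelse(s$Z > 0, "P", "N"))
    pidx <- which(state == "P")
    nidx <- which(state == "N")
    if (!length(pidx)) next
    ## group consecutive positive markers: same run if separated only by
    ## <= gapMarkers undefined markers (any negative marker breaks)
    grp <- cumsum(c(1, vapply(seq_along(pidx)[-1], function(i) {
      between <- if (pidx[i] - pidx[i - 1] <= 1) character(0)
                 else state[(pidx[i - 1] + 1):(pidx[i] - 1)]
      brk <- any(between == "N") || sum(between == "U") > gapMarkers
      as.integer(brk)
    }, 0L)))
    for (g in unique(grp)) {
      sel <- pidx[grp == g]
      lo <- sel[1]; hi <- sel[length(sel)]
      nBefore <- nidx[nidx < lo]; nAfter <- nidx[nidx > hi]
      startPos <- if (length(nBefore)) s$pos[max(nBefore)] + 1L else s$pos[1]
      endPos <- if (length(nAfter)) s$pos[min(nAfter)] - 1L
                else s$pos[nrow(s)]
      k <- k + 1L
      out[[k]] <- data.frame(chrom = c1, start = startPos, end = endPos,
                             nMarkers = length(sel),
                             maxZ = max(s$Z[sel]), maxLOD = max(s$LOD[sel]),
                             stringsAsFactors = FALSE)
    }
  }
  if (!k)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      nMarkers = integer(), maxZ = numeric(), maxLOD = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
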