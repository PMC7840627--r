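## Mendelian-error parentage verification. For a single putative parent the
## only direct Mendelian contradiction at a biallelic marker is the pair of
## opposing homozygotes (child hom for one allele, candidate hom for the
## other): a heterozygous child can never exclude one parent on its own.
## Trio-level inconsistencies (child het, both parents hom ref, etc.) are a
## separate diagnostic handled during trio phasing.

#' Verify parentage of a candidate parent by opposing homozygotes
#'
#' Counts markers at which both individuals are genotyped (informative
#' markers) and, among them, markers where the two are homozygous for
#' opposite alleles. The verdict is thresholded on the opposing-homozygote
#' rate: real parent-offspring pairs show a rate near the genotyping error
#' rate, non-parents a rate orders of magnitude higher.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param child,candidate sample ids.
#' @param confirmThreshold error-rate below which parentage is confirmed.
#' @param excludeThreshold error-rate above which parentage is excluded;
#'   rates in between give an "ambiguous" verdict, as does an overlap of
#'   zero informative markers.
#' @return One-row data.frame: child, candidate, nInformative, nOpposing,
#'   errorRate, verdict ("confirmed"/"excluded"/"ambiguous").
#' @examples
#' gm <- GenotypeMatrix(rbind(kid = c(0, 1, 2), sire = c(0, 1, 2)),
#'                      chrom = "1", pos = c(1, 2, 3) * 100)
#' verifyParentage(gm, "kid", "sire")$verdict
#' @export
verifyParentage <- function(gm, child, candidate,
                            confirmThreshold = 0.001, excludeThreshold = 0.01) {
  cl <- calls(gm)
  stopifnot(child %in% rownames(cl), candidate %in% rownames(cl))
  a <- cl[child, ]; b <- cl[candidate, ]
  inf <- !is.na(a) & !is.na(b)
  opp <- inf & ((a == 0L & b == 2L) | (a == 2L & b == 0L))
  nInf <- sum(inf); nOpp <- sum(opp)
  rate <- if (nInf > 0) nOpp / nInf else NA_real_
  verdict <- if (nInf == 0) "ambiguous"
             else if (rate < confirmThreshold) "confirmed"
             else if (rate > excludeThreshold) "excluded"
             else "ambiguous"
  data.frame(child = child, candidate = candidate, nInformative = nInf,
             nOpposing = nOpp, errorRate = rate, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Rank candidate dams of a child by Mendelian evidence
#'
#' Applies \code{\link{verifyParentage}} to every candidate and ranks them
#' by ascending opposing-homozygote rate (candidates with no informative
#' markers are ranked last and left ambiguous). At most one candidate can be
#' confirmed: when two or more candidates tie at the lowest confirmed rate
#' (e.g. identical twins) the tie is flagged and none is confirmed.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param child sample id.
#' @param candidateDams character vector of candidate ids.
#' @param ... thresholds passed to \code{\link{verifyParentage}}.
#' @return data.frame of verdicts, one row per candidate, ranked; extra
#'   column \code{tied} flags an unresolved tie among best candidates.
#' @export
assignMaternity <- function(gm, child, candidateDams, ...) {
  stopifnot(length(candidateDams) >= 1)
  res <- do.call(rbind, lapply(candidateDams, function(d)
    verifyParentage(gm, child, d, ...)))
  res$tied <- FALSE
  ## NA error rates (no informative markers) rank last
  res <- res[order(is.na(res$errorRate), res$errorRate), , drop = FALSE]
  conf <- which(res$verdict == "confirmed")
  if (length(conf) >= 2 &&
      res$errorRate[conf[1]] == res$errorRate[conf[2]]) {
    tiedSet <- conf[res$errorRate[conf] == res$errorRate[conf[1]]]
    res$tied[tiedSet] <- TRUE
    res$verdict[tiedSet] <- "ambiguous"
  } else if (length(conf) >= 2) {
    ## only the best-supported candidate keeps the confirmation
    res$verdict[conf[-1]] <- "ambiguous"
  }
  rownames(res) <- NULL
  res
}

#' Complete parent-offspring trios restricted to genotyped members
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param gm a \linkS4class{GenotypeMatrix} (or a plain character vector of
#'   genotyped/sequenced sample ids); a trio is returned only when child,
#'   sire and dam are all among its samples.
#' @return data.frame with columns child, sire, dam; children with
#'   "affected" phenotype listed first.
#' @export
buildTrios <- function(ped, gm) {
  tb <- pedTable(ped)
  gt <- if (is.character(gm)) gm else sampleIds(gm)
  ok <- tb$id %in% gt & !is.na(tb$sire) & !is.na(tb$dam) &
    tb$sire %in% gt & tb$dam %in% gt
  out <- tb[ok, c("id", "sire", "dam")]
  names(out)[1] <- "child"
  aff <- tb$phenotype[ok] == "affected"
  out <- out[order(!aff), , drop = FALSE]
  rownames(out) <- NULL
  out
}
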