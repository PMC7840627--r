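## Sample- and marker-level quality control. Only missingness filters are
## applied: minor-allele-frequency and Hardy-Weinberg filters are invalid in
## a single family and are deliberately absent.

#' Per-sample call rates
#'
#' @param gm a \linkS4class{GenotypeMatrix} with at least one marker.
#' @param minCallRate samples strictly below this fraction of non-missing
#'   calls are flagged (default 0.90).
#' @return data.frame with columns sample, callRate, pass.
#' @export
sampleCallRates <- function(gm, minCallRate = 0.90) {
  cl <- calls(gm)
  stopifnot(ncol(cl) >= 1)
  cr <- rowMeans(!is.na(cl))
  data.frame(sample = rownames(cl), callRate = unname(cr),
             pass = unname(cr >= minCallRate), stringsAsFactors = FALSE)
}

#' @rdname sampleCallRates
#' @export
callRate <- function(gm) mean(!is.na(calls(gm)))

#' Prune markers by missingness
#'
#' Removes markers whose missing-call fraction exceeds \code{maxMissing}
#' (strictly: a marker at exactly the threshold is retained). The sample set
#' is untouched, retained markers keep their order and their calls are never
#' altered, so pruning is idempotent.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param maxMissing maximum tolerated missing fraction per marker
#'   (default 0.10).
#' @return The pruned \linkS4class{GenotypeMatrix}, with an attribute
#'   \code{prunedMarkers} giving the removed marker ids.
#' @export
pruneMarkersByMissingness <- function(gm, maxMissing = 0.10) {
  cl <- calls(gm)
  missFrac <- colMeans(is.na(cl))
  keep <- missFrac <= maxMissing
  if (!any(keep))
    stop(sprintf(
      "all %d markers exceed the missingness threshold %.2f; review the threshold or the genotype data",
      ncol(cl), maxMissing))
  out <- gm[, keep]
  attr(out, "prunedMarkers") <- markerIds(gm)[!keep]
  out
}
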