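## Runs-of-homozygosity (autozygosity) detection and allele-matched shared
## segments across affected animals. Rule-based consecutive-run scanning
## with het/missing tolerances (not a sliding-window heuristic); defaults
## are calibrated to a ~50k-marker array on a ~2.6 Gb genome and are all
## overridable. Segments are per-chromosome and never joined across
## chromosome boundaries.

#' @useDynLib comphet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Detect runs of homozygosity for one sample
#'
#' Maximal runs of consecutive homozygous calls, tolerating up to
#' \code{maxHet} heterozygous and \code{maxMiss} missing calls per run;
#' runs start and end on homozygous markers. Runs are reported when they
#' contain at least \code{minSnps} markers and span at least
#' \code{minLengthBp}.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param sample sample id.
#' @param minSnps minimum markers per segment (default 40).
#' @param minLengthBp minimum physical span in bp (default 2e6).
#' @param maxHet,maxMiss tolerated heterozygous / missing calls per run
#'   (defaults 1 and 2).
#' @return data.frame: sample, chrom, start, end, nSnps, nHet, nMiss.
#' @export
detectRoh <- function(gm, sample, minSnps = 40, minLengthBp = 2e6,
                      maxHet = 1, maxMiss = 2) {
  cl <- calls(gm)
  stopifnot(sample %in% rownames(cl))
  mk <- markerRanges(gm)
  ch <- as.character(seqnames(mk)); pos <- start(mk)
  out <- list()
  for (c1 in unique(ch)) {
    idx <- which(ch == c1)
    runs <- rohRunsC(cl[sample, idx], as.integer(maxHet), as.integer(maxMiss))
    if (!nrow(runs)) next
    st <- pos[idx[runs[, "start"]]]
    en <- pos[idx[runs[, "end"]]]
    n <- runs[, "end"] - runs[, "start"] + 1L
    keep <- n >= minSnps & (en - st + 1L) >= minLengthBp
    if (!any(keep)) next
    out[[c1]] <- data.frame(sample = sample, chrom = c1,
                            start = st[keep], end = en[keep],
                            nSnps = n[keep], nHet = runs[keep, "nHet"],
                            nMiss = runs[keep, "nMiss"],
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(), nSnps = integer(),
                      nHet = integer(), nMiss = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shared allele-matched autozygosity across cases
#'
#' Intersects the ROH segments of all cases and enforces, marker by marker,
#' that every case with a non-missing call is homozygous for the same
#' allele. Intervals are split at violating markers (a heterozygous call or
#' two cases homozygous for opposite alleles), so every returned interval is
#' contained in an ROH segment of every case and is allele-consistent at all
#' its non-missing markers.
#'
#' @param segments list of per-case ROH data.frames (as from
#'   \code{\link{detectRoh}}), one element per case.
#' @param gm the \linkS4class{GenotypeMatrix}.
#' @param cases character vector of case ids (>= 2), parallel to
#'   \code{segments}.
#' @param minMarkers minimum supporting markers per reported interval
#'   (default 2).
#' @return data.frame: chrom, start, end, nMarkers (possibly zero rows).
#' @export
sharedAutozygosity <- function(segments, gm, cases, minMarkers = 2) {
  stopifnot(length(cases) >= 2, length(segments) == length(cases))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), nMarkers = integer())
  lev <- unique(unlist(lapply(segments, function(s) s$chrom)))
  if (!length(lev)) return(empty)
  grs <- lapply(segments, function(s)
    GRanges(factor(s$chrom, levels = lev), IRanges(s$start, s$end)))
  common <- Reduce(GenomicRanges::intersect, grs)
  if (!length(common)) return(empty)
  cl <- calls(gm)[cases, , drop = FALSE]
  mk <- markerRanges(gm)
  ch <- as.character(seqnames(mk)); pos <- start(mk)
  out <- list(); k <- 0L
  for (i in seq_along(common)) {
    c1 <- as.character(seqnames(common))[i]
    idx <- which(ch == c1 & pos >= start(common)[i] & pos <= end(common)[i])
    if (length(idx) < minMarkers) next
    sub <- cl[, idx, drop = FALSE]
    anyHet <- apply(sub, 2, function(g) any(g == 1L, na.rm = TRUE))
    opposed <- apply(sub, 2, function(g)
      any(g == 0L, na.rm = TRUE) && any(g == 2L, na.rm = TRUE))
    ok <- !(anyHet | opposed)
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= minMarkers)) {
      k <- k + 1L
      sel <- idx[starts[j]:ends[j]]
      out[[k]] <- data.frame(chrom = c1, start = pos[sel[1]],
                             end = pos[sel[length(sel)]],
                             nMarkers = length(sel), stringsAsFactors = FALSE)
    }
  }
  if (!k) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
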