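## Isoform-aware transcript consequence engine: genomic -> coding-DNA
## coordinate mapping with intronic offsets, SNV classification against the
## spliced CDS (so codons spanning exon junctions are handled correctly),
## canonical splice-site disruption with cryptic-site rescue, frameshift
## translation, and HGVS naming. Canonical sites are strictly the GT/AG
## dinucleotides at intronic positions +/-1, +/-2; positions 3..8 from an
## exon are annotated splice_region but are not protein-changing. The
## cryptic-acceptor model takes the nearest downstream AG within a fixed
## exonic scan window (no splice-strength scoring); donor loss mirrors it
## with upstream GT scanning and is flagged lower-confidence. Truncation is
## reported as such: nonsense-mediated decay is never predicted.

## exons in transcript orientation with transcript/CDS coordinates
txLayout <- function(tx) {
  ex <- tx@exons
  ord <- if (tx@strand == "+") seq_along(ex) else rev(seq_along(ex))
  widths <- IRanges::width(ex)[ord]
  txStart <- cumsum(c(1L, widths))[seq_along(ord)]
  ## transcript coordinate of a genomic exonic position
  g2t <- function(gpos) {
    for (k in seq_along(ord)) {
      e <- ord[k]
      s <- IRanges::start(ex)[e]; en <- IRanges::end(ex)[e]
      if (gpos >= s && gpos <= en) {
        off <- if (tx@strand == "+") gpos - s else en - gpos
        return(txStart[k] + off)
      }
    }
    NA_integer_
  }
  cds5g <- if (tx@strand == "+") tx@cdsStart else tx@cdsEnd
  cds3g <- if (tx@strand == "+") tx@cdsEnd else tx@cdsStart
  list(exonOrder = ord, txStart = txStart, g2t = g2t,
       cds5t = g2t(cds5g), cds3t = g2t(cds3g))
}

cdnaLabel <- function(t, lay) {
  if (t < lay$cds5t) paste0("-", lay$cds5t - t)
  else if (t > lay$cds3t) paste0("*", t - lay$cds3t)
  else as.character(t - lay$cds5t + 1L)
}

#' Map a genomic position to coding-DNA (c.) coordinates
#'
#' Exonic positions map to c.N (or c.-N / c.*N in the UTRs); intronic
#' positions map to the nearest exon boundary with a +/- offset in
#' transcript orientation (ties go to the donor side). Reverse-strand
#' transcripts are handled by the reverse-complement convention.
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param gpos genomic 1-based position.
#' @return list: region ("cds", "utr5", "utr3", "intron", "outside"),
#'   baseLabel (coding coordinate label of the position or of the nearest
#'   exonic base), offset (0 for exonic, signed intronic offset otherwise),
#'   cdsPos (CDS coordinate, NA unless region == "cds"), label (the full
#'   coordinate string, e.g. "210-2").
#' @export
mapGenomicToCdna <- function(tx, gpos) {
  ex <- tx@exons
  lay <- txLayout(tx)
  if (gpos < min(IRanges::start(ex)) || gpos > max(IRanges::end(ex)))
    return(list(region = "outside", baseLabel = NA_character_,
                offset = NA_integer_, cdsPos = NA_integer_,
                label = NA_character_))
  t <- lay$g2t(gpos)
  if (!is.na(t)) {
    bl <- cdnaLabel(t, lay)
    region <- if (t < lay$cds5t) "utr5" else if (t > lay$cds3t) "utr3" else "cds"
    return(list(region = region, baseLabel = bl, offset = 0L,
                cdsPos = if (region == "cds") t - lay$cds5t + 1L else NA_integer_,
                label = bl))
  }
  ## intronic: flanking exon boundaries in genomic coordinates
  prevEnd <- max(IRanges::end(ex)[IRanges::end(ex) < gpos])
  nextStart <- min(IRanges::start(ex)[IRanges::start(ex) > gpos])
  donorB <- if (tx@strand == "+") prevEnd else nextStart
  accB <- if (tx@strand == "+") nextStart else prevEnd
  dDon <- abs(gpos - donorB); dAcc <- abs(gpos - accB)
  if (dDon <= dAcc) {
    bl <- cdnaLabel(lay$g2t(donorB), lay)
    off <- dDon
  } else {
    bl <- cdnaLabel(lay$g2t(accB), lay)
    off <- -dAcc
  }
  list(region = "intron", baseLabel = bl, offset = as.integer(off),
       cdsPos = NA_integer_,
       label = paste0(bl, sprintf("%+d", off)))
}

## transcript-strand alleles of a genomic ref/alt pair
txAlleles <- function(tx, ref, alt) {
  if (tx@strand == "-") {
    comp <- function(x) as.character(reverseComplement(DNAString(x)))
    list(ref = comp(ref), alt = comp(alt))
  } else list(ref = ref, alt = alt)
}

codonAt <- function(cds, cdsPos) {
  ci <- (cdsPos - 1L) %/% 3L
  as.character(subseq(cds, ci * 3L + 1L, ci * 3L + 3L))
}

aaOf <- function(codon)
  as.character(translate(DNAString(codon), if.fuzzy.codon = "X"))

#' Classify a single-nucleotide variant on one transcript
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param gpos,ref,alt genomic position and genomic-strand alleles (the
#'   reference allele is checked against the model's sequence).
#' @return The effect class: splice_acceptor / splice_donor (canonical
#'   +/-2 nt dinucleotide positions), splice_region (intronic 3..8 from an
#'   exon; not protein-changing), missense, nonsense, synonymous,
#'   start_lost, stop_lost, or non_coding (UTR, deep intron, or any variant
#'   on a non-translatable model).
#' @export
classifySnv <- function(tx, gpos, ref, alt) {
  obs <- as.character(subseq(tx@chromSeq, gpos, gpos))
  if (obs != ref)
    stop(sprintf("reference allele mismatch at %s:%d: expected %s, model has %s",
                 tx@chrom, gpos, ref, obs))
  mp <- mapGenomicToCdna(tx, gpos)
  if (mp$region == "outside") return("non_coding")
  if (mp$region == "intron") {
    if (abs(mp$offset) <= 2L)
      return(if (mp$offset < 0L) "splice_acceptor" else "splice_donor")
    if (abs(mp$offset) <= 8L) return("splice_region")
    return("non_coding")
  }
  if (mp$region != "cds") return("non_coding")
  if (!tx@translatable) return("non_coding")
  al <- txAlleles(tx, ref, alt)
  cds <- tx@cds
  codon <- codonAt(cds, mp$cdsPos)
  inCodon <- (mp$cdsPos - 1L) %% 3L + 1L
  mcodon <- codon
  substr(mcodon, inCodon, inCodon) <- al$alt
  aaR <- aaOf(codon); aaA <- aaOf(mcodon)
  ci <- (mp$cdsPos - 1L) %/% 3L + 1L
  if (aaR == aaA) return("synonymous")
  if (ci == 1L && aaR == "M") return("start_lost")
  if (aaR == "*") return(if (aaA == "*") "synonymous" else "stop_lost")
  if (aaA == "*") return("nonsense")
  "missense"
}

## deletion of transcript positions tDel (sorted) restricted to the CDS,
## applied to the cached spliced CDS
deleteFromCds <- function(tx, tDel) {
  lay <- txLayout(tx)
  cdsDel <- tDel[tDel >= lay$cds5t & tDel <= lay$cds3t] - lay$cds5t + 1L
  s <- strsplit(as.character(tx@cds), "")[[1]]
  if (length(cdsDel)) s <- s[-cdsDel]
  list(mutantCds = DNAString(paste(s, collapse = "")),
       nCdsDeleted = length(cdsDel))
}

#' Model the transcript outcome of a canonical acceptor-site loss
#'
#' When a variant destroys the canonical AG of an intron acceptor (c.N-1 or
#' c.N-2), the downstream exon's 5' boundary is moved to just after the
#' nearest downstream AG dinucleotide found within \code{scanWindow} bases
#' of exonic sequence (cryptic-acceptor activation). If no AG exists in the
#' window, the exon is skipped instead and the call is flagged; if skipping
#' would remove the CDS start, no rescue model is available.
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param gpos,ref,alt the acceptor variant (genomic strand).
#' @param scanWindow exonic scan window in bases (default 50).
#' @return list: model ("cryptic_acceptor", "exon_skip", "no_rescue"),
#'   deletionLength (bases removed from the spliced transcript),
#'   nCdsDeleted, mutantCds, frameshift (TRUE when nCdsDeleted %% 3 != 0),
#'   exonIndex (transcript-order index of the affected exon).
#' @export
applyAcceptorLoss <- function(tx, gpos, ref, alt, scanWindow = 50) {
  cls <- classifySnv(tx, gpos, ref, alt)
  if (cls != "splice_acceptor")
    stop("variant does not destroy a canonical acceptor dinucleotide")
  ex <- tx@exons
  lay <- txLayout(tx)
  ## affected exon: transcript-downstream of the intron containing gpos
  accBoundary <- if (tx@strand == "+")
    min(IRanges::start(ex)[IRanges::start(ex) > gpos])
  else
    max(IRanges::end(ex)[IRanges::end(ex) < gpos])
  eIdx <- if (tx@strand == "+") which(IRanges::start(ex) == accBoundary)
          else which(IRanges::end(ex) == accBoundary)
  eTxIdx <- match(eIdx, lay$exonOrder)
  exSeq <- subseq(tx@chromSeq, IRanges::start(ex)[eIdx], IRanges::end(ex)[eIdx])
  if (tx@strand == "-") exSeq <- reverseComplement(exSeq)
  exLen <- length(exSeq)
  scan <- as.character(subseq(exSeq, 1L, min(scanWindow, exLen)))
  hit <- regexpr("AG", scan, fixed = TRUE)
  tFirst <- lay$txStart[eTxIdx]             # transcript coord of exon base 1
  if (hit > 0) {
    d <- as.integer(hit) + 1L               # deletion ends at the AG's G
    del <- deleteFromCds(tx, tFirst:(tFirst + d - 1L))
    list(model = "cryptic_acceptor", deletionLength = d,
         nCdsDeleted = del$nCdsDeleted, mutantCds = del$mutantCds,
         frameshift = del$nCdsDeleted %% 3L != 0L, exonIndex = eTxIdx)
  } else {
    ## no cryptic AG: exon-skipping model
    tDel <- tFirst:(tFirst + exLen - 1L)
    if (lay$cds5t >= tFirst && lay$cds5t <= tFirst + exLen - 1L)
      return(list(model = "no_rescue", deletionLength = NA_integer_,
                  nCdsDeleted = NA_integer_, mutantCds = NULL,
                  frameshift = NA, exonIndex = eTxIdx))
    del <- deleteFromCds(tx, tDel)
    list(model = "exon_skip", deletionLength = exLen,
         nCdsDeleted = del$nCdsDeleted, mutantCds = del$mutantCds,
         frameshift = del$nCdsDeleted %% 3L != 0L, exonIndex = eTxIdx)
  }
}

#' Model the transcript outcome of a canonical donor-site loss
#'
#' Mirror of \code{\link{applyAcceptorLoss}}: the upstream exon's 3' end is
#' moved to just before the nearest upstream GT dinucleotide within
#' \code{scanWindow} bases of its end (cryptic-donor activation), falling
#' back to exon skipping. Donor rescue is flagged lower-confidence
#' (\code{confidence = "low"}): only the acceptor model is anchored by the
#' cryptic-site behaviour this engine was built around.
#'
#' @inheritParams applyAcceptorLoss
#' @return As \code{\link{applyAcceptorLoss}}, plus \code{confidence}.
#' @export
applyDonorLoss <- function(tx, gpos, ref, alt, scanWindow = 50) {
  cls <- classifySnv(tx, gpos, ref, alt)
  if (cls != "splice_donor")
    stop("variant does not destroy a canonical donor dinucleotide")
  ex <- tx@exons
  lay <- txLayout(tx)
  donBoundary <- if (tx@strand == "+")
    max(IRanges::end(ex)[IRanges::end(ex) < gpos])
  else
    min(IRanges::start(ex)[IRanges::start(ex) > gpos])
  eIdx <- if (tx@strand == "+") which(IRanges::end(ex) == donBoundary)
          else which(IRanges::start(ex) == donBoundary)
  eTxIdx <- match(eIdx, lay$exonOrder)
  exSeq <- subseq(tx@chromSeq, IRanges::start(ex)[eIdx], IRanges::end(ex)[eIdx])
  if (tx@strand == "-") exSeq <- reverseComplement(exSeq)
  exLen <- length(exSeq)
  from <- max(1L, exLen - scanWindow + 1L)
  scan <- as.character(subseq(exSeq, from, exLen))
  hits <- gregexpr("GT", scan, fixed = TRUE)[[1]]
  tFirst <- lay$txStart[eTxIdx]
  if (hits[1] > 0) {
    gtStart <- from + hits[length(hits)] - 1L   # nearest (last) upstream GT
    d <- exLen - gtStart + 1L
    del <- deleteFromCds(tx, (tFirst + gtStart - 1L):(tFirst + exLen - 1L))
    list(model = "cryptic_donor", deletionLength = d,
         nCdsDeleted = del$nCdsDeleted, mutantCds = del$mutantCds,
         frameshift = del$nCdsDeleted %% 3L != 0L, exonIndex = eTxIdx,
         confidence = "low")
  } else {
    tDel <- tFirst:(tFirst + exLen - 1L)
    if (lay$cds5t >= tFirst && lay$cds5t <= tFirst + exLen - 1L)
      return(list(model = "no_rescue", deletionLength = NA_integer_,
                  nCdsDeleted = NA_integer_, mutantCds = NULL,
                  frameshift = NA, exonIndex = eTxIdx, confidence = "low"))
    del <- deleteFromCds(tx, tDel)
    list(model = "exon_skip", deletionLength = exLen,
         nCdsDeleted = del$nCdsDeleted, mutantCds = del$mutantCds,
         frameshift = del$nCdsDeleted %% 3L != 0L, exonIndex = eTxIdx,
         confidence = "low")
  }
}

#' Translate a mutant CDS and name the protein change
#'
#' Translates from the reference start codon to the first stop and names
#' the change against the reference protein: identity "p.(=)"; a stop at
#' the first divergent residue "p.Xn Ter" (nonsense-style); otherwise
#' frameshift notation "p.<Ref><n><New>fsTer<k>" with k the stop index in
#' the new frame counting the first changed residue as 1 ("fsTer?" flagged
#' when no stop is reached before the sequence ends).
#'
#' @param mutantCds a \code{DNAString} (must begin at the reference start
#'   codon).
#' @param referenceProtein an \code{AAString} (no stop residue).
#' @return list: hgvsP, mutantProteinLength, fractionTruncated
#'   (1 - mutant/reference length), terFound.
#' @export
translateMutant <- function(mutantCds, referenceProtein) {
  n3 <- (length(mutantCds) %/% 3L) * 3L
  aa <- if (n3 >= 3L)
    as.character(translate(subseq(mutantCds, 1L, n3), if.fuzzy.codon = "X"))
  else ""
  aaVec <- strsplit(aa, "")[[1]]
  stopAt <- match("*", aaVec)
  terFound <- !is.na(stopAt)
  mut <- if (terFound) aaVec[seq_len(stopAt - 1L)] else aaVec
  ref <- strsplit(as.character(referenceProtein), "")[[1]]
  refLen <- length(ref); mutLen <- length(mut)

  if (terFound && mutLen == refLen && all(mut == ref))
    return(list(hgvsP = "p.(=)", mutantProteinLength = mutLen,
                fractionTruncated = 0, terFound = TRUE))

  nCmp <- min(refLen, mutLen)
  div <- which(mut[seq_len(nCmp)] != ref[seq_len(nCmp)])
  i <- if (length(div)) div[1] else nCmp + 1L

  frac <- 1 - mutLen / refLen
  if (i > mutLen) {
    ## first divergence is the stop itself: substitution to Ter
    hgvs <- formatHgvsP(ref[i], i, "*")
  } else if (terFound && mutLen == refLen &&
             all(mut[-seq_len(i)] == ref[-seq_len(i)])) {
    hgvs <- formatHgvsP(ref[i], i, mut[i])   # plain substitution
  } else {
    k <- if (terFound) mutLen - i + 2L else "?"
    hgvs <- formatHgvsP(ref[i], i, mut[i], fsTer = k)
  }
  list(hgvsP = hgvs, mutantProteinLength = mutLen,
       fractionTruncated = frac, terFound = terFound)
}

#' Annotate a variant on every covering isoform
#'
#' One \code{ConsequenceCall} row per transcript whose span covers the
#' variant. A single genomic variant may differ in class between isoforms
#' (e.g. missense on an insert-bearing isoform, nonsense on the shorter
#' one). Acceptor/donor losses are run through the cryptic-site rescue
#' model to obtain protein-level consequences.
#'
#' @param gpos,ref,alt genomic position and genomic-strand alleles.
#' @param models list of \linkS4class{TranscriptModel}.
#' @param scanWindow cryptic-site scan window (default 50).
#' @param chrom optional chromosome name; when given, only models on that
#'   chromosome are considered.
#' @return data.frame: transcriptId, geneId, effectClass, hgvsC, hgvsP,
#'   mutantProteinLength, fractionTruncated, spliceModel.
#' @export
annotateAllIsoforms <- function(gpos, ref, alt, models, scanWindow = 50,
                                chrom = NULL) {
  rows <- list(); k <- 0L
  for (tx in models) {
    if (!is.null(chrom) && tx@chrom != chrom) next
    ex <- tx@exons
    if (gpos < min(IRanges::start(ex)) || gpos > max(IRanges::end(ex))) next
    cls <- classifySnv(tx, gpos, ref, alt)
    mp <- mapGenomicToCdna(tx, gpos)
    al <- txAlleles(tx, ref, alt)
    hgvsC <- paste0("c.", mp$label, al$ref, ">", al$alt)
    hgvsP <- NA_character_
    mutLen <- NA_integer_; frac <- NA_real_; spliceModel <- NA_character_
    if (cls %in% c("missense", "nonsense", "synonymous", "stop_lost",
                   "start_lost") && tx@translatable) {
      codon <- codonAt(tx@cds, mp$cdsPos)
      inCodon <- (mp$cdsPos - 1L) %% 3L + 1L
      mcodon <- codon
      substr(mcodon, inCodon, inCodon) <- al$alt
      ci <- (mp$cdsPos - 1L) %/% 3L + 1L
      refLen <- length(tx@protein)
      hgvsP <- formatHgvsP(aaOf(codon), ci, aaOf(mcodon))
      if (cls == "nonsense") {
        mutLen <- ci - 1L
        frac <- 1 - mutLen / refLen
      } else if (cls %in% c("missense", "synonymous")) {
        mutLen <- refLen; frac <- 0
      }
    } else if (cls %in% c("splice_acceptor", "splice_donor") &&
               tx@translatable) {
      res <- if (cls == "splice_acceptor")
        applyAcceptorLoss(tx, gpos, ref, alt, scanWindow)
      else applyDonorLoss(tx, gpos, ref, alt, scanWindow)
      spliceModel <- res$model
      if (!is.null(res$mutantCds)) {
        tr <- translateMutant(res$mutantCds, tx@protein)
        hgvsP <- tr$hgvsP
        mutLen <- tr$mutantProteinLength
        frac <- tr$fractionTruncated
      }
    }
    k <- k + 1L
    rows[[k]] <- data.frame(
      transcriptId = tx@transcriptId, geneId = tx@geneId, effectClass = cls,
      hgvsC = hgvsC, hgvsP = hgvsP, mutantProteinLength = mutLen,
      fractionTruncated = frac, spliceModel = spliceModel,
      stringsAsFactors = FALSE)
  }
  if (!k)
    return(data.frame(transcriptId = character(), geneId = character(),
                      effectClass = character(), hgvsC = character(),
                      hgvsP = character(), mutantProteinLength = integer(),
                      fractionTruncated = numeric(), spliceModel = character()))
  do.call(rbind, rows)
}
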