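#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom stats setNames
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
NULL

## Genotype call codes used throughout the package:
## 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
## NA = missing. Missing is a first-class state and is never imputed.
GENO_LEVELS <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)

#' GenotypeMatrix: individuals x biallelic markers
#'
#' Container for SNP-array (or any biallelic) genotype calls. Rows are
#' samples, columns are markers; calls are coded 0 (hom ref), 1 (het),
#' 2 (hom alt) with \code{NA} for missing. Marker coordinates are stored as
#' a \link[GenomicRanges]{GRanges} parallel to the columns and must be
#' sorted with strictly increasing positions within each chromosome.
#'
#' @slot calls integer matrix, samples x markers, values in \{0,1,2,NA\}.
#' @slot markers \code{GRanges} of width-1 marker positions, one per column.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(calls = "matrix", markers = "GRanges"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  cl <- object@calls
  if (!is.integer(cl)) msg <- c(msg, "'calls' must be an integer matrix")
  bad <- cl[!is.na(cl)]
  if (length(bad) && !all(bad %in% 0:2))
    msg <- c(msg, "genotype calls must be 0, 1, 2 or NA")
  if (ncol(cl) != length(object@markers))
    msg <- c(msg, sprintf("ncol(calls) [%d] != length(markers) [%d]",
                          ncol(cl), length(object@markers)))
  if (is.null(rownames(cl))) msg <- c(msg, "'calls' must have sample ids as rownames")
  if (anyDuplicated(rownames(cl))) msg <- c(msg, "duplicated sample ids")
  if (length(object@markers)) {
    ch <- as.character(seqnames(object@markers))
    pos <- start(object@markers)
    for (c1 in unique(ch)) {
      p <- pos[ch == c1]
      if (any(diff(p) <= 0)) {
        msg <- c(msg, sprintf("marker positions not strictly increasing on %s", c1))
        break
      }
    }
    if (!is.null(names(object@markers)) && anyDuplicated(names(object@markers)))
      msg <- c(msg, "duplicated marker ids")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls numeric/integer matrix (samples x markers) with values
#'   0/1/2/NA; rownames are sample ids.
#' @param chrom character vector of marker chromosomes (length = ncol).
#' @param pos integer vector of 1-based marker positions.
#' @param markerIds optional marker identifiers; defaults to
#'   \code{colnames(calls)} or \code{chrom:pos}.
#' @return A \code{GenotypeMatrix}.
#' @examples
#' gm <- GenotypeMatrix(rbind(s1 = c(0, 1, 2), s2 = c(0, NA, 1)),
#'                      chrom = c("1", "1", "2"), pos = c(100, 200, 50))
#' callRate(gm)
#' @export
GenotypeMatrix <- function(calls, chrom, pos, markerIds = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(markerIds))
    markerIds <- if (!is.null(colnames(calls))) colnames(calls)
                 else paste0(chrom, ":", pos)
  mk <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  names(mk) <- markerIds
  colnames(calls) <- markerIds
  new("GenotypeMatrix", calls = calls, markers = mk)
}

#' Pedigree of a (livestock) family
#'
#' Individuals with sire/dam links, sex and phenotype. Ungenotyped ancestors
#' (e.g. a phantom maternal grandsire) are ordinary rows whose own parents
#' are unknown; every referenced parent id must itself be a row.
#'
#' @slot tbl data.frame with columns id, sire, dam (NA when unknown),
#'   sex ("male"/"female"/"unknown"), phenotype
#'   ("affected"/"unaffected"/"unknown").
#' @exportClass Pedigree
setClass("Pedigree", representation(tbl = "data.frame"))

setValidity("Pedigree", function(object) {
  tb <- object@tbl
  msg <- character()
  need <- c("id", "sire", "dam", "sex", "phenotype")
  if (!all(need %in% names(tb)))
    return(paste("pedigree table must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$id)) msg <- c(msg, "duplicated individual ids")
  for (col in c("sire", "dam")) {
    ref <- tb[[col]][!is.na(tb[[col]])]
    miss <- setdiff(ref, tb$id)
    if (length(miss))
      msg <- c(msg, sprintf("unresolved %s id(s): %s", col,
                            paste(miss, collapse = ", ")))
  }
  if (!all(tb$sex %in% c("male", "female", "unknown")))
    msg <- c(msg, "sex must be male/female/unknown")
  if (!all(tb$phenotype %in% c("affected", "unaffected", "unknown")))
    msg <- c(msg, "phenotype must be affected/unaffected/unknown")
  sx <- setNames(tb$sex, tb$id)
  badsire <- tb$sire[!is.na(tb$sire)]
  badsire <- badsire[sx[badsire] == "female"]
  if (length(badsire)) msg <- c(msg, "sire(s) recorded as female")
  baddam <- tb$dam[!is.na(tb$dam)]
  baddam <- baddam[sx[baddam] == "male"]
  if (length(baddam)) msg <- c(msg, "dam(s) recorded as male")
  ## no individual is its own ancestor
  if (!length(msg)) {
    par <- rbind(setNames(tb$sire, tb$id), setNames(tb$dam, tb$id))
    for (id in tb$id) {
      seen <- character(); stack <- par[, id]
      while (length(stack <- stack[!is.na(stack)])) {
        if (id %in% stack) { msg <- c(msg, sprintf("%s is its own ancestor", id)); break }
        stack <- setdiff(stack, seen); seen <- c(seen, stack)
        stack <- as.vector(par[, stack[stack %in% colnames(par)], drop = FALSE])
      }
      if (length(msg)) break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Pedigree
#'
#' @param id,sire,dam character vectors; use NA for unknown parents.
#' @param sex,phenotype character vectors, recycled; see class slots.
#' @return A \code{Pedigree}.
#' @examples
#' ped <- Pedigree(id = c("GS", "D1", "S", "C1"),
#'                 sire = c(NA, "GS", NA, "S"), dam = c(NA, NA, NA, "D1"),
#'                 sex = c("male", "female", "male", "male"),
#'                 phenotype = c("unknown", "unaffected", "unaffected", "affected"))
#' affectedIds(ped)
#' @export
Pedigree <- function(id, sire = NA, dam = NA, sex = "unknown",
                     phenotype = "unknown") {
  n <- length(id)
  tb <- data.frame(
    id = as.character(id),
    sire = as.character(rep_len(sire, n)),
    dam = as.character(rep_len(dam, n)),
    sex = rep_len(sex, n),
    phenotype = rep_len(phenotype, n),
    stringsAsFactors = FALSE)
  new("Pedigree", tbl = tb)
}

#' VariantTable: called sequence variants with per-sample genotypes
#'
#' Biallelic variant records (multiallelic sites are decomposed at ingest)
#' with the same four-state genotype coding as \linkS4class{GenotypeMatrix}.
#'
#' @slot info data.frame with columns chrom, pos (1-based), ref, alt,
#'   geneId, effectClass; row per variant. Rownames are variant ids
#'   ("chrom:pos:ref:alt").
#' @slot geno integer matrix, variants x samples, values in \{0,1,2,NA\}.
#' @exportClass VariantTable
setClass("VariantTable", representation(info = "data.frame", geno = "matrix"))

setValidity("VariantTable", function(object) {
  msg <- character()
  need <- c("chrom", "pos", "ref", "alt", "geneId", "effectClass")
  if (!all(need %in% names(object@info)))
    return(paste("info must have columns", paste(need, collapse = ", ")))
  if (nrow(object@info) != nrow(object@geno))
    msg <- c(msg, "info and geno row counts differ")
  if (any(object@info$ref == object@info$alt))
    msg <- c(msg, "ref and alt alleles must differ")
  g <- object@geno[!is.na(object@geno)]
  if (length(g) && !all(g %in% 0:2)) msg <- c(msg, "genotypes must be 0/1/2/NA")
  if (length(msg)) msg else TRUE
})

#' Construct a VariantTable
#'
#' @param chrom,pos,ref,alt per-variant fields (pos is 1-based).
#' @param geno integer matrix variants x samples (0/1/2/NA), with sample ids
#'   as colnames. May have zero columns for site-only records.
#' @param geneId,effectClass optional annotations (NA when unknown).
#' @return A \code{VariantTable}.
#' @export
VariantTable <- function(chrom, pos, ref, alt, geno = NULL,
                         geneId = NA_character_, effectClass = NA_character_) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  info <- data.frame(chrom = rep_len(as.character(chrom), n),
                     pos = rep_len(as.integer(pos), n),
                     ref = rep_len(as.character(ref), n),
                     alt = rep_len(as.character(alt), n),
                     geneId = as.character(rep_len(geneId, n)),
                     effectClass = as.character(rep_len(effectClass, n)),
                     stringsAsFactors = FALSE)
  rownames(info) <- paste(info$chrom, info$pos, info$ref, info$alt, sep = ":")
  if (is.null(geno)) geno <- matrix(integer(), nrow = n, ncol = 0)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  rownames(geno) <- rownames(info)
  new("VariantTable", info = info, geno = geno)
}

#' TranscriptModel: strand-aware exon/CDS gene model plus sequence
#'
#' Exon structure and CDS bounds in genomic coordinates (1-based, closed,
#' exons sorted by genomic position) together with the chromosome sequence,
#' from which the spliced CDS and protein are derived at construction time.
#' Models whose CDS length is not a multiple of 3 or whose CDS contains an
#' internal stop are flagged non-translatable with a warning.
#'
#' @slot transcriptId,geneId,chrom character scalars.
#' @slot strand "+" or "-".
#' @slot exons \code{IRanges} of exon genomic intervals, ascending, non-overlapping.
#' @slot cdsStart,cdsEnd genomic 1-based CDS bounds (cdsStart <= cdsEnd).
#' @slot chromSeq \code{DNAString} of the (toy) chromosome.
#' @slot cds cached spliced CDS (\code{DNAString}, transcript orientation).
#' @slot protein cached translation (\code{AAString}, without the stop).
#' @slot translatable logical flag.
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(transcriptId = "character", geneId = "character",
                 chrom = "character", strand = "character",
                 exons = "IRanges", cdsStart = "integer", cdsEnd = "integer",
                 chromSeq = "DNAString", cds = "DNAString",
                 protein = "AAString", translatable = "logical"))

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  ex <- object@exons
  if (length(ex) > 1) {
    if (any(diff(IRanges::start(ex)) <= 0) ||
        any(IRanges::start(ex)[-1] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be ordered and non-overlapping")
  }
  inExon <- function(p) any(p >= IRanges::start(ex) & p <= IRanges::end(ex))
  if (!inExon(object@cdsStart) || !inExon(object@cdsEnd))
    msg <- c(msg, "CDS bounds must fall inside exons")
  if (object@cdsStart > object@cdsEnd) msg <- c(msg, "cdsStart > cdsEnd")
  if (length(msg)) msg else TRUE
})
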