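#' @importFrom GenomicRanges GRanges seqnames start
NULL

setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
setGeneric("calls", function(x) standardGeneric("calls"))
setGeneric("markerRanges", function(x) standardGeneric("markerRanges"))
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
setGeneric("pedTable", function(x) standardGeneric("pedTable"))
setGeneric("pedIds", function(x) standardGeneric("pedIds"))
setGeneric("affectedIds", function(x) standardGeneric("affectedIds"))
setGeneric("founderIds", function(x) standardGeneric("founderIds"))
setGeneric("parentsOf", function(x, id) standardGeneric("parentsOf"))
setGeneric("splicedCds", function(x) standardGeneric("splicedCds"))
setGeneric("refProtein", function(x) standardGeneric("refProtein"))

#' @describeIn GenotypeMatrix sample identifiers
#' @param x a GenotypeMatrix
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@calls))

#' @describeIn GenotypeMatrix marker identifiers
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) names(x@markers))

#' @describeIn GenotypeMatrix the calls matrix (samples x markers)
#' @export
setMethod("calls", "GenotypeMatrix", function(x) x@calls)

#' @describeIn GenotypeMatrix marker coordinates as GRanges
#' @export
setMethod("markerRanges", "GenotypeMatrix", function(x) x@markers)

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@calls))

#' Subset a GenotypeMatrix by samples (i) and/or markers (j)
#' @param x a GenotypeMatrix
#' @param i,j sample / marker subscripts (ids, indices or logical)
#' @param ... ignored
#' @param drop ignored (never drops)
#' @export
setMethod("[", c("GenotypeMatrix", "ANY", "ANY"), function(x, i, j, ..., drop = FALSE) {
  cl <- x@calls; mk <- x@markers
  if (!missing(i)) cl <- cl[i, , drop = FALSE]
  if (!missing(j)) { cl <- cl[, j, drop = FALSE]; mk <- mk[j] }
  new("GenotypeMatrix", calls = cl, markers = mk)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d markers on %d chromosome(s)\n",
              nrow(object@calls), ncol(object@calls),
              length(unique(as.character(seqnames(object@markers))))))
  cat(sprintf("  overall call rate %.3f\n",
              mean(!is.na(object@calls))))
})

#' @describeIn Pedigree the underlying data.frame
#' @param x a Pedigree
#' @export
setMethod("pedTable", "Pedigree", function(x) x@tbl)

#' @describeIn Pedigree all individual ids
#' @export
setMethod("pedIds", "Pedigree", function(x) x@tbl$id)

#' @describeIn Pedigree ids of affected individuals
#' @export
setMethod("affectedIds", "Pedigree", function(x) x@tbl$id[x@tbl$phenotype == "affected"])

#' @describeIn Pedigree ids of founders (both parents unknown)
#' @export
setMethod("founderIds", "Pedigree", function(x)
  x@tbl$id[is.na(x@tbl$sire) & is.na(x@tbl$dam)])

#' @describeIn Pedigree named c(sire, dam) of one individual (NA if unknown)
#' @param id individual id
#' @export
setMethod("parentsOf", "Pedigree", function(x, id) {
  row <- x@tbl[match(id, x@tbl$id), ]
  c(sire = row$sire, dam = row$dam)
})

setMethod("show", "Pedigree", function(object) {
  tb <- object@tbl
  cat(sprintf("Pedigree: %d individuals (%d affected, %d founders)\n",
              nrow(tb), sum(tb$phenotype == "affected"),
              sum(is.na(tb$sire) & is.na(tb$dam))))
})

#' @describeIn VariantTable variant identifiers (chrom:pos:ref:alt)
#' @param x a VariantTable
#' @export
setMethod("variantIds", "VariantTable", function(x) rownames(x@info))

#' @describeIn VariantTable per-variant info data.frame
#' @export
setMethod("variantInfo", "VariantTable", function(x) x@info)

#' @describeIn VariantTable genotype matrix (variants x samples)
#' @export
setMethod("genotypes", "VariantTable", function(x) x@geno)

#' @describeIn VariantTable sample identifiers
#' @export
setMethod("sampleIds", "VariantTable", function(x) colnames(x@geno))

#' Subset a VariantTable by variants (i) and/or samples (j)
#' @param x a VariantTable
#' @param i,j variant / sample subscripts
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", c("VariantTable", "ANY", "ANY"), function(x, i, j, ..., drop = FALSE) {
  info <- x@info; g <- x@geno
  if (!missing(i)) { info <- info[i, , drop = FALSE]; g <- g[i, , drop = FALSE] }
  if (!missing(j)) g <- g[, j, drop = FALSE]
  new("VariantTable", info = info, geno = g)
})

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d variant(s) x %d sample(s)\n",
              nrow(object@info), ncol(object@geno)))
  if (nrow(object@info))
    print(utils::head(object@info, 5))
})

#' @describeIn TranscriptModel cached spliced CDS (transcript orientation)
#' @param x a TranscriptModel
#' @export
setMethod("splicedCds", "TranscriptModel", function(x) x@cds)

#' @describeIn TranscriptModel cached reference protein (no stop residue)
#' @export
setMethod("refProtein", "TranscriptModel", function(x) x@protein)

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s (gene %s) %s%s: %d exon(s), CDS %d nt%s\n",
              object@transcriptId, object@geneId, object@chrom, object@strand,
              length(object@exons), length(object@cds),
              if (object@translatable)
                sprintf(", protein %d aa", length(object@protein))
              else " [non-translatable]"))
})
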