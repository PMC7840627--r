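## VCF 4.2 ingest (via VariantAnnotation) and emission. Multiallelic sites
## are decomposed into one biallelic record per ALT allele; the per-sample
## genotype of each decomposed record is the count of that ALT allele in the
## GT field, so the total non-reference allele count per sample is conserved.
## Phased separators ("|") are accepted but phase is discarded: phase is
## recomputed from trios downstream.

#' Read a VCF file into a VariantTable
#'
#' @param path path to an (uncompressed or bgzipped) VCF 4.2 file.
#' @return A \linkS4class{VariantTable}; multiallelic records decomposed,
#'   genotypes recoded to 0/1/2/NA, and per-variant \code{geneId} /
#'   \code{effectClass} taken from INFO fields \code{GENE} / \code{EFFECT}
#'   when present.
#' @export
readVcfFile <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(seqnames(rr))
  pos <- start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  inf <- VariantAnnotation::info(vcf)
  gene <- if ("GENE" %in% names(inf)) unlist(lapply(inf$GENE, `[`, 1)) else
    rep(NA_character_, length(rr))
  eff <- if ("EFFECT" %in% names(inf)) unlist(lapply(inf$EFFECT, `[`, 1)) else
    rep(NA_character_, length(rr))
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT,
                 error = function(e) NULL)
  if (is.null(gt)) gt <- matrix(character(), nrow = length(rr), ncol = 0)
  smp <- colnames(gt)

  out <- list(); k <- 0L
  for (i in seq_along(rr)) {
    alts <- as.character(altL[[i]])
    gti <- gt[i, ]
    acounts <- lapply(seq_along(alts), function(a) alleleCount(gti, a, i))
    for (a in seq_along(alts)) {
      k <- k + 1L
      out[[k]] <- list(chrom = chrom[i], pos = pos[i], ref = ref[i],
                       alt = alts[a], geneId = gene[i], effectClass = eff[i],
                       geno = acounts[[a]])
    }
  }
  geno <- do.call(rbind, lapply(out, `[[`, "geno"))
  if (is.null(geno)) geno <- matrix(integer(), nrow = 0, ncol = length(smp))
  colnames(geno) <- smp
  VariantTable(chrom = vapply(out, `[[`, "", "chrom"),
               pos = vapply(out, `[[`, 1L, "pos"),
               ref = vapply(out, `[[`, "", "ref"),
               alt = vapply(out, `[[`, "", "alt"),
               geno = geno,
               geneId = vapply(out, `[[`, "", "geneId"),
               effectClass = vapply(out, `[[`, "", "effectClass"))
}

## count of ALT allele index 'a' per sample from GT strings; NA when any
## called allele is missing
alleleCount <- function(gtRow, a, recIdx) {
  if (!length(gtRow)) return(integer(0))
  ok <- grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gtRow)
  if (any(!ok))
    stop(sprintf("malformed GT field '%s' in VCF record %d",
                 gtRow[which(!ok)[1]], recIdx))
  vapply(strsplit(gtRow, "[/|]"), function(al) {
    if (any(al == ".")) NA_integer_ else sum(al == as.character(a))
  }, 1L)
}

#' Write a VariantTable as VCF 4.2
#'
#' Emits one biallelic record per variant with GT genotypes
#' (0/0, 0/1, 1/1, ./.) and INFO fields GENE / EFFECT where annotated.
#'
#' @param vt a \linkS4class{VariantTable}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeVcfFile <- function(vt, path) {
  info <- variantInfo(vt)
  g <- genotypes(vt)
  smp <- colnames(g)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(info$chrom), ">"),
           '##INFO=<ID=GENE,Number=1,Type=String,Description="Annotated gene id">',
           '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Annotated effect class">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (length(smp)) c("FORMAT", smp)), collapse = "\t"))
  ord <- order(info$chrom, info$pos)
  gtStr <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(ord, function(i) {
    infoStr <- paste(c(
      if (!is.na(info$geneId[i])) paste0("GENE=", info$geneId[i]),
      if (!is.na(info$effectClass[i])) paste0("EFFECT=", info$effectClass[i])),
      collapse = ";")
    if (!nzchar(infoStr)) infoStr <- "."
    fields <- c(info$chrom[i], info$pos[i], rownames(info)[i], info$ref[i],
                info$alt[i], ".", "PASS", infoStr)
    if (length(smp)) {
      gi <- g[i, ]
      fields <- c(fields, "GT",
                  ifelse(is.na(gi), "./.", gtStr[as.character(gi)]))
    }
    paste(fields, collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
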