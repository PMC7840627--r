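## Gene model (exon/CDS) I/O: GFF3 in via rtracklayer, FASTA via Biostrings.
## A TranscriptModel caches its spliced CDS and protein at construction;
## models whose CDS length is not a multiple of 3 (or that contain an
## internal stop) are flagged non-translatable with a warning rather than
## rejected.

#' @importFrom Biostrings DNAString DNAStringSet AAString readDNAStringSet
#'   writeXStringSet reverseComplement subseq translate
NULL

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneId,chrom identifiers.
#' @param strand "+" or "-".
#' @param exonStarts,exonEnds genomic 1-based exon bounds, ascending.
#' @param cdsStart,cdsEnd genomic 1-based CDS bounds (cdsStart <= cdsEnd in
#'   genomic coordinates, regardless of strand).
#' @param genome a \code{DNAStringSet} containing \code{chrom}.
#' @return A \linkS4class{TranscriptModel} with cached spliced CDS and
#'   protein.
#' @export
makeTranscriptModel <- function(transcriptId, geneId, chrom, strand,
                                exonStarts, exonEnds, cdsStart, cdsEnd,
                                genome) {
  stopifnot(chrom %in% names(genome))
  exons <- IRanges(as.integer(exonStarts), as.integer(exonEnds))
  chromSeq <- genome[[chrom]]
  cdsRanges <- IRanges::intersect(exons, IRanges(cdsStart, cdsEnd))
  pieces <- lapply(seq_along(cdsRanges), function(i)
    subseq(chromSeq, IRanges::start(cdsRanges)[i], IRanges::end(cdsRanges)[i]))
  cds <- do.call(Biostrings::xscat, pieces)
  if (strand == "-") cds <- reverseComplement(cds)
  cds <- DNAString(as.character(cds))

  translatable <- TRUE
  protein <- AAString("")
  if (length(cds) %% 3L != 0L) {
    warning(sprintf("transcript %s: CDS length %d not divisible by 3; flagged non-translatable",
                    transcriptId, length(cds)))
    translatable <- FALSE
  } else {
    aa <- as.character(translate(DNAStringSet(cds), if.fuzzy.codon = "X")[[1]])
    body <- sub("\\*$", "", aa)
    if (grepl("\\*", body)) {
      warning(sprintf("transcript %s: internal stop codon in reference CDS; flagged non-translatable",
                      transcriptId))
      translatable <- FALSE
    } else {
      protein <- AAString(body)
    }
  }
  new("TranscriptModel", transcriptId = transcriptId, geneId = geneId,
      chrom = chrom, strand = strand, exons = exons,
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd),
      chromSeq = chromSeq, cds = cds, protein = protein,
      translatable = translatable)
}

#' Read transcript models from GFF3 + FASTA
#'
#' Expects conventional gene/mRNA/exon/CDS features with ID/Parent
#' attributes; exon and CDS features are grouped by their Parent transcript.
#'
#' @param gffPath path to a GFF3 file.
#' @param fastaPath path to the matching FASTA (sequence names must cover the
#'   transcript chromosomes).
#' @return A named list of \linkS4class{TranscriptModel}.
#' @export
readGeneModels <- function(gffPath, fastaPath) {
  genome <- readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gffPath)
  type <- as.character(gr$type)
  mrna <- gr[type == "mRNA"]
  txIds <- as.character(mrna$ID)
  parent1 <- function(x) vapply(x, function(p) if (length(p)) p[1] else NA_character_, "")
  geneOf <- setNames(parent1(mrna$Parent), txIds)
  models <- list()
  for (tx in txIds) {
    sel <- vapply(gr$Parent, function(p) tx %in% p, TRUE)
    ex <- gr[type == "exon" & sel]
    cds <- gr[type == "CDS" & sel]
    if (!length(ex) || !length(cds))
      stop(sprintf("transcript %s: missing exon or CDS features", tx))
    ex <- sort(ex)
    models[[tx]] <- makeTranscriptModel(
      transcriptId = tx, geneId = geneOf[[tx]],
      chrom = as.character(seqnames(ex))[1],
      strand = as.character(BiocGenerics::strand(ex))[1],
      exonStarts = start(ex), exonEnds = end(ex),
      cdsStart = min(start(cds)), cdsEnd = max(end(cds)),
      genome = genome)
  }
  models
}

#' Write transcript models as GFF3 (+ optional FASTA)
#'
#' @param models list of \linkS4class{TranscriptModel} (may share a genome).
#' @param gffPath output GFF3 path.
#' @param fastaPath optional output FASTA path for the chromosome sequences.
#' @return Invisibly, the GFF3 path.
#' @export
writeGeneModels <- function(models, gffPath, fastaPath = NULL) {
  rows <- c("##gff-version 3")
  genes <- unique(vapply(models, function(m) m@geneId, ""))
  for (g in genes) {
    mg <- Filter(function(m) m@geneId == g, models)
    sp <- range(unlist(lapply(mg, function(m)
      c(IRanges::start(m@exons), IRanges::end(m@exons)))))
    st <- mg[[1]]@strand
    rows <- c(rows, paste(mg[[1]]@chrom, "comphet", "gene", sp[1], sp[2], ".",
                          st, ".", paste0("ID=", g), sep = "\t"))
    for (m in mg) {
      rows <- c(rows, paste(m@chrom, "comphet", "mRNA",
                            min(IRanges::start(m@exons)), max(IRanges::end(m@exons)),
                            ".", st, ".",
                            paste0("ID=", m@transcriptId, ";Parent=", g), sep = "\t"))
      for (i in seq_along(m@exons))
        rows <- c(rows, paste(m@chrom, "comphet", "exon",
                              IRanges::start(m@exons)[i], IRanges::end(m@exons)[i],
                              ".", st, ".",
                              paste0("Parent=", m@transcriptId), sep = "\t"))
      cdsR <- IRanges::intersect(m@exons, IRanges(m@cdsStart, m@cdsEnd))
      for (i in seq_along(cdsR))
        rows <- c(rows, paste(m@chrom, "comphet", "CDS",
                              IRanges::start(cdsR)[i], IRanges::end(cdsR)[i],
                              ".", st, "0",
                              paste0("Parent=", m@transcriptId), sep = "\t"))
    }
  }
  writeLines(rows, gffPath)
  if (!is.null(fastaPath)) {
    chroms <- unique(vapply(models, function(m) m@chrom, ""))
    seqs <- DNAStringSet(lapply(chroms, function(ch) {
      m <- Filter(function(x) x@chrom == ch, models)[[1]]
      m@chromSeq
    }))
    names(seqs) <- chroms
    writeXStringSet(seqs, fastaPath)
  }
  invisible(gffPath)
}
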