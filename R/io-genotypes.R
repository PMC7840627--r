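## PLINK text-dialect PED/MAP and simple TSV genotype I/O.
## PED alleles are written as A (reference) / B (alternate), missing as "0 0";
## the reader accepts arbitrary allele letters, taking "A" (or, failing that,
## the alphabetically first observed allele) as the reference allele, so that
## write -> read is the identity for matrices written by this package.

#' Read PLINK-style PED + MAP genotypes
#'
#' @param pedPath path to a whitespace-separated PED file (6 leading columns:
#'   family, id, sire, dam, sex, phenotype; then two allele columns per marker;
#'   "0 0" encodes a missing call).
#' @param mapPath path to the matching MAP file (chrom, marker id, cM, pos).
#' @param refAllele allele treated as reference at each marker; default "A"
#'   (the writer's convention). If absent at a marker, the alphabetically
#'   first observed allele is used.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypesPed <- function(pedPath, mapPath, refAllele = "A") {
  map <- utils::read.table(mapPath, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"))
  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nm <- nrow(map)
  want <- 6L + 2L * nm
  for (i in seq_along(toks))
    if (length(toks[[i]]) != want)
      stop(sprintf(
        "PED format error at line %d: %d fields, expected %d (6 + 2 x %d markers)",
        i, length(toks[[i]]), want, nm))
  ped <- do.call(rbind, toks)
  ids <- ped[, 2]
  a1 <- ped[, 6L + 2L * seq_len(nm) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(nm), drop = FALSE]
  calls <- matrix(NA_integer_, nrow = length(ids), ncol = nm,
                  dimnames = list(ids, map$id))
  for (j in seq_len(nm)) {
    obs <- setdiff(unique(c(a1[, j], a2[, j])), "0")
    ref <- if (refAllele %in% obs || !length(obs)) refAllele else sort(obs)[1]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    calls[, j] <- (a1[, j] != ref) + (a2[, j] != ref)
    calls[miss, j] <- NA_integer_
  }
  GenotypeMatrix(calls, chrom = as.character(map$chrom), pos = map$pos,
                 markerIds = map$id)
}

#' Write a GenotypeMatrix as PLINK-style PED + MAP
#'
#' Alleles are emitted as A (reference) / B (alternate); missing calls as
#' "0 0". Pedigree columns are filled from \code{ped} when supplied,
#' otherwise zeroed.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param pedPath,mapPath output paths.
#' @param ped optional \linkS4class{Pedigree} for the six leading columns.
#' @return Invisibly, the PED path.
#' @export
writeGenotypesPed <- function(gm, pedPath, mapPath, ped = NULL) {
  mk <- markerRanges(gm)
  utils::write.table(
    data.frame(as.character(seqnames(mk)), names(mk), 0, start(mk)),
    mapPath, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  cl <- calls(gm)
  lead <- famColumns(ped, rownames(cl))
  con <- file(pedPath, "w"); on.exit(close(con))
  codes <- rbind(`0` = c("A", "A"), `1` = c("A", "B"), `2` = c("B", "B"))
  for (i in seq_len(nrow(cl))) {
    g <- cl[i, ]
    al <- matrix("0", nrow = 2, ncol = length(g))
    ok <- !is.na(g)
    al[, ok] <- t(codes[as.character(g[ok]), , drop = FALSE])
    writeLines(paste(c(unlist(lead[i, ]), as.vector(al)), collapse = " "), con)
  }
  invisible(pedPath)
}

famColumns <- function(ped, ids) {
  sexCode <- c(male = 1L, female = 2L, unknown = 0L)
  pheCode <- c(unaffected = 1L, affected = 2L, unknown = 0L)
  if (is.null(ped)) {
    data.frame(fam = "FAM1", id = ids, sire = "0", dam = "0",
               sex = 0L, phe = 0L, stringsAsFactors = FALSE)
  } else {
    tb <- pedTable(ped)
    row <- tb[match(ids, tb$id), ]
    data.frame(fam = "FAM1", id = ids,
               sire = ifelse(is.na(row$sire), "0", row$sire),
               dam = ifelse(is.na(row$dam), "0", row$dam),
               sex = unname(sexCode[row$sex]),
               phe = unname(pheCode[row$phenotype]), stringsAsFactors = FALSE)
  }
}

#' Read / write genotypes as a plain TSV of 0/1/2/NA codes
#'
#' Tabular alternative to the PED dialect: first three columns chrom, pos,
#' marker id, then one column per sample.
#'
#' @param path file path.
#' @return \code{readGenotypesTsv}: a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypesTsv <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  calls <- t(as.matrix(tb[, -(1:3), drop = FALSE]))
  GenotypeMatrix(calls, chrom = as.character(tb[[1]]), pos = tb[[2]],
                 markerIds = as.character(tb[[3]]))
}

#' @rdname readGenotypesTsv
#' @param gm a \linkS4class{GenotypeMatrix} to write.
#' @export
writeGenotypesTsv <- function(gm, path) {
  mk <- markerRanges(gm)
  tb <- data.frame(chrom = as.character(seqnames(mk)), pos = start(mk),
                   marker = names(mk), check.names = FALSE)
  tb <- cbind(tb, as.data.frame(t(calls(gm))))
  utils::write.table(tb, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read / write a FAM-format pedigree
#'
#' Standard six-column FAM: family, id, sire, dam, sex (1/2/0),
#' phenotype (2 = affected, 1 = unaffected, 0/-9 = unknown). "0" parents
#' are unknown.
#'
#' @param path file path.
#' @return \code{readFam}: a \linkS4class{Pedigree}.
#' @export
readFam <- function(path) {
  tb <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("fam", "id", "sire", "dam", "sex", "phe"))
  Pedigree(id = tb$id,
           sire = ifelse(tb$sire == "0", NA, tb$sire),
           dam = ifelse(tb$dam == "0", NA, tb$dam),
           sex = c("unknown", "male", "female")[match(tb$sex, c(0, 1, 2))],
           phenotype = ifelse(tb$phe == 2, "affected",
                       ifelse(tb$phe == 1, "unaffected", "unknown")))
}

#' @rdname readFam
#' @param ped a \linkS4class{Pedigree} to write.
#' @export
writeFam <- function(ped, path) {
  tb <- famColumns(ped, pedIds(ped))
  utils::write.table(tb, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
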