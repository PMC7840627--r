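## HGVS c./p. formatting and parsing. Protein notation uses 3-letter amino
## acid codes with "Ter" for stop ("*" is accepted on input and normalised
## to Ter). Coding-DNA notation supports intronic offsets (c.210-2A>G) and
## UTR coordinates (c.-12, c.*33). Every string the package emits is
## parseable by these parsers (round-trip identity).

AA_3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter", X = "Xaa")
AA_1 <- setNames(names(AA_3), AA_3)

aa3 <- function(x) unname(AA_3[x])

#' Format / parse HGVS coding-DNA single-nucleotide changes
#'
#' @param baseLabel coding coordinate label: "210" (CDS), "-12" (5'UTR) or
#'   "*33" (3'UTR).
#' @param offset intronic offset (0 for exonic positions).
#' @param ref,alt transcript-strand alleles.
#' @return \code{formatHgvsC}: the c. string, e.g. "c.210-2A>G".
#' @export
formatHgvsC <- function(baseLabel, offset, ref, alt) {
  off <- if (offset == 0) "" else sprintf("%+d", offset)
  paste0("c.", baseLabel, off, ref, ">", alt)
}

#' @rdname formatHgvsC
#' @param x an HGVS c. string.
#' @return \code{parseHgvsC}: list(baseLabel, offset, ref, alt).
#' @export
parseHgvsC <- function(x) {
  m <- regmatches(x, regexec(
    "^c\\.(\\*?-?[0-9]+)([+-][0-9]+)?([ACGT])>([ACGT])$", x))[[1]]
  if (!length(m)) stop(sprintf("unparseable HGVS c. string: '%s'", x))
  list(baseLabel = m[2],
       offset = if (nzchar(m[3])) as.integer(m[3]) else 0L,
       ref = m[4], alt = m[5])
}

#' Format / parse HGVS protein changes
#'
#' Supported forms: identity "p.(=)"; substitution "p.Leu396Phe" /
#' "p.Gln396Ter"; frameshift "p.Leu71TrpfsTer3" (Ter index counts the first
#' changed residue as 1; "fsTer?" when no stop is reached).
#'
#' @param refAa,newAa single-letter amino acids ("*" for stop).
#' @param pos 1-based residue position.
#' @param fsTer for frameshifts, the stop index in the new frame (integer or
#'   "?"); NULL for plain substitutions.
#' @return \code{formatHgvsP}: the p. string.
#' @export
formatHgvsP <- function(refAa, pos, newAa, fsTer = NULL) {
  if (is.null(fsTer))
    paste0("p.", aa3(refAa), pos, aa3(newAa))
  else
    paste0("p.", aa3(refAa), pos, aa3(newAa), "fsTer", fsTer)
}

#' @rdname formatHgvsP
#' @param x an HGVS p. string ("*" accepted for Ter on input).
#' @return \code{parseHgvsP}: list(kind = "identity"/"substitution"/
#'   "frameshift", refAa, pos, newAa (single-letter), fsTer).
#' @export
parseHgvsP <- function(x) {
  if (x == "p.(=)")
    return(list(kind = "identity", refAa = NA, pos = NA, newAa = NA, fsTer = NULL))
  x2 <- gsub("\\*", "Ter", x)
  m <- regmatches(x2, regexec(
    "^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})fsTer([0-9]+|\\?)$", x2))[[1]]
  if (length(m))
    return(list(kind = "frameshift", refAa = unname(AA_1[m[2]]),
                pos = as.integer(m[3]), newAa = unname(AA_1[m[4]]),
                fsTer = if (m[5] == "?") "?" else as.integer(m[5])))
  m <- regmatches(x2, regexec(
    "^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", x2))[[1]]
  if (length(m))
    return(list(kind = "substitution", refAa = unname(AA_1[m[2]]),
                pos = as.integer(m[3]), newAa = unname(AA_1[m[4]]),
                fsTer = NULL))
  stop(sprintf("unparseable HGVS p. string: '%s'", x))
}
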