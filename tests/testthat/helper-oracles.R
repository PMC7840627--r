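# Independent oracles used across the suite. These deliberately use
# brute-force enumeration / naive code paths, never the package's own
# estimators.

# alleles of a genotype code, slot 1 = ref copy where het
allelesOf <- function(g) switch(as.character(g),
                                "0" = c(0L, 0L), "1" = c(0L, 1L),
                                "2" = c(1L, 1L))

# Exhaustive-enumeration oracle for the pairwise sharing statistic on a
# fully genotyped sire + dams + children pedigree: enumerate all
# transmission slot configurations consistent with the genotypes (uniform
# prior over the 4^k configurations), and average the IBD count through
# shared parents over the consistent ones. Children with missing genotype
# are unconstrained.
enumSharingOracle <- function(sg, damG, childG, damOf) {
  k <- length(childG)
  sAl <- allelesOf(sg)
  dAl <- lapply(damG, allelesOf)
  slots <- expand.grid(rep(list(1:2), 2 * k))
  consistent <- apply(slots, 1, function(sl) {
    for (i in seq_len(k)) {
      if (is.na(childG[i])) next
      a <- sAl[sl[i]]
      b <- dAl[[damOf[i]]][sl[k + i]]
      if (a + b != childG[i]) return(FALSE)
    }
    TRUE
  })
  sl <- slots[consistent, , drop = FALSE]
  if (!nrow(sl)) return(NA_real_)
  Svals <- apply(sl, 1, function(s) {
    tot <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      tot <- tot + (s[i] == s[j])                      # shared sire
      if (damOf[i] == damOf[j]) tot <- tot + (s[k + i] == s[k + j])
    }
    tot
  })
  mean(Svals)
}

# Enumeration oracle for trio phasing over genotype codes (0/1/2):
# enumerate which parent transmitted the alt allele across all consistent
# transmissions.
enumPhaseOracle <- function(cg, sg, dg) {
  if (cg != 1L) return("not_applicable")
  pat <- (sg >= 1L) && (dg <= 1L)   # sire can give alt AND dam can give ref
  mat <- (dg >= 1L) && (sg <= 1L)
  if (pat && !mat) "paternal"
  else if (mat && !pat) "maternal"
  else if (pat && mat) "ambiguous"
  else "inconsistent"
}

# Naive codon-by-codon translator (independent of Biostrings::translate)
bruteTranslate <- function(dna) {
  codonTable <- c(
    TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
    ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
    TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
    ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
    TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
    AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
    TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
    AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  s <- toupper(as.character(dna))
  n <- nchar(s) %/% 3
  out <- character(n)
  for (i in seq_len(n)) {
    aa <- codonTable[substr(s, 3 * i - 2, 3 * i)]
    out[i] <- aa
    if (aa == "*") return(paste(out[1:i], collapse = ""))
  }
  paste(out, collapse = "")
}

# small deterministic GenotypeMatrix builder
tinyGm <- function(calls, chrom = NULL, pos = NULL) {
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  GenotypeMatrix(calls, chrom = chrom, pos = pos)
}

# simulate genotypes for a sire + dams + children family at one marker
# (used to generate consistent configurations for the enumeration oracle)
dropFamilyMarker <- function(nDams, damOf, freq) {
  g <- function() sum(stats::rbinom(2, 1, freq))
  sAl <- stats::rbinom(2, 1, freq)
  dAl <- replicate(nDams, stats::rbinom(2, 1, freq), simplify = FALSE)
  k <- length(damOf)
  childG <- integer(k)
  for (i in seq_len(k))
    childG[i] <- sAl[sample(2, 1)] + dAl[[damOf[i]]][sample(2, 1)]
  list(sg = sum(sAl), damG = vapply(dAl, sum, 1L), childG = childG)
}
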