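## Constructed fixtures: the candidate-funnel variant set (planted so the
## local/global privacy and inheritance filters reproduce the 6 -> 4 stage
## counts), the 71-animal two-variant census fixture, and toy gene models
## whose structural properties (10-base cryptic-acceptor deletion, 54-codon
## insert exon with a dual missense/nonsense SNV) are verified at
## generation time.

## Family variant set for the sequenced trios (sire, two dams, two cases).
## Causal genotypes may be supplied (from a simulation's truth); decoys are
## planted patterns. Count tables carry the control-cohort carrier numbers.
funnelVariantSet <- function(sireId, damIds, caseIds, chromCausal, posA, posB,
                             mode = "compound_het", withDecoys = TRUE,
                             nLocal = 60, nGlobal = 453,
                             causalGenoA = NULL, causalGenoB = NULL) {
  smp <- c(sireId, damIds, caseIds)
  nd <- length(damIds); nc <- length(caseIds)
  pat <- function(sire, dam, case) c(sire, rep(dam, nd), rep(case, nc))
  rows <- list()
  addv <- function(chrom, pos, ref, alt, gene, eff, geno, local = 0L,
                   global = 0L)
    rows[[length(rows) + 1L]] <<- list(chrom = chrom, pos = pos, ref = ref,
                                       alt = alt, gene = gene, eff = eff,
                                       geno = geno, local = local,
                                       global = global)
  if (mode == "compound_het") {
    gA <- if (is.null(causalGenoA)) pat(0L, 1L, 1L) else causalGenoA
    gB <- if (is.null(causalGenoB)) pat(1L, 0L, 1L) else causalGenoB
    addv(chromCausal, posA, "T", "C", "GENE_CH", "splice_acceptor", gA)
    addv(chromCausal, posB, "G", "A", "GENE_CH", "missense", gB)
  } else {
    gA <- if (is.null(causalGenoA)) pat(1L, 1L, 2L) else causalGenoA
    addv(chromCausal, posA, "T", "C", "GENE_CH", "splice_acceptor", gA)
  }
  if (withDecoys) {
    ## survive the local funnel, removed by the global cohort:
    addv("5", 41200300L, "C", "T", "GENE_DCH", "missense", pat(1L, 0L, 1L))
    addv("5", 41210450L, "G", "A", "GENE_DCH", "missense", pat(0L, 1L, 1L),
         global = 3L)
    addv("9", 12345678L, "A", "G", "GENE_R1", "missense", pat(1L, 1L, 2L))
    addv("12", 6543210L, "C", "G", "GENE_R2", "missense", pat(1L, 1L, 2L),
         global = 5L)
    ## removed before the inheritance stage:
    addv("7", 22000100L, "T", "A", "GENE_S", "synonymous", pat(1L, 0L, 1L))
    addv("2", 90000200L, "G", "C", "GENE_L", "missense", pat(0L, 1L, 1L),
         local = 2L, global = 10L)
    addv("4", 70000300L, "A", "T", "GENE_P", "missense",
         c(1L, rep(0L, nd), 1L, rep(0L, nc - 1L)))
    addv("6", 30000400L, "C", "A", "GENE_N", "non_coding", pat(0L, 1L, 1L))
  }
  geno <- do.call(rbind, lapply(rows, `[[`, "geno"))
  colnames(geno) <- smp
  vt <- VariantTable(chrom = vapply(rows, `[[`, "", "chrom"),
                     pos = vapply(rows, function(r) as.integer(r$pos), 1L),
                     ref = vapply(rows, `[[`, "", "ref"),
                     alt = vapply(rows, `[[`, "", "alt"),
                     geno = geno,
                     geneId = vapply(rows, `[[`, "", "gene"),
                     effectClass = vapply(rows, `[[`, "", "eff"))
  ctab <- function(col, n) data.frame(
    chrom = variantInfo(vt)$chrom, pos = variantInfo(vt)$pos,
    ref = variantInfo(vt)$ref, alt = variantInfo(vt)$alt,
    nCarriers = vapply(rows, function(r) as.integer(r[[col]]), 1L),
    nSamples = n, stringsAsFactors = FALSE)
  list(vt = vt, local = ctab("local", nLocal), global = ctab("global", nGlobal))
}

#' Candidate-funnel fixture reproducing the 6 -> 4 stage counts
#'
#' A family variant table (sire, two dams, two affected lambs) plus local
#' and global control count tables constructed so that exactly six variants
#' survive the protein-changing + local-privacy + inheritance filter (one
#' compound-het causal pair, one compound-het decoy pair, two recessive
#' decoys), of which two are carried in the global cohort, leaving four;
#' among the four, the recessive decoy lies outside all linked regions and
#' the causal pair inside one.
#'
#' @param withDecoys drop the decoys to collapse the funnel to 1 -> 1
#'   (default TRUE).
#' @return list: vt, local, global (as \code{funnelVariantSet}), ped,
#'   trios, cases, linkedRegions (a region covering the causal pair).
#' @export
makeFunnelFixture <- function(withDecoys = TRUE) {
  sire <- "SIRE"; dams <- c("DAM1", "DAM2"); cases <- c("CASE1", "CASE2")
  posA <- 230766713L; posB <- 230750869L
  fam <- funnelVariantSet(sire, dams, cases, chromCausal = "3",
                          posA = posA, posB = posB, withDecoys = withDecoys)
  ped <- Pedigree(
    id = c("GS", "ED1", "ED2", sire, dams, cases),
    sire = c(NA, NA, NA, NA, "GS", "GS", sire, sire),
    dam = c(NA, NA, NA, NA, "ED1", "ED2", "DAM1", "DAM2"),
    sex = c("male", "female", "female", "male", "female", "female",
            "male", "female"),
    phenotype = c(rep("unknown", 3), "unaffected", "unaffected",
                  "unaffected", "affected", "affected"))
  trios <- data.frame(child = cases, sire = sire, dam = dams,
                      stringsAsFactors = FALSE)
  linkedRegions <- data.frame(chrom = "3", start = posB - 2e6,
                              end = posA + 2e6, stringsAsFactors = FALSE)
  c(fam, list(ped = ped, trios = trios, cases = cases,
              linkedRegions = linkedRegions))
}

#' The 71-animal two-variant segregation fixture
#'
#' Pedigree and genotype table for the full flock exactly as censused: 52
#' ewes (27 heterozygous for the intron-2 variant A, 25 wild type), the
#' sire heterozygous for the exon-8 variant B, 5 affected lambs carrying
#' both variants, and 13 unaffected lambs (3 wild type, 7 het B, 3 het A).
#' All lambs are sired by the ram; the dams of the affected lambs (and of
#' the het-A unaffected lambs) are carrier ewes; the ungenotyped maternal
#' grandsire is a phantom pedigree row.
#'
#' @return list: ped (\linkS4class{Pedigree}), vt (2-variant
#'   \linkS4class{VariantTable} over all 71 genotyped animals), plus the
#'   id sets (ewes, affectedLambs, unaffectedLambs, sire).
#' @export
encodeFig2aFixture <- function() {
  ewes <- sprintf("E%02d", 1:52)
  carriers <- ewes[1:27]
  affected <- sprintf("LA%d", 1:5)
  unaffected <- sprintf("LU%02d", 1:13)
  hetA_lambs <- unaffected[1:3]       # carry the intron-2 variant
  hetB_lambs <- unaffected[4:10]      # carry the exon-8 variant
  wt_lambs <- unaffected[11:13]
  lambs <- c(affected, unaffected)
  damOf <- stats::setNames(c(carriers[1:5], carriers[6:8], ewes[28:34],
                             ewes[35:37]),
                           c(affected, hetA_lambs, hetB_lambs, wt_lambs))
  eweDams <- sprintf("ED%02d", 1:52)
  ped <- Pedigree(
    id = c("GS", eweDams, "SIRE", ewes, lambs),
    sire = c(NA, rep(NA, 52), NA, rep("GS", 52), rep("SIRE", 18)),
    dam = c(NA, rep(NA, 52), NA, eweDams, unname(damOf[lambs])),
    sex = c("male", rep("female", 52), "male", rep("female", 52),
            rep("unknown", 18)),
    phenotype = c(rep("unknown", 53), "unaffected", rep("unaffected", 52),
                  rep("affected", 5), rep("unaffected", 13)))
  genotyped <- c("SIRE", ewes, lambs)
  gA <- stats::setNames(rep(0L, length(genotyped)), genotyped)
  gB <- gA
  gA[c(carriers, affected, hetA_lambs)] <- 1L
  gB[c("SIRE", affected, hetB_lambs)] <- 1L
  vt <- VariantTable(chrom = c("3", "3"), pos = c(230766713L, 230750869L),
                     ref = c("T", "G"), alt = c("C", "A"),
                     geno = rbind(gA, gB), geneId = "PLA2G6",
                     effectClass = c("splice_acceptor", "missense"))
  list(ped = ped, vt = vt, ewes = ewes, sire = "SIRE",
       affectedLambs = affected, unaffectedLambs = unaffected,
       carrierEwes = carriers)
}

## random in-frame codon soup without stop codons
randomCodons <- function(n) {
  bases <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  ok <- setdiff(all3, c("TAA", "TAG", "TGA"))
  paste(sample(ok, n, replace = TRUE), collapse = "")
}

randomBases <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

## genomic intron: canonical GT ... AG
mkIntron <- function(n) paste0("GT", randomBases(n - 4L), "AG")

#' Toy gene models for the consequence engine
#'
#' Builds, with construction-time verification: (a) a 4-exon gene whose
#' exon-3 acceptor loss activates a cryptic AG at exon positions 9-10,
#' deleting exactly 10 bases and truncating the 752-residue protein to 72
#' residues (p.Leu71TrpfsTer3); (b) a two-isoform gene sharing all exons
#' except a 54-codon in-frame insert exon, with a single genomic SNV that
#' is missense (Leu>Phe) on the insert-bearing isoform and nonsense
#' (Gln>Ter) on the short one; (c) reverse-strand mirrors of both.
#'
#' @param seed integer seed for the random sequence background.
#' @return list: models (named list of \linkS4class{TranscriptModel}),
#'   genome (\code{DNAStringSet}), variants (data.frame of the planted
#'   SNVs with chrom, pos, ref, alt and the mirrored copies).
#' @export
makeToyGenes <- function(seed = 1) {
  set.seed(seed)
  ## ---- gene (a): acceptor-loss / cryptic-site gene, + strand ----------
  cdsA <- strsplit(randomCodons(753L), "")[[1]]       # 752 aa + stop
  cdsA[1:3] <- c("A", "T", "G")
  cdsA[211:229] <- strsplit("CTTCCCCAAGTGGGCTTAA", "")[[1]]
  cdsA[2257:2259] <- c("T", "A", "A")
  cdsA <- paste(cdsA, collapse = "")
  utr5 <- randomBases(50L); utr3 <- randomBases(60L)
  i1 <- mkIntron(200L); i2 <- mkIntron(300L); i3 <- mkIntron(250L)
  flank <- randomBases(100L)
  seqA <- paste0(flank,
                 utr5, substr(cdsA, 1, 100), i1,
                 substr(cdsA, 101, 210), i2,
                 substr(cdsA, 211, 420), i3,
                 substr(cdsA, 421, 2259), utr3, flank)
  e1s <- 101L; e1e <- e1s + 50L + 100L - 1L
  e2s <- e1e + 200L + 1L; e2e <- e2s + 110L - 1L
  e3s <- e2e + 300L + 1L; e3e <- e3s + 210L - 1L
  e4s <- e3e + 250L + 1L; e4e <- e4s + 1839L + 60L - 1L
  genome <- list(toyA = seqA)
  modA <- function(genomeSet) makeTranscriptModel(
    "TOYA.1", "TOYA", "toyA", "+", c(e1s, e2s, e3s, e4s),
    c(e1e, e2e, e3e, e4e), e1s + 50L, e4e - 60L, genomeSet)
  varA <- list(chrom = "toyA", pos = e3s - 2L, ref = "A", alt = "G")

  ## ---- gene (b): two isoforms, 54-codon insert exon, + strand ---------
  cdsS <- strsplit(randomCodons(753L), "")[[1]]
  cdsS[1:3] <- c("A", "T", "G")
  cdsS[1186:1188] <- c("C", "A", "G")                  # Gln396, junction codon
  cdsS[2257:2259] <- c("T", "A", "A")
  cdsS <- paste(cdsS, collapse = "")
  insert <- paste0("TT", paste(sample(c("CCT", "CCA", "CCG", "CCC"), 53L,
                                      replace = TRUE), collapse = ""), "C")
  stopifnot(nchar(insert) == 162L)
  utr5b <- randomBases(30L); utr3b <- randomBases(40L)
  j1 <- mkIntron(180L); j2a <- mkIntron(150L); j2b <- mkIntron(160L)
  j3 <- mkIntron(140L)
  seqB <- paste0(flank,
                 utr5b, substr(cdsS, 1, 600), j1,
                 substr(cdsS, 601, 1186), j2a,
                 insert, j2b,
                 substr(cdsS, 1187, 1800), j3,
                 substr(cdsS, 1801, 2259), utr3b, flank)
  b1s <- 101L; b1e <- b1s + 30L + 600L - 1L
  b2s <- b1e + 180L + 1L; b2e <- b2s + 586L - 1L       # CDS 601..1186
  b8s <- b2e + 150L + 1L; b8e <- b8s + 162L - 1L       # insert exon
  b3s <- b8e + 160L + 1L; b3e <- b3s + 614L - 1L       # CDS 1187..1800
  b4s <- b3e + 140L + 1L; b4e <- b4s + 459L + 40L - 1L
  genome$toyB <- seqB
  modBshort <- function(g) makeTranscriptModel(
    "TOYB.short", "TOYB", "toyB", "+", c(b1s, b2s, b3s, b4s),
    c(b1e, b2e, b3e, b4e), b1s + 30L, b4e - 40L, g)
  modBlong <- function(g) makeTranscriptModel(
    "TOYB.long", "TOYB", "toyB", "+", c(b1s, b2s, b8s, b3s, b4s),
    c(b1e, b2e, b8e, b3e, b4e), b1s + 30L, b4e - 40L, g)
  varB <- list(chrom = "toyB", pos = b2e, ref = "C", alt = "T")

  ## ---- reverse-strand mirrors ----------------------------------------
  mirror <- function(seqStr) as.character(reverseComplement(DNAString(seqStr)))
  genome$toyArev <- mirror(seqA)
  genome$toyBrev <- mirror(seqB)
  gset <- DNAStringSet(unlist(genome))
  flipc <- function(L, s, e) c(L - e + 1L, L - s + 1L)
  LA <- nchar(seqA); LB <- nchar(seqB)
  rev1 <- function(L, x) L - x + 1L
  modArev <- makeTranscriptModel(
    "TOYArev.1", "TOYArev", "toyArev", "-",
    rev(rev1(LA, c(e1e, e2e, e3e, e4e))), rev(rev1(LA, c(e1s, e2s, e3s, e4s))),
    rev1(LA, e4e - 60L), rev1(LA, e1s + 50L), gset)
  modBrevShort <- makeTranscriptModel(
    "TOYBrev.short", "TOYBrev", "toyBrev", "-",
    rev(rev1(LB, c(b1e, b2e, b3e, b4e))), rev(rev1(LB, c(b1s, b2s, b3s, b4s))),
    rev1(LB, b4e - 40L), rev1(LB, b1s + 30L), gset)
  modBrevLong <- makeTranscriptModel(
    "TOYBrev.long", "TOYBrev", "toyBrev", "-",
    rev(rev1(LB, c(b1e, b2e, b8e, b3e, b4e))),
    rev(rev1(LB, c(b1s, b2s, b8s, b3s, b4s))),
    rev1(LB, b4e - 40L), rev1(LB, b1s + 30L), gset)

  models <- list(TOYA.1 = modA(gset), TOYB.short = modBshort(gset),
                 TOYB.long = modBlong(gset), TOYArev.1 = modArev,
                 TOYBrev.short = modBrevShort, TOYBrev.long = modBrevLong)

  comp <- function(x) as.character(reverseComplement(DNAString(x)))
  variants <- data.frame(
    name = c("acceptorA", "dualB", "acceptorA.rev", "dualB.rev"),
    chrom = c("toyA", "toyB", "toyArev", "toyBrev"),
    pos = c(varA$pos, varB$pos, rev1(LA, varA$pos), rev1(LB, varB$pos)),
    ref = c(varA$ref, varB$ref, comp(varA$ref), comp(varB$ref)),
    alt = c(varA$alt, varB$alt, comp(varA$alt), comp(varB$alt)),
    stringsAsFactors = FALSE)

  ## construction-time verification of the planted structural properties
  stopifnot(
    all(vapply(models, function(m) m@translatable, TRUE)),
    length(models$TOYA.1@protein) == 752L,
    length(models$TOYB.short@protein) == 752L,
    length(models$TOYB.long@protein) == 752L + 54L,
    length(models$TOYB.long@cds) - length(models$TOYB.short@cds) == 162L,
    as.character(subseq(models$TOYA.1@cds, 211L, 220L)) == "CTTCCCCAAG",
    as.character(subseq(gset[["toyA"]], varA$pos, varA$pos)) == varA$ref,
    as.character(subseq(gset[["toyB"]], varB$pos, varB$pos)) == varB$ref)
  list(models = models, genome = gset, variants = variants)
}
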