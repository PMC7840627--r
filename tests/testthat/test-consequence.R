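tg <- makeToyGenes(seed = 1)
txA <- tg$models$TOYA.1
vA <- tg$variants[tg$variants$name == "acceptorA", ]
vB <- tg$variants[tg$variants$name == "dualB", ]

test_that("genomic -> cDNA mapping: CDS start, intronic offsets, UTRs", {
  ## first CDS base is c.1
  cds1g <- txA@cdsStart
  expect_equal(mapGenomicToCdna(txA, cds1g)$label, "1")
  ## 2 bases upstream of exon 3's first CDS base, acceptor side: c.211-2
  mp <- mapGenomicToCdna(txA, vA$pos)
  expect_equal(mp$region, "intron")
  expect_equal(mp$label, "211-2")
  expect_equal(mp$offset, -2L)
  ## donor side of intron 2: first intron base is c.210+1
  e2end <- IRanges::end(txA@exons)[2]
  expect_equal(mapGenomicToCdna(txA, e2end + 1L)$label, "210+1")
  ## UTRs
  expect_equal(mapGenomicToCdna(txA, txA@cdsStart - 1L)$label, "-1")
  expect_equal(mapGenomicToCdna(txA, txA@cdsEnd + 1L)$label, "*1")
  ## outside the transcript span
  expect_equal(mapGenomicToCdna(txA, 1L)$region, "outside")
})

test_that("SNV classification covers splice, missense, nonsense, synonymous, start/stop", {
  expect_equal(classifySnv(txA, vA$pos, vA$ref, vA$alt), "splice_acceptor")
  ## exon 2 last base +1/+2 are donor positions
  e2end <- IRanges::end(txA@exons)[2]
  don <- as.character(Biostrings::subseq(txA@chromSeq, e2end + 1L, e2end + 1L))
  expect_equal(classifySnv(txA, e2end + 1L, don, "C"), "splice_donor")
  ## start-lost at the A of the start codon
  expect_equal(classifySnv(txA, txA@cdsStart, "A", "G"), "start_lost")
  ## stop-lost at the final stop codon (TAA -> CAA)
  stopG <- txA@cdsEnd - 2L
  expect_equal(classifySnv(txA, stopG, "T", "C"), "stop_lost")
  ## wrong reference allele is an error
  expect_error(classifySnv(txA, txA@cdsStart, "C", "G"), "mismatch")
  ## the dual-isoform SNV: nonsense on the short, missense on the long
  expect_equal(classifySnv(tg$models$TOYB.short, vB$pos, vB$ref, vB$alt),
               "nonsense")
  expect_equal(classifySnv(tg$models$TOYB.long, vB$pos, vB$ref, vB$alt),
               "missense")
})

test_that("synonymous wobble changes are classified and filtered as non-protein-changing", {
  ## find a codon whose third base tolerates a change: scan exon 4 interior
  cds <- as.character(splicedCds(txA))
  found <- FALSE
  for (ci in 200:400) {
    codon <- substr(cds, 3 * ci - 2, 3 * ci)
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, 3, 3))) {
      mut <- codon; substr(mut, 3, 3) <- alt
      if (bruteTranslate(codon) == bruteTranslate(mut)) {
        gpos <- IRanges::start(txA@exons)[4] + (3 * ci - 421)
        ## CDS position 3*ci sits in exon 4 (CDS 421..) at this offset
        expect_equal(classifySnv(txA, gpos, substr(codon, 3, 3), alt),
                     "synonymous")
        found <- TRUE
      }
      if (found) break
    }
    if (found) break
  }
  expect_true(found)
})

test_that("acceptor loss activates the nearest cryptic AG: 10-base deletion, frameshift", {
  res <- applyAcceptorLoss(txA, vA$pos, vA$ref, vA$alt)
  expect_equal(res$model, "cryptic_acceptor")
  expect_equal(res$deletionLength, 10L)
  expect_true(res$frameshift)
  expect_equal(length(res$mutantCds), length(splicedCds(txA)) - 10L)
  ## the truncated protein: 72 residues, named by the frameshift rule
  tr <- translateMutant(res$mutantCds, refProtein(txA))
  expect_equal(tr$hgvsP, "p.Leu71TrpfsTer3")
  expect_equal(tr$mutantProteinLength, 72L)
  expect_gt(tr$fractionTruncated, 0.9)
})

test_that("an exon starting with AG gives an immediate 2-base deletion; no AG skips the exon", {
  ## hand-built gene: exon2 begins "AG", exon3 ("CTT"... only) has no AG
  exon1 <- paste0("ATG", strrep("CAT", 9))              # 30 nt
  exon2 <- paste0("AG", strrep("CAT", 10))              # 32 nt
  exon3 <- paste0(strrep("CTT", 11), "C")               # 34 nt, AG-free
  intron <- paste0("GT", strrep("C", 46), "AG")         # 50 nt canonical
  geneSeq <- paste0(strrep("T", 50), exon1, intron, exon2, intron, exon3,
                    strrep("T", 50))
  genome <- Biostrings::DNAStringSet(c(chr = geneSeq))
  e1s <- 51L; e1e <- e1s + 30L - 1L
  e2s <- e1e + 50L + 1L; e2e <- e2s + 32L - 1L
  e3s <- e2e + 50L + 1L; e3e <- e3s + 34L - 1L
  tx <- makeTranscriptModel("t", "g", "chr", "+", c(e1s, e2s, e3s),
                            c(e1e, e2e, e3e), e1s, e3e, genome)
  expect_true(tx@translatable)
  accVar <- e2s - 2L   # the A of intron 1's AG
  r <- applyAcceptorLoss(tx, accVar, "A", "G")
  expect_equal(r$model, "cryptic_acceptor")
  expect_equal(r$deletionLength, 2L)
  ## exon 3 with no AG in the window: exon-skip fallback
  accVar3 <- e3s - 2L
  r3 <- applyAcceptorLoss(tx, accVar3, "A", "G", scanWindow = 20)
  expect_equal(r3$model, "exon_skip")
  expect_equal(r3$deletionLength, 34L)
  expect_equal(r3$nCdsDeleted, 34L)
  expect_true(r3$frameshift)
})

test_that("frameshift whose first new-frame codon is a stop uses p.XnTer; identity is p.(=)", {
  ref <- Biostrings::AAString("MKLVAQ")
  ## mutant CDS stops exactly where residue 3 should be
  mut <- Biostrings::DNAString("ATGAAATAA")
  tr <- translateMutant(mut, ref)
  expect_equal(tr$hgvsP, "p.Leu3Ter")
  expect_equal(tr$mutantProteinLength, 2L)
  refCds <- Biostrings::DNAString("ATGAAACTTGTTGCTCAATAA")
  tr2 <- translateMutant(refCds, ref)
  expect_equal(tr2$hgvsP, "p.(=)")
  expect_equal(tr2$fractionTruncated, 0)
  ## no stop before the sequence ends: Ter? flagged
  noStop <- Biostrings::DNAString("ATGAAACCCGGG")
  tr3 <- translateMutant(noStop, ref)
  expect_match(tr3$hgvsP, "fsTer\\?$")
  expect_false(tr3$terFound)
})

test_that("translateMutant agrees with a codon-by-codon brute-force translator", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    n <- sample(5:40, 1)
    cds <- paste0("ATG", paste(sample(bases, 3 * n, replace = TRUE),
                               collapse = ""))
    refAa <- bruteTranslate(Biostrings::DNAString(cds))
    refClean <- sub("\\*.*$", "", refAa)
    if (nchar(refClean) < 2) next
    ref <- Biostrings::AAString(refClean)
    mutSeq <- paste0("ATG", paste(sample(bases, 3 * n, replace = TRUE),
                                  collapse = ""))
    tr <- translateMutant(Biostrings::DNAString(mutSeq), ref)
    oracleAa <- bruteTranslate(Biostrings::DNAString(mutSeq))
    oracleLen <- nchar(sub("\\*$", "", oracleAa))
    expect_equal(tr$mutantProteinLength, oracleLen)
    expect_equal(tr$fractionTruncated, 1 - oracleLen / nchar(refClean))
  }
})

test_that("isoform annotation is strand-symmetric on all toy genes", {
  for (nm in c("acceptorA", "dualB")) {
    v <- tg$variants[tg$variants$name == nm, ]
    vr <- tg$variants[tg$variants$name == paste0(nm, ".rev"), ]
    fwdModels <- Filter(function(m) m@chrom == v$chrom, tg$models)
    revModels <- Filter(function(m) m@chrom == vr$chrom, tg$models)
    fwd <- annotateAllIsoforms(v$pos, v$ref, v$alt, fwdModels)
    rev <- annotateAllIsoforms(vr$pos, vr$ref, vr$alt, revModels)
    ord <- order(fwd$transcriptId); ordR <- order(rev$transcriptId)
    expect_equal(fwd$effectClass[ord], rev$effectClass[ordR])
    expect_equal(fwd$hgvsC[ord], rev$hgvsC[ordR])
    expect_equal(fwd$hgvsP[ord], rev$hgvsP[ordR])
    expect_equal(fwd$mutantProteinLength[ord], rev$mutantProteinLength[ordR])
  }
})

test_that("a variant in an isoform-specific exon yields one call; deep intronic ones are non-coding", {
  ## inside the insert exon (long isoform only): exon 3 of TOYB.long
  ins <- tg$models$TOYB.long@exons[3]
  gpos <- IRanges::start(ins) + 5L
  ref <- as.character(Biostrings::subseq(tg$models$TOYB.long@chromSeq,
                                         gpos, gpos))
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  callsB <- annotateAllIsoforms(gpos, ref, alt,
                                tg$models[c("TOYB.short", "TOYB.long")])
  ## long isoform: coding; short isoform: deep intronic -> non_coding
  expect_equal(nrow(callsB), 2L)
  expect_equal(callsB$effectClass[callsB$transcriptId == "TOYB.short"],
               "non_coding")
  expect_true(callsB$effectClass[callsB$transcriptId == "TOYB.long"] %in%
              c("missense", "synonymous", "nonsense"))
})

test_that("HGVS c. and p. strings round-trip through the parsers", {
  cs <- c("c.1A>G", "c.210-2A>G", "c.1186C>T", "c.210+1G>T", "c.-12C>A",
          "c.*33T>C")
  for (x in cs) {
    p <- parseHgvsC(x)
    expect_equal(formatHgvsC(p$baseLabel, p$offset, p$ref, p$alt), x)
  }
  ps <- c("p.Leu71TrpfsTer3", "p.Gln396Ter", "p.Leu396Phe", "p.Met1Val",
          "p.Ala12GlyfsTer7")
  for (x in ps) {
    p <- parseHgvsP(x)
    expect_equal(formatHgvsP(p$refAa, p$pos, p$newAa, p$fsTer), x)
  }
  ## "*" is accepted on input and normalised to Ter
  p <- parseHgvsP("p.Gln396*")
  expect_equal(formatHgvsP(p$refAa, p$pos, p$newAa, p$fsTer), "p.Gln396Ter")
  ## every emitted string parses
  ann <- rbind(annotateAllIsoforms(vA$pos, vA$ref, vA$alt, tg$models["TOYA.1"]),
               annotateAllIsoforms(vB$pos, vB$ref, vB$alt,
                                   tg$models[c("TOYB.short", "TOYB.long")]))
  for (i in seq_len(nrow(ann))) {
    expect_silent(parseHgvsC(sub("^c\\.", "c.", ann$hgvsC[i])))
    expect_silent(parseHgvsP(ann$hgvsP[i]))
  }
})

test_that("acceptor rescue arithmetic: mutant CDS length and frameshift parity", {
  res <- applyAcceptorLoss(txA, vA$pos, vA$ref, vA$alt, scanWindow = 50)
  expect_equal(length(res$mutantCds),
               length(splicedCds(txA)) - res$nCdsDeleted)
  expect_equal(res$frameshift, res$nCdsDeleted %% 3L != 0L)
})
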