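test_that("protein-changing filter keeps the declared effect set, in order", {
  set.seed(71)
  effects <- c("missense", "synonymous", "nonsense", "non_coding",
               "frameshift", "splice_acceptor", "splice_donor", "start_lost",
               "stop_lost", "inframe_indel", "other_protein_changing")
  eff <- sample(effects, 20, replace = TRUE)
  vt <- VariantTable(chrom = "1", pos = seq_len(20) * 100, ref = "A",
                     alt = "T", geno = matrix(1L, 20, 1,
                                              dimnames = list(NULL, "s")),
                     effectClass = eff)
  out <- filterProteinChanging(vt)
  oracle <- !(eff %in% c("synonymous", "non_coding"))
  expect_equal(nrow(variantInfo(out)), sum(oracle))
  expect_identical(variantIds(out), variantIds(vt)[oracle])
  ## unannotated records are routed back for annotation
  vtNA <- VariantTable(chrom = "1", pos = 1, ref = "A", alt = "T",
                       geno = matrix(1L, 1, 1, dimnames = list(NULL, "s")))
  expect_error(filterProteinChanging(vtNA), "annotate")
})

test_that("privacy filter removes control-carried variants and non-case-shared ones", {
  geno <- rbind(v1 = c(1L, 1L), v2 = c(1L, 1L), v3 = c(1L, 0L))
  colnames(geno) <- c("case1", "case2")
  vt <- VariantTable(chrom = "1", pos = c(100L, 200L, 300L), ref = "A",
                     alt = "G", geno = geno, effectClass = "missense")
  controls <- data.frame(chrom = "1", pos = 200L, ref = "A", alt = "G",
                         nCarriers = 1L, nSamples = 60L)
  out <- filterPrivate(vt, c("case1", "case2"), controls)
  ## v2 carried by one control, v3 absent from one case
  expect_identical(variantIds(out), variantIds(vt)[1])
  expect_equal(unname(attr(out, "controlCarriers")), 0L)
  expect_identical(attr(out, "unobservedInControls"), variantIds(vt)[1])
  ## empty control table: the filter is the identity on case-carried variants
  empt <- controls[0, ]
  out2 <- filterPrivate(vt, c("case1", "case2"), empt)
  expect_identical(variantIds(out2), variantIds(vt)[1:2])
})

test_that("trio phasing matches the enumerated 27-configuration oracle exactly", {
  for (cg in 0:2) for (sg in 0:2) for (dg in 0:2) {
    geno <- matrix(c(cg, sg, dg), nrow = 1,
                   dimnames = list(NULL, c("kid", "pa", "ma")))
    vt <- VariantTable(chrom = "1", pos = 1L, ref = "A", alt = "T",
                       geno = geno)
    ph <- phaseByTrio(vt, 1, "kid", "pa", "ma")
    oracle <- enumPhaseOracle(cg, sg, dg)
    if (oracle == "inconsistent") {
      expect_equal(ph$origin, "ambiguous")
      expect_true(ph$mendelianInconsistent)
    } else {
      expect_equal(ph$origin, oracle)
      if (oracle != "not_applicable") expect_false(ph$mendelianInconsistent)
    }
  }
})

test_that("inheritance classification: recessive pattern, trans pair, cis rejection", {
  fx <- makeFunnelFixture()
  smp <- sampleIds(fx$vt)
  ## the study patterns: chr15-like recessive (hom in cases, het in parents)
  ## and the causal pair (dams carry one variant, the sire the other)
  calls <- classifyInheritance(fx$vt, fx$trios, fx$cases)
  rec <- calls[calls$mode == "recessive_hom", ]
  expect_setequal(rec$geneId, c("GENE_R1", "GENE_R2"))
  ch <- calls[calls$mode == "compound_het", ]
  expect_setequal(ch$geneId, c("GENE_CH", "GENE_DCH"))
  expect_equal(ch$nPhasedCases[ch$geneId == "GENE_CH"], 2L)
  ## a same-gene pair inherited in cis (both paternal) must be rejected
  genoCis <- rbind(x1 = c(1L, 0L, 0L, 1L, 1L), x2 = c(1L, 0L, 0L, 1L, 1L))
  colnames(genoCis) <- smp
  vtCis <- VariantTable(chrom = "3", pos = c(10L, 20L), ref = "A", alt = "G",
                        geno = genoCis, geneId = "CISGENE",
                        effectClass = "missense")
  cCis <- classifyInheritance(vtCis, fx$trios, fx$cases)
  expect_false(any(cCis$mode == "compound_het"))
  ## variant het in cases but carried by neither parent: incompatible + flag
  genoBad <- rbind(y1 = c(0L, 0L, 0L, 1L, 1L))
  colnames(genoBad) <- smp
  vtBad <- VariantTable(chrom = "2", pos = 5L, ref = "C", alt = "T",
                        geno = genoBad, geneId = "BADGENE",
                        effectClass = "missense")
  cBad <- classifyInheritance(vtBad, fx$trios, fx$cases)
  expect_equal(cBad$mode, "incompatible")
  expect_true(cBad$mendelianFlag)
})

test_that("classification reproduces the simulator's planted mode with error-free trios", {
  for (s in 1:4) {
    fl <- simulateFlock(flockConfig(seed = 700 + s, nMarkers = 300,
                                    withDecoys = FALSE))
    trios <- buildTrios(fl$ped, sampleIds(fl$vcf))
    cc <- classifyInheritance(fl$vcf, trios, fl$cases)
    expect_equal(cc$mode[cc$geneId == "GENE_CH"], "compound_het")
    fr <- simulateFlock(flockConfig(seed = 750 + s, nMarkers = 300,
                                    mode = "recessive", withDecoys = FALSE))
    triosR <- buildTrios(fr$ped, sampleIds(fr$vcf))
    ccR <- classifyInheritance(fr$vcf, triosR, fr$cases)
    expect_equal(ccR$mode[ccR$geneId == "GENE_CH"], "recessive_hom")
  }
})

test_that("the funnel fixture reproduces the 6 -> 4 stage counts (and 1 -> 1 without decoys)", {
  fx <- makeFunnelFixture()
  vt1 <- filterProteinChanging(fx$vt)
  vt2 <- filterPrivate(vt1, fx$cases, fx$local)
  cc <- classifyInheritance(vt2, fx$trios, fx$cases)
  keep <- unique(unlist(strsplit(
    cc$variantIds[cc$mode %in% c("recessive_hom", "compound_het")], ",")))
  expect_equal(length(keep), 6L)   # six inheritance-compatible variants
  vt3 <- filterPrivate(vt2[variantIds(vt2) %in% keep, ], fx$cases, fx$global)
  expect_equal(nrow(variantInfo(vt3)), 4L)   # four after the global cohort
  ## independent recount of the global-stage survivors
  gkey <- paste(fx$global$chrom, fx$global$pos, fx$global$ref, fx$global$alt,
                sep = ":")
  carried <- gkey[fx$global$nCarriers > 0]
  expect_setequal(variantIds(vt3), setdiff(keep, carried))
  ## without decoys the funnel is 1 pair in, 1 pair out
  fx0 <- makeFunnelFixture(withDecoys = FALSE)
  v1 <- filterPrivate(filterProteinChanging(fx0$vt), fx0$cases, fx0$local)
  cc0 <- classifyInheritance(v1, fx0$trios, fx0$cases)
  expect_equal(cc0$mode[cc0$geneId == "GENE_CH"], "compound_het")
  v2 <- filterPrivate(v1, fx0$cases, fx0$global)
  expect_equal(nrow(variantInfo(v2)), 2L)
})

test_that("segregation census reproduces the flock fixture class counts", {
  fx <- encodeFig2aFixture()
  cen <- segregationCensus(fx$vt, fx$ped)
  expect_equal(sum(cen$counts), 71L)              # every sample in a class
  expect_equal(unname(cen$counts["hetA_hetB"]), 5L)
  expect_setequal(cen$doubleHet, fx$affectedLambs)
  expect_equal(length(cen$doubleHetUnaffected), 0L)
  ewes <- segregationCensus(fx$vt, fx$ped, samples = fx$ewes)
  expect_equal(unname(ewes$counts["wt_wt"]), 25L)
  expect_equal(unname(ewes$counts["hetA_only"]), 27L)
  lambs <- segregationCensus(fx$vt, fx$ped, samples = fx$unaffectedLambs)
  expect_equal(unname(lambs$counts["hetB_only"]), 7L)
  expect_equal(unname(lambs$counts["hetA_only"]), 3L)
  expect_equal(unname(lambs$counts["wt_wt"]), 3L)
})

test_that("census puts missing genotypes in an untyped class, never dropped", {
  geno <- rbind(a = c(0L, NA, 1L), b = c(0L, 1L, 1L))
  colnames(geno) <- c("s1", "s2", "s3")
  vt <- VariantTable(chrom = "1", pos = c(1L, 2L), ref = "A", alt = "G",
                     geno = geno)
  ped <- Pedigree(id = c("s1", "s2", "s3"), phenotype = "unknown")
  cen <- segregationCensus(vt, ped)
  expect_equal(unname(cen$counts["untyped"]), 1L)
  expect_equal(sum(cen$counts), 3L)
})

test_that("the phantom maternal grandsire is deduced an obligate carrier (or mosaic)", {
  fx <- encodeFig2aFixture()
  carriersA <- c(fx$carrierEwes, fx$affectedLambs, fx$unaffectedLambs[1:3])
  genotyped <- c(fx$sire, fx$ewes, fx$affectedLambs, fx$unaffectedLambs)
  ded <- deduceAncestorCarrier(fx$ped, carriersA, genotyped)
  expect_equal(ded$status, "obligate_carrier_or_mosaic")
  expect_equal(ded$ancestor, "GS")
  ## the lambs' carrier status is explained by their genotyped carrier dams,
  ## so the unexplained set is exactly the carrier ewes
  expect_setequal(ded$unexplainedCarriers, fx$carrierEwes)
  ## disjoint ancestries: no single-ancestor explanation
  ped2 <- Pedigree(id = c("F1", "F2", "a", "b"), sire = c(NA, NA, "F1", "F2"),
                   sex = c("male", "male", "female", "female"),
                   phenotype = "unknown")
  ded2 <- deduceAncestorCarrier(ped2, c("a", "b"), c("a", "b"))
  expect_equal(ded2$status, "no_single_ancestor")
  ## no carriers: empty statement
  expect_equal(deduceAncestorCarrier(ped2, character(0), "a")$status, "none")
})

test_that("prioritisation follows the regional-support logic with explicit rationale", {
  fx <- makeFunnelFixture()
  vt2 <- filterPrivate(filterProteinChanging(fx$vt), fx$cases, fx$local)
  cc <- classifyInheritance(vt2, fx$trios, fx$cases)
  keep <- unique(unlist(strsplit(
    cc$variantIds[cc$mode %in% c("recessive_hom", "compound_het")], ",")))
  vt3 <- filterPrivate(vt2[variantIds(vt2) %in% keep, ], fx$cases, fx$global)
  cc3 <- classifyInheritance(vt3, fx$trios, fx$cases)
  rep1 <- prioritizeCandidates(cc3, vt3, fx$linkedRegions,
                               sharedRoh = NULL)
  expect_equal(rep1$geneId[1], "GENE_CH")
  expect_true(rep1$inLinkedRegion[1])
  recRow <- rep1[rep1$mode == "recessive_hom", ]
  expect_match(recRow$rationale, "neither in a linked region")
  ## no regions at all: fall back to inheritance evidence, flagged
  rep2 <- prioritizeCandidates(cc3, vt3, NULL, NULL)
  expect_false(attr(rep2, "regionsAvailable"))
  expect_match(rep2$rationale[1], "no region evidence")
})

test_that("funnel stages are monotone on random decoy subsets", {
  fx <- makeFunnelFixture()
  set.seed(72)
  for (i in 1:5) {
    keep <- sort(unique(c(1:2, sample(nrow(variantInfo(fx$vt)), 5))))
    vt <- fx$vt[keep, ]
    n0 <- nrow(variantInfo(vt))
    v1 <- filterProteinChanging(vt)
    v2 <- filterPrivate(v1, fx$cases, fx$local)
    expect_lte(nrow(variantInfo(v1)), n0)
    expect_lte(nrow(variantInfo(v2)), nrow(variantInfo(v1)))
    expect_true(all(variantIds(v2) %in% variantIds(v1)))
  }
})
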