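## The trio WGS candidate funnel: effect-class filtering, privacy against
## local and global control cohorts, trio phasing, inheritance-mode
## classification (recessive homozygous vs compound heterozygous),
## flock-wide segregation census, obligate-carrier deduction for phantom
## ancestors, and prioritisation by region overlap. Each filter returns a
## subset of its input (the funnel is monotone) and stage counts are
## recorded by the orchestration layer.

## Declared protein-changing effect classes ("splice" means the canonical
## +/- 2 nt dinucleotides; extended splice-region variants are not
## protein-changing).
PROTEIN_CHANGING <- c("missense", "nonsense", "frameshift", "splice_acceptor",
                      "splice_donor", "start_lost", "stop_lost",
                      "inframe_indel", "other_protein_changing")

#' Keep protein-changing variants
#'
#' @param vt a \linkS4class{VariantTable} with \code{effectClass} annotated
#'   (records with missing annotation raise an error: route them through the
#'   consequence engine first).
#' @return The subset of \code{vt} with protein-changing effect class, in
#'   input order.
#' @export
filterProteinChanging <- function(vt) {
  eff <- variantInfo(vt)$effectClass
  if (anyNA(eff))
    stop(sprintf("%d variant(s) lack an effect-class annotation; annotate them (consequence engine or VCF EFFECT field) before effect filtering",
                 sum(is.na(eff))))
  vt[eff %in% PROTEIN_CHANGING, ]
}

#' Filter to variants private to the cases
#'
#' Retains variants at which every case carries at least one alternate
#' allele and at most \code{maxCarriers} control samples carry any
#' alternate allele (default 0: strict privacy, the alt allele is absent
#' from the control cohort).
#'
#' @param vt a \linkS4class{VariantTable} with case genotypes.
#' @param caseIds sample ids of the cases.
#' @param controls either a \linkS4class{VariantTable} of control genotypes
#'   or a site-level count data.frame with columns chrom, pos, ref, alt,
#'   nCarriers. Variants absent from the control data are treated as 0
#'   carriers and flagged.
#' @param maxCarriers tolerated control carriers (default 0).
#' @return Subset of \code{vt}; attributes \code{controlCarriers} (named
#'   count per retained variant) and \code{unobservedInControls} (ids never
#'   seen in the control data).
#' @export
filterPrivate <- function(vt, caseIds, controls, maxCarriers = 0) {
  g <- genotypes(vt)
  stopifnot(all(caseIds %in% colnames(g)))
  cg <- g[, caseIds, drop = FALSE]
  allCasesCarry <- apply(cg, 1, function(x) all(!is.na(x) & x >= 1L))
  ids <- variantIds(vt)
  carriers <- controlCarrierCounts(vt, controls)
  keep <- allCasesCarry & carriers <= maxCarriers
  out <- vt[keep, ]
  attr(out, "controlCarriers") <- carriers[keep]
  attr(out, "unobservedInControls") <- ids[keep][attr(carriers, "unobserved")[keep]]
  out
}

controlCarrierCounts <- function(vt, controls) {
  ids <- variantIds(vt)
  if (is(controls, "VariantTable")) {
    g <- genotypes(controls)
    cnt <- rep(0L, length(ids)); unob <- rep(TRUE, length(ids))
    m <- match(ids, variantIds(controls))
    hit <- !is.na(m)
    cnt[hit] <- apply(g[m[hit], , drop = FALSE], 1,
                      function(x) sum(x >= 1L, na.rm = TRUE))
    unob[hit] <- FALSE
  } else {
    key <- paste(controls$chrom, controls$pos, controls$ref, controls$alt,
                 sep = ":")
    m <- match(ids, key)
    cnt <- ifelse(is.na(m), 0L, controls$nCarriers[m])
    unob <- is.na(m)
  }
  names(cnt) <- ids
  attr(cnt, "unobserved") <- unob
  cnt
}

#' Parental origin of a child's heterozygous alternate allele
#'
#' @param vt a \linkS4class{VariantTable}.
#' @param variant variant id or row index.
#' @param child,sire,dam sample ids forming the trio.
#' @return list: origin ("paternal", "maternal", "ambiguous" or
#'   "not_applicable" when the child is not heterozygous),
#'   mendelianInconsistent (TRUE when no Mendelian transmission explains
#'   the child's genotype, e.g. neither parent carries the alt allele).
#' @details The origin is deduced by enumerating the transmissions
#'   consistent with all three genotypes: the alt allele is paternal when
#'   only "sire gives alt, dam gives ref" is possible, maternal in the
#'   mirror case, ambiguous when both are (e.g. both parents
#'   heterozygous). A missing parent genotype constrains nothing, so e.g.
#'   a child het with dam hom-ref phases paternal even without the sire.
#' @export
phaseByTrio <- function(vt, variant, child, sire, dam) {
  g <- genotypes(vt)[variant, ]
  cg <- g[child]; sg <- g[sire]; dg <- g[dam]
  if (is.na(cg) || cg != 1L)
    return(list(origin = "not_applicable", mendelianInconsistent = FALSE))
  givesAlt <- function(p) is.na(p) || p >= 1L
  givesRef <- function(p) is.na(p) || p <= 1L
  patOK <- givesAlt(sg) && givesRef(dg)   # sire -> alt, dam -> ref
  matOK <- givesAlt(dg) && givesRef(sg)   # dam -> alt, sire -> ref
  if (patOK && !matOK)
    list(origin = "paternal", mendelianInconsistent = FALSE)
  else if (matOK && !patOK)
    list(origin = "maternal", mendelianInconsistent = FALSE)
  else if (patOK && matOK)
    list(origin = "ambiguous", mendelianInconsistent = FALSE)
  else
    list(origin = "ambiguous", mendelianInconsistent = TRUE)
}

#' Classify inheritance mode of candidate variants
#'
#' A variant is \code{recessive_hom} when every case is homozygous
#' alternate and every genotyped parent (from the supplied trios) is
#' heterozygous. Two variants in the same annotated gene form a
#' \code{compound_het} pair when every case is heterozygous for both and,
#' in every case whose trio phases both variants, the two alternate alleles
#' have opposite parental origins (one paternal, one maternal); a case with
#' both alleles from the same parent (cis) disqualifies the pair. Variants
#' fitting neither mode are \code{incompatible}.
#'
#' @param vt a \linkS4class{VariantTable}.
#' @param trios data.frame (child, sire, dam) from \code{\link{buildTrios}}.
#' @param caseIds sample ids of the (sequenced) cases.
#' @return data.frame, one row per call: candidateId, mode, geneId,
#'   variantIds (comma-separated pair for compound_het), nPhasedCases,
#'   phaseDetail, mendelianFlag.
#' @export
classifyInheritance <- function(vt, trios, caseIds) {
  stopifnot(nrow(trios) >= 1)
  info <- variantInfo(vt)
  g <- genotypes(vt)
  ids <- variantIds(vt)
  trios <- trios[trios$child %in% caseIds, , drop = FALSE]
  calls <- list(); k <- 0L

  allHomCases <- apply(g[, caseIds, drop = FALSE], 1,
                       function(x) all(!is.na(x) & x == 2L))
  allHetCases <- apply(g[, caseIds, drop = FALSE], 1,
                       function(x) all(!is.na(x) & x == 1L))

  claimed <- rep(FALSE, length(ids))

  ## recessive homozygous
  for (v in which(allHomCases)) {
    parents <- unique(c(trios$sire, trios$dam))
    pg <- g[v, parents]
    if (all(!is.na(pg) & pg == 1L)) {
      k <- k + 1L; claimed[v] <- TRUE
      calls[[k]] <- data.frame(
        candidateId = ids[v], mode = "recessive_hom", geneId = info$geneId[v],
        variantIds = ids[v], nPhasedCases = 0L, phaseDetail = "",
        mendelianFlag = FALSE, stringsAsFactors = FALSE)
    }
  }

  ## compound heterozygous: one reported pair per gene
  for (gene in unique(stats::na.omit(info$geneId[allHetCases]))) {
    vs <- which(allHetCases & !is.na(info$geneId) & info$geneId == gene)
    if (length(vs) < 2) next
    found <- FALSE
    for (a in seq_along(vs)[-length(vs)]) {
      if (found) break
      for (b in (a + 1):length(vs)) {
        v1 <- vs[a]; v2 <- vs[b]
        res <- pairPhase(vt, v1, v2, trios)
        if (res$valid) {
          k <- k + 1L; found <- TRUE
          claimed[c(v1, v2)] <- TRUE
          calls[[k]] <- data.frame(
            candidateId = paste0(gene, ":comphet"), mode = "compound_het",
            geneId = gene, variantIds = paste(ids[c(v1, v2)], collapse = ","),
            nPhasedCases = res$nPhased, phaseDetail = res$detail,
            mendelianFlag = res$mendel, stringsAsFactors = FALSE)
          break
        }
      }
    }
  }

  ## everything else is incompatible with both models
  for (v in which(!claimed)) {
    mendel <- FALSE
    for (t in seq_len(nrow(trios))) {
      ph <- phaseByTrio(vt, v, trios$child[t], trios$sire[t], trios$dam[t])
      mendel <- mendel || ph$mendelianInconsistent
    }
    k <- k + 1L
    calls[[k]] <- data.frame(
      candidateId = ids[v], mode = "incompatible", geneId = info$geneId[v],
      variantIds = ids[v], nPhasedCases = 0L, phaseDetail = "",
      mendelianFlag = mendel, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

## check one candidate compound-het pair against all case trios
pairPhase <- function(vt, v1, v2, trios) {
  nPhased <- 0L; detail <- character(); mendel <- FALSE; valid <- TRUE
  for (t in seq_len(nrow(trios))) {
    ph1 <- phaseByTrio(vt, v1, trios$child[t], trios$sire[t], trios$dam[t])
    ph2 <- phaseByTrio(vt, v2, trios$child[t], trios$sire[t], trios$dam[t])
    mendel <- mendel || ph1$mendelianInconsistent || ph2$mendelianInconsistent
    o1 <- ph1$origin; o2 <- ph2$origin
    if (o1 %in% c("paternal", "maternal") && o2 %in% c("paternal", "maternal")) {
      if (o1 == o2) valid <- FALSE          # cis: same parental origin
      else {
        nPhased <- nPhased + 1L
        detail <- c(detail, sprintf("%s:%s/%s", trios$child[t], o1, o2))
      }
    }
  }
  ## at least one case must actually phase in trans
  list(valid = valid && nPhased >= 1L, nPhased = nPhased,
       detail = paste(detail, collapse = ";"), mendel = mendel)
}

#' Two-variant segregation census over the full flock
#'
#' Cross-tabulates every sample by its genotype at the two candidate
#' variants: homozygous wild type at both, carrier of only the first, only
#' the second, double heterozygote, any other combination (e.g. homozygous
#' alternate), or untyped (missing either genotype; never silently
#' dropped). Double carriers are cross-checked against the phenotype.
#'
#' @param vt a \linkS4class{VariantTable} with exactly 2 variants genotyped
#'   on the flock.
#' @param ped a \linkS4class{Pedigree} supplying phenotypes.
#' @param samples optional subset of samples to census (default: all
#'   genotyped samples).
#' @return list: \code{counts} (named vector over the classes; sums to the
#'   number of censused samples), \code{doubleHet} (ids het for both),
#'   \code{doubleHetAffected} / \code{doubleHetUnaffected} (phenotype
#'   cross-check).
#' @export
segregationCensus <- function(vt, ped, samples = NULL) {
  stopifnot(nrow(variantInfo(vt)) == 2)
  g <- genotypes(vt)
  if (is.null(samples)) samples <- colnames(g)
  g <- g[, samples, drop = FALSE]
  gA <- g[1, ]; gB <- g[2, ]
  class <- ifelse(is.na(gA) | is.na(gB), "untyped",
           ifelse(gA == 0L & gB == 0L, "wt_wt",
           ifelse(gA == 1L & gB == 0L, "hetA_only",
           ifelse(gA == 0L & gB == 1L, "hetB_only",
           ifelse(gA == 1L & gB == 1L, "hetA_hetB", "other")))))
  lev <- c("wt_wt", "hetA_only", "hetB_only", "hetA_hetB", "other", "untyped")
  counts <- table(factor(class, levels = lev))
  dbl <- samples[class == "hetA_hetB"]
  phe <- setNames(pedTable(ped)$phenotype, pedTable(ped)$id)[dbl]
  list(counts = stats::setNames(as.integer(counts), lev),
       doubleHet = dbl,
       doubleHetAffected = dbl[phe == "affected"],
       doubleHetUnaffected = dbl[!is.na(phe) & phe == "unaffected"])
}

#' Deduce obligate-carrier status of phantom ancestors
#'
#' Given the observed carriers of a (maternally transmitted) variant,
#' identifies carriers whose status is not explained by a genotyped carrier
#' parent and asks whether a single ungenotyped ancestor could have
#' supplied the allele to all of them under Mendelian transmission.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param carrierIds ids observed to carry the variant.
#' @param genotypedIds ids with known genotypes (carriers outside this set
#'   cannot "explain" a descendant).
#' @return list with \code{status}: "none" (no unexplained carriers),
#'   "obligate_carrier_or_mosaic" with \code{ancestor} (single phantom
#'   ancestor shared by every unexplained carrier), or
#'   "no_single_ancestor" (disjoint ancestries: germline mosaicism or
#'   multiple mutation origins needed).
#' @export
deduceAncestorCarrier <- function(ped, carrierIds, genotypedIds) {
  if (!length(carrierIds)) return(list(status = "none", ancestor = NA_character_))
  tb <- pedTable(ped)
  explained <- vapply(carrierIds, function(id) {
    par <- unlist(tb[match(id, tb$id), c("sire", "dam")])
    any(!is.na(par) & par %in% carrierIds & par %in% genotypedIds)
  }, TRUE)
  need <- carrierIds[!explained]
  if (!length(need)) return(list(status = "none", ancestor = NA_character_))
  ## ungenotyped ancestors of each unexplained carrier
  anc <- lapply(need, function(id)
    setdiff(ancestorsClosure(ped, id), c(id, genotypedIds)))
  common <- Reduce(intersect, anc)
  if (length(common))
    list(status = "obligate_carrier_or_mosaic", ancestor = common[1],
         unexplainedCarriers = need)
  else
    list(status = "no_single_ancestor", ancestor = NA_character_,
         unexplainedCarriers = need)
}

#' Prioritise inheritance-compatible candidates by regional evidence
#'
#' A compound-heterozygous candidate is supported when its variants fall in
#' a linked region; a recessive-homozygous candidate when it falls in a
#' shared autozygosity segment (the evidence its model demands: a recessive
#' allele descending from a common ancestor must sit in a segment of shared
#' homozygosity of the cases). Supported candidates rank first, then
#' candidates merely overlapping a linked region, then the rest;
#' incompatible variants are excluded. An explicit rationale string records
#' why each candidate was ranked down.
#'
#' @param calls data.frame from \code{\link{classifyInheritance}}.
#' @param vt the \linkS4class{VariantTable} (for variant positions).
#' @param linkedRegions data.frame (chrom, start, end) of linked regions,
#'   or NULL/empty when no scan is available.
#' @param sharedRoh data.frame (chrom, start, end) of shared autozygosity
#'   segments, or NULL/empty.
#' @return data.frame: the candidate report, ordered; columns of
#'   \code{calls} plus inLinkedRegion, inSharedRoh, supported, rank,
#'   rationale. Attribute \code{regionsAvailable} is FALSE when ordering
#'   fell back to inheritance evidence alone.
#' @export
prioritizeCandidates <- function(calls, vt, linkedRegions = NULL,
                                 sharedRoh = NULL) {
  cand <- calls[calls$mode %in% c("recessive_hom", "compound_het"), ,
                drop = FALSE]
  info <- variantInfo(vt)
  pos <- function(vids) {
    v <- strsplit(vids, ",")[[1]]
    info[v, c("chrom", "pos"), drop = FALSE]
  }
  inRegions <- function(vids, reg) {
    if (is.null(reg) || !nrow(reg)) return(FALSE)
    p <- pos(vids)
    all(vapply(seq_len(nrow(p)), function(i)
      any(reg$chrom == p$chrom[i] & reg$start <= p$pos[i] &
          reg$end >= p$pos[i]), TRUE))
  }
  regionsAvailable <- !is.null(linkedRegions) && nrow(linkedRegions) > 0
  cand$inLinkedRegion <- vapply(cand$variantIds, inRegions, TRUE,
                                reg = linkedRegions)
  cand$inSharedRoh <- vapply(cand$variantIds, inRegions, TRUE, reg = sharedRoh)
  cand$supported <- ifelse(cand$mode == "compound_het",
                           cand$inLinkedRegion, cand$inSharedRoh)
  if (!regionsAvailable) cand$supported <- NA
  cand$rationale <- mapply(function(mode, lnk, roh) {
    if (!regionsAvailable)
      "no region evidence available; ranked by inheritance mode alone"
    else if (mode == "compound_het" && lnk)
      "compound heterozygous pair within a linked region"
    else if (mode == "recessive_hom" && roh)
      "recessive homozygous variant within a shared autozygosity segment"
    else if (mode == "recessive_hom" && !roh && !lnk)
      "less likely candidate: neither in a linked region nor in a shared homozygosity segment"
    else if (mode == "recessive_hom" && !roh)
      "less likely candidate: not in a shared homozygosity segment"
    else
      "less likely candidate: not in a linked region"
  }, cand$mode, cand$inLinkedRegion, cand$inSharedRoh)
  ord <- order(if (regionsAvailable) -(cand$supported * 2 + cand$inLinkedRegion)
               else rep(0, nrow(cand)),
               -cand$nPhasedCases)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  attr(cand, "regionsAvailable") <- regionsAvailable
  cand
}
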