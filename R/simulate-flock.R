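## Gene-drop flock simulator. Emulates the study design of a closed hill
## flock: one phantom grandsire heterozygous for variant A sires the ewe
## cohort (each daughter inherits A with probability 1/2); the genotyped
## sire is heterozygous for variant B; a lamb is affected iff it carries
## both A (maternal) and B (paternal) -- or, in recessive mode, iff it is
## homozygous for a single variant descending from the grandsire through
## both parents. Array markers are simulated without linkage
## disequilibrium but with genetic linkage within chromosomes
## (recombination from physical distance at 1 cM/Mb, Haldane map), which is
## what the linkage and autozygosity scans consume; LD is irrelevant to
## every implemented statistic. Ground truth (founder-haplotype labels of
## every transmitted chromosome) is recorded for oracle tests.

#' Flock simulation configuration
#'
#' Defaults reproduce the study conditions: 52 ewes, 18 lambs, a 2.6 Gb
#' genome in 26 chromosomes, ~45k-scalable marker panel, 2% missingness,
#' fully penetrant phenotype, 60 local and 453 global control genomes
#' carrying neither causal variant.
#'
#' @param nEwes number of ewes (daughters of the phantom grandsire).
#' @param nLambs number of lambs (all sired by the genotyped ram; dams
#'   drawn from the ewes without replacement).
#' @param nMarkers array markers, spread over the genome (default 5000;
#'   scalable to 45000).
#' @param nChromosomes,genomeBp genome shape (default 26 autosomes, 2.6e9 bp).
#' @param mafRange alternate-allele frequency range, uniform (default
#'   c(0.1, 0.9)).
#' @param missingRate per-call missing probability (default 0.02).
#' @param errorRate per-call genotyping error probability (default 0; an
#'   erroneous call is replaced by one of the other two states uniformly).
#' @param nLocalControls,nGlobalControls control cohort sizes (60 / 453).
#' @param penetrance fixed at 1 (fully penetrant lethal phenotype).
#' @param mode "compound_het" (two-variant design) or "recessive"
#'   (single variant, affected lambs homozygous, inside a shared
#'   autozygous segment by construction).
#' @param withDecoys plant the decoy variant set reproducing the candidate
#'   funnel in the family VCF (default TRUE).
#' @param minAffected minimum affected lambs; lamb transmissions are
#'   redrawn (bounded) until reached. The affected count itself is
#'   binomial, never forced.
#' @param maxRedraws bound on redraws (default 25).
#' @param cMperMb genetic map density (default 1).
#' @param seed mandatory integer seed.
#' @return A validated config list of class \code{FlockConfig}.
#' @export
flockConfig <- function(nEwes = 52, nLambs = 18, nMarkers = 5000,
                        nChromosomes = 26, genomeBp = 2.6e9,
                        mafRange = c(0.1, 0.9), missingRate = 0.02,
                        errorRate = 0, nLocalControls = 60,
                        nGlobalControls = 453, penetrance = 1,
                        mode = c("compound_het", "recessive"),
                        withDecoys = TRUE, minAffected = 2, maxRedraws = 25,
                        cMperMb = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory in the flock configuration")
  mode <- match.arg(mode)
  cfg <- list(nEwes = nEwes, nLambs = nLambs, nMarkers = nMarkers,
              nChromosomes = nChromosomes, genomeBp = genomeBp,
              mafRange = mafRange, missingRate = missingRate,
              errorRate = errorRate, nLocalControls = nLocalControls,
              nGlobalControls = nGlobalControls, penetrance = penetrance,
              mode = mode, withDecoys = withDecoys, minAffected = minAffected,
              maxRedraws = maxRedraws, cMperMb = cMperMb,
              seed = as.integer(seed))
  stopifnot(nEwes > 0, nLambs > 0, nLambs <= nEwes, nMarkers > 0,
            all(mafRange >= 0 & mafRange <= 1),
            missingRate >= 0, missingRate <= 1,
            errorRate >= 0, errorRate <= 1, penetrance == 1,
            minAffected >= 1)
  class(cfg) <- "FlockConfig"
  cfg
}

## one meiosis over the locus grid: returns the transmitted founder-
## haplotype label vector. rAdj: recombination fraction between adjacent
## grid loci (0.5 across chromosome boundaries). forceIdx/forceSlot
## optionally condition the transmitted haplotype slot at one locus
## (implemented by flipping the whole path, valid by exchangeability of
## the two strands).
meiosisDrop <- function(hap, rAdj, forceIdx = NULL, forceSlot = NULL) {
  n <- nrow(hap)
  sw <- stats::rbinom(n - 1L, 1L, rAdj)
  slot <- (stats::rbinom(1L, 1L, 0.5) + cumsum(c(0L, sw))) %% 2L
  if (!is.null(forceIdx) && slot[forceIdx] != forceSlot) slot <- 1L - slot
  ifelse(slot == 0L, hap[, 1L], hap[, 2L])
}

#' Simulate a synthetic flock with known truth
#'
#' @param config a \code{\link{flockConfig}}.
#' @return list: \code{config}; \code{ped} (\linkS4class{Pedigree}
#'   including the phantom grandsire and phantom ewe dams); \code{gm}
#'   (\linkS4class{GenotypeMatrix} of the array-genotyped subset: sire,
#'   affected lambs, their dams, up to 3 unaffected lambs); \code{vcf}
#'   (family \linkS4class{VariantTable} for the sequenced trios: sire, two
#'   case lambs, their dams); \code{localControls} / \code{globalControls}
#'   (site-level carrier-count tables); \code{truth} (founder-haplotype
#'   labels per individual and locus, causal locus indices, carrier sets);
#'   \code{cases} (sequenced case ids), \code{affected} (all affected
#'   lambs), \code{causal} (positions/gene of the planted variants).
#' @export
simulateFlock <- function(config) {
  stopifnot(inherits(config, "FlockConfig"))
  set.seed(config$seed)
  nC <- config$nChromosomes
  chromLen <- round(config$genomeBp * (nC + 1 - seq_len(nC)) /
                    sum(seq_len(nC)))
  chromNames <- as.character(seq_len(nC))

  ## marker grid
  nPer <- pmax(1L, round(config$nMarkers * chromLen / sum(chromLen)))
  mChrom <- rep(chromNames, nPer)
  mPos <- unlist(lapply(seq_len(nC), function(i)
    sort(sample.int(chromLen[i] - 1000L, nPer[i]))))
  maf <- stats::runif(length(mPos), config$mafRange[1], config$mafRange[2])

  ## causal locus (two variant positions ~16 kb apart mid-chromosome 3)
  cChrom <- "3"
  posB <- floor(chromLen[3] * 0.55)
  posA <- posB + 15844L
  grid <- data.frame(chrom = c(mChrom, cChrom, cChrom),
                     pos = c(mPos, posA, posB),
                     maf = c(maf, 0, 0),
                     isMarker = c(rep(TRUE, length(mPos)), FALSE, FALSE))
  grid <- grid[order(match(grid$chrom, chromNames), grid$pos), ]
  ## drop rare position collisions with markers
  dup <- duplicated(grid[, c("chrom", "pos")])
  grid <- grid[!dup, ]
  rownames(grid) <- NULL
  nG <- nrow(grid)
  idxA <- which(!grid$isMarker & grid$pos == posA)
  idxB <- which(!grid$isMarker & grid$pos == posB)

  ## recombination fractions between adjacent grid loci (Haldane, cM/Mb)
  d <- diff(grid$pos) * 1e-6 * config$cMperMb / 100
  rAdj <- 0.5 * (1 - exp(-2 * d))
  rAdj[diff(match(grid$chrom, chromNames)) != 0] <- 0.5

  ## pedigree ids
  ewes <- sprintf("E%03d", seq_len(config$nEwes))
  eweDams <- sprintf("ED%03d", seq_len(config$nEwes))
  recessive <- config$mode == "recessive"
  founders <- c("GS", eweDams, if (recessive) "SD" else "SIRE")
  nonFounderSire <- recessive   # SIRE = son of GS x SD in recessive mode

  ## founder haplotypes: rows = grid loci, two columns per founder
  hapIds <- paste0(rep(founders, each = 2), ".", 1:2)
  H <- matrix(stats::rbinom(nG * length(hapIds), 1L,
                            rep(grid$maf, length(hapIds))),
              nrow = nG, ncol = length(hapIds), dimnames = list(NULL, hapIds))
  H[c(idxA, idxB), ] <- 0L
  H[idxA, "GS.1"] <- 1L                       # variant A on a grandsire haplotype
  if (!recessive) H[idxB, "SIRE.1"] <- 1L     # variant B on a sire haplotype

  lab <- function(hapId) rep.int(match(hapId, hapIds), nG)
  hap <- list()
  for (f in founders) hap[[f]] <- cbind(lab(paste0(f, ".1")),
                                        lab(paste0(f, ".2")))
  genoOf <- function(id) {
    m <- hap[[id]]
    H[cbind(seq_len(nG), m[, 1])] + H[cbind(seq_len(nG), m[, 2])]
  }

  if (recessive) {
    ## sire is a grandsire son conditioned to carry the causal haplotype
    hap[["SIRE"]] <- cbind(
      meiosisDrop(hap[["GS"]], rAdj, forceIdx = idxA, forceSlot = 0L),
      meiosisDrop(hap[["SD"]], rAdj))
  }
  for (i in seq_along(ewes))
    hap[[ewes[i]]] <- cbind(meiosisDrop(hap[["GS"]], rAdj),
                            meiosisDrop(hap[[eweDams[i]]], rAdj))

  lambs <- sprintf("L%02d", seq_len(config$nLambs))
  carriesAt <- function(id, idx) genoOf(id)[idx] >= 1L
  draw <- 0L
  repeat {
    draw <- draw + 1L
    damOf <- stats::setNames(sample(ewes, config$nLambs), lambs)
    for (l in lambs)
      hap[[l]] <- cbind(meiosisDrop(hap[["SIRE"]], rAdj),
                        meiosisDrop(hap[[damOf[l]]], rAdj))
    gA <- vapply(lambs, function(l) genoOf(l)[idxA], 1L)
    affected <- if (recessive) gA == 2L
                else gA >= 1L & vapply(lambs, function(l)
                  genoOf(l)[idxB] >= 1L, 1L) >= 1L
    if (sum(affected) >= config$minAffected) break
    if (draw > config$maxRedraws)
      stop(sprintf("no draw with >= %d affected lambs in %d attempts; review the configuration",
                   config$minAffected, config$maxRedraws))
  }
  affLambs <- lambs[affected]
  unaffLambs <- lambs[!affected]

  ped <- Pedigree(
    id = c("GS", eweDams, if (recessive) "SD", "SIRE", ewes, lambs),
    sire = c(NA, rep(NA, length(eweDams)), if (recessive) NA,
             if (recessive) "GS" else NA, rep("GS", length(ewes)),
             rep("SIRE", length(lambs))),
    dam = c(NA, rep(NA, length(eweDams)), if (recessive) NA,
            if (recessive) "SD" else NA, eweDams, unname(damOf[lambs])),
    sex = c("male", rep("female", length(eweDams)), if (recessive) "female",
            "male", rep("female", length(ewes)),
            sample(c("male", "female"), length(lambs), replace = TRUE)),
    phenotype = c("unknown", rep("unknown", length(eweDams)),
                  if (recessive) "unknown", "unaffected",
                  rep("unaffected", length(ewes)),
                  ifelse(affected, "affected", "unaffected")))

  ## array-genotyped subset mirrors the study: sire, affected lambs, their
  ## dams, up to 3 unaffected lambs
  genotyped <- c("SIRE", affLambs, unique(unname(damOf[affLambs])),
                 utils::head(unaffLambs, 3L))
  mkIdx <- which(grid$isMarker)
  callsM <- t(vapply(genotyped, function(id) genoOf(id)[mkIdx],
                     integer(length(mkIdx))))
  ## self-audit: truth labels must reproduce the emitted genotypes
  stopifnot(identical(callsM["SIRE", ],
                      (H[cbind(mkIdx, hap[["SIRE"]][mkIdx, 1])] +
                       H[cbind(mkIdx, hap[["SIRE"]][mkIdx, 2])])))
  if (config$errorRate > 0) {
    err <- matrix(stats::runif(length(callsM)) < config$errorRate,
                  nrow = nrow(callsM))
    shift <- matrix(sample(1:2, length(callsM), replace = TRUE),
                    nrow = nrow(callsM))
    callsM[err] <- (callsM[err] + shift[err]) %% 3L
  }
  if (config$missingRate > 0)
    callsM[matrix(stats::runif(length(callsM)) < config$missingRate,
                  nrow = nrow(callsM))] <- NA_integer_
  gm <- GenotypeMatrix(callsM, chrom = grid$chrom[mkIdx],
                       pos = grid$pos[mkIdx],
                       markerIds = sprintf("M%05d", seq_along(mkIdx)))

  ## sequenced trios: first two cases + their dams + the sire
  cases <- utils::head(affLambs, 2L)
  caseDams <- unname(damOf[cases])
  seqIds <- c("SIRE", caseDams, cases)
  causalGeno <- vapply(seqIds, function(id)
    c(genoOf(id)[idxA], genoOf(id)[idxB]), integer(2))
  fam <- funnelVariantSet(
    sireId = "SIRE", damIds = caseDams, caseIds = cases,
    chromCausal = cChrom, posA = posA, posB = posB,
    mode = config$mode, withDecoys = config$withDecoys,
    nLocal = config$nLocalControls, nGlobal = config$nGlobalControls,
    causalGenoA = causalGeno[1, ], causalGenoB = causalGeno[2, ])

  truth <- list(grid = grid[, c("chrom", "pos", "maf", "isMarker")],
                hapLabels = hap, hapIds = hapIds, founderAlleles = H,
                idxA = idxA, idxB = idxB,
                eweCarriersA = ewes[vapply(ewes, carriesAt, TRUE, idx = idxA)],
                damOf = damOf, genoOf = genoOf)
  list(config = config, ped = ped, gm = gm, vcf = fam$vt,
       localControls = fam$local, globalControls = fam$global,
       truth = truth, cases = cases, affected = affLambs,
       causal = list(chrom = cChrom, posA = posA, posB = posB,
                     geneId = "GENE_CH",
                     variantIds = if (recessive)
                       paste0(cChrom, ":", posA, ":T:C")
                     else paste0(cChrom, ":", c(posA, posB), ":",
                                 c("T", "G"), ":", c("C", "A"))))
}
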