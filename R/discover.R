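## End-to-end discovery pipeline: QC -> parentage -> shared autozygosity ->
## linkage -> variant funnel -> prioritised candidate report, with a run
## log recording every stage's input/output counts (the funnel counts are
## monotonically non-increasing) and every threshold in force.

#' Run the full discovery pipeline on a (simulated or assembled) flock
#'
#' @param flock a list as returned by \code{\link{simulateFlock}}, or an
#'   equivalent assembled from files: elements \code{ped}, \code{gm},
#'   \code{vcf}, \code{localControls}, \code{globalControls}, \code{cases}.
#' @param seed integer seed for the linkage null (mandatory).
#' @param nReps gene drops per frequency for the linkage null.
#' @param gapMarkers linked-region gap tolerance (see
#'   \code{\link{linkageScan}}).
#' @param rohParams named list overriding \code{\link{detectRoh}} defaults;
#'   the pipeline default raises the per-run missing-call budget to 25
#'   (2 percent missingness over the ~1000-marker segments a dense map
#'   produces).
#' @param maxCarriers privacy filter tolerance (default 0).
#' @param models optional list of \linkS4class{TranscriptModel} for
#'   consequence annotation of the top candidates.
#' @return list: \code{report} (prioritised candidate data.frame),
#'   \code{log} (named stage counts and parameters), \code{scan},
#'   \code{regions}, \code{sharedRoh}, \code{parentage},
#'   \code{consequences} (NULL without \code{models}).
#' @export
runDiscover <- function(flock, seed, nReps = 1000, gapMarkers = 20,
                        rohParams = list(maxMiss = 25), maxCarriers = 0, models = NULL) {
  if (missing(seed)) stop("a seed is mandatory (linkage null)")
  for (el in c("ped", "gm", "vcf", "localControls", "globalControls", "cases"))
    if (is.null(flock[[el]]))
      stop(sprintf("flock input lacks element '%s'; nothing was computed", el))
  log <- list(seed = seed, nReps = nReps, gapMarkers = gapMarkers,
              maxCarriers = maxCarriers)

  ## --- genotype QC ----------------------------------------------------
  cr <- sampleCallRates(flock$gm)
  gm <- pruneMarkersByMissingness(flock$gm)
  log$nSamples <- nrow(cr)
  log$nSamplesPassCallRate <- sum(cr$pass)
  log$nMarkersIn <- ncol(calls(flock$gm))
  log$nMarkersAfterPruning <- ncol(calls(gm))

  ## --- parentage ------------------------------------------------------
  tb <- pedTable(flock$ped)
  lambs <- tb$id[!is.na(tb$sire) & tb$sire %in% sampleIds(gm) &
                 tb$id %in% sampleIds(gm)]
  parentage <- do.call(rbind, lapply(lambs, function(l)
    verifyParentage(gm, l, tb$sire[tb$id == l])))
  log$nSireConfirmed <- sum(parentage$verdict == "confirmed")
  log$nSireChecked <- nrow(parentage)

  ## --- autozygosity ---------------------------------------------------
  affected <- intersect(affectedIds(flock$ped), sampleIds(gm))
  segs <- lapply(affected, function(a)
    do.call(detectRoh, c(list(gm = gm, sample = a), rohParams)))
  sharedRoh <- if (length(affected) >= 2)
    sharedAutozygosity(segs, gm, affected)
  else data.frame(chrom = character(), start = integer(), end = integer(),
                  nMarkers = integer())
  log$nSharedRohSegments <- nrow(sharedRoh)

  ## --- linkage --------------------------------------------------------
  lk <- linkageScan(gm, flock$ped, affected, nReps = nReps, seed = seed,
                    gapMarkers = gapMarkers)
  log$nLinkedRegions <- nrow(lk$regions)

  ## --- variant funnel -------------------------------------------------
  vt <- flock$vcf
  cases <- flock$cases
  log$nVariantsIn <- nrow(variantInfo(vt))
  vt1 <- filterProteinChanging(vt)
  log$nProteinChanging <- nrow(variantInfo(vt1))
  vt2 <- filterPrivate(vt1, cases, flock$localControls,
                       maxCarriers = maxCarriers)
  log$nPrivateLocal <- nrow(variantInfo(vt2))
  trios <- buildTrios(flock$ped, sampleIds(vt))
  calls2 <- classifyInheritance(vt2, trios, cases)
  compatible <- calls2[calls2$mode %in% c("recessive_hom", "compound_het"), ]
  keepIds <- unique(unlist(strsplit(compatible$variantIds, ",")))
  log$nInheritanceCompatible <- length(keepIds)
  vt3 <- filterPrivate(vt2[variantIds(vt2) %in% keepIds, ], cases,
                       flock$globalControls, maxCarriers = maxCarriers)
  log$nPrivateGlobal <- nrow(variantInfo(vt3))
  calls3 <- classifyInheritance(vt3, trios, cases)
  report <- prioritizeCandidates(calls3, vt3, lk$regions, sharedRoh)
  log$nCandidates <- nrow(report)

  ## --- consequences (optional) ----------------------------------------
  consequences <- NULL
  if (!is.null(models) && nrow(report)) {
    topIds <- strsplit(report$variantIds[1], ",")[[1]]
    inf <- variantInfo(vt3)[topIds, , drop = FALSE]
    consequences <- do.call(rbind, lapply(seq_len(nrow(inf)), function(i) {
      ann <- annotateAllIsoforms(inf$pos[i], inf$ref[i], inf$alt[i], models,
                                 chrom = inf$chrom[i])
      if (nrow(ann)) cbind(variantId = topIds[i], ann) else NULL
    }))
  }

  stopifnot(log$nVariantsIn >= log$nProteinChanging,
            log$nProteinChanging >= log$nPrivateLocal,
            log$nPrivateLocal >= log$nInheritanceCompatible,
            log$nInheritanceCompatible >= log$nPrivateGlobal)
  list(report = report, log = log, scan = lk$scan, regions = lk$regions,
       sharedRoh = sharedRoh, parentage = parentage,
       consequences = consequences)
}
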