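#' @include AllClasses.R utils.R synthetic-cohort.R
NULL

## polynomial rolling hash of a character string, for provenance blocks
.configHash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Construct a pipeline configuration
#'
#' All stage defaults equal the defaults of the individual stage functions;
#' the CEUS phantom of the full pipeline uses a reduced grid (2 x 24 x 24,
#' 60 frames) so that a whole cohort can be simulated and analyzed per run.
#'
#' @param cohort a \linkS4class{CohortSpec}.
#' @param ceus list of CEUS options: \code{grid}, \code{nFrames},
#'   \code{frameInterval}, \code{burstFrame}, \code{noiseSd},
#'   \code{lesionRelativePerfusion}, \code{aarThreshold}.
#' @param crc list of CRC options: \code{noiseSd}.
#' @param oxphos list of oxygraph options: \code{noiseSd},
#'   \code{inhibitedOcr} (named floors for rotenone/TTFA/azide stages).
#' @param stats list of statistics options: \code{correlationMethod}.
#' @param seed global integer seed.
#' @param outDir output directory; "" keeps results in memory only.
#' @return a \linkS4class{PipelineConfig}
#' @export
pipelineConfig <- function(cohort = cohortSpec(),
                           ceus = list(), crc = list(), oxphos = list(),
                           stats = list(), seed = 7L, outDir = "") {
  ceusDef <- list(grid = c(2L, 24L, 24L), nFrames = 60L, frameInterval = 0.5,
                  burstFrame = 11L, noiseSd = 1,
                  lesionRelativePerfusion = 0.1, aarThreshold = 0.26)
  crcDef <- list(noiseSd = 2)
  oxDef <- list(noiseSd = 0.2,
                inhibitedOcr = c(GM = 3, rotenone = 2, TTFA = 3, azide = 5))
  statsDef <- list(correlationMethod = "spearman")
  new("PipelineConfig", cohort = cohort,
      ceus = utils::modifyList(ceusDef, ceus),
      crc = utils::modifyList(crcDef, crc),
      oxphos = utils::modifyList(oxDef, oxphos),
      stats = utils::modifyList(statsDef, stats),
      seed = asCount(seed, "seed"), outDir = outDir)
}

## Simulate + analyze the CEUS stage of one animal: returns the measured
## AAR percent (NA on stage failure).
.pipelineCeus <- function(aarTarget, cfg, seed) {
  frac <- min(max(aarTarget / 100, 0), 0.95)
  spec <- ceusPhantomSpec(grid = cfg$grid, nFrames = cfg$nFrames,
                          frameInterval = cfg$frameInterval,
                          burstFrame = cfg$burstFrame,
                          lesionRelativePerfusion = cfg$lesionRelativePerfusion,
                          lesionFraction = frac, noiseSd = cfg$noiseSd,
                          seed = seed)
  ph <- makeCeusPhantom(spec)
  pm <- computePerfusionMap(ph$sequence)
  rel <- normalizePerfusion(pm, ph$partition)
  aarPercent(segmentAar(rel, ph$partition, threshold = cfg$aarThreshold))
}

.pipelineCrc <- function(crcTarget, cfg, seed) {
  n <- max(0L, as.integer(round(crcTarget / 10)))
  tr <- makeCrcTrace(crcTraceSpec(nRetained = n, noiseSd = cfg$noiseSd,
                                  seed = seed))
  crcPerMg(computeCrc(tr$trace))
}

.pipelineOxphos <- function(ci, cii, civ, cfg, seed) {
  base <- cfg$inhibitedOcr
  ocrs <- c(GM = unname(base["GM"]),
            ADP = ci + unname(base["rotenone"]),
            rotenone = unname(base["rotenone"]),
            succinate = cii + unname(base["TTFA"]),
            TTFA = unname(base["TTFA"]),
            TMPD_ascorbate = civ + unname(base["azide"]),
            azide = unname(base["azide"]))
  ox <- makeOxygraphTrace(oxygraphSpec(stagePlan = titrationPlan(ocrs),
                                       noiseSd = cfg$noiseSd, seed = seed))
  cr <- computeComplexRates(stageOcrs(ox$trace))
  c(CI = cr@ci, CII = cr@cii, CIV = cr@civ)
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> CEUS -> lesion -> assays -> statistics for every
#' animal of the configured cohort: per-animal ground-truth endpoints are
#' drawn from the cohort spec, raw data (CEUS phantom, lesion label volume,
#' CRC and oxygraph traces) are simulated from them, the measurement chain
#' is run on the raw data, excluded animals are filtered by the protocol
#' criteria, and the cohort statistics are computed on the measured
#' endpoints of the included animals. Deterministic under the config seed;
#' a failing stage for one animal records an exclusion, it does not abort
#' the run.
#'
#' @param config a \linkS4class{PipelineConfig}
#' @return a \linkS4class{PipelineReport}
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(seed = 7)
#' rep <- runPipeline(cfg)
#' groupSummaries(rep)
#' }
#' @export
runPipeline <- function(config) {
  cspec <- config@cohort
  methods::slot(cspec, "seed") <- deriveSeeds(config@seed, 1L)[1]
  co <- makeCohort(cspec)
  animals <- co$cohort
  n <- nrow(animals)
  seeds <- matrix(deriveSeeds(config@seed + 1L, 4L * n), ncol = 4L)

  meas <- data.frame(aar_percent = rep(NA_real_, n), hlvc_percent = NA_real_,
                     endpoint_ratio = NA_real_, crc_ipsi = NA_real_,
                     crc_contra = NA_real_, ocr_CI_ipsi = NA_real_,
                     ocr_CII_ipsi = NA_real_, ocr_CIV_ipsi = NA_real_,
                     ocr_CI_contra = NA_real_, ocr_CII_contra = NA_real_,
                     ocr_CIV_contra = NA_real_)
  for (i in seq_len(n)) {
    ok <- tryCatch({
      meas$aar_percent[i] <- .pipelineCeus(animals$aar_percent[i],
                                           config@ceus, seeds[i, 1])
      lab <- makeLesionLabels(min(animals$hlvc_percent[i], 100),
                              nContraVox = 3000L)
      ## a zero AAR leaves the endpoint ratio undefined (NA) for this animal
      aarForRatio <- if (isTRUE(meas$aar_percent[i] > 0))
        meas$aar_percent[i] else NA_real_
      vol <- volumetryFromLabels(lab$labels, aarPercent = aarForRatio)
      meas$hlvc_percent[i] <- hlvcPercent(vol)
      meas$endpoint_ratio[i] <- endpointRatioValue(vol)
      meas$crc_ipsi[i] <- .pipelineCrc(animals$crc_ipsi[i], config@crc,
                                       seeds[i, 2])
      meas$crc_contra[i] <- .pipelineCrc(animals$crc_contra[i], config@crc,
                                         seeds[i, 2] + 1L)
      oi <- .pipelineOxphos(animals$ocr_CI_ipsi[i], animals$ocr_CII_ipsi[i],
                            animals$ocr_CIV_ipsi[i], config@oxphos,
                            seeds[i, 3])
      oc <- .pipelineOxphos(animals$ocr_CI_contra[i],
                            animals$ocr_CII_contra[i],
                            animals$ocr_CIV_contra[i], config@oxphos,
                            seeds[i, 4])
      meas[i, c("ocr_CI_ipsi", "ocr_CII_ipsi", "ocr_CIV_ipsi")] <- oi
      meas[i, c("ocr_CI_contra", "ocr_CII_contra", "ocr_CIV_contra")] <- oc
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      animals$included[i] <- FALSE
      if (animals$exclusion_reason[i] == "")
        animals$exclusion_reason[i] <- "stage failure during processing"
    }
  }
  ## replace ground-truth endpoint draws by the measured values
  truthCols <- names(meas)
  out <- animals
  out[truthCols] <- meas

  included <- out[out$included, , drop = FALSE]
  endpoints <- c("aar_percent", "hlvc_percent", "endpoint_ratio",
                 "crc_ipsi", "crc_contra", "ocr_CI_ipsi", "ocr_CII_ipsi",
                 "ocr_CIV_ipsi")
  summaries <- do.call(rbind, lapply(unique(included$group), function(g) {
    do.call(rbind, lapply(endpoints, function(ep) {
      v <- included[[ep]][included$group == g]
      v <- v[is.finite(v)]
      if (!length(v)) return(NULL)
      s <- summarizeMedianIqr(v)
      data.frame(group = g, endpoint = ep, n = s@n, median = s@median,
                 q25 = s@q25, q75 = s@q75, stringsAsFactors = FALSE)
    }))
  }))

  grp <- function(g) included[included$group == g, , drop = FALSE]
  tests <- list()
  addMw <- function(name, a, b, ep) {
    va <- grp(a)[[ep]]; vb <- grp(b)[[ep]]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (length(va) && length(vb))
      tests[[name]] <<- mannWhitney(va, vb)
  }
  addMw("aar_tMCAO_vs_pMCAO", "tMCAO", "pMCAO", "aar_percent")
  addMw("ratio_tMCAO_vs_pMCAO", "tMCAO", "pMCAO", "endpoint_ratio")
  addMw("aar_tMCAO_vs_CsA", "tMCAO", "tMCAO_CsA", "aar_percent")
  addMw("ratio_tMCAO_vs_CsA", "tMCAO", "tMCAO_CsA", "endpoint_ratio")
  addMw("crc_ipsi_tMCAO_vs_CsA", "tMCAO", "tMCAO_CsA", "crc_ipsi")

  kwGroups <- lapply(c("Sham", "tMCAO", "pMCAO"), function(g) grp(g)$crc_ipsi)
  if (all(vapply(kwGroups, function(v) sum(is.finite(v)) > 0, logical(1))))
    tests$crc_ipsi_KW <- kruskalWallis(kwGroups)

  ns <- included[!is.na(included$neuroscore) &
                   included$group %in% c("tMCAO", "pMCAO"), ]
  if (nrow(ns) && length(unique(ns$group)) == 2L) {
    tab <- table(ns$group, categorizeNeuroscore(ns$neuroscore))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) >= 2L)
      tests$neuroscore_tMCAO_vs_pMCAO <- chiSquareOutcome(tab)
  }

  mcao <- included[included$group != "Sham", ]
  if (sum(stats::complete.cases(mcao[, c("hlvc_percent", "crc_ipsi")])) >= 4)
    tests$lesion_crc_correlation <-
      correlateLesionCrc(mcao$hlvc_percent, mcao$crc_ipsi,
                         method = config@stats$correlationMethod)

  two <- included[included$group %in% c("tMCAO", "tMCAO_CsA"), ]
  if (length(unique(two$group)) == 2L && all(table(two$group) >= 3))
    tests$ancova_lesion_on_aar_CsA <- ancovaLesionOnAar(two)

  cfgString <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  report <- new("PipelineReport", animals = out,
                summaries = summaries, tests = tests,
                provenance = list(seed = config@seed,
                                  configHash = .configHash(cfgString),
                                  version = as.character(
                                    utils::packageVersion("strokeIR"))))
  if (nzchar(config@outDir)) {
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    writeCohortCsv(out, file.path(config@outDir, "animals.csv"))
    writeReportJson(report, file.path(config@outDir, "report.json"))
  }
  report
}

#' Serialize a pipeline report to JSON
#'
#' @param report a \linkS4class{PipelineReport}
#' @param path output JSON path.
#' @return invisibly, the path
#' @export
writeReportJson <- function(report, path) {
  tests <- lapply(report@tests, function(tr) {
    list(method = tr@method, statistic = as.list(tr@statistic),
         p_value = tr@pValue, effect = as.list(tr@effect),
         note = tr@note)
  })
  jsonlite::write_json(
    list(provenance = report@provenance,
         summaries = report@summaries,
         tests = tests,
         animals = report@animals),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors the \code{\link{pipelineConfig}} arguments; round-trips
#' losslessly.
#'
#' @param config a \linkS4class{PipelineConfig}
#' @param path YAML path.
#' @return \code{readPipelineConfig}: a \linkS4class{PipelineConfig}
#' @export
writePipelineConfig <- function(config, path) {
  co <- config@cohort
  np <- lapply(seq_len(nrow(co@neuroscoreProbs)),
               function(i) unname(co@neuroscoreProbs[i, ]))
  names(np) <- rownames(co@neuroscoreProbs)
  yaml::write_yaml(list(
    seed = config@seed, outDir = config@outDir,
    ceus = config@ceus, crc = config@crc,
    oxphos = list(noiseSd = config@oxphos$noiseSd,
                  inhibitedOcr = as.list(config@oxphos$inhibitedOcr)),
    stats = config@stats,
    cohort = list(groupSizes = as.list(co@groupSizes),
                  exclusionProb = as.list(co@exclusionProb),
                  severityCoupling = co@severityCoupling,
                  seed = co@seed,
                  endpointTargets = as.list(co@endpointTargets),
                  neuroscoreProbs = np)),
    path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  et <- as.data.frame(y$cohort$endpointTargets, stringsAsFactors = FALSE)
  np <- do.call(rbind, y$cohort$neuroscoreProbs)
  colnames(np) <- as.character(0:5)
  cspec <- cohortSpec(groupSizes = unlist(y$cohort$groupSizes),
                      endpointTargets = et,
                      neuroscoreProbs = np,
                      exclusionProb = unlist(y$cohort$exclusionProb),
                      severityCoupling = y$cohort$severityCoupling,
                      seed = y$cohort$seed)
  ox <- y$oxphos
  ox$inhibitedOcr <- unlist(ox$inhibitedOcr)
  pipelineConfig(cohort = cspec,
                 ceus = lapply(y$ceus, function(v)
                   if (is.list(v)) unlist(v) else v),
                 crc = y$crc, oxphos = ox, stats = y$stats,
                 seed = y$seed, outDir = y$outDir)
}
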