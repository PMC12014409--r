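#' @include AllClasses.R utils.R
NULL

## z value of the 0.75 standard-normal quantile used by the quartile fit
.zQ75 <- 0.6745

#' Log-normal parameters from a median and quartiles
#'
#' Endpoint distributions are modelled log-normal (positive, right-skewed),
#' parameterized from the median/IQR summaries that preclinical cohorts are
#' reported with. \code{mu = log(median)}; the two quartile constraints
#' \eqn{\log(q75/median) = 0.6745\sigma} and
#' \eqn{\log(median/q25) = 0.6745\sigma} over-determine \eqn{\sigma}, so the
#' two implied values are averaged.
#'
#' @param median,q25,q75 positive reals with \code{q25 <= median <= q75}.
#' @return list with \code{mu}, \code{sigma} and logical \code{degenerate}
#'   (TRUE when q25 = median = q75, i.e. sigma = 0).
#' @examples
#' lognormalFromMedianIqr(105, 80, 118)
#' @export
lognormalFromMedianIqr <- function(median, q25, q75) {
  if (any(!is.finite(c(median, q25, q75))) || any(c(median, q25, q75) <= 0))
    stop("median and quartiles must be positive finite numbers")
  if (q25 > median || median > q75)
    stop("quantiles must satisfy q25 <= median <= q75")
  sHi <- log(q75 / median) / .zQ75
  sLo <- log(median / q25) / .zQ75
  sigma <- (sHi + sLo) / 2
  degenerate <- sigma == 0
  if (degenerate)
    warning("q25 = median = q75: degenerate (zero-variance) distribution")
  list(mu = log(median), sigma = sigma, degenerate = degenerate)
}

## Default endpoint targets of the four-arm cohort. Imaging and assay
## endpoints are calibrated to the group median [q25; q75] summaries of the
## study conditions; hlvc targets are the endpoint-ratio medians applied to
## the AAR medians; Sham imaging endpoints and the CsA complex II rate are
## not reported and use plausible values (see the methods vignette).
.defaultEndpointTargets <- function() {
  rbind(
    data.frame(group = "Sham", endpoint = c(
      "aar_percent", "hlvc_percent", "crc_ipsi", "crc_contra",
      "ocr_CI_ipsi", "ocr_CII_ipsi", "ocr_CIV_ipsi",
      "ocr_CI_contra", "ocr_CII_contra", "ocr_CIV_contra"),
      median = c(1, 0.5, 105, 100, 24, 15.9, 24.8, 24, 15.9, 24.8),
      q25    = c(0.5, 0.3, 80, 85, 21.1, 14.7, 23.2, 21.1, 14.7, 23.2),
      q75    = c(2, 0.8, 118, 115, 29.5, 19.3, 32.9, 29.5, 19.3, 32.9)),
    data.frame(group = "tMCAO", endpoint = c(
      "aar_percent", "hlvc_percent", "crc_ipsi", "crc_contra",
      "ocr_CI_ipsi", "ocr_CII_ipsi", "ocr_CIV_ipsi",
      "ocr_CI_contra", "ocr_CII_contra", "ocr_CIV_contra"),
      median = c(48, 40, 70, 100, 13.4, 11.5, 23.0, 24, 15.9, 24.8),
      q25    = c(34, 25, 50, 85, 11.1, 6.7, 18.6, 21.1, 14.7, 23.2),
      q75    = c(61, 55, 90, 115, 16.2, 12.7, 23.5, 29.5, 19.3, 32.9)),
    data.frame(group = "tMCAO_CsA", endpoint = c(
      "aar_percent", "hlvc_percent", "crc_ipsi", "crc_contra",
      "ocr_CI_ipsi", "ocr_CII_ipsi", "ocr_CIV_ipsi",
      "ocr_CI_contra", "ocr_CII_contra", "ocr_CIV_contra"),
      median = c(46, 23, 90, 100, 18.8, 13, 23.8, 24, 15.9, 24.8),
      q25    = c(39, 15, 70, 85, 15.2, 10, 22.2, 21.1, 14.7, 23.2),
      q75    = c(50, 33, 110, 115, 24.1, 16, 28.2, 29.5, 19.3, 32.9)),
    data.frame(group = "pMCAO", endpoint = c(
      "aar_percent", "hlvc_percent", "crc_ipsi", "crc_contra",
      "ocr_CI_ipsi", "ocr_CII_ipsi", "ocr_CIV_ipsi",
      "ocr_CI_contra", "ocr_CII_contra", "ocr_CIV_contra"),
      median = c(52, 48, 60, 100, 11, 6.93, 15.1, 24, 15.9, 24.8),
      q25    = c(41, 35, 25, 85, 4.8, 4.2, 12.1, 21.1, 14.7, 23.2),
      q75    = c(56, 65, 65, 115, 16.4, 9.2, 21.4, 29.5, 19.3, 32.9))
  )
}

.defaultNeuroscoreProbs <- function() {
  m <- rbind(
    Sham      = c(0.00, 0.00, 0.00, 0.05, 0.15, 0.80),
    tMCAO     = c(0.08, 0.22, 0.30, 0.25, 0.10, 0.05),
    tMCAO_CsA = c(0.05, 0.20, 0.10, 0.10, 0.40, 0.15),
    pMCAO     = c(0.25, 0.30, 0.25, 0.12, 0.06, 0.02)
  )
  colnames(m) <- as.character(0:5)
  m
}

#' Construct a synthetic cohort specification
#'
#' Defaults emulate the four-arm study design: 12 Sham, 14 tMCAO,
#' 12 tMCAO + CsA, 14 pMCAO (52 randomized), endpoint log-normals
#' calibrated to the group median/IQR summaries, neuroscore category
#' probabilities matched to the group score medians, and a per-group
#' exclusion probability close to the realized exclusion rate.
#'
#' @param groupSizes named integer vector of animals per group.
#' @param endpointTargets data.frame (group, endpoint, median, q25, q75).
#' @param neuroscoreProbs matrix (groups x scores 0..5), rows summing to 1.
#' @param exclusionProb named per-group probability of exclusion.
#' @param severityCoupling loading of the latent per-animal ischemic
#'   severity factor in \[0, 1): more severely ischemic animals have larger
#'   AAR and lesion and lower ipsilateral CRC/OCR, while the marginal
#'   per-endpoint distributions stay exactly the calibrated log-normals.
#' @param seed integer random seed.
#' @return a \linkS4class{CohortSpec}
#' @export
cohortSpec <- function(groupSizes = c(Sham = 12L, tMCAO = 14L,
                                      tMCAO_CsA = 12L, pMCAO = 14L),
                       endpointTargets = .defaultEndpointTargets(),
                       neuroscoreProbs = .defaultNeuroscoreProbs(),
                       exclusionProb = c(Sham = 0.05, tMCAO = 0.22,
                                         tMCAO_CsA = 0.22, pMCAO = 0.22),
                       severityCoupling = 0.6,
                       seed = 1L) {
  new("CohortSpec", groupSizes = stats::setNames(as.integer(groupSizes),
                                                 names(groupSizes)),
      endpointTargets = endpointTargets, neuroscoreProbs = neuroscoreProbs,
      exclusionProb = exclusionProb, severityCoupling = severityCoupling,
      seed = asCount(seed, "seed"))
}

## Loading sign of each endpoint on the latent ischemic-severity factor:
## +1 lesion-side imaging endpoints, -1 protective ipsilateral assay
## endpoints, 0 contralateral endpoints.
.severityDirection <- function(endpoint) {
  if (endpoint %in% c("aar_percent", "hlvc_percent")) 1
  else if (grepl("_ipsi$", endpoint)) -1
  else 0
}

#' Generate a synthetic cohort of animal records
#'
#' Draws one row per animal: group label, log-normal endpoint values,
#' ordinal neuroscore, exclusion flags and the resulting inclusion status
#' (first failing criterion in protocol order is the reported reason).
#' Endpoints within an animal are coupled through a latent ischemic
#' severity factor (see \code{\link{cohortSpec}}): writing the log-scale
#' draw as \eqn{\mu + \sigma (\rho s z + \sqrt{1-\rho^2} e)} with shared
#' \eqn{z} and independent \eqn{e} keeps each marginal exactly
#' log-normal(\eqn{\mu, \sigma}) while severely ischemic animals get
#' larger lesions and weaker mitochondria, as observed cohorts do.
#' Reproducible under the spec's seed.
#'
#' @param spec a \linkS4class{CohortSpec}
#' @return list with \code{cohort} (data.frame of animal records) and
#'   \code{truth} (per group x endpoint log-normal parameters).
#' @examples
#' co <- makeCohort(cohortSpec())
#' table(co$cohort$group)
#' @export
makeCohort <- function(spec) {
  validObject(spec)
  groups <- names(spec@groupSizes)
  tg <- spec@endpointTargets
  endpoints <- unique(tg$endpoint)

  params <- do.call(rbind, lapply(seq_len(nrow(tg)), function(i) {
    p <- lognormalFromMedianIqr(tg$median[i], tg$q25[i], tg$q75[i])
    data.frame(group = tg$group[i], endpoint = tg$endpoint[i],
               mu = p$mu, sigma = p$sigma, stringsAsFactors = FALSE)
  }))

  ## exclusion reasons in the order they are assessed
  reasons <- c("no occlusion on per-occlusion Doppler",
               "no perfusion defect on CEUS",
               "incomplete follow-up",
               "infarct outside MCA territory",
               "lesion exceeds AAR")
  flagCols <- c("occlusion_on_doppler", "perfusion_defect_on_ceus",
                "complete_followup", "infarct_in_mca_territory",
                "lesion_within_aar")

  cohort <- withSeed(spec@seed, {
    rows <- lapply(groups, function(g) {
      n <- spec@groupSizes[[g]]
      if (n == 0L) return(NULL)
      df <- data.frame(id = character(n), group = g,
                       stringsAsFactors = FALSE)
      rho <- spec@severityCoupling
      z <- stats::rnorm(n)    # latent per-animal ischemic severity
      for (ep in endpoints) {
        pr <- params[params$group == g & params$endpoint == ep, ]
        df[[ep]] <- if (nrow(pr) == 1L) {
          s <- .severityDirection(ep)
          mix <- if (s == 0) stats::rnorm(n)
          else rho * s * z + sqrt(1 - rho^2) * stats::rnorm(n)
          exp(pr$mu + pr$sigma * mix)
        } else NA_real_
      }
      probs <- spec@neuroscoreProbs[g, ]
      df$neuroscore <- sample(0:5, n, replace = TRUE, prob = probs)
      excl <- stats::runif(n) < spec@exclusionProb[[g]]
      which_reason <- sample(seq_along(reasons), n, replace = TRUE,
                             prob = c(0.3, 0.15, 0.3, 0.15, 0.1))
      for (j in seq_along(flagCols)) df[[flagCols[j]]] <- TRUE
      for (i in which(excl)) df[[flagCols[which_reason[i]]]][i] <- FALSE
      df
    })
    do.call(rbind, rows)
  })
  cohort$id <- sprintf("M%03d", seq_len(nrow(cohort)))
  cohort$endpoint_ratio <- ifelse(cohort$aar_percent > 0,
                                  100 * cohort$hlvc_percent / cohort$aar_percent,
                                  NA_real_)

  incl <- lapply(seq_len(nrow(cohort)), function(i)
    applyExclusionCriteria(cohort[i, ]))
  cohort$included <- vapply(incl, `[[`, logical(1), "included")
  cohort$exclusion_reason <- vapply(incl, `[[`, character(1), "reason")

  rownames(cohort) <- NULL
  list(cohort = cohort, truth = params)
}
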