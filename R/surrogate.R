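## Analytic dose-prediction surrogate: exponential falloff of dose with
## distance to the target, with modality-specific falloff lengths.

#' FalloffParams: parameters of the analytic dose surrogate
#'
#' The surrogate assigns the prescription dose inside the target and an
#' exponential falloff with distance-to-target outside it:
#' `dose = max(bath, prescription * exp(-DPTV / lambda))`, zero outside the
#' body. A shorter falloff length for protons (`lambdaPT < lambdaXT`)
#' expresses the proton plan's sharper dose gradient around the target; the
#' bath terms model the low-dose wash that rotational photon delivery leaves
#' through the body. Optional Gaussian dose noise (spatially correlated,
#' correlation length `noiseCorrMm`) emulates the error of a dose-prediction
#' model; it is added outside the target only.
#'
#' @slot prescription Prescription dose, Gy.
#' @slot lambdaXT,lambdaPT Falloff lengths in mm, > 0, `lambdaPT < lambdaXT`.
#' @slot bathXT,bathPT Low-dose floor inside the body, Gy, >= 0.
#' @slot noiseSd Voxelwise noise standard deviation, Gy, >= 0.
#' @slot noiseCorrMm Noise correlation length, mm, >= 0.
#'
#' @name FalloffParams-class
#' @aliases FalloffParams-class
#' @export FalloffParams
#' @exportClass FalloffParams
FalloffParams <- setClass("FalloffParams",
  slots = c(prescription = "numeric", lambdaXT = "numeric",
            lambdaPT = "numeric", bathXT = "numeric", bathPT = "numeric",
            noiseSd = "numeric", noiseCorrMm = "numeric"))

setValidity("FalloffParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@prescription) || object@prescription <= 0)
    msg <- c(msg, "'prescription' must be a positive dose (Gy)")
  if (!one(object@lambdaXT) || !one(object@lambdaPT) ||
      object@lambdaXT <= 0 || object@lambdaPT <= 0)
    msg <- c(msg, "falloff lengths must be positive (mm)")
  else if (object@lambdaPT >= object@lambdaXT)
    msg <- c(msg, "'lambdaPT' must be below 'lambdaXT' (proton sparing)")
  if (!one(object@bathXT) || !one(object@bathPT) ||
      object@bathXT < 0 || object@bathPT < 0)
    msg <- c(msg, "bath doses must be non-negative (Gy)")
  if (!one(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "'noiseSd' must be non-negative (Gy)")
  if (!one(object@noiseCorrMm) || object@noiseCorrMm < 0)
    msg <- c(msg, "'noiseCorrMm' must be non-negative (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct FalloffParams
#'
#' Defaults give a photon falloff length of 22 mm with a 6 Gy dose bath and
#' a proton falloff length of 11.5 mm with a 1 Gy bath at the 73.92 Gy
#' prescription level, which places synthetic head-and-neck cohorts around
#' the grade-2 dysphagia decision boundary (see the package vignette).
#' Noise defaults to 3.2 Gy with a 6 mm correlation length, which yields
#' voxel-level mean absolute errors inside the organs at risk of a few
#' percent of prescription while perturbing structure mean doses by only a
#' fraction of a Gray, as a well-trained dose-prediction model would.
#'
#' @param prescription Prescription dose in Gy.
#' @param lambdaXT,lambdaPT Falloff lengths, mm.
#' @param bathXT,bathPT Low-dose floors, Gy.
#' @param noiseSd Dose-noise standard deviation, Gy.
#' @param noiseCorrMm Noise correlation length, mm.
#' @return A [FalloffParams-class] object.
#' @export
falloffParams <- function(prescription = 73.92, lambdaXT = 22,
                          lambdaPT = 11.5, bathXT = 6, bathPT = 1,
                          noiseSd = 3.2, noiseCorrMm = 6) {
  new("FalloffParams", prescription = prescription, lambdaXT = lambdaXT,
      lambdaPT = lambdaPT, bathXT = bathXT, bathPT = bathPT,
      noiseSd = noiseSd, noiseCorrMm = noiseCorrMm)
}

#' @rdname FalloffParams-class
#' @param object A `FalloffParams` object.
setMethod("show", "FalloffParams", function(object) {
  cat(sprintf(paste0(
    "FalloffParams: prescription %.2f Gy; lambda XT %.1f / PT %.1f mm; ",
    "bath XT %.1f / PT %.1f Gy; noise %.2f Gy (corr %.0f mm)\n"),
    object@prescription, object@lambdaXT, object@lambdaPT,
    object@bathXT, object@bathPT, object@noiseSd, object@noiseCorrMm))
})

#' Predict a dose distribution from geometry alone
#'
#' The analytic stand-in for a learned dose-prediction model: any function
#' with this signature (structures, modality, params, ...) returning a dose
#' [VoxelGrid-class] can replace it in the pipeline, so a trained predictor
#' can be plugged in without touching the downstream NTCP and decision
#' stages.
#'
#' The surrogate returns the prescription dose inside the PTV; inside the
#' body it falls off exponentially with the distance-to-target map, floored
#' at the modality's bath dose; outside the body the dose is zero. With
#' `noiseSd > 0` a seeded, spatially correlated Gaussian error field is
#' added outside the target (doses clipped at 0).
#'
#' @param structures A [StructureSet-class] with `ptv` and `body`.
#' @param modality `"XT"` or `"PT"`.
#' @param params A [FalloffParams-class].
#' @param dptv Optional precomputed [distanceToTarget()] map (recomputed if
#'   `NULL`).
#' @param noiseSeed Integer seed for the noise field; required when
#'   `params@noiseSd > 0`.
#' @return A dose [VoxelGrid-class] in Gy.
#' @examples
#' ss <- hnPhantomStructures(hnPhantomSpec(), caseSeed = 1)
#' d <- predictDose(ss, "XT", falloffParams(noiseSd = 0))
#' meanDose(d, structureMask(ss, "oral_cavity"))
#' @export
predictDose <- function(structures, modality = c("XT", "PT"), params,
                        dptv = NULL, noiseSeed = NULL) {
  modality <- match.arg(modality)
  stopifnot(is(params, "FalloffParams"))
  miss <- setdiff(c("ptv", "body"), structureNames(structures))
  if (length(miss))
    stop("missing structure(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ptv <- structureMask(structures, "ptv")
  body <- structureMask(structures, "body")
  if (is.null(dptv)) dptv <- distanceToTarget(ptv, body)

  lambda <- if (modality == "XT") params@lambdaXT else params@lambdaPT
  bath <- if (modality == "XT") params@bathXT else params@bathPT
  P <- params@prescription

  dist <- gridValues(dptv)
  inPtv <- gridValues(ptv) > 0
  inBody <- gridValues(body) > 0

  dose <- array(0, dim = dim(dist))
  out <- inBody & !inPtv
  dose[out] <- pmax(bath, P * exp(-dist[out] / lambda))
  dose[inPtv] <- P

  if (params@noiseSd > 0) {
    if (is.null(noiseSeed))
      stop("'noiseSeed' is required when params@noiseSd > 0", call. = FALSE)
    noise <- withSeed(noiseSeed,
      correlatedNoise(dim(dose), voxelSpacing(ptv), params@noiseCorrMm))
    dose[out] <- pmax(0, dose[out] + params@noiseSd * noise[out])
  }

  VoxelGrid(dose, spacing = voxelSpacing(ptv), origin = gridOrigin(ptv))
}
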