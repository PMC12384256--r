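#' @import methods
NULL

#' Organ-at-risk and endpoint vocabularies
#'
#' `ntcpOars()` returns the seven organ-at-risk (OAR) names whose mean doses
#' drive the NIPP NTCP models: both parotids, the submandibular gland, the
#' oral cavity and the upper/middle/inferior pharyngeal constrictor muscles
#' (PCM). `ntcpEndpoints()` returns the four modelled toxicity endpoints:
#' grade >=2 and grade >=3 xerostomia and dysphagia at 6 months.
#' `requiredStructures()` adds the planning target volume (PTV) and the
#' external body contour, which the volumetric stages need.
#'
#' @return Character vector of canonical names.
#' @export
ntcpOars <- function() {
  c("parotid_l", "parotid_r", "submandibular", "oral_cavity",
    "pcm_u", "pcm_m", "pcm_i")
}

#' @rdname ntcpOars
#' @export
ntcpEndpoints <- function() c("Xer2+", "Xer3+", "Dys2+", "Dys3+")

#' @rdname ntcpOars
#' @export
requiredStructures <- function() c("ptv", "body", ntcpOars())

## ---------------------------------------------------------------------------
## VoxelGrid
## ---------------------------------------------------------------------------

#' VoxelGrid: a 3D scalar lattice with physical spacing
#'
#' The elementary container of the package: a 3D array of voxel values (dose
#' in Gy, a binary mask, CT numbers, or distances in mm) together with the
#' voxel spacing and the physical origin, both in millimetres. Values refer
#' to voxel centres. `NA` marks voxels where the quantity is undefined (e.g.
#' distance-to-target outside the body).
#'
#' @slot values 3D numeric array.
#' @slot spacing Numeric length-3, voxel size in mm along each axis; > 0.
#' @slot origin Numeric length-3, physical coordinate of the centre of voxel
#'   (1,1,1), in mm.
#'
#' @name VoxelGrid-class
#' @aliases VoxelGrid-class
#' @export VoxelGrid
#' @exportClass VoxelGrid
VoxelGrid <- setClass("VoxelGrid",
  slots = c(values = "array", spacing = "numeric", origin = "numeric"),
  prototype = prototype(
    values = array(0, dim = c(1L, 1L, 1L)),
    spacing = c(1, 1, 1), origin = c(0, 0, 0)
  )
)

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite values (mm)")
  if (any(is.infinite(object@values)))
    msg <- c(msg, "'values' must be finite (NA allowed for undefined voxels)")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param values 3D numeric array of voxel values.
#' @param spacing Voxel spacing in mm (length 3, recycled from length 1).
#' @param origin Physical position of the first voxel centre, mm.
#' @return A [VoxelGrid-class] object.
#' @examples
#' vg <- VoxelGrid(array(50, dim = c(4, 4, 4)), spacing = c(2, 2, 3))
#' gridDim(vg)
#' @export
VoxelGrid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.double(values)) # logical/integer masks become numeric storage
    values <- array(as.numeric(values), dim = dim(values))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VoxelGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

## ---------------------------------------------------------------------------
## StructureSet
## ---------------------------------------------------------------------------

#' StructureSet: named binary masks on a shared lattice
#'
#' A collection of binary [VoxelGrid-class] masks (1 inside the structure, 0
#' outside) sharing one lattice. The NTCP pipeline expects the names returned
#' by [requiredStructures()]: `ptv`, `body` and the seven NTCP OARs.
#'
#' @slot masks Named list of binary `VoxelGrid` objects.
#'
#' @name StructureSet-class
#' @aliases StructureSet-class
#' @export StructureSet
#' @exportClass StructureSet
StructureSet <- setClass("StructureSet", slots = c(masks = "list"))

setValidity("StructureSet", function(object) {
  msg <- character()
  m <- object@masks
  if (length(m) == 0L) return("at least one mask required")
  if (is.null(names(m)) || any(!nzchar(names(m))) || anyDuplicated(names(m)))
    msg <- c(msg, "masks must have unique non-empty names")
  if (!all(vapply(m, is, logical(1), class2 = "VoxelGrid")))
    return("all masks must be VoxelGrid objects")
  ref <- m[[1L]]
  for (nm in names(m)) {
    g <- m[[nm]]
    if (!identical(dim(g@values), dim(ref@values)) ||
        !isTRUE(all.equal(g@spacing, ref@spacing)) ||
        !isTRUE(all.equal(g@origin, ref@origin)))
      msg <- c(msg, sprintf("mask '%s' is not on the shared lattice", nm))
    v <- g@values
    if (anyNA(v) || !all(v %in% c(0, 1)))
      msg <- c(msg, sprintf("mask '%s' is not binary {0,1}", nm))
  }
  if ("ptv" %in% names(m) && "body" %in% names(m)) {
    if (any(m[["ptv"]]@values > m[["body"]]@values))
      msg <- c(msg, "'ptv' must be contained in 'body'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StructureSet
#'
#' @param masks Named list of binary [VoxelGrid-class] masks on one lattice.
#' @return A [StructureSet-class] object.
#' @export
StructureSet <- function(masks) new("StructureSet", masks = masks)

## ---------------------------------------------------------------------------
## OarDoseSummary
## ---------------------------------------------------------------------------

#' OarDoseSummary: per-OAR mean doses for one plan
#'
#' The scalar reduction of a dose distribution that the NTCP models consume:
#' one mean dose (Gy) per organ at risk, plus the prescription dose of the
#' plan (used to normalise dose errors to percent of prescription).
#'
#' @slot dmean Named numeric vector of mean doses in Gy, non-negative.
#' @slot prescription Prescription dose in Gy.
#'
#' @name OarDoseSummary-class
#' @aliases OarDoseSummary-class
#' @export OarDoseSummary
#' @exportClass OarDoseSummary
OarDoseSummary <- setClass("OarDoseSummary",
  slots = c(dmean = "numeric", prescription = "numeric"))

setValidity("OarDoseSummary", function(object) {
  msg <- character()
  if (is.null(names(object@dmean)) || any(!nzchar(names(object@dmean))))
    msg <- c(msg, "'dmean' must be a named vector")
  if (any(!is.finite(object@dmean)) || any(object@dmean < 0))
    msg <- c(msg, "'dmean' must be finite and non-negative (Gy)")
  if (length(object@prescription) != 1L || !is.finite(object@prescription) ||
      object@prescription <= 0)
    msg <- c(msg, "'prescription' must be a single positive dose (Gy)")
  if (length(msg)) msg else TRUE
})

#' Construct an OarDoseSummary
#'
#' @param dmean Named numeric vector of mean doses (Gy), one per OAR.
#' @param prescription Prescription dose in Gy (default 73.92, the PGTV74
#'   level).
#' @return An [OarDoseSummary-class] object.
#' @examples
#' ds <- OarDoseSummary(c(parotid_l = 25, parotid_r = 25, submandibular = 35,
#'                        oral_cavity = 30, pcm_u = 40, pcm_m = 35, pcm_i = 30))
#' doseMeans(ds)
#' @export
OarDoseSummary <- function(dmean, prescription = 73.92) {
  new("OarDoseSummary", dmean = dmean, prescription = as.numeric(prescription))
}

## ---------------------------------------------------------------------------
## NTCPProfile / DeltaProfile
## ---------------------------------------------------------------------------

#' NTCPProfile: the four endpoint probabilities for one modality
#'
#' Normal tissue complication probabilities for the four NIPP endpoints,
#' stored as fractions in (0, 1), labelled with the treatment modality
#' (`"XT"` photon or `"PT"` proton).
#'
#' @slot modality `"XT"` or `"PT"`.
#' @slot ntcp Named numeric of length 4 (names [ntcpEndpoints()]),
#'   each strictly in (0, 1).
#'
#' @name NTCPProfile-class
#' @aliases NTCPProfile-class
#' @export NTCPProfile
#' @exportClass NTCPProfile
NTCPProfile <- setClass("NTCPProfile",
  slots = c(modality = "character", ntcp = "numeric"))

setValidity("NTCPProfile", function(object) {
  msg <- character()
  if (!identical(length(object@modality), 1L) ||
      !object@modality %in% c("XT", "PT"))
    msg <- c(msg, "'modality' must be \"XT\" or \"PT\"")
  if (!setequal(names(object@ntcp), ntcpEndpoints()))
    msg <- c(msg, "'ntcp' must be named by the four NIPP endpoints")
  if (any(!is.finite(object@ntcp)) || any(object@ntcp <= 0) ||
      any(object@ntcp >= 1))
    msg <- c(msg, "probabilities must lie strictly in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct an NTCPProfile
#'
#' @param modality `"XT"` (photon) or `"PT"` (proton).
#' @param ntcp Named probabilities (fractions) for the four endpoints.
#' @return An [NTCPProfile-class] object.
#' @export
NTCPProfile <- function(modality, ntcp) {
  new("NTCPProfile", modality = modality, ntcp = ntcp[ntcpEndpoints()])
}

#' DeltaProfile: per-endpoint NTCP reduction from protons
#'
#' For one patient, the per-endpoint difference
#' `delta = NTCP_XT - NTCP_PT` (the expected toxicity-risk reduction from
#' protons), plus the photon-plan NTCP levels retained for the decision
#' tree's photon-level gate. The grade-2 and grade-3 sums used by the
#' combined decision steps are available via [deltaSum2()] and [deltaSum3()].
#'
#' @slot delta Named numeric of length 4, each in (-1, 1).
#' @slot xtLevels Named numeric of length 4: the photon NTCP levels.
#'
#' @name DeltaProfile-class
#' @aliases DeltaProfile-class
#' @export DeltaProfile
#' @exportClass DeltaProfile
DeltaProfile <- setClass("DeltaProfile",
  slots = c(delta = "numeric", xtLevels = "numeric"))

setValidity("DeltaProfile", function(object) {
  msg <- character()
  if (!setequal(names(object@delta), ntcpEndpoints()) ||
      !setequal(names(object@xtLevels), ntcpEndpoints()))
    msg <- c(msg, "'delta' and 'xtLevels' must be named by the four endpoints")
  if (any(!is.finite(object@delta)) || any(abs(object@delta) >= 1))
    msg <- c(msg, "'delta' values must lie in (-1, 1)")
  if (any(!is.finite(object@xtLevels)) || any(object@xtLevels <= 0) ||
      any(object@xtLevels >= 1))
    msg <- c(msg, "'xtLevels' must lie strictly in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a DeltaProfile directly from numbers
#'
#' Mostly useful in tests and threshold studies; the usual route is
#' [deltaProfile()] from two [NTCPProfile-class] objects.
#'
#' @param delta Named per-endpoint NTCP differences (fractions).
#' @param xtLevels Named photon NTCP levels (fractions).
#' @return A [DeltaProfile-class] object.
#' @export
DeltaProfile <- function(delta, xtLevels) {
  new("DeltaProfile", delta = delta[ntcpEndpoints()],
      xtLevels = xtLevels[ntcpEndpoints()])
}

## ---------------------------------------------------------------------------
## DecisionThresholds / DecisionResult
## ---------------------------------------------------------------------------

#' DecisionThresholds: the NIPP decision-tree cut-offs
#'
#' Thresholds on delta-NTCP (fractions of probability). Grade-2 endpoints
#' use the single-endpoint threshold 0.10 and (when neither fires) a
#' combined-sum threshold; grade-3 endpoints use 0.05 and their combined
#' sum. A photon-level gate can require at least one grade-2 photon NTCP to
#' reach `xtGate` before any proton indication is considered.
#'
#' @slot t2Single Grade-2 single-endpoint threshold (default 0.10).
#' @slot t2Sum Grade-2 combined-sum threshold (default 0.15).
#' @slot t3Single Grade-3 single-endpoint threshold (default 0.05).
#' @slot t3Sum Grade-3 combined-sum threshold (default 0.075).
#' @slot xtGate Minimum grade-2 photon NTCP for gate (default 0.10).
#' @slot gateEnabled Whether the photon-level gate is applied (default TRUE).
#'
#' @name DecisionThresholds-class
#' @aliases DecisionThresholds-class
#' @export DecisionThresholds
#' @exportClass DecisionThresholds
DecisionThresholds <- setClass("DecisionThresholds",
  slots = c(t2Single = "numeric", t2Sum = "numeric", t3Single = "numeric",
            t3Sum = "numeric", xtGate = "numeric", gateEnabled = "logical"))

setValidity("DecisionThresholds", function(object) {
  msg <- character()
  vals <- c(object@t2Single, object@t2Sum, object@t3Single, object@t3Sum,
            object@xtGate)
  if (length(vals) != 5L || any(!is.finite(vals)) || any(vals <= 0) ||
      any(vals >= 1))
    msg <- c(msg, "all thresholds must be single values strictly in (0, 1)")
  else if (object@t3Single >= object@t2Single)
    msg <- c(msg, "grade-3 single threshold must be below the grade-2 one")
  if (length(object@gateEnabled) != 1L || is.na(object@gateEnabled))
    msg <- c(msg, "'gateEnabled' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct DecisionThresholds
#'
#' Defaults follow the Dutch NIPP convention: 10% for a single grade-2
#' endpoint, 15% for the grade-2 sum, 5% for a single grade-3 endpoint,
#' 7.5% for the grade-3 sum, and a 10% photon-level gate on the grade-2
#' endpoints.
#'
#' @param t2Single,t2Sum,t3Single,t3Sum,xtGate Thresholds as fractions.
#' @param gateEnabled Apply the photon-level gate?
#' @return A [DecisionThresholds-class] object.
#' @examples
#' decisionThresholds()
#' decisionThresholds(gateEnabled = FALSE)
#' @export
decisionThresholds <- function(t2Single = 0.10, t2Sum = 0.15,
                               t3Single = 0.05, t3Sum = 0.075,
                               xtGate = 0.10, gateEnabled = TRUE) {
  new("DecisionThresholds", t2Single = t2Single, t2Sum = t2Sum,
      t3Single = t3Single, t3Sum = t3Sum, xtGate = xtGate,
      gateEnabled = gateEnabled)
}

#' DecisionResult: a modality recommendation with its audit trace
#'
#' The outcome of running the NIPP decision tree on one patient: the
#' recommended modality, the identifier of the rule that fired, and a trace
#' recording every rule evaluated, the quantity compared, the threshold and
#' the outcome.
#'
#' @slot modality `"PT"` or `"XT"`.
#' @slot ruleFired One of `"gate"`, `"single2"`, `"sum2"`, `"single3"`,
#'   `"sum3"`, `"none"`.
#' @slot trace data.frame with columns `rule`, `quantity`, `threshold`,
#'   `outcome`.
#'
#' @name DecisionResult-class
#' @aliases DecisionResult-class
#' @export DecisionResult
#' @exportClass DecisionResult
DecisionResult <- setClass("DecisionResult",
  slots = c(modality = "character", ruleFired = "character",
            trace = "data.frame"))

setValidity("DecisionResult", function(object) {
  msg <- character()
  if (!object@modality %in% c("PT", "XT"))
    msg <- c(msg, "'modality' must be \"PT\" or \"XT\"")
  ok <- c("gate", "single2", "sum2", "single3", "sum3", "none")
  if (!object@ruleFired %in% ok)
    msg <- c(msg, "unknown 'ruleFired'")
  need <- c("rule", "quantity", "threshold", "outcome")
  if (!all(need %in% names(object@trace)))
    msg <- c(msg, "trace must have rule/quantity/threshold/outcome columns")
  if ((object@modality == "PT") !=
      (object@ruleFired %in% c("single2", "sum2", "single3", "sum3")))
    msg <- c(msg, "PT recommendation must coincide with an accepting rule")
  if (length(msg)) msg else TRUE
})
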