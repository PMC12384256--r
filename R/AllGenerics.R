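## Generics and accessors. Slots are never touched directly by user code.

#' @rdname VoxelGrid-class
#' @param object,x A package object.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname StructureSet-class
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' @rdname StructureSet-class
#' @export
setGeneric("structureMask", function(x, name) standardGeneric("structureMask"))

#' @rdname OarDoseSummary-class
#' @export
setGeneric("doseMeans", function(x) standardGeneric("doseMeans"))

#' @rdname OarDoseSummary-class
#' @export
setGeneric("prescriptionDose", function(x) standardGeneric("prescriptionDose"))

#' @rdname NTCPProfile-class
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname NTCPProfile-class
#' @export
setGeneric("ntcpValues", function(x) standardGeneric("ntcpValues"))

#' @rdname DeltaProfile-class
#' @export
setGeneric("deltaValues", function(x) standardGeneric("deltaValues"))

#' @rdname DeltaProfile-class
#' @export
setGeneric("xtLevels", function(x) standardGeneric("xtLevels"))

#' @rdname DeltaProfile-class
#' @export
setGeneric("deltaSum2", function(x) standardGeneric("deltaSum2"))

#' @rdname DeltaProfile-class
#' @export
setGeneric("deltaSum3", function(x) standardGeneric("deltaSum3"))

#' @rdname DecisionResult-class
#' @export
setGeneric("ruleFired", function(x) standardGeneric("ruleFired"))

#' @rdname DecisionResult-class
#' @export
setGeneric("decisionTrace", function(x) standardGeneric("decisionTrace"))

## ---------------------------------------------------------------------------
## Methods
## ---------------------------------------------------------------------------

#' @rdname VoxelGrid-class
setMethod("gridValues", "VoxelGrid", function(x) x@values)

#' @rdname VoxelGrid-class
setMethod("voxelSpacing", "VoxelGrid", function(x) x@spacing)

#' @rdname VoxelGrid-class
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)

#' @rdname VoxelGrid-class
setMethod("gridDim", "VoxelGrid", function(x) dim(x@values))

#' @rdname VoxelGrid-class
setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  rng <- suppressWarnings(range(object@values, na.rm = TRUE))
  cat(sprintf("VoxelGrid %d x %d x %d, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = " x ")))
  cat(sprintf("  value range: [%.4g, %.4g], %d NA voxels\n",
              rng[1], rng[2], sum(is.na(object@values))))
})

#' @rdname StructureSet-class
setMethod("structureNames", "StructureSet", function(x) names(x@masks))

#' @rdname StructureSet-class
#' @param name Structure name.
setMethod("structureMask", "StructureSet", function(x, name) {
  if (!name %in% names(x@masks))
    stop("structure '", name, "' not present; available: ",
         paste(names(x@masks), collapse = ", "), call. = FALSE)
  x@masks[[name]]
})

#' @rdname StructureSet-class
setMethod("show", "StructureSet", function(object) {
  ref <- object@masks[[1L]]
  d <- dim(ref@values)
  cat(sprintf("StructureSet of %d masks on a %d x %d x %d lattice\n",
              length(object@masks), d[1], d[2], d[3]))
  nv <- vapply(object@masks, function(m) sum(m@values), numeric(1))
  cat(paste0("  ", format(names(object@masks)), " : ", nv, " voxels\n"),
      sep = "")
})

#' @rdname OarDoseSummary-class
setMethod("doseMeans", "OarDoseSummary", function(x) x@dmean)

#' @rdname OarDoseSummary-class
setMethod("prescriptionDose", "OarDoseSummary", function(x) x@prescription)

#' @rdname OarDoseSummary-class
setMethod("show", "OarDoseSummary", function(object) {
  cat(sprintf("OarDoseSummary (prescription %.2f Gy)\n", object@prescription))
  cat(paste0("  ", format(names(object@dmean)), " : ",
             sprintf("%6.2f Gy", object@dmean), "\n"), sep = "")
})

#' @rdname NTCPProfile-class
setMethod("modality", "NTCPProfile", function(x) x@modality)

#' @rdname NTCPProfile-class
setMethod("ntcpValues", "NTCPProfile", function(x) x@ntcp)

#' @rdname NTCPProfile-class
setMethod("show", "NTCPProfile", function(object) {
  cat(sprintf("NTCPProfile [%s]\n", object@modality))
  cat(paste0("  ", format(names(object@ntcp)), " : ",
             sprintf("%5.1f %%", 100 * object@ntcp), "\n"), sep = "")
})

#' @rdname DeltaProfile-class
setMethod("deltaValues", "DeltaProfile", function(x) x@delta)

#' @rdname DeltaProfile-class
setMethod("xtLevels", "DeltaProfile", function(x) x@xtLevels)

#' @rdname DeltaProfile-class
setMethod("deltaSum2", "DeltaProfile",
          function(x) unname(x@delta[["Xer2+"]] + x@delta[["Dys2+"]]))

#' @rdname DeltaProfile-class
setMethod("deltaSum3", "DeltaProfile",
          function(x) unname(x@delta[["Xer3+"]] + x@delta[["Dys3+"]]))

#' @rdname DeltaProfile-class
setMethod("show", "DeltaProfile", function(object) {
  cat("DeltaProfile (NTCP_XT - NTCP_PT)\n")
  cat(paste0("  ", format(names(object@delta)), " : ",
             sprintf("%+5.1f %% (XT %5.1f %%)", 100 * object@delta,
                     100 * object@xtLevels), "\n"), sep = "")
  cat(sprintf("  grade-2 sum %+5.1f %%, grade-3 sum %+5.1f %%\n",
              100 * deltaSum2(object), 100 * deltaSum3(object)))
})

#' @rdname DecisionResult-class
setMethod("modality", "DecisionResult", function(x) x@modality)

#' @rdname DecisionResult-class
setMethod("ruleFired", "DecisionResult", function(x) x@ruleFired)

#' @rdname DecisionResult-class
setMethod("decisionTrace", "DecisionResult", function(x) x@trace)

#' @rdname DecisionResult-class
setMethod("show", "DecisionResult", function(object) {
  cat(sprintf("DecisionResult: %s (rule '%s')\n",
              object@modality, object@ruleFired))
  tr <- object@trace
  cat(paste0("  ", format(tr$rule), "  ",
             sprintf("%7.4f vs %6.4f", tr$quantity, tr$threshold), "  ",
             tr$outcome, "\n"), sep = "")
})

#' @rdname DecisionThresholds-class
setMethod("show", "DecisionThresholds", function(object) {
  cat(sprintf(paste0(
    "DecisionThresholds: grade-2 %.3f (sum %.3f), grade-3 %.3f (sum %.3f),",
    " gate %s at %.3f\n"),
    object@t2Single, object@t2Sum, object@t3Single, object@t3Sum,
    if (object@gateEnabled) "on" else "off", object@xtGate))
})
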