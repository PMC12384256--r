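## Readers/writers: NIfTI volumes, CSV tables (comma, UTF-8, header row,
## '.' decimal), JSON traces.

#' Read and write voxel grids as NIfTI
#'
#' Grids are stored as NIfTI-1 with the voxel spacing in `pixdim` and a
#' diagonal sform carrying spacing and origin. Values round-trip at 32-bit
#' float precision; masks are written as {0,1} volumes and re-binarised on
#' read.
#'
#' @param x A [VoxelGrid-class].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `readVoxelGrid` returns a [VoxelGrid-class].
#' @export
writeVoxelGrid <- function(x, path) {
  stopifnot(is(x, "VoxelGrid"))
  v <- gridValues(x)
  v[is.na(v)] <- -1 # NA encoded as -1 (distances/doses are >= 0)
  img <- RNifti::asNifti(v, pixdim = voxelSpacing(x))
  m <- diag(c(voxelSpacing(x), 1))
  m[1:3, 4] <- gridOrigin(x)
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVoxelGrid
#' @param mask Logical; if `TRUE`, values are re-binarised to {0,1}.
#' @export
readVoxelGrid <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  spacing <- abs(diag(xf)[1:3])
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  v <- array(as.numeric(img), dim = dim(img))
  if (mask) v <- round(v)
  VoxelGrid(v, spacing = spacing, origin = origin)
}

#' Tabular round-trip formats
#'
#' CSV writers/readers for the pipeline's tabular artifacts. Dialect:
#' comma-separated, UTF-8, header row, '.' decimal point.
#'
#' `writeMeanDoseTable`: columns `patient`, `oar`, `dmean_Gy`,
#' `prescription_Gy`. `writeNtcpTable`: `patient`, `modality`, `endpoint`,
#' `ntcp`. `writeDecisionTable`: `patient`, `modality`, `rule_fired`.
#' `writeDvhTable`: `dose_Gy`, `volume_pct`.
#'
#' @param summaries Named/indexed list of [OarDoseSummary-class].
#' @param path Output CSV path.
#' @return Readers return data.frames (or lists of objects, see each
#'   function); writers return the path invisibly.
#' @export
writeMeanDoseTable <- function(summaries, path) {
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    id <- if (!is.null(names(summaries)) && nzchar(names(summaries)[i]))
      names(summaries)[i] else as.character(i)
    data.frame(patient = id, oar = names(doseMeans(s)),
               dmean_Gy = unname(doseMeans(s)),
               prescription_Gy = prescriptionDose(s))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeMeanDoseTable
#' @export
readMeanDoseTable <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("patient", "oar", "dmean_Gy", "prescription_Gy")
  if (!all(need %in% names(df)))
    stop("mean-dose table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  out <- lapply(split(df, df$patient), function(d)
    OarDoseSummary(stats::setNames(d$dmean_Gy, d$oar),
                   prescription = d$prescription_Gy[1]))
  out[unique(as.character(df$patient))]
}

#' @rdname writeMeanDoseTable
#' @param profiles List of [NTCPProfile-class]; `patient` taken from list
#'   names or position. For reading, returns a data.frame.
#' @export
writeNtcpTable <- function(profiles, path) {
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    id <- if (!is.null(names(profiles)) && nzchar(names(profiles)[i]))
      names(profiles)[i] else as.character(i)
    data.frame(patient = id, modality = modality(p),
               endpoint = names(ntcpValues(p)), ntcp = unname(ntcpValues(p)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeMeanDoseTable
#' @export
readNtcpTable <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("patient", "modality", "endpoint", "ntcp")
  if (!all(need %in% names(df)))
    stop("NTCP table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname writeMeanDoseTable
#' @param decisions List of [DecisionResult-class].
#' @export
writeDecisionTable <- function(decisions, path) {
  df <- data.frame(
    patient = if (!is.null(names(decisions))) names(decisions)
              else as.character(seq_along(decisions)),
    modality = vapply(decisions, modality, character(1)),
    rule_fired = vapply(decisions, ruleFired, character(1)))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeMeanDoseTable
#' @export
readDecisionTable <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("patient", "modality", "rule_fired")
  if (!all(need %in% names(df)))
    stop("decision table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname writeMeanDoseTable
#' @param dvh data.frame from [cumulativeDVH()].
#' @export
writeDvhTable <- function(dvh, path) {
  utils::write.csv(dvh, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Decision traces as JSON
#'
#' One JSON object per patient holding the recommended modality, the rule
#' fired and the full rule-by-rule trace, so any cohort-level attribution
#' can be audited offline.
#'
#' @param decisions List of [DecisionResult-class].
#' @param path Output `.json` path.
#' @return `readTracesJSON` returns the parsed list.
#' @export
writeTracesJSON <- function(decisions, path) {
  ids <- if (!is.null(names(decisions))) names(decisions)
         else as.character(seq_along(decisions))
  payload <- stats::setNames(lapply(decisions, function(d) list(
    modality = modality(d), rule_fired = ruleFired(d),
    trace = decisionTrace(d))), ids)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname writeTracesJSON
#' @export
readTracesJSON <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
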