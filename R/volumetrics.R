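## Dose/mask reductions: mean dose, DVH queries, distance-to-target map.

sameLattice <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    isTRUE(all.equal(a@spacing, b@spacing)) &&
    isTRUE(all.equal(a@origin, b@origin))
}

checkLattice <- function(dose, mask, what = "mask") {
  if (!sameLattice(dose, mask))
    stop("dose grid and ", what, " are not on the same lattice ",
         "(shape/spacing/origin mismatch)", call. = FALSE)
  invisible(TRUE)
}

#' Mean dose over a structure
#'
#' Arithmetic mean of the dose over the voxels of a binary mask. Voxels
#' outside the mask never contribute.
#'
#' @param dose A [VoxelGrid-class] of dose values in Gy.
#' @param mask A binary [VoxelGrid-class] on the same lattice.
#' @param structure Optional structure name, used in error messages.
#' @return Mean dose in Gy (scalar).
#' @examples
#' d <- VoxelGrid(array(c(10, 30, 0, 0), dim = c(4, 1, 1)))
#' m <- VoxelGrid(array(c(1, 1, 0, 0), dim = c(4, 1, 1)))
#' meanDose(d, m) # 20
#' @export
meanDose <- function(dose, mask, structure = "structure") {
  checkLattice(dose, mask, structure)
  idx <- mask@values > 0
  if (!any(idx))
    stop("empty mask for '", structure, "': mean dose undefined",
         call. = FALSE)
  v <- dose@values[idx]
  if (anyNA(v))
    stop("dose is undefined (NA) inside '", structure, "'", call. = FALSE)
  mean(v)
}

#' Cumulative dose-volume histogram
#'
#' Cumulative DVH of a structure: the percentage of the structure volume
#' receiving at least each dose level. Bins run from 0 to just above the
#' maximum dose in steps of `binWidth`; the curve starts at 100% and is
#' monotonically non-increasing.
#'
#' @inheritParams meanDose
#' @param binWidth Dose bin width in Gy (> 0).
#' @return A data.frame with columns `dose_Gy` and `volume_pct`.
#' @seealso [volumeAtDose()] for exact V_D queries, [maxDose()].
#' @export
cumulativeDVH <- function(dose, mask, binWidth = 0.1, structure = "structure") {
  if (!is.numeric(binWidth) || length(binWidth) != 1L || binWidth <= 0)
    stop("'binWidth' must be a single positive dose in Gy", call. = FALSE)
  checkLattice(dose, mask, structure)
  idx <- mask@values > 0
  if (!any(idx))
    stop("empty mask for '", structure, "': DVH undefined", call. = FALSE)
  v <- dose@values[idx]
  levels <- seq(0, max(v) + binWidth, by = binWidth)
  vol <- vapply(levels, function(d) 100 * mean(v >= d), numeric(1))
  data.frame(dose_Gy = levels, volume_pct = vol)
}

#' Exact dose-volume queries
#'
#' `volumeAtDose()` returns V_D: the percentage of the structure volume
#' receiving at least `level` Gy (e.g. the per-protocol target criterion
#' V73.92 >= 95%). `maxDose()` returns the maximum voxel dose inside the
#' structure.
#'
#' @inheritParams meanDose
#' @param level Dose level D in Gy.
#' @return Percent volume (for `volumeAtDose`) or Gy (for `maxDose`).
#' @export
volumeAtDose <- function(dose, mask, level, structure = "structure") {
  checkLattice(dose, mask, structure)
  idx <- mask@values > 0
  if (!any(idx))
    stop("empty mask for '", structure, "'", call. = FALSE)
  100 * mean(dose@values[idx] >= level)
}

#' @rdname volumeAtDose
#' @export
maxDose <- function(dose, mask, structure = "structure") {
  checkLattice(dose, mask, structure)
  idx <- mask@values > 0
  if (!any(idx))
    stop("empty mask for '", structure, "'", call. = FALSE)
  max(dose@values[idx])
}

#' Distance-to-target (DPTV) map
#'
#' For every voxel of normal tissue inside the body but outside the planning
#' target volume, the minimum Euclidean distance (mm, anisotropic spacing
#' respected) to the nearest PTV voxel centre. The distance is 0 inside the
#' PTV and `NA` outside the body. This is the geometric input channel the
#' dose-falloff surrogate consumes.
#'
#' Distances are measured centre-to-centre, to the nearest PTV voxel centre
#' rather than to a polygonal PTV surface; for a voxelised target the two
#' conventions differ by at most half a voxel diagonal.
#'
#' @param ptv Binary [VoxelGrid-class] of the target.
#' @param body Binary [VoxelGrid-class] of the external contour; must
#'   contain the PTV.
#' @return A [VoxelGrid-class] of distances in mm (`NA` outside the body).
#' @export
distanceToTarget <- function(ptv, body) {
  checkLattice(ptv, body, "body")
  pv <- ptv@values > 0
  if (!any(pv))
    stop("empty PTV: distance map undefined", call. = FALSE)
  if (any(pv & !(body@values > 0)))
    stop("'ptv' must be contained in 'body'", call. = FALSE)
  d <- .edt3d(as.logical(pv), dim(ptv@values), ptv@spacing)
  d <- array(d, dim = dim(ptv@values))
  d[body@values <= 0] <- NA_real_
  VoxelGrid(d, spacing = ptv@spacing, origin = ptv@origin)
}

#' Reduce one case to its OAR mean doses
#'
#' Applies [meanDose()] to each of the seven NTCP organs at risk of a
#' [StructureSet-class] and returns the [OarDoseSummary-class] the NTCP
#' models consume.
#'
#' @param dose A [VoxelGrid-class] of dose in Gy.
#' @param structures A [StructureSet-class] containing all of [ntcpOars()].
#' @param prescription Prescription dose in Gy.
#' @return An [OarDoseSummary-class].
#' @export
summarizeCase <- function(dose, structures, prescription = 73.92) {
  oars <- ntcpOars()
  missing <- setdiff(oars, structureNames(structures))
  if (length(missing))
    stop("missing OAR structure(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dm <- vapply(oars, function(nm)
    meanDose(dose, structureMask(structures, nm), structure = nm),
    numeric(1))
  OarDoseSummary(dm, prescription = prescription)
}
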