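## Parametric head-and-neck dose phantom: a jittered template anatomy whose
## paired photon/proton doses place the cohort around the NIPP decision
## boundary. Lateral parotids partially overlap the target (so protons gain
## little on xerostomia), while the swallowing structures sit centrally at a
## distance (so protons spare them strongly) -- the geometry that makes
## grade-2 dysphagia the dominant selection endpoint.

#' Head-and-neck phantom specification
#'
#' Describes the template anatomy (all sizes and positions in mm, positions
#' relative to the lattice centre), the per-case jitter, and the dose
#' surrogate parameters. Axes: x left-right, y posterior-anterior (positive
#' anterior), z inferior-superior.
#'
#' The template: an elliptic body; a central PTV whose lateral extent
#' overlaps both parotids; the oral cavity anterior; one (combined)
#' submandibular gland inferior-lateral; and the upper/middle/inferior
#' pharyngeal constrictor muscles stacked posterior-centrally. Per-case
#' variability is mild jitter of structure centres and sizes around the
#' template, so decision drivers remain interpretable.
#'
#' @param dims Lattice size in voxels (length 3).
#' @param spacing Voxel spacing in mm (length 3).
#' @param params A [FalloffParams-class] for the dose surrogate.
#' @param centerJitterMm SD of the Gaussian jitter of structure centres, mm.
#' @param sizeJitter Half-width of the uniform relative jitter of semi-axes
#'   (0.1 means factors in 0.9--1.1).
#' @param cohortSize Default cohort size.
#' @param geometry Named list of template ellipsoids; each element is a list
#'   with `center` and `semiAxes` in mm. Defaults define the anatomy above.
#' @return A list of class `"hnPhantomSpec"`.
#' @examples
#' spec <- hnPhantomSpec()
#' names(spec$geometry)
#' @export
hnPhantomSpec <- function(dims = c(40L, 44L, 36L), spacing = c(4, 4, 4),
                          params = falloffParams(),
                          centerJitterMm = 3.5, sizeJitter = 0.18,
                          cohortSize = 48L,
                          geometry = NULL) {
  if (is.null(geometry)) {
    geometry <- list(
      body          = list(center = c(0, 0, 0),     semiAxes = c(74, 82, 70)),
      ptv           = list(center = c(0, 0, 0),     semiAxes = c(34, 26, 30)),
      parotid_l     = list(center = c(-31, -2, 2),  semiAxes = c(12, 14, 16)),
      parotid_r     = list(center = c(31, -2, 2),   semiAxes = c(12, 14, 16)),
      submandibular = list(center = c(20, 26, -26), semiAxes = c(11, 10, 9)),
      oral_cavity   = list(center = c(0, 36, -8),   semiAxes = c(17, 13, 12)),
      pcm_u         = list(center = c(0, -35, 12),  semiAxes = c(13, 6, 8)),
      pcm_m         = list(center = c(0, -36, -4),  semiAxes = c(13, 6, 8)),
      pcm_i         = list(center = c(0, -37, -20), semiAxes = c(13, 6, 8))
    )
  }
  stopifnot(length(dims) == 3L, length(spacing) == 3L, all(spacing > 0),
            is(params, "FalloffParams"),
            all(requiredStructures() %in% names(geometry)))
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 params = params, centerJitterMm = centerJitterMm,
                 sizeJitter = sizeJitter, cohortSize = as.integer(cohortSize),
                 geometry = geometry),
            class = "hnPhantomSpec")
}

# Binary ellipsoid on the lattice; center in mm relative to lattice centre.
ellipsoidMask <- function(dims, spacing, center, semiAxes) {
  mid <- (dims - 1) / 2 * spacing
  ax <- (seq_len(dims[1]) - 1) * spacing[1] - mid[1]
  ay <- (seq_len(dims[2]) - 1) * spacing[2] - mid[2]
  az <- (seq_len(dims[3]) - 1) * spacing[3] - mid[3]
  u2 <- ((ax - center[1]) / semiAxes[1])^2
  v2 <- ((ay - center[2]) / semiAxes[2])^2
  w2 <- ((az - center[3]) / semiAxes[3])^2
  inside <- outer(outer(u2, v2, `+`), w2, `+`) <= 1
  array(as.numeric(inside), dim = dims)
}

# Jittered structure set for one case; shrinks the jitter and retries if a
# structure voxelises empty (degenerate geometry).
#' Generate the jittered structure set of one phantom case
#'
#' @param spec An [hnPhantomSpec()] specification.
#' @param caseSeed Integer seed controlling the geometry jitter.
#' @return A [StructureSet-class] with all of [requiredStructures()].
#' @export
hnPhantomStructures <- function(spec, caseSeed) {
  stopifnot(inherits(spec, "hnPhantomSpec"))
  jitterScale <- 1
  for (attempt in 1:5) {
    ss <- withSeed(caseSeed + (attempt - 1L) * 997L, {
      masks <- list()
      bodyArr <- NULL
      for (nm in names(spec$geometry)) {
        g <- spec$geometry[[nm]]
        if (nm == "body") {
          cen <- g$center
          sa <- g$semiAxes
        } else {
          cen <- g$center +
            stats::rnorm(3, sd = spec$centerJitterMm * jitterScale)
          sa <- g$semiAxes *
            stats::runif(3, 1 - spec$sizeJitter * jitterScale,
                         1 + spec$sizeJitter * jitterScale)
        }
        arr <- ellipsoidMask(spec$dims, spec$spacing, cen, sa)
        if (nm == "body") bodyArr <- arr else arr <- arr * bodyArr
        masks[[nm]] <- VoxelGrid(arr, spacing = spec$spacing)
      }
      masks
    })
    nvox <- vapply(ss, function(m) sum(gridValues(m)), numeric(1))
    if (all(nvox > 0)) return(StructureSet(ss))
    jitterScale <- jitterScale / 2
    message("phantom case seed ", caseSeed, ": empty structure after ",
            "voxelisation; retrying with jitter scale ", jitterScale)
  }
  stop("degenerate phantom geometry for seed ", caseSeed, call. = FALSE)
}

#' Generate one synthetic phantom case
#'
#' Builds a jittered anatomy, computes its distance-to-target map, predicts
#' noise-free photon and proton doses (the stand-in for dosimetrist-made
#' reference plans), runs the full reference pipeline (mean doses, NTCP,
#' decision tree) to obtain the case's reference modality label, and then
#' adds seeded dose noise to produce the "predicted" doses that downstream
#' evaluation compares against that label.
#'
#' @param spec An [hnPhantomSpec()].
#' @param caseSeed Integer seed for this case (geometry and noise).
#' @param thresholds A [DecisionThresholds-class] for the reference label.
#' @return A list with elements `structures`, `ct`, `doseXT`, `dosePT`
#'   (noisy predictions), `refDoseXT`, `refDosePT` (noise-free references),
#'   `referenceLabel`, `referenceRule`, `referenceDelta`
#'   (a [DeltaProfile-class]), `dptv` and `caseSeed`.
#' @export
generateCase <- function(spec, caseSeed,
                         thresholds = decisionThresholds()) {
  structures <- hnPhantomStructures(spec, caseSeed)
  ptv <- structureMask(structures, "ptv")
  body <- structureMask(structures, "body")
  dptv <- distanceToTarget(ptv, body)

  noiseFree <- spec$params
  noiseFree@noiseSd <- 0
  refXT <- predictDose(structures, "XT", noiseFree, dptv = dptv)
  refPT <- predictDose(structures, "PT", noiseFree, dptv = dptv)

  P <- spec$params@prescription
  sumXT <- summarizeCase(refXT, structures, prescription = P)
  sumPT <- summarizeCase(refPT, structures, prescription = P)
  dp <- deltaProfile(evaluateNTCP(sumXT, "XT"), evaluateNTCP(sumPT, "PT"))
  ref <- decide(dp, thresholds)

  if (spec$params@noiseSd > 0) {
    doseXT <- predictDose(structures, "XT", spec$params, dptv = dptv,
                          noiseSeed = caseSeed * 2L + 1L)
    dosePT <- predictDose(structures, "PT", spec$params, dptv = dptv,
                          noiseSeed = caseSeed * 2L + 2L)
  } else {
    doseXT <- refXT
    dosePT <- refPT
  }

  # simple synthetic CT: air outside the body, soft tissue inside,
  # slightly denser target
  ctArr <- array(-1000, dim = spec$dims)
  ctArr[gridValues(body) > 0] <- 30
  ctArr[gridValues(ptv) > 0] <- 60
  ct <- VoxelGrid(ctArr, spacing = spec$spacing)

  list(structures = structures, ct = ct,
       doseXT = doseXT, dosePT = dosePT,
       refDoseXT = refXT, refDosePT = refPT,
       referenceLabel = modality(ref), referenceRule = ruleFired(ref),
       referenceDelta = dp, dptv = dptv, caseSeed = caseSeed)
}

#' Generate a synthetic cohort
#'
#' Per-case seeds are drawn deterministically from the master seed, so a
#' cohort is fully reproducible from `(spec, n, masterSeed)`.
#'
#' @param spec An [hnPhantomSpec()].
#' @param n Cohort size; defaults to `spec$cohortSize`.
#' @param masterSeed Integer master seed.
#' @param thresholds A [DecisionThresholds-class] for reference labels.
#' @return A list with `cases` (list of [generateCase()] results) and
#'   `manifest` (data.frame: case, seed, reference label/rule, the grade-2
#'   dysphagia delta and the grade-2 photon NTCP levels of the reference).
#' @export
generateCohort <- function(spec, n = spec$cohortSize, masterSeed = 20260101,
                           thresholds = decisionThresholds()) {
  # seeds kept well below .Machine$integer.max: per-case noise seeds are
  # derived as small integer multiples of the case seed
  seeds <- withSeed(masterSeed, sample.int(2L^28L, n))
  cases <- lapply(seeds, generateCase, spec = spec, thresholds = thresholds)
  manifest <- data.frame(
    case = seq_len(n),
    seed = seeds,
    referenceLabel = vapply(cases, `[[`, character(1), "referenceLabel"),
    referenceRule = vapply(cases, `[[`, character(1), "referenceRule"),
    refDeltaDys2 = vapply(cases, function(cs)
      deltaValues(cs$referenceDelta)[["Dys2+"]], numeric(1)),
    refDeltaXer2 = vapply(cases, function(cs)
      deltaValues(cs$referenceDelta)[["Xer2+"]], numeric(1)),
    refXtXer2 = vapply(cases, function(cs)
      xtLevels(cs$referenceDelta)[["Xer2+"]], numeric(1)),
    refXtDys2 = vapply(cases, function(cs)
      xtLevels(cs$referenceDelta)[["Dys2+"]], numeric(1))
  )
  list(cases = cases, manifest = manifest)
}

#' Quality-control checks for one phantom case
#'
#' Mirrors the per-protocol plan checks a physicist would run: target
#' coverage V(prescription) >= 95% on the noise-free plans, dose zero
#' outside the body, and non-empty OAR volumes. Failures are reported, not
#' fatal.
#'
#' @param case A case from [generateCase()].
#' @param prescription Prescription dose in Gy.
#' @return data.frame with columns `check`, `value`, `criterion`, `pass`.
#' @export
qcCase <- function(case, prescription = 73.92) {
  ss <- case$structures
  ptv <- structureMask(ss, "ptv")
  body <- structureMask(ss, "body")
  rows <- list()
  for (mod in c("XT", "PT")) {
    d <- case[[paste0("refDose", mod)]]
    v <- volumeAtDose(d, ptv, 0.999 * prescription, "ptv")
    rows[[paste0("coverage_", mod)]] <- data.frame(
      check = paste0("V", prescription, " [%] on PTV, ", mod),
      value = v, criterion = ">=95", pass = v >= 95)
    outside <- max(gridValues(d)[gridValues(body) <= 0])
    rows[[paste0("outside_", mod)]] <- data.frame(
      check = paste0("max dose outside body [Gy], ", mod),
      value = outside, criterion = "=0", pass = outside == 0)
  }
  for (nm in ntcpOars()) {
    nv <- sum(gridValues(structureMask(ss, nm)))
    rows[[paste0("vol_", nm)]] <- data.frame(
      check = paste0("voxels in ", nm), value = nv,
      criterion = ">0", pass = nv > 0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
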