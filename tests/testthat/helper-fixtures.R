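# Small in-code fixtures shared across test files.

# Dose summary with arbitrary but physiological mean doses.
fixtureSummary <- function(pl = 25, pr = 25, sub = 35, oc = 30,
                           pcmU = 40, pcmM = 35, pcmI = 30,
                           prescription = 73.92) {
  OarDoseSummary(c(parotid_l = pl, parotid_r = pr, submandibular = sub,
                   oral_cavity = oc, pcm_u = pcmU, pcm_m = pcmM,
                   pcm_i = pcmI), prescription = prescription)
}

# NTCP profile built directly from probabilities.
fixtureProfile <- function(modality, xer2, xer3, dys2, dys3) {
  NTCPProfile(modality, c("Xer2+" = xer2, "Xer3+" = xer3,
                          "Dys2+" = dys2, "Dys3+" = dys3))
}

# Delta profile with photon levels comfortably above the gate.
fixtureDelta <- function(dXer2 = 0, dXer3 = 0, dDys2 = 0, dDys3 = 0,
                         xtXer2 = 0.45, xtXer3 = 0.13, xtDys2 = 0.17,
                         xtDys3 = 0.04) {
  DeltaProfile(
    delta = c("Xer2+" = dXer2, "Xer3+" = dXer3, "Dys2+" = dDys2,
              "Dys3+" = dDys3),
    xtLevels = c("Xer2+" = xtXer2, "Xer3+" = xtXer3, "Dys2+" = xtDys2,
                 "Dys3+" = xtDys3))
}

# A small box-in-box geometry: PTV block inside a full body.
fixtureBoxStructures <- function(dims = c(10L, 10L, 10L),
                                 spacing = c(2, 2, 2),
                                 ptvIdx = list(4:6, 4:6, 4:6)) {
  ptv <- array(0, dims)
  ptv[ptvIdx[[1]], ptvIdx[[2]], ptvIdx[[3]]] <- 1
  list(ptv = VoxelGrid(ptv, spacing),
       body = VoxelGrid(array(1, dims), spacing))
}

# Brute-force all-pairs distance oracle for distanceToTarget.
bruteForceDptv <- function(ptv, body) {
  dims <- gridDim(ptv)
  sp <- voxelSpacing(ptv)
  pts <- which(gridValues(ptv) > 0, arr.ind = TRUE)
  pc <- sweep(pts - 1, 2, sp, `*`)
  out <- array(NA_real_, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (gridValues(body)[i, j, k] <= 0) next
      p <- (c(i, j, k) - 1) * sp
      out[i, j, k] <- sqrt(min(colSums((t(pc) - p)^2)))
    }
  out
}

# Small phantom spec for fast cohort tests (coarser lattice, noise-free by
# default).
fixtureSpec <- function(noiseSd = 0, ...) {
  hnPhantomSpec(dims = c(30L, 32L, 26L), spacing = c(5.5, 5.5, 5.5),
                params = falloffParams(noiseSd = noiseSd, ...))
}
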