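## Internal helpers: RNG scoping and separable Gaussian smoothing.

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
# Circular convolution at the edges (applied to noise fields only).
smooth3d <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    dm <- dim(a)
    m <- matrix(a, nrow = dm[1])
    m <- stats::filter(m, k, sides = 2, circular = TRUE) # columnwise
    a <- array(as.numeric(m), dim = dm)
    arr <- aperm(a, order(perm))
  }
  arr
}

# Spatially correlated Gaussian noise field with unit marginal sd.
correlatedNoise <- function(dims, spacing, corrMm) {
  w <- array(stats::rnorm(prod(dims)), dim = dims)
  if (corrMm > 0) {
    w <- smooth3d(w, corrMm / spacing)
    w <- w / stats::sd(w)
  }
  w
}
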