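## NIPP logistic NTCP models: mean-dose linear predictor -> logistic.

#' Load an NTCP coefficient registry
#'
#' The four NIPP logistic models (grade >=2 / >=3 xerostomia and dysphagia)
#' are shipped as a versioned JSON resource rather than hard-coded, so an
#' updated NIPP release can be swapped in via `path`. Each endpoint carries
#' an intercept, per-predictor weights in 1/Gy, and a fixed baseline-
#' complaint offset. The xerostomia models use the summed parotid mean dose
#' (`parotid_sum`) as a single predictor plus the submandibular gland; the
#' dysphagia models use the oral cavity and the three pharyngeal constrictor
#' muscles.
#'
#' @param path Path to a coefficient JSON file; default is the NIPP v2.2 set
#'   shipped with the package.
#' @return A list with elements `version` and `endpoints` (named list of
#'   `intercept`, `baseline_offset`, `weights`).
#' @examples
#' cf <- nippCoefficients()
#' cf$endpoints[["Xer2+"]]$intercept
#' @export
nippCoefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nipp_coefficients_v2.2.json",
                        package = "protonSelect", mustWork = TRUE)
  cf <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(ntcpEndpoints() %in% names(cf$endpoints)))
    stop("coefficient file must define all four endpoints: ",
         paste(ntcpEndpoints(), collapse = ", "), call. = FALSE)
  for (ep in ntcpEndpoints()) {
    e <- cf$endpoints[[ep]]
    if (!is.finite(e$intercept) || !is.finite(e$baseline_offset))
      stop("non-finite constants for endpoint ", ep, call. = FALSE)
    w <- unlist(e$weights)
    bad <- setdiff(names(w), c(ntcpOars(), "parotid_sum"))
    if (length(bad))
      stop("endpoint ", ep, " references unsupported predictor(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  cf
}

#' Linear predictor S of one NTCP model
#'
#' Evaluates `S = intercept + sum(weight_i * Dmean_i) + baseline_offset`
#' for one endpoint. The `parotid_sum` predictor is expanded to
#' `Dmean(parotid_l) + Dmean(parotid_r)`.
#'
#' @param endpoint One of [ntcpEndpoints()].
#' @param doses An [OarDoseSummary-class].
#' @param coefficients A registry from [nippCoefficients()].
#' @return The unitless linear predictor S.
#' @examples
#' ds <- OarDoseSummary(c(parotid_l = 25, parotid_r = 25, submandibular = 35,
#'                        oral_cavity = 0, pcm_u = 0, pcm_m = 0, pcm_i = 0))
#' linearPredictor("Xer2+", ds) # -2.2951 + 0.0996*50 + 0.0182*35
#' @export
linearPredictor <- function(endpoint, doses, coefficients = nippCoefficients()) {
  endpoint <- match.arg(endpoint, ntcpEndpoints())
  e <- coefficients$endpoints[[endpoint]]
  dm <- doseMeans(doses)
  w <- unlist(e$weights)
  s <- e$intercept + e$baseline_offset
  for (pred in names(w)) {
    need <- if (pred == "parotid_sum") c("parotid_l", "parotid_r") else pred
    missing <- setdiff(need, names(dm))
    if (length(missing))
      stop("mean dose missing for OAR(s): ",
           paste(missing, collapse = ", "), " (endpoint ", endpoint, ")",
           call. = FALSE)
    s <- s + w[[pred]] * sum(dm[need])
  }
  unname(s)
}

#' Logistic NTCP from a linear predictor
#'
#' The standard logistic `NTCP = 1 / (1 + exp(-S))`, evaluated stably for
#' large |S| (via `plogis`). Strictly increasing in S; `ntcpFromS(0)` is 0.5.
#'
#' @param s Unitless linear predictor(s); must be finite.
#' @return Probability fraction(s) in (0, 1).
#' @export
ntcpFromS <- function(s) {
  if (any(!is.finite(s)))
    stop("linear predictor must be finite", call. = FALSE)
  stats::plogis(s)
}

#' Evaluate all four NTCP endpoints for one plan
#'
#' @param doses An [OarDoseSummary-class] with all seven NTCP OARs.
#' @param modality `"XT"` (photon) or `"PT"` (proton) label for the profile.
#' @param coefficients A registry from [nippCoefficients()].
#' @return An [NTCPProfile-class].
#' @examples
#' ds <- OarDoseSummary(c(parotid_l = 30, parotid_r = 28, submandibular = 40,
#'                        oral_cavity = 35, pcm_u = 45, pcm_m = 38, pcm_i = 30))
#' evaluateNTCP(ds, "XT")
#' @export
evaluateNTCP <- function(doses, modality = c("XT", "PT"),
                         coefficients = nippCoefficients()) {
  modality <- match.arg(modality)
  missing <- setdiff(ntcpOars(), names(doseMeans(doses)))
  if (length(missing))
    stop("mean dose missing for OAR(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- vapply(ntcpEndpoints(), function(ep)
    ntcpFromS(linearPredictor(ep, doses, coefficients)), numeric(1))
  NTCPProfile(modality = modality, ntcp = p)
}
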