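## Evaluation: dose-prediction error (MAE/ME as % of prescription), decision
## confusion metrics, rank-based AUC, paired t-test.

#' Voxelwise dose-prediction error statistics
#'
#' For each organ at risk, the mean absolute error and the mean (signed)
#' error between predicted and reference doses, averaged first over the
#' structure's voxels within a case and then over cases, normalised by the
#' prescription dose and expressed in percent:
#' `MAE = mean_cases( mean_voxels |D_pred - D_ref| ) / prescription * 100`,
#' and ME the same without the absolute value.
#'
#' @param pred,ref Paired lists of dose [VoxelGrid-class] objects (same
#'   length, same lattices).
#' @param structureSets List of [StructureSet-class], one per case.
#' @param prescription Prescription dose in Gy.
#' @param oars Structure names to evaluate (default the seven NTCP OARs).
#' @return data.frame with columns `oar`, `mae_pct`, `me_pct`.
#' @export
doseErrorStats <- function(pred, ref, structureSets, prescription = 73.92,
                           oars = ntcpOars()) {
  if (length(pred) != length(ref) || length(pred) != length(structureSets))
    stop("'pred', 'ref' and 'structureSets' must be paired lists of equal ",
         "length", call. = FALSE)
  n <- length(pred)
  if (n == 0L) stop("no cases supplied", call. = FALSE)
  perOar <- lapply(oars, function(nm) {
    mae <- me <- numeric(n)
    for (j in seq_len(n)) {
      checkLattice(pred[[j]], ref[[j]], "reference dose")
      m <- structureMask(structureSets[[j]], nm)
      idx <- gridValues(m) > 0
      if (!any(idx))
        stop("empty mask for '", nm, "' in case ", j, call. = FALSE)
      diff <- gridValues(pred[[j]])[idx] - gridValues(ref[[j]])[idx]
      mae[j] <- mean(abs(diff))
      me[j] <- mean(diff)
    }
    data.frame(oar = nm,
               mae_pct = mean(mae) / prescription * 100,
               me_pct = mean(me) / prescription * 100)
  })
  out <- do.call(rbind, perOar)
  rownames(out) <- NULL
  out
}

#' Confusion counts for modality recommendations
#'
#' Positive means the selection of proton therapy: a true positive is a PT
#' recommendation where the reference is PT.
#'
#' @param decisions Character vector (or list of [DecisionResult-class]) of
#'   recommended modalities, `"PT"`/`"XT"`.
#' @param reference Character vector of reference labels, `"PT"`/`"XT"`.
#' @return Named integer vector with elements `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusionCounts(c("PT", "PT", "XT"), c("PT", "XT", "XT"))
#' @export
confusionCounts <- function(decisions, reference) {
  if (is.list(decisions))
    decisions <- vapply(decisions, modality, character(1))
  if (length(decisions) != length(reference))
    stop("decisions and reference labels must be paired", call. = FALSE)
  if (length(decisions) == 0L)
    stop("empty cohort", call. = FALSE)
  if (!all(decisions %in% c("PT", "XT")) || !all(reference %in% c("PT", "XT")))
    stop("labels must be \"PT\" or \"XT\"", call. = FALSE)
  c(tp = sum(decisions == "PT" & reference == "PT"),
    fp = sum(decisions == "PT" & reference == "XT"),
    fn = sum(decisions == "XT" & reference == "PT"),
    tn = sum(decisions == "XT" & reference == "XT"))
}

#' Classification metrics from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+FP+FN+TN)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, `F-score = 2TP/(2TP+FN+FP)`. Arithmetic is
#' exact; rounding is left to the caller or report layer. Metrics with a
#' zero denominator are returned as `NA` and flagged.
#'
#' @param counts Named vector from [confusionCounts()] (elements `tp`, `fp`,
#'   `fn`, `tn`).
#' @return List with `accuracy`, `sensitivity`, `specificity`, `f_score`
#'   (fractions in \[0,1\] or `NA`) and `flags` (character vector naming any
#'   undefined metrics).
#' @examples
#' m <- decisionMetrics(c(tp = 33, fp = 1, fn = 2, tn = 12))
#' round(100 * m$accuracy, 1) # 93.8
#' @export
decisionMetrics <- function(counts) {
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(counts)))
    stop("counts must contain tp/fp/fn/tn", call. = FALSE)
  counts <- counts[need]
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  flags <- character()
  rat <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, what)
      return(NA_real_)
    }
    num / den
  }
  list(accuracy = rat(tp + tn, tp + fp + fn + tn, "accuracy"),
       sensitivity = rat(tp, tp + fn, "sensitivity"),
       specificity = rat(tn, tn + fp, "specificity"),
       f_score = rat(2 * tp, 2 * tp + fn + fp, "f_score"),
       flags = flags)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic with
#' tie correction: the probability that a random positive case scores above
#' a random negative one, counting ties as one half. Scores are the
#' continuous proton-benefit scores of [benefitScore()]; labels use the
#' positive-means-PT convention.
#'
#' @param scores Numeric vector of continuous scores.
#' @param labels Character vector of `"PT"`/`"XT"` (or logical, TRUE = PT).
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  if (is.character(labels)) labels <- labels == "PT"
  if (length(scores) != length(labels))
    stop("scores and labels must be paired", call. = FALSE)
  npos <- sum(labels)
  nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    stop("AUC requires both classes present", call. = FALSE)
  r <- rank(scores) # midranks handle ties
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Paired two-sided t-test with degenerate-case flagging
#'
#' Thin wrapper over `stats::t.test(paired = TRUE)` that flags the
#' degenerate case of zero-variance differences (identical pairs give
#' `t = 0, p = 1`; a constant non-zero shift is reported as infinite
#' evidence) instead of erroring.
#'
#' @param a,b Paired numeric vectors.
#' @return List with `t`, `p`, `df`, `meanDiff` and `flag` (`NA` or a
#'   description of the degeneracy).
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("'a' and 'b' must be paired vectors of length >= 2", call. = FALSE)
  d <- a - b
  # same degeneracy guard as t.test ("data are essentially constant"),
  # but flagged instead of raised
  if (stats::sd(d) == 0 ||
      stats::sd(d) / sqrt(length(d)) < 10 * .Machine$double.eps *
        abs(mean(d))) {
    if (all(d == 0))
      return(list(t = 0, p = 1, df = length(d) - 1, meanDiff = 0,
                  flag = "identical pairs: no evidence of a difference"))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                meanDiff = mean(d),
                flag = "zero-variance differences: constant shift"))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), meanDiff = unname(tt$estimate), flag = NA)
}
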