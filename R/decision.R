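## NIPP delta-NTCP decision tree with auditable rule traces.

#' Delta-NTCP profile from paired photon/proton NTCP profiles
#'
#' Computes `delta = NTCP_XT - NTCP_PT` per endpoint and retains the photon
#' levels for the decision tree's photon-level gate.
#'
#' @param xt An [NTCPProfile-class] with modality `"XT"`.
#' @param pt An [NTCPProfile-class] with modality `"PT"`.
#' @return A [DeltaProfile-class].
#' @export
deltaProfile <- function(xt, pt) {
  if (modality(xt) != "XT" || modality(pt) != "PT")
    stop("expected one XT and one PT profile, in that order (got ",
         modality(xt), ", ", modality(pt), ")", call. = FALSE)
  DeltaProfile(delta = ntcpValues(xt) - ntcpValues(pt),
               xtLevels = ntcpValues(xt))
}

ruleRow <- function(rule, quantity, threshold, outcome) {
  data.frame(rule = rule, quantity = quantity, threshold = threshold,
             outcome = outcome, stringsAsFactors = FALSE)
}

#' Apply the NIPP decision tree to one patient
#'
#' Rules are evaluated in a fixed order and the first accepting rule wins:
#'
#' 1. *Gate* (optional): if no grade-2 photon NTCP reaches `xtGate`, the
#'    expected benefit is immaterial and the patient stays with photons.
#' 2. *single2*: delta Xer2+ or delta Dys2+ at or above the grade-2
#'    single-endpoint threshold (10%) indicates protons.
#' 3. *sum2*: the grade-2 delta sum at or above its combined threshold.
#' 4. *single3*: delta Xer3+ or delta Dys3+ at or above the grade-3
#'    threshold (5%).
#' 5. *sum3*: the grade-3 delta sum at or above its combined threshold.
#'
#' All comparisons are inclusive (>=). Every evaluated rule is recorded in
#' the trace, so cohort-level attribution (which rule selected each proton
#' patient) can be reconstructed from the results.
#'
#' @param dp A [DeltaProfile-class].
#' @param thresholds A [DecisionThresholds-class].
#' @return A [DecisionResult-class].
#' @examples
#' dp <- DeltaProfile(
#'   delta = c("Xer2+" = 0.02, "Dys2+" = 0.12, "Xer3+" = 0.01, "Dys3+" = 0.03),
#'   xtLevels = c("Xer2+" = 0.45, "Dys2+" = 0.17, "Xer3+" = 0.13, "Dys3+" = 0.04))
#' decide(dp)
#' @export
decide <- function(dp, thresholds = decisionThresholds()) {
  stopifnot(is(dp, "DeltaProfile"), is(thresholds, "DecisionThresholds"))
  d <- deltaValues(dp)
  lv <- xtLevels(dp)
  trace <- list()

  if (thresholds@gateEnabled) {
    gateLevel <- max(lv[["Xer2+"]], lv[["Dys2+"]])
    pass <- gateLevel >= thresholds@xtGate
    trace[["gate"]] <- ruleRow("gate", gateLevel, thresholds@xtGate,
                               if (pass) "pass" else "stop")
    if (!pass)
      return(DecisionResult(modality = "XT", ruleFired = "gate",
                            trace = do.call(rbind, trace)))
  }

  q1 <- max(d[["Xer2+"]], d[["Dys2+"]])
  hit1 <- q1 >= thresholds@t2Single
  trace[["single2"]] <- ruleRow("single2", q1, thresholds@t2Single,
                                if (hit1) "accept" else "continue")
  if (hit1)
    return(DecisionResult(modality = "PT", ruleFired = "single2",
                          trace = do.call(rbind, trace)))

  q2 <- deltaSum2(dp)
  hit2 <- q2 >= thresholds@t2Sum
  trace[["sum2"]] <- ruleRow("sum2", q2, thresholds@t2Sum,
                             if (hit2) "accept" else "continue")
  if (hit2)
    return(DecisionResult(modality = "PT", ruleFired = "sum2",
                          trace = do.call(rbind, trace)))

  q3 <- max(d[["Xer3+"]], d[["Dys3+"]])
  hit3 <- q3 >= thresholds@t3Single
  trace[["single3"]] <- ruleRow("single3", q3, thresholds@t3Single,
                                if (hit3) "accept" else "continue")
  if (hit3)
    return(DecisionResult(modality = "PT", ruleFired = "single3",
                          trace = do.call(rbind, trace)))

  q4 <- deltaSum3(dp)
  hit4 <- q4 >= thresholds@t3Sum
  trace[["sum3"]] <- ruleRow("sum3", q4, thresholds@t3Sum,
                             if (hit4) "accept" else "reject")
  if (hit4)
    return(DecisionResult(modality = "PT", ruleFired = "sum3",
                          trace = do.call(rbind, trace)))

  DecisionResult(modality = "XT", ruleFired = "none",
                 trace = do.call(rbind, trace))
}

#' Apply the decision tree to a cohort
#'
#' Order-preserving map of [decide()] over paired profiles.
#'
#' @param xtProfiles,ptProfiles Lists of [NTCPProfile-class] objects, paired
#'   by position.
#' @param thresholds A [DecisionThresholds-class].
#' @return A list of [DecisionResult-class] objects.
#' @export
decideCohort <- function(xtProfiles, ptProfiles,
                         thresholds = decisionThresholds()) {
  if (length(xtProfiles) != length(ptProfiles))
    stop("XT and PT profile lists must be paired (equal length)",
         call. = FALSE)
  lapply(seq_along(xtProfiles), function(i)
    decide(deltaProfile(xtProfiles[[i]], ptProfiles[[i]]), thresholds))
}

#' Continuous proton-benefit score
#'
#' The decision tree is binary; for ROC analysis a continuous score is
#' needed. The score is the threshold-normalised maximum rule margin: each
#' accepting rule's quantity divided by its threshold, maximised over rules,
#' so a score >= 1 corresponds exactly to a proton indication (when the gate
#' passes). Any strictly monotone transform of the margins would give the
#' same ROC ranking within a rule.
#'
#' @param dp A [DeltaProfile-class].
#' @param thresholds A [DecisionThresholds-class].
#' @return A unitless score; >= 1 iff the tree (gate aside) indicates PT.
#' @export
benefitScore <- function(dp, thresholds = decisionThresholds()) {
  d <- deltaValues(dp)
  max(d[["Xer2+"]] / thresholds@t2Single,
      d[["Dys2+"]] / thresholds@t2Single,
      deltaSum2(dp) / thresholds@t2Sum,
      d[["Xer3+"]] / thresholds@t3Single,
      d[["Dys3+"]] / thresholds@t3Single,
      deltaSum3(dp) / thresholds@t3Sum)
}
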