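#' Confusion counts between an observed and a predicted web
#'
#' Cross-tabulates all S^2 cells (diagonal included) of two predation
#' matrices over the same community: true positives (link observed and
#' predicted), true negatives, false positives, false negatives.
#'
#' @param observed,predicted `predation_matrix` objects over the same
#'   community, same orientation.
#' @return Named integer vector with elements `TP`, `TN`, `FP`, `FN`
#'   (class `confusion_counts`); the four always sum to S^2.
#' @export
confusion_counts <- function(observed, predicted) {
  stopifnot(inherits(observed, "predation_matrix"),
            inherits(predicted, "predation_matrix"))
  if (!same_community(observed$community, predicted$community)) {
    stop("observed and predicted webs are over different communities")
  }
  o <- observed$links
  p <- predicted$links
  TP <- sum(o == 1L & p == 1L)
  FN <- sum(o == 1L & p == 0L)
  FP <- sum(o == 0L & p == 1L)
  TN <- sum(o == 0L & p == 0L)
  structure(c(TP = TP, TN = TN, FP = FP, FN = FN), class = "confusion_counts")
}

#' True skill statistic
#'
#' `TSS = (TP*TN - FP*FN) / ((TP + FN) * (FP + TN))`, in \[-1, 1\]: +1 is a
#' perfect prediction, 0 and below no better than random. The statistic is
#' undefined when the observed web has no links (`TP + FN = 0`) or no
#' absences (`FP + TN = 0`); such degenerate observations raise an error.
#' The numerator is formed in exact arithmetic before the single division.
#'
#' @param counts a `confusion_counts` vector (or any named numeric with
#'   `TP`, `TN`, `FP`, `FN`).
#' @return TSS value in \[-1, 1\].
#' @examples
#' true_skill_statistic(c(TP = 3, TN = 4, FP = 2, FN = 1))  # 10/24
#' @export
true_skill_statistic <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); TN <- as.numeric(counts[["TN"]])
  FP <- as.numeric(counts[["FP"]]); FN <- as.numeric(counts[["FN"]])
  if (any(c(TP, TN, FP, FN) < 0)) stop("confusion counts must be non-negative")
  if (TP + FN == 0) {
    stop("TSS undefined: observed web has no links (TP + FN = 0)")
  }
  if (FP + TN == 0) {
    stop("TSS undefined: observed web has no absent links (FP + TN = 0)")
  }
  (TP * TN - FP * FN) / ((TP + FN) * (FP + TN))
}

#' ABC distance between an observed and a predicted web
#'
#' `1 - TSS`, ranging over \[0, 2\]; 0 if and only if the prediction matches
#' the observation in every cell, 2 for the exact complement.
#'
#' @inheritParams confusion_counts
#' @return Distance in \[0, 2\].
#' @export
web_distance <- function(observed, predicted) {
  1 - true_skill_statistic(confusion_counts(observed, predicted))
}

# Fast TSS against a fixed observed web for the ABC loop: only TP and FP
# need counting, the other two counts follow from L and S^2. The final
# formula is evaluated with the exact same floating-point operations as
# true_skill_statistic(), so stored and recomputed values agree bitwise.
obs_stats <- function(observed) {
  o <- observed$links
  L <- sum(o)
  S2 <- length(o)
  if (L == 0 || L == S2) {
    stop("observed web is degenerate (connectance 0 or 1); TSS is undefined")
  }
  list(idx = which(o == 1L), L = L, S2 = S2)
}

tss_fast <- function(pred_links, os) {
  TP <- sum(pred_links[os$idx])
  FP <- sum(pred_links) - TP
  FN <- os$L - TP
  TN <- os$S2 - os$L - FP
  (TP * TN - FP * FN) / ((TP + FN) * (FP + TN))
}
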