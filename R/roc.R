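#' ROC area and accuracy at the Youden-optimal threshold
#'
#' AUC by the rank (Mann-Whitney) statistic, treating larger scores as
#' evidence for the positive class; ties contribute 1/2. The reported
#' accuracy is at the threshold maximising Youden's J = sensitivity +
#' specificity - 1 (classification rule: score >= threshold is positive).
#'
#' @param scores numeric classifier scores.
#' @param binary_labels logical or 0/1 vector; both classes must occur.
#' @return `list(auc, threshold, accuracy, sensitivity, specificity)`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
roc_auc <- function(scores, binary_labels) {
  y <- as.integer(as.logical(binary_labels))
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (length(scores) != length(y)) stop("lengths differ", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  best <- c(j = -Inf, thr = NA, acc = NA, se = NA, sp = NA)
  for (t in thr) {
    pred <- scores >= t
    se <- mean(pred[y == 1]); sp <- mean(!pred[y == 0])
    j <- se + sp - 1
    if (j > best[["j"]])
      best <- c(j = j, thr = t, acc = mean(pred == (y == 1)), se = se, sp = sp)
  }
  list(auc = auc, threshold = best[["thr"]], accuracy = best[["acc"]],
       sensitivity = best[["se"]], specificity = best[["sp"]])
}
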