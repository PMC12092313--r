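# Evaluation metrics: 3x3 confusion matrices and per-class one-vs-rest
# sensitivity / specificity / accuracy in percent.

#' Build a 3x3 confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the fixed order
#' (AL, ATTR, CTRL).
#'
#' @param truth,pred Character vectors of class labels (or factors).
#' @param levels Class order; defaults to \code{\link{classLabels}}.
#' @return Integer matrix with dimnames (truth x predicted).
#' @export
#' @examples
#' confusionMatrix3(c("AL", "AL", "CTRL"), c("AL", "ATTR", "CTRL"))
confusionMatrix3 <- function(truth, pred, levels = classLabels()) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred))
    stop("confusionMatrix3: truth and pred lengths differ")
  bad <- setdiff(unique(c(truth, pred)), levels)
  if (length(bad))
    stop("confusionMatrix3: unknown labels: ", paste(bad, collapse = ", "))
  cm <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  m <- matrix(as.integer(cm), length(levels), length(levels),
              dimnames = list(truth = levels, predicted = levels))
  m
}

#' Per-class metrics from a confusion matrix
#'
#' One-vs-rest for each class c: sensitivity = TP / (TP + FN), specificity
#' = TN / (TN + FP), accuracy = (TP + TN) / total; overall accuracy =
#' trace / total. All values are percentages. A class with an empty truth
#' row has undefined sensitivity, reported as NaN with a warning (never
#' silently zero).
#'
#' @param cm Square confusion matrix of counts (rows = truth).
#' @return List with `perClass` (data.frame: class, sensitivity,
#'   specificity, accuracy) and `overall` (percent).
#' @export
#' @examples
#' cm <- confusionMatrix3(rep(classLabels(), c(3, 2, 2)),
#'                        c("AL", "AL", "ATTR", "ATTR", "ATTR", "CTRL", "CTRL"))
#' confusionMetrics(cm)
confusionMetrics <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("confusionMetrics: empty confusion matrix")
  if (any(cm < 0)) stop("confusionMetrics: negative counts")
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  rows <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    sens <- if (tp + fn == 0) {
      warning("confusionMetrics: class '", classes[i],
              "' has no true instances; sensitivity undefined",
              call. = FALSE)
      NaN
    } else 100 * tp / (tp + fn)
    spec <- if (tn + fp == 0) NaN else 100 * tn / (tn + fp)
    data.frame(class = classes[i], sensitivity = sens, specificity = spec,
               accuracy = 100 * (tp + tn) / total,
               stringsAsFactors = FALSE)
  })
  list(perClass = do.call(rbind, rows),
       overall = 100 * sum(diag(cm)) / total)
}

#' Subject-level majority vote over per-slice predictions
#'
#' Convenience aggregation: each subject is assigned the modal predicted
#' class of its slices; ties are broken in favour of the class listed first
#' in `levels`.
#'
#' @param subject_id Character vector, one entry per slice.
#' @param pred Predicted class labels, one per slice.
#' @param levels Class order used for tie-breaking.
#' @return Named character vector, one prediction per subject.
#' @export
majorityVote <- function(subject_id, pred, levels = classLabels()) {
  vapply(split(factor(pred, levels = levels), subject_id), function(p) {
    tab <- table(p)
    names(tab)[which.max(tab)]
  }, character(1))
}
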