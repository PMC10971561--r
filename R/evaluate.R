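# Confusion-matrix evaluation: overall accuracy, Cohen's kappa, and
# per-class user/producer accuracy. Orientation convention throughout:
# rows = predicted, columns = actual, so user accuracy is the row-wise
# diagonal share and producer accuracy the column-wise one.

#' Confusion matrix of predicted vs actual damage levels
#'
#' @param predicted,actual Integer level vectors of equal length.
#' @param labels Class labels defining the matrix order (default: sorted
#'   union of both vectors).
#' @return Object of class `confusion_matrix`: list with `C` (k x k
#'   counts, rows = predicted), `labels`, `S` (total), `N_p` (row sums,
#'   predicted totals) and `N_t` (column sums, actual totals).
#' @export
confusion_matrix <- function(predicted, actual, labels = NULL) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  if (length(predicted) == 0) stop("empty predictions")
  if (is.null(labels)) labels <- sort(unique(c(predicted, actual)))
  C <- table(factor(predicted, levels = labels),
             factor(actual, levels = labels))
  C <- matrix(as.integer(C), nrow = length(labels),
              dimnames = list(predicted = as.character(labels),
                              actual = as.character(labels)))
  structure(list(C = C, labels = labels, S = sum(C),
                 N_p = rowSums(C), N_t = colSums(C)),
            class = "confusion_matrix")
}

.as_cm <- function(C) {
  if (inherits(C, "confusion_matrix")) return(C)
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("confusion matrix must be square")
  labels <- rownames(C)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(C)))
  structure(list(C = C, labels = labels, S = sum(C),
                 N_p = rowSums(C), N_t = colSums(C)),
            class = "confusion_matrix")
}

#' Overall accuracy
#'
#' Fraction of agreeing predictions, `trace(C) / S` — the multiclass form
#' of the two-class `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param C A [confusion_matrix()] or plain square count matrix.
#' @return Accuracy in \[0, 1\].
#' @export
overall_accuracy <- function(C) {
  cm <- .as_cm(C)
  if (cm$S == 0) stop("empty confusion matrix")
  sum(diag(cm$C)) / cm$S
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement `(OA - p_e) / (1 - p_e)` with expected
#' agreement `p_e = sum_c N_p(c) N_t(c) / S^2` from the matrix margins.
#' When `p_e = 1` (all mass in a single class on both axes) kappa is
#' undefined and `NA` is returned with a warning.
#'
#' @inheritParams overall_accuracy
#' @return Kappa in \[-1, 1\], or `NA` for the degenerate case.
#' @export
kappa_coefficient <- function(C) {
  cm <- .as_cm(C)
  if (cm$S == 0) stop("empty confusion matrix")
  pe <- sum(as.numeric(cm$N_p) * as.numeric(cm$N_t)) / cm$S^2
  if (pe >= 1) {
    warning("expected agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (overall_accuracy(cm) - pe) / (1 - pe)
}

#' Per-class user and producer accuracy
#'
#' User accuracy (commission view) is the diagonal over the predicted
#' total `C[c, c] / N_p(c)`; producer accuracy (omission view) is the
#' diagonal over the actual total `C[c, c] / N_t(c)`. Classes with a zero
#' margin get `NA`, not an error.
#'
#' @inheritParams overall_accuracy
#' @return `data.frame` with columns `class`, `UA`, `PA`.
#' @export
class_accuracies <- function(C) {
  cm <- .as_cm(C)
  d <- diag(cm$C)
  UA <- ifelse(cm$N_p > 0, d / cm$N_p, NA_real_)
  PA <- ifelse(cm$N_t > 0, d / cm$N_t, NA_real_)
  data.frame(class = cm$labels, UA = unname(UA), PA = unname(PA),
             row.names = NULL)
}

#' Assemble an evaluation report
#'
#' @param predicted,actual Integer level vectors (test set).
#' @param labels Class labels (default 1..4).
#' @param importances Optional named feature-importance vector.
#' @param meta Optional named list of run metadata (feature set, model,
#'   size, seed, ...).
#' @return Object of class `evaluation_report`: confusion matrix, `OA`,
#'   `Kappa`, per-class accuracies, importances and metadata.
#' @export
evaluation_report <- function(predicted, actual, labels = 1:4,
                              importances = NULL, meta = list()) {
  cm <- confusion_matrix(predicted, actual, labels)
  structure(list(confusion = cm, OA = overall_accuracy(cm),
                 Kappa = kappa_coefficient(cm),
                 class_accuracy = class_accuracies(cm),
                 importances = importances, meta = meta),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (length(x$meta))
    cat(paste(names(x$meta), unlist(x$meta), sep = "=", collapse = "  "),
        "\n")
  cat(sprintf("OA = %.4f, Kappa = %.4f  (n = %d)\n", x$OA, x$Kappa,
              x$confusion$S))
  cat("confusion matrix (rows = predicted, cols = actual):\n")
  print(x$confusion$C)
  acc <- x$class_accuracy
  cat(sprintf("%-10s UA = %s  PA = %s\n", acc$class,
              formatC(acc$UA, digits = 4, format = "f"),
              formatC(acc$PA, digits = 4, format = "f")), sep = "")
  invisible(x)
}

#' Write a confusion matrix as CSV
#'
#' Rows are predicted classes, columns actual classes; orientation is
#' recorded in the header names.
#'
#' @param cm A [confusion_matrix()].
#' @param path File path.
#' @export
write_confusion <- function(cm, path) {
  cm <- .as_cm(cm)
  df <- as.data.frame(cm$C)
  df <- cbind(predicted = rownames(cm$C), df)
  colnames(df)[-1] <- paste0("actual_", cm$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
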