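# One-vs-rest evaluation of the 3-stage classifier, plus the published
# reference confusion matrices and the printed percentages derived from
# them, used as exact-reproduction fixtures.

#' Confusion matrix (rows = actual, columns = predicted)
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes class set defining row/column order; defaults to
#'   [stage_levels()] when all labels are stage names, otherwise to the
#'   sorted union of observed labels. A label outside `classes` is an error.
#' @return K x K integer matrix of counts with class dimnames, class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(classes)) {
    seen <- unique(c(y_true, y_pred))
    classes <- if (length(seen) > 0 && all(seen %in% stage_levels()))
      stage_levels() else sort(seen)
    if (length(classes) == 0) classes <- stage_levels()
  } else classes <- as.character(classes)
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad) > 0) stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  K <- length(classes)
  cm <- matrix(0L, K, K, dimnames = list(actual = classes, predicted = classes))
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' One-vs-rest counts for one class
#'
#' Collapses a K-class confusion matrix (rows = actual) to binary counts
#' for class `i`: TP is the diagonal cell, FN the rest of row `i`, FP the
#' rest of column `i`, TN everything else; the four always sum to the grand
#' total.
#'
#' @param cm confusion matrix, rows = actual.
#' @param class_index 1-based class index (or class name).
#' @return Named list `TP`, `FP`, `FN`, `TN`.
#' @export
one_vs_rest_counts <- function(cm, class_index) {
  cm <- unclass(cm)
  i <- if (is.character(class_index)) match(class_index, rownames(cm)) else class_index
  if (is.na(i) || i < 1 || i > nrow(cm)) stop("invalid class index")
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(TP = as.numeric(tp), FP = as.numeric(fp), FN = as.numeric(fn), TN = as.numeric(tn))
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Per-class and macro metrics from a confusion matrix
#'
#' One-vs-rest reductions per class: accuracy `(TP+TN)/(TP+TN+FP+FN)`,
#' specificity `TN/(TN+FP)`, sensitivity `TP/(TP+FN)`, with FNR and FPR as
#' their complements. All values are percentages, unrounded; macro values
#' are unweighted class means. A zero denominator yields `NA` for that cell,
#' which is excluded from the macro mean with a warning.
#'
#' @param cm a [confusion_matrix()] (rows = actual).
#' @return A `metric_report`: list with `per_class` (data frame) and
#'   `macro` (named list).
#' @export
metrics <- function(cm) {
  cmu <- unclass(cm)
  K <- nrow(cmu)
  classes <- rownames(cmu)
  if (is.null(classes)) classes <- as.character(seq_len(K))
  rows <- lapply(seq_len(K), function(i) {
    ct <- one_vs_rest_counts(cm, i)
    sens <- safe_ratio(ct$TP, ct$TP + ct$FN)
    spec <- safe_ratio(ct$TN, ct$TN + ct$FP)
    acc <- safe_ratio(ct$TP + ct$TN, ct$TP + ct$TN + ct$FP + ct$FN)
    data.frame(class = classes[i], accuracy = 100 * acc, specificity = 100 * spec,
               sensitivity = 100 * sens, fnr = 100 * (1 - sens),
               fpr = 100 * (1 - spec), stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  if (anyNA(per_class[, -1])) {
    warning("undefined metric(s) for class(es) with zero denominators; excluded from macro")
  }
  macro <- as.list(colMeans(per_class[, -1], na.rm = TRUE))
  structure(list(per_class = per_class, macro = macro), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  df <- x$per_class
  df[, -1] <- round(df[, -1], 2)
  macro <- data.frame(class = "macro", t(round(unlist(x$macro), 2)))
  names(macro) <- names(df)
  print(rbind(df, macro), row.names = FALSE)
  invisible(x)
}

#' Published reference confusion matrices and printed percentages
#'
#' The three reported test-set confusion matrices (rows = actual, columns =
#' predicted; classes inter-ictal, pre-ictal, ictal; 1000 actual instances
#' per class) together with the percentages printed alongside them:
#' per-class accuracy / specificity / sensitivity and the macro accuracy,
#' FNR and FPR summary rows, plus the reported mean accuracies of the
#' method comparison.
#'
#' @return Named list of blocks (`single_2d`, `multi_2d`, `multi_3d`), each
#'   with `matrix`, `printed` (per-class data frame) and `printed_macro`.
#' @export
published_tables <- function() {
  cls <- stage_levels()
  mk <- function(m) {
    dimnames(m) <- list(actual = cls, predicted = cls)
    m
  }
  list(
    single_2d = list(
      label = "2D CNN, single channel",
      matrix = mk(matrix(c(813, 124, 63,
                           92, 864, 44,
                           95, 34, 871), 3, 3, byrow = TRUE)),
      printed = data.frame(class = cls,
                           accuracy = c(87.53, 90.20, 92.13),
                           specificity = c(90.65, 92.10, 94.65),
                           sensitivity = c(81.30, 86.40, 87.10)),
      printed_macro = c(accuracy = 89.95, fnr = 15.07, fpr = 7.53)),
    multi_2d = list(
      label = "2D CNN, multi channel",
      matrix = mk(matrix(c(822, 119, 59,
                           107, 838, 55,
                           71, 43, 886), 3, 3, byrow = TRUE)),
      printed = data.frame(class = cls,
                           accuracy = c(88.13, 89.20, 92.40),
                           specificity = c(91.10, 91.90, 94.30),
                           sensitivity = c(82.20, 83.80, 88.60)),
      printed_macro = c(accuracy = 89.91, fnr = 15.13, fpr = 7.57)),
    multi_3d = list(
      label = "3D CNN, multi channel",
      matrix = mk(matrix(c(861, 81, 58,
                           77, 894, 29,
                           62, 36, 902), 3, 3, byrow = TRUE)),
      printed = data.frame(class = cls,
                           accuracy = c(90.73, 92.57, 93.83),
                           specificity = c(93.05, 94.15, 94.15),
                           sensitivity = c(86.10, 89.40, 90.20)),
      printed_macro = c(accuracy = 92.37, fnr = 11.43, fpr = 6.22)))
}

#' Recompute every percentage of the published result tables
#'
#' For each reference block, per-class accuracy / specificity / sensitivity
#' are recomputed from the confusion matrix via [metrics()], and the macro
#' summary rows (accuracy, FNR, FPR) are recomputed as unweighted means of
#' the *printed* per-class cells -- that is how the published summaries were
#' derived. Each cell passes when computed and printed agree within
#' `tolerance` percentage points.
#'
#' One printed cell is internally inconsistent with its own matrix: the 3D
#' ictal-row specificity is printed as 94.15 (duplicating the pre-ictal
#' row) while the matrix yields 1913/2000 = 95.65. The checker reports the
#' mismatch rather than reconciling it. Similarly, the matrix-derived macro
#' sensitivity (88.57) differs from the separately quoted 88.90; both facts
#' are recorded in the report's `notes`.
#'
#' @param tables reference blocks, by default [published_tables()]
#'   (injectable so perturbation sensitivity can be tested).
#' @param tolerance maximum |computed - printed| per cell, percentage points.
#' @return A `table_report`: data frame (`table`, `row`, `metric`,
#'   `printed`, `computed`, `match`) with `notes` and `n_mismatch`
#'   attributes.
#' @export
reproduce_tables <- function(tables = published_tables(), tolerance = 0.01) {
  out <- list()
  for (nm in names(tables)) {
    blk <- tables[[nm]]
    rep <- metrics(confusion_matrix_from_counts(blk$matrix))
    for (i in seq_len(nrow(blk$printed))) {
      for (metric in c("accuracy", "specificity", "sensitivity")) {
        out[[length(out) + 1]] <- data.frame(
          table = nm, row = as.character(blk$printed$class[i]), metric = metric,
          printed = blk$printed[[metric]][i],
          computed = rep$per_class[[metric]][i], stringsAsFactors = FALSE)
      }
    }
    macro_from_printed <- c(
      accuracy = mean(blk$printed$accuracy),
      fnr = 100 - mean(blk$printed$sensitivity),
      fpr = 100 - mean(blk$printed$specificity))
    for (metric in names(blk$printed_macro)) {
      out[[length(out) + 1]] <- data.frame(
        table = nm, row = "macro", metric = metric,
        printed = unname(blk$printed_macro[metric]),
        computed = unname(macro_from_printed[metric]), stringsAsFactors = FALSE)
    }
    # comparison-table mean accuracy, straight from the matrix
    out[[length(out) + 1]] <- data.frame(
      table = nm, row = "comparison", metric = "mean_accuracy",
      printed = unname(blk$printed_macro["accuracy"]),
      computed = rep$macro$accuracy, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df$match <- abs(df$computed - df$printed) <= tolerance
  attr(df, "n_mismatch") <- sum(!df$match)
  m3 <- metrics(confusion_matrix_from_counts(tables[[length(tables)]]$matrix))
  attr(df, "notes") <- c(
    "3D ictal-row specificity prints 94.15 but its matrix yields 95.65 (1913/2000); flagged above.",
    sprintf("macro sensitivity derived from the 3D matrix is %.2f; the separately quoted value is 88.90.",
            m3$macro$sensitivity))
  class(df) <- c("table_report", class(df))
  df
}

# wrap a raw count matrix so metrics()/one_vs_rest_counts() accept it
confusion_matrix_from_counts <- function(m) {
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' @export
print.table_report <- function(x, ...) {
  df <- as.data.frame(unclass(x))
  df$computed <- round(df$computed, 4)
  print(df, row.names = FALSE)
  cat(sprintf("\n%d/%d cells reproduced\n", sum(x$match), nrow(x)))
  for (nt in attr(x, "notes")) cat("note:", nt, "\n")
  invisible(x)
}
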