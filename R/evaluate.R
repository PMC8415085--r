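# Agreement metrics between annotations: per-type precision/recall/F-score,
# Cohen's kappa, fold changes of type percentages, and the all-vs-all
# cross-comparison matrix. Mean F averages over the union of types observed
# in either annotation, scoring absent types 0 — this penalizes missed
# types and makes the cross-comparison matrix symmetric.

labels_at_level <- function(ann, h, level) {
  if (is.null(h) || level == 1) return(ann$labels)
  merge_to_level(ann$labels, h, level)
}

#' Confusion table between two labelings
#'
#' @param reference,predicted character label vectors over the same cells.
#' @return contingency table (reference rows, predicted columns) over the
#'   union of observed labels.
#' @export
confusion_table <- function(reference, predicted) {
  stop_if_not(length(reference) == length(predicted),
              "label vectors must cover the same cells")
  u <- sort(union(unique(reference), unique(predicted)))
  table(factor(reference, levels = u), factor(predicted, levels = u))
}

#' Per-type F-scores between two annotations
#'
#' Both annotations are merged to the requested granularity level, then for
#' each type t: precision = TP/(TP+FP), recall = TP/(TP+FN), and F the
#' harmonic mean of the two (0 when undefined). `mean_f` averages over the
#' union of observed types, with types absent from one annotation scoring 0.
#'
#' @param reference,predicted `annotation_set`s over the same cells.
#' @param level granularity level 1..4.
#' @param h a `cell_type_hierarchy` (NULL to skip merging).
#' @return an `evaluation_report` list: `per_type` data.frame (type,
#'   precision, recall, f_score), `mean_f`, `kappa`, `level`, `pair`.
#' @export
f_scores <- function(reference, predicted, level = 1, h = NULL) {
  r <- labels_at_level(reference, h, level)
  p <- labels_at_level(predicted, h, level)
  ct <- confusion_table(r, p)
  types <- rownames(ct)
  tp <- diag(ct)
  fp <- colSums(ct) - tp
  fn <- rowSums(ct) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    per_type = data.frame(type = types, precision = unname(prec),
                          recall = unname(rec), f_score = unname(f),
                          stringsAsFactors = FALSE),
    mean_f = mean(f),
    kappa = kappa_from_table(ct),
    level = level,
    pair = list(reference = reference$provenance,
                predicted = predicted$provenance)
  ), class = "evaluation_report")
}

kappa_from_table <- function(ct) {
  n <- sum(ct)
  po <- sum(diag(ct)) / n
  pe <- sum(rowSums(ct) * colSums(ct)) / n^2
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Cohen's kappa between two annotations
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`. Reported unclipped
#' (negative values indicate worse-than-chance agreement). When both
#' annotations are the same constant labelling, kappa is defined as 1.
#'
#' @inheritParams f_scores
#' @return scalar kappa.
#' @export
cohen_kappa <- function(reference, predicted, level = 1, h = NULL) {
  r <- labels_at_level(reference, h, level)
  p <- labels_at_level(predicted, h, level)
  kappa_from_table(confusion_table(r, p))
}

#' Fold changes of cell-type percentages
#'
#' `FC(t) = (pct_pred(t) + pseudo) / (pct_ref(t) + pseudo)` with
#' percentages on `[0, 100]`; the pseudocount guards types absent from one
#' annotation.
#'
#' @inheritParams f_scores
#' @param pseudo pseudocount in percentage points.
#' @return data.frame with type, pct_reference, pct_predicted, fold_change,
#'   log2_fold_change.
#' @export
fold_changes <- function(reference, predicted, level = 1, h = NULL,
                         pseudo = 0.01) {
  r <- labels_at_level(reference, h, level)
  p <- labels_at_level(predicted, h, level)
  u <- sort(union(unique(r), unique(p)))
  pr <- 100 * as.numeric(table(factor(r, levels = u))) / length(r)
  pp <- 100 * as.numeric(table(factor(p, levels = u))) / length(p)
  fc <- (pp + pseudo) / (pr + pseudo)
  data.frame(type = u, pct_reference = pr, pct_predicted = pp,
             fold_change = fc, log2_fold_change = log2(fc),
             stringsAsFactors = FALSE)
}

#' All-vs-all cross-comparison of annotations
#'
#' Entry (i, j) is the mean F with annotation i as reference and j as
#' prediction, averaged over the union of observed types (absent types
#' score 0) — a convention under which the matrix is symmetric and the
#' diagonal is 1.
#'
#' @param annotations named list of `annotation_set`s over the same cells.
#' @param level granularity level.
#' @param h a `cell_type_hierarchy` (NULL to skip merging).
#' @return square numeric matrix with annotation names on both axes.
#' @export
cross_comparison <- function(annotations, level = 1, h = NULL) {
  stop_if_not(length(annotations) >= 2, "need at least 2 annotations")
  n <- length(annotations)
  nm <- names(annotations)
  if (is.null(nm)) nm <- paste0("ann", seq_len(n))
  out <- matrix(1, n, n, dimnames = list(nm, nm))
  merged <- lapply(annotations, labels_at_level, h = h, level = level)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ct <- confusion_table(merged[[i]], merged[[j]])
      tp <- diag(ct)
      fp <- colSums(ct) - tp
      fn <- rowSums(ct) - tp
      prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
      rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
      f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
      out[i, j] <- out[j, i] <- mean(f)
    }
  }
  out
}

#' Summarize a cross-comparison matrix by provenance factor
#'
#' Averages the off-diagonal entries of a [cross_comparison()] matrix,
#' grouping columns (predictions) by treatment or algorithm.
#'
#' @param matrix square matrix from [cross_comparison()].
#' @param annotations the named list the matrix was computed from (for
#'   provenance).
#' @param factor "treatment" or "algorithm".
#' @return data.frame with level, mean and population sd per factor level.
#' @export
summarize_by_factor <- function(matrix, annotations,
                                factor = c("treatment", "algorithm")) {
  factor <- match.arg(factor)
  nm <- colnames(matrix)
  lv <- vapply(annotations[nm], function(a) {
    v <- a$provenance[[factor]]
    if (is.null(v)) a$provenance$kind else v
  }, "")
  groups <- unique(lv)
  res <- lapply(groups, function(g) {
    cols <- which(lv == g)
    vals <- unlist(lapply(cols, function(j) matrix[-j, j]))
    data.frame(level = g, mean = mean(vals), sd = pop_sd(vals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
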