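#' Classify a sequence as TM segment or signal peptide
#'
#' A sequence is called a TM segment when its maximum window score strictly
#' exceeds `tau_first`; otherwise it is called a signal peptide. Ties at
#' exactly `tau_first` are classified SP ("exceeds" read strictly).
#'
#' @param seq Residue string.
#' @param scale A [hydropathy_scale].
#' @param params A [windowing_params].
#' @param tau_first Decision threshold (default 2.7).
#' @return `"TM"` or `"SP"`.
#' @export
classify_segment <- function(seq, scale, params = windowing_params(),
                             tau_first = 2.7) {
  stopifnot(is.numeric(tau_first), length(tau_first) == 1L)
  if (max_window_score(seq, scale, params)$score > tau_first) "TM" else "SP"
}

#' Rank-based ROC AUC
#'
#' Computes the area under the ROC curve as the Mann-Whitney concordance
#' probability: over all (positive, negative) score pairs, a pair counts 1
#' when the positive scores higher, 0.5 on a tie. Midranks make this exact
#' under ties.
#'
#' @param scores Numeric scores.
#' @param labels Character or factor labels, same length as `scores`.
#' @param positive Label of the positive class (default `"TM"`).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(3, 4, 1, 2), c("TM", "TM", "SP", "SP"))  # 1
#' @export
auc <- function(scores, labels, positive = "TM") {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs at least one positive and one negative example",
         call. = FALSE)
  }
  r <- rank(scores)  # midranks
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the observed scores (classifying
#' `score > threshold` as positive) and returns the (FPR, TPR) operating
#' points, anchored at (0,0) and (1,1).
#'
#' @inheritParams auc
#' @return A data frame with columns `threshold`, `fpr`, `tpr`, ordered so
#'   that both rates are non-decreasing.
#' @export
roc_points <- function(scores, labels, positive = "TM") {
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative example",
         call. = FALSE)
  }
  # thresholds from high to low; Inf gives the (0,0) anchor, and the minimum
  # score classifies everything positive, giving (1,1)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(scores[pos] > t) / n_pos, 0)
  fpr <- vapply(th, function(t) sum(scores[!pos] > t) / n_neg, 0)
  tpr <- c(tpr, 1)
  fpr <- c(fpr, 1)
  th <- c(th, -Inf)
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

#' Evaluate SP/TM discrimination of a scale on a labeled dataset
#'
#' Scores every example by its maximum window score and summarizes the
#' separation between the TM (positive) and SP (negative) classes by the ROC
#' curve and its AUC. The result is deterministic for fixed inputs.
#'
#' @param dataset List of labeled examples, as returned by
#'   [load_labeled_dataset()] or [generate_dataset()].
#' @param scale A [hydropathy_scale].
#' @param params A [windowing_params].
#' @param tau_first Threshold used for the reported predicted labels
#'   (default 2.7); it does not affect the AUC.
#' @return A list of class `discrimination_result` with `auc`, `roc` (data
#'   frame of ROC points) and `scores` (data frame: id, label, score,
#'   predicted_label).
#' @export
evaluate_discrimination <- function(dataset, scale,
                                    params = windowing_params(),
                                    tau_first = 2.7) {
  stopifnot(length(dataset) > 0L)
  ids <- vapply(dataset, function(ex) ex$record$id, "")
  labs <- vapply(dataset, function(ex) ex$label, "")
  sc <- vapply(dataset, function(ex)
    max_window_score(ex$record$residues, scale, params)$score, 0)
  res <- list(
    auc = auc(sc, labs, positive = "TM"),
    roc = roc_points(sc, labs, positive = "TM"),
    scores = data.frame(id = ids, label = labs, score = sc,
                        predicted_label = ifelse(sc > tau_first, "TM", "SP"),
                        stringsAsFactors = FALSE)
  )
  class(res) <- "discrimination_result"
  res
}

#' @export
print.discrimination_result <- function(x, ...) {
  tab <- table(x$scores$label)
  cat(sprintf("SP/TM discrimination: %d examples (%s), AUC = %.4f\n",
              nrow(x$scores),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              x$auc))
  invisible(x)
}

#' Export discrimination scores and ROC curve as TSV
#'
#' @param result A `discrimination_result`.
#' @param scores_path Path for the per-example score table (id, label, score,
#'   predicted_label); `NULL` to skip.
#' @param roc_path Path for the ROC table (threshold, fpr, tpr); `NULL` to
#'   skip.
#' @return Invisibly, the written paths.
#' @export
write_discrimination_tsv <- function(result, scores_path = NULL,
                                     roc_path = NULL) {
  stopifnot(inherits(result, "discrimination_result"))
  if (!is.null(scores_path)) {
    df <- result$scores
    df$score <- sprintf("%.6f", df$score)
    write.table(df, scores_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(roc_path)) {
    df <- result$roc
    df$fpr <- sprintf("%.6f", df$fpr)
    df$tpr <- sprintf("%.6f", df$tpr)
    write.table(df, roc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(scores_path, roc_path))
}
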