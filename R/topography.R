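#' Topography scan parameters
#'
#' Parameters of the two-threshold greedy scan that localizes TM segments.
#' `tau_first` gates the first (signal-anchor-like) segment, `tau_next` the
#' subsequent ones; at least `gap` residues must separate consecutive
#' segments. `nterm_limit` encodes the observation that signal recognition
#' particle binding declines once the nascent chain exceeds roughly 110-140
#' residues: when active, a protein is only called a membrane protein if its
#' first segment starts within the limit.
#'
#' @param tau_first First-segment threshold (default 2.7).
#' @param tau_next Threshold for subsequent segments (default 2.1).
#' @param gap Minimum residues between consecutive segments (default 2).
#' @param nterm_limit Maximum 1-based start of the first segment for the
#'   membrane-protein call (default 140); `NA` disables the limit.
#' @param limit_localization If `TRUE`, the `nterm_limit` also aborts pure
#'   localization when no first segment is found within the limit; by default
#'   it only affects [predict_membrane()].
#' @param windowing A [windowing_params] (window length, default 23).
#' @return A list of class `topography_params`.
#' @export
topography_params <- function(tau_first = 2.7, tau_next = 2.1, gap = 2L,
                              nterm_limit = 140L,
                              limit_localization = FALSE,
                              windowing = windowing_params()) {
  stopifnot(is.numeric(tau_first), is.numeric(tau_next),
            inherits(windowing, "windowing_params"))
  gap <- as.integer(gap)
  if (is.na(gap) || gap < 0L) stop("gap must be >= 0", call. = FALSE)
  if (!is.null(nterm_limit) && !is.na(nterm_limit)) {
    nterm_limit <- as.integer(nterm_limit)
    if (nterm_limit < 1L) stop("nterm_limit must be >= 1", call. = FALSE)
  } else {
    nterm_limit <- NA_integer_
  }
  if (tau_first < tau_next) {
    warning("tau_first < tau_next: the first segment is gated less strictly than subsequent ones",
            call. = FALSE)
  }
  structure(list(tau_first = tau_first, tau_next = tau_next, gap = gap,
                 nterm_limit = nterm_limit,
                 limit_localization = isTRUE(limit_localization),
                 windowing = windowing),
            class = "topography_params")
}

#' Localize TM segments by a two-threshold greedy scan
#'
#' Scans the window profile left to right. The first window whose score
#' strictly exceeds `tau_first` becomes segment 1, occupying exactly `n`
#' residues. Scanning resumes `gap + 1` residues after the segment end, and
#' every subsequent segment only needs to exceed the laxer `tau_next`. The
#' scan is deterministic.
#'
#' @param seq Residue string.
#' @param scale A [hydropathy_scale].
#' @param params A [topography_params].
#' @param sequence_id Identifier carried into the result.
#' @return A list of class `topography_prediction` with `sequence_id`,
#'   `segments` (data frame: rank, start, end, score; 1-based inclusive
#'   coordinates) and `is_membrane` (the [predict_membrane()] call under
#'   `params`).
#' @examples
#' s <- paste0(strrep("S", 10), strrep("L", 23), strrep("S", 10))
#' locate_tm_segments(s, builtin_scale("PMIscale"))$segments  # [7, 29]
#' @export
locate_tm_segments <- function(seq, scale, params = topography_params(),
                               sequence_id = "seq") {
  stopifnot(inherits(params, "topography_params"))
  prof <- sequence_profile(seq, scale, params$windowing, sequence_id)
  n <- params$windowing$n
  n_win <- length(prof$starts)
  starts <- integer(0)
  scores <- numeric(0)
  i <- 1L
  tau <- params$tau_first
  while (i <= n_win) {
    if (prof$scores[i] > tau) {
      if (length(starts) == 0L && params$limit_localization &&
          !is.na(params$nterm_limit) && prof$starts[i] > params$nterm_limit) {
        break
      }
      starts <- c(starts, prof$starts[i])
      scores <- c(scores, prof$scores[i])
      tau <- params$tau_next
      i <- i + n + params$gap   # next window start >= end + gap + 1
    } else {
      i <- i + 1L
    }
  }
  segments <- data.frame(rank = seq_along(starts), start = starts,
                         end = starts + n - 1L, score = scores)
  pred <- structure(list(sequence_id = sequence_id, segments = segments,
                         is_membrane = NA),
                    class = "topography_prediction")
  pred$is_membrane <- nrow(segments) > 0L &&
    (is.na(params$nterm_limit) || segments$start[1L] <= params$nterm_limit)
  pred
}

#' @export
print.topography_prediction <- function(x, ...) {
  cat(sprintf("'%s': %d TM segment(s), membrane = %s\n", x$sequence_id,
              nrow(x$segments), x$is_membrane))
  if (nrow(x$segments)) print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Membrane-protein call
#'
#' A protein is called a membrane protein when the greedy scan finds a first
#' TM segment and, if `nterm_limit` is set, that segment starts within the
#' N-terminal limit.
#'
#' @inheritParams locate_tm_segments
#' @return Logical scalar.
#' @export
predict_membrane <- function(seq, scale, params = topography_params()) {
  locate_tm_segments(seq, scale, params)$is_membrane
}

# Validate a segment table (data frame with start/end, or 2-column matrix).
as_segment_df <- function(x, what = "segments") {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  if (is.matrix(x)) x <- data.frame(start = x[, 1L], end = x[, 2L])
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  df <- data.frame(start = as.integer(x$start), end = as.integer(x$end))
  if (any(df$end < df$start)) {
    stop(sprintf("%s with end < start", what), call. = FALSE)
  }
  if (is.unsorted(df$start, strictly = TRUE)) {
    stop(sprintf("%s must be sorted by start", what), call. = FALSE)
  }
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)])) {
    stop(sprintf("%s must be non-overlapping", what), call. = FALSE)
  }
  df
}

#' Match predicted against observed TM segments
#'
#' One-to-one greedy matching in sequence order: walking both sorted segment
#' lists from the N-terminus, a predicted/observed pair is matched when their
#' overlap is at least `min_overlap` residues; otherwise the segment ending
#' first is discarded (a false positive if predicted, false negative if
#' observed).
#'
#' @param predicted,observed Data frames (or 2-column matrices) of 1-based
#'   inclusive `start`/`end` coordinates, sorted and non-overlapping within
#'   each list.
#' @param min_overlap Minimum residue overlap for a match (default 5).
#' @return A list with `tp`, `fp`, `fn` counts and `protein_correct`
#'   (`TRUE` iff `fp == 0` and `fn == 0`).
#' @export
match_segments <- function(predicted, observed, min_overlap = 5L) {
  pred <- as_segment_df(predicted, "predicted segments")
  obs <- as_segment_df(observed, "observed segments")
  min_overlap <- as.integer(min_overlap)
  stopifnot(min_overlap >= 1L)
  i <- 1L; j <- 1L; tp <- 0L
  while (i <= nrow(pred) && j <= nrow(obs)) {
    ov <- min(pred$end[i], obs$end[j]) - max(pred$start[i], obs$start[j]) + 1L
    if (ov >= min_overlap) {
      tp <- tp + 1L
      i <- i + 1L
      j <- j + 1L
    } else if (pred$end[i] < obs$end[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  fp <- nrow(pred) - tp
  fn <- nrow(obs) - tp
  list(tp = tp, fp = fp, fn = fn, protein_correct = fp == 0L && fn == 0L)
}

#' Topography benchmark over an annotated dataset
#'
#' Predicts TM segments for every protein and scores them against the
#' annotated segments with [match_segments()]. Reported metrics follow the
#' convention of TM-helix benchmark servers: sensitivity is the fraction of
#' observed segments recovered, `sum(tp) / (sum(tp) + sum(fn))`;
#' "specificity" is segment-level precision, `sum(tp) / (sum(tp) + sum(fp))`
#' (not a true-negative rate); `correctly_predicted` is the fraction of
#' proteins with neither false-positive nor false-negative segments. All
#' three are percentages. Degenerate zero-denominator ratios (no observed or
#' no predicted segments at all) are reported as 100 with a warning.
#'
#' @param dataset List of labeled examples with annotated `segments`
#'   (possibly empty data frames).
#' @param scale A [hydropathy_scale].
#' @param params A [topography_params].
#' @param min_overlap Minimum residue overlap for a segment match.
#' @return A list with `sensitivity`, `specificity`, `correctly_predicted`
#'   (percent), the aggregate counts `tp`, `fp`, `fn`, and `per_protein`
#'   (data frame: id, tp, fp, fn, protein_correct).
#' @export
benchmark_topography <- function(dataset, scale,
                                 params = topography_params(),
                                 min_overlap = 5L) {
  if (length(dataset) == 0L) stop("empty dataset", call. = FALSE)
  rows <- lapply(dataset, function(ex) {
    pred <- locate_tm_segments(ex$record$residues, scale, params,
                               sequence_id = ex$record$id)
    m <- match_segments(pred$segments, ex$segments, min_overlap)
    data.frame(id = ex$record$id, tp = m$tp, fp = m$fp, fn = m$fn,
               protein_correct = m$protein_correct,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
  ratio_pct <- function(num, den, what) {
    if (den == 0L) {
      warning(sprintf("%s undefined (zero denominator); reported as 100",
                      what), call. = FALSE)
      return(100)
    }
    100 * num / den
  }
  list(sensitivity = ratio_pct(tp, tp + fn, "sensitivity"),
       specificity = ratio_pct(tp, tp + fp, "specificity (precision)"),
       correctly_predicted = 100 * mean(per$protein_correct),
       tp = tp, fp = fp, fn = fn, per_protein = per)
}

#' Export topography predictions as TSV and/or GFF3
#'
#' The TSV has one row per predicted segment (`sequence_id`, `rank`, `start`,
#' `end`, `score`); the GFF3 uses feature type `transmembrane_helix` with
#' 1-based inclusive coordinates. A per-protein summary TSV
#' (`sequence_id`, `n_segments`, `is_membrane`) can also be written.
#'
#' @param predictions A `topography_prediction` or list of them.
#' @param tsv_path,gff3_path,summary_path Output paths; `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_topography <- function(predictions, tsv_path = NULL, gff3_path = NULL,
                             summary_path = NULL) {
  if (inherits(predictions, "topography_prediction")) {
    predictions <- list(predictions)
  }
  seg_rows <- do.call(rbind, lapply(predictions, function(p) {
    if (nrow(p$segments) == 0L) return(NULL)
    cbind(data.frame(sequence_id = p$sequence_id, stringsAsFactors = FALSE),
          p$segments)
  }))
  if (is.null(seg_rows)) {
    seg_rows <- data.frame(sequence_id = character(0), rank = integer(0),
                           start = integer(0), end = integer(0),
                           score = numeric(0))
  }
  if (!is.null(tsv_path)) {
    out <- seg_rows[, c("sequence_id", "rank", "start", "end", "score")]
    out$score <- sprintf("%.6f", as.numeric(out$score))
    write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(gff3_path)) {
    lines <- "##gff-version 3"
    if (nrow(seg_rows)) {
      lines <- c(lines, sprintf(
        "%s\tpmiscale\ttransmembrane_helix\t%d\t%d\t%.6f\t.\t.\tID=%s.tm%d",
        seg_rows$sequence_id, seg_rows$start, seg_rows$end,
        as.numeric(seg_rows$score), seg_rows$sequence_id, seg_rows$rank))
    }
    writeLines(lines, gff3_path)
  }
  if (!is.null(summary_path)) {
    summ <- data.frame(
      sequence_id = vapply(predictions, `[[`, "", "sequence_id"),
      n_segments = vapply(predictions, function(p) nrow(p$segments), 0L),
      is_membrane = vapply(predictions, `[[`, NA, "is_membrane"))
    write.table(summ, summary_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(tsv_path, gff3_path, summary_path))
}
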