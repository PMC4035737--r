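#' Windowing parameters
#'
#' @param n Window length in residues. The default of 23 matches the fixed
#'   window length the TM localization method was calibrated with.
#' @return A list of class `windowing_params`.
#' @export
windowing_params <- function(n = 23L) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n))
  if (n < 1L) stop("window length n must be >= 1", call. = FALSE)
  structure(list(n = n), class = "windowing_params")
}

# Convert a residue string to per-position scale values. Lowercase letters are
# upper-cased silently; non-canonical letters (B, J, O, U, X, Z, ...) score
# 0.0, near the neutral region of the built-in scales, with a warning.
residue_values <- function(seq, scale) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  vals <- scale$values[chars]
  if (anyNA(vals)) {
    bad <- unique(chars[is.na(vals)])
    warning(sprintf("non-canonical residue(s) [%s] scored as 0.0",
                    paste(bad, collapse = ",")), call. = FALSE)
    vals[is.na(vals)] <- 0
  }
  unname(vals)
}

#' Score a single fixed-length window
#'
#' The window score is the arithmetic mean of the scale values of its
#' residues: `H = (1/n) * sum(h(r_j))`.
#'
#' @param residues Residue string of exactly `n` letters.
#' @param scale A [hydropathy_scale].
#' @param params A [windowing_params]; `residues` must have length
#'   `params$n`.
#' @return The window mean score (numeric scalar).
#' @examples
#' window_score(strrep("L", 23), builtin_scale("PMIscale"))  # 3.8
#' @export
window_score <- function(residues, scale, params = windowing_params()) {
  stopifnot(inherits(scale, "hydropathy_scale"),
            inherits(params, "windowing_params"))
  if (nchar(residues) != params$n) {
    stop(sprintf("window must have exactly n = %d residues (got %d)",
                 params$n, nchar(residues)), call. = FALSE)
  }
  mean(residue_values(residues, scale))
}

#' Sliding-window profile of a sequence
#'
#' Computes the mean scale value of every length-`n` window along the
#' sequence. For a sequence of length `L >= n` the profile has `L - n + 1`
#' entries at 1-based start positions `1..L-n+1`. A running-sum (cumulative
#' sum) implementation keeps the cost linear in `L`.
#'
#' Sequences shorter than `n` are scored as a single whole-sequence window
#' (mean over all residues) with a warning, so that short entries are not
#' silently dropped.
#'
#' @param seq Residue string.
#' @param scale A [hydropathy_scale].
#' @param params A [windowing_params].
#' @param sequence_id Identifier stored in the profile.
#' @return A list of class `window_profile` with elements `sequence_id`,
#'   `starts` (integer, 1-based) and `scores` (numeric, same length).
#' @export
sequence_profile <- function(seq, scale, params = windowing_params(),
                             sequence_id = "seq") {
  stopifnot(inherits(scale, "hydropathy_scale"),
            inherits(params, "windowing_params"))
  vals <- residue_values(seq, scale)
  L <- length(vals)
  n <- params$n
  if (L < n) {
    warning(sprintf(
      "sequence '%s' shorter than window (L = %d < n = %d); scored as one whole-sequence window",
      sequence_id, L, n), call. = FALSE)
    scores <- mean(vals)
    starts <- 1L
  } else {
    cs <- cumsum(c(0, vals))
    starts <- seq_len(L - n + 1L)
    scores <- (cs[starts + n] - cs[starts]) / n
  }
  structure(list(sequence_id = sequence_id,
                 starts = as.integer(starts),
                 scores = as.numeric(scores)),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("Window profile of '%s': %d windows, max %.4f at start %d\n",
              x$sequence_id, length(x$starts),
              max(x$scores), x$starts[which.max(x$scores)]))
  invisible(x)
}

#' Maximum window score of a sequence (its PMI value)
#'
#' The per-sequence score used for SP/TM discrimination is the maximum value
#' obtained when sliding the window along the sequence.
#'
#' @inheritParams sequence_profile
#' @return A list with `score` (the maximum window mean) and `start` (the
#'   1-based position of the first window attaining it).
#' @examples
#' s <- paste0(strrep("S", 10), strrep("I", 23), strrep("S", 10))
#' max_window_score(s, builtin_scale("PMIscale"))  # score 6.5 at start 11
#' @export
max_window_score <- function(seq, scale, params = windowing_params()) {
  prof <- sequence_profile(seq, scale, params)
  i <- which.max(prof$scores)
  list(score = prof$scores[i], start = prof$starts[i])
}

#' Export window profiles as TSV
#'
#' Writes columns `sequence_id`, `start`, `score` with deterministic
#' 6-decimal score formatting.
#'
#' @param profiles A `window_profile` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  if (inherits(profiles, "window_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(sequence_id = p$sequence_id, start = p$starts,
               score = sprintf("%.6f", p$scores),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
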