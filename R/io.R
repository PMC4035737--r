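#' Construct a sequence record
#'
#' @param id Non-empty identifier (no whitespace; FASTA ids are truncated at
#'   the first whitespace on re-read).
#' @param residues Residue string; upper-cased on construction.
#' @param description Optional free-text description.
#' @return A list of class `sequence_record`.
#' @export
sequence_record <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  if (!nzchar(id)) stop("record id must be non-empty", call. = FALSE)
  if (!nzchar(residues)) {
    stop(sprintf("record '%s' has an empty sequence", id), call. = FALSE)
  }
  structure(list(id = id, description = as.character(description)[1],
                 residues = toupper(residues)),
            class = "sequence_record")
}

#' Construct a labeled example
#'
#' Carrier for SP/TM-labeled sequences, optionally with annotated TM segment
#' coordinates (1-based inclusive, sorted, non-overlapping). Segments require
#' the TM label.
#'
#' @param record A [sequence_record].
#' @param label `"SP"` or `"TM"`.
#' @param segments Optional data frame (or 2-column matrix) of annotated
#'   `start`/`end` coordinates.
#' @return A list of class `labeled_example`.
#' @export
labeled_example <- function(record, label, segments = NULL) {
  stopifnot(inherits(record, "sequence_record"))
  if (!label %in% c("SP", "TM")) {
    stop(sprintf("label must be 'SP' or 'TM' (got '%s')", label),
         call. = FALSE)
  }
  segments <- as_segment_df(segments, sprintf("segments of '%s'", record$id))
  if (nrow(segments) > 0L && label != "TM") {
    stop(sprintf("record '%s' has annotated segments but label '%s'",
                 record$id, label), call. = FALSE)
  }
  structure(list(record = record, label = label, segments = segments),
            class = "labeled_example")
}

#' Read a FASTA file
#'
#' Parses standard FASTA through Biostrings; multi-line sequences are joined,
#' record order is preserved, residues are upper-cased, and the id is the
#' header up to the first whitespace (the remainder becomes the description).
#'
#' @param path Path to a FASTA file.
#' @return A list of [sequence_record] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  xs <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(xs) == 0L)) {
    stop(sprintf("empty sequence(s) in %s: %s", path,
                 paste(names(xs)[Biostrings::width(xs) == 0L],
                       collapse = ", ")), call. = FALSE)
  }
  headers <- names(xs)
  ids <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S+", "", headers))
  seqs <- as.character(xs)
  mapply(sequence_record, ids, seqs, desc,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write records to FASTA
#'
#' Deterministic output that round-trips with [read_fasta()]. Note that ids
#' containing whitespace come back truncated at the first whitespace.
#'
#' @param records List of [sequence_record] objects (an empty list writes an
#'   empty file).
#' @param path Output path.
#' @param line_width Sequence line wrapping width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  if (inherits(records, "sequence_record")) records <- list(records)
  if (length(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  seqs <- vapply(records, `[[`, "", "residues")
  ids <- vapply(records, `[[`, "", "id")
  desc <- vapply(records, `[[`, "", "description")
  xs <- Biostrings::BStringSet(seqs)
  names(xs) <- ifelse(nzchar(desc), paste(ids, desc), ids)
  Biostrings::writeXStringSet(xs, path, width = as.integer(line_width))
  invisible(path)
}

#' Load a labeled dataset from FASTA plus an annotation sidecar
#'
#' The annotation file is tab-separated with a header row and columns `id`,
#' `label` (SP or TM) and optional `tm_start`, `tm_end`. A TM example with
#' several annotated segments uses one row per segment. Every annotation row
#' must match a FASTA sequence; loading never silently drops records.
#'
#' @param fasta_path Path to the sequences.
#' @param annotation_path Path to the annotation TSV.
#' @return A list of [labeled_example] objects, in FASTA order.
#' @export
load_labeled_dataset <- function(fasta_path, annotation_path) {
  records <- read_fasta(fasta_path)
  if (!file.exists(annotation_path)) {
    stop(sprintf("annotation file not found: %s", annotation_path),
         call. = FALSE)
  }
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  req <- c("id", "label")
  if (!all(req %in% names(ann))) {
    stop(sprintf("annotation file must have columns id, label (found: %s)",
                 paste(names(ann), collapse = ", ")), call. = FALSE)
  }
  ids <- vapply(records, `[[`, "", "id")
  problems <- character(0)
  unmatched <- setdiff(ann$id, ids)
  if (length(unmatched)) {
    problems <- c(problems, sprintf(
      "annotation id(s) absent from FASTA: %s",
      paste(unique(unmatched), collapse = ", ")))
  }
  bad_label <- !ann$label %in% c("SP", "TM")
  if (any(bad_label)) {
    problems <- c(problems, sprintf(
      "bad label in row(s) %s (must be SP or TM)",
      paste(which(bad_label), collapse = ", ")))
  }
  has_coord_cols <- all(c("tm_start", "tm_end") %in% names(ann))
  if (has_coord_cols) {
    st <- suppressWarnings(as.integer(ann$tm_start))
    en <- suppressWarnings(as.integer(ann$tm_end))
    given <- nzchar(ann$tm_start) & !is.na(ann$tm_start)
    malformed <- given & (is.na(st) | is.na(en) | en < st | st < 1L)
    if (any(malformed)) {
      problems <- c(problems, sprintf(
        "malformed coordinates in row(s) %s",
        paste(which(malformed), collapse = ", ")))
    }
  }
  unannotated <- setdiff(ids, ann$id)
  if (length(unannotated)) {
    problems <- c(problems, sprintf(
      "FASTA record(s) without annotation: %s",
      paste(unannotated, collapse = ", ")))
  }
  if (length(problems)) {
    stop(paste(c(sprintf("invalid dataset (%s):", annotation_path),
                 problems), collapse = "\n  "), call. = FALSE)
  }
  lapply(records, function(rec) {
    rows <- ann[ann$id == rec$id, , drop = FALSE]
    label <- unique(rows$label)
    if (length(label) != 1L) {
      stop(sprintf("conflicting labels for id '%s'", rec$id), call. = FALSE)
    }
    segs <- NULL
    if (has_coord_cols) {
      given <- nzchar(rows$tm_start) & !is.na(rows$tm_start)
      if (any(given)) {
        segs <- data.frame(start = as.integer(rows$tm_start[given]),
                           end = as.integer(rows$tm_end[given]))
        segs <- segs[order(segs$start), , drop = FALSE]
      }
    }
    labeled_example(rec, label, segs)
  })
}

#' Auto-detect and load a labeled supplementary dataset
#'
#' Recognizes two dialects: (a) a FASTA file whose headers carry an `SP` or
#' `TM` class token (as a standalone word, e.g. `>P12345 TM 11 33`), and
#' (b) a FASTA file accompanied by a sidecar annotation TSV at
#' `<path>.annotations.tsv` (or the same base name with a `.tsv` extension).
#' The detected dialect is reported via `message()`.
#'
#' @param path Path to the dataset FASTA.
#' @return A list of [labeled_example] objects.
#' @export
sniff_supplementary <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("dataset file not found: %s", path), call. = FALSE)
  }
  head_bytes <- readBin(path, "raw", n = 4096L)
  if (any(head_bytes == as.raw(0L))) {
    stop(sprintf(
      "unrecognized dialect: %s is not a text file; convert it manually to FASTA plus an annotation TSV (see ?load_labeled_dataset)",
      path), call. = FALSE)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop(sprintf(
      "unrecognized dialect: %s does not look like FASTA; convert it manually to FASTA plus an annotation TSV (see ?load_labeled_dataset)",
      path), call. = FALSE)
  }
  sidecars <- c(paste0(path, ".annotations.tsv"),
                paste0(sub("\\.[^.]*$", "", path), ".tsv"))
  sidecars <- sidecars[file.exists(sidecars)]
  if (length(sidecars)) {
    message(sprintf("detected dialect: FASTA + sidecar annotation (%s)",
                    sidecars[1L]))
    return(load_labeled_dataset(path, sidecars[1L]))
  }
  records <- read_fasta(path)
  tokens <- lapply(records, function(rec) {
    toks <- strsplit(paste(rec$id, rec$description), "[\\s|;,]+",
                     perl = TRUE)[[1L]]
    intersect(toupper(toks), c("SP", "TM"))
  })
  n_tok <- vapply(tokens, length, 0L)
  if (all(n_tok == 1L)) {
    message("detected dialect: FASTA with SP/TM class tokens in headers")
    return(mapply(function(rec, tok) labeled_example(rec, tok),
                  records, lapply(tokens, `[[`, 1L),
                  SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  stop(sprintf(
    "unrecognized dialect: %d of %d headers lack a unique SP/TM token and no sidecar annotation file was found; convert the data manually to FASTA plus an annotation TSV (see ?load_labeled_dataset)",
    sum(n_tok != 1L), length(records)), call. = FALSE)
}

#' Write a labeled dataset as FASTA plus annotation TSV
#'
#' Inverse of [load_labeled_dataset()].
#'
#' @param dataset List of [labeled_example] objects.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_labeled_dataset <- function(dataset, fasta_path, annotation_path) {
  write_fasta(lapply(dataset, `[[`, "record"), fasta_path)
  rows <- do.call(rbind, lapply(dataset, function(ex) {
    if (nrow(ex$segments)) {
      data.frame(id = ex$record$id, label = ex$label,
                 tm_start = ex$segments$start, tm_end = ex$segments$end,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = ex$record$id, label = ex$label,
                 tm_start = "", tm_end = "", stringsAsFactors = FALSE)
    }
  }))
  write.table(rows, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta_path, annotation_path))
}
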