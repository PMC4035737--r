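# --- explicit seedable random stream ------------------------------------
# Generators never touch the ambient RNG: every draw goes through a stream
# object that owns its own .Random.seed state.

#' Create an explicit random stream
#'
#' A small wrapper around R's Mersenne-Twister state that makes randomness an
#' explicit argument of the generators rather than ambient global state. The
#' global `.Random.seed` is saved and restored around every draw.
#'
#' @param seed Integer seed.
#' @return An environment of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  class(e) <- "rng_stream"
  e
}

# Evaluate `expr` under the stream's RNG state, advancing the stream.
stream_eval <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  expr
}

stream_sample <- function(stream, x, size, prob = NULL) {
  stream_eval(stream, sample(x, size, replace = TRUE, prob = prob))
}

stream_int <- function(stream, range) {
  stream_eval(stream, sample(seq(range[1L], range[2L]), 1L))
}

# --- default residue compositions ----------------------------------------
# TM cores are strongly enriched in the large hydrophobics; signal-peptide
# h-regions lean on L/A/V with a shorter hydrophobic stretch; the background
# (flanks, loops, n/c-regions) is polar-enriched. Vectors sum to 1.
.default_composition <- function(kind) {
  v <- setNames(numeric(20), AMINO_ACIDS)
  switch(kind,
    tm = {
      v[c("I", "L", "F", "V", "A", "G", "W", "Y")] <-
        c(.18, .22, .12, .14, .10, .06, .05, .05)
      rest <- setdiff(AMINO_ACIDS, c("I", "L", "F", "V", "A", "G", "W", "Y"))
      v[rest] <- (1 - sum(v)) / length(rest)
    },
    sp_h = {
      v[c("L", "A", "V", "C")] <- c(.35, .25, .15, .05)
      rest <- setdiff(AMINO_ACIDS, c("L", "A", "V", "C"))
      v[rest] <- (1 - sum(v)) / length(rest)
    },
    background = {
      v[c("S", "T", "N", "Q", "D", "E", "K", "R")] <- .075
      v[c("G", "P", "A", "H")] <- .05
      v[c("C", "F", "I", "L", "M", "V", "W", "Y")] <- .025
    },
    stop("unknown composition kind: ", kind)
  )
  v
}

#' Synthetic-data generator configuration
#'
#' Describes the structure of the emulated training data: TM examples are a
#' hydrophobic core (19-25 residues) plus 10 flanking residues on each side;
#' SP examples are truncated protein N-termini of at most 60 residues with a
#' basic n-region, a hydrophobic h-region and a polar c-region/mature-start
#' filler.
#'
#' @param seed Integer seed of the example stream.
#' @param tm_core_length_range Length-2 integer range of the TM core
#'   (default `c(19, 25)`).
#' @param flank_length Flanking residues on each side of a TM core
#'   (default 10).
#' @param sp_total_length_max Maximum SP example length (default 60).
#' @param composition_tm,composition_sp_h,composition_background Named
#'   20-entry residue frequency vectors summing to 1; defaults concentrate TM
#'   mass on I/L/F/V/A/G/W/Y, h-region mass on L/A/V/C, and background mass
#'   on polar residues.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 42L,
                             tm_core_length_range = c(19L, 25L),
                             flank_length = 10L,
                             sp_total_length_max = 60L,
                             composition_tm = .default_composition("tm"),
                             composition_sp_h = .default_composition("sp_h"),
                             composition_background =
                               .default_composition("background")) {
  check_comp <- function(v, what) {
    if (!is.numeric(v) || length(v) != 20L ||
        !setequal(names(v), AMINO_ACIDS)) {
      stop(sprintf("%s must be a named 20-entry frequency vector", what),
           call. = FALSE)
    }
    v <- v[AMINO_ACIDS]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop(sprintf("%s must be non-negative and sum to 1", what),
           call. = FALSE)
    }
    v
  }
  tm_core_length_range <- as.integer(tm_core_length_range)
  stopifnot(length(tm_core_length_range) == 2L,
            all(tm_core_length_range >= 1L),
            tm_core_length_range[1L] <= tm_core_length_range[2L],
            flank_length >= 0L, sp_total_length_max >= 15L)
  structure(list(
    seed = as.integer(seed),
    tm_core_length_range = tm_core_length_range,
    flank_length = as.integer(flank_length),
    sp_total_length_max = as.integer(sp_total_length_max),
    composition_tm = check_comp(composition_tm, "composition_tm"),
    composition_sp_h = check_comp(composition_sp_h, "composition_sp_h"),
    composition_background = check_comp(composition_background,
                                        "composition_background")
  ), class = "generator_config")
}

draw_residues <- function(stream, k, comp) {
  if (k == 0L) return("")
  paste(stream_sample(stream, AMINO_ACIDS, k, prob = comp), collapse = "")
}

#' Generate one TM-labeled example
#'
#' A hydrophobic core with length drawn from `tm_core_length_range` and
#' composition `composition_tm`, flanked on each side by `flank_length`
#' background residues; the annotated segment is exactly the core.
#'
#' @param config A [generator_config].
#' @param stream An [rng_stream()]; a fresh stream from `config$seed` is used
#'   when omitted.
#' @param id Record identifier.
#' @return A [labeled_example] with label `"TM"` and one annotated segment.
#' @export
generate_tm_example <- function(config = generator_config(),
                                stream = rng_stream(config$seed),
                                id = "tm_1") {
  core_len <- stream_int(stream, config$tm_core_length_range)
  fl <- config$flank_length
  seqs <- paste0(
    draw_residues(stream, fl, config$composition_background),
    draw_residues(stream, core_len, config$composition_tm),
    draw_residues(stream, fl, config$composition_background))
  labeled_example(
    sequence_record(id, seqs, "synthetic signal-anchor segment"),
    "TM",
    data.frame(start = fl + 1L, end = fl + core_len))
}

#' Generate one SP-labeled example
#'
#' An N-terminal fragment of at most `sp_total_length_max` residues: an
#' n-region of 1-5 residues containing at least one K/R, an h-region of 6-12
#' residues from `composition_sp_h`, then c-region and mature-start filler
#' from the background composition.
#'
#' @inheritParams generate_tm_example
#' @return A [labeled_example] with label `"SP"` and no segments.
#' @export
generate_sp_example <- function(config = generator_config(),
                                stream = rng_stream(config$seed),
                                id = "sp_1") {
  n_len <- stream_int(stream, c(1L, 5L))
  h_len <- stream_int(stream, c(6L, 12L))
  total <- stream_int(stream, c(max(30L, n_len + h_len + 5L),
                                config$sp_total_length_max))
  n_region <- strsplit(draw_residues(stream, n_len,
                                     config$composition_background),
                       "")[[1L]]
  basic_pos <- stream_int(stream, c(1L, n_len))
  n_region[basic_pos] <- stream_sample(stream, c("K", "R"), 1L)
  seqs <- paste0(
    paste(n_region, collapse = ""),
    draw_residues(stream, h_len, config$composition_sp_h),
    draw_residues(stream, total - n_len - h_len,
                  config$composition_background))
  labeled_example(
    sequence_record(id, seqs, "synthetic signal peptide (first 60 aa)"),
    "SP")
}

#' Generate a labeled SP/TM dataset
#'
#' Exactly `n_tm` TM and `n_sp` SP examples, deterministically shuffled by
#' the stream so the two classes are interleaved as in a real benchmark file.
#'
#' @param n_tm,n_sp Class counts (non-negative).
#' @param config A [generator_config]; its `seed` drives everything.
#' @return A list of [labeled_example] objects of length `n_tm + n_sp`.
#' @examples
#' ds <- generate_dataset(5, 10, generator_config(seed = 1))
#' table(vapply(ds, `[[`, "", "label"))
#' @export
generate_dataset <- function(n_tm, n_sp, config = generator_config()) {
  stopifnot(n_tm >= 0L, n_sp >= 0L)
  stream <- rng_stream(config$seed)
  tm <- lapply(seq_len(n_tm), function(i)
    generate_tm_example(config, stream, sprintf("tm_%04d", i)))
  sp <- lapply(seq_len(n_sp), function(i)
    generate_sp_example(config, stream, sprintf("sp_%04d", i)))
  all <- c(tm, sp)
  if (length(all) > 1L) {
    all <- all[stream_eval(stream, sample.int(length(all)))]
  }
  all
}

#' Generate a whole protein with known TM topography
#'
#' Background loops (length >= 25 residues, drawn from 25-60) alternate with
#' 23-residue TM cores drawn from `composition_tm`; the ground-truth segment
#' coordinates are recorded. With `n_segments = 0` the protein is a plain
#' background (soluble-like) chain of 150-400 residues.
#'
#' @param n_segments Number of TM segments (>= 0).
#' @inheritParams generate_tm_example
#' @return A [labeled_example]; label `"TM"` with annotated segments when
#'   `n_segments > 0`, otherwise label `"SP"` with none.
#' @export
generate_topography_protein <- function(n_segments,
                                        config = generator_config(),
                                        stream = rng_stream(config$seed),
                                        id = "prot_1") {
  stopifnot(n_segments >= 0L)
  if (n_segments == 0L) {
    len <- stream_int(stream, c(150L, 400L))
    return(labeled_example(
      sequence_record(id, draw_residues(stream, len,
                                        config$composition_background),
                      "synthetic soluble protein"),
      "SP"))
  }
  tm_len <- 23L
  pieces <- character(0)
  starts <- integer(0)
  pos <- 0L
  for (k in seq_len(n_segments)) {
    loop_len <- stream_int(stream, c(25L, 60L))
    pieces <- c(pieces, draw_residues(stream, loop_len,
                                      config$composition_background))
    pos <- pos + loop_len
    starts <- c(starts, pos + 1L)
    pieces <- c(pieces, draw_residues(stream, tm_len, config$composition_tm))
    pos <- pos + tm_len
  }
  loop_len <- stream_int(stream, c(25L, 60L))
  pieces <- c(pieces, draw_residues(stream, loop_len,
                                    config$composition_background))
  labeled_example(
    sequence_record(id, paste(pieces, collapse = ""),
                    sprintf("synthetic membrane protein (%d TM)",
                            n_segments)),
    "TM",
    data.frame(start = starts, end = starts + tm_len - 1L))
}
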