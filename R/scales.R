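#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
NULL

#' The 20 canonical amino-acid one-letter codes
#'
#' Alphabetically ordered vector of the canonical residue letters used as the
#' key set of every hydropathy scale.
#'
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Translocon insertion-propensity scale (PMIscale). High values mark residues
# that favour membrane insertion of the window through the translocon.
.PMISCALE_VALUES <- c(
  A =  1.8, C =  2.1, D = -8.5, E = -11.5, F = 5.8,
  G =  1.6, H = -0.2, I =  6.5, K =   0.1, L = 3.8,
  M =  1.9, N = -3.5, P = -4.6, Q =  -4.5, R = 0.5,
  S = -1.8, T =  2.3, V =  4.2, W =   5.7, Y = 6.1
)

# Kyte & Doolittle (1982) hydropathy indexes, the standard published table.
# Used as the starting point of the scale optimizer.
.KD_VALUES <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

#' Construct and validate a hydropathy scale
#'
#' A hydropathy scale maps each of the 20 canonical amino acids to a
#' dimensionless score. Validation enforces exactly one finite value per
#' canonical residue.
#'
#' @param values Named numeric vector with exactly the 20 canonical one-letter
#'   codes as names (any order) and finite values.
#' @param name Label for the scale.
#' @return An object of class `hydropathy_scale`: a list with elements
#'   `name` (string) and `values` (named numeric vector ordered as
#'   [AMINO_ACIDS]).
#' @examples
#' sc <- hydropathy_scale(setNames(rep(0, 20), AMINO_ACIDS), "flat")
#' sc$values[["W"]]
#' @export
hydropathy_scale <- function(values, name = "custom") {
  if (!is.numeric(values) || is.null(names(values))) {
    stop("scale values must be a named numeric vector", call. = FALSE)
  }
  nm <- names(values)
  missing <- setdiff(AMINO_ACIDS, nm)
  extra <- setdiff(nm, AMINO_ACIDS)
  if (length(missing) || length(extra) || anyDuplicated(nm)) {
    stop(sprintf(
      "invalid scale '%s': missing [%s], unexpected [%s], duplicated [%s]",
      name,
      paste(missing, collapse = ","),
      paste(extra, collapse = ","),
      paste(unique(nm[duplicated(nm)]), collapse = ",")
    ), call. = FALSE)
  }
  v <- unname(values[AMINO_ACIDS])
  if (!all(is.finite(v))) {
    stop(sprintf("invalid scale '%s': non-finite value for [%s]", name,
                 paste(AMINO_ACIDS[!is.finite(v)], collapse = ",")),
         call. = FALSE)
  }
  structure(list(name = as.character(name)[1],
                 values = setNames(as.numeric(v), AMINO_ACIDS)),
            class = "hydropathy_scale")
}

#' @export
print.hydropathy_scale <- function(x, ...) {
  cat(sprintf("Hydropathy scale '%s'\n", x$name))
  print(round(x$values, 4))
  invisible(x)
}

#' Built-in hydropathy scales
#'
#' Returns one of the scales shipped with the package: `"PMIscale"`, the
#' translocon membrane-insertion propensity scale, or `"KD"`, the Kyte &
#' Doolittle (1982) hydropathy index used to initialize the scale optimizer.
#' Identifiers are case-insensitive.
#'
#' @param name Scale identifier, one of `"PMIscale"` or `"KD"`
#'   (case-insensitive).
#' @return A [hydropathy_scale] object.
#' @examples
#' builtin_scale("PMIscale")$values[["I"]]  # 6.5
#' builtin_scale("kd")$values[["I"]]        # 4.5
#' @export
builtin_scale <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  registry <- list(pmiscale = list("PMIscale", .PMISCALE_VALUES),
                   kd = list("KD", .KD_VALUES))
  key <- tolower(name)
  if (!key %in% names(registry)) {
    stop(sprintf("unknown scale '%s'; available scales: %s", name,
                 paste(vapply(registry, `[[`, "", 1L), collapse = ", ")),
         call. = FALSE)
  }
  hydropathy_scale(registry[[key]][[2L]], registry[[key]][[1L]])
}

#' Affine transformation of a scale
#'
#' Maps every value `v` of a scale to `a * v + b`. With `a > 0` this is
#' order-preserving, which makes it useful for testing invariance of
#' rank-based statistics such as the ROC AUC.
#'
#' @param scale A [hydropathy_scale].
#' @param a Multiplier; must be non-zero.
#' @param b Offset.
#' @return A new [hydropathy_scale] with transformed values and an annotated
#'   name.
#' @export
affine_transform <- function(scale, a, b = 0) {
  stopifnot(inherits(scale, "hydropathy_scale"),
            is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (a == 0) stop("multiplier 'a' must be non-zero", call. = FALSE)
  hydropathy_scale(a * scale$values + b,
                   sprintf("%s*%g%+g", scale$name, a, b))
}

#' Read a hydropathy scale from a two-column text file
#'
#' The file format is one `LETTER<TAB>value` row per residue; `#` starts a
#' comment and blank lines are ignored. Values are read with full float
#' precision so that [write_scale()] followed by `read_scale()` round-trips
#' exactly.
#'
#' @param path Path to the scale file.
#' @param name Scale label; defaults to the file name.
#' @return A [hydropathy_scale].
#' @export
read_scale <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop(sprintf("scale file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[\t ]+")
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad)) {
    stop(sprintf("malformed scale rows: %s",
                 paste(lines[bad], collapse = " | ")), call. = FALSE)
  }
  letters_ <- toupper(vapply(parts, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(vals)) {
    stop(sprintf("non-numeric scale values in rows: %s",
                 paste(lines[is.na(vals)], collapse = " | ")), call. = FALSE)
  }
  hydropathy_scale(setNames(vals, letters_), name)
}

#' Write a hydropathy scale to the two-column text format
#'
#' @param scale A [hydropathy_scale].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "hydropathy_scale"))
  # %.17g guarantees exact double round-trip
  rows <- sprintf("%s\t%.17g", names(scale$values), scale$values)
  writeLines(c(sprintf("# scale: %s", scale$name), rows), path)
  invisible(path)
}
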