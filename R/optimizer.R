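#' Optimizer configuration
#'
#' Settings of the grouped steepest-ascent local search that learns a
#' 20-value scale by maximizing discrimination AUC on a labeled training set.
#' The 20 residues are partitioned into ordered groups that are optimized one
#' after another; within a group, every combination of
#' {unchanged, -delta, +delta} over the group's values is a candidate
#' neighbor, and deltas decrease along `delta_schedule`.
#'
#' @param groups Ordered named list of residue groups partitioning the 20
#'   amino acids. The default is the grouping the method was published with:
#'   G1 = F,L,I,V,Y,W; G2 = A,T,D,E,R,G,H; G3 = C,K,S,M,N,P,Q.
#' @param delta_schedule Strictly positive, non-increasing step sizes;
#'   default `c(3, 2, 1, 0.5, 0.25, 0.1)` (the search starts with +/-3 moves
#'   and gradually refines).
#' @param initial_scale Starting [hydropathy_scale]; default the Kyte &
#'   Doolittle indexes.
#' @param windowing A [windowing_params].
#' @param max_steps_per_phase Safety cap on accepted moves within one
#'   (group, delta) phase (default 1000); exceeding it is an error carrying
#'   the trace so far.
#' @param recycle If `TRUE`, the group/delta phases are repeated until a full
#'   pass accepts no move; the default is the single sequential
#'   G1 -> G2 -> G3 pass.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(groups = list(
                               G1 = c("F", "L", "I", "V", "Y", "W"),
                               G2 = c("A", "T", "D", "E", "R", "G", "H"),
                               G3 = c("C", "K", "S", "M", "N", "P", "Q")),
                             delta_schedule = c(3, 2, 1, 0.5, 0.25, 0.1),
                             initial_scale = builtin_scale("KD"),
                             windowing = windowing_params(),
                             max_steps_per_phase = 1000L,
                             recycle = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 1L,
            inherits(initial_scale, "hydropathy_scale"),
            inherits(windowing, "windowing_params"),
            is.numeric(delta_schedule), length(delta_schedule) >= 1L)
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, AMINO_ACIDS)) {
    stop("groups must be a disjoint partition of the 20 amino acids",
         call. = FALSE)
  }
  if (any(delta_schedule <= 0) || is.unsorted(rev(delta_schedule))) {
    stop("delta_schedule must be strictly positive and non-increasing",
         call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("G", seq_along(groups))
  }
  structure(list(groups = groups,
                 delta_schedule = as.numeric(delta_schedule),
                 initial_scale = initial_scale,
                 windowing = windowing,
                 max_steps_per_phase = as.integer(max_steps_per_phase),
                 recycle = isTRUE(recycle)),
            class = "optimizer_config")
}

# Move matrix in deterministic enumeration order: residues alphabetical
# within the group (first residue most significant), move codes ordered
# unchanged < -delta < +delta; the all-unchanged identity (k = 0) is
# excluded. Rows are neighbors, columns the group's residues.
neighbor_moves <- function(g, delta) {
  ks <- seq_len(3L^g - 1L)
  codes <- outer(ks, seq_len(g),
                 function(k, j) (k %/% 3L^(g - j)) %% 3L)
  matrix(c(0, -delta, delta)[codes + 1L], nrow = length(ks))
}

#' Enumerate the neighbor scales of one optimizer move
#'
#' All `3^|group| - 1` combinations of keeping, decreasing, or increasing by
#' `delta` each of the group's values, excluding the all-unchanged identity.
#' Residues outside the group are untouched. Enumeration order is
#' deterministic: residues alphabetical within the group, move order
#' unchanged < -delta < +delta.
#'
#' @param scale Current [hydropathy_scale].
#' @param group Character vector of residues (non-empty subset of the 20).
#' @param delta Step size (> 0).
#' @return A list of [hydropathy_scale] objects.
#' @export
enumerate_neighbors <- function(scale, group, delta) {
  stopifnot(inherits(scale, "hydropathy_scale"))
  if (length(group) == 0L) stop("empty group", call. = FALSE)
  if (!all(group %in% AMINO_ACIDS) || anyDuplicated(group)) {
    stop("group must be distinct canonical residues", call. = FALSE)
  }
  if (!is.numeric(delta) || delta <= 0) {
    stop("delta must be > 0", call. = FALSE)
  }
  group <- sort(group)
  mv <- neighbor_moves(length(group), delta)
  lapply(seq_len(nrow(mv)), function(k) {
    v <- scale$values
    v[group] <- v[group] + mv[k, ]
    hydropathy_scale(v, scale$name)
  })
}

# --- fast evaluation kernel ----------------------------------------------
# Scoring a candidate scale on the training set reduces to linear algebra:
# each window's mean is the inner product of the window's residue-frequency
# vector with the 20 scale values. Stacking all windows of all sequences
# (padded to a common per-sequence window count by repeating the first
# window, which cannot change a maximum) gives one matrix multiplication per
# batch of candidate scales, followed by a per-sequence running maximum.

make_training_context <- function(training, windowing) {
  stopifnot(length(training) >= 2L)
  n <- windowing$n
  labels <- vapply(training, `[[`, "", "label")
  if (length(unique(labels)) < 2L) {
    stop("training set must contain both SP and TM examples", call. = FALSE)
  }
  freqs <- lapply(training, function(ex) {
    chars <- strsplit(ex$record$residues, "", fixed = TRUE)[[1L]]
    idx <- match(chars, AMINO_ACIDS)
    L <- length(chars)
    M <- matrix(0, L, 20L)
    ok <- !is.na(idx)   # non-canonical residues contribute 0
    M[cbind(which(ok), idx[ok])] <- 1
    if (L < n) {
      matrix(colSums(M) / L, nrow = 1L)
    } else {
      cs <- rbind(0, apply(M, 2L, cumsum))
      st <- seq_len(L - n + 1L)
      (cs[st + n, , drop = FALSE] - cs[st, , drop = FALSE]) / n
    }
  })
  wmax <- max(vapply(freqs, nrow, 0L))
  padded <- lapply(freqs, function(f) {
    if (nrow(f) < wmax) {
      rbind(f, f[rep(1L, wmax - nrow(f)), , drop = FALSE])
    } else {
      f
    }
  })
  list(freq = do.call(rbind, padded),   # (nseq * wmax) x 20, sequence-major
       wmax = wmax,
       nseq = length(training),
       pos = labels == "TM",
       n_pos = sum(labels == "TM"),
       n_neg = sum(labels == "SP"))
}

# Max window score per sequence for each candidate scale.
# hmat: 20 x K matrix of candidate scale values (rows ordered as
# AMINO_ACIDS). Returns nseq x K matrix.
context_max_scores <- function(ctx, hmat) {
  out <- matrix(NA_real_, ctx$nseq, ncol(hmat))
  chunk <- 512L
  col_sets <- split(seq_len(ncol(hmat)),
                    ceiling(seq_len(ncol(hmat)) / chunk))
  for (cols in col_sets) {
    P <- ctx$freq %*% hmat[, cols, drop = FALSE]
    M <- P[seq(1L, nrow(P), by = ctx$wmax), , drop = FALSE]
    if (ctx$wmax > 1L) {
      for (i in 2L:ctx$wmax) {
        M <- pmax(M, P[seq(i, nrow(P), by = ctx$wmax), , drop = FALSE])
      }
    }
    out[, cols] <- M
  }
  out
}

context_aucs <- function(ctx, hmat) {
  M <- context_max_scores(ctx, hmat)
  apply(M, 2L, function(s) {
    r <- rank(s)
    (sum(r[ctx$pos]) - ctx$n_pos * (ctx$n_pos + 1) / 2) /
      (ctx$n_pos * ctx$n_neg)
  })
}

describe_move <- function(group, moves) {
  nz <- moves != 0
  if (!any(nz)) return("identity")
  paste(sprintf("%s%+g", group[nz], moves[nz]), collapse = ",")
}

# Shared worker for steepest_step()/optimize_scale(); assumes `group` sorted.
steepest_step_ctx <- function(scale, group, delta, ctx, current_auc = NULL) {
  if (is.null(current_auc)) {
    current_auc <- context_aucs(ctx, matrix(scale$values, ncol = 1L))
  }
  if (length(group) > 7L) {
    warning(sprintf(
      "group of %d residues: full neighborhood (3^%d) too large, falling back to single-coordinate moves",
      length(group), length(group)), call. = FALSE)
    mv <- matrix(0, 2L * length(group), length(group))
    for (j in seq_along(group)) {
      mv[2L * j - 1L, j] <- -delta
      mv[2L * j, j] <- delta
    }
  } else {
    mv <- neighbor_moves(length(group), delta)
  }
  gi <- match(group, AMINO_ACIDS)
  hmat <- matrix(scale$values, 20L, nrow(mv))
  hmat[gi, ] <- hmat[gi, ] + t(mv)
  aucs <- context_aucs(ctx, hmat)
  best <- which.max(aucs)   # first maximum = enumeration-order tie-break
  if (aucs[best] > current_auc) {
    v <- scale$values
    v[group] <- v[group] + mv[best, ]
    list(improved = TRUE,
         scale = hydropathy_scale(v, scale$name),
         auc = aucs[best],
         move = describe_move(group, mv[best, ]),
         current_auc = current_auc)
  } else {
    list(improved = FALSE, scale = scale, auc = current_auc,
         move = NA_character_, current_auc = current_auc)
  }
}

#' One steepest-ascent step
#'
#' Evaluates the discrimination AUC of every neighbor of `scale` (all
#' combinations of {unchanged, -delta, +delta} over `group`) on the training
#' set and returns the best neighbor if it strictly improves on the current
#' AUC; ties among equal-AUC neighbors are broken by enumeration order.
#'
#' @param scale Current [hydropathy_scale].
#' @param group Character vector of residues to vary.
#' @param delta Step size (> 0).
#' @param training List of [labeled_example] objects with both classes.
#' @param windowing A [windowing_params].
#' @return A list with `improved` (logical), `scale`, `auc`, `move` (string
#'   like `"F+3,W-3"`, `NA` when not improved) and `current_auc`.
#' @export
steepest_step <- function(scale, group, delta, training,
                          windowing = windowing_params()) {
  stopifnot(inherits(scale, "hydropathy_scale"))
  if (length(group) == 0L) stop("empty group", call. = FALSE)
  if (!is.numeric(delta) || delta <= 0) {
    stop("delta must be > 0", call. = FALSE)
  }
  ctx <- make_training_context(training, windowing)
  steepest_step_ctx(scale, sort(group), delta, ctx)
}

#' Learn a hydropathy scale by grouped steepest-ascent local search
#'
#' Starting from `config$initial_scale` (Kyte & Doolittle by default), the
#' search processes the residue groups in order; for each group it walks
#' down the delta schedule, repeating [steepest_step()] at each delta until
#' no neighbor improves the training AUC. The procedure is entirely
#' deterministic: identical inputs reproduce the identical trace.
#'
#' @param training List of [labeled_example] objects containing both classes.
#' @param config An [optimizer_config].
#' @return A list of class `scale_fit` with `scale` (the learned
#'   [hydropathy_scale], renamed `"optimized"`), `trace` (data frame: step,
#'   group, delta, move, auc — AUC strictly increasing over accepted moves),
#'   `initial_auc` and `final_auc`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(30, 60, generator_config(seed = 1))
#' fit <- optimize_scale(ds, optimizer_config(delta_schedule = c(3, 1)))
#' fit$final_auc
#' }
#' @export
optimize_scale <- function(training, config = optimizer_config()) {
  stopifnot(inherits(config, "optimizer_config"))
  ctx <- make_training_context(training, config$windowing)
  scale <- hydropathy_scale(config$initial_scale$values, "optimized")
  cur_auc <- context_aucs(ctx, matrix(scale$values, ncol = 1L))
  initial_auc <- cur_auc
  trace <- list()
  step_no <- 0L
  repeat {
    accepted_in_pass <- 0L
    for (gname in names(config$groups)) {
      group <- sort(config$groups[[gname]])
      for (delta in config$delta_schedule) {
        phase_steps <- 0L
        repeat {
          st <- steepest_step_ctx(scale, group, delta, ctx, cur_auc)
          if (!st$improved) break
          step_no <- step_no + 1L
          phase_steps <- phase_steps + 1L
          accepted_in_pass <- accepted_in_pass + 1L
          scale <- st$scale
          cur_auc <- st$auc
          trace[[step_no]] <- data.frame(
            step = step_no, group = gname, delta = delta, move = st$move,
            auc = cur_auc, stringsAsFactors = FALSE)
          if (phase_steps > config$max_steps_per_phase) {
            err <- simpleError(sprintf(
              "max_steps_per_phase (%d) exceeded in group %s at delta %g",
              config$max_steps_per_phase, gname, delta))
            err$trace <- do.call(rbind, trace)
            stop(err)
          }
        }
      }
    }
    if (!config$recycle || accepted_in_pass == 0L) break
  }
  trace_df <- if (length(trace)) {
    do.call(rbind, trace)
  } else {
    data.frame(step = integer(0), group = character(0), delta = numeric(0),
               move = character(0), auc = numeric(0),
               stringsAsFactors = FALSE)
  }
  structure(list(scale = scale, trace = trace_df,
                 initial_auc = as.numeric(initial_auc),
                 final_auc = as.numeric(cur_auc)),
            class = "scale_fit")
}

#' @export
print.scale_fit <- function(x, ...) {
  cat(sprintf(
    "Scale optimization: %d accepted moves, training AUC %.4f -> %.4f\n",
    nrow(x$trace), x$initial_auc, x$final_auc))
  invisible(x)
}

#' Export an optimizer trace as TSV
#'
#' Columns: step, group, delta, move, auc.
#'
#' @param fit A `scale_fit` from [optimize_scale()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "scale_fit"))
  df <- fit$trace
  df$auc <- sprintf("%.6f", df$auc)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
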