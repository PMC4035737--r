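pmi <- builtin_scale("PMIscale")
kd <- builtin_scale("KD")

small_training <- function(seed = 2, n_tm = 15, n_sp = 25) {
  generate_dataset(n_tm, n_sp, generator_config(seed = seed))
}

test_that("enumerate_neighbors produces 3^g - 1 scales in deterministic order", {
  expect_length(enumerate_neighbors(kd, "L", 1), 2L)
  expect_length(enumerate_neighbors(kd, c("L", "I"), 1), 8L)
  expect_length(enumerate_neighbors(kd, c("C", "K", "S", "M", "N", "P", "Q"),
                                    0.5), 2186L)
  expect_error(enumerate_neighbors(kd, character(0), 1), "empty group")
  expect_error(enumerate_neighbors(kd, "L", 0), "delta")
  expect_error(enumerate_neighbors(kd, c("L", "L"), 1), "distinct")

  # order: residues alphabetical, move order unchanged < -delta < +delta
  nb <- enumerate_neighbors(kd, c("L", "I"), 2)
  deltas <- t(vapply(nb, function(s)
    (s$values - kd$values)[c("I", "L")], numeric(2)))
  expect_equal(unname(deltas),
               matrix(c(0, -2, 0, 2, -2, 0, -2, -2, -2, 2, 2, 0, 2, -2, 2, 2),
                      ncol = 2, byrow = TRUE))
  # residues outside the group are untouched
  untouched <- setdiff(AMINO_ACIDS, c("I", "L"))
  for (s in nb) expect_identical(s$values[untouched], kd$values[untouched])
  # the identity combination is excluded
  expect_true(all(rowSums(deltas != 0) > 0))
})

test_that("steepest_step picks the exhaustively-best neighbor", {
  training <- small_training()
  st <- steepest_step(kd, c("I", "L", "V"), 1, training)
  # dual route: score every neighbor through the public evaluation path
  nb <- enumerate_neighbors(kd, c("I", "L", "V"), 1)
  aucs <- vapply(nb, function(s)
    evaluate_discrimination(training, s)$auc, 0)
  cur <- evaluate_discrimination(training, kd)$auc
  expect_equal(st$current_auc, cur)
  if (max(aucs) > cur) {
    expect_true(st$improved)
    best <- which.max(aucs)
    expect_equal(st$auc, aucs[best])
    expect_identical(st$scale$values, nb[[best]]$values)
  } else {
    expect_false(st$improved)
  }
})

test_that("steepest_step signals no-improvement when the AUC cannot rise", {
  # perfectly separated training: AUC is already 1.0
  sep <- c(
    lapply(1:5, function(i) labeled_example(
      sequence_record(paste0("t", i),
                      paste0(strrep("S", 8), strrep("I", 23), strrep("S", 8))),
      "TM")),
    lapply(1:5, function(i) labeled_example(
      sequence_record(paste0("s", i), strrep("S", 45)), "SP")))
  st <- steepest_step(pmi, c("I", "L"), 1, sep)
  expect_false(st$improved)
  expect_identical(st$scale$values, pmi$values)

  # moving a residue absent from every sequence leaves all scores tied
  st2 <- steepest_step(pmi, "W", 3, sep)
  expect_false(st2$improved)
})

test_that("optimize_scale leaves a separated training set untouched", {
  cfg <- optimizer_config(delta_schedule = c(3, 1))
  sep <- c(
    lapply(1:6, function(i) labeled_example(
      sequence_record(paste0("t", i),
                      paste0(strrep("S", 8), strrep("I", 23), strrep("S", 8))),
      "TM")),
    lapply(1:6, function(i) labeled_example(
      sequence_record(paste0("s", i), strrep("S", 45)), "SP")))
  fit <- optimize_scale(sep, cfg)
  expect_equal(fit$final_auc, 1.0)
  expect_equal(nrow(fit$trace), 0L)
  expect_identical(fit$scale$values, kd$values)
})

test_that("accepted moves strictly increase the training AUC and only touch traced residues", {
  training <- small_training(seed = 8, n_tm = 20, n_sp = 30)
  fit <- optimize_scale(training,
                        optimizer_config(delta_schedule = c(3, 1, 0.5)))
  if (nrow(fit$trace) > 0L) {
    expect_true(all(diff(c(fit$initial_auc, fit$trace$auc)) > 0))
    moved <- unique(unlist(regmatches(
      fit$trace$move, gregexpr("[A-Y](?=[+-])", fit$trace$move, perl = TRUE))))
    unmoved <- setdiff(AMINO_ACIDS, moved)
    expect_identical(fit$scale$values[unmoved], kd$values[unmoved])
  }
  expect_equal(fit$final_auc,
               evaluate_discrimination(training, fit$scale)$auc)
})

test_that("optimization is deterministic", {
  training <- small_training(seed = 9)
  cfg <- optimizer_config(delta_schedule = c(3, 1))
  f1 <- optimize_scale(training, cfg)
  f2 <- optimize_scale(training, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$scale$values, f2$scale$values)
})

test_that("a single-residue group matches exhaustive hill-climbing on the value grid", {
  training <- generate_dataset(12, 18, inverted_config(3))
  # brute-force oracle: literal 1-d hill climb over the reachable grid of
  # L-values, every candidate scored through the public evaluation path
  climb <- function(delta) {
    v <- kd$values
    cur <- evaluate_discrimination(training, hydropathy_scale(v))$auc
    repeat {
      cand <- lapply(c(-delta, delta), function(d) {
        w <- v; w[["L"]] <- w[["L"]] + d; w
      })
      aucs <- vapply(cand, function(w)
        evaluate_discrimination(training, hydropathy_scale(w))$auc, 0)
      if (max(aucs) <= cur) break
      v <- cand[[which.max(aucs)]]
      cur <- max(aucs)
    }
    list(value = v[["L"]], auc = cur)
  }
  oracle <- climb(2)
  st <- kd
  cur <- evaluate_discrimination(training, st)$auc
  repeat {
    s <- steepest_step(st, "L", 2, training)
    if (!s$improved) break
    st <- s$scale
    cur <- s$auc
  }
  expect_equal(st$values[["L"]], oracle$value)
  expect_equal(cur, oracle$auc)
})

test_that("oversized groups fall back to single-coordinate moves with a warning", {
  training <- small_training(seed = 10, n_tm = 8, n_sp = 8)
  expect_warning(
    steepest_step(kd, AMINO_ACIDS[1:9], 1, training),
    "single-coordinate")
})

test_that("exceeding max_steps_per_phase errors with the trace attached", {
  training <- generate_dataset(30, 30, inverted_config(4))
  cfg <- optimizer_config(delta_schedule = 3, max_steps_per_phase = 1L)
  err <- tryCatch(optimize_scale(training, cfg), error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "max_steps_per_phase")
  expect_s3_class(err$trace, "data.frame")
  expect_true(nrow(err$trace) >= 2L)
})

test_that("trace TSV export carries step, group, delta, move and auc", {
  training <- generate_dataset(20, 20, inverted_config(5))
  fit <- optimize_scale(training, optimizer_config(delta_schedule = c(3, 1)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace_tsv(fit, path)
  df <- read.delim(path)
  expect_identical(names(df), c("step", "group", "delta", "move", "auc"))
  expect_true(!is.unsorted(df$auc))
})
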