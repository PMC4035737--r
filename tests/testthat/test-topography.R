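pmi <- builtin_scale("PMIscale")

test_that("the greedy scan localizes the first window above tau_first", {
  s <- paste0(strrep("S", 10), strrep("L", 23), strrep("S", 10))
  pred <- locate_tm_segments(s, pmi)
  expect_equal(nrow(pred$segments), 1L)
  expect_identical(pred$segments$start, 7L)
  expect_identical(pred$segments$end, 29L)
  expect_equal(pred$segments$score, 65 / 23)  # (4*(-1.8) + 19*3.8) / 23
  expect_true(pred$is_membrane)
})

test_that("a low constant profile yields no segments and no membrane call", {
  pred <- locate_tm_segments(strrep("S", 100), pmi)
  expect_equal(nrow(pred$segments), 0L)
  expect_false(pred$is_membrane)
})

test_that("subsequent segments are gated by tau_next after a 2-residue gap", {
  s <- paste0(strrep("G", 5), strrep("L", 23), strrep("G", 5),
              strrep("I", 23), strrep("G", 5))
  segs <- locate_tm_segments(s, pmi)$segments
  expect_equal(segs$start, c(1L, 26L))   # resume index = 23 + 2 + 1
  expect_equal(segs$end, c(23L, 48L))
  expect_equal(segs$score, c(76.4, 116.9) / 23)
  expect_true(all(segs$score > c(2.7, 2.1)))
})

test_that("the membrane call honors the N-terminal start limit", {
  expect_false(predict_membrane(strrep("S", 300), pmi))
  expect_true(predict_membrane(
    paste0(strrep("S", 10), strrep("L", 23), strrep("S", 10)), pmi))
  late <- paste0(strrep("S", 199), strrep("I", 23), strrep("S", 50))
  expect_false(predict_membrane(late, pmi))  # first window starts at 200
  expect_true(predict_membrane(late, pmi,
                               topography_params(nterm_limit = NA)))
})

test_that("parameter validation warns on inverted thresholds", {
  expect_warning(topography_params(tau_first = 2.0, tau_next = 2.5),
                 "tau_first < tau_next")
  expect_error(topography_params(gap = -1), "gap")
  expect_error(topography_params(nterm_limit = 0), "nterm_limit")
})

test_that("match_segments pairs intervals greedily by overlap", {
  a <- data.frame(start = c(10L, 50L), end = c(32L, 72L))
  m <- match_segments(a, a)
  expect_equal(m[c("tp", "fp", "fn")], list(tp = 2L, fp = 0L, fn = 0L))
  expect_true(m$protein_correct)

  m2 <- match_segments(data.frame(start = 1, end = 23),
                       data.frame(start = 50, end = 72))
  expect_equal(m2[c("tp", "fp", "fn")], list(tp = 0L, fp = 1L, fn = 1L))
  expect_false(m2$protein_correct)

  m3 <- match_segments(data.frame(start = 7, end = 29),
                       data.frame(start = 11, end = 33), min_overlap = 5)
  expect_equal(m3$tp, 1L)  # overlap = 19 residues
  expect_true(m3$protein_correct)

  expect_error(
    match_segments(data.frame(start = c(1, 10), end = c(12, 30)),
                   data.frame(start = 1, end = 23)),
    "non-overlapping")
})

test_that("benchmark_topography aggregates per-segment and per-protein accuracy", {
  cfg <- generator_config(seed = 5)
  stream <- rng_stream(cfg$seed)
  dataset <- lapply(1:20, function(i)
    generate_topography_protein(rep(1:3, length.out = 20)[i], cfg, stream,
                                sprintf("p%02d", i)))
  bench <- benchmark_topography(dataset, pmi)
  expect_true(all(c(bench$sensitivity, bench$specificity,
                    bench$correctly_predicted) >= 0))
  expect_true(all(c(bench$sensitivity, bench$specificity,
                    bench$correctly_predicted) <= 100))
  expect_equal(nrow(bench$per_protein), 20L)

  # over-prediction: two hydrophobic stretches, only one annotated
  over <- labeled_example(
    sequence_record("over", paste0(strrep("S", 30), strrep("L", 23),
                                   strrep("S", 30), strrep("I", 23),
                                   strrep("S", 30))),
    "TM", data.frame(start = 31L, end = 53L))
  b1 <- benchmark_topography(list(over), pmi)
  expect_equal(b1$sensitivity, 100)
  expect_equal(b1$specificity, 50)
  expect_equal(b1$correctly_predicted, 0)

  # degenerate: nothing observed, nothing predicted
  sol <- labeled_example(sequence_record("sol", strrep("S", 120)), "SP")
  w <- capture_warnings(b2 <- benchmark_topography(list(sol), pmi))
  expect_match(w, "undefined", all = TRUE)
  expect_length(w, 2L)  # both ratios degenerate
  expect_equal(b2$specificity, 100)
  expect_equal(b2$sensitivity, 100)
  expect_equal(b2$correctly_predicted, 100)
  expect_error(benchmark_topography(list(), pmi), "empty dataset")
})

test_that("predicted segments obey the structural invariants on random proteins", {
  set.seed(31)
  params <- topography_params()
  for (i in 1:40) {
    s <- random_seq(sample(60:300, 1))
    segs <- locate_tm_segments(s, pmi, params)$segments
    if (nrow(segs) == 0L) next
    expect_true(all(segs$end - segs$start + 1L == 23L))
    expect_true(all(segs$score > c(2.7, rep(2.1, nrow(segs) - 1L))))
    if (nrow(segs) > 1L) {
      expect_true(all(segs$start[-1L] >= segs$end[-nrow(segs)] + 3L))
    }
    expect_identical(segs$start,
                     brute_scan(s, pmi, 23L, 2.7, 2.1, 2L))
  }
})

test_that("raising tau_next never increases the number of segments", {
  set.seed(32)
  for (i in 1:20) {
    s <- random_seq(sample(80:250, 1))
    counts <- vapply(c(1.5, 2.1, 2.5, 3.0), function(tn) {
      p <- suppressWarnings(
        topography_params(tau_first = 2.7, tau_next = tn))
      nrow(locate_tm_segments(s, pmi, p)$segments)
    }, 0L)
    expect_true(!is.unsorted(rev(counts)))
  }
})

test_that("the scan is deterministic", {
  s <- random_seq(400)
  expect_identical(locate_tm_segments(s, pmi), locate_tm_segments(s, pmi))
})

test_that("predictions export as segment TSV, GFF3 and per-protein summary", {
  s <- paste0(strrep("S", 10), strrep("L", 23), strrep("S", 10))
  pred <- locate_tm_segments(s, pmi, sequence_id = "demo")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gff <- withr::local_tempfile(fileext = ".gff3")
  summ <- withr::local_tempfile(fileext = ".tsv")
  write_topography(pred, tsv, gff, summ)
  seg <- read.delim(tsv)
  expect_identical(names(seg),
                   c("sequence_id", "rank", "start", "end", "score"))
  expect_equal(seg$start, 7L)
  glines <- readLines(gff)
  expect_identical(glines[1L], "##gff-version 3")
  fields <- strsplit(glines[2L], "\t")[[1L]]
  expect_length(fields, 9L)
  expect_identical(fields[3L], "transmembrane_helix")
  expect_identical(fields[4:5], c("7", "29"))
  sm <- read.delim(summ)
  expect_identical(sm$n_segments, 1L)
  expect_true(sm$is_membrane)
})
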