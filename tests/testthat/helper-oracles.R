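# Independent brute-force oracles used to cross-check the implementation.

random_seq <- function(len, letters = AMINO_ACIDS) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Naive O(L*n) window profile: re-averages every window from scratch.
naive_profile <- function(seq, scale, n) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  vals <- unname(scale$values[chars])
  vals[is.na(vals)] <- 0
  L <- length(vals)
  if (L < n) return(mean(vals))
  vapply(seq_len(L - n + 1L), function(i) mean(vals[i:(i + n - 1L)]), 0)
}

# Brute-force Mann-Whitney concordance: explicit double loop over all
# (positive, negative) pairs.
brute_auc <- function(scores, labels, positive = "TM") {
  p <- scores[labels == positive]
  q <- scores[labels != positive]
  total <- 0
  for (a in p) for (b in q) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(p) * length(q))
}

# Leftmost window (1-based start) whose naive mean strictly exceeds tau,
# scanning only starts >= from; NA when none qualifies.
leftmost_qualifying_window <- function(seq, scale, n, tau, from = 1L) {
  prof <- naive_profile(seq, scale, n)
  starts <- seq_along(prof)
  hits <- starts[starts >= from & prof > tau]
  if (length(hits)) hits[1L] else NA_integer_
}

# Full brute-force re-implementation of the two-threshold greedy scan,
# written independently of locate_tm_segments().
brute_scan <- function(seq, scale, n, tau_first, tau_next, gap) {
  starts <- integer(0)
  from <- 1L
  tau <- tau_first
  repeat {
    s <- leftmost_qualifying_window(seq, scale, n, tau, from)
    if (is.na(s)) break
    starts <- c(starts, s)
    from <- s + n + gap
    tau <- tau_next
  }
  starts
}

# Inverted-hydrophobicity generator configuration: TM cores drawn from
# KD-hydrophilic residues, SP h-regions from KD-hydrophobic ones, uniform
# background. Under the KD start the classes score backwards.
inverted_config <- function(seed) {
  tm <- setNames(rep(0, 20), AMINO_ACIDS)
  tm[c("D", "E", "N", "Q", "K", "R")] <- c(.25, .25, .15, .15, .1, .1)
  h <- setNames(rep(0, 20), AMINO_ACIDS)
  h[c("I", "L", "F", "V")] <- c(.3, .3, .2, .2)
  bg <- setNames(rep(0.05, 20), AMINO_ACIDS)
  generator_config(seed = seed, composition_tm = tm, composition_sp_h = h,
                   composition_background = bg)
}

# Converted supplementary benchmark datasets are looked up under
# inst/extdata/supplementary; absent files abort with conversion guidance.
supplementary_dataset <- function(name) {
  dir <- system.file("extdata", "supplementary", package = "pmiscale")
  path <- file.path(dir, paste0(name, ".fasta"))
  if (!nzchar(dir) || !file.exists(path)) {
    stop(sprintf(
      "supplementary dataset '%s' not available: convert the published file to FASTA (+ optional sidecar TSV) and place it at inst/extdata/supplementary/%s.fasta",
      name, name), call. = FALSE)
  }
  sniff_supplementary(path)
}
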