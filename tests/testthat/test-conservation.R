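test_that("global alignment handles identity and single-gap cases", {
  self <- global_align("ACDE", "ACDE")
  expect_equal(paste(self$human, collapse = ""), "ACDE")
  expect_equal(paste(self$ortholog, collapse = ""), "ACDE")

  gapped <- global_align("ACDE", "ACE")
  expect_equal(paste(gapped$human, collapse = ""), "ACDE")
  expect_equal(sum(gapped$ortholog == "-"), 1L)
  # identity over human positions: 3 of 4
  m <- sum(gapped$human == gapped$ortholog & gapped$ortholog != "-")
  expect_equal(m / 4, 0.75)

  expect_error(global_align("AC1E", "ACE"), "illegal character")
  expect_error(global_align("", "ACE"), "empty")
})

test_that("pairwise identity is symmetric on random sequence pairs", {
  set.seed(3)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    a <- sample(aa, 30, replace = TRUE)
    b <- a
    flip <- sample(30, 6)
    for (s in flip) b[s] <- sample(setdiff(aa, a[s]), 1)
    a <- paste(a, collapse = ""); b <- paste(b, collapse = "")
    id_ab <- with(global_align(a, b), mean(human == ortholog))
    id_ba <- with(global_align(b, a), mean(human == ortholog))
    expect_equal(id_ab, id_ba)
    expect_equal(id_ab, 24 / 30)
  }
})

test_that("aligned pairs validate lengths and drop gap-in-both columns", {
  p <- aligned_pair("AC-DE", "AG-DE")
  expect_equal(length(p$human), 4L)  # shared gap column removed
  expect_error(aligned_pair("ACDE", "ACE"), "equal length")
  expect_error(aligned_pair("ACDE", "AC!E"), "illegal")
})

test_that("sliding-window identity matches hand computations", {
  s60 <- paste(rep("ACDEFGHIKL", 6), collapse = "")
  ident <- aligned_pair(s60, s60)
  track <- sliding_window_identity(ident, window = 30)
  expect_equal(sum(!is.na(track)), 31L)
  expect_true(all(track[1:31] == 100))

  # one substitution inside every window: 29/30 matches
  sub <- strsplit(s60, "")[[1]]
  sub[30] <- if (sub[30] == "A") "C" else "A"
  one_off <- aligned_pair(s60, paste(sub, collapse = ""))
  t2 <- sliding_window_identity(one_off, window = 30)
  expect_equal(t2[1], 100 * 29 / 30)
  expect_equal(t2[1], 96.6667, tolerance = 1e-4)

  # fully distinct sequences: 0 everywhere
  distinct <- aligned_pair(paste(rep("A", 40), collapse = ""),
                           paste(rep("C", 40), collapse = ""))
  expect_true(all(sliding_window_identity(distinct, 30) == 0, na.rm = TRUE))

  expect_error(sliding_window_identity(ident, window = 61), "larger")
})

test_that("window values equal a brute-force recount on random gapped pairs", {
  set.seed(17)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep_i in 1:20) {
    L <- sample(15:40, 1)
    h <- sample(aa, L, replace = TRUE)
    o <- h
    o[stats::runif(L) < 0.3] <- sample(aa, sum(stats::runif(L) < 0.3) + 1,
                                       replace = TRUE)[1]
    o[stats::runif(L) < 0.1] <- "-"
    pair <- aligned_pair(paste(h, collapse = ""), paste(o, collapse = ""))
    w <- sample(2:min(10, L), 1)
    track <- sliding_window_identity(pair, window = w)
    hp <- which(pair$human != "-")
    for (p in seq_len(length(hp) - w + 1L)) {
      cols <- hp[p:(p + w - 1L)]
      brute <- 100 * sum(pair$human[cols] == pair$ortholog[cols] &
                           pair$ortholog[cols] != "-") / w
      expect_equal(track[p], brute)
    }
  }
})

test_that("an additional mismatch never increases any window value", {
  set.seed(29)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    h <- sample(aa, 30, replace = TRUE)
    o <- h
    pair0 <- aligned_pair(paste(h, collapse = ""), paste(o, collapse = ""))
    t0 <- sliding_window_identity(pair0, window = 10)
    site <- sample(30, 1)
    o[site] <- sample(setdiff(aa, h[site]), 1)
    t1 <- sliding_window_identity(
      aligned_pair(paste(h, collapse = ""), paste(o, collapse = "")),
      window = 10)
    expect_true(all(t1 <= t0, na.rm = TRUE))
  }
})

test_that("per-site conservation counts orthologs with identical residues", {
  human <- paste(rep("A", 10), collapse = "")
  all_match <- lapply(1:12, function(k) aligned_pair(human, human,
                                                     paste0("o", k)))
  expect_true(all(per_site_conservation(all_match) == 1))

  half <- c(lapply(1:6, function(k) aligned_pair(human, human, paste0("m", k))),
            lapply(1:6, function(k)
              aligned_pair(human, paste(rep("C", 10), collapse = ""),
                           paste0("x", k))))
  expect_true(all(per_site_conservation(half) == 0.5))

  bad <- list(aligned_pair("AAAA", "AAAA"), aligned_pair("CCCC", "CCCC"))
  expect_error(per_site_conservation(bad), "same human sequence")
})

test_that("a gap in the ortholog counts against the ortholog denominator", {
  pairs <- list(aligned_pair("ACDE", "ACDE", "full"),
                aligned_pair("ACDE", "A-DE", "gappy"))
  ps <- per_site_conservation(pairs)
  expect_equal(as.numeric(ps), c(1, 0.5, 1, 1))
})

test_that("region means implement both candidate definitions", {
  expect_equal(region_mean_conservation(rep(1, 50), 10, 20), 100)
  expect_equal(region_mean_conservation(c(1, 0.5), 1, 2), 75)
  expect_error(region_mean_conservation(rep(1, 50), 30, 20), "interval")
  expect_error(region_mean_conservation(rep(1, 50), 1, 60), "interval")

  set.seed(41)
  pairs <- mk_gapfree_panel(n_orth = 8, len = 120, p_sub = 0.2)
  prof <- conservation_profile(pairs, window = 10)
  a <- region_mean_conservation(prof, 20, 80, method = "per_site")
  b <- region_mean_conservation(prof, 20, 80, method = "windowed")
  expect_equal(a, b, tolerance = 0.05)  # differ only via window edges
})

test_that("mean per-site equals mean ortholog identity on gap-free panels", {
  set.seed(37)
  pairs <- mk_gapfree_panel(n_orth = 6, len = 60, p_sub = 0.25)
  ps <- per_site_conservation(pairs)
  per_orth <- vapply(pairs, function(p) mean(p$human == p$ortholog),
                     numeric(1))
  expect_equal(mean(ps), mean(per_orth))
})

test_that("per-site conservation recovers the generator substitution rate", {
  set.seed(53)
  pairs <- mk_gapfree_panel(n_orth = 12, len = 585, p_sub = 0.2)
  ps <- per_site_conservation(pairs)
  se <- sqrt(0.2 * 0.8 / (12 * 585))
  expect_lt(abs(mean(ps) - 0.8), 3 * se)
})

test_that("ortholog panels read back from FASTA and Clustal formats", {
  sim <- simulate_orthologs(n_orthologs = 4, seed = 13)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_orthologs_fasta(sim, fa)
  pairs <- read_ortholog_panel(fa, human_id = "human_synthetic_reference")
  expect_length(pairs, 4L)
  prof_file <- conservation_profile(pairs)
  prof_mem <- conservation_profile(sim$pairs)
  expect_equal(prof_file$per_site, prof_mem$per_site)

  # Clustal round-trip via an in-code writer
  aln <- withr::local_tempfile(fileext = ".aln")
  seqs <- c(human_ref = sim$reference, sim$orthologs)
  chunks <- seq(1, nchar(sim$reference), by = 60)
  lines <- c("CLUSTAL W (synthetic) multiple sequence alignment", "", "")
  for (st in chunks) {
    lines <- c(lines, vapply(names(seqs), function(nm)
      sprintf("%-16s%s", nm, substr(seqs[[nm]], st, st + 59)), character(1)),
      "")
  }
  writeLines(lines, aln)
  pairs2 <- read_ortholog_panel(aln, human_id = "human_ref")
  expect_equal(conservation_profile(pairs2)$per_site, prof_mem$per_site)
})

test_that("unaligned FASTA input triggers the built-in pairwise aligner", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">NP_004174_human", "MTITYTSQVANARLGSFSRLLLCW",
               ">ortholog_short", "MTITYTSQVANARLGSFSRLLCW"), fa)
  pairs <- read_ortholog_panel(fa)
  expect_length(pairs, 1L)
  expect_equal(sum(pairs[[1]]$ortholog == "-"), 1L)
})
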