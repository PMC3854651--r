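test_that("threshold resolution: absolute, fractional (ceil), bounds", {
  expect_equal(resolve_threshold(mining_params(gap = 3, min_support = 3), 3), 3L)
  expect_equal(
    resolve_threshold(mining_params(gap = 3, min_support_frac = 0.9), 3000),
    2700L)
  expect_equal(
    resolve_threshold(mining_params(gap = 3, min_support_frac = 1.0), 5), 5L)
  # ceil, not floor
  expect_equal(
    resolve_threshold(mining_params(gap = 3, min_support_frac = 0.5), 5), 3L)
  expect_warning(
    resolve_threshold(mining_params(gap = 3, min_support = 4), 3),
    "no pattern can qualify")
  expect_error(mining_params(gap = 3, min_support_frac = 0), "\\(0, 1\\]")
  expect_error(mining_params(gap = 3, min_support_frac = 1.2), "\\(0, 1\\]")
  expect_error(mining_params(gap = 0, min_support = 1), ">= 1")
  expect_error(mining_params(gap = 3), "required")
})

test_that("counting matrices reproduce the worked example step by step", {
  idx <- build_index(worked_example_db())
  mC <- initial_matrix(idx, "C")
  expect_equal(unclass(mC), list(4L, c(3L, 5L), c(4L, 6L)),
               ignore_attr = TRUE)
  mT <- initial_matrix(idx, "T")  # independent scan: {(2,7),(2),(1)}
  expect_equal(unclass(mT), list(c(2L, 7L), 2L, 1L), ignore_attr = TRUE)

  mCA <- extend_matrix(idx, mC, "A", G = 3)
  expect_equal(unclass(mCA), list(6L, c(4L, 7L), 7L), ignore_attr = TRUE)
  expect_equal(support_of(mCA), 3L)

  mA <- initial_matrix(idx, "A")
  mAT <- extend_matrix(idx, mA, "T", G = 3)
  expect_equal(unclass(mAT), list(c(2L, 7L), 2L, integer(0)),
               ignore_attr = TRUE)
  expect_equal(support_of(mAT), 2L)
})

test_that("extension retains every qualifying position, not the minimum", {
  db <- seq_db("ACCGT", alphabet = "dna")
  idx <- build_index(db)
  mA <- initial_matrix(idx, "A")
  mAC <- extend_matrix(idx, mA, "C", G = 3)
  expect_equal(mAC[[1]], c(2L, 3L))
  # the crippled min-only rule keeps just position 2
  expect_equal(extend_matrix(idx, mA, "C", G = 3, retain = "min-only")[[1]], 2L)
})

test_that("support counts non-empty rows only", {
  expect_equal(support_of(structure(list(6L, c(4L, 7L), 7L),
                                    class = "counting_matrix")), 3L)
  expect_equal(support_of(structure(list(c(2L, 7L), 2L, integer(0)),
                                    class = "counting_matrix")), 2L)
  expect_equal(support_of(structure(list(integer(0), integer(0)),
                                    class = "counting_matrix")), 0L)
})

test_that("mine reproduces the worked example and prunes below failures", {
  db <- worked_example_db()
  res <- mine(db, mining_params(gap = 3, min_support = 3))
  m <- res$motifs
  expect_equal(m$support[m$pattern == "C*A"], 3L)
  expect_false("A*T" %in% m$pattern)
  # no recursion beneath the failed candidate
  expect_false(any(startsWith(m$pattern, "A*T*")))
  expect_true(all(m$support >= res$threshold))
  expect_equal(m$support_fraction, m$support / 3)
})

test_that("mine matches hand enumeration on a three-sequence toy", {
  db <- seq_db(c("AC", "AC", "AG"), alphabet = "dna")
  res <- mine(db, mining_params(gap = 2, min_support = 2))
  expect_setequal(support_set(res), c("A 3", "C 2", "A*C 2"))
})

test_that("unreachable thresholds yield an empty result with a warning", {
  db <- worked_example_db()
  expect_warning(res <- mine(db, mining_params(gap = 3, min_support = 4)),
                 "no pattern can qualify")
  expect_equal(nrow(res$motifs), 0L)
})

test_that("length-1 supports equal the number of sequences holding the item", {
  set.seed(5)
  for (s in sample.int(1e6, 5)) {
    db <- random_db(seed = s)
    res <- mine(db, mining_params(gap = 3, min_support = 1, max_length = 1))
    for (it in db$alphabet$items) {
      expected <- sum(grepl(it, db$sequences, fixed = TRUE))
      got <- res$motifs$support[res$motifs$pattern == it]
      if (expected == 0L) expect_length(got, 0L)
      else expect_equal(got, expected)
    }
  }
})

test_that("anti-monotonicity holds along every reported pattern", {
  set.seed(21)
  for (s in sample.int(1e6, 8)) {
    db <- random_db(seed = s)
    lam <- sample.int(db$N, 1)
    res <- mine(db, mining_params(gap = sample(2:4, 1), min_support = lam))
    m <- res$motifs
    supp <- setNames(m$support, m$pattern)
    long <- m[m$length >= 2L, ]
    if (nrow(long) == 0L) next
    prefix <- sub("\\*[^*]$", "", long$pattern)
    expect_true(all(prefix %in% m$pattern))
    expect_true(all(supp[prefix] >= long$support))
  }
})

test_that("min_length and max_length trim reporting and recursion", {
  db <- worked_example_db()
  res <- mine(db, mining_params(gap = 3, min_support = 3, min_length = 2))
  expect_true(all(res$motifs$length >= 2L))
  expect_true("C*A" %in% res$motifs$pattern)
  res1 <- mine(db, mining_params(gap = 3, min_support = 3, max_length = 1))
  expect_setequal(res1$motifs$pattern, c("A", "C", "G", "T"))
})

test_that("DFS preorder is deterministic; --sort reorders lexicographically", {
  db <- random_db(seed = 777)
  p <- mining_params(gap = 3, min_support = 2)
  expect_identical(mine(db, p), mine(db, p))
  srt <- mine(db, p, sort = TRUE)
  expect_false(is.unsorted(srt$motifs$pattern))
})

test_that("report_positions snapshots agree with supports", {
  db <- worked_example_db()
  res <- mine(db, mining_params(gap = 3, min_support = 3,
                                report_positions = TRUE))
  snap <- res$positions[["C*A"]]
  expect_named(snap, c("X", "Y", "Z"))
  expect_equal(unname(unclass(snap)), list(6L, c(4L, 7L), 7L),
               ignore_attr = TRUE)
  for (k in seq_len(nrow(res$motifs))) {
    s <- res$positions[[res$motifs$pattern[k]]]
    expect_equal(sum(lengths(s) > 0L), res$motifs$support[k])
  }
})

test_that("motif TSV output has the documented shape", {
  db <- worked_example_db()
  res <- mine(db, mining_params(gap = 3, min_support = 3,
                                report_positions = TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_motifs(res, f, positions_path = fp)
  tab <- read.delim(f, colClasses = c("character", "integer", "integer",
                                      "character"))
  expect_named(tab, c("pattern", "length", "support", "support_fraction"))
  row <- tab[tab$pattern == "C*A", ]
  expect_equal(row$length, 2L)
  expect_equal(row$support, 3L)
  expect_equal(row$support_fraction, "1.000000")
  pos <- read.delim(fp)
  expect_named(pos, c("pattern", "sequence_id", "end_positions"))
})
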