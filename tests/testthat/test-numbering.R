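test_that("template sequences number sequentially with no insertion codes", {
  for (ct in c("heavy", "light")) {
    chain <- assign_kabat_numbering(kabat_template(ct), ct)
    expect_identical(attr(chain, "framework_identity"), 1)
    expect_true(all(chain$insertion_code == ""))
    expect_identical(chain$kabat_number, seq_len(nrow(chain)))
    expect_identical(chain_sequence(chain), kabat_template(ct))
  }
})

test_that("an extra FR3 residue is numbered 82A", {
  fv <- make_fv_sequence("heavy", fr3_insertions = 1, seed = 11)
  chain <- assign_kabat_numbering(fv$sequence, "heavy")
  ins <- chain$label[chain$insertion_code != ""]
  expect_identical(ins, "82A")
  expect_identical(chain$region[chain$label == "82A"], "FR3")
})

test_that("a long CDR-H3 gains insertion codes 100A, 100B, 100C", {
  fv <- make_fv_sequence("heavy", cdr_lengths = c(5, 16, 11), seed = 12)
  chain <- assign_kabat_numbering(fv$sequence, "heavy")
  expect_identical(chain$label[chain$insertion_code != ""],
                   c("100A", "100B", "100C"))
  expect_true(all(chain$region[chain$insertion_code != ""] == "CDR3"))
})

test_that("numbering round-trips and regions partition the chain", {
  for (seed in 1:25) {
    ct <- if (seed %% 2 == 0) "heavy" else "light"
    cdr <- if (ct == "heavy") {
      c(sample(5:7, 1), sample(14:19, 1), sample(5:14, 1))
    } else {
      c(sample(10:16, 1), 7, sample(8:11, 1))
    }
    fv <- withr::with_seed(seed, make_fv_sequence(ct, cdr_lengths = cdr,
                                                  seed = seed + 100))
    chain <- assign_kabat_numbering(fv$sequence, ct)
    # round trip
    expect_identical(chain_sequence(chain), fv$sequence)
    # partition: every residue in exactly one region, ordered FR1..FR4
    expect_identical(sum(table(chain$region)), nrow(chain))
    expect_identical(unique(chain$region),
                     intersect(c("FR1", "CDR1", "FR2", "CDR2", "FR3",
                                 "CDR3", "FR4"), unique(chain$region)))
    # strict (number, insertion code) ordering
    key <- chain$kabat_number * 100 +
      match(chain$insertion_code, c("", LETTERS))
    expect_true(all(diff(key) > 0))
  }
})

test_that("numbering recovers generator ground truth on fuzzed sequences", {
  n_ok <- 0L
  n <- 1000L
  set.seed(20240915)
  for (i in seq_len(n)) {
    ct <- sample(c("heavy", "light"), 1)
    cdr <- if (ct == "heavy") {
      c(sample(4:7, 1), sample(14:19, 1), sample(4:16, 1))
    } else {
      c(sample(9:16, 1), 7, sample(6:12, 1))
    }
    k <- if (ct == "heavy") sample(0:3, 1) else 0
    fv <- make_fv_sequence(ct, cdr_lengths = cdr, fr3_insertions = k,
                           fr1_trunc = sample(0:2, 1),
                           mutation_rate = 0.12, seed = i)
    chain <- assign_kabat_numbering(fv$sequence, ct)
    if (identical(chain$label, fv$chain$label) &&
        identical(chain$region, fv$chain$region)) n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, n)
})

test_that("numbering equals the exhaustive placement oracle", {
  set.seed(42)
  for (i in 1:20) {
    ct <- if (i %% 2 == 0) "heavy" else "light"
    k <- if (ct == "heavy") sample(0:3, 1) else 0
    cdr <- if (ct == "heavy") {
      c(sample(4:7, 1), sample(14:18, 1), sample(5:12, 1))
    } else {
      c(sample(9:14, 1), 7, sample(7:11, 1))
    }
    fv <- make_fv_sequence(ct, cdr_lengths = cdr, fr3_insertions = k,
                           mutation_rate = 0.15, seed = 5000 + i)
    chain <- assign_kabat_numbering(fv$sequence, ct)
    best <- oracle_segment(fv$sequence, ct)
    expect_equal(attr(chain, "framework_identity"), best$identity,
                 tolerance = 1e-12)
    got <- c(sum(chain$insertion_code != "" & chain$region == "FR3"),
             sum(chain$region == "CDR1"), sum(chain$region == "CDR2"),
             sum(chain$region == "CDR3"))
    expect_identical(got, as.integer(c(best$k, best$c1, best$c2, best$c3)))
  }
})

test_that("region boundaries place H63/H65 in CDR2, H66 in FR3, L26 in CDR1", {
  expect_identical(kabat_region_of(c(63, 65), "heavy"), c("CDR2", "CDR2"))
  expect_identical(kabat_region_of(66, "heavy"), "FR3")
  expect_identical(kabat_region_of(26, "light"), "CDR1")
  heavy <- assign_kabat_numbering(kabat_template("heavy"), "heavy")
  expect_true(all(heavy$region[heavy$kabat_number %in% 50:65] == "CDR2"))
})

test_that("annotate_regions is idempotent and re-derives from numbers", {
  chain <- assign_kabat_numbering(kabat_template("light"), "light")
  scrambled <- chain
  scrambled$region <- "FR1"
  expect_identical(annotate_regions(scrambled)$region, chain$region)
})

test_that("upper core sets match the published position lists", {
  expect_identical(as.integer(upper_core_positions("heavy")),
                   c(2L, 4L, 24L, 27L, 29L, 47L, 48L, 49L, 69L, 71L, 78L,
                     94L))
  expect_identical(as.integer(upper_core_positions("light")),
                   c(2L, 4L, 64L, 66L, 71L))
  # disjoint from CDRs under the boundary table
  for (ct in c("heavy", "light")) {
    regions <- kabat_region_of(as.integer(upper_core_positions(ct)), ct)
    expect_false(any(startsWith(regions, "CDR")))
  }
  expect_error(upper_core_positions("heavy", extra = 52), "framework")
  expect_error(upper_core_positions("nano"))
})

test_that("non-antibody and malformed input is rejected", {
  junk <- paste(rep("GA", 55), collapse = "")
  expect_error(assign_kabat_numbering(junk, "heavy"), "not-an-Fv")
  expect_error(assign_kabat_numbering("EVQLB", "heavy"), "illegal|length")
  expect_error(
    assign_kabat_numbering(strrep("A", 50), "heavy"), "length")
  expect_error(
    assign_kabat_numbering(paste0(kabat_template("heavy"), "J"), "heavy"),
    "illegal")
})

test_that("X is tolerated outside anchors and never matches", {
  seq <- kabat_template("heavy")
  substr(seq, 10, 10) <- "X"
  chain <- assign_kabat_numbering(seq, "heavy")
  expect_identical(chain$residue[10], "X")
  expect_lt(attr(chain, "framework_identity"), 1)
})

test_that("numbering TSV uses 0-based seq_index", {
  chain <- assign_kabat_numbering(kabat_template("light"), "light")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_numbering_tsv(chain, path)
  tsv <- readr::read_tsv(path, show_col_types = FALSE)
  expect_identical(tsv$seq_index[1], 0)
  expect_identical(nrow(tsv), nrow(chain))
})
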