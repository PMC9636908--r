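toy_genome <- c(chr1 = "ACGTACGT")

test_that("motif extraction is strand-aware and transcript-oriented", {
  expect_equal(motif_at(toy_genome, "chr1", 4, "+", c(-1, 1)), "GTA")
  # minus strand: reverse complement of genomic positions 3..5, via oracle
  expect_equal(motif_at(toy_genome, "chr1", 4, "-", c(-1, 1)),
               oracle_revcomp(substring(toy_genome[["chr1"]], 3, 5)))
  expect_equal(motif_at(toy_genome, "chr1", 4, "-", c(-1, 1)), "TAC")
  expect_equal(motif_at(toy_genome, "chr1", 4, "+", c(0, 0)), "T")
  expect_equal(motif_at(toy_genome, "chr1", 4, "-", c(0, 0)), "A")
  expect_error(motif_at(toy_genome, "chr1", 2, "+", c(-3, 1)), "bounds")
})

test_that("consensus levels match their definitions and reject bad input", {
  expect_equal(consensus_level("TTGAT"), 1L)
  expect_equal(consensus_level("ATGAC"), 3L)
  expect_equal(consensus_level("GCGAT"), 4L)
  expect_equal(consensus_level("GGGCT"), 0L)
  expect_equal(consensus_level("TTNAT"), 0L)  # N never matches
  expect_error(consensus_level("TTGA"), "5-mers")
})

test_that("consensus leveling is nested and agrees with regex predicates", {
  set.seed(7)
  alphabet <- c("A", "C", "G", "T", "N")
  for (i in 1:500) {
    m <- paste(sample(alphabet, 5, replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    expect_equal(consensus_level(m), oracle_consensus(m), info = m)
  }
})

test_that("positional adjustment finds the closest YTNAY with downstream ties", {
  # planted YTNAY ("TTCAT") centered at position 10 of a G-padded contig
  g <- c(c1 = paste0(strrep("G", 6), "TTCAT", strrep("G", 6)))  # center = 10
  expect_equal(adjust_bp_position(g, "c1", 10, "+"), 10)   # fixed point
  expect_equal(adjust_bp_position(g, "c1", 11, "+"), 10)   # off by one
  expect_equal(adjust_bp_position(g, "c1", 8, "+"), 10)    # off by two
  expect_equal(adjust_bp_position(g, "c1", 13, "+"), 13)   # out of window: unchanged
  # exhaustive-scan oracle over candidate shifts
  for (p in 8:12) {
    cands <- c(0, 1, -1, 2, -2)
    match5 <- vapply(cands, function(d) {
      m <- substring(g[["c1"]], p + d - 3, p + d + 1)
      grepl("^[CT]T[ACGT]A[CT]$", m)
    }, logical(1))
    expected <- if (any(match5)) p + cands[which(match5)[1]] else p
    expect_equal(adjust_bp_position(g, "c1", p, "+"), expected)
  }
  # tie: YTNAY centered at both p-2 and p+2 but not in between; downstream wins
  g2 <- c(c1 = paste0(strrep("G", 10), "CTGACTGAC", strrep("G", 10)))
  p <- 16L  # centers 14 and 18 both carry a YTNAY window
  expect_equal(consensus_level(substring(g2[["c1"]], 11, 15)), 1L)
  expect_equal(consensus_level(substring(g2[["c1"]], 15, 19)), 1L)
  expect_equal(adjust_bp_position(g2, "c1", p, "+"), 18L)
  # same geometry mirrored onto the minus strand prefers downstream too
  g2m <- c(c1 = oracle_revcomp(g2[["c1"]]))
  L <- nchar(g2m[["c1"]])
  expect_equal(adjust_bp_position(g2m, "c1", L - p + 1L, "-"), L - 18L + 1L)
})

test_that("adjustment is idempotent and a no-op without nearby YTNAY", {
  fx <- generate_adjustment_fixture(n = 60, n_offby = 15, seed = 9)
  a1 <- adjust_bp_position(fx$genome, fx$records$contig, fx$records$pos, fx$records$strand)
  a2 <- adjust_bp_position(fx$genome, fx$records$contig, a1, fx$records$strand)
  expect_identical(a1, a2)
  # pure-G contig has no YTNAY anywhere
  g <- c(flat = strrep("G", 50))
  expect_equal(adjust_bp_position(g, "flat", 25, "+"), 25)
})

test_that("dataset adjustment merges collided records and reports deltas", {
  g <- c(c1 = paste0(strrep("G", 6), "TTCAT", strrep("G", 6)))
  rec <- data.frame(contig = "c1", pos = c(10L, 11L), strand = "+",
                    dataset_id = "d", evidence_class = "experimental",
                    stringsAsFactors = FALSE)
  out <- adjust_dataset(g, rec)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$pos, 10L)
  expect_equal(out$report$delta, -1)
  expect_equal(out$records$bp_base, "A")

  flat <- data.frame(contig = "c1", pos = c(3L, 4L), strand = "+",
                     dataset_id = "d", evidence_class = "experimental",
                     stringsAsFactors = FALSE)
  g0 <- c(c1 = strrep("G", 20))
  out0 <- adjust_dataset(g0, flat)
  expect_equal(out0$report$delta, 0)

  mixed <- rec; mixed$dataset_id <- c("d1", "d2")
  expect_error(adjust_dataset(g, mixed), "single dataset")
})

test_that("planted off-by-one records shrink the dataset by exactly their count", {
  fx <- generate_adjustment_fixture(n = 100, n_offby = 10, seed = 3)
  out <- adjust_dataset(fx$genome, fx$records)
  expect_equal(out$report$n_raw, 110)
  expect_equal(out$report$delta, fx$expected_delta)
  expect_equal(out$report$delta, -10)
})

test_that("merging assigns classes by evidence span and is order-independent", {
  g <- c(c1 = strrep("TTCATG", 40))
  mk <- function(pos, ds, cls) data.frame(contig = "c1", pos = pos, strand = "+",
                                          dataset_id = ds, evidence_class = cls,
                                          stringsAsFactors = FALSE)
  e1 <- mk(c(11, 23, 35), "e1", "experimental")
  e2 <- mk(c(11, 47), "e2", "experimental")
  c1 <- mk(c(23, 47, 59), "c1", "computational")
  db <- merge_datasets(list(e1, e2, c1), genome = g)
  lookup <- function(p) db[db$pos == p, ]
  expect_equal(lookup(11)$bp_class, "eBP"); expect_equal(lookup(11)$n_sources, 2L)
  expect_equal(lookup(23)$bp_class, "mBP"); expect_equal(lookup(23)$n_sources, 2L)
  expect_equal(lookup(35)$bp_class, "eBP"); expect_equal(lookup(35)$n_sources, 1L)
  expect_equal(lookup(47)$bp_class, "mBP")
  expect_equal(lookup(59)$bp_class, "cBP"); expect_equal(lookup(59)$n_sources, 1L)
  # set-algebra oracle for the class partition
  pe <- union(e1$pos, e2$pos); pc <- c1$pos
  expect_setequal(db$pos[db$bp_class == "mBP"], intersect(pe, pc))
  expect_setequal(db$pos[db$bp_class == "eBP"], setdiff(pe, pc))
  expect_setequal(db$pos[db$bp_class == "cBP"], setdiff(pc, pe))
  # permuting the dataset list changes nothing
  db2 <- merge_datasets(list(c1, e2, e1), genome = g)
  expect_identical(db, db2)
  # name grammar
  expect_true(all(grepl("^[mec]BP_[^_]+_[0-9]+_[+-]_[ACGTN]$", db$bp_name)))
})

test_that("base composition percentages recover planted mixtures", {
  expect_equal(unname(composition_summary(c("A", "C", "G", "T"))), rep(25, 4))
  expect_equal(unname(composition_summary(rep("A", 7))), c(100, 0, 0, 0))
  planted <- c(rep("A", 23), rep("C", 11), rep("G", 9), rep("T", 7))  # n = 50
  expect_equal(unname(composition_summary(sample(planted))), c(46, 22, 18, 14))
  expect_error(composition_summary(character(0)), "empty")
})
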