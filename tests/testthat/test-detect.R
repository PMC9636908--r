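test_that("variant typing covers SNVs, indels and complex substitutions", {
  sv <- classify_variant("A", "T", 100L)
  expect_equal(sv$var_type, "snv")
  expect_equal(c(sv$affected_start, sv$affected_end), c(100L, 100L))

  dl <- classify_variant("ATTGC", "A", 100L)
  expect_equal(dl$var_type, "4 nt-deletion")
  expect_equal(c(dl$affected_start, dl$affected_end), c(101L, 104L))
  tr <- oracle_trim("ATTGC", "A", 100L)
  expect_equal(dl$affected_start, tr$pos)
  expect_equal(dl$affected_end, tr$pos + nchar(tr$ref) - 1L)

  ins <- classify_variant("A", "ATT", 100L)
  expect_equal(ins$var_type, "2 nt-insertion")
  expect_equal(c(ins$affected_start, ins$affected_end), c(100L, 101L))

  cx <- classify_variant("AGG", "ATC", 100L)
  expect_true(cx$complex)
  expect_equal(cx$var_type, "2 nt-deletion")

  expect_error(classify_variant("A", "A", 100L), "identical")
})

one_row_variant <- function(ref, alt, pos) classify_variants(
  data.frame(contig = "c1", pos = pos, id = ".", ref = ref, alt = alt,
             stringsAsFactors = FALSE))

test_that("hit offsets reproduce the canonical SNV/deletion/insertion geometries", {
  b <- 1000L
  # SNV at the BP itself
  expect_equal(as.integer(hit_offsets(one_row_variant("T", "C", b), b, "+")), 0L)
  expect_equal(as.integer(hit_offsets(one_row_variant("T", "C", b), b, "-")), 0L)
  # SNV at BP-2 (plus: b-2; minus: b+2)
  expect_equal(as.integer(hit_offsets(one_row_variant("T", "A", b - 2L), b, "+")), -2L)
  expect_equal(as.integer(hit_offsets(one_row_variant("T", "A", b + 2L), b, "-")), -2L)
  # SNV at BP-3: outside the window
  expect_length(hit_offsets(one_row_variant("T", "A", b - 3L), b, "+"), 0)
  # 20 nt deletion spanning the whole motif
  del <- classify_variants(data.frame(contig = "c1", pos = b - 10L, id = ".",
                                      ref = strrep("A", 21), alt = "A"))
  expect_equal(as.integer(hit_offsets(del, b, "+")), c(-2L, -1L, 0L))
  # 1 nt deletion removing exactly BP-2
  d1 <- one_row_variant("CA", "C", b - 3L)  # deletes base b-2
  expect_equal(as.integer(hit_offsets(d1, b, "+")), -2L)
  # insertion strictly inside the window reports both flanks, low confidence
  i1 <- one_row_variant("A", "AGG", b - 2L)  # breakpoint between b-2 and b-1
  h <- hit_offsets(i1, b, "+")
  expect_equal(as.integer(h), c(-2L, -1L))
  expect_true(attr(h, "low_confidence"))
  # insertion at the window edge (between b and b+1) does not count
  i2 <- one_row_variant("A", "AGG", b)
  expect_length(hit_offsets(i2, b, "+"), 0)
})

test_that("a fuzzed sweep of SNVs around a BP hits exactly the [-2, 0] window", {
  f <- generate_fixture(seed = 13, n_genes = 4, n_variants = 1)
  bp <- f$manifest_bp[1, ]
  g <- f$genome[[1]]
  offs <- -30:10
  site <- if (bp$strand == "+") bp$pos + offs else bp$pos - offs
  ref <- substring(g, site, site)
  alt <- ifelse(ref == "A", "C", "A")
  vars <- data.frame(contig = names(f$genome), pos = site,
                     id = sprintf("off%d", offs), ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  res <- run_detection(f$genome, f$exons, f$bp_datasets, vars)
  det_for_this_bp <- res$detections[res$detections$bp_pos == bp$pos, ]
  got_offs <- sort(unique(as.integer(sub("off", "", det_for_this_bp$id))))
  expect_equal(got_offs, c(-2L, -1L, 0L))
})

test_that("detection emits one row per transcript membership and sorts deterministically", {
  g <- c(c1 = strrep("G", 400))
  gc <- strsplit(g[["c1"]], "")[[1]]
  gc[101:102] <- c("G", "T"); gc[199:200] <- c("A", "G")
  gc[168:172] <- strsplit("TTCAT", "")[[1]]  # BP at 171, distance -30
  g <- c(c1 = paste(gc, collapse = ""))
  ex <- rbind(
    data.frame(transcript_id = "T1", gene_symbol = "G1", contig = "c1", strand = "+",
               start = c(1, 201), end = c(100, 300), canonical = TRUE),
    data.frame(transcript_id = "T2", gene_symbol = "G1", contig = "c1", strand = "+",
               start = c(1, 201), end = c(100, 260), canonical = FALSE))
  bp <- list(data.frame(contig = "c1", pos = 171L, strand = "+", dataset_id = "d1",
                        evidence_class = "experimental", stringsAsFactors = FALSE))
  vars <- data.frame(contig = "c1", pos = 171L, id = "v1", ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  res <- run_detection(g, ex, bp, vars)
  expect_equal(nrow(res$detections), 2)
  expect_equal(length(unique(res$detections$bp_name)), 1)
  expect_setequal(res$detections$transcript, c("T1_IVS1", "T2_IVS1"))
  res2 <- run_detection(g, ex, bp, vars)
  expect_identical(res$detections, res2$detections)
  # canonical-only drops the T2 row
  resc <- run_detection(g, ex, bp, vars, canonical_only = TRUE)
  expect_equal(resc$detections$transcript, "T1_IVS1")
  # empty variant set yields an empty, well-formed table
  res0 <- run_detection(g, ex, bp, vars[0, ])
  expect_equal(nrow(res0$detections), 0)
  expect_true(all(c("bp_name", "hit_positions", "score") %in% names(res0$detections)))
  # unknown contig is skipped with a warning
  vbad <- data.frame(contig = "cX", pos = 10L, id = "v2", ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  expect_warning(detect(classify_variants(vbad), res$mapped, res$introns$memberships),
                 "absent")
})

test_that("detect agrees with the brute-force all-pairs oracle on random fixtures", {
  for (seed in c(2, 8)) {
    f <- generate_fixture(seed = seed, n_genes = 20, n_variants = 150)
    res <- run_detection(f$genome, f$exons, f$bp_datasets, f$variants)
    bp_idx <- unique(res$mapped[, c("bp_name", "pos", "strand")])
    got <- unique(res$detections[, c("variant_key", "bp_name", "hit_positions")])
    got <- got[order(got$variant_key, got$bp_name), ]
    exp_rows <- list()
    for (i in seq_len(nrow(res$variants))) {
      v <- res$variants[i, ]
      vs <- oracle_variant_sites(v$ref, v$alt, v$pos)
      oh <- oracle_hits_all_bps(vs, bp_idx$pos, bp_idx$strand)
      if (nrow(oh))
        exp_rows[[length(exp_rows) + 1L]] <- data.frame(
          variant_key = v$variant_key, bp_name = bp_idx$bp_name[oh$bp_i],
          hit_positions = oh$hits, stringsAsFactors = FALSE)
    }
    expected <- unique(do.call(rbind, exp_rows))
    expected <- expected[order(expected$variant_key, expected$bp_name), ]
    rownames(got) <- NULL; rownames(expected) <- NULL
    expect_equal(got, expected)
  }
})

test_that("mirroring a fixture to the opposite strand preserves every detection", {
  f <- generate_fixture(seed = 17, n_genes = 12, n_variants = 80)
  r1 <- run_detection(f$genome, f$exons, f$bp_datasets, f$variants)
  m <- mirror_fixture(f)
  r2 <- run_detection(m$genome, m$exons, m$bp_datasets, m$variants)
  k1 <- r1$detections[order(r1$detections$id, r1$detections$distance_to_3ss), ]
  k2 <- r2$detections[order(r2$detections$id, r2$detections$distance_to_3ss), ]
  expect_equal(nrow(k1), nrow(k2))
  expect_equal(k1$hit_positions, k2$hit_positions)
  expect_equal(k1$distance_to_3ss, k2$distance_to_3ss)
  expect_equal(k1$bp_rank, k2$bp_rank)
  expect_equal(k1$consensus_level, k2$consensus_level)
})

test_that("tallies count each variant once under its best hit", {
  b <- build_validation_fixture()
  res <- run_detection(b$genome, b$exons, b$bp_datasets, b$variants, tracks = b$tracks)
  t <- tally_detections(res$detections)
  expect_equal(t$n_variants, 40L)
  expect_equal(sum(t$by_hit), 40L)
  expect_equal(sum(t$by_rank), 40L)
  # single detection: all tallies 0 or 1
  one <- res$detections[res$detections$variant_key == res$detections$variant_key[1], ]
  t1 <- tally_detections(one)
  expect_equal(t1$n_variants, 1L)
  expect_true(all(t1$by_hit %in% 0:1))
})
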