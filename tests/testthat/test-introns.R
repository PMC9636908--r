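make_exons <- function(tx, gene, contig, strand, starts, ends) {
  data.frame(transcript_id = tx, gene_symbol = gene, contig = contig,
             strand = strand, start = starts, end = ends, canonical = TRUE,
             stringsAsFactors = FALSE)
}

test_that("introns are the exon gaps, deduplicated, with strand-aware dinucleotides", {
  g <- c(c1 = strrep("G", 300))
  # plus strand: GT at 101-102, AG at 199-200
  gc <- strsplit(g[["c1"]], "")[[1]]
  gc[101:102] <- c("G", "T"); gc[199:200] <- c("A", "G")
  gp <- c(c1 = paste(gc, collapse = ""))
  ex <- make_exons("T1", "G1", "c1", "+", c(1, 201), c(100, 300))
  out <- extract_introns(ex, gp)
  expect_equal(nrow(out$introns), 1)
  expect_equal(c(out$introns$start, out$introns$end), c(101L, 200L))
  expect_equal(out$introns$length, 100L)
  expect_equal(out$memberships$intron_number, 1L)
  expect_equal(out$introns$donor, "GT")
  expect_equal(out$introns$acceptor, "AG")

  # the same intron in two transcripts: one record, two memberships
  ex2 <- rbind(ex, make_exons("T2", "G1", "c1", "+", c(1, 201), c(100, 260)))
  out2 <- extract_introns(ex2, gp)
  expect_equal(nrow(out2$introns), 1)
  expect_equal(nrow(out2$memberships), 2)

  # minus strand: transcript-sense donor read from positions 200,199 complemented
  gc[101:102] <- c("C", "T"); gc[199:200] <- c("A", "C")
  gm <- c(c1 = paste(gc, collapse = ""))
  exm <- make_exons("T3", "G2", "c1", "-", c(1, 201), c(100, 300))
  outm <- extract_introns(exm, gm)
  expect_equal(c(outm$introns$start, outm$introns$end), c(101L, 200L))
  expect_equal(outm$introns$donor, oracle_revcomp(substring(gm[["c1"]], 199, 200)))
  expect_equal(outm$introns$donor, "GT")
  expect_equal(outm$introns$acceptor, "AG")
  expect_equal(outm$memberships$intron_number, 1L)

  expect_error(extract_introns(make_exons("T4", "G3", "c1", "+", c(1, 50), c(60, 120)), gp),
               "overlapping")
})

test_that("minus-strand multi-intron transcripts number introns 5' to 3'", {
  g <- c(c1 = strrep("G", 500))
  ex <- make_exons("T1", "G1", "c1", "-", c(1, 151, 301), c(100, 250, 400))
  out <- extract_introns(ex, g)
  mem <- out$memberships[order(out$memberships$intron_key), ]
  # genomically first gap [101,150] is intron 2 on the minus strand
  k1 <- out$introns$intron_key[out$introns$start == 101]
  k2 <- out$introns$intron_key[out$introns$start == 251]
  expect_equal(out$memberships$intron_number[out$memberships$intron_key == k1], 2L)
  expect_equal(out$memberships$intron_number[out$memberships$intron_key == k2], 1L)
})

test_that("spliceosome typing uses the AT-AC heuristic with list override", {
  expect_equal(classify_intron("GT", "AG"), "major")
  expect_equal(classify_intron("AT", "AC"), "minor")
  expect_equal(classify_intron("GT", "AG", key = "k1", minor_list = "k1"), "minor")
})

test_that("BP map to 3'-proximal introns with the documented distance convention", {
  g <- c(c1 = strrep("G", 400))
  ex <- make_exons("T1", "G1", "c1", "+", c(1, 251), c(100, 350))  # intron [101,250]
  intr <- extract_introns(ex, g)
  mk_db <- function(pos) data.frame(
    contig = "c1", pos = pos, strand = "+", bp_base = "A", bp_class = "cBP",
    n_sources = 1L, sources = "d", consensus_level = 0L,
    bp_name = sprintf("cBP_c1_%d_+_A", pos), stringsAsFactors = FALSE)
  m <- map_bp_to_introns(mk_db(c(231L, 150L, 248L, 249L, 105L)), intr, g)
  # 20 bases from the 3' end (19 bases follow it) -> distance -20
  expect_equal(m$distance[m$pos == 231], -20L)
  expect_false(150 %in% m$pos)   # distance -101: just outside the window
  expect_true(248 %in% m$pos)    # distance -3: the closest position retained
  expect_equal(m$distance[m$pos == 248], -3L)
  expect_false(249 %in% m$pos)   # distance -2: inside the acceptor margin, dropped
  expect_false(105 %in% m$pos)   # -146, far outside
  # two BP at -24 and -30 in one intron rank #1/2 and #2/2
  m2 <- map_bp_to_introns(mk_db(c(227L, 221L)), intr, g)
  expect_equal(m2$rank[m2$distance == -24], 1L)
  expect_equal(m2$rank[m2$distance == -30], 2L)
  expect_true(all(m2$total == 2L))
})

test_that("rank vectors are permutations and mapping matches the all-pairs oracle", {
  f <- generate_fixture(seed = 21, n_genes = 25, n_variants = 1)
  res <- run_detection(f$genome, f$exons, f$bp_datasets, f$variants)
  mapped <- res$mapped
  for (k in unique(mapped$intron_key)) {
    r <- sort(mapped$rank[mapped$intron_key == k])
    expect_equal(r, seq_along(r))
  }
  om <- oracle_map(unique(res$db[, c("contig", "pos", "strand")]), res$introns$introns)
  got <- mapped[order(mapped$pos, mapped$intron_key),
                c("pos", "strand", "intron_key", "distance", "rank")]
  rownames(got) <- NULL; rownames(om) <- NULL
  expect_equal(got, om[, c("pos", "strand", "intron_key", "distance", "rank")])
})

test_that("distance and per-intron histograms recover planted proportions", {
  mk_mapped <- function(dist, key) data.frame(intron_key = key, distance = dist,
                                              stringsAsFactors = FALSE)
  # 57 of 100 BP planted in [-30, -21]
  planted <- mk_mapped(c(rep(-25L, 57), rep(-45L, 43)),
                       sprintf("i%03d", 1:100))
  h <- intron_bp_distribution(planted)
  expect_equal(sum(h$distance[as.integer(names(h$distance)) >= -30 &
                              as.integer(names(h$distance)) <= -21]), 57L)
  expect_equal(sum(h$distance), 100L)
  expect_equal(unname(h$distance[["-10"]]), 0L)  # empty bins render as 0
  # three BP in one intron: one intron carries 3 BP
  h3 <- intron_bp_distribution(mk_mapped(c(-10L, -20L, -30L), "iX"))
  expect_equal(h3$per_intron, c(`3` = 1L))
  expect_error(intron_bp_distribution(mk_mapped(integer(0), character(0))), "no mapped")
})

test_that("duplex pair-scoring: perfect complement, mismatches, monotonicity", {
  # TACTAAC pairs perfectly with U2 GUAGUA around the bulged BP adenosine:
  # pairs U:A, A:U, C:G, U:A, A:U, C:G = 2+2+3+2+2+3 = 14
  perfect <- binding_energy("TACTAAC", "U2")
  expect_equal(perfect$energy, -14)
  expect_equal(binding_energy("CCACCAA", "U2")$energy, 0)  # all mismatches
  # substituting any single paired base strictly raises the energy
  flanks <- c(1:5, 7)
  for (i in flanks) {
    for (b in setdiff(c("A", "C", "G", "T"), substring("TACTAAC", i, i))) {
      mut <- "TACTAAC"
      substring(mut, i, i) <- b
      expect_gt(binding_energy(mut, "U2")$energy, perfect$energy)
    }
  }
  # U12 default pairs its own branch consensus (UCCUUAAC core) perfectly:
  # pairs C:G, C:G, U:A, U:A, A:U, C:G = 3+3+2+2+2+3 = 15
  expect_equal(binding_energy("CCTTAAC", "U12")$energy, -15)
  expect_error(binding_energy("TACTAA", "U2"), "7-mer")
})
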