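## Deterministic synthetic-data generation: toy genomes, annotations, BP
## datasets and VCFs with controlled geometry, plus a reconstruction of the
## published 48-variant validation set's local geometry (distances, ranks,
## hit offsets, deletion lengths) on synthetic loci.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(x) unname(COMP[x])

# motif templates by consensus level, covering transcript offsets [-3, +1]
LEVEL_MOTIF <- c(`1` = "TTCAT", `2` = "TTCAG", `3` = "GTCAT", `4` = "GCAAT")

# write a transcript-sense sequence into a genome character vector:
# offset 0 is at genomic position pos0; on the minus strand offsets run
# genomically backwards and bases are complemented
plant_seq <- function(chars, pos0, strand, offsets, seq) {
  bases <- strsplit(seq, "")[[1]]
  stopifnot(length(bases) == length(offsets))
  gpos <- if (strand == "+") pos0 + offsets else pos0 - offsets
  if (strand == "-") bases <- comp_base(bases)
  chars[gpos] <- bases
  chars
}

# genomic position of a transcript-sense distance d (< 0) from the 3'ss of
# an intron [istart, iend]; the final intron base is d = -1
pos_at_distance <- function(istart, iend, strand, d) {
  if (strand == "+") iend + d + 1L else istart - d - 1L
}

#' Embedded geometry of the 48-variant retrospective validation set
#'
#' One row per published pathogenic BP variant: variant class, deletion
#' length and shape, BP distance to the 3'ss, BP rank and intron total,
#' expected hit offsets, not-detected status, and the consensus level,
#' BP class, population and conservation context assigned consistently with
#' the published aggregate tallies. Genomic coordinates are synthetic; only
#' the local geometry is reproduced.
#'
#' @return `data.frame` with one row per variant.
#' @export
validation_rows <- function() {
  r <- function(gene, vclass, ref, alt, del_len, del_start, dist, rank, total,
                hit, nd, strand, level, bp_class, pop = "none", cons = "pos",
                share_prev = FALSE) {
    data.frame(gene = gene, vclass = vclass, ref = ref, alt = alt,
               del_len = del_len, del_start = del_start, dist = dist,
               rank = rank, total = total, hit = hit, nd = nd, strand = strand,
               level = level, bp_class = bp_class, pop = pop, cons = cons,
               share_prev = share_prev, stringsAsFactors = FALSE)
  }
  rows <- rbind(
    r("ABCC8",    "snv", "T", "C", NA, NA, -20, 1, 1, "0",        FALSE, "-", 2, "mBP"),
    r("ALPL",     "del", NA,  NA,  20, -2, -33, 1, 1, "-2|-1|0",  FALSE, "+", 1, "mBP"),
    r("BBS1",     "snv", "A", "T", NA, NA, -21, 1, 1, "0",        FALSE, "+", 1, "mBP", cons = "neg"),
    r("BTK",      "snv", "T", "C", NA, NA, -23, 1, 1, "0",        FALSE, "-", 1, "mBP", pop = "rare"),
    r("C21orf2",  "snv", "T", "A", NA, NA, -23, 2, 3, "0",        FALSE, "-", 3, "mBP"),
    r("CAPN3",    "del", NA,  NA,   1, -2, -29, 1, 1, "-2",       FALSE, "-", 1, "mBP"),
    r("CD40LG",   "del", NA,  NA,   8, -2, -32, 1, 1, "-2|-1|0",  FALSE, "+", 1, "mBP"),
    r("CDT1",     "snv", "A", "G", NA, NA, -24, 1, 1, "0",        FALSE, "+", 1, "mBP", cons = "mixed"),
    r("COL4A5",   "snv", "A", "G", NA, NA, -40, 1, 1, "0",        FALSE, "+", 1, "mBP", cons = "neg"),
    r("COL5A1",   "snv", "T", "G", NA, NA, -25, 1, 2, "-2",       FALSE, "+", 2, "mBP"),
    r("COL7A1",   "snv", "T", "C", NA, NA, -23, 1, 1, "0",        FALSE, "-", 1, "mBP"),
    r("CPS1",     "snv", "A", "G", NA, NA, -24, 1, 2, "0",        FALSE, "+", 2, "mBP"),
    r("DYSF",     "snv", "A", "G", NA, NA, -33, 2, 2, "0",        FALSE, "+", 3, "mBP"),
    r("ENG",      "snv", "A", "G", NA, NA, -22, 1, 2, "-2",       FALSE, "-", 2, "mBP"),
    r("F8",       "snv", "T", "C", NA, NA, -27, 1, 1, "0",        FALSE, "-", 1, "mBP"),
    r("F9",       "snv", "A", "G", NA, NA, -25, 1, 1, "0",        FALSE, "+", 1, "eBP", pop = "rare"),
    r("FAS",      "snv", "A", "G", NA, NA, -16, NA, NA, "",       TRUE,  "-", 1, "cBP"),
    r("FBN2",     "snv", "A", "C", NA, NA, -26, 1, 1, "-2",       FALSE, "-", 1, "mBP"),
    r("FBN2",     "snv", "T", "C", NA, NA, -15, NA, NA, "",       TRUE,  "-", 1, "cBP"),
    r("FGD1",     "del", NA,  NA,   1,  0, -35, 1, 1, "0",        FALSE, "-", 1, "mBP"),
    r("HEXB",     "snv", "A", "G", NA, NA, -17, NA, NA, "",       TRUE,  "+", 1, "cBP"),
    r("IKBKG",    "snv", "A", "T", NA, NA, -23, 1, 1, "0",        FALSE, "+", 1, "mBP", cons = "mixed"),
    r("ITGB2",    "snv", "A", "C", NA, NA, -12, NA, NA, "",       TRUE,  "-", 1, "cBP"),
    r("ITGB4",    "snv", "T", "A", NA, NA, -25, 1, 1, "-2",       FALSE, "+", 1, "mBP"),
    r("ITGB4",    "snv", "T", "A", NA, NA, -19, 1, 1, "-2",       FALSE, "+", 1, "cBP"),
    r("KCNH2",    "snv", "T", "C", NA, NA, -28, 1, 1, "0",        FALSE, "-", 1, "cBP", cons = "neg"),
    r("L1CAM",    "snv", "T", "G", NA, NA, -19, 2, 3, "0",        FALSE, "-", 3, "cBP"),
    r("LCAT",     "snv", "A", "G", NA, NA, -22, 1, 2, "-2",       FALSE, "-", 2, "cBP"),
    r("LIPC",     "snv", "A", "G", NA, NA, -14, NA, NA, "",       TRUE,  "+", 1, "cBP"),
    r("LMX1B",    "del", NA,  NA,  17, -2, -37, 1, 1, "-2|-1|0",  FALSE, "+", 1, "cBP"),
    r("MLH1",     "snv", "T", "G", NA, NA, -26, 2, 3, "-2",       FALSE, "+", 3, "cBP"),
    r("MLH1",     "snv", "A", "G", NA, NA, -24, 2, 3, "0",        FALSE, "+", 3, "cBP"),
    r("MSH2",     "snv", "A", "G", NA, NA, -24, 1, 1, "0",        FALSE, "+", 1, "cBP", cons = "neg"),
    r("MSH6",     "snv", "T", "G", NA, NA, -26, 2, 3, "-2",       FALSE, "+", 3, "cBP"),
    r("NPC1",     "snv", "T", "C", NA, NA, -28, 1, 1, "0",        FALSE, "-", 1, "cBP", cons = "neg"),
    r("NTRK1",    "snv", "T", "A", NA, NA, -33, 1, 1, "-2",       FALSE, "+", 1, "cBP"),
    r("RB1",      "snv", "A", "T", NA, NA, -26, 1, 2, "-1",       FALSE, "+", 4, "cBP"),
    r("SLC25A20", "snv", "A", "C", NA, NA, -10, NA, NA, "",       TRUE,  "-", 1, "cBP"),
    r("SLC5A2",   "del", NA,  NA,  22, -2, -31, 1, 2, "-2|-1|0",  FALSE, "-", 2, "cBP"),
    r("TH",       "snv", "A", "T", NA, NA, -24, 3, 3, "-2",       FALSE, "-", 3, "cBP"),
    r("TSC2",     "snv", "A", "G", NA, NA, -18, 1, 2, "0",        FALSE, "+", 2, "cBP"),
    r("UROS",     "snv", "A", "C", NA, NA, -31, 1, 2, "-2",       FALSE, "-", 2, "cBP"),
    r("USH2A",    "snv", "T", "C", NA, NA, -17, NA, NA, "",       TRUE,  "+", 1, "cBP"),
    r("VMA21",    "snv", "A", "C", NA, NA, -27, 1, 1, "0",        FALSE, "+", 1, "cBP"),
    r("VMA21",    "snv", "A", "T", NA, NA, -27, 1, 1, "0",        FALSE, "+", 1, "cBP", share_prev = TRUE),
    r("VWF",      "snv", "T", "A", NA, NA, -20, 1, 2, "0",        FALSE, "-", 1, "cBP"),
    r("XPC",      "snv", "T", "C", NA, NA, -24, 1, 1, "0",        FALSE, "-", 1, "cBP"),
    r("XPC",      "snv", "A", "T", NA, NA,  -9, NA, NA, "",       TRUE,  "-", 1, "cBP", share_prev = TRUE)
  )
  rows$row_id <- sprintf("%s_%02d", rows$gene, seq_len(nrow(rows)))
  rows
}

#' Expected detection tallies for the embedded validation geometry
#' @return Named list of the tallies the fixture is built to reproduce.
#' @export
validation_expected <- function() {
  list(detected = 40L, not_detected = 8L,
       snv_at_0 = 22L, snv_at_m2 = 11L, snv_at_m1 = 1L,
       full_motif_deletions = 4L, del_at_m2 = 1L, del_at_0 = 1L,
       only_bp = 24L, first_bp = 9L, nonfirst_bp = 7L,
       single_bp_snv_bp_bp2 = 19L,
       consensus = c(`1` = 24L, `2` = 8L, `3` = 7L, `4` = 1L),
       classes = c(mBP = 19L, eBP = 1L, cBP = 20L))
}

#' Build the validation-geometry fixture
#'
#' Synthesizes one locus per variant row of [validation_rows()] on a single
#' contig: a two-exon (or three-exon, for genes with two affected introns)
#' transcript per gene, intronic BP positions planted at the published
#' distances with motifs of the assigned consensus level, rank-filler BP
#' where the published rank demands them, VCF variants whose affected
#' intervals reproduce the published hit offsets (or miss the BP window, for
#' the not-detected rows), and MAF/AC/GERP/PhyloP tracks consistent with the
#' published aggregate annotation counts.
#'
#' @param dir Optional directory; when given, all files (FASTA, GTF, BP
#'   TSVs, VCF, track TSVs, manifest) are written there.
#' @return In-memory bundle: `list(genome, exons, bp_datasets, variants,
#'   tracks, manifest, expected, paths)`.
#' @export
build_validation_fixture <- function(dir = NULL) {
  rows <- validation_rows()
  contig <- "chrT2"
  exon_len <- 50L; intron_len <- 150L; gap <- 100L
  genes <- unique(rows$gene)
  n_intron_units <- sum(!rows$share_prev)
  glen <- n_intron_units * (exon_len + intron_len) + length(genes) * (exon_len + gap) + gap
  chars <- rep("G", glen)

  exons <- list(); bp <- list(); vcf <- list(); manifest <- list()
  track_rows <- list(maf = list(), ac = list(), gerp = list(), phylop = list())
  cur <- gap
  tx_counter <- 0L

  add_bp <- function(pos, strand, class) {
    ds <- switch(class,
                 mBP = list(c("ds_exp", "experimental"), c("ds_comp1", "computational")),
                 eBP = list(c("ds_exp", "experimental")),
                 cBP = list(c("ds_comp1", "computational"), c("ds_comp2", "computational")),
                 cBP1 = list(c("ds_comp1", "computational")))
    lapply(ds, function(d) data.frame(contig = contig, pos = pos, strand = strand,
                                      dataset_id = d[1], evidence_class = d[2],
                                      stringsAsFactors = FALSE))
  }

  for (gene in genes) {
    grows <- rows[rows$gene == gene, , drop = FALSE]
    strand <- grows$strand[1]
    units <- which(!grows$share_prev)
    k <- length(units)
    # exon/intron genomic skeleton: k introns, k+1 exons
    ex_start <- integer(k + 1L); ex_end <- integer(k + 1L)
    in_start <- integer(k); in_end <- integer(k)
    p <- cur
    for (i in seq_len(k + 1L)) {
      ex_start[i] <- p + 1L; ex_end[i] <- p + exon_len; p <- p + exon_len
      if (i <= k) { in_start[i] <- p + 1L; in_end[i] <- p + intron_len; p <- p + intron_len }
    }
    cur <- p + gap
    tx_counter <- tx_counter + 1L
    tx_id <- sprintf("ENST%07d", tx_counter)
    exons[[length(exons) + 1L]] <- data.frame(
      transcript_id = tx_id, gene_symbol = gene, contig = contig,
      strand = strand, start = ex_start, end = ex_end, canonical = TRUE,
      stringsAsFactors = FALSE)

    for (u in seq_len(k)) {
      is <- in_start[u]; ie <- in_end[u]
      # transcript-sense GT..AG terminal dinucleotides
      if (strand == "+") {
        chars[c(is, is + 1L)] <- c("G", "T"); chars[c(ie - 1L, ie)] <- c("A", "G")
      } else {
        chars[c(is, is + 1L)] <- c("C", "T"); chars[c(ie - 1L, ie)] <- c("A", "C")
      }
      urows <- grows[c(units[u], if (u == k && any(grows$share_prev)) which(grows$share_prev)), ,
                     drop = FALSE]
      main <- urows[1, , drop = FALSE]
      bp_dist <- if (main$nd) main$dist - 9L else main$dist
      bp_pos <- pos_at_distance(is, ie, strand, bp_dist)
      motif <- LEVEL_MOTIF[[as.character(main$level)]]
      chars <- plant_seq(chars, bp_pos, strand, -3:1, motif)
      bp <- c(bp, add_bp(bp_pos, strand, main$bp_class))
      # rank fillers (single-source computational)
      if (!main$nd && main$total > 1L) {
        extra_d <- c(if (main$rank > 1L) -(abs(main$dist) - 9L * seq_len(main$rank - 1L)),
                     if (main$total > main$rank) -(abs(main$dist) + 9L * seq_len(main$total - main$rank)))
        for (d in extra_d) {
          ep <- pos_at_distance(is, ie, strand, d)
          chars <- plant_seq(chars, ep, strand, -3:1, LEVEL_MOTIF[["1"]])
          bp <- c(bp, add_bp(ep, strand, "cBP1"))
        }
      }
      # annotation tracks at BP and BP-2 of the main BP
      bp2 <- bp2_position(bp_pos, strand)
      if (!main$nd) {
        if (main$pop == "rare") {
          track_rows$maf[[length(track_rows$maf) + 1L]] <- c(contig, bp_pos, 2e-5)
          track_rows$ac[[length(track_rows$ac) + 1L]] <- c(contig, bp_pos, 3)
        }
        gv <- switch(main$cons, pos = c(2.5, 1.2), neg = c(-1.0, -0.5), mixed = c(1.3, -0.4))
        for (p2 in c(bp_pos, bp2)) {
          track_rows$gerp[[length(track_rows$gerp) + 1L]] <- c(contig, p2, gv[1])
          track_rows$phylop[[length(track_rows$phylop) + 1L]] <- c(contig, p2, gv[2])
        }
      }
      # variants of this intron unit
      for (j in seq_len(nrow(urows))) {
        vr <- urows[j, , drop = FALSE]
        if (vr$vclass == "snv") {
          site <- if (vr$nd) pos_at_distance(is, ie, strand, vr$dist)
                  else {
                    o <- as.integer(vr$hit)
                    if (strand == "+") bp_pos + o else bp_pos - o
                  }
          if (vr$nd) chars[site] <- vr$ref
          if (chars[site] != vr$ref)
            stop("fixture inconsistency: genome ", chars[site], " != REF ", vr$ref,
                 " for ", vr$row_id)
          vcf[[length(vcf) + 1L]] <- data.frame(
            contig = contig, pos = site, id = vr$row_id, ref = vr$ref, alt = vr$alt,
            stringsAsFactors = FALSE)
        } else {
          offs <- vr$del_start + seq_len(vr$del_len) - 1L
          gsite <- if (strand == "+") bp_pos + offs else bp_pos - offs
          astart <- min(gsite); aend <- max(gsite)
          anchor <- astart - 1L
          ref <- paste(chars[anchor:aend], collapse = "")
          vcf[[length(vcf) + 1L]] <- data.frame(
            contig = contig, pos = anchor, id = vr$row_id,
            ref = ref, alt = chars[anchor], stringsAsFactors = FALSE)
        }
        manifest[[length(manifest) + 1L]] <- data.frame(
          row_id = vr$row_id, gene = gene, contig = contig, strand = strand,
          vclass = vr$vclass, nd = vr$nd, dist = vr$dist,
          rank = vr$rank, total = vr$total, hit = vr$hit,
          level = vr$level, bp_class = vr$bp_class, bp_pos = bp_pos,
          stringsAsFactors = FALSE)
      }
    }
  }

  genome <- stats::setNames(paste(chars, collapse = ""), contig)
  exons <- do.call(rbind, exons)
  bp_all <- do.call(rbind, bp)
  bp_datasets <- lapply(split(bp_all, bp_all$dataset_id), function(d) {
    d <- unique(d); rownames(d) <- NULL; d
  })
  variants <- do.call(rbind, vcf)
  manifest <- do.call(rbind, manifest)
  mk_track <- function(kind, rows_l) {
    if (length(rows_l) == 0L) return(position_track(character(), integer(), numeric(), kind))
    m <- do.call(rbind, rows_l)
    position_track(m[, 1], as.integer(m[, 2]), as.numeric(m[, 3]), kind)
  }
  tracks <- list(maf = mk_track("MAF", track_rows$maf),
                 ac = mk_track("AC", track_rows$ac),
                 gerp = mk_track("GERP", track_rows$gerp),
                 phylop = mk_track("PhyloP", track_rows$phylop))
  bundle <- list(genome = genome, exons = exons, bp_datasets = bp_datasets,
                 variants = variants, tracks = tracks, manifest = manifest,
                 expected = validation_expected(),
                 track_rows = lapply(track_rows, function(l)
                   if (length(l)) do.call(rbind, l) else NULL))
  if (!is.null(dir)) bundle$paths <- write_fixture(bundle, dir)
  bundle
}

#' Write a fixture bundle to standard-format files
#'
#' Emits FASTA, GTF (exon features), one BP TSV per dataset, a VCF, the four
#' track TSVs and the manifest TSV.
#'
#' @param bundle A fixture bundle.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  # FASTA
  paths$genome <- file.path(dir, "genome.fa")
  con <- file(paths$genome, "w")
  for (ctg in names(bundle$genome)) {
    writeLines(paste0(">", ctg), con)
    s <- bundle$genome[[ctg]]
    writeLines(substring(s, seq(1, nchar(s), 70), pmin(seq(1, nchar(s), 70) + 69, nchar(s))), con)
  }
  close(con)
  # GTF
  paths$gtf <- file.path(dir, "annotation.gtf")
  ex <- bundle$exons
  writeLines(sprintf(
    "%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tgene_name \"%s\"; transcript_id \"%s\"; tag \"Ensembl_canonical\";",
    ex$contig, ex$start, ex$end, ex$strand, ex$gene_symbol, ex$transcript_id),
    paths$gtf)
  # BP datasets
  paths$bp <- character()
  for (ds in names(bundle$bp_datasets)) {
    p <- file.path(dir, paste0(ds, ".tsv"))
    d <- bundle$bp_datasets[[ds]]
    utils::write.table(d[, c("contig", "pos", "strand", "dataset_id", "evidence_class")],
                       p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths$bp[ds] <- p
  }
  # VCF
  paths$vcf <- file.path(dir, "variants.vcf")
  v <- bundle$variants[order(bundle$variants$contig, bundle$variants$pos), , drop = FALSE]
  con <- file(paths$vcf, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                     v$contig, v$pos, v$id, v$ref, v$alt), con)
  close(con)
  # tracks
  for (kind in c("maf", "ac", "gerp", "phylop")) {
    m <- bundle$track_rows[[kind]]
    p <- file.path(dir, paste0(kind, ".tsv"))
    if (is.null(m)) m <- matrix(character(), ncol = 3)
    utils::write.table(m, p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths[[kind]] <- p
  }
  # manifest
  paths$manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(bundle$manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  paths
}

#' Generate a random detection fixture with a ground-truth manifest
#'
#' Builds a toy genome of multi-intron genes on both strands, plants BP at
#' controlled distances (spaced so motif windows never collide), and plants
#' variants at known transcript offsets around chosen BP, including offsets
#' outside the `[-2, 0]` detection window. Expected hit offsets are recorded
#' in the manifest by construction (planted-offset arithmetic), independent
#' of the detection code.
#'
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param n_genes Number of genes.
#' @param n_variants Number of planted variants.
#' @param p_del,p_ins Probability that a planted variant is a deletion /
#'   insertion (the rest are SNVs).
#' @return Fixture bundle as in [build_validation_fixture()] (without tracks).
#' @export
generate_fixture <- function(seed = 1L, n_genes = 20L, n_variants = 100L,
                             p_del = 0.2, p_ins = 0.1) {
  set.seed(seed)
  contig <- "chrR"
  exon_len <- 50L; intron_len <- 150L; gap <- 60L
  slots <- seq(-6L, -96L, by = -9L)  # candidate BP distances, collision-free
  exons <- list(); bp <- list(); manifest_bp <- list()
  cur <- gap
  chars_len <- n_genes * (2L * exon_len + intron_len + gap) + gap
  chars <- rep("G", chars_len)
  for (gi in seq_len(n_genes)) {
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    ex1 <- c(cur + 1L, cur + exon_len)
    is <- cur + exon_len + 1L; ie <- is + intron_len - 1L
    ex2 <- c(ie + 1L, ie + exon_len)
    cur <- ex2[2] + gap
    tx <- sprintf("RTX%04d", gi)
    exons[[gi]] <- data.frame(transcript_id = tx, gene_symbol = sprintf("RG%04d", gi),
                              contig = contig, strand = strand,
                              start = c(ex1[1], ex2[1]), end = c(ex1[2], ex2[2]),
                              canonical = TRUE, stringsAsFactors = FALSE)
    if (strand == "+") {
      chars[c(is, is + 1L)] <- c("G", "T"); chars[c(ie - 1L, ie)] <- c("A", "G")
    } else {
      chars[c(is, is + 1L)] <- c("C", "T"); chars[c(ie - 1L, ie)] <- c("A", "C")
    }
    nbp <- sample(1:3, 1)
    dists <- sort(sample(slots, nbp))
    for (d in dists) {
      pos <- pos_at_distance(is, ie, strand, d)
      lev <- sample(names(LEVEL_MOTIF), 1)
      chars <- plant_seq(chars, pos, strand, -3:1, LEVEL_MOTIF[[lev]])
      ds <- sample(list(c("rexp", "experimental"), c("rcomp", "computational")),
                   sample(1:2, 1))
      for (dd in ds)
        bp[[length(bp) + 1L]] <- data.frame(contig = contig, pos = pos, strand = strand,
                                            dataset_id = dd[1], evidence_class = dd[2],
                                            stringsAsFactors = FALSE)
      manifest_bp[[length(manifest_bp) + 1L]] <- data.frame(
        contig = contig, pos = pos, strand = strand, dist = d,
        intron_start = is, intron_end = ie, level = as.integer(lev),
        stringsAsFactors = FALSE)
    }
  }
  genome <- stats::setNames(paste(chars, collapse = ""), contig)
  mbp <- do.call(rbind, manifest_bp)
  # plant variants around randomly chosen BP at known transcript offsets
  vcf <- list(); manifest_var <- list()
  g <- genome
  for (vi in seq_len(n_variants)) {
    b <- mbp[sample(nrow(mbp), 1), , drop = FALSE]
    u <- stats::runif(1)
    site_of <- function(o) if (b$strand == "+") b$pos + o else b$pos - o
    if (u < p_del) {
      len <- sample(1:4, 1)
      o1 <- sample(-5:2, 1)  # transcript offset of the first deleted base
      offs <- o1 + seq_len(len) - 1L
      gsite <- vapply(offs, site_of, integer(1))
      astart <- min(gsite); aend <- max(gsite)
      anchor <- astart - 1L
      ref <- substring(g, anchor, aend); alt <- substring(g, anchor, anchor)
      pos <- anchor
      exp_hits <- sort(intersect(offs, -2:0))
      vtype <- "deletion"
    } else if (u < p_del + p_ins) {
      o1 <- sample(-4:2, 1)  # breakpoint between transcript offsets o1 and o1+1
      gpair <- sort(c(site_of(o1), site_of(o1 + 1L)))
      anchor <- gpair[1]
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
                   collapse = "")
      ref <- substring(g, anchor, anchor); alt <- paste0(ref, ins)
      pos <- anchor
      exp_hits <- if (all(c(o1, o1 + 1L) %in% -2:0)) c(o1, o1 + 1L) else integer(0)
      vtype <- "insertion"
    } else {
      o <- sample(-8:4, 1)
      pos <- site_of(o)
      ref <- substring(g, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      exp_hits <- intersect(o, -2:0)
      vtype <- "snv"
    }
    id <- sprintf("rv%04d", vi)
    vcf[[vi]] <- data.frame(contig = contig, pos = pos, id = id, ref = ref, alt = alt,
                            stringsAsFactors = FALSE)
    manifest_var[[vi]] <- data.frame(
      id = id, vtype = vtype, bp_pos = b$pos, bp_strand = b$strand,
      expected_hits = paste(exp_hits, collapse = "|"),
      stringsAsFactors = FALSE)
  }
  list(genome = genome, exons = do.call(rbind, exons),
       bp_datasets = split_bp_datasets(do.call(rbind, bp)),
       variants = do.call(rbind, vcf),
       manifest_bp = mbp, manifest_var = do.call(rbind, manifest_var),
       tracks = NULL)
}

split_bp_datasets <- function(bp_all) {
  lapply(split(bp_all, bp_all$dataset_id), function(d) {
    d <- unique(d); rownames(d) <- NULL; d
  })
}

#' Generate a raw BP dataset with planted off-by-one positions
#'
#' Creates `n` YTNAY-centered BP loci on a toy contig; `n_offby` of them get
#' an additional raw record shifted by one nucleotide. Consensus-guided
#' adjustment moves the shifted records back onto the planted positions, so
#' the dataset shrinks by exactly `n_offby` after deduplication.
#'
#' @param n Number of true BP loci.
#' @param n_offby Number of loci that also carry a shifted duplicate record.
#' @param seed Seed.
#' @return `list(genome, records, expected_delta)`.
#' @export
generate_adjustment_fixture <- function(n = 100L, n_offby = 10L, seed = 1L) {
  set.seed(seed)
  contig <- "adjC"
  spacing <- 12L
  glen <- (n + 2L) * spacing
  chars <- rep("G", glen)
  pos <- spacing * seq_len(n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  for (i in seq_len(n))
    chars <- plant_seq(chars, pos[i], strand[i], -3:1, "TTCAT")
  shifted <- sample(n, n_offby)
  rec <- data.frame(contig = contig,
                    pos = c(pos, pos[shifted] + 1L),
                    strand = c(strand, strand[shifted]),
                    dataset_id = "raw_ds", evidence_class = "experimental",
                    stringsAsFactors = FALSE)
  rec <- rec[sample(nrow(rec)), , drop = FALSE]
  rownames(rec) <- NULL
  list(genome = stats::setNames(paste(chars, collapse = ""), contig),
       records = rec, expected_delta = -n_offby)
}

#' Reverse-complement an entire fixture bundle
#'
#' Mirrors the genome, annotation, BP datasets, variants and tracks of a
#' bundle onto the opposite strand: position `p` maps to `L - p + 1`,
#' strands flip, sequences reverse-complement, and VCF alleles are re-anchored
#' against the mirrored genome. Detection distances, ranks and hit offsets
#' are invariant under this transformation.
#'
#' @param bundle A fixture bundle with a single-contig genome.
#' @return The mirrored bundle.
#' @export
mirror_fixture <- function(bundle) {
  stopifnot(length(bundle$genome) == 1L)
  L <- nchar(bundle$genome[[1]])
  ctg <- names(bundle$genome)
  m <- bundle
  m$genome <- stats::setNames(revcomp(bundle$genome[[1]]), ctg)
  flip <- function(s) ifelse(s == "+", "-", "+")
  ex <- bundle$exons
  new_start <- L - ex$end + 1L
  ex$end <- L - ex$start + 1L
  ex$start <- new_start
  ex$strand <- flip(ex$strand)
  m$exons <- ex
  m$bp_datasets <- lapply(bundle$bp_datasets, function(d) {
    d$pos <- L - d$pos + 1L; d$strand <- flip(d$strand); d
  })
  g2 <- m$genome[[1]]
  v <- bundle$variants
  for (i in seq_len(nrow(v))) {
    cv <- classify_variant(v$ref[i], v$alt[i], v$pos[i])
    if (cv$type_class == "snv") {
      p2 <- L - cv$trimmed_pos + 1L
      v$pos[i] <- p2; v$ref[i] <- comp_base(cv$trimmed_ref); v$alt[i] <- comp_base(cv$trimmed_alt)
    } else if (cv$type_class == "deletion") {
      s2 <- L - cv$affected_end + 1L; e2 <- L - cv$affected_start + 1L
      anchor <- s2 - 1L
      v$pos[i] <- anchor
      v$ref[i] <- substring(g2, anchor, e2)
      v$alt[i] <- substring(g2, anchor, anchor)
    } else {  # insertion between affected_start and affected_end
      anchor <- L - cv$affected_end + 1L  # mirrored breakpoint left base
      v$pos[i] <- anchor
      v$ref[i] <- substring(g2, anchor, anchor)
      v$alt[i] <- paste0(v$ref[i], revcomp(cv$trimmed_alt))
    }
  }
  m$variants <- v
  if (!is.null(bundle$manifest_bp)) {
    mb <- bundle$manifest_bp
    mb$pos <- L - mb$pos + 1L
    new_is <- L - mb$intron_end + 1L
    mb$intron_end <- L - mb$intron_start + 1L
    mb$intron_start <- new_is
    mb$strand <- flip(mb$strand)
    m$manifest_bp <- mb
  }
  if (!is.null(bundle$manifest_var)) {
    mv <- bundle$manifest_var
    mv$bp_pos <- L - mv$bp_pos + 1L
    mv$bp_strand <- flip(mv$bp_strand)
    m$manifest_var <- mv
  }
  m
}
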