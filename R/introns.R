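## Intron extraction, spliceosome typing, BP-to-intron mapping, and a simple
## BP/snRNA duplex pair-scoring model.

intron_key <- function(contig, start, end, strand) {
  sprintf("%s:%d-%d:%s", contig, start, end, strand)
}

#' Extract unique introns from transcript models
#'
#' Introns are the gaps between consecutive exons of a transcript,
#' deduplicated by `(contig, start, end, strand)` across transcripts.
#' Intron numbers count 5' to 3' in transcript orientation (so on the minus
#' strand intron 1 is the genomically last gap). Terminal dinucleotides are
#' read strand-aware from the genome when one is supplied.
#'
#' @param exons Exon table from [load_transcript_models()].
#' @param genome Optional genome for donor/acceptor dinucleotides and
#'   spliceosome typing.
#' @param minor_list Optional character vector of intron keys
#'   (`contig:start-end:strand`) to force-classify as minor.
#' @return `list(introns = data.frame(intron_key, contig, strand, start, end,
#'   length, donor, acceptor, intron_type), memberships = data.frame(
#'   intron_key, transcript_id, gene_symbol, intron_number))`.
#' @export
extract_introns <- function(exons, genome = NULL, minor_list = NULL) {
  mem <- list(); intr <- list()
  for (tx in split(exons, exons$transcript_id)) {
    tx <- tx[order(tx$start), , drop = FALSE]
    if (nrow(tx) > 1L && any(tx$start[-1] <= tx$end[-nrow(tx)]))
      stop("overlapping exons in transcript ", tx$transcript_id[1])
    if (nrow(tx) < 2L) next
    gs <- tx$end[-nrow(tx)] + 1L
    ge <- tx$start[-1] - 1L
    keep <- ge >= gs  # adjacent exons leave no intron
    if (!any(keep)) next
    gs <- gs[keep]; ge <- ge[keep]
    strand <- tx$strand[1]
    n <- length(gs)
    num <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    k <- intron_key(tx$contig[1], gs, ge, strand)
    intr[[length(intr) + 1L]] <- data.frame(
      intron_key = k, contig = tx$contig[1], strand = strand,
      start = gs, end = ge, length = ge - gs + 1L, stringsAsFactors = FALSE)
    mem[[length(mem) + 1L]] <- data.frame(
      intron_key = k, transcript_id = tx$transcript_id[1],
      gene_symbol = tx$gene_symbol[1], intron_number = num,
      stringsAsFactors = FALSE)
  }
  introns <- unique(do.call(rbind, intr))
  memberships <- do.call(rbind, mem)
  if (is.null(introns)) {
    introns <- data.frame(intron_key = character(), contig = character(),
                          strand = character(), start = integer(), end = integer(),
                          length = integer(), stringsAsFactors = FALSE)
    memberships <- data.frame(intron_key = character(), transcript_id = character(),
                              gene_symbol = character(), intron_number = integer(),
                              stringsAsFactors = FALSE)
  }
  rownames(introns) <- NULL
  if (!is.null(genome) && nrow(introns) > 0L) {
    g <- as_genome_strings(genome)
    plus <- introns$strand == "+"
    donor <- acceptor <- character(nrow(introns))
    donor[plus] <- unname(substring(g[introns$contig[plus]], introns$start[plus],
                                    introns$start[plus] + 1L))
    acceptor[plus] <- unname(substring(g[introns$contig[plus]], introns$end[plus] - 1L,
                                       introns$end[plus]))
    if (any(!plus)) {
      donor[!plus] <- revcomp(substring(g[introns$contig[!plus]],
                                        introns$end[!plus] - 1L, introns$end[!plus]))
      acceptor[!plus] <- revcomp(substring(g[introns$contig[!plus]],
                                           introns$start[!plus], introns$start[!plus] + 1L))
    }
    introns$donor <- donor
    introns$acceptor <- acceptor
    introns$intron_type <- classify_intron(donor, acceptor, introns$intron_key, minor_list)
  } else if (nrow(introns) > 0L) {
    introns$donor <- NA_character_
    introns$acceptor <- NA_character_
    introns$intron_type <- "major"
  } else {
    introns$donor <- character(); introns$acceptor <- character()
    introns$intron_type <- character()
  }
  list(introns = introns, memberships = memberships)
}

#' Classify spliceosome type of introns
#'
#' A membership list (e.g. a curated minor-intron catalog) overrides the
#' heuristic; without one, AT-AC terminal dinucleotides classify as minor and
#' everything else as major. The heuristic is conservative: most minor
#' (U12-type) introns are GT-AG and can only be recovered via `minor_list`.
#'
#' @param donor,acceptor Transcript-sense terminal dinucleotides.
#' @param key Intron keys (for the override list).
#' @param minor_list Optional character vector of intron keys that are minor.
#' @return Character vector `"major"`/`"minor"`.
#' @export
classify_intron <- function(donor, acceptor, key = NULL, minor_list = NULL) {
  type <- ifelse(donor == "AT" & acceptor == "AC", "minor", "major")
  if (!is.null(minor_list) && !is.null(key)) type[key %in% minor_list] <- "minor"
  type
}

#' Map branchpoints to 3'-proximal introns
#'
#' A BP maps to an intron when contig and strand match, the BP lies inside
#' the intron, and its distance to the 3' splice site falls in `[-100, -3]`.
#' The distance convention makes the final intron base (the G of the AG
#' acceptor) position -1. Ranks are assigned per intron by ascending
#' `|distance|`: rank 1 is the BP closest to the 3'ss.
#'
#' @param db Merged BP database from [merge_datasets()].
#' @param introns_obj Output of [extract_introns()].
#' @param genome Optional genome to attach the `[-9, +3]` motif and the
#'   consensus level.
#' @param window Distance window kept, default `c(-100L, -3L)`.
#' @return `data.frame`, one row per (BP, intron) association: all BP columns
#'   plus `intron_key`, `distance`, `rank`, `total`, `motif`,
#'   `consensus_level`, `intron_type`, `intron_length`.
#' @export
map_bp_to_introns <- function(db, introns_obj, genome = NULL,
                              window = c(-100L, -3L)) {
  introns <- introns_obj$introns
  empty <- function() {
    out <- db[0, , drop = FALSE]
    out$intron_key <- character(); out$distance <- integer()
    out$rank <- integer(); out$total <- integer()
    out$motif <- character(); out$intron_type <- character()
    out$intron_length <- integer()
    out
  }
  if (nrow(db) == 0L || nrow(introns) == 0L) return(empty())
  lev <- union(unique(db$contig), unique(introns$contig))
  bp_gr <- GenomicRanges::GRanges(factor(db$contig, levels = lev),
                                  IRanges::IRanges(db$pos, db$pos),
                                  strand = db$strand)
  in_gr <- GenomicRanges::GRanges(factor(introns$contig, levels = lev),
                                  IRanges::IRanges(introns$start, introns$end),
                                  strand = introns$strand)
  ov <- GenomicRanges::findOverlaps(bp_gr, in_gr, type = "within", ignore.strand = FALSE)
  bi <- S4Vectors::queryHits(ov); ii <- S4Vectors::subjectHits(ov)
  if (length(bi) == 0L) return(empty())
  dist <- ifelse(introns$strand[ii] == "+",
                 db$pos[bi] - introns$end[ii] - 1L,
                 introns$start[ii] - db$pos[bi] - 1L)
  keep <- dist >= window[1] & dist <= window[2]
  bi <- bi[keep]; ii <- ii[keep]; dist <- as.integer(dist[keep])
  if (length(bi) == 0L) return(empty())
  mapped <- db[bi, , drop = FALSE]
  mapped$intron_key <- introns$intron_key[ii]
  mapped$distance <- dist
  mapped$intron_type <- introns$intron_type[ii]
  mapped$intron_length <- introns$length[ii]
  # rank per intron by proximity to the 3'ss; ties cannot occur on one strand
  for (k in unique(mapped$intron_key)) {
    sel <- mapped$intron_key == k
    d <- abs(mapped$distance[sel])
    if (anyDuplicated(d)) stop("two BP equidistant from the 3'ss in ", k)
    mapped$rank[sel] <- rank(d)
    mapped$total[sel] <- sum(sel)
  }
  mapped$rank <- as.integer(mapped$rank)
  mapped$total <- as.integer(mapped$total)
  if (!is.null(genome)) {
    g <- as_genome_strings(genome)
    mapped$motif <- motif_at_safe(g, mapped$contig, mapped$pos, mapped$strand, c(-9L, 3L))
    m5 <- motif_at_safe(g, mapped$contig, mapped$pos, mapped$strand, c(-3L, 1L))
    mapped$consensus_level <- ifelse(is.na(m5), NA_integer_,
                                     consensus_level(ifelse(is.na(m5), "NNNNN", m5)))
  } else {
    mapped$motif <- NA_character_
    if (!"consensus_level" %in% names(mapped)) mapped$consensus_level <- NA_integer_
  }
  mapped <- mapped[order(mapped$contig, mapped$pos, mapped$intron_key), , drop = FALSE]
  rownames(mapped) <- NULL
  mapped
}

#' Distance and per-intron-count distributions of mapped branchpoints
#'
#' @param mapped Output of [map_bp_to_introns()].
#' @param window Distance window, for rendering empty bins as 0.
#' @return `list(distance = named integer vector over every distance in the
#'   window, per_intron = named integer vector: how many introns carry k BP)`.
#' @export
intron_bp_distribution <- function(mapped, window = c(-100L, -3L)) {
  if (nrow(mapped) == 0L) stop("no mapped BP")
  dists <- seq(window[2], window[1])
  dcount <- table(factor(mapped$distance, levels = dists))
  percount <- table(table(mapped$intron_key))
  list(distance = stats::setNames(as.integer(dcount), names(dcount)),
       per_intron = stats::setNames(as.integer(percount), names(percount)))
}

#' Pair-scoring estimate of BP motif / snRNA binding energy
#'
#' A deliberately simple duplex model: the BP base (offset 0 of the 7-mer
#' covering `[-5, +1]`) bulges out, and the remaining six bases are paired
#' antiparallel against the snRNA branch-recognition hexamer. Each Watson-
#' Crick or wobble pair contributes (GC = 3, AU = 2, GU = 1), mismatches 0,
#' and the energy is the negated sum, so lower = stronger binding. The U2
#' hexamer is GUAGUA; the U12 default, GUAAGG, is derived as the antiparallel
#' complement of the minor-spliceosome branch consensus UCCUUAAC with the BP
#' adenosine bulged out, and can be overridden via `snrna_seq`.
#'
#' @param motif7 7-mer over transcript offsets `[-5, +1]` (DNA or RNA
#'   alphabet).
#' @param snrna `"U2"` or `"U12"`.
#' @param snrna_seq Optional explicit hexamer (RNA alphabet, 5'->3')
#'   replacing the built-in default.
#' @return `list(energy = numeric, snrna = character, pairs = character)`.
#' @export
binding_energy <- function(motif7, snrna = c("U2", "U12"), snrna_seq = NULL) {
  snrna <- match.arg(snrna)
  if (nchar(motif7) != 7L) stop("binding_energy expects a 7-mer over [-5, +1]")
  hex <- if (!is.null(snrna_seq)) snrna_seq else
    switch(snrna, U2 = "GUAGUA", U12 = "GUAAGG")
  if (nchar(hex) != 6L) stop("snRNA branch-recognition sequence must be a hexamer")
  m <- strsplit(chartr("Tt", "Uu", toupper(motif7)), "")[[1]]
  m <- m[-6]  # bulge out the BP base (offset 0)
  h <- strsplit(toupper(hex), "")[[1]]
  score_pair <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) 3 else if (p %in% c("AU", "UA")) 2 else
      if (p %in% c("GU", "UG")) 1 else 0
  }
  # antiparallel: motif position i pairs snRNA position 7 - i
  s <- vapply(seq_len(6), function(i) score_pair(m[i], h[7L - i]), numeric(1))
  list(energy = -sum(s), snrna = snrna,
       pairs = paste(sprintf("%s:%s", m, rev(h)), collapse = ","))
}
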