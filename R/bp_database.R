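## Branchpoint database assembly: strand-aware motif extraction, consensus
## leveling, consensus-guided positional adjustment, and dataset merging.

IUPAC_Y <- c("C", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

as_genome_strings <- function(genome) {
  if (is.character(genome)) return(genome)
  stats::setNames(as.character(genome), names(genome))
}

#' Extract a motif around a branchpoint, in transcript orientation
#'
#' Offsets are transcript-sense: offset 0 is the BP base, negative offsets are
#' upstream (toward the 5' end of the intron), positive offsets downstream
#' (toward the 3' splice site). On the minus strand the genomic segment is
#' reverse-complemented so that the returned string always reads 5'->3' in
#' the transcript.
#'
#' @param genome `DNAStringSet` (or named character vector of contigs).
#' @param contig,pos,strand Vectors describing BP positions (1-based).
#' @param window Length-2 integer vector `c(a, b)` of offsets, `a <= b`.
#' @return Character vector of motifs of length `b - a + 1`.
#' @export
motif_at <- function(genome, contig, pos, strand, window = c(-9L, 3L)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  g <- as_genome_strings(genome)
  n <- max(length(contig), length(pos), length(strand))
  contig <- rep_len(contig, n); pos <- rep_len(pos, n); strand <- rep_len(strand, n)
  if (!all(strand %in% c("+", "-"))) stop("strand must be + or -")
  if (!all(contig %in% names(g))) stop("contig not in genome: ",
                                       paste(unique(contig[!contig %in% names(g)]), collapse = ","))
  len <- nchar(g)[contig]
  s <- ifelse(strand == "+", pos + window[1], pos - window[2])
  e <- ifelse(strand == "+", pos + window[2], pos - window[1])
  if (any(s < 1L | e > len))
    stop("motif window out of contig bounds at ",
         paste(contig[s < 1L | e > len], pos[s < 1L | e > len], collapse = "; "))
  m <- unname(substring(g[contig], s, e))
  neg <- strand == "-"
  if (any(neg)) m[neg] <- revcomp(m[neg])
  m
}

# like motif_at but returns NA (never errors) when the window leaves the contig
motif_at_safe <- function(g, contig, pos, strand, window) {
  len <- nchar(g)[contig]
  s <- ifelse(strand == "+", pos + window[1], pos - window[2])
  e <- ifelse(strand == "+", pos + window[2], pos - window[1])
  ok <- s >= 1L & e <= len & !is.na(len)
  m <- rep(NA_character_, length(pos))
  m[ok] <- unname(substring(g[contig[ok]], s[ok], e[ok]))
  neg <- ok & strand == "-"
  if (any(neg)) m[neg] <- revcomp(m[neg])
  m
}

#' Consensus level of a 5-mer branchpoint motif
#'
#' The 5-mer covers transcript offsets `[-3, +1]` around the BP (offset 0 is
#' position 4 of the string). Matching is nested and the most stringent level
#' is reported: 1 = YTNAY, 2 = YTNA, 3 = TNA, 4 = YNA, 0 = none
#' (Y = C/T, N = any base). Any `N` base in the input yields level 0.
#'
#' @param motif5 Character vector of 5-mers.
#' @return Integer vector of levels in `{0, 1, 2, 3, 4}`.
#' @export
consensus_level <- function(motif5) {
  if (any(nchar(motif5) != 5L)) stop("consensus_level expects 5-mers")
  c1 <- substring(motif5, 1, 1); c2 <- substring(motif5, 2, 2)
  c4 <- substring(motif5, 4, 4); c5 <- substring(motif5, 5, 5)
  has_n <- grepl("N", motif5, fixed = TRUE)
  l1 <- c1 %in% IUPAC_Y & c2 == "T" & c4 == "A" & c5 %in% IUPAC_Y
  l2 <- c1 %in% IUPAC_Y & c2 == "T" & c4 == "A"
  l3 <- c2 == "T" & c4 == "A"
  l4 <- c2 %in% IUPAC_Y & c4 == "A"
  lev <- ifelse(l1, 1L, ifelse(l2, 2L, ifelse(l3, 3L, ifelse(l4, 4L, 0L))))
  lev[has_n] <- 0L
  as.integer(lev)
}

is_ytnay <- function(motif5) {
  m <- ifelse(is.na(motif5) | nchar(motif5) != 5L, "NNNNN", motif5)
  consensus_level(m) == 1L
}

#' Consensus-guided positional adjustment of raw branchpoint positions
#'
#' Each raw BP position is screened over a `[-2, +2]` transcript-sense window;
#' the position is moved to the closest candidate whose centered 5-mer
#' (offsets `[-3, +1]`) perfectly matches YTNAY. A position already centered
#' on YTNAY is a fixed point. When YTNAY matches at both `-d` and `+d`, the
#' transcript-downstream candidate (closer to the 3' splice site) wins. If no
#' candidate matches, the position is returned unchanged.
#'
#' @param genome Genome (`DNAStringSet` or named character).
#' @param contig,pos,strand Vectors of raw BP positions.
#' @param window Maximum shift, in nt (default 2).
#' @return Integer vector of adjusted genomic positions.
#' @export
adjust_bp_position <- function(genome, contig, pos, strand, window = 2L) {
  g <- as_genome_strings(genome)
  n <- max(length(contig), length(pos), length(strand))
  contig <- rep_len(contig, n); pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  offsets <- unlist(lapply(0:window, function(k) if (k == 0L) 0L else c(k, -k)))
  adjusted <- pos
  undecided <- rep(TRUE, n)
  for (d in offsets) {
    if (!any(undecided)) break
    idx <- which(undecided)
    cand <- ifelse(strand[idx] == "+", pos[idx] + d, pos[idx] - d)
    m5 <- motif_at_safe(g, contig[idx], cand, strand[idx], c(-3L, 1L))
    hit <- !is.na(m5) & is_ytnay(m5)
    adjusted[idx[hit]] <- cand[hit]
    undecided[idx[hit]] <- FALSE
  }
  adjusted
}

#' Adjust a whole branchpoint dataset and report the effect
#'
#' Applies [adjust_bp_position()] to every record, collapses records that now
#' share `(contig, pos, strand)`, and reports the size delta and base
#' composition before/after. Adjustment only merges records, never creates
#' them, so the delta is always `<= 0`.
#'
#' @param genome Genome.
#' @param records BP record `data.frame` (one `dataset_id`).
#' @return `list(records = adjusted data.frame with bp_base, report = one-row
#'   data.frame)`.
#' @export
adjust_dataset <- function(genome, records) {
  if (length(unique(records$dataset_id)) != 1L)
    stop("adjust_dataset expects records from a single dataset")
  g <- as_genome_strings(genome)
  base_before <- motif_at(g, records$contig, records$pos, records$strand, c(0L, 0L))
  newpos <- adjust_bp_position(g, records$contig, records$pos, records$strand)
  n_moved <- sum(newpos != records$pos)
  adj <- records
  adj$pos <- newpos
  adj$bp_base <- motif_at(g, adj$contig, adj$pos, adj$strand, c(0L, 0L))
  dup <- duplicated(adj[, c("contig", "pos", "strand")])
  adj <- adj[!dup, , drop = FALSE]
  rownames(adj) <- NULL
  report <- data.frame(
    dataset_id = records$dataset_id[1],
    n_raw = nrow(records),
    n_moved = n_moved,
    n_after_dedup = nrow(adj),
    delta = nrow(adj) - nrow(records),
    stringsAsFactors = FALSE
  )
  comp_b <- composition_summary(base_before)
  comp_a <- composition_summary(adj$bp_base)
  for (b in c("A", "C", "G", "T")) {
    report[[paste0("pct_", b, "_before")]] <- comp_b[[b]]
    report[[paste0("pct_", b, "_after")]] <- comp_a[[b]]
  }
  list(records = adj, report = report)
}

#' Merge adjusted branchpoint datasets into a unified database
#'
#' One merged record per unique `(contig, pos, strand)`. Sources are the
#' sorted unique dataset ids; the class is `mBP` when both an experimental
#' and a computational source support the position, otherwise `eBP` or `cBP`.
#' Names follow the grammar `{m|e|c}BP_{contig}_{pos}_{strand}_{base}`.
#'
#' @param datasets List of adjusted record data.frames (each with
#'   `dataset_id` and `evidence_class`; `bp_base` is recomputed from `genome`
#'   when supplied).
#' @param genome Optional genome used to (re)compute `bp_base` and the
#'   consensus level of the centered 5-mer.
#' @return `data.frame`: `bp_name`, `contig`, `pos`, `strand`, `bp_base`,
#'   `bp_class`, `n_sources`, `sources`, `consensus_level`.
#' @export
merge_datasets <- function(datasets, genome = NULL) {
  all <- do.call(rbind, lapply(datasets, function(d)
    d[, intersect(c("contig", "pos", "strand", "dataset_id", "evidence_class", "bp_base"),
                  names(d)), drop = FALSE]))
  key <- paste(all$contig, all$pos, all$strand, sep = "\r")
  grp <- split(seq_len(nrow(all)), key)
  rows <- lapply(grp, function(ix) {
    src <- sort(unique(all$dataset_id[ix]))
    cls <- unique(all$evidence_class[ix])
    bp_class <- if (all(c("experimental", "computational") %in% cls)) "mBP"
                else if (identical(cls, "experimental")) "eBP" else "cBP"
    data.frame(contig = all$contig[ix[1]], pos = all$pos[ix[1]],
               strand = all$strand[ix[1]],
               bp_base = if ("bp_base" %in% names(all)) all$bp_base[ix[1]] else NA_character_,
               bp_class = bp_class,
               n_sources = length(src),
               sources = paste(src, collapse = ","),
               stringsAsFactors = FALSE)
  })
  db <- do.call(rbind, rows)
  db <- db[order(db$contig, db$pos, db$strand), , drop = FALSE]
  rownames(db) <- NULL
  if (!is.null(genome)) {
    g <- as_genome_strings(genome)
    db$bp_base <- motif_at(g, db$contig, db$pos, db$strand, c(0L, 0L))
    m5 <- motif_at_safe(g, db$contig, db$pos, db$strand, c(-3L, 1L))
    db$consensus_level <- ifelse(is.na(m5), NA_integer_, consensus_level(
      ifelse(is.na(m5), "NNNNN", m5)))
  } else {
    db$consensus_level <- NA_integer_
  }
  db$bp_name <- paste(db$bp_class, db$contig, db$pos, db$strand, db$bp_base, sep = "_")
  db[, c("bp_name", "contig", "pos", "strand", "bp_base", "bp_class",
         "n_sources", "sources", "consensus_level")]
}

#' Base composition of branchpoint nucleotides
#'
#' @param x Either a character vector of bases or a record `data.frame` with a
#'   `bp_base` column.
#' @return Named numeric vector of percentages for A, C, G, T (summing to 100
#'   up to rounding of non-ACGT content).
#' @export
composition_summary <- function(x) {
  bases <- if (is.data.frame(x)) x$bp_base else x
  if (length(bases) == 0L) stop("composition_summary: empty input")
  tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
  stats::setNames(100 * as.vector(tab) / length(bases), c("A", "C", "G", "T"))
}

#' Build the integrated branchpoint database from raw datasets
#'
#' Convenience pipeline: per-dataset consensus-guided adjustment, then merge.
#'
#' @param genome Genome.
#' @param datasets List of raw BP record data.frames (one dataset each).
#' @param adjust Apply positional adjustment first (default `TRUE`).
#' @return `list(db = merged database, reports = adjustment report rows)`.
#' @export
build_bp_database <- function(genome, datasets, adjust = TRUE) {
  if (adjust) {
    adj <- lapply(datasets, function(d) adjust_dataset(genome, d))
    reports <- do.call(rbind, lapply(adj, `[[`, "report"))
    recs <- lapply(adj, `[[`, "records")
  } else {
    reports <- NULL
    recs <- datasets
  }
  list(db = merge_datasets(recs, genome = genome), reports = reports)
}
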