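## Core detection engine: variant typing, BP hit-offset computation in
## transcript orientation, and assembly of the annotated detection table.

#' Trim shared prefix and suffix bases from a REF/ALT allele pair
#'
#' The shared prefix is removed first (advancing the position, which keeps
#' VCF-style anchored indels on their anchored interval), then the shared
#' suffix; either allele may end up empty. Trimming is idempotent.
#'
#' @param ref,alt Allele strings.
#' @param pos 1-based position of the first REF base.
#' @return `list(pos, ref, alt)` after trimming.
#' @export
trim_alleles <- function(ref, alt, pos) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 0L && length(a) > 0L && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  while (length(r) > 0L && length(a) > 0L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Type a variant and compute its affected genomic interval
#'
#' After prefix/suffix trimming: equal-length single bases are SNVs;
#' an empty trimmed ALT is an `x nt-deletion` whose affected interval is the
#' deleted bases; an empty trimmed REF is an `x nt-insertion` whose affected
#' interval is the two bases flanking the insertion breakpoint. Complex
#' substitutions (both sides multi-base after trimming) are typed as a
#' deletion of the REF side and flagged.
#'
#' @param ref,alt Alleles as written in the VCF (shared anchors allowed).
#' @param pos 1-based POS of the first REF base.
#' @return `list(var_type, type_class, net_len, affected_start, affected_end,
#'   trimmed_pos, trimmed_ref, trimmed_alt, complex)`.
#' @export
classify_variant <- function(ref, alt, pos) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (identical(ref, alt)) stop("REF and ALT are identical at pos ", pos)
  tr <- trim_alleles(ref, alt, pos)
  nr <- nchar(tr$ref); na <- nchar(tr$alt)
  complex <- FALSE
  if (nr == 1L && na == 1L) {
    var_type <- "snv"; type_class <- "snv"; net <- 0L
    astart <- tr$pos; aend <- tr$pos
  } else if (na == 0L) {
    var_type <- sprintf("%d nt-deletion", nr); type_class <- "deletion"; net <- -nr
    astart <- tr$pos; aend <- tr$pos + nr - 1L
  } else if (nr == 0L) {
    var_type <- sprintf("%d nt-insertion", na); type_class <- "insertion"; net <- na
    astart <- tr$pos - 1L; aend <- tr$pos  # breakpoint between these two bases
  } else {
    # complex substitution: treat the REF side as deleted, flag it
    complex <- TRUE
    var_type <- sprintf("%d nt-deletion", nr); type_class <- "deletion"; net <- na - nr
    astart <- tr$pos; aend <- tr$pos + nr - 1L
  }
  list(var_type = var_type, type_class = type_class, net_len = as.integer(net),
       affected_start = as.integer(astart), affected_end = as.integer(aend),
       trimmed_pos = tr$pos, trimmed_ref = tr$ref, trimmed_alt = tr$alt,
       complex = complex)
}

#' Offsets of a branchpoint's [-2, 0] window hit by a variant
#'
#' Offsets are transcript-sense: for a genomic site `s` and BP `b`, the
#' offset is `s - b` on the plus strand and `b - s` on the minus strand.
#' SNVs hit the single offset they fall on; deletions hit every offset whose
#' genomic base they remove; insertions hit the pair of flanking offsets only
#' when the breakpoint falls strictly between BP-2 and BP (these hits are
#' flagged low-confidence via the `low_confidence` attribute).
#'
#' @param variant One-row variant record (as from [load_variants()]).
#' @param bp_pos,bp_strand BP genomic position and strand.
#' @return Integer vector, a subset of `c(-2L, -1L, 0L)` (empty = no hit),
#'   with attribute `low_confidence`.
#' @export
hit_offsets <- function(variant, bp_pos, bp_strand) {
  site_of <- function(o) if (bp_strand == "+") bp_pos + o else bp_pos - o
  offset_of <- function(s) if (bp_strand == "+") s - bp_pos else bp_pos - s
  lc <- FALSE
  if (variant$type_class == "snv") {
    o <- offset_of(variant$affected_start)
    hits <- if (o >= -2L && o <= 0L) o else integer(0)
  } else if (variant$type_class == "deletion") {
    cand <- c(-2L, -1L, 0L)
    sites <- vapply(cand, site_of, integer(1))
    hits <- cand[sites >= variant$affected_start & sites <= variant$affected_end]
  } else {  # insertion: affected interval is the two breakpoint-flanking bases
    o1 <- offset_of(variant$affected_start)
    o2 <- offset_of(variant$affected_end)
    both <- sort(c(o1, o2))
    if (all(both %in% c(-2L, -1L, 0L))) { hits <- both; lc <- TRUE }
    else hits <- integer(0)
  }
  structure(sort(as.integer(hits)), low_confidence = lc)
}

render_hits <- function(hits) paste(hits, collapse = "|")

#' Detect variants that disrupt the [-2, 0] region of mapped branchpoints
#'
#' The central operation: every variant is tested against every BP window on
#' its contig, and each (variant, BP, intron-membership) combination with a
#' nonempty hit-offset set yields one annotated output row carrying the full
#' set of reporting fields plus the prioritization score.
#'
#' @param variants Variant records from [load_variants()].
#' @param mapped Mapped BP from [map_bp_to_introns()].
#' @param memberships Intron memberships from [extract_introns()].
#' @param tracks Optional named list of annotation tracks (`maf`, `ac`,
#'   `gerp`, `phylop`).
#' @param min_score Optional score threshold; rows below it are dropped.
#' @param weights Scoring weights, see [score_weights()].
#' @return `data.frame`, one row per hit, sorted by
#'   `(contig, pos, bp_name, transcript)`.
#' @export
detect <- function(variants, mapped, memberships, tracks = NULL,
                   min_score = NULL, weights = score_weights()) {
  out <- list()
  known_contigs <- unique(mapped$contig)
  skipped <- unique(variants$contig[!variants$contig %in% known_contigs])
  if (length(skipped) > 0L)
    warning("variant contig(s) absent from BP database, skipped: ",
            paste(skipped, collapse = ","))
  if (nrow(variants) > 0L && nrow(mapped) > 0L) {
    # candidate pairing via interval overlap of the BP [-2, 0] genomic window
    win_lo <- ifelse(mapped$strand == "+", mapped$pos - 2L, mapped$pos)
    win_hi <- win_lo + 2L
    lev <- union(unique(variants$contig), known_contigs)
    v_gr <- GenomicRanges::GRanges(factor(variants$contig, levels = lev),
                                   IRanges::IRanges(variants$affected_start,
                                                    variants$affected_end))
    w_gr <- GenomicRanges::GRanges(factor(mapped$contig, levels = lev),
                                   IRanges::IRanges(win_lo, win_hi))
    ov <- GenomicRanges::findOverlaps(v_gr, w_gr)
    vi <- S4Vectors::queryHits(ov); mi <- S4Vectors::subjectHits(ov)
    for (k in seq_along(vi)) {
      v <- variants[vi[k], , drop = FALSE]
      b <- mapped[mi[k], , drop = FALSE]
      hits <- hit_offsets(v, b$pos, b$strand)
      if (length(hits) == 0L) next
      lc <- attr(hits, "low_confidence")
      full_motif <- v$type_class == "deletion" && all(c(-2L, -1L, 0L) %in% hits)
      ann <- annotate_position(tracks, b$contig, b$pos, b$strand)
      snv_change <- NA_character_
      if (v$type_class == "snv") {
        tr_ref <- if (b$strand == "+") v$trimmed_ref else revcomp(v$trimmed_ref)
        tr_alt <- if (b$strand == "+") v$trimmed_alt else revcomp(v$trimmed_alt)
        snv_change <- paste0(tr_ref, ">", tr_alt)
      }
      sc <- bp_score(hits = as.integer(hits), full_motif = full_motif,
                     rank = b$rank, total = b$total,
                     consensus_level = b$consensus_level,
                     n_sources = b$n_sources, bp_class = b$bp_class,
                     annotation = ann, snv_change = snv_change,
                     weights = weights)
      mem <- memberships[memberships$intron_key == b$intron_key, , drop = FALSE]
      if (nrow(mem) == 0L)
        mem <- data.frame(intron_key = b$intron_key, transcript_id = ".",
                          gene_symbol = ".", intron_number = NA_integer_,
                          stringsAsFactors = FALSE)
      for (j in seq_len(nrow(mem))) {
        out[[length(out) + 1L]] <- data.frame(
          contig = v$contig, pos = v$pos, id = v$id, ref = v$ref, alt = v$alt,
          variant_key = v$variant_key, var_type = v$var_type,
          gene_symbol = mem$gene_symbol[j],
          transcript = sprintf("%s_IVS%d", mem$transcript_id[j], mem$intron_number[j]),
          bp_name = b$bp_name, bp_class = b$bp_class,
          bp_pos = b$pos, bp_strand = b$strand,
          rank = b$rank, total = b$total,
          bp_rank = sprintf("#%d/%d", b$rank, b$total),
          hit_positions = render_hits(hits),
          full_motif = full_motif,
          distance_to_3ss = b$distance,
          consensus_level = b$consensus_level,
          n_sources = b$n_sources, sources = b$sources,
          maf_bp = ann$maf_bp, maf_bp2 = ann$maf_bp2,
          gerp_bp = ann$gerp_bp, gerp_bp2 = ann$gerp_bp2,
          phylop_bp = ann$phylop_bp, phylop_bp2 = ann$phylop_bp2,
          intron_type = b$intron_type, intron_length = b$intron_length,
          low_confidence = lc, score = sc$total,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else empty_detections()
  if (!is.null(min_score)) res <- res[res$score >= min_score, , drop = FALSE]
  res <- res[order(res$contig, res$pos, res$bp_name, res$transcript), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_detections <- function() {
  data.frame(contig = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), variant_key = character(),
             var_type = character(), gene_symbol = character(),
             transcript = character(), bp_name = character(),
             bp_class = character(), bp_pos = integer(), bp_strand = character(),
             rank = integer(), total = integer(), bp_rank = character(),
             hit_positions = character(), full_motif = logical(),
             distance_to_3ss = integer(), consensus_level = integer(),
             n_sources = integer(), sources = character(),
             maf_bp = numeric(), maf_bp2 = numeric(), gerp_bp = numeric(),
             gerp_bp2 = numeric(), phylop_bp = numeric(), phylop_bp2 = numeric(),
             intron_type = character(), intron_length = integer(),
             low_confidence = logical(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Variants that produced no detection row
#' @param variants Variant records.
#' @param detections Output of [detect()].
#' @return Subset of `variants`, for the side "not detected" report.
#' @export
undetected_variants <- function(variants, detections) {
  variants[!variants$variant_key %in% detections$variant_key, , drop = FALSE]
}

#' Tally detections by hit category, rank category, consensus level and class
#'
#' Each detected variant is counted once under its best hit: the BP of lowest
#' rank (ties broken by `|distance|` then name). Deletions covering the whole
#' `[-2, 0]` window count as full-motif deletions; other variants are tallied
#' at their hit offset closest to the BP.
#'
#' @param detections Output of [detect()].
#' @return `list(n_variants, by_hit, by_rank, by_consensus, by_class)`.
#' @export
tally_detections <- function(detections) {
  by_hit <- c("full-motif-deletion" = 0L, "deletion@0" = 0L, "deletion@-1" = 0L,
              "deletion@-2" = 0L, "snv@0" = 0L, "snv@-1" = 0L, "snv@-2" = 0L,
              "insertion" = 0L)
  by_rank <- c(only = 0L, first = 0L, nonfirst = 0L)
  by_consensus <- stats::setNames(integer(5), as.character(c(1:4, 0)))
  by_class <- c(mBP = 0L, eBP = 0L, cBP = 0L)
  if (nrow(detections) > 0L) {
    for (vk in unique(detections$variant_key)) {
      rows <- detections[detections$variant_key == vk, , drop = FALSE]
      rows <- rows[order(rows$rank, abs(rows$distance_to_3ss), rows$bp_name), , drop = FALSE]
      r <- rows[1, , drop = FALSE]
      hits <- as.integer(strsplit(r$hit_positions, "|", fixed = TRUE)[[1]])
      cat_name <- if (grepl("insertion", r$var_type)) "insertion"
        else if (r$full_motif) "full-motif-deletion"
        else {
          best <- if (0L %in% hits) 0L else if (-2L %in% hits) -2L else -1L
          kind <- if (r$var_type == "snv") "snv" else "deletion"
          sprintf("%s@%d", kind, best)
        }
      by_hit[cat_name] <- by_hit[cat_name] + 1L
      rk <- if (r$total == 1L) "only" else if (r$rank == 1L) "first" else "nonfirst"
      by_rank[rk] <- by_rank[rk] + 1L
      cl <- as.character(r$consensus_level)
      by_consensus[cl] <- by_consensus[cl] + 1L
      by_class[r$bp_class] <- by_class[r$bp_class] + 1L
    }
  }
  list(n_variants = length(unique(detections$variant_key)),
       by_hit = by_hit, by_rank = by_rank,
       by_consensus = by_consensus, by_class = by_class)
}
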