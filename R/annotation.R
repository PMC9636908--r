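## Population-frequency and conservation context for branchpoint positions.

#' Genomic position of BP-2, strand-aware
#'
#' BP-2 is two nucleotides upstream of the BP in transcript sense: `pos - 2`
#' on the plus strand, `pos + 2` on the minus strand.
#' @param pos,strand BP genomic position(s) and strand(s).
#' @export
bp2_position <- function(pos, strand) ifelse(strand == "+", pos - 2L, pos + 2L)

#' Annotate a branchpoint position with track context
#'
#' Looks up MAF, allele count, GERP and PhyloP at the BP and BP-2 genomic
#' positions. Any subset of tracks may be supplied; missing tracks or
#' positions yield `NA` (rendered "." on output). The MAF class follows the
#' population convention: singleton (AC = 1), rare (MAF < 1%), common
#' (MAF >= 1%), or none when no variant overlaps the BP position.
#'
#' @param tracks Named list with any of `maf`, `ac`, `gerp`, `phylop`
#'   ([position_track()] objects), or `NULL`.
#' @param contig Contig name.
#' @param pos BP genomic position.
#' @param strand BP strand (used to locate BP-2).
#' @return One-row `data.frame`: `maf_bp`, `maf_bp2`, `ac_bp`, `gerp_bp`,
#'   `gerp_bp2`, `phylop_bp`, `phylop_bp2`, `maf_class`.
#' @export
annotate_position <- function(tracks, contig, pos, strand) {
  p2 <- bp2_position(pos, strand)
  lk <- function(kind, p) {
    t <- if (is.null(tracks)) NULL else tracks[[kind]]
    track_lookup(t, contig, p)
  }
  maf_bp <- lk("maf", pos); maf_bp2 <- lk("maf", p2)
  ac_bp <- lk("ac", pos)
  cls <- maf_classify(maf_bp, ac_bp)
  data.frame(maf_bp = maf_bp, maf_bp2 = maf_bp2, ac_bp = ac_bp,
             gerp_bp = lk("gerp", pos), gerp_bp2 = lk("gerp", p2),
             phylop_bp = lk("phylop", pos), phylop_bp2 = lk("phylop", p2),
             maf_class = cls, stringsAsFactors = FALSE)
}

#' Classify population allele frequency at a position
#' @param maf MAF value(s), `NA` when no variant is present.
#' @param ac Optional total allele count(s); AC = 1 marks a singleton.
#' @return `"singleton"`, `"rare"`, `"common"` or `"none"`.
#' @export
maf_classify <- function(maf, ac = NA_real_) {
  n <- max(length(maf), length(ac))
  maf <- rep_len(maf, n); ac <- rep_len(ac, n)
  out <- rep("none", n)
  has <- !is.na(maf)
  out[has & maf >= 0.01] <- "common"
  out[has & maf < 0.01] <- "rare"
  out[has & !is.na(ac) & ac == 1] <- "singleton"
  out
}

#' Fraction of a position set carrying population variants
#'
#' @param positions `data.frame` with `contig` and `pos` (and optionally
#'   `strand`, unused here).
#' @param maf_track MAF [position_track()] (may be `NULL`-free but empty).
#' @param ac_track Optional AC track for singleton calls.
#' @return `list(fraction = covered / total, counts = table over maf_class of
#'   the covered positions)`.
#' @export
summarize_occupancy <- function(positions, maf_track, ac_track = NULL) {
  if (nrow(positions) == 0L) stop("empty position set")
  maf <- track_lookup(maf_track, positions$contig, positions$pos)
  ac <- track_lookup(ac_track, positions$contig, positions$pos)
  cls <- maf_classify(maf, ac)
  covered <- cls != "none"
  list(fraction = sum(covered) / nrow(positions),
       counts = table(factor(cls[covered], levels = c("singleton", "rare", "common"))))
}
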