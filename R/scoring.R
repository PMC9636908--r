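## Prioritization score (0-10) and the seven strategy flags.

#' Default scoring weights
#'
#' An additive scheme over six reward terms and one penalty, clamped to
#' `[0, 10]`. The weights honor the ordinal structure of the prioritization
#' strategy (central hits beat peripheral ones, better-supported and
#' better-conserved BP score higher, a T>C / C>T substitution at BP-2 is
#' deprioritized) and live in a plain list so an alternative published
#' weight table can be dropped in.
#'
#' @param ... Name = value overrides of any default weight.
#' @return Named list of weights.
#' @export
score_weights <- function(...) {
  w <- list(
    hit_full_or_bp = 3, hit_bp2 = 2, hit_bp1 = 1,
    rank_only = 2, rank_first_of3 = 1.5, rank_second_of3 = 1, rank_other = 0,
    consensus = c(`1` = 2, `2` = 1.5, `3` = 1, `4` = 0.5, `0` = 0),
    source_multi = 1, source_mbp_bonus = 0.5, source_cap = 1,
    pop_none = 1, pop_rare = 0.5, pop_common = 0,
    cons_positive = 1, cons_missing = 0.5, cons_negative = 0,
    bp2_transition_penalty = -1,
    max_total = 10
  )
  dots <- list(...)
  for (nm in names(dots)) w[[nm]] <- dots[[nm]]
  w
}

#' Compute the prioritization score for one detection
#'
#' Additive terms: hit position (full-motif deletion or BP itself = 3,
#' BP-2 = 2, BP-1 = 1); rank (only BP = 2, first of <= 3 = 1.5, second of
#' <= 3 = 1, else 0); consensus level (2 / 1.5 / 1 / 0.5 / 0 for levels
#' 1/2/3/4/0); sources (1 for multiple sources, mBP bonus 0.5, capped at 1);
#' population (1 when no variant sits at BP or BP-2, 0.5 when only
#' singleton/rare variants do, 0 when a common variant does); conservation
#' (1 when GERP or PhyloP is positive at the hit position, 0.5 when both are
#' missing, else 0); and a -1 penalty for a T>C or C>T substitution at BP-2.
#' The total is clamped to `[0, 10]`.
#'
#' @param hits Integer subset of `c(-2, -1, 0)`; must be nonempty.
#' @param full_motif `TRUE` for a deletion removing the whole window.
#' @param rank,total BP rank within its intron and the intron's BP count.
#' @param consensus_level Integer 0-4.
#' @param n_sources,bp_class Support count and class (`mBP`/`eBP`/`cBP`).
#' @param annotation One-row frame from [annotate_position()] (or `NULL`).
#' @param snv_change Transcript-sense substitution like `"T>C"`, or `NA` for
#'   non-SNVs.
#' @param weights From [score_weights()].
#' @return `list` with each term and the clamped `total`.
#' @export
bp_score <- function(hits, full_motif, rank, total, consensus_level,
                     n_sources, bp_class, annotation = NULL,
                     snv_change = NA_character_, weights = score_weights()) {
  if (length(hits) == 0L) stop("bp_score requires a nonempty hit set")
  w <- weights
  hit_term <- if (full_motif || 0L %in% hits) w$hit_full_or_bp
              else if (-2L %in% hits) w$hit_bp2 else w$hit_bp1
  rank_term <- if (total == 1L) w$rank_only
               else if (rank == 1L && total <= 3L) w$rank_first_of3
               else if (rank == 2L && total <= 3L) w$rank_second_of3
               else w$rank_other
  consensus_term <- unname(w$consensus[as.character(consensus_level)])
  if (is.na(consensus_term)) consensus_term <- 0
  source_term <- min(w$source_cap,
                     (n_sources >= 2L) * w$source_multi +
                       (bp_class == "mBP") * w$source_mbp_bonus)
  maf_bp <- if (is.null(annotation)) NA_real_ else annotation$maf_bp
  maf_bp2 <- if (is.null(annotation)) NA_real_ else annotation$maf_bp2
  population_term <- if (is.na(maf_bp) && is.na(maf_bp2)) w$pop_none
    else if ((!is.na(maf_bp) && maf_bp >= 0.01) ||
             (!is.na(maf_bp2) && maf_bp2 >= 0.01)) w$pop_common
    else w$pop_rare
  # conservation is read at the hit position: BP-2 when only BP-2 is hit
  use_bp2 <- !full_motif && !(0L %in% hits) && (-2L %in% hits)
  gerp <- if (is.null(annotation)) NA_real_ else
    if (use_bp2) annotation$gerp_bp2 else annotation$gerp_bp
  phylop <- if (is.null(annotation)) NA_real_ else
    if (use_bp2) annotation$phylop_bp2 else annotation$phylop_bp
  conservation_term <- if (is.na(gerp) && is.na(phylop)) w$cons_missing
    else if ((!is.na(gerp) && gerp > 0) || (!is.na(phylop) && phylop > 0)) w$cons_positive
    else w$cons_negative
  penalty <- 0
  if (!is.na(snv_change) && identical(as.integer(hits), -2L) &&
      snv_change %in% c("T>C", "C>T"))
    penalty <- w$bp2_transition_penalty
  total_score <- hit_term + rank_term + consensus_term + source_term +
    population_term + conservation_term + penalty
  total_score <- max(0, min(w$max_total, total_score))
  list(hit_term = hit_term, rank_term = rank_term,
       consensus_term = consensus_term, source_term = source_term,
       population_term = population_term, conservation_term = conservation_term,
       bp2_transition_penalty = penalty, total = total_score)
}

#' The seven prioritization-strategy flags for one detection
#'
#' Each flag mirrors one item of the prioritization strategy: (1) full-motif
#' deletion or a hit at BP or BP-2; (2) only BP of the intron, or first or
#' second BP of an intron with at most three; (3) strict YTNAY consensus,
#' with a relaxed sub-tag for YTNA; (4) more than one supporting source;
#' (5) no or only rare population variants at the BP; (6) positive GERP or
#' PhyloP; (7) deprioritize: T>C or C>T substitution at BP-2.
#'
#' @inheritParams bp_score
#' @return Named logical vector `flag1`..`flag7` plus `flag3_relaxed`.
#' @export
prioritization_flags <- function(hits, full_motif, rank, total,
                                 consensus_level, n_sources,
                                 annotation = NULL, snv_change = NA_character_) {
  maf_bp <- if (is.null(annotation)) NA_real_ else annotation$maf_bp
  gerp <- if (is.null(annotation)) NA_real_ else annotation$gerp_bp
  phylop <- if (is.null(annotation)) NA_real_ else annotation$phylop_bp
  c(flag1 = full_motif || any(c(0L, -2L) %in% hits),
    flag2 = total == 1L || (rank <= 2L && total <= 3L),
    flag3 = consensus_level %in% c(1L, 2L),
    flag3_relaxed = consensus_level == 2L,
    flag4 = n_sources > 1L,
    flag5 = is.na(maf_bp) || maf_bp < 0.01,
    flag6 = (!is.na(gerp) && gerp > 0) || (!is.na(phylop) && phylop > 0),
    flag7 = !is.na(snv_change) && identical(as.integer(hits), -2L) &&
      snv_change %in% c("T>C", "C>T"))
}
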