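## End-to-end convenience wrappers: in-memory and file-based runs.

#' Type a raw variant table
#'
#' Adds the [classify_variant()] columns to a `data.frame` of
#' `contig`, `pos`, `id`, `ref`, `alt` (e.g. a fixture bundle's variant set),
#' producing the same shape as [load_variants()].
#'
#' @param v Raw variant `data.frame`.
#' @return Typed variant records.
#' @export
classify_variants <- function(v) {
  if (nrow(v) == 0L) return(empty_variants())
  rows <- lapply(seq_len(nrow(v)), function(i) {
    cv <- classify_variant(v$ref[i], v$alt[i], v$pos[i])
    data.frame(contig = v$contig[i], pos = as.integer(v$pos[i]),
               id = if ("id" %in% names(v)) v$id[i] else ".",
               ref = toupper(v$ref[i]), alt = toupper(v$alt[i]),
               var_type = cv$var_type, type_class = cv$type_class,
               net_len = cv$net_len,
               affected_start = cv$affected_start, affected_end = cv$affected_end,
               trimmed_pos = cv$trimmed_pos, trimmed_ref = cv$trimmed_ref,
               trimmed_alt = cv$trimmed_alt, complex = cv$complex,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$variant_key <- paste(res$contig, res$pos, res$ref, res$alt, sep = ":")
  res
}

#' Run the full detection pipeline on in-memory objects
#'
#' Builds the adjusted, merged BP database, extracts and types introns, maps
#' BP to 3'-proximal introns, and runs detection with annotation and scoring.
#'
#' @param genome Genome (`DNAStringSet` or named character vector).
#' @param exons Exon table (see [load_transcript_models()]).
#' @param bp_datasets List of raw BP record data.frames.
#' @param variants Variant records (typed, or raw with
#'   `contig`/`pos`/`id`/`ref`/`alt`).
#' @param tracks Optional named list of tracks (`maf`, `ac`, `gerp`,
#'   `phylop`).
#' @param adjust Apply consensus-guided positional adjustment.
#' @param canonical_only Restrict to canonical transcripts.
#' @param minor_list Optional minor-intron override keys.
#' @param min_score Optional score filter.
#' @param weights Scoring weights.
#' @return `list(detections, not_detected, db, reports, introns, mapped,
#'   variants)`.
#' @export
run_detection <- function(genome, exons, bp_datasets, variants, tracks = NULL,
                          adjust = TRUE, canonical_only = FALSE,
                          minor_list = NULL, min_score = NULL,
                          weights = score_weights()) {
  if (canonical_only) exons <- exons[exons$canonical, , drop = FALSE]
  if (!"type_class" %in% names(variants)) variants <- classify_variants(variants)
  dbres <- build_bp_database(genome, bp_datasets, adjust = adjust)
  intr <- extract_introns(exons, genome, minor_list = minor_list)
  mapped <- map_bp_to_introns(dbres$db, intr, genome)
  det <- detect(variants, mapped, intr$memberships, tracks = tracks,
                min_score = min_score, weights = weights)
  list(detections = det,
       not_detected = undetected_variants(variants, det),
       db = dbres$db, reports = dbres$reports,
       introns = intr, mapped = mapped, variants = variants)
}

#' Run the full detection pipeline from files
#'
#' @param genome_path FASTA file.
#' @param gtf_path GTF file.
#' @param bp_paths Named character vector of BP TSV paths; names are dataset
#'   ids (optional).
#' @param bp_classes Character vector parallel to `bp_paths`
#'   (`"experimental"`/`"computational"`), or `NULL` to use the file column.
#' @param vcf_path VCF file.
#' @param track_paths Optional named list/vector with any of `maf`, `ac`,
#'   `gerp`, `phylop`.
#' @inheritParams run_detection
#' @return As [run_detection()].
#' @export
run_detection_files <- function(genome_path, gtf_path, bp_paths,
                                bp_classes = NULL, vcf_path,
                                track_paths = NULL, adjust = TRUE,
                                canonical_only = FALSE, minor_list = NULL,
                                min_score = NULL, weights = score_weights()) {
  genome <- load_genome(genome_path)
  exons <- load_transcript_models(gtf_path, canonical_only = FALSE)
  datasets <- lapply(seq_along(bp_paths), function(i)
    load_bp_records(bp_paths[[i]],
                    dataset_id = if (!is.null(names(bp_paths))) names(bp_paths)[i] else NULL,
                    evidence_class = if (!is.null(bp_classes)) bp_classes[i] else NULL))
  variants <- load_variants(vcf_path)
  kinds <- c(maf = "MAF", ac = "AC", gerp = "GERP", phylop = "PhyloP")
  tracks <- NULL
  if (!is.null(track_paths)) {
    tracks <- list()
    for (nm in intersect(names(kinds), names(track_paths)))
      if (!is.null(track_paths[[nm]]) && file.exists(track_paths[[nm]]) &&
          file.size(track_paths[[nm]]) > 0L)
        tracks[[nm]] <- load_position_track(track_paths[[nm]], kinds[[nm]])
  }
  run_detection(genome, exons, datasets, variants, tracks = tracks,
                adjust = adjust, canonical_only = canonical_only,
                minor_list = minor_list, min_score = min_score,
                weights = weights)
}
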