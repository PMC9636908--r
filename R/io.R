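#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into a collection of contig sequences. Bases are
#' uppercased on load; every contig is retrievable by name and positions are
#' 1-based inclusive throughout the package.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  if (file.size(path) == 0L) return(Biostrings::DNAStringSet())
  genome <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  # keep only the first whitespace-delimited token of each header
  names(genome) <- sub("\\s.*$", "", names(genome))
  Biostrings::DNAStringSet(toupper(genome))
}

#' Extract genomic sequence (plus strand) from a loaded genome
#'
#' @param genome A `DNAStringSet` from [load_genome()].
#' @param contig Contig name.
#' @param start,end 1-based inclusive bounds; must lie within the contig.
#' @return Character scalar, plus-strand sequence.
#' @export
genome_seq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) stop("contig not in genome: ", contig)
  len <- length(genome[[contig]])
  if (start < 1L || end > len || start > end)
    stop(sprintf("out-of-range lookup %s:%d-%d (contig length %d)", contig, start, end, len))
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}

#' Single-base lookup, 1-based
#' @inheritParams genome_seq
#' @param pos 1-based position.
#' @export
genome_base <- function(genome, contig, pos) genome_seq(genome, contig, pos, pos)

#' Load transcript models from a GTF file
#'
#' Exon features are grouped per transcript and sorted by genomic start
#' (regardless of strand). Canonical transcripts are recognized from GTF
#' attribute tags; the tag names looked at are configurable because annotation
#' sources differ in how they mark their representative isoform.
#'
#' @param path GTF file with `exon` features carrying `transcript_id` and a
#'   gene attribute (`gene_name` or `gene_id`).
#' @param canonical_only If `TRUE`, keep only transcripts carrying a
#'   recognized canonical tag.
#' @param canonical_tags Attribute values (of the GTF `tag` field) that mark a
#'   transcript as canonical.
#' @return A `data.frame` with one row per exon: `transcript_id`,
#'   `gene_symbol`, `contig`, `strand`, `start`, `end`, `canonical`.
#' @export
load_transcript_models <- function(path, canonical_only = FALSE,
                                   canonical_tags = c("Ensembl_canonical", "MANE_Select", "canonical")) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  n_skipped <- 0L
  if (!"transcript_id" %in% names(df)) {
    warning("no exon carries a transcript_id; returning empty model set")
    df <- df[0, , drop = FALSE]
  } else {
    bad <- is.na(df$transcript_id) | df$transcript_id == ""
    n_skipped <- sum(bad)
    if (n_skipped > 0L)
      warning(sprintf("skipped %d exon feature(s) without transcript_id", n_skipped))
    df <- df[!bad, , drop = FALSE]
  }
  gene <- if ("gene_name" %in% names(df)) df$gene_name else
    if ("gene_id" %in% names(df)) df$gene_id else rep(NA_character_, nrow(df))
  gene[is.na(gene)] <- "."
  tag <- if ("tag" %in% names(df)) as.character(df$tag) else rep(NA_character_, nrow(df))
  exons <- data.frame(
    transcript_id = as.character(df$transcript_id),
    gene_symbol   = gene,
    contig        = as.character(df$seqnames),
    strand        = as.character(df$strand),
    start         = as.integer(df$start),
    end           = as.integer(df$end),
    canonical     = !is.na(tag) & tag %in% canonical_tags,
    stringsAsFactors = FALSE
  )
  if (nrow(exons) > 0L) {
    # a transcript is canonical if any of its exon lines carries the tag
    canon_tx <- unique(exons$transcript_id[exons$canonical])
    exons$canonical <- exons$transcript_id %in% canon_tx
    if (any(!exons$strand %in% c("+", "-")))
      stop("exon with strand other than +/- in ", path)
    exons <- exons[order(exons$transcript_id, exons$start, exons$end), , drop = FALSE]
    rownames(exons) <- NULL
  }
  if (canonical_only) {
    exons <- exons[exons$canonical, , drop = FALSE]
    if (nrow(exons) == 0L) warning("canonical_only=TRUE but no transcript carries a canonical tag")
  }
  exons
}

#' Load a branchpoint dataset from TSV (or BED)
#'
#' The native dialect is tab-delimited with columns
#' `contig`, `pos` (1-based), `strand`, `dataset_id`, `evidence_class`
#' (a header line is accepted and detected). BED input (0-based half-open,
#' strand in column 6) is converted to 1-based on load, with `dataset_id`
#' and `evidence_class` supplied by the caller.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"bed"`.
#' @param dataset_id,evidence_class Required for BED input; for TSV input they
#'   override the file columns when given.
#' @return `data.frame` with columns `contig`, `pos`, `strand`, `dataset_id`,
#'   `evidence_class`; exact duplicate rows within a dataset are collapsed.
#' @export
load_bp_records <- function(path, format = c("tsv", "bed"),
                            dataset_id = NULL, evidence_class = NULL) {
  format <- match.arg(format)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("empty BP dataset: ", path)
  if (format == "bed") {
    if (ncol(raw) < 6L) stop("BED BP input needs >= 6 columns (strand in col 6): ", path)
    if (is.null(dataset_id) || is.null(evidence_class))
      stop("dataset_id and evidence_class must be supplied for BED input")
    rec <- data.frame(contig = raw[[1]], pos = as.integer(raw[[2]]) + 1L,
                      strand = raw[[6]], dataset_id = dataset_id,
                      evidence_class = evidence_class, stringsAsFactors = FALSE)
  } else {
    # drop a header line if present
    if (tolower(raw[1, 1]) %in% c("contig", "chrom", "chr")) raw <- raw[-1, , drop = FALSE]
    if (ncol(raw) < 5L) stop("BP TSV needs 5 columns (contig pos strand dataset_id evidence_class): ", path)
    pos <- suppressWarnings(as.integer(raw[[2]]))
    if (anyNA(pos))
      stop("non-integer BP position at line(s) ", paste(which(is.na(pos)), collapse = ","), " of ", path)
    rec <- data.frame(contig = raw[[1]], pos = pos, strand = raw[[3]],
                      dataset_id = raw[[4]], evidence_class = raw[[5]],
                      stringsAsFactors = FALSE)
    if (!is.null(dataset_id)) rec$dataset_id <- dataset_id
    if (!is.null(evidence_class)) rec$evidence_class <- evidence_class
  }
  bad <- !rec$strand %in% c("+", "-")
  if (any(bad))
    stop("unknown strand symbol '", rec$strand[which(bad)[1]], "' at line ",
         which(bad)[1], " of ", path)
  rec$evidence_class <- normalize_evidence_class(rec$evidence_class)
  rec <- unique(rec)
  rownames(rec) <- NULL
  rec
}

normalize_evidence_class <- function(x) {
  out <- rep(NA_character_, length(x))
  out[tolower(x) %in% c("e", "exp", "experimental")] <- "experimental"
  out[tolower(x) %in% c("c", "comp", "computational")] <- "computational"
  if (anyNA(out))
    stop("evidence_class must be experimental or computational, got: ",
         paste(unique(x[is.na(out)]), collapse = ","))
  out
}

#' Load variants from a VCF file
#'
#' Only the first five columns (CHROM, POS, ID, REF, ALT) are required.
#' Multi-allelic rows are split into one record per ALT allele. Shared
#' REF/ALT prefix and suffix bases are trimmed before typing; left-alignment
#' is not performed (inputs are expected to be normalized).
#'
#' @param path VCF 4.x file.
#' @return `data.frame` of normalized variant records, one per ALT allele,
#'   with typing columns from [classify_variant()]: `var_type`, `type_class`,
#'   `net_len`, `affected_start`, `affected_end`, `trimmed_pos`,
#'   `trimmed_ref`, `trimmed_alt`, `complex`, `variant_key`.
#' @export
load_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) return(empty_variants())
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]; pos <- as.integer(fix[i, "POS"])
    id <- fix[i, "ID"]; ref <- toupper(fix[i, "REF"])
    alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    if (!grepl("^[ACGTN]+$", ref))
      stop(sprintf("REF with non-ACGTN characters at %s:%d (%s)", chrom, pos, ref))
    rows <- lapply(alts, function(a) {
      cv <- classify_variant(ref, a, pos)
      data.frame(contig = chrom, pos = pos,
                 id = ifelse(is.na(id), ".", id),
                 ref = ref, alt = a,
                 var_type = cv$var_type, type_class = cv$type_class,
                 net_len = cv$net_len,
                 affected_start = cv$affected_start, affected_end = cv$affected_end,
                 trimmed_pos = cv$trimmed_pos,
                 trimmed_ref = cv$trimmed_ref, trimmed_alt = cv$trimmed_alt,
                 complex = cv$complex,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  res$variant_key <- paste(res$contig, res$pos, res$ref, res$alt, sep = ":")
  rownames(res) <- NULL
  res
}

empty_variants <- function() {
  data.frame(contig = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), var_type = character(),
             type_class = character(), net_len = integer(),
             affected_start = integer(), affected_end = integer(),
             trimmed_pos = integer(), trimmed_ref = character(),
             trimmed_alt = character(), complex = logical(),
             variant_key = character(), stringsAsFactors = FALSE)
}

#' Write variant records back to a minimal VCF body
#'
#' Emits a five-column VCF (plus fileformat header) from loaded variant
#' records, merging records that came from one multi-allelic row is not
#' attempted: one line per record. Round-tripping a loaded file through
#' [write_variants()] and [load_variants()] yields identical records.
#'
#' @param variants Output of [load_variants()].
#' @param path Destination file.
#' @export
write_variants <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0L)
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       variants$contig, variants$pos, variants$id,
                       variants$ref, variants$alt), con)
  invisible(path)
}

#' Load a per-position annotation track
#'
#' Tab-delimited `contig`, `pos` (1-based), `value`. Lookups at unlisted
#' positions return `NA` (rendered "." on output), which is distinct from a
#' stored value of 0.
#'
#' @param path TSV file.
#' @param track_kind One of `"MAF"`, `"AC"`, `"GERP"`, `"PhyloP"`.
#' @return A track object (environment-backed hash) with attribute
#'   `track_kind`, to be queried with [track_lookup()].
#' @export
load_position_track <- function(path, track_kind = c("MAF", "AC", "GERP", "PhyloP")) {
  track_kind <- match.arg(track_kind)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character")
  if (tolower(raw[1, 1]) %in% c("contig", "chrom", "chr")) raw <- raw[-1, , drop = FALSE]
  if (ncol(raw) < 3L) stop("track TSV needs 3 columns (contig pos value): ", path)
  pos <- suppressWarnings(as.integer(raw[[2]]))
  val <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(pos))
    stop("non-integer position at line(s) ", paste(which(is.na(pos)), collapse = ","), " of ", path)
  if (anyNA(val))
    stop("non-numeric value at line(s) ", paste(which(is.na(val)), collapse = ","), " of ", path)
  position_track(raw[[1]], pos, val, track_kind)
}

#' Build a position track in memory
#' @param contig,pos,value Parallel vectors.
#' @param track_kind Track label.
#' @export
position_track <- function(contig, pos, value, track_kind = "MAF") {
  env <- new.env(parent = emptyenv(), size = max(1L, length(pos)))
  keys <- paste0(contig, ":", pos)
  for (i in seq_along(keys)) assign(keys[i], value[i], envir = env)
  structure(list(values = env), class = "bp_track", track_kind = track_kind)
}

#' Query a position track
#' @param track A `bp_track`, or `NULL` (always missing).
#' @param contig,pos Query position(s); vectors recycle.
#' @return Numeric vector; `NA` where the position is absent.
#' @export
track_lookup <- function(track, contig, pos) {
  n <- max(length(contig), length(pos))
  if (is.null(track)) return(rep(NA_real_, n))
  stopifnot(inherits(track, "bp_track"))
  keys <- paste0(rep_len(contig, n), ":", rep_len(pos, n))
  vapply(keys, function(k) {
    if (exists(k, envir = track$values, inherits = FALSE))
      get(k, envir = track$values) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write a detection table as TSV with "." for missing values
#' @param df Data frame.
#' @param path Destination.
#' @export
write_tsv_dot <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    col <- as.character(col)
    col[is.na(col)] <- "."
    out[[j]] <- col
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
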