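# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive enumerations / regex formulations that do not
# share code paths with the package internals they validate.

# reverse complement, built from first principles
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# consensus predicates as plain regexes (N bases never match)
oracle_consensus <- function(m5) {
  if (grepl("N", m5, fixed = TRUE)) return(0L)
  if (grepl("^[CT]T[ACGT]A[CT]$", m5)) return(1L)
  if (grepl("^[CT]T[ACGT]A[ACGT]$", m5)) return(2L)
  if (grepl("^[ACGT]T[ACGT]A[ACGT]$", m5)) return(3L)
  if (grepl("^[ACGT][CT][ACGT]A[ACGT]$", m5)) return(4L)
  0L
}

# naive allele trimming: drop shared leading bases (advancing pos), then
# shared trailing bases
oracle_trim <- function(ref, alt, pos) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) && length(a) && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  while (length(r) && length(a) && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# per-variant precomputation for the brute-force detection oracle
oracle_variant_sites <- function(ref, alt, pos) {
  tr <- oracle_trim(ref, alt, pos)
  nr <- nchar(tr$ref); na <- nchar(tr$alt)
  if (nr == 1L && na == 1L) list(kind = "snv", sites = tr$pos)
  else if (na == 0L) list(kind = "del", sites = tr$pos:(tr$pos + nr - 1L))
  else if (nr == 0L) list(kind = "ins", sites = c(tr$pos - 1L, tr$pos))
  else list(kind = "del", sites = tr$pos:(tr$pos + nr - 1L))
}

# brute force: for one variant, enumerate every BP and every offset in
# {-2,-1,0}; returns data.frame(bp_i, hits) for BPs with nonempty hit sets
oracle_hits_all_bps <- function(vs, bp_pos, bp_strand) {
  out_i <- integer(); out_h <- character()
  for (i in seq_along(bp_pos)) {
    b <- bp_pos[i]
    off_of <- function(s) if (bp_strand[i] == "+") s - b else b - s
    if (vs$kind == "ins") {
      o <- sort(off_of(vs$sites))
      hits <- if (all(o %in% -2:0)) o else integer(0)
    } else {
      hits <- sort(intersect(vapply(vs$sites, off_of, integer(1)), -2:0))
    }
    if (length(hits)) {
      out_i <- c(out_i, i)
      out_h <- c(out_h, paste(hits, collapse = "|"))
    }
  }
  data.frame(bp_i = out_i, hits = out_h, stringsAsFactors = FALSE)
}

# all-pairs BP-to-intron mapping scan
oracle_map <- function(bp_df, intron_df, window = c(-100L, -3L)) {
  rows <- list()
  for (i in seq_len(nrow(bp_df))) for (j in seq_len(nrow(intron_df))) {
    if (bp_df$contig[i] != intron_df$contig[j]) next
    if (bp_df$strand[i] != intron_df$strand[j]) next
    if (bp_df$pos[i] < intron_df$start[j] || bp_df$pos[i] > intron_df$end[j]) next
    d <- if (intron_df$strand[j] == "+") bp_df$pos[i] - intron_df$end[j] - 1L
         else intron_df$start[j] - bp_df$pos[i] - 1L
    if (d < window[1] || d > window[2]) next
    rows[[length(rows) + 1L]] <- data.frame(
      pos = bp_df$pos[i], strand = bp_df$strand[i],
      intron_key = intron_df$intron_key[j], distance = d,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(pos = integer(), strand = character(),
                                       intron_key = character(), distance = integer(),
                                       rank = integer(), stringsAsFactors = FALSE))
  m <- do.call(rbind, rows)
  m$rank <- NA_integer_
  for (k in unique(m$intron_key)) {
    sel <- m$intron_key == k
    m$rank[sel] <- order(order(abs(m$distance[sel])))
  }
  m[order(m$pos, m$intron_key), , drop = FALSE]
}

# tiny helper: write a FASTA file from a named character vector
write_fasta <- function(genome, path) {
  con <- file(path, "w")
  for (ctg in names(genome)) {
    writeLines(paste0(">", ctg), con)
    writeLines(genome[[ctg]], con)
  }
  close(con)
  path
}

# tiny helper: write a minimal VCF from contig/pos/id/ref/alt vectors
write_vcf <- function(df, path) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       df$contig, df$pos, df$id, df$ref, df$alt), con)
  close(con)
  path
}
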