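#' Read transcript models from GTF/GFF3
#'
#' Parses exon features into a [transcript_set()]. GTF/GFF 1-based inclusive
#' coordinates are converted to the package's internal 0-based half-open
#' convention. For GTF, `transcript_id`/`gene_id` attributes are used; for
#' GFF3 the exon `Parent` serves as the transcript id and the gene id is
#' resolved through mRNA/transcript features when present. Exon records with
#' no resolvable transcript id are dropped with a message (their count is
#' available as `attr(, "n_rejected")`).
#'
#' @param path GTF or GFF3 file.
#' @param format `"auto"` (by extension), `"gtf"` or `"gff3"`.
#' @return A `transcript_set` (empty file yields an empty set).
#' @seealso [write_gtf()]
#' @export
read_gtf <- function(path, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  empty <- transcript_set(data.frame(
    transcript_id = character(0), gene_id = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0)))
  if (length(readLines(path, n = 200L, warn = FALSE)) == 0L) return(empty)
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stopf("parse error in %s: %s", path, conditionMessage(e))
  )
  df <- as.data.frame(gr)
  if (!nrow(df)) return(empty)
  if ("type" %in% names(df)) df <- df[df$type == "exon", , drop = FALSE]
  if (!nrow(df)) return(empty)

  if ("transcript_id" %in% names(df) && any(!is.na(df$transcript_id))) {
    txid <- as.character(df$transcript_id)
  } else if ("Parent" %in% names(df)) {
    txid <- vapply(df$Parent, function(p) {
      if (length(p)) as.character(p[[1]]) else NA_character_
    }, character(1))
    txid <- sub("^transcript:", "", txid)
  } else {
    txid <- rep(NA_character_, nrow(df))
  }
  bad <- is.na(txid) | !nzchar(txid)
  n_rejected <- sum(bad)
  if (n_rejected) {
    message(sprintf("read_gtf: dropped %d exon record(s) without transcript_id", n_rejected))
    df <- df[!bad, , drop = FALSE]
    txid <- txid[!bad]
  }
  if (!nrow(df)) {
    attr(empty, "n_rejected") <- n_rejected
    return(empty)
  }

  if ("gene_id" %in% names(df) && any(!is.na(df$gene_id))) {
    gid <- as.character(df$gene_id)
  } else {
    # GFF3: map transcript -> gene through mRNA/transcript feature Parents
    all_df <- as.data.frame(gr)
    gid <- rep(NA_character_, nrow(df))
    if (all(c("type", "ID", "Parent") %in% names(all_df))) {
      tx_feats <- all_df[all_df$type %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA"), , drop = FALSE]
      if (nrow(tx_feats)) {
        tid <- sub("^transcript:", "", as.character(tx_feats$ID))
        tgid <- vapply(tx_feats$Parent, function(p) {
          if (length(p)) sub("^gene:", "", as.character(p[[1]])) else NA_character_
        }, character(1))
        gid <- tgid[match(txid, tid)]
      }
    }
    gid[is.na(gid)] <- txid[is.na(gid)]
  }
  out <- transcript_set(data.frame(
    transcript_id = txid,
    gene_id = gid,
    chrom = as.character(df$seqnames),
    start = df$start - 1L,   # 1-based inclusive -> 0-based half-open
    end = df$end,
    strand = as.character(df$strand),
    stringsAsFactors = FALSE
  ))
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a transcript set as GTF
#'
#' Emits one `exon` feature per exon with `transcript_id`/`gene_id`
#' attributes, converting internal 0-based half-open coordinates back to GTF's
#' 1-based inclusive convention. `read_gtf(write_gtf(x))` reproduces `x`.
#'
#' @param ts a `transcript_set`.
#' @param path output file.
#' @param source feature source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ts, path, source = "spikelnc") {
  stopifnot(inherits(ts, "transcript_set"))
  ex <- ts$exons
  strand <- ex$strand
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = source, type = "exon",
    transcript_id = ex$transcript_id, gene_id = ex$gene_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by transcript id (first word of
#'   each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}
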