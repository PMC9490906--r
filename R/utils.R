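`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Gap between two genomic intervals
#'
#' Nearest-edge distance between two 0-based half-open intervals: 0 when they
#' overlap or abut over at least one base, the number of intervening bases
#' otherwise, and `Inf` when the intervals sit on different chromosomes.
#' All arguments recycle.
#'
#' @param chrom_a,start_a,end_a first interval (chromosome, 0-based start,
#'   exclusive end).
#' @param chrom_b,start_b,end_b second interval.
#' @return Numeric vector of distances in bp (`Inf` = different chromosome).
#' @examples
#' interval_gap("chr1", 100, 200, "chr1", 150, 300) # 0, overlap
#' interval_gap("chr1", 100, 200, "chr1", 250, 300) # 50
#' @export
interval_gap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  gap <- pmax(start_b - end_a, start_a - end_b, 0)
  gap[chrom_a != chrom_b] <- Inf
  as.numeric(gap)
}

# any-base overlap of half-open intervals (same chromosome assumed checked)
intervals_overlap <- function(start_a, end_a, start_b, end_b) {
  start_a < end_b & start_b < end_a
}

#' Construct a transcript set
#'
#' A transcript set is the package's container for exon-structured transcript
#' models: a validated exon table plus a per-transcript summary. Exons are
#' stored 0-based half-open, sorted by position within each transcript, and
#' must be pairwise disjoint and share one chromosome and strand.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (one row per exon).
#' @return An object of class `transcript_set`: list with `$exons` (validated
#'   exon table) and `$transcripts` (one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `n_exons`, `length`, where
#'   `length` is the spliced length, i.e. the sum of exon widths).
#' @export
transcript_set <- function(exons) {
  need <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stopf("exon table missing column(s): %s", paste(miss, collapse = ", "))
  exons <- as.data.frame(exons)[, need]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(is.na(exons$start) | is.na(exons$end))) stopf("NA exon coordinates")
  if (any(exons$start < 0L) || any(exons$start >= exons$end))
    stopf("invalid exon interval (need 0 <= start < end)")
  if (any(!nzchar(exons$chrom))) stopf("empty chromosome identifier")
  if (any(!exons$strand %in% c("+", "-", "."))) stopf("strand must be one of +, -, .")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (tx in names(by_tx)) {
    i <- by_tx[[tx]]
    if (length(unique(exons$chrom[i])) > 1L || length(unique(exons$strand[i])) > 1L)
      stopf("transcript %s mixes chromosomes or strands", tx)
    if (length(i) > 1L) {
      s <- exons$start[i]; e <- exons$end[i]
      if (any(s[-1] < e[-length(e)]))
        stopf("transcript %s has overlapping exons", tx)
    }
  }
  first <- vapply(by_tx, `[`, integer(1), 1L)
  tx <- data.frame(
    transcript_id = names(by_tx),
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    start = vapply(by_tx, function(i) min(exons$start[i]), integer(1)),
    end = vapply(by_tx, function(i) max(exons$end[i]), integer(1)),
    strand = exons$strand[first],
    n_exons = lengths(by_tx),
    length = vapply(by_tx, function(i) sum(exons$end[i] - exons$start[i]), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(tx) <- NULL
  structure(list(exons = exons, transcripts = tx), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d exons, %d chromosome(s)\n",
              nrow(x$transcripts), nrow(x$exons),
              length(unique(x$exons$chrom))))
  invisible(x)
}

#' @export
length.transcript_set <- function(x) nrow(x$transcripts)

# exon rows of one transcript
tx_exons <- function(ts, id) {
  ts$exons[ts$exons$transcript_id == id, , drop = FALSE]
}

# introns of an exon table (assumes sorted, disjoint); 0-based half-open
exon_introns <- function(ex) {
  n <- nrow(ex)
  if (n < 2L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = ex$end[-n], end = ex$start[-1])
}

#' Subset a transcript set by transcript id
#'
#' @param ts a `transcript_set`.
#' @param ids transcript ids to keep.
#' @return A `transcript_set` restricted to `ids`.
#' @export
subset_transcripts <- function(ts, ids) {
  transcript_set(ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE])
}
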