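#' Read genomic intervals from BED
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' Records with `start >= end` are skipped with a message (count available as
#' `attr(, "n_rejected")`); 3-column records get auto-generated names
#' `region_<n>`.
#'
#' @param path BED3/4/6 file.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- tryCatch(
    read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
               comment.char = "#", fill = TRUE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame())
      stopf("parse error in %s: %s", path, conditionMessage(e))
    })
  if (!nrow(raw)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0))
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  if (ncol(raw) < 3L) stopf("BED needs >= 3 columns: %s", path)
  out <- data.frame(chrom = as.character(raw[[1]]),
                    start = as.integer(raw[[2]]),
                    end = as.integer(raw[[3]]),
                    stringsAsFactors = FALSE)
  auto <- sprintf("region_%d", seq_len(nrow(out)))
  out$name <- if (ncol(raw) >= 4L) {
    nm <- as.character(raw[[4]])
    ifelse(is.na(nm) | !nzchar(nm), auto, nm)
  } else auto
  bad <- out$start >= out$end
  if (any(bad)) {
    message(sprintf("read_bed: skipped %d record(s) with start >= end", sum(bad)))
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write intervals as BED4
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  name <- intervals$name %||% sprintf("region_%d", seq_len(nrow(intervals)))
  write.table(data.frame(intervals$chrom, intervals$start, intervals$end, name),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column = feature id, remaining columns = per-sample abundances
#' (FPKM). Values must be non-negative and labels unique.
#'
#' @param path TSV with header row.
#' @return Numeric matrix, features x samples.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stopf("duplicate feature ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stopf("duplicate sample ids in %s", path)
  if (any(m < 0, na.rm = TRUE)) stopf("negative abundance values in %s", path)
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat features x samples numeric matrix.
#' @param path output file.
#' @param id_col name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# generic TSV helpers used by the pipeline writers
read_tsv_file <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
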