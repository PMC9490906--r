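CLASS_CODE_PRECEDENCE <- c("=", "c", "j", "e", "i", "o", "x", "u")

# strand compatibility: "." (unknown) is treated as same-strand-compatible
# and never as antisense
strand_same <- function(q, r) q == r | q == "." | r == "."
strand_anti <- function(q, r) (q == "+" & r == "-") | (q == "-" & r == "+")

# classify one query exon table against one reference exon table
classify_vs_ref <- function(qex, rex) {
  same <- strand_same(qex$strand[1], rex$strand[1])
  anti <- strand_anti(qex$strand[1], rex$strand[1])
  q_introns <- exon_introns(qex)
  r_introns <- exon_introns(rex)
  exonic <- any(outer(qex$start, rex$end, `<`) & t(outer(rex$start, qex$end, `<`)))

  if (same) {
    same_chain <- nrow(q_introns) == nrow(r_introns) &&
      (nrow(q_introns) == 0L ||
         all(q_introns$start == r_introns$start & q_introns$end == r_introns$end))
    if (exonic && same_chain) return("=")

    contained <- min(qex$start) >= min(rex$start) && max(qex$end) <= max(rex$end) &&
      all(vapply(seq_len(nrow(qex)), function(i) {
        any(rex$start <= qex$start[i] & qex$end[i] <= rex$end)
      }, logical(1))) &&
      (nrow(q_introns) == 0L ||
         all(paste(q_introns$start, q_introns$end) %in%
               paste(r_introns$start, r_introns$end)))
    if (contained) return("c")

    if (nrow(qex) > 1L && nrow(r_introns) > 0L &&
        any(paste(q_introns$start, q_introns$end) %in%
              paste(r_introns$start, r_introns$end))) return("j")

    intronic_ov <- nrow(r_introns) > 0L &&
      any(outer(qex$start, r_introns$end, `<`) & t(outer(r_introns$start, qex$end, `<`)))
    if (nrow(qex) == 1L && exonic && intronic_ov) return("e")

    if (nrow(r_introns) > 0L &&
        any(r_introns$start <= min(qex$start) & max(qex$end) <= r_introns$end))
      return("i")

    if (exonic) return("o")
  }
  if (anti && exonic) return("x")
  "u"
}

#' Assign a structural class code to one transcript
#'
#' Compares an assembled transcript with every same-chromosome reference
#' transcript and returns a single deterministic class code in gffcompare
#' style, evaluated with precedence `=` > `c` > `j` > `e` > `i` > `o` > `x` >
#' `u`:
#' \describe{
#'   \item{`=`}{same strand, identical intron chain, exonic overlap}
#'   \item{`c`}{contained: query exons within reference exons, query introns a
#'     subset of reference introns}
#'   \item{`j`}{multi-exon query sharing at least one exact intron
#'     (splice-junction pair) with a reference transcript}
#'   \item{`e`}{single-exon query overlapping both exon and intron of a
#'     reference transcript}
#'   \item{`i`}{query fully contained within a single reference intron}
#'   \item{`o`}{other same-strand exonic overlap}
#'   \item{`x`}{antisense exonic overlap}
#'   \item{`u`}{intergenic / no classifiable overlap}
#' }
#' Transcripts that touch only intronic sequence on the same strand without
#' being fully contained in one intron fall through to `u` (the `o` predicate
#' requires exonic overlap). Unknown strand (`.`) is treated as
#' same-strand-compatible and never antisense. The matched reference id is
#' the one attaining the best code (ties broken lexicographically), `NA` for
#' `u`.
#'
#' @param query one-transcript [transcript_set()] or an exon data.frame with
#'   columns `chrom`, `start`, `end`, `strand`.
#' @param reference a `transcript_set` of reference transcripts.
#' @return list with `code` (single character) and `ref_id`.
#' @export
assign_class_code <- function(query, reference) {
  if (inherits(query, "transcript_set")) {
    if (nrow(query$transcripts) != 1L) stopf("query must be a single transcript")
    qex <- query$exons
  } else {
    qex <- as.data.frame(query)
    qex <- qex[order(qex$start), , drop = FALSE]
  }
  if (nrow(qex) == 0L) stopf("query transcript has zero exons")
  stopifnot(inherits(reference, "transcript_set"))

  refs <- reference$transcripts
  refs <- refs[refs$chrom == qex$chrom[1], , drop = FALSE]
  # cheap prefilter: only references whose span comes near the query
  refs <- refs[refs$start < max(qex$end) & min(qex$start) < refs$end, , drop = FALSE]
  if (!nrow(refs)) return(list(code = "u", ref_id = NA_character_))

  refs <- refs[order(refs$transcript_id), , drop = FALSE]
  best_code <- "u"; best_ref <- NA_character_
  best_rank <- match("u", CLASS_CODE_PRECEDENCE)
  for (rid in refs$transcript_id) {
    code <- classify_vs_ref(qex, tx_exons(reference, rid))
    rank <- match(code, CLASS_CODE_PRECEDENCE)
    if (rank < best_rank) {
      best_rank <- rank; best_code <- code; best_ref <- rid
      if (rank == 1L) break
    }
  }
  if (best_code == "u") best_ref <- NA_character_
  list(code = best_code, ref_id = best_ref)
}

#' Classify every transcript of an assembly against a reference
#'
#' Vectorised driver for [assign_class_code()].
#'
#' @param assembly,reference `transcript_set` objects.
#' @return data.frame with `transcript_id`, `class_code`, `ref_id`.
#' @export
classify_transcripts <- function(assembly, reference) {
  ids <- assembly$transcripts$transcript_id
  res <- lapply(ids, function(id) {
    assign_class_code(
      structure(list(exons = tx_exons(assembly, id),
                     transcripts = assembly$transcripts[
                       assembly$transcripts$transcript_id == id, , drop = FALSE]),
                class = "transcript_set"),
      reference)
  })
  data.frame(transcript_id = ids,
             class_code = vapply(res, `[[`, character(1), "code"),
             ref_id = vapply(res, `[[`, character(1), "ref_id"),
             stringsAsFactors = FALSE)
}

#' Expression filter
#'
#' Keeps features whose abundance exceeds `min_fpkm` (strictly) in at least
#' `ceiling(min_fraction * n_samples)` samples — the "expressed" rule of the
#' discovery pipeline (default: FPKM > 0.1 in at least 20\% of samples).
#'
#' @param mat features x samples expression matrix.
#' @param min_fpkm strict lower abundance bound (default 0.1).
#' @param min_fraction minimum fraction of samples (default 0.2), in (0, 1].
#' @return Character vector of kept feature ids.
#' @export
expression_filter <- function(mat, min_fpkm = 0.1, min_fraction = 0.2) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  if (!nrow(mat) || !ncol(mat)) {
    warnf("expression_filter: empty matrix")
    return(character(0))
  }
  need <- ceiling(min_fraction * ncol(mat))
  rownames(mat)[rowSums(mat > min_fpkm) >= need]
}

#' Identify candidate lncRNAs
#'
#' Intersects the four discovery rules: expressed (see
#' [expression_filter()]), spliced length strictly greater than `min_len`,
#' structural class code in \{i, j, o, u\}, and a unanimous non-coding
#' verdict across every coding-potential predictor in `coding_calls`.
#' Transcripts passing the first three rules but absent from `coding_calls`
#' are excluded and reported as no-calls, never silently kept.
#'
#' @param assembly `transcript_set` of assembled transcripts.
#' @param reference `transcript_set` of reference (coding) annotation.
#' @param expr expression matrix covering the assembly.
#' @param coding_calls data.frame with columns `transcript_id`, `predictor`,
#'   `verdict` (`"coding"`/`"noncoding"`), as produced by external
#'   coding-potential tools.
#' @param min_len strict spliced-length cutoff in bp (default 200).
#' @param min_fpkm,min_fraction expression-filter thresholds.
#' @return list of class `lncrna_calls`: `$candidates` (per-candidate table
#'   with class code, expression summaries), `$funnel` (named counts through
#'   each filter), `$no_call` (ids lacking coding-potential calls).
#' @export
identify_lncrnas <- function(assembly, reference, expr, coding_calls,
                             min_len = 200, min_fpkm = 0.1,
                             min_fraction = 0.2) {
  tx <- assembly$transcripts
  funnel <- c(input = nrow(tx))

  codes <- classify_transcripts(assembly, reference)
  keep_code <- codes$class_code %in% c("i", "j", "o", "u")
  funnel["class_code"] <- sum(keep_code)

  long_enough <- tx$length > min_len
  funnel["length"] <- sum(keep_code & long_enough)

  expressed_ids <- expression_filter(expr, min_fpkm, min_fraction)
  expressed <- tx$transcript_id %in% expressed_ids
  funnel["expressed"] <- sum(keep_code & long_enough & expressed)

  pass3 <- tx$transcript_id[keep_code & long_enough & expressed]

  cc <- coding_calls[coding_calls$transcript_id %in% pass3, , drop = FALSE]
  verdicts <- tapply(cc$verdict, cc$transcript_id,
                     function(v) all(v == "noncoding"))
  no_call <- setdiff(pass3, names(verdicts))
  noncoding_ids <- names(verdicts)[verdicts]
  final <- intersect(pass3, noncoding_ids)
  funnel["noncoding"] <- length(final)

  i <- match(final, tx$transcript_id)
  sub_expr <- expr[intersect(final, rownames(expr)), , drop = FALSE]
  n_expr <- rowSums(sub_expr > min_fpkm)
  mean_fpkm <- rowMeans(sub_expr)
  out <- data.frame(
    tx[i, c("transcript_id", "gene_id", "chrom", "start", "end", "strand",
            "n_exons", "length")],
    class_code = codes$class_code[match(final, codes$transcript_id)],
    ref_id = codes$ref_id[match(final, codes$transcript_id)],
    n_expressed_samples = as.integer(n_expr[final]),
    mean_fpkm = as.numeric(mean_fpkm[final]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(list(candidates = out, funnel = funnel, no_call = no_call,
                 class_codes = codes),
            class = "lncrna_calls")
}

#' @export
print.lncrna_calls <- function(x, ...) {
  cat("lncRNA discovery funnel:\n")
  for (nm in names(x$funnel)) cat(sprintf("  %-12s %d\n", nm, x$funnel[[nm]]))
  if (length(x$no_call))
    cat(sprintf("  (%d transcript(s) excluded for missing coding-potential calls)\n",
                length(x$no_call)))
  invisible(x)
}

#' Summary statistics contrasting lncRNAs with mRNAs
#'
#' Per-class median spliced length, exon-count distribution, GC content (when
#' sequences are supplied), expressed-sample counts, and per-Mb feature
#' densities per chromosome.
#'
#' @param candidates candidate table (as in `lncrna_calls$candidates`) or a
#'   `transcript_set`.
#' @param mrnas reference `transcript_set` of protein-coding transcripts.
#' @param expr expression matrix; used for expressed-sample counts
#'   (abundance > `min_fpkm`).
#' @param sequences optional named [Biostrings::DNAStringSet] for GC content.
#' @param min_fpkm threshold defining "expressed in a sample".
#' @return list with `$summary` (per-class medians), `$exon_counts`,
#'   `$density` (features per Mb per chromosome and class).
#' @export
feature_stats <- function(candidates, mrnas, expr = NULL, sequences = NULL,
                          min_fpkm = 0.1) {
  ltab <- if (inherits(candidates, "transcript_set")) candidates$transcripts else candidates
  mtab <- mrnas$transcripts
  if (!nrow(ltab) || !nrow(mtab)) stopf("feature_stats: empty input")
  classes <- list(lncRNA = ltab, mRNA = mtab)

  gc_of <- function(ids) {
    if (is.null(sequences)) return(NA_real_)
    missing_ids <- setdiff(ids, names(sequences))
    if (length(missing_ids))
      stopf("sequences missing for: %s", paste(head(missing_ids, 5), collapse = ", "))
    f <- Biostrings::letterFrequency(sequences[ids], letters = c("G", "C"))
    tot <- sum(Biostrings::width(sequences[ids]))
    sum(f) / tot
  }
  expressed_samples <- function(ids) {
    if (is.null(expr)) return(NA_real_)
    ids <- intersect(ids, rownames(expr))
    if (!length(ids)) return(NA_real_)
    mean(rowSums(expr[ids, , drop = FALSE] > min_fpkm))
  }
  summary <- do.call(rbind, lapply(names(classes), function(cl) {
    t <- classes[[cl]]
    data.frame(class = cl, n = nrow(t),
               median_length = median(t$length),
               median_exons = median(t$n_exons),
               frac_single_exon = mean(t$n_exons == 1L),
               gc_content = gc_of(t$transcript_id),
               mean_expressed_samples = expressed_samples(t$transcript_id),
               stringsAsFactors = FALSE)
  }))
  exon_counts <- do.call(rbind, lapply(names(classes), function(cl) {
    tab <- table(classes[[cl]]$n_exons)
    data.frame(class = cl, n_exons = as.integer(names(tab)),
               count = as.integer(tab), stringsAsFactors = FALSE)
  }))
  density <- do.call(rbind, lapply(names(classes), function(cl) {
    t <- classes[[cl]]
    agg <- aggregate(list(count = t$transcript_id),
                     by = list(chrom = t$chrom), FUN = length)
    span <- vapply(agg$chrom, function(ch) max(t$end[t$chrom == ch]), numeric(1))
    data.frame(class = cl, chrom = agg$chrom, count = agg$count,
               per_mb = agg$count / (span / 1e6), stringsAsFactors = FALSE)
  }))
  list(summary = summary, exon_counts = exon_counts, density = density)
}
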