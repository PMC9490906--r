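# Brute-force class-code classifier: every overlap predicate evaluated on
# explicit per-base sets and naive loops. Deliberately slow and simple --
# the independent route against which assign_class_code is checked.
oracle_class_code <- function(qex, reference) {
  qex <- qex[order(qex$start), , drop = FALSE]
  q_bases <- unlist(lapply(seq_len(nrow(qex)),
                           function(i) seq(qex$start[i], qex$end[i] - 1L)))
  q_intr <- if (nrow(qex) > 1L)
    paste(qex$end[-nrow(qex)], qex$start[-1]) else character(0)
  precedence <- c("=", "c", "j", "e", "i", "o", "x", "u")
  best <- "u"; best_ref <- NA_character_
  for (rid in sort(reference$transcripts$transcript_id)) {
    rex <- reference$exons[reference$exons$transcript_id == rid, , drop = FALSE]
    if (rex$chrom[1] != qex$chrom[1]) next
    r_bases <- unlist(lapply(seq_len(nrow(rex)),
                             function(i) seq(rex$start[i], rex$end[i] - 1L)))
    r_intr <- if (nrow(rex) > 1L)
      paste(rex$end[-nrow(rex)], rex$start[-1]) else character(0)
    r_intr_bases <- unlist(lapply(which(seq_len(nrow(rex)) > 1L), function(i)
      seq(rex$end[i - 1L], rex$start[i] - 1L)))
    qs <- qex$strand[1]; rs <- rex$strand[1]
    same <- qs == rs || qs == "." || rs == "."
    anti <- (qs == "+" && rs == "-") || (qs == "-" && rs == "+")
    exonic <- length(intersect(q_bases, r_bases)) > 0L

    code <- "u"
    if (same) {
      if (exonic && length(q_intr) == length(r_intr) &&
            all(q_intr == r_intr)) {
        code <- "="
      } else if (all(q_bases %in% r_bases) && all(q_intr %in% r_intr) &&
                   min(q_bases) >= min(r_bases) && max(q_bases) <= max(r_bases)) {
        code <- "c"
      } else if (nrow(qex) > 1L && any(q_intr %in% r_intr)) {
        code <- "j"
      } else if (nrow(qex) == 1L && exonic &&
                   length(intersect(q_bases, r_intr_bases)) > 0L) {
        code <- "e"
      } else if (length(r_intr)) {
        inside_one <- FALSE
        for (k in seq_along(r_intr)) {
          b <- seq(rex$end[k], rex$start[k + 1L] - 1L)
          if (all(q_bases %in% b)) inside_one <- TRUE
        }
        if (inside_one) code <- "i" else if (exonic) code <- "o"
      } else if (exonic) {
        code <- "o"
      }
    }
    if (code == "u" && anti && exonic) code <- "x"
    if (match(code, precedence) < match(best, precedence)) {
      best <- code; best_ref <- rid
    }
  }
  if (best == "u") best_ref <- NA_character_
  list(code = best, ref_id = best_ref)
}

# random small transcript instance on coordinates < 1000
random_exons <- function(n_exons, lo = 0L, hi = 1000L, strand = NULL) {
  pts <- sort(sample(lo:hi, 2L * n_exons))
  # ensure strictly increasing half-open exons with >= 1 bp gaps
  ok <- FALSE
  while (!ok) {
    pts <- sort(sample(lo:hi, 2L * n_exons))
    s <- pts[seq(1, 2 * n_exons, 2)]
    e <- pts[seq(2, 2 * n_exons, 2)]
    ok <- all(e > s) && (n_exons == 1 || all(s[-1] > e[-n_exons]))
  }
  data.frame(start = s, end = e,
             strand = strand %||% sample(c("+", "-", "."), 1),
             stringsAsFactors = FALSE)
}

random_class_instance <- function() {
  n_ref <- sample(1:5, 1)
  refs <- do.call(rbind, lapply(seq_len(n_ref), function(k) {
    ex <- random_exons(sample(1:4, 1), strand = sample(c("+", "-"), 1))
    data.frame(transcript_id = sprintf("ref%02d", k),
               gene_id = sprintf("g%02d", k), chrom = "chr1",
               start = ex$start, end = ex$end, strand = ex$strand[1],
               stringsAsFactors = FALSE)
  }))
  qex <- random_exons(sample(1:3, 1))
  qex <- data.frame(transcript_id = "q", gene_id = "q", chrom = "chr1",
                    start = qex$start, end = qex$end, strand = qex$strand[1],
                    stringsAsFactors = FALSE)
  list(query = qex, reference = transcript_set(refs))
}

# exhaustive nucleotide-diversity oracle: mean pairwise hamming distance per
# bp over all haplotype pairs
oracle_pi <- function(hap, span) {
  n <- nrow(hap)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(hap[i, ] != hap[j, ])
  tot / choose(n, 2) / span
}
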