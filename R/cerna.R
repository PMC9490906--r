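#' Validate a miRNA binding-site table
#'
#' Checks 0-based half-open spans against transcript lengths when provided;
#' rows whose span exceeds the transcript are rejected with a message.
#'
#' @param sites data.frame with `transcript_id`, `mirna_id`, `start`, `end`,
#'   optionally `expectation` (consumed prediction score).
#' @param transcript_lengths optional named integer vector.
#' @return Validated data.frame (rejected-row count as `attr(, "n_rejected")`).
#' @export
validate_binding_sites <- function(sites, transcript_lengths = NULL) {
  stopifnot(all(c("transcript_id", "mirna_id", "start", "end") %in% names(sites)))
  bad <- sites$start < 0 | sites$start >= sites$end
  if (!is.null(transcript_lengths)) {
    len <- transcript_lengths[sites$transcript_id]
    bad <- bad | (!is.na(len) & sites$end > len)
  }
  if (any(bad)) {
    message(sprintf("validate_binding_sites: rejected %d record(s) with invalid spans",
                    sum(bad)))
    sites <- sites[!bad, , drop = FALSE]
    rownames(sites) <- NULL
  }
  attr(sites, "n_rejected") <- sum(bad)
  sites
}

#' Shared miRNAs between lncRNAs and mRNAs
#'
#' Exact miRNA-id intersection per (lncRNA, mRNA) candidate pair: one row per
#' triple for which both transcripts carry a binding site of the same miRNA.
#'
#' @param lnc_sites,mrna_sites binding-site tables (see
#'   [validate_binding_sites()]).
#' @param expectation_max keep binding rows with prediction expectation score
#'   at or below this cutoff (default 5, the conventional default of the
#'   consumed predictor); ignored when no `expectation` column is present.
#' @return data.frame `lncrna_id`, `mirna_id`, `mrna_id`, `lnc_start`,
#'   `lnc_end`, `mrna_start`, `mrna_end` (deduplicated triples; the first
#'   recorded span per triple is reported).
#' @export
shared_mirnas <- function(lnc_sites, mrna_sites, expectation_max = 5) {
  if ("expectation" %in% names(lnc_sites))
    lnc_sites <- lnc_sites[lnc_sites$expectation <= expectation_max, , drop = FALSE]
  if ("expectation" %in% names(mrna_sites))
    mrna_sites <- mrna_sites[mrna_sites$expectation <= expectation_max, , drop = FALSE]
  m <- merge(
    data.frame(lncrna_id = lnc_sites$transcript_id, mirna_id = lnc_sites$mirna_id,
               lnc_start = lnc_sites$start, lnc_end = lnc_sites$end,
               stringsAsFactors = FALSE),
    data.frame(mrna_id = mrna_sites$transcript_id, mirna_id = mrna_sites$mirna_id,
               mrna_start = mrna_sites$start, mrna_end = mrna_sites$end,
               stringsAsFactors = FALSE),
    by = "mirna_id")
  m <- m[!duplicated(m[, c("lncrna_id", "mirna_id", "mrna_id")]), , drop = FALSE]
  m <- m[order(m$lncrna_id, m$mirna_id, m$mrna_id), , drop = FALSE]
  rownames(m) <- NULL
  m[, c("lncrna_id", "mirna_id", "mrna_id",
        "lnc_start", "lnc_end", "mrna_start", "mrna_end")]
}

#' Enumerate ceRNA triangles
#'
#' Keeps the lncRNA-miRNA-mRNA triples from [shared_mirnas()] whose
#' lncRNA-mRNA Spearman correlation satisfies the configured sign,
#' `|rho| >= rho_min` and `p < alpha`. Triples with the lncRNA or mRNA absent
#' from the expression matrix are skipped with a count; miRNA expression is
#' not required (small-RNA abundances are generally not in an RNA-seq FPKM
#' matrix).
#'
#' @param shared output of [shared_mirnas()].
#' @param expr expression matrix.
#' @param rho_min absolute-correlation threshold (default 0.5, inclusive).
#' @param alpha significance level (default 0.05).
#' @param sign `"negative"` (default: lncRNA and mRNA anti-correlated),
#'   `"positive"`, or `"either"`.
#' @return data.frame of triangles with `rho` and `p_value`, attribute
#'   `n_skipped` (triples with members missing from `expr`).
#' @export
build_triangles <- function(shared, expr, rho_min = 0.5, alpha = 0.05,
                            sign = c("negative", "positive", "either")) {
  sign <- match.arg(sign)
  n_skipped <- 0L
  keep <- logical(nrow(shared))
  rho <- p <- rep(NA_real_, nrow(shared))
  for (i in seq_len(nrow(shared))) {
    l <- shared$lncrna_id[i]; g <- shared$mrna_id[i]
    if (!(l %in% rownames(expr)) || !(g %in% rownames(expr))) {
      n_skipped <- n_skipped + 1L
      next
    }
    sc <- tryCatch(spearman_cor(expr[l, ], expr[g, ]), error = function(e) NULL)
    if (is.null(sc)) next
    rho[i] <- sc$rho; p[i] <- sc$p_value
    sign_ok <- switch(sign, negative = sc$rho < 0, positive = sc$rho > 0, TRUE)
    keep[i] <- sign_ok && abs(sc$rho) >= rho_min && sc$p_value < alpha
  }
  out <- cbind(shared, rho = rho, p_value = p)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Export a ceRNA network as node/edge tables
#'
#' Typed nodes (lncRNA/miRNA/mRNA) and edges (`binds` for
#' miRNA-transcript binding, `pairs_with` for the lncRNA-mRNA co-expression
#' side), a degree table, and a miRNA hub report ranked by triangle
#' participation.
#'
#' @param triangles output of [build_triangles()].
#' @param pairs optional [build_pairs()] table; when given, lncRNA-mRNA edges
#'   present there are annotated as supported target pairs.
#' @return list with `$nodes`, `$edges`, `$degree`, `$hubs`.
#' @export
network_export <- function(triangles, pairs = NULL) {
  if (!nrow(triangles)) {
    empty <- data.frame(id = character(0), type = character(0))
    return(list(nodes = empty,
                edges = data.frame(from = character(0), to = character(0),
                                   type = character(0)),
                degree = data.frame(id = character(0), degree = integer(0)),
                hubs = data.frame(mirna_id = character(0),
                                  n_triangles = integer(0))))
  }
  nodes <- unique(rbind(
    data.frame(id = triangles$lncrna_id, type = "lncRNA", stringsAsFactors = FALSE),
    data.frame(id = triangles$mirna_id, type = "miRNA", stringsAsFactors = FALSE),
    data.frame(id = triangles$mrna_id, type = "mRNA", stringsAsFactors = FALSE)))
  edges <- unique(rbind(
    data.frame(from = triangles$mirna_id, to = triangles$lncrna_id,
               type = "binds", stringsAsFactors = FALSE),
    data.frame(from = triangles$mirna_id, to = triangles$mrna_id,
               type = "binds", stringsAsFactors = FALSE),
    data.frame(from = triangles$lncrna_id, to = triangles$mrna_id,
               type = "pairs_with", stringsAsFactors = FALSE)))
  if (!is.null(pairs) && nrow(pairs)) {
    supported <- paste(triangles$lncrna_id, triangles$mrna_id) %in%
      paste(pairs$lncrna_id, pairs$mrna_id)
    edges$supported_pair <- with(edges, ifelse(
      type == "pairs_with",
      paste(from, to) %in% paste(pairs$lncrna_id, pairs$mrna_id), NA))
  }
  deg <- table(c(edges$from, edges$to))
  degree <- data.frame(id = names(deg), degree = as.integer(deg),
                       stringsAsFactors = FALSE)
  degree <- degree[order(-degree$degree, degree$id), ]
  rownames(degree) <- NULL
  hub <- table(triangles$mirna_id)
  hubs <- data.frame(mirna_id = names(hub), n_triangles = as.integer(hub),
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$n_triangles, hubs$mirna_id), ]
  rownames(hubs) <- NULL
  list(nodes = nodes, edges = edges, degree = degree, hubs = hubs)
}
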