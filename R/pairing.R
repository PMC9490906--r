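#' Spearman rank correlation with large-sample p-value
#'
#' Rho is Pearson correlation on mid-ranks (average ranks for ties); the
#' p-value comes from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`
#' on `n - 2` degrees of freedom, two-sided. With no ties this reproduces the
#' classical rank-difference formula `1 - 6*sum(d^2)/(n*(n^2-1))`.
#'
#' @param x,y numeric vectors of equal length `n >= 5`.
#' @return list with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 5L) stopf("need n >= 5 observations")
  if (anyNA(x) || anyNA(y)) stopf("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) stopf("undefined correlation: constant vector")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Distance between a lncRNA and a gene
#'
#' Nearest-edge gap in bp: 0 when the intervals overlap, `Inf` across
#' chromosomes (always a trans relationship). Vectorised wrapper around
#' [interval_gap()] for transcript-table rows.
#'
#' @param lnc,gene single rows (or equal-length tables) with `chrom`,
#'   `start`, `end`.
#' @return numeric distance(s) in bp.
#' @export
pair_distance <- function(lnc, gene) {
  interval_gap(lnc$chrom, lnc$start, lnc$end, gene$chrom, gene$start, gene$end)
}

#' Build cis/trans lncRNA-mRNA target pairs
#'
#' Cis candidates are genes within `cis_window` bp (nearest-edge) of a
#' lncRNA; each lncRNA is assigned at most its single nearest gene in cis
#' (ties broken by distance, then lexicographic gene id). Trans candidates
#' are the entries of the pairing free-energy table lying beyond the window
#' or on another chromosome, kept when `energy <= ndg_max`. Every emitted
#' pair must satisfy `|rho| > rho_min` and `p < alpha` on Spearman
#' co-expression. Features absent from the expression matrix are skipped with
#' a warning; trans table entries within the cis window are ignored (they are
#' cis territory).
#'
#' @param candidates candidate lncRNA table (needs `transcript_id`, `chrom`,
#'   `start`, `end`) or a `transcript_set`.
#' @param mrnas protein-coding `transcript_set` (gene models).
#' @param expr expression matrix covering both feature sets.
#' @param energy_table data.frame `lncrna_id`, `mrna_id`, `energy`
#'   (normalised pairing free energy, consumed scale), or `NULL` for no trans
#'   pairing.
#' @param rho_min strict absolute-correlation threshold (default 0.9).
#' @param alpha per-pair significance level (default 0.05); when
#'   `fdr = TRUE`, applied to Benjamini-Hochberg adjusted p-values instead.
#' @param cis_window cis distance threshold in bp (default 100 kb).
#' @param ndg_max free-energy cutoff, pairs kept at `energy <= ndg_max`
#'   (default -0.1).
#' @param energy_on_cis also require an energy-table pass for cis pairs
#'   (default `FALSE`: the energy filter applies to trans only).
#' @param fdr apply BH adjustment across all tested pairs (default `FALSE`,
#'   matching a plain per-pair p < alpha rule).
#' @return data.frame of pairs (`lncrna_id`, `mrna_id`, `mode`, `distance`,
#'   `rho`, `p_value`, `energy`) with an attribute `counts` (candidates
#'   tested, skipped for missing expression, trans rows lacking energy).
#' @export
build_pairs <- function(candidates, mrnas, expr, energy_table = NULL,
                        rho_min = 0.9, alpha = 0.05, cis_window = 100000,
                        ndg_max = -0.1, energy_on_cis = FALSE, fdr = FALSE) {
  ltab <- if (inherits(candidates, "transcript_set")) candidates$transcripts else candidates
  if (!"transcript_id" %in% names(ltab)) stopf("candidates need a transcript_id column")
  gtab <- mrnas$transcripts
  counts <- c(cis_candidates = 0L, trans_candidates = 0L, missing_expr = 0L,
              trans_no_energy = 0L)

  energy_of <- function(l, g) {
    if (is.null(energy_table)) return(NA_real_)
    hit <- energy_table$energy[energy_table$lncrna_id == l &
                                 energy_table$mrna_id == g]
    if (length(hit)) hit[1] else NA_real_
  }

  rows <- list()
  test_pair <- function(l, g, mode, dist, energy) {
    if (!(l %in% rownames(expr)) || !(g %in% rownames(expr))) {
      counts["missing_expr"] <<- counts["missing_expr"] + 1L
      warnf("build_pairs: feature missing from expression matrix (%s / %s)", l, g)
      return(NULL)
    }
    sc <- tryCatch(spearman_cor(expr[l, ], expr[g, ]), error = function(e) NULL)
    if (is.null(sc)) return(NULL)
    data.frame(lncrna_id = l, mrna_id = g, mode = mode, distance = dist,
               rho = sc$rho, p_value = sc$p_value, energy = energy,
               stringsAsFactors = FALSE)
  }

  # cis: one nearest gene per lncRNA within the window
  for (i in seq_len(nrow(ltab))) {
    same <- gtab[gtab$chrom == ltab$chrom[i], , drop = FALSE]
    if (!nrow(same)) next
    d <- interval_gap(ltab$chrom[i], ltab$start[i], ltab$end[i],
                      same$chrom, same$start, same$end)
    inwin <- which(d <= cis_window)
    if (!length(inwin)) next
    counts["cis_candidates"] <- counts["cis_candidates"] + 1L
    ord <- inwin[order(d[inwin], same$gene_id[inwin])]
    pick <- ord[1]
    en <- energy_of(ltab$transcript_id[i], same$transcript_id[pick])
    if (energy_on_cis && (is.na(en) || en > ndg_max)) next
    rows[[length(rows) + 1L]] <- test_pair(
      ltab$transcript_id[i], same$transcript_id[pick], "cis", d[pick], en)
  }

  # trans: energy-table entries beyond the window
  if (!is.null(energy_table)) {
    for (k in seq_len(nrow(energy_table))) {
      l <- energy_table$lncrna_id[k]; g <- energy_table$mrna_id[k]
      li <- match(l, ltab$transcript_id)
      gi <- match(g, gtab$transcript_id)
      if (is.na(li) || is.na(gi)) next
      d <- interval_gap(ltab$chrom[li], ltab$start[li], ltab$end[li],
                        gtab$chrom[gi], gtab$start[gi], gtab$end[gi])
      if (d <= cis_window) next
      counts["trans_candidates"] <- counts["trans_candidates"] + 1L
      en <- energy_table$energy[k]
      if (is.na(en)) {
        counts["trans_no_energy"] <- counts["trans_no_energy"] + 1L
        next
      }
      if (en > ndg_max) next
      rows[[length(rows) + 1L]] <- test_pair(l, g, "trans", d, en)
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncrna_id = character(0), mrna_id = character(0),
               mode = character(0), distance = numeric(0), rho = numeric(0),
               p_value = numeric(0), energy = numeric(0))
  if (nrow(out)) {
    p_use <- if (fdr) p.adjust(out$p_value, "BH") else out$p_value
    keep <- abs(out$rho) > rho_min & p_use < alpha
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "counts") <- counts
  out
}
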