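#' Per-SNP association scan with principal-component structure correction
#'
#' For each SNP passing the MAF filter, fits the linear model
#' `phenotype ~ dosage + PC1..PCk` (k = `n_pcs` genotype principal
#' components) and reports the per-allele slope, t statistic and two-sided
#' p-value. The significance threshold is `1/Ne`, where `Ne` is the
#' effective number of independent tests (the post-filter SNP count unless
#' supplied), applied as a strict less-than.
#'
#' @param geno SNP x sample dosage matrix (0/1/2), rownames = SNP ids.
#' @param pheno named numeric phenotype vector; sample overlap with `geno`
#'   must be >= 30.
#' @param positions optional data.frame (`snp_id`, `chrom`, `pos`) carried
#'   through to the output.
#' @param n_pcs number of genotype PCs as covariates (default 3).
#' @param maf minor-allele-frequency filter (default 0.05); monomorphic SNPs
#'   are always skipped.
#' @param ne effective test count; default = number of SNPs tested.
#' @return data.frame (`snp_id`, `chrom`, `pos`, `effect`, `se`, `t`,
#'   `p_value`, `passes_threshold`) with attributes `ne`, `threshold`,
#'   `n_samples`.
#' @export
gwas_scan <- function(geno, pheno, positions = NULL, n_pcs = 3, maf = 0.05,
                      ne = NULL) {
  common <- intersect(colnames(geno), names(pheno))
  if (length(common) < 30L) stopf("need >= 30 samples shared by genotypes and phenotype")
  g <- geno[, common, drop = FALSE]
  y <- pheno[common]
  if (anyNA(y)) {
    keep <- !is.na(y)
    g <- g[, keep, drop = FALSE]; y <- y[keep]
  }
  if (var(y) == 0) stopf("phenotype has zero variance")
  n <- length(y)

  p_alt <- rowMeans(g, na.rm = TRUE) / 2
  maf_v <- pmin(p_alt, 1 - p_alt)
  keep_snp <- maf_v >= maf & maf_v > 0
  g <- g[keep_snp, , drop = FALSE]
  if (!nrow(g)) stopf("no SNPs pass the MAF filter")

  n_pcs <- min(n_pcs, n - 3L)
  X <- matrix(1, n, 1)
  if (n_pcs > 0) {
    gs <- scale(t(g))
    gs[is.na(gs)] <- 0
    pcs <- prcomp(gs, center = FALSE, scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
    X <- cbind(X, pcs)
  }
  # residualize phenotype and dosages on the covariates, then per-SNP OLS
  Q <- qr.Q(qr(X))
  ry <- y - Q %*% (t(Q) %*% y)
  gm <- g
  gm[is.na(gm)] <- rowMeans(g, na.rm = TRUE)[which(is.na(g), arr.ind = TRUE)[, 1]]
  rg <- t(gm) - Q %*% (t(Q) %*% t(gm))

  ss_g <- colSums(rg^2)
  xy <- as.numeric(t(rg) %*% ry)
  slope <- xy / ss_g
  df <- n - ncol(X) - 1L
  rss <- sum(ry^2) - slope^2 * ss_g
  rss[rss < 0] <- 0
  se <- sqrt((rss / df) / ss_g)
  tstat <- slope / se
  pval <- 2 * pt(-abs(tstat), df = df)

  ne <- ne %||% nrow(g)
  threshold <- 1 / ne
  out <- data.frame(snp_id = rownames(g), effect = slope, se = se, t = tstat,
                    p_value = pval, passes_threshold = pval < threshold,
                    stringsAsFactors = FALSE)
  if (!is.null(positions)) {
    i <- match(out$snp_id, positions$snp_id)
    out$chrom <- positions$chrom[i]
    out$pos <- positions$pos[i]
    out <- out[, c("snp_id", "chrom", "pos", "effect", "se", "t", "p_value",
                   "passes_threshold")]
  }
  rownames(out) <- NULL
  attr(out, "ne") <- ne
  attr(out, "threshold") <- threshold
  attr(out, "n_samples") <- n
  out
}

#' Linkage disequilibrium r-squared between two dosage vectors
#'
#' Composite (genotype-based) LD: squared Pearson correlation of allele
#' dosages.
#'
#' @param dosage_a,dosage_b numeric dosage vectors.
#' @return r-squared in \[0, 1\], or `NA` if either vector is constant.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' LD decay with distance
#'
#' Mean pairwise r-squared in distance bins up to `max_dist`, plus the
#' distance at which mean r-squared first drops below `r2_threshold` (the
#' window-setting convention for candidate-gene assignment).
#'
#' @param geno SNP x sample dosage matrix.
#' @param positions data.frame `snp_id`, `chrom`, `pos` for the rows of
#'   `geno`.
#' @param max_dist maximum pairwise distance considered (bp).
#' @param bin_size distance bin width (bp).
#' @param r2_threshold decay threshold (default 0.2).
#' @return list with `$bins` (`mid`, `mean_r2`, `n_pairs`) and
#'   `$decay_distance` (first bin midpoint with mean r2 < threshold, `NA` if
#'   never reached).
#' @export
ld_decay <- function(geno, positions, max_dist = 10e6, bin_size = 1e6,
                     r2_threshold = 0.2) {
  i <- match(rownames(geno), positions$snp_id)
  chrom <- positions$chrom[i]; pos <- positions$pos[i]
  dists <- numeric(0); r2s <- numeric(0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < 2L) next
    cm <- suppressWarnings(cor(t(geno[idx, , drop = FALSE])))^2
    dm <- abs(outer(pos[idx], pos[idx], `-`))
    ut <- upper.tri(dm)
    sel <- ut & dm <= max_dist & !is.na(cm)
    dists <- c(dists, dm[sel]); r2s <- c(r2s, cm[sel])
  }
  if (!length(dists)) stopf("no SNP pairs within max_dist")
  bin <- pmin(floor(dists / bin_size), ceiling(max_dist / bin_size) - 1)
  agg <- aggregate(list(mean_r2 = r2s), by = list(bin = bin), FUN = mean)
  np <- as.integer(table(bin)[as.character(agg$bin)])
  bins <- data.frame(mid = (agg$bin + 0.5) * bin_size, mean_r2 = agg$mean_r2,
                     n_pairs = np)
  below <- which(bins$mean_r2 < r2_threshold)
  list(bins = bins,
       decay_distance = if (length(below)) bins$mid[min(below)] else NA_real_)
}

#' Assign features to trait-associated SNPs
#'
#' Every feature whose interval comes within `window` bp (nearest-edge) of a
#' threshold-passing SNP is assigned to that hit. Output order is canonical
#' (by trait, SNP, feature), so feature input order is irrelevant.
#'
#' @param hits [gwas_scan()] output with `chrom`/`pos` columns (plus
#'   optionally `trait`).
#' @param features data.frame with a feature id column and `chrom`, `start`,
#'   `end`.
#' @param window assignment window in bp (default 5 Mb).
#' @return data.frame `feature_id`, `snp_id`, `trait`, `distance`, `p_value`.
#' @export
assign_candidates <- function(hits, features, window = 5e6) {
  idcol <- intersect(c("feature_id", "transcript_id", "name"), names(features))[1]
  if (is.na(idcol)) stopf("features need an id column")
  hits <- hits[hits$passes_threshold, , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(hits))) {
    d <- interval_gap(features$chrom, features$start, features$end,
                      hits$chrom[k], hits$pos[k], hits$pos[k] + 1L)
    sel <- which(d <= window)
    if (!length(sel)) next
    rows[[k]] <- data.frame(
      feature_id = features[[idcol]][sel], snp_id = hits$snp_id[k],
      trait = if ("trait" %in% names(hits)) hits$trait[k] else NA_character_,
      distance = d[sel], p_value = hits$p_value[k], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(0), snp_id = character(0),
               trait = character(0), distance = numeric(0),
               p_value = numeric(0))
  out <- out[order(out$trait, out$snp_id, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-localization of features with interval sets
#'
#' Any-base intersection between half-open feature intervals and QTL or
#' introgression intervals; an interval whose start equals a feature's end
#' does not overlap.
#'
#' @param features data.frame with feature id column, `chrom`, `start`,
#'   `end`.
#' @param intervals data.frame (e.g. from [read_bed()]) with `chrom`,
#'   `start`, `end`, `name`.
#' @return data.frame `feature_id`, `interval_name`, `overlap_bp`.
#' @export
colocalize <- function(features, intervals) {
  idcol <- intersect(c("feature_id", "transcript_id", "name"), names(features))[1]
  if (is.na(idcol)) stopf("features need an id column")
  rows <- list()
  for (k in seq_len(nrow(intervals))) {
    same <- features$chrom == intervals$chrom[k]
    ov <- same & intervals_overlap(features$start, features$end,
                                   intervals$start[k], intervals$end[k])
    if (!any(ov)) next
    rows[[k]] <- data.frame(
      feature_id = features[[idcol]][ov],
      interval_name = intervals$name[k],
      overlap_bp = pmin(features$end[ov], intervals$end[k]) -
        pmax(features$start[ov], intervals$start[k]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(0), interval_name = character(0),
               overlap_bp = integer(0))
  rownames(out) <- NULL
  out
}

#' Fisher's exact test (two-sided) for a 2x2 enrichment table
#'
#' Exact hypergeometric enumeration: with row margins fixed, the two-sided
#' p-value is the sum of probabilities of all tables whose probability does
#' not exceed the observed table's (with a relative tolerance of 1e-7
#' guarding floating-point comparison, as is conventional).
#'
#' @param a,b,c,d the 2x2 cell counts (`a` = in both sets, rows = set 1
#'   membership, columns = set 2 membership).
#' @return Two-sided p-value.
#' @export
fisher_enrichment <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stopf("negative cell count")
  if (a + b + c + d == 0) stopf("all-zero 2x2 table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
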