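# per-site unbiased diversity and allele counts for a sample subset;
# returns data.frame aligned with panel$sites
site_pi_components <- function(panel, samples, min_alleles = 4L) {
  g <- panel$geno[, samples, drop = FALSE]
  n <- 2L * rowSums(!is.na(g))
  ac <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n > 0L, ac / n, NA_real_)
  pi <- ifelse(n >= 2L, (n / (n - 1)) * 2 * p * (1 - p), NA_real_)
  usable <- n >= min_alleles
  data.frame(n_alleles = n, alt_count = ac, p = p, pi = pi, usable = usable)
}

group_samples <- function(panel, group) {
  s <- panel$samples[panel$groups == group]
  if (!length(s)) stopf("unknown group: %s", group)
  s
}

# 50 kb (or window_size) tiling over the chromosome extents seen in the panel
tile_windows <- function(panel, window_size) {
  out <- lapply(split(panel$sites$pos, panel$sites$chrom), function(pos) {
    hi <- max(pos) + 1L
    starts <- seq(0L, hi - 1L, by = window_size)
    data.frame(start = starts, end = pmin(starts + window_size, as.integer(hi)))
  })
  chrom <- rep(names(out), vapply(out, nrow, integer(1)))
  out <- do.call(rbind, out)
  data.frame(chrom = chrom, start = out$start,
             end = out$end,
             name = sprintf("%s:%d-%d", chrom, out$start, out$end),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site diversity uses the unbiased estimator
#' `pi_site = n/(n-1) * 2*p*(1-p)` with `n` the number of non-missing allele
#' copies in the group at that site; windowed pi is the sum of per-site
#' values divided by the full window span in bp (the VCFtools
#' `--window-pi` convention). Sites with fewer than `min_alleles` non-missing
#' copies in the group are skipped.
#'
#' @param panel a [variant_panel()].
#' @param groups group labels to evaluate (default: all groups in the panel).
#' @param windows either `NULL` (tile the genome with `window_size` windows)
#'   or a data.frame of feature intervals (`chrom`, `start`, `end`,
#'   optionally `name`).
#' @param window_size tiling window span in bp (default 50 kb).
#' @param min_alleles minimum non-missing allele copies per used site
#'   (default 4).
#' @return data.frame with `scope`, `chrom`, `start`, `end`, `group`, `pi`,
#'   `n_sites`, `n_chromosomes` (mean non-missing allele count over used
#'   sites). Windows with no usable site report `pi = 0` and `n_sites = 0`.
#' @export
nucleotide_diversity <- function(panel, groups = NULL, windows = NULL,
                                 window_size = 50000, min_alleles = 4L) {
  stopifnot(inherits(panel, "variant_panel"))
  groups <- groups %||% sort(unique(panel$groups))
  if (is.null(windows)) windows <- tile_windows(panel, window_size)
  if (is.null(windows$name))
    windows$name <- sprintf("%s:%d-%d", windows$chrom, windows$start, windows$end)

  out <- list()
  for (grp in groups) {
    s <- group_samples(panel, grp)
    if (length(s) < 2L) stopf("group %s has fewer than 2 samples", grp)
    comp <- site_pi_components(panel, s, min_alleles)
    for (w in seq_len(nrow(windows))) {
      idx <- which(panel$sites$chrom == windows$chrom[w] &
                     panel$sites$pos >= windows$start[w] &
                     panel$sites$pos < windows$end[w] & comp$usable)
      span <- windows$end[w] - windows$start[w]
      out[[length(out) + 1L]] <- data.frame(
        scope = windows$name[w], chrom = windows$chrom[w],
        start = windows$start[w], end = windows$end[w], group = grp,
        pi = if (length(idx)) sum(comp$pi[idx]) / span else 0,
        n_sites = length(idx),
        n_chromosomes = if (length(idx)) mean(comp$n_alleles[idx]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pairwise Weir-Cockerham Fst between two groups
#'
#' Two-population Weir & Cockerham (1984) estimator from genotype data
#' (variance components a, b, c including observed heterozygosity),
#' aggregated as a ratio of sums across sites (`sum(a) / sum(a+b+c)`, the
#' "weighted" Fst of VCFtools). Sites monomorphic across both groups, or
#' with fewer than 2 genotyped individuals in either group, are excluded.
#' Small negative estimates are preserved and flagged; values below -0.05
#' are clamped.
#'
#' @param panel a [variant_panel()].
#' @param group_a,group_b group labels (each with >= 2 samples).
#' @return list with `group_a`, `group_b`, `fst` (ratio of sums),
#'   `fst_site_mean` (mean of per-site ratios), `n_sites`, `negative` flag.
#' @export
pairwise_fst <- function(panel, group_a, group_b) {
  stopifnot(inherits(panel, "variant_panel"))
  sa <- group_samples(panel, group_a)
  sb <- group_samples(panel, group_b)
  if (length(sa) < 2L || length(sb) < 2L) stopf("both groups need >= 2 samples")

  ga <- panel$geno[, sa, drop = FALSE]
  gb <- panel$geno[, sb, drop = FALSE]
  n1 <- rowSums(!is.na(ga)); n2 <- rowSums(!is.na(gb))
  p1 <- rowSums(ga, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(gb, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(ga == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(gb == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  usable <- n1 >= 2 & n2 >= 2 & pbar > 0 & pbar < 1
  if (!any(usable)) stopf("no usable (polymorphic) sites between %s and %s",
                          group_a, group_b)
  a <- a[usable]; b <- b[usable]; cc <- cc[usable]
  fst <- sum(a) / sum(a + b + cc)
  per_site <- a / (a + b + cc)
  negative <- fst < 0
  if (fst < -0.05) fst <- -0.05
  list(group_a = group_a, group_b = group_b, fst = fst,
       fst_site_mean = mean(per_site[is.finite(per_site)]),
       n_sites = sum(usable), negative = negative)
}

#' SNP density per feature
#'
#' Number of panel sites inside each (half-open) feature interval per kb of
#' feature span.
#'
#' @param panel a [variant_panel()].
#' @param features data.frame with `chrom`, `start`, `end` and a feature id
#'   column (`feature_id` or `transcript_id`).
#' @return data.frame `feature_id`, `n_snps`, `span_bp`, `snps_per_kb`.
#' @export
snp_density <- function(panel, features) {
  idcol <- intersect(c("feature_id", "transcript_id", "name"), names(features))[1]
  if (is.na(idcol)) stopf("features need an id column")
  n <- vapply(seq_len(nrow(features)), function(i) {
    sum(panel$sites$chrom == features$chrom[i] &
          panel$sites$pos >= features$start[i] &
          panel$sites$pos < features$end[i])
  }, numeric(1))
  span <- features$end - features$start
  data.frame(feature_id = features[[idcol]], n_snps = as.integer(n),
             span_bp = span, snps_per_kb = n / (span / 1000),
             stringsAsFactors = FALSE)
}

#' Haplotype table for one feature
#'
#' Builds per-chromosome-copy haplotype strings over the feature's SNP sites
#' in positional order, using nucleotide letters (REF/ALT). Only phased or
#' fully homozygous samples contribute; samples with any unphased
#' heterozygote or missing call across the feature's sites are excluded with
#' a count (no statistical phasing is attempted). Within each group, the
#' major haplotype is the one with frequency strictly greater than 50%, if
#' any.
#'
#' @param panel a [variant_panel()].
#' @param feature list/row with `chrom`, `start`, `end` (0-based half-open).
#' @param groups group labels (default: all).
#' @return list of class `haplotype_table`: `$sites` (site table used),
#'   `$by_group` (data.frame `group`, `haplotype`, `count`, `frequency`,
#'   `major`), `$excluded` (named count of excluded samples per group).
#' @export
haplotypes <- function(panel, feature, groups = NULL) {
  stopifnot(inherits(panel, "variant_panel"))
  groups <- groups %||% sort(unique(panel$groups))
  idx <- which(panel$sites$chrom == feature$chrom &
                 panel$sites$pos >= feature$start &
                 panel$sites$pos < feature$end)
  if (!length(idx)) stopf("no panel sites inside the feature")
  idx <- idx[order(panel$sites$pos[idx])]
  ref <- panel$sites$ref[idx]; alt <- panel$sites$alt[idx]

  rows <- list(); excluded <- setNames(integer(length(groups)), groups)
  for (grp in groups) {
    s <- group_samples(panel, grp)
    h1 <- panel$hap1[idx, s, drop = FALSE]
    h2 <- panel$hap2[idx, s, drop = FALSE]
    ok <- colSums(is.na(h1)) == 0L & colSums(is.na(h2)) == 0L
    excluded[grp] <- sum(!ok)
    if (!any(ok)) next
    string_of <- function(col) paste(ifelse(col == 1L, alt, ref), collapse = "")
    haps <- c(apply(h1[, ok, drop = FALSE], 2L, string_of),
              apply(h2[, ok, drop = FALSE], 2L, string_of))
    tab <- sort(table(haps), decreasing = TRUE)
    freq <- as.numeric(tab) / sum(tab)
    rows[[grp]] <- data.frame(group = grp, haplotype = names(tab),
                              count = as.integer(tab), frequency = freq,
                              major = freq > 0.5, stringsAsFactors = FALSE)
  }
  by_group <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), haplotype = character(0),
               count = integer(0), frequency = numeric(0), major = logical(0))
  rownames(by_group) <- NULL
  structure(list(sites = panel$sites[idx, , drop = FALSE],
                 by_group = by_group, excluded = excluded),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table over %d site(s)\n", nrow(x$sites)))
  print(x$by_group)
  invisible(x)
}

#' Diversity shifts along lineage edges
#'
#' For each parent -> child transition of a configured lineage (e.g. wild ->
#' domesticated -> improved), reports the sign of the diversity change, the
#' pi ratio, and a bottleneck flag (`ratio < 1`).
#'
#' @param pi_by_group named numeric vector of group-level pi.
#' @param lineage_edges data.frame with `parent`, `child` group labels.
#' @return data.frame `parent`, `child`, `pi_parent`, `pi_child`, `sign`
#'   (-1/0/+1), `ratio`, `bottleneck`.
#' @export
diversity_shift <- function(pi_by_group, lineage_edges) {
  need <- unique(c(lineage_edges$parent, lineage_edges$child))
  miss <- setdiff(need, names(pi_by_group))
  if (length(miss)) stopf("missing group(s) in pi vector: %s",
                          paste(miss, collapse = ", "))
  pp <- pi_by_group[lineage_edges$parent]
  pc <- pi_by_group[lineage_edges$child]
  data.frame(parent = lineage_edges$parent, child = lineage_edges$child,
             pi_parent = as.numeric(pp), pi_child = as.numeric(pc),
             sign = sign(pc - pp), ratio = as.numeric(pc / pp),
             bottleneck = as.numeric(pc / pp) < 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default nine-group lineage edges
#'
#' The domestication/improvement transitions of the diploid (A), tetraploid
#' (AB) and hexaploid (ABD) wheat lineages: wild einkorn -> domesticated
#' einkorn; wild emmer -> domesticated emmer -> durum; bread-wheat landrace
#' -> cultivar.
#'
#' @return data.frame with `parent`, `child`.
#' @export
default_lineage_edges <- function() {
  data.frame(parent = c("A1", "AB1", "AB2", "ABD1"),
             child = c("A2", "AB2", "AB3", "ABD2"),
             stringsAsFactors = FALSE)
}
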