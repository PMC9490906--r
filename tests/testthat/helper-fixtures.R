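# quick transcript-set builder: ex = list(c(start, end), ...)
make_tx <- function(id, ex, chrom = "chr1", strand = "+", gene = NULL) {
  data.frame(transcript_id = id, gene_id = gene %||% id, chrom = chrom,
             start = vapply(ex, `[`, numeric(1), 1),
             end = vapply(ex, `[`, numeric(1), 2),
             strand = strand, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_ts <- function(...) transcript_set(do.call(rbind, list(...)))

# panel from an explicit dosage matrix (sites x samples)
make_panel <- function(geno, groups, chrom = "chr1",
                       pos = seq_len(nrow(geno)) * 10L,
                       ref = "A", alt = "G", hap1 = NULL, hap2 = NULL,
                       phased = NULL) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("s%02d", seq_len(ncol(geno)))
  if (is.null(names(groups))) names(groups) <- colnames(geno)
  variant_panel(
    sites = data.frame(chrom = chrom, pos = pos,
                       ref = rep_len(ref, nrow(geno)),
                       alt = rep_len(alt, nrow(geno))),
    geno = geno, groups = groups, hap1 = hap1, hap2 = hap2, phased = phased)
}

# panel built from a haplotype matrix (2n haplotypes x sites of 0/1),
# fully phased
panel_from_haplotypes <- function(hap, groups = NULL, span = NULL) {
  stopifnot(nrow(hap) %% 2 == 0)
  n <- nrow(hap) / 2
  h1 <- t(hap[seq_len(n), , drop = FALSE])
  h2 <- t(hap[n + seq_len(n), , drop = FALSE])
  colnames(h1) <- colnames(h2) <- sprintf("s%02d", seq_len(n))
  groups <- groups %||% setNames(rep("G", n), colnames(h1))
  make_panel(h1 + h2, groups, pos = seq_len(ncol(hap)),
             hap1 = h1, hap2 = h2,
             phased = matrix(TRUE, ncol(hap), n))
}

# scaled-down simulation for structural tests
small_config <- function(seed = 11, ...) {
  simulation_config(seed = seed, n_genes = 40, n_lncrnas = 30,
                    n_planted_cis = 5, n_planted_trans = 3,
                    n_planted_triangles = 3,
                    planted_class_codes = c(i = 1, j = 1, o = 1),
                    n_background_snps = 600, n_array_snps = 400, ...)
}
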