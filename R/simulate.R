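#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' statistical structure of a population-transcriptome lncRNA study of the
#' wheat spike: 186 expression samples; a nine-group Triticum/Aegilops
#' diversity panel of 261 accessions; lncRNAs shorter and mostly single-exon
#' versus longer multi-exon mRNAs; planted cis/trans co-expression pairs,
#' ceRNA triangles, group diversity targets halving along the
#' domestication/improvement lineage edges, a planted major-haplotype
#' pattern, and one planted causal SNP per phenotype.
#'
#' @param seed integer RNG seed. Each generator stage draws from its own
#'   stream derived from `seed` plus a fixed stage offset, so stages are
#'   reproducible independently.
#' @param n_samples_expr number of expression samples (default 186).
#' @param n_genes,n_lncrnas feature counts.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param group_sizes named accession counts for the nine panel groups
#'   (defaults sum to 261).
#' @param group_diversity named per-bp nucleotide-diversity targets; defaults
#'   halve along each lineage edge (bottleneck).
#' @param lineage_edges parent/child group transitions
#'   (default [default_lineage_edges()]).
#' @param fraction_single_exon fraction of single-exon lncRNAs (default
#'   0.892).
#' @param n_planted_cis,rho_cis number and Spearman target of planted cis
#'   pairs.
#' @param n_planted_trans,rho_trans same for trans pairs (both pair classes
#'   are planted at the same strength: the emission rule is identical).
#' @param n_planted_triangles,rho_triangle ceRNA triangles and their
#'   (negative) lncRNA-mRNA correlation.
#' @param planted_class_codes named counts of lncRNAs planted with class
#'   codes `i`, `j`, `o` (all other lncRNAs are intergenic, `u`).
#' @param fraction_silent fraction of unplanted lncRNAs emitted at
#'   near-zero abundance (exercises the expression filter).
#' @param n_mirnas number of miRNA identifiers.
#' @param site_spacing SNP spacing inside features (bp).
#' @param n_background_snps genome-wide background SNPs.
#' @param n_pheno_samples genotyped/phenotyped accessions for association
#'   (default 93).
#' @param causal_snps data.frame `trait`, `effect`, `h2` (one planted causal
#'   SNP per phenotype).
#' @param n_array_snps array SNP count.
#' @param haplotype_major_freq named per-group frequencies of the planted
#'   major haplotype at the designated feature.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_samples_expr = 186,
                              n_genes = 120,
                              n_lncrnas = 90,
                              chrom_lengths = c(chr1A = 4e7, chr2B = 4e7,
                                                chr3D = 4e7),
                              group_sizes = c(A1 = 31, A2 = 31, A3 = 29,
                                              AB1 = 28, AB2 = 29, AB3 = 13,
                                              ABD1 = 45, ABD2 = 25, D1 = 30),
                              group_diversity = c(A1 = 1e-3, A2 = 5e-4,
                                                  A3 = 8e-4, AB1 = 1e-3,
                                                  AB2 = 5e-4, AB3 = 2.5e-4,
                                                  ABD1 = 4e-4, ABD2 = 2e-4,
                                                  D1 = 6e-4),
                              lineage_edges = default_lineage_edges(),
                              fraction_single_exon = 0.892,
                              n_planted_cis = 15, rho_cis = 0.95,
                              n_planted_trans = 8, rho_trans = 0.95,
                              n_planted_triangles = 6, rho_triangle = -0.8,
                              planted_class_codes = c(i = 3, j = 3, o = 3),
                              fraction_silent = 0.05,
                              n_mirnas = 20,
                              site_spacing = 150,
                              n_background_snps = 2400,
                              n_pheno_samples = 93,
                              causal_snps = data.frame(
                                trait = c("HD", "SL"), effect = 1, h2 = 0.5,
                                stringsAsFactors = FALSE),
                              n_array_snps = 1200,
                              haplotype_major_freq = c(AB3 = 0.77,
                                                       ABD1 = 0.93,
                                                       ABD2 = 1.0)) {
  cfg <- as.list(environment())
  if (abs(max(cfg$rho_cis, cfg$rho_trans, abs(cfg$rho_triangle))) > 0.999)
    stopf("|target rho| > 0.999: rank correlation saturates")
  if (any(cfg$causal_snps$h2 <= 0 | cfg$causal_snps$h2 >= 1))
    stopf("heritability must lie in (0, 1)")
  if (any(cfg$group_diversity > 0.5))
    stopf("per-site diversity cannot exceed 0.5")
  needed <- cfg$n_planted_cis + cfg$n_planted_trans +
    cfg$n_planted_triangles + sum(cfg$planted_class_codes)
  if (needed > cfg$n_lncrnas)
    stopf("n_lncrnas (%d) too small for the planted roles (%d)",
          cfg$n_lncrnas, needed)
  structure(cfg, class = "simulation_config")
}

# latent Pearson correlation yielding a target Spearman under a Gaussian
# copula: rho_s = (6/pi) asin(rho/2)  =>  rho = 2 sin(pi rho_s / 6)
latent_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate reference and assembled annotation
#'
#' Generates mRNA gene models (spliced length centred near 3,953 bp,
#' multi-exon) and lncRNA candidates (centred near 1,584 bp, ~89%
#' single-exon) on a small multi-chromosome genome. Planted cis lncRNAs are
#' placed within 100 kb of their partner gene with that gene as nearest
#' neighbour; trans partners sit on other chromosomes; class-planted lncRNAs
#' are constructed so that [assign_class_code()] returns the requested code
#' (`i`: inside a widened host intron; `j`: sharing one host intron exactly
#' while escaping containment; `o`: same-strand terminal-exon overlap); all
#' remaining lncRNAs are intergenic (`u`), placed beyond 100 kb of any gene.
#'
#' @param config a [simulation_config()].
#' @return list with `reference` / `assembly` ([transcript_set()]s),
#'   `sequences` (DNAStringSet), `coding_calls` (CPC/LGC/Pfam-style
#'   consensus table), and `truth` (per-lncRNA roles and partners).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 101L)
  chroms <- names(config$chrom_lengths)

  n_tri <- config$n_planted_triangles
  roles <- c(rep("cis", config$n_planted_cis),
             rep("trans", config$n_planted_trans),
             rep("triangle", n_tri),
             rep(names(config$planted_class_codes),
                 config$planted_class_codes))
  roles <- c(roles, rep("u", config$n_lncrnas - length(roles)))
  n_lnc <- config$n_lncrnas

  lnc_len <- pmax(210L, as.integer(round(stats::rlnorm(n_lnc, log(1584), 0.5))))
  lnc_len[roles == "triangle"] <- pmax(lnc_len[roles == "triangle"], 450L)
  # deterministic single-exon quota; class-j plants are 2-exon by
  # construction and count against the multi-exon share
  n_multi <- round((1 - config$fraction_single_exon) * n_lnc)
  extra_multi <- max(0L, n_multi - sum(roles == "j"))
  eligible <- which(roles %in% c("u", "trans", "triangle"))
  single <- rep(TRUE, n_lnc)
  if (extra_multi > 0L && length(eligible))
    single[sample(eligible, min(extra_multi, length(eligible)))] <- FALSE
  single[roles == "j"] <- FALSE

  gene_len <- pmax(400L, as.integer(round(stats::rlnorm(config$n_genes, log(3953), 0.5))))
  gene_nex <- 1L + stats::rpois(config$n_genes, 3)
  gene_chrom <- chroms[(seq_len(config$n_genes) - 1L) %% length(chroms) + 1L]
  gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)

  # hosts for class-planted lncRNAs need enough exons / a wide first intron
  idx_i <- which(roles == "i"); idx_j <- which(roles == "j")
  idx_o <- which(roles == "o")
  hosts <- sample(config$n_genes, length(idx_i) + length(idx_j) + length(idx_o))
  host_i <- hosts[seq_along(idx_i)]
  host_j <- hosts[length(idx_i) + seq_along(idx_j)]
  host_o <- hosts[length(idx_i) + length(idx_j) + seq_along(idx_o)]
  gene_nex[c(host_i, host_j)] <- pmax(gene_nex[c(host_i, host_j)], 3L)

  gene_id <- sprintf("gene%04d", seq_len(config$n_genes))
  gene_tx <- paste0(gene_id, ".1")

  # lay out gene exon structures
  exon_rows <- list(); gene_span <- data.frame()
  cursor <- setNames(rep(200000L, length(chroms)), chroms)
  wide_intron <- rep(NA_integer_, config$n_genes)
  wide_intron[host_i] <- lnc_len[idx_i] + 600L
  for (k in seq_len(config$n_genes)) {
    ch <- gene_chrom[k]
    nex <- gene_nex[k]
    prop <- stats::rexp(nex) + 0.2
    exlen <- pmax(60L, as.integer(round(gene_len[k] * prop / sum(prop))))
    if (nex > 1L) {
      intr <- pmax(80L, as.integer(round(stats::rlnorm(nex - 1L, log(800), 0.6))))
      if (!is.na(wide_intron[k])) intr[1] <- wide_intron[k]
    } else intr <- integer(0)
    start <- cursor[ch] + as.integer(round(runif(1, 60000, 120000)))
    s <- start + c(0L, cumsum(exlen[-nex] + intr))
    e <- s + exlen
    if (max(e) + 200000 > config$chrom_lengths[ch])
      stopf("chromosome %s too short; increase chrom_lengths", ch)
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      transcript_id = gene_tx[k], gene_id = gene_id[k], chrom = ch,
      start = s, end = e, strand = gene_strand[k], stringsAsFactors = FALSE)
    cursor[ch] <- max(e)
    gene_span <- rbind(gene_span, data.frame(
      k = k, chrom = ch, start = min(s), end = max(e),
      stringsAsFactors = FALSE))
  }
  ref_exons <- do.call(rbind, exon_rows)
  reference <- transcript_set(ref_exons)

  # region reserved for intergenic lncRNAs: beyond every gene + 150 kb
  lnc_cursor <- cursor + 150000L

  lnc_id <- sprintf("lnc%04d.1", seq_len(n_lnc))
  lnc_rows <- list()
  truth <- data.frame(lncrna_id = lnc_id, role = roles,
                      partner_gene = NA_character_,
                      planted_class = NA_character_,
                      rho_target = NA_real_, stringsAsFactors = FALSE)
  add_lnc <- function(i, ch, starts, ends, strand) {
    lnc_rows[[length(lnc_rows) + 1L]] <<- data.frame(
      transcript_id = lnc_id[i], gene_id = sub("\\.1$", "", lnc_id[i]),
      chrom = ch, start = starts, end = ends, strand = strand,
      stringsAsFactors = FALSE)
  }
  place_intergenic <- function(i) {
    ch <- chroms[(i - 1L) %% length(chroms) + 1L]
    start <- lnc_cursor[ch] + as.integer(round(runif(1, 120000, 200000)))
    len <- lnc_len[i]
    if (start + len + 1000 > config$chrom_lengths[ch])
      stopf("chromosome %s too short; increase chrom_lengths", ch)
    if (single[i]) {
      add_lnc(i, ch, start, start + len, sample(c("+", "-"), 1))
    } else {
      l1 <- as.integer(round(len * 0.6))
      gap <- as.integer(round(runif(1, 200, 1500)))
      add_lnc(i, ch, c(start, start + l1 + gap),
              c(start + l1, start + len + gap), sample(c("+", "-"), 1))
    }
    lnc_cursor[ch] <<- start + len + 2000L
    ch
  }

  # partner genes for cis/trans/triangle roles are assigned disjointly so no
  # gene carries two conflicting planted correlations
  avail <- setdiff(seq_len(config$n_genes), hosts)
  take_partner <- function(not_chrom = NULL) {
    cand <- if (is.null(not_chrom)) avail else avail[gene_chrom[avail] != not_chrom]
    if (!length(cand)) stopf("not enough free partner genes; increase n_genes")
    k <- cand[1]
    avail <<- setdiff(avail, k)
    k
  }
  for (i in seq_len(n_lnc)) {
    role <- roles[i]
    if (role == "cis") {
      k <- take_partner()
      g <- gene_span[gene_span$k == k, ]
      d <- as.integer(round(runif(1, 1000, 20000)))
      start <- g$end + d
      add_lnc(i, g$chrom, start, start + lnc_len[i], gene_strand[k])
      truth$partner_gene[i] <- gene_tx[k]
      truth$rho_target[i] <- config$rho_cis
      truth$planted_class[i] <- "u"
    } else if (role == "trans") {
      ch <- place_intergenic(i)
      k <- take_partner(not_chrom = ch)
      truth$partner_gene[i] <- gene_tx[k]
      truth$rho_target[i] <- config$rho_trans
      truth$planted_class[i] <- "u"
    } else if (role == "triangle") {
      place_intergenic(i)
      k <- take_partner()
      truth$partner_gene[i] <- gene_tx[k]
      truth$rho_target[i] <- config$rho_triangle
      truth$planted_class[i] <- "u"
    } else if (role == "i") {
      k <- host_i[match(i, idx_i)]
      hex <- ref_exons[ref_exons$transcript_id == gene_tx[k], ]
      intr <- exon_introns(hex)
      start <- intr$start[1] + 200L
      add_lnc(i, hex$chrom[1], start, start + lnc_len[i], hex$strand[1])
      truth$planted_class[i] <- "i"
    } else if (role == "j") {
      k <- host_j[match(i, idx_j)]
      hex <- ref_exons[ref_exons$transcript_id == gene_tx[k], ]
      intr <- exon_introns(hex)
      e1 <- max(60L, min(150L, hex$end[1] - hex$start[1] - 10L))
      # second exon runs through host exon 2 into intron 2 -> defeats 'c'
      s1 <- intr$start[1] - e1
      e2_start <- intr$end[1]
      e2_end <- hex$end[2] + 60L
      add_lnc(i, hex$chrom[1], c(s1, e2_start), c(intr$start[1], e2_end),
              hex$strand[1])
      truth$planted_class[i] <- "j"
    } else if (role == "o") {
      k <- host_o[match(i, idx_o)]
      hex <- ref_exons[ref_exons$transcript_id == gene_tx[k], ]
      last <- nrow(hex)
      ov <- min(100L, hex$end[last] - hex$start[last] - 10L)
      start <- hex$end[last] - ov
      add_lnc(i, hex$chrom[1], start, start + lnc_len[i], hex$strand[1])
      truth$planted_class[i] <- "o"
    } else {
      place_intergenic(i)
      truth$planted_class[i] <- "u"
    }
  }
  lnc_exons <- do.call(rbind, lnc_rows)
  assembly <- transcript_set(rbind(ref_exons, lnc_exons))

  tx <- assembly$transcripts
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(tx)), function(r) {
    gc <- if (grepl("^lnc", tx$transcript_id[r])) 0.44 else 0.46
    random_dna(tx$length[r], gc)
  }, character(1)))
  names(seqs) <- tx$transcript_id

  coding_calls <- do.call(rbind, lapply(c("CPC", "LGC", "Pfam"), function(p) {
    data.frame(transcript_id = tx$transcript_id, predictor = p,
               verdict = ifelse(grepl("^lnc", tx$transcript_id),
                                "noncoding", "coding"),
               stringsAsFactors = FALSE)
  }))

  list(reference = reference, assembly = assembly, sequences = seqs,
       coding_calls = coding_calls, truth = truth)
}

#' Simulate the expression matrix
#'
#' Gaussian-copula construction: a latent normal per feature, with planted
#' pairs and triangle members given the latent correlation
#' `2*sin(pi*rho_s/6)` that yields the target Spearman correlation, then a
#' monotone transform to log-normal FPKM (mRNAs expressed above lncRNAs; a
#' configured fraction of unplanted lncRNAs near-silent). The monotone
#' transform leaves Spearman correlations untouched. All-constant features
#' would be dropped with a warning (the log-normal marginals never produce
#' one).
#'
#' @param config a [simulation_config()].
#' @param annotation output of [simulate_annotation()].
#' @return FPKM matrix, features x samples.
#' @export
simulate_expression <- function(config, annotation) {
  set.seed(config$seed + 202L)
  n <- config$n_samples_expr
  tx <- annotation$assembly$transcripts
  ids <- tx$transcript_id
  z <- matrix(rnorm(length(ids) * n), length(ids), n,
              dimnames = list(ids, sprintf("S%03d", seq_len(n))))

  truth <- annotation$truth
  planted <- truth[!is.na(truth$partner_gene), , drop = FALSE]
  for (r in seq_len(nrow(planted))) {
    rl <- latent_rho(planted$rho_target[r])
    zl <- z[planted$lncrna_id[r], ]
    z[planted$partner_gene[r], ] <- rl * zl + sqrt(1 - rl^2) * rnorm(n)
  }

  meanlog <- ifelse(grepl("^lnc", ids), log(1.5), log(8))
  unplanted <- setdiff(ids[grepl("^lnc", ids)], planted$lncrna_id)
  n_silent <- round(config$fraction_silent * length(unplanted))
  silent <- utils::tail(unplanted, n_silent)
  meanlog[ids %in% silent] <- log(0.02)

  fpkm <- qlnorm(pnorm(z), meanlog = meanlog, sdlog = 1)
  constant <- apply(fpkm, 1L, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    warnf("simulate_expression: dropped %d all-constant feature(s)", sum(constant))
    fpkm <- fpkm[!constant, , drop = FALSE]
  }
  round(fpkm, 4)
}

# Balding-Nichols drift parameter hitting a per-bp diversity target at the
# given site spacing; E[2p(1-p)] under p ~ U(0.05, 0.95) is 0.365
bn_drift <- function(pi_target, spacing) {
  f <- 1 - pi_target * spacing / 0.365
  pmin(pmax(f, 0), 0.95)
}

#' Simulate the population genotype panel
#'
#' Sites are placed at regular spacing inside every feature plus a uniform
#' genome-wide background. Per-group allele frequencies follow a
#' Balding-Nichols model around an ancestral frequency (Uniform(0.05, 0.95)),
#' with the group drift parameter calibrated so realised feature-level
#' diversity tracks the per-group targets. Genotypes are drawn as two phased
#' Bernoulli haplotypes per accession. The configured major-haplotype
#' pattern is planted at the first cis lncRNA's sites for the groups listed
#' in `haplotype_major_freq` (major haplotype = all-alt).
#'
#' @param config a [simulation_config()].
#' @param features data.frame `feature_id`, `chrom`, `start`, `end`
#'   (typically the lncRNA and mRNA spans of the annotation).
#' @return A [variant_panel()]; `attr(, "truth")` records per-group drift and
#'   the planted-haplotype feature.
#' @export
simulate_population <- function(config, features) {
  set.seed(config$seed + 303L)
  gs <- config$group_sizes
  samples <- sprintf("acc%03d", seq_len(sum(gs)))
  groups <- setNames(rep(names(gs), gs), samples)

  pos_list <- lapply(seq_len(nrow(features)), function(i) {
    p <- seq(features$start[i], features$end[i] - 1L, by = config$site_spacing)
    data.frame(chrom = features$chrom[i], pos = as.integer(p),
               stringsAsFactors = FALSE)
  })
  per_chrom <- round(config$n_background_snps / length(config$chrom_lengths))
  bg <- do.call(rbind, lapply(names(config$chrom_lengths), function(ch) {
    data.frame(chrom = ch,
               pos = sort(sample.int(config$chrom_lengths[[ch]], per_chrom)),
               stringsAsFactors = FALSE)
  }))
  sites <- unique(rbind(do.call(rbind, pos_list), bg))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  n_sites <- nrow(sites)
  base <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt_of <- c(A = "G", C = "T", G = "A", T = "C")
  sites <- data.frame(sites, ref = base, alt = alt_of[base],
                      stringsAsFactors = FALSE)

  anc <- runif(n_sites, 0.05, 0.95)
  h1 <- h2 <- matrix(NA_integer_, n_sites, length(samples),
                     dimnames = list(NULL, samples))
  drift <- setNames(numeric(length(gs)), names(gs))
  for (g in names(gs)) {
    f <- bn_drift(config$group_diversity[[g]], config$site_spacing)
    drift[g] <- f
    pg <- if (f < 1e-6) anc else
      rbeta(n_sites, anc * (1 - f) / f, (1 - anc) * (1 - f) / f)
    cols <- which(groups == g)
    h1[, cols] <- rbinom(n_sites * length(cols), 1L, pg)
    h2[, cols] <- rbinom(n_sites * length(cols), 1L, pg)
  }

  # planted major-haplotype pattern at the first cis lncRNA
  hap_feature <- NULL
  if (length(config$haplotype_major_freq)) {
    feat_ids <- grep("^lnc", features$feature_id)
    if (length(feat_ids)) {
      fi <- feat_ids[1]
      hap_feature <- features$feature_id[fi]
      idx <- which(sites$chrom == features$chrom[fi] &
                     sites$pos >= features$start[fi] &
                     sites$pos < features$end[fi])
      for (g in names(config$haplotype_major_freq)) {
        cols <- which(groups == g)
        copies <- 2L * length(cols)
        n_major <- round(config$haplotype_major_freq[[g]] * copies)
        carrier <- c(rep(1L, n_major), rep(0L, copies - n_major))
        h1[idx, cols] <- rep(carrier[seq_along(cols)], each = length(idx))
        h2[idx, cols] <- rep(carrier[length(cols) + seq_along(cols)],
                             each = length(idx))
      }
    }
  }

  geno <- h1 + h2
  panel <- variant_panel(sites[, c("chrom", "pos", "ref", "alt")], geno,
                         groups, hap1 = h1, hap2 = h2,
                         phased = matrix(TRUE, n_sites, length(samples)))
  attr(panel, "truth") <- list(drift = drift, hap_feature = hap_feature,
                               group_diversity = config$group_diversity)
  panel
}

#' Simulate array genotypes and phenotypes
#'
#' Array SNPs are uniform over the genome with ancestral frequencies in
#' (0.1, 0.9); each configured trait gets one planted causal SNP — the array
#' SNP nearest to the corresponding planted cis lncRNA — and the phenotype is
#' `effect x dosage` plus Gaussian noise scaled so the causal SNP explains
#' the configured heritability. All remaining SNPs are unassociated.
#'
#' @param config a [simulation_config()].
#' @param annotation output of [simulate_annotation()].
#' @return list with `geno` (SNP x sample dosage), `positions`, `pheno`
#'   (sample x trait data.frame), `causal` (truth table).
#' @export
simulate_phenotype_and_array <- function(config, annotation) {
  set.seed(config$seed + 404L)
  n <- config$n_pheno_samples
  samples <- sprintf("gt%03d", seq_len(n))
  per_chrom <- round(config$n_array_snps / length(config$chrom_lengths))
  pos <- do.call(rbind, lapply(names(config$chrom_lengths), function(ch) {
    data.frame(chrom = ch,
               pos = sort(sample.int(config$chrom_lengths[[ch]], per_chrom)),
               stringsAsFactors = FALSE)
  }))
  pos$snp_id <- sprintf("AX-sim%05d", seq_len(nrow(pos)))
  freq <- runif(nrow(pos), 0.1, 0.9)
  geno <- matrix(rbinom(nrow(pos) * n, 2L, freq), nrow(pos), n,
                 dimnames = list(pos$snp_id, samples))

  truth <- annotation$truth
  cis_lnc <- truth$lncrna_id[truth$role == "cis"]
  tx <- annotation$assembly$transcripts
  pheno <- data.frame(sample = samples, stringsAsFactors = FALSE)
  causal <- data.frame()
  for (k in seq_len(nrow(config$causal_snps))) {
    trait <- config$causal_snps$trait[k]
    b <- config$causal_snps$effect[k]
    h2 <- config$causal_snps$h2[k]
    anchor <- tx[tx$transcript_id == cis_lnc[min(k, length(cis_lnc))], ]
    d <- interval_gap(pos$chrom, pos$pos, pos$pos + 1L,
                      anchor$chrom, anchor$start, anchor$end)
    snp <- pos$snp_id[which.min(d)]
    g <- geno[snp, ]
    if (var(g) == 0) stopf("causal SNP for %s is monomorphic", trait)
    sigma <- sqrt(b^2 * var(g) * (1 - h2) / h2)
    pheno[[trait]] <- as.numeric(b * g + rnorm(n, 0, sigma))
    causal <- rbind(causal, data.frame(
      trait = trait, snp_id = snp, chrom = pos$chrom[match(snp, pos$snp_id)],
      pos = pos$pos[match(snp, pos$snp_id)], effect = b, h2 = h2,
      stringsAsFactors = FALSE))
  }
  list(geno = geno, positions = pos[, c("snp_id", "chrom", "pos")],
       pheno = pheno, causal = causal)
}

#' Simulate miRNA binding sites and pairing energies
#'
#' Each planted triangle's lncRNA and mRNA share one miRNA with recorded
#' binding spans of 21 nt (lncRNA span 368-389, mRNA span 313-334, 0-based
#' half-open), plus decoy rows (including over-threshold expectation scores)
#' and an energy table in which planted pairs pass the free-energy cutoff
#' while decoy pairs do not.
#'
#' @param config a [simulation_config()].
#' @param annotation output of [simulate_annotation()].
#' @return list with `lnc_sites`, `mrna_sites` (binding tables), `energy`
#'   (pairing free-energy table), `triangles` (truth triples).
#' @export
simulate_binding_and_energy <- function(config, annotation) {
  set.seed(config$seed + 505L)
  truth <- annotation$truth
  mirnas <- sprintf("tae-miRsim%03d", seq_len(config$n_mirnas))
  tri <- truth[truth$role == "triangle", , drop = FALSE]
  tri$mirna_id <- mirnas[(seq_len(nrow(tri)) - 1L) %% config$n_mirnas + 1L]

  lnc_sites <- data.frame(transcript_id = tri$lncrna_id,
                          mirna_id = tri$mirna_id,
                          start = 368L, end = 389L,
                          expectation = round(runif(nrow(tri), 0.5, 4), 2),
                          stringsAsFactors = FALSE)
  mrna_sites <- data.frame(transcript_id = tri$partner_gene,
                           mirna_id = tri$mirna_id,
                           start = 313L, end = 334L,
                           expectation = round(runif(nrow(tri), 0.5, 4), 2),
                           stringsAsFactors = FALSE)

  # decoys: unshared miRNA rows plus a few over-threshold expectations
  tx <- annotation$assembly$transcripts
  other_lnc <- setdiff(tx$transcript_id[grepl("^lnc", tx$transcript_id)],
                       tri$lncrna_id)
  other_mrna <- setdiff(tx$transcript_id[!grepl("^lnc", tx$transcript_id)],
                        tri$partner_gene)
  n_decoy <- 15L
  decoy_lnc <- data.frame(
    transcript_id = sample(other_lnc, n_decoy, replace = TRUE),
    mirna_id = sample(mirnas[seq(1, config$n_mirnas, 2)], n_decoy, TRUE),
    start = 10L, end = 31L,
    expectation = round(runif(n_decoy, 0.5, 7), 2), stringsAsFactors = FALSE)
  decoy_mrna <- data.frame(
    transcript_id = sample(other_mrna, n_decoy, replace = TRUE),
    mirna_id = sample(mirnas[seq(2, config$n_mirnas, 2)], n_decoy, TRUE),
    start = 50L, end = 71L,
    expectation = round(runif(n_decoy, 0.5, 7), 2), stringsAsFactors = FALSE)

  pairs <- truth[truth$role %in% c("cis", "trans"), , drop = FALSE]
  energy <- data.frame(lncrna_id = pairs$lncrna_id,
                       mrna_id = pairs$partner_gene,
                       energy = round(runif(nrow(pairs), -0.4, -0.15), 3),
                       stringsAsFactors = FALSE)
  decoy_energy <- data.frame(
    lncrna_id = sample(other_lnc, 10L),
    mrna_id = sample(other_mrna, 10L),
    energy = round(runif(10L, -0.05, 0.3), 3), stringsAsFactors = FALSE)

  list(lnc_sites = rbind(lnc_sites, decoy_lnc),
       mrna_sites = rbind(mrna_sites, decoy_mrna),
       energy = rbind(energy, decoy_energy),
       triangles = data.frame(lncrna_id = tri$lncrna_id,
                              mirna_id = tri$mirna_id,
                              mrna_id = tri$partner_gene,
                              stringsAsFactors = FALSE))
}

#' Simulate cross-species homolog hits
#'
#' Per-species conservation decays with planted divergence depth; hits carry
#' identity and coverage whose product reproduces the per-species score plus
#' noise. A configurable fraction of queries receive a duplicate hit in one
#' species (excluding them from the single-copy set).
#'
#' @param config a [simulation_config()].
#' @param queries lncRNA ids to align (default: the first 40 simulated
#'   lncRNAs, or all of them if fewer).
#' @param species named numeric vector of divergence depths; the defaults
#'   keep even the deepest split above the 0.6 retention threshold so the
#'   single-copy set spans all species (the tree-building precondition),
#'   while preserving the progenitor-to-outgroup ordering.
#' @return data.frame of hits (`query`, `species`, `subject`, `identity`,
#'   `coverage`, `e_value`).
#' @export
simulate_homology <- function(config, queries = NULL,
                              species = c(T.turgidum = 0.03,
                                          Ae.tauschii = 0.06,
                                          T.urartu = 0.09, H.vulgare = 0.15,
                                          Z.mays = 0.24, O.sativa = 0.27,
                                          S.bicolor = 0.30,
                                          A.thaliana = 0.35)) {
  set.seed(config$seed + 606L)
  queries <- queries %||%
    sprintf("lnc%04d.1", seq_len(min(40L, config$n_lncrnas)))
  rows <- list()
  for (q in queries) {
    for (s in names(species)) {
      score <- max(0.05, min(0.99, exp(-species[[s]]) - runif(1, 0, 0.04)))
      idy <- min(1, sqrt(score) + runif(1, 0, 0.03))
      cov <- score / idy
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, species = s, subject = paste0(s, "_scaf1"),
        identity = round(idy, 4), coverage = round(min(cov, 1), 4),
        e_value = signif(10^-runif(1, 6, 40), 3), stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, rows)
  # one in five queries gets a duplicated strong hit in the closest species
  dup <- queries[seq(1, length(queries), by = 5L)]
  extra <- hits[hits$query %in% dup & hits$species == names(species)[1], ]
  if (nrow(extra)) {
    extra$subject <- paste0(extra$subject, "_copy2")
    hits <- rbind(hits, extra)
  }
  rownames(hits) <- NULL
  hits
}

#' Run the full generator and write all pipeline inputs
#'
#' Produces every input file the pipeline consumes (reference.gtf,
#' assembly.gtf, transcripts.fasta, expr.tsv, coding_calls.tsv, panel.vcf,
#' groups.tsv, array.tsv, array_positions.tsv, pheno.tsv, binding_lnc.tsv,
#' binding_mrna.tsv, energy.tsv, homology_hits.tsv, qtl.bed,
#' introgression.bed) plus truth.json. Identical configurations yield
#' byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed); `NULL` returns the
#'   objects without writing files.
#' @return (invisibly) list of all simulated objects and the ground truth.
#' @export
simulate_all <- function(config, out_dir = NULL) {
  ann <- simulate_annotation(config)
  expr <- simulate_expression(config, ann)
  tx <- ann$assembly$transcripts
  features <- data.frame(feature_id = tx$transcript_id, chrom = tx$chrom,
                         start = tx$start, end = tx$end,
                         stringsAsFactors = FALSE)
  lnc_first <- features[grepl("^lnc", features$feature_id), ][1, ]
  panel <- simulate_population(config, features)
  assoc <- simulate_phenotype_and_array(config, ann)
  bind <- simulate_binding_and_energy(config, ann)
  hits <- simulate_homology(config)

  set.seed(config$seed + 707L)
  truth_pairs <- ann$truth[ann$truth$role %in% c("cis", "trans"), , drop = FALSE]
  # QTL intervals around a few planted features + decoys elsewhere
  some <- tx[tx$transcript_id %in% truth_pairs$lncrna_id[1:5], ]
  qtl <- data.frame(chrom = some$chrom,
                    start = pmax(0L, some$start - 500000L),
                    end = some$end + 500000L,
                    name = sprintf("QTL_%d", seq_len(nrow(some))),
                    stringsAsFactors = FALSE)
  intro <- data.frame(chrom = names(config$chrom_lengths)[1],
                      start = c(0L, 20000000L),
                      end = c(5000000L, 26000000L),
                      name = c("intro_1", "intro_2"), stringsAsFactors = FALSE)

  truth <- list(
    lncrna_ids = ann$truth$lncrna_id,
    roles = ann$truth,
    pairs = truth_pairs,
    triangles = bind$triangles,
    causal = assoc$causal,
    group_diversity = as.list(config$group_diversity),
    hap_feature = attr(panel, "truth")$hap_feature,
    haplotype_major_freq = as.list(config$haplotype_major_freq)
  )

  out <- list(config = config, annotation = ann, expr = expr, panel = panel,
              assoc = assoc, binding = bind, homology = hits, qtl = qtl,
              introgression = intro, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_gtf(ann$reference, p("reference.gtf"))
    write_gtf(ann$assembly, p("assembly.gtf"))
    Biostrings::writeXStringSet(ann$sequences, p("transcripts.fasta"))
    write_expression(expr, p("expr.tsv"))
    write_tsv_file(ann$coding_calls, p("coding_calls.tsv"))
    write_vcf(panel, p("panel.vcf"))
    write_group_map(panel$groups, p("groups.tsv"))
    write_expression(assoc$geno, p("array.tsv"), id_col = "snp_id")
    write_tsv_file(assoc$positions, p("array_positions.tsv"))
    write_tsv_file(assoc$pheno, p("pheno.tsv"))
    write_tsv_file(bind$lnc_sites, p("binding_lnc.tsv"))
    write_tsv_file(bind$mrna_sites, p("binding_mrna.tsv"))
    write_tsv_file(bind$energy, p("energy.tsv"))
    write_tsv_file(hits, p("homology_hits.tsv"))
    write_bed(qtl, p("qtl.bed"))
    write_bed(intro, p("introgression.bed"))
    jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(out)
}
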