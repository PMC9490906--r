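# one scaled-down simulation shared across this file
cfg <- small_config()
sim <- simulate_all(cfg)

test_that("configuration guards reject impossible settings", {
  expect_error(simulation_config(rho_cis = 0.9999), "saturates")
  expect_error(simulation_config(causal_snps = data.frame(
    trait = "HD", effect = 1, h2 = 1.2)), "heritability")
  expect_error(simulation_config(group_diversity = c(A1 = 0.7)), "0.5")
  expect_error(simulation_config(n_lncrnas = 3), "too small")
  # the nine default group sizes total the full diversity panel
  expect_equal(sum(simulation_config()$group_sizes), 261)
})

test_that("annotation emulates the length and exon-count contrasts", {
  tx <- sim$annotation$assembly$transcripts
  lnc <- tx[grepl("^lnc", tx$transcript_id), ]
  mrna <- tx[!grepl("^lnc", tx$transcript_id), ]
  expect_lt(median(lnc$length), median(mrna$length))
  expect_gt(median(mrna$n_exons), 1)
  expect_equal(mean(lnc$n_exons == 1L), cfg$fraction_single_exon,
               tolerance = 0.05)
  # planted cis lncRNAs sit within 100 kb of their partner gene
  tr <- sim$truth$roles
  for (i in which(tr$role == "cis")) {
    l <- tx[tx$transcript_id == tr$lncrna_id[i], ]
    g <- tx[tx$transcript_id == tr$partner_gene[i], ]
    expect_lte(pair_distance(l, g), 100000)
  }
  # trans partners are on other chromosomes
  for (i in which(tr$role == "trans")) {
    l <- tx[tx$transcript_id == tr$lncrna_id[i], ]
    g <- tx[tx$transcript_id == tr$partner_gene[i], ]
    expect_false(l$chrom == g$chrom)
  }
})

test_that("planted class codes are recovered by the classifier on the emitted files", {
  tr <- sim$truth$roles
  planted <- tr[tr$planted_class %in% c("i", "j", "o"), ]
  cls <- classify_transcripts(
    subset_transcripts(sim$annotation$assembly, planted$lncrna_id),
    sim$annotation$reference)
  expect_equal(cls$class_code[match(planted$lncrna_id, cls$transcript_id)],
               planted$planted_class)
  # unplanted intergenic lncRNAs classify as u
  u_ids <- tr$lncrna_id[tr$role == "u"]
  cls_u <- classify_transcripts(
    subset_transcripts(sim$annotation$assembly, u_ids),
    sim$annotation$reference)
  expect_true(all(cls_u$class_code == "u"))
})

test_that("planted pair correlations land near their targets, decoys near zero", {
  tr <- sim$truth$roles
  planted <- tr[!is.na(tr$partner_gene), ]
  for (i in seq_len(nrow(planted))) {
    rho <- spearman_cor(sim$expr[planted$lncrna_id[i], ],
                        sim$expr[planted$partner_gene[i], ])$rho
    # sampling sd of Spearman's rho scales with 1 - rho^2: the strong pair
    # targets get the tight band, the weaker triangle correlation a wider one
    band <- if (abs(planted$rho_target[i]) >= 0.9) 0.05 else 0.1
    expect_lt(abs(rho - planted$rho_target[i]), band)
  }
  # unplanted pairs behave like independent features
  set.seed(2)
  u_ids <- tr$lncrna_id[tr$role == "u"][1:8]
  genes <- sim$annotation$reference$transcripts$transcript_id
  free <- setdiff(genes, planted$partner_gene)
  rho0 <- vapply(seq_along(u_ids), function(i) {
    spearman_cor(sim$expr[u_ids[i], ], sim$expr[sample(free, 1), ])$rho
  }, numeric(1))
  expect_true(all(abs(rho0) < 0.3))
})

test_that("silent features fail the expression filter but stay in the matrix", {
  kept <- expression_filter(sim$expr, 0.1, 0.2)
  lnc_ids <- sim$truth$lncrna_ids
  expect_gt(length(setdiff(lnc_ids, kept)), 0)
  expect_true(all(lnc_ids %in% rownames(sim$expr)))
})

test_that("population panel tracks group diversity targets and plants haplotypes", {
  tx <- sim$annotation$assembly$transcripts
  feats <- data.frame(feature_id = tx$transcript_id, chrom = tx$chrom,
                      start = tx$start, end = tx$end)
  pi <- nucleotide_diversity(sim$panel, groups = c("A1", "A2"), windows = feats)
  w <- feats$end - feats$start
  m <- tapply(seq_len(nrow(pi)), pi$group, function(i)
    sum(pi$pi[i] * w[(i - 1) %% nrow(feats) + 1]) / sum(w))
  # targets halve from A1 to A2; realized ratio within the configured band
  ratio <- m[["A2"]] / m[["A1"]]
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
  # realized diversity within 20% of target
  expect_lt(abs(m[["A1"]] / cfg$group_diversity[["A1"]] - 1), 0.2)
  # planted major haplotype frequencies
  hf <- sim$truth$hap_feature
  fi <- feats[feats$feature_id == hf, ]
  h <- haplotypes(sim$panel, fi, groups = names(cfg$haplotype_major_freq))
  for (g in names(cfg$haplotype_major_freq)) {
    top <- max(h$by_group$frequency[h$by_group$group == g])
    expect_equal(top, cfg$haplotype_major_freq[[g]], tolerance = 0.05)
  }
})

test_that("identical allele-frequency draws give near-zero Fst, fixed difference gives 1", {
  set.seed(44)
  n_sites <- 2000; n <- 25
  p <- runif(n_sites, 0.1, 0.9)
  draw <- function() matrix(rbinom(n_sites * n, 2, p), n_sites, n)
  g <- cbind(draw(), draw())   # both groups drawn from identical frequencies
  colnames(g) <- sprintf("s%02d", seq_len(2 * n))
  panel <- make_panel(g, setNames(rep(c("X", "Y"), each = n), colnames(g)))
  expect_lt(abs(pairwise_fst(panel, "X", "Y")$fst), 0.02)
})

test_that("phenotype construction orders dosage groups and respects heritability", {
  assoc <- sim$assoc
  for (k in seq_len(nrow(assoc$causal))) {
    g <- assoc$geno[assoc$causal$snp_id[k], ]
    y <- assoc$pheno[[assoc$causal$trait[k]]]
    expect_gt(mean(y[g == 2]), mean(y[g == 0]))
  }
})

test_that("the generator is fully deterministic given the config", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_all(small_config(seed = 33), d1)
  simulate_all(small_config(seed = 33), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_setequal(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_all(small_config(seed = 34), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "expr.tsv"))),
                         unname(tools::md5sum(file.path(d3, "expr.tsv")))))
})

test_that("ground truth references only features present in the emitted annotation", {
  ids <- sim$annotation$assembly$transcripts$transcript_id
  expect_true(all(sim$truth$lncrna_ids %in% ids))
  expect_true(all(sim$truth$pairs$partner_gene %in% ids))
  expect_true(all(sim$truth$triangles$lncrna_id %in% ids))
  expect_true(all(sim$truth$triangles$mrna_id %in% ids))
  expect_true(all(sim$truth$causal$snp_id %in% rownames(sim$assoc$geno)))
})
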