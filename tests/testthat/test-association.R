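make_assoc_fixture <- function(seed = 15, n = 93, n_snps = 300, h2 = 0.5) {
  set.seed(seed)
  freq <- runif(n_snps, 0.1, 0.9)
  geno <- matrix(rbinom(n_snps * n, 2, freq), n_snps, n,
                 dimnames = list(sprintf("snp%03d", seq_len(n_snps)),
                                 sprintf("s%02d", seq_len(n))))
  causal <- "snp050"
  g <- geno[causal, ]
  sigma <- sqrt(var(g) * (1 - h2) / h2)
  y <- setNames(g + rnorm(n, 0, sigma), colnames(geno))
  list(geno = geno, pheno = y, causal = causal)
}

test_that("gwas_scan matches per-SNP lm fits with PC covariates", {
  fx <- make_assoc_fixture()
  scan <- gwas_scan(fx$geno, fx$pheno, n_pcs = 3)
  gs <- scale(t(fx$geno[rownames(fx$geno) %in% scan$snp_id, ]))
  pcs <- prcomp(gs, center = FALSE)$x[, 1:3]
  for (snp in c("snp050", "snp001", "snp200")) {
    fit <- summary(lm(fx$pheno ~ fx$geno[snp, ] + pcs))$coefficients
    row <- scan[scan$snp_id == snp, ]
    expect_equal(row$effect, unname(fit[2, 1]), tolerance = 1e-8)
    expect_equal(row$p_value, unname(fit[2, 4]), tolerance = 1e-8)
  }
})

test_that("the planted causal SNP dominates the scan and the 1/Ne rule is strict", {
  fx <- make_assoc_fixture()
  scan <- gwas_scan(fx$geno, fx$pheno, ne = 21868)
  expect_equal(attr(scan, "threshold"), 1 / 21868)
  expect_equal(scan$snp_id[which.min(scan$p_value)], fx$causal)
  expect_identical(scan$passes_threshold, scan$p_value < 1 / 21868)
})

test_that("permuted phenotypes give calibrated null p-values", {
  fx <- make_assoc_fixture(seed = 99, n_snps = 1000)
  set.seed(7)
  y_perm <- setNames(sample(fx$pheno), names(fx$pheno))
  scan <- gwas_scan(fx$geno, y_perm, n_pcs = 3, maf = 0)
  frac <- mean(scan$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("monomorphic and low-MAF SNPs are excluded; sanity errors fire", {
  fx <- make_assoc_fixture()
  g <- fx$geno
  g["snp001", ] <- 2L
  scan <- gwas_scan(g, fx$pheno)
  expect_false("snp001" %in% scan$snp_id)
  expect_error(gwas_scan(g, setNames(rep(1, 93), colnames(g))), "zero variance")
  expect_error(gwas_scan(g[, 1:10], fx$pheno[1:10]), ">= 30")
})

test_that("ld_r2 is 1 on self and decreases with random flips", {
  set.seed(4)
  a <- rbinom(200, 2, 0.4)
  expect_equal(ld_r2(a, a), 1)
  flip <- function(x, rate) {
    i <- runif(length(x)) < rate
    x[i] <- sample(0:2, sum(i), replace = TRUE)
    x
  }
  r10 <- ld_r2(a, flip(a, 0.10))
  r40 <- ld_r2(a, flip(a, 0.40))
  expect_true(r40 < r10 && r10 < 1)
  expect_true(is.na(ld_r2(a, rep(1, 200))))
})

test_that("independent sites show r2 near the 1/(n-1) bias level and decay is reported", {
  set.seed(23)
  n <- 93; n_snps <- 120
  geno <- matrix(rbinom(n_snps * n, 2, 0.5), n_snps, n,
                 dimnames = list(sprintf("s%03d", 1:n_snps), NULL))
  pos <- data.frame(snp_id = rownames(geno), chrom = "chr1",
                    pos = sort(sample.int(2e7, n_snps)))
  dec <- ld_decay(geno, pos, max_dist = 2e7, bin_size = 5e6)
  expect_equal(mean(dec$bins$mean_r2), 1 / (n - 1), tolerance = 0.25)
  expect_false(is.na(dec$decay_distance))  # independent sites decay immediately
})

test_that("candidate assignment respects the 5 Mb window and overlap distance 0", {
  hits <- data.frame(snp_id = "hit1", chrom = "chr1", pos = 10e6,
                     p_value = 1e-8, passes_threshold = TRUE)
  feats <- data.frame(feature_id = c("near", "far", "onTop"),
                      chrom = "chr1",
                      start = c(10e6 + 4.9e6, 10e6 + 5.1e6, 10e6 - 100),
                      end = c(10e6 + 4.95e6, 10e6 + 5.2e6, 10e6 + 200))
  got <- assign_candidates(hits, feats, window = 5e6)
  expect_setequal(got$feature_id, c("near", "onTop"))
  expect_equal(got$distance[got$feature_id == "onTop"], 0)
  # widening the window never removes assignments
  wider <- assign_candidates(hits, feats, window = 6e6)
  expect_true(all(got$feature_id %in% wider$feature_id))
  # invariant to feature order
  perm <- assign_candidates(hits, feats[c(3, 1, 2), ], window = 5e6)
  expect_equal(got, perm)
})

test_that("colocalization uses half-open any-base intersection", {
  feats <- data.frame(feature_id = c("a", "b"), chrom = "chr1",
                      start = c(100, 500), end = c(200, 600))
  iv <- data.frame(chrom = "chr1", start = c(150, 200), end = c(160, 300),
                   name = c("q1", "q2"))
  ov <- colocalize(feats, iv)
  expect_equal(ov$feature_id, "a")
  expect_equal(ov$interval_name, "q1")   # q2 abuts feature a (start = end)
  expect_equal(ov$overlap_bp, 10)
})

test_that("fisher_enrichment reproduces exact worked values", {
  expect_equal(fisher_enrichment(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_enrichment(5, 5, 5, 5), 1)
  expect_error(fisher_enrichment(0, 0, 0, 0), "all-zero")
})

test_that("fisher_enrichment agrees with stats::fisher.test on random tables", {
  set.seed(12)
  for (k in 1:50) {
    tb <- matrix(rpois(4, 6), 2, 2)
    if (sum(tb) == 0) next
    want <- fisher.test(tb)$p.value
    got <- fisher_enrichment(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(got, want, tolerance = 1e-9)
  }
})
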