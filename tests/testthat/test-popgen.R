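test_that("windowed pi matches the worked per-site value and scales with span", {
  # 10 haplotypes, one site at p = 0.5, window of 100 bp
  hap <- matrix(0L, 10, 1)
  hap[1:5, 1] <- 1L
  panel <- panel_from_haplotypes(hap)
  w100 <- data.frame(chrom = "chr1", start = 0, end = 100)
  pi100 <- nucleotide_diversity(panel, windows = w100)$pi
  expect_equal(pi100, (10 / 9) * 2 * 0.25 / 100)
  expect_equal(pi100, oracle_pi(hap, 100))
  # doubling the span halves pi
  w200 <- data.frame(chrom = "chr1", start = 0, end = 200)
  expect_equal(nucleotide_diversity(panel, windows = w200)$pi, pi100 / 2)
  # monomorphic window
  panel0 <- panel_from_haplotypes(matrix(0L, 10, 3))
  expect_equal(nucleotide_diversity(panel0, windows = w100)$pi, 0)
})

test_that("per-site pi equals the exhaustive mean-pairwise-difference oracle", {
  set.seed(77)
  for (k in 1:40) {
    n_hap <- 2 * sample(3:10, 1)
    n_site <- sample(1:50, 1)
    hap <- matrix(rbinom(n_hap * n_site, 1, runif(1, 0.1, 0.9)), n_hap, n_site)
    span <- n_site * 10 + 5
    panel <- panel_from_haplotypes(hap)
    pi <- nucleotide_diversity(panel,
                               windows = data.frame(chrom = "chr1", start = 0,
                                                    end = span))$pi
    expect_equal(pi, oracle_pi(hap, span), tolerance = 1e-12)
  }
})

test_that("Weir-Cockerham Fst hits the boundary cases", {
  # identical genotype matrices -> ~0 (the estimator is slightly negative
  # when the between-group variance component is exactly zero)
  g <- matrix(rep(rep(c(0L, 1L, 2L, 1L, 0L, 2L), each = 10), 10), 10, 60,
              byrow = TRUE)
  colnames(g) <- sprintf("s%02d", 1:60)
  panel <- make_panel(g, setNames(rep(c("A", "B"), each = 30), colnames(g)))
  expect_lt(abs(pairwise_fst(panel, "A", "B")$fst), 0.05)
  # fixed difference, no missing -> exactly 1
  g2 <- cbind(matrix(0L, 20, 5), matrix(2L, 20, 5))
  colnames(g2) <- sprintf("s%02d", 1:10)
  panel2 <- make_panel(g2, setNames(rep(c("A", "B"), each = 5), colnames(g2)))
  expect_identical(pairwise_fst(panel2, "A", "B")$fst, 1)
})

test_that("Fst variance components match a term-by-term hand computation", {
  # 2 sites; group A: 0,0,1,2 ; group B: 2,2,1,2 (site 1)
  #          group A: 0,0,0,1 ; group B: 0,1,1,2 (site 2)
  g <- rbind(c(0L, 0L, 1L, 2L, 2L, 2L, 1L, 2L),
             c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 2L))
  colnames(g) <- sprintf("s%d", 1:8)
  panel <- make_panel(g, setNames(rep(c("A", "B"), each = 4), colnames(g)))
  got <- pairwise_fst(panel, "A", "B")$fst

  # independent spreadsheet-style evaluation of Weir & Cockerham (1984)
  wc_site <- function(gA, gB) {
    n1 <- length(gA); n2 <- length(gB); r <- 2
    p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
    h1 <- mean(gA == 1); h2 <- mean(gB == 1)
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) /
                          (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    c(a = a, bc = b + hbar / 2)
  }
  t1 <- wc_site(c(0, 0, 1, 2), c(2, 2, 1, 2))
  t2 <- wc_site(c(0, 0, 0, 1), c(0, 1, 1, 2))
  want <- (t1["a"] + t2["a"]) / (t1["a"] + t1["bc"] + t2["a"] + t2["bc"])
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("larger simulated divergence gives monotonically larger Fst", {
  set.seed(13)
  n_sites <- 1500; n <- 30
  anc <- runif(n_sites, 0.1, 0.9)
  draw_group <- function(f) {
    p <- if (f < 1e-9) anc else rbeta(n_sites, anc * (1 - f) / f,
                                      (1 - anc) * (1 - f) / f)
    matrix(rbinom(n_sites * n, 2, p), n_sites, n)
  }
  fst <- vapply(c(0.02, 0.1, 0.3, 0.6), function(f) {
    g <- cbind(draw_group(0.01), draw_group(f))
    colnames(g) <- sprintf("s%02d", seq_len(2 * n))
    panel <- make_panel(g, setNames(rep(c("A", "B"), each = n), colnames(g)))
    pairwise_fst(panel, "A", "B")$fst
  }, numeric(1))
  expect_true(all(diff(fst) > 0))
})

test_that("snp_density counts half-open and normalises per kb", {
  g <- matrix(1L, 6, 4, dimnames = list(NULL, sprintf("s%d", 1:4)))
  panel <- make_panel(g, setNames(rep("A", 4), sprintf("s%d", 1:4)),
                      pos = c(100L, 200L, 300L, 400L, 500L, 1000L))
  feats <- data.frame(feature_id = c("f1", "f2"), chrom = "chr1",
                      start = c(0L, 2000L), end = c(1000L, 3000L))
  d <- snp_density(panel, feats)
  expect_equal(d$n_snps, c(5L, 0L))        # site at pos 1000 = end excluded
  expect_equal(d$snps_per_kb, c(5, 0))
})

test_that("major haplotype requires frequency strictly above one half", {
  # 13 chromosomes: 10 carry H1 -> 76.9%, major
  hap <- matrix(0L, 26, 4)
  hap[1:20, ] <- 1L   # 20 of 26 copies = 76.92%
  panel <- panel_from_haplotypes(hap)
  h <- haplotypes(panel, list(chrom = "chr1", start = 0, end = 100))
  top <- h$by_group[which.max(h$by_group$frequency), ]
  expect_equal(top$frequency, 20 / 26, tolerance = 1e-12)
  expect_true(top$major)
  # exact 50/50 -> no major
  hap2 <- rbind(matrix(1L, 5, 3), matrix(0L, 5, 3))
  h2 <- haplotypes(panel_from_haplotypes(hap2),
                   list(chrom = "chr1", start = 0, end = 100))
  expect_false(any(h2$by_group$major))
  # all identical -> single haplotype at 100%
  h3 <- haplotypes(panel_from_haplotypes(matrix(1L, 8, 2)),
                   list(chrom = "chr1", start = 0, end = 100))
  expect_equal(nrow(h3$by_group), 1L)
  expect_equal(h3$by_group$frequency, 1)
})

test_that("unphased heterozygotes are excluded from haplotype tables with a count", {
  g <- rbind(c(1L, 0L), c(1L, 2L))
  colnames(g) <- c("sHet", "sHom")
  panel <- make_panel(g, c(sHet = "A", sHom = "A"))  # no hap matrices: het unphased
  h <- haplotypes(panel, list(chrom = "chr1", start = 0, end = 100))
  expect_equal(unname(h$excluded["A"]), 1L)
  expect_equal(sum(h$by_group$count), 2L)  # two copies from the homozygote
  expect_equal(h$by_group$haplotype, "AG")
})

test_that("diversity_shift signs bottlenecks along lineage edges", {
  pi <- c(A1 = 1e-3, A2 = 5e-4, AB1 = 2e-4, AB2 = 2e-4)
  edges <- data.frame(parent = c("A1", "AB1"), child = c("A2", "AB2"))
  sh <- diversity_shift(pi, edges)
  expect_equal(sh$sign, c(-1, 0))
  expect_equal(sh$ratio[1], 0.5)
  expect_true(sh$bottleneck[1])
  expect_false(sh$bottleneck[2])
  expect_error(diversity_shift(pi, data.frame(parent = "A1", child = "ZZ")),
               "missing group")
})
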