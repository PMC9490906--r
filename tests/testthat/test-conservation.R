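test_that("conservation scores multiply coverage and identity with strict retention", {
  hits <- data.frame(query = "q1", species = c("sp1", "sp2", "sp3"),
                     identity = c(1.0, 0.9, 1.0),
                     coverage = c(1.0, 0.8, 0.5),
                     e_value = 1e-10)
  sc <- conservation_score(hits)
  expect_equal(sc$score, c(1.0, 0.72, 0.5))
  expect_equal(sc$retained, c(TRUE, TRUE, FALSE))
  # alternative mean formula
  sc2 <- conservation_score(hits, formula = "mean")
  expect_equal(sc2$score[3], 0.75)
  expect_error(conservation_score(transform(hits, identity = 1.2)), "\\[0, 1\\]")
})

test_that("best hits break ties by e-value then subject id", {
  hits <- conservation_score(data.frame(
    query = "q", species = "sp",
    identity = c(0.9, 0.9, 0.9), coverage = c(0.9, 0.9, 0.8),
    e_value = c(1e-10, 1e-20, 1e-30),
    subject = c("scafB", "scafA", "scafC")))
  b <- best_hits(hits)
  expect_equal(nrow(b), 1L)
  expect_equal(b$subject, "scafA")  # same score, lower e-value wins
})

test_that("single-copy set requires exactly one retained hit per species", {
  rec <- conservation_score(data.frame(
    query = c("q1", "q1", "q2", "q2", "q2", "q3"),
    species = c("sp1", "sp2", "sp1", "sp1", "sp2", "sp1"),
    identity = 0.9, coverage = 0.9, e_value = 1e-10,
    subject = c("a", "b", "c", "d", "e", "f")))
  sc <- single_copy_set(rec, c("sp1", "sp2"))
  expect_equal(sc, "q1")           # q2 has two sp1 hits, q3 misses sp2
  expect_error(single_copy_set(rec, character(0)), "empty species")
})

test_that("raising the retention threshold never grows the retained or single-copy sets", {
  set.seed(6)
  rec <- data.frame(query = rep(sprintf("q%02d", 1:20), each = 3),
                    species = c("sp1", "sp2", "sp3"),
                    identity = runif(60, 0.5, 1), coverage = runif(60, 0.5, 1),
                    e_value = 1e-8, subject = "s")
  lo <- conservation_score(rec, threshold = 0.5)
  hi <- conservation_score(rec, threshold = 0.8)
  expect_true(all(which(hi$retained) %in% which(lo$retained)))
  expect_true(all(single_copy_set(hi, c("sp1", "sp2", "sp3")) %in%
                    single_copy_set(lo, c("sp1", "sp2", "sp3"))))
})

test_that("NJ recovers an additive 4-taxon tree exactly", {
  # tree ((A:1,B:2):1.5,(C:3,D:4)) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5.5
  d["A", "D"] <- d["D", "A"] <- 6.5
  d["B", "C"] <- d["C", "B"] <- 6.5
  d["B", "D"] <- d["D", "B"] <- 7.5
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_tree(d)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
               d, tolerance = 1e-12)
})

test_that("3 taxa give the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  tip_edge <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                       tr$tip.label)
  expect_equal(tip_edge[["A"]], (3 + 4 - 5) / 2)
  expect_equal(tip_edge[["B"]], (3 + 5 - 4) / 2)
  expect_equal(tip_edge[["C"]], (4 + 5 - 3) / 2)
})

test_that("NJ topology is invariant to taxon input order", {
  set.seed(30)
  n <- 6
  base <- matrix(runif(n * n, 1, 5), n, n)
  d <- (base + t(base)) / 2; diag(d) <- 0
  dimnames(d) <- list(letters[1:n], letters[1:n])
  t1 <- nj_tree(d)
  perm <- sample(n)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), setNames(0, "PH85"), ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(nj_tree(bad), "symmetric")
})

test_that("synthetic homolog tables place the closest species next to the focal taxon", {
  cfg <- small_config()
  hits <- simulate_homology(cfg)
  rec <- conservation_score(hits)
  sp <- sort(unique(rec$species))
  sc <- single_copy_set(rec, sp)
  expect_gt(length(sc), 0)
  d <- species_distances(rec, focal = "T.aestivum", species = sp, queries = sc)
  tr <- nj_tree(d)
  coph <- as.matrix(ape::cophenetic.phylo(tr))
  # T.turgidum was planted as the shallowest divergence from the focal taxon
  expect_equal(names(which.min(coph["T.aestivum",
                                    setdiff(colnames(coph), "T.aestivum")])),
               "T.turgidum")
  # duplicated-hit queries are excluded from the single-copy set
  dup_queries <- sprintf("lnc%04d.1", seq(1, 40, by = 5))
  expect_false(any(dup_queries %in% sc))
})
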