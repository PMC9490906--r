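ref1 <- make_ts(
  make_tx("ref1.1", list(c(100, 300), c(1000, 1200), c(2000, 2300)),
          gene = "ref1"),
  make_tx("ref2.1", list(c(5000, 5600)), gene = "ref2", strand = "-"))

test_that("class codes follow the structural predicates", {
  # single-exon query wholly inside intron 1 of a same-strand reference -> i
  q <- make_tx("q1", list(c(400, 700)))
  expect_equal(assign_class_code(q, ref1)$code, "i")
  # chromosome absent from the reference -> u
  q <- make_tx("q2", list(c(100, 300)), chrom = "chrZ")
  expect_equal(assign_class_code(q, ref1)$code, "u")
  # 2-exon query sharing reference intron (300, 1000) exactly -> j
  q <- make_tx("q3", list(c(200, 300), c(1000, 1500)))
  res <- assign_class_code(q, ref1)
  expect_equal(res$code, "j")
  expect_equal(res$ref_id, "ref1.1")
  # identical intron chain with exonic overlap -> =
  q <- make_tx("q4", list(c(150, 300), c(1000, 1200), c(2000, 2200)))
  expect_equal(assign_class_code(q, ref1)$code, "=")
  # exons nested in reference exons, introns a subset -> c
  q <- make_tx("q5", list(c(150, 250)))
  expect_equal(assign_class_code(q, ref1)$code, "c")
  # single exon spanning exon/intron boundary -> e
  q <- make_tx("q6", list(c(250, 500)))
  expect_equal(assign_class_code(q, ref1)$code, "e")
  # antisense exonic overlap -> x
  q <- make_tx("q7", list(c(5100, 5400)))
  expect_equal(assign_class_code(q, ref1)$code, "x")
  # same-strand exonic overlap extending outside -> o
  q <- make_tx("q8", list(c(2200, 2600)))
  expect_equal(assign_class_code(q, ref1)$code, "o")
  # multi-exon transcript wholly inside one intron still counts as i
  q <- make_tx("q9", list(c(320, 340), c(700, 900)))
  expect_equal(assign_class_code(q, ref1)$code, "i")
  # intron overlap without exon overlap or full containment falls to u
  # (the o predicate requires exonic overlap)
  q <- make_tx("q10", list(c(400, 500), c(4000, 4100)))
  expect_equal(assign_class_code(q, ref1)$code, "u")
  # zero exons rejected
  empty_q <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0))
  expect_error(assign_class_code(empty_q, ref1), "zero exons")
})

test_that("class-code assignment is invariant to reference input order", {
  set.seed(42)
  for (k in 1:20) {
    inst <- random_class_instance()
    code1 <- assign_class_code(inst$query, inst$reference)
    perm <- inst$reference$exons[sample(nrow(inst$reference$exons)), ]
    code2 <- assign_class_code(inst$query, transcript_set(perm))
    expect_identical(code1, code2)
  }
})

test_that("class codes agree with the brute-force per-base oracle", {
  set.seed(101)
  for (k in 1:150) {
    inst <- random_class_instance()
    got <- assign_class_code(inst$query, inst$reference)
    want <- oracle_class_code(inst$query, inst$reference)
    expect_identical(got, want,
                     label = sprintf("instance %d (%s)", k, got$code))
  }
})

test_that("expression filter applies strict FPKM bound and ceiling sample rule", {
  m <- matrix(0, 3, 186, dimnames = list(c("a", "b", "c"), NULL))
  m["a", 1:50] <- 0.2      # 50 >= ceiling(0.2*186) = 38 -> kept
  m["b", ] <- 0.1          # exactly at the bound everywhere -> dropped
  # c all zero -> dropped
  expect_equal(expression_filter(m, 0.1, 0.2), "a")
  m["a", ] <- 0
  m["a", 1:37] <- 0.2      # 37 < 38 -> dropped
  expect_equal(expression_filter(m, 0.1, 0.2), character(0))
  expect_warning(expression_filter(m[0, , drop = FALSE]), "empty")
})

test_that("raising expression thresholds never grows the kept set", {
  set.seed(5)
  m <- matrix(rexp(50 * 40), 50, 40,
              dimnames = list(sprintf("f%02d", 1:50), NULL))
  base <- expression_filter(m, 0.5, 0.2)
  expect_true(all(expression_filter(m, 0.8, 0.2) %in% base))
  expect_true(all(expression_filter(m, 0.5, 0.5) %in% base))
})

test_that("identify_lncrnas intersects the four rules and reports no-calls", {
  ref <- make_ts(make_tx("g1.1", list(c(1000, 2000), c(3000, 4000)), gene = "g1"))
  asm <- make_ts(
    make_tx("g1.1", list(c(1000, 2000), c(3000, 4000)), gene = "g1"),  # "=" -> out
    make_tx("lncA", list(c(10000, 10500))),       # u, passes everything
    make_tx("lncB", list(c(20000, 20150))),       # 150 bp -> too short
    make_tx("lncC", list(c(30000, 30500))),       # flagged coding by one tool
    make_tx("lncD", list(c(40000, 40500))),       # missing coding calls
    make_tx("lncE", list(c(50000, 50500))))       # not expressed
  expr <- matrix(5, 6, 20, dimnames = list(
    c("g1.1", "lncA", "lncB", "lncC", "lncD", "lncE"), NULL))
  expr["lncE", ] <- 0.05
  calls <- data.frame(
    transcript_id = rep(c("g1.1", "lncA", "lncB", "lncC"), each = 2),
    predictor = c("CPC", "LGC"),
    verdict = c("coding", "coding", "noncoding", "noncoding",
                "noncoding", "noncoding", "noncoding", "coding"))
  res <- identify_lncrnas(asm, ref, expr, calls)
  expect_equal(res$candidates$transcript_id, "lncA")
  expect_equal(res$candidates$class_code, "u")
  expect_equal(res$no_call, "lncD")
  expect_equal(unname(res$funnel["input"]), 6)
  expect_equal(unname(res$funnel["noncoding"]), 1)
})

test_that("feature_stats contrasts lncRNA and mRNA properties", {
  lnc <- make_ts(make_tx("l1", list(c(0, 400))),
                 make_tx("l2", list(c(1000, 1300))))
  mrna <- make_ts(make_tx("m1", list(c(0, 2000), c(3000, 5000)), gene = "m1"))
  seqs <- Biostrings::DNAStringSet(c(l1 = strrep("AT", 200),
                                     l2 = strrep("GC", 150),
                                     m1 = strrep("ATGC", 1000)))
  st <- feature_stats(lnc, mrna, sequences = seqs)
  expect_lt(st$summary$median_length[st$summary$class == "lncRNA"],
            st$summary$median_length[st$summary$class == "mRNA"])
  expect_equal(st$summary$gc_content[st$summary$class == "mRNA"], 0.5)
  expect_equal(st$summary$frac_single_exon[st$summary$class == "lncRNA"], 1)
  # GC of l1 (all AT) + l2 (all GC): 300/700
  expect_equal(st$summary$gc_content[st$summary$class == "lncRNA"], 300 / 700)
})
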