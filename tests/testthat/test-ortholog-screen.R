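test_that("self-alignment bit score matches the diagonal sum", {
  raw <- localAlignBitscore("WWWW", "WWWW", raw = TRUE)
  expect_equal(raw, 44)
  bits <- localAlignBitscore("WWWW", "WWWW")
  expect_equal(bits, (0.267 * 44 - log(0.041)) / log(2))
})

test_that("local alignment scores are symmetric and floored at zero", {
  set.seed(3)
  for (i in 1:10) {
    a <- aaString(sample(5:30, 1), 50 + i)
    b <- aaString(sample(5:30, 1), 80 + i)
    expect_equal(localAlignBitscore(a, b), localAlignBitscore(b, a))
  }
  # no positive-scoring residue pair: best local alignment is empty
  expect_equal(localAlignBitscore("AAAA", "WWWW", raw = TRUE), 0)
  expect_error(localAlignBitscore("", "MK"), "empty")
})

test_that("raw scores match exhaustive enumeration on short peptides", {
  mat <- blosum62()
  set.seed(9)
  for (i in 1:25) {
    a <- aaString(sample(3:6, 1), 200 + i)
    b <- aaString(sample(3:6, 1), 300 + i)
    expect_equal(localAlignBitscore(a, b, raw = TRUE),
                 oracleLocalScore(a, b, mat),
                 info = paste(a, b))
  }
})

test_that("score is monotone when the subject gains matching residues", {
  set.seed(21)
  for (i in 1:8) {
    q <- aaString(20, 400 + i)
    sub <- substr(q, 5, 12)
    ext <- paste0(sub, substr(q, 13, 16))  # extend with the query's residues
    expect_gte(localAlignBitscore(q, ext, raw = TRUE),
               localAlignBitscore(q, sub, raw = TRUE))
  }
})

test_that("best hit is the pairwise maximum over the database", {
  set.seed(5)
  q <- aaString(25, 1)
  db <- vapply(1:10, function(i) aaString(25, 600 + i), character(1))
  names(db) <- paste0("s", 1:10)
  bh <- bestHitScore(q, db)
  expect_equal(bh$bits, max(vapply(db, function(s)
    localAlignBitscore(q, s), numeric(1))))

  db2 <- c(db, exact = q)
  expect_equal(bestHitScore(q, db2)$subject, "exact")

  one <- bestHitScore(q, db[1])
  expect_true(one$hitCount %in% c(0L, 1L))
})

test_that("preliminary orthology rule is a strict two-way comparison", {
  expect_true(preliminaryOrthologyRule(50, 80, 70)$passed)
  tie <- preliminaryOrthologyRule(80, 80, 90)
  expect_false(tie$passed)
  expect_equal(tie$reason, "outgroup-score-not-smaller")
  expect_error(preliminaryOrthologyRule(NA, 80, 90), "missing score")

  set.seed(13)
  for (i in 1:1000) {
    tr <- stats::runif(3, 0, 100)
    got <- preliminaryOrthologyRule(tr[1], tr[2], tr[3])$passed
    expect_identical(got, tr[1] < tr[2] && tr[1] < tr[3])
  }
})

test_that("rule decision is invariant to adding a worse database member", {
  set.seed(33)
  q <- aaString(30, 2)
  db <- vapply(1:5, function(i) aaString(30, 700 + i), character(1))
  names(db) <- paste0("s", 1:5)
  base <- bestHitScore(q, db)
  worse <- c(db, w = substr(q, 1, 3))  # short fragment scores lower
  stopifnot(localAlignBitscore(q, worse[["w"]]) < base$bits)
  expect_equal(bestHitScore(q, worse)$bits, base$bits)
})

test_that("copy-number filter uses a strict threshold", {
  expect_false(copyNumberFilter(501)$passed)
  expect_equal(copyNumberFilter(501)$reason, "copy-number-exceeded")
  expect_true(copyNumberFilter(500)$passed)
  expect_true(copyNumberFilter(0)$passed)
})

test_that("end trimming removes exactly the gappy flanks", {
  dense <- GeneAlignment(c(a = aaString(40, 1), b = aaString(40, 2)))
  out <- trimAlignmentEnds(dense, window = 5, minOccupancy = 1)
  expect_equal(seqMatrix(out), seqMatrix(dense))

  core <- aaString(30, 3)
  gappy <- GeneAlignment(c(ref = paste0(strrep("-", 20), core),
                           oth = aaString(50, 4)))
  out <- trimAlignmentEnds(gappy, referenceTaxa = "ref", window = 5,
                           minOccupancy = 1)
  expect_equal(nSites(out), 30L)

  allgap <- GeneAlignment(c(ref = strrep("-", 30), oth = aaString(30, 5)))
  expect_error(trimAlignmentEnds(allgap, referenceTaxa = "ref",
                                 window = 5, minOccupancy = 1),
               "empty after trimming")
  expect_error(trimAlignmentEnds(dense, referenceTaxa = "zz"),
               "not in alignment")
})

test_that("trimming matches a direct column-scan reference", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 60
    m <- matrix(sample(c(chondroclock:::.AA_STATES, "-"), 3 * n,
                       replace = TRUE, prob = c(rep(0.03, 20), 0.4)),
                3, n, dimnames = list(c("r1", "r2", "o"), NULL))
    aln <- GeneAlignment(m)
    ref <- oracleTrim(m, c("r1", "r2"), window = 4, minOcc = 0.5,
                      missingChars = c("-", "X"))
    if (is.null(ref)) {
      expect_error(trimAlignmentEnds(aln, c("r1", "r2"), window = 4,
                                     minOccupancy = 0.5), "empty")
    } else {
      got <- trimAlignmentEnds(aln, c("r1", "r2"), window = 4,
                               minOccupancy = 0.5)
      expect_equal(unname(seqMatrix(got)), unname(ref))
    }
  }
})

test_that("screenGenes combines scores, rule and copy filter", {
  scores <- data.frame(gene = c("g1", "g2", "g3"),
                       s_co = c(50, 90, 40),
                       s_cs = c(80, 85, 90),
                       s_cr = c(70, 95, 95),
                       hit_count = c(3, 2, 600))
  out <- screenGenes(scores = scores)
  expect_equal(out$passed, c(TRUE, FALSE, FALSE))
  expect_equal(out$reason,
               c("passed", "outgroup-score-not-smaller",
                 "copy-number-exceeded"))
})

test_that("score-triple TSV loads and validates", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts_co\ts_cs\ts_cr", "g1\t50\t80\t70"), tf)
  tab <- readScoreTriples(tf)
  expect_equal(tab$s_cs, 80)
  writeLines(c("gene\ts_co\ts_cs\ts_cr", "g1\t-5\t80\t70"), tf)
  expect_error(readScoreTriples(tf), "non-negative")
})
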