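test_that("FASTA reading parses, normalizes and validates", {
  tf <- tempfile(fileext = ".fa")
  writeLines(c(">a", "MK", ">b", "M-"), tf)
  s <- readFasta(tf)
  expect_equal(unname(nchar(s)), c(2L, 2L))
  expect_named(s, c("a", "b"))

  writeLines(c(">a", "mkv"), tf)
  expect_equal(unname(readFasta(tf)["a"]), "MKV")

  writeLines(character(), tf)
  expect_error(readFasta(tf), "no records")

  writeLines(c(">a", "MK", ">a", "MR"), tf)
  expect_error(readFasta(tf), "duplicate")

  writeLines(c(">a", "MKJ"), tf)
  expect_error(readFasta(tf, alphabet = "AA"), "position 3")
})

test_that("FASTA round-trips through write and read", {
  set.seed(42)
  for (rep in 1:5) {
    seqs <- vapply(1:6, function(i) aaString(sample(10:40, 1), rep * 10 + i),
                   character(1))
    names(seqs) <- paste0("sp", 1:6)
    tf <- tempfile(fileext = ".fa")
    writeFasta(seqs, tf)
    back <- readFasta(tf)
    expect_equal(unname(back[names(seqs)]), unname(seqs))
  }
})

test_that("concatenation sums columns and records partitions", {
  a <- GeneAlignment(c(x = "MK", y = "MR"))
  b <- GeneAlignment(c(x = "V", y = "I"))
  cc <- concatenateAlignments(list(a, b), c("g1", "g2"))
  expect_equal(nSites(cc), 3L)
  expect_equal(genePartitions(cc)$start, c(0L, 2L))
  expect_equal(genePartitions(cc)$end, c(2L, 3L))

  one <- concatenateAlignments(list(a), "g1")
  expect_equal(seqMatrix(one), seqMatrix(a))

  u <- GeneAlignment(c(x = "M", y = "K"))
  v <- GeneAlignment(c(x = "V", y = "I"))
  two <- concatenateAlignments(list(u, v), c("p", "q"))
  expect_equal(genePartitions(two)$start, c(0L, 1L))
  expect_equal(genePartitions(two)$end, c(1L, 2L))
})

test_that("taxon-set mismatch errors unless padMissing", {
  a <- GeneAlignment(c(x = "MK", y = "MR"))
  b <- GeneAlignment(c(x = "V", z = "I"))
  expect_error(concatenateAlignments(list(a, b)), "taxon sets differ")
  cc <- concatenateAlignments(list(a, b), padMissing = TRUE)
  expect_equal(sort(taxonNames(cc)), c("x", "y", "z"))
  expect_equal(paste(seqMatrix(cc)["z", ], collapse = ""), "--I")
})

test_that("concatenate then split-by-partition reproduces the inputs", {
  set.seed(7)
  alns <- lapply(1:4, function(i) {
    seqs <- vapply(1:3, function(j) aaString(10 + i, 100 * i + j),
                   character(1))
    names(seqs) <- c("a", "b", "c")
    GeneAlignment(seqs)
  })
  cc <- concatenateAlignments(alns, paste0("g", 1:4))
  back <- splitByPartition(cc)
  for (i in 1:4)
    expect_equal(seqMatrix(back[[i]])[taxonNames(alns[[i]]), ],
                 seqMatrix(alns[[i]]))
})

test_that("complete deletion keeps exactly the fully determined columns", {
  aln <- GeneAlignment(c(a = "AAC", b = "A-C"))
  out <- completeDeletion(aln)
  expect_equal(nSites(out), 2L)
  expect_equal(paste(seqMatrix(out)["a", ], collapse = ""), "AC")

  clean <- GeneAlignment(c(a = "MKV", b = "MRV"))
  expect_equal(seqMatrix(completeDeletion(clean)), seqMatrix(clean))

  # random alignment vs per-column scan oracle, and idempotence
  set.seed(11)
  m <- matrix(sample(c(chondroclock:::.AA_STATES, "-", "X"), 400,
                     replace = TRUE, prob = c(rep(0.04, 20), 0.1, 0.1)),
              4, 100, dimnames = list(paste0("t", 1:4), NULL))
  aln <- GeneAlignment(m)
  out <- completeDeletion(aln)
  keepOracle <- sum(apply(m, 2, function(col) !any(col %in% c("-", "X"))))
  expect_equal(nSites(out), keepOracle)
  expect_equal(seqMatrix(completeDeletion(out)), seqMatrix(out))
})

test_that("newick parsing and writing round-trip", {
  tr <- readNewick("(((Hs,(Gg,Md)),((Ol,Fr),Dr)),Xt);")
  expect_equal(length(tr$tip.label), 7L)

  tr2 <- readNewick("(a:1,b:2);")
  expect_equal(sort(tr2$edge.length), c(1, 2))

  expect_error(readNewick("((a,b);"), "parse error")
  expect_error(readNewick("(a,a);"), "duplicate")

  for (i in 1:100) {
    tr <- randomTree(sample(4:12, 1), i)
    s <- writeNewick(tr)
    expect_equal(writeNewick(readNewick(s)), s)
  }
})

test_that("calibration tables read and validate", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("clade_tips\tlower_Ma\tupper_Ma\tstyle",
               "a,b\t100\t200\tsoft",
               "a,c\t250\tNA\thard-lower"), tf)
  cal <- readCalibrations(tf)
  expect_equal(cal$clade_tips[[1]], c("a", "b"))
  expect_equal(cal$lower_Ma, c(100, 250))

  writeLines(c("clade_tips\tlower_Ma\tupper_Ma\tstyle",
               "a,b\t300\t200\tsoft"), tf)
  expect_error(readCalibrations(tf), "lower >= upper")
  writeLines(c("clade_tips\tlower_Ma\tupper_Ma\tstyle",
               "a,b\t100\t200\thard-lower"), tf)
  expect_error(readCalibrations(tf), "upper bound")
})

test_that("GeneAlignment validity catches bad input", {
  expect_error(GeneAlignment(c(a = "MK", b = "MKV")), "not aligned")
  expect_error(GeneAlignment(c(a = "MJ", b = "MK"), alphabet = "AA"),
               "illegal character")
  expect_error(GeneAlignment(c("MK", "MR")), "rownames")
})
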