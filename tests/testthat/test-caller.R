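test_that("resolution collapse descends until tied pairs agree", {
  # single best pair: reported at full resolution
  r <- collapseResolution(list(c("A*02:01:01", "A*03:01:01")))
  expect_equal(r$alleles, c("A*02:01:01", "A*03:01:01"))
  expect_equal(r$resolution, "full")
  expect_false(r$ambiguous)

  # divergence at six-digit collapses to a four-digit consensus
  r <- collapseResolution(list(c("A*02:01:01", "A*03:01:01"),
                               c("A*02:01:02", "A*03:01:01")))
  expect_equal(r$alleles, c("A*02:01", "A*03:01"))
  expect_equal(r$resolution, "4")
  expect_false(r$ambiguous)

  # divergence at eight-digit collapses to six
  r <- collapseResolution(list(c("A*02:01:01:01", "A*03:01:01:01"),
                               c("A*02:01:01:02", "A*03:01:01:01")))
  expect_equal(r$alleles, c("A*02:01:01", "A*03:01:01"))
  expect_equal(r$resolution, "6")

  # divergence at four-digit: ambiguous, all pairs listed
  r <- collapseResolution(list(c("A*02:01", "A*03:01"),
                               c("A*02:05", "A*03:01")))
  expect_true(r$ambiguous)
  expect_equal(length(r$pairs), 2L)

  # never deeper than the shallowest tied name
  r <- collapseResolution(list(c("A*02:01", "A*03:01:01"),
                               c("A*02:01", "A*03:01:02")))
  expect_equal(r$resolution, "4")
  expect_equal(r$alleles, c("A*02:01", "A*03:01"))
})

test_that("prediction accuracy reproduces hand-computed values on a fixture", {
  truth <- data.frame(
    locus = c("A", "B", "C", "DQA1", "DQB1"),
    allele1 = c("A*01:01", "B*02:01", "C*03:01", "DQA1*04:01", "DQB1*05:01"),
    allele2 = c("A*11:01", "B*02:01", "C*07:02", "DQA1*04:02", "DQB1*05:01"))
  calls <- data.frame(
    locus = c("A", "B", "C", "DQA1", "DQB1"),
    allele1 = c("A*01:01", "B*02:01", NA, "DQA1*09:01", "DQB1*05:01"),
    allele2 = c("A*11:01", "B*03:01", NA, "DQA1*10:01", "DQB1*05:01"),
    ambiguous = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # A: 2/2; B: hom truth vs het call sharing one allele: 1/2;
  # C: ambiguous: 0/2; DQA1: both wrong: 0/2; DQB1: 2/2  -> 5/10
  acc <- scorePredictions(calls, truth, 4L)
  expect_equal(as.numeric(acc), 0.5)
  expect_equal(attr(acc, "correct"), 5L)
  expect_equal(attr(acc, "total"), 10L)

  # at two-digit, DQA1*09/10 still mismatch *04 but B still scores 1/2
  expect_equal(as.numeric(scorePredictions(calls, truth, 2L)), 0.5)

  # loci missing from the truth table leave the denominator
  acc2 <- scorePredictions(calls, truth[truth$locus != "C", ], 4L)
  expect_equal(attr(acc2, "total"), 8L)
  expect_equal(as.numeric(acc2), 5 / 8)

  # perfect calls
  perfect <- data.frame(locus = truth$locus, allele1 = truth$allele1,
                        allele2 = truth$allele2, ambiguous = FALSE)
  expect_equal(as.numeric(scorePredictions(perfect, truth, 4L)), 1.0)

  # a one-allele report counts as homozygous
  one <- data.frame(locus = "B", allele1 = "B*02:01", allele2 = NA_character_,
                    ambiguous = FALSE)
  accb <- scorePredictions(one, truth[truth$locus == "B", ], 4L)
  expect_equal(as.numeric(accb), 1.0)
})

test_that("an empty alignment yields an explicit no-call", {
  db <- buildToyDb(simConfig(n_loci = 1, alleles_per_locus = 4,
                             groups_per_locus = 2, seed = 3))
  sam <- tempfile(fileext = ".sam")
  wd <- setNames(Biostrings::width(db@genomic), names(db@genomic))
  writeTinySam(sam, wd, list())
  res <- typeHLA(sam, db)
  expect_equal(res$status, "no_reads")
  expect_true(is.na(res$allele1))
  expect_equal(res$n_reads_used, 0L)
  unlink(sam)
})

test_that("heterozygous and homozygous truths are recovered end to end", {
  db <- buildToyDb(simConfig(n_loci = 1, seed = 21))
  als <- alleleNames(db, "A")
  het <- data.frame(locus = "A", allele1 = als[1], allele2 = als[10])
  hom <- data.frame(locus = "A", allele1 = als[4], allele2 = als[4])
  cfg <- simConfig(n_loci = 1, coverage = 100, seed = 22)
  for (truth in list(het, hom)) {
    reads <- simulateReads(db, truth, cfg)
    aln <- alignSimReads(reads, db)
    sam <- tempfile(fileext = ".sam")
    writeSimSam(aln, db, sam)
    res <- suppressWarnings(typeHLA(sam, db))
    expect_equal(as.numeric(scorePredictions(res, truth, 4L)), 1.0)
    got_hom <- renderAllele(res$allele1, 4) == renderAllele(res$allele2, 4)
    want_hom <- renderAllele(truth$allele1, 4) == renderAllele(truth$allele2, 4)
    expect_equal(got_hom, want_hom)
    unlink(sam)
  }
})

test_that("p-values are reported but never drive the called pair", {
  db <- buildToyDb(simConfig(n_loci = 1, seed = 31))
  als <- alleleNames(db, "A")
  truth <- data.frame(locus = "A", allele1 = als[1], allele2 = als[7])
  cfg <- simConfig(n_loci = 1, coverage = 80, seed = 32)
  reads <- simulateReads(db, truth, cfg)
  aln <- alignSimReads(reads, db)
  rs <- HLApair:::readSetsFromAlignments(aln, db)
  out <- suppressWarnings(callLocus(rs[["A"]], db))
  # decision comes from the likelihood table alone: the called pair is
  # the ll_total argmax regardless of any p-value
  best <- out$pairs[1, ]
  expect_setequal(renderAllele(c(out$result$allele1, out$result$allele2), 4),
                  renderAllele(c(best$allele1, best$allele2), 4))
  # reported p-values belong to the called alleles' groups
  expect_true(all(is.na(out$result[, c("p_value_1", "p_value_2")]) |
                  (out$result$p_value_1 >= 0 & out$result$p_value_1 <= 1)))
})

test_that("typing output is byte-identical across repeated runs", {
  db <- buildToyDb(simConfig(n_loci = 2, seed = 41))
  truth <- drawTruth(db, 0)
  cfg <- simConfig(n_loci = 2, coverage = 50, seed = 42)
  reads <- simulateReads(db, truth, cfg)
  aln <- alignSimReads(reads, db)
  sam <- tempfile(fileext = ".sam")
  writeSimSam(aln, db, sam)
  out1 <- tempfile(); out2 <- tempfile()
  suppressWarnings(typeHLA(sam, db, out = out1))
  suppressWarnings(typeHLA(sam, db, out = out2))
  expect_identical(readLines(out1), readLines(out2))
  expect_identical(unname(tools::md5sum(out1)), unname(tools::md5sum(out2)))
  unlink(c(sam, out1, out2))
})
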