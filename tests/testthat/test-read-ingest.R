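test_that("SAM ingestion projects reads onto the locus frame", {
  # allele with genomic offset 100: contig pos 10 (0-based) -> frame 110
  db <- tinyDb(c("A*02:01" = paste(rep("A", 60), collapse = ""),
                 "A*02:05" = paste(rep("A", 60), collapse = "")),
               offsets = c("A*02:01" = 100L, "A*02:05" = 100L))
  sam <- tempfile(fileext = ".sam")
  writeTinySam(sam, c("A*02:01" = 60L, "A*02:05" = 60L), list(
    list(qname = "r1", flag = 0L, rname = "A*02:01", pos1 = 11L,
         cigar = "10M", seq = paste(rep("A", 10), collapse = "")),
    list(qname = "r1", flag = 256L, rname = "A*02:05", pos1 = 11L,
         cigar = "10M", seq = paste(rep("A", 10), collapse = ""))))
  rs <- ingestAlignments(sam, db)
  o <- readObservations(rs[["A"]])
  expect_equal(nrow(o), 1L)                      # two alignments, one observation
  expect_equal(o$hits[[1]], c("A*02:01", "A*02:05"))
  expect_equal(o$pos[[1]], 110:119)
  expect_equal(o$quals[[1]], rep(30L, 10))       # '*' qualities -> default Phred
  unlink(sam)
})

test_that("CIGAR insertions/deletions/clips are honoured in projection", {
  db <- tinyDb(c("A*02:01" = paste(rep("A", 60), collapse = "")))
  sam <- tempfile(fileext = ".sam")
  # 3S skips read bases; 4M; 2D skips frame; 3M; 2I skips read; 2M
  writeTinySam(sam, c("A*02:01" = 60L), list(
    list(qname = "r1", flag = 0L, rname = "A*02:01", pos1 = 6L,
         cigar = "3S4M2D3M2I2M", seq = "TTTACGTCCAGGAT")))
  rs <- ingestAlignments(sam, db)
  o <- readObservations(rs[["A"]])
  expect_equal(o$pos[[1]], c(5:8, 11:13, 14:15))
  expect_equal(paste(o$bases[[1]], collapse = ""), "ACGTCCAAT")
  unlink(sam)
})

test_that("alignments to unknown contigs are skipped with a count", {
  db <- tinyDb(c("A*02:01" = paste(rep("A", 60), collapse = "")))
  sam <- tempfile(fileext = ".sam")
  writeTinySam(sam, c("A*02:01" = 60L, "chrUn" = 60L), list(
    list(qname = "r1", flag = 0L, rname = "A*02:01", pos1 = 1L,
         cigar = "5M", seq = "AAAAA"),
    list(qname = "r2", flag = 0L, rname = "chrUn", pos1 = 1L,
         cigar = "5M", seq = "AAAAA")))
  expect_warning(rs <- ingestAlignments(sam, db), "skipped")
  expect_equal(attr(rs, "skipped"), 1L)
  expect_equal(nrow(readObservations(rs[["A"]])), 1L)
  unlink(sam)
})

test_that("optimal marking takes the SNP-site identity argmax with ties", {
  # 5 SNP sites; read matches a at 5/5, b at 4/5
  db <- tinyDb(c("A*01:01" = "ACGTA", "A*02:01" = "ACGTC", "A*03:01" = "TGCAG"))
  sites <- snpSites(db, "A")
  expect_equal(sites, 0:4)
  rs <- makeReadSet("A", list(
    list(uid = "r1/1", pos = 0:4, bases = c("A", "C", "G", "T", "A")),
    list(uid = "r2/1", pos = 0:3, bases = c("A", "C", "G", "T")),  # tie a/b
    list(uid = "r3/1", pos = 10:12, bases = c("A", "A", "A"))))    # no SNP site
  rs <- markOptimalReads(rs, db, alleleNames(db, "A"), sites)
  o <- readObservations(rs)
  expect_equal(o$optimal[[1]], "A*01:01")
  expect_equal(o$optimal[[2]], c("A*01:01", "A*02:01"))
  expect_equal(o$optimal[[3]], character(0))
})

test_that("the 99% identity floor is applied literally at the boundary", {
  a1 <- paste(rep("A", 150), collapse = "")
  a2 <- paste(rep("C", 150), collapse = "")
  db <- tinyDb(c("A*01:01" = a1, "A*02:01" = a2))
  sites <- snpSites(db, "A")
  mk <- function(nbad) {
    b <- rep("A", 100)
    if (nbad > 0) b[seq_len(nbad)] <- "G"   # matches neither allele
    makeReadSet("A", list(list(uid = "r/1", pos = 0:99, bases = b)))
  }
  o99 <- readObservations(markOptimalReads(mk(1), db, alleleNames(db, "A"), sites))
  o98 <- readObservations(markOptimalReads(mk(2), db, alleleNames(db, "A"), sites))
  expect_equal(o99$optimal[[1]], "A*01:01")        # 99/100 = 0.99 >= 0.99
  expect_equal(o98$optimal[[1]], character(0))     # 98/100 < 0.99
  # identity agrees with the naive computation
  M <- frameBaseMatrix(db, "A")
  expect_equal(oracleIdentity(0:99, c("G", rep("A", 99)), M[, "A*01:01"]), 0.99)
})

test_that("non-SNP mismatches never affect optimality", {
  # alleles differ only at site 0; read mismatches both at non-SNP positions
  db <- tinyDb(c("A*01:01" = "AAAAAAA", "A*02:01" = "CAAAAAA"))
  expect_equal(snpSites(db, "A"), 0L)
  rs <- makeReadSet("A", list(
    list(uid = "r/1", pos = 0:6, bases = c("A", "T", "T", "T", "T", "T", "T"))))
  o <- readObservations(markOptimalReads(rs, db, alleleNames(db, "A")))
  expect_equal(o$optimal[[1]], "A*01:01")
})

test_that("removing a non-argmax allele never shrinks a read's optimal set", {
  for (seed in 1:10) {
    inst <- randomScoringInstance(n_alleles = 5, n_sites = 12,
                                  n_reads = 15, seed = 300 + seed)
    db <- inst$db
    sites <- snpSites(db, "A")
    rs <- makeReadSet("A", lapply(split(inst$snpTab, inst$snpTab$uid), function(t) {
      list(uid = t$uid[1], pos = t$site, bases = t$base,
           quals = rep(30L, nrow(t)))
    }))
    full <- readObservations(markOptimalReads(rs, db, inst$alleles, sites,
                                              min_identity = 0))
    for (drop in inst$alleles) {
      keep <- setdiff(inst$alleles, drop)
      red <- readObservations(markOptimalReads(rs, db, keep, sites,
                                               min_identity = 0))
      for (i in seq_len(nrow(full))) {
        if (!(drop %in% full$optimal[[i]])) {
          expect_true(all(full$optimal[[i]] %in% red$optimal[[i]]),
                      info = paste("seed", seed, "drop", drop, "read", i))
        }
      }
    }
  }
})

test_that("error-free simulated reads are optimal for their source allele", {
  db <- buildToyDb(simConfig(n_loci = 1, seed = 5))
  truth <- data.frame(locus = "A", allele1 = alleleNames(db, "A")[1],
                      allele2 = alleleNames(db, "A")[7])
  cfg <- simConfig(n_loci = 1, coverage = 20, error_rate = 0, seed = 9)
  reads <- simulateReads(db, truth, cfg)
  aln <- alignSimReads(reads, db)
  rs <- HLApair:::readSetsFromAlignments(aln, db)[["A"]]
  sites <- snpSites(db, "A")
  rs <- markOptimalReads(rs, db, alleleNames(db, "A"), sites)
  o <- readObservations(rs)
  src <- setNames(paste0(reads$qname, "/", reads$mate), NULL)
  srcmap <- setNames(reads$source, paste0(reads$qname, "/", reads$mate))
  covering <- lengths(lapply(o$pos, function(p) intersect(p, sites))) > 0
  for (i in which(covering)) {
    expect_true(srcmap[[o$uid[i]]] %in% o$optimal[[i]],
                info = o$uid[i])
  }
})
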