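test_that("per-base genotype model matches direct evaluation and sums to one", {
  # perfect-match limit
  expect_equal(baseGenotypeLik("A", "A", "A", 1e-12), 1, tolerance = 1e-9)
  # homozygous mismatch: q/3
  expect_equal(baseGenotypeLik("C", "A", "A", 0.001), 0.001 / 3)
  expect_equal(log(baseGenotypeLik("C", "A", "A", 0.001)), -8.006368,
               tolerance = 1e-6)
  # heterozygous match on one allele
  expect_equal(baseGenotypeLik("A", "A", "C", 0.01),
               0.5 * 0.99 + 0.5 * 0.01 / 3)
  # the 4-outcome distribution sums to 1 for several q, hom and het
  for (q in c(1e-6, 0.001, 0.01, 0.2, 0.5)) {
    expect_equal(sum(baseGenotypeLik(c("A", "C", "G", "T"), "A", "A", q)), 1)
    expect_equal(sum(baseGenotypeLik(c("A", "C", "G", "T"), "A", "G", q)), 1)
  }
})

test_that("two-site phase model has the 1+15 state structure and sums to one", {
  bases <- c("A", "C", "G", "T")
  states <- expand.grid(di = bases, dj = bases, stringsAsFactors = FALSE)
  for (q in c(0.001, 0.01, 0.1)) {
    # single phased haplotype (self-pair): 1 in-phase + 15 out-of-phase
    p <- pairPhaseLik(states$di, states$dj, "A", "G", "A", "G", q, q)
    qij <- 1 - (1 - q)^2
    expect_equal(sum(p), 1)
    expect_equal(sum(abs(p - (1 - qij)) < 1e-12), 1L)
    expect_equal(sum(abs(p - qij / 15) < 1e-12), 15L)
  }
  # perfect-match limit
  expect_equal(pairPhaseLik("A", "G", "A", "G", "A", "G", 1e-12, 1e-12), 1,
               tolerance = 1e-9)
})

test_that("frequency log-likelihood sums log group priors with the floor", {
  freq <- data.frame(group = c("A*02:01", "A*03:01"),
                     population = c("EUR", "EUR"),
                     frequency = c(0.27, 0.15))
  db <- tinyDb(c("A*02:01" = "AAAA", "A*03:01" = "CCCC", "A*09:01" = "GGGG"),
               freq = freq)
  expect_equal(freqLogLik(c("A*02:01", "A*03:01"), db),
               log(0.27) + log(0.15))
  expect_equal(freqLogLik(c("A*02:01", "A*03:01"), db), -3.2064533,
               tolerance = 1e-6)
  # self-pair
  db5 <- tinyDb(c("A*02:01" = "AAAA", "A*03:01" = "CCCC"),
                freq = data.frame(group = "A*02:01", population = "EUR",
                                  frequency = 0.5))
  expect_equal(freqLogLik(c("A*02:01", "A*02:01"), db5), 2 * log(0.5))
  # unrecorded allele sits at the floor
  expect_equal(freqLogLik(c("A*09:01", "A*09:01"), db), 2 * log(1e-6))
})

test_that("true phase beats the recombinant phase on consistent reads", {
  # a = (A,A), b = (C,C) at two sites; recombinants ar = (A,C), br = (C,A)
  db <- tinyDb(c("A*01:01" = "AA", "A*02:01" = "CC",
                 "A*03:01" = "AC", "A*04:01" = "CA"))
  M <- frameBaseMatrix(db, "A")
  snpTab <- do.call(rbind, lapply(1:10, function(i) {
    b <- if (i %% 2) c("A", "A") else c("C", "C")
    data.frame(uid = sprintf("r%d/1", i), qname = sprintf("r%d", i),
               site = 0:1, base = b, q = 0.001)
  }))
  up <- phaseUnitPairs(snpTab)
  ll_true <- phaseLogLik(c("A*01:01", "A*02:01"), up, M)
  ll_rec <- phaseLogLik(c("A*03:01", "A*04:01"), up, M)
  expect_gt(ll_true, ll_rec)
  # no informative units -> no phase evidence
  expect_equal(phaseLogLik(c("A*01:01", "A*02:01"),
                           phaseUnitPairs(snpTab[snpTab$site == 0, ]), M), 0)
})

test_that("linked mates form one phase-informative unit", {
  db <- tinyDb(c("A*01:01" = "AAAA", "A*02:01" = "CCCC"))
  # two mates of one fragment, covering one site each
  snpTab <- data.frame(uid = c("f1/1", "f1/2"), qname = c("f1", "f1"),
                       site = c(0L, 3L), base = c("A", "A"), q = 0.01)
  up <- phaseUnitPairs(snpTab)
  expect_equal(nrow(up), 1L)
  expect_equal(up$site_i, 0L)
  expect_equal(up$site_j, 3L)
  # two unpaired reads covering one site each: no unit
  snpTab2 <- transform(snpTab, uid = c("f1/1", "f2/1"), qname = c("f1", "f2"))
  expect_equal(nrow(phaseUnitPairs(snpTab2)), 0L)
})

test_that("all pairs including self-pairs are scored, symmetrically", {
  inst <- randomScoringInstance(5, 10, 30, seed = 77)
  up <- phaseUnitPairs(inst$snpTab)
  sc <- scoreAllPairs(inst$alleles, inst$snpTab, up, inst$M, inst$db)
  expect_equal(nrow(sc), 5 * 6 / 2)
  expect_equal(sc$ll_total, sc$ll_geno + sc$ll_phase + sc$ll_freq)
  expect_true(all(sc$ll_total <= 0))
  # unordered: the scorer canonicalises pair order, so (a,b) == (b,a)
  g1 <- genotypeLogLik(c(inst$alleles[1], inst$alleles[2]), inst$snpTab, inst$M)
  g2 <- genotypeLogLik(c(inst$alleles[2], inst$alleles[1]), inst$snpTab, inst$M)
  expect_equal(g1, g2)
  expect_equal(nrow(scoreAllPairs(character(), inst$snpTab, up, inst$M,
                                  inst$db)), 0L)
})

test_that("flipping a pair-consistent base to an inconsistent one lowers the score", {
  db <- tinyDb(c("A*01:01" = "AAAA", "A*02:01" = "AACA"))
  M <- frameBaseMatrix(db, "A")
  tab <- data.frame(uid = "r1/1", qname = "r1", site = 2L, base = "A",
                    q = 0.01)
  bad <- transform(tab, base = "G")   # consistent with neither allele
  pair <- c("A*01:01", "A*02:01")
  expect_gt(genotypeLogLik(pair, tab, M), genotypeLogLik(pair, bad, M))
})

test_that("pair scores match the naive brute-force scorer", {
  for (seed in 1:25) {
    set.seed(1000 + seed)
    inst <- randomScoringInstance(n_alleles = sample(2:8, 1),
                                  n_sites = sample(5:30, 1),
                                  n_reads = sample(20:120, 1),
                                  seed = 2000 + seed)
    up <- phaseUnitPairs(inst$snpTab)
    sc <- scoreAllPairs(inst$alleles, inst$snpTab, up, inst$M, inst$db)
    for (r in sample(seq_len(nrow(sc)), min(6, nrow(sc)))) {
      want <- oracleScorePair(sc$allele1[r], sc$allele2[r], inst$snpTab,
                              inst$M, inst$db@frequencies,
                              inst$db@freqFloor)
      expect_equal(sc$ll_geno[r], unname(want["ll_geno"]), tolerance = 1e-9)
      expect_equal(sc$ll_phase[r], unname(want["ll_phase"]), tolerance = 1e-9)
      expect_equal(sc$ll_freq[r], unname(want["ll_freq"]), tolerance = 1e-9)
      expect_equal(sc$ll_total[r], unname(want["ll_total"]), tolerance = 1e-9)
    }
  }
})

test_that("the frequency prior only breaks data ties", {
  # two alleles CDS-identical within reads' reach: data cannot separate
  # the self-pairs; the prior decides, and removing it leaves a tie
  freq <- data.frame(group = c("A*02:01", "A*03:01"),
                     population = "EUR", frequency = c(0.3, 0.05))
  db <- tinyDb(c("A*02:01" = "AAAA", "A*03:01" = "AAAA",
                 "A*05:01" = "CCCC"), freq = freq)
  M <- frameBaseMatrix(db, "A")
  tab <- data.frame(uid = "r1/1", qname = "r1", site = 0L, base = "A",
                    q = 0.001)
  up <- phaseUnitPairs(tab)
  sc <- scoreAllPairs(c("A*02:01", "A*03:01"), tab, up, M, db)
  expect_equal(sc$allele1[1], "A*02:01")
  expect_equal(sc$allele2[1], "A*02:01")   # higher prior wins the tie
  expect_equal(length(unique(sc$ll_geno)), 1L)  # data part is tied
  # without the prior all three pairs tie exactly
  expect_equal(length(unique(sc$ll_geno + sc$ll_phase)), 1L)
})
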