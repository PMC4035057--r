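# Small hand-built fixtures used across test files. Everything is
# constructed in code; no binary data.

# A database from explicit genomic sequences; CDS = full genomic span
# (single exon) unless an exon table is supplied.
tinyDb <- function(genomic, cds = NULL, exons = NULL, freq = NULL,
                   floor = 1e-6, offsets = NULL) {
  if (is.null(cds)) cds <- genomic
  if (is.null(exons)) {
    exons <- do.call(rbind, lapply(names(cds), function(a) {
      data.frame(allele = a, exon = 1L, frame_start = 0L,
                 frame_end = nchar(cds[[a]]), cds_start = 0L)
    }))
  }
  HLAAlleleDb(genomic, cds, exons, genomic_offset = offsets,
              frequencies = freq, freqFloor = floor)
}

# A database whose locus alignment is given as a gapped character
# matrix (rows = frame positions, cols = alleles, NA = gap/deletion).
# CDS = the non-gap characters; exon blocks = runs of coverage.
dbFromAlignment <- function(locus, aln) {
  genomic <- character(); cds <- character(); exons <- NULL
  for (a in colnames(aln)) {
    col <- aln[, a]
    cov <- !is.na(col)
    seqc <- paste(col[cov], collapse = "")
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    blk <- which(r$values)
    cds_off <- 0L
    for (bi in seq_along(blk)) {
      b <- blk[bi]
      w <- r$lengths[b]
      exons <- rbind(exons, data.frame(
        allele = a, exon = bi, frame_start = starts[b] - 1L,
        frame_end = ends[b], cds_start = cds_off))
      cds_off <- cds_off + w
    }
    genomic[a] <- seqc
    cds[a] <- seqc
  }
  HLAAlleleDb(genomic, cds, exons)
}

# Build a LocusReadSet from a list of observations. Each observation:
# list(uid, pos, bases, quals, hits, mate = 1L, qname = sub("/.*","",uid)).
makeReadSet <- function(locus, obs_list) {
  obs <- data.frame(
    uid = vapply(obs_list, `[[`, character(1), "uid"),
    qname = vapply(obs_list, function(o) {
      if (!is.null(o$qname)) o$qname else sub("/.*$", "", o$uid)
    }, character(1)),
    mate = vapply(obs_list, function(o) {
      if (!is.null(o$mate)) o$mate else 1L
    }, integer(1)),
    stringsAsFactors = FALSE)
  obs$hits <- lapply(obs_list, function(o) {
    if (!is.null(o$hits)) o$hits else character()
  })
  obs$pos <- lapply(obs_list, function(o) as.integer(o$pos))
  obs$bases <- lapply(obs_list, `[[`, "bases")
  obs$quals <- lapply(obs_list, function(o) {
    if (!is.null(o$quals)) as.integer(o$quals) else rep(30L, length(o$pos))
  })
  obs$optimal <- rep(list(character()), nrow(obs))
  new("LocusReadSet", locus = locus, observations = obs)
}

# Write a SAM file from alignment rows: list(qname, flag, rname, pos1,
# cigar, seq, qual = NULL).
writeTinySam <- function(path, contigs, rows) {
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), unname(contigs)))
  for (r in rows) {
    qual <- if (is.null(r$qual)) "*" else r$qual
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                              r$qname, r$flag, r$rname, r$pos1, r$cigar,
                              r$seq, qual))
  }
  writeLines(lines, path)
  path
}

# Random likelihood-scoring instance: a locus of n_alleles over
# n_sites, reads covering contiguous site windows with random bases
# and qualities. Returns the pieces both the package path and the
# oracle consume.
randomScoringInstance <- function(n_alleles, n_sites, n_reads, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  alleles <- sprintf("A*%02d:%02d", rep(1:ceiling(n_alleles / 2), each = 2)[1:n_alleles],
                     rep(1:2, length.out = n_alleles))
  aln <- matrix(sample(bases, n_sites * n_alleles, replace = TRUE),
                nrow = n_sites, dimnames = list(NULL, alleles))
  genomic <- apply(aln, 2, paste, collapse = "")
  groups <- unique(proteinGroupId(alleles))
  freq <- data.frame(group = rep(groups, each = 2),
                     population = rep(c("EUR", "ASIA"), length(groups)),
                     frequency = round(runif(2 * length(groups), 0.01, 0.5), 4))
  # leave one group unrecorded now and then, to exercise the floor
  if (length(groups) > 1 && runif(1) < 0.3) {
    freq <- freq[freq$group != groups[length(groups)], , drop = FALSE]
  }
  db <- tinyDb(genomic, freq = freq)
  rows <- lapply(seq_len(n_reads), function(i) {
    w <- sample.int(min(4L, n_sites), 1L)
    s0 <- sample.int(n_sites - w + 1L, 1L) - 1L
    sites <- s0 + 0:(w - 1L)
    src <- sample(alleles, 1L)
    obs <- aln[sites + 1L, src]
    flip <- runif(w) < 0.1
    obs[flip] <- sample(bases, sum(flip), replace = TRUE)
    data.frame(uid = sprintf("r%04d/1", i), qname = sprintf("r%04d", i),
               site = sites, base = unname(obs),
               q = 10^(-sample(10:40, w, replace = TRUE) / 10),
               stringsAsFactors = FALSE)
  })
  snpTab <- do.call(rbind, rows)
  list(db = db, alleles = alleles, M = frameBaseMatrix(db, "A"),
       snpTab = snpTab)
}
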