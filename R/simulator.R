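#' Simulation configuration
#'
#' Parameters of the toy allele database and read simulator. Defaults
#' emulate a common short-read regime: kb-scale loci, 2x100 bp
#' paired-end reads at 100-fold coverage with a 0.001 per-base
#' substitution error (Phred 30). Read lengths from 37 to 250 bp and
#' coverage from tens- to hundreds-fold are the intended operating
#' range. The seed fully determines all output.
#'
#' @param n_loci number of loci in the toy database.
#' @param alleles_per_locus alleles per locus.
#' @param groups_per_locus protein groups per locus.
#' @param seq_length genomic length of each locus (bases).
#' @param snp_density fraction of CDS positions carrying planted
#'   polymorphism.
#' @param read_length read length in bases (37-250 typical).
#' @param paired paired-end if TRUE, single-end otherwise.
#' @param insert_mean,insert_sd fragment (insert) size distribution for
#'   paired-end mode.
#' @param coverage fold coverage of each locus.
#' @param error_rate per-base substitution error probability; the
#'   emitted Phred quality is its rounded Phred transform.
#' @param group_sites number of shared polymorphic coding sites inside
#'   the hypervariable window; every protein group carries its own base
#'   pattern over these sites.
#' @param hypervar_window length (bases) of the hypervariable coding
#'   window in which group-defining polymorphism clusters, mimicking the
#'   dense exon-2/3 polymorphism of real class I/II loci.
#' @param seed integer RNG seed.
#' @return classed list of configuration values.
#' @export
simConfig <- function(n_loci = 6L, alleles_per_locus = 70L,
                      groups_per_locus = 32L, seq_length = 1000L,
                      snp_density = 0.02, read_length = 100L,
                      paired = TRUE, insert_mean = 300L, insert_sd = 30L,
                      coverage = 100, error_rate = 0.001,
                      group_sites = 40L, hypervar_window = 150L, seed = 1L) {
  cfg <- list(n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              groups_per_locus = as.integer(groups_per_locus),
              seq_length = as.integer(seq_length),
              snp_density = snp_density,
              group_sites = as.integer(group_sites),
              hypervar_window = as.integer(hypervar_window),
              read_length = as.integer(read_length),
              paired = isTRUE(paired),
              insert_mean = as.integer(insert_mean),
              insert_sd = as.numeric(insert_sd),
              coverage = as.numeric(coverage),
              error_rate = as.numeric(error_rate),
              seed = as.integer(seed))
  stopifnot(cfg$n_loci > 0, cfg$alleles_per_locus > 0,
            cfg$groups_per_locus > 0, cfg$seq_length > 0,
            cfg$snp_density > 0, cfg$read_length > 0,
            cfg$coverage > 0, cfg$error_rate >= 0, cfg$error_rate < 0.75,
            cfg$group_sites > 0, cfg$hypervar_window > 0)
  if (cfg$read_length > cfg$seq_length) {
    stop("read_length exceeds seq_length")
  }
  class(cfg) <- "SimConfig"
  cfg
}

toyLocusNames <- function(n) {
  base <- c("A", "B", "C", "DQA1", "DQB1", "DRB1")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("L", seq_len(n - length(base))))
}

#' Build a synthetic toy allele database
#'
#' Constructs, per locus, a random ancestor sequence with a two-exon
#' layout (CDS covering roughly 70\% of the locus) and derives alleles
#' by planting substitutions. Protein groups are distinguished by their
#' base patterns over a set of shared polymorphic sites clustered in a
#' hypervariable coding window (emulating the dense exon-2/3
#' polymorphism of real loci, where allele groups differ at many nearby
#' positions); within a group, six-digit variants add scattered
#' synonymous-role coding substitutions and eight-digit variants add
#' intronic substitutions. Group prior frequencies are drawn decreasing over
#' group rank and recorded for two populations, the larger value being
#' the operative prior. The planted polymorphic coding sites are kept in
#' \code{metadata$planted_sites} so recomputed SNP sites can be checked
#' against them.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @return an \linkS4class{HLAAlleleDb}; \code{metadata} carries
#'   \code{planted_sites} (per locus) and the \code{cfg}.
#' @export
buildToyDb <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  L <- cfg$seq_length
  nG <- cfg$groups_per_locus
  nA <- cfg$alleles_per_locus
  S <- cfg$group_sites
  cds_len <- floor(0.7 * L)
  e1w <- cds_len %/% 2L
  W <- min(cfg$hypervar_window, e1w)
  n_scatter <- max(nA, round(cfg$snp_density * cds_len))
  if (S > W || n_scatter > cds_len - W || 4^S < 4 * nG) {
    stop("infeasible config: not enough coding sequence space for ",
         nA, " distinguishable alleles over ", nG, " groups")
  }
  genomic <- character(); cds <- character()
  exons <- NULL; freqs <- NULL
  planted <- list()
  for (l in toyLocusNames(cfg$n_loci)) {
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    e2w <- cds_len - e1w
    e1 <- c(10L, 10L + e1w)                       # frame interval of exon 1
    e2 <- c(L - 10L - e2w, L - 10L)               # frame interval of exon 2
    coding_pos <- c(seq(e1[1], e1[2] - 1L), seq(e2[1], e2[2] - 1L))
    intron_pos <- setdiff(seq(0L, L - 1L), coding_pos)
    # hypervariable window inside exon 1: shared polymorphic sites where
    # every group carries its own base pattern, as in the dense exon-2/3
    # polymorphism of real loci
    ws <- e1[1] + sample.int(e1w - W + 1L, 1L) - 1L
    window_pos <- seq(ws, ws + W - 1L)
    wsites <- sort(sample(window_pos, S))
    patt <- matrix(rep(anc[wsites + 1L], nG), nrow = S)
    repeat {
      for (g in seq_len(nG)) {
        mut <- runif(S) < 0.5
        patt[, g] <- anc[wsites + 1L]
        patt[mut, g] <- vapply(anc[wsites + 1L][mut], mutateBase, character(1))
      }
      if (!anyDuplicated(apply(patt, 2L, paste, collapse = ""))) break
    }
    # distribute alleles over groups: first groups get the extras
    sizes <- rep(nA %/% nG, nG) + c(rep(1L, nA %% nG), rep(0L, nG - nA %% nG))
    spool <- sample(setdiff(coding_pos, window_pos))  # synonymous scatter
    ipool <- sample(intron_pos)
    si <- 1L; ii <- 1L
    loc_sites <- wsites[apply(patt, 1L, function(r) length(unique(r)) > 1L)]
    for (g in seq_len(nG)) {
      gseq <- anc
      gseq[wsites + 1L] <- patt[, g]
      f3 <- 1L; f4 <- 1L
      prev <- gseq                                # members form a mutation chain
      for (m in seq_len(sizes[g])) {
        aseq <- prev
        if (m > 1L && m %% 2L == 0L) {            # synonymous coding variant
          f3 <- f3 + 1L; f4 <- 1L
          ssite <- spool[si]; si <- si + 1L
          aseq[ssite + 1L] <- mutateBase(aseq[ssite + 1L])
          loc_sites <- c(loc_sites, ssite)
        } else if (m > 1L) {                      # non-coding variant
          f4 <- f4 + 1L
          isite <- ipool[ii]; ii <- ii + 1L
          aseq[isite + 1L] <- mutateBase(aseq[isite + 1L])
        }
        prev <- aseq
        nm <- sprintf("%s*%02d:01:%02d:%02d", l, g, f3, f4)
        genomic[nm] <- paste(aseq, collapse = "")
        cds[nm] <- paste(aseq[coding_pos + 1L], collapse = "")
        exons <- rbind(exons, data.frame(
          allele = nm, exon = 1:2,
          frame_start = c(e1[1], e2[1]), frame_end = c(e1[2], e2[2]),
          cds_start = c(0L, e1w), stringsAsFactors = FALSE))
      }
    }
    planted[[l]] <- sort(loc_sites)
    # geometric-decay group frequencies, jittered and normalised: a few
    # common protein groups and a long tail of rare ones
    gf <- sort(0.85^seq_len(nG) * runif(nG, 0.5, 1.5), decreasing = TRUE)
    gf <- pmax(round(gf / sum(gf), 5), 1e-5)
    freqs <- rbind(freqs, data.frame(
      group = sprintf("%s*%02d:01", l, seq_len(nG)),
      population = "EUR", frequency = gf),
      data.frame(
      group = sprintf("%s*%02d:01", l, seq_len(nG)),
      population = "ASIA", frequency = pmax(round(gf * runif(nG, 0.3, 0.9), 5), 1e-5)))
  }
  HLAAlleleDb(genomic, cds, exons, frequencies = freqs,
              metadata = list(planted_sites = planted, cfg = cfg))
}

mutateBase <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' Write an allele database as plain-text files
#'
#' Emits \code{genomic.fasta}, \code{cds.fasta}, \code{exons.tsv},
#' \code{offsets.tsv} and \code{freq.tsv} into a directory, the format
#' \code{\link{loadAlleleDb}} reads back.
#'
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeAlleleDb <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(db@genomic, file.path(dir, "genomic.fasta"))
  Biostrings::writeXStringSet(db@cds, file.path(dir, "cds.fasta"))
  write.table(db@exons, file.path(dir, "exons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  off <- data.frame(allele = db@alleles$name,
                    genomic_offset = db@alleles$genomic_offset,
                    imputed = db@alleles$imputed)
  write.table(off, file.path(dir, "offsets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(db@frequencies, file.path(dir, "freq.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Draw a diploid truth genotype from a toy database
#'
#' Samples one allele pair per locus, with a configurable homozygote
#' share (the two alleles drawn identical).
#'
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param homozygous_frac expected fraction of homozygous loci.
#' @return data.frame with columns \code{locus}, \code{allele1},
#'   \code{allele2}.
#' @export
drawTruth <- function(db, homozygous_frac = 0.2) {
  loci <- hlaLoci(db)
  rows <- lapply(loci, function(l) {
    als <- alleleNames(db, l)
    a1 <- sample(als, 1L)
    a2 <- if (runif(1) < homozygous_frac) a1 else sample(als, 1L)
    data.frame(locus = l, allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate sequencing reads from a diploid truth
#'
#' Fragments are sampled uniformly over each haplotype's genomic
#' sequence, the haplotype chosen with probability 1/2 per fragment.
#' Per-base substitution errors are Bernoulli with the configured rate,
#' uniform over the three alternative bases; emitted Phred qualities
#' are consistent with that rate. The number of fragments per locus
#' targets the configured fold coverage of the locus sequence.
#'
#' @param db an \linkS4class{HLAAlleleDb} (toy database).
#' @param truth data.frame (locus, allele1, allele2).
#' @param cfg a \code{\link{simConfig}}; \code{cfg$seed} seeds the draw.
#' @return data.frame of reads: \code{qname}, \code{mate} (0 when
#'   single-end), \code{locus}, \code{source} (true allele),
#'   \code{start} (0-based frame position), \code{seq}, \code{phred}
#'   (integer quality shared by all bases).
#' @export
simulateReads <- function(db, truth, cfg = simConfig()) {
  set.seed(cfg$seed)
  rl <- cfg$read_length
  phred <- max(2L, as.integer(round(-10 * log10(max(cfg$error_rate, 1e-9)))))
  out <- list()
  for (i in seq_len(nrow(truth))) {
    l <- truth$locus[i]
    hap <- c(truth$allele1[i], truth$allele2[i])
    seqs <- lapply(hap, function(a) strsplit(as.character(db@genomic[[a]]), "")[[1]])
    L <- length(seqs[[1]])
    if (rl > L) stop("read_length exceeds locus length for ", l)
    per_frag <- if (cfg$paired) 2L * rl else rl
    nfrag <- max(1L, as.integer(round(cfg$coverage * L / per_frag)))
    hidx <- sample(1:2, nfrag, replace = TRUE)
    if (cfg$paired) {
      ins <- pmin(L, pmax(2L * rl, as.integer(round(
        rnorm(nfrag, cfg$insert_mean, cfg$insert_sd)))))
      start <- vapply(ins, function(s) sample.int(L - s + 1L, 1L) - 1L, integer(1))
      s1 <- start; s2 <- start + ins - rl
      qn <- sprintf("%s_frag%05d", l, seq_len(nfrag))
      for (m in 1:2) {
        st <- if (m == 1L) s1 else s2
        sq <- vapply(seq_len(nfrag), function(k) {
          paste(seqs[[hidx[k]]][(st[k] + 1L):(st[k] + rl)], collapse = "")
        }, character(1))
        out[[length(out) + 1L]] <- data.frame(
          qname = qn, mate = m, locus = l, source = hap[hidx],
          start = st, seq = addErrors(sq, cfg$error_rate), phred = phred,
          stringsAsFactors = FALSE)
      }
    } else {
      start <- sample.int(L - rl + 1L, nfrag, replace = TRUE) - 1L
      sq <- vapply(seq_len(nfrag), function(k) {
        paste(seqs[[hidx[k]]][(start[k] + 1L):(start[k] + rl)], collapse = "")
      }, character(1))
      out[[length(out) + 1L]] <- data.frame(
        qname = sprintf("%s_read%05d", l, seq_len(nfrag)),
        mate = 0L, locus = l, source = hap[hidx],
        start = start, seq = addErrors(sq, cfg$error_rate), phred = phred,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

addErrors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  ch <- strsplit(seqs, "")
  lens <- lengths(ch)
  flat <- unlist(ch)
  err <- which(runif(length(flat)) < rate)
  if (length(err)) {
    flat[err] <- vapply(flat[err], mutateBase, character(1))
  }
  vapply(split(flat, rep(seq_along(lens), lens)), paste, character(1),
         collapse = "")
}

#' Place simulated reads on allele contigs (k-mismatch alignment)
#'
#' A deliberately simple placement aligner for the self-contained test
#' path: each read is placed at its frame interval on every allele of
#' its locus whose sequence matches within \code{k} mismatches
#' (full-length, no indels). The best-matching placement comes first;
#' real data should come pre-aligned by a genuine aligner.
#'
#' @param reads read table from \code{\link{simulateReads}}.
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param k maximum mismatches for a placement.
#' @return data.frame of alignments: \code{qname}, \code{mate},
#'   \code{contig}, \code{pos} (0-based contig position),
#'   \code{mismatches}, \code{seq}, \code{phred}, \code{primary}.
#' @export
alignSimReads <- function(reads, db, k = 4L) {
  out <- list()
  for (l in unique(reads$locus)) {
    als <- alleleNames(db, l)
    conmat <- vapply(als, function(a) {
      strsplit(as.character(db@genomic[[a]]), "")[[1]]
    }, character(length(db@genomic[[als[1]]])))
    offs <- setNames(db@alleles$genomic_offset[match(als, db@alleles$name)], als)
    rd <- reads[reads$locus == l, , drop = FALSE]
    rl <- nchar(rd$seq[1])
    hitidx <- vector("list", nrow(rd))
    hitmm <- vector("list", nrow(rd))
    for (j in seq_len(nrow(rd))) {
      fr <- rd$start[j]
      rch <- strsplit(rd$seq[j], "")[[1]]
      mm <- colSums(conmat[(fr + 1L):(fr + rl), , drop = FALSE] != rch)
      hit <- which(mm <= k)
      hit <- hit[order(mm[hit])]
      hitidx[[j]] <- hit
      hitmm[[j]] <- as.integer(mm[hit])
    }
    n <- lengths(hitidx)
    idx <- rep(seq_len(nrow(rd)), n)
    hit <- unlist(hitidx)
    out[[length(out) + 1L]] <- data.frame(
      qname = rd$qname[idx], mate = rd$mate[idx],
      contig = als[hit], pos = rd$start[idx] - unname(offs[hit]),
      mismatches = unlist(hitmm),
      seq = rd$seq[idx], phred = rd$phred[idx],
      primary = unlist(lapply(n, function(m) seq_len(m) == 1L)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write simulated alignments as a SAM file
#'
#' @param aln alignment table from \code{\link{alignSimReads}}.
#' @param db an \linkS4class{HLAAlleleDb} (for the \code{@SQ} header).
#' @param path output SAM path.
#' @return the path, invisibly.
#' @export
writeSimSam <- function(aln, db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  nm <- db@alleles$name
  wd <- Biostrings::width(db@genomic)[match(nm, names(db@genomic))]
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, wd), con)
  if (is.null(aln) || !nrow(aln)) return(invisible(path))
  flag <- integer(nrow(aln))
  paired <- aln$mate > 0L
  flag[paired] <- 0x1L + ifelse(aln$mate[paired] == 1L, 0x40L, 0x80L)
  flag <- flag + ifelse(aln$primary, 0L, 0x100L)
  rl <- nchar(aln$seq)
  qual <- strrep(vapply(aln$phred + 33L, function(x) rawToChar(as.raw(x)),
                        character(1)), rl)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                     aln$qname, flag, aln$contig, aln$pos + 1L,
                     ifelse(aln$primary, 60L, 0L), rl, aln$seq, qual), con)
  invisible(path)
}

#' Write simulated reads as FASTQ (Sanger Phred+33)
#'
#' Paired-end reads go to \code{<prefix>_1.fastq} / \code{<prefix>_2.fastq}
#' with mate 2 reverse-complemented (as sequenced); single-end reads go
#' to \code{<prefix>.fastq}.
#'
#' @param reads read table from \code{\link{simulateReads}}.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
writeSimFastq <- function(reads, prefix) {
  emit <- function(rd, path, revcomp) {
    sq <- rd$seq
    if (revcomp) {
      sq <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sq)))
    }
    qual <- strrep(vapply(rd$phred + 33L, function(x) rawToChar(as.raw(x)),
                          character(1)), nchar(sq))
    writeLines(paste0("@", rd$qname, "\n", sq, "\n+\n", qual), path)
    path
  }
  if (any(reads$mate > 0L)) {
    p1 <- emit(reads[reads$mate == 1L, ], paste0(prefix, "_1.fastq"), FALSE)
    p2 <- emit(reads[reads$mate == 2L, ], paste0(prefix, "_2.fastq"), TRUE)
    invisible(c(p1, p2))
  } else {
    invisible(emit(reads, paste0(prefix, ".fastq"), FALSE))
  }
}

#' Run one seeded end-to-end simulation and typing replicate
#'
#' Builds reads from a truth drawn on the supplied toy database, aligns
#' them with the placement aligner, writes a SAM file, ingests it, and
#' types every locus. A convenience harness for parameter-recovery and
#' trend experiments.
#'
#' @param db toy \linkS4class{HLAAlleleDb}.
#' @param cfg a \code{\link{simConfig}}; its seed drives truth, reads
#'   and errors.
#' @param config pipeline configuration (\code{\link{hlaConfig}}).
#' @param homozygous_frac expected homozygous-locus fraction of the
#'   truth draw.
#' @param via_sam route the reads through a SAM file and
#'   \code{\link{ingestAlignments}} (default) instead of building read
#'   sets in memory.
#' @return list with \code{truth}, \code{calls} (result table) and
#'   \code{accuracy4}, \code{accuracy2} (per-allele accuracies).
#' @export
simulateAndType <- function(db, cfg = simConfig(), config = hlaConfig(),
                            homozygous_frac = 0.2, via_sam = TRUE) {
  set.seed(cfg$seed)
  truth <- drawTruth(db, homozygous_frac)
  reads <- simulateReads(db, truth, cfg)
  aln <- alignSimReads(reads, db)
  if (via_sam) {
    sam <- tempfile(fileext = ".sam")
    on.exit(unlink(sam), add = TRUE)
    writeSimSam(aln, db, sam)
    calls <- typeHLA(sam, db, config)
  } else {
    calls <- typeHLA(readSetsFromAlignments(aln, db, config$default_phred),
                     db, config)
  }
  list(truth = truth, calls = calls,
       accuracy4 = as.numeric(scorePredictions(calls, truth, 4L)),
       accuracy2 = as.numeric(scorePredictions(calls, truth, 2L)))
}

# Build LocusReadSet objects directly from a placement-alignment table,
# bypassing the SAM round-trip (same projection rules, no indels).
readSetsFromAlignments <- function(aln, db, default_phred = 30L) {
  aidx <- match(aln$contig, db@alleles$name)
  locus <- db@alleles$locus[aidx]
  offs <- db@alleles$genomic_offset[aidx]
  fstart <- aln$pos + offs
  uid <- paste0(aln$qname, "/", aln$mate)
  out <- list()
  for (l in unique(locus)) {
    li <- which(locus == l)
    first <- li[!duplicated(uid[li])]
    hits_by_uid <- lapply(split(aln$contig[li], uid[li]),
                          function(v) sort(unique(v)))
    obs <- data.frame(uid = uid[first], qname = aln$qname[first],
                      mate = aln$mate[first], stringsAsFactors = FALSE)
    obs$hits <- unname(hits_by_uid[obs$uid])
    obs$pos <- lapply(first, function(k) fstart[k] + seq_len(nchar(aln$seq[k])) - 1L)
    obs$bases <- lapply(first, function(k) strsplit(aln$seq[k], "")[[1]])
    obs$quals <- lapply(first, function(k) rep(aln$phred[k], nchar(aln$seq[k])))
    obs$optimal <- rep(list(character()), nrow(obs))
    out[[l]] <- new("LocusReadSet", locus = l, observations = obs)
  }
  out
}
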