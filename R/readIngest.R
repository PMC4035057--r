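#' Ingest SAM/BAM alignments against allele contigs
#'
#' Reads alignments whose target contigs are allele sequences from the
#' database, projects each read onto the per-locus coordinate frame
#' (1-based SAM POS converted to 0-based frame positions via the
#' allele's genomic offset, CIGAR honoured: insertions and soft clips
#' consume read bases only, deletions/skips consume frame only), and
#' merges multiple alignments of the same read into a single observation
#' whose \code{hits} is the union of target alleles. Unmapped records
#' are skipped; records on contigs not in the database are skipped with
#' a warning and counted in \code{attr(result, "skipped")}.
#'
#' @param path SAM or BAM file. SAM input is converted with
#'   \code{Rsamtools::asBam} on the fly.
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param default_phred Phred quality substituted when the file carries
#'   no base qualities (\code{*}).
#' @return named list of \linkS4class{LocusReadSet}, one per locus with
#'   alignments; attribute \code{skipped} counts dropped records.
#' @export
ingestAlignments <- function(path, db, default_phred = 30L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  if (n == 0L) return(structure(list(), skipped = 0L))

  mapped <- bitwAnd(res$flag, 0x4L) == 0L & !is.na(res$pos)
  contig <- as.character(res$rname)
  known <- contig %in% db@alleles$name |
    sub("^HLA-", "", contig) %in% db@alleles$name
  skipped <- sum(mapped & !known)
  if (skipped > 0L) {
    warning(skipped, " alignment(s) on contigs absent from the database were skipped")
  }
  keep <- which(mapped & known)
  if (!length(keep)) return(structure(list(), skipped = skipped))

  contig <- sub("^HLA-", "", contig[keep])
  aidx <- match(contig, db@alleles$name)
  locus <- db@alleles$locus[aidx]
  offset <- db@alleles$genomic_offset[aidx]
  mate <- ifelse(bitwAnd(res$flag[keep], 0x40L) > 0L, 1L,
                 ifelse(bitwAnd(res$flag[keep], 0x80L) > 0L, 2L, 0L))
  qname <- res$qname[keep]
  uid <- paste0(qname, "/", mate)
  pos0 <- res$pos[keep] - 1L + offset
  cig <- res$cigar[keep]

  out <- list()
  for (l in unique(locus)) {
    li <- which(locus == l)
    first <- !duplicated(uid[li])
    obs_i <- li[first]
    # sequences/qualities are only needed for the primary observation
    seqs <- as.character(res$seq[keep][obs_i])
    quals <- as.character(res$qual[keep][obs_i])
    proj <- lapply(seq_along(obs_i), function(j) {
      projectCigar(pos0[obs_i[j]], cig[obs_i[j]], seqs[j], quals[j],
                   default_phred)
    })
    hits_by_uid <- lapply(split(contig[li], uid[li]), function(v) sort(unique(v)))
    obs <- data.frame(uid = uid[obs_i], qname = qname[obs_i],
                      mate = mate[obs_i], stringsAsFactors = FALSE)
    obs$hits <- unname(hits_by_uid[obs$uid])
    obs$pos <- lapply(proj, `[[`, "pos")
    obs$bases <- lapply(proj, `[[`, "bases")
    obs$quals <- lapply(proj, `[[`, "quals")
    obs$optimal <- rep(list(character()), nrow(obs))
    out[[l]] <- new("LocusReadSet", locus = l, observations = obs)
  }
  structure(out, skipped = skipped)
}

# Walk a CIGAR string: returns 0-based frame positions with the read
# bases and integer Phred qualities they carry. M/=/X consume both, I/S
# consume the read, D/N consume the frame, H/P neither.
projectCigar <- function(start0, cigar, seq, qual, default_phred = 30L) {
  if (grepl("^[0-9]+M$", cigar)) {       # fast path: ungapped alignment
    w <- as.integer(sub("M", "", cigar, fixed = TRUE))
    qv <- if (identical(qual, "*") || is.na(qual)) {
      rep(default_phred, w)
    } else {
      as.integer(charToRaw(qual)) - 33L
    }
    qv[qv < 0L | qv > 93L] <- default_phred
    return(list(pos = start0 + seq_len(w) - 1L,
                bases = strsplit(seq, "")[[1]], quals = qv))
  }
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  code <- sub("^[0-9]+", "", ops)
  bases <- strsplit(seq, "")[[1]]
  qv <- if (identical(qual, "*") || is.na(qual)) {
    rep(default_phred, length(bases))
  } else {
    as.integer(charToRaw(qual)) - 33L
  }
  qv[qv < 0L | qv > 93L] <- default_phred  # absent qualities ('*' / 0xff)

  rpos <- 0L; fpos <- start0
  pos <- integer(); bi <- integer()
  for (i in seq_along(ops)) {
    w <- lens[i]
    if (code[i] %in% c("M", "=", "X")) {
      pos <- c(pos, fpos + seq_len(w) - 1L)
      bi <- c(bi, rpos + seq_len(w))
      rpos <- rpos + w; fpos <- fpos + w
    } else if (code[i] %in% c("I", "S")) {
      rpos <- rpos + w
    } else if (code[i] %in% c("D", "N")) {
      fpos <- fpos + w
    }
  }
  list(pos = pos, bases = bases[bi], quals = qv[bi])
}

#' Raw per-allele read counts from initial mapping
#'
#' Counts, per allele, the read units whose alignment hits include that
#' allele. This is the pre-selection count, computed before the
#' optimal-read filter.
#'
#' @param lrs a \linkS4class{LocusReadSet}.
#' @return named integer vector over the alleles hit.
#' @export
rawAlleleCounts <- function(lrs) {
  o <- readObservations(lrs)
  if (!nrow(o)) return(setNames(integer(), character()))
  tab <- table(unlist(o$hits))
  setNames(as.integer(tab), names(tab))
}

#' Mark optimal reads against a retained allele set
#'
#' For each read, sequence identity is computed over the SNP sites the
#' read covers, against every retained allele: matches / covered sites.
#' The read is optimal for the allele(s) attaining the maximum identity
#' (all ties), provided that identity is at least \code{min_identity}
#' (default 0.99, i.e. at most 1\% of covered SNP sites mismatched).
#' Mismatches outside SNP sites never affect optimality; sites where the
#' read's alignment carries an indel contribute no base. Reads covering
#' no SNP site are uninformative and get an empty optimal set.
#'
#' @param lrs a \linkS4class{LocusReadSet}.
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param retained allele names to evaluate against.
#' @param sites SNP sites (0-based frame positions); defaults to
#'   \code{snpSites(db, locus, retained)}.
#' @param min_identity minimum SNP-site identity to count a read.
#' @return the read set with the \code{optimal} column filled.
#' @export
markOptimalReads <- function(lrs, db, retained,
                             sites = NULL, min_identity = 0.99) {
  retained <- parseAlleleName(retained)$name
  if (is.null(sites)) sites <- snpSites(db, lrs@locus, retained)
  o <- readObservations(lrs)
  if (!nrow(o)) return(lrs)
  M <- frameBaseMatrix(db, lrs@locus, retained)
  o$optimal <- lapply(seq_len(nrow(o)), function(i) {
    keep <- o$pos[[i]] %in% sites
    if (!any(keep)) return(character())
    s <- o$pos[[i]][keep]
    d <- o$bases[[i]][keep]
    ab <- M[s + 1L, , drop = FALSE]
    ncmp <- colSums(!is.na(ab))
    nmatch <- colSums(ab == d, na.rm = TRUE)
    ident <- ifelse(ncmp > 0L, nmatch / ncmp, NA_real_)
    best <- max(ident, na.rm = TRUE)
    if (is.na(best) || best < min_identity) return(character())
    sort(colnames(M)[!is.na(ident) & ident >= best - 1e-12])
  })
  new("LocusReadSet", locus = lrs@locus, observations = o)
}

#' Long table of read bases at SNP sites
#'
#' Flattens a read set to one row per (read unit, covered SNP site) with
#' the observed base and its Phred-derived error rate. Used by the
#' genotype likelihood.
#'
#' @param lrs a \linkS4class{LocusReadSet}.
#' @param sites SNP sites (0-based frame positions).
#' @param units optional subset of read-unit ids.
#' @return data.frame with columns \code{uid}, \code{qname},
#'   \code{site}, \code{base}, \code{q} (error probability).
#' @export
snpBaseTable <- function(lrs, sites, units = NULL) {
  o <- readObservations(lrs)
  if (!is.null(units)) o <- o[o$uid %in% units, , drop = FALSE]
  if (!nrow(o)) {
    return(data.frame(uid = character(), qname = character(),
                      site = integer(), base = character(), q = numeric()))
  }
  keep <- lapply(o$pos, function(p) which(p %in% sites))
  nk <- lengths(keep)
  idx <- rep(seq_len(nrow(o)), nk)
  data.frame(
    uid = o$uid[idx],
    qname = o$qname[idx],
    site = unlist(mapply(function(p, k) p[k], o$pos, keep, SIMPLIFY = FALSE)),
    base = unlist(mapply(function(b, k) b[k], o$bases, keep, SIMPLIFY = FALSE)),
    q = 10^(-unlist(mapply(function(q, k) q[k], o$quals, keep,
                           SIMPLIFY = FALSE)) / 10),
    stringsAsFactors = FALSE
  )
}

#' Adjacent SNP-site pairs observed by phase-informative units
#'
#' A phase-informative unit is a read, or a linked mate pair, covering
#' at least two SNP sites. Mates are merged by \code{qname}; a site
#' covered by both mates keeps the higher-quality base. Each unit
#' contributes its consecutive covered-site pairs (adjacent in frame
#' order), avoiding quadratic re-counting of the same evidence.
#'
#' @param snpTab output of \code{\link{snpBaseTable}}.
#' @param pairing \code{"adjacent"} (default) for consecutive covered
#'   site pairs, \code{"all"} for every covered pair of a unit.
#' @return data.frame with columns \code{qname}, \code{site_i},
#'   \code{site_j}, \code{base_i}, \code{base_j}, \code{q_i},
#'   \code{q_j}.
#' @export
phaseUnitPairs <- function(snpTab, pairing = c("adjacent", "all")) {
  pairing <- match.arg(pairing)
  empty <- data.frame(qname = character(), site_i = integer(),
                      site_j = integer(), base_i = character(),
                      base_j = character(), q_i = numeric(), q_j = numeric())
  if (!nrow(snpTab)) return(empty)
  t <- snpTab[order(snpTab$qname, snpTab$site, snpTab$q), , drop = FALSE]
  t <- t[!duplicated(t[, c("qname", "site")]), , drop = FALSE]  # keep min q
  n_by_unit <- table(t$qname)
  t <- t[t$qname %in% names(n_by_unit)[n_by_unit >= 2L], , drop = FALSE]
  if (!nrow(t)) return(empty)
  if (pairing == "adjacent") {
    last <- !duplicated(t$qname, fromLast = TRUE)
    i <- which(!last)         # row i pairs with row i+1 within each unit
    j <- i + 1L
  } else {
    grp <- split(seq_len(nrow(t)), t$qname)
    ij <- do.call(rbind, lapply(grp, function(rows) {
      cmb <- utils::combn(rows, 2L)
      cbind(cmb[1L, ], cmb[2L, ])
    }))
    i <- ij[, 1L]; j <- ij[, 2L]
  }
  data.frame(qname = t$qname[i],
             site_i = t$site[i], site_j = t$site[j],
             base_i = t$base[i], base_j = t$base[j],
             q_i = t$q[i], q_j = t$q[j],
             stringsAsFactors = FALSE)
}
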