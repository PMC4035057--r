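#' Construct an HLAAlleleDb from in-memory parts
#'
#' Lower-level constructor used by \code{\link{loadAlleleDb}} and the
#' simulator. Sequence sets may be named character vectors or
#' \code{DNAStringSet}s.
#'
#' @param genomic named sequences, one per allele (full genomic span).
#' @param cds named sequences, one per allele (concatenated exons).
#' @param exons exon map data.frame (allele, exon, frame_start,
#'   frame_end, cds_start), 0-based half-open frame coordinates.
#' @param genomic_offset named integer vector: frame position of each
#'   allele's genomic sequence start (default 0 for all).
#' @param frequencies data.frame (group, population, frequency); may be
#'   empty.
#' @param freqFloor frequency used for groups with no record.
#' @param imputed named logical: whether the genomic sequence was imputed
#'   from the locus reference allele.
#' @param metadata free-form list.
#' @return an \linkS4class{HLAAlleleDb}.
#' @export
HLAAlleleDb <- function(genomic, cds, exons,
                        genomic_offset = NULL,
                        frequencies = NULL,
                        freqFloor = 1e-6,
                        imputed = NULL,
                        metadata = list()) {
  if (!is(genomic, "DNAStringSet")) genomic <- Biostrings::DNAStringSet(genomic)
  if (!is(cds, "DNAStringSet")) cds <- Biostrings::DNAStringSet(cds)
  nms <- names(genomic)
  if (is.null(nms) || any(!nzchar(nms))) stop("genomic sequences must be named by allele")
  if (any(Biostrings::width(genomic) == 0L) || any(Biostrings::width(cds) == 0L)) {
    stop("empty sequence in allele database")
  }
  parsed <- parseAlleleName(nms)
  if (anyDuplicated(parsed$name)) {
    stop("duplicate allele name(s): ",
         paste(unique(parsed$name[duplicated(parsed$name)]), collapse = ", "))
  }
  names(genomic) <- parsed$name
  names(cds) <- parseAlleleName(names(cds))$name
  if (is.null(genomic_offset)) {
    genomic_offset <- setNames(integer(length(nms)), parsed$name)
  } else {
    names(genomic_offset) <- parseAlleleName(names(genomic_offset))$name
  }
  if (is.null(imputed)) imputed <- setNames(logical(length(nms)), parsed$name)
  if (is.null(frequencies)) {
    frequencies <- data.frame(group = character(), population = character(),
                              frequency = numeric())
  }
  exons$allele <- parseAlleleName(exons$allele)$name
  alleles <- cbind(parsed,
                   genomic_offset = as.integer(genomic_offset[parsed$name]),
                   imputed = as.logical(imputed[parsed$name]))
  rownames(alleles) <- NULL
  new("HLAAlleleDb", alleles = alleles, genomic = genomic, cds = cds,
      exons = exons, frequencies = frequencies,
      freqFloor = freqFloor, metadata = metadata)
}

#' Load an allele database from plain-text files
#'
#' Expects a directory with \code{genomic.fasta}, \code{cds.fasta}
#' (headers carry allele names), \code{exons.tsv} (allele, exon,
#' frame_start, frame_end, cds_start), \code{offsets.tsv} (allele,
#' genomic_offset, imputed) and optionally \code{freq.tsv} (group,
#' population, frequency). Alleles present only as CDS records are
#' genomic-imputed from the locus reference allele (the allele at
#' genomic offset 0 with the longest genomic sequence).
#'
#' @param dir database directory.
#' @param freqFloor frequency floor for groups with no record.
#' @return an \linkS4class{HLAAlleleDb}.
#' @export
loadAlleleDb <- function(dir, freqFloor = 1e-6) {
  fa <- function(f) Biostrings::readDNAStringSet(file.path(dir, f))
  genomic <- fa("genomic.fasta")
  cds <- fa("cds.fasta")
  exons <- read.delim(file.path(dir, "exons.tsv"), stringsAsFactors = FALSE)
  off <- read.delim(file.path(dir, "offsets.tsv"), stringsAsFactors = FALSE)
  freqp <- file.path(dir, "freq.tsv")
  freqs <- if (file.exists(freqp)) {
    read.delim(freqp, stringsAsFactors = FALSE)
  } else NULL
  off$allele <- parseAlleleName(off$allele)$name
  exons$allele <- parseAlleleName(exons$allele)$name
  offv <- setNames(as.integer(off$genomic_offset), off$allele)
  impv <- setNames(as.logical(off$imputed), off$allele)

  cdsnames <- parseAlleleName(names(cds))$name
  gennames <- parseAlleleName(names(genomic))$name
  names(cds) <- cdsnames
  names(genomic) <- gennames
  missing_gen <- setdiff(cdsnames, gennames)
  if (length(missing_gen)) {
    loci <- parseAlleleName(missing_gen)$locus
    for (i in seq_along(missing_gen)) {
      al <- missing_gen[i]
      ref <- locusReferenceAllele(gennames, genomic, offv, loci[i])
      imp <- imputeGenomicSeq(cds[[al]], al, genomic[[ref]], ref, exons)
      genomic <- c(genomic, Biostrings::DNAStringSet(setNames(as.character(imp), al)))
      offv[al] <- offv[ref]
      impv[al] <- TRUE
    }
  }
  HLAAlleleDb(genomic, cds, exons, genomic_offset = offv[names(genomic)],
              frequencies = freqs, freqFloor = freqFloor,
              imputed = impv[names(genomic)])
}

locusReferenceAllele <- function(gennames, genomic, offv, locus) {
  cand <- gennames[parseAlleleName(gennames)$locus == locus]
  if (!length(cand)) stop("no genomic reference allele for locus ", locus)
  cand <- cand[order(offv[cand], -Biostrings::width(genomic)[match(cand, names(genomic))])]
  cand[1]
}

imputeGenomicSeq <- function(cds_seq, allele, ref_genomic, ref_allele, exons) {
  ex <- exons[exons$allele == allele, , drop = FALSE]
  if (!nrow(ex)) ex <- exons[exons$allele == ref_allele, , drop = FALSE]
  ex <- ex[order(ex$exon), , drop = FALSE]
  widths <- ex$frame_end - ex$frame_start
  if (sum(widths) != length(cds_seq)) {
    stop("CDS length of ", allele, " (", length(cds_seq),
         ") incompatible with exon layout (", sum(widths), ")")
  }
  out <- strsplit(as.character(ref_genomic), "")[[1]]
  cdsch <- strsplit(as.character(cds_seq), "")[[1]]
  for (i in seq_len(nrow(ex))) {
    fr <- (ex$frame_start[i] + 1L):ex$frame_end[i]
    cs <- ex$cds_start[i] + seq_len(widths[i])
    out[fr] <- cdsch[cs]
  }
  Biostrings::DNAString(paste(out, collapse = ""))
}

#' Impute the genomic sequence of a CDS-only allele
#'
#' Fills the non-coding positions of an allele known only through its CDS
#' with the genomic sequence of the locus reference allele: exon frame
#' positions carry the allele's own CDS bases, all other positions carry
#' the reference's bases. Already-genomic alleles are returned unchanged
#' (the operation is idempotent).
#'
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param allele allele name to impute.
#' @param reference reference allele name (full genomic sequence).
#' @return the database with the allele's genomic sequence filled in and
#'   its \code{imputed} flag set.
#' @export
imputeGenomic <- function(db, allele, reference) {
  allele <- parseAlleleName(allele)$name
  reference <- parseAlleleName(reference)$name
  i <- match(allele, db@alleles$name)
  if (is.na(i)) stop("unknown allele: ", allele)
  if (db@alleles$imputed[i]) return(db)
  wg <- Biostrings::width(db@genomic)[match(allele, names(db@genomic))]
  wc <- Biostrings::width(db@cds)[match(allele, names(db@cds))]
  if (wg > wc) return(db)  # already has a true genomic sequence
  imp <- imputeGenomicSeq(db@cds[[allele]], allele,
                          db@genomic[[reference]], reference, db@exons)
  db@genomic[[allele]] <- imp
  db@alleles$imputed[i] <- TRUE
  db@alleles$genomic_offset[i] <-
    db@alleles$genomic_offset[match(reference, db@alleles$name)]
  validObject(db)
  db
}

#' Partition alleles into protein groups with prior frequencies
#'
#' Alleles sharing a four-digit identity form one protein group. The
#' group's prior frequency is the maximum frequency reported for the
#' group over all populations in the database's frequency table; groups
#' with no record receive the floor frequency.
#'
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param locus optional locus restriction.
#' @return data.frame with columns \code{group}, \code{allele},
#'   \code{prior}.
#' @export
proteinGroups <- function(db, locus = NULL) {
  a <- db@alleles
  if (!is.null(locus)) a <- a[a$locus == locus, , drop = FALSE]
  if (any(is.na(a$f2))) {
    stop("allele(s) without a four-digit identity: ",
         paste(a$name[is.na(a$f2)], collapse = ", "))
  }
  grp <- proteinGroupId(a$name)
  data.frame(group = grp, allele = a$name,
             prior = groupFrequency(db, grp),
             stringsAsFactors = FALSE)
}

#' Prior frequency of protein groups
#'
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param group character vector of group ids (four-digit names).
#' @return numeric vector of frequencies (max over populations, floor
#'   where unrecorded).
#' @export
groupFrequency <- function(db, group) {
  f <- db@frequencies
  out <- rep(db@freqFloor, length(group))
  if (nrow(f)) {
    f$group <- parseAlleleName(f$group)$name
    mx <- tapply(f$frequency, f$group, max)
    hit <- match(group, names(mx))
    out[!is.na(hit)] <- as.numeric(mx[hit[!is.na(hit)]])
  }
  out
}

#' Per-locus frame base matrix over the CDS
#'
#' Builds a character matrix of CDS bases in the locus coordinate frame:
#' one row per frame position (1-based row \code{i} is frame position
#' \code{i - 1}), one column per allele; \code{NA} where the allele's CDS
#' does not cover the position (introns, or deletions relative to the
#' frame).
#'
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param locus locus identifier.
#' @param alleles allele names (default: all alleles of the locus).
#' @return character matrix with allele columns.
#' @export
frameBaseMatrix <- function(db, locus, alleles = NULL) {
  if (is.null(alleles)) alleles <- alleleNames(db, locus)
  alleles <- parseAlleleName(alleles)$name
  ex <- db@exons[db@exons$allele %in% alleles, , drop = FALSE]
  a <- db@alleles[match(alleles, db@alleles$name), , drop = FALSE]
  flen <- max(a$genomic_offset +
              Biostrings::width(db@genomic)[match(alleles, names(db@genomic))],
              if (nrow(ex)) ex$frame_end else 0L)
  M <- matrix(NA_character_, nrow = flen, ncol = length(alleles),
              dimnames = list(NULL, alleles))
  for (al in alleles) {
    exa <- ex[ex$allele == al, , drop = FALSE]
    if (!nrow(exa)) next
    cdsch <- strsplit(as.character(db@cds[[al]]), "")[[1]]
    for (i in seq_len(nrow(exa))) {
      w <- exa$frame_end[i] - exa$frame_start[i]
      M[(exa$frame_start[i] + 1L):exa$frame_end[i], al] <-
        cdsch[exa$cds_start[i] + seq_len(w)]
    }
  }
  M
}

#' SNP sites of a locus over a retained allele set
#'
#' The SNP sites of a locus are the union of the polymorphic CDS
#' positions (>= 2 distinct bases) among the retained alleles, excluding
#' any position that coincides with an indel in a retained allele, i.e.
#' any frame column not covered by the CDS of every retained allele.
#' Identity filtering and all likelihoods operate only on these sites.
#'
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param locus locus identifier.
#' @param retained allele names defining the site set (default: all
#'   alleles of the locus).
#' @return sorted integer vector of 0-based frame positions.
#' @export
snpSites <- function(db, locus, retained = NULL) {
  if (is.null(retained)) retained <- alleleNames(db, locus)
  if (!length(retained)) stop("empty retained allele set for locus ", locus)
  M <- frameBaseMatrix(db, locus, retained)
  covered <- rowSums(is.na(M)) == 0L
  ndistinct <- apply(M, 1L, function(r) length(unique(r[!is.na(r)])))
  sort(which(covered & ndistinct >= 2L) - 1L)
}
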