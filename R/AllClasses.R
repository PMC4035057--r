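#' @import methods
#' @importFrom stats pnorm quantile rbinom rnorm runif sd setNames
#' @importFrom utils read.delim write.table head
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Rsamtools scanBam ScanBamParam asBam
NULL

#' HLAAlleleDb: an indexed HLA allele reference
#'
#' Holds, per allele: the parsed name, genomic and CDS sequences, the
#' offset of the genomic sequence in the per-locus common coordinate
#' frame, and an exon map placing CDS segments into that frame. Allele
#' (protein-group) frequencies are carried as a long table
#' (group, population, frequency); groups without a record fall back to
#' the floor frequency.
#'
#' All coordinates are 0-based half-open positions in the locus frame,
#' which is defined by a designated reference allele per locus. Positions
#' are therefore comparable across all alleles of a locus.
#'
#' @slot alleles data.frame with columns \code{name}, \code{locus},
#'   \code{f1}..\code{f4}, \code{genomic_offset}, \code{imputed}.
#' @slot genomic \linkS4class{DNAStringSet} of genomic sequences, named by
#'   allele.
#' @slot cds \linkS4class{DNAStringSet} of CDS sequences, named by allele.
#' @slot exons data.frame with columns \code{allele}, \code{exon},
#'   \code{frame_start}, \code{frame_end}, \code{cds_start}: exon
#'   \code{i} of \code{allele} occupies frame interval
#'   \code{[frame_start, frame_end)} and CDS interval
#'   \code{[cds_start, cds_start + frame_end - frame_start)}.
#' @slot frequencies data.frame with columns \code{group},
#'   \code{population}, \code{frequency}.
#' @slot freqFloor numeric scalar; frequency assigned to groups with no
#'   record.
#' @slot metadata list of free-form annotations (e.g. simulator truth).
#' @export
setClass("HLAAlleleDb",
  representation(
    alleles = "data.frame",
    genomic = "DNAStringSet",
    cds = "DNAStringSet",
    exons = "data.frame",
    frequencies = "data.frame",
    freqFloor = "numeric",
    metadata = "list"
  ),
  prototype(freqFloor = 1e-6, metadata = list())
)

setValidity("HLAAlleleDb", function(object) {
  a <- object@alleles
  msg <- character()
  need <- c("name", "locus", "f1", "f2", "f3", "f4", "genomic_offset", "imputed")
  if (!all(need %in% names(a))) {
    return(paste("alleles table must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(a$name)) {
    msg <- c(msg, paste("duplicate allele name(s):",
                        paste(unique(a$name[duplicated(a$name)]), collapse = ", ")))
  }
  if (!setequal(names(object@genomic), a$name) ||
      !setequal(names(object@cds), a$name)) {
    msg <- c(msg, "genomic/cds sequence names must match the alleles table")
  }
  badchr <- function(ss) any(vapply(seq_along(ss), function(i) {
    f <- Biostrings::alphabetFrequency(ss[[i]])
    sum(f) > sum(f[c("A", "C", "G", "T", "N")])
  }, logical(1)))
  if (length(object@genomic) && badchr(object@genomic)) {
    msg <- c(msg, "genomic sequences may contain only A,C,G,T,N")
  }
  if (length(object@cds) && badchr(object@cds)) {
    msg <- c(msg, "cds sequences may contain only A,C,G,T,N")
  }
  if (length(object@cds) && length(object@genomic)) {
    wg <- Biostrings::width(object@genomic)[match(a$name, names(object@genomic))]
    wc <- Biostrings::width(object@cds)[match(a$name, names(object@cds))]
    if (any(wc > wg)) {
      msg <- c(msg, "cds length must not exceed genomic length")
    }
  }
  e <- object@exons
  eneed <- c("allele", "exon", "frame_start", "frame_end", "cds_start")
  if (!all(eneed %in% names(e))) {
    msg <- c(msg, paste("exons table must have columns:", paste(eneed, collapse = ", ")))
  } else if (nrow(e)) {
    if (any(e$frame_end <= e$frame_start)) msg <- c(msg, "empty exon interval in exon map")
    if (!all(e$allele %in% a$name)) msg <- c(msg, "exon map names unknown allele")
  }
  f <- object@frequencies
  if (nrow(f) && (any(f$frequency <= 0) || any(f$frequency > 1))) {
    msg <- c(msg, "frequencies must lie in (0, 1]")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' LocusReadSet: aligned read observations of one locus
#'
#' One row of \code{observations} per read (mate), after projection onto
#' the locus coordinate frame. \code{hits}, \code{pos}, \code{bases} and
#' \code{quals} are list-columns; \code{optimal} is filled by
#' \code{\link{markOptimalReads}} and holds, per read, the allele names
#' the read is optimal for (possibly none).
#'
#' @slot locus character scalar.
#' @slot observations data.frame with columns \code{uid} (read-unit id,
#'   \code{qname/mate}), \code{qname}, \code{mate} (0 = unpaired),
#'   and list-columns \code{hits}, \code{pos}, \code{bases},
#'   \code{quals}, \code{optimal}.
#' @export
setClass("LocusReadSet",
  representation(locus = "character", observations = "data.frame")
)

setValidity("LocusReadSet", function(object) {
  o <- object@observations
  need <- c("uid", "qname", "mate", "hits", "pos", "bases", "quals", "optimal")
  if (!all(need %in% names(o))) {
    return(paste("observations must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(o$uid)) return("duplicate read-unit ids")
  lens_ok <- all(mapply(function(p, b, q) length(p) == length(b) && length(p) == length(q),
                        o$pos, o$bases, o$quals))
  if (!isTRUE(lens_ok)) return("pos/bases/quals lengths differ within a read")
  TRUE
})

setMethod("show", "HLAAlleleDb", function(object) {
  a <- object@alleles
  cat("HLAAlleleDb with", nrow(a), "alleles over",
      length(unique(a$locus)), "loci\n")
  for (l in sort(unique(a$locus))) {
    n <- sum(a$locus == l)
    g <- length(unique(proteinGroupId(a$name[a$locus == l])))
    cat("  ", l, ": ", n, " alleles, ", g, " protein groups\n", sep = "")
  }
  cat("frequency records:", nrow(object@frequencies),
      "| floor:", object@freqFloor, "\n")
})

setMethod("show", "LocusReadSet", function(object) {
  o <- object@observations
  cat("LocusReadSet for locus", object@locus, "with", nrow(o), "read units\n")
  nopt <- sum(lengths(o$optimal) > 0)
  cat("  optimal-marked:", nopt, "of", nrow(o), "\n")
})

#' @describeIn HLAAlleleDb loci present in the database.
#' @param x an \code{HLAAlleleDb}.
#' @export
hlaLoci <- function(x) sort(unique(x@alleles$locus))

#' @describeIn HLAAlleleDb allele names, optionally restricted to a locus.
#' @param locus optional locus identifier.
#' @export
alleleNames <- function(x, locus = NULL) {
  a <- x@alleles
  if (!is.null(locus)) a <- a[a$locus == locus, , drop = FALSE]
  a$name
}

#' @describeIn LocusReadSet observation table accessor.
#' @param x a \code{LocusReadSet}.
#' @export
readObservations <- function(x) x@observations
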