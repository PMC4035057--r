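#' Parse an HLA allele name
#'
#' Splits an IMGT-style allele name such as \code{"A*02:01:01:01"} into its
#' locus and colon-separated numeric fields. The optional \code{"HLA-"}
#' prefix is accepted and dropped; the canonical internal spelling is
#' \code{locus*f1:f2[:f3[:f4]]}.
#'
#' Field semantics follow the hierarchical nomenclature: field 1 is the
#' serologic (two-digit) group, field 2 the protein (four-digit) identity,
#' field 3 a synonymous coding variant, field 4 a non-coding variant.
#'
#' @param x character vector of allele names.
#' @return A data.frame with columns \code{name} (canonical spelling),
#'   \code{locus}, and \code{f1}..\code{f4} (character, \code{NA} where the
#'   field is absent).
#' @examples
#' parseAlleleName(c("A*02:01:01:01", "HLA-DQB1*02:01"))
#' @export
parseAlleleName <- function(x) {
  x <- as.character(x)
  stripped <- sub("^HLA-", "", x)
  ok <- grepl("^[A-Za-z][A-Za-z0-9]*\\*[0-9]+(:[0-9]+){0,3}$", stripped)
  if (!all(ok)) {
    stop("unparseable allele name(s): ", paste(x[!ok], collapse = ", "))
  }
  locus <- sub("\\*.*$", "", stripped)
  fieldstr <- sub("^[^*]*\\*", "", stripped)
  fields <- strsplit(fieldstr, ":", fixed = TRUE)
  pad <- function(f) c(f, rep(NA_character_, 4L - length(f)))[1:4]
  m <- do.call(rbind, lapply(fields, pad))
  data.frame(
    name = paste0(locus, "*", fieldstr),
    locus = locus,
    f1 = m[, 1], f2 = m[, 2], f3 = m[, 3], f4 = m[, 4],
    stringsAsFactors = FALSE
  )
}

#' Render allele names at a fixed nomenclature resolution
#'
#' Renders allele names at two-, four-, six- or eight-digit resolution,
#' i.e. keeping the first \code{digits/2} name fields. Rendering deeper
#' than the fields a name carries is an error rather than a silent pad.
#'
#' @param x character vector of allele names (any accepted spelling).
#' @param digits resolution: 2, 4, 6 or 8.
#' @return character vector of rendered names.
#' @examples
#' renderAllele("A*02:01:01:01", 4)   # "A*02:01"
#' @export
renderAllele <- function(x, digits) {
  stopifnot(length(digits) == 1L, digits %in% c(2L, 4L, 6L, 8L))
  p <- parseAlleleName(x)
  k <- digits / 2L
  fm <- as.matrix(p[, c("f1", "f2", "f3", "f4")])[, seq_len(k), drop = FALSE]
  if (anyNA(fm)) {
    bad <- p$name[apply(is.na(fm), 1L, any)]
    stop("cannot render at ", digits, "-digit resolution, name too shallow: ",
         paste(bad, collapse = ", "))
  }
  paste0(p$locus, "*", apply(fm, 1L, paste, collapse = ":"))
}

#' Number of name fields carried by each allele name
#' @param x character vector of allele names.
#' @return integer vector (1 to 4).
#' @export
alleleNameDepth <- function(x) {
  p <- parseAlleleName(x)
  4L - rowSums(is.na(as.matrix(p[, c("f1", "f2", "f3", "f4")])))
}

#' Protein-group (four-digit) identity of allele names
#'
#' The protein group of an allele is its four-digit rendering: all alleles
#' encoding the same protein share it. Names with fewer than two fields
#' have no four-digit identity and raise an error.
#'
#' @param x character vector of allele names.
#' @return character vector of group ids, e.g. \code{"A*02:01"}.
#' @export
proteinGroupId <- function(x) renderAllele(x, 4L)
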