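#' Collapse tied allele pairs to a consensus resolution
#'
#' A single best pair is reported at full resolution. When several
#' pairs are equally likely, resolution descends from eight- to
#' six- to four-digit, comparing pairs as unordered sets of rendered
#' names, and stops at the first resolution where all tied pairs render
#' identically. Descent starts no deeper than the shallowest name among
#' the tied pairs. With no consensus at four-digit or better the locus
#' is ambiguous and all tied pairs are listed.
#'
#' @param tied_pairs list of character(2) allele-name vectors, all
#'   within the likelihood tie tolerance of the best pair.
#' @return list with \code{alleles} (character(2), rendered),
#'   \code{resolution} ("full", 8, 6 or 4, or NA when ambiguous),
#'   \code{ambiguous} (logical) and \code{pairs} (the input pairs).
#' @export
collapseResolution <- function(tied_pairs) {
  stopifnot(length(tied_pairs) >= 1L)
  tied_pairs <- lapply(tied_pairs, function(p) sort(parseAlleleName(p)$name))
  tied_pairs <- unique(tied_pairs)
  if (length(tied_pairs) == 1L) {
    return(list(alleles = tied_pairs[[1]], resolution = "full",
                ambiguous = FALSE, pairs = tied_pairs))
  }
  depth <- min(alleleNameDepth(unlist(tied_pairs))) * 2L
  for (d in seq(min(8L, depth), 4L, by = -2L)) {
    rendered <- lapply(tied_pairs, function(p) sort(renderAllele(p, d)))
    if (length(unique(rendered)) == 1L) {
      return(list(alleles = rendered[[1]], resolution = as.character(d),
                  ambiguous = FALSE, pairs = tied_pairs))
    }
  }
  list(alleles = c(NA_character_, NA_character_), resolution = NA_character_,
       ambiguous = TRUE, pairs = tied_pairs)
}

#' Type one locus from its read set
#'
#' Runs the full per-locus pipeline: quantile pre-selection on raw
#' counts, SNP-site computation over the retained alleles, optimal-read
#' marking (99\% SNP-site identity), non-redundant protein-group
#' re-counting, leveled candidate selection with descriptive z-test
#' p-values, exhaustive pair likelihood scoring over the candidates,
#' and resolution collapse of tied best pairs. Deterministic given
#' identical inputs and configuration; the p-values never influence the
#' called pair.
#'
#' @param lrs a \linkS4class{LocusReadSet}.
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param config configuration list from \code{\link{hlaConfig}}.
#' @return list with elements \code{result} (one-row data.frame:
#'   \code{locus}, \code{allele1}, \code{allele2}, \code{resolution},
#'   \code{ambiguous}, \code{status}, \code{ll_total},
#'   \code{p_value_1}, \code{p_value_2}, \code{n_reads_used}),
#'   \code{pairs} (all scored pairs), \code{tied_pairs},
#'   \code{selection}, and \code{pvalues}.
#' @export
callLocus <- function(lrs, db, config = hlaConfig()) {
  locus <- lrs@locus
  nocall <- function(status) {
    list(result = data.frame(
           locus = locus, allele1 = NA_character_, allele2 = NA_character_,
           resolution = NA_character_, ambiguous = NA, status = status,
           ll_total = NA_real_, p_value_1 = NA_real_, p_value_2 = NA_real_,
           n_reads_used = 0L, stringsAsFactors = FALSE),
         pairs = NULL, tied_pairs = list(), selection = NULL, pvalues = NULL)
  }
  raw <- rawAlleleCounts(lrs)
  if (!length(raw)) return(nocall("no_reads"))
  retained <- preselectAlleles(raw, db, locus, config$preselect_quantile)
  if (!length(retained)) return(nocall("no_candidates"))
  sites <- snpSites(db, locus, retained)
  M <- frameBaseMatrix(db, locus, retained)

  if (length(sites)) {
    lrs <- markOptimalReads(lrs, db, retained, sites, config$min_identity)
    allele_reads <- recountOptimal(lrs)
    grp_reads <- groupReadSets(allele_reads)
    selection <- rankAndSelect(grp_reads, config$unique_frac,
                               config$explain_frac, config$account_frac)
    if (!nrow(selection)) return(nocall("no_candidates"))
    pvals <- groupPvalues(grp_reads, selection, config$min_background)
    grp_all <- proteinGroupId(retained)
    candidates <- retained[grp_all %in% selection$group]
    cand_units <- unique(unlist(allele_reads[intersect(names(allele_reads),
                                                       candidates)]))
  } else {
    # retained alleles are CDS-identical: no data evidence, priors decide
    selection <- data.frame(group = unique(proteinGroupId(retained)),
                            level = 0L, count = NA_integer_)
    pvals <- setNames(rep(NA_real_, nrow(selection)), selection$group)
    candidates <- retained
    cand_units <- character()
  }

  snpTab <- snpBaseTable(lrs, sites, units = cand_units)
  unitPairs <- phaseUnitPairs(snpTab, pairing = config$phase_pairing)
  pairs <- scoreAllPairs(candidates, snpTab, unitPairs, M, db)
  if (!nrow(pairs)) return(nocall("no_candidates"))

  best <- pairs$ll_total[1]
  tied <- pairs[pairs$ll_total >= best - config$tie_tol, , drop = FALSE]
  coll <- collapseResolution(
    lapply(seq_len(nrow(tied)), function(i) c(tied$allele1[i], tied$allele2[i])))

  called <- coll$alleles
  pv <- if (coll$ambiguous) c(NA_real_, NA_real_) else {
    vapply(called, function(a) {
      g <- tryCatch(proteinGroupId(a), error = function(e) NA_character_)
      if (!is.na(g) && g %in% names(pvals)) pvals[[g]] else NA_real_
    }, numeric(1))
  }
  list(result = data.frame(
         locus = locus, allele1 = called[1], allele2 = called[2],
         resolution = coll$resolution, ambiguous = coll$ambiguous,
         status = "called", ll_total = best,
         p_value_1 = unname(pv[1]), p_value_2 = unname(pv[2]),
         n_reads_used = length(cand_units), stringsAsFactors = FALSE),
       pairs = pairs, tied_pairs = coll$pairs,
       selection = selection, pvalues = pvals)
}

#' Type all loci of an alignment file
#'
#' Ingests a SAM/BAM file aligned against the database's allele contigs
#' and calls each locus independently with \code{\link{callLocus}}.
#'
#' @param path SAM/BAM file, or a pre-built list of
#'   \linkS4class{LocusReadSet} objects.
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param config configuration list from \code{\link{hlaConfig}}.
#' @param out optional path; when given, the result table is written as
#'   TSV.
#' @return data.frame with one row per locus (columns as in
#'   \code{\link{callLocus}}); attribute \code{detail} holds the
#'   per-locus pair tables and selections.
#' @export
typeHLA <- function(path, db, config = hlaConfig(), out = NULL) {
  readsets <- if (is.list(path)) path else {
    ingestAlignments(path, db, config$default_phred)
  }
  loci <- hlaLoci(db)
  detail <- list()
  rows <- lapply(loci, function(l) {
    if (!l %in% names(readsets)) {
      lrs <- new("LocusReadSet", locus = l, observations = data.frame(
        uid = character(), qname = character(), mate = integer(),
        hits = I(list()), pos = I(list()), bases = I(list()),
        quals = I(list()), optimal = I(list())))
    } else {
      lrs <- readsets[[l]]
    }
    res <- callLocus(lrs, db, config)
    detail[[l]] <<- res[c("pairs", "tied_pairs", "selection", "pvalues")]
    res$result
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out)) writeTypingTable(tab, out)
  attr(tab, "detail") <- detail
  tab
}

#' Write a typing result table as TSV
#' @param tab result table from \code{\link{typeHLA}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTypingTable <- function(tab, path) {
  attr(tab, "detail") <- NULL
  write.table(format(tab, digits = 15, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-allele typing accuracy against a truth table
#'
#' Each locus contributes two alleles. Calls and truth are rendered at
#' the requested resolution and matched as multisets: the number of
#' correct alleles at a locus is the multiset overlap, so a
#' heterozygous call against a homozygous truth (or vice versa) with one
#' shared allele scores one mistake out of two. An ambiguous
#' (unresolved) call scores zero at its locus, as does a no-call. A
#' one-allele call is treated as homozygous. Loci absent from the truth
#' table are excluded from the denominator.
#'
#' @param calls data.frame with columns \code{locus}, \code{allele1},
#'   \code{allele2}, and optionally \code{ambiguous}/\code{status}.
#' @param truth data.frame with columns \code{locus}, \code{allele1},
#'   \code{allele2} (homozygous loci list the allele twice).
#' @param digits resolution for matching: 2 or 4.
#' @return accuracy in [0, 1]; attributes \code{correct} and
#'   \code{total} give the counts.
#' @export
scorePredictions <- function(calls, truth, digits = 4L) {
  stopifnot(digits %in% c(2L, 4L))
  correct <- 0L; total <- 0L
  for (i in seq_len(nrow(truth))) {
    l <- truth$locus[i]
    j <- match(l, calls$locus)
    if (is.na(j)) next
    tr <- sort(renderAllele(c(truth$allele1[i], truth$allele2[i]), digits))
    total <- total + 2L
    amb <- if ("ambiguous" %in% names(calls)) isTRUE(calls$ambiguous[j]) else FALSE
    nocall <- is.na(calls$allele1[j])
    if (amb || nocall) next
    ca <- c(calls$allele1[j], calls$allele2[j])
    ca <- ca[!is.na(ca)]
    if (length(ca) == 1L) ca <- rep(ca, 2L)
    enough <- alleleNameDepth(ca) >= digits / 2L
    if (!all(enough)) next   # call too shallow for this resolution
    cr <- renderAllele(ca, digits)
    for (u in unique(tr)) {
      correct <- correct + min(sum(tr == u), sum(cr == u))
    }
  }
  structure(if (total) correct / total else NA_real_,
            correct = correct, total = total)
}
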