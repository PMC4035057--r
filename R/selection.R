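#' Default pipeline configuration
#'
#' Tunable parameters of the typing pipeline with their defaults:
#' \describe{
#'   \item{preselect_quantile}{upper quantile of raw per-allele counts
#'     retained at pre-selection (0.90).}
#'   \item{min_identity}{minimum SNP-site identity for an optimal read
#'     (0.99).}
#'   \item{unique_frac}{level-0 runner-up rule: second-ranked group kept
#'     if its unique reads exceed this fraction of the top group's count
#'     (0.01).}
#'   \item{explain_frac}{level-2 trigger: levels 0-1 must explain at
#'     least this fraction of locus reads (0.90).}
#'   \item{account_frac}{level-2 admission: a new group must account for
#'     more than this fraction of the locus reads (0.10).}
#'   \item{min_background}{minimum number of non-selected groups needed
#'     to fit the Gaussian background for p-values (3).}
#'   \item{freq_floor}{prior frequency for unrecorded protein groups
#'     (1e-6).}
#'   \item{default_phred}{Phred quality assumed when the alignment file
#'     carries none (30).}
#'   \item{tie_tol}{absolute log-likelihood tolerance within which pairs
#'     are considered equally likely (1e-9).}
#'   \item{phase_pairing}{"adjacent" (consecutive covered site pairs per
#'     unit) or "all" (every covered pair).}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return named list of configuration values.
#' @export
hlaConfig <- function(...) {
  cfg <- list(
    preselect_quantile = 0.90,
    min_identity = 0.99,
    unique_frac = 0.01,
    explain_frac = 0.90,
    account_frac = 0.10,
    min_background = 3L,
    freq_floor = 1e-6,
    default_phred = 30L,
    tie_tol = 1e-9,
    phase_pairing = "adjacent"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Quantile pre-selection of alleles on raw read counts
#'
#' Retains the alleles whose raw mapped-read count reaches the upper
#' quantile (default 90th percentile, empirical quantile with linear
#' interpolation) of the locus's per-allele count distribution. To be
#' conservative, every allele sharing a four-digit identity with a
#' selected allele is retained as well, even at zero count.
#'
#' @param raw_counts named integer vector of per-allele counts.
#' @param db an \linkS4class{HLAAlleleDb}.
#' @param locus locus identifier.
#' @param quantile upper quantile threshold.
#' @return character vector of retained allele names (empty if no
#'   counts).
#' @export
preselectAlleles <- function(raw_counts, db, locus, quantile = 0.90) {
  if (!length(raw_counts)) return(character())
  thr <- stats::quantile(as.numeric(raw_counts), quantile, names = FALSE)
  kept <- names(raw_counts)[raw_counts >= thr]
  all_of_locus <- alleleNames(db, locus)
  mates <- all_of_locus[proteinGroupId(all_of_locus) %in% proteinGroupId(kept)]
  sort(unique(c(kept, mates)))
}

#' Re-count reads using only optimal assignments
#'
#' After \code{\link{markOptimalReads}}, each read is counted only for
#' the allele(s) it is optimal for; suboptimal reads count nowhere.
#'
#' @param lrs a \linkS4class{LocusReadSet} with \code{optimal} filled.
#' @return named list: allele -> character vector of read-unit ids.
#' @export
recountOptimal <- function(lrs) {
  o <- readObservations(lrs)
  n <- lengths(o$optimal)
  if (!sum(n)) return(setNames(list(), character()))
  long <- data.frame(allele = unlist(o$optimal),
                     uid = rep(o$uid, n), stringsAsFactors = FALSE)
  lapply(split(long$uid, long$allele), unique)
}

#' Non-redundant protein-group read sets
#'
#' Pools the optimal-read id sets of the member alleles of each protein
#' group; a read counted for several members counts once for the group.
#'
#' @param allele_reads named list allele -> read-unit ids (from
#'   \code{\link{recountOptimal}}).
#' @return named list group -> character vector of read-unit ids.
#' @export
groupReadSets <- function(allele_reads) {
  if (!length(allele_reads)) return(setNames(list(), character()))
  grp <- proteinGroupId(names(allele_reads))
  lapply(split(allele_reads, grp), function(x) unique(unlist(x)))
}

#' Leveled protein-group ranking and candidate selection
#'
#' Implements the three-level selection on non-redundant group read
#' counts:
#' \itemize{
#'   \item Level 0: the group(s) with the largest count (ties included);
#'     additionally the second-ranked group if its reads not shared with
#'     the level-0 selections exceed \code{unique_frac} of the top
#'     group's count.
#'   \item Level 1: counts of the remaining groups are adjusted by
#'     removing reads counted for any level-0 selected group; the top
#'     adjusted group(s) with positive count are selected.
#'   \item Level 2 (conditional): if the selected groups explain less
#'     than \code{explain_frac} of the locus reads, the procedure runs
#'     once more, admitting new top groups whose adjusted count exceeds
#'     \code{account_frac} of the total. Runs at most once.
#' }
#'
#' @param group_reads named list group -> read-unit ids.
#' @param unique_frac,explain_frac,account_frac selection thresholds.
#' @return data.frame with columns \code{group}, \code{level},
#'   \code{count} (the count used at the group's selection level);
#'   attribute \code{total} is the number of distinct reads counted at
#'   the locus.
#' @export
rankAndSelect <- function(group_reads, unique_frac = 0.01,
                          explain_frac = 0.90, account_frac = 0.10) {
  sel <- data.frame(group = character(), level = integer(), count = integer())
  all_reads <- unique(unlist(group_reads))
  total <- length(all_reads)
  if (!length(group_reads) || total == 0L) {
    attr(sel, "total") <- 0L
    return(sel)
  }
  counts0 <- lengths(group_reads)

  # level 0: top group(s), plus qualifying runner-up
  top <- names(counts0)[counts0 == max(counts0)]
  level0 <- top
  rest <- setdiff(names(counts0), top)
  if (length(rest)) {
    second_count <- max(counts0[rest])
    second <- rest[counts0[rest] == second_count]
    top_union <- unique(unlist(group_reads[top]))
    for (g in second) {
      uniq <- setdiff(group_reads[[g]], top_union)
      if (length(uniq) > unique_frac * max(counts0[top])) {
        level0 <- c(level0, g)
      }
    }
  }
  sel <- data.frame(group = level0, level = 0L,
                    count = as.integer(counts0[level0]),
                    stringsAsFactors = FALSE)

  # level 1: adjust counts by removing reads of level-0 selections
  selected_reads <- unique(unlist(group_reads[level0]))
  remaining <- setdiff(names(group_reads), level0)
  adj1 <- vapply(group_reads[remaining],
                 function(r) length(setdiff(r, selected_reads)), integer(1))
  if (length(adj1) && max(adj1) > 0L) {
    top1 <- remaining[adj1 == max(adj1)]
    sel <- rbind(sel, data.frame(group = top1, level = 1L,
                                 count = as.integer(adj1[top1]),
                                 stringsAsFactors = FALSE))
  }

  # level 2: once, if levels 0-1 leave too many reads unexplained
  selected_reads <- unique(unlist(group_reads[sel$group]))
  if (length(selected_reads) < explain_frac * total) {
    remaining <- setdiff(names(group_reads), sel$group)
    adj2 <- vapply(group_reads[remaining],
                   function(r) length(setdiff(r, selected_reads)), integer(1))
    if (length(adj2) && max(adj2) > account_frac * total) {
      top2 <- remaining[adj2 == max(adj2)]
      sel <- rbind(sel, data.frame(group = top2, level = 2L,
                                   count = as.integer(adj2[top2]),
                                   stringsAsFactors = FALSE))
    }
  }
  attr(sel, "total") <- total
  rownames(sel) <- NULL
  sel
}

#' One-tailed Gaussian z-test p-values for selected groups
#'
#' At each selection level, the non-selected (lower-ranking) groups'
#' counts form the Gaussian background: their mean and sample variance
#' are estimated and each selected group receives the upper-tail
#' probability of its count. Groups selected at any level are excluded
#' from every background fit (they are the outliers under test). With
#' fewer than \code{min_background} background groups the p-value is
#' reported as \code{NA} (not computable); a zero-variance background
#' yields the smallest representable positive value with a warning.
#'
#' These p-values are purely descriptive: the caller never uses them to
#' choose the final allele pair.
#'
#' @param group_reads named list group -> read-unit ids.
#' @param selection output of \code{\link{rankAndSelect}}.
#' @param min_background minimum background group count.
#' @return named numeric vector of p-values for the selected groups.
#' @export
groupPvalues <- function(group_reads, selection, min_background = 3L) {
  out <- setNames(rep(NA_real_, nrow(selection)), selection$group)
  if (!nrow(selection)) return(out)
  background <- setdiff(names(group_reads), selection$group)
  for (lev in unique(selection$level)) {
    sel_l <- selection[selection$level == lev, , drop = FALSE]
    removed <- if (lev == 0L) character() else {
      unique(unlist(group_reads[selection$group[selection$level < lev]]))
    }
    lev_count <- function(g) length(setdiff(group_reads[[g]], removed))
    bg <- vapply(background, lev_count, integer(1))
    if (length(bg) < min_background) next
    m <- mean(bg); s <- stats::sd(bg)
    if (s == 0) {
      warning("zero variance among background groups at level ", lev,
              "; p-values set to the smallest positive value")
      out[sel_l$group] <- .Machine$double.xmin
    } else {
      out[sel_l$group] <- stats::pnorm(sel_l$count, mean = m, sd = s,
                                       lower.tail = FALSE)
    }
  }
  out
}
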