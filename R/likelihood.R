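#' Per-base genotype likelihood
#'
#' The canonical pileup model for a diploid genotype \eqn{G = \{b_1,
#' b_2\}}: the observed base comes from either allele with probability
#' 1/2; a correctly read base matches its template with probability
#' \eqn{1 - q} and is otherwise one of the three alternatives with
#' probability \eqn{q/3}, where \eqn{q} is the Phred-derived error rate.
#' So \eqn{P(d \mid G) = \tfrac12 f(d \mid b_1) + \tfrac12 f(d \mid
#' b_2)} with \eqn{f(d \mid b) = 1-q} if \eqn{d = b} else \eqn{q/3}.
#' The four-outcome distribution sums to one for any \eqn{q}.
#'
#' @param d observed bases (character vector).
#' @param b1,b2 genotype bases (recycled).
#' @param q per-base error probabilities.
#' @return numeric vector of probabilities.
#' @export
baseGenotypeLik <- function(d, b1, b2, q) {
  f1 <- ifelse(d == b1, 1 - q, q / 3)
  f2 <- ifelse(d == b2, 1 - q, q / 3)
  0.5 * f1 + 0.5 * f2
}

#' Two-site phase likelihood of an observed base pair
#'
#' The phase analogue of the single-site model: a phased two-site
#' haplotype has \eqn{4 \times 4 = 16} possible observed states, one
#' in-phase (both bases match the haplotype) and 15 out-of-phase. The
#' joint error rate of the two observed bases is \eqn{q_{ij} = 1 - (1 -
#' q_i)(1 - q_j)}; the in-phase state has probability \eqn{1 - q_{ij}}
#' and each out-of-phase state \eqn{q_{ij}/15}. For an allele pair the
#' two phased haplotypes are mixed evenly:
#' \eqn{P = \tfrac12 g(d \mid h_1) + \tfrac12 g(d \mid h_2)}.
#'
#' @param di,dj observed bases at the two sites.
#' @param h1i,h1j first haplotype's bases at the two sites.
#' @param h2i,h2j second haplotype's bases.
#' @param qi,qj per-base error probabilities.
#' @return numeric vector of probabilities.
#' @export
pairPhaseLik <- function(di, dj, h1i, h1j, h2i, h2j, qi, qj) {
  qij <- 1 - (1 - qi) * (1 - qj)
  g1 <- ifelse(di == h1i & dj == h1j, 1 - qij, qij / 15)
  g2 <- ifelse(di == h2i & dj == h2j, 1 - qij, qij / 15)
  0.5 * g1 + 0.5 * g2
}

#' Genotype log-likelihood of an allele pair
#'
#' Sums, over all read bases observed at SNP sites, the log of the
#' per-base genotype likelihood under the genotype the pair defines at
#' each site. Sites not covered by any read contribute nothing; rows
#' whose site is not covered by both alleles of the pair are skipped.
#'
#' @param pair character vector of two allele names (equal for a
#'   homozygous self-pair).
#' @param snpTab long base table from \code{\link{snpBaseTable}}.
#' @param M frame base matrix from \code{\link{frameBaseMatrix}}
#'   containing both alleles.
#' @return log-likelihood (natural log, <= 0).
#' @export
genotypeLogLik <- function(pair, snpTab, M) {
  if (!nrow(snpTab)) return(0)
  b1 <- M[cbind(snpTab$site + 1L, match(pair[1], colnames(M)))]
  b2 <- M[cbind(snpTab$site + 1L, match(pair[2], colnames(M)))]
  ok <- !is.na(b1) & !is.na(b2)
  if (!any(ok)) return(0)
  sum(log(baseGenotypeLik(snpTab$base[ok], b1[ok], b2[ok], snpTab$q[ok])))
}

#' Phase log-likelihood of an allele pair
#'
#' Sums, over the phase-informative units' site pairs, the log of the
#' two-site phase likelihood under the two phased haplotypes the allele
#' pair defines. With no informative unit the phase term is 0 (no
#' evidence).
#'
#' @param pair character vector of two allele names.
#' @param unitPairs site-pair table from \code{\link{phaseUnitPairs}}.
#' @param M frame base matrix containing both alleles.
#' @return log-likelihood (natural log, <= 0).
#' @export
phaseLogLik <- function(pair, unitPairs, M) {
  if (!nrow(unitPairs)) return(0)
  c1 <- match(pair[1], colnames(M)); c2 <- match(pair[2], colnames(M))
  h1i <- M[cbind(unitPairs$site_i + 1L, c1)]
  h1j <- M[cbind(unitPairs$site_j + 1L, c1)]
  h2i <- M[cbind(unitPairs$site_i + 1L, c2)]
  h2j <- M[cbind(unitPairs$site_j + 1L, c2)]
  ok <- !is.na(h1i) & !is.na(h1j) & !is.na(h2i) & !is.na(h2j)
  if (!any(ok)) return(0)
  sum(log(pairPhaseLik(unitPairs$base_i[ok], unitPairs$base_j[ok],
                       h1i[ok], h1j[ok], h2i[ok], h2j[ok],
                       unitPairs$q_i[ok], unitPairs$q_j[ok])))
}

#' Frequency log-likelihood of an allele pair
#'
#' Sum of the log prior frequencies of the two alleles; each allele's
#' frequency is that of its protein group (maximum reported over
#' populations, floor where unrecorded).
#'
#' @param pair character vector of two allele names.
#' @param db an \linkS4class{HLAAlleleDb}.
#' @return log prior (natural log, <= 0 for frequencies <= 1).
#' @export
freqLogLik <- function(pair, db) {
  sum(log(groupFrequency(db, proteinGroupId(pair))))
}

#' Score all candidate allele pairs
#'
#' Exhaustively scores every unordered pair of candidate alleles,
#' including self-pairs (homozygous calls), with
#' \eqn{LL_{total} = LL_{geno} + LL_{phase} + LL_{freq}}.
#' Deterministic given identical inputs.
#'
#' @param candidates character vector of candidate allele names.
#' @param snpTab long base table (\code{\link{snpBaseTable}}) of the
#'   reads to be explained.
#' @param unitPairs phase site-pair table (\code{\link{phaseUnitPairs}}).
#' @param M frame base matrix covering the candidates.
#' @param db an \linkS4class{HLAAlleleDb} (for prior frequencies).
#' @return data.frame with one row per pair: \code{allele1},
#'   \code{allele2}, \code{ll_geno}, \code{ll_phase}, \code{ll_freq},
#'   \code{ll_total}, sorted by decreasing \code{ll_total}.
#' @export
scoreAllPairs <- function(candidates, snpTab, unitPairs, M, db) {
  candidates <- sort(unique(candidates))
  n <- length(candidates)
  if (!n) {
    return(data.frame(allele1 = character(), allele2 = character(),
                      ll_geno = numeric(), ll_phase = numeric(),
                      ll_freq = numeric(), ll_total = numeric()))
  }
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  a1 <- candidates[idx[, "row"]]
  a2 <- candidates[idx[, "col"]]
  llg <- mapply(function(x, y) genotypeLogLik(c(x, y), snpTab, M), a1, a2)
  llp <- mapply(function(x, y) phaseLogLik(c(x, y), unitPairs, M), a1, a2)
  llf <- mapply(function(x, y) freqLogLik(c(x, y), db), a1, a2)
  out <- data.frame(allele1 = a1, allele2 = a2,
                    ll_geno = as.numeric(llg), ll_phase = as.numeric(llp),
                    ll_freq = as.numeric(llf),
                    stringsAsFactors = FALSE)
  out$ll_total <- out$ll_geno + out$ll_phase + out$ll_freq
  out <- out[order(-out$ll_total, out$allele1, out$allele2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
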