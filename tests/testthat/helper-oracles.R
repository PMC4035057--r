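# Independent brute-force oracles. These re-derive the quantities the
# package computes, with naive loop-based code sharing nothing with the
# implementation, so agreement is meaningful.

# Polymorphic-site scan over a gapped alignment matrix (rows = frame
# positions, cols = alleles, NA = gap). A site qualifies when it shows
# >= 2 distinct bases and no allele has a gap there.
oracleSnpSites <- function(aln) {
  out <- integer()
  for (i in seq_len(nrow(aln))) {
    col <- aln[i, ]
    if (any(is.na(col))) next
    if (length(unique(col)) >= 2) out <- c(out, i - 1L)
  }
  out
}

# Naive per-read SNP-site identity of one read against one allele
# column; bases: named by site (character of 0-based site).
oracleIdentity <- function(read_sites, read_bases, allele_col) {
  n <- 0L; m <- 0L
  for (k in seq_along(read_sites)) {
    b <- allele_col[read_sites[k] + 1L]
    if (is.na(b)) next
    n <- n + 1L
    if (b == read_bases[k]) m <- m + 1L
  }
  if (n == 0L) return(NA_real_)
  m / n
}

# Naive pair scorer: ll_geno, ll_phase, ll_freq, ll_total for one
# unordered pair given the long SNP base table, the alignment matrix,
# and the frequency table (max over populations, floor otherwise).
oracleScorePair <- function(a1, a2, snpTab, M, freqTab, floor = 1e-6) {
  ll_geno <- 0
  for (r in seq_len(nrow(snpTab))) {
    s <- snpTab$site[r]; d <- snpTab$base[r]; q <- snpTab$q[r]
    b1 <- M[s + 1L, a1]; b2 <- M[s + 1L, a2]
    if (is.na(b1) || is.na(b2)) next
    p1 <- if (d == b1) 1 - q else q / 3
    p2 <- if (d == b2) 1 - q else q / 3
    ll_geno <- ll_geno + log(p1 / 2 + p2 / 2)
  }
  ll_phase <- 0
  for (u in unique(snpTab$qname)) {
    rows <- snpTab[snpTab$qname == u, , drop = FALSE]
    # one base per site: keep the lowest error rate
    rows <- rows[order(rows$site, rows$q), , drop = FALSE]
    rows <- rows[!duplicated(rows$site), , drop = FALSE]
    if (nrow(rows) < 2L) next
    for (k in seq_len(nrow(rows) - 1L)) {
      si <- rows$site[k]; sj <- rows$site[k + 1L]
      di <- rows$base[k]; dj <- rows$base[k + 1L]
      qi <- rows$q[k]; qj <- rows$q[k + 1L]
      h1 <- c(M[si + 1L, a1], M[sj + 1L, a1])
      h2 <- c(M[si + 1L, a2], M[sj + 1L, a2])
      if (any(is.na(c(h1, h2)))) next
      qij <- 1 - (1 - qi) * (1 - qj)
      g1 <- if (di == h1[1] && dj == h1[2]) 1 - qij else qij / 15
      g2 <- if (di == h2[1] && dj == h2[2]) 1 - qij else qij / 15
      ll_phase <- ll_phase + log(g1 / 2 + g2 / 2)
    }
  }
  ll_freq <- 0
  for (a in c(a1, a2)) {
    g <- renderAllele(a, 4L)
    hits <- freqTab$frequency[freqTab$group == g]
    f <- if (length(hits)) max(hits) else floor
    ll_freq <- ll_freq + log(f)
  }
  c(ll_geno = ll_geno, ll_phase = ll_phase, ll_freq = ll_freq,
    ll_total = ll_geno + ll_phase + ll_freq)
}

# Step-by-step re-statement of the leveled selection rules on group
# read-id sets. Returns data.frame(group, level).
oracleRankSelect <- function(group_reads, unique_frac = 0.01,
                             explain_frac = 0.90, account_frac = 0.10) {
  groups <- names(group_reads)
  counts <- sapply(group_reads, length)
  picked <- character(); levels <- integer()
  if (!length(groups) || sum(counts) == 0) {
    return(data.frame(group = character(), level = integer()))
  }
  # level 0
  mx <- max(counts)
  tops <- groups[counts == mx]
  picked <- tops; levels <- rep(0L, length(tops))
  others <- setdiff(groups, tops)
  if (length(others)) {
    mx2 <- max(counts[others])
    seconds <- others[counts[others] == mx2]
    union0 <- unique(unlist(group_reads[tops]))
    for (g in seconds) {
      uniq <- sum(!(group_reads[[g]] %in% union0))
      if (uniq > unique_frac * mx) {
        picked <- c(picked, g); levels <- c(levels, 0L)
      }
    }
  }
  # level 1
  used <- unique(unlist(group_reads[picked]))
  rem <- setdiff(groups, picked)
  if (length(rem)) {
    adj <- sapply(rem, function(g) sum(!(group_reads[[g]] %in% used)))
    if (max(adj) > 0) {
      w <- rem[adj == max(adj)]
      picked <- c(picked, w); levels <- c(levels, rep(1L, length(w)))
    }
  }
  # level 2, at most once
  total <- length(unique(unlist(group_reads)))
  used <- unique(unlist(group_reads[picked]))
  if (length(used) < explain_frac * total) {
    rem <- setdiff(groups, picked)
    if (length(rem)) {
      adj <- sapply(rem, function(g) sum(!(group_reads[[g]] %in% used)))
      if (max(adj) > account_frac * total) {
        w <- rem[adj == max(adj)]
        picked <- c(picked, w); levels <- c(levels, rep(2L, length(w)))
      }
    }
  }
  data.frame(group = picked, level = levels, stringsAsFactors = FALSE)
}

# Random group-read-set configuration for the selection oracle.
randomGroupConfig <- function(seed) {
  set.seed(seed)
  n_groups <- sample(3:10, 1)
  universe <- sprintf("r%03d", seq_len(sample(30:200, 1)))
  gr <- lapply(seq_len(n_groups), function(i) {
    sz <- sample.int(length(universe), 1)
    sample(universe, sz)
  })
  names(gr) <- sprintf("G*%02d:01", seq_len(n_groups))
  gr
}
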