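# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately written in the most literal way possible
# (enumeration, direct summation) and never reuse package internals.

make_sites <- function(n, chrom = "2L", step = 1000L) {
  data.frame(chrom = chrom, pos = seq_len(n) * step,
             allele0 = "A", allele1 = "T", stringsAsFactors = FALSE)
}

# population with a given allele1 count (out of 2N chromosomes) per site;
# carriers are the leading columns, so the content is deterministic
make_pop <- function(counts1, N, chrom = "2L") {
  n <- length(counts1)
  m <- matrix(0L, n, 2L * N)
  for (s in seq_len(n)) if (counts1[s] > 0L) m[s, seq_len(counts1[s])] <- 1L
  population(make_sites(n, chrom), array(as.raw(m), dim = dim(m)))
}

# one-site population at p = 0.5 with exact Hardy-Weinberg genotype counts
# (N/4 homozygous carriers, N/2 heterozygotes), for infinite-N selection
# oracles that assume HW proportions
make_hw_pop <- function(N) {
  stopifnot(N %% 4L == 0L)
  alleles <- c(rep(1L, N / 2L), rep(c(1L, 0L), N / 2L), rep(0L, N / 2L))
  population(make_sites(1L), array(as.raw(alleles), c(1L, 2L * N)))
}

flat_map <- function(rate = 0, len = 10^7, chrom = "2L", sex_mode = FALSE) {
  recombination_map(data.frame(chrom = chrom, start = 0, end = len,
                               rate = rate), sex_mode = sex_mode)
}

scores_df <- function(p, selected) {
  label_snps(data.frame(chrom = "2L", pos = seq_along(p) * 10L, p.value = p,
                        stringsAsFactors = FALSE),
             selected_loci("2L", which(selected) * 10L, "T", 0.1, 0.5))
}

# brute-force ROC: enumerate every unique p-value threshold and count
brute_roc <- function(p, sel) {
  P <- sum(sel)
  Nn <- sum(!sel)
  fpr <- 0
  tpr <- 0
  for (t in sort(unique(p))) {
    tpr <- c(tpr, sum(sel & p <= t) / P)
    fpr <- c(fpr, sum(!sel & p <= t) / Nn)
  }
  cbind(fpr = fpr, tpr = tpr)
}

# brute-force trapezoid over the polyline, clipped at fpr_max
brute_pauc <- function(points, fpr_max) {
  area <- 0
  for (i in seq_len(nrow(points) - 1L)) {
    x1 <- points[i, 1L]; y1 <- points[i, 2L]
    x2 <- points[i + 1L, 1L]; y2 <- points[i + 1L, 2L]
    if (x1 >= fpr_max) break
    if (x2 > fpr_max) {
      y2 <- y1 + (y2 - y1) * (fpr_max - x1) / (x2 - x1)
      x2 <- fpr_max
    }
    area <- area + (x2 - x1) * (y1 + y2) / 2
  }
  area
}

# deterministic single-locus selection recursion (infinite-N oracle)
recursion_step <- function(p, s, h) {
  q <- 1 - p
  w22 <- 1 + s
  w12 <- 1 + h * s
  wbar <- p^2 * w22 + 2 * p * q * w12 + q^2
  p * (p * w22 + q * w12) / wbar
}

# CMH statistic via stats::mantelhaen.test (independent textbook oracle);
# mantelhaen.test needs k >= 2, so the single-stratum case falls back to the
# textbook identity MH = (n - 1) / n * Pearson chi-square
oracle_cmh <- function(base, evolved) {
  k <- dim(evolved)[3]
  if (k == 1L) {
    tab <- rbind(base, evolved[1, , 1])
    n <- sum(tab)
    stat <- unname(stats::chisq.test(tab, correct = FALSE)$statistic) *
      (n - 1) / n
    return(list(statistic = stat,
                p.value = stats::pchisq(stat, 1, lower.tail = FALSE)))
  }
  arr <- array(0, c(2, 2, k))
  for (r in seq_len(k)) {
    arr[1, , r] <- base
    arr[2, , r] <- evolved[1, , r]
  }
  stats::mantelhaen.test(arr, correct = FALSE)
}

# one-site allele count table
tiny_table <- function(base, evolved_list) {
  allele_count_table(make_sites(1L), matrix(base, 1L),
                     lapply(evolved_list, function(x) matrix(x, 1L)))
}
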