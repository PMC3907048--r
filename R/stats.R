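#' Exact allele counts of base and evolved populations
#'
#' Chromosome counts (2N per population) of the two alleles at every site of
#' the shared site list, for the base population and each evolved replicate.
#'
#' @param pop_base the base `Population`.
#' @param pops_evolved list of evolved `Population`s (the k replicates).
#' @return An `AlleleCountTable`.
#' @export
count_alleles <- function(pop_base, pops_evolved) {
  stopifnot(inherits(pop_base, "Population"), length(pops_evolved) >= 1L)
  for (p in pops_evolved) {
    if (!identical(p$sites[c("chrom", "pos")],
                   pop_base$sites[c("chrom", "pos")]))
      stop("evolved population does not share the base site list")
  }
  two_n <- function(pop) ncol(pop$haplotypes)
  c1 <- site_counts_cpp(pop_base$haplotypes)
  base <- unname(cbind(two_n(pop_base) - c1, c1))
  evolved <- array(0L, dim = c(nrow(base), 2L, length(pops_evolved)))
  for (r in seq_along(pops_evolved)) {
    e1 <- site_counts_cpp(pops_evolved[[r]]$haplotypes)
    evolved[, 1L, r] <- two_n(pops_evolved[[r]]) - e1
    evolved[, 2L, r] <- e1
  }
  allele_count_table(pop_base$sites, base, evolved)
}

#' Build an allele count table from recorded trajectories
#'
#' Converts allele-frequency snapshots (see [evolve()]) back into exact
#' chromosome counts, avoiding the need to keep whole populations in memory.
#'
#' @param sites shared site table.
#' @param base_freq,evolved_freq allele1 frequencies of the base population
#'   and a sites x k matrix for the evolved replicates.
#' @param n_base,n_evolved diploid census sizes.
#' @return An `AlleleCountTable`.
#' @export
counts_from_freq <- function(sites, base_freq, evolved_freq, n_base,
                             n_evolved = n_base) {
  evolved_freq <- as.matrix(evolved_freq)
  b1 <- as.integer(round(base_freq * 2L * n_base))
  k <- ncol(evolved_freq)
  evolved <- array(0L, dim = c(length(b1), 2L, k))
  for (r in seq_len(k)) {
    e1 <- as.integer(round(evolved_freq[, r] * 2L * n_evolved))
    evolved[, 1L, r] <- 2L * n_evolved - e1
    evolved[, 2L, r] <- e1
  }
  allele_count_table(sites, cbind(2L * n_base - b1, b1), evolved)
}

#' Pool-Seq sampling of an allele count table
#'
#' Models pooled sequencing: at each site and population, a read depth is
#' drawn (fixed at `coverage`, or Poisson-distributed around it) and read
#' counts are sampled binomially at the population allele frequency, i.e.
#' alleles are drawn from the pool with replacement.
#'
#' @param table an `AlleleCountTable` of exact counts.
#' @param coverage mean reads per site (> 0).
#' @param mode `"fixed"` depth, or `"poisson"` for per-site Poisson depth
#'   (coverage heterogeneity).
#' @param seed optional integer seed.
#' @return An `AlleleCountTable` of read counts.
#' @export
poolseq_sample <- function(table, coverage, mode = c("fixed", "poisson"),
                           seed = NULL) {
  stopifnot(inherits(table, "AlleleCountTable"), coverage > 0)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table$sites)
  draw <- function(c0, c1) {
    tot <- c0 + c1
    p1 <- ifelse(tot > 0L, c1 / tot, 0)
    d <- if (mode == "fixed") rep(as.integer(round(coverage)), n)
         else rpois(n, coverage)
    r1 <- rbinom(n, d, p1)
    cbind(d - r1, r1)
  }
  base <- draw(table$base[, 1L], table$base[, 2L])
  evolved <- array(0L, dim = dim(table$evolved))
  for (r in seq_len(table$k))
    evolved[, , r] <- draw(table$evolved[, 1L, r], table$evolved[, 2L, r])
  out <- allele_count_table(table$sites, base, evolved)
  attr(out, "poolseq") <- list(coverage = coverage, mode = mode)
  out
}

#' Cochran-Mantel-Haenszel test per SNP
#'
#' Classical CMH chi-square (1 df, no continuity correction) on the
#' 2 x 2 x k table of (base vs evolved) x (allele0 vs allele1) counts across
#' the k replicates:
#' statistic = (sum_k (a_k - E\[a_k\]))^2 / sum_k Var(a_k) with
#' E\[a_k\] = R1k C1k / nk and Var(a_k) = R1k R2k C1k C2k / (nk^2 (nk - 1)),
#' where a_k is the base-population allele0 count. SNPs monomorphic in every
#' stratum carry no information and get statistic 0, p = 1 and
#' `informative = FALSE`, keeping the test's denominator of evaluated SNPs
#' stable across designs.
#'
#' @param table an `AlleleCountTable`.
#' @param replicates which replicates to use (default all k).
#' @return Data frame with chrom, pos, statistic, p.value, informative.
#' @export
cmh_test <- function(table, replicates = seq_len(table$k)) {
  stopifnot(inherits(table, "AlleleCountTable"), length(replicates) >= 1L)
  b0 <- as.numeric(table$base[, 1L])
  b1 <- as.numeric(table$base[, 2L])
  R1 <- b0 + b1
  sumA <- sumE <- sumV <- 0
  for (r in replicates) {
    e0 <- as.numeric(table$evolved[, 1L, r])
    e1 <- as.numeric(table$evolved[, 2L, r])
    R2 <- e0 + e1
    C1 <- b0 + e0
    C2 <- b1 + e1
    n <- R1 + R2
    ok <- n > 1
    E <- ifelse(ok, R1 * C1 / n, 0)
    V <- ifelse(ok, R1 * R2 * C1 * C2 / (n * n * (n - 1)), 0)
    sumA <- sumA + ifelse(n > 0, b0, 0)
    sumE <- sumE + E
    sumV <- sumV + V
  }
  informative <- sumV > 0
  stat <- ifelse(informative, (sumA - sumE)^2 / sumV, 0)
  p <- ifelse(informative, pchisq(stat, df = 1L, lower.tail = FALSE), 1)
  p <- pmax(p, .Machine$double.xmin)  # p-values in (0, 1]
  data.frame(chrom = table$sites$chrom, pos = table$sites$pos,
             statistic = stat, p.value = p, informative = informative,
             stringsAsFactors = FALSE)
}

#' Average pairwise FST per SNP
#'
#' Heterozygosity-based per-SNP estimator, averaged over the (base, evolved
#' replicate) pairs: FST = (pi_T - pi_S) / pi_T, where pi_S is the mean of
#' the two within-population heterozygosities 2p(1-p) and pi_T the
#' heterozygosity at the mean frequency; 0 where pi_T = 0. No sample-size
#' correction is applied.
#'
#' @param table an `AlleleCountTable`.
#' @return Numeric vector of per-SNP FST values in \[0, 1\].
#' @export
pairwise_fst <- function(table) {
  stopifnot(inherits(table, "AlleleCountTable"))
  tot_b <- table$base[, 1L] + table$base[, 2L]
  pb <- ifelse(tot_b > 0L, table$base[, 2L] / tot_b, 0)
  acc <- 0
  for (r in seq_len(table$k)) {
    tot_e <- table$evolved[, 1L, r] + table$evolved[, 2L, r]
    pe <- ifelse(tot_e > 0L, table$evolved[, 2L, r] / tot_e, 0)
    pi_s <- (2 * pb * (1 - pb) + 2 * pe * (1 - pe)) / 2
    pbar <- (pb + pe) / 2
    pi_t <- 2 * pbar * (1 - pbar)
    acc <- acc + ifelse(pi_t > 0, (pi_t - pi_s) / pi_t, 0)
  }
  acc / table$k
}

#' Write per-SNP test results
#'
#' @param results data frame from [cmh_test()].
#' @param path output TSV; statistic and p-value in scientific notation with
#'   6 significant digits.
#' @param header_lines optional comment lines (prefixed `#`) written first.
#' @export
write_results <- function(results, path, header_lines = character(0)) {
  con <- out_conn(path)
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  out <- data.frame(chrom = results$chrom, pos = results$pos,
                    statistic = format(results$statistic, digits = 6,
                                       scientific = TRUE),
                    p.value = format(results$p.value, digits = 6,
                                     scientific = TRUE))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
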