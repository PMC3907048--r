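#' Genome window specification
#'
#' Windows tile the simulated genome and carry both the expected pairwise
#' nucleotide diversity (theta = pi per site) and the female recombination
#' rate used by the founder generator and the recombination map.
#'
#' @param chrom,start,end window coordinates (0-based, half-open, bp).
#' @param theta expected pairwise diversity per site within the window.
#' @param rate female recombination rate in cM/Mb.
#' @return A data frame of class `WindowSpec`.
#' @export
window_spec <- function(chrom, start, end, theta, rate) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), theta = as.numeric(theta),
                   rate = as.numeric(rate), stringsAsFactors = FALSE)
  if (any(df$theta < 0)) stop("theta must be >= 0")
  if (any(df$end <= df$start)) stop("windows must satisfy start < end")
  class(df) <- c("WindowSpec", "data.frame")
  df
}

#' @param path TSV with columns chrom, start, end, theta, rate.
#' @rdname window_spec
#' @export
read_windows <- function(path) {
  con <- in_conn(path)
  on.exit(close(con))
  df <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  window_spec(df$chrom, df$start, df$end, df$theta, df$rate)
}

#' @param windows a `WindowSpec` table.
#' @param sex_mode passed to [recombination_map()].
#' @rdname window_spec
#' @export
as_recombination_map <- function(windows, sex_mode = TRUE) {
  recombination_map(windows[, c("chrom", "start", "end", "rate")],
                    sex_mode = sex_mode)
}

## expected pairwise diversity contributed by one SNP under the neutral 1/i
## site-frequency spectrum, by direct summation:
##   E[pi] = sum_i (1/i) * 2 i (n-i) / (n (n-1)) / H_{n-1} = 1 / H_{n-1}
sfs_harmonic <- function(n) sum(1 / seq_len(n - 1L))

#' Simulate neutral founder haplotypes
#'
#' Generates a synthetic base population mimicking coalescent-derived
#' standing variation: within each window the expected SNP count is
#' `width * theta * H`, with `H` the harmonic number `sum(1/i)` for
#' `i = 1..n-1` (so that realized pairwise diversity per site matches
#' `theta`); the derived-allele count of each SNP is drawn from the neutral
#' site-frequency spectrum (probability proportional to `1/i`), carriers are
#' a uniform random subset of genomes, and positions are uniform within the
#' window. Founder sites carry no linkage disequilibrium; LD in the
#' experiment arises from the inbred-line expansion and drift.
#'
#' @param windows a `WindowSpec` table.
#' @param n_haploid number of haploid founder genomes (>= 2).
#' @param seed optional integer seed.
#' @return A `HaplotypeSet`.
#' @export
simulate_founder_haplotypes <- function(windows, n_haploid, seed = NULL) {
  stopifnot(inherits(windows, "data.frame"), n_haploid >= 2L)
  if (!is.null(seed)) set.seed(seed)
  H <- sfs_harmonic(n_haploid)
  i_class <- seq_len(n_haploid - 1L)
  sfs_p <- (1 / i_class) / H
  out_sites <- vector("list", nrow(windows))
  out_mat <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    width <- windows$end[w] - windows$start[w]
    lambda <- width * windows$theta[w] * H
    if (lambda > width)
      stop("theta too large: expected SNP count exceeds window width in ",
           windows$chrom[w], ":", windows$start[w])
    n_snp <- rpois(1L, lambda)
    n_snp <- min(n_snp, width)
    if (n_snp == 0L) next
    pos <- windows$start[w] + sort(sample.int(width, n_snp))
    counts <- sample(i_class, n_snp, replace = TRUE, prob = sfs_p)
    # fill a raw matrix directly: one byte per call keeps large genomes
    # (hundreds of thousands of SNPs x thousands of genomes) affordable
    mat <- matrix(as.raw(0L), n_snp, n_haploid)
    one <- as.raw(1L)
    for (s in seq_len(n_snp))
      mat[s, sample.int(n_haploid, counts[s])] <- one
    anc <- sample(NUCS, n_snp, replace = TRUE)
    der <- vapply(anc, function(a) sample(setdiff(NUCS, a), 1L), "")
    out_sites[[w]] <- data.frame(chrom = windows$chrom[w], pos = pos,
                                 allele0 = anc, allele1 = unname(der),
                                 stringsAsFactors = FALSE)
    out_mat[[w]] <- mat
  }
  keep <- !vapply(out_sites, is.null, TRUE)
  if (!any(keep)) {  # theta = 0 everywhere: a valid, empty haplotype set
    return(haplotype_set(data.frame(chrom = character(0), pos = integer(0),
                                    allele0 = character(0),
                                    allele1 = character(0)),
                         matrix(raw(0), 0L, n_haploid)))
  }
  sites <- do.call(rbind, out_sites[keep])
  mat <- do.call(rbind, out_mat[keep])
  haplotype_set(sites, mat)
}

#' Diploid population
#'
#' `N` diploid individuals over a shared site list; individual `i` owns
#' haplotype columns `2i-1` and `2i`.
#'
#' @param sites site table (see [haplotype_set()]).
#' @param haplotypes raw matrix, sites x 2N.
#' @param generation generation counter (0 = base population).
#' @return An object of class `Population`.
#' @export
population <- function(sites, haplotypes, generation = 0L) {
  stopifnot(is.raw(haplotypes), ncol(haplotypes) %% 2L == 0L,
            nrow(haplotypes) == nrow(sites))
  structure(list(sites = sites, haplotypes = haplotypes,
                 N = ncol(haplotypes) %/% 2L,
                 generation = as.integer(generation)),
            class = "Population")
}

#' @export
print.Population <- function(x, ...) {
  cat(sprintf("Population: N=%d diploids, %d sites, generation %d\n",
              x$N, nrow(x$sites), x$generation))
  invisible(x)
}

#' Allele frequencies of a population
#'
#' @param pop a `Population` (or `HaplotypeSet`).
#' @return Numeric vector of allele1 (derived-label) frequencies per site.
#' @export
allele_freq <- function(pop) {
  site_counts_cpp(pop$haplotypes) / ncol(pop$haplotypes)
}

#' Expand founder haplotypes into a diploid base population
#'
#' With fewer founder haplotypes than chromosomes in the target population
#' (`n_haploid < 2N`), each founder genome is replicated into
#' `N / n_haploid` identical homozygous individuals, mimicking inbred
#' isofemale lines (e.g. 50 founders at N = 1000 put every haplotype into 20
#' homozygous individuals). With `n_haploid == 2N` the haplotypes are paired
#' uniformly at random without replacement into heterozygous individuals.
#'
#' @param hs a `HaplotypeSet` of founder genomes.
#' @param N target diploid census size (constant during the experiment).
#' @return A `Population` at generation 0.
#' @export
expand_to_population <- function(hs, N) {
  stopifnot(inherits(hs, "HaplotypeSet"))
  n_h <- ncol(hs$haplotypes)
  N <- as.integer(N)
  if (n_h == 2L * N) {
    ord <- sample.int(n_h)
    haps <- hs$haplotypes[, ord, drop = FALSE]
  } else if (n_h < 2L * N && N %% n_h == 0L) {
    copies <- 2L * N %/% n_h
    haps <- hs$haplotypes[, rep(seq_len(n_h), each = copies), drop = FALSE]
  } else {
    stop("need n_haploid == 2N, or N divisible by n_haploid (inbred lines)")
  }
  population(hs$sites, haps, generation = 0L)
}

#' Pick beneficial loci from a base population
#'
#' Three-step picker: draw a segregating site uniformly at random; assign the
#' beneficial role to one of its two alleles by a fair coin; discard and
#' redraw if the beneficial allele's starting frequency exceeds `freq_cap`
#' (default 80%, which keeps the selected allele detectable). Draws are
#' capped at `1000 * n` before giving up.
#'
#' @param pop a `Population` (base population).
#' @param n number of loci to pick.
#' @param s,h selection and dominance coefficients assigned to every locus.
#' @param freq_cap maximum allowed starting frequency of the beneficial
#'   allele.
#' @param seed optional integer seed.
#' @return A `SelectedLoci` table of `n` distinct loci.
#' @export
pick_selected_loci <- function(pop, n, s, h = 0.5, freq_cap = 0.8,
                               seed = NULL) {
  stopifnot(inherits(pop, "Population"), n >= 1L, freq_cap > 0, freq_cap <= 1)
  if (!is.null(seed)) set.seed(seed)
  freq1 <- allele_freq(pop)
  seg <- which(freq1 > 0 & freq1 < 1)
  if (length(seg) < n) stop("fewer than n segregating sites")
  chosen <- integer(0)
  ben <- integer(0)
  draws <- 0L
  max_draws <- 1000L * as.integer(n)
  while (length(chosen) < n) {
    if (draws >= max_draws)
      stop("could not find ", n, " eligible loci within ", max_draws,
           " draws (freq_cap too strict?)")
    draws <- draws + 1L
    site <- seg[sample.int(length(seg), 1L)]
    if (site %in% chosen) next
    allele <- if (runif(1L) < 0.5) 1L else 0L
    f <- if (allele == 1L) freq1[site] else 1 - freq1[site]
    if (f > freq_cap) next
    chosen <- c(chosen, site)
    ben <- c(ben, allele)
  }
  o <- order(chosen)
  chosen <- chosen[o]
  ben <- ben[o]
  nuc <- ifelse(ben == 1L, pop$sites$allele1[chosen],
                pop$sites$allele0[chosen])
  selected_loci(pop$sites$chrom[chosen], pop$sites$pos[chosen], nuc, s, h)
}
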