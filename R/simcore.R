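#' Genetic positions of sites under a recombination map
#'
#' Converts the window map into, per site, a cumulative genetic position in
#' Morgans relative to the start of its chromosome, plus the full effective
#' map length of every chromosome. Every site must fall inside a window.
#'
#' @param map a `RecombinationMap`.
#' @param sites site table of the population/haplotype set.
#' @return List with `genpos` (Morgans per site), `chrom_offsets` (0-based
#'   site offsets per chromosome, length nchrom+1) and `chrom_len`
#'   (effective Morgans per chromosome).
#' @export
genetic_positions <- function(map, sites) {
  stopifnot(inherits(map, "RecombinationMap"))
  chroms <- unique(sites$chrom)   # sites arrive sorted
  genpos <- numeric(nrow(sites))
  offsets <- integer(length(chroms) + 1L)
  clen <- numeric(length(chroms))
  m_per_bp <- 1e-8  # 1 cM/Mb = 1e-8 Morgan/bp
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    idx <- which(sites$chrom == ch)
    offsets[ci + 1L] <- offsets[ci] + length(idx)
    w <- map$windows[map$windows$chrom == ch, , drop = FALSE]
    if (nrow(w) == 0L) stop("no recombination windows for chromosome ", ch)
    cumM <- c(0, cumsum((w$end - w$start) * w$effective_rate * m_per_bp))
    clen[ci] <- cumM[length(cumM)]
    p <- sites$pos[idx]
    wi <- findInterval(p - 1L, w$start)
    bad <- wi == 0L | (p - 1L) >= w$end[pmax(wi, 1L)]
    if (any(bad))
      stop("site not covered by the recombination map: ", ch, ":",
           p[which(bad)[1L]])
    genpos[idx] <- cumM[wi] + (p - w$start[wi]) * w$effective_rate[wi] * m_per_bp
  }
  list(genpos = genpos, chrom_offsets = offsets, chrom_len = clen)
}

#' Fitness model over selected loci
#'
#' Per locus the three genotype fitnesses are `w11 = 1`, `w12 = 1 + h s`,
#' `w22 = 1 + s`, the genotype being the number of copies of the beneficial
#' allele; fitness is multiplicative across loci. An empty model (no loci)
#' gives every individual fitness 1, i.e. neutral evolution.
#'
#' @param loci a `SelectedLoci` table, or NULL for a neutral model.
#' @param sites site table of the population the model will act on.
#' @return An object of class `FitnessModel`.
#' @export
fitness_model <- function(loci = NULL, sites = NULL) {
  if (is.null(loci) || nrow(loci) == 0L) {
    return(structure(list(site0 = integer(0), allele = integer(0),
                          s = numeric(0), h = numeric(0),
                          w1 = numeric(0), w2 = numeric(0),
                          loci = selected_loci(character(0), integer(0),
                                               character(0), numeric(0),
                                               numeric(0))),
                     class = "FitnessModel"))
  }
  stopifnot(!is.null(sites))
  key <- paste(sites$chrom, sites$pos)
  idx <- match(paste(loci$chrom, loci$pos), key)
  if (anyNA(idx))
    stop("selected locus absent from the site list: ",
         paste(loci$chrom[is.na(idx)][1L], loci$pos[is.na(idx)][1L]))
  allele <- ifelse(loci$allele == sites$allele1[idx], 1L,
                   ifelse(loci$allele == sites$allele0[idx], 0L, NA_integer_))
  if (anyNA(allele))
    stop("beneficial allele is not one of the two alleles at its site")
  structure(list(site0 = idx - 1L, allele = as.integer(allele),
                 s = loci$s, h = loci$h,
                 w1 = 1 + loci$h * loci$s, w2 = 1 + loci$s, loci = loci),
            class = "FitnessModel")
}

#' @export
print.FitnessModel <- function(x, ...) {
  if (length(x$site0) == 0L) cat("FitnessModel: neutral (no selected loci)\n")
  else cat(sprintf("FitnessModel: %d selected loci, s in [%g, %g]\n",
                   length(x$site0), min(x$s), max(x$s)))
  invisible(x)
}

#' Fitness of one multilocus genotype
#'
#' @param counts copies of the beneficial allele (0, 1 or 2) at each locus.
#' @param model a `FitnessModel` with as many loci as `counts`.
#' @return Positive scalar fitness: the product over loci of 1, `1+hs` or
#'   `1+s`.
#' @export
individual_fitness <- function(counts, model) {
  stopifnot(inherits(model, "FitnessModel"),
            length(counts) == length(model$w1), all(counts %in% 0:2))
  if (length(counts) == 0L) return(1)
  w <- ifelse(counts == 0L, 1, ifelse(counts == 1L, model$w1, model$w2))
  if (length(w) > 50L) exp(sum(log(w))) else prod(w)
}

#' Fitness of every individual in a population
#'
#' @param pop a `Population`.
#' @param model a `FitnessModel`.
#' @return Numeric vector of length N.
#' @export
population_fitness <- function(pop, model) {
  fitness_cpp(pop$haplotypes, model$site0, model$allele, model$w1, model$w2)
}

#' Form one gamete with recombination
#'
#' Crossover counts are Poisson with mean equal to the chromosome's effective
#' map length in Morgans; breakpoints are uniform in genetic distance (no
#' interference); the gamete starts from a fair-coin choice of the two
#' parental haplotypes and switches at every breakpoint; chromosomes assort
#' independently.
#'
#' @param pop a `Population`.
#' @param individual 1-based index of the parent.
#' @param map a `RecombinationMap` covering all sites.
#' @return List with `haplotype` (raw 0/1 vector over sites) and
#'   `crossovers` (count per chromosome).
#' @export
make_gamete <- function(pop, individual, map) {
  stopifnot(inherits(pop, "Population"),
            individual >= 1L, individual <= pop$N)
  gp <- genetic_positions(map, pop$sites)
  res <- gamete_cpp(pop$haplotypes, as.integer(individual) - 1L, gp$genpos,
                    gp$chrom_offsets, gp$chrom_len)
  cx <- res$crossovers
  names(cx) <- unique(pop$sites$chrom)
  list(haplotype = res$gamete, crossovers = cx)
}

evolve_internal <- function(pop, model, map, generations, record_at,
                            return_population) {
  gp <- genetic_positions(map, pop$sites)
  evolve_cpp(pop$haplotypes, gp$genpos, gp$chrom_offsets, gp$chrom_len,
             model$site0, model$allele, model$w1, model$w2,
             as.integer(generations), as.integer(record_at),
             return_population)
}

#' Advance a population by one generation
#'
#' Fecundity selection with non-overlapping hermaphrodite generations:
#' exactly N offspring are produced; for each offspring both parents are
#' drawn independently with probability proportional to fitness, the second
#' parent being redrawn until it differs from the first (selfing excluded);
#' each parent contributes one recombinant gamete.
#'
#' @inheritParams make_gamete
#' @param model a `FitnessModel`.
#' @return A `Population` at generation + 1.
#' @export
next_generation <- function(pop, model, map) {
  res <- evolve_internal(pop, model, map, 1L, integer(0), TRUE)
  population(pop$sites, res$haps, pop$generation + 1L)
}

#' Run forward simulation and record allele-frequency trajectories
#'
#' Repeated application of [next_generation()]; allele (allele1) frequencies
#' are recorded at the requested generations, generation 0 being the input
#' base population. No de novo mutation arises: a fixed or lost allele never
#' resegregates.
#'
#' @inheritParams next_generation
#' @param generations number of generations to simulate (>= 0).
#' @param record_at generations at which to record frequencies (within
#'   `[0, generations]`).
#' @param return_population keep the final population in the result (set to
#'   FALSE to save memory on large site lists).
#' @return An object of class `Trajectory`: site table, recorded
#'   generations, a sites x generations frequency matrix `freq`, and the
#'   final `Population` (unless disabled).
#' @export
evolve <- function(pop, model, map, generations, record_at = generations,
                   return_population = TRUE) {
  stopifnot(inherits(pop, "Population"), generations >= 0L)
  record_at <- sort(unique(as.integer(record_at)))
  if (length(record_at) && (min(record_at) < 0L || max(record_at) > generations))
    stop("record_at outside [0, generations]")
  res <- evolve_internal(pop, model, map, generations, record_at,
                         return_population)
  colnames(res$freq) <- as.character(record_at)
  structure(list(sites = pop$sites, generations = record_at,
                 freq = res$freq,
                 final = if (return_population)
                   population(pop$sites, res$haps,
                              pop$generation + as.integer(generations))),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d sites, recorded at generation(s) %s\n",
              nrow(x$sites), paste(x$generations, collapse = ", ")))
  invisible(x)
}

#' Neutral drift phase
#'
#' Evolves the population without selection, as done to break up founder
#' linkage before an experiment; low-frequency beneficial alleles may be
#' lost to drift during this phase.
#'
#' @inheritParams evolve
#' @return The drifted `Population`.
#' @export
drift_phase <- function(pop, generations, map) {
  if (generations == 0L) return(pop)
  ev <- evolve(pop, fitness_model(NULL), map, generations,
               record_at = integer(0), return_population = TRUE)
  ev$final
}
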