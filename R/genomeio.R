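#' @useDynLib erdesign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq rbinom rpois runif qt sd cor setNames
#' @importFrom utils read.table write.table head tail packageVersion
NULL

NUCS <- c("A", "T", "C", "G")

## connection that is transparent to gzip on both ends; plain files pass
## through unchanged (gzfile reads uncompressed input as well)
in_conn <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gzfile(path, "rt")
}
out_conn <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Biallelic haplotype set
#'
#' Container for a set of haploid genomes over a shared list of biallelic,
#' segregating SNPs. Sites are kept sorted by (chromosome, position); allele
#' calls are stored as 0/1 indices (one byte each) with the two nucleotide
#' labels stored once per site, so a population of thousands of genomes with
#' millions of SNPs stays within commodity memory.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `allele0`,
#'   `allele1` (nucleotide labels; `allele0` is the ancestral allele).
#' @param haplotypes raw or integer matrix of 0/1 allele indices, one row per
#'   site and one column per haploid genome (at least 2 columns).
#' @return An object of class `HaplotypeSet`.
#' @export
haplotype_set <- function(sites, haplotypes) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "allele0", "allele1") %in% names(sites)))
  if (!is.raw(haplotypes)) {
    stopifnot(all(haplotypes %in% c(0L, 1L)))
    haplotypes <- array(as.raw(haplotypes), dim = dim(haplotypes))
  }
  stopifnot(nrow(haplotypes) == nrow(sites))
  if (ncol(haplotypes) < 2L) stop("need at least 2 haploid genomes")
  sites <- data.frame(chrom = as.character(sites$chrom),
                      pos = as.integer(sites$pos),
                      allele0 = as.character(sites$allele0),
                      allele1 = as.character(sites$allele1),
                      stringsAsFactors = FALSE)
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  o <- order(sites$chrom, sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) {  # avoid copying sorted input
    sites <- sites[o, , drop = FALSE]
    haplotypes <- haplotypes[o, , drop = FALSE]
  }
  rownames(sites) <- NULL
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicated (chromosome, position)")
  bad <- !(sites$allele0 %in% NUCS) | !(sites$allele1 %in% NUCS) |
    sites$allele0 == sites$allele1
  if (any(bad))
    stop("sites must be biallelic with two distinct nucleotides among A/C/G/T")
  cnt <- site_counts_cpp(haplotypes)
  if (any(cnt == 0L | cnt == ncol(haplotypes)))
    stop("all sites must be segregating (both alleles present)")
  structure(list(sites = sites, haplotypes = haplotypes),
            class = "HaplotypeSet")
}

#' @export
print.HaplotypeSet <- function(x, ...) {
  cat(sprintf("HaplotypeSet: %d sites x %d haploid genomes on %d chromosome(s)\n",
              nrow(x$sites), ncol(x$haplotypes),
              length(unique(x$sites$chrom))))
  invisible(x)
}

#' Number of haploid genomes in a set
#' @param hs a `HaplotypeSet`.
#' @return Integer count of haploid genomes.
#' @export
n_haplotypes <- function(hs) ncol(hs$haplotypes)

#' Read / write haplotype files
#'
#' Plain-text (optionally gzip-compressed) haplotype format: a header line
#' `#chr pos ancestral alleles g1 ... gn` followed by one tab-separated row
#' per SNP giving chromosome, 1-based position, ancestral nucleotide, the two
#' alleles as `a0/a1`, and the nucleotide carried by each haploid genome.
#' Externally generated haplotypes (e.g. from a coalescent simulator) can be
#' supplied through this format.
#'
#' @param path file to read or write; `.gz` handled transparently.
#' @return `read_haplotypes` returns a `HaplotypeSet`.
#' @export
read_haplotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- in_conn(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 2L) stop("haplotype file needs a header and >= 1 site")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1L]])
  if (ncols < 6L) stop("haplotype header must name at least 2 genomes")
  n_h <- ncols - 4L
  bad <- which(vapply(fields[-1L], length, 0L) != ncols)
  if (length(bad))
    stop("malformed haplotype row at line ", bad[1L] + 1L,
         ": expected ", ncols, " tab-separated fields")
  body <- fields[-1L]
  chrom <- vapply(body, `[[`, "", 1L)
  pos <- as.integer(vapply(body, `[[`, "", 2L))
  anc <- vapply(body, `[[`, "", 3L)
  al <- strsplit(vapply(body, `[[`, "", 4L), "/", fixed = TRUE)
  if (any(vapply(al, length, 0L) != 2L))
    stop("allele field must be of the form a0/a1")
  allele0 <- vapply(al, `[[`, "", 1L)
  allele1 <- vapply(al, `[[`, "", 2L)
  if (any(anc != allele0)) stop("ancestral nucleotide must equal allele0")
  geno <- matrix(unlist(lapply(body, `[`, -(1:4))), nrow = length(body),
                 byrow = TRUE)
  idx <- matrix(0L, nrow(geno), ncol(geno))
  idx[geno == allele1] <- 1L
  known <- geno == allele0 | geno == allele1
  if (!all(known)) {
    r <- which(rowSums(!known) > 0L)[1L]
    stop("line ", r + 1L, ": allele not among the site's two alleles ",
         "(more than two alleles, or a typo)")
  }
  haplotype_set(data.frame(chrom = chrom, pos = pos, allele0 = allele0,
                           allele1 = allele1, stringsAsFactors = FALSE),
                array(as.raw(idx), dim = dim(idx)))
}

#' @param hs a `HaplotypeSet`.
#' @rdname read_haplotypes
#' @export
write_haplotypes <- function(hs, path) {
  stopifnot(inherits(hs, "HaplotypeSet"))
  if (nrow(hs$sites) == 0L)
    stop("empty site list: nothing to simulate, refusing to write")
  n_h <- ncol(hs$haplotypes)
  mat <- matrix(as.integer(hs$haplotypes), nrow(hs$sites), n_h)
  cols <- lapply(seq_len(n_h), function(j)
    ifelse(mat[, j] == 1L, hs$sites$allele1, hs$sites$allele0))
  header <- paste(c("#chr", "pos", "ancestral", "alleles",
                    paste0("g", seq_len(n_h))), collapse = "\t")
  body <- do.call(paste, c(list(hs$sites$chrom, hs$sites$pos,
                                hs$sites$allele0,
                                paste0(hs$sites$allele0, "/", hs$sites$allele1)),
                           cols, sep = "\t"))
  con <- out_conn(path)
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Recombination map
#'
#' Window-based recombination map. Windows are half-open, 0-based
#' `[start, end)` intervals carrying a rate in cM/Mb. When `sex_mode` is TRUE
#' the supplied rates are female rates for a hermaphrodite simulation of a
#' species without male recombination (e.g. *Drosophila*), and the effective
#' per-gamete rate is the input divided by 2.
#'
#' @param windows data frame with columns `chrom`, `start`, `end`, `rate`.
#' @param sex_mode halve the (female) input rate for the effective map.
#' @return An object of class `RecombinationMap`; `$effective_rate` holds the
#'   per-gamete rate in cM/Mb actually used.
#' @export
recombination_map <- function(windows, sex_mode = FALSE) {
  stopifnot(is.data.frame(windows),
            all(c("chrom", "start", "end", "rate") %in% names(windows)))
  w <- data.frame(chrom = as.character(windows$chrom),
                  start = as.numeric(windows$start),
                  end = as.numeric(windows$end),
                  rate = as.numeric(windows$rate), stringsAsFactors = FALSE)
  if (any(w$rate < 0)) stop("negative recombination rate")
  if (any(w$end <= w$start)) stop("windows must satisfy start < end")
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  rownames(w) <- NULL
  for (ch in unique(w$chrom)) {
    wc <- w[w$chrom == ch, , drop = FALSE]
    if (nrow(wc) > 1L && any(wc$start[-1L] < wc$end[-nrow(wc)]))
      stop("overlapping recombination windows on ", ch)
  }
  w$effective_rate <- if (sex_mode) w$rate / 2 else w$rate
  structure(list(windows = w, sex_mode = sex_mode),
            class = "RecombinationMap")
}

#' @export
print.RecombinationMap <- function(x, ...) {
  cat(sprintf("RecombinationMap: %d window(s), %d chromosome(s), sex_mode=%s\n",
              nrow(x$windows), length(unique(x$windows$chrom)),
              x$sex_mode))
  cat(sprintf("  total effective map length: %.4f Morgan\n",
              sum((x$windows$end - x$windows$start) *
                  x$windows$effective_rate) * 1e-8))
  invisible(x)
}

#' @param path TSV with columns chrom, start, end, rate (cM/Mb).
#' @rdname recombination_map
#' @export
read_recombination_map <- function(path, sex_mode = FALSE) {
  con <- in_conn(path)
  on.exit(close(con))
  w <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  comment.char = "#")
  recombination_map(w, sex_mode = sex_mode)
}

#' @param map a `RecombinationMap` (input-scale rates are written).
#' @rdname recombination_map
#' @export
write_recombination_map <- function(map, path) {
  stopifnot(inherits(map, "RecombinationMap"))
  con <- out_conn(path)
  on.exit(close(con))
  write.table(map$windows[, c("chrom", "start", "end", "rate")], con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Selected loci
#'
#' A table of beneficial loci: chromosome, 1-based position, the beneficial
#' nucleotide, the selection coefficient `s` (homozygote fitness 1+s) and the
#' dominance coefficient `h` (heterozygote fitness 1+hs).
#'
#' @param chrom,pos,allele,s,h vectors of equal length (recycled where
#'   length 1).
#' @return A data frame of class `SelectedLoci`.
#' @export
selected_loci <- function(chrom, pos, allele, s, h) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   allele = as.character(allele), s = as.numeric(s),
                   h = as.numeric(h), stringsAsFactors = FALSE)
  if (any(df$s <= -1)) stop("selection coefficient must be > -1")
  if (!all(df$allele %in% NUCS)) stop("beneficial allele must be a nucleotide")
  class(df) <- c("SelectedLoci", "data.frame")
  df
}

#' @param path TSV with columns chrom, pos, allele, s, h.
#' @rdname selected_loci
#' @export
read_selected_loci <- function(path) {
  con <- in_conn(path)
  on.exit(close(con))
  df <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  selected_loci(df$chrom, df$pos, df$allele, df$s, df$h)
}

#' @param loci a `SelectedLoci` table.
#' @rdname selected_loci
#' @export
write_selected_loci <- function(loci, path) {
  con <- out_conn(path)
  on.exit(close(con))
  write.table(as.data.frame(loci), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Allele count table
#'
#' Per-SNP counts of the two alleles in the base population and in each of
#' `k` evolved replicate populations: the input of the CMH test and the
#' content of a PoPoolation2 sync file. For exact (whole-population) counts
#' the per-population totals equal twice the census size; Pool-Seq sampled
#' tables carry read counts instead.
#'
#' @param sites site table as in [haplotype_set()].
#' @param base integer matrix, one row per site, columns (allele0, allele1).
#' @param evolved integer array `sites x 2 x k`, or a list of `k` matrices
#'   shaped like `base`.
#' @return An object of class `AlleleCountTable` with element `k`.
#' @export
allele_count_table <- function(sites, base, evolved) {
  if (is.list(evolved))
    evolved <- array(unlist(evolved),
                     dim = c(nrow(base), 2L, length(evolved)))
  stopifnot(nrow(base) == nrow(sites), ncol(base) == 2L,
            length(dim(evolved)) == 3L, dim(evolved)[1] == nrow(sites),
            dim(evolved)[2] == 2L)
  storage.mode(base) <- "integer"
  storage.mode(evolved) <- "integer"
  if (any(base < 0L) || any(evolved < 0L)) stop("negative allele counts")
  structure(list(sites = sites, base = base, evolved = evolved,
                 k = dim(evolved)[3]),
            class = "AlleleCountTable")
}

#' @export
print.AlleleCountTable <- function(x, ...) {
  cat(sprintf("AlleleCountTable: %d SNPs, base + %d evolved replicate(s)\n",
              nrow(x$sites), x$k))
  invisible(x)
}

sync_field <- function(counts0, counts1, allele0, allele1) {
  m <- matrix(0L, length(counts0), 6L)
  i0 <- match(allele0, NUCS)
  i1 <- match(allele1, NUCS)
  m[cbind(seq_along(counts0), i0)] <- counts0
  ok <- !is.na(i1)
  m[cbind(which(ok), i1[ok])] <- counts1[ok]
  apply(m, 1L, paste, collapse = ":")
}

#' Read / write PoPoolation2 sync files
#'
#' Standard sync format: chromosome, position, reference allele, then one
#' `A:T:C:G:N:del` count sextuple per population. Column order is the base
#' population first, followed by the evolved replicates in order. On reading,
#' the reference nucleotide becomes allele0 and the non-reference nucleotide
#' with the largest total count becomes allele1.
#'
#' @param table an `AlleleCountTable`.
#' @param path file to write or read; `.gz` handled transparently.
#' @return `read_sync` returns an `AlleleCountTable`.
#' @export
write_sync <- function(table, path) {
  stopifnot(inherits(table, "AlleleCountTable"))
  s <- table$sites
  cols <- vector("list", table$k + 1L)
  cols[[1L]] <- sync_field(table$base[, 1L], table$base[, 2L],
                           s$allele0, s$allele1)
  for (r in seq_len(table$k))
    cols[[r + 1L]] <- sync_field(table$evolved[, 1L, r],
                                 table$evolved[, 2L, r],
                                 s$allele0, s$allele1)
  body <- do.call(paste, c(list(s$chrom, s$pos, s$allele0), cols, sep = "\t"))
  con <- out_conn(path)
  on.exit(close(con))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_sync
#' @export
read_sync <- function(path) {
  con <- in_conn(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  npop <- length(fields[[1L]]) - 3L
  if (npop < 2L) stop("sync file needs a base and >= 1 evolved population")
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  ref <- vapply(fields, `[[`, "", 3L)
  cnt <- array(0L, dim = c(length(lines), 4L, npop))
  for (p in seq_len(npop)) {
    parts <- strsplit(vapply(fields, `[[`, "", 3L + p), ":", fixed = TRUE)
    cnt[, , p] <- matrix(as.integer(unlist(parts)), ncol = 6L,
                         byrow = TRUE)[, 1:4]
  }
  tot <- apply(cnt, c(1L, 2L), sum)
  i0 <- match(ref, NUCS)
  tot[cbind(seq_along(ref), i0)] <- -1L  # exclude ref when picking allele1
  i1 <- max.col(tot, ties.method = "first")
  none <- tot[cbind(seq_along(ref), i1)] <= 0L
  i1[none] <- NA_integer_
  take <- function(p, i) ifelse(is.na(i), 0L,
                                cnt[cbind(seq_along(ref), i, rep(p, length(ref)))])
  base <- cbind(cnt[cbind(seq_along(ref), i0, rep(1L, length(ref)))],
                take(1L, i1))
  evolved <- array(0L, dim = c(length(ref), 2L, npop - 1L))
  for (r in seq_len(npop - 1L)) {
    evolved[, 1L, r] <- cnt[cbind(seq_along(ref), i0, rep(r + 1L, length(ref)))]
    evolved[, 2L, r] <- take(r + 1L, i1)
  }
  alt <- ifelse(is.na(i1), NA_character_, NUCS[i1])
  sites <- data.frame(chrom = chrom, pos = pos, allele0 = ref,
                      allele1 = alt, stringsAsFactors = FALSE)
  allele_count_table(sites, base, evolved)
}
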