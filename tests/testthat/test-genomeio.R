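test_that("haplotype files round-trip bit-exactly, plain and gzipped", {
  set.seed(11)
  hs <- simulate_founder_haplotypes(window_spec("2L", 0, 5e4, 0.003, 2), 8,
                                    seed = 3)
  for (ext in c(".tsv", ".tsv.gz")) {
    path <- tempfile(fileext = ext)
    write_haplotypes(hs, path)
    back <- read_haplotypes(path)
    expect_identical(back$sites, hs$sites)
    expect_identical(back$haplotypes, hs$haplotypes)
  }
  # format definition: 2 sites x 2 genomes -> header naming 2 genomes + 2 rows
  small <- haplotype_set(make_sites(2L),
                         matrix(as.raw(c(0, 1, 1, 0)), 2L, 2L))
  path <- tempfile()
  write_haplotypes(small, path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_identical(lines[1L], "#chr\tpos\tancestral\talleles\tg1\tg2")
})

test_that("haplotype validation rejects degenerate input", {
  # all genomes carry allele0 at a site -> not segregating
  expect_error(haplotype_set(make_sites(1L), matrix(as.raw(0), 1L, 4L)),
               "segregating")
  # a third allele in a genome column
  path <- tempfile()
  writeLines(c("#chr\tpos\tancestral\talleles\tg1\tg2\tg3",
               "2L\t100\tA\tA/C\tA\tC\tT"), path)
  expect_error(read_haplotypes(path), "two alleles")
  # malformed row names its line number
  writeLines(c("#chr\tpos\tancestral\talleles\tg1\tg2",
               "2L\t100\tA\tA/C\tA\tC",
               "2L\t200\tA\tA/C\tA"), path)
  expect_error(read_haplotypes(path), "line 3")
  # empty set can exist (theta = 0) but cannot be written
  empty <- simulate_founder_haplotypes(window_spec("2L", 0, 1e4, 0, 2), 4)
  expect_identical(nrow(empty$sites), 0L)
  expect_error(write_haplotypes(empty, tempfile()), "nothing to simulate")
})

test_that("recombination maps: sex-mode halving, validation, round trip", {
  m <- recombination_map(data.frame(chrom = "2L", start = 0, end = 1e5,
                                    rate = 2), sex_mode = TRUE)
  expect_equal(m$windows$effective_rate, 1)   # female 2 cM/Mb -> 1 cM/Mb
  m2 <- recombination_map(data.frame(chrom = "2L", start = 0, end = 1e5,
                                     rate = 2), sex_mode = FALSE)
  expect_equal(m2$windows$effective_rate, 2)
  expect_error(recombination_map(data.frame(chrom = "2L", start = 0,
                                            end = 1e5, rate = -1)),
               "negative")
  expect_error(recombination_map(
    data.frame(chrom = "2L", start = c(0, 5e4), end = c(1e5, 1.5e5),
               rate = 1)), "overlap")
  path <- tempfile(fileext = ".tsv")
  write_recombination_map(m, path)
  back <- read_recombination_map(path, sex_mode = TRUE)
  expect_equal(back$windows, m$windows)
})

test_that("selected-loci files round-trip and validate", {
  loci <- selected_loci(c("2L", "3R"), c(100L, 5000L), c("A", "G"),
                        c(0.1, 0.05), 0.5)
  path <- tempfile(fileext = ".tsv.gz")
  write_selected_loci(loci, path)
  expect_equal(read_selected_loci(path), loci)
  expect_error(selected_loci("2L", 1L, "A", -1, 0.5), "> -1")
  expect_error(selected_loci("2L", 1L, "X", 0.1, 0.5), "nucleotide")
})

test_that("sync output follows the PoPoolation2 column layout", {
  tab <- allele_count_table(
    data.frame(chrom = "2L", pos = 5000L, allele0 = "A", allele1 = "T"),
    matrix(c(120L, 80L), 1L), list(matrix(c(40L, 160L), 1L)))
  path <- tempfile(fileext = ".sync")
  write_sync(tab, path)
  expect_identical(readLines(path),
                   "2L\t5000\tA\t120:80:0:0:0:0\t40:160:0:0:0:0")
  # zero-count population and k = 3 -> base + 3 evolved columns
  tab3 <- allele_count_table(
    data.frame(chrom = "2L", pos = 1L, allele0 = "C", allele1 = "G"),
    matrix(c(10L, 10L), 1L),
    list(matrix(c(0L, 0L), 1L), matrix(c(5L, 5L), 1L),
         matrix(c(20L, 0L), 1L)))
  write_sync(tab3, path)
  fields <- strsplit(readLines(path), "\t")[[1L]]
  expect_length(fields, 7L)
  expect_identical(fields[4L], "0:0:10:10:0:0")  # C and G slots of base
  expect_identical(fields[5L], "0:0:0:0:0:0")
})

test_that("sync files round-trip through the reader", {
  set.seed(4)
  n <- 50L
  sites <- make_sites(n)
  sites$allele0 <- sample(c("A", "T", "C", "G"), n, replace = TRUE)
  sites$allele1 <- vapply(sites$allele0, function(a)
    sample(setdiff(c("A", "T", "C", "G"), a), 1L), "")
  base <- cbind(sample(10:100, n, TRUE), sample(10:100, n, TRUE))
  ev <- list(cbind(sample(10:100, n, TRUE), sample(10:100, n, TRUE)),
             cbind(sample(10:100, n, TRUE), sample(10:100, n, TRUE)))
  tab <- allele_count_table(sites, base, ev)
  path <- tempfile(fileext = ".sync.gz")
  write_sync(tab, path)
  back <- read_sync(path)
  expect_equal(back$base, tab$base, ignore_attr = TRUE)
  expect_equal(back$evolved, tab$evolved)
  expect_identical(back$sites$allele1, sites$allele1)
  expect_identical(back$k, 2L)
})
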