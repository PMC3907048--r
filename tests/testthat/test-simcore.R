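test_that("multiplicative fitness over selected loci", {
  sites <- make_sites(3L)
  m1 <- fitness_model(selected_loci("2L", 1000L, "T", 0.1, 0.5), sites)
  expect_equal(individual_fitness(1L, m1), 1.05)   # heterozygote 1 + hs
  m2 <- fitness_model(selected_loci("2L", c(1000L, 2000L), "T", 0.1, 0.5),
                      sites)
  expect_equal(individual_fitness(c(2L, 2L), m2), 1.21)  # 1.1^2
  expect_equal(individual_fitness(integer(0), fitness_model(NULL)), 1)
  # log-space path (>50 loci) agrees with the direct product
  m60 <- fitness_model(selected_loci("2L", seq_len(60) * 10L, "T", 0.1, 0.5),
                       make_sites(60L, step = 10L))
  counts <- rep(c(0L, 1L, 2L), 20)
  expect_equal(individual_fitness(counts, m60),
               prod(ifelse(counts == 0, 1, ifelse(counts == 1, 1.05, 1.1))),
               tolerance = 1e-12)
})

test_that("population fitness agrees with per-individual evaluation", {
  pop <- make_pop(c(3L, 1L), 4L)  # 4 diploids, 2 sites
  loci <- selected_loci("2L", c(1000L, 2000L), "T", c(0.2, 0.5), c(0.5, 1))
  model <- fitness_model(loci, pop$sites)
  m <- matrix(as.integer(pop$haplotypes), 2L)
  expected <- vapply(1:4, function(i) {
    cnt <- m[, 2 * i - 1] + m[, 2 * i]
    individual_fitness(cnt, model)
  }, 0)
  expect_equal(population_fitness(pop, model), expected)
})

test_that("gametes from homozygotes and zero-length maps are intact", {
  pop <- make_pop(c(800L, 1200L, 399L), 1000L)
  # individual 1 carries allele1 on both haplotypes at sites 1-2 (see
  # make_pop) -> homozygous; gamete identical regardless of crossovers
  g <- make_gamete(pop, 1L, flat_map(rate = 100))
  expect_identical(g$haplotype, pop$haplotypes[, 1L])
  # map length 0: the gamete is one whole parental haplotype
  het <- population(make_sites(2L),
                    array(as.raw(c(0L, 1L, 1L, 0L)), c(2L, 2L)))
  for (i in 1:20) {
    g0 <- make_gamete(het, 1L, flat_map(rate = 0))
    expect_identical(sum(g0$crossovers), 0L)
    expect_true(identical(g0$haplotype, het$haplotypes[, 1L]) ||
                  identical(g0$haplotype, het$haplotypes[, 2L]))
  }
})

test_that("selfing is excluded: with N = 2 the two individuals always pair", {
  # parent 1 homozygous allele0, parent 2 homozygous allele1 at both sites:
  # every offspring must receive one gamete from each, hence be heterozygous
  haps <- array(as.raw(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)), c(2L, 4L))
  pop <- population(make_sites(2L), haps)
  set.seed(8)
  for (i in 1:10) {
    off <- next_generation(pop, fitness_model(NULL), flat_map(rate = 0))
    m <- matrix(as.integer(off$haplotypes), 2L)
    expect_true(all(m[, c(1, 3)] + m[, c(2, 4)] == 1L))
  }
})

test_that("strong selection from intermediate frequency fixes the allele", {
  # deterministic recursion reaches > 0.999 by ~generation 25 at s = 0.5;
  # with 2Ns = 1000 drift loss from p = 0.5 is vanishingly rare
  pop <- make_pop(1000L, 1000L)
  model <- fitness_model(selected_loci("2L", 1000L, "T", 0.5, 0.5),
                         pop$sites)
  map <- flat_map(rate = 0)
  set.seed(13)
  fixed <- vapply(1:100, function(i) {
    tr <- evolve(pop, model, map, 60L, record_at = 60L,
                 return_population = FALSE)
    tr$freq[1L, 1L] == 1
  }, TRUE)
  expect_gte(sum(fixed), 99L)
})

test_that("trajectories record exactly the requested generations", {
  pop <- make_pop(c(500L, 100L), 500L)
  map <- flat_map(rate = 1)
  tr0 <- evolve(pop, fitness_model(NULL), map, 0L)
  expect_identical(tr0$generations, 0L)
  expect_equal(tr0$freq[, 1L], c(0.5, 0.1))
  set.seed(3)
  tr <- evolve(pop, fitness_model(NULL), map, 10L, record_at = c(0L, 3L, 10L))
  expect_identical(colnames(tr$freq), c("0", "3", "10"))
  expect_identical(tr$final$generation, 10L)
  expect_identical(tr$final$N, 500L)
  expect_error(evolve(pop, fitness_model(NULL), map, 5L, record_at = 6L),
               "record_at")
})

test_that("no mutation: lost or fixed alleles never resegregate", {
  set.seed(40)
  hs <- simulate_founder_haplotypes(window_spec("2L", 0, 3e4, 0.005, 2), 20,
                                    seed = 41)
  pop <- expand_to_population(hs, 20)
  tr <- evolve(pop, fitness_model(NULL), flat_map(rate = 5), 40L,
               record_at = 0:40, return_population = FALSE)
  for (s in seq_len(nrow(tr$freq))) {
    f <- tr$freq[s, ]
    hit0 <- which(f == 0)
    hit1 <- which(f == 1)
    if (length(hit0)) expect_true(all(f[hit0[1L]:length(f)] == 0))
    if (length(hit1)) expect_true(all(f[hit1[1L]:length(f)] == 1))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("with map length zero whole haplotypes are only reassorted", {
  set.seed(50)
  hs <- simulate_founder_haplotypes(window_spec("2L", 0, 3e4, 0.005, 2), 10,
                                    seed = 51)
  pop <- expand_to_population(hs, 50)
  tr <- evolve(pop, fitness_model(NULL), flat_map(rate = 0), 10L)
  founders <- apply(matrix(as.integer(hs$haplotypes), nrow(hs$sites)), 2,
                    paste, collapse = "")
  finals <- apply(matrix(as.integer(tr$final$haplotypes), nrow(hs$sites)), 2,
                  paste, collapse = "")
  expect_true(all(finals %in% founders))
})

test_that("drift phase is neutral evolution and 0 generations is identity", {
  pop <- make_pop(c(100L, 900L), 500L)
  expect_identical(drift_phase(pop, 0L, flat_map(rate = 1)), pop)
  set.seed(60)
  drifted <- drift_phase(pop, 5L, flat_map(rate = 1))
  expect_identical(drifted$generation, 5L)
  expect_identical(drifted$N, pop$N)
})
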