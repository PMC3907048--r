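test_that("labelling flags exactly the selected positions", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  sc <- scores_df(p, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(sum(sc$selected), 2L)
  expect_error(
    label_snps(data.frame(chrom = "2L", pos = 10L, p.value = 0.5),
               selected_loci("2L", 999L, "T", 0.1, 0.5)),
    "absent")
})

test_that("ROC sweep handles ties and matches the hand-built curve", {
  sc <- scores_df(c(0.01, 0.02, 0.03, 0.04), c(TRUE, FALSE, TRUE, FALSE))
  curve <- roc(sc)
  expect_equal(curve$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(curve$tpr, c(0, 0.5, 0.5, 1, 1))
  # perfect classifier passes through (0, 1)
  perfect <- roc(scores_df(c(0.001, 0.002, 0.5, 0.6),
                           c(TRUE, TRUE, FALSE, FALSE)))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  # all p-values tied: single segment (0,0) -> (1,1)
  flat <- roc(scores_df(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                       FALSE)))
  expect_equal(as.matrix(flat), cbind(fpr = c(0, 1), tpr = c(0, 1)),
               ignore_attr = TRUE)
  expect_error(roc(scores_df(c(0.1, 0.2), c(TRUE, TRUE))), "negatives")
})

test_that("pAUC integrates the clipped curve by trapezoids", {
  perfect <- roc(scores_df(c(0.001, 0.002, 0.5, 0.6),
                           c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(pauc(perfect, 0.01), 0.01)
  expect_equal(pauc(perfect, 0.01, normalized = TRUE), 1)
  chance <- roc(scores_df(rep(0.5, 4), c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(pauc(chance, 0.01), 5e-5)   # triangle 0.01^2 / 2
  four <- roc(scores_df(c(0.01, 0.02, 0.03, 0.04),
                        c(TRUE, FALSE, TRUE, FALSE)))
  expect_lt(abs(pauc(four, 0.5) -
                  brute_pauc(as.matrix(four), 0.5)), 1e-12)
  expect_error(pauc(four, 0), "fpr_max")
  expect_error(pauc(four, 1.2), "fpr_max")
})

test_that("ROC and pAUC match a brute-force oracle on random instances", {
  set.seed(71)
  for (trial in 1:3) {
    n <- sample(c(500L, 5000L, 10000L), 1L)
    p <- round(runif(n), sample(2:4, 1L))  # rounding forces ties
    sel <- runif(n) < 0.03
    if (!any(sel)) sel[1L] <- TRUE
    sc <- scores_df(p, sel)
    curve <- roc(sc)
    ref <- brute_roc(p, sel)
    expect_equal(as.matrix(curve), ref, ignore_attr = TRUE,
                 tolerance = 1e-14)
    for (fmax in c(0.01, 0.1, 1)) {
      expect_lt(abs(pauc(curve, fmax) - brute_pauc(ref, fmax)), 1e-12)
    }
    # pauc at fpr_max = 1 is the full AUC
    expect_lt(abs(pauc(curve, 1) - brute_pauc(ref, 1)), 1e-12)
  }
  # chance-level scores give AUC ~ 0.5
  p <- runif(5000)
  sel <- runif(5000) < 0.2
  auc <- pauc(roc(scores_df(p, sel)), 1)
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("TPR at bounded FPR reads off the tie-respecting sweep", {
  perfect <- scores_df(c(0.001, 0.002, 0.5, 0.6),
                       c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tpr_at_fpr(perfect, 0.01), 1)
  worst <- scores_df(c(0.9, 0.95, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tpr_at_fpr(worst, 0), 0)
  four <- scores_df(c(0.01, 0.02, 0.03, 0.04), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(tpr_at_fpr(four, 0.5), 1)
})

test_that("top-n true positives count and break ties deterministically", {
  four <- scores_df(c(0.01, 0.02, 0.03, 0.04), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.integer(top_n_true_positives(four, 2L)), 1L)
  expect_equal(as.integer(top_n_true_positives(four, 4L)), 2L)
  perfect <- scores_df(c(rep(1e-6, 3), rep(0.5, 3)),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(as.integer(top_n_true_positives(perfect, 3L)), 3L)
  # boundary tie: same tie seed -> same count; RNG state is untouched
  tied <- scores_df(c(0.01, rep(0.5, 9)),
                    c(TRUE, rep(c(TRUE, FALSE), c(4, 5))))
  set.seed(42); seq_ref <- runif(3)
  set.seed(42); u1 <- runif(1)
  a <- top_n_true_positives(tied, 5L, tie_seed = 3L)
  b <- top_n_true_positives(tied, 5L, tie_seed = 3L)
  expect_identical(a, b)
  expect_identical(c(u1, runif(2)), seq_ref)  # global RNG state untouched
  expect_error(top_n_true_positives(tied, 11L), "n <=")
})

test_that("run_design produces the documented schema, deterministically", {
  d <- er_design(N = 100L, replicates = 2L, generations = 5L,
                 n_haploid = 20L, s = 0.2, n_loci = 5L,
                 drift_generations = 2L, top_n = 10L,
                 windows = window_spec("2L", 0, 5e4, 0.004, 2))
  r1 <- run_design(d, repetitions = 2L, seed = 99L,
                   eval_generations = c(2L, 5L), eval_replicates = c(1L, 2L))
  expect_s3_class(r1, "design_result")
  expect_identical(nrow(r1$per_repetition), 8L)  # 2 reps x 2 gens x 2 ks
  expect_true(all(c("pauc", "pauc_norm", "tpr", "top10", "n_lost") %in%
                    names(r1$per_repetition)))
  expect_identical(nrow(r1$summary), 4L)
  r2 <- run_design(d, repetitions = 2L, seed = 99L,
                   eval_generations = c(2L, 5L), eval_replicates = c(1L, 2L))
  expect_identical(r1$per_repetition, r2$per_repetition)
  # Pool-Seq layer changes counts but not the schema
  dp <- er_design(N = 100L, replicates = 2L, generations = 5L,
                  n_haploid = 20L, s = 0.2, n_loci = 5L, coverage = 50,
                  windows = window_spec("2L", 0, 5e4, 0.004, 2))
  rp <- run_design(dp, repetitions = 1L, seed = 7L)
  expect_identical(nrow(rp$per_repetition), 1L)
})
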