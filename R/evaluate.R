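#' Label SNP results with the known selected loci
#'
#' True positives are defined at the nucleotide level: a SNP is a positive
#' only if it is exactly a selected site. All other SNPs are negatives, so a
#' hitchhiking neighbour with a small p-value counts as a false positive.
#' Beneficial alleles lost during a drift phase stay flagged and count as
#' false negatives if undetected.
#'
#' @param results per-SNP data frame with chrom, pos, p.value (e.g. from
#'   [cmh_test()]).
#' @param loci a `SelectedLoci` table; every locus must be present in
#'   `results`.
#' @return A data frame of class `LabelledScores` with columns chrom, pos,
#'   p.value, selected.
#' @export
label_snps <- function(results, loci) {
  key <- paste(results$chrom, results$pos)
  idx <- match(paste(loci$chrom, loci$pos), key)
  if (anyNA(idx))
    stop("selected locus absent from the results: ",
         paste(loci$chrom[is.na(idx)][1L], loci$pos[is.na(idx)][1L]))
  selected <- logical(nrow(results))
  selected[idx] <- TRUE
  out <- data.frame(chrom = results$chrom, pos = results$pos,
                    p.value = results$p.value, selected = selected,
                    stringsAsFactors = FALSE)
  class(out) <- c("LabelledScores", "data.frame")
  out
}

#' ROC curve from labelled p-values
#'
#' Threshold sweep over the unique p-values in ascending order; all SNPs
#' sharing a p-value enter together (one vertex per unique p), and the curve
#' is anchored at (0,0) and ends at (1,1).
#'
#' @param scores a `LabelledScores` data frame.
#' @return A data frame of class `RocCurve` with columns fpr, tpr.
#' @export
roc <- function(scores) {
  sel <- scores$selected
  P <- sum(sel)
  Nn <- sum(!sel)
  if (P == 0L) stop("no positives among the scores")
  if (Nn == 0L) stop("no negatives among the scores")
  o <- order(scores$p.value)
  ps <- scores$p.value[o]
  ss <- sel[o]
  last <- which(!duplicated(ps, fromLast = TRUE))  # last index of each group
  tpr <- cumsum(ss)[last] / P
  fpr <- cumsum(!ss)[last] / Nn
  out <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  class(out) <- c("RocCurve", "data.frame")
  out
}

#' @param x a `RocCurve`.
#' @param ... passed to [graphics::plot()].
#' @rdname roc
#' @export
plot.RocCurve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
                 ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Partial area under the ROC curve
#'
#' Trapezoidal area under the (piecewise linear) ROC curve for FPR in
#' `[0, fpr_max]`, linearly interpolating at `fpr_max`. The raw area lies in
#' `[0, fpr_max]`; the normalized variant divides by `fpr_max` so a perfect
#' classifier scores 1.
#'
#' @param curve a `RocCurve`.
#' @param fpr_max upper FPR bound, in (0, 1].
#' @param normalized divide by `fpr_max`.
#' @return Scalar pAUC.
#' @export
pauc <- function(curve, fpr_max = 0.01, normalized = FALSE) {
  stopifnot(inherits(curve, "RocCurve"))
  if (!(fpr_max > 0 && fpr_max <= 1)) stop("fpr_max must be in (0, 1]")
  x <- curve$fpr
  y <- curve$tpr
  if (fpr_max < max(x)) {
    keep <- x <= fpr_max
    i <- which(!keep)[1L]           # first vertex beyond the bound
    x2 <- x[keep]
    y2 <- y[keep]
    if (x[i] > x2[length(x2)]) {    # interpolate on the crossing segment
      f <- (fpr_max - x2[length(x2)]) / (x[i] - x2[length(x2)])
      x2 <- c(x2, fpr_max)
      y2 <- c(y2, y2[length(y2)] + f * (y[i] - y2[length(y2)]))
    }
    x <- x2
    y <- y2
  }
  area <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  if (normalized) area / fpr_max else area
}

#' True positive rate at a bounded false positive rate
#'
#' Largest TPR achievable at FPR <= `fpr` along the tie-respecting threshold
#' sweep of [roc()].
#'
#' @param scores a `LabelledScores` data frame.
#' @param fpr FPR bound.
#' @return Scalar TPR in \[0, 1\].
#' @export
tpr_at_fpr <- function(scores, fpr = 0.01) {
  curve <- roc(scores)
  max(curve$tpr[curve$fpr <= fpr + 1e-12])
}

#' True positives among the top-n SNPs
#'
#' Number of selected loci among the `n` most significant SNPs. Ties at the
#' boundary are broken by a deterministic seeded shuffle within the tied
#' group; the seed used is attached as attribute `tie_seed`.
#'
#' @param scores a `LabelledScores` data frame.
#' @param n number of top SNPs to consider (<= number of SNPs).
#' @param tie_seed seed for the tie-breaking shuffle.
#' @return Integer count of true positives.
#' @export
top_n_true_positives <- function(scores, n, tie_seed = 0L) {
  stopifnot(n <= nrow(scores))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(tie_seed)
  shuffle <- sample.int(nrow(scores))
  o <- order(scores$p.value, shuffle)
  out <- sum(scores$selected[o[seq_len(n)]])
  attr(out, "tie_seed") <- tie_seed
  out
}

#' Specify an E&R experimental design
#'
#' Bundles the parameters of one evolve-and-resequence design. The defaults
#' mirror a common fly-lab setup: 1000 homozygous founder genomes, census
#' size 1000, 3 replicates, 60 generations of selection, 150 codominant
#' beneficial loci capped at 80% starting frequency, exact allele counts
#' (set `coverage` for Pool-Seq sampling). The default genome is a single
#' 1-Mb chromosome at diversity 0.005 and a female rate of 2 cM/Mb (halved
#' for hermaphrodites), a deliberately scaled-down stand-in for a fly genome
#' that keeps desk runs fast; supply your own `windows` for larger genomes.
#'
#' @param N diploid census size of every population.
#' @param replicates number of biological replicates k.
#' @param generations generations of selection.
#' @param n_haploid founder haploid genomes (see [expand_to_population()]).
#' @param s,h selection and dominance coefficients of the beneficial loci.
#' @param n_loci number of beneficial loci.
#' @param drift_generations neutral generations before selection starts.
#' @param coverage Pool-Seq mean depth, or NULL for exact counts.
#' @param coverage_mode `"fixed"` or `"poisson"` (see [poolseq_sample()]).
#' @param freq_cap maximum starting frequency of a beneficial allele.
#' @param fpr_max FPR bound of the pAUC / TPR operating point.
#' @param top_n top-SNP list sizes to report true positives for.
#' @param windows a `WindowSpec` table describing the genome.
#' @param sex_mode halve the female recombination rate (hermaphrodites of a
#'   species without male recombination).
#' @return An object of class `er_design`.
#' @export
er_design <- function(N = 1000L, replicates = 3L, generations = 60L,
                      n_haploid = 1000L, s = 0.1, h = 0.5, n_loci = 150L,
                      drift_generations = 0L, coverage = NULL,
                      coverage_mode = "fixed", freq_cap = 0.8,
                      fpr_max = 0.01, top_n = c(10L, 100L),
                      windows = window_spec("2L", 0, 1e6, 0.005, 2),
                      sex_mode = TRUE) {
  d <- list(N = as.integer(N), replicates = as.integer(replicates),
            generations = as.integer(generations),
            n_haploid = as.integer(n_haploid), s = s, h = h,
            n_loci = as.integer(n_loci),
            drift_generations = as.integer(drift_generations),
            coverage = coverage, coverage_mode = coverage_mode,
            freq_cap = freq_cap, fpr_max = fpr_max,
            top_n = as.integer(top_n), windows = windows,
            sex_mode = sex_mode)
  stopifnot(d$N >= 2L, d$replicates >= 1L, d$generations >= 0L,
            d$n_haploid >= 2L, d$n_loci >= 1L, d$drift_generations >= 0L,
            d$fpr_max > 0, d$fpr_max <= 1)
  structure(d, class = "er_design")
}

#' @export
print.er_design <- function(x, ...) {
  cat(sprintf(paste0("E&R design: N=%d, k=%d replicates, %d generations",
                     " (+%d drift), %d founder haplotypes\n"),
              x$N, x$replicates, x$generations, x$drift_generations,
              x$n_haploid))
  cat(sprintf("  %d beneficial loci, s=%g, h=%g, freq cap %g; %s\n",
              x$n_loci, x$s, x$h, x$freq_cap,
              if (is.null(x$coverage)) "exact allele counts"
              else paste0("Pool-Seq coverage ", x$coverage)))
  invisible(x)
}

## deterministic sub-seed from a master seed and a stream label, so the
## founder, locus-picking, per-replicate and Pool-Seq streams stay
## independent and reproducible (changing coverage never perturbs the
## trajectories)
derive_seed <- function(master, ...) {
  lab <- paste(c(master, ...), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Evaluate an experimental design by repeated simulation
#'
#' Runs the full pipeline for `repetitions` independent repetitions: fresh
#' founders and freshly picked beneficial loci per repetition, an optional
#' neutral drift phase, `k` independently evolved replicates from the same
#' base population, optional Pool-Seq sampling, the CMH test across
#' replicates, and ROC-based performance measures. The base counts entering
#' the CMH test are taken after the drift phase (what an experimenter would
#' sequence at the start of selection); loci are picked, and the frequency
#' cap applied, before it, so alleles lost to drift count as false
#' negatives.
#'
#' Nested designs can be read off the same simulations: `eval_generations`
#' adds earlier readout generations and `eval_replicates` smaller replicate
#' subsets, each evaluated separately.
#'
#' @param design an [er_design()].
#' @param repetitions independent repetitions (confidence intervals are
#'   computed across them).
#' @param seed master seed; all stage seeds derive from it.
#' @param eval_generations generations at which to evaluate (default: the
#'   design's endpoint).
#' @param eval_replicates replicate-subset sizes to evaluate (default: all
#'   k).
#' @return An object of class `design_result`: `$per_repetition` rows per
#'   (repetition, generations, replicates) with pAUC (raw and normalized),
#'   TPR at the FPR bound, top-n true positives and the number of loci lost
#'   in the drift phase; `$summary` with mean, sd and 95% CI per evaluated
#'   design.
#' @export
run_design <- function(design, repetitions = 10L, seed = 1L,
                       eval_generations = design$generations,
                       eval_replicates = design$replicates) {
  stopifnot(inherits(design, "er_design"), repetitions >= 1L)
  eval_generations <- sort(unique(as.integer(eval_generations)))
  eval_replicates <- sort(unique(as.integer(eval_replicates)))
  stopifnot(max(eval_generations) <= design$generations,
            max(eval_replicates) <= design$replicates,
            min(eval_generations) >= 1L, min(eval_replicates) >= 1L)
  map <- as_recombination_map(design$windows, sex_mode = design$sex_mode)
  rows <- list()
  for (rep_i in seq_len(repetitions)) {
    founders <- simulate_founder_haplotypes(
      design$windows, design$n_haploid,
      seed = derive_seed(seed, "founders", rep_i))
    set.seed(derive_seed(seed, "expand", rep_i))
    pop0 <- expand_to_population(founders, design$N)
    rm(founders)   # the expanded population carries all information
    loci <- pick_selected_loci(pop0, design$n_loci, design$s, design$h,
                               design$freq_cap,
                               seed = derive_seed(seed, "loci", rep_i))
    model <- fitness_model(loci, pop0$sites)
    set.seed(derive_seed(seed, "drift", rep_i))
    base <- drift_phase(pop0, design$drift_generations, map)
    base_freq <- allele_freq(base)
    ben1 <- model$allele == 1L
    ben_freq <- ifelse(ben1, base_freq[model$site0 + 1L],
                       1 - base_freq[model$site0 + 1L])
    n_lost <- sum(ben_freq == 0)
    ev_freq <- array(0, dim = c(nrow(base$sites), length(eval_generations),
                                design$replicates))
    for (r in seq_len(design$replicates)) {
      set.seed(derive_seed(seed, "replicate", rep_i, r))
      tr <- evolve(base, model, map, design$generations,
                   record_at = eval_generations, return_population = FALSE)
      ev_freq[, , r] <- tr$freq
    }
    for (gi in seq_along(eval_generations)) {
      tab_full <- counts_from_freq(base$sites, base_freq,
                                   ev_freq[, gi, , drop = TRUE],
                                   design$N)
      if (!is.null(design$coverage))
        tab_full <- poolseq_sample(tab_full, design$coverage,
                                   design$coverage_mode,
                                   seed = derive_seed(seed, "poolseq", rep_i,
                                                      eval_generations[gi]))
      for (k in eval_replicates) {
        res <- cmh_test(tab_full, replicates = seq_len(k))
        scores <- label_snps(res, loci)
        curve <- roc(scores)
        row <- data.frame(repetition = rep_i,
                          generations = eval_generations[gi],
                          replicates = k,
                          n_snps = nrow(scores),
                          n_loci = design$n_loci, n_lost = n_lost,
                          pauc = pauc(curve, design$fpr_max),
                          pauc_norm = pauc(curve, design$fpr_max,
                                           normalized = TRUE),
                          tpr = tpr_at_fpr(scores, design$fpr_max))
        for (n in design$top_n)
          row[[paste0("top", n)]] <-
            as.integer(top_n_true_positives(scores, min(n, nrow(scores))))
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  metrics <- setdiff(names(per_rep),
                     c("repetition", "generations", "replicates"))
  groups <- unique(per_rep[c("generations", "replicates")])
  summ <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sub <- per_rep[per_rep$generations == groups$generations[i] &
                     per_rep$replicates == groups$replicates[i], ]
    out <- groups[i, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      out[[paste0(m, "_mean")]] <- mean(v)
      se <- sd(v) / sqrt(length(v))
      ci <- if (length(v) > 1L) qt(0.975, length(v) - 1L) * se else NA_real_
      out[[paste0(m, "_ci95")]] <- ci
    }
    out
  }))
  rownames(summ) <- NULL
  structure(list(design = design, repetitions = repetitions, seed = seed,
                 per_repetition = per_rep, summary = summ),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  print(x$design)
  cat(sprintf("%d repetitions (master seed %s)\n", x$repetitions,
              format(x$seed)))
  s <- x$summary
  show <- intersect(c("generations", "replicates", "pauc_norm_mean",
                      "pauc_norm_ci95", "tpr_mean", "n_lost_mean",
                      grep("^top\\d+_mean$", names(s), value = TRUE)),
                    names(s))
  print(s[show], digits = 4, row.names = FALSE)
  invisible(x)
}
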