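#' Allele frequencies per locus
#'
#' @param gt a [geno_table()] of individual genotypes.
#' @return named list per locus of named frequency vectors (allele
#'   codes as names); loci with no calls return `NULL` entries.
#' @export
allele_freqs <- function(gt) {
  out <- lapply(seq_along(gt$loci), function(l) {
    alle <- c(gt$a1[, l], gt$a2[, l])
    alle <- alle[!is.na(alle)]
    if (!length(alle)) return(NULL)
    tab <- table(alle)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  names(out) <- gt$loci
  out
}

#' Genetic diversity summaries
#'
#' Per-locus allele count (Na), observed heterozygosity (Ho), expected
#' heterozygosity (He = 1 - sum p^2, the biased form), and fixation
#' index F = (He - Ho)/He, with across-locus means and SEs. Allele
#' frequencies are computed from the supplied individuals. Monomorphic
#' loci have F undefined and are flagged; loci untyped in the set are
#' excluded.
#'
#' @param gt a [geno_table()] with one genotype per individual.
#' @param unbiased multiply He by 2n/(2n-1) (off by default).
#' @return list of class `diversity_stats`: `by_locus` data frame
#'   (`locus, n, na, ho, he, f, flagged`), and `means` data frame
#'   (`metric, mean, se`).
#' @export
diversity <- function(gt, unbiased = FALSE) {
  if (nrow(gt$a1) < 2) stop("need >= 2 individuals")
  rows <- lapply(seq_along(gt$loci), function(l) {
    a1 <- gt$a1[, l]; a2 <- gt$a2[, l]
    ok <- !is.na(a1)
    n <- sum(ok)
    if (n == 0) return(NULL)
    p <- table(c(a1[ok], a2[ok]))
    p <- as.numeric(p) / sum(p)
    he <- 1 - sum(p^2)
    if (unbiased) he <- he * 2 * n / (2 * n - 1)
    ho <- mean(a1[ok] != a2[ok])
    f <- if (he > 0) (he - ho) / he else NA_real_
    data.frame(locus = gt$loci[l], n = n, na = length(p), ho = ho,
               he = he, f = f, flagged = he == 0,
               stringsAsFactors = FALSE)
  })
  by_locus <- do.call(rbind, rows)
  means <- data.frame(
    metric = c("na", "ho", "he", "f"),
    mean = c(mean(by_locus$na), mean(by_locus$ho), mean(by_locus$he),
             mean(by_locus$f, na.rm = TRUE)),
    se = c(se_mean(by_locus$na), se_mean(by_locus$ho),
           se_mean(by_locus$he), se_mean(by_locus$f)),
    stringsAsFactors = FALSE)
  structure(list(by_locus = by_locus, means = means),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("diversity over", nrow(x$by_locus), "loci:\n")
  for (i in seq_len(nrow(x$means)))
    cat(sprintf("  %-2s %.3f (+/- %.3f SE)\n", x$means$metric[i],
                x$means$mean[i], x$means$se[i]))
  invisible(x)
}

#' Mann-Whitney rank-sum comparison of per-locus metrics
#'
#' Two-sided test of a per-locus metric between two sessions; exact
#' when sample sizes permit (no ties, combined n small), otherwise the
#' tie-corrected normal approximation, as provided by
#' [stats::wilcox.test()].
#'
#' @param x,y per-locus metric values for the two groups.
#' @return list `U`, `p`, `method`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("need >= 1 value per group")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact =
                                              (length(x) + length(y)) <= 50))
  list(U = unname(wt$statistic), p = wt$p.value, method = wt$method)
}

#' Ritland pairwise relatedness
#'
#' Frequency-weighted allele-sharing estimator: per locus l with
#' alleles a at reference frequency p_a,
#' \deqn{r_l = \sum_a P_{xa} P_{ya} / p_a - 1}
#' where P is the allele dosage (0, 0.5, 1) of each individual, and
#' the multilocus estimate weights loci by their allele number,
#' \deqn{R = 2 \sum_l r_l / \sum_l (k_l - 1).}
#' Unrelated pairs have expectation 0; first-order kin ~0.5. Estimates
#' are not bounded.
#'
#' @param gt a [geno_table()] with one genotype per individual.
#' @param freqs optional reference frequencies (as from
#'   [allele_freqs()]); default: computed from `gt` itself.
#' @param bins cutpoints classifying R into pedigree-order bins
#'   (midpoints between 0.5/0.25/0.125 orders and unrelated).
#' @return list of class `relatedness_matrix`: `R` (symmetric matrix,
#'   diagonal `NA`), `pairs` long data frame (`id1, id2, R, bin`).
#' @export
ritland_relatedness <- function(gt, freqs = NULL,
                                bins = c(first = 0.375, second = 0.1875,
                                         third = 0.09375)) {
  if (is.null(freqs)) freqs <- allele_freqs(gt)
  n <- nrow(gt$a1)
  ids <- gt$meta$sample_id
  L <- length(gt$loci)
  weight <- numeric(L)
  for (l in seq_len(L)) {
    p <- freqs[[gt$loci[l]]]
    if (is.null(p) || length(p) < 2) next
    seen <- unique(stats::na.omit(c(gt$a1[, l], gt$a2[, l])))
    if (!all(as.character(seen) %in% names(p)))
      stop("allele with zero reference frequency at locus ", gt$loci[l])
    weight[l] <- length(p) - 1
  }
  if (all(weight == 0)) stop("no polymorphic locus with usable frequencies")
  R <- ritland_pairs(gt, freqs, weight)
  bin_of <- function(r) {
    if (is.na(r)) return(NA_character_)
    if (r > bins[1]) "first" else if (r > bins[2]) "second"
    else if (r > bins[3]) "third" else "unrelated"
  }
  ut <- which(upper.tri(R), arr.ind = TRUE)
  pairs <- data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
                      R = R[ut], stringsAsFactors = FALSE)
  pairs$bin <- vapply(pairs$R, bin_of, character(1))
  structure(list(R = R, pairs = pairs, bins = bins),
            class = "relatedness_matrix")
}

# vectorized pairwise Ritland numerator/denominator
ritland_pairs <- function(gt, freqs, weight) {
  n <- nrow(gt$a1)
  ids <- gt$meta$sample_id
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (l in seq_along(gt$loci)) {
    if (weight[l] == 0) next
    p <- freqs[[gt$loci[l]]]
    alle_names <- names(p)
    a1 <- as.character(gt$a1[, l]); a2 <- as.character(gt$a2[, l])
    P <- matrix(0, n, length(p))
    for (k in seq_along(alle_names))
      P[, k] <- 0.5 * ((a1 == alle_names[k]) + (a2 == alle_names[k]))
    called <- !is.na(gt$a1[, l])
    P[!called, ] <- 0
    S <- (P %*% diag(1 / p, length(p))) %*% t(P)   # sum_a Pxa Pya / pa
    ok <- outer(called, called, "&")
    num <- num + ifelse(ok, S - 1, 0)
    den <- den + ifelse(ok, weight[l], 0)
  }
  R <- ifelse(den > 0, 2 * num / den, NA_real_)
  diag(R) <- NA_real_
  dimnames(R) <- list(ids, ids)
  R
}

#' Effective population size by the linkage-disequilibrium method
#'
#' Burrows composite disequilibrium between dosages,
#' `delta = cov(X, Y) / 2`, squared and standardized by the
#' Hardy-Weinberg denominator `pA qA pB qB` (the r-squared form the
#' Waples bias corrections were calibrated for), averaged
#' over all pairs of retained loci; the sampling component is removed
#' and the drift component transformed to Ne using the random-mating
#' formulas of Waples (2006) as applied by LDNe/NeEstimator:
#' for sample size S >= 30, `E(r2_sample) = 1/S + 3.19/S^2` and
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')`; for S < 30 the
#' constants 0.0018 + 0.907/S + 4.44/S^2 and
#' `Ne = (0.308 + sqrt(0.308^2 - 2.08 r2')) / (2 r2')`. Alleles at
#' frequency at or below `maf_cutoff` are excluded before pairing. The
#' 95% CI is parametric: a chi-square interval on mean r-squared with
#' df = number of locus-pair comparisons, pushed through the same
#' transformation. A non-positive drift component yields an infinite
#' estimate.
#'
#' @param gt a [geno_table()] with one genotype per individual.
#' @param maf_cutoff minor-allele-frequency exclusion threshold
#'   (default 0.02).
#' @return list of class `ne_estimate`: `ne`, `ci` (low, high; high
#'   may be `Inf`), `r2_mean`, `r2_drift`, `n_comparisons`,
#'   `mean_sample_size`, `maf_cutoff`, `n_loci`.
#' @export
ld_ne <- function(gt, maf_cutoff = 0.02) {
  fr <- allele_freqs(gt)
  # biallelic dosage per locus; polymorphic above the MAF cutoff
  use <- which(vapply(fr, function(p)
    !is.null(p) && length(p) >= 2 && min(p) > maf_cutoff, logical(1)))
  if (length(use) < 2) stop("need >= 2 polymorphic loci after MAF cutoff")
  dos <- lapply(use, function(l) {
    ref <- as.integer(names(fr[[l]])[1])
    (gt$a1[, l] == ref) + (gt$a2[, l] == ref)
  })
  L <- length(dos)
  r2 <- numeric(0); ss <- numeric(0)
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    ok <- !is.na(dos[[i]]) & !is.na(dos[[j]])
    if (sum(ok) < 3) next
    a <- dos[[i]][ok]; b <- dos[[j]][ok]
    if (stats::var(a) == 0 || stats::var(b) == 0) next
    pA <- mean(a) / 2; pB <- mean(b) / 2
    if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) next
    delta <- stats::cov(a, b) / 2
    r2 <- c(r2, delta^2 / (pA * (1 - pA) * pB * (1 - pB)))
    ss <- c(ss, sum(ok))
  }
  if (!length(r2)) stop("no usable locus pairs")
  r2_mean <- mean(r2)
  S <- 1 / mean(1 / ss)   # harmonic mean sample size across pairs
  df <- length(r2)
  ne_of <- function(r2bar) {
    if (S >= 30) {
      rd <- r2bar - (1 / S + 3.19 / S^2)
      if (rd <= 0) return(Inf)
      disc <- 1 / 9 - 2.76 * rd
      if (disc < 0) disc <- 0
      (1 / 3 + sqrt(disc)) / (2 * rd)
    } else {
      rd <- r2bar - (0.0018 + 0.907 / S + 4.44 / S^2)
      if (rd <= 0) return(Inf)
      disc <- 0.308^2 - 2.08 * rd
      if (disc < 0) disc <- 0
      (0.308 + sqrt(disc)) / (2 * rd)
    }
  }
  ne <- ne_of(r2_mean)
  r2_lo <- r2_mean * df / stats::qchisq(0.025, df, lower.tail = FALSE)
  r2_hi <- r2_mean * df / stats::qchisq(0.975, df, lower.tail = FALSE)
  ci <- sort(c(ne_of(r2_hi), ne_of(r2_lo)))
  structure(list(ne = ne, ci = ci, r2_mean = r2_mean,
                 r2_drift = if (S >= 30) r2_mean - (1 / S + 3.19 / S^2)
                 else r2_mean - (0.0018 + 0.907 / S + 4.44 / S^2),
                 n_comparisons = df, mean_sample_size = S,
                 maf_cutoff = maf_cutoff, n_loci = L),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("LD-method Ne = %.1f (95%% CI %.1f-%s) from %d loci, %d comparisons\n",
              x$ne, x$ci[1],
              if (is.finite(x$ci[2])) sprintf("%.1f", x$ci[2]) else "Inf",
              x$n_loci, x$n_comparisons))
  invisible(x)
}
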