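#' Amplification rates across samples, loci and replicate groups
#'
#' Amplification (call rate) is the proportion of loci scored per run
#' and the proportion of runs scored per locus.
#'
#' @param gt a [geno_table()].
#' @return list of class `amp_report`: `by_run` (data frame with
#'   `sample_id`, `replicate`, `amplification`), `by_locus`,
#'   `by_replicate` (per replicate group mean and SE), and overall
#'   `mean`/`se` across runs.
#' @export
amplification_rates <- function(gt) {
  if (nrow(gt$a1) == 0) stop("empty genotype table")
  called <- !is.na(gt$a1)
  by_run <- data.frame(sample_id = gt$meta$sample_id,
                       replicate = gt$meta$replicate,
                       amplification = rowMeans(called),
                       stringsAsFactors = FALSE)
  by_locus <- data.frame(locus = gt$loci,
                         amplification = colMeans(called),
                         stringsAsFactors = FALSE)
  groups <- split(by_run$amplification, by_run$replicate)
  by_rep <- data.frame(replicate = names(groups),
                       mean = vapply(groups, mean, numeric(1)),
                       se = vapply(groups, se_mean, numeric(1)),
                       stringsAsFactors = FALSE)
  structure(list(by_run = by_run, by_locus = by_locus,
                 by_replicate = by_rep,
                 mean = mean(by_run$amplification),
                 se = se_mean(by_run$amplification)),
            class = "amp_report")
}

#' @export
print.amp_report <- function(x, ...) {
  cat(sprintf("amplification: mean %.3f (+/- %.3f SE; range %.2f-%.2f) over %d runs\n",
              x$mean, x$se, min(x$by_run$amplification),
              max(x$by_run$amplification), nrow(x$by_run)))
  invisible(x)
}

#' Consensus genotype from two replicate runs
#'
#' Per locus: both replicates missing leaves the call missing; a call
#' missing in one replicate is filled in from the other provided the
#' donor run's sample amplification exceeds `fill_floor`; conflicting
#' calls keep the call from the replicate with the higher sample
#' amplification (ties keep the first replicate).
#'
#' @param a1a,a2a,a1b,a2b integer allele vectors of replicates A and B
#'   over the same loci.
#' @param amp_a,amp_b sample amplification of each replicate.
#' @param fill_floor minimum donor amplification for fill-in (default
#'   0.2).
#' @return list `a1`, `a2` consensus allele vectors.
#' @export
consensus_genotype <- function(a1a, a2a, a1b, a2b, amp_a, amp_b,
                               fill_floor = 0.2) {
  if (length(a1a) != length(a1b))
    stop("replicates cover different locus sets")
  a_called <- !is.na(a1a); b_called <- !is.na(a1b)
  a1 <- rep(NA_integer_, length(a1a)); a2 <- a1
  use_a <- (a_called & !b_called & amp_a > fill_floor) |
    (a_called & b_called & amp_a >= amp_b)
  use_b <- (b_called & !a_called & amp_b > fill_floor) |
    (a_called & b_called & amp_b > amp_a)
  a1[use_a] <- a1a[use_a]; a2[use_a] <- a2a[use_a]
  a1[use_b] <- a1b[use_b]; a2[use_b] <- a2b[use_b]
  list(a1 = a1, a2 = a2)
}

#' Collapse replicate runs to one consensus genotype per sample
#'
#' Runs of each sample are combined pairwise by [consensus_genotype()]
#' in descending order of amplification; with more than two replicates
#' the running consensus plays the role of the higher-amplification
#' member.
#'
#' @param gt a [geno_table()] with replicate runs.
#' @param fill_floor minimum donor amplification for fill-in.
#' @return A [geno_table()] with one run per sample (`replicate = 0`).
#' @export
consensus_table <- function(gt, fill_floor = 0.2) {
  amp <- rowMeans(!is.na(gt$a1))
  ids <- unique(gt$meta$sample_id)
  L <- length(gt$loci)
  a1 <- matrix(NA_integer_, length(ids), L)
  a2 <- a1
  meta_cols <- setdiff(names(gt$meta), "replicate")
  meta <- gt$meta[match(ids, gt$meta$sample_id), meta_cols, drop = FALSE]
  for (i in seq_along(ids)) {
    rows <- which(gt$meta$sample_id == ids[i])
    rows <- rows[order(amp[rows], decreasing = TRUE)]
    c1 <- gt$a1[rows[1], ]; c2 <- gt$a2[rows[1], ]
    camp <- amp[rows[1]]
    for (r in rows[-1]) {
      cons <- consensus_genotype(c1, c2, gt$a1[r, ], gt$a2[r, ],
                                 camp, amp[r], fill_floor)
      c1 <- cons$a1; c2 <- cons$a2
      camp <- max(camp, mean(!is.na(c1)))
    }
    a1[i, ] <- c1; a2[i, ] <- c2
  }
  meta$replicate <- 0L
  geno_table(a1, a2, meta, gt$loci)
}

#' Allelic dropout and false-allele rates from replicate pairs
#'
#' Pairs of replicate runs of the same sample are compared per locus.
#' A comparison where one member is heterozygous and the other is a
#' homozygote for one of its alleles scores one allelic dropout; any
#' other discordance between two called genotypes scores one false
#' allele event. Dropout follows the per-reaction convention (each
#' replicate of a pair is one amplification of a putative
#' heterozygote): ADO per locus = dropout events / (2 x pairs with at
#' least one heterozygous member). False alleles are scored per
#' comparison: FA per locus = false-allele events / pairs with both
#' members called. (A false allele in either of the two reactions
#' surfaces as one discordant pattern, while roughly half of false
#' alleles are masked as dropout-like patterns, so the per-comparison
#' event rate tracks the per-reaction probability.) Means and SEs are
#' taken across loci.
#'
#' @param gt a [geno_table()] holding >= 2 replicates for at least one
#'   sample.
#' @return list of class `error_rates`: `by_locus` data frame (`locus`,
#'   `ado`, `fa`, `n_het_comparisons`, `n_comparisons`, `flagged`),
#'   `ado_mean`, `ado_se`, `fa_mean`, `fa_se`, `n_pairs`.
#' @export
error_rates <- function(gt) {
  ids <- unique(gt$meta$sample_id)
  L <- length(gt$loci)
  drop_ev <- het_n <- fa_ev <- both_n <- numeric(L)
  n_pairs <- 0L
  for (id in ids) {
    rows <- which(gt$meta$sample_id == id)
    if (length(rows) < 2) next
    prs <- utils::combn(rows, 2)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1, k]; j <- prs[2, k]
      x1 <- gt$a1[i, ]; x2 <- gt$a2[i, ]
      y1 <- gt$a1[j, ]; y2 <- gt$a2[j, ]
      both <- !is.na(x1) & !is.na(y1)
      if (!any(both)) next
      n_pairs <- n_pairs + 1L
      hx <- both & x1 != x2; hy <- both & y1 != y2
      # dropout: het in one member, matching one-allele homozygote in other
      do_x <- hy & !hx & (x1 == y1 | x1 == y2)   # member i dropped
      do_y <- hx & !hy & (y1 == x1 | y1 == x2)   # member j dropped
      concord <- both & x1 == y1 & x2 == y2
      discord <- both & !concord
      fa_here <- discord & !do_x & !do_y
      both_n <- both_n + both
      het_n <- het_n + (hx | hy)
      drop_ev <- drop_ev + do_x + do_y
      fa_ev <- fa_ev + fa_here
    }
  }
  if (n_pairs == 0) stop("no replicate pair with jointly scored loci")
  ado <- ifelse(het_n > 0, drop_ev / (2 * het_n), NA_real_)
  fa <- ifelse(both_n > 0, fa_ev / both_n, NA_real_)
  by_locus <- data.frame(locus = gt$loci, ado = ado, fa = fa,
                         n_het_comparisons = het_n, n_comparisons = both_n,
                         flagged = het_n == 0 | both_n == 0,
                         stringsAsFactors = FALSE)
  structure(list(by_locus = by_locus,
                 ado_mean = mean(ado, na.rm = TRUE), ado_se = se_mean(ado),
                 fa_mean = mean(fa, na.rm = TRUE), fa_se = se_mean(fa),
                 n_pairs = n_pairs),
            class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf("error_rates over %d replicate pairs:\n", x$n_pairs))
  cat(sprintf("  allelic dropout %.3f (+/- %.3f SE)\n", x$ado_mean, x$ado_se))
  cat(sprintf("  false alleles   %.3f (+/- %.3f SE)\n", x$fa_mean, x$fa_se))
  invisible(x)
}

#' Correlation between per-locus error rate and amplification
#'
#' Pearson correlation with a two-sided t-based p-value, flagged
#' undefined on zero-variance input.
#'
#' @param error per-locus error rates.
#' @param amplification per-locus amplification rates (same order).
#' @return list `rho`, `p`, `n`, `flag`.
#' @export
error_amp_correlation <- function(error, amplification) {
  ok <- !is.na(error) & !is.na(amplification)
  if (sum(ok) < 3) stop("need >= 3 paired loci")
  e <- error[ok]; a <- amplification[ok]
  if (stats::sd(e) == 0 || stats::sd(a) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok),
                flag = "zero variance"))
  ct <- stats::cor.test(e, a, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok), flag = "ok")
}

#' Filter samples and loci on amplification
#'
#' Two-stage: first drop runs and loci with amplification below
#' `drop_floor` (default 0.2) and recompute rates on the subset; then
#' apply the analysis floors in a fixed order, samples before loci, one
#' pass each.
#'
#' @param gt a [geno_table()].
#' @param sample_floor,locus_floor analysis amplification floors.
#' @param drop_floor hard pre-filter floor.
#' @return A filtered [geno_table()]; its `audit` attribute records
#'   counts removed at each stage.
#' @export
filter_samples_loci <- function(gt, sample_floor = 0.7, locus_floor = 0.8,
                                drop_floor = 0.2) {
  stopifnot(sample_floor >= 0, sample_floor <= 1,
            locus_floor >= 0, locus_floor <= 1,
            drop_floor >= 0, drop_floor <= 1)
  audit <- list()
  # stage 1: hard drop
  ramp <- rowMeans(!is.na(gt$a1))
  camp <- colMeans(!is.na(gt$a1))
  keep_r <- ramp >= drop_floor
  keep_c <- camp >= drop_floor
  audit$drop_stage <- c(samples = sum(!keep_r), loci = sum(!keep_c))
  gt <- gt_subset(gt, keep_r, keep_c)
  if (nrow(gt$a1) == 0 || length(gt$loci) == 0)
    stop("all samples or loci removed at the drop stage")
  # stage 2: recomputed floors, samples then loci, one pass each
  ramp <- rowMeans(!is.na(gt$a1))
  keep_r <- ramp >= sample_floor
  audit$sample_floor <- sum(!keep_r)
  gt <- gt_subset(gt, keep_r, NULL)
  if (nrow(gt$a1) == 0) stop("all samples removed by the sample floor")
  camp <- colMeans(!is.na(gt$a1))
  keep_c <- camp >= locus_floor
  audit$locus_floor <- sum(!keep_c)
  gt <- gt_subset(gt, NULL, keep_c)
  if (length(gt$loci) == 0) stop("all loci removed by the locus floor")
  attr(gt, "audit") <- audit
  gt
}

#' Sweep sample and locus amplification floors
#'
#' Utility reporting, for each floor combination, the numbers of
#' samples and loci retained — supporting a user-driven choice of
#' thresholds.
#'
#' @param gt a [geno_table()].
#' @param sample_floors,locus_floors candidate floors.
#' @param drop_floor hard pre-filter floor.
#' @return data frame `sample_floor, locus_floor, n_samples, n_loci`.
#' @export
threshold_sweep <- function(gt, sample_floors = seq(0.6, 0.9, by = 0.1),
                            locus_floors = seq(0.6, 0.9, by = 0.1),
                            drop_floor = 0.2) {
  grid <- expand.grid(sample_floor = sample_floors,
                      locus_floor = locus_floors)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    out <- try(filter_samples_loci(gt, grid$sample_floor[i],
                                   grid$locus_floor[i], drop_floor),
               silent = TRUE)
    if (inherits(out, "try-error")) c(NA_integer_, NA_integer_)
    else c(nrow(out$a1), length(out$loci))
  })
  grid$n_samples <- vapply(res, `[`, numeric(1), 1)
  grid$n_loci <- vapply(res, `[`, numeric(1), 2)
  grid
}
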