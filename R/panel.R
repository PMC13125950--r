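#' Thresholds for the SNP panel filtering cascade
#'
#' Defaults follow the reduced-representation panel-design workflow for
#' a small, bottlenecked focal population: one SNP per sequence tag, no
#' flanking variants within 30 bp of the target, base quality >= 30,
#' sequence length >= 50 bp, mean read depth in \[8, 100\], locus call
#' rate >= 0.78, no paralog similarity flag, minor allele frequency
#' >= 0.34 in the focal population and >= 0.14 elsewhere, no
#' significant Hardy-Weinberg departure (p >= 0.05), expected
#' heterozygosity in \[0.4, 0.6\], and LD pruning at r-squared > 0.3.
#'
#' @param max_snps_per_tag,flank_bp,min_q,min_length,depth_range
#'   sequence-level thresholds.
#' @param min_call_rate locus call-rate floor.
#' @param maf_focal,maf_other minor-allele-frequency floors for the
#'   focal and the other populations.
#' @param hwe_alpha HWE significance level.
#' @param hwe_strict `"any"` removes a locus significant in any one
#'   population; `"all"` requires significance in every population.
#' @param he_range retained expected-heterozygosity window (inclusive).
#' @param max_ld_r2 LD pruning threshold on r-squared.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_snps_per_tag = 1L, flank_bp = 30,
                              min_q = 30, min_length = 50,
                              depth_range = c(8, 100),
                              min_call_rate = 0.78,
                              maf_focal = 0.34, maf_other = 0.14,
                              hwe_alpha = 0.05,
                              hwe_strict = c("any", "all"),
                              he_range = c(0.4, 0.6),
                              max_ld_r2 = 0.3) {
  structure(list(max_snps_per_tag = max_snps_per_tag, flank_bp = flank_bp,
                 min_q = min_q, min_length = min_length,
                 depth_range = depth_range, min_call_rate = min_call_rate,
                 maf_focal = maf_focal, maf_other = maf_other,
                 hwe_alpha = hwe_alpha, hwe_strict = match.arg(hwe_strict),
                 he_range = he_range, max_ld_r2 = max_ld_r2),
            class = "filter_thresholds")
}

#' Build a locus catalog
#'
#' One row per locus with sequencing metadata, plus per-population
#' minor allele frequency, expected heterozygosity and HWE p-value
#' supplied as a long table.
#'
#' @param info data frame, one row per locus: `locus`, `n_snps_tag`,
#'   `flank_snp` (logical: another SNP within the flanking window),
#'   `q_score`, `seq_length`, `depth`, `call_rate`, `paralog`
#'   (logical).
#' @param popstats data frame, one row per locus x population: `locus`,
#'   `pop`, `maf`, `he`, `hwe_p`.
#' @param focal_pop name of the focal population in `popstats`.
#' @return list of class `locus_catalog`.
#' @export
locus_catalog <- function(info, popstats, focal_pop) {
  req_i <- c("locus", "n_snps_tag", "flank_snp", "q_score", "seq_length",
             "depth", "call_rate", "paralog")
  req_p <- c("locus", "pop", "maf", "he", "hwe_p")
  if (!all(req_i %in% names(info)))
    stop("info requires columns: ", paste(req_i, collapse = ", "))
  if (!all(req_p %in% names(popstats)))
    stop("popstats requires columns: ", paste(req_p, collapse = ", "))
  if (!focal_pop %in% popstats$pop)
    stop("focal population '", focal_pop, "' absent from popstats")
  if (any(info$depth < 0) || any(info$call_rate < 0))
    stop("depth and call rate must be >= 0")
  structure(list(info = as.data.frame(info),
                 popstats = as.data.frame(popstats),
                 focal_pop = focal_pop),
            class = "locus_catalog")
}

#' @export
print.locus_catalog <- function(x, ...) {
  cat("locus_catalog:", nrow(x$info), "loci,",
      length(unique(x$popstats$pop)), "populations (focal:",
      x$focal_pop, ")\n")
  invisible(x)
}

#' Apply the panel filtering cascade
#'
#' Steps run in a fixed order (multi-SNP tag, flanking SNP, quality,
#' length, depth, call rate, paralog, MAF, HWE, He window, LD pruning)
#' and an audit records removals per step. LD pruning needs pairwise
#' r-squared values (`ld_pairs`); the member of an offending pair with
#' the lower focal-population MAF is dropped, ties broken by locus id.
#'
#' @param catalog a [locus_catalog()].
#' @param thresholds a [filter_thresholds()].
#' @param ld_pairs optional data frame `locus_a, locus_b, r2`.
#' @return list with `retained` (character vector of locus ids) and
#'   `audit` (data frame `step, threshold, removed, remaining`).
#' @export
filter_loci <- function(catalog, thresholds = filter_thresholds(),
                        ld_pairs = NULL) {
  info <- catalog$info
  ps <- catalog$popstats
  th <- thresholds
  keep <- info$locus
  audit <- data.frame(step = character(), threshold = character(),
                      removed = integer(), remaining = integer(),
                      stringsAsFactors = FALSE)
  drop_step <- function(step, threshold, bad_ids) {
    bad_ids <- intersect(bad_ids, keep)
    keep <<- setdiff(keep, bad_ids)
    audit <<- rbind(audit, data.frame(
      step = step, threshold = threshold,
      removed = length(bad_ids), remaining = length(keep),
      stringsAsFactors = FALSE))
  }
  need <- function(col, step) {
    if (anyNA(info[[col]][info$locus %in% keep]))
      stop("missing ", col, " for step '", step, "' at locus ",
           info$locus[info$locus %in% keep & is.na(info[[col]])][1])
    info[[col]]
  }
  drop_step("multi_snp_tag", sprintf("> %d SNP/tag", th$max_snps_per_tag),
            info$locus[need("n_snps_tag", "multi_snp_tag") > th$max_snps_per_tag])
  drop_step("flanking_snp", sprintf("SNP within %g bp", th$flank_bp),
            info$locus[need("flank_snp", "flanking_snp")])
  drop_step("quality", sprintf("Q < %g", th$min_q),
            info$locus[need("q_score", "quality") < th$min_q])
  drop_step("length", sprintf("< %g bp", th$min_length),
            info$locus[need("seq_length", "length") < th$min_length])
  drop_step("depth", sprintf("outside [%g, %g]", th$depth_range[1],
                             th$depth_range[2]),
            info$locus[need("depth", "depth") < th$depth_range[1] |
                       info$depth > th$depth_range[2]])
  drop_step("call_rate", sprintf("< %g", th$min_call_rate),
            info$locus[need("call_rate", "call_rate") < th$min_call_rate])
  drop_step("paralog", "similarity flag",
            info$locus[need("paralog", "paralog")])
  focal <- ps$pop == catalog$focal_pop
  bad_maf <- unique(c(ps$locus[focal & ps$maf < th$maf_focal],
                      ps$locus[!focal & ps$maf < th$maf_other]))
  drop_step("maf", sprintf("focal < %g | other < %g", th$maf_focal,
                           th$maf_other), bad_maf)
  sig <- ps$hwe_p < th$hwe_alpha
  bad_hwe <- if (th$hwe_strict == "any") unique(ps$locus[sig]) else {
    tab <- tapply(sig, ps$locus, all)
    names(tab)[tab]
  }
  drop_step("hwe", sprintf("p < %g (%s population)", th$hwe_alpha,
                           th$hwe_strict), bad_hwe)
  he_focal <- ps[focal, ]
  bad_he <- he_focal$locus[he_focal$he < th$he_range[1] |
                           he_focal$he > th$he_range[2]]
  drop_step("he_window", sprintf("outside [%g, %g]", th$he_range[1],
                                 th$he_range[2]), bad_he)
  # LD pruning: drop the lower-MAF member of each offending pair
  bad_ld <- character()
  if (!is.null(ld_pairs) && nrow(ld_pairs)) {
    maf_f <- stats::setNames(he_focal$maf, he_focal$locus)
    off <- ld_pairs[ld_pairs$r2 > th$max_ld_r2, , drop = FALSE]
    off <- off[off$locus_a %in% keep & off$locus_b %in% keep, , drop = FALSE]
    off <- off[order(off$locus_a, off$locus_b), , drop = FALSE]
    for (i in seq_len(nrow(off))) {
      a <- off$locus_a[i]; b <- off$locus_b[i]
      if (!(a %in% keep) || !(b %in% keep)) next
      ma <- maf_f[a]; mb <- maf_f[b]
      victim <- if (is.na(ma) || is.na(mb)) max(a, b)
      else if (ma < mb) a else if (mb < ma) b else max(a, b)
      bad_ld <- c(bad_ld, victim)
      keep <- setdiff(keep, victim)
    }
    keep <- c(keep, character(0))
  }
  # record via audit (keep already updated for LD)
  audit <- rbind(audit, data.frame(
    step = "ld_prune", threshold = sprintf("r2 > %g", th$max_ld_r2),
    removed = length(bad_ld), remaining = length(keep),
    stringsAsFactors = FALSE))
  list(retained = info$locus[info$locus %in% keep], audit = audit)
}

#' Hardy-Weinberg equilibrium test
#'
#' Biallelic loci use the exact conditional test: given the observed
#' allele counts, the probability of every possible heterozygote count
#' is enumerated and the p-value sums the probabilities no larger than
#' that of the observed configuration. Loci with more than two alleles
#' use a chi-square test on HWE expected genotype counts.
#'
#' @param counts for a biallelic locus, a length-3 vector
#'   `c(nAA, nAB, nBB)`; for a multiallelic locus, a symmetric matrix
#'   of genotype counts (upper triangle + diagonal used).
#' @return list `p` (p-value), `method`, and `monomorphic` flag
#'   (monomorphic loci return p = 1).
#' @export
hwe_test <- function(counts) {
  if (is.matrix(counts)) return(hwe_chisq_multi(counts))
  if (length(counts) != 3 || any(counts < 0))
    stop("biallelic counts must be c(nAA, nAB, nBB), non-negative")
  if (sum(counts) < 1) stop("at least one individual required")
  nA <- 2 * counts[1] + counts[2]
  nB <- 2 * counts[3] + counts[2]
  if (nA == 0 || nB == 0)
    return(list(p = 1, method = "exact", monomorphic = TRUE))
  n <- sum(counts)
  rare <- min(nA, nB)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_AB = h | nA, nB) per Levene/Haldane conditional distribution
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- match(counts[2], hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  p <- sum(pr[pr <= pr[obs] * (1 + 1e-9)])
  list(p = min(1, p), method = "exact", monomorphic = FALSE)
}

hwe_chisq_multi <- function(counts) {
  k <- nrow(counts)
  counts <- counts + t(counts) - diag(diag(counts))  # symmetrize
  n <- sum(counts[upper.tri(counts, diag = TRUE)])
  alle <- rowSums(counts) + diag(counts)             # allele counts x2 total
  p <- alle / sum(alle)
  if (sum(p > 0) < 2) return(list(p = 1, method = "chisq", monomorphic = TRUE))
  stat <- 0; df <- 0
  for (i in 1:k) for (j in i:k) {
    e <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
    if (e > 0) {
      o <- counts[i, j]
      stat <- stat + (o - e)^2 / e
      df <- df + 1
    }
  }
  df <- df - sum(p > 0)  # k(k+1)/2 cells - k allele frequencies... minus 1
  df <- max(df, 1)
  list(p = stats::pchisq(stat, df, lower.tail = FALSE),
       method = "chisq", monomorphic = FALSE, stat = stat, df = df)
}

#' Composite linkage-disequilibrium r-squared from unphased genotypes
#'
#' Burrows composite measure: the squared Pearson correlation of
#' genotype dosages, algebraically identical to
#' \eqn{\hat\Delta^2 / ((p_Aq_A+D_A)(p_Bq_B+D_B))} where the
#' \eqn{D}s are homozygote-excess terms — no phase or HWE assumption.
#'
#' @param dos_a,dos_b numeric dosage vectors (0/1/2 copies of a chosen
#'   reference allele; `NA` allowed; pairwise-complete cases used).
#' @return list `r2` and `flag` (`"ok"` or `"monomorphic"`; r2 is `NA`
#'   when flagged).
#' @export
ld_r2 <- function(dos_a, dos_b) {
  ok <- !is.na(dos_a) & !is.na(dos_b)
  if (sum(ok) < 2) stop("need >= 2 individuals called at both loci")
  a <- dos_a[ok]; b <- dos_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    return(list(r2 = NA_real_, flag = "monomorphic"))
  list(r2 = stats::cor(a, b)^2, flag = "ok")
}

#' Per-locus probability of identity
#'
#' `PID = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2`: the probability two
#' unrelated individuals share a genotype at the locus.
#'
#' @param p allele-frequency vector.
#' @return numeric scalar.
#' @export
pid_locus <- function(p) {
  sum(p^4) + sum((2 * outer(p, p))[upper.tri(diag(length(p)))]^2)
}

#' Per-locus sibling probability of identity
#'
#' `PIDsib = 0.25 + 0.5 sum(p_i^2) + 0.5 (sum(p_i^2))^2 -
#' 0.25 sum(p_i^4)`: the analogous probability for full siblings, the
#' conservative benchmark for individual identification.
#'
#' @param p allele-frequency vector.
#' @return numeric scalar.
#' @export
pidsib_locus <- function(p) {
  s2 <- sum(p^2)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * sum(p^4)
}

#' Cumulative probability-of-identity power curve
#'
#' Orders loci (by default most informative first, i.e. ascending
#' per-locus PID), takes cumulative products of per-locus PID and
#' PIDsib, and reports the minimum number of loci whose cumulative
#' probability reaches a threshold — the locus count needed to resolve
#' unrelated individuals and siblings respectively.
#'
#' @param loci named list of allele-frequency vectors.
#' @param threshold identification threshold (default 1e-4).
#' @param order `"informativeness"` (ascending per-locus PID) or
#'   `"given"` (catalog order).
#' @return list of class `pid_curve`: `locus`, `pid`, `pidsib`
#'   (per-locus), `cum_pid`, `cum_pidsib`, `n_pid`, `n_pidsib`
#'   (minimum locus counts; `NA` if the threshold is never reached),
#'   `threshold`.
#' @export
pid_curve <- function(loci, threshold = 1e-4,
                      order = c("informativeness", "given")) {
  if (length(loci) == 0) stop("empty locus set")
  order <- match.arg(order)
  pid <- vapply(loci, pid_locus, numeric(1))
  sib <- vapply(loci, pidsib_locus, numeric(1))
  o <- if (order == "informativeness") base::order(pid) else seq_along(pid)
  pid <- pid[o]; sib <- sib[o]
  cum_pid <- cumprod(pid); cum_sib <- cumprod(sib)
  first_at <- function(x) {
    i <- unname(which(x <= threshold))
    if (length(i)) i[1] else NA_integer_
  }
  structure(list(locus = names(loci)[o], pid = pid, pidsib = sib,
                 cum_pid = cum_pid, cum_pidsib = cum_sib,
                 n_pid = first_at(cum_pid), n_pidsib = first_at(cum_sib),
                 threshold = threshold),
            class = "pid_curve")
}

#' @export
print.pid_curve <- function(x, ...) {
  cat(sprintf("pid_curve over %d loci, threshold %g\n", length(x$locus),
              x$threshold))
  cat(sprintf("  loci needed: %s (unrelated), %s (siblings)\n",
              format(x$n_pid), format(x$n_pidsib)))
  invisible(x)
}
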