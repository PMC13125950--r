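# fixtures built in code, shared across test files

# geno_table from a compact genotype string matrix: "11", "12", "" = missing
gt_from_strings <- function(m, sample_ids = NULL, replicate = 1L,
                            loci = NULL) {
  m <- as.matrix(m)
  a1 <- apply(m, c(1, 2), function(s)
    if (!nzchar(s)) NA_integer_ else as.integer(substr(s, 1, 1)))
  a2 <- apply(m, c(1, 2), function(s)
    if (!nzchar(s)) NA_integer_ else as.integer(substr(s, 2, 2)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(ncol(m)))
  geno_table(a1, a2,
             data.frame(sample_id = sample_ids,
                        replicate = rep(replicate, length.out = nrow(m)),
                        stringsAsFactors = FALSE),
             loci)
}

# sample sheet emulating the survey tally: 59 individuals, 87 samples
# (16 individuals recaptured, 28 recapture events)
make_survey_samples <- function(n_ind = 59,
                                extras = c(rep(2, 12), rep(1, 4))) {
  ids <- sprintf("I%04d", seq_len(n_ind))
  counts <- rep(1L, n_ind)
  counts[seq_along(extras)] <- 1L + extras
  data.frame(sample_id = sprintf("S%04d", seq_len(sum(counts))),
             individual = rep(ids, counts), stringsAsFactors = FALSE)
}

# fraction of samples whose cluster maps (by majority) to their true source
assignment_accuracy <- function(assign, truth) {
  if (inherits(assign, "cluster_assignment")) assign <- assign$assignment
  m <- merge(assign, truth, by = "sample_id",
             suffixes = c(".est", ".true"))
  tab <- table(m$individual.est, m$individual.true)
  maj <- colnames(tab)[max.col(tab, "first")]
  mean(maj[match(m$individual.est, rownames(tab))] == m$individual.true)
}

# discrete-generation Wright-Fisher forward simulation: N diploids,
# L unlinked biallelic loci, random union of gametes (selfing allowed)
wf_population <- function(N, L, gens, seed, p0_range = c(0.3, 0.7)) {
  set.seed(seed)
  p0 <- stats::runif(L, p0_range[1], p0_range[2])
  a1 <- sapply(p0, function(p) stats::rbinom(N, 1, p))
  a2 <- sapply(p0, function(p) stats::rbinom(N, 1, p))
  for (g in seq_len(gens)) {
    pr1 <- sample.int(N, N, replace = TRUE)
    pr2 <- sample.int(N, N, replace = TRUE)
    pick <- function(par) {
      u <- matrix(stats::runif(N * L) < 0.5, N, L)
      ifelse(u, a1[par, ], a2[par, ])
    }
    na1 <- pick(pr1); na2 <- pick(pr2)
    a1 <- na1; a2 <- na2
  }
  geno_table(a1 + 1L, a2 + 1L,
             data.frame(sample_id = sprintf("W%03d", seq_len(N)),
                        replicate = 1L, stringsAsFactors = FALSE),
             sprintf("L%02d", seq_len(L)))
}

# detections data frame -> capture history, expanding multi-scat counts
# into one event per scat
history_from_detections <- function(det, layout) {
  ev <- det[rep(seq_len(nrow(det)), det$count), , drop = FALSE]
  ev$sample_id <- sprintf("E%05d", seq_len(nrow(ev)))
  build_capture_history(ev[c("sample_id", "individual")],
                        ev[c("sample_id", "session", "occasion",
                             "detector")],
                        layout)
}

# single-session layout of arbitrary detector coordinates
toy_layout <- function(x, y, n_occ = 1L, session = "s1") {
  lay <- data.frame(detector_id = sprintf("T%02d", seq_along(x)),
                    x = x, y = y, stringsAsFactors = FALSE)
  u <- list(matrix(1L, length(x), n_occ,
                   dimnames = list(lay$detector_id, NULL)))
  names(u) <- session
  attr(lay, "usage") <- u
  lay
}
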