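test_that("allelic mismatches follow the multiset-difference definition", {
  gt <- gt_from_strings(rbind("11", "12", "22", "13"))
  mm <- mismatch_matrix(gt)$mismatch
  expect_equal(mm["S01", "S02"], 1)   # AA vs AB
  expect_equal(mm["S01", "S03"], 2)   # AA vs BB
  expect_equal(mm["S02", "S04"], 1)   # AB vs AC
  expect_equal(mm["S02", "S02"], 0)
  expect_true(isSymmetric(mm))
})

test_that("mismatch counts skip missing data and match a brute-force recount", {
  set.seed(23)
  m <- matrix(sample(c("11", "12", "22", ""), 8 * 12, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 8, 12)
  gt <- gt_from_strings(m)
  res <- mismatch_matrix(gt)
  # brute force over pairs and loci using explicit multisets
  for (i in 1:7) for (j in (i + 1):8) {
    mis <- 0; shared <- 0
    for (l in 1:12) {
      if (!nzchar(m[i, l]) || !nzchar(m[j, l])) next
      shared <- shared + 1
      gi <- as.integer(strsplit(m[i, l], "")[[1]])
      gj <- as.integer(strsplit(m[j, l], "")[[1]])
      common <- 0
      pool <- gj
      for (al in gi) {
        hit <- match(al, pool)
        if (!is.na(hit)) { common <- common + 1; pool <- pool[-hit] }
      }
      mis <- mis + (2 - common)
    }
    expect_equal(res$mismatch[i, j], mis)
    expect_equal(res$shared[i, j], shared)
    expect_lte(res$mismatch[i, j], 2 * res$shared[i, j])
  }
})

test_that("pairs with no shared loci are incomparable and never merge", {
  m <- rbind(c("12", ""), c("", "12"), c("12", ""))
  gt <- gt_from_strings(m)
  mm <- mismatch_matrix(gt)
  expect_true(mm$incomparable[1, 2])
  ca <- cluster_samples(mm, h = 0)
  grp <- ca$assignment$individual
  expect_false(grp[1] == grp[2])
  expect_equal(grp[1], grp[3])   # identical genotypes merge at h = 0
})

test_that("cutting at h = 0 yields genotype-identity classes; h >= max yields one group", {
  set.seed(29)
  base <- matrix(sample(c("11", "12", "22"), 30, replace = TRUE), 3, 10)
  m <- base[c(1, 1, 2, 2, 3), ]
  gt <- gt_from_strings(m)
  mm <- mismatch_matrix(gt)
  ca0 <- cluster_samples(mm, 0)
  grp <- ca0$assignment$individual[match(gt$meta$sample_id,
                                         ca0$assignment$sample_id)]
  expect_equal(grp[1], grp[2])
  expect_equal(grp[3], grp[4])
  expect_false(grp[1] == grp[3])
  ca_all <- cluster_samples(mm, max(mm$mismatch))
  expect_equal(length(ca_all$sizes), 1L)
  expect_error(cluster_samples(mm, -1), ">= 0")
})

test_that("the partition is invariant to sample order", {
  set.seed(31)
  m <- matrix(sample(c("11", "12", "22"), 60, replace = TRUE), 6, 10)
  gt <- gt_from_strings(m)
  perm <- c(4, 2, 6, 1, 3, 5)
  gtp <- gt_subset(gt, perm, NULL)
  a <- cluster_samples(mismatch_matrix(gt), 2)$assignment
  b <- cluster_samples(mismatch_matrix(gtp), 2)$assignment
  b <- b[match(a$sample_id, b$sample_id), ]
  # same partition: co-membership identical
  same_a <- outer(a$individual, a$individual, "==")
  same_b <- outer(b$individual, b$individual, "==")
  expect_equal(same_a, same_b)
})

test_that("zero-noise samples cluster perfectly below the between-individual minimum", {
  set.seed(37)
  smp <- make_survey_samples(20, extras = rep(1, 6))
  pop <- data.frame(id = unique(smp$individual))
  tg <- simulate_genotypes(pop, snp_loci(30, 0.5), seed = 41)
  gt <- simulate_genotyping(tg, smp, noise_model(0, 0, 0, 0, 1L), seed = 43)
  cons <- consensus_table(gt)
  mm <- mismatch_matrix(cons)
  truth <- smp
  same_true <- outer(truth$individual, truth$individual, "==")
  between_min <- min(mm$mismatch[!same_true])
  for (h in c(0, floor(between_min / 2), between_min - 1)) {
    ca <- cluster_samples(mm, h)
    expect_equal(assignment_accuracy(ca, truth), 1)
    expect_equal(length(ca$sizes), 20L)
  }
})

test_that("threshold diagnostics sweep is monotone with sensible percentiles", {
  set.seed(47)
  smp <- make_survey_samples(12, extras = rep(2, 6))
  pop <- data.frame(id = unique(smp$individual))
  tg <- simulate_genotypes(pop, snp_loci(40, 0.5), seed = 53)
  gt <- simulate_genotyping(tg, smp, noise_preset("snp"), seed = 59)
  cons <- consensus_table(gt)
  mm <- mismatch_matrix(cons)
  diag <- cluster_diagnostics(mm, h_max = 10)
  expect_false(diag$degenerate)
  expect_true(all(diff(diag$elbow$n_groups) <= 0))
  # well-separated clusters: no overlap at the suggested threshold
  expect_false(is.na(diag$suggested_h))
  at <- diag$elbow[diag$elbow$h == diag$suggested_h, ]
  expect_false(at$overlap)
  expect_true(at$within_q < at$between_q)
  # single sample: degenerate
  one <- cluster_diagnostics(mismatch_matrix(gt_from_strings(rbind("12"))))
  expect_true(one$degenerate)
})

test_that("capture histories balance detections, individuals and recaptures", {
  lay <- toy_layout(c(0, 150, 300), 0, n_occ = 2L)
  assign <- data.frame(sample_id = sprintf("S%d", 1:5),
                       individual = c("A", "A", "B", "C", "A"))
  meta <- data.frame(sample_id = sprintf("S%d", 1:5),
                     session = "s1",
                     occasion = c(1, 1, 1, 2, 2),
                     detector = c("T01", "T01", "T02", "T03", "T02"))
  ch <- build_capture_history(assign, meta, lay)
  expect_equal(ch$n_detections, 5L)
  expect_equal(ch$n_individuals, 3L)
  expect_equal(ch$n_recaptures, 2L)
  expect_equal(ch$n_detections, ch$n_individuals + ch$n_recaptures)
  # brute-force group-by: A at T01/occ1 pooled to count 2
  a11 <- ch$detections[ch$detections$individual == "A" &
                         ch$detections$occasion == 1, ]
  expect_equal(a11$count, 2L)
  # single sample: one detection, zero recaptures
  ch1 <- build_capture_history(assign[1, ], meta[1, ], lay)
  expect_equal(ch1$n_detections, 1L)
  expect_equal(ch1$n_recaptures, 0L)
})

test_that("samples at unsearched detector-occasions are rejected", {
  lay <- toy_layout(c(0, 150), 0, n_occ = 2L)
  attr(lay, "usage")[[1]][2, 2] <- 0L
  assign <- data.frame(sample_id = "S1", individual = "A")
  bad <- data.frame(sample_id = "S1", session = "s1", occasion = 2,
                    detector = "T02")
  expect_error(build_capture_history(assign, bad, lay), "unsearched")
  ok <- data.frame(sample_id = "S1", session = "s1", occasion = 1,
                   detector = "T02")
  expect_silent(build_capture_history(assign, ok, lay))
})

test_that("recapture distances enumerate all unordered detection pairs", {
  lay <- toy_layout(c(0, 150, 450), 0, n_occ = 3L)
  assign <- data.frame(sample_id = sprintf("S%d", 1:4),
                       individual = c("A", "A", "B", "B"))
  meta <- data.frame(sample_id = sprintf("S%d", 1:4), session = "s1",
                     occasion = c(1, 2, 1, 2),
                     detector = c("T01", "T02", "T03", "T03"))
  ch <- build_capture_history(assign, meta, lay)
  rd <- recapture_distances(ch)
  expect_setequal(rd$distances, c(150, 0))
  expect_equal(rd$mean, 75)
  expect_equal(rd$share_near, 1)   # 0 m and 150 m are both below 200 m
  # all detections at one detector: all distances zero
  meta2 <- within(meta, detector <- "T01")
  rd2 <- recapture_distances(build_capture_history(assign, meta2, lay))
  expect_true(all(rd2$distances == 0))
  # brute-force enumeration on a multi-count toy
  assign3 <- data.frame(sample_id = sprintf("S%d", 1:3),
                        individual = "A")
  meta3 <- data.frame(sample_id = sprintf("S%d", 1:3), session = "s1",
                      occasion = 1, detector = c("T01", "T02", "T03"))
  rd3 <- recapture_distances(build_capture_history(assign3, meta3, lay))
  expect_setequal(rd3$distances, c(150, 450, 300))
})

test_that("assignment concordance classifies match, split and different", {
  a <- data.frame(sample_id = sprintf("S%d", 1:6),
                  individual = c("g1", "g1", "g2", "g2", "g3", "g4"))
  # method B: splits g1, matches g2, merges g3+g4
  b <- data.frame(sample_id = sprintf("S%d", 1:6),
                  individual = c("h1", "h2", "h3", "h3", "h4", "h4"))
  cc <- concordance(a, b)
  cats <- cc$by_sample$category
  expect_equal(cats[1:2], c("split", "split"))
  expect_equal(cats[3:4], c("match", "match"))
  expect_equal(cats[5:6], c("split", "split"))
  # identical partitions: all match
  cc2 <- concordance(a, a)
  expect_true(all(cc2$by_sample$category == "match"))
  expect_equal(unname(cc2$shares["match"]), 1)
  # cross-cutting groups are "different"
  a3 <- data.frame(sample_id = sprintf("S%d", 1:4),
                   individual = c("g1", "g1", "g2", "g2"))
  b3 <- data.frame(sample_id = sprintf("S%d", 1:4),
                   individual = c("h1", "h2", "h2", "h1"))
  expect_true(all(concordance(a3, b3)$by_sample$category == "different"))
  expect_error(concordance(a, data.frame(sample_id = "zz",
                                         individual = "q")), "no shared")
})

test_that("chi-square association on a 2x2 toy equals hand computation", {
  a <- data.frame(sample_id = sprintf("S%d", 1:8),
                  individual = c("g1", "g1", "g2", "g3", "g4", "g5",
                                 "g6", "g7"))
  b <- data.frame(sample_id = sprintf("S%d", 1:8),
                  individual = c("h1", "h2", "h3", "h4", "h5", "h6",
                                 "h7", "h8"))
  cov <- data.frame(sample_id = sprintf("S%d", 1:8),
                    err = c(0.3, 0.25, 0.02, 0.01, 0.3, 0.01, 0.02, 0.28))
  cc <- concordance(a, b, covariates = cov)
  tab <- table(cc$by_sample$category == "match",
               cov$err > stats::median(cov$err))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq_hand <- sum((tab - e)^2 / e)
  expect_equal(cc$associations$chisq, chisq_hand, tolerance = 1e-12)
})

test_that("representative genotypes prefer later sessions then amplification", {
  m <- rbind(c("12", "12", "12"),   # S1: amp 1, session 2020
             c("12", "12", ""),     # S2: amp 2/3, session 2021
             c("11", "", ""))       # S3: other individual
  gt <- gt_from_strings(m)
  gt$meta$session <- c("2020", "2021", "2020")
  assign <- data.frame(sample_id = c("S01", "S02", "S03"),
                       individual = c("A", "A", "B"))
  rep_gt <- representative_genotypes(gt, assign)
  picked <- rep_gt$meta$source_sample[rep_gt$meta$sample_id == "A"]
  expect_equal(picked, "S02")   # 2021 preferred despite lower amplification
  rep_gt2 <- representative_genotypes(gt, assign,
                                      prefer_last_session = FALSE)
  expect_equal(rep_gt2$meta$source_sample[rep_gt2$meta$sample_id == "A"],
               "S01")
})
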