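test_that("mask area agrees with a fine-grid geometric oracle", {
  land <- simulate_landscape(sim_config())
  lay <- land$layout
  mask <- build_mask(lay, land$habitat, buffer = 600, spacing = 100)
  area <- nrow(mask) * attr(mask, "cell_area")
  # oracle: same disc-union region measured on a 4x finer grid
  fine <- build_mask(lay, NULL, buffer = 600, spacing = 25)
  area_fine <- nrow(fine) * attr(fine, "cell_area")
  expect_lt(abs(area - area_fine) / area_fine, 0.01)
  # every cell carries one of the four vegetation categories
  expect_true(all(mask$habitat %in% sim_config()$habitat_categories))
  expect_error(build_mask(lay, NULL, buffer = -5), "buffer")
})

test_that("suggested buffer tracks the simulated movement scale", {
  cfg <- sim_config(margin = 0)
  land <- simulate_landscape(cfg)
  lay <- land$layout
  buffers <- vapply(c(50, 100, 200), function(sig) {
    pop <- simulate_population(land$habitat,
                               c(bare = 0.15, dense_shrubland = 0.15,
                                 scattered_shrubland = 0.15,
                                 dense_mulga = 0.15), seed = 89)
    det <- simulate_detections(pop, lay, det_params("HN", 0.8, sig),
                               seed = 97)
    as.numeric(suggest_buffer(history_from_detections(det, lay)))
  }, numeric(1))
  expect_true(all(diff(buffers) > 0))
  # all detections at one detector: fallback with warning
  assign <- data.frame(sample_id = c("S1", "S2"), individual = "A")
  meta <- data.frame(sample_id = c("S1", "S2"), session = "2020",
                     occasion = c(1, 2), detector = "D001")
  ch1 <- build_capture_history(assign, meta, lay)
  expect_warning(b <- suggest_buffer(ch1), "fallback|spacing")
  expect_gt(b, 0)
})

test_that("the likelihood matches fine quadrature on a two-detector toy", {
  lay <- toy_layout(c(-50, 50), c(0, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session,individual,occasion,detector,count",
               "s1,I1,1,T01,2", "s1,I1,1,T02,1"), path)
  ch <- read_capture_history(path, lay)
  mask <- build_mask(lay, NULL, buffer = 500, spacing = 10)
  fine <- build_mask(lay, NULL, buffer = 500, spacing = 1)
  th <- c(log(0.05), log(0.4), log(120))
  for (fam in c("HN", "EX", "HR")) {
    thf <- if (fam == "HR") c(th, log(2)) else th
    v <- secr_nll(thf, history = ch, mask = mask, family = fam)
    v_fine <- secr_nll(thf, history = ch, mask = fine, family = fam)
    expect_lt(abs(v - v_fine), 1e-4)
  }
  # refining spacing 2x changes the NLL by < 0.1%
  half <- build_mask(lay, NULL, buffer = 500, spacing = 5)
  v10 <- secr_nll(th, history = ch, mask = mask, family = "HN")
  v5 <- secr_nll(th, history = ch, mask = half, family = "HN")
  expect_lt(abs(v10 - v5) / abs(v5), 0.001)
})

test_that("zero detection intensity gives an infinite likelihood", {
  lay <- toy_layout(0, 0)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session,individual,occasion,detector,count",
               "s1,I1,1,T01,1"), path)
  ch <- read_capture_history(path, lay)
  mask <- build_mask(lay, NULL, buffer = 300, spacing = 50)
  expect_true(is.infinite(secr_nll(c(log(0.05), -Inf, log(100)),
                                   history = ch, mask = mask)))
})

test_that("multisession likelihood is the sum of per-session likelihoods", {
  lay2 <- data.frame(detector_id = c("T01", "T02"), x = c(-50, 50), y = 0)
  attr(lay2, "usage") <- list(
    a = matrix(1L, 2, 2, dimnames = list(lay2$detector_id, NULL)),
    b = matrix(1L, 2, 1, dimnames = list(lay2$detector_id, NULL)))
  mask <- build_mask(lay2, NULL, buffer = 400, spacing = 25)
  mk_hist <- function(lines) {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("session,individual,occasion,detector,count", lines),
               path, sep = "\n")
    read_capture_history(path, lay2)
  }
  both <- mk_hist(c("a,I1,1,T01,1", "a,I1,2,T02,2", "b,I2,1,T02,1"))
  th <- c(log(0.04), log(0.3), log(100))
  v_both <- secr_nll(th, history = both, mask = mask)
  lay_a <- lay2; attr(lay_a, "usage") <- attr(lay2, "usage")["a"]
  lay_b <- lay2; attr(lay_b, "usage") <- attr(lay2, "usage")["b"]
  ha <- mk_hist(c("a,I1,1,T01,1", "a,I1,2,T02,2"))
  ha$layout <- lay_a; ha$sessions <- "a"
  hb <- mk_hist("b,I2,1,T02,1")
  hb$layout <- lay_b; hb$sessions <- "b"
  v_a <- secr_nll(th, history = ha, mask = mask)
  v_b <- secr_nll(th, history = hb, mask = mask)
  expect_equal(v_both, v_a + v_b, tolerance = 1e-10)
})

test_that("likelihood is invariant to mask-cell and detector ordering", {
  land <- simulate_landscape(sim_config(margin = 0))
  lay <- land$layout
  pop <- simulate_population(land$habitat,
                             c(bare = 0.1, dense_shrubland = 0.1,
                               scattered_shrubland = 0.1,
                               dense_mulga = 0.1), seed = 101)
  det <- simulate_detections(pop, lay, det_params("HN", 0.5, 150),
                             seed = 103)
  ch <- history_from_detections(det, lay)
  mask <- build_mask(lay, NULL, buffer = 500, spacing = 150)
  th <- c(log(0.03), log(0.4), log(150))
  v1 <- secr_nll(th, history = ch, mask = mask)
  # permute detectors (and usage rows accordingly)
  perm <- sample(nrow(lay))
  lay_p <- lay[perm, ]
  attr(lay_p, "usage") <- lapply(attr(lay, "usage"),
                                 function(u) u[perm, , drop = FALSE])
  ch_p <- ch; ch_p$layout <- lay_p
  v2 <- secr_nll(th, history = ch_p, mask = mask)
  # permute mask cells
  mask_p <- mask[sample(nrow(mask)), ]
  for (at in c("spacing", "cell_area", "buffer"))
    attr(mask_p, at) <- attr(mask, at)
  v3 <- secr_nll(th, history = ch, mask = mask_p)
  expect_equal(v1, v2, tolerance = 1e-10)
  expect_equal(v1, v3, tolerance = 1e-10)
})

test_that("fitting recovers the generating model on simulated data", {
  cfg <- sim_config(margin = 0, spacing = 150)
  land <- simulate_landscape(cfg)
  lay <- land$layout
  mask <- build_mask(lay, NULL, buffer = 600, spacing = 150)
  Dtrue <- 50 / (nrow(mask) * attr(mask, "cell_area"))
  pop <- simulate_population(mask, c(all = Dtrue), seed = 107)
  det <- simulate_detections(pop, lay, det_params("HN", 0.6, 150),
                             seed = 109)
  ch <- history_from_detections(det, lay)
  fit <- fit_secr(ch, mask, ~1, "HN")
  expect_true(fit$convergence)
  Dhat <- fit$estimates$estimate[1]
  seD <- sqrt(fit$vcov[1, 1])
  ci <- exp(log(Dhat) + c(-1.96, 1.96) * seD)
  expect_gt(Dtrue, ci[1] * 0.5)    # estimate in the right ballpark
  expect_lt(abs(Dhat - Dtrue) / Dtrue, 0.6)
  # HN-generated data: HN beats EX by AICc in most replicates
  wins <- vapply(1:6, function(r) {
    popr <- simulate_population(mask, c(all = Dtrue), seed = 200 + r)
    detr <- simulate_detections(popr, lay, det_params("HN", 0.6, 150),
                                seed = 300 + r)
    chr <- history_from_detections(detr, lay)
    fhn <- fit_secr(chr, mask, ~1, "HN")
    fex <- fit_secr(chr, mask, ~1, "EX")
    fhn$AICc < fex$AICc
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("AICc arithmetic and ranking table behave as specified", {
  expect_equal(aicc(-100, 4, 59), 200 + 8 + 40 / 54)
  expect_equal(aicc(-100, 4, 59), 208.7407, tolerance = 1e-6)
  expect_error(aicc(-100, 4, 5), "undefined")
  mk_fit <- function(ll, K, id = "x") {
    structure(list(logLik = ll, K = K, AICc = aicc(ll, K, 59),
                   D = ~1, detfn = "HN", data_id = id),
              class = "secr_fit")
  }
  tab <- aicc_table(mk_fit(-100, 4), mk_fit(-99, 6), mk_fit(-90, 8))
  expect_equal(tab$dAICc[1], 0)
  expect_true(all(diff(tab$AICc) >= 0))
  # single model: dAICc = 0
  expect_equal(aicc_table(mk_fit(-100, 4))$dAICc, 0)
  # the 5-unit similarity window
  expect_equal(tab$similar, tab$dAICc < 5)
  expect_error(aicc_table(mk_fit(-100, 4, "x"), mk_fit(-100, 4, "y")),
               "different datasets")
})

test_that("abundance is the density-area sum product with delta-method SE", {
  cfg <- sim_config(margin = 0, spacing = 150)
  land <- simulate_landscape(cfg)
  lay <- land$layout
  mask <- build_mask(lay, NULL, buffer = 500, spacing = 150)
  Dtrue <- 60 / (nrow(mask) * attr(mask, "cell_area"))
  pop <- simulate_population(mask, c(all = Dtrue), seed = 113)
  det <- simulate_detections(pop, lay, det_params("HN", 0.6, 150),
                             seed = 127)
  ch <- history_from_detections(det, lay)
  fit <- fit_secr(ch, mask, ~1, "HN")
  ab <- abundance(fit)
  tot <- ab[ab$habitat == "TOTAL" & ab$session == "2020", ]
  # single-habitat homogeneous density: N = D x A exactly
  area <- nrow(mask) * attr(mask, "cell_area")
  expect_equal(tot$N, fit$estimates$estimate[1] * area, tolerance = 1e-8)
  # delta-method SE vs parametric bootstrap through the coefficient
  # covariance (log-normal density coefficient)
  set.seed(131)
  draws <- stats::rnorm(1000, fit$beta[1], sqrt(fit$vcov[1, 1]))
  boot_se <- stats::sd(exp(draws) * area)
  expect_lt(abs(tot$se - boot_se) / boot_se, 0.2)
  # non-converged fits are refused
  bad <- fit; bad$convergence <- FALSE
  expect_error(abundance(bad), "converge")
})

test_that("flat detection at large sigma makes HN and EX agree", {
  lay <- toy_layout(c(-50, 50), c(0, 0), n_occ = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session,individual,occasion,detector,count",
               "s1,I1,1,T01,1", "s1,I1,2,T02,1"), path)
  ch <- read_capture_history(path, lay)
  mask <- build_mask(lay, NULL, buffer = 200, spacing = 20)
  th_flat <- function(fam) c(log(0.02), log(0.3), log(1e7))
  v_hn <- secr_nll(th_flat("HN"), history = ch, mask = mask, family = "HN")
  v_ex <- secr_nll(th_flat("EX"), history = ch, mask = mask, family = "EX")
  expect_equal(v_hn, v_ex, tolerance = 1e-3)
})
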