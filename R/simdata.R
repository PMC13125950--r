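#' Simulation configuration for a transect-based scat survey
#'
#' Describes the survey geometry and session structure that the
#' generator emulates: a fenced reserve searched along parallel
#' transects of regularly spaced scat-collection plots ("detectors"),
#' over one or more annual sessions each comprising one or more search
#' occasions. Defaults reproduce a 9-transect, 99-detector design with
#' 150 m spacing along and 500 m between transects, three occasions in
#' the first session and one in the second, and a four-category
#' vegetation mosaic.
#'
#' @param n_transects number of parallel transects.
#' @param points_per_transect detectors per transect.
#' @param point_spacing metres between detectors along a transect.
#' @param transect_spacing metres between transects.
#' @param habitat_categories labels of the habitat mosaic.
#' @param habitat_shares expected area share per category (sums to 1).
#' @param sessions named integer vector: occasions per session label.
#' @param margin metres of habitat map extending beyond the detector
#'   array on every side.
#' @param spacing metres between habitat-map grid cell centres.
#' @param rng_seed integer seed used by [simulate_landscape()] for the
#'   habitat mosaic.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_transects = 9L,
                       points_per_transect = 11L,
                       point_spacing = 150,
                       transect_spacing = 500,
                       habitat_categories = c("bare", "dense_shrubland",
                                              "scattered_shrubland",
                                              "dense_mulga"),
                       habitat_shares = c(0.15, 0.20, 0.50, 0.15),
                       sessions = c("2020" = 3L, "2021" = 1L),
                       margin = 600,
                       spacing = 100,
                       rng_seed = 1L) {
  if (n_transects < 1 || points_per_transect < 1)
    stop("configuration error: zero detectors")
  if (point_spacing <= 0 || transect_spacing <= 0 || spacing <= 0)
    stop("spacing values must be strictly positive")
  if (length(sessions) < 1 || any(sessions < 1))
    stop("at least one session with >= 1 occasion required")
  if (length(habitat_shares) != length(habitat_categories))
    stop("one share per habitat category required")
  habitat_shares <- habitat_shares / sum(habitat_shares)
  structure(list(n_transects = as.integer(n_transects),
                 points_per_transect = as.integer(points_per_transect),
                 point_spacing = point_spacing,
                 transect_spacing = transect_spacing,
                 habitat_categories = habitat_categories,
                 habitat_shares = habitat_shares,
                 sessions = sessions,
                 margin = margin, spacing = spacing,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Generate a detector layout and habitat mosaic
#'
#' Detectors are laid on parallel transects (x along transects, y
#' across). The habitat map is a regular grid whose cells take
#' categories from a seeded Voronoi tessellation: random seed points
#' are assigned categories with probabilities equal to the configured
#' shares and every cell inherits the category of its nearest seed,
#' giving contiguous patches rather than salt-and-pepper noise.
#'
#' @param config a [sim_config()].
#' @param n_patch_seeds number of Voronoi seed points.
#' @return A list with elements `layout` (data frame `detector_id, x,
#'   y, habitat` with a `usage` attribute: per-session 0/1 matrices of
#'   detectors x occasions) and `habitat` (data frame `x, y, habitat`
#'   with `spacing` and `cell_area` (ha) attributes).
#' @export
simulate_landscape <- function(config = sim_config(), n_patch_seeds = 45L) {
  set.seed(config$rng_seed)
  nx <- config$points_per_transect; ny <- config$n_transects
  det <- expand.grid(px = seq_len(nx), py = seq_len(ny))
  layout <- data.frame(
    detector_id = sprintf("D%03d", seq_len(nrow(det))),
    x = (det$px - 1) * config$point_spacing,
    y = (det$py - 1) * config$transect_spacing,
    stringsAsFactors = FALSE)

  m <- config$margin
  xr <- range(layout$x) + c(-m, m)
  yr <- range(layout$y) + c(-m, m)
  sp <- config$spacing
  gx <- seq(xr[1] + sp / 2, xr[2], by = sp)
  gy <- seq(yr[1] + sp / 2, yr[2], by = sp)
  grid <- expand.grid(x = gx, y = gy)

  seeds <- data.frame(x = stats::runif(n_patch_seeds, xr[1], xr[2]),
                      y = stats::runif(n_patch_seeds, yr[1], yr[2]),
                      habitat = sample(config$habitat_categories,
                                       n_patch_seeds, replace = TRUE,
                                       prob = config$habitat_shares))
  nearest <- nearest_index(grid$x, grid$y, seeds$x, seeds$y)
  grid$habitat <- seeds$habitat[nearest]

  layout$habitat <- grid$habitat[nearest_index(layout$x, layout$y,
                                               grid$x, grid$y)]
  usage <- lapply(config$sessions, function(k)
    matrix(1L, nrow(layout), k,
           dimnames = list(layout$detector_id, NULL)))
  names(usage) <- names(config$sessions)
  attr(layout, "usage") <- usage
  attr(grid, "spacing") <- sp
  attr(grid, "cell_area") <- sp * sp / 1e4   # hectares
  list(layout = layout, habitat = grid)
}

# index of nearest (rx, ry) point for each (x, y); chunked to bound memory
nearest_index <- function(x, y, rx, ry) {
  out <- integer(length(x))
  chunk <- 2000L
  for (i in seq(1, length(x), by = chunk)) {
    j <- i:min(i + chunk - 1L, length(x))
    d2 <- outer(x[j], rx, "-")^2 + outer(y[j], ry, "-")^2
    out[j] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Simulate activity centres from habitat-specific densities
#'
#' Draws an inhomogeneous Poisson point process whose intensity is
#' constant within each habitat category: per grid cell the count is
#' Poisson with mean density x cell area, and points are placed
#' uniformly within the cell.
#'
#' @param habitat habitat grid from [simulate_landscape()].
#' @param density_by_habitat named vector, animals per hectare.
#' @param seed integer seed.
#' @return data frame `id, x, y, habitat` of class `true_population`.
#' @export
simulate_population <- function(habitat, density_by_habitat, seed = 1L) {
  if (any(density_by_habitat < 0)) stop("densities must be >= 0")
  miss <- setdiff(unique(habitat$habitat), names(density_by_habitat))
  if (length(miss))
    stop("no density given for habitat: ", paste(miss, collapse = ", "))
  set.seed(seed)
  area <- attr(habitat, "cell_area")
  sp <- attr(habitat, "spacing")
  mu <- density_by_habitat[habitat$habitat] * area
  n <- stats::rpois(length(mu), mu)
  idx <- rep(seq_along(n), n)
  if (length(idx) == 0)
    return(structure(data.frame(id = character(), x = numeric(),
                                y = numeric(), habitat = character(),
                                stringsAsFactors = FALSE),
                     class = c("true_population", "data.frame")))
  pop <- data.frame(
    id = sprintf("I%04d", seq_along(idx)),
    x = habitat$x[idx] + stats::runif(length(idx), -sp / 2, sp / 2),
    y = habitat$y[idx] + stats::runif(length(idx), -sp / 2, sp / 2),
    habitat = habitat$habitat[idx],
    stringsAsFactors = FALSE)
  class(pop) <- c("true_population", "data.frame")
  pop
}

#' Simulate true multilocus genotypes
#'
#' Unrelated individuals are drawn in Hardy-Weinberg proportions from
#' the supplied allele frequencies. A fraction of individuals can be
#' regenerated as offspring of randomly paired parents by Mendelian
#' transmission (one allele from each parent per locus), providing
#' known first-order relatives for relatedness validation.
#'
#' @param pop a `true_population` (or anything with an `id` column).
#' @param loci named list of per-locus allele-frequency vectors
#'   (frequencies sum to 1; allele codes are the vector positions).
#' @param family_fraction fraction of individuals generated as
#'   offspring of pairs among the remainder.
#' @param seed integer seed.
#' @return A [geno_table()] with one run per individual
#'   (`sample_id` = individual id); parent-offspring links in the
#'   `pedigree` attribute.
#' @export
simulate_genotypes <- function(pop, loci, family_fraction = 0, seed = 1L) {
  if (length(loci) == 0) stop("empty locus set")
  bad <- vapply(loci, function(p) abs(sum(p) - 1) > 1e-9, logical(1))
  if (any(bad))
    stop("allele frequencies must sum to 1 at locus ",
         names(loci)[which(bad)[1]])
  set.seed(seed)
  ids <- pop$id
  n <- length(ids); L <- length(loci)
  a1 <- matrix(NA_integer_, n, L); a2 <- a1
  for (l in seq_len(L)) {
    p <- loci[[l]]
    a1[, l] <- sample.int(length(p), n, replace = TRUE, prob = p)
    a2[, l] <- sample.int(length(p), n, replace = TRUE, prob = p)
  }
  n_off <- floor(family_fraction * n)
  ped <- NULL
  if (n_off > 0) {
    if (n - n_off < 2) stop("too few founders for requested family_fraction")
    off <- (n - n_off + 1):n
    ped <- data.frame(id = ids[off],
                      parent1 = character(n_off), parent2 = character(n_off),
                      stringsAsFactors = FALSE)
    for (k in seq_along(off)) {
      pr <- sample(n - n_off, 2)
      for (l in seq_len(L)) {
        g1 <- c(a1[pr[1], l], a2[pr[1], l])
        g2 <- c(a1[pr[2], l], a2[pr[2], l])
        a1[off[k], l] <- g1[sample.int(2, 1)]
        a2[off[k], l] <- g2[sample.int(2, 1)]
      }
      ped$parent1[k] <- ids[pr[1]]; ped$parent2[k] <- ids[pr[2]]
    }
  }
  gt <- geno_table(a1, a2,
                   data.frame(sample_id = ids, replicate = 1L,
                              stringsAsFactors = FALSE),
                   names(loci))
  attr(gt, "pedigree") <- ped
  gt
}

#' Detection (distance-decay) parameters
#'
#' @param family `"HN"` (half-normal), `"HR"` (hazard rate) or `"EX"`
#'   (negative exponential).
#' @param lambda0 expected count per occasion at distance zero.
#' @param sigma spatial scale in metres.
#' @param z shape parameter, hazard-rate family only (must exceed 1).
#' @return list of class `det_params`.
#' @export
det_params <- function(family = c("HN", "HR", "EX"), lambda0 = 0.25,
                       sigma = 100, z = NULL) {
  family <- match.arg(family)
  if (lambda0 < 0) stop("lambda0 must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (family == "HR") {
    if (is.null(z)) z <- 3
    if (z <= 1) stop("hazard-rate shape z must exceed 1")
  } else z <- NULL
  structure(list(family = family, lambda0 = lambda0, sigma = sigma, z = z),
            class = "det_params")
}

# distance-decay kernel f(d) in [0, 1]; f(0) = 1
detect_kernel <- function(d, par) {
  switch(par$family,
         HN = exp(-d^2 / (2 * par$sigma^2)),
         EX = exp(-d / par$sigma),
         HR = 1 - exp(-(pmax(d, 1e-300) / par$sigma)^(-par$z)),
         stop("unknown detection family: ", par$family))
}

#' Simulate scat detections at count detectors
#'
#' Per individual, detector, session and searched occasion the number
#' of scats found is Poisson with mean `lambda0 * f(d)` where `d` is
#' the distance from the individual's activity centre to the detector
#' and `f` the chosen distance-decay shape. Unsearched
#' detector-occasions (usage 0) yield nothing.
#'
#' @param pop `true_population`.
#' @param layout detector layout from [simulate_landscape()].
#' @param detpar a [det_params()].
#' @param seed integer seed.
#' @param alive optional logical matrix individuals x sessions; rows of
#'   `pop`, columns the sessions of the layout usage. Default: all
#'   alive in every session.
#' @return data frame `sample_id, individual, session, occasion,
#'   detector, count` (one row per individual-detector-occasion with at
#'   least one scat).
#' @export
simulate_detections <- function(pop, layout, detpar = det_params(),
                                seed = 1L, alive = NULL) {
  usage <- attr(layout, "usage")
  if (is.null(usage)) stop("layout lacks a usage attribute")
  set.seed(seed)
  n <- nrow(pop)
  if (is.null(alive)) alive <- matrix(TRUE, n, length(usage))
  d <- sqrt(outer(pop$x, layout$x, "-")^2 + outer(pop$y, layout$y, "-")^2)
  lam <- detpar$lambda0 * detect_kernel(d, detpar)   # n x ndet
  out <- vector("list", 0)
  for (s in seq_along(usage)) {
    u <- usage[[s]]
    for (k in seq_len(ncol(u))) {
      live <- which(alive[, s])
      if (!length(live)) next
      mu <- lam[live, , drop = FALSE] *
        rep(u[, k], each = length(live))
      y <- matrix(stats::rpois(length(mu), mu), nrow = length(live))
      hit <- which(y > 0, arr.ind = TRUE)
      if (nrow(hit))
        out[[length(out) + 1]] <- data.frame(
          individual = pop$id[live[hit[, 1]]],
          session = names(usage)[s], occasion = k,
          detector = layout$detector_id[hit[, 2]],
          count = y[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), individual = character(),
                      session = character(), occasion = integer(),
                      detector = character(), count = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$session, res$occasion, res$detector, res$individual), ]
  res <- cbind(sample_id = sprintf("S%04d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  res
}

#' Genotyping noise model
#'
#' Parameters of the replicate genotyping-error process: whole-run
#' amplification failure, per-call missingness, allelic dropout of
#' heterozygotes, and false alleles. Presets reflect typical scat-DNA
#' error levels for a SNP panel (`ado = 0.045`, no false alleles) and
#' for microsatellites (`ado = 0.081`, `fa = 0.027`).
#'
#' @param p_sample_fail probability a run fails wholesale (its
#'   amplification drops below ~0.2).
#' @param p_locus_missing per-call missingness probability.
#' @param ado_rate per-heterozygous-call allelic dropout probability.
#' @param fa_rate per-call false-allele probability.
#' @param n_replicates genotyping runs per sample.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(p_sample_fail = 0.05, p_locus_missing = 0.2,
                        ado_rate = 0.045, fa_rate = 0, n_replicates = 2L) {
  p <- c(p_sample_fail, p_locus_missing, ado_rate, fa_rate)
  if (any(p < 0 | p > 1)) stop("noise probabilities must lie in [0, 1]")
  structure(list(p_sample_fail = p_sample_fail,
                 p_locus_missing = p_locus_missing,
                 ado_rate = ado_rate, fa_rate = fa_rate,
                 n_replicates = as.integer(n_replicates)),
            class = "noise_model")
}

#' @rdname noise_model
#' @param preset `"snp"` or `"msat"`.
#' @export
noise_preset <- function(preset = c("snp", "msat")) {
  switch(match.arg(preset),
         snp  = noise_model(p_sample_fail = 0.05, p_locus_missing = 0.20,
                            ado_rate = 0.045, fa_rate = 0),
         msat = noise_model(p_sample_fail = 0.03, p_locus_missing = 0.20,
                            ado_rate = 0.081, fa_rate = 0.027))
}

#' Simulate noisy replicate genotyping of scat samples
#'
#' Each scat sample yields `n_replicates` genotyping runs of its source
#' individual's true genotype, independently corrupted: whole-run
#' failure inflates missingness to ~0.9; otherwise each call is missing
#' with `p_locus_missing`; surviving heterozygous calls drop one allele
#' (chosen uniformly) with `ado_rate`; each surviving call substitutes
#' one allele with a uniformly chosen other allele of the locus with
#' `fa_rate`.
#'
#' @param true_gt [geno_table()] of true genotypes keyed by individual.
#' @param samples detection data frame from [simulate_detections()]
#'   (columns `sample_id`, `individual`, plus metadata carried through).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param allele_sets optional named list of allele codes per locus;
#'   defaults to alleles observed in `true_gt`.
#' @return A [geno_table()] of noisy replicated runs.
#' @export
simulate_genotyping <- function(true_gt, samples, noise = noise_model(),
                                seed = 1L, allele_sets = NULL) {
  set.seed(seed)
  idx <- match(samples$individual, true_gt$meta$sample_id)
  if (anyNA(idx)) stop("sample references unknown individual")
  L <- length(true_gt$loci)
  if (is.null(allele_sets))
    allele_sets <- lapply(seq_len(L), function(l)
      sort(unique(c(true_gt$a1[, l], true_gt$a2[, l]))))
  R <- noise$n_replicates
  nrun <- nrow(samples) * R
  a1 <- true_gt$a1[rep(idx, each = R), , drop = FALSE]
  a2 <- true_gt$a2[rep(idx, each = R), , drop = FALSE]
  # whole-run failure
  fail <- stats::runif(nrun) < noise$p_sample_fail
  pmiss <- matrix(ifelse(fail, 0.9, noise$p_locus_missing), nrun, L)
  # allelic dropout on heterozygous calls
  het <- !is.na(a1) & a1 != a2
  drop <- het & matrix(stats::runif(nrun * L) < noise$ado_rate, nrun, L)
  keep_first <- matrix(stats::runif(nrun * L) < 0.5, nrun, L)
  a1[drop & !keep_first] <- a2[drop & !keep_first]
  a2[drop & keep_first] <- a1[drop & keep_first]
  # false alleles: substitute one allele with another allele of the locus
  fa <- !is.na(a1) & matrix(stats::runif(nrun * L) < noise$fa_rate, nrun, L)
  if (any(fa)) {
    for (l in which(colSums(fa) > 0)) {
      alleles <- allele_sets[[l]]
      if (length(alleles) < 2) next
      rows <- which(fa[, l])
      which_allele <- stats::runif(length(rows)) < 0.5
      for (i in seq_along(rows)) {
        r <- rows[i]
        cur <- if (which_allele[i]) a1[r, l] else a2[r, l]
        new <- sample(setdiff(alleles, cur), 1)
        if (which_allele[i]) a1[r, l] <- new else a2[r, l] <- new
      }
    }
  }
  # missingness
  miss <- matrix(stats::runif(nrun * L), nrun, L) < pmiss
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  meta <- samples[rep(seq_len(nrow(samples)), each = R),
                  intersect(c("sample_id", "session", "occasion", "detector",
                              "individual"), names(samples)),
                  drop = FALSE]
  meta$replicate <- rep(seq_len(R), nrow(samples))
  gt <- geno_table(a1, a2, meta, true_gt$loci)
  gt
}

#' Generate idealized biallelic locus frequency sets
#'
#' @param n number of loci.
#' @param maf minor allele frequency (recycled).
#' @return named list of frequency vectors usable by
#'   [simulate_genotypes()] and [pid_curve()].
#' @export
snp_loci <- function(n, maf = 0.5) {
  maf <- rep(maf, length.out = n)
  out <- lapply(maf, function(p) c(1 - p, p))
  names(out) <- sprintf("SNP%03d", seq_len(n))
  out
}

#' Random multiallelic (microsatellite-like) locus frequency sets
#'
#' Dirichlet-distributed frequencies over `n_alleles` alleles.
#'
#' @param n number of loci.
#' @param n_alleles alleles per locus (recycled).
#' @param conc Dirichlet concentration; larger = more even.
#' @param seed integer seed.
#' @return named list of frequency vectors.
#' @export
msat_loci <- function(n, n_alleles = 4L, conc = 2, seed = 1L) {
  set.seed(seed)
  n_alleles <- rep(n_alleles, length.out = n)
  out <- lapply(n_alleles, function(k) {
    g <- stats::rgamma(k, conc)
    g / sum(g)
  })
  names(out) <- sprintf("MS%02d", seq_len(n))
  out
}

#' Simulate a complete scat-survey study
#'
#' Chains landscape, population, genotypes, detections and noisy
#' genotyping into one reproducible bundle with ground truth attached,
#' mirroring a two-session scat survey on a fenced reserve.
#'
#' @param config a [sim_config()].
#' @param density_by_habitat animals per hectare by habitat category.
#' @param loci named list of allele-frequency vectors.
#' @param detpar a [det_params()].
#' @param noise a [noise_model()].
#' @param family_fraction fraction of individuals simulated as
#'   offspring of pairs.
#' @param survival per-session survival probability applied between
#'   sessions (1 = closed across sessions).
#' @param seed master integer seed; stage seeds are derived from it.
#' @return list of class `sim_study`: `layout`, `habitat`, `pop`,
#'   `true_gt`, `samples`, `gt` (noisy runs), plus the inputs.
#' @export
simulate_study <- function(config = sim_config(),
                           density_by_habitat = c(
                             bare = 0.04, dense_shrubland = 0.06,
                             scattered_shrubland = 0.16, dense_mulga = 0.05),
                           loci = snp_loci(46, maf = 0.4),
                           detpar = det_params("HN", lambda0 = 0.6,
                                               sigma = 110),
                           noise = noise_preset("snp"),
                           family_fraction = 0.1,
                           survival = 0.85,
                           seed = 1L) {
  seeds <- derive_seeds(seed, 4L)
  config$rng_seed <- derive_seeds(seed, 5L)[5]
  land <- simulate_landscape(config)
  pop <- simulate_population(land$habitat, density_by_habitat, seeds[1])
  true_gt <- simulate_genotypes(pop, loci, family_fraction, seeds[2])
  ns <- length(config$sessions)
  alive <- matrix(TRUE, nrow(pop), ns)
  if (ns > 1 && survival < 1) {
    set.seed(seeds[4])
    for (s in 2:ns)
      alive[, s] <- alive[, s - 1] & (stats::runif(nrow(pop)) < survival)
  }
  samples <- simulate_detections(pop, land$layout, detpar, seeds[3],
                                 alive = alive)
  gt <- simulate_genotyping(true_gt, samples, noise, seeds[4])
  structure(list(layout = land$layout, habitat = land$habitat,
                 pop = pop, alive = alive, true_gt = true_gt,
                 samples = samples, gt = gt,
                 config = config, detpar = detpar, noise = noise,
                 density_by_habitat = density_by_habitat, seed = seed),
            class = "sim_study")
}

# deterministic sub-seeds below 2^31 derived from one master seed
derive_seeds <- function(seed, n) {
  (as.integer(seed) * 7919L + 104729L * seq_len(n)) %% 2147483629L
}
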