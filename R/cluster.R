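#' Pairwise allelic mismatch matrix
#'
#' For each sample pair, loci missing in either member are skipped;
#' each jointly scored locus contributes the size of the allele
#' multiset difference (AA vs AB = 1, AA vs BB = 2, AB vs AB = 0,
#' AB vs AC = 1). A companion matrix counts jointly scored loci; pairs
#' with none are flagged incomparable (`NA` mismatch).
#'
#' @param gt a [geno_table()] with one consensus genotype per sample.
#' @return list of class `mismatch_matrix`: `mismatch` (sample x
#'   sample), `shared` (jointly scored loci), `incomparable` (logical).
#' @export
mismatch_matrix <- function(gt) {
  if (anyDuplicated(gt$meta$sample_id))
    stop("one consensus genotype per sample required")
  n <- nrow(gt$a1)
  ids <- gt$meta$sample_id
  mm <- matrix(0, n, n, dimnames = list(ids, ids))
  sh <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(sh) <- rowSums(!is.na(gt$a1))
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    x1 <- gt$a1[i, ]; x2 <- gt$a2[i, ]
    y1 <- gt$a1[j, ]; y2 <- gt$a2[j, ]
    both <- !is.na(x1) & !is.na(y1)
    sh[i, j] <- sh[j, i] <- sum(both)
    if (!any(both)) {
      mm[i, j] <- mm[j, i] <- NA_real_
      next
    }
    direct <- (x1 == y1) + (x2 == y2)
    cross <- (x1 == y2) + (x2 == y1)
    m <- 2 - pmax(direct, cross)
    mm[i, j] <- mm[j, i] <- sum(m[both])
  }
  structure(list(mismatch = mm, shared = sh,
                 incomparable = is.na(mm) & !diag(n)),
            class = "mismatch_matrix")
}

#' Cluster samples into putative individuals
#'
#' Agglomerative hierarchical clustering on the mismatch matrix, cut at
#' height `h`: samples whose cluster merges at no more than `h` allelic
#' mismatches are declared the same individual. Incomparable pairs are
#' assigned the matrix maximum + 1 so they can never merge. Cluster
#' labels are canonical: renumbered by first sample in sample-id order,
#' so permuting input order cannot change the partition.
#'
#' @param mm a [mismatch_matrix()].
#' @param h maximum allelic mismatches for grouping (>= 0).
#' @param linkage `"complete"` (default; bounds within-group pairwise
#'   mismatches by construction), `"average"` or `"single"`.
#' @return list of class `cluster_assignment`: `assignment` data frame
#'   (`sample_id`, `individual`), `h`, `linkage`, `sizes`.
#' @export
cluster_samples <- function(mm, h, linkage = c("complete", "average",
                                               "single")) {
  if (h < 0) stop("h must be >= 0")
  linkage <- match.arg(linkage)
  d <- mm$mismatch
  if (any(mm$incomparable))
    d[is.na(d)] <- max(d, na.rm = TRUE) + 1
  n <- nrow(d)
  ids <- rownames(d)
  ord <- order(ids)
  d <- d[ord, ord]
  if (n == 1) {
    grp <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    grp <- stats::cutree(hc, h = h)
    names(grp) <- ids[ord]
  }
  # canonical labels: by first occurrence in sample-id order
  first <- !duplicated(grp)
  relabel <- stats::setNames(seq_len(sum(first)), grp[first])
  grp <- relabel[as.character(grp)]
  assignment <- data.frame(sample_id = sort(ids),
                           individual = sprintf("G%03d", unname(grp)),
                           stringsAsFactors = FALSE)
  sizes <- table(assignment$individual)
  structure(list(assignment = assignment, h = h, linkage = linkage,
                 sizes = sizes),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples -> %d individuals (h = %g, %s linkage)\n",
              nrow(x$assignment), length(x$sizes), x$h, x$linkage))
  invisible(x)
}

#' Threshold-selection diagnostics for mismatch clustering
#'
#' Sweeps the mismatch threshold `h` and reports the number of groups
#' at each value (the elbow curve) plus, at each `h`, the distributions
#' of pairwise mismatches within and between groups with percentile
#' markers (upper 0.995 within, lower 0.005 between) and an overlap
#' flag when the within marker reaches or exceeds the between marker.
#' Also returns an advisory `h`: the smallest value whose within
#' percentile lies strictly below the between percentile.
#'
#' @param mm a [mismatch_matrix()].
#' @param h_max largest threshold to sweep (default: matrix maximum).
#' @param linkage linkage method passed to [cluster_samples()].
#' @param within_q,between_q percentile levels (defaults 0.995, 0.005).
#' @return list of class `threshold_diagnostics`: `elbow` data frame
#'   (`h`, `n_groups`, `within_q`, `between_q`, `overlap`),
#'   `suggested_h`, `degenerate` flag.
#' @export
cluster_diagnostics <- function(mm, h_max = NULL,
                                linkage = "complete",
                                within_q = 0.995, between_q = 0.005) {
  d <- mm$mismatch
  n <- nrow(d)
  if (n < 2)
    return(structure(list(elbow = NULL, suggested_h = NA_real_,
                          degenerate = TRUE),
                     class = "threshold_diagnostics"))
  if (is.null(h_max)) h_max <- max(d, na.rm = TRUE)
  hs <- 0:h_max
  pairs_up <- upper.tri(d)
  rows <- lapply(hs, function(h) {
    ca <- cluster_samples(mm, h, linkage)
    grp <- ca$assignment$individual[match(rownames(d),
                                          ca$assignment$sample_id)]
    same <- outer(grp, grp, "==")
    within <- d[pairs_up & same]
    between <- d[pairs_up & !same]
    wq <- if (length(within)) stats::quantile(within, within_q,
                                              na.rm = TRUE, names = FALSE)
          else NA_real_
    bq <- if (length(between)) stats::quantile(between, between_q,
                                               na.rm = TRUE, names = FALSE)
          else NA_real_
    data.frame(h = h, n_groups = length(ca$sizes), within_q = wq,
               between_q = bq,
               overlap = !is.na(wq) & !is.na(bq) & wq >= bq)
  })
  elbow <- do.call(rbind, rows)
  ok <- which(!is.na(elbow$within_q) & !is.na(elbow$between_q) &
                elbow$within_q < elbow$between_q)
  suggested <- if (length(ok)) elbow$h[ok[1]] else NA_real_
  structure(list(elbow = elbow, suggested_h = suggested,
                 degenerate = FALSE),
            class = "threshold_diagnostics")
}

#' Build a spatial capture history from an assignment
#'
#' Aggregates scat samples to counts per individual x session x
#' occasion x detector. The number of detections equals the number of
#' samples (each sample is one detection event); recaptures are
#' detections beyond the first per individual, within and between
#' sessions.
#'
#' @param assignment a [cluster_assignment()] (or a data frame with
#'   `sample_id`, `individual`).
#' @param meta data frame with `sample_id`, `session`, `occasion`,
#'   `detector` for every assigned sample.
#' @param layout detector layout (with `usage` attribute) from
#'   [simulate_landscape()] or [read_layout()].
#' @return list of class `capture_history`: `detections` data frame
#'   (`individual, session, occasion, detector, count`), `layout`,
#'   `sessions`, `n_detections`, `n_individuals`, `n_recaptures`.
#' @export
build_capture_history <- function(assignment, meta, layout) {
  if (inherits(assignment, "cluster_assignment"))
    assignment <- assignment$assignment
  m <- merge(assignment, meta, by = "sample_id")
  if (nrow(m) < nrow(assignment))
    stop("metadata missing for some assigned samples")
  usage <- attr(layout, "usage")
  if (is.null(usage)) stop("layout lacks a usage attribute")
  di <- match(m$detector, layout$detector_id)
  if (anyNA(di)) stop("sample at unknown detector: ",
                      m$detector[which(is.na(di))[1]])
  si <- match(as.character(m$session), names(usage))
  if (anyNA(si)) stop("sample in unknown session: ",
                      m$session[which(is.na(si))[1]])
  for (r in seq_len(nrow(m))) {
    u <- usage[[si[r]]]
    if (m$occasion[r] < 1 || m$occasion[r] > ncol(u) ||
        u[di[r], m$occasion[r]] == 0)
      stop("sample ", m$sample_id[r], " at unsearched detector/occasion (",
           m$detector[r], ", occasion ", m$occasion[r], ")")
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(m))),
                          by = list(individual = m$individual,
                                    session = as.character(m$session),
                                    occasion = m$occasion,
                                    detector = m$detector),
                          FUN = sum)
  agg <- agg[order(agg$session, agg$individual, agg$occasion,
                   agg$detector), ]
  rownames(agg) <- NULL
  n_det <- sum(agg$count)
  n_ind <- length(unique(agg$individual))
  structure(list(detections = agg, layout = layout,
                 sessions = names(usage),
                 n_detections = n_det, n_individuals = n_ind,
                 n_recaptures = n_det - n_ind),
            class = "capture_history")
}

#' @export
print.capture_history <- function(x, ...) {
  cat(sprintf("capture_history: %d detections of %d individuals (%d recaptures) over %d sessions\n",
              x$n_detections, x$n_individuals, x$n_recaptures,
              length(x$sessions)))
  invisible(x)
}

#' Distances between recaptures
#'
#' Euclidean distances between all unordered pairs of detection events
#' of the same individual (counts expand to events), with a binned
#' summary.
#'
#' @param history a [capture_history()].
#' @param near,far metres defining the "near" and "far" summary bins
#'   (defaults 200 and 600).
#' @return list `distances` (numeric vector), `mean`, `range`,
#'   `share_near`, `share_far`.
#' @export
recapture_distances <- function(history, near = 200, far = 600) {
  det <- history$detections
  lay <- history$layout
  xi <- lay$x[match(det$detector, lay$detector_id)]
  yi <- lay$y[match(det$detector, lay$detector_id)]
  ev_x <- rep(xi, det$count); ev_y <- rep(yi, det$count)
  ev_id <- rep(det$individual, det$count)
  out <- numeric(0)
  for (id in unique(ev_id)) {
    w <- which(ev_id == id)
    if (length(w) < 2) next
    dd <- stats::dist(cbind(ev_x[w], ev_y[w]))
    out <- c(out, as.vector(dd))
  }
  if (!length(out))
    return(list(distances = numeric(0), mean = NA_real_,
                range = c(NA_real_, NA_real_), share_near = NA_real_,
                share_far = NA_real_))
  list(distances = out, mean = mean(out), range = range(out),
       share_near = mean(out < near), share_far = mean(out > far))
}

#' Concordance of two individual assignments
#'
#' Each sample shared by both assignments is classified by comparing
#' its co-member set under method A with that under method B: `match`
#' when the sets are identical, `split` when one set is a strict subset
#' of the other (grouped by one method, split by the other), and
#' `different` otherwise. Optional binary covariates are tested for
#' association with match status by chi-square.
#'
#' @param assign_a,assign_b [cluster_assignment()]s (or data frames
#'   with `sample_id`, `individual`).
#' @param covariates optional data frame with `sample_id` plus numeric
#'   covariate columns; each is binned at its median for the
#'   chi-square association with match status.
#' @return list of class `concordance`: `by_sample` data frame
#'   (`sample_id`, `category`), `shares` (proportions), and
#'   `associations` (per covariate: `chisq`, `p`).
#' @export
concordance <- function(assign_a, assign_b, covariates = NULL) {
  if (inherits(assign_a, "cluster_assignment")) assign_a <- assign_a$assignment
  if (inherits(assign_b, "cluster_assignment")) assign_b <- assign_b$assignment
  shared <- intersect(assign_a$sample_id, assign_b$sample_id)
  if (!length(shared)) stop("no shared samples between assignments")
  ga <- assign_a$individual[match(shared, assign_a$sample_id)]
  gb <- assign_b$individual[match(shared, assign_b$sample_id)]
  cat_of <- character(length(shared))
  for (i in seq_along(shared)) {
    A <- shared[ga == ga[i]]
    B <- shared[gb == gb[i]]
    cat_of[i] <- if (setequal(A, B)) "match"
    else if (all(A %in% B) || all(B %in% A)) "split"
    else "different"
  }
  by_sample <- data.frame(sample_id = shared, category = cat_of,
                          stringsAsFactors = FALSE)
  shares <- prop.table(table(factor(cat_of,
                                    levels = c("match", "split",
                                               "different"))))
  associations <- NULL
  if (!is.null(covariates)) {
    matchbin <- as.integer(cat_of == "match")
    associations <- lapply(setdiff(names(covariates), "sample_id"),
                           function(cv) {
      v <- covariates[[cv]][match(shared, covariates$sample_id)]
      ok <- !is.na(v)
      bins <- v[ok] > stats::median(v[ok])
      tab <- table(matchbin[ok], bins)
      if (any(dim(tab) < 2))
        return(data.frame(covariate = cv, chisq = NA_real_, p = NA_real_))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(covariate = cv, chisq = unname(ct$statistic),
                 p = ct$p.value)
    })
    associations <- do.call(rbind, associations)
  }
  structure(list(by_sample = by_sample, shares = shares,
                 associations = associations),
            class = "concordance")
}

#' Pick one representative genotype per individual
#'
#' For downstream population-genetic summaries: the sample with the
#' highest amplification, preferring a later-session sample when an
#' individual was detected in more than one session.
#'
#' @param gt consensus [geno_table()] (one run per sample).
#' @param assignment a [cluster_assignment()].
#' @param prefer_last_session prefer samples from the latest session.
#' @return A [geno_table()] with one run per individual (`sample_id`
#'   replaced by individual id; source sample kept in `source_sample`).
#' @export
representative_genotypes <- function(gt, assignment,
                                     prefer_last_session = TRUE) {
  if (inherits(assignment, "cluster_assignment"))
    assignment <- assignment$assignment
  amp <- rowMeans(!is.na(gt$a1))
  ind <- assignment$individual[match(gt$meta$sample_id,
                                     assignment$sample_id)]
  keep <- which(!is.na(ind))
  sess <- if (prefer_last_session && "session" %in% names(gt$meta))
    as.character(gt$meta$session) else rep("", nrow(gt$a1))
  pick <- vapply(unique(ind[keep]), function(g) {
    rows <- keep[ind[keep] == g]
    rows[order(sess[rows], amp[rows], decreasing = TRUE)][1]
  }, integer(1))
  sel <- gt_subset(gt, pick, NULL)
  sel$meta$source_sample <- sel$meta$sample_id
  sel$meta$sample_id <- unique(ind[keep])
  sel
}
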