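#' Build a habitat mask around a detector array
#'
#' Regular grid of potential activity-centre cells clipped to the
#' region within `buffer` metres of any detector. Each cell carries a
#' habitat category looked up (nearest cell centre) from a habitat
#' source; without one, a single `"all"` category is used.
#'
#' @param layout detector layout data frame (`detector_id, x, y`).
#' @param habitat optional habitat grid (`x, y, habitat`), e.g. from
#'   [simulate_landscape()].
#' @param buffer buffer width in metres (>= 0).
#' @param spacing mask cell spacing in metres (> 0).
#' @return data frame of class `habitat_mask` (`x, y, habitat`) with
#'   attributes `spacing`, `cell_area` (ha), `buffer`.
#' @export
build_mask <- function(layout, habitat = NULL, buffer = 400,
                       spacing = 100) {
  if (buffer < 0 || spacing <= 0) stop("buffer >= 0 and spacing > 0 required")
  xr <- range(layout$x) + c(-buffer, buffer)
  yr <- range(layout$y) + c(-buffer, buffer)
  gx <- seq(xr[1] + spacing / 2, xr[2], by = spacing)
  gy <- seq(yr[1] + spacing / 2, yr[2], by = spacing)
  grid <- expand.grid(x = gx, y = gy)
  # clip to buffered region around detectors
  keep <- logical(nrow(grid))
  chunk <- 4000L
  for (i in seq(1, nrow(grid), by = chunk)) {
    j <- i:min(i + chunk - 1L, nrow(grid))
    d2 <- outer(grid$x[j], layout$x, "-")^2 +
      outer(grid$y[j], layout$y, "-")^2
    keep[j] <- sqrt(apply(d2, 1, min)) <= buffer + 1e-9
  }
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0) stop("no mask cells; spacing too coarse for buffer")
  grid$habitat <- if (is.null(habitat)) "all" else
    habitat$habitat[nearest_index(grid$x, grid$y, habitat$x, habitat$y)]
  rownames(grid) <- NULL
  attr(grid, "spacing") <- spacing
  attr(grid, "cell_area") <- spacing^2 / 1e4
  attr(grid, "buffer") <- buffer
  class(grid) <- c("habitat_mask", "data.frame")
  grid
}

#' Suggest a mask buffer width from a capture history
#'
#' Initial spatial scale is estimated as the root pooled spatial
#' variance (RPSV) of within-individual detection locations; the
#' suggested buffer is four times that. Histories without spatial
#' recaptures fall back to four times the median nearest-detector
#' spacing, with a warning.
#'
#' @param history a [capture_history()].
#' @return buffer width in metres; the `sigma` attribute carries the
#'   RPSV estimate (`NA` on the fallback path).
#' @export
suggest_buffer <- function(history) {
  det <- history$detections
  if (is.null(det) || nrow(det) == 0) stop("empty capture history")
  lay <- history$layout
  x <- rep(lay$x[match(det$detector, lay$detector_id)], det$count)
  y <- rep(lay$y[match(det$detector, lay$detector_id)], det$count)
  id <- rep(det$individual, det$count)
  ss <- 0; df <- 0
  for (g in unique(id)) {
    w <- which(id == g)
    if (length(w) < 2) next
    ss <- ss + sum((x[w] - mean(x[w]))^2 + (y[w] - mean(y[w]))^2)
    df <- df + length(w) - 1
  }
  if (df == 0 || ss == 0) {
    dd <- as.matrix(stats::dist(cbind(lay$x, lay$y)))
    diag(dd) <- Inf
    sp <- stats::median(apply(dd, 1, min))
    warning("no spatial recaptures; falling back to 4 x median detector spacing")
    return(structure(4 * sp, sigma = NA_real_))
  }
  sigma <- sqrt(ss / (2 * df))
  structure(4 * sigma, sigma = sigma)
}

# ---- likelihood internals -------------------------------------------------

# precompute session-level pieces used by every likelihood evaluation
prepare_secr <- function(history, mask) {
  lay <- history$layout
  usage <- attr(lay, "usage")
  sessions <- history$sessions
  cell_area <- attr(mask, "cell_area")
  dist2 <- outer(mask$x, lay$x, "-")^2 + outer(mask$y, lay$y, "-")^2
  per_session <- lapply(seq_along(sessions), function(s) {
    u <- usage[[sessions[s]]]
    occ_used <- rowSums(u)                      # searched occasions per detector
    det <- history$detections[history$detections$session == sessions[s], ,
                              drop = FALSE]
    inds <- unique(det$individual)
    Y <- matrix(0, nrow(lay), length(inds),
                dimnames = list(lay$detector_id, inds))
    if (nrow(det)) {
      ij <- cbind(match(det$detector, lay$detector_id),
                  match(det$individual, inds))
      Y[ij] <- Y[ij] + det$count
    }
    const <- sum(lgamma(det$count + 1))
    list(occ_used = occ_used, Y = Y, n_ind = length(inds), const = const)
  })
  names(per_session) <- sessions
  list(dist2 = dist2, dist = sqrt(dist2), per_session = per_session,
       cell_area = cell_area, mask = mask, sessions = sessions,
       n_ind_total = length(unique(history$detections$individual)))
}

# log f(d) per family on the precomputed distance matrices
log_kernel <- function(prep, family, sigma, z) {
  switch(family,
         HN = -prep$dist2 / (2 * sigma^2),
         EX = -prep$dist / sigma,
         HR = log1p(-exp(-(pmax(prep$dist, 1e-12) / sigma)^(-z))),
         stop("unknown detection family: ", family))
}

# unpack transformed parameter vector
unpack_theta <- function(theta, n_beta, family) {
  list(beta = theta[seq_len(n_beta)],
       lambda0 = exp(theta[n_beta + 1]),
       sigma = exp(theta[n_beta + 2]),
       z = if (family == "HR") 1 + exp(theta[n_beta + 3]) else NULL)
}

#' Negative log likelihood of the count-detector SECR model
#'
#' Full likelihood with Poisson counts: activity centres form an
#' inhomogeneous Poisson process with density D(s) on the mask; given a
#' centre, counts at detector j on a searched occasion are Poisson with
#' mean `lambda0 * f(d(s, j))`. Per session,
#' \deqn{-\ell = \Lambda - \sum_i \log \int D(s) \prod_{jk}
#'   \mathrm{Pois}(y_{ijk}; u_{jk}\lambda_j(s))\, ds}
#' with \eqn{\Lambda = \int D(s)(1 - e^{-\sum_{jk} u_{jk}\lambda_j(s)})
#' ds}, integrals evaluated as sums over mask cells times cell area;
#' sessions are independent and their contributions add.
#'
#' @param theta transformed parameter vector: density coefficients
#'   (log link), `log(lambda0)`, `log(sigma)` and, for `"HR"`,
#'   `log(z - 1)`.
#' @param prep result of the internal preparation step (see
#'   [fit_secr()]); alternatively pass `history` and `mask`.
#' @param X density design matrix (mask cells stacked per session).
#' @param family detection function family.
#' @param history,mask used (with `D`) when `prep`/`X` are not given.
#' @param D density formula over `session` and `habitat` (default
#'   `~1`).
#' @return negative log likelihood (scalar; `Inf` when `lambda0` is 0
#'   with a non-empty history).
#' @export
secr_nll <- function(theta, prep = NULL, X = NULL, family = "HN",
                     history = NULL, mask = NULL, D = ~1) {
  if (is.null(prep)) {
    if (is.null(history) || is.null(mask))
      stop("supply either prep/X or history/mask")
    prep <- prepare_secr(history, mask)
    X <- secr_design(prep, D)
  }
  n_beta <- ncol(X)
  par <- unpack_theta(theta, n_beta, family)
  if (!is.finite(par$lambda0) || !is.finite(par$sigma)) return(1e10)
  n_cells <- nrow(prep$dist2)
  logf <- log_kernel(prep, family, par$sigma, par$z)
  a <- prep$cell_area
  nll <- 0
  for (s in seq_along(prep$per_session)) {
    ps <- prep$per_session[[s]]
    Dcell <- exp(X[(s - 1) * n_cells + seq_len(n_cells), , drop = FALSE] %*%
                   par$beta)[, 1]
    lam_tot <- par$lambda0 * (exp(logf) %*% ps$occ_used)[, 1]
    Lambda <- sum(Dcell * a * (1 - exp(-lam_tot)))
    nll <- nll + Lambda
    if (ps$n_ind == 0) next
    if (par$lambda0 <= 0) return(Inf)
    loglam <- log(par$lambda0) + logf
    ll <- loglam %*% ps$Y                    # cells x individuals
    ll <- ll - lam_tot                       # recycled down columns
    shift <- apply(ll, 2, max)
    Li <- colSums(Dcell * a * exp(sweep(ll, 2, shift)))
    if (any(Li <= 0) || any(!is.finite(Li))) return(1e10)
    nll <- nll - sum(log(Li) + shift) + ps$const
  }
  if (!is.finite(nll)) stop("non-finite likelihood at theta = ",
                            paste(signif(theta, 4), collapse = ", "))
  nll
}

# density design matrix: mask cells stacked session by session
secr_design <- function(prep, D) {
  cells <- prep$mask
  df <- do.call(rbind, lapply(prep$sessions, function(s)
    data.frame(session = s, habitat = cells$habitat,
               stringsAsFactors = FALSE)))
  df$session <- factor(df$session, levels = prep$sessions)
  df$habitat <- factor(df$habitat)
  vars <- all.vars(D)
  for (v in vars)
    if (nlevels(df[[v]]) < 2)
      stop("density covariate '", v, "' has fewer than 2 levels")
  stats::model.matrix(D, df)
}

#' Fit a spatially explicit capture-recapture model
#'
#' Maximizes the count-detector full likelihood ([secr_nll()]) by
#' quasi-Newton search on transformed scales (log-link density
#' coefficients, log lambda0, log sigma, log(z - 1)), with three
#' deterministic jittered restarts; the best converged likelihood
#' wins. Standard errors come from the inverse numeric Hessian.
#'
#' @param history a [capture_history()].
#' @param mask a [build_mask()] result.
#' @param D density formula: `~1`, `~session`, `~habitat` or
#'   `~habitat + session`.
#' @param detfn `"HN"`, `"HR"` or `"EX"`.
#' @param start optional named start values on the natural scale:
#'   `list(D = , lambda0 = , sigma = , z = )`.
#' @return object of class `secr_fit`: `beta` (transformed estimates),
#'   `vcov`, `estimates` (natural-scale table with SEs), `logLik`,
#'   `K`, `n`, `AICc`, `convergence`, plus model metadata.
#' @export
fit_secr <- function(history, mask, D = ~1, detfn = c("HN", "HR", "EX"),
                     start = NULL) {
  detfn <- match.arg(detfn)
  prep <- prepare_secr(history, mask)
  X <- secr_design(prep, D)
  n_beta <- ncol(X)
  area <- nrow(prep$mask) * prep$cell_area
  # heuristic starts
  if (is.null(start)) start <- list()
  D0 <- start$D %||% max(prep$n_ind_total / area, 1e-4)
  n_occ_total <- sum(vapply(prep$per_session,
                            function(p) max(p$occ_used), numeric(1)))
  lam0 <- start$lambda0 %||%
    max(sum(vapply(prep$per_session, function(p) sum(p$Y), numeric(1))) /
          max(prep$n_ind_total, 1) / max(n_occ_total, 1), 0.05)
  sig0 <- start$sigma %||% {
    sb <- suppressWarnings(try(suggest_buffer(history), silent = TRUE))
    s <- if (inherits(sb, "try-error")) NA_real_ else attr(sb, "sigma")
    if (is.na(s) || s <= 0) attr(mask, "spacing") * 2 else s
  }
  theta0 <- c(log(D0), rep(0, n_beta - 1), log(lam0), log(sig0))
  if (detfn == "HR") theta0 <- c(theta0, log((start$z %||% 3) - 1))
  jitters <- list(0 * theta0,
                  c(rep(0, n_beta), 0.5, -0.4,
                    if (detfn == "HR") 0 else NULL),
                  c(rep(0, n_beta), -0.5, 0.4,
                    if (detfn == "HR") 0 else NULL))
  best <- NULL
  for (jt in jitters) {
    fit <- try(stats::optim(theta0 + jt, secr_nll, prep = prep, X = X,
                            family = detfn, method = "BFGS",
                            control = list(maxit = 300, reltol = 1e-9)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  H <- try(stats::optimHess(best$par, secr_nll, prep = prep, X = X,
                            family = detfn), silent = TRUE)
  V <- if (inherits(H, "try-error")) NULL else
    tryCatch(solve(H), error = function(e) NULL)
  converged <- best$convergence == 0 && !is.null(V) &&
    all(is.finite(diag(V))) && all(diag(V) > 0)
  se_theta <- if (!is.null(V)) sqrt(pmax(diag(V), 0)) else
    rep(NA_real_, length(best$par))
  par <- unpack_theta(best$par, n_beta, detfn)
  nm <- c(paste0("D.", colnames(X)), "lambda0", "sigma",
          if (detfn == "HR") "z")
  est_nat <- c(exp(best$par[1]), best$par[seq_len(n_beta)][-1],
               par$lambda0, par$sigma, if (detfn == "HR") par$z)
  se_nat <- se_theta
  se_nat[1] <- exp(best$par[1]) * se_theta[1]
  se_nat[n_beta + 1] <- par$lambda0 * se_theta[n_beta + 1]
  se_nat[n_beta + 2] <- par$sigma * se_theta[n_beta + 2]
  if (detfn == "HR")
    se_nat[n_beta + 3] <- (par$z - 1) * se_theta[n_beta + 3]
  estimates <- data.frame(parameter = nm, estimate = est_nat, se = se_nat,
                          stringsAsFactors = FALSE)
  K <- length(best$par)
  n <- prep$n_ind_total
  ll <- -best$value
  aicc_val <- aicc(ll, K, n)
  structure(list(beta = best$par, vcov = V, estimates = estimates,
                 logLik = ll, K = K, n = n, AICc = aicc_val,
                 convergence = converged, optim_code = best$convergence,
                 D = D, detfn = detfn, n_beta = n_beta,
                 X = X, prep = prep, mask = mask,
                 data_id = digest_history(history)),
            class = "secr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1)`, with `n` the number
#' of distinct individuals (the sample-size convention used throughout
#' the SECR fits).
#'
#' @param logLik maximized log likelihood.
#' @param K number of estimated parameters.
#' @param n effective sample size.
#' @return numeric scalar.
#' @export
aicc <- function(logLik, K, n) {
  if (n <= K + 1) stop("AICc undefined for n <= K + 1")
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

# lightweight fingerprint used to refuse AICc comparison across datasets
digest_history <- function(history) {
  d <- history$detections
  paste(nrow(d), sum(d$count), length(unique(d$individual)),
        paste(history$sessions, collapse = "+"))
}

#' @export
print.secr_fit <- function(x, ...) {
  cat(sprintf("secr_fit: D %s, detectfn %s; logLik %.3f, K %d, n %d, AICc %.3f%s\n",
              deparse(x$D), x$detfn, x$logLik, x$K, x$n, x$AICc,
              if (x$convergence) "" else " [NOT CONVERGED]"))
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' AICc model-ranking table
#'
#' Ranks fits on the same data by AICc; the reported sample size is the
#' number of distinct individuals. Models within 5 AICc units of the
#' best are flagged as similarly supported.
#'
#' @param ... `secr_fit` objects, or a single list of them.
#' @param similar_window dAICc window for the "similar" flag
#'   (default 5).
#' @return data frame `model, detectfn, K, logLik, AICc, dAICc,
#'   similar`, sorted ascending by AICc.
#' @export
aicc_table <- function(..., similar_window = 5) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "secr_fit"))
    fits <- fits[[1]]
  ids <- vapply(fits, function(f) f$data_id, character(1))
  if (length(unique(ids)) > 1)
    stop("fits were made on different datasets")
  tab <- data.frame(
    model = vapply(fits, function(f) paste("D", deparse(f$D)), character(1)),
    detectfn = vapply(fits, function(f) f$detfn, character(1)),
    K = vapply(fits, function(f) f$K, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc), ]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  tab$similar <- tab$dAICc < similar_window
  rownames(tab) <- NULL
  tab
}

#' Abundance by session and habitat with delta-method SE
#'
#' Expected abundance is the sum product of fitted density and habitat
#' area: per session and habitat, `N = sum over cells of D(cell) x
#' cell area`; standard errors propagate the density-coefficient
#' covariance through the log link by the delta method.
#'
#' @param fit a converged [fit_secr()] result.
#' @param mask optionally override the fitting mask (must carry the
#'   same habitat categories).
#' @return data frame of class `abundance_estimate`: one row per
#'   session x habitat plus per-session `TOTAL` rows, with `density`
#'   (animals/ha), `area_ha`, `N`, `se`.
#' @export
abundance <- function(fit, mask = NULL) {
  if (!fit$convergence)
    stop("fit did not converge; refusing abundance estimate")
  if (is.null(mask)) mask <- fit$mask
  prep <- fit$prep
  n_cells <- nrow(mask)
  a <- attr(mask, "cell_area")
  beta <- fit$beta[seq_len(fit$n_beta)]
  Vb <- fit$vcov[seq_len(fit$n_beta), seq_len(fit$n_beta), drop = FALSE]
  out <- list()
  for (s in seq_along(prep$sessions)) {
    Xs <- fit$X[(s - 1) * n_cells + seq_len(n_cells), , drop = FALSE]
    Dcell <- exp(Xs %*% beta)[, 1]
    groups <- c(split(seq_len(n_cells), mask$habitat),
                list(TOTAL = seq_len(n_cells)))
    for (g in names(groups)) {
      idx <- groups[[g]]
      N <- sum(Dcell[idx]) * a
      grad <- crossprod(Xs[idx, , drop = FALSE], Dcell[idx] * a)
      se <- sqrt(max(t(grad) %*% Vb %*% grad, 0))
      out[[length(out) + 1]] <- data.frame(
        session = prep$sessions[s], habitat = g,
        density = mean(Dcell[idx]), area_ha = length(idx) * a,
        N = N, se = as.numeric(se), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("abundance_estimate", "data.frame")
  res
}
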