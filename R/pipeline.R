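#' Read and write detector layouts
#'
#' Tab-separated layout with columns `detector_id, x, y, habitat` plus
#' one `usage_<session>` column per session holding 0/1 occasion
#' strings (e.g. `"111"` = searched on all three occasions).
#'
#' @param path file path.
#' @return `read_layout`: a layout data frame with a `usage`
#'   attribute; `write_layout`: `path`, invisibly.
#' @export
read_layout <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  ucols <- grep("^usage_", names(df), value = TRUE)
  if (!length(ucols)) stop("layout lacks usage_<session> columns")
  usage <- lapply(ucols, function(cl) {
    s <- as.character(df[[cl]])
    k <- nchar(s[1])
    if (any(nchar(s) != k))
      stop("ragged usage strings in column ", cl)
    m <- matrix(as.integer(unlist(strsplit(s, ""))),
                nrow = length(s), ncol = k, byrow = TRUE)
    rownames(m) <- df$detector_id
    m
  })
  names(usage) <- sub("^usage_", "", ucols)
  layout <- df[setdiff(names(df), ucols)]
  attr(layout, "usage") <- usage
  layout
}

#' @rdname read_layout
#' @param layout layout data frame with a `usage` attribute.
#' @export
write_layout <- function(layout, path) {
  usage <- attr(layout, "usage")
  df <- as.data.frame(layout)
  for (s in names(usage))
    df[[paste0("usage_", s)]] <- apply(usage[[s]], 1, paste, collapse = "")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write capture-history CSV
#'
#' Columns `session, individual, occasion, detector, count`.
#'
#' @param path file path.
#' @param layout layout (with usage) to attach.
#' @return a [capture_history()].
#' @export
read_capture_history <- function(path, layout) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        comment.char = "#")
  req <- c("session", "individual", "occasion", "detector", "count")
  if (!all(req %in% names(df)))
    stop("capture-history CSV requires columns: ",
         paste(req, collapse = ", "))
  df$session <- as.character(df$session)
  usage <- attr(layout, "usage")
  structure(list(detections = df, layout = layout,
                 sessions = names(usage),
                 n_detections = sum(df$count),
                 n_individuals = length(unique(df$individual)),
                 n_recaptures = sum(df$count) -
                   length(unique(df$individual))),
            class = "capture_history")
}

#' @rdname read_capture_history
#' @param history a [capture_history()].
#' @export
write_capture_history <- function(history, path) {
  utils::write.csv(history$detections[
    c("session", "individual", "occasion", "detector", "count")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Thresholds and seeds for the full scat-to-abundance pipeline, with
#' per-stage sections. `pipeline_config()` supplies defaults;
#' `read_config()` loads a YAML file whose entries override them.
#'
#' @param qc list: `drop_floor`, `sample_floor`, `locus_floor`,
#'   `fill_floor`.
#' @param cluster list: `h`, `linkage`.
#' @param popgen list: `maf_cutoff`.
#' @param secr list: `buffer` (`NA` = suggest from data), `spacing`,
#'   `detfn` (families to try), `models` (density formulas as
#'   strings).
#' @param seed integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = list(), cluster = list(), popgen = list(),
                            secr = list(), seed = 1L) {
  defaults <- list(
    qc = list(drop_floor = 0.2, sample_floor = 0.7, locus_floor = 0.8,
              fill_floor = 0.2),
    cluster = list(h = 3, linkage = "complete"),
    popgen = list(maf_cutoff = 0.02),
    secr = list(buffer = NA_real_, spacing = 100, detfn = "HN",
                models = c("~1")),
    seed = seed)
  merge_list <- function(a, b) {
    for (nm in names(b)) a[[nm]] <- b[[nm]]
    a
  }
  cfg <- defaults
  cfg$qc <- merge_list(cfg$qc, qc)
  cfg$cluster <- merge_list(cfg$cluster, cluster)
  cfg$popgen <- merge_list(cfg$popgen, popgen)
  cfg$secr <- merge_list(cfg$secr, secr)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML config path.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(qc = y$qc %||% list(), cluster = y$cluster %||% list(),
                  popgen = y$popgen %||% list(),
                  secr = y$secr %||% list(),
                  seed = y$seed %||% 1L)
}

#' Run the full scat-to-abundance pipeline
#'
#' QC (consensus, error rates, amplification filtering) then mismatch
#' clustering into individuals, capture-history construction,
#' per-session genetic summaries, and SECR density/abundance
#' estimation. Stage thresholds come from the config; progress is
#' narrated via `message()`.
#'
#' @param gt replicated genotype runs ([geno_table()]) with
#'   `session`, `occasion`, `detector` metadata.
#' @param layout detector layout with `usage` attribute.
#' @param config a [pipeline_config()].
#' @param habitat optional habitat grid for the mask and habitat
#'   density models.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return list of class `pipeline_result`: `qc` (amplification +
#'   error reports), `filtered`, `consensus`, `assignment`, `history`,
#'   `diversity` (per session), `ne` (per session, `NULL` when too few
#'   individuals), `fits`, `aicc`, `abundance`.
#' @export
run_pipeline <- function(gt, layout, config = pipeline_config(),
                         habitat = NULL, out_dir = NULL) {
  stage <- function(...) message("[scatCMR] ", ...)
  stage("QC: ", nrow(gt$a1), " runs, ", length(gt$loci), " loci")
  amp <- amplification_rates(gt)
  err <- try(error_rates(gt), silent = TRUE)
  if (inherits(err, "try-error")) err <- NULL
  filtered <- filter_samples_loci(gt, config$qc$sample_floor,
                                  config$qc$locus_floor,
                                  config$qc$drop_floor)
  aud <- attr(filtered, "audit")
  stage("QC: dropped ", aud$drop_stage["samples"], " runs / ",
        aud$drop_stage["loci"], " loci at the ", config$qc$drop_floor,
        " stage; floors removed ", aud$sample_floor, " runs and ",
        aud$locus_floor, " loci")
  cons <- consensus_table(filtered, config$qc$fill_floor)
  stage("consensus: ", nrow(cons$a1), " samples x ", length(cons$loci),
        " loci")
  mm <- mismatch_matrix(cons)
  assign <- cluster_samples(mm, config$cluster$h, config$cluster$linkage)
  stage("clustering: ", length(assign$sizes), " individuals at h = ",
        config$cluster$h)
  meta_cols <- c("sample_id", "session", "occasion", "detector")
  history <- build_capture_history(assign, cons$meta[meta_cols], layout)
  stage("capture history: ", history$n_detections, " detections = ",
        history$n_individuals, " individuals + ", history$n_recaptures,
        " recaptures")
  reps <- representative_genotypes(cons, assign)
  sess <- as.character(reps$meta$session)
  div <- list(); ne <- list()
  for (s in unique(sess)) {
    sub <- gt_subset(reps, sess == s, NULL)
    div[[s]] <- if (nrow(sub$a1) >= 2) diversity(sub) else NULL
    ne[[s]] <- tryCatch(ld_ne(sub, config$popgen$maf_cutoff),
                        error = function(e) NULL)
  }
  buffer <- config$secr$buffer
  if (is.na(buffer)) {
    buffer <- as.numeric(suggest_buffer(history))
    stage("suggested buffer: ", round(buffer), " m")
  }
  mask <- build_mask(layout, habitat, buffer, config$secr$spacing)
  fits <- list()
  for (fam in config$secr$detfn) for (f in config$secr$models) {
    lbl <- paste0(fam, " D", f)
    fits[[lbl]] <- tryCatch(
      fit_secr(history, mask, stats::as.formula(f), fam),
      error = function(e) {
        stage("fit failed (", lbl, "): ", conditionMessage(e))
        NULL
      })
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("secr stage failed: no model could be fitted")
  tab <- aicc_table(fits)
  best <- fits[[order(vapply(fits, function(f) f$AICc, numeric(1)))[1]]]
  ab <- if (best$convergence) abundance(best) else NULL
  res <- structure(list(qc = list(amplification = amp, errors = err),
                        filtered = filtered, consensus = cons,
                        assignment = assign, history = history,
                        diversity = div, ne = ne,
                        fits = fits, aicc = tab, abundance = ab,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$assignment$assignment,
                   file.path(out_dir, "assignment.csv"), row.names = FALSE)
  write_capture_history(res$history,
                        file.path(out_dir, "capture_history.csv"))
  utils::write.csv(res$aicc, file.path(out_dir, "aicc.csv"),
                   row.names = FALSE)
  if (!is.null(res$abundance))
    utils::write.csv(res$abundance, file.path(out_dir, "abundance.csv"),
                     row.names = FALSE)
  summary <- list(
    n_detections = res$history$n_detections,
    n_individuals = res$history$n_individuals,
    n_recaptures = res$history$n_recaptures,
    ne = lapply(res$ne, function(x) if (is.null(x)) NULL else
      list(ne = x$ne, ci = x$ci)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
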