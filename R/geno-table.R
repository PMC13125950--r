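#' Genotype tables
#'
#' A `geno_table` holds one genotyping run per row: two integer allele
#' matrices (rows = runs, columns = loci; `NA` = missing call, alleles
#' stored with `a1 <= a2`) plus per-run metadata linking runs to field
#' samples (replicate number, session, occasion, detector).
#'
#' @param a1,a2 integer matrices of first/second allele codes, same
#'   dimensions; `NA` marks a missing call (both entries must be `NA`
#'   together).
#' @param meta data frame with one row per run; must contain
#'   `sample_id` and `replicate`; `session`, `occasion` and `detector`
#'   columns are carried when present.
#' @param loci character vector of locus names (defaults to the column
#'   names of `a1`).
#' @return An object of class `geno_table`.
#' @export
geno_table <- function(a1, a2, meta, loci = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2)))
    stop("allele matrices must have identical dimensions")
  if (nrow(meta) != nrow(a1))
    stop("meta must have one row per genotyping run")
  if (!all(c("sample_id", "replicate") %in% names(meta)))
    stop("meta requires sample_id and replicate columns")
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  # canonicalize: sorted allele pairs, missingness symmetric
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  colnames(a1) <- colnames(a2) <- loci
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  structure(list(a1 = a1, a2 = a2, meta = meta, loci = loci),
            class = "geno_table")
}

#' @export
print.geno_table <- function(x, ...) {
  cat("geno_table:", nrow(x$a1), "runs x", length(x$loci), "loci;",
      length(unique(x$meta$sample_id)), "samples\n")
  amp <- mean(!is.na(x$a1))
  cat(sprintf("  overall call rate %.3f\n", amp))
  invisible(x)
}

#' @export
dim.geno_table <- function(x) dim(x$a1)

#' Subset a genotype table by runs and/or loci
#'
#' @param gt a [geno_table()].
#' @param rows,cols index vectors (logical, integer or names for loci).
#' @return A `geno_table`.
#' @export
gt_subset <- function(gt, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(gt$a1))
  if (is.null(cols)) cols <- seq_along(gt$loci)
  geno_table(gt$a1[rows, cols, drop = FALSE],
             gt$a2[rows, cols, drop = FALSE],
             gt$meta[rows, , drop = FALSE],
             gt$loci[if (is.character(cols)) match(cols, gt$loci) else cols])
}

#' Read a long-format genotype CSV
#'
#' Expected columns: `sample_id, replicate, locus, allele1, allele2`
#' with `"0"` (or empty) marking a missing call; optional metadata
#' columns `session`, `occasion`, `detector` are carried through.
#' Allele codes must be non-negative integers.
#'
#' @param path path to a CSV file.
#' @return A [geno_table()].
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        comment.char = "#")
  req <- c("sample_id", "replicate", "locus", "allele1", "allele2")
  if (!all(req %in% names(df)))
    stop("genotype CSV must contain columns: ", paste(req, collapse = ", "))
  key <- paste(df$sample_id, df$replicate, df$locus, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop("duplicate (sample, replicate, locus) row at line ", bad + 1L)
  }
  parse_allele <- function(x, col) {
    x[x %in% c("", "0", "NA")] <- NA
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop("malformed ", col, " token '", x[bad[1]], "' at data row ", bad[1])
    out
  }
  df$allele1 <- parse_allele(as.character(df$allele1), "allele1")
  df$allele2 <- parse_allele(as.character(df$allele2), "allele2")
  loci <- unique(df$locus)
  runs <- unique(df[c("sample_id", "replicate")])
  rid <- match(paste(df$sample_id, df$replicate), paste(runs$sample_id, runs$replicate))
  cid <- match(df$locus, loci)
  a1 <- matrix(NA_integer_, nrow(runs), length(loci))
  a2 <- a1
  a1[cbind(rid, cid)] <- df$allele1
  a2[cbind(rid, cid)] <- df$allele2
  meta <- runs
  for (mc in c("session", "occasion", "detector")) {
    if (mc %in% names(df)) {
      first <- df[!duplicated(rid), , drop = FALSE]
      v <- first[[mc]][order(rid[!duplicated(rid)])]
      if (mc %in% c("session", "detector")) v <- as.character(v)
      meta[[mc]] <- v
    }
  }
  geno_table(a1, a2, meta, loci)
}

#' Write a genotype table as long-format CSV
#'
#' Missing calls are written as `0` in both allele columns.
#'
#' @param gt a [geno_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  n <- nrow(gt$a1); L <- length(gt$loci)
  df <- data.frame(
    sample_id = rep(gt$meta$sample_id, times = L),
    replicate = rep(gt$meta$replicate, times = L),
    locus     = rep(gt$loci, each = n),
    allele1   = as.vector(gt$a1),
    allele2   = as.vector(gt$a2),
    stringsAsFactors = FALSE)
  for (mc in c("session", "occasion", "detector"))
    if (mc %in% names(gt$meta)) df[[mc]] <- rep(gt$meta[[mc]], times = L)
  df$allele1[is.na(df$allele1)] <- 0L
  df$allele2[is.na(df$allele2)] <- 0L
  df <- df[order(df$sample_id, df$replicate, match(df$locus, gt$loci)), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# standard error of the mean, NA-tolerant
se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
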