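#' Multi-sample variant read-count matrix
#'
#' The central data container: for one patient, the number of variant-
#' supporting reads (`K`) and the total coverage (`N`) for every variant in
#' every sample, plus per-sample neoplastic cell content (purity) estimates.
#'
#' @param mut_reads Integer matrix (variants x samples) of variant reads.
#' @param coverage Integer matrix of the same shape with total read depth.
#' @param purity Optional numeric vector of per-sample purities in (0,1];
#'   may be `NULL` and estimated later with [estimate_purity()].
#' @param patient_id Patient identifier.
#' @param variants Optional data frame of variant annotations (one row per
#'   variant; columns such as chrom, pos, ref, alt, gene). Row order must
#'   match `mut_reads`.
#'
#' @return An object of class `variant_call_matrix` with elements
#'   `patient_id`, `samples`, `variants`, `mut_reads`, `coverage`, `purity`.
#' @examples
#' K <- matrix(c(10L, 0L, 12L, 9L), 2, 2,
#'             dimnames = list(c("v1", "v2"), c("S1", "S2")))
#' N <- matrix(20L, 2, 2, dimnames = dimnames(K))
#' variant_call_matrix(K, N, purity = c(S1 = 0.5, S2 = 0.4))
#' @export
variant_call_matrix <- function(mut_reads, coverage, purity = NULL,
                                patient_id = "patient", variants = NULL) {
  mut_reads <- as.matrix(mut_reads)
  coverage <- as.matrix(coverage)
  if (!identical(dim(mut_reads), dim(coverage)))
    stop("mut_reads and coverage must have identical dimensions")
  if (is.null(colnames(mut_reads)))
    colnames(mut_reads) <- colnames(coverage) <- paste0("S", seq_len(ncol(mut_reads)))
  if (is.null(rownames(mut_reads)))
    rownames(mut_reads) <- rownames(coverage) <- paste0("v", seq_len(nrow(mut_reads)))
  if (!identical(dimnames(mut_reads), dimnames(coverage)))
    stop("mut_reads and coverage must share row and column names")
  if (ncol(mut_reads) < 2L) stop("need at least two samples")
  if (nrow(mut_reads) < 1L) stop("need at least one variant")
  if (any(mut_reads < 0) || any(coverage < 0))
    stop("read counts must be non-negative")
  if (any(mut_reads > coverage)) {
    bad <- which(mut_reads > coverage, arr.ind = TRUE)[1L, ]
    stop(sprintf("mut_reads exceeds coverage for variant '%s' in sample '%s'",
                 rownames(mut_reads)[bad[1L]], colnames(mut_reads)[bad[2L]]))
  }
  if (!is.null(purity)) {
    purity <- validate_purity(purity, colnames(mut_reads))
  }
  if (!is.null(variants)) {
    if (nrow(variants) != nrow(mut_reads))
      stop("variants annotation must have one row per variant")
    rownames(variants) <- rownames(mut_reads)
  }
  structure(list(patient_id = patient_id,
                 samples = colnames(mut_reads),
                 variants = variants,
                 mut_reads = mut_reads,
                 coverage = coverage,
                 purity = purity),
            class = "variant_call_matrix")
}

validate_purity <- function(purity, samples) {
  if (!is.null(names(purity))) {
    missing <- setdiff(samples, names(purity))
    if (length(missing))
      stop("purity missing for sample(s): ", paste(missing, collapse = ", "))
    purity <- purity[samples]
  } else if (length(purity) != length(samples)) {
    stop("purity must be named or have one entry per sample")
  } else {
    names(purity) <- samples
  }
  if (any(purity <= 0 | purity > 1))
    stop("purity values must lie in (0,1]")
  purity
}

#' @export
print.variant_call_matrix <- function(x, ...) {
  cat(sprintf("variant_call_matrix: patient %s, %d variants x %d samples\n",
              x$patient_id, nrow(x$mut_reads), ncol(x$mut_reads)))
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  if (!is.null(x$purity))
    cat("purity:", paste(sprintf("%s=%.2f", names(x$purity), x$purity),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Read paired variant-read / coverage count tables
#'
#' Both files are tab-separated with the variant key in the first column and
#' one column per sample. Extra annotation columns (e.g. a gene name) are
#' tolerated and kept as variant annotations when present in both files.
#'
#' @param mut_reads_path Path to the table of variant-supporting read counts.
#' @param coverage_path Path to the table of total coverage.
#' @param purity Optional per-sample purity: a named numeric vector or the
#'   path of a two-column TSV (sample, purity).
#' @param patient_id Patient identifier (defaults to the file stem).
#' @param annotation_cols Character vector of column names to treat as
#'   variant annotations rather than samples (auto-detected: any non-numeric
#'   column is an annotation).
#' @return A [variant_call_matrix()].
#' @export
read_count_tables <- function(mut_reads_path, coverage_path, purity = NULL,
                              patient_id = NULL, annotation_cols = NULL) {
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(mut_reads_path))
  km <- read_one_count_table(mut_reads_path, annotation_cols)
  nm <- read_one_count_table(coverage_path, annotation_cols)
  if (!setequal(rownames(km$counts), rownames(nm$counts))) {
    off <- c(setdiff(rownames(km$counts), rownames(nm$counts)),
             setdiff(rownames(nm$counts), rownames(km$counts)))
    stop("variant keys differ between the two tables: ",
         paste(utils::head(off, 5L), collapse = ", "))
  }
  if (!setequal(colnames(km$counts), colnames(nm$counts))) {
    off <- c(setdiff(colnames(km$counts), colnames(nm$counts)),
             setdiff(colnames(nm$counts), colnames(km$counts)))
    stop("sample columns differ between the two tables: ",
         paste(off, collapse = ", "))
  }
  N <- nm$counts[rownames(km$counts), colnames(km$counts), drop = FALSE]
  if (is.character(purity) && length(purity) == 1L) {
    ptab <- utils::read.delim(purity, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    purity <- stats::setNames(as.numeric(ptab[[2L]]), ptab[[1L]])
  }
  variant_call_matrix(km$counts, N, purity = purity, patient_id = patient_id,
                      variants = km$annot)
}

read_one_count_table <- function(path, annotation_cols = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("count table needs a key column and >=2 samples: ", path)
  key <- as.character(tab[[1L]])
  if (anyDuplicated(key))
    stop("duplicated variant keys in ", path, ": ",
         paste(utils::head(unique(key[duplicated(key)]), 3L), collapse = ", "))
  body <- tab[, -1L, drop = FALSE]
  if (is.null(annotation_cols)) {
    # a column is an annotation only when nothing in it parses as a number;
    # a numeric column with stray garbage is a malformed sample column
    all_text <- vapply(body, function(col) {
      suppressWarnings(all(is.na(as.numeric(col))))
    }, logical(1L))
    annotation_cols <- names(body)[all_text]
  }
  annot <- body[, intersect(names(body), annotation_cols), drop = FALSE]
  body <- body[, setdiff(names(body), annotation_cols), drop = FALSE]
  counts <- vapply(body, function(col) {
    x <- suppressWarnings(as.numeric(col))
    if (anyNA(x)) {
      bad <- key[which(is.na(x))[1L]]
      stop("unparseable count for variant '", bad, "' in ", path)
    }
    x
  }, numeric(nrow(tab)))
  counts <- matrix(counts, nrow = nrow(tab),
                   dimnames = list(key, names(body)))
  if (any(counts != round(counts)) || any(counts < 0))
    stop("counts must be non-negative integers in ", path)
  list(counts = counts, annot = if (ncol(annot)) annot else NULL)
}

#' Write a variant_call_matrix back to paired TSV tables
#'
#' Inverse of [read_count_tables()]; round-trips losslessly.
#'
#' @param x A `variant_call_matrix`.
#' @param mut_reads_path,coverage_path Output file paths.
#' @param purity_path Optional path for a two-column purity TSV.
#' @return Invisibly, the paths written.
#' @export
write_count_tables <- function(x, mut_reads_path, coverage_path,
                               purity_path = NULL) {
  wr <- function(mat, path) {
    df <- data.frame(variant = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(x$mut_reads, mut_reads_path)
  wr(x$coverage, coverage_path)
  if (!is.null(purity_path) && !is.null(x$purity)) {
    utils::write.table(
      data.frame(sample = names(x$purity), purity = x$purity),
      purity_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(mut_reads_path, coverage_path))
}

#' Estimate per-sample purity from putative founder variants
#'
#' Purity is estimated as `min(1, 2 * median VAF)` of the founder variants
#' (variants classified present in every sample by the binary baseline),
#' assuming heterozygous-diploid clonal variants. If no founder variant
#' exists, all variants are used instead and a warning is emitted.
#' User-supplied purities on the matrix are returned unchanged.
#'
#' @param x A [variant_call_matrix()].
#' @param config A [patient_config()] (used by the baseline classification).
#' @param override Logical; if `TRUE`, re-estimate even when the matrix
#'   already carries purities.
#' @return Named numeric vector of per-sample purities in (0,1].
#' @export
estimate_purity <- function(x, config = patient_config(), override = FALSE) {
  stopifnot(inherits(x, "variant_call_matrix"))
  if (!is.null(x$purity) && !override) return(x$purity)
  present <- binary_classification(x, config)
  founders <- which(rowSums(present) == ncol(present))
  vaf <- x$mut_reads / pmax(x$coverage, 1L)
  if (length(founders) == 0L) {
    warning("no founder variants found; falling back to all variants")
    founders <- seq_len(nrow(vaf))
  }
  gamma <- apply(vaf[founders, , drop = FALSE], 2L, stats::median)
  pmin(1, 2 * gamma)
}

#' Apply the minimal sample median coverage filter
#'
#' Drops samples whose median coverage is below
#' `config$min_median_coverage`. With the default threshold 0 this is a
#' no-op.
#'
#' @param x A [variant_call_matrix()].
#' @param config A [patient_config()].
#' @return A possibly reduced `variant_call_matrix`.
#' @export
filter_samples <- function(x, config = patient_config()) {
  if (config$min_median_coverage <= 0) return(x)
  med <- apply(x$coverage, 2L, stats::median)
  keep <- med >= config$min_median_coverage
  if (all(keep)) return(x)
  if (sum(keep) < 2L)
    stop("min_median_coverage filter would leave fewer than two samples")
  variant_call_matrix(x$mut_reads[, keep, drop = FALSE],
                      x$coverage[, keep, drop = FALSE],
                      purity = if (!is.null(x$purity)) x$purity[keep],
                      patient_id = x$patient_id, variants = x$variants)
}
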