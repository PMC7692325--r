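#' @title Expression matrix input/output, normalization and QC
#' @name expression_io
#' @description
#' Expression matrices are plain numeric matrices of normalized log2
#' intensities with probeset ids as row names and sample ids as column
#' names — the output of upstream array preprocessing. Quantile
#' normalization is offered as a desk-scale convenience for raw-ish log2
#' matrices; it is not a substitute for platform-specific preprocessing
#' such as frozen RMA, which is upstream of this package.
NULL

validate_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression input must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must have probeset row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate probeset ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(expr))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (any(is.infinite(expr))) {
    stop("expression values must be finite or NA", call. = FALSE)
  }
  invisible(expr)
}

#' Read a tab-delimited expression table
#'
#' Expects a header row of sample ids, a first column of probeset ids and
#' numeric log2 intensities; empty cells become `NA`.
#'
#' @param path file path.
#' @return Numeric matrix, probesets x samples.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty expression file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  samples <- header[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in header", call. = FALSE)
  }
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    stop("ragged rows at line(s): ",
         paste(which(widths != n_col) + 1L, collapse = ", "), call. = FALSE)
  }
  probesets <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(probesets)) {
    stop("duplicate probeset ids", call. = FALSE)
  }
  values <- vapply(body, function(f) {
    v <- f[-1L]
    v[!nzchar(v)] <- NA_character_
    as.numeric(v)
  }, numeric(length(samples)))
  expr <- if (length(samples) == 1L) {
    matrix(values, ncol = 1L)
  } else {
    t(values)
  }
  dimnames(expr) <- list(probesets, samples)
  validate_expression_matrix(expr)
  expr
}

#' Write a tab-delimited expression table
#'
#' @param expr numeric matrix, probesets x samples.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  validate_expression_matrix(expr)
  df <- data.frame(probeset_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample's value distribution onto the across-sample mean
#' quantile vector (ties averaged, missing values left missing). Delegates
#' to [limma::normalizeQuantiles()].
#'
#' @param expr numeric matrix, probesets x samples, at least 2 samples.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(expr) {
  validate_expression_matrix(expr)
  if (ncol(expr) < 2L) {
    warning("single-sample matrix: quantile normalization is the identity")
    return(expr)
  }
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Default sample QC thresholds
#'
#' @param max_fraction_missing flag samples with more missing values.
#' @param min_correlation flag samples whose Pearson correlation to the
#'   cohort median profile falls below this.
#' @param median_range flag samples whose median intensity leaves this
#'   range (log2 units).
#' @param iqr_range flag samples whose intensity IQR leaves this range.
#' @return Named list of thresholds for [qc_flag()].
#' @export
qc_thresholds <- function(max_fraction_missing = 0.5,
                          min_correlation = 0.5,
                          median_range = c(2, 14),
                          iqr_range = c(0.1, 10)) {
  list(max_fraction_missing = max_fraction_missing,
       min_correlation = min_correlation,
       median_range = median_range,
       iqr_range = iqr_range)
}

#' Flag low-quality samples
#'
#' A simplified, deterministic surrogate for full array-level QC: four
#' generic per-sample metrics (median intensity, IQR, fraction missing,
#' correlation to the cohort median profile) compared against fixed
#' thresholds. It is not equivalent to vendor-recommended array QC.
#'
#' @param expr numeric matrix, probesets x samples.
#' @param thresholds list from [qc_thresholds()].
#' @return Data frame with one row per sample: the four metrics, a logical
#'   `flagged`, and a `reasons` string (`;`-separated, empty if clean).
#' @export
qc_flag <- function(expr, thresholds = qc_thresholds()) {
  validate_expression_matrix(expr)
  if (nrow(expr) == 0L || ncol(expr) == 0L) {
    stop("empty expression matrix", call. = FALSE)
  }
  median_profile <- apply(expr, 1L, stats::median, na.rm = TRUE)
  per_sample <- lapply(seq_len(ncol(expr)), function(i) {
    v <- expr[, i]
    ok <- is.finite(v) & is.finite(median_profile)
    corr <- if (sum(ok) >= 3L &&
                stats::sd(v[ok]) > 0 && stats::sd(median_profile[ok]) > 0) {
      stats::cor(v[ok], median_profile[ok])
    } else {
      NA_real_
    }
    data.frame(
      sample_id = colnames(expr)[i],
      median_intensity = stats::median(v, na.rm = TRUE),
      iqr = stats::IQR(v, na.rm = TRUE),
      fraction_missing = mean(!is.finite(v)),
      cor_to_median_profile = corr,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, per_sample)
  reasons <- vapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    why <- character(0)
    if (r$fraction_missing > thresholds$max_fraction_missing) {
      why <- c(why, "fraction_missing")
    }
    if (!is.na(r$cor_to_median_profile) &&
        r$cor_to_median_profile < thresholds$min_correlation) {
      why <- c(why, "low_correlation")
    }
    if (!is.na(r$median_intensity) &&
        (r$median_intensity < thresholds$median_range[1] ||
         r$median_intensity > thresholds$median_range[2])) {
      why <- c(why, "median_intensity")
    }
    if (!is.na(r$iqr) &&
        (r$iqr < thresholds$iqr_range[1] || r$iqr > thresholds$iqr_range[2])) {
      why <- c(why, "iqr")
    }
    paste(why, collapse = ";")
  }, "")
  report$flagged <- nzchar(reasons)
  report$reasons <- reasons
  rownames(report) <- NULL
  report
}

#' Read a tab-delimited clinical annotation table
#'
#' Requires a `sample_id` column; all other columns pass through with
#' empty cells as `NA`.
#'
#' @param path file path.
#' @return Data frame with one row per sample.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df)) {
    stop("clinical table lacks required column 'sample_id'", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in clinical table", call. = FALSE)
  }
  df
}

#' Write a tab-delimited clinical annotation table
#'
#' @param clinical data frame with a `sample_id` column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  stopifnot("sample_id" %in% names(clinical))
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
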