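#' Read an expression matrix from TSV/CSV
#'
#' The canonical on-disk layout is features as rows and samples as columns
#' (the series-matrix convention), first column holding feature ids. Set
#' `orientation = "samples_in_rows"` for the transpose.
#'
#' Missing cells are kept as `NA` and flagged with a warning; nothing is
#' imputed. Duplicate feature or sample ids and non-numeric cells are hard
#' errors.
#'
#' @param path TSV (default) or CSV file; the delimiter is inferred from the
#'   file extension (`.csv` means comma).
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @return numeric matrix, features in rows, samples in columns, with
#'   dimnames.
#' @export
read_expression <- function(path,
                            orientation = c("features_in_rows",
                                            "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2L) stop("expression file needs an id column plus data")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate ids in ", basename(path), ": ",
         paste(dup, collapse = ", "))
  }
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body) &
                 !(trimws(body) %in% c("", "NA", "na", "NaN")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row %d, column '%s' (value '%s')",
                 bad[1, 1], colnames(body)[bad[1, 2]],
                 body[bad[1, 1], bad[1, 2]]))
  }
  dimnames(num) <- list(ids, colnames(df)[-1L])
  cdup <- unique(colnames(num)[duplicated(colnames(num))])
  if (length(cdup)) {
    stop("duplicate ids in ", basename(path), ": ",
         paste(cdup, collapse = ", "))
  }
  if (orientation == "samples_in_rows") num <- t(num)
  if (anyNA(num)) {
    warning(sum(is.na(num)), " missing cells in ", basename(path),
            " kept as NA (not imputed)")
  }
  num
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: features in rows, id column first.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output TSV/CSV path (delimiter from extension).
#' @param id_column name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, id_column = "feature_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(mat))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Expected columns: `sample_id`, `pfs_months` (> 0), `event` (0/1),
#' optionally `response` (CR/PR/SD/PD) and arbitrary covariate columns.
#' Character covariates are left as characters; their level order on use is
#' first occurrence.
#'
#' @param path TSV/CSV file.
#' @return a `data.frame` of class `clinical_cohort`.
#' @export
read_clinical <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  as_clinical_cohort(df)
}

#' Construct a clinical cohort from a data frame
#'
#' @param df data frame with at least `sample_id`, `pfs_months`, `event`.
#' @return validated `clinical_cohort` data frame.
#' @export
as_clinical_cohort <- function(df) {
  need <- c("sample_id", "pfs_months", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table lacks column(s): ",
                         paste(miss, collapse = ", "))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  bad_t <- which(!is.finite(df$pfs_months) | df$pfs_months <= 0)
  if (length(bad_t)) {
    stop("pfs_months must be positive; offending row(s): ",
         paste(bad_t, collapse = ", "))
  }
  if (!all(df$event %in% c(0, 1))) {
    stop("event must be 0 or 1; offending row(s): ",
         paste(which(!df$event %in% c(0, 1)), collapse = ", "))
  }
  if ("response" %in% colnames(df)) {
    ok <- df$response %in% c("CR", "PR", "SD", "PD") | is.na(df$response)
    if (!all(ok)) {
      stop("response must be CR/PR/SD/PD or NA; offending row(s): ",
           paste(which(!ok), collapse = ", "))
    }
  }
  class(df) <- c("clinical_cohort", "data.frame")
  df
}

#' @rdname read_clinical
#' @param cohort a `clinical_cohort`.
#' @param path output file path.
#' @export
write_clinical <- function(cohort, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(cohort), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a tumour-normal pairing map
#'
#' Three columns: `pair_id`, `tumour`, `normal` (sample ids of the
#' expression matrix).
#'
#' @param path TSV/CSV file.
#' @return data frame with columns `pair_id`, `tumour`, `normal`.
#' @export
read_pairing <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("pair_id", "tumour", "normal")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("pairing map lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_pairing
#' @param pairing pairing data frame.
#' @export
write_pairing <- function(pairing, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(pairing, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an RMIP table
#'
#' TSV with columns `feature_id`, `rmip`, `count`, `B`, `rank`, sorted by
#' RMIP descending (ties broken lexicographically by feature id).
#'
#' @param rmip an `rmip_table` from [bag_lasso()].
#' @param path output TSV.
#' @export
write_rmip_table <- function(rmip, path) {
  stopifnot(inherits(rmip, "rmip_table"))
  df <- as.data.frame(rmip)
  df <- df[order(df$rank), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rmip_table
#' @export
read_rmip_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new_rmip_table(setNames(df$count, df$feature_id), B = df$B[1L])
}

#' Write / read a risk signature as JSON
#'
#' Fields: `features`, `coefficients`, `cutoff`, `ties_method`,
#' `created_from` (manifest digest or label).
#'
#' @param signature a `risk_signature` from [fit_signature()].
#' @param path JSON path.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "risk_signature"))
  jsonlite::write_json(
    list(features = signature$features,
         coefficients = signature$coefficients,
         cutoff = signature$cutoff,
         ties_method = signature$ties_method,
         created_from = signature$created_from),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_risk_signature(features = raw$features,
                     coefficients = as.numeric(raw$coefficients),
                     cutoff = raw$cutoff,
                     ties_method = raw$ties_method,
                     created_from = raw$created_from)
}
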