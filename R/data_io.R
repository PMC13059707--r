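#' @keywords internal
"_PACKAGE"

#' Canonical treatment levels
#'
#' The four-arm fermentation design: anaerobic control, 5% oxygen, 1% fiber,
#' and oxygen plus fiber.
#' @export
TREATMENT_LEVELS <- c("Control", "Oxygen", "Fiber", "OxygenFiber")

#' Normalize treatment labels to the canonical four-level set
#'
#' Matching is case-insensitive and ignores separators, so "oxygen+fiber",
#' "Oxygen_Fiber" and "OxygenFiber" all map to `"OxygenFiber"`.
#'
#' @param x character vector of treatment labels.
#' @return factor with levels [TREATMENT_LEVELS].
#' @export
normalize_treatment <- function(x) {
  key <- tolower(gsub("[^A-Za-z]", "", as.character(x)))
  canon_key <- tolower(TREATMENT_LEVELS)
  idx <- match(key, canon_key)
  if (anyNA(idx)) {
    bad <- unique(as.character(x)[is.na(idx)])
    stop("unknown treatment level(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(TREATMENT_LEVELS, collapse = ", "))
  }
  factor(TREATMENT_LEVELS[idx], levels = TREATMENT_LEVELS)
}

#' Validate a count table
#'
#' A count table is a samples x features matrix of non-negative integers with
#' unique sample and feature dimnames.
#'
#' @param counts numeric matrix, samples in rows, features in columns.
#' @return the validated matrix (integer storage), invisibly usable.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix (samples x features)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and feature colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate feature id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative count at sample '%s', feature '%s'",
                 rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  counts
}

#' Read an ASV/feature count table
#'
#' On disk the table follows the QIIME convention: features as rows, samples
#' as columns, first column holding the feature id. In memory the table is
#' samples x features.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"biom"` (BIOM 2.1/1.0, requires the
#'   `biomformat` package).
#' @param features_as_rows for TSV, whether rows on disk are features
#'   (default `TRUE`).
#' @return integer matrix, samples x features.
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             features_as_rows = TRUE) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("BIOM support requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # features x samples
    return(validate_count_table(t(m)))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate ", if (features_as_rows) "feature" else "sample",
         " id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count values in ", path)
  rownames(m) <- ids
  if (features_as_rows) m <- t(m)
  validate_count_table(m)
}

#' Write a count table as TSV (features as rows)
#'
#' @param counts samples x features matrix.
#' @param path output path.
#' @param id_column name of the first (feature id) column.
#' @export
write_count_table <- function(counts, path, id_column = "feature_id") {
  counts <- validate_count_table(counts)
  out <- data.frame(colnames(counts), t(counts), check.names = FALSE)
  names(out)[1] <- id_column
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Requires columns `sample_id`, `donor`, `treatment`, `time_h`, `replicate`.
#' Treatment labels are normalized case-insensitively to the canonical set.
#'
#' @param path TSV path.
#' @return data.frame with one row per sample; `treatment` is a factor with
#'   levels [TREATMENT_LEVELS], `donor` a factor.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate sample metadata
#'
#' @param meta data.frame of per-sample metadata.
#' @param counts optional count table; if given, every sample in the count
#'   table must have a metadata row.
#' @return normalized metadata data.frame.
#' @export
validate_metadata <- function(meta, counts = NULL) {
  req <- c("sample_id", "donor", "treatment", "time_h", "replicate")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$donor <- factor(meta$donor)
  meta$treatment <- normalize_treatment(meta$treatment)
  meta$time_h <- as.numeric(meta$time_h)
  meta$replicate <- as.integer(meta$replicate)
  if (anyNA(meta$time_h) || anyNA(meta$replicate))
    stop("metadata time_h/replicate must be numeric")
  if (!is.null(counts)) {
    absent <- setdiff(rownames(counts), meta$sample_id)
    if (length(absent) > 0)
      stop("count table sample(s) missing from metadata: ",
           paste(absent, collapse = ", "))
  }
  meta
}

#' Write sample metadata as TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample chemistry table
#'
#' Requires columns `sample_id`, `pH` and the three major short-chain fatty
#' acids `acetate`, `propionate`, `butyrate` in micromolar.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_chem <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_chem(df)
}

#' Validate a chemistry table
#'
#' @param chem data.frame with pH and SCFA columns.
#' @param counts optional count table for cross-reference checking.
#' @return validated data.frame.
#' @export
validate_chem <- function(chem, counts = NULL) {
  req <- c("sample_id", "pH", "acetate", "propionate", "butyrate")
  missing_cols <- setdiff(req, names(chem))
  if (length(missing_cols) > 0)
    stop("chemistry table missing column(s): ", paste(missing_cols, collapse = ", "))
  chem$sample_id <- as.character(chem$sample_id)
  if (anyDuplicated(chem$sample_id))
    stop("duplicate sample_id in chemistry table")
  for (v in c("pH", "acetate", "propionate", "butyrate")) {
    chem[[v]] <- as.numeric(chem[[v]])
    if (anyNA(chem[[v]])) stop("non-numeric values in chemistry column ", v)
  }
  if (any(chem$pH <= 0 | chem$pH >= 14)) stop("pH out of range (0, 14)")
  if (any(chem$acetate < 0 | chem$propionate < 0 | chem$butyrate < 0))
    stop("SCFA concentrations must be non-negative")
  if (!is.null(counts)) {
    absent <- setdiff(rownames(counts), chem$sample_id)
    if (length(absent) > 0)
      stop("count table sample(s) missing from chemistry table: ",
           paste(absent, collapse = ", "))
  }
  chem
}

#' Write a chemistry table as TSV
#' @param chem chemistry data.frame.
#' @param path output path.
#' @export
write_chem <- function(chem, path) {
  utils::write.table(chem, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
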