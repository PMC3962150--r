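#' @include AllClasses.R AllGenerics.R
#' @importFrom data.table fread fwrite
NULL

# round half up, the printing convention of clinical summary tables
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Read a probe-by-sample expression matrix
#'
#' Reads the tab-delimited Affymetrix-style layout: first row holds sample
#' IDs (first cell is a probe-ID column header), every following row a probe
#' ID and its numeric intensities.
#'
#' @param path path to the tab-delimited file.
#' @param platform platform label stored with the matrix.
#' @param impute `"none"` (default): any missing cell is a hard error;
#'   `"median"`: missing cells are imputed with the probe's median across
#'   samples.
#' @return An [ExpressionMatrix-class].
#' @details Duplicate probe IDs, non-numeric cells (reported with their
#'   row/column coordinates) and empty files are hard errors.
#' @export
readExpressionMatrix <- function(path, platform = "unspecified",
                                 impute = c("none", "median")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  if (file.size(path) == 0) stop("empty expression matrix file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              data.table = FALSE, na.strings = c("NA", ""))
  if (nrow(dt) == 0 || ncol(dt) < 2)
    stop("expression matrix must have at least one probe and one sample: ",
         path)
  probes <- dt[[1]]
  dup <- probes[duplicated(probes)]
  if (length(dup))
    stop("duplicate probe ID '", dup[1], "' in ", path)
  samples <- colnames(dt)[-1]
  vals <- matrix(NA_real_, nrow(dt), length(samples),
                 dimnames = list(probes, samples))
  for (j in seq_along(samples)) {
    col <- dt[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop(sprintf(
        "non-numeric value '%s' at probe '%s' (row %d), sample '%s' (column %d)",
        col[bad[1]], probes[bad[1]], bad[1], samples[j], j + 1L))
    vals[, j] <- num
  }
  if (anyNA(vals)) {
    if (impute == "none") {
      miss <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "missing value at probe '%s', sample '%s' (use impute = 'median' to impute)",
        probes[miss[1]], samples[miss[2]]))
    }
    for (i in which(rowSums(is.na(vals)) > 0)) {
      med <- stats::median(vals[i, ], na.rm = TRUE)
      if (is.na(med)) stop("probe '", probes[i], "' has no observed values")
      vals[i, is.na(vals[i, ])] <- med
    }
  }
  m <- ExpressionMatrix(vals, platform = platform)
  message(sprintf("read %d probes x %d samples from %s [%s]",
                  nrow(m), ncol(m), path, platform))
  m
}

#' Write an expression matrix in the tab-delimited exchange layout
#'
#' Inverse of [readExpressionMatrix()]: a read-write-read round trip
#' reproduces the matrix to numeric printing precision (15 significant
#' digits).
#'
#' @param m an [ExpressionMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(m, path) {
  v <- exprValues(m)
  df <- data.frame(probe_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Merge two single-platform matrices into one profile per sample
#'
#' Concatenates the probe rows of `a` and `b` (a's first) over the samples
#' present on both platforms, emulating the compilation of two-chip patient
#' profiles into one file. Sample order follows `a`; the platform label of
#' the result is `"merged"`.
#'
#' @param a,b [ExpressionMatrix-class] objects with disjoint probe sets
#'   sharing at least one sample ID.
#' @return The merged [ExpressionMatrix-class].
#' @export
mergePlatforms <- function(a, b) {
  collide <- intersect(probeIds(a), probeIds(b))
  if (length(collide))
    stop("probe ID collision between platforms: '", collide[1], "'")
  shared <- intersect(sampleIds(a), sampleIds(b))
  if (!length(shared))
    stop("platforms share no sample IDs; cannot merge")
  shared <- sampleIds(a)[sampleIds(a) %in% shared]  # a's order
  vals <- rbind(exprValues(a)[, shared, drop = FALSE],
                exprValues(b)[, shared, drop = FALSE])
  m <- ExpressionMatrix(vals, platform = "merged")
  message(sprintf("merged %d + %d probes over %d shared samples",
                  nrow(a), nrow(b), length(shared)))
  m
}

#' Read a sample metadata table
#'
#' CSV with a header; requires columns `sample_id` and `er_status`. ER status
#' is normalised to lower case and any value other than `positive` or
#' `negative` (including blanks and missing values) is coded `unknown`.
#'
#' @param path path to the CSV file.
#' @return data.frame with one row per sample.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateSampleMetadata(meta)
}

validateSampleMetadata <- function(meta) {
  if (!all(c("sample_id", "er_status") %in% names(meta)))
    stop("metadata must contain sample_id and er_status columns")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: '",
         meta$sample_id[duplicated(meta$sample_id)][1], "'")
  er <- tolower(trimws(as.character(meta$er_status)))
  er[is.na(er) | !er %in% c("positive", "negative")] <- "unknown"
  meta$er_status <- er
  meta
}

#' Retain only estrogen-receptor-positive samples
#'
#' Drops every sample whose ER status is negative, unknown, or absent from
#' the metadata (absent samples are treated as unknown, with a warning), the
#' cohort filter applied before screening.
#'
#' @param m an [ExpressionMatrix-class].
#' @param meta sample metadata data.frame (see [readSampleMetadata()]).
#' @return The filtered [ExpressionMatrix-class].
#' @export
filterERPositive <- function(m, meta) {
  meta <- validateSampleMetadata(meta)
  status <- stats::setNames(meta$er_status, meta$sample_id)
  s <- sampleIds(m)
  er <- unname(status[s])
  missing <- is.na(er)
  if (any(missing)) {
    warning(sum(missing), " sample(s) absent from metadata treated as ",
            "ER-unknown and excluded")
    er[missing] <- "unknown"
  }
  keep <- er == "positive"
  message(sprintf(
    "ER filter: %d retained, %d negative, %d unknown/blank excluded",
    sum(keep), sum(er == "negative"), sum(er == "unknown")))
  if (!any(keep)) stop("no ER+ samples")
  m[, keep]
}

#' Summarise a cohort metadata table
#'
#' For every categorical column: per-level counts and percentages of the
#' column's non-missing total, rounded half-up to one decimal (the printing
#' convention of clinical characteristics tables). For every numeric column:
#' mean, median and range.
#'
#' @param meta sample metadata data.frame; the `sample_id` column is ignored.
#' @return list with elements `categorical` (data.frame: `field`, `level`,
#'   `count`, `percentage`) and `numeric` (data.frame: `field`, `mean`,
#'   `median`, `min`, `max`).
#' @export
summarizeCohort <- function(meta) {
  stopifnot(nrow(meta) >= 1)
  fields <- setdiff(names(meta), "sample_id")
  cat_rows <- list()
  num_rows <- list()
  for (f in fields) {
    x <- meta[[f]]
    if (is.numeric(x)) {
      num_rows[[f]] <- data.frame(
        field = f, mean = mean(x, na.rm = TRUE),
        median = stats::median(x, na.rm = TRUE),
        min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE),
        stringsAsFactors = FALSE)
    } else {
      x <- as.character(x)
      x <- x[!is.na(x) & nzchar(x)]
      if (!length(x)) {
        message("field '", f, "' has no non-missing values; skipped")
        next
      }
      tab <- table(x)
      cat_rows[[f]] <- data.frame(
        field = f, level = names(tab), count = as.integer(tab),
        percentage = roundHalfUp(100 * as.integer(tab) / sum(tab), 1),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  list(
    categorical = if (length(cat_rows)) do.call(rbind, c(cat_rows, list(make.row.names = FALSE)))
                  else data.frame(field = character(), level = character(),
                                  count = integer(), percentage = numeric()),
    numeric = if (length(num_rows)) do.call(rbind, c(num_rows, list(make.row.names = FALSE)))
              else data.frame(field = character(), mean = numeric(),
                              median = numeric(), min = numeric(),
                              max = numeric()))
}

#' Read a probe-to-gene-symbol annotation table
#'
#' Two-column tab-delimited file: probe ID, gene symbol. A header line is
#' detected (first field equal to `probe_id`) and skipped.
#'
#' @param path path to the annotation file.
#' @return data.frame with columns `probe_id` and `gene_symbol`.
#' @export
readProbeAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- fread(path, sep = "\t", header = FALSE, colClasses = "character",
               data.table = FALSE)
  if (ncol(ann) < 2) stop("annotation must have two tab-delimited columns")
  ann <- ann[, 1:2]
  names(ann) <- c("probe_id", "gene_symbol")
  if (nrow(ann) && ann$probe_id[1] == "probe_id") ann <- ann[-1, ]
  validateProbeAnnotation(ann)
}

validateProbeAnnotation <- function(ann) {
  if (!all(c("probe_id", "gene_symbol") %in% names(ann)))
    stop("annotation must contain probe_id and gene_symbol columns")
  if (anyDuplicated(ann$probe_id))
    stop("duplicate probe_id in annotation: '",
         ann$probe_id[duplicated(ann$probe_id)][1], "'")
  if (any(is.na(ann$gene_symbol) | !nzchar(ann$gene_symbol)))
    stop("annotation gene symbols must be non-empty")
  ann
}

#' Map probe IDs to gene symbols
#'
#' Platform suffix tags (`_A`/`_B`, as used when probes from two chips are
#' pooled in one table) are stripped before lookup. Probes without an
#' annotation entry pass through as their own identifier and are flagged in
#' the `unannotated` attribute of the result.
#'
#' @param probes character vector of probe IDs; order is preserved.
#' @param ann annotation data.frame (see [readProbeAnnotation()]).
#' @return Character vector of gene symbols, named by the input probes, with
#'   a logical attribute `unannotated`.
#' @examples
#' ann <- data.frame(probe_id = "206170_at", gene_symbol = "ADRB2")
#' mapProbesToSymbols(c("206170_at", "ZZZ_at"), ann)
#' @export
mapProbesToSymbols <- function(probes, ann) {
  ann <- validateProbeAnnotation(ann)
  lookup <- stats::setNames(ann$gene_symbol, ann$probe_id)
  stripped <- sub("_(A|B)$", "", probes)
  sym <- unname(lookup[stripped])
  unann <- is.na(sym)
  sym[unann] <- probes[unann]
  structure(stats::setNames(sym, probes), unannotated = unann)
}
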