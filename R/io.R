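#' Read a sample x ASV count table
#'
#' Reads an amplicon count table from TSV, CSV or BIOM. Text tables must have
#' identifiers in the first row and first column; the `orientation` flag says
#' which margin holds the ASVs (the common on-disk convention, and the default
#' here, is ASVs as rows). BIOM files (read through the biomformat package,
#' which accepts both the JSON and the HDF5 flavour) are always observation
#' (ASV) by sample and the flag is ignored for them.
#'
#' The returned matrix always has samples as rows and ASVs as columns, the
#' in-memory convention used throughout the package (as in vegan community
#' matrices). Cells must be non-negative whole numbers.
#'
#' @param path Path to a `.tsv`/`.txt` (tab), `.csv` (comma) or `.biom` file.
#' @param orientation `"asvs_as_rows"` (default) or `"samples_as_rows"`,
#'   describing the file layout, not the returned layout.
#' @return Integer matrix, samples as rows, ASVs as columns, dimnames set.
#' @export
read_count_table <- function(path,
                             orientation = c("asvs_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("count table file does not exist: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # observations x samples
    tab <- t(m)
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE, colClasses = "character",
                     comment.char = "")
    if (nrow(df) == 0L || ncol(df) < 2L) {
      stop("count table has an empty body: ", path)
    }
    ids <- df[[1L]]
    body <- df[, -1L, drop = FALSE]
    num <- suppressWarnings(
      vapply(body, function(col) as.numeric(col), numeric(nrow(body)))
    )
    if (is.null(dim(num))) num <- matrix(num, nrow = nrow(body))
    bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]]))
    }
    dimnames(num) <- list(ids, colnames(body))
    tab <- if (orientation == "asvs_as_rows") t(num) else num
  }
  as_count_table(tab)
}

#' Validate a samples x ASVs count matrix
#'
#' Checks the count-table invariants (unique identifiers on both margins,
#' non-negative whole-number cells) and returns the matrix in integer storage.
#'
#' @param x Numeric matrix, samples as rows, ASVs as columns, dimnames set.
#' @return The validated matrix, storage mode integer.
#' @export
as_count_table <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count table must carry sample and ASV identifiers as dimnames")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate ASV identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  if (anyNA(x)) stop("count table contains missing values")
  if (any(x < 0)) stop("count table contains negative values")
  if (any(abs(x - round(x)) > 1e-8)) {
    stop("count table contains non-integral values")
  }
  storage.mode(x) <- "integer"
  x
}

#' Write a count table to TSV, CSV or BIOM
#'
#' @param x Samples x ASVs count matrix.
#' @param path Output path; format chosen by extension (`.biom` via
#'   biomformat, `.csv` comma, anything else tab).
#' @param orientation On-disk layout for text formats; see
#'   [read_count_table()].
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path,
                              orientation = c("asvs_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  x <- as_count_table(x)
  ext <- tolower(tools::file_ext(path))
  if (ext == "biom") {
    biomformat::write_biom(biomformat::make_biom(t(x)), path)
    return(invisible(path))
  }
  sep <- if (ext == "csv") "," else "\t"
  out <- if (orientation == "asvs_as_rows") t(x) else x
  df <- data.frame(id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- if (orientation == "asvs_as_rows") "asv_id" else "sample_id"
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.sample_types <- c("host", "rock", "seawater", "other_host")

#' Read a sample metadata table
#'
#' Reads a tab-separated metadata table with one row per sample. Required
#' columns are `sample_id` and `sample_type`; optional columns `site`, `date`
#' (ISO-8601, parsed to `Date`), `host_species` and `sampling_event` are kept
#' when present and tolerated when absent. Sample types are case-folded and
#' must land in the fixed vocabulary `host`, `rock`, `seawater`, `other_host`;
#' arbitrary study labels can be translated first through `type_map` (a named
#' character vector, names = labels in the file, values = vocabulary terms).
#'
#' @param path Path to a TSV file with a header row.
#' @param type_map Optional named character vector mapping study-specific
#'   sample-type labels onto the fixed vocabulary.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path, type_map = NULL) {
  if (!file.exists(path)) stop("metadata file does not exist: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "",
                   colClasses = "character")
  required <- c("sample_id", "sample_type")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  ty <- df$sample_type
  if (!is.null(type_map)) {
    hit <- ty %in% names(type_map)
    ty[hit] <- unname(type_map[ty[hit]])
  }
  ty <- tolower(trimws(ty))
  unknown <- setdiff(unique(ty), .sample_types)
  if (length(unknown) > 0L) {
    stop("unknown sample_type value(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(.sample_types, collapse = ", "), ")")
  }
  df$sample_type <- ty
  if ("date" %in% colnames(df)) {
    parsed <- as.Date(df$date, format = "%Y-%m-%d")
    bad <- !is.na(df$date) & nzchar(df$date) & is.na(parsed)
    if (any(bad)) {
      stop("dates not in ISO-8601 (YYYY-MM-DD): ",
           paste(df$date[bad][seq_len(min(3L, sum(bad)))], collapse = ", "))
    }
    df$date <- parsed
  }
  need_species <- df$sample_type %in% c("host", "other_host")
  if (any(need_species) && !"host_species" %in% colnames(df)) {
    message("note: host/other_host samples present but no host_species column")
  }
  df
}

#' Align a count table with its metadata
#'
#' @param x Samples x ASVs count matrix.
#' @param meta Metadata data.frame from [read_metadata()].
#' @param policy `"intersect"` keeps the samples present on both sides (in
#'   table order) and messages how many were dropped; `"strict"` errors on
#'   any mismatch, naming the offending identifiers.
#' @return List with elements `counts` and `metadata`, row-aligned.
#' @export
align_samples <- function(x, meta, policy = c("intersect", "strict")) {
  policy <- match.arg(policy)
  x <- as_count_table(x)
  tab_ids <- rownames(x)
  meta_ids <- meta$sample_id
  only_tab <- setdiff(tab_ids, meta_ids)
  only_meta <- setdiff(meta_ids, tab_ids)
  if (policy == "strict" && (length(only_tab) > 0L || length(only_meta) > 0L)) {
    stop("sample identifiers do not match; only in table: [",
         paste(only_tab, collapse = ", "), "]; only in metadata: [",
         paste(only_meta, collapse = ", "), "]")
  }
  keep <- tab_ids[tab_ids %in% meta_ids]
  if (length(only_tab) > 0L || length(only_meta) > 0L) {
    message(sprintf("align: dropped %d table sample(s) and %d metadata row(s)",
                    length(only_tab), length(only_meta)))
  }
  list(counts = x[keep, , drop = FALSE],
       metadata = meta[match(keep, meta$sample_id), , drop = FALSE])
}

# shared helper: write a result data.frame as TSV
write_result_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
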