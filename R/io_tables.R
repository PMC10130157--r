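#' Construct a validated feature table
#'
#' A feature table is the central object of the package: a numeric matrix of
#' non-negative counts (or abundances) with samples as rows and taxa (ASVs,
#' genera, families, pathways, ...) as columns. All community metrics,
#' PERMANOVA and enterotyping consume this object.
#'
#' @param counts numeric matrix, samples x taxa, with unique non-empty
#'   dimnames.
#' @param drop_empty_samples drop samples whose row sum is zero (with a
#'   message) instead of failing validation.
#' @return the validated matrix with class `"feature_table"`.
#' @export
feature_table <- function(counts, drop_empty_samples = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (length(counts) == 0L) stop("feature table is empty")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("feature table needs sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  bad <- which(counts < 0 | is.na(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("negative or missing count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    if (drop_empty_samples) {
      message("dropping ", sum(empty), " all-zero sample(s): ",
              paste(rownames(counts)[empty], collapse = ", "))
      counts <- counts[!empty, , drop = FALSE]
      if (nrow(counts) == 0L) stop("all samples are empty")
    } else {
      stop("all-zero sample(s): ", paste(rownames(counts)[empty], collapse = ", "))
    }
  }
  structure(counts, class = c("feature_table", class(counts)))
}

#' Read a feature table from TSV or BIOM
#'
#' TSV dialect: tab-separated, UTF-8, '.' decimal, first column sample ids,
#' header row of taxon ids (canonical orientation: samples are rows). A file
#' in the transposed orientation can be fixed downstream by [align()], which
#' disambiguates using metadata sample ids. BIOM v1 (JSON) tables are read
#' through the biomformat package and transposed to samples-as-rows.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @inheritParams feature_table
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, format = c("tsv", "biom"),
                               drop_empty_samples = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("BIOM input needs the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))   # taxa x samples in BIOM
    return(feature_table(t(m), drop_empty_samples = drop_empty_samples))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty feature table: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- ids
  feature_table(m, drop_empty_samples = drop_empty_samples)
}

#' Write a feature table as TSV
#'
#' Inverse of [read_feature_table()]: `read_feature_table(write_feature_table(x))`
#' returns counts bit-equal to `x` for integer-valued input.
#'
#' @param table a feature table (samples x taxa).
#' @param path output path.
#' @param id_column name of the first (sample id) column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, id_column = "sample_id") {
  df <- data.frame(rownames(table), as.data.frame(unclass(table),
                                                  check.names = FALSE),
                   check.names = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

ranks_ordered <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Construct or read a taxonomy lineage table
#'
#' Maps taxon ids to the ranks kingdom..genus. Missing or empty rank strings
#' are replaced by the sentinel `"unclassified_<rank>"` so that aggregation
#' never silently drops counts.
#'
#' @param x data.frame with a `taxon_id` column and any subset of the rank
#'   columns kingdom, phylum, class, order, family, genus.
#' @return data.frame of class `"taxonomy"` with all six rank columns.
#' @export
taxonomy <- function(x) {
  if (!"taxon_id" %in% names(x)) stop("taxonomy needs a 'taxon_id' column")
  if (anyDuplicated(x$taxon_id))
    stop("duplicate taxon ids in taxonomy: ",
         paste(unique(x$taxon_id[duplicated(x$taxon_id)]), collapse = ", "))
  out <- data.frame(taxon_id = as.character(x$taxon_id),
                    stringsAsFactors = FALSE)
  for (r in ranks_ordered) {
    v <- if (r %in% names(x)) as.character(x[[r]]) else rep(NA_character_, nrow(x))
    v[is.na(v) | !nzchar(v)] <- paste0("unclassified_", r)
    out[[r]] <- v
  }
  class(out) <- c("taxonomy", "data.frame")
  out
}

#' @rdname taxonomy
#' @param path TSV path with columns taxon_id, kingdom..genus.
#' @export
read_taxonomy <- function(path) {
  taxonomy(utils::read.delim(path, sep = "\t", quote = "",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8"))
}

sample_roles <- c("feces", "culture", "control")

#' Construct or read per-sample metadata
#'
#' Metadata carries the experimental factors of the culture design: donor,
#' medium, time in hours, replicate and the sample role. Feces samples are the
#' uncultured reference and carry no medium; if one is given it is dropped
#' with a warning.
#'
#' @param x data.frame with columns sample_id, donor, medium, time_h,
#'   replicate, role.
#' @return data.frame of class `"sample_metadata"`.
#' @export
sample_metadata <- function(x) {
  need <- c("sample_id", "donor", "medium", "time_h", "replicate", "role")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L)
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  bad_role <- setdiff(unique(x$role), sample_roles)
  if (length(bad_role) > 0L)
    stop("unknown role(s) ", paste(shQuote(bad_role), collapse = ", "),
         "; allowed roles: ", paste(sample_roles, collapse = ", "))
  x$time_h <- as.numeric(x$time_h)
  feces_med <- x$role == "feces" & !is.na(x$medium) & nzchar(as.character(x$medium))
  if (any(feces_med)) {
    warning("feces sample(s) with a medium set; medium ignored: ",
            paste(x$sample_id[feces_med], collapse = ", "))
    x$medium[feces_med] <- NA
  }
  rownames(x) <- x$sample_id
  class(x) <- c("sample_metadata", "data.frame")
  x
}

#' @rdname sample_metadata
#' @param path TSV path.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sample_metadata(utils::read.delim(path, sep = "\t", quote = "",
                                    check.names = FALSE,
                                    stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8"))
}

#' @rdname sample_metadata
#' @param meta a sample_metadata object.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Align a feature table with sample metadata
#'
#' Restricts both objects to their common samples, in the same order, and
#' reports how many samples were dropped from each side. If the table has no
#' sample overlap on its rows but its *columns* match the metadata sample
#' ids, the table is transposed first (a file stored in the transposed
#' orientation); when both orientations overlap the input is ambiguous and an
#' error is raised.
#'
#' Idempotent: aligning an already aligned pair is the identity.
#'
#' @param table a [feature_table()].
#' @param meta a [sample_metadata()].
#' @return `list(table =, meta =)`, samples identically ordered.
#' @export
align <- function(table, meta) {
  row_hit <- intersect(rownames(table), meta$sample_id)
  col_hit <- intersect(colnames(table), meta$sample_id)
  if (length(row_hit) == 0L && length(col_hit) > 0L) {
    message("feature table appears transposed (sample ids on columns); transposing")
    table <- feature_table(t(unclass(table)))
    row_hit <- col_hit
  } else if (length(row_hit) > 0L && length(col_hit) > 0L) {
    stop("ambiguous orientation: sample ids found on both axes of the feature table")
  }
  common <- intersect(rownames(table), meta$sample_id)
  if (length(common) == 0L)
    stop("no samples shared between feature table and metadata")
  dropped_tab <- nrow(table) - length(common)
  dropped_meta <- nrow(meta) - length(common)
  if (dropped_tab + dropped_meta > 0L)
    message(sprintf("align: dropped %d table sample(s) and %d metadata row(s)",
                    dropped_tab, dropped_meta))
  tab <- unclass(table)[common, , drop = FALSE]
  m <- meta[match(common, meta$sample_id), , drop = FALSE]
  class(m) <- c("sample_metadata", "data.frame")
  list(table = feature_table(tab), meta = m)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature table: %d samples x %d taxa (total count %s)\n",
              nrow(x), ncol(x), format(sum(x))))
  invisible(x)
}
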