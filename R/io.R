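#' Read a feature table (TSV or BIOM)
#'
#' TSV tables follow the dominant microbiome export convention of features as
#' rows (first column feature IDs, header = sample IDs); BIOM files (JSON or
#' HDF5) are read through the biomformat package. Internally tables are
#' oriented samples x features.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"biom"`.
#' @param min_feature_count Drop low-total features via [filter_features()].
#' @param strict Passed to [filter_features()]: drop totals `<=` the
#'   threshold (`TRUE`, default) or `<` it.
#' @param transpose For TSV input whose rows are samples rather than features.
#' @return Samples x features numeric matrix.
#' @export
read_table <- function(path, format = c("auto", "tsv", "biom"),
                       min_feature_count = 0, strict = TRUE, transpose = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # features x samples
    tab <- t(m)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop("duplicate IDs in table: ", ids[duplicated(ids)][1], call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric cells in table", call. = FALSE)
    if (anyDuplicated(colnames(m)))
      stop("duplicate IDs in table header", call. = FALSE)
    rownames(m) <- ids
    tab <- if (transpose) m else t(m)
  }
  check_count_table(tab)
  if (min_feature_count > 0)
    tab <- filter_features(tab, min_feature_count, strict = strict)
  tab
}

#' Filter features by total count
#'
#' Retains features whose total count across samples exceeds `min_count`
#' (strictly greater by default; `strict = FALSE` keeps ties).
#'
#' @param table Samples x features count matrix.
#' @param min_count Total-count threshold.
#' @param strict Drop features with total exactly `min_count` too.
#' @return The filtered table; messages the number of removed features.
#' @export
filter_features <- function(table, min_count, strict = TRUE) {
  tot <- colSums(table)
  keep <- if (strict) tot > min_count else tot >= min_count
  if (any(!keep))
    message(sum(!keep), " feature(s) removed by total-count filter")
  table[, keep, drop = FALSE]
}

#' Write a feature table (TSV or BIOM)
#'
#' @param table Samples x features matrix.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"tsv"` (features as rows) or
#'   `"biom"`.
#' @export
write_table <- function(table, path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  if (format == "biom") {
    biomformat::write_biom(biomformat::make_biom(t(table)), path)
  } else {
    df <- data.frame(feature_id = colnames(table), t(table),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read sample metadata (TSV, sample IDs in the first column)
#'
#' @param path Input file.
#' @return Data frame with sample IDs as rownames.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample IDs in metadata", call. = FALSE)
  rownames(df) <- ids
  df[, -1, drop = FALSE]
}

#' Write sample metadata
#'
#' @param metadata Data frame with sample IDs as rownames (or first column).
#' @param path Output file.
#' @param id_name Header for the sample-ID column.
#' @export
write_metadata <- function(metadata, path, id_name = "sample_id") {
  md <- normalize_metadata(metadata)
  df <- data.frame(rownames(md), md, check.names = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labeled square distance matrix (TSV)
#'
#' @param path File path.
#' @return `read_distance`: symmetric numeric matrix with matching row and
#'   column labels.
#' @export
read_distance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!identical(rownames(m), colnames(m)))
    stop("distance matrix labels do not match", call. = FALSE)
  m
}

#' @param d Distance matrix (`dist` or labeled symmetric matrix).
#' @rdname read_distance
#' @export
write_distance <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write ordination results (text format)
#'
#' The standard sectioned ordination-results text format: `Eigvals`,
#' `Proportion explained`, `Species` (feature/node loadings), `Site` (sample
#' scores), `Biplot` and `Site constraints` sections separated by blank
#' lines.
#'
#' @param ord A `treecoda_ordination`.
#' @param path File path.
#' @export
write_ordination <- function(ord, path) {
  r <- ord$rank
  num <- function(x) paste(sprintf("%.10g", x), collapse = "\t")
  lines <- c(
    paste0("Eigvals\t", r), num(ord$eigenvalues), "",
    paste0("Proportion explained\t", r), num(ord$proportion_explained), "",
    paste0("Species\t", nrow(ord$feature_loadings), "\t", r),
    paste0(rownames(ord$feature_loadings), "\t",
           apply(ord$feature_loadings, 1, num)), "",
    paste0("Site\t", nrow(ord$sample_scores), "\t", r),
    paste0(rownames(ord$sample_scores), "\t",
           apply(ord$sample_scores, 1, num)), "",
    "Biplot\t0\t0", "",
    "Site constraints\t0\t0")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ordination
#' @return `read_ordination`: a `treecoda_ordination`.
#' @export
read_ordination <- function(path) {
  lines <- readLines(path)
  find <- function(tag) grep(paste0("^", tag, "\t"), lines)[1]
  getvec <- function(tag) as.numeric(strsplit(lines[find(tag) + 1], "\t")[[1]])
  getmat <- function(tag) {
    i <- find(tag)
    hdr <- as.integer(strsplit(lines[i], "\t")[[1]][-1])
    if (hdr[1] == 0) return(NULL)
    rows <- lines[(i + 1):(i + hdr[1])]
    parts <- strsplit(rows, "\t")
    m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
    rownames(m) <- vapply(parts, `[`, "", 1)
    m
  }
  ev <- getvec("Eigvals")
  prop <- getvec("Proportion explained")
  loadings <- getmat("Species")
  scores <- getmat("Site")
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(ev))
  new_ordination(ev, prop, scores, loadings)
}

# plain-text run manifest: key = value lines
write_manifest <- function(path, params) {
  lines <- c(sprintf("treecoda_version = %s",
                     as.character(utils::packageVersion("treecoda"))),
             sprintf("created = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(params),
                    function(k) sprintf("%s = %s", k,
                                        paste(as.character(params[[k]]), collapse = ",")),
                    ""))
  writeLines(lines, path)
  invisible(path)
}
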