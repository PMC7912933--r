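# Plain-text serialization: square TSV and PHYLIP for distance matrices,
# TSV with a '#key: value' metadata block for MeTRe matrices, JSON for
# summaries. Machine-readable files carry proportions; percentages appear
# only in human-facing reports.

#' Write a distance matrix as square TSV
#'
#' First row and first column carry the labels; a `#gap_mode:` comment
#' line precedes the table when known.
#'
#' @param dm a `dist_matrix` (or any labelled symmetric matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  gm <- attr(dm, "gap_mode")
  if (!is.null(gm)) writeLines(paste0("#gap_mode: ", gm), con)
  writeLines(paste(c("", rownames(dm)), collapse = "\t"), con)
  m <- unclass(dm)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i],
                       format(m[i, ], digits = 12, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a square TSV distance matrix written by [write_distance_tsv()]
#'
#' @param path input path.
#' @return a `dist_matrix`.
#' @export
read_distance_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  labels <- fields[[1L]][-1L]
  m <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_along(labels))
    m[i, ] <- as.numeric(fields[[i + 1L]][-1L])
  gm <- sub("^#gap_mode: ", "", grep("^#gap_mode:", meta, value = TRUE))
  structure(m, gap_mode = if (length(gm)) gm else NULL,
            class = c("dist_matrix", "matrix"))
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm labelled symmetric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_square <- function(dm, path) {
  m <- unclass(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(sprintf("%-10s", rownames(m)[i]),
                       sprintf("%.8f", m[i, ])), collapse = "  "), con)
  invisible(path)
}

#' Write a MeTRe matrix as TSV with a metadata header
#'
#' @param m a `metre_matrix`.
#' @param path output path.
#' @param marker optional marker label recorded in the header.
#' @return `path`, invisibly.
#' @export
write_metre_tsv <- function(m, path, marker = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#mode: ", attr(m, "mode")), con)
  if (!is.null(attr(m, "Th")))
    writeLines(paste0("#Th: ", format(attr(m, "Th"), digits = 12)), con)
  gm <- attr(m, "provenance")$gap_mode
  if (!is.null(gm)) writeLines(paste0("#gap_mode: ", gm), con)
  if (!is.null(marker)) writeLines(paste0("#marker: ", marker), con)
  writeLines(paste(c("", rownames(m)), collapse = "\t"), con)
  mm <- unclass(m)
  for (i in seq_len(nrow(mm)))
    writeLines(paste(c(rownames(mm)[i],
                       format(mm[i, ], digits = 12, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Write a MeTRe summary as JSON
#'
#' @param s a `metre_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metre_summary_json <- function(s, path) {
  jsonlite::write_json(unclass(s), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
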