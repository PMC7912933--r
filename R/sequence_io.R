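# Sequence sets are named character vectors of uppercase residues with an
# optional "descriptions" attribute (named by id). Ids are the first
# whitespace-delimited token of the FASTA header; the rest is description.

validate_seqs <- function(x, gapped = FALSE, context = "sequence set") {
  if (length(x) == 0L)
    stop(context, ": empty sequence set", call. = FALSE)
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)))
    stop(context, ": every record needs a non-empty id", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(context, ": duplicate id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  empty <- ids[!nzchar(x)]
  if (length(empty))
    stop(context, ": empty sequence for record(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  allowed <- c(IUPAC_CODES, if (gapped) "-")
  bad <- vapply(x, function(s) {
    chars <- unique(strsplit(s, "", fixed = TRUE)[[1L]])
    any(!chars %in% allowed)
  }, logical(1L))
  if (any(bad))
    stop(context, ": invalid residue characters in record(s): ",
         paste(ids[bad], collapse = ", "),
         if (!gapped) " (gap characters are forbidden in unaligned records)",
         call. = FALSE)
  invisible(x)
}

#' Read a FASTA file
#'
#' Residues are uppercased; `T` is used for `U`. The record id is the first
#' whitespace-delimited token of the header and must be unique within the
#' file; the remainder of the header is kept as the description.
#'
#' @param path path to a FASTA file.
#' @param gapped accept `-` gap characters (aligned FASTA). Default `FALSE`.
#' @return named character vector of residues, with a `descriptions`
#'   attribute (named character vector, `""` where the header had no
#'   description).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 an example", "acgt"), f)
#' read_fasta(f)
read_fasta <- function(path, gapped = FALSE) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  validate_seqs(seqs, gapped = gapped, context = path)
  attr(seqs, "descriptions") <- setNames(desc, ids)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of residues (optionally with a
#'   `descriptions` attribute, as returned by [read_fasta()]).
#' @param path output path.
#' @param wrap line width for wrapping sequence lines. Default 80.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 80L) {
  stopifnot(is.character(seqs), length(seqs) > 0L, wrap >= 1L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every record needs a non-empty id", call. = FALSE)
  desc <- attr(seqs, "descriptions")
  headers <- names(seqs)
  if (!is.null(desc)) {
    d <- desc[headers]
    has <- !is.na(d) & nzchar(d)
    headers[has] <- paste(headers[has], d[has])
  }
  set <- Biostrings::BStringSet(setNames(unname(seqs), headers))
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(wrap))
  invisible(path)
}

#' Load a strain-to-species table
#'
#' Reads a tab-separated table with header columns `strain_id`, `species`
#' and `is_type` (0/1). At most one type strain is allowed per species, and
#' a strain may not be listed under two species.
#'
#' @param path path to the TSV file.
#' @return an object of class `species_map`: a list with `species` (named
#'   character vector, strain id -> species label) and `type_strains`
#'   (named character vector, species label -> type strain id).
#' @export
load_species_map <- function(path) {
  if (!file.exists(path))
    stop("species map not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("strain_id", "species", "is_type")
  if (!all(need %in% names(df)))
    stop("species map must have columns strain_id, species, is_type",
         call. = FALSE)
  species_map(df$strain_id, df$species, as.integer(df$is_type) == 1L)
}

#' Construct a species map from vectors
#'
#' @param strain_id character vector of strain ids.
#' @param species character vector of species labels, parallel to
#'   `strain_id`.
#' @param is_type logical vector flagging type strains.
#' @return a `species_map` object; see [load_species_map()].
#' @export
species_map <- function(strain_id, species, is_type = rep(FALSE, length(strain_id))) {
  stopifnot(length(strain_id) == length(species),
            length(strain_id) == length(is_type))
  if (any(!is_type %in% c(TRUE, FALSE)))
    stop("is_type must be 0/1", call. = FALSE)
  dup <- duplicated(strain_id)
  if (any(dup)) {
    # duplicates allowed only when fully consistent
    for (id in unique(strain_id[dup])) {
      sp <- unique(species[strain_id == id])
      if (length(sp) > 1L)
        stop("strain ", id, " listed with conflicting species: ",
             paste(sp, collapse = ", "), call. = FALSE)
    }
    keep <- !dup
    strain_id <- strain_id[keep]; species <- species[keep]
    is_type <- is_type[keep]
  }
  types <- strain_id[is_type]
  tsp <- species[is_type]
  if (anyDuplicated(tsp))
    stop("two type strains for species: ",
         paste(unique(tsp[duplicated(tsp)]), collapse = ", "), call. = FALSE)
  out <- list(species = setNames(species, strain_id),
              type_strains = setNames(types, tsp))
  class(out) <- "species_map"
  out
}

#' @export
print.species_map <- function(x, ...) {
  tab <- table(x$species)
  cat("species_map:", length(x$species), "strains in", length(tab),
      "species;", length(x$type_strains), "type strain(s)\n")
  print(tab)
  invisible(x)
}

#' Look up the species of a strain
#'
#' Captured-marker ids may carry a `.k` copy suffix (`genome.1`,
#' `genome.2`, ...); if the id is not found verbatim the suffix is stripped
#' and the lookup retried.
#'
#' @param map a `species_map`.
#' @param ids character vector of strain ids.
#' @return character vector of species labels.
#' @export
species_of <- function(map, ids) {
  sp <- unname(map$species[ids])
  miss <- is.na(sp)
  if (any(miss)) {
    stripped <- sub("\\.[0-9]+$", "", ids[miss])
    sp[miss] <- unname(map$species[stripped])
  }
  if (anyNA(sp))
    stop("strain(s) not in species map: ",
         paste(ids[is.na(sp)], collapse = ", "), call. = FALSE)
  sp
}
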