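# Raw p-distances: the proportion of compared sites at which two aligned
# sequences differ (transitions and transversions both count). Sites with
# a gap or an IUPAC ambiguity code are excluded -- globally under complete
# deletion, per pair under pairwise deletion. A pair with zero retained
# sites is undefined (NA), never 0.

ACGT <- c("A", "C", "G", "T")

#' Raw p-distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or an ambiguity code are
#' excluded; the distance is the number of differing retained sites over
#' the number of retained sites. For a single pair, complete and pairwise
#' deletion coincide.
#'
#' @param a,b gapped sequences of equal length (character scalars).
#' @return proportion in `[0, 1]`, or `NA` when no site is retained.
#' @export
#' @examples
#' p_distance("ACGT", "ACGA")   # 0.25
#' p_distance("AC-T", "ACGT")   # 0 over 3 retained sites
p_distance <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb))
    stop("sequences differ in aligned length", call. = FALSE)
  keep <- ca %in% ACGT & cb %in% ACGT
  n <- sum(keep)
  if (n == 0L) return(NA_real_)
  sum(ca[keep] != cb[keep]) / n
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln a `multi_alignment` (or a named character vector of equal-
#'   length gapped sequences).
#' @param gap_mode `"complete_deletion"` (default): sites containing a gap
#'   or ambiguity in any record are excluded globally before comparison;
#'   `"pairwise_deletion"`: exclusion is per pair.
#' @return object of class `dist_matrix`: a symmetric numeric matrix with
#'   zero diagonal, labels in input order, `NA` for undefined pairs, and
#'   the gap mode in attribute `gap_mode`.
#' @export
distance_matrix <- function(aln,
                            gap_mode = c("complete_deletion",
                                         "pairwise_deletion")) {
  gap_mode <- match.arg(gap_mode)
  if (inherits(aln, "multi_alignment")) aln <- aln$records
  if (length(aln) < 2L) stop("need >= 2 records", call. = FALSE)
  chars <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  if (is.null(dim(chars)) || anyNA(chars))
    stop("records differ in aligned length", call. = FALSE)
  valid <- matrix(chars %in% ACGT, nrow = nrow(chars))
  if (gap_mode == "complete_deletion") {
    keep <- apply(valid, 2L, all)
    chars <- chars[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- valid[i, ] & valid[j, ]
    m <- sum(keep)
    d[i, j] <- d[j, i] <-
      if (m == 0L) NA_real_ else sum(chars[i, keep] != chars[j, keep]) / m
  }
  structure(d, gap_mode = gap_mode, class = c("dist_matrix", "matrix"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("p-distance matrix (", attr(x, "gap_mode"), "), ", nrow(x),
      " sequences\n", sep = "")
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(m, digits = 4)
  invisible(x)
}

#' Within- and between-species mean distances
#'
#' Within-species means average all unordered strain pairs inside one
#' species; between-species means average all cross pairs of two species
#' (arithmetic means). Singleton species have an undefined (NA) within
#' mean, never 0.
#'
#' @param dm a `dist_matrix` (any symmetric labelled matrix works).
#' @param map a `species_map`; every matrix label must resolve to a
#'   species (captured-marker `.k` suffixes are handled).
#' @return object of class `group_dist_summary`: list with `within`
#'   (named numeric), `n_within`, `between` (symmetric species x species
#'   matrix, NA diagonal), `n_between`, and `gap_mode`.
#' @export
group_means <- function(dm, map) {
  labels <- rownames(dm)
  sp <- species_of(map, labels)
  species <- unique(sp)
  ns <- length(species)
  within <- setNames(rep(NA_real_, ns), species)
  n_within <- setNames(integer(ns), species)
  between <- matrix(NA_real_, ns, ns, dimnames = list(species, species))
  n_between <- matrix(0L, ns, ns, dimnames = list(species, species))
  for (i in seq_len(ns)) {
    ii <- which(sp == species[i])
    if (length(ii) >= 2L) {
      vals <- dm[ii, ii][upper.tri(diag(length(ii)))]
      vals <- vals[!is.na(vals)]
      n_within[i] <- length(vals)
      if (length(vals)) within[i] <- mean(vals)
    }
    if (i < ns) for (j in (i + 1L):ns) {
      jj <- which(sp == species[j])
      vals <- as.vector(dm[ii, jj, drop = FALSE])
      vals <- vals[!is.na(vals)]
      n_between[i, j] <- n_between[j, i] <- length(vals)
      if (length(vals))
        between[i, j] <- between[j, i] <- mean(vals)
    }
  }
  structure(list(within = within, n_within = n_within, between = between,
                 n_between = n_between, gap_mode = attr(dm, "gap_mode")),
            class = "group_dist_summary")
}

#' @export
print.group_dist_summary <- function(x, ...) {
  cat("group mean p-distances:", length(x$within), "species\n")
  cat("within:\n")
  print(round(x$within, 5))
  cat("between:\n")
  print(round(x$between, 5))
  invisible(x)
}

#' Distances from one species' strains to a reference type strain
#'
#' The data behind per-species distance panels: every strain of
#' `focal_species` is compared with the type strain of
#' `reference_species`. When focal and reference coincide, the type strain
#' itself is excluded.
#'
#' @param dm a `dist_matrix`.
#' @param map a `species_map` whose `type_strains` contains
#'   `reference_species`.
#' @param focal_species,reference_species species labels.
#' @return named numeric vector of distances (names = focal strain ids).
#' @export
distances_to_type <- function(dm, map, focal_species, reference_species) {
  type_id <- map$type_strains[reference_species]
  if (is.na(type_id) || is.null(type_id) || !type_id %in% rownames(dm))
    stop("no type strain of '", reference_species,
         "' present in the distance matrix", call. = FALSE)
  labels <- rownames(dm)
  sp <- species_of(map, labels)
  focal <- labels[sp == focal_species & labels != type_id]
  setNames(dm[focal, type_id], focal)
}

#' Tidy table of group mean distances
#'
#' One row per species (within) and per unordered species pair (between),
#' with the number of contributing pairs.
#'
#' @param gs a `group_dist_summary`.
#' @return data frame with columns `species_i`, `species_j`,
#'   `mean_distance`, `n_pairs`.
#' @export
group_means_table <- function(gs) {
  species <- names(gs$within)
  rows <- data.frame(species_i = species, species_j = species,
                     mean_distance = unname(gs$within),
                     n_pairs = unname(gs$n_within),
                     stringsAsFactors = FALSE)
  ns <- length(species)
  if (ns >= 2L) for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    rows <- rbind(rows, data.frame(
      species_i = species[i], species_j = species[j],
      mean_distance = gs$between[i, j], n_pairs = gs$n_between[i, j],
      stringsAsFactors = FALSE))
  }
  rows
}
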