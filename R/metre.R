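# Mean Taxonomic Resolution (MeTRe): the mean between-species distance of
# a pair, expressed in units of the pair's internal variability -- either
# the sum of the two species' mean within-species distances
# (actual-variability form) or a fixed marker threshold Th equal to two
# half-thresholds (fixed-threshold form). MeTRe > 1: the marker resolves
# the pair; MeTRe <= 1: it does not. The matrix diagonal is 1 by
# convention (a species against itself).

#' MeTRe of one species pair (actual variability)
#'
#' `dist_ij / (dist_i + dist_j)`. A zero denominator with positive
#' separation yields `Inf` (flagged degenerate, excluded from summaries);
#' 0/0 yields `NaN` (undefined).
#'
#' @param dist_ij mean between-species distance (proportion).
#' @param dist_i,dist_j mean within-species distances (proportions).
#' @return the MeTRe value.
#' @export
#' @examples
#' metre_pair(0.05, 0.02, 0.03)  # 1: boundary of resolution
#' metre_pair(0.10, 0.02, 0.03)  # 2
metre_pair <- function(dist_ij, dist_i, dist_j) {
  vals <- c(dist_ij, dist_i, dist_j)
  if (anyNA(vals)) return(NA_real_)
  if (any(vals < 0)) stop("distances must be non-negative", call. = FALSE)
  denom <- dist_i + dist_j
  if (denom == 0) return(if (dist_ij > 0) Inf else NaN)
  dist_ij / denom
}

#' MeTRe of one species pair (fixed threshold)
#'
#' `dist_ij / Th`, where `Th` is the sum of the two half-thresholds
#' accepted for the marker (e.g. 0.014 for ITS, 0.010 for LSU).
#'
#' @param dist_ij mean between-species distance (proportion).
#' @param Th threshold distance (proportion), `> 0`.
#' @return the MeTRe value.
#' @export
#' @examples
#' metre_pair_threshold(0.028, 0.014)  # 2
metre_pair_threshold <- function(dist_ij, Th) {
  if (is.na(Th) || Th <= 0) stop("Th must be > 0", call. = FALSE)
  if (is.na(dist_ij)) return(NA_real_)
  if (dist_ij < 0) stop("distances must be non-negative", call. = FALSE)
  dist_ij / Th
}

#' Assemble a MeTRe matrix
#'
#' Off-diagonal cells hold the MeTRe of each species pair; the descending
#' diagonal is exactly 1 by convention (the intraspecific distance divided
#' by itself).
#'
#' @param summary a `group_dist_summary` from [group_means()].
#' @param mode `"actual_variability"` (default) uses each species' mean
#'   within-species distance; `"fixed_threshold"` uses `Th`.
#' @param Th threshold proportion, required in fixed-threshold mode.
#' @param fallback_within optional within-species distance used for
#'   species whose own within mean is undefined (singletons) in
#'   actual-variability mode; when absent such pairs are `NA`.
#' @return object of class `metre_matrix`: square numeric matrix with
#'   unit diagonal and attributes `mode`, `Th` and `provenance` (the
#'   input summary).
#' @export
metre_matrix <- function(summary,
                         mode = c("actual_variability", "fixed_threshold"),
                         Th = NULL, fallback_within = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_threshold" && (is.null(Th) || Th <= 0))
    stop("fixed_threshold mode requires Th > 0", call. = FALSE)
  species <- names(summary$within)
  ns <- length(species)
  m <- matrix(NA_real_, ns, ns, dimnames = list(species, species))
  diag(m) <- 1
  w <- summary$within
  if (!is.null(fallback_within)) w[is.na(w)] <- fallback_within
  if (ns >= 2L) for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    b <- summary$between[i, j]
    v <- if (mode == "fixed_threshold") metre_pair_threshold(b, Th)
         else metre_pair(b, w[i], w[j])
    m[i, j] <- m[j, i] <- v
  }
  structure(m, mode = mode, Th = Th, provenance = summary,
            class = c("metre_matrix", "matrix"))
}

#' @export
print.metre_matrix <- function(x, ...) {
  cat("MeTRe matrix (", attr(x, "mode"),
      if (!is.null(attr(x, "Th"))) paste0(", Th = ", attr(x, "Th")),
      "), ", nrow(x), " species\n", sep = "")
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(round(m, 3))
  invisible(x)
}

#' Classify species pairs as resolved or unresolved
#'
#' A pair is resolved by the marker when its MeTRe is strictly greater
#' than 1 (`MeTRe <= 1` means no resolution). Infinite values (zero
#' internal variability, positive separation) classify as resolved;
#' undefined values as unresolved, flagged in attribute `undefined`.
#'
#' @param m a `metre_matrix`.
#' @return logical matrix, `FALSE` on the diagonal.
#' @export
classify_resolution <- function(m) {
  res <- unclass(m) > 1
  res[is.na(res)] <- FALSE
  diag(res) <- FALSE
  attr(res, "undefined") <- which(is.na(unclass(m)), arr.ind = TRUE)
  res
}

#' Summary statistics of a MeTRe matrix
#'
#' Mean, min and max over the unordered off-diagonal pairs (upper
#' triangle); per-species row means excluding the diagonal. Infinite
#' entries are excluded from means and counted separately; undefined
#' entries likewise.
#'
#' @param m a `metre_matrix`.
#' @return object of class `metre_summary`: list with
#'   `mean_off_diagonal`, `min`, `max`, `per_species_mean`,
#'   `n_unresolved_pairs` (off-diagonal pairs with MeTRe <= 1),
#'   `n_infinite`, `n_undefined`, `n_pairs`, `mode`, `Th`.
#' @export
summarize_metre <- function(m) {
  stopifnot(nrow(m) >= 2L)
  v <- unclass(m)[upper.tri(m)]
  fin <- v[is.finite(v)]
  if (length(fin) == 0L)
    stop("no defined finite MeTRe values to summarize", call. = FALSE)
  per <- vapply(seq_len(nrow(m)), function(i) {
    row <- unclass(m)[i, -i]
    mean(row[is.finite(row)])
  }, numeric(1L))
  structure(list(
    mean_off_diagonal = mean(fin),
    min = min(fin), max = max(fin),
    per_species_mean = setNames(per, rownames(m)),
    n_unresolved_pairs = sum(v <= 1, na.rm = TRUE),
    n_infinite = sum(is.infinite(v)),
    n_undefined = sum(is.na(v) & !is.nan(v)) + sum(is.nan(v)),
    n_pairs = length(v),
    mode = attr(m, "mode"), Th = attr(m, "Th")),
    class = "metre_summary")
}

#' @export
print.metre_summary <- function(x, ...) {
  cat("MeTRe summary (", x$mode, "): mean ",
      round(x$mean_off_diagonal, 3), ", range [",
      round(x$min, 3), ", ", round(x$max, 3), "], ",
      x$n_unresolved_pairs, "/", x$n_pairs, " pairs unresolved\n",
      sep = "")
  invisible(x)
}
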