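# Marker capture: anchor on maximal exact matches between probe and
# genome (both orientations), chain colinear anchors per locus, extract
# the bounding region. Coordinates are 1-based inclusive on the genome
# (reference) and on the probe in its forward orientation.

#' Find maximal exact matches between a genome and a probe
#'
#' Reports every maximal exact match of length `>= min_match_len` between
#' the probe (in either orientation) and any contig of the genome,
#' regardless of uniqueness. A match is maximal when it cannot be extended
#' on either side. Only A/C/G/T match; N and ambiguity codes break matches.
#'
#' @param genome named character vector of contig sequences.
#' @param probe a single probe sequence (character scalar, or a length-1
#'   named vector).
#' @param min_match_len minimum anchor length. Default 20.
#' @return data frame with columns `contig`, `ref_start`, `ref_end`,
#'   `qry_start`, `qry_end`, `length`, `strand`. Probe coordinates are
#'   always on the forward probe; for reverse-strand matches the genome
#'   region matches the reverse complement of
#'   `probe[qry_start..qry_end]`.
#' @export
find_exact_matches <- function(genome, probe, min_match_len = 20L) {
  if (length(genome) == 0L) stop("empty genome", call. = FALSE)
  probe <- unname(probe)[1L]
  m <- nchar(probe)
  if (m < min_match_len)
    stop("probe (", m, " nt) shorter than min_match_len (",
         min_match_len, ")", call. = FALSE)
  rc <- revcomp(probe)
  res <- vector("list", 2L * length(genome))
  k <- 0L
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    fwd <- .mem_scan(genome[[ci]], probe, as.integer(min_match_len))
    if (nrow(fwd)) {
      k <- k + 1L
      res[[k]] <- data.frame(contig = contig, fwd, strand = "forward",
                             stringsAsFactors = FALSE)
    }
    rev <- .mem_scan(genome[[ci]], rc, as.integer(min_match_len))
    if (nrow(rev)) {
      # map probe coordinates back to the forward orientation
      qs <- m - rev[, "qry_end"] + 1L
      qe <- m - rev[, "qry_start"] + 1L
      rev[, "qry_start"] <- qs
      rev[, "qry_end"] <- qe
      k <- k + 1L
      res[[k]] <- data.frame(contig = contig, rev, strand = "reverse",
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(contig = character(), ref_start = integer(),
                      ref_end = integer(), qry_start = integer(),
                      qry_end = integer(), length = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res[seq_len(k)])
  out <- out[order(out$contig, out$strand, out$ref_start, out$qry_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# best colinear chain (maximum total matched bases) within one cluster of
# anchors on one contig+strand; O(n^2) dynamic programme.
chain_cluster <- function(mm, reverse) {
  n <- nrow(mm)
  ord <- order(mm$ref_start, mm$qry_start)
  mm <- mm[ord, , drop = FALSE]
  best <- mm$length
  prev <- rep(0L, n)
  if (n > 1L) {
    for (j in 2:n) {
      for (i in 1:(j - 1L)) {
        ok <- mm$ref_start[j] > mm$ref_end[i] &&
          (if (reverse) mm$qry_end[j] < mm$qry_start[i]
           else mm$qry_start[j] > mm$qry_end[i])
        if (ok && best[i] + mm$length[j] > best[j]) {
          best[j] <- best[i] + mm$length[j]
          prev[j] <- i
        }
      }
    }
  }
  end <- which.max(best)           # first index on ties: deterministic
  idx <- integer(0)
  while (end != 0L) {
    idx <- c(end, idx)
    end <- prev[end]
  }
  chain <- mm[idx, , drop = FALSE]
  list(S1 = min(chain$ref_start), E1 = max(chain$ref_end),
       matched = sum(chain$length), n_anchors = nrow(chain))
}

#' Chain exact matches into candidate marker loci
#'
#' Per contig and strand, anchors are clustered (a new cluster starts when
#' the genomic gap to the previous anchor exceeds `max_gap`) and the best
#' colinear chain of each cluster — the ordered subset, non-overlapping and
#' increasing in both coordinates (probe coordinates decreasing on the
#' reverse strand), that maximizes total matched bases — becomes one
#' candidate locus. Coverage is the fraction of probe bases covered by the
#' chain.
#'
#' @param matches data frame as returned by [find_exact_matches()].
#' @param probe_len probe length in bases.
#' @param max_gap genomic gap that splits clusters; default `probe_len`.
#' @return data frame with columns `contig`, `strand`, `S1`, `E1`,
#'   `matched_bases`, `n_anchors`, `coverage`.
#' @export
chain_matches <- function(matches, probe_len, max_gap = probe_len) {
  empty <- data.frame(contig = character(), strand = character(),
                      S1 = integer(), E1 = integer(),
                      matched_bases = integer(), n_anchors = integer(),
                      coverage = numeric(), stringsAsFactors = FALSE)
  if (is.null(matches) || nrow(matches) == 0L) return(empty)
  stopifnot(probe_len >= 1)
  out <- list()
  for (key in split(seq_len(nrow(matches)),
                    paste(matches$contig, matches$strand, sep = "\r"))) {
    mm <- matches[key, , drop = FALSE]
    mm <- mm[order(mm$ref_start, mm$qry_start), , drop = FALSE]
    gap_before <- c(0, mm$ref_start[-1L] - cummax(mm$ref_end)[-nrow(mm)])
    cluster <- cumsum(gap_before > max_gap)
    for (cl in split(seq_len(nrow(mm)), cluster)) {
      sub <- mm[cl, , drop = FALSE]
      ch <- chain_cluster(sub, reverse = sub$strand[1L] == "reverse")
      out[[length(out) + 1L]] <- data.frame(
        contig = sub$contig[1L], strand = sub$strand[1L],
        S1 = ch$S1, E1 = ch$E1, matched_bases = ch$matched,
        n_anchors = ch$n_anchors,
        coverage = ch$matched / probe_len, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$strand, out$S1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a genome region
#'
#' `S1` and `E1` are 1-based and both inclusive (faidx region semantics).
#' Reverse-strand extraction returns the reverse complement of the slice.
#'
#' @param genome named character vector of contigs.
#' @param contig contig id.
#' @param S1,E1 region bounds, 1-based inclusive, `S1 <= E1`.
#' @param strand `"forward"` or `"reverse"`.
#' @return the extracted residues (character scalar).
#' @export
#' @examples
#' extract_region(c(chr = "ACGTACGT"), "chr", 2, 4)           # "CGT"
#' extract_region(c(chr = "ACGTACGT"), "chr", 2, 4, "reverse") # "ACG"
extract_region <- function(genome, contig, S1, E1,
                           strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  if (!contig %in% names(genome))
    stop("unknown contig: ", contig, call. = FALSE)
  len <- nchar(genome[[contig]])
  if (S1 < 1 || E1 > len || S1 > E1)
    stop("region ", S1, "-", E1, " out of range for contig ", contig,
         " (length ", len, ")", call. = FALSE)
  s <- substr(genome[[contig]], S1, E1)
  if (strand == "reverse") s <- revcomp(s)
  s
}

#' Capture a marker locus from a genome assembly
#'
#' Runs anchor finding and chaining, keeps candidate loci with coverage at
#' least `min_coverage`, merges candidates whose genomic regions overlap by
#' more than half of the shorter region (keeping the higher-coverage one;
#' ties broken by longer region, then contig, then smaller start), and
#' extracts each surviving region. Reverse-strand hits are
#' reverse-complemented so all captured sequences share the probe's
#' orientation. Multiple disjoint hits (multi-copy loci, hybrid genomes)
#' are all returned, with ids `genome_id.1`, `genome_id.2`, ... ordered by
#' descending coverage then by contig and start.
#'
#' @param genome named character vector of contigs.
#' @param probe probe sequence (character scalar or length-1 named vector).
#' @param genome_id id used for the captured records; defaults to the name
#'   of `probe`'s genome, `"genome"` when unknown.
#' @param marker marker label stored with each hit.
#' @param min_match_len minimum anchor length (default 20).
#' @param min_coverage minimum fraction of probe bases an accepted locus
#'   must cover (default 0.5).
#' @return data frame of class `captured_markers` with columns `hit_id`,
#'   `genome_id`, `marker`, `contig`, `S1`, `E1`, `strand`, `coverage`,
#'   `sequence`. Zero rows (with a warning naming genome and marker) when
#'   no candidate passes `min_coverage`.
#' @export
capture_marker <- function(genome, probe, genome_id = "genome",
                           marker = "marker", min_match_len = 20L,
                           min_coverage = 0.5) {
  matches <- find_exact_matches(genome, probe, min_match_len)
  probe_len <- nchar(unname(probe)[1L])
  cand <- chain_matches(matches, probe_len)
  cand <- cand[cand$coverage >= min_coverage, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no hit passed coverage ", min_coverage, " for marker '",
            marker, "' in genome '", genome_id, "'", call. = FALSE)
    out <- data.frame(hit_id = character(), genome_id = character(),
                      marker = character(), contig = character(),
                      S1 = integer(), E1 = integer(), strand = character(),
                      coverage = numeric(), sequence = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("captured_markers", class(out))
    return(out)
  }
  # merge candidates whose regions overlap > 50% of the shorter region
  reglen <- cand$E1 - cand$S1 + 1L
  pref <- order(-cand$coverage, -reglen, cand$contig, cand$S1)
  cand <- cand[pref, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (cand$contig[i] != cand$contig[j]) next
      ov <- min(cand$E1[i], cand$E1[j]) - max(cand$S1[i], cand$S1[j]) + 1L
      shorter <- min(cand$E1[i] - cand$S1[i], cand$E1[j] - cand$S1[j]) + 1L
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(-cand$coverage, cand$contig, cand$S1), , drop = FALSE]
  ids <- if (nrow(cand) == 1L) genome_id else
    paste(genome_id, seq_len(nrow(cand)), sep = ".")
  seqs <- vapply(seq_len(nrow(cand)), function(i)
    extract_region(genome, cand$contig[i], cand$S1[i], cand$E1[i],
                   cand$strand[i]), character(1L))
  out <- data.frame(hit_id = ids, genome_id = genome_id, marker = marker,
                    contig = cand$contig, S1 = cand$S1, E1 = cand$E1,
                    strand = cand$strand, coverage = cand$coverage,
                    sequence = seqs, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("captured_markers", class(out))
  out
}

#' Capture one marker across many genomes
#'
#' @param genomes named list of genomes (each a named character vector of
#'   contigs); the list names are the genome ids.
#' @param probe,marker,min_match_len,min_coverage see [capture_marker()].
#' @return a single `captured_markers` data frame (row-bound hits).
#' @export
capture_marker_set <- function(genomes, probe, marker = "marker",
                               min_match_len = 20L, min_coverage = 0.5) {
  stopifnot(is.list(genomes), !is.null(names(genomes)))
  hits <- lapply(names(genomes), function(gid)
    capture_marker(genomes[[gid]], probe, genome_id = gid, marker = marker,
                   min_match_len = min_match_len,
                   min_coverage = min_coverage))
  out <- do.call(rbind, hits)
  class(out) <- c("captured_markers", "data.frame")
  out
}

#' Sequences of captured markers as a FASTA-ready set
#'
#' Record ids follow `<hit_id>|<marker>|<contig>:<S1>-<E1>(<strand>)` when
#' `annotate = TRUE`, else plain hit ids.
#'
#' @param hits a `captured_markers` data frame.
#' @param annotate include coordinates in the record description.
#' @return named character vector of sequences.
#' @export
captured_sequences <- function(hits, annotate = TRUE) {
  seqs <- setNames(hits$sequence, hits$hit_id)
  if (annotate && nrow(hits)) {
    strand_sym <- ifelse(hits$strand == "forward", "+", "-")
    attr(seqs, "descriptions") <- setNames(
      sprintf("%s|%s:%d-%d(%s)", hits$marker, hits$contig, hits$S1,
              hits$E1, strand_sym), hits$hit_id)
  }
  seqs
}
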