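# Synthetic fixtures with exact, known divergences. Substitution-only
# construction on disjoint site sets, so every pairwise p-distance is
# exact by bookkeeping, not in expectation: each species ancestor differs
# from a common reference at a_i private sites, each strain from its
# ancestor at p_i private sites, with
#   p_i = intra_div_i * seq_len / 2   and   a_i = inter_div * seq_len / 2 - p_i,
# giving within-pair distance exactly intra_div_i and every between-pair
# distance exactly inter_div. Terminal flanks of the locus are kept free
# of substitutions (conserved primer-binding regions), which also makes
# probe-based capture recover the full locus.

#' Specification of a synthetic species set
#'
#' @param n_species number of species.
#' @param strains_per_species strains per species (>= 1).
#' @param seq_len marker length in bases.
#' @param intra_div exact within-species pairwise divergence (proportion);
#'   scalar or one value per species. `intra_div * seq_len / 2` must be a
#'   whole number.
#' @param inter_div exact between-species pairwise divergence
#'   (proportion), identical for all pairs; `inter_div * seq_len / 2`
#'   must be a whole number and at least `intra_div * seq_len / 2` for
#'   every species.
#' @param genome_len background genome length for [implant_markers()].
#' @param conserved_flank substitution-free bases kept at each end of the
#'   locus. Default 30.
#' @param seed integer seed; same seed, byte-identical fixtures.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species = 2L, strains_per_species = 3L,
                           seq_len = 1000L, intra_div = 0.02,
                           inter_div = 0.10, genome_len = 10000L,
                           conserved_flank = 30L, seed = 1L) {
  stopifnot(n_species >= 1L, strains_per_species >= 1L, seq_len >= 1L,
            all(intra_div >= 0), all(intra_div <= 1),
            inter_div >= 0, inter_div <= 1, length(inter_div) == 1L,
            conserved_flank >= 0L, 2L * conserved_flank < seq_len)
  intra_div <- rep_len(intra_div, n_species)
  p <- intra_div * seq_len / 2
  half_b <- inter_div * seq_len / 2
  tol <- 1e-9
  if (any(abs(p - round(p)) > tol) || abs(half_b - round(half_b)) > tol)
    stop("unrealizable divergences: intra_div*seq_len/2 and ",
         "inter_div*seq_len/2 must be whole numbers", call. = FALSE)
  p <- as.integer(round(p)); half_b <- as.integer(round(half_b))
  a <- half_b - p
  if (n_species >= 2L && any(a < 0))
    stop("unrealizable divergences: inter_div must be at least intra_div",
         call. = FALSE)
  editable <- seq_len - 2L * conserved_flank
  budget <- sum(a) + sum(p * strains_per_species)
  if (budget > editable)
    stop("site budget exceeded: need ", budget, " editable sites, have ",
         editable, call. = FALSE)
  structure(list(n_species = as.integer(n_species),
                 strains_per_species = as.integer(strains_per_species),
                 seq_len = as.integer(seq_len), intra_div = intra_div,
                 inter_div = inter_div, genome_len = as.integer(genome_len),
                 conserved_flank = as.integer(conserved_flank),
                 seed = as.integer(seed),
                 p_sites = p, a_sites = a),
            class = "synthetic_spec")
}

random_dna <- function(n) paste(sample(ACGT, n, replace = TRUE),
                                collapse = "")

substitute_sites <- function(chars, sites) {
  for (s in sites) {
    chars[s] <- sample(setdiff(ACGT, chars[s]), 1L)
  }
  chars
}

#' Generate a synthetic species set with exact divergences
#'
#' See [synthetic_spec()] for the construction. The first strain of each
#' species is flagged as its type strain. The returned truth holds the
#' exact within/between divergences the pipeline must recover.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `sequences` (named character vector,
#'   `<species>_s<k>`), `reference` (the common ancestral sequence, usable
#'   as a capture probe), `map` (a `species_map`) and `truth` (list with
#'   `within` and `between` in the [group_means()] layout).
#' @export
make_species_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  L <- spec$seq_len
  ref <- strsplit(random_dna(L), "", fixed = TRUE)[[1L]]
  editable <- (spec$conserved_flank + 1L):(L - spec$conserved_flank)
  need <- sum(spec$a_sites) + sum(spec$p_sites * spec$strains_per_species)
  pool <- if (need > 0L) sample(editable, need) else integer(0)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  species <- sprintf("sp%02d", seq_len(spec$n_species))
  seqs <- character(0)
  ids <- character(0)
  sp_of <- character(0)
  for (i in seq_len(spec$n_species)) {
    anc <- substitute_sites(ref, take(spec$a_sites[i]))
    for (s in seq_len(spec$strains_per_species)) {
      strain <- substitute_sites(anc, take(spec$p_sites[i]))
      ids <- c(ids, sprintf("%s_s%d", species[i], s))
      sp_of <- c(sp_of, species[i])
      seqs <- c(seqs, paste(strain, collapse = ""))
    }
  }
  names(seqs) <- ids
  map <- species_map(ids, sp_of,
                     is_type = !duplicated(sp_of))
  within <- setNames(spec$intra_div, species)
  if (spec$strains_per_species < 2L) within[] <- NA_real_
  between <- matrix(spec$inter_div, spec$n_species, spec$n_species,
                    dimnames = list(species, species))
  diag(between) <- NA_real_
  list(sequences = seqs, reference = paste(ref, collapse = ""),
       map = map, truth = list(within = within, between = between))
}

#' Implant marker sequences in a random background genome
#'
#' Builds a uniform-composition background contig and copies each marker
#' sequence to its position, reverse-complemented for reverse-strand
#' implants. Implants must be within bounds and non-overlapping.
#'
#' @param genome_len background length in bases.
#' @param implants data frame with columns `marker`, `sequence`,
#'   `position` (1-based start) and `strand` (`"forward"`/`"reverse"`).
#' @param seed optional integer seed for the background draw.
#' @param contig contig id. Default `"chr1"`.
#' @return list with `genome` (named character vector of one contig) and
#'   `truth` (data frame `contig`, `marker`, `S1`, `E1`, `strand`).
#' @export
implant_markers <- function(genome_len, implants, seed = NULL,
                            contig = "chr1") {
  stopifnot(is.data.frame(implants),
            all(c("marker", "sequence", "position", "strand") %in%
                  names(implants)))
  if (!is.null(seed)) set.seed(seed)
  S1 <- as.integer(implants$position)
  E1 <- S1 + nchar(implants$sequence) - 1L
  if (any(S1 < 1L) || any(E1 > genome_len))
    stop("implant out of bounds", call. = FALSE)
  ord <- order(S1)
  if (any(S1[ord][-1L] <= E1[ord][-length(ord)]))
    stop("implants overlap", call. = FALSE)
  chars <- strsplit(random_dna(genome_len), "", fixed = TRUE)[[1L]]
  for (i in seq_len(nrow(implants))) {
    s <- implants$sequence[i]
    if (implants$strand[i] == "reverse") s <- revcomp(s)
    chars[S1[i]:E1[i]] <- strsplit(s, "", fixed = TRUE)[[1L]]
  }
  genome <- setNames(paste(chars, collapse = ""), contig)
  truth <- data.frame(contig = contig, marker = implants$marker,
                      S1 = S1, E1 = E1, strand = implants$strand,
                      stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}
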