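# End-to-end pipeline: capture -> align -> distances -> group means ->
# MeTRe -> trees, one marker at a time, writing a deterministic report
# bundle. Defaults mirror the package-wide conventions: gap open 15,
# extension 6.66, transition weight 0.3, thresholds 1.4% (ITS) and 1.0%
# (LSU); markers without an accepted threshold run in actual-variability
# mode only.

#' Default fixed thresholds per marker (proportions)
#'
#' ITS 0.014 and LSU 0.010: the accepted taxonomic thresholds, each the
#' sum of two half-thresholds (0.7% and 0.5%).
#' @return named numeric vector.
#' @export
default_thresholds <- function() c(ITS = 0.014, LSU = 0.010)

#' Assemble a pipeline configuration
#'
#' @param genomes_dir directory of genome FASTA files (`.fa`, `.fasta`,
#'   `.fna`); the file name without extension is the genome/strain id.
#' @param probes path to a FASTA of probe sequences, one per marker; the
#'   record id is the marker label.
#' @param species_map path to the strain/species TSV
#'   (see [load_species_map()]).
#' @param out_dir output directory for the report bundle.
#' @param references optional FASTA of reference (e.g. amplicon-based
#'   type-strain) sequences to include in each marker's alignment; record
#'   ids must be strain ids known to the species map.
#' @param min_match_len,min_coverage capture parameters.
#' @param gap_open,gap_ext,transition_weight,engine alignment parameters.
#' @param gap_mode distance gap handling.
#' @param thresholds named vector of fixed thresholds (proportions) per
#'   marker; markers absent from it are scored in actual-variability mode
#'   only.
#' @param compare_with optional named list, marker -> path of a square
#'   distance TSV (e.g. from amplicon-based sequences) to compare against
#'   with a Mantel test.
#' @param seed integer seed (Mantel permutations).
#' @param n_perm Mantel permutation count.
#' @return a `run_config` list.
#' @export
run_config <- function(genomes_dir, probes, species_map, out_dir,
                       references = NULL, min_match_len = 20L,
                       min_coverage = 0.5, gap_open = 15, gap_ext = 6.66,
                       transition_weight = 0.3, engine = "builtin",
                       gap_mode = "complete_deletion",
                       thresholds = default_thresholds(),
                       compare_with = NULL, seed = 1L, n_perm = 999L) {
  cfg <- list(genomes_dir = genomes_dir, probes = probes,
              species_map = species_map, out_dir = out_dir,
              references = references, min_match_len = min_match_len,
              min_coverage = min_coverage, gap_open = gap_open,
              gap_ext = gap_ext, transition_weight = transition_weight,
              engine = engine, gap_mode = gap_mode,
              thresholds = thresholds, compare_with = compare_with,
              seed = as.integer(seed), n_perm = as.integer(n_perm))
  class(cfg) <- "run_config"
  cfg
}

read_genomes_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|fna)$",
                      full.names = TRUE)
  if (!length(files)) stop("no FASTA files in ", dir, call. = FALSE)
  genomes <- lapply(files, read_fasta)
  names(genomes) <- sub("\\.(fa|fasta|fna)$", "", basename(files))
  genomes[order(names(genomes))]
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full marker-evaluation pipeline
#'
#' For each probe: captures the marker from every genome, merges in any
#' reference sequences, aligns, computes the p-distance matrix, group
#' means, distances to each type strain, MeTRe matrices
#' (actual-variability always; fixed-threshold when the marker has a
#' threshold), summary statistics, and a neighbor-joining tree when the
#' matrix allows one. All outputs are plain text under `out_dir`, and a
#' run log records every parameter, so a rerun with the same
#' configuration and seed reproduces the bundle byte for byte.
#'
#' @param config a `run_config` (or path to a JSON file of one).
#' @return invisibly, a named list of per-marker results (`captures`,
#'   `alignment`, `distances`, `group_means`, `metre_actual`,
#'   `metre_threshold`, `summary`, `tree`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg$thresholds <- unlist(cfg$thresholds)
    config <- do.call(run_config, cfg)
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  genomes <- stage("load_genomes", read_genomes_dir(config$genomes_dir))
  probes <- stage("load_probes", read_fasta(config$probes))
  map <- stage("load_species_map", load_species_map(config$species_map))
  refs <- if (!is.null(config$references))
    stage("load_references", read_fasta(config$references)) else NULL

  log_lines <- c("metre run log",
                 paste0("n_genomes: ", length(genomes)),
                 paste0("markers: ", paste(names(probes), collapse = ", ")),
                 vapply(c("min_match_len", "min_coverage", "gap_open",
                          "gap_ext", "transition_weight", "engine",
                          "gap_mode", "seed", "n_perm"),
                        function(k) paste0(k, ": ",
                                           paste(config[[k]], collapse = " ")),
                        character(1L)))

  results <- list()
  for (marker in names(probes)) {
    probe <- probes[marker]
    mdir <- file.path(config$out_dir, marker)
    dir.create(mdir, showWarnings = FALSE)

    hits <- stage(paste0("capture:", marker),
                  capture_marker_set(genomes, probe, marker = marker,
                                     min_match_len = config$min_match_len,
                                     min_coverage = config$min_coverage))
    seqs <- captured_sequences(hits)
    write_fasta(seqs, file.path(mdir, "captured.fasta"))
    write.table(hits[, setdiff(names(hits), "sequence")],
                file.path(mdir, "coordinates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(refs)) {
      add <- refs[setdiff(names(refs), names(seqs))]
      if (length(add)) seqs <- c(seqs, add)
    }
    if (length(seqs) < 2L)
      stop("pipeline stage 'align:", marker,
           "' failed: fewer than 2 sequences captured", call. = FALSE)

    aln <- stage(paste0("align:", marker),
                 align_multiple(seqs, gap_open = config$gap_open,
                                gap_ext = config$gap_ext,
                                transition_weight = config$transition_weight,
                                engine = config$engine))
    write_fasta(aln$records, file.path(mdir, "alignment.fasta"))

    dm <- stage(paste0("distances:", marker),
                distance_matrix(aln, gap_mode = config$gap_mode))
    write_distance_tsv(dm, file.path(mdir, "distances.tsv"))
    write_phylip_square(dm, file.path(mdir, "distances.phy"))

    gs <- stage(paste0("group_means:", marker), group_means(dm, map))
    write.table(group_means_table(gs),
                file.path(mdir, "group_means.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    # distances of every species' strains to every available type strain
    t2t <- list()
    for (ref_sp in names(map$type_strains)) {
      if (!map$type_strains[ref_sp] %in% rownames(dm)) next
      for (foc_sp in unique(species_of(map, rownames(dm)))) {
        v <- distances_to_type(dm, map, foc_sp, ref_sp)
        if (length(v))
          t2t[[length(t2t) + 1L]] <- data.frame(
            focal_species = foc_sp, reference_species = ref_sp,
            strain = names(v), distance = unname(v),
            stringsAsFactors = FALSE)
      }
    }
    if (length(t2t))
      write.table(do.call(rbind, t2t),
                  file.path(mdir, "distances_to_type.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)

    n_species <- length(unique(species_of(map, rownames(dm))))
    if (n_species < 2L)
      stop("pipeline stage 'metre:", marker,
           "' failed: need >= 2 species (found ", n_species, ")",
           call. = FALSE)
    ma <- stage(paste0("metre:", marker),
                metre_matrix(gs, mode = "actual_variability"))
    write_metre_tsv(ma, file.path(mdir, "metre_actual.tsv"),
                    marker = marker)
    smry <- list(actual_variability = unclass(summarize_metre(ma)))
    mt <- NULL
    th <- unname(config$thresholds[marker])
    if (length(th) == 1L && !is.na(th)) {
      mt <- metre_matrix(gs, mode = "fixed_threshold", Th = th)
      write_metre_tsv(mt, file.path(mdir, "metre_threshold.tsv"),
                      marker = marker)
      smry$fixed_threshold <- unclass(summarize_metre(mt))
    }
    jsonlite::write_json(smry, file.path(mdir, "metre_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    tree <- NULL
    if (nrow(dm) >= 3L && !anyNA(dm)) {
      tree <- stage(paste0("tree:", marker), nj_tree(dm))
      ape::write.tree(tree, file.path(mdir, "nj.nwk"))
    }

    mantel <- NULL
    cw <- config$compare_with[[marker]]
    if (!is.null(cw)) {
      mantel <- stage(paste0("mantel:", marker),
                      mantel_test(dm, read_distance_tsv(cw),
                                  n_perm = config$n_perm,
                                  seed = config$seed))
      jsonlite::write_json(unclass(mantel),
                           file.path(mdir, "mantel.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
    }

    results[[marker]] <- list(captures = hits, alignment = aln,
                              distances = dm, group_means = gs,
                              metre_actual = ma, metre_threshold = mt,
                              summary = smry, tree = tree,
                              mantel = mantel)
    log_lines <- c(log_lines,
                   paste0("marker ", marker, ": ", nrow(hits),
                          " captured sequence(s), ", n_species,
                          " species"))
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(results)
}
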