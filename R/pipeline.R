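#' Default end-to-end pipeline configuration
#'
#' All stochastic stages carry explicit seeds derived from the master seed.
#' The configuration round-trips losslessly through YAML
#' (\code{\link{write_config}} / \code{\link{read_config}}).
#'
#' @param seed master seed.
#' @param ... named overrides of any top-level section (lists are merged).
#' @return nested list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = list(n_species = 20L, amplicon_length = 200L,
                    within_genus_divergence = 0.1,
                    n_ra = 4L, n_mets = 2L, timepoints = c("T0", "T3"),
                    marker = "16S", depth = 2000L, substitution_rate = 0.005,
                    n_pathways = 40L),
    cluster = list(grid = c(20L, 20L), rounds = 10000L,
                   cohesion_threshold = 0.95, subgrid = c(10L, 10L),
                   width = 200L),
    assign = list(min_alignment_length = 200L, match = 1, mismatch = -1,
                  gap_open = -2, gap_extend = -1),
    pathways = list(rollup = c("H1", "H2")),
    alpha = 0.05)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full synthetic-to-summary pipeline
#'
#' Executes simulate -> cluster -> assign -> frequency table -> community
#' metrics -> pathway scores end to end and writes every stage's table plus
#' a manifest (seeds, per-stage sizes and file hashes) into \code{out_dir}.
#' Rerunning with the same configuration reproduces identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("amplisom_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  sim <- config$simulate

  say("stage simulate: %d species, %d+%d donors", sim$n_species, sim$n_ra, sim$n_mets)
  reference <- generate_reference(sim$n_species, sim$amplicon_length,
                                  sim$within_genus_divergence,
                                  seed = child_seed(seed, 1L))
  design <- cohort_design(sim$n_ra, sim$n_mets, timepoints = sim$timepoints,
                          seed = child_seed(seed, 2L))
  comp <- generate_composition(design, reference, marker = sim$marker,
                               seed = child_seed(seed, 3L))
  db <- generate_pathway_db(reference, sim$n_pathways,
                            seed = child_seed(seed, 4L))
  write_reference(reference, file.path(out_dir, "reference.fasta"),
                  file.path(out_dir, "taxonomy.tsv"))
  utils::write.table(db, file.path(out_dir, "pathway_db.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  hits <- list()
  for (i in seq_len(nrow(comp$samples))) {
    sid <- comp$samples$sample_id[i]
    reads <- simulate_reads(comp, reference, depth = sim$depth,
                            substitution_rate = sim$substitution_rate,
                            seed = child_seed(seed, 100L + i), sample_id = sid)
    cl <- cluster_reads(reads, width = config$cluster$width,
                        grid = config$cluster$grid,
                        rounds = config$cluster$rounds,
                        cohesion_threshold = config$cluster$cohesion_threshold,
                        subgrid = config$cluster$subgrid,
                        seed = child_seed(seed, 200L + i))
    hit <- assign_clusters(cl, reference,
                           min_alignment_length = config$assign$min_alignment_length,
                           match = config$assign$match,
                           mismatch = config$assign$mismatch,
                           gap_open = config$assign$gap_open,
                           gap_extend = config$assign$gap_extend)
    hits[[sid]] <- hit
    say("stage cluster/assign: %s -> %d clusters (%d dropped by length filter)",
        sid, nrow(hit), attr(hit, "n_dropped"))
  }
  hits_all <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  freq <- build_frequency_table(hits_all)
  utils::write.table(freq, file.path(out_dir, "frequencies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  m <- freq_matrix(freq, reference)

  metrics <- data.frame(
    sample_id = rownames(m),
    simpson = apply(m, 1L, simpson_diversity),
    richness = apply(m, 1L, richness))
  utils::write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  phyla <- rollup_taxonomy(m, reference, "phylum")
  utils::write.table(data.frame(sample_id = rownames(phyla), phyla,
                                check.names = FALSE),
                     file.path(out_dir, "phylum_rollup.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ps <- sample_pathway_scores(m, db)
  h1 <- rollup_hierarchy(ps, "H1")
  shifts <- group_shift_summary(h1, comp$samples)
  utils::write.table(shifts, file.path(out_dir, "pathway_shifts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("amplisom")),
                   seed = seed,
                   n_samples = nrow(comp$samples),
                   files = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  say("pipeline complete: %s", out_dir)
  invisible(list(reference = reference, design = design, composition = comp,
                 frequencies = freq, freq_matrix = m, metrics = metrics,
                 phylum_rollup = phyla, pathway_scores = ps,
                 pathway_shifts = shifts, manifest = manifest,
                 out_dir = out_dir))
}
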