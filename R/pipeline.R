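#' Pipeline configuration
#'
#' Bundles every threshold the analysis stages use, with study-scale
#' defaults: orthogroup presence at the 27-of-33 proportion, bootstrap
#' collapse below 50, duplication-ratio exclusion above 1.2, 700-aa length
#' filter, 1000 stochastic maps and a two-sided 0.05 significance level.
#'
#' @param seed Master seed; each stage derives its own sub-seed from it.
#' @param n_species Species-tree size for the simulated data set.
#' @param n_og Number of simulated orthogroups.
#' @param n_gene_trees Gene trees for the supertree stage.
#' @param supertree_taxa Taxa used in the supertree demonstration (must be
#'   <= 8 for exhaustive mode).
#' @param supertree_mode `"exhaustive"` or `"nni"`.
#' @param min_present_frac Orthogroup presence fraction (27/33 analogue).
#' @param support_threshold Bootstrap collapse threshold.
#' @param dup_ratio_threshold Duplication-ratio exclusion threshold.
#' @param length_filter Minimum amino-acid length for gene-family members.
#' @param n_maps Stochastic maps per character.
#' @param alpha_level Two-sided significance level for PGLS.
#' @param genes_per_scaffold,n_scaffolds Synthetic annotation layout.
#' @param intron_contraction Intron-length scale factor planted in the
#'   second synthetic species (mimics genome compaction).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_species = 24, n_og = 150,
                            n_gene_trees = 30, supertree_taxa = 6,
                            supertree_mode = "exhaustive",
                            min_present_frac = 27 / 33,
                            support_threshold = 50,
                            dup_ratio_threshold = 1.2, length_filter = 700,
                            n_maps = 1000, alpha_level = 0.05,
                            genes_per_scaffold = 40, n_scaffolds = 2,
                            intron_contraction = 0.8) {
  cfg <- list(seed = as.integer(seed), n_species = n_species, n_og = n_og,
              n_gene_trees = n_gene_trees, supertree_taxa = supertree_taxa,
              supertree_mode = supertree_mode,
              min_present_frac = min_present_frac,
              support_threshold = support_threshold,
              dup_ratio_threshold = dup_ratio_threshold,
              length_filter = length_filter, n_maps = n_maps,
              alpha_level = alpha_level,
              genes_per_scaffold = genes_per_scaffold,
              n_scaffolds = n_scaffolds,
              intron_contraction = intron_contraction)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks threshold domains and stage-precondition consistency without
#' running anything; problems are report rows, not errors.
#'
#' @param config A [pipeline_config()].
#' @return Tibble `field`, `problem` (zero rows when valid).
#' @export
validate_pipeline_config <- function(config) {
  probs <- list()
  add <- function(field, problem) {
    probs[[length(probs) + 1L]] <<- tibble::tibble(field = field,
                                                   problem = problem)
  }
  if (config$n_species < 2) add("n_species", "must be at least 2")
  if (config$min_present_frac <= 0 || config$min_present_frac > 1) {
    add("min_present_frac", "must lie in (0, 1]")
  }
  if (config$support_threshold < 0) add("support_threshold", "negative")
  if (config$dup_ratio_threshold <= 0) add("dup_ratio_threshold",
                                           "must be positive")
  if (config$n_maps < 1) add("n_maps", "must be at least 1")
  if (config$alpha_level <= 0 || config$alpha_level >= 1) {
    add("alpha_level", "must lie in (0, 1)")
  }
  if (config$supertree_mode == "exhaustive" && config$supertree_taxa > 8) {
    add("supertree_taxa",
        "exhaustive search requires <= 8 taxa; use mode 'nni'")
  }
  if (config$intron_contraction <= 0) add("intron_contraction",
                                          "must be positive")
  if (length(probs) == 0L) {
    return(tibble::tibble(field = character(), problem = character()))
  }
  dplyr::bind_rows(probs)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates every input class with [pipeline_config()]-controlled
#' parameters, then runs each analysis stage in dependency order, writing
#' plain tab-separated outputs, Newick trees and the resolved configuration
#' into `outdir`. Reruns with the same configuration are byte-identical
#' (no timestamps are written).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  probs <- validate_pipeline_config(config)
  if (nrow(probs)) {
    stop("invalid configuration:\n",
         paste0("  ", probs$field, ": ", probs$problem, collapse = "\n"),
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  logit <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  seed <- config$seed
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  logit("stage simulate: seed=", seed, " n_species=", config$n_species)

  # --- simulate --------------------------------------------------------
  sp <- sim_species_tree(config$n_species, birth_rate = 1, seed = seed)
  write_newick(sp$tree, file.path(outdir, "species_tree.nwk"))
  og <- sim_orthogroup_table(
    sp$tree$tip.label, n_og = config$n_og,
    planted_dup_species = sp$tree$tip.label[1:2],
    planted_dup_fraction = 0.4, p_present = 0.92, seed = seed + 1)
  write_og_table(og$table, file.path(outdir, "orthogroups.tsv"))
  char <- sim_discrete_character(sp$tree, er_rate = 0.3, k_states = 2,
                                 seed = seed + 2)
  write_tsv_plain(char$tip_states, file.path(outdir, "character.tsv"))
  traits <- sim_brownian_traits(sp$tree, beta = c(80, 10), sigma2 = 25,
                                seed = seed + 3)
  write_tsv_plain(traits$traits, file.path(outdir, "traits.tsv"))

  # --- orthology -------------------------------------------------------
  policy <- selection_policy(
    n_species_total = config$n_species,
    min_present = ceiling(config$min_present_frac * config$n_species),
    double_allowed_species = sp$tree$tip.label[1:2],
    support_threshold = config$support_threshold)
  selected <- select_single_copy(og$table, policy)
  writeLines(selected, file.path(outdir, "selected_orthogroups.txt"))
  qc <- qc_screen(og$table,
                  presence_min = ceiling(0.8 * config$n_species),
                  threshold = config$dup_ratio_threshold)
  write_tsv_plain(qc, file.path(outdir, "qc_report.tsv"))
  logit("stage orthology: ", length(selected), " orthogroups selected, ",
        sum(qc$excluded), " species excluded by duplication ratio")

  # --- supertree -------------------------------------------------------
  st_taxa_tree <- sim_species_tree(config$supertree_taxa, seed = seed + 4)
  gts <- sim_gene_trees(st_taxa_tree$tree, config$n_gene_trees,
                        p_perturb = 0.2, seed = seed + 5)
  prof <- build_quartet_profile(gts, st_taxa_tree$tree$tip.label)
  st <- search_supertree(prof, mode = config$supertree_mode,
                         seed = seed + 6)
  write_newick(st$tree, file.path(outdir, "supertree.nwk"))
  write_tsv_plain(quartet_profile_table(prof),
                  file.path(outdir, "quartet_profile.tsv"))
  logit("stage supertree: mode=", st$mode, " score=", st$score)

  # --- ancestral -------------------------------------------------------
  fit <- fit_er_rate(sp$tree,
                     stats::setNames(char$tip_states$state,
                                     char$tip_states$taxon))
  model <- mk_model(fit$k, max(fit$alpha, 1e-8))
  maps <- sample_stochastic_maps(
    sp$tree, stats::setNames(char$tip_states$state, char$tip_states$taxon),
    model, n_maps = config$n_maps, seed = seed + 7)
  summ <- summarize_maps(maps)
  write_tsv_plain(summ$node_posterior,
                  file.path(outdir, "ancestral_posteriors.tsv"))
  logit("stage ancestral: alpha_hat=", format(fit$alpha, digits = 6),
        " n_maps=", config$n_maps)

  # --- pgls ------------------------------------------------------------
  pg <- pgls_fit(traits$traits, "y", "x1", sp$tree)
  write_tsv_plain(tidy(pg), file.path(outdir, "pgls_coefficients.tsv"))
  logit("stage pgls: slope=",
        format(tidy(pg)$estimate[tidy(pg)$term == "x1"], digits = 6),
        " alpha_level=", config$alpha_level)

  # --- genomestats -----------------------------------------------------
  ann_a <- sim_annotation_and_assembly(
    n_scaffolds = config$n_scaffolds,
    genes_per_scaffold = config$genes_per_scaffold, seed = seed + 8)
  contraction <- config$intron_contraction
  ann_b <- sim_annotation_and_assembly(
    n_scaffolds = config$n_scaffolds,
    genes_per_scaffold = config$genes_per_scaffold,
    intron_len_gen = function(n) {
      pmax(1L, as.integer(round(contraction * (40L + stats::rpois(n, 60)))))
    },
    seed = seed + 8) # same seed: same exon structure, contracted introns
  write_annotation(ann_a$annotation, file.path(outdir, "species_a.gff3"))
  write_annotation(ann_b$annotation, file.path(outdir, "species_b.gff3"))
  Biostrings::writeXStringSet(ann_a$assembly,
                              file.path(outdir, "species_a.fasta"))
  am <- assembly_metrics(ann_a$assembly)
  write_tsv_plain(am, file.path(outdir, "assembly_metrics.tsv"))
  gs_a <- gene_structure_stats(ann_a$annotation)
  gs_b <- gene_structure_stats(ann_b$annotation)
  pairs <- tibble::tibble(gene_a = gs_a$gene_id, gene_b = gs_a$gene_id)
  pairs <- pairs[pairs$gene_b %in% gs_b$gene_id, ]
  ratios <- ortholog_log2_ratios(gs_a, gs_b, pairs)
  write_tsv_plain(ratios, file.path(outdir, "ortholog_log2_ratios.tsv"))
  write_tsv_plain(species_structure_summary(ann_a$annotation),
                  file.path(outdir, "structure_summary_a.tsv"))
  logit("stage genomestats: n50=", am$n50, " genes=", nrow(gs_a))

  # --- genefamily ------------------------------------------------------
  fam <- sim_gene_family(sp$tree, dup_rate = 0.05, loss_rate = 0,
                         force_root_duplication = TRUE, seed = seed + 9)
  rec <- NULL
  if (!fam$empty && !is.null(fam$tree)) {
    lengths <- tibble::tibble(
      sequence_id = fam$species_map$leaf,
      length_aa = 650L + 20L * seq_len(nrow(fam$species_map)))
    kept <- filter_by_length(lengths, config$length_filter)
    rec <- infer_duplication_nodes(fam$tree, fam$species_map)
    write_tsv_plain(rec$events, file.path(outdir, "genefamily_events.tsv"))
    dup_nodes <- rec$events$node[rec$events$event == "duplication"]
    if (length(dup_nodes)) {
      rates <- post_duplication_rates(rec, dup_nodes[1])
      write_tsv_plain(rates, file.path(outdir, "postdup_rates.tsv"))
    }
    # plant a meristic character: one clade of the root duplication gets a
    # reduced domain count, mimicking repeat loss in one paralogue
    counts <- stats::setNames(rep(13L, nrow(fam$species_map)),
                              fam$species_map$leaf)
    if (length(fam$duplication_clades)) {
      first <- fam$duplication_clades[[1]]
      half <- fam$tree$tip.label[fam$tree$tip.label %in% first]
      sub <- utils::head(half, ceiling(length(half) / 2))
      counts[sub] <- 10L
    }
    dc <- ancestral_domain_counts(fam$tree, counts,
                                  n_maps = min(config$n_maps, 500),
                                  seed = seed + 10)
    write_tsv_plain(dc$node_posterior,
                    file.path(outdir, "domain_count_posteriors.tsv"))
    logit("stage genefamily: ", length(dup_nodes), " duplication node(s), ",
          attr(kept, "n_dropped"), " sequence(s) dropped by length filter")
  } else {
    logit("stage genefamily: family extinct under simulated losses")
  }

  writeLines(log_lines, file.path(outdir, "pipeline.log"))
  invisible(list(species_tree = sp, orthogroups = og, qc = qc,
                 supertree = st, map_summary = summ, pgls = pg,
                 ratios = ratios, reconciled = rec))
}

#' One-command demonstration run
#'
#' Runs [run_pipeline()] with a small, fast configuration; doubles as the
#' end-to-end integration check.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @return Invisibly, the stage results.
#' @export
run_demo <- function(outdir, seed = 1) {
  run_pipeline(pipeline_config(seed = seed, n_species = 16, n_og = 120,
                               n_maps = 300, genes_per_scaffold = 25),
               outdir)
}
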