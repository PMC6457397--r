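#' Selection policy for single-copy orthogroup filtering
#'
#' Encodes the selection thresholds used when choosing orthogroups for
#' phylogenomic analysis: an orthogroup qualifies when present in at least
#' `min_present` of the `n_species_total` species and single copy
#' everywhere, except in `double_allowed_species` (assemblies with known
#' uncollapsed heterozygosity, or transcriptome-only species) where up to
#' two copies are tolerated.
#'
#' @param n_species_total Size of the species universe.
#' @param min_present Minimum number of species with at least one sequence
#'   (the study-scale value is 27 of 33).
#' @param double_allowed_species Species allowed up to two copies.
#' @param support_threshold Bootstrap cutoff used when screening gene trees
#'   (default 50; edges below it are collapsed first).
#' @return An object of class `selection_policy`.
#' @export
selection_policy <- function(n_species_total, min_present,
                             double_allowed_species = character(),
                             support_threshold = 50) {
  if (min_present < 1 || min_present > n_species_total) {
    stop("`min_present` must lie in 1..n_species_total", call. = FALSE)
  }
  structure(list(n_species_total = as.integer(n_species_total),
                 min_present = as.integer(min_present),
                 double_allowed_species = double_allowed_species,
                 support_threshold = support_threshold),
            class = "selection_policy")
}

validate_og_table <- function(table) {
  need <- c("orthogroup_id", "species", "sequence_id", "length_aa")
  if (!all(need %in% names(table))) {
    stop("orthogroup table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table$sequence_id)) {
    stop("sequence_ids must be globally unique", call. = FALSE)
  }
  if (any(table$length_aa <= 0)) stop("lengths must be positive", call. = FALSE)
  invisible(table)
}

#' Read / write a tab-separated orthogroup table
#'
#' Columns: `orthogroup_id`, `species`, `sequence_id`, `length_aa`.
#'
#' @param file Path to a TSV file.
#' @return A validated tibble.
#' @export
read_og_table <- function(file) {
  tb <- tibble::as_tibble(utils::read.delim(file, stringsAsFactors = FALSE))
  validate_og_table(tb)
  tb
}

#' @rdname read_og_table
#' @param table An orthogroup tibble.
#' @export
write_og_table <- function(table, file) {
  validate_og_table(table)
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Ingest an OrthoFinder-style orthogroup matrix
#'
#' Converts the wide `Orthogroups.tsv` layout (first column the orthogroup
#' id, one column per species holding comma-separated sequence ids) into
#' the long table this package uses, deriving sequence lengths from a
#' protein FASTA.
#'
#' @param file Path to the wide orthogroup TSV.
#' @param fasta Path to (or [Biostrings::AAStringSet] of) the protein
#'   sequences; names must match the sequence ids.
#' @return A validated orthogroup tibble.
#' @export
read_orthofinder_og <- function(file, fasta) {
  wide <- utils::read.delim(file, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (is.character(fasta)) fasta <- Biostrings::readAAStringSet(fasta)
  lens <- stats::setNames(Biostrings::width(fasta), names(fasta))
  long <- tidyr::pivot_longer(tibble::as_tibble(wide), -1,
                              names_to = "species", values_to = "ids")
  names(long)[1] <- "orthogroup_id"
  long <- long[!is.na(long$ids) & nzchar(trimws(long$ids)), ]
  out <- long |>
    dplyr::mutate(sequence_id = strsplit(.data$ids, ",\\s*")) |>
    tidyr::unnest("sequence_id") |>
    dplyr::select("orthogroup_id", "species", "sequence_id")
  missing <- setdiff(out$sequence_id, names(lens))
  if (length(missing)) {
    stop("sequences absent from the FASTA: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out$length_aa <- as.integer(lens[out$sequence_id])
  validate_og_table(out)
  out
}

#' Select single-copy orthogroups under a policy
#'
#' An orthogroup is selected iff (a) at least `min_present` species have a
#' sequence and (b) every species has at most one sequence, except species
#' in `double_allowed_species`, which may have up to two.
#'
#' @param table Orthogroup tibble (see [read_og_table()]).
#' @param policy A [selection_policy()].
#' @return Sorted character vector of selected orthogroup ids.
#' @export
select_single_copy <- function(table, policy) {
  validate_og_table(table)
  unknown <- setdiff(policy$double_allowed_species, unique(table$species))
  if (length(unknown)) {
    stop("policy names species absent from the table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- dplyr::count(table, .data$orthogroup_id, .data$species)
  ok <- counts |>
    dplyr::mutate(limit = ifelse(
      .data$species %in% policy$double_allowed_species, 2L, 1L)) |>
    dplyr::group_by(.data$orthogroup_id) |>
    dplyr::summarise(n_present = dplyr::n(),
                     copy_ok = all(.data$n <= .data$limit)) |>
    dplyr::filter(.data$copy_ok, .data$n_present >= policy$min_present)
  sort(ok$orthogroup_id)
}

# can the leaf set `s` (tip indices) be a clade in some refinement of the
# tree's polytomies? yes iff s is nested-or-disjoint with every node clade
compatible_clade <- function(tip_sets, ntip, s) {
  for (x in tip_sets[(ntip + 1L):length(tip_sets)]) {
    i <- length(intersect(x, s))
    if (i > 0L && i < length(s) && i < length(x)) return(FALSE)
    if (i == length(s) && i == length(x)) next
  }
  TRUE
}

#' Screen an orthogroup gene tree for paralogy
#'
#' Reproduces tree-based paralogue pruning: edges with bootstrap support
#' below the policy threshold are collapsed first; the orthogroup is
#' discarded if any species' sequences cannot form a clade on the collapsed
#' tree (polytomy children are treated as mutually compatible, i.e. the
#' test is monophyly in some refinement), or if a species has more than two
#' sequences. For a kept orthogroup, each species with two sequences
#' (in-paralogues) retains the longer one; ties break to the
#' lexicographically smaller sequence id.
#'
#' @param og_tree `phylo` gene tree whose leaves are sequence ids, internal
#'   labels bootstrap supports.
#' @param og_records Tibble with columns `species`, `sequence_id`,
#'   `length_aa` covering every leaf.
#' @param policy A [selection_policy()] (only `support_threshold` is used).
#' @return A list: `decision` (`"keep"` or `"discard"`), `retained` (tibble
#'   of one sequence per represented species when kept, empty otherwise)
#'   and `reason`.
#' @examples
#' tr <- read_newick("((A_1:1,A_2:1)95:1,(B_1:1,C_1:1)95:1);")
#' recs <- tibble::tibble(species = c("A", "A", "B", "C"),
#'                        sequence_id = c("A_1", "A_2", "B_1", "C_1"),
#'                        length_aa = c(300, 250, 200, 200))
#' screen_paralogs(tr, recs, selection_policy(3, 2))
#' @export
screen_paralogs <- function(og_tree, og_records, policy) {
  validate_phylo(og_tree)
  missing <- setdiff(og_tree$tip.label, og_records$sequence_id)
  if (length(missing)) {
    stop("leaf without an orthogroup record: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  recs <- og_records[og_records$sequence_id %in% og_tree$tip.label, ]
  collapsed <- collapse_low_support(og_tree, policy$support_threshold)
  ntip <- length(collapsed$tip.label)
  tip_sets <- node_tip_sets(collapsed)
  by_sp <- split(recs$sequence_id, recs$species)
  for (sp in names(by_sp)) {
    ids <- by_sp[[sp]]
    if (length(ids) > 2L) {
      return(list(decision = "discard", retained = recs[0, ],
                  reason = paste0("species ", sp, " has ", length(ids),
                                  " sequences")))
    }
    if (length(ids) == 2L) {
      s <- match(ids, collapsed$tip.label)
      if (!compatible_clade(tip_sets, ntip, s)) {
        return(list(decision = "discard", retained = recs[0, ],
                    reason = paste0("species ", sp,
                                    " is non-monophyletic after collapsing")))
      }
    }
  }
  retained <- recs |>
    dplyr::group_by(.data$species) |>
    dplyr::arrange(dplyr::desc(.data$length_aa), .data$sequence_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  list(decision = "keep", retained = retained,
       reason = "single-copy after in-paralogue resolution")
}

#' Per-species duplication ratio over a set of orthogroups
#'
#' Total number of the species' sequences in the orthogroup subset divided
#' by the number of those orthogroups containing at least one sequence for
#' the species. Always >= 1; equals 1 iff the species is single copy in
#' every counted orthogroup.
#'
#' @param table Orthogroup tibble.
#' @param og_subset Character vector of orthogroup ids (non-empty).
#' @param species One species name.
#' @return The ratio (double).
#' @export
duplication_ratio <- function(table, og_subset, species) {
  validate_og_table(table)
  if (length(og_subset) == 0L) stop("`og_subset` is empty", call. = FALSE)
  sub <- table[table$orthogroup_id %in% og_subset &
                 table$species == species, ]
  n_og <- length(unique(sub$orthogroup_id))
  if (n_og == 0L) {
    stop("species '", species, "' absent from every orthogroup in subset",
         call. = FALSE)
  }
  nrow(sub) / n_og
}

#' Assembly-quality screen by duplication ratio
#'
#' Selects orthogroups present in at least `presence_min` species with mean
#' per-present-species copy count at most `mean_count_max`, computes each
#' species' duplication ratio over that subset, and flags species whose
#' ratio strictly exceeds `threshold` (uncollapsed-heterozygosity
#' signature; the study-scale threshold is 1.2).
#'
#' @param table Orthogroup tibble.
#' @param species Species to report; defaults to all in the table.
#' @param presence_min Minimum species presence per orthogroup.
#' @param mean_count_max Maximum mean copy count per present species.
#' @param threshold Exclusion threshold (strict `>`).
#' @return A tibble (`species`, `n_ogs`, `n_seqs`, `duplication_ratio`,
#'   `excluded`) with the selection parameters attached as attribute
#'   `params`. Zero rows (with a warning) when no orthogroup passes.
#' @export
qc_screen <- function(table, species = NULL, presence_min,
                      mean_count_max = 1.5, threshold = 1.2) {
  validate_og_table(table)
  if (presence_min <= 0 || mean_count_max <= 0 || threshold <= 0) {
    stop("parameters must be positive", call. = FALSE)
  }
  if (is.null(species)) species <- sort(unique(table$species))
  sel <- table |>
    dplyr::count(.data$orthogroup_id, .data$species) |>
    dplyr::group_by(.data$orthogroup_id) |>
    dplyr::summarise(n_present = dplyr::n(), mean_count = mean(.data$n)) |>
    dplyr::filter(.data$n_present >= presence_min,
                  .data$mean_count <= mean_count_max)
  params <- list(presence_min = presence_min,
                 mean_count_max = mean_count_max, threshold = threshold,
                 n_ogs_selected = nrow(sel))
  if (nrow(sel) == 0L) {
    warning("no orthogroup passed the presence/mean-count selection",
            call. = FALSE)
    out <- tibble::tibble(species = character(), n_ogs = integer(),
                          n_seqs = integer(), duplication_ratio = double(),
                          excluded = logical())
    attr(out, "params") <- params
    return(out)
  }
  sub <- table[table$orthogroup_id %in% sel$orthogroup_id, ]
  out <- dplyr::bind_rows(lapply(species, function(sp) {
    ss <- sub[sub$species == sp, ]
    n_og <- length(unique(ss$orthogroup_id))
    tibble::tibble(species = sp, n_ogs = n_og, n_seqs = nrow(ss),
                   duplication_ratio = if (n_og > 0) nrow(ss) / n_og else NA_real_)
  }))
  out$excluded <- !is.na(out$duplication_ratio) &
    out$duplication_ratio > threshold
  attr(out, "params") <- params
  out
}
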