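#' Filter sequence records by minimum length
#'
#' Records of length at least `min_len` are retained ("shorter than"
#' semantics: a record of exactly `min_len` stays). Used to drop fragmented
#' gene models before gene-family tree analysis (study-scale cutoff: 700
#' amino acids for Notch-like receptors).
#'
#' @param records Tibble with columns `sequence_id`, `length_aa`.
#' @param min_len Minimum retained length.
#' @return The retained tibble, with attribute `n_dropped`.
#' @export
filter_by_length <- function(records, min_len = 700) {
  if (nrow(records) && any(records$length_aa <= 0)) {
    stop("lengths must be positive", call. = FALSE)
  }
  keep <- records$length_aa >= min_len
  out <- records[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Infer duplication nodes by species overlap
#'
#' An internal node of a rooted gene tree is labelled a duplication iff the
#' species sets of at least two of its child subtrees intersect; otherwise
#' a speciation. This reads gene-duplication events directly off the gene
#' tree topology (exact when no gene losses occurred).
#'
#' @param gene_tree Rooted `phylo` whose leaves map to species.
#' @param species_map Tibble `leaf`, `species`, covering every leaf.
#' @return An object of class `reconciled_tree`: list with `tree`,
#'   `species_map`, and `events` (tibble `node`, `clade`, `event`,
#'   `n_tips`).
#' @examples
#' fam <- sim_gene_family(sim_species_tree(5, seed = 2)$tree,
#'                        dup_rate = 0.3, loss_rate = 0, seed = 2)
#' if (!is.null(fam$tree)) infer_duplication_nodes(fam$tree, fam$species_map)
#' @export
infer_duplication_nodes <- function(gene_tree, species_map) {
  validate_phylo(gene_tree)
  gene_tree <- ape::reorder.phylo(gene_tree, "cladewise")
  unmapped <- setdiff(gene_tree$tip.label, species_map$leaf)
  if (length(unmapped)) {
    stop("leaves without a species mapping: ",
         paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
  }
  ntip <- length(gene_tree$tip.label)
  sp <- species_map$species[match(gene_tree$tip.label, species_map$leaf)]
  kids <- split(seq_len(nrow(gene_tree$edge)), gene_tree$edge[, 1])
  sp_sets <- vector("list", ntip + gene_tree$Nnode)
  for (i in seq_len(ntip)) sp_sets[[i]] <- sp[i]
  post <- rev(unique(gene_tree$edge[, 1]))
  event <- character(gene_tree$Nnode)
  for (node in post) {
    child_sets <- lapply(kids[[as.character(node)]], function(r) {
      sp_sets[[gene_tree$edge[r, 2]]]
    })
    dup <- FALSE
    if (length(child_sets) > 1L) {
      for (i in seq_len(length(child_sets) - 1L)) {
        for (j in (i + 1L):length(child_sets)) {
          if (length(intersect(child_sets[[i]], child_sets[[j]]))) {
            dup <- TRUE
          }
        }
      }
    }
    event[node - ntip] <- if (dup) "duplication" else "speciation"
    sp_sets[[node]] <- unique(unlist(child_sets))
  }
  clades <- node_clade_ids(gene_tree)
  tip_sets <- node_tip_sets(gene_tree)
  events <- tibble::tibble(
    node = ntip + seq_len(gene_tree$Nnode),
    clade = clades[ntip + seq_len(gene_tree$Nnode)],
    event = event,
    n_tips = vapply(tip_sets[ntip + seq_len(gene_tree$Nnode)], length, 0L))
  structure(list(tree = gene_tree, species_map = species_map,
                 events = events),
            class = "reconciled_tree")
}

#' @export
print.reconciled_tree <- function(x, ...) {
  nd <- sum(x$events$event == "duplication")
  cat("Reconciled gene tree:", length(x$tree$tip.label), "leaves,",
      nd, "duplication node(s)\n")
  invisible(x)
}

#' Flag within-species duplicate leaves
#'
#' Species represented by more than one leaf (candidate within-species
#' duplications or uncollapsed haplotypes); flagged only, never removed.
#'
#' @param reconciled A `reconciled_tree`.
#' @return Tibble `species`, `n_leaves`, `leaves`.
#' @export
flag_within_species_duplicates <- function(reconciled) {
  reconciled$species_map |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_leaves = dplyr::n(),
                     leaves = paste(sort(.data$leaf), collapse = ";")) |>
    dplyr::filter(.data$n_leaves > 1)
}

#' Post-duplication substitution-rate comparison
#'
#' For a duplication node, computes for each child clade the mean path
#' length (substitutions per site) from the duplication node to each
#' descendant tip — i.e. the child's own branch plus the within-clade
#' root-to-tip path. Diverging means between the two clades indicate
#' asymmetric rate evolution of the paralogues. `mode = "edges"` instead
#' averages the individual edge lengths within each clade (including the
#' subtending branch).
#'
#' @param reconciled A `reconciled_tree` from [infer_duplication_nodes()].
#' @param dup_node Node number (or clade string) of a duplication node.
#' @param mode `"path"` (default) or `"edges"`.
#' @return Tibble `clade`, `n_tips`, `mean_length` (one row per child
#'   clade).
#' @export
post_duplication_rates <- function(reconciled, dup_node,
                                   mode = c("path", "edges")) {
  mode <- match.arg(mode)
  tree <- reconciled$tree
  ntip <- length(tree$tip.label)
  if (is.character(dup_node)) {
    i <- match(dup_node, reconciled$events$clade)
    if (is.na(i)) stop("no node with clade '", dup_node, "'", call. = FALSE)
    dup_node <- reconciled$events$node[i]
  }
  ev <- reconciled$events$event[match(dup_node, reconciled$events$node)]
  if (is.na(ev) || ev != "duplication") {
    stop("node ", dup_node, " is not labelled a duplication", call. = FALSE)
  }
  rows <- which(tree$edge[, 1] == dup_node)
  tip_sets <- node_tip_sets(tree)
  dplyr::bind_rows(lapply(rows, function(r) {
    child <- tree$edge[r, 2]
    tips <- tip_sets[[child]]
    ml <- if (mode == "path") {
      mean(vapply(tips, function(tp) {
        tree$edge.length[r] + path_length(tree, child, tp)
      }, 0))
    } else {
      # all edges inside the child clade plus the subtending edge
      in_clade <- vapply(seq_len(nrow(tree$edge)), function(rr) {
        all(tip_sets[[tree$edge[rr, 2]]] %in% tips)
      }, TRUE)
      mean(c(tree$edge.length[r], tree$edge.length[in_clade & tree$edge[, 2] != child]))
    }
    tibble::tibble(
      clade = paste(sort(tree$tip.label[tips]), collapse = ";"),
      n_tips = length(tips), mean_length = ml)
  }))
}

#' Ancestral reconstruction of domain counts on a gene tree
#'
#' Distinct observed counts (e.g. EGF-like repeat numbers) become unordered
#' states of an equal-rates Mk model; the rate is fitted by maximum
#' likelihood and `n_maps` stochastic character maps are summarized into
#' per-node posteriors over the count values.
#'
#' @param gene_tree Rooted `phylo` with branch lengths.
#' @param counts Tibble `leaf`, `count` (or named integer vector) covering
#'   every leaf.
#' @param n_maps Number of stochastic maps (study-scale value 1000).
#' @param seed Integer seed.
#' @return A list: `node_posterior` tibble (`node`, `clade`, `count`,
#'   `prob`), `alpha` (fitted rate), `states` (count values in state
#'   order).
#' @export
ancestral_domain_counts <- function(gene_tree, counts, n_maps = 1000,
                                    seed = 1) {
  validate_phylo(gene_tree)
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts[[2]], counts[[1]])
  }
  miss <- setdiff(gene_tree$tip.label, names(counts))
  if (length(miss)) {
    stop("no count for leaf: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  counts <- counts[gene_tree$tip.label]
  values <- sort(unique(counts))
  ntip <- length(gene_tree$tip.label)
  clades <- node_clade_ids(gene_tree)
  nodes <- (ntip + 1L):(ntip + gene_tree$Nnode)
  if (length(values) == 1L) {
    post <- tibble::tibble(node = nodes, clade = clades[nodes],
                           count = values, prob = 1)
    return(list(node_posterior = post, alpha = 0, states = values))
  }
  states <- stats::setNames(match(counts, values) - 1L,
                            gene_tree$tip.label)
  fit <- fit_er_rate(gene_tree, states, k = length(values))
  model <- mk_model(length(values), max(fit$alpha, 1e-8))
  maps <- sample_stochastic_maps(gene_tree, states, model, n_maps = n_maps,
                                 seed = seed)
  post <- summarize_maps(maps)$node_posterior |>
    dplyr::mutate(count = values[.data$state + 1L]) |>
    dplyr::select("node", "clade", "count", "prob")
  list(node_posterior = post, alpha = fit$alpha, states = values)
}
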