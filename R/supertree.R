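# restricted-split machinery: for a tree, return a logical clade-membership
# matrix over `taxa` (rows = internal-node clades, cols = taxa); taxa absent
# from the tree contribute all-FALSE columns
clade_matrix <- function(tree, taxa) {
  ntip <- length(tree$tip.label)
  sets <- node_tip_sets(tree)
  idx <- match(tree$tip.label, taxa)
  nint <- tree$Nnode
  M <- matrix(FALSE, nint, length(taxa))
  for (i in seq_len(nint)) {
    tips <- idx[sets[[ntip + i]]]
    tips <- tips[!is.na(tips)]
    M[i, tips] <- TRUE
  }
  M
}

# induced resolution of the 4-subset `q` (indices into taxa, sorted) given a
# clade matrix: 0 unresolved, else 1/2/3 = partner of q[1] is q[2]/q[3]/q[4].
# A quartet is resolved iff some clade restricted to q has exactly two taxa
# (equivalently its complement does), i.e. some split separates it 2|2.
quartet_resolution <- function(M, q) {
  sub <- M[, q, drop = FALSE]
  rs <- rowSums(sub)
  cand <- which(rs == 2L)
  for (r in cand) {
    inside <- sub[r, ]
    pair <- which(if (inside[1]) inside else !inside)
    return(pair[2] - 1L) # partner position of q[1] among 2..4 -> 1..3
  }
  0L
}

#' Build a quartet profile from gene trees
#'
#' For every 4-taxon subset of `taxa`, counts how many gene trees induce
#' each of the three possible unrooted resolutions. Gene trees may miss
#' taxa (the subset is simply not counted there) and polytomy-induced
#' unresolved quartets count towards `unresolved`. Counting uses restricted
#' bipartitions, so it is invariant to gene-tree rooting.
#'
#' @param gene_trees List of `phylo` objects.
#' @param taxa Character vector of taxon names (the species universe).
#' @return An object of class `quartet_profile`: list with `taxa`, `counts`
#'   (named list: key `"t1|t2|t3|t4"` sorted; value integer vector of
#'   length 4 — the three resolutions then the unresolved tally).
#' @export
build_quartet_profile <- function(gene_trees, taxa) {
  taxa <- sort(taxa)
  extra <- setdiff(unlist(lapply(gene_trees, `[[`, "tip.label")), taxa)
  if (length(extra)) {
    stop("gene-tree leaves outside the taxon set: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  counts <- new.env(parent = emptyenv())
  for (tr in gene_trees) {
    present <- which(taxa %in% tr$tip.label)
    if (length(present) < 4L) next
    M <- clade_matrix(tr, taxa)
    combs <- utils::combn(present, 4L)
    for (j in seq_len(ncol(combs))) {
      q <- combs[, j]
      key <- paste(taxa[q], collapse = "|")
      cur <- get0(key, envir = counts, ifnotfound = integer(4))
      res <- quartet_resolution(M, q)
      slot <- if (res == 0L) 4L else res
      cur[slot] <- cur[slot] + 1L
      assign(key, cur, envir = counts)
    }
  }
  structure(list(taxa = taxa, counts = counts), class = "quartet_profile")
}

#' @export
print.quartet_profile <- function(x, ...) {
  cat("Quartet profile over", length(x$taxa), "taxa,",
      length(ls(x$counts)), "counted 4-subsets\n")
  invisible(x)
}

#' Quartet profile as a tibble
#'
#' @param profile A `quartet_profile`.
#' @return Tibble with columns `quartet`, `res1`, `res2`, `res3`,
#'   `unresolved`; `resJ` counts gene trees pairing the first taxon of the
#'   sorted subset with its (J+1)-th member.
#' @export
quartet_profile_table <- function(profile) {
  keys <- sort(ls(profile$counts))
  dplyr::bind_rows(lapply(keys, function(k) {
    v <- get(k, envir = profile$counts)
    tibble::tibble(quartet = k, res1 = v[1], res2 = v[2], res3 = v[3],
                   unresolved = v[4])
  }))
}

#' Quartet score of a candidate species tree
#'
#' Sum over all 4-taxon subsets of the number of gene trees whose induced
#' resolution matches the candidate's — the objective maximized by
#' quartet-based coalescent summary methods.
#'
#' @param candidate `phylo` containing every taxon in the profile.
#' @param profile A [build_quartet_profile()] result.
#' @return Integer score.
#' @export
quartet_score <- function(candidate, profile) {
  missing <- setdiff(profile$taxa, candidate$tip.label)
  if (length(missing)) {
    stop("candidate tree is missing taxa: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  M <- clade_matrix(candidate, profile$taxa)
  keys <- ls(profile$counts)
  total <- 0L
  for (k in keys) {
    q <- match(strsplit(k, "|", fixed = TRUE)[[1]], profile$taxa)
    res <- quartet_resolution(M, q)
    if (res > 0L) total <- total + get(k, envir = profile$counts)[res]
  }
  total
}

#' Search for the maximum-quartet-score supertree
#'
#' `mode = "exhaustive"` enumerates every unrooted binary topology (allowed
#' up to 8 taxa, 10,395 topologies) and returns the global maximizer, ties
#' broken by the lexicographically smallest canonical Newick.
#' `mode = "nni"` hill-climbs by nearest-neighbour interchange from a
#' random-addition start until no neighbour improves the score.
#'
#' @param profile A [build_quartet_profile()] result.
#' @param taxa Taxon set (defaults to the profile's).
#' @param mode `"exhaustive"` or `"nni"`.
#' @param seed Integer seed (NNI start; ignored by exhaustive search).
#' @param start Optional `phylo` start tree for NNI.
#' @return A list: `tree` (`phylo`), `score`, `mode`.
#' @examples
#' sp <- sim_species_tree(6, seed = 7)$tree
#' gts <- sim_gene_trees(sp, 20, p_perturb = 0, seed = 7)
#' prof <- build_quartet_profile(gts, sp$tip.label)
#' search_supertree(prof, mode = "exhaustive")$score
#' @export
search_supertree <- function(profile, taxa = profile$taxa,
                             mode = c("exhaustive", "nni"), seed = 1,
                             start = NULL) {
  mode <- match.arg(mode)
  taxa <- sort(taxa)
  n <- length(taxa)
  if (mode == "exhaustive") {
    if (n > 8L) {
      stop("exhaustive search is limited to 8 taxa (10,395 topologies); ",
           "use mode = \"nni\"", call. = FALSE)
    }
    trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    best_score <- -1L
    best_tree <- NULL
    best_key <- NULL
    for (ti in seq_along(trees)) {
      tr <- trees[[ti]] # [[ restores tip labels on compressed multiPhylo
      s <- quartet_score(tr, profile)
      if (s > best_score) {
        best_score <- s
        best_tree <- tr
        best_key <- canonical_topology(tr)
      } else if (s == best_score) {
        key <- canonical_topology(tr)
        if (key < best_key) {
          best_tree <- tr
          best_key <- key
        }
      }
    }
    return(list(tree = best_tree, score = best_score, mode = mode))
  }
  with_seed(seed, {
    cur <- if (is.null(start)) {
      ape::rtree(n, tip.label = sample(taxa), br = NULL)
    } else {
      start
    }
    cur <- ape::unroot(cur)
    cur_score <- quartet_score(cur, profile)
    repeat {
      nb <- phangorn::nni(cur)
      scores <- vapply(nb, quartet_score, 0L, profile = profile)
      if (max(scores) <= cur_score) break
      cur <- nb[[which.max(scores)]]
      cur_score <- max(scores)
    }
    list(tree = cur, score = cur_score, mode = mode)
  })
}
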