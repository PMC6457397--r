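#' @importFrom rlang .data
NULL

# run expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Lineages split at per-lineage rate `birth_rate`; the process is observed
#' one exponential waiting time after the n-th species arises, so all
#' terminal branches are strictly positive and tips are contemporaneous
#' (an ultrametric, clock-like tree). Species are labelled `s01`, `s02`, ...
#'
#' @param n_species Number of extant species (>= 2).
#' @param birth_rate Speciation rate per lineage per unit time (> 0).
#' @param seed Integer seed; output is reproducible given it.
#' @return A list: `tree` (a `phylo`) and `node_depths`, a tibble of every
#'   node's depth from the root (`node`, `clade`, `depth`).
#' @examples
#' sim_species_tree(6, birth_rate = 1, seed = 42)$tree
#' @export
sim_species_tree <- function(n_species, birth_rate = 1, seed = 1) {
  if (n_species < 2) stop("`n_species` must be at least 2", call. = FALSE)
  if (birth_rate <= 0) stop("`birth_rate` must be positive", call. = FALSE)
  with_seed(seed, {
    # lineage-table construction: ids 1 and 2 are the root's two children,
    # opened at time 0 (the root's own stem is not represented)
    n_total <- 2L * n_species
    parent <- integer(n_total)
    born <- numeric(n_total)
    is_tip <- logical(n_total)
    next_id <- 3L
    lineage <- c(1L, 2L) # currently open lineage ids
    t_now <- 0
    parent[1:2] <- 0L
    born[1:2] <- 0
    while (length(lineage) < n_species) {
      t_now <- t_now + stats::rexp(1, length(lineage) * birth_rate)
      i <- sample.int(length(lineage), 1L)
      id <- lineage[i]
      c1 <- next_id; c2 <- next_id + 1L; next_id <- next_id + 2L
      parent[c(c1, c2)] <- id
      born[c(c1, c2)] <- t_now
      lineage <- c(lineage[-i], c1, c2)
    }
    t_end <- t_now + stats::rexp(1, length(lineage) * birth_rate)
    is_tip[lineage] <- TRUE
    ends <- numeric(next_id - 1L)
    ends[] <- NA_real_
    ends[lineage] <- t_end
    for (id in seq_len(next_id - 1L)) {
      if (!is_tip[id]) {
        kid <- which(parent == id)[1]
        ends[id] <- born[kid]
      }
    }
    # build newick recursively from the implicit root (children: ids 1, 2)
    tip_counter <- 0L
    lab <- character(next_id - 1L)
    build <- function(id) {
      len <- ends[id] - born[id]
      if (is_tip[id]) {
        tip_counter <<- tip_counter + 1L
        lab[id] <<- sprintf("s%02d", tip_counter)
        return(paste0(lab[id], ":", format(len, digits = 15)))
      }
      ch <- which(parent == id)
      paste0("(", paste(vapply(ch, build, ""), collapse = ","), "):",
             format(len, digits = 15))
    }
    txt <- paste0("(", build(1L), ",", build(2L), ");")
    tree <- read_newick(txt)
    depths <- ape::node.depth.edgelength(tree)
    clades <- node_clade_ids(tree)
    list(tree = tree,
         node_depths = tibble::tibble(
           node = seq_along(depths), clade = clades, depth = depths))
  })
}

#' Simulate a discrete character on a tree under the equal-rates Mk model
#'
#' The root state is uniform over the k states; along every branch the state
#' jumps at total rate `er_rate` to a uniformly chosen different state.
#' The realized internal-node states (the true history) are returned with
#' the tip data.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param er_rate Total leaving rate (>= 0).
#' @param k_states Number of states (>= 2).
#' @param seed Integer seed.
#' @return A list: `tip_states` (tibble `taxon`, `state`), `node_states`
#'   (tibble `node`, `clade`, `state` for internal nodes), and
#'   `n_transitions` (realized change count over the whole tree).
#' @export
sim_discrete_character <- function(tree, er_rate, k_states = 2, seed = 1) {
  validate_phylo(tree)
  if (k_states < 2) stop("`k_states` must be at least 2", call. = FALSE)
  if (er_rate < 0) stop("`er_rate` must be non-negative", call. = FALSE)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nn <- ntip + tree$Nnode
    st <- integer(nn)
    st[ntip + 1L] <- sample.int(k_states, 1L)
    n_trans <- 0L
    for (r in seq_len(nrow(tree$edge))) {
      p <- tree$edge[r, 1]; ch <- tree$edge[r, 2]
      s <- st[p]
      t_rem <- tree$edge.length[r]
      if (er_rate > 0) {
        repeat {
          w <- stats::rexp(1, er_rate)
          if (w >= t_rem) break
          t_rem <- t_rem - w
          others <- seq_len(k_states)[-s]
          s <- others[sample.int(length(others), 1L)]
          n_trans <- n_trans + 1L
        }
      }
      st[ch] <- s
    }
    clades <- node_clade_ids(tree)
    list(
      tip_states = tibble::tibble(taxon = tree$tip.label,
                                  state = st[seq_len(ntip)] - 1L),
      node_states = tibble::tibble(
        node = (ntip + 1L):nn, clade = clades[(ntip + 1L):nn],
        state = st[(ntip + 1L):nn] - 1L),
      n_transitions = n_trans)
  })
}

#' Simulate continuous traits with a planted linear effect and Brownian
#' residuals
#'
#' The response is `X beta + e` with `e ~ MVN(0, sigma2 * C)`, `C` the
#' Brownian covariance of the tree ([bm_covariance()]). Predictors default
#' to iid standard normal draws per species; pass `predictor_gen` to change
#' that.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param beta Coefficient vector: intercept followed by one slope per
#'   predictor.
#' @param sigma2 Brownian residual variance (>= 0).
#' @param predictor_gen Function `(n, p)` returning an `n x p` predictor
#'   matrix.
#' @param seed Integer seed.
#' @return A list: `traits` (tibble `species`, `y`, `x1`, ...), `beta`
#'   (the planted coefficients) and `sigma2`.
#' @export
sim_brownian_traits <- function(tree, beta, sigma2, predictor_gen = NULL,
                                seed = 1) {
  validate_phylo(tree)
  if (sigma2 < 0) stop("`sigma2` must be non-negative", call. = FALSE)
  p <- length(beta) - 1L
  if (p < 1L) stop("`beta` must contain an intercept and >= 1 slope",
                   call. = FALSE)
  with_seed(seed, {
    n <- length(tree$tip.label)
    Xp <- if (is.null(predictor_gen)) {
      matrix(stats::rnorm(n * p), n, p)
    } else {
      predictor_gen(n, p)
    }
    X <- cbind(1, Xp)
    if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient",
                                   call. = FALSE)
    C <- bm_covariance(tree, tree$tip.label)
    eps <- if (sigma2 > 0) {
      as.vector(t(chol(sigma2 * C)) %*% stats::rnorm(n))
    } else {
      numeric(n)
    }
    y <- as.vector(X %*% beta) + eps
    traits <- tibble::as_tibble(
      stats::setNames(as.data.frame(Xp), paste0("x", seq_len(p))))
    traits <- dplyr::bind_cols(
      tibble::tibble(species = tree$tip.label, y = y), traits)
    list(traits = traits, beta = beta, sigma2 = sigma2)
  })
}

# internal recursive structure for gene-family simulation
gf_node <- function(type, children = NULL, species = NULL, length = 0,
                    dup = FALSE) {
  list(type = type, children = children, species = species, length = length,
       dup = dup)
}

#' Simulate a gene family evolving inside a species tree
#'
#' A single gene enters the species-tree root (two if
#' `force_root_duplication`). Along each species-tree branch every gene
#' lineage duplicates at rate `dup_rate` and is lost at rate `loss_rate`
#' (per unit branch length); at speciation nodes surviving lineages enter
#' both daughter branches. Gene-tree leaves are labelled
#' `species__copyN`. Recorded "true" duplication nodes are those with
#' surviving descendants through both daughter lineages (with
#' `loss_rate = 0` that is every duplication).
#'
#' @param species_tree A rooted `phylo` with branch lengths.
#' @param dup_rate,loss_rate Per-lineage event rates (>= 0).
#' @param force_root_duplication Plant one duplication at the root.
#' @param seed Integer seed.
#' @return A list: `tree` (gene tree `phylo`, or `NULL` if the family went
#'   extinct), `species_map` (tibble `leaf`, `species`), `duplication_clades`
#'   (list of character vectors: leaf sets below each true duplication node)
#'   and `empty` (logical).
#' @export
sim_gene_family <- function(species_tree, dup_rate, loss_rate,
                            force_root_duplication = FALSE, seed = 1) {
  validate_phylo(species_tree)
  if (dup_rate < 0 || loss_rate < 0) stop("rates must be non-negative",
                                          call. = FALSE)
  ntip <- length(species_tree$tip.label)
  kids <- split(seq_len(nrow(species_tree$edge)), species_tree$edge[, 1])
  total <- dup_rate + loss_rate
  with_seed(seed, {
    # evolve one gene lineage from the top of species-tree edge row r, with
    # t_rem branch length remaining; returns a gf_node or NULL (lost)
    evolve_edge <- function(r, t_rem, acc_len) {
      repeat {
        w <- if (total > 0) stats::rexp(1, total) else Inf
        if (w >= t_rem) {
          acc_len <- acc_len + t_rem
          sp_node <- species_tree$edge[r, 2]
          if (sp_node <= ntip) {
            return(gf_node("leaf",
                           species = species_tree$tip.label[sp_node],
                           length = acc_len))
          }
          sub <- lapply(kids[[as.character(sp_node)]], function(rr) {
            evolve_edge(rr, species_tree$edge.length[rr], 0)
          })
          sub <- sub[!vapply(sub, is.null, TRUE)]
          if (length(sub) == 0L) return(NULL)
          if (length(sub) == 1L) {
            s <- sub[[1]]
            s$length <- s$length + acc_len
            return(s)
          }
          return(gf_node("node", children = sub, length = acc_len))
        }
        t_rem <- t_rem - w
        acc_len <- acc_len + w
        if (stats::runif(1) < dup_rate / total) {
          a <- evolve_edge_from(r, t_rem)
          b <- evolve_edge_from(r, t_rem)
          surv <- Filter(Negate(is.null), list(a, b))
          if (length(surv) == 0L) return(NULL)
          if (length(surv) == 1L) {
            s <- surv[[1]]
            s$length <- s$length + acc_len
            return(s)
          }
          return(gf_node("node", children = surv, length = acc_len,
                         dup = TRUE))
        } else {
          return(NULL) # loss
        }
      }
    }
    evolve_edge_from <- function(r, t_rem) evolve_edge(r, t_rem, 0)

    root_lineages <- lapply(
      seq_len(if (force_root_duplication) 2L else 1L),
      function(i) {
        sub <- lapply(kids[[as.character(ntip + 1L)]], function(rr) {
          evolve_edge(rr, species_tree$edge.length[rr], 0)
        })
        sub <- sub[!vapply(sub, is.null, TRUE)]
        if (length(sub) == 0L) return(NULL)
        if (length(sub) == 1L) return(sub[[1]])
        gf_node("node", children = sub, length = 0)
      })
    root_lineages <- Filter(Negate(is.null), root_lineages)
    if (length(root_lineages) == 0L) {
      return(list(tree = NULL, species_map = tibble::tibble(
        leaf = character(), species = character()),
        duplication_clades = list(), empty = TRUE))
    }
    root <- if (length(root_lineages) == 1L) {
      root_lineages[[1]]
    } else {
      gf_node("node", children = root_lineages, length = 0,
              dup = force_root_duplication)
    }
    # name leaves species__copyN in a deterministic traversal order
    copy_count <- new.env()
    dup_clades <- list()
    name_rec <- function(nd) {
      if (nd$type == "leaf") {
        i <- (get0(nd$species, envir = copy_count, ifnotfound = 0L)) + 1L
        assign(nd$species, i, envir = copy_count)
        nd$label <- paste0(nd$species, "__copy", i)
        return(nd)
      }
      nd$children <- lapply(nd$children, name_rec)
      nd
    }
    root <- name_rec(root)
    leaves_of <- function(nd) {
      if (nd$type == "leaf") return(nd$label)
      unlist(lapply(nd$children, leaves_of))
    }
    collect_dups <- function(nd) {
      if (nd$type == "leaf") return(invisible())
      if (isTRUE(nd$dup)) {
        dup_clades[[length(dup_clades) + 1L]] <<- sort(leaves_of(nd))
      }
      lapply(nd$children, collect_dups)
      invisible()
    }
    collect_dups(root)
    to_newick <- function(nd) {
      if (nd$type == "leaf") {
        return(paste0(nd$label, ":", format(nd$length, digits = 15)))
      }
      paste0("(", paste(vapply(nd$children, to_newick, ""), collapse = ","),
             "):", format(nd$length, digits = 15))
    }
    leaves <- leaves_of(root)
    if (length(leaves) == 1L) {
      tree <- NULL # a single surviving copy carries no tree structure
    } else {
      tree <- read_newick(paste0(to_newick(root), ";"))
    }
    list(tree = tree,
         species_map = tibble::tibble(
           leaf = leaves, species = sub("__copy[0-9]+$", "", leaves)),
         duplication_clades = dup_clades,
         empty = FALSE)
  })
}

#' Simulate gene trees as NNI-perturbed copies of a species tree
#'
#' Stand-in for gene-tree discordance in supertree testing: each gene tree
#' is the species topology with `n_moves` random nearest-neighbour
#' interchanges applied with probability `p_perturb`, and branch lengths
#' redrawn.
#'
#' @param species_tree A rooted `phylo`.
#' @param n_trees Number of gene trees.
#' @param p_perturb Probability a gene tree is perturbed at all.
#' @param n_moves NNI moves applied to a perturbed tree.
#' @param seed Integer seed.
#' @return List of `phylo` gene trees.
#' @export
sim_gene_trees <- function(species_tree, n_trees, p_perturb = 0.2,
                           n_moves = 1, seed = 1) {
  validate_phylo(species_tree)
  with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      tr <- species_tree
      if (stats::runif(1) < p_perturb) {
        for (m in seq_len(n_moves)) {
          nb <- phangorn::nni(tr)
          tr <- nb[[sample.int(length(nb), 1L)]]
        }
      }
      tr$edge.length <- stats::rexp(nrow(tr$edge), 10)
      tr$node.label <- NULL
      tr
    })
  })
}

#' Simulate an annotation and matching assembly with known gene structure
#'
#' Genes are laid head-to-tail along scaffolds separated by intergenic gaps;
#' each gene has exons separated by introns, all lengths drawn from the
#' supplied generators. A configurable fraction of genes receives a second,
#' shorter isoform, and a fraction is placed overlapping its predecessor.
#' Ground-truth per-gene intron counts/spans and per-pair intergenic
#' distances are returned alongside the annotation.
#'
#' @param n_scaffolds,genes_per_scaffold Layout counts.
#' @param exon_count_gen,exon_len_gen,intron_len_gen,intergenic_gen
#'   Functions `(n)` returning positive integer lengths (counts >= 1).
#' @param p_multi_isoform Fraction of genes given a second isoform (a strict
#'   subset of exons, hence never the longest).
#' @param p_overlap Fraction of genes placed overlapping the previous gene.
#' @param n_fraction Fraction of assembly bases replaced by `N`.
#' @param seed Integer seed.
#' @return A list: `annotation` (an `annotation_set`, see
#'   [as_annotation_set()]), `assembly` (a [Biostrings::DNAStringSet]),
#'   `gene_truth` (tibble `gene_id`, `intron_count`, `intron_span`,
#'   `exon_span`) and `intergenic_truth` (tibble of adjacent-pair gaps).
#' @export
sim_annotation_and_assembly <- function(
    n_scaffolds = 2, genes_per_scaffold = 25,
    exon_count_gen = function(n) 1L + stats::rpois(n, 3),
    exon_len_gen = function(n) 50L + stats::rpois(n, 150),
    intron_len_gen = function(n) 40L + stats::rpois(n, 60),
    intergenic_gen = function(n) 200L + stats::rpois(n, 300),
    p_multi_isoform = 0.1, p_overlap = 0, n_fraction = 0.002, seed = 1) {
  with_seed(seed, {
    rows <- list()
    truth <- list()
    inter <- list()
    seqs <- character(n_scaffolds)
    gene_i <- 0L
    for (sc in seq_len(n_scaffolds)) {
      scaf <- sprintf("scaffold_%02d", sc)
      pos <- 0L
      prev_end <- NA_integer_
      prev_gene <- NA_character_
      for (g in seq_len(genes_per_scaffold)) {
        gene_i <- gene_i + 1L
        gid <- sprintf("gene%04d", gene_i)
        tid <- paste0(gid, ".t1")
        n_ex <- as.integer(exon_count_gen(1))
        ex_len <- as.integer(exon_len_gen(n_ex))
        in_len <- if (n_ex > 1) as.integer(intron_len_gen(n_ex - 1L)) else integer()
        if (any(c(ex_len, in_len) <= 0L)) {
          stop("length generators must return strictly positive values",
               call. = FALSE)
        }
        gap <- as.integer(intergenic_gen(1))
        overlap_this <- g > 1 && stats::runif(1) < p_overlap
        start <- if (overlap_this) {
          max(1L, prev_end - min(50L, prev_end - 1L))
        } else {
          pos + gap + 1L
        }
        ex_start <- integer(n_ex); ex_end <- integer(n_ex)
        cur <- start
        for (e in seq_len(n_ex)) {
          ex_start[e] <- cur
          ex_end[e] <- cur + ex_len[e] - 1L
          cur <- ex_end[e] + (if (e < n_ex) in_len[e] else 0L) + 1L
        }
        gend <- ex_end[n_ex]
        strand <- sample(c("+", "-"), 1L)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          seqid = scaf, type = c("gene", "mRNA", rep("exon", n_ex)),
          start = c(start, start, ex_start), end = c(gend, gend, ex_end),
          strand = strand,
          id = c(gid, tid, paste0(tid, ".e", seq_len(n_ex))),
          parent = c(NA_character_, gid, rep(tid, n_ex)))
        if (stats::runif(1) < p_multi_isoform && n_ex > 1) {
          tid2 <- paste0(gid, ".t2")
          keep <- sort(sample(n_ex, n_ex - 1L)) # drop one exon
          rows[[length(rows) + 1L]] <- tibble::tibble(
            seqid = scaf, type = c("mRNA", rep("exon", length(keep))),
            start = c(ex_start[keep[1]], ex_start[keep]),
            end = c(ex_end[keep[length(keep)]], ex_end[keep]),
            strand = strand,
            id = c(tid2, paste0(tid2, ".e", seq_along(keep))),
            parent = c(gid, rep(tid2, length(keep))))
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          gene_id = gid, intron_count = n_ex - 1L,
          intron_span = sum(in_len), exon_span = sum(ex_len))
        if (g > 1 && !overlap_this) {
          inter[[length(inter) + 1L]] <- tibble::tibble(
            seqid = scaf, gene_a = prev_gene, gene_b = gid,
            distance = start - prev_end - 1L)
        } else if (g > 1) {
          inter[[length(inter) + 1L]] <- tibble::tibble(
            seqid = scaf, gene_a = prev_gene, gene_b = gid,
            distance = max(0L, start - prev_end - 1L))
        }
        prev_end <- gend
        prev_gene <- gid
        pos <- max(pos, gend)
      }
      slen <- pos + as.integer(intergenic_gen(1))
      s <- sample(c("A", "C", "G", "T"), slen, replace = TRUE)
      nN <- floor(n_fraction * slen)
      if (nN > 0) s[sample.int(slen, nN)] <- "N"
      seqs[sc] <- paste(s, collapse = "")
      names(seqs)[sc] <- scaf
    }
    ann <- as_annotation_set(dplyr::bind_rows(rows))
    assembly <- Biostrings::DNAStringSet(seqs)
    list(annotation = ann, assembly = assembly,
         gene_truth = dplyr::bind_rows(truth),
         intergenic_truth = dplyr::bind_rows(inter))
  })
}

#' Simulate an orthogroup membership table with planted duplications
#'
#' Every orthogroup holds one sequence per present species, except species
#' in `planted_dup_species`, which carry two copies in a
#' `planted_dup_fraction` share of the orthogroups where they occur.
#'
#' @param species Character vector of species names.
#' @param n_og Number of orthogroups.
#' @param planted_dup_species Species planted with duplicates.
#' @param planted_dup_fraction Fraction (0--1) of their orthogroups carrying
#'   two copies.
#' @param p_present Per-species presence probability per orthogroup.
#' @param seed Integer seed.
#' @return A list: `table` (tibble `orthogroup_id`, `species`,
#'   `sequence_id`, `length_aa`) and `true_ratios` (tibble `species`,
#'   `duplication_ratio` from the generator's own bookkeeping).
#' @export
sim_orthogroup_table <- function(species, n_og = 200,
                                 planted_dup_species = character(),
                                 planted_dup_fraction = 0,
                                 p_present = 1, seed = 1) {
  if (planted_dup_fraction < 0 || planted_dup_fraction > 1) {
    stop("`planted_dup_fraction` must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    n_seq <- stats::setNames(integer(length(species)), species)
    n_present <- stats::setNames(integer(length(species)), species)
    for (i in seq_len(n_og)) {
      og <- sprintf("OG%05d", i)
      for (sp in species) {
        if (stats::runif(1) > p_present) next
        dup_here <- sp %in% planted_dup_species &&
          stats::runif(1) < planted_dup_fraction
        n_copies <- if (dup_here) 2L else 1L
        for (cp in seq_len(n_copies)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            orthogroup_id = og, species = sp,
            sequence_id = paste0(sp, "_", og, "_", cp),
            length_aa = as.integer(round(stats::rlnorm(1, log(400), 0.4))) + 1L)
        }
        n_seq[sp] <- n_seq[sp] + n_copies
        n_present[sp] <- n_present[sp] + 1L
      }
    }
    list(table = dplyr::bind_rows(rows),
         true_ratios = tibble::tibble(
           species = species,
           duplication_ratio = unname(ifelse(n_present > 0,
                                             n_seq / n_present, NA_real_))))
  })
}
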