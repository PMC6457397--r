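#' Parse a Newick string or file into a phylogenetic tree
#'
#' Trees are represented as [ape::read.tree()] `phylo` objects throughout the
#' package: edge lengths in substitutions per site, internal node labels
#' holding integer bootstrap supports (0--100) where present. Trees are
#' treated as rooted as written; no re-rooting is performed.
#'
#' @param text A single Newick statement terminated by `";"`, or `NULL` if
#'   `file` is given.
#' @param file Path to a Newick file (one tree per line or per file).
#' @return A `phylo` object. Leaf labels are checked to be unique and
#'   non-empty and branch lengths non-negative.
#' @examples
#' tr <- read_newick("((A:0.1,B:0.2)90:0.05,C:0.3);")
#' node_support(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) {
    stop("supply either `text` or `file`", call. = FALSE)
  }
  if (is.null(text)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  text <- trimws(text)
  check_newick_syntax(text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick string", call. = FALSE)
  validate_phylo(tr)
  tr
}

# balanced-parenthesis / terminator pre-scan; reports the 1-based character
# offset of the first defect so malformed input fails with a usable message
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("Newick parse error: unmatched ')' at character %d", i),
             call. = FALSE)
      }
    }
    if (ch == ";" && depth > 0L) {
      stop(sprintf(
        "Newick parse error: ';' at character %d inside %d unclosed '('",
        i, depth), call. = FALSE)
    }
  }
  if (depth > 0L) {
    stop(sprintf(
      "Newick parse error: %d unclosed '(' at end of input (character %d)",
      depth, length(chars)), call. = FALSE)
  }
  if (length(chars) == 0L || chars[length(chars)] != ";") {
    stop(sprintf("Newick parse error: missing terminating ';' (character %d)",
                 length(chars) + 1L), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate the tree invariants assumed by the package
#'
#' Checks unique non-empty leaf labels, non-negative branch lengths and a
#' single root. Polytomies are permitted.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly; errors describe the violated invariant.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object", call. = FALSE)
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty leaf label", call. = FALSE)
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length", call. = FALSE)
  }
  invisible(tree)
}

#' Write a tree as a Newick string
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is written there.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when `file` is given).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  validate_phylo(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Numeric support values of internal nodes
#'
#' Internal Newick labels that parse as integers in 0--100 are interpreted as
#' bootstrap supports; any other label (or no label) yields `NA`.
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode`, in ape's internal-node
#'   order (root first).
#' @export
node_support <- function(tree) {
  if (is.null(tree$node.label)) {
    return(rep(NA_real_, tree$Nnode))
  }
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[!is.na(sup) & (sup < 0 | sup > 100 | sup != round(sup))] <- NA_real_
  sup
}

#' Collapse poorly supported internal edges into polytomies
#'
#' Every internal edge whose child node carries a numeric support strictly
#' below `threshold` is contracted: the node's children are re-attached to
#' its parent and the contracted edge's length is discarded (downstream
#' screening uses topology only). Edges without a numeric support annotation
#' are kept. The leaf set is unchanged.
#'
#' @param tree A `phylo` object with supports in its internal node labels.
#' @param threshold Non-negative support cutoff; the paper-scale default used
#'   by paralogue screening is 50.
#' @return A `phylo` object, possibly multifurcating.
#' @examples
#' tr <- read_newick("(((A:1,B:1)40:1,C:1)90:1,D:1);")
#' collapse_low_support(tr, 50)
#' @export
collapse_low_support <- function(tree, threshold) {
  validate_phylo(tree)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  sup <- node_support(tree)
  drop <- !is.na(sup) & sup < threshold
  # node numbers (ape numbering) slated for contraction; the root is never
  # contracted -- it subtends no edge
  drop_nodes <- (ntip + seq_len(tree$Nnode))[drop]
  drop_nodes <- setdiff(drop_nodes, root)
  if (length(drop_nodes) == 0L) return(tree)

  has_len <- !is.null(tree$edge.length)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  # rebuild the newick string recursively, splicing contracted nodes'
  # children into their grandparent
  frag <- function(node, len) {
    if (node <= ntip) {
      s <- tree$tip.label[node]
    } else {
      rows <- kids[[as.character(node)]]
      parts <- unlist(lapply(rows, function(r) {
        frag(tree$edge[r, 2],
             if (has_len) tree$edge.length[r] else NULL)
      }))
      if (node %in% drop_nodes) {
        return(parts) # contracted: length discarded, children float up
      }
      lab <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
      if (is.na(lab)) lab <- ""
      s <- paste0("(", paste(parts, collapse = ","), ")", lab)
    }
    if (!is.null(len)) s <- paste0(s, ":", format(len, digits = 15)) else s
  }
  root_parts <- unlist(lapply(kids[[as.character(root)]], function(r) {
    frag(tree$edge[r, 2], if (has_len) tree$edge.length[r] else NULL)
  }))
  root_lab <- if (!is.null(tree$node.label)) tree$node.label[1] else ""
  if (is.na(root_lab)) root_lab <- ""
  txt <- paste0("(", paste(root_parts, collapse = ","), ")", root_lab, ";")
  read_newick(txt)
}

# resolve a node argument (ape node number, tip label, or internal node
# label) to an ape node number
resolve_node <- function(tree, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    nmax <- length(tree$tip.label) + tree$Nnode
    if (node < 1L || node > nmax) {
      stop("node number ", node, " out of range", call. = FALSE)
    }
    return(node)
  }
  i <- match(node, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(node, tree$node.label)
    if (!is.na(j)) return(length(tree$tip.label) + j)
  }
  stop("node '", node, "' not found in tree", call. = FALSE)
}

#' Sum of branch lengths along an ancestor-to-descendant path
#'
#' @param tree A `phylo` object with edge lengths.
#' @param ancestor,descendant Node numbers (ape numbering) or labels;
#'   `descendant` must lie in the subtree rooted at `ancestor`.
#' @return Non-negative path length; 0 when the two nodes coincide.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' path_length(tr, length(tr$tip.label) + 1, "A") # root -> A = 2
#' @export
path_length <- function(tree, ancestor, descendant) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  a <- resolve_node(tree, ancestor)
  d <- resolve_node(tree, descendant)
  if (a == d) return(0)
  parent <- integer(length(tree$tip.label) + tree$Nnode)
  elen <- numeric(length(parent))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  total <- 0
  cur <- d
  while (cur != a) {
    if (parent[cur] == 0L) {
      stop("descendant is not in the subtree of ancestor", call. = FALSE)
    }
    total <- total + elen[cur]
    cur <- parent[cur]
  }
  total
}

# descendant tip indices for every node; list indexed by node number;
# independent of the edge-matrix row order
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) {
      sets[[node]] <<- node
      return(node)
    }
    s <- sort(unlist(lapply(kids[[as.character(node)]], rec)))
    sets[[node]] <<- s
    s
  }
  rec(ntip + 1L)
  sets
}

# canonical rotation-invariant newick of a topology (no lengths/supports):
# children sorted by their smallest tip label, recursively
canonical_topology <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) {
      return(list(key = tree$tip.label[node], txt = tree$tip.label[node]))
    }
    sub <- lapply(kids[[as.character(node)]], rec)
    ord <- order(vapply(sub, `[[`, "", "key"))
    sub <- sub[ord]
    list(key = sub[[1]]$key,
         txt = paste0("(", paste(vapply(sub, `[[`, "", "txt"),
                                 collapse = ","), ")"))
  }
  paste0(rec(ntip + 1L)$txt, ";")
}
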