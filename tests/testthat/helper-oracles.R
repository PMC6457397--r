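# Independent oracles used across tests. These deliberately avoid the
# package's own algorithms: likelihoods by exhaustive enumeration of
# internal-state assignments, quartet scores by a double loop over pruned
# 4-taxon trees, GLS by explicit matrix inversion.

er_prob <- function(k, alpha, t) {
  beta <- alpha / (k - 1)
  e <- exp(-k * beta * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- (1 - e) / k + e
  P
}

# exhaustive sum over all k^Nnode internal-node state assignments
enum_loglik <- function(tree, states, k, alpha, prior = rep(1 / k, k)) {
  ntip <- length(tree$tip.label)
  grid <- expand.grid(rep(list(seq_len(k)), tree$Nnode))
  total <- 0
  Pl <- lapply(seq_len(nrow(tree$edge)),
               function(r) er_prob(k, alpha, tree$edge.length[r]))
  for (g in seq_len(nrow(grid))) {
    asg <- c(states + 1L, as.integer(grid[g, ]))
    p <- prior[asg[ntip + 1L]]
    for (r in seq_len(nrow(tree$edge))) {
      p <- p * Pl[[r]][asg[tree$edge[r, 1]], asg[tree$edge[r, 2]]]
    }
    total <- total + p
  }
  log(total)
}

# exact marginal posterior at each internal node by the same enumeration
enum_marginals <- function(tree, states, k, alpha, prior = rep(1 / k, k)) {
  ntip <- length(tree$tip.label)
  grid <- expand.grid(rep(list(seq_len(k)), tree$Nnode))
  Pl <- lapply(seq_len(nrow(tree$edge)),
               function(r) er_prob(k, alpha, tree$edge.length[r]))
  post <- matrix(0, tree$Nnode, k)
  for (g in seq_len(nrow(grid))) {
    asg <- c(states + 1L, as.integer(grid[g, ]))
    p <- prior[asg[ntip + 1L]]
    for (r in seq_len(nrow(tree$edge))) {
      p <- p * Pl[[r]][asg[tree$edge[r, 1]], asg[tree$edge[r, 2]]]
    }
    for (i in seq_len(tree$Nnode)) {
      post[i, asg[ntip + i]] <- post[i, asg[ntip + i]] + p
    }
  }
  sweep(post, 1, rowSums(post), "/")
}

# brute-force quartet score: loop over all 4-subsets and all gene trees,
# comparing pruned 4-taxon topologies by Robinson-Foulds distance
brute_quartet_score <- function(candidate, gene_trees, taxa) {
  total <- 0L
  combs <- utils::combn(sort(taxa), 4L)
  for (j in seq_len(ncol(combs))) {
    q <- combs[, j]
    if (!all(q %in% candidate$tip.label)) next
    cq <- ape::unroot(ape::keep.tip(candidate, q))
    cq$edge.length <- NULL
    if (cq$Nnode < 2) next # candidate unresolved on this subset
    for (gt in gene_trees) {
      if (!all(q %in% gt$tip.label)) next
      gq <- ape::unroot(ape::keep.tip(gt, q))
      gq$edge.length <- NULL
      if (gq$Nnode < 2) next
      if (phangorn::RF.dist(cq, gq) == 0) total <- total + 1L
    }
  }
  total
}

# explicit-inverse GLS: beta = (X' C^-1 X)^-1 X' C^-1 y
matrix_gls <- function(y, X, C) {
  Ci <- solve(C)
  XtCi <- t(X) %*% Ci
  beta <- solve(XtCi %*% X, XtCi %*% y)
  resid <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  sigma2 <- as.numeric(t(resid) %*% Ci %*% resid) / (n - p)
  se <- sqrt(sigma2 * diag(solve(XtCi %*% X)))
  list(beta = as.vector(beta), se = se)
}

random_er_fixture <- function(n_tips, k = 2, seed) {
  tr <- sim_species_tree(n_tips, seed = seed)$tree
  sim <- sim_discrete_character(tr, er_rate = 0.6, k_states = k,
                                seed = seed + 1000)
  list(tree = tr,
       states = stats::setNames(sim$tip_states$state, sim$tip_states$taxon))
}
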