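#' Equal-rates Mk model specification
#'
#' A k-state continuous-time Markov model in which every change leaves a
#' state at total rate `alpha`, split equally over the k - 1 target states
#' (so for k = 2 the rate each way is `alpha`). The root state prior is
#' uniform by default.
#'
#' @param k Number of states (>= 2).
#' @param alpha Total leaving rate (>= 0), in expected changes per unit
#'   branch length (substitutions/site for the trees used here).
#' @param root_prior Probability vector over the k states; must sum to 1.
#' @return An object of class `mk_model`.
#' @examples
#' mk_model(2, alpha = 0.5)
#' @export
mk_model <- function(k, alpha, root_prior = rep(1 / k, k)) {
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be non-negative", call. = FALSE)
  if (length(root_prior) != k || abs(sum(root_prior) - 1) > 1e-12 ||
      any(root_prior < 0)) {
    stop("`root_prior` must be a length-k probability vector", call. = FALSE)
  }
  structure(list(k = as.integer(k), alpha = alpha, root_prior = root_prior),
            class = "mk_model")
}

# ER transition probability matrix over time t: closed form
# P_ii = 1/k + (k-1)/k * exp(-k*beta*t), P_ij = 1/k - 1/k * exp(-k*beta*t)
# with beta = alpha/(k-1) the per-target rate.
mk_prob_matrix <- function(k, alpha, t) {
  beta <- alpha / (k - 1)
  e <- exp(-k * beta * t)
  off <- (1 - e) / k
  P <- matrix(off, k, k)
  diag(P) <- off + e
  P
}

# normalize a tip-state input (tibble/data.frame with taxon,state columns or
# a named vector) to an integer vector named by taxon, states in 0..k-1
tip_states <- function(character, tree, k = NULL) {
  if (is.data.frame(character)) {
    x <- stats::setNames(character[[2]], character[[1]])
  } else {
    x <- character
  }
  if (is.null(names(x))) stop("tip states must be named by taxon", call. = FALSE)
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) {
    stop("no observed state for leaf: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.integer(x[tree$tip.label])
  if (!is.null(k) && any(x < 0 | x >= k)) {
    stop("tip states must lie in 0..k-1", call. = FALSE)
  }
  x
}

# Felsenstein pruning with per-node scaling. Returns list(loglik, partials,
# scale_log): partials[node, ] are scaled conditional likelihoods.
mk_pruning <- function(tree, states, model) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  k <- model$k
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  partial <- matrix(0, nn, k)
  scale_log <- numeric(nn)
  partial[cbind(seq_len(ntip), states + 1L)] <- 1
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  # parents appear before children in cladewise preorder, so the reversed
  # unique parent list is a valid postorder over internal nodes
  post <- rev(unique(tree$edge[, 1]))
  for (node in post) {
    L <- rep(1, k)
    sl <- 0
    for (r in kids[[as.character(node)]]) {
      child <- tree$edge[r, 2]
      P <- mk_prob_matrix(k, model$alpha, tree$edge.length[r])
      L <- L * as.vector(P %*% partial[child, ])
      sl <- sl + scale_log[child]
    }
    m <- max(L)
    if (m > 0) {
      partial[node, ] <- L / m
      scale_log[node] <- sl + log(m)
    } else {
      partial[node, ] <- 0
      scale_log[node] <- sl
    }
  }
  root <- ntip + 1L
  lik <- sum(model$root_prior * partial[root, ])
  loglik <- if (lik > 0) log(lik) + scale_log[root] else -Inf
  list(loglik = loglik, partial = partial, scale_log = scale_log)
}

#' Log-likelihood of a discrete character under the equal-rates Mk model
#'
#' Felsenstein pruning over the rooted tree, root state marginalized under
#' the model's prior. For `alpha = 0` the likelihood is the prior mass of
#' the shared tip state (or `-Inf` if tips disagree).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param character Tip states: a data frame with columns `taxon`, `state`
#'   (integers `0..k-1`) or a named integer vector. Every leaf must have a
#'   state; missing data are not supported.
#' @param model An [mk_model()].
#' @return The log-likelihood (possibly `-Inf`).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' x <- c(A = 0, B = 0, C = 1, D = 1)
#' mk_loglik(tr, x, mk_model(2, 0.5))
#' @export
mk_loglik <- function(tree, character, model) {
  validate_phylo(tree)
  states <- tip_states(character, tree, model$k)
  mk_pruning(tree, states, model)$loglik
}

#' Maximum-likelihood equal-rates transition rate
#'
#' One-dimensional bounded maximization of [mk_loglik()] over
#' `alpha` in `[0, alpha_max]`. A monomorphic character sits at the `alpha = 0`
#' boundary and is returned as such.
#'
#' @inheritParams mk_loglik
#' @param k Number of states; defaults to the number of distinct observed
#'   states (at least 2).
#' @param alpha_max Upper bound of the search interval.
#' @param tol Convergence tolerance passed to [stats::optimize()].
#' @return A list with `alpha` (the MLE), `loglik`, `k`, and `boundary`
#'   (`TRUE` when the optimum lies at either end of the interval).
#' @export
fit_er_rate <- function(tree, character, k = NULL, alpha_max = 100,
                        tol = 1e-8) {
  validate_phylo(tree)
  if (is.null(k)) {
    x <- if (is.data.frame(character)) character[[2]] else character
    k <- max(2L, length(unique(x)))
  }
  states <- tip_states(character, tree, k)
  if (length(unique(states)) == 1L) {
    model <- mk_model(k, 0)
    return(list(alpha = 0, loglik = mk_pruning(tree, states, model)$loglik,
                k = k, boundary = TRUE))
  }
  f <- function(a) mk_pruning(tree, states, mk_model(k, a))$loglik
  # the ER profile flattens for large alpha, which can strand a single
  # golden-section search on the plateau; bracket the peak on a log grid
  # first, then refine within the bracketing interval
  grid <- c(0, 10^seq(-5, log10(alpha_max), length.out = 40))
  vals <- vapply(grid, f, 0)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
  alpha <- opt$maximum
  loglik <- opt$objective
  if (vals[i] > loglik) {
    alpha <- grid[i]
    loglik <- vals[i]
  }
  boundary <- alpha < 10 * tol || alpha > alpha_max - 10 * tol
  list(alpha = alpha, loglik = loglik, k = k, boundary = boundary)
}

# clade identifier for output tables: sorted leaf labels joined by ";"
node_clade_ids <- function(tree) {
  sets <- node_tip_sets(tree)
  vapply(sets, function(s) paste(sort(tree$tip.label[s]), collapse = ";"), "")
}

#' Exact marginal ancestral state posteriors
#'
#' Up-pass (pruning) and down-pass over the rooted tree give, for every
#' internal node, the exact marginal posterior over states given the tip
#' data, the model and the root prior.
#'
#' @inheritParams mk_loglik
#' @return A tibble with columns `node` (ape node number), `clade` (sorted
#'   descendant leaf labels, `;`-separated), `state`, `prob`; probabilities
#'   sum to 1 within each node.
#' @export
marginal_posteriors <- function(tree, character, model) {
  validate_phylo(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  states <- tip_states(character, tree, model$k)
  k <- model$k
  ntip <- length(tree$tip.label)
  up <- mk_pruning(tree, states, model)
  if (!is.finite(up$loglik)) {
    stop("character has zero likelihood under the model", call. = FALSE)
  }
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  # down[node, s]: (unnormalized) likelihood of everything outside node's
  # subtree given state s at node, including the prior
  down <- matrix(0, nn, k)
  down[root, ] <- model$root_prior
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  pre <- unique(tree$edge[, 1]) # cladewise order: parents before children
  for (node in pre) {
    rows <- kids[[as.character(node)]]
    msgs <- lapply(rows, function(r) {
      P <- mk_prob_matrix(k, model$alpha, tree$edge.length[r])
      as.vector(P %*% up$partial[tree$edge[r, 2], ])
    })
    for (i in seq_along(rows)) {
      child <- tree$edge[rows[i], 2]
      if (child <= ntip) next
      sib <- rep(1, k)
      for (j in seq_along(rows)) if (j != i) sib <- sib * msgs[[j]]
      P <- mk_prob_matrix(k, model$alpha, tree$edge.length[rows[i]])
      down[child, ] <- as.vector(t(P) %*% (down[node, ] * sib))
      m <- max(down[child, ])
      if (m > 0) down[child, ] <- down[child, ] / m
    }
  }
  clades <- node_clade_ids(tree)
  res <- lapply(ntip + seq_len(tree$Nnode), function(node) {
    w <- down[node, ] * up$partial[node, ]
    tibble::tibble(node = node, clade = clades[node],
                   state = 0:(k - 1), prob = w / sum(w))
  })
  dplyr::bind_rows(res)
}

# sample one path of the ER chain on a branch of length t conditioned on
# endpoint states a -> b (1-based), by uniformization at rate alpha: the
# embedded jump chain is uniform over the other k-1 states, so R^n entries
# have a closed recursion; returns matrix of (state, duration) segments.
sample_branch_history <- function(a, b, t, k, alpha) {
  if (alpha == 0 || t == 0) {
    if (a != b) stop("infeasible endpoint pair with alpha = 0", call. = FALSE)
    return(cbind(state = a, duration = t))
  }
  # R^n_{ij}: same-state s_n, different-state d_n for the uniform jump chain
  # s_n = (1/k)((k-1)^(1-n)... ) computed iteratively to avoid sign slips
  pab <- mk_prob_matrix(k, alpha, t)[a, b]
  # sample N | endpoints: prob(N = n) = pois(n; alpha t) * Rn[a,b] / pab
  lam <- alpha * t
  u <- stats::runif(1)
  n <- 0L
  s_n <- 1 # [R^0]_{aa}
  d_n <- 0 # [R^0]_{ab}, a != b
  cum <- 0
  repeat {
    rab <- if (a == b) s_n else d_n
    cum <- cum + stats::dpois(n, lam) * rab / pab
    if (u <= cum || n > 10000L) break
    n <- n + 1L
    s_new <- d_n               # to be "same" after one more jump you must
    d_new <- (s_n + (k - 2) * d_n) / (k - 1) # have been elsewhere
    s_n <- s_new
    d_n <- d_new
  }
  if (n == 0L) return(cbind(state = a, duration = t))
  # jump times: order statistics of uniforms on (0, t)
  times <- sort(stats::runif(n, 0, t))
  # powers of the jump chain summarized by (same, diff) entries
  s_pow <- numeric(n + 1L); d_pow <- numeric(n + 1L)
  s_pow[1] <- 1; d_pow[1] <- 0
  for (m in seq_len(n)) {
    s_pow[m + 1L] <- d_pow[m]
    d_pow[m + 1L] <- (s_pow[m] + (k - 2) * d_pow[m]) / (k - 1)
  }
  rn_entry <- function(m, i, j) if (i == j) s_pow[m + 1L] else d_pow[m + 1L]
  states <- integer(n)
  cur <- a
  for (i in seq_len(n)) {
    rem <- n - i
    # next state j != cur with prob proportional to (1/(k-1)) * R^rem_{j,b}
    others <- setdiff(seq_len(k), cur)
    w <- vapply(others, function(j) rn_entry(rem, j, b), 0)
    cur <- others[sample.int(length(others), 1L, prob = w)]
    states[i] <- cur
  }
  stopifnot(states[n] == b)
  segs <- cbind(state = c(a, states),
                duration = diff(c(0, times, t)))
  # merge consecutive equal states (cannot occur with this jump chain, but
  # keep the invariant explicit)
  keep <- c(TRUE, segs[-1, 1] != segs[-nrow(segs), 1])
  if (all(keep)) return(segs)
  out <- segs[keep, , drop = FALSE]
  grp <- cumsum(keep)
  out[, 2] <- tapply(segs[, 2], grp, sum)
  out
}

#' Sample stochastic character maps
#'
#' Joint node states are drawn by backward filtering / forward sampling
#' (pruning partials up, then root-to-tip conditional sampling); each branch
#' history is then drawn exactly conditional on its endpoint states by
#' uniformization. Segment durations on every branch sum to the branch
#' length, and tip-adjacent segments end in the observed tip states.
#'
#' @inheritParams mk_loglik
#' @param n_maps Number of independent histories to simulate (the analyses
#'   this package mirrors used 1000).
#' @param seed Integer seed; the map set is reproducible given it.
#' @return An object of class `stochastic_maps`: list with the `tree`,
#'   `model`, per-map realized `node_states` and per-branch segment
#'   matrices.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' x <- c(A = 0, B = 0, C = 1, D = 1)
#' maps <- sample_stochastic_maps(tr, x, mk_model(2, 0.5), n_maps = 10, seed = 1)
#' summarize_maps(maps)$node_posterior
#' @export
sample_stochastic_maps <- function(tree, character, model, n_maps = 1000,
                                   seed = 1) {
  validate_phylo(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  states <- tip_states(character, tree, model$k)
  k <- model$k
  if (model$alpha == 0 && length(unique(states)) > 1L) {
    stop("alpha = 0 with polymorphic tips: no feasible history", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  up <- mk_pruning(tree, states, model)
  if (!is.finite(up$loglik)) {
    stop("character has zero likelihood under the model", call. = FALSE)
  }
  nedge <- nrow(tree$edge)
  Plist <- lapply(seq_len(nedge), function(r) {
    mk_prob_matrix(k, model$alpha, tree$edge.length[r])
  })
  pre <- seq_len(nedge) # cladewise edge order: parents precede children
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  maps <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    node_state <- integer(ntip + tree$Nnode)
    node_state[seq_len(ntip)] <- states + 1L
    w <- model$root_prior * up$partial[root, ]
    node_state[root] <- sample.int(k, 1L, prob = w)
    segs <- vector("list", nedge)
    for (r in pre) {
      p <- tree$edge[r, 1]; ch <- tree$edge[r, 2]
      if (ch <= ntip) {
        s_child <- node_state[ch]
      } else {
        w <- Plist[[r]][node_state[p], ] * up$partial[ch, ]
        s_child <- sample.int(k, 1L, prob = w)
        node_state[ch] <- s_child
      }
      segs[[r]] <- sample_branch_history(node_state[p], s_child,
                                         tree$edge.length[r], k, model$alpha)
    }
    maps[[m]] <- list(node_states = node_state[(ntip + 1L):(ntip + tree$Nnode)],
                      segments = segs)
  }
  structure(list(tree = tree, model = model, n_maps = n_maps, maps = maps),
            class = "stochastic_maps")
}

#' Summarize a set of stochastic maps
#'
#' Node posteriors are the empirical frequencies of realized node states
#' across maps; dwell times and transition counts are averaged across maps.
#'
#' @param maps A `stochastic_maps` object from [sample_stochastic_maps()].
#' @return A list of tibbles: `node_posterior` (`node`, `clade`, `state`,
#'   `prob`), `dwell_times` (`state`, `mean_time`), and `transitions`
#'   (`from`, `to`, `mean_count`).
#' @export
summarize_maps <- function(maps) {
  if (!inherits(maps, "stochastic_maps")) {
    stop("`maps` must come from sample_stochastic_maps()", call. = FALSE)
  }
  if (maps$n_maps < 1L) stop("empty map set", call. = FALSE)
  tree <- maps$tree
  k <- maps$model$k
  ntip <- length(tree$tip.label)
  freq <- matrix(0, tree$Nnode, k)
  dwell <- numeric(k)
  trans <- matrix(0, k, k)
  for (mm in maps$maps) {
    freq[cbind(seq_len(tree$Nnode), mm$node_states)] <-
      freq[cbind(seq_len(tree$Nnode), mm$node_states)] + 1
    for (segs in mm$segments) {
      st <- segs[, 1]
      for (i in seq_len(nrow(segs))) {
        dwell[st[i]] <- dwell[st[i]] + segs[i, 2]
      }
      if (length(st) > 1L) {
        for (i in seq_len(length(st) - 1L)) {
          trans[st[i], st[i + 1L]] <- trans[st[i], st[i + 1L]] + 1
        }
      }
    }
  }
  clades <- node_clade_ids(tree)
  node_posterior <- dplyr::bind_rows(lapply(seq_len(tree$Nnode), function(i) {
    tibble::tibble(node = ntip + i, clade = clades[ntip + i],
                   state = 0:(k - 1), prob = freq[i, ] / maps$n_maps)
  }))
  list(
    node_posterior = node_posterior,
    dwell_times = tibble::tibble(state = 0:(k - 1),
                                 mean_time = dwell / maps$n_maps),
    transitions = tidyr::expand_grid(from = 0:(k - 1), to = 0:(k - 1)) |>
      dplyr::filter(.data$from != .data$to) |>
      dplyr::mutate(mean_count = purrr::map2_dbl(
        .data$from + 1, .data$to + 1, ~ trans[.x, .y] / maps$n_maps))
  )
}

#' @export
print.stochastic_maps <- function(x, ...) {
  cat("Stochastic character map set:", x$n_maps, "maps,",
      x$model$k, "states, alpha =", format(x$model$alpha, digits = 4), "\n")
  invisible(x)
}
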