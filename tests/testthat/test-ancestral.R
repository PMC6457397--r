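test_that("mk likelihood limits at rate zero follow the root prior", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  same <- c(A = 0, B = 0, C = 0, D = 0)
  expect_equal(mk_loglik(tr, same, mk_model(2, 0)), log(0.5))
  mixed <- c(A = 0, B = 0, C = 1, D = 1)
  expect_equal(mk_loglik(tr, mixed, mk_model(2, 0)), -Inf)
  expect_error(mk_loglik(tr, c(A = 0, B = 0, C = 1), mk_model(2, 1)),
               "state")
})

test_that("pruning equals exhaustive enumeration on random trees", {
  # trees up to 7 leaves, k = 2 and 3, random ER fixtures
  for (i in 1:60) {
    k <- if (i %% 3 == 0) 3L else 2L
    fx <- random_er_fixture(sample(4:7, 1), k = k, seed = i)
    alpha <- stats::runif(1, 0.05, 2)
    ll <- mk_loglik(fx$tree, fx$states, mk_model(k, alpha))
    oracle <- enum_loglik(fx$tree, fx$states, k, alpha)
    expect_equal(ll, oracle, tolerance = 1e-10)
  }
})

test_that("fitted ER rate agrees with phytools and is scale-invariant", {
  skip_if_not_installed("phytools")
  fx <- random_er_fixture(12, seed = 77)
  fit <- fit_er_rate(fx$tree, fx$states)
  fm <- phytools::fitMk(fx$tree,
                        stats::setNames(factor(fx$states), names(fx$states)),
                        model = "ER")
  expect_equal(fit$alpha, as.numeric(fm$rates), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(fm$logLik), tolerance = 1e-6)

  # identifiability: tree scaled by c, rate divided by c, same loglik
  scaled <- fx$tree
  scaled$edge.length <- scaled$edge.length * 3
  ll1 <- mk_loglik(fx$tree, fx$states, mk_model(2, fit$alpha))
  ll2 <- mk_loglik(scaled, fx$states, mk_model(2, fit$alpha / 3))
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("monomorphic characters hit the zero-rate boundary", {
  tr <- sim_species_tree(6, seed = 2)$tree
  x <- stats::setNames(rep(0L, 6), tr$tip.label)
  fit <- fit_er_rate(tr, x, k = 2)
  expect_equal(fit$alpha, 0)
  expect_true(fit$boundary)
})

test_that("the ER rate is recovered in simulation", {
  alphas <- vapply(1:40, function(s) {
    tr <- sim_species_tree(150, seed = s)$tree
    sim <- sim_discrete_character(tr, er_rate = 1.0, k_states = 2,
                                  seed = s + 700)
    st <- stats::setNames(sim$tip_states$state, sim$tip_states$taxon)
    if (length(unique(st)) < 2) return(NA_real_)
    fit_er_rate(tr, st)$alpha
  }, 0)
  expect_lt(abs(stats::median(alphas, na.rm = TRUE) - 1.0), 0.4)
})

test_that("marginal posteriors match enumeration and symmetry", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  allone <- c(A = 1, B = 1, C = 1, D = 1)
  mp0 <- marginal_posteriors(tr, allone, mk_model(2, 0))
  expect_true(all(mp0$prob[mp0$state == 1] == 1))

  mixed <- c(A = 0, B = 0, C = 1, D = 1)
  mp <- marginal_posteriors(tr, mixed, mk_model(2, 0.8))
  root <- mp[mp$clade == "A;B;C;D", ]
  expect_equal(root$prob, c(0.5, 0.5), tolerance = 1e-12)

  for (i in 1:20) {
    fx <- random_er_fixture(5, seed = i + 300)
    alpha <- stats::runif(1, 0.1, 1.5)
    mp <- marginal_posteriors(fx$tree, fx$states, mk_model(2, alpha))
    oracle <- enum_marginals(fx$tree, fx$states, 2, alpha)
    got <- matrix(mp$prob, ncol = 2, byrow = TRUE)
    expect_lt(max(abs(got - oracle)), 1e-10)
  }
})

test_that("stochastic maps satisfy their structural invariants", {
  fx <- random_er_fixture(6, seed = 41)
  model <- mk_model(2, 0.7)
  maps <- sample_stochastic_maps(fx$tree, fx$states, model, n_maps = 50,
                                 seed = 9)
  tree <- maps$tree
  ntip <- length(tree$tip.label)
  for (mm in maps$maps) {
    for (r in seq_len(nrow(tree$edge))) {
      segs <- mm$segments[[r]]
      # durations sum to the branch length
      expect_equal(sum(segs[, 2]), tree$edge.length[r], tolerance = 1e-9)
      # consecutive segments change state
      if (nrow(segs) > 1) {
        expect_true(all(diff(segs[, 1]) != 0))
      }
      # tip-adjacent terminal segment matches the observed state
      child <- tree$edge[r, 2]
      if (child <= ntip) {
        expect_equal(unname(segs[nrow(segs), 1]) - 1L,
                     unname(fx$states[tree$tip.label[child]]))
      }
    }
  }
})

test_that("maps are reproducible under a seed and alpha = 0 maps are flat", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  x <- c(A = 1, B = 1, C = 1)
  m1 <- sample_stochastic_maps(tr, x, mk_model(2, 0), n_maps = 5, seed = 4)
  expect_true(all(vapply(m1$maps, function(mm) {
    all(vapply(mm$segments, nrow, 0L) == 1)
  }, TRUE)))
  a <- sample_stochastic_maps(tr, x, mk_model(2, 0.5), n_maps = 20, seed = 8)
  b <- sample_stochastic_maps(tr, x, mk_model(2, 0.5), n_maps = 20, seed = 8)
  expect_identical(a$maps, b$maps)
  expect_error(sample_stochastic_maps(tr, c(A = 0, B = 1, C = 0),
                                      mk_model(2, 0), 5, 1), "alpha = 0")
})

test_that("map-frequency posteriors converge to the exact marginals", {
  fx <- random_er_fixture(6, seed = 55)
  model <- mk_model(2, 0.6)
  exact <- marginal_posteriors(fx$tree, fx$states, model)
  linf <- vapply(c(100, 1000), function(n) {
    s <- summarize_maps(sample_stochastic_maps(fx$tree, fx$states, model,
                                               n_maps = n, seed = 13))
    j <- dplyr::inner_join(s$node_posterior, exact, by = c("node", "state"))
    max(abs(j$prob.x - j$prob.y))
  }, 0)
  expect_lt(linf[2], 0.05)
  expect_lt(linf[2], linf[1] + 0.02) # error shrinks with more maps
})

test_that("summaries conserve dwell time and collapse for a single map", {
  fx <- random_er_fixture(5, seed = 60)
  model <- mk_model(2, 0.9)
  one <- sample_stochastic_maps(fx$tree, fx$states, model, n_maps = 1,
                                seed = 3)
  s <- summarize_maps(one)
  expect_equal(sum(s$dwell_times$mean_time), sum(fx$tree$edge.length),
               tolerance = 1e-9)
  expect_true(all(s$node_posterior$prob %in% c(0, 1)))
  many <- sample_stochastic_maps(fx$tree, fx$states, model, n_maps = 30,
                                 seed = 3)
  s2 <- summarize_maps(many)
  expect_equal(sum(s2$dwell_times$mean_time), sum(fx$tree$edge.length),
               tolerance = 1e-9)
})

test_that("branch histories match an endpoint-conditioned rejection oracle", {
  # expected number of transitions on one branch, endpoints 0 -> 1,
  # alpha = 1, t = 1, k = 2: forward-simulation rejection sampler vs the
  # package's uniformization sampler
  set.seed(123)
  fwd_once <- function(alpha, t) {
    s <- 1L; n <- 0L; clock <- 0
    repeat {
      w <- stats::rexp(1, alpha)
      if (clock + w >= t) break
      clock <- clock + w
      s <- 3L - s
      n <- n + 1L
    }
    c(s, n)
  }
  draws <- replicate(20000, fwd_once(1, 1))
  oracle <- mean(draws[2, draws[1, ] == 2L])
  sampler <- nemacomp:::sample_branch_history
  got <- mean(replicate(20000, nrow(sampler(1L, 2L, 1, 2, 1)) - 1L))
  expect_equal(got, oracle, tolerance = 0.05)
})
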