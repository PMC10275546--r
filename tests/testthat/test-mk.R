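test_that("pruning likelihood matches closed forms and brute force", {
  # two tips, ER q = 0.5, both in state 0, flat root prior:
  # P00(t) = 1/2 + 1/2 exp(-2qt)
  t2 <- read_tree("(A:1,B:1);")
  ll <- mk_loglik(t2, c(A = "0", B = "0"), "ER", 0.5,
                  root_prior = "flat", states = c("0", "1"))
  p00 <- 0.5 + 0.5 * exp(-1); p01 <- 0.5 - 0.5 * exp(-1)
  expect_equal(ll, log(0.5 * (p00^2 + p01^2)), tolerance = 1e-12)

  # q -> 0 with all tips in one state: likelihood = root-prior mass
  ll0 <- mk_loglik(t2, c(A = "0", B = "0"), "ER", 1e-12,
                   root_prior = c(0.3, 0.7), states = c("0", "1"))
  expect_equal(ll0, log(0.3), tolerance = 1e-6)

  # 10-tip simulated data: pruning equals brute-force state summation
  tr <- simulate_tree(10, seed = 11)
  Q <- ouregime:::build_Q(c("0", "1"), "ER", 1.3)
  tips <- simulate_discrete(tr, Q, seed = 12)$tip_states
  pr <- c(0.5, 0.5); names(pr) <- c("0", "1")
  expect_equal(mk_loglik(tr, tips, "ER", 1.3, root_prior = "flat"),
               brute_mk_loglik(tr, tips, Q, pr), tolerance = 1e-10)

  # ARD on 3 states vs brute force on a smaller tree
  tr6 <- simulate_tree(6, seed = 13)
  Q3 <- ouregime:::build_Q(c("a", "b", "c"), "ARD", c(2, .5, 1, .7, .3, 1.4))
  tips3 <- simulate_discrete(tr6, Q3, seed = 14)$tip_states
  if (length(unique(tips3)) >= 2) {
    pr3 <- ouregime:::stationary_dist(Q3)
    expect_equal(mk_loglik(tr6, tips3, "ARD", c(2, .5, 1, .7, .3, 1.4),
                           root_prior = "stationary"),
                 brute_mk_loglik(tr6, tips3, Q3, pr3), tolerance = 1e-10)
  }
  expect_error(mk_loglik(t2, c(A = "0", B = "weird"), "ER", 1,
                         states = c("0", "1")), "unknown state")
})

test_that("pruning likelihood is invariant to tip order and rerooting", {
  tr <- simulate_tree(12, seed = 21)
  Q <- ouregime:::build_Q(c("a", "b", "c"), "SYM", c(1, .4, .8))
  tips <- simulate_discrete(tr, Q, seed = 22)$tip_states
  st <- c("a", "b", "c")
  l1 <- mk_loglik(tr, tips, "SYM", c(1, .4, .8), states = st)
  expect_equal(mk_loglik(tr, tips[sample(names(tips))], "SYM", c(1, .4, .8),
                         states = st),
               l1, tolerance = 1e-9)
  # reversible model + stationary root: invariant to rerooting at a node
  tr2 <- ape::root(ape::unroot(tr), node = 16, resolve.root = TRUE)
  tr2$scaled <- TRUE
  l2 <- mk_loglik(as_ou_phylo(tr2), tips, "SYM", c(1, .4, .8), states = st)
  expect_equal(l2, l1, tolerance = 1e-9)
})

test_that("fit_mk optimizes rates and selects structures by AICc", {
  tr <- simulate_tree(80, seed = 31)
  Q <- ouregime:::build_Q(c("0", "1"), "ER", 1)
  tips <- simulate_discrete(tr, Q, seed = 32)$tip_states
  f <- fit_mk(tr, tips, "ER")
  # dual route: ape::ace ML rate on the same data
  ac <- ape::ace(tips[tr$tip.label], tr, type = "discrete", model = "ER")
  expect_equal(unname(f$rates), unname(ac$rates), tolerance = 0.02)

  fa <- fit_mk(tr, tips, "auto")
  expect_equal(nrow(fa$candidates), 3)
  expect_equal(fa$AICc, min(fa$candidates$AICc))
  # AICc arithmetic consistent with its own lnL and k
  k <- fa$k_free; n <- fa$n_tips
  expect_equal(fa$AICc, -2 * fa$logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1))

  expect_error(fit_mk(tr, stats::setNames(rep("0", 80), tr$tip.label)),
               "degenerate")
})

test_that("fit_mk recovers the generating rate across replicates", {
  ok <- 0
  for (i in 1:50) {
    tr <- simulate_tree(200, seed = 4000 + i)
    Q <- ouregime:::build_Q(c("0", "1"), "ER", 1)
    tips <- simulate_discrete(tr, Q, seed = 5000 + i)$tip_states
    if (length(unique(tips)) < 2) next
    f <- fit_mk(tr, tips, "ER")
    if (abs(f$rates - 1) <= 0.5) ok <- ok + 1
  }
  expect_gte(ok, 45)  # >= 90% of 50 replicates within 50% of truth
})

test_that("marginal ancestral states match closed form and brute force", {
  # q -> 0, all tips one state: root marginal degenerates on that state
  tr <- simulate_tree(8, seed = 41)
  tips <- stats::setNames(rep("a", 8), tr$tip.label)
  f <- list(states = c("a", "b"),
            Q = ouregime:::build_Q(c("a", "b"), "ER", 1e-9),
            root_prior = c(a = 0.5, b = 0.5))
  anc <- ancestral_states(f, tr, tips)
  expect_gt(anc$marginal[9, "a"], 1 - 1e-6)

  # two-taxon case with unequal branches, closed form for the root marginal
  t2 <- read_tree("(A:0.5,B:1.5);")
  q <- 0.7
  Q <- ouregime:::build_Q(c("0", "1"), "ER", q)
  f2 <- list(states = c("0", "1"), Q = Q, root_prior = c(`0` = .5, `1` = .5))
  anc2 <- ancestral_states(f2, t2, c(A = "0", B = "1"))
  psame <- function(t) 0.5 + 0.5 * exp(-2 * q * t)
  pdiff <- function(t) 0.5 - 0.5 * exp(-2 * q * t)
  m0 <- psame(0.5) * pdiff(1.5); m1 <- pdiff(0.5) * psame(1.5)
  expect_equal(unname(anc2$marginal[3, ]), c(m0, m1) / (m0 + m1),
               tolerance = 1e-9)

  # 6-tip tree: every node's marginal equals brute-force enumeration
  tr6 <- simulate_tree(6, seed = 42)
  Q2 <- ouregime:::build_Q(c("a", "b"), "ER", 1.2)
  tips6 <- simulate_discrete(tr6, Q2, seed = 43)$tip_states
  f6 <- list(states = c("a", "b"), Q = Q2, root_prior = c(a = .5, b = .5))
  anc6 <- ancestral_states(f6, tr6, tips6)
  for (v in 7:11)
    expect_equal(unname(anc6$marginal[v, ]),
                 brute_mk_marginal(tr6, tips6, Q2, c(.5, .5), v),
                 tolerance = 1e-9)
  expect_true(all(abs(rowSums(anc6$marginal) - 1) < 1e-12))
})

test_that("stochastic maps are valid, seeded, and agree with theory", {
  tr <- simulate_tree(10, seed = 51)
  Q <- ouregime:::build_Q(c("a", "b"), "ER", 1.5)
  tips <- simulate_discrete(tr, Q, seed = 52)$tip_states
  f <- fit_mk(tr, tips, "ER")

  m1 <- stochastic_maps(f, tr, tips, n_maps = 3, seed = 99)
  m2 <- stochastic_maps(f, tr, tips, n_maps = 3, seed = 99)
  expect_identical(m1, m2)  # byte-identical under the same seed

  for (m in m1) {
    expect_silent(validate_painting(m, tr))
    # painting endpoints agree with the sampled node states and tip data
    expect_identical(unname(m$node_states[1:10]), unname(tips[tr$tip.label]))
    for (e in seq_len(nrow(tr$edge))) {
      seg <- m$maps[[e]]
      expect_equal(names(seg)[1], m$node_states[tr$edge[e, 1]])
      expect_equal(names(seg)[length(seg)], m$node_states[tr$edge[e, 2]])
    }
  }

  # near-zero rates: every map is the constant painting
  tips_const <- stats::setNames(rep("a", 10), tr$tip.label)
  f0 <- list(states = c("a", "b"),
             Q = ouregime:::build_Q(c("a", "b"), "ER", 1e-9),
             root_prior = c(a = 1, b = 0))
  maps0 <- stochastic_maps(f0, tr, tips_const, n_maps = 5, seed = 1)
  for (m in maps0)
    expect_true(all(vapply(m$maps, function(s) identical(names(s), "a"), TRUE)))
})

test_that("branch-path sampling matches a rejection-sampling oracle", {
  # single branch conditioned on endpoints: mean number of changes
  Q <- ouregime:::build_Q(c("a", "b"), "ER", 0.8)
  len <- 1.5
  set.seed(77)
  # oracle: unconditioned Gillespie paths, keep those ending in "b" from "a"
  n_changes_oracle <- c()
  while (length(n_changes_oracle) < 2000) {
    cur <- "a"; t_at <- 0; ch <- 0
    repeat {
      dt <- stats::rexp(1, -Q[cur, cur])
      if (t_at + dt >= len) break
      t_at <- t_at + dt; ch <- ch + 1
      cur <- if (cur == "a") "b" else "a"
    }
    if (cur == "b") n_changes_oracle <- c(n_changes_oracle, ch)
  }
  P <- ape::matexpo(Q * len)
  set.seed(78)
  n_changes_unif <- replicate(2000, {
    seg <- ouregime:::sample_branch_path(Q, c("a", "b"), "a", "b", len, P[1, 2])
    length(seg) - 1
  })
  se <- sqrt(stats::var(n_changes_oracle) / 2000 +
             stats::var(n_changes_unif) / 2000)
  expect_lt(abs(mean(n_changes_oracle) - mean(n_changes_unif)), 3 * se)
})
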