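test_that("transition probabilities match the closed form and its limits", {
  expect_equal(transition_probability(1, 2, 0), diag(2), ignore_attr = TRUE)
  P_inf <- transition_probability(1, 2, 1e6)
  expect_equal(unname(P_inf[1, ]), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(unname(P_inf[2, ]), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(transition_probability(1, 1, log(2) / 2)[1, 2], 0.25)
  ## cross-check against a numerical matrix exponential of the generator
  Q <- matrix(c(-0.7, 1.3, 0.7, -1.3), 2, 2)
  expect_equal(unname(transition_probability(0.7, 1.3, 0.9)),
               ape::matexpo(Q * 0.9), tolerance = 1e-10)
  expect_true(all(abs(rowSums(transition_probability(2, 0.1, 0.3)) - 1) < 1e-12))
})

test_that("pruning likelihood matches brute-force enumeration", {
  set.seed(20)
  for (k in 1:40) {
    n <- sample(3:6, 1)
    tree <- ape::rcoal(n)
    pat <- setNames(sample(0:1, n, replace = TRUE), tree$tip.label)
    g <- runif(1, 0.2, 3); l <- runif(1, 0.2, 3)
    m <- gainloss_model(g, l, gamma = FALSE)
    bf <- brute_gainloss(tree, pat, g, l)
    expect_equal(as.numeric(pattern_loglik(tree, pat, m)), log(bf$lik),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to leaf order and behaves in the g->0 limit", {
  tree <- ape::rcoal(5)
  pat <- setNames(c(1, 0, 1, 1, 0), tree$tip.label)
  m <- gainloss_model(0.7, 1.1, gamma = FALSE)
  ll1 <- as.numeric(pattern_loglik(tree, pat, m))
  ll2 <- as.numeric(pattern_loglik(tree, pat[sample(names(pat))], m))
  expect_equal(ll1, ll2, tolerance = 1e-12)
  ## both leaves absent, vanishing gain: the chain stays absent almost
  ## surely and the log-likelihood approaches log P(root absent) -> 0
  two <- read_newick(text = "(A:1,B:1);")
  m0 <- gainloss_model(1e-9, 1, gamma = FALSE)
  ll <- as.numeric(pattern_loglik(two, setNames(c(0, 0), c("A", "B")), m0))
  expect_lt(abs(ll), 1e-6)
})

test_that("the gamma mixture averages the category-pair likelihoods", {
  set.seed(4)
  tree <- ape::rcoal(5)
  pat <- setNames(sample(0:1, 5, replace = TRUE), tree$tip.label)
  if (sum(pat) == 0) pat[1] <- 1
  m <- gainloss_model(0.5, 1.2, alpha_gain = 0.7, alpha_loss = 2, gamma = TRUE)
  rg <- discrete_gamma(0.7, 4); rl <- discrete_gamma(2, 4)
  manual <- 0
  for (i in 1:4) for (j in 1:4) {
    manual <- manual +
      brute_gainloss(tree, pat, 0.5 * rg[i], 1.2 * rl[j])$lik / 16
  }
  expect_equal(as.numeric(pattern_loglik(tree, pat, m)), log(manual),
               tolerance = 1e-10)
  expect_equal(mean(discrete_gamma(0.31, 4)), 1, tolerance = 1e-12)
  expect_equal(discrete_gamma(5, 1), 1)
})

test_that("ancestral posteriors match brute-force marginals", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(3:6, 1)
    tree <- ape::rcoal(n)
    pat <- setNames(sample(0:1, n, replace = TRUE), tree$tip.label)
    g <- runif(1, 0.2, 2); l <- runif(1, 0.2, 2)
    m <- gainloss_model(g, l, gamma = FALSE)
    bf <- brute_gainloss(tree, pat, g, l)
    anc <- ancestral_posteriors(tree, pat, m)
    expect_equal(unname(anc$posterior[, 1]),
                 unname(bf$post[rownames(anc$posterior)]), tolerance = 1e-8)
  }
})

test_that("posteriors respect ubiquitous and absent lineages", {
  tree <- simulate_tree(8, seed = 2)
  hosts <- tree$tip.label
  x <- cbind(everywhere = rep(1, 8), nowhere = rep(0, 8))
  rownames(x) <- hosts
  m <- gainloss_model(0.5, 0.05, gamma = FALSE) # slow loss
  anc <- ancestral_posteriors(tree, x, m)
  expect_gt(anc$posterior["9", "everywhere"], 0.99)
  m2 <- gainloss_model(0.2, 1, gamma = FALSE)   # gain < loss
  anc2 <- ancestral_posteriors(tree, x, m2)
  expect_true(all(anc2$posterior[, "nowhere"] < 0.5))
  ## proper probabilities and additive expected sizes
  expect_true(all(anc$posterior >= 0 & anc$posterior <= 1))
  expect_equal(unname(anc$expected_size),
               unname(rowSums(anc$posterior)))
})

test_that("ML fitting recovers generating rates and flags degenerate input", {
  tree <- simulate_tree(32, seed = 7)
  x <- simulate_gainloss(tree, 500, gain = 1, loss = 2, seed = 11)
  fit <- fit_gainloss(tree, x, gamma = FALSE, n_restarts = 3, seed = 1)
  expect_lt(abs(fit$gain - 1) / 1, 0.25)
  expect_lt(abs(fit$loss - 2) / 2, 0.25)
  ## the optimum cannot be worse than the truth
  truth <- gainloss_model(1, 2, gamma = FALSE)
  expect_gte(fit$loglik, as.numeric(pattern_loglik(tree, x, truth)) - 1e-6)
  ## an all-present matrix drives the loss rate to the boundary
  ones <- matrix(1, 32, 3, dimnames = list(tree$tip.label, paste0("o", 1:3)))
  expect_warning(fit_gainloss(tree, ones, gamma = FALSE, n_restarts = 1,
                              seed = 1), "boundary")
})

test_that("gain/loss simulation is seed-deterministic", {
  tree <- simulate_tree(10, seed = 3)
  a <- simulate_gainloss(tree, 50, 1, 1, seed = 5)
  b <- simulate_gainloss(tree, 50, 1, 1, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_gainloss(tree, 50, 1, 1, seed = 6)))
})
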