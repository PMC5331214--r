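test_that("independent swap preserves margins and toggles checkerboards", {
  cb <- matrix(c(1, 0,
                 0, 1), 2, 2, byrow = TRUE)
  sw <- independent_swap(cb, iterations = 50, seed = 1)
  expect_equal(rowSums(sw), rowSums(cb))
  expect_equal(colSums(sw), colSums(cb))

  set.seed(5)
  x <- matrix(rbinom(200, 1, 0.4), 10, 20)
  y <- independent_swap(x, iterations = 50000, seed = 3)
  expect_identical(rowSums(y), rowSums(x))
  expect_identical(colSums(y), colSums(x))
  expect_gt(sum(y != x), 0)

  ones <- matrix(1, 3, 3)
  expect_warning(z <- independent_swap(ones, iterations = 100, seed = 1),
                 "no swappable")
  expect_identical(z, ones)
})

test_that("SES columns satisfy the definition and flag degenerate nulls", {
  tree <- simulate_tree(8, seed = 4)
  pres <- simulate_gainloss(tree, 80, gain = 0.5, loss = 0.5, seed = 9)
  pres <- pres[, colSums(pres) > 0 & colSums(pres) < nrow(pres), drop = FALSE]
  ses <- ses_profile(tree, pres, n_null = 25, seed = 2,
                     swap_iterations = 2000, refit = FALSE, gamma = FALSE,
                     n_restarts = 1)
  ok <- is.finite(ses$ses)
  expect_equal(ses$ses[ok],
               (ses$observed[ok] - ses$null_mean[ok]) / ses$null_sd[ok])
  expect_true(all(ses$p_value > 0 & ses$p_value <= 1))
  expect_equal(ses$significant, ses$p_value <= 0.05)
  ## ages are the host-tree node depths
  expect_equal(ses$age[ses$node == 9], tree_height(tree))
})

test_that("host-structured communities show phylosymbiosis at the root", {
  tree <- simulate_tree(10, seed = 4)
  pres <- simulate_gainloss(tree, 150, gain = 0.5, loss = 0.5, seed = 9)
  pres <- pres[, colSums(pres) > 0 & colSums(pres) < nrow(pres), drop = FALSE]
  ses <- ses_profile(tree, pres, n_null = 30, seed = 2,
                     swap_iterations = 5000, refit = TRUE, gamma = FALSE,
                     n_restarts = 1)
  root <- ses[ses$node == 11, ]
  expect_gt(root$ses, 0)
  expect_true(root$significant)
})

test_that("SES is invariant to relabelling OTU columns", {
  tree <- simulate_tree(6, seed = 8)
  pres <- simulate_gainloss(tree, 40, gain = 0.6, loss = 0.6, seed = 3)
  pres <- pres[, colSums(pres) > 0 & colSums(pres) < nrow(pres), drop = FALSE]
  relabelled <- pres
  colnames(relabelled) <- paste0("renamed_", rev(colnames(pres)))
  a <- ses_profile(tree, pres, n_null = 20, seed = 5, swap_iterations = 1000,
                   refit = FALSE, gamma = FALSE, n_restarts = 1)
  b <- ses_profile(tree, relabelled, n_null = 20, seed = 5,
                   swap_iterations = 1000, refit = FALSE, gamma = FALSE,
                   n_restarts = 1)
  expect_equal(a$observed, b$observed, tolerance = 1e-8)
  expect_equal(a$ses, b$ses, tolerance = 1e-6)
})

test_that("the SES-age regression is descriptive OLS with residuals", {
  ses <- data.frame(node = 1:5, age = c(1, 2, 3, 4, 5),
                    ses = c(10, 8, 6, 4, 2))
  reg <- suppressWarnings(ses_age_regression(ses))
  expect_equal(reg$slope, -2)
  expect_equal(unname(reg$residuals), rep(0, 5), tolerance = 1e-12)
  flat <- data.frame(node = 1:4, age = 1:4, ses = rep(3, 4))
  expect_equal(suppressWarnings(ses_age_regression(flat))$slope, 0,
               tolerance = 1e-12)
  expect_error(ses_age_regression(data.frame(node = 1, age = 1, ses = 1)),
               ">= 3")
})

test_that("the omnivory-aware diet distance treats omnivory as a union", {
  expect_equal(omnivory_diet_distance(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(omnivory_diet_distance(c(1, 0, 0), c(0, 0, 1)), 1)
  expect_equal(omnivory_diet_distance(c(1, 0, 0), c(0, 1, 0)), 1 / 3)
  expect_equal(omnivory_diet_distance(c(0, 1, 0), c(0, 1, 0)), 0)
  ## bounded on random probability vectors, deterministic per seed
  set.seed(1)
  for (k in 1:10) {
    pa <- rgamma(3, 1); pa <- pa / sum(pa)
    pb <- rgamma(3, 1); pb <- pb / sum(pb)
    d1 <- omnivory_diet_distance(pa, pb, n_draws = 50, seed = k)
    expect_gte(d1, 0); expect_lte(d1, 1)
    expect_equal(d1, omnivory_diet_distance(pa, pb, n_draws = 50, seed = k))
  }
})

test_that("dietary shifts localise at the generated transition", {
  tree <- simulate_tree(8, seed = 12)
  n_tip <- 8
  nodes <- as.character(1:(n_tip + tree$Nnode))
  probs <- matrix(rep(c(1, 0, 0), each = length(nodes)), length(nodes), 3,
                  dimnames = list(nodes, c("carnivore", "omnivore",
                                           "herbivore")))
  ses <- data.frame(node = (n_tip + 1):(n_tip + tree$Nnode),
                    age = node_depths(tree)[(n_tip + 1):(n_tip + tree$Nnode)],
                    ses = rnorm(tree$Nnode))
  ## all-carnivore probabilities: every shift 0, correlation undefined
  out <- dietary_shift_vs_residuals(ses, probs, tree)
  expect_true(all(out$shift == 0))
  expect_true(out$degenerate)

  ## flip one internal node's subtree to herbivore: the parent node of the
  ## flipped clade carries the maximal shift
  target <- n_tip + 3
  ## flip target and its entire subtree to herbivore
  cw <- ape::reorder.phylo(tree, "cladewise")
  in_clade <- logical(n_tip + tree$Nnode)
  in_clade[target] <- TRUE
  for (e in seq_len(nrow(cw$edge))) {
    if (in_clade[cw$edge[e, 1]]) in_clade[cw$edge[e, 2]] <- TRUE
  }
  probs2 <- probs
  probs2[as.character(which(in_clade)), ] <-
    rep(c(0, 0, 1), each = sum(in_clade))
  out2 <- dietary_shift_vs_residuals(ses, probs2, tree)
  parent <- tree$edge[tree$edge[, 2] == target, 1]
  expect_equal(unname(which.max(out2$shift)),
               unname(which(ses$node == parent)))
  expect_true(all(out2$shift >= 0 & out2$shift <= 1))
})
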