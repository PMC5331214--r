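random_dist <- function(n, seed) {
  set.seed(seed)
  as_distance_matrix(as.matrix(dist(matrix(rnorm(2 * n), n,
                              dimnames = list(paste0("h", 1:n), NULL)))))
}

test_that("MRM reduces to squared Pearson with one predictor", {
  d <- random_dist(5, 1)
  fit <- mrm(d, d, n_perm = 99, seed = 1)
  expect_equal(fit$r_squared, 1)
  e <- random_dist(5, 2)
  fit2 <- mrm(d, e, n_perm = 99, seed = 1)
  lo <- chronosym:::.lower
  expect_equal(fit2$r_squared, cor(lo(d), lo(e))^2, tolerance = 1e-12)
  ## and agrees with vegan's Mantel statistic
  vm <- vegan::mantel(d, e, permutations = 0)
  expect_equal(fit2$r_squared, vm$statistic^2, tolerance = 1e-10)
  expect_gte(fit2$p_value, 1 / 100)
  expect_error(mrm(d * 0, e), "constant")
})

test_that("MRM permutation p-values are valid under the null", {
  ## type-I at alpha = 0.1 over independent response/predictor pairs
  hits <- 0
  for (s in 1:200) {
    d <- random_dist(8, 1000 + s)
    e <- random_dist(8, 5000 + s)
    p <- mrm(d, e, n_perm = 49, seed = s)$p_value
    hits <- hits + (p <= 0.1)
  }
  rate <- hits / 200
  expect_lt(abs(rate - 0.10), 3 * sqrt(0.1 * 0.9 / 200) + 1e-9)
})

test_that("null envelopes flag a perfect correlation and respect defaults", {
  d <- random_dist(10, 3)
  env <- null_envelope(d, d, n_shuffles = 100, seed = 2)
  expect_true(env$significant)
  expect_equal(env$r_squared, 1)
  expect_equal(env$n_shuffles, 100)
  expect_lte(env$lower, env$upper)
  expect_error(null_envelope(d, d, n_shuffles = 5), ">= 20")
  ## default shuffle count mirrors the standard 100-shuffle envelope
  expect_equal(formals(null_envelope)$n_shuffles, 100L)
})

test_that("variance partitioning follows the intersection identity", {
  vp <- variance_partition(0.5, 0.3, 0.6)
  expect_equal(vp$r2_intersection, 0.2)
  expect_equal(variance_partition(0.4, 0, 0.4)$r2_intersection, 0)
  ## illustrative inputs on the scale of real profiles give a small
  ## intersection term
  expect_equal(variance_partition(0.38, 0.08, 0.42)$r2_intersection, 0.04)
})

test_that("PERMANOVA pseudo-F matches vegan and separates clear clusters", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(10, 0), 5), matrix(rnorm(10, 6), 5))
  rownames(pts) <- paste0("h", 1:10)
  d <- as_distance_matrix(as.matrix(dist(pts)))
  g <- rep(c(0, 1), each = 5)
  res <- permanova(d, g, n_perm = 199, seed = 1)
  ad <- vegan::adonis2(stats::as.dist(d) ~ factor(g), permutations = 2)
  expect_equal(res$pseudo_f, ad$F[1], tolerance = 1e-10)
  ## only relabelings reproducing the observed grouping can tie the F
  expect_gt(res$pseudo_f, 50)
  expect_lte(res$p_value, 0.05)
  expect_error(permanova(d, rep(0, 10)), "two non-empty")
})

test_that("PERMANOVA sampled p converges to the exhaustive permutation p", {
  d <- random_dist(5, 77)
  g <- c(0, 0, 1, 1, 1)
  p_ex <- exhaustive_permanova_p(d, g)
  res <- permanova(d, g, n_perm = 4999, seed = 3)
  ## sampled null and exhaustive null share the same exceedance probability
  expect_lt(abs(res$p_value - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / 5000) + 1e-3)
})

test_that("per-OTU screens flag clade-mirroring lineages and obey BH", {
  tree <- simulate_tree(12, seed = 5)
  hd <- as_distance_matrix(ape::cophenetic.phylo(tree))
  hosts <- rownames(hd)
  ## one OTU mirrors a host clade, others are noise; one is everywhere
  sizes <- vapply(13:23, function(v)
    length(ape::extract.clade(tree, v)$tip.label), integer(1))
  node <- (13:23)[which(sizes >= 4 & sizes <= 6)[1]]
  clade <- ape::extract.clade(tree, node)$tip.label
  set.seed(2)
  x <- matrix(rbinom(12 * 8, 1, 0.5), 12, 8,
              dimnames = list(hosts, paste0("o", 1:8)))
  x[, 1] <- as.integer(hosts %in% clade)
  x[, 2] <- 1
  assoc <- per_otu_association(x, host_dist = hd, n_perm = 499, seed = 4)
  expect_false(assoc$testable[assoc$otu == "o2"])
  expect_true(assoc$sig_phylo[assoc$otu == "o1"])
  ok <- assoc$testable
  expect_true(all(assoc$q_phylo[ok] >= assoc$p_phylo[ok] - 1e-12))
})

test_that("specialist classification follows the occupancy rule", {
  hosts <- paste0("h", 1:6)
  guild <- setNames(rep(c("herbivore", "carnivore", "omnivore"), each = 2), hosts)
  x <- matrix(0, 6, 3, dimnames = list(hosts, c("a", "b", "c")))
  x[guild == "herbivore", "a"] <- 1
  x[c(1, 3), "b"] <- 1           # one herbivore + one carnivore
  x[guild == "omnivore", "c"] <- 1
  assoc <- data.frame(otu = c("a", "b", "c"), sig_diet = TRUE)
  out <- classify_specialists(x, guild, assoc)
  expect_equal(unname(out[c("a", "b", "c")]),
               c("herbivore-specific", "mixed", "omnivore-specific"))
  assoc$sig_diet <- c(TRUE, TRUE, FALSE)
  expect_equal(unname(classify_specialists(x, guild, assoc)["c"]), "none")
})

test_that("omnivores built as guild mixtures yield no omnivore specialists", {
  ## generator mimicking mixed-diet hosts: omnivores carry only unions of
  ## herbivore- and carnivore-associated lineages
  hosts <- paste0("h", 1:9)
  guild <- setNames(rep(c("herbivore", "carnivore", "omnivore"), each = 3), hosts)
  set.seed(31)
  herb_otus <- paste0("H", 1:5); carn_otus <- paste0("C", 1:5)
  x <- matrix(0, 9, 10, dimnames = list(hosts, c(herb_otus, carn_otus)))
  x[guild == "herbivore", herb_otus] <- rbinom(15, 1, 0.9)
  x[guild == "carnivore", carn_otus] <- rbinom(15, 1, 0.9)
  x[guild == "omnivore", ] <- rbinom(30, 1, 0.6)
  assoc <- data.frame(otu = colnames(x), sig_diet = TRUE)
  out <- classify_specialists(x, guild, assoc)
  expect_false(any(out == "omnivore-specific"))
})
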