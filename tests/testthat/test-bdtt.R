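fixture_tree <- function() read_newick(text = "((A:1,B:1):1,C:2);")

test_that("tree slicing follows the depth rule, including the tie rule", {
  tr <- fixture_tree()
  expect_equal(unname(sort(vapply(slice_tree(tr, 0)$clades, paste, "", collapse = ""))),
               c("A", "B", "C"))
  cl <- slice_tree(tr, 1.5)$clades
  expect_equal(unname(sort(vapply(cl, paste, "", collapse = ","))), c("A,B", "C"))
  ## a node whose depth equals t belongs to the clade rooted at itself
  cl_tie <- slice_tree(tr, 1)$clades
  expect_equal(unname(sort(vapply(cl_tie, paste, "", collapse = ","))), c("A,B", "C"))
  expect_equal(length(slice_tree(tr, 2.5)$clades), 1L)
  expect_error(slice_tree(tr, -0.1), ">= 0")
})

test_that("slicing is piecewise constant and clade counts shrink with depth", {
  for (s in 1:5) {
    set.seed(s)
    tr <- as_timetree(ape::rcoal(10))
    bp <- sort(unique(attr(tr, "node_depth")))
    n_prev <- Inf
    for (k in seq_len(length(bp) - 1L)) {
      t1 <- bp[k] + 0.25 * (bp[k + 1] - bp[k])
      t2 <- bp[k] + 0.75 * (bp[k + 1] - bp[k])
      c1 <- slice_tree(tr, t1)
      c2 <- slice_tree(tr, t2)
      canon <- function(cl) {
        ids <- cl$leaf_clade[tr$tip.label]
        unname(match(ids, unique(ids)))
      }
      expect_identical(canon(c1), canon(c2))
      expect_identical(length(c1$clades), length(c2$clades))
      expect_lte(length(c1$clades), n_prev)
      n_prev <- length(c1$clades)
    }
  }
})

test_that("collapsing sums member counts and conserves host totals", {
  tr <- fixture_tree()
  tab <- matrix(c(2, 3, 1,
                  0, 4, 7), 2, 3, byrow = TRUE,
                dimnames = list(c("h1", "h2"), c("A", "B", "C")))
  id <- collapse_table(tab, slice_tree(tr, 0))
  expect_equal(sort(unname(colSums(id))), sort(unname(colSums(tab))))
  cl <- collapse_table(tab, slice_tree(tr, 1.5))
  expect_equal(unname(rowSums(cl)), unname(rowSums(tab)))
  ab_col <- grep("n5", colnames(cl))
  expect_equal(unname(cl[, ab_col]), c(5, 4)) # A+B summed per host
  one <- collapse_table(tab, slice_tree(tr, 2.5))
  expect_equal(unname(one[, 1]), unname(rowSums(tab)))
  bad <- tab; colnames(bad)[1] <- "Z"
  expect_error(collapse_table(bad, slice_tree(tr, 0)), "Z")
})

test_that("Sorensen and Bray-Curtis match hand values and vegan", {
  ps <- matrix(c(1, 1, 0,
                 0, 1, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("h1", "h2"), c("a", "b", "c")))
  expect_equal(sorensen(ps)["h1", "h2"], 0.5)
  expect_equal(sorensen(rbind(ps, h3 = c(1, 1, 0)))["h1", "h3"], 0)
  expect_equal(sorensen(rbind(ps, h3 = c(0, 0, 1)))["h1", "h3"], 1)

  tab <- matrix(c(2, 0, 4,
                  1, 1, 3), 2, 3, byrow = TRUE,
                dimnames = list(c("h1", "h2"), c("a", "b", "c")))
  expect_equal(bray_curtis(tab)["h1", "h2"], 3 / 11)
  expect_equal(bray_curtis(rbind(tab, h3 = c(2, 0, 4)))["h1", "h3"], 0)
  expect_equal(bray_curtis(rbind(tab, h3 = c(0, 9, 0)))["h1", "h3"], 1)

  set.seed(11)
  big <- matrix(rpois(80, 2), 8, 10,
                dimnames = list(paste0("h", 1:8), paste0("s", 1:10)))
  big[rowSums(big) == 0, 1] <- 1
  expect_equal(unname(bray_curtis(big)),
               unname(as.matrix(vegan::vegdist(big, "bray"))),
               tolerance = 1e-12)
  expect_equal(unname(sorensen(big)),
               unname(as.matrix(vegan::vegdist(big, "bray", binary = TRUE))),
               tolerance = 1e-12)

  empty <- rbind(tab, h3 = c(0, 0, 0))
  expect_equal(suppressWarnings(bray_curtis(empty))["h1", "h3"], 1)
  expect_error(bray_curtis(rbind(empty, h4 = c(0, 0, 0))), "empty")
})

test_that("unweighted UniFrac matches branch enumeration and picante", {
  tr <- fixture_tree()
  comm <- matrix(c(1, 0, 0,
                   0, 0, 1), 2, 3, byrow = TRUE,
                 dimnames = list(c("h1", "h2"), c("A", "B", "C")))
  ## disjoint presence on this tree shares no branch: all spanned length is
  ## unique (value computed by brute-force branch enumeration)
  expect_equal(unweighted_unifrac(tr, comm)["h1", "h2"], 1)
  comm2 <- matrix(c(1, 1, 0,
                    1, 0, 1), 2, 3, byrow = TRUE,
                  dimnames = list(c("h1", "h2"), c("A", "B", "C")))
  ## unique = B edge (1) + C edge (2); union = all four edges (5)
  expect_equal(unweighted_unifrac(tr, comm2)["h1", "h2"], 0.6)
  same <- comm2; same[2, ] <- same[1, ]
  expect_equal(unweighted_unifrac(tr, same)["h1", "h2"], 0)

  skip_if_not_installed("picante")
  for (s in 1:5) {
    fx <- random_presence_fixture(12, 5, seed = 100 + s)
    pu <- as.matrix(picante::unifrac(fx$x, fx$tree))
    pu <- pu[rownames(fx$x), rownames(fx$x)]
    expect_equal(unname(unweighted_unifrac(fx$tree, fx$x)), unname(pu),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("the slice profile decomposes UniFrac exactly on ultrametric trees", {
  for (s in 1:25) {
    fx <- random_presence_fixture(sample(5:20, 1), 4, seed = 200 + s)
    expect_equal(unname(unifrac_from_slices(fx$tree, fx$x)),
                 unname(unweighted_unifrac(fx$tree, fx$x)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("bdtt_profile slices consistently across the grid", {
  fx <- random_presence_fixture(10, 6, seed = 42)
  prof0 <- bdtt_profile(fx$tree, fx$x, depths = 0)
  expect_equal(prof0$matrices[[1]], sorensen(fx$x), ignore_attr = TRUE)

  ## piecewise constancy: profile at breakpoints equals profile just inside
  ## the following interval
  bp <- slice_depths(fx$tree, breakpoints = TRUE)
  k <- length(bp) - 1L
  eps <- 0.5 * min(diff(bp))
  p1 <- bdtt_profile(fx$tree, fx$x, depths = bp[k])
  p2 <- bdtt_profile(fx$tree, fx$x, depths = bp[k] + eps * 0.9)
  expect_equal(p1$matrices[[1]], p2$matrices[[1]], ignore_attr = TRUE)

  ## saturation: everyone occupies the single root clade
  occupied <- fx$x
  deep <- bdtt_profile(fx$tree, occupied, depths = tree_height(fx$tree))
  expect_true(all(deep$matrices[[1]] == 0))
  expect_error(bdtt_profile(fx$tree, fx$x, depths = numeric()), "empty")
})
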