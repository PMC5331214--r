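## Seeded synthetic-data generators: the four-step BDTT validation experiment
## (tree -> scale-dependent traits -> filtered communities -> profile) and a
## host-microbiome cohort generator with deep diet-filtered clades and
## shallow vertically inherited clades.

#' Simulate an ultrametric pure-birth phylogeny scaled to height 1
#'
#' @param n number of leaves (>= 2).
#' @param seed integer seed; the tree is deterministic given the seed.
#' @return a `timetree` with `n` leaves and unit height.
#' @export
simulate_tree <- function(n, seed = 1L) {
  stopifnot(n >= 2L)
  tree <- with_seed(seed, ape::rphylo(n, birth = 1, death = 0))
  tree$edge.length <- tree$edge.length / max(node_depths(tree))
  as_timetree(tree, "myr")
}

#' Simulate a trait under Brownian motion with time-varying rate (ACDC)
#'
#' Instantaneous variance `sigma^2(tau) = sigma0^2 * exp(beta * tau)` with
#' `tau` the time since the root.  `beta < 0` concentrates divergence early
#' (deep phylogenetic signal), `beta > 0` concentrates it toward the tips
#' (shallow signal), `beta = 0` is ordinary Brownian motion.  The variance
#' accrued on a branch is the exact integral
#' `sigma0^2 * (exp(beta t2) - exp(beta t1)) / beta`.
#'
#' @param tree ultrametric `timetree`.
#' @param sigma0 base rate (standard-deviation scale), default 1.
#' @param beta rate-change exponent.
#' @param seed integer seed.
#' @return named numeric vector of leaf trait values; all node values in
#'   attribute `"node_values"`.
#' @export
simulate_scaled_trait <- function(tree, sigma0 = 1, beta = 0, seed = 1L) {
  stopifnot(is_ultrametric_tree(tree))
  tt <- .gl_tree(tree)
  t_root <- ape::node.depth.edgelength(tree) # time since root, per node
  with_seed(seed, {
    x <- numeric(tt$n_node)
    for (i in rev(seq_along(tt$len))) { # preorder
      p <- tt$parent[i]; ch <- tt$child[i]
      t1 <- t_root[p]; t2 <- t_root[ch]
      v <- if (abs(beta) < 1e-12) sigma0^2 * (t2 - t1)
           else sigma0^2 * (exp(beta * t2) - exp(beta * t1)) / beta
      x[ch] <- x[p] + rnorm(1L, 0, sqrt(v))
    }
    out <- setNames(x[seq_len(tt$n_tip)], tt$tips)
    attr(out, "node_values") <- x
    out
  })
}

#' Assemble communities by Gaussian environmental filtering
#'
#' Species `s` occurs at site `j` with probability
#' `exp(-(x_s1 - E_j1)^2 / (2 w1^2)) * exp(-(x_s2 - E_j2)^2 / (2 w2^2))`:
#' two independent gradients, each filtering on one trait.  Counts are unit
#' presences.
#'
#' @param traits species x 2 matrix (or list of two named vectors) of trait
#'   values.
#' @param sites sites x 2 matrix of gradient positions.
#' @param w filter widths, length 2 (default `c(0.15, 0.15)`).
#' @param seed integer seed.
#' @return sites x species binary abundance matrix.
#' @export
assemble_communities <- function(traits, sites, w = c(0.15, 0.15), seed = 1L) {
  if (is.list(traits)) traits <- cbind(traits[[1L]], traits[[2L]])
  stopifnot(ncol(traits) == 2L, ncol(sites) == 2L, all(w > 0))
  n_sp <- nrow(traits); n_site <- nrow(sites)
  p1 <- exp(-outer(sites[, 1L], traits[, 1L], "-")^2 / (2 * w[1L]^2))
  p2 <- exp(-outer(sites[, 2L], traits[, 2L], "-")^2 / (2 * w[2L]^2))
  p <- p1 * p2
  x <- with_seed(seed,
                 matrix(rbinom(length(p), 1L, p), n_site, n_sp))
  rownames(x) <- if (!is.null(rownames(sites))) rownames(sites)
                 else paste0("site", seq_len(n_site))
  colnames(x) <- rownames(traits)
  if (any(rowSums(p) < 0.5)) {
    warning("site(s) with near-zero expected richness")
  }
  x
}

.rescale01 <- function(x) (x - min(x)) / (max(x) - min(x))

#' Four-step validation of the BDTT scale-disparity signal
#'
#' Simulates a 200-species phylogeny, evolves two environmental-preference
#' traits with opposite ACDC exponents (deep vs shallow phylogenetic
#' signal), assembles site communities under two Gaussian filters, runs the
#' BDTT profile and asks, for each gradient, at which slice depth the
#' Mantel R-squared with the site's gradient distances peaks.  The expected
#' outcome is that the deep-signal gradient peaks deeper than the
#' shallow-signal gradient.
#'
#' @param n_species leaves of the simulated phylogeny (default 200).
#' @param beta_deep,beta_shallow ACDC exponents for the two traits
#'   (defaults -3 and +3: about a 20-fold rate change over the unit-height
#'   tree).
#' @param n_sites number of sites (default 30), gradient values evenly
#'   spaced on \[0, 1\] (the second gradient is a seeded permutation, making
#'   the two filters independent).
#' @param w filter widths (default 0.15).
#' @param n_slices slice-grid size (default 40).
#' @param seed integer seed.
#' @return list with `peak_deep`, `peak_shallow` (depths of the R-squared
#'   maxima), `ordering_correct` (`peak_deep > peak_shallow`), and the
#'   per-slice `r2` data frame.
#' @export
validate_bdtt <- function(n_species = 200L, beta_deep = -3, beta_shallow = 3,
                          n_sites = 30L, w = c(0.15, 0.15), n_slices = 40L,
                          seed = 1L) {
  tree <- simulate_tree(n_species, seed = seed)
  tr_deep <- .rescale01(simulate_scaled_trait(tree, beta = beta_deep,
                                              seed = seed + 1L))
  tr_shallow <- .rescale01(simulate_scaled_trait(tree, beta = beta_shallow,
                                                 seed = seed + 2L))
  g1 <- seq(0, 1, length.out = n_sites)
  g2 <- with_seed(seed + 3L, sample(g1))
  sites <- cbind(g1, g2)
  rownames(sites) <- paste0("site", seq_len(n_sites))
  comm <- assemble_communities(cbind(tr_deep, tr_shallow), sites, w = w,
                               seed = seed + 4L)
  keep <- rowSums(comm) > 0
  comm <- comm[keep, , drop = FALSE]
  sites <- sites[keep, , drop = FALSE]
  d_deep <- as_distance_matrix(as.matrix(dist(sites[, 1L, drop = FALSE])))
  d_shallow <- as_distance_matrix(as.matrix(dist(sites[, 2L, drop = FALSE])))
  depths <- seq(0, tree_height(tree), length.out = n_slices)
  prof <- bdtt_profile(tree, comm, depths = depths, metric = "sorensen")
  r2 <- data.frame(depth = depths, deep = NA_real_, shallow = NA_real_)
  for (i in seq_along(depths)) {
    m <- prof$matrices[[i]]
    if (sd(.lower(m)) == 0) next
    r2$deep[i] <- cor(.lower(m), .lower(d_deep))^2
    r2$shallow[i] <- cor(.lower(m), .lower(d_shallow))^2
  }
  peak_deep <- depths[which.max(r2$deep)]
  peak_shallow <- depths[which.max(r2$shallow)]
  list(peak_deep = peak_deep, peak_shallow = peak_shallow,
       ordering_correct = peak_deep > peak_shallow, r2 = r2)
}

#' Generate a ground-truthed host-microbiome cohort
#'
#' Emulates the two inheritance regimes the BDTT decomposition is designed
#' to separate.  A host tree (unit height) carries diet guilds evolved under
#' a symmetric 3-state Markov chain.  A bacterial tree (height
#' `bacteria_height`, so bacteria long predate the hosts) is cut at
#' `deep_frac * height` into deep clades and at `shallow_frac * height` into
#' shallow clades.  Half the deep clades are "diet" clades: each receives a
#' herbivore or carnivore affinity, and each member leaf occurs in each
#' matching-guild host with probability `p_match` (mismatching: `p_miss`) --
#' horizontal, diet-filtered acquisition whose signal aggregates at deep
#' slices.  The other deep clades are "vertical": each *shallow* clade
#' inside them inherits one presence pattern evolved along the host tree
#' under a low-rate gain/loss chain, its members sharing that pattern up to
#' a small dropout -- host-phylogeny signal that lives at shallow slices and
#' washes out at deep ones (a deep vertical clade unions many independent
#' patterns).  The diet table places Dirichlet-noised percentage mass on the
#' guild's food items.
#'
#' @param n_hosts hosts (default 32).
#' @param n_bacteria bacterial leaves (default 600).
#' @param bacteria_height bacterial tree height in host-tree units
#'   (default 10).
#' @param deep_frac,shallow_frac cut depths as fractions of the bacterial
#'   tree height (defaults 0.5 and 0.05).
#' @param p_match,p_miss occurrence probabilities of a diet-clade member in
#'   matching / mismatching hosts (defaults 0.5 and 0.05).
#' @param gain,loss host-tree gain/loss rates of the vertical patterns
#'   (defaults 0.3 and 0.3: slow turnover relative to the host tree).
#' @param dropout per-leaf, per-host probability of losing an inherited
#'   presence (default 0.1).
#' @param guild_rate transition rate of the diet-guild chain (default 0.7).
#' @param regime `"mixed"` (default), `"vertical"` (diet clades also follow
#'   the vertical process) or `"diet"` (vertical clades also follow the
#'   diet process): the single-process controls.
#' @param seed integer seed.
#' @return list with `host_tree`, `bacteria_tree`, `abundance` (hosts x
#'   leaves), `diet` (percentage table), `guilds` (named factor) and
#'   `truth` (per-OTU regime and affinity, plus every generating parameter).
#' @export
generate_host_microbiome <- function(n_hosts = 32L, n_bacteria = 600L,
                                     bacteria_height = 10,
                                     deep_frac = 0.5, shallow_frac = 0.05,
                                     p_match = 0.5, p_miss = 0.05,
                                     gain = 0.3, loss = 0.3, dropout = 0.1,
                                     guild_rate = 0.7,
                                     regime = c("mixed", "vertical", "diet"),
                                     seed = 1L) {
  regime <- match.arg(regime)
  host_tree <- simulate_tree(n_hosts, seed = seed)
  ## diet guilds: symmetric 3-state chain; re-draw until all guilds occur
  guilds <- NULL
  Q <- matrix(guild_rate / 2, 3L, 3L); diag(Q) <- -guild_rate
  dimnames(Q) <- list(DIET_CLASSES, DIET_CLASSES)
  for (k in 0:20) {
    g <- simulate_mk(host_tree, Q, states = DIET_CLASSES, seed = seed + k)
    if (length(unique(g)) == 3L) { guilds <- g; break }
  }
  if (is.null(guilds)) guilds <- g
  guild_f <- factor(unclass(guilds)[host_tree$tip.label], levels = DIET_CLASSES)
  names(guild_f) <- host_tree$tip.label

  btree <- simulate_tree(n_bacteria, seed = seed + 100L)
  btree$edge.length <- btree$edge.length * bacteria_height
  btree <- as_timetree(btree, "myr")
  btree$tip.label <- paste0("sp", seq_len(n_bacteria))
  deep <- slice_tree(btree, deep_frac * bacteria_height)
  shallow <- slice_tree(btree, shallow_frac * bacteria_height)

  deep_ids <- names(deep$clades)
  with_seed(seed + 200L, {
    n_deep <- length(deep_ids)
    is_diet_clade <- rep(c(TRUE, FALSE), length.out = n_deep)[sample.int(n_deep)]
    if (regime == "vertical") is_diet_clade[] <- FALSE
    if (regime == "diet") is_diet_clade[] <- TRUE
    affinity <- sample(c("herbivore", "carnivore"), n_deep, replace = TRUE)
    affinity[!is_diet_clade] <- NA
    names(is_diet_clade) <- names(affinity) <- deep_ids

    x <- matrix(0L, n_hosts, n_bacteria,
                dimnames = list(host_tree$tip.label, btree$tip.label))
    otu_regime <- setNames(rep("vertical", n_bacteria), btree$tip.label)
    otu_affinity <- setNames(rep(NA_character_, n_bacteria), btree$tip.label)

    ## diet-filtered leaves: independent noisy occurrence in matching hosts
    for (cid in deep_ids[is_diet_clade]) {
      members <- deep$clades[[cid]]
      aff <- affinity[cid]
      otu_regime[members] <- "diet"
      otu_affinity[members] <- aff
      match_host <- guild_f == aff | guild_f == "omnivore"
      for (m in members) {
        p <- ifelse(match_host, p_match, p_miss)
        x[, m] <- rbinom(n_hosts, 1L, p)
      }
    }
    ## vertical leaves: one gain/loss pattern per shallow clade, with dropout
    vert_leaves <- names(otu_regime)[otu_regime == "vertical"]
    if (length(vert_leaves)) {
      vert_shallow <- unique(shallow$leaf_clade[vert_leaves])
      pat <- simulate_gainloss(host_tree, length(vert_shallow), gain, loss,
                               seed = seed + 300L)
      colnames(pat) <- vert_shallow
      for (m in vert_leaves) {
        base <- pat[rownames(x), shallow$leaf_clade[m]]
        keep <- rbinom(n_hosts, 1L, 1 - dropout)
        x[, m] <- base * keep
      }
    }
  })

  diet <- .synthesize_diet_table(guild_f, seed = seed + 400L)
  list(host_tree = host_tree, bacteria_tree = btree, abundance = x,
       diet = diet, guilds = guild_f,
       truth = list(otu_regime = otu_regime, otu_affinity = otu_affinity,
                    clade_is_diet = is_diet_clade, clade_affinity = affinity,
                    params = list(n_hosts = n_hosts, n_bacteria = n_bacteria,
                                  bacteria_height = bacteria_height,
                                  deep_frac = deep_frac,
                                  shallow_frac = shallow_frac,
                                  p_match = p_match, p_miss = p_miss,
                                  gain = gain, loss = loss,
                                  dropout = dropout, guild_rate = guild_rate,
                                  regime = regime, seed = seed)))
}

## Dirichlet-noised EltonTraits-style percentages per guild.
.synthesize_diet_table <- function(guilds, seed = 1L, concentration = 8) {
  animal <- c("Invertebrate", "Vertebrate", "RottingCarcass", "Fish",
              "UnknownVertebrate")
  plant <- c("Fruit", "Nectar", "Seed", "OtherPlant")
  with_seed(seed, {
    out <- matrix(0, length(guilds), 9L,
                  dimnames = list(names(guilds), DIET_CATEGORIES))
    for (i in seq_along(guilds)) {
      mean_p <- switch(as.character(guilds[i]),
        carnivore = c(rep(0.19, 5L), rep(0.0125, 4L)),
        herbivore = c(rep(0.01, 5L), rep(0.2375, 4L)),
        omnivore  = c(rep(0.10, 5L), rep(0.125, 4L)))
      a <- rgamma(9L, shape = mean_p * concentration, rate = 1)
      out[i, ] <- 100 * a / sum(a)
    }
    validate_diet_table(out)
  })
}
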