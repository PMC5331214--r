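## Independent oracles and fixture builders shared across the suite.
## These deliberately avoid the package's pruning/aggregation code paths.

## Brute-force likelihood and marginal posteriors of the 2-state gain/loss
## chain by exhaustive enumeration of internal-node states.
brute_gainloss <- function(tree, pattern, g, l, prior = c(l, g) / (g + l)) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  states <- rep(NA_integer_, nn)
  states[seq_len(nt)] <- pattern[tree$tip.label]
  ints <- (nt + 1L):nn
  tot <- 0
  post <- setNames(numeric(length(ints)), ints)
  for (mask in 0:(2^length(ints) - 1L)) {
    s <- states
    s[ints] <- bitwAnd(bitwShiftR(mask, 0:(length(ints) - 1L)), 1L)
    p <- prior[s[nt + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      P <- transition_probability(g, l, tree$edge.length[e])
      p <- p * P[s[tree$edge[e, 1L]] + 1L, s[tree$edge[e, 2L]] + 1L]
    }
    tot <- tot + p
    post <- post + p * s[ints]
  }
  list(lik = tot, post = post / tot)
}

## Brute-force k-state Mk marginals by enumeration (uses the matrix
## exponential directly, not the package's pruning pass).
brute_mk <- function(tree, x_idx, Q, prior) {
  k <- nrow(Q)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  ints <- (nt + 1L):nn
  Pe <- lapply(seq_len(nrow(tree$edge)),
               function(e) ape::matexpo(Q * tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(ints))))
  tot <- 0
  post <- matrix(0, length(ints), k, dimnames = list(ints, NULL))
  for (r in seq_len(nrow(grid))) {
    s <- integer(nn)
    s[seq_len(nt)] <- x_idx
    s[ints] <- grid[r, ]
    p <- prior[s[nt + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Pe[[e]][s[tree$edge[e, 1L]], s[tree$edge[e, 2L]]]
    }
    tot <- tot + p
    for (j in seq_along(ints)) post[j, s[ints[j]]] <- post[j, s[ints[j]]] + p
  }
  list(lik = tot, post = post / tot)
}

## Exhaustive PERMANOVA p-value over all label permutations (small N).
exhaustive_permanova_p <- function(dist, groups) {
  perms <- combinat_permutations(length(groups))
  f <- function(g) permanova_stat(dist, g)
  f_obs <- f(groups)
  f_all <- apply(perms, 1L, function(ix) f(groups[ix]))
  mean(f_all >= f_obs - 1e-12)
}

permanova_stat <- function(dist, g) {
  n <- nrow(dist)
  d2 <- dist^2
  a <- length(unique(g))
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ssw <- 0
  for (k in unique(g)) {
    idx <- which(g == k)
    ssw <- ssw + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
  }
  ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
}

combinat_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- combinat_permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}

## Random ultrametric tree + random presence table fixture.
random_presence_fixture <- function(n_leaves, n_hosts, seed) {
  set.seed(seed)
  tree <- as_timetree(ape::rcoal(n_leaves))
  x <- matrix(rbinom(n_hosts * n_leaves, 1L, 0.5), n_hosts, n_leaves,
              dimnames = list(paste0("h", seq_len(n_hosts)), tree$tip.label))
  ## ensure no host is empty (UniFrac needs non-empty presence sets)
  for (i in seq_len(n_hosts)) if (sum(x[i, ]) == 0) x[i, sample(n_leaves, 1L)] <- 1L
  list(tree = tree, x = x)
}

## Noiseless block fixture: each diet guild carries its own OTU block plus a
## shared block, mirroring separable diet-specific clades.
separable_diet_fixture <- function(per_class = 4L) {
  hosts <- paste0("h", seq_len(3L * per_class))
  labs <- setNames(rep(c("carnivore", "omnivore", "herbivore"),
                       each = per_class), hosts)
  pres <- matrix(0, length(hosts), 9L,
                 dimnames = list(hosts, paste0("o", 1:9)))
  carn <- which(labs == "carnivore"); omn <- which(labs == "omnivore")
  herb <- which(labs == "herbivore")
  pres[carn, 1:3] <- 1
  pres[herb, 4:6] <- 1
  pres[omn, c(1, 4, 7)] <- 1
  list(presence = pres, labels = labs)
}
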