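## Clade-wise phylosymbiosis: independent-swap nulls, standard effect sizes
## of expected ancestral community size, SES-age decay and dietary shifts.

#' Independent-swap randomisation of a binary occurrence matrix
#'
#' Sequential checkerboard swaps: at each iteration two random rows and two
#' random columns are drawn and, if they form a checkerboard (`10/01` or
#' `01/10`), the 2x2 submatrix is toggled.  Row sums (host richness) and
#' column sums (OTU occupancy) are preserved exactly; both margins are
#' asserted after every run.
#'
#' @param presence binary (0/1) matrix.
#' @param iterations number of swap attempts (default 50000).
#' @param seed integer seed; output is deterministic given the seed.
#' @return randomised binary matrix with identical margins.
#' @export
independent_swap <- function(presence, iterations = 50000L, seed = 1L) {
  stopifnot(iterations >= 1L, all(presence %in% c(0, 1)))
  x <- presence
  nr <- nrow(x); nc <- ncol(x)
  if (nr < 2L || nc < 2L) {
    warning("matrix too small to swap; returned unchanged")
    return(x)
  }
  successes <- 0L
  with_seed(seed, {
    r1 <- sample.int(nr, iterations, replace = TRUE)
    r2 <- sample.int(nr, iterations, replace = TRUE)
    c1 <- sample.int(nc, iterations, replace = TRUE)
    c2 <- sample.int(nc, iterations, replace = TRUE)
    for (i in seq_len(iterations)) {
      if (r1[i] == r2[i] || c1[i] == c2[i]) next
      a <- x[r1[i], c1[i]]; b <- x[r1[i], c2[i]]
      d <- x[r2[i], c1[i]]; e <- x[r2[i], c2[i]]
      if (a == e && b == d && a != b) {
        x[r1[i], c1[i]] <- b; x[r1[i], c2[i]] <- a
        x[r2[i], c1[i]] <- e; x[r2[i], c2[i]] <- d
        successes <- successes + 1L
      }
    }
  })
  if (successes == 0L && !.has_checkerboard(x)) {
    warning("no swappable 2x2 submatrix; matrix returned unchanged")
  }
  stopifnot(identical(rowSums(x), rowSums(presence)),
            identical(colSums(x), colSums(presence)))
  x
}

.has_checkerboard <- function(x) {
  nc <- ncol(x)
  for (j in seq_len(nc - 1L)) {
    for (k in (j + 1L):nc) {
      d <- x[, j] - x[, k]
      if (any(d > 0) && any(d < 0)) return(TRUE)
    }
  }
  FALSE
}

#' Phylosymbiosis standard effect sizes along the host tree
#'
#' For every internal host-tree node, the observed expected ancestral
#' community size (sum of per-OTU presence posteriors under the fitted
#' gain/loss model) is compared with its distribution over `n_null`
#' independent-swap randomisations of the presence table:
#' `SES = (observed - null mean) / null sd` and
#' `p = (1 + #\{null >= observed\}) / (n_null + 1)`; a node is significant
#' when `p <= 0.05`.  A large positive SES at a node means the clade's members share more
#' lineages than expected under random host-bacteria association, i.e. a
#' clade-specific phylosymbiosis signal.  By default the gain/loss model is
#' re-fit on every null table (as when the null is taken seriously as a data
#' set); `refit = FALSE` reuses the observed fit and is considerably faster.
#'
#' @param host_tree rooted, ultrametric host tree.
#' @param presence hosts x OTU binary matrix.
#' @param n_null number of null tables (default 100; >= 20).
#' @param seed integer seed.
#' @param swap_iterations swap attempts per null table (default 50000).
#' @param refit re-fit the model per null table (default TRUE).
#' @param gamma fit the gamma mixture (default FALSE: homogeneous rates,
#'   which is the economical choice when the SES is the target).
#' @param ... further arguments passed to [fit_gainloss()].
#' @return object of class `ses_result`: data frame with one row per internal
#'   node: `node` (ape id), `age`, `observed`, `null_mean`, `null_sd`, `ses`,
#'   `p_value`, `significant` (p <= 0.05).
#' @export
ses_profile <- function(host_tree, presence, n_null = 100L, seed = 1L,
                        swap_iterations = 50000L, refit = TRUE,
                        gamma = FALSE, ...) {
  if (n_null < 20L) stop("need n_null >= 20")
  fit_obs <- fit_gainloss(host_tree, presence, gamma = gamma, seed = seed, ...)
  anc_obs <- ancestral_posteriors(host_tree, presence, fit_obs)
  obs <- anc_obs$expected_size
  null_sizes <- matrix(NA_real_, n_null, length(obs))
  for (r in seq_len(n_null)) {
    xr <- independent_swap(presence, iterations = swap_iterations,
                           seed = seed + 1000L + r)
    ## randomised tables legitimately drive rates to the search bound; the
    ## boundary warning is expected there and not re-raised per replicate
    fit_r <- if (refit) suppressWarnings(
               fit_gainloss(host_tree, xr, gamma = gamma, seed = seed, ...))
             else fit_obs
    null_sizes[r, ] <- ancestral_posteriors(host_tree, xr, fit_r)$expected_size
  }
  mu <- colMeans(null_sizes)
  sdv <- apply(null_sizes, 2L, sd)
  ses <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  p <- (1 + colSums(null_sizes >= rep(obs, each = n_null))) / (n_null + 1)
  out <- data.frame(node = as.integer(names(obs)), age = anc_obs$node_age,
                    observed = obs, null_mean = mu, null_sd = sdv,
                    ses = ses, p_value = p, significant = p <= 0.05,
                    row.names = NULL)
  class(out) <- c("ses_result", class(out))
  attr(out, "n_null") <- n_null
  out
}

#' Decay of the phylosymbiosis signal with node age
#'
#' Ordinary least squares of SES on node (crown) age.  No p-value is
#' attached: the node values are phylogenetically non-independent, so the
#' slope and R-squared are descriptive.
#'
#' @param ses a [ses_profile()] result (or any data frame with `ses`, `age`,
#'   `node` columns); needs >= 3 nodes with defined SES.
#' @return list with `slope`, `intercept`, `r_squared` and `residuals`
#'   (named by node id; `NA` where SES was undefined).
#' @export
ses_age_regression <- function(ses) {
  ok <- is.finite(ses$ses)
  if (sum(ok) < 3L) stop("need >= 3 nodes with defined SES")
  fit <- lm(ses ~ age, data = ses[ok, ])
  r2 <- summary(fit)$r.squared
  res <- setNames(rep(NA_real_, nrow(ses)), ses$node)
  res[ok] <- resid(fit)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = r2, residuals = res)
}

#' Omnivory-aware dietary distance between two nodes
#'
#' Each node carries a probability vector over (carnivore, omnivore,
#' herbivore).  Per repetition one diet is drawn per node from its
#' multinomial; omnivory is recoded as the union \{carnivore, herbivore\},
#' carnivory as \{carnivore\} and herbivory as \{herbivore\}; the Sorensen
#' distance between the two resulting sets is computed, and the mean over
#' `n_draws` repetitions is returned.  This treats a specialist diet as a
#' subset of omnivory: certain carnivore vs certain omnivore gives 1/3, not 1.
#'
#' @param p_a,p_b length-3 probability vectors `(carnivore, omnivore,
#'   herbivore)`, each summing to 1.
#' @param n_draws multinomial repetitions (default 100).
#' @param seed integer seed.
#' @return mean Sorensen distance in \[0, 1\].
#' @export
omnivory_diet_distance <- function(p_a, p_b, n_draws = 100L, seed = 1L) {
  stopifnot(length(p_a) == 3L, length(p_b) == 3L,
            abs(sum(p_a) - 1) < 1e-8, abs(sum(p_b) - 1) < 1e-8)
  ## state -> two-state set: columns (has_carnivore, has_herbivore)
  sets <- rbind(c(1, 0), c(1, 1), c(0, 1))
  with_seed(seed, {
    da <- sample.int(3L, n_draws, replace = TRUE, prob = p_a)
    db <- sample.int(3L, n_draws, replace = TRUE, prob = p_b)
    A <- sets[da, , drop = FALSE]; B <- sets[db, , drop = FALSE]
    inter <- rowSums(A * B)
    mean(1 - 2 * inter / (rowSums(A) + rowSums(B)))
  })
}

#' Dietary shifts versus phylosymbiosis residuals
#'
#' The magnitude of the dietary shift at an internal node is the mean
#' [omnivory_diet_distance()] between the node and each of its (two)
#' descendant nodes (tips included as descendants, excluded as focal nodes).
#' The function correlates these shifts with the residuals of the SES-age
#' regression: a negative correlation means nodes whose descendants changed
#' diet carry less phylosymbiosis than their age predicts.
#'
#' @param ses a [ses_profile()] result.
#' @param diet_probs matrix (all tree nodes x 3, rownames = ape node ids,
#'   columns carnivore/omnivore/herbivore) of diet probabilities, e.g. from
#'   [ancestral_states()] plus certain rows for the tips.
#' @param host_tree the host tree.
#' @param n_draws,seed passed to [omnivory_diet_distance()].
#' @return list with `shift` (named per focal node) and `correlation`
#'   (Pearson R with the SES-age residuals; `NA` with a flag when degenerate).
#' @export
dietary_shift_vs_residuals <- function(ses, diet_probs, host_tree,
                                       n_draws = 100L, seed = 1L) {
  reg <- ses_age_regression(ses)
  edge <- host_tree$edge
  shift <- setNames(rep(NA_real_, nrow(ses)), ses$node)
  for (i in seq_len(nrow(ses))) {
    v <- ses$node[i]
    kids <- edge[edge[, 1L] == v, 2L]
    dists <- vapply(seq_along(kids), function(j) {
      omnivory_diet_distance(diet_probs[as.character(v), ],
                             diet_probs[as.character(kids[j]), ],
                             n_draws = n_draws, seed = seed + i * 10L + j)
    }, numeric(1L))
    shift[i] <- mean(dists)
  }
  ok <- is.finite(shift) & is.finite(reg$residuals)
  degenerate <- sd(shift[ok]) == 0 || sd(reg$residuals[ok]) == 0
  r <- if (degenerate) NA_real_ else cor(reg$residuals[ok], shift[ok])
  list(shift = shift, correlation = r, degenerate = degenerate,
       residuals = reg$residuals)
}
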