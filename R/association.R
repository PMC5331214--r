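## Distance-matrix regression, permutation nulls, variance partitioning and
## per-lineage PERMANOVA screens.

.lower <- function(m) m[lower.tri(m)]

#' Multiple regression on distance matrices (Mantel/MRM)
#'
#' Ordinary least squares of the unfolded strict lower triangle of the
#' response on those of the predictors.  Significance by permutation: the
#' rows and columns of the response matrix are permuted jointly and the
#' coefficient of determination recomputed;
#' `p = (1 + #\{permuted R2 >= observed\}) / (n_perm + 1)`.
#' With a single predictor the R2 equals the squared Pearson correlation of
#' the unfolded distances (the classic Mantel r squared).
#'
#' @param response labelled distance matrix.
#' @param predictors one labelled distance matrix or a list of them; all must
#'   share the response's labels (use [align_labels()] first if needed).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return object of class `mrm_result`: list with `r_squared`, `coefficients`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
mrm <- function(response, predictors, n_perm = 999L, seed = 1L) {
  if (is.matrix(predictors)) predictors <- list(predictors)
  stopifnot(n_perm >= 1L, length(predictors) >= 1L)
  labs <- rownames(response)
  for (p in predictors) {
    if (!identical(rownames(p), labs)) stop("predictor labels not aligned with response")
  }
  X <- cbind(1, vapply(predictors, .lower, numeric(sum(lower.tri(response)))))
  y <- .lower(response)
  if (sd(y) == 0) stop("constant response matrix: R2 undefined")
  for (j in seq_along(predictors)) {
    if (sd(X[, j + 1L]) == 0) stop("constant predictor matrix: R2 undefined")
  }
  fit <- stats::lm.fit(X, y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  n <- nrow(response)
  perm_r2 <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    ord <- sample.int(n)
    yp <- .lower(response[ord, ord])
    fp <- stats::lm.fit(X, yp)
    1 - sum(fp$residuals^2) / sum((yp - mean(yp))^2)
  }, numeric(1L)))
  p <- (1 + sum(perm_r2 >= r2)) / (n_perm + 1)
  structure(list(r_squared = r2, coefficients = fit$coefficients,
                 p_value = p, n_perm = n_perm, seed = seed),
            class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("MRM: R2 = %.4f, p = %.4g (%d permutations)\n",
              x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}

#' Null envelope of R-squared under predictor label shuffling
#'
#' Host names are shuffled in the predictor matrix (rows and columns jointly)
#' and the regression R2 recomputed per shuffle; the 2.5% and 97.5% empirical
#' quantiles form a 95% envelope.  A correlation is called significant when
#' the observed R2 exceeds the upper bound.
#'
#' @param response labelled distance matrix.
#' @param predictor labelled distance matrix.
#' @param n_shuffles number of shuffles (default 100); at least 20 for a 95%
#'   envelope.
#' @param seed integer seed.
#' @return list with `lower`, `upper`, `r_squared` (observed), `significant`,
#'   `null_r2`, `n_shuffles`.
#' @export
null_envelope <- function(response, predictor, n_shuffles = 100L, seed = 1L) {
  if (n_shuffles < 20L) stop("need >= 20 shuffles for a 95% envelope")
  obs <- mrm(response, predictor, n_perm = 1L, seed = seed)$r_squared
  n <- nrow(predictor)
  y <- .lower(response)
  null_r2 <- with_seed(seed, vapply(seq_len(n_shuffles), function(k) {
    ord <- sample.int(n)
    cor(y, .lower(predictor[ord, ord]))^2
  }, numeric(1L)))
  qs <- unname(quantile(null_r2, c(0.025, 0.975), type = 7))
  list(lower = qs[1L], upper = qs[2L], r_squared = obs,
       significant = obs > qs[2L], null_r2 = null_r2,
       n_shuffles = n_shuffles)
}

#' Variance partitioning of two distance predictors
#'
#' Given the R2 of each predictor alone and of the two-predictor model, the
#' intersection (jointly explained) component is
#' `R2_a + R2_b - R2_union`.
#'
#' @param r2_a,r2_b,r2_union coefficients of determination in \[0, 1\].
#' @return list with `r2_a`, `r2_b`, `r2_union`, `r2_intersection`.
#' @export
variance_partition <- function(r2_a, r2_b, r2_union) {
  stopifnot(all(c(r2_a, r2_b, r2_union) >= 0),
            all(c(r2_a, r2_b, r2_union) <= 1))
  list(r2_a = r2_a, r2_b = r2_b, r2_union = r2_union,
       r2_intersection = r2_a + r2_b - r2_union)
}

#' Per-slice correlation profile against host factors
#'
#' Runs [mrm()] of each slice's dissimilarity matrix on each predictor, plus
#' the two-predictor model and [variance_partition()] when two predictors are
#' given, and [null_envelope()]s per factor.
#'
#' @param profile a [bdtt_profile()].
#' @param predictors named list of labelled distance matrices (e.g.
#'   `list(phylogeny = H, diet = D)`).
#' @param n_perm permutations for the MRM p-value (default 999).
#' @param n_shuffles envelope shuffles (default 100).
#' @param seed integer seed.
#' @return data frame with one row per slice x predictor: depth, predictor,
#'   r_squared, p_value, envelope bounds, significance; two-predictor
#'   partition columns attached as attribute `"partition"` when applicable.
#' @export
correlate_profile <- function(profile, predictors, n_perm = 999L,
                              n_shuffles = 100L, seed = 1L) {
  stopifnot(inherits(profile, "bdtt_profile"), length(names(predictors)) > 0L)
  rows <- list()
  part <- NULL
  for (i in seq_along(profile$depths)) {
    resp <- profile$matrices[[i]]
    aligned <- do.call(align_labels, c(list(resp), predictors))
    resp_a <- aligned[[1L]]
    preds <- aligned[-1L]
    names(preds) <- names(predictors)
    r2s <- numeric(length(preds))
    for (j in seq_along(preds)) {
      fit <- mrm(resp_a, preds[[j]], n_perm = n_perm, seed = seed + j)
      env <- null_envelope(resp_a, preds[[j]], n_shuffles = n_shuffles,
                           seed = seed + j)
      r2s[j] <- fit$r_squared
      rows[[length(rows) + 1L]] <- data.frame(
        depth = profile$depths[i], predictor = names(preds)[j],
        r_squared = fit$r_squared, p_value = fit$p_value,
        env_lower = env$lower, env_upper = env$upper,
        significant = env$significant)
    }
    if (length(preds) == 2L) {
      r2u <- mrm(resp_a, preds, n_perm = 1L, seed = seed)$r_squared
      vp <- variance_partition(min(r2s[1L], 1), min(r2s[2L], 1),
                               min(max(r2u, 0), 1))
      part <- rbind(part, data.frame(depth = profile$depths[i],
                                     r2_union = vp$r2_union,
                                     r2_intersection = vp$r2_intersection))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "partition") <- part
  out
}

#' Distance-based permutation MANOVA (one factor)
#'
#' Pseudo-F for a grouping of hosts on a distance matrix:
#' `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `F = ((SS_total - SS_within)/(a-1)) / (SS_within/(N-a))`,
#' with significance by permutation of the group labels.
#'
#' @param dist labelled distance matrix.
#' @param groups factor/vector of group memberships, named by host or in row
#'   order; every group must be non-empty.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @return list with `pseudo_f`, `p_value`, `n_perm`.
#' @export
permanova <- function(dist, groups, n_perm = 999L, seed = 1L) {
  n <- nrow(dist)
  if (!is.null(names(groups))) groups <- groups[rownames(dist)]
  g <- as.integer(factor(groups))
  a <- length(unique(g))
  if (a < 2L) stop("need at least two non-empty groups")
  if (any(tabulate(g) == 0L)) stop("empty group")
  d2 <- dist^2
  ss_total <- sum(.lower(d2)) / n
  stat <- function(g) {
    ssw <- 0
    for (k in unique(g)) {
      idx <- which(g == k)
      ssw <- ssw + sum(.lower(d2[idx, idx, drop = FALSE])) / length(idx)
    }
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- stat(g)
  f_perm <- with_seed(seed, vapply(seq_len(n_perm),
                                   function(k) stat(sample(g)), numeric(1L)))
  list(pseudo_f = f_obs,
       p_value = (1 + sum(f_perm >= f_obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Screen every lineage for association with host factors
#'
#' For each OTU (column of the collapsed table), its presence/absence across
#' hosts defines a two-group partition; [permanova()] asks whether hosts
#' carrying the OTU are closer to each other than expected on the host
#' phylogenetic and dietary distance matrices.  OTUs present in fewer than 2
#' or absent from fewer than 2 hosts are flagged untestable.  p-values are
#' Benjamini-Hochberg adjusted across testable OTUs per factor.
#'
#' @param collapsed hosts x OTU count matrix (a [collapse_table()] result).
#' @param host_dist,diet_dist labelled host distance matrices (either may be
#'   `NULL` to skip that factor).
#' @param alpha FDR significance level (default 0.05).
#' @param n_perm permutations per test (default 999).
#' @param seed integer seed.
#' @return data frame, one row per OTU: `otu`, `testable`, `f_phylo`,
#'   `p_phylo`, `q_phylo`, `sig_phylo`, and the same for diet.
#' @export
per_otu_association <- function(collapsed, host_dist = NULL, diet_dist = NULL,
                                alpha = 0.05, n_perm = 999L, seed = 1L) {
  pres <- collapsed > 0
  n_pres <- colSums(pres)
  testable <- n_pres >= 2 & (nrow(pres) - n_pres) >= 2
  out <- data.frame(otu = colnames(collapsed), testable = testable,
                    row.names = NULL)
  for (factor_name in c("phylo", "diet")) {
    dmat <- if (factor_name == "phylo") host_dist else diet_dist
    if (is.null(dmat)) next
    dmat <- dmat[rownames(pres), rownames(pres)]
    f <- p <- rep(NA_real_, ncol(pres))
    for (j in which(testable)) {
      res <- permanova(dmat, ifelse(pres[, j], 1L, 0L),
                       n_perm = n_perm, seed = seed + j)
      f[j] <- res$pseudo_f; p[j] <- res$p_value
    }
    q <- rep(NA_real_, length(p))
    q[testable] <- p.adjust(p[testable], method = "BH")
    out[[paste0("f_", factor_name)]] <- f
    out[[paste0("p_", factor_name)]] <- p
    out[[paste0("q_", factor_name)]] <- q
    out[[paste0("sig_", factor_name)]] <- !is.na(q) & q < alpha
  }
  out
}

#' Classify diet-associated lineages as diet specialists
#'
#' Among OTUs significantly associated with diet, an OTU is
#' herbivore-specific when it occurs only in herbivores, carnivore-specific
#' when only in carnivores, omnivore-specific when only in omnivores, and
#' `"mixed"` otherwise.  Non-significant or untestable OTUs are labelled
#' `"none"`.
#'
#' @param collapsed hosts x OTU count matrix.
#' @param diet_labels named vector host -> `"carnivore"`/`"omnivore"`/
#'   `"herbivore"`.
#' @param assoc a [per_otu_association()] table with a `sig_diet` column.
#' @return named character vector of per-OTU labels.
#' @export
classify_specialists <- function(collapsed, diet_labels, assoc) {
  stopifnot(all(rownames(collapsed) %in% names(diet_labels)),
            "sig_diet" %in% names(assoc))
  guild <- diet_labels[rownames(collapsed)]
  sig <- setNames(assoc$sig_diet, assoc$otu)[colnames(collapsed)]
  out <- setNames(rep("none", ncol(collapsed)), colnames(collapsed))
  for (j in which(sig)) {
    hosts <- guild[collapsed[, j] > 0]
    u <- unique(hosts)
    out[j] <- if (length(u) == 1L) paste0(u, "-specific") else "mixed"
  }
  out
}
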