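## Microbiome-based diet inference: diet distances and discretisation,
## ordination + multinomial regression with AIC axis selection, projection of
## (possibly probabilistic) ancestral communities, score, entropy, LOO-CV.

DIET_CLASSES <- c("carnivore", "omnivore", "herbivore")

#' Euclidean distance between hosts' dietary percentage profiles
#'
#' @param diet hosts x 9 percentage matrix (see [read_diet_table()]).
#' @return labelled distance matrix.
#' @export
euclidean_diet_distance <- function(diet) {
  validate_diet_table(diet)
  as_distance_matrix(as.matrix(dist(diet, method = "euclidean")))
}

#' Discretise dietary percentages into three diet classes
#'
#' The plant share is `Fruit + Nectar + Seed + OtherPlant`; a host is
#' herbivore when plant share >= `plant_threshold`, carnivore when plant
#' share <= `100 - plant_threshold`, omnivore otherwise.  The default 90
#' keeps only strongly specialised feeders out of the omnivore class.
#'
#' @param diet hosts x 9 percentage matrix.
#' @param plant_threshold percentage in (50, 100\] (default 90).
#' @return named factor host -> carnivore/omnivore/herbivore.
#' @export
discretize_diet <- function(diet, plant_threshold = 90) {
  stopifnot(plant_threshold > 50, plant_threshold <= 100)
  validate_diet_table(diet)
  plant <- rowSums(diet[, c("Fruit", "Nectar", "Seed", "OtherPlant"),
                        drop = FALSE])
  out <- ifelse(plant >= plant_threshold, "herbivore",
                ifelse(plant <= 100 - plant_threshold, "carnivore",
                       "omnivore"))
  factor(setNames(out, rownames(diet)), levels = DIET_CLASSES)
}

#' Shannon entropy of a probability vector
#'
#' `H = -sum_i p_i log p_i` (natural log, `0 log 0 = 0`).  Low entropy means
#' a confident diet call; the maximum for three classes is `log(3)`.
#'
#' @param p probability vector summing to 1.
#' @return non-negative entropy.
#' @export
diet_entropy <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= -1e-12))
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Linear carnivory-herbivory score of a diet probability vector
#'
#' Weights 0 (carnivore), 0.5 (omnivore) and 1 (herbivore): the score maps a
#' probability vector onto a single gradient where 0 is a certain carnivore
#' and 1 a certain herbivore.
#'
#' @param p length-3 probability vector `(carnivore, omnivore, herbivore)`.
#' @return score in \[0, 1\].
#' @export
diet_score <- function(p) {
  stopifnot(length(p) == 3L, abs(sum(p) - 1) < 1e-8)
  sum(p * c(0, 0.5, 1))
}

#' Build a microbiome-based diet predictor
#'
#' Centers the presence matrix of diet-associated OTUs, extracts its
#' principal axes, and for each candidate number of axes `m = 1..max_axes`
#' fits a three-class multinomial logistic regression of diet on the first
#' `m` host coordinates (with a small L2 penalty so perfect separation does
#' not blow up the fit); the retained `m` minimises AIC with
#' `k = (n_classes - 1)(m + 1)` parameters.
#'
#' @param presence hosts x OTU presence (0/1) matrix restricted to the
#'   diet-significant roster (see [per_otu_association()]).
#' @param diet_labels named factor host -> carnivore/omnivore/herbivore; at
#'   least two classes must be present.
#' @param max_axes maximum ordination axes to consider (default 5, bounded by
#'   hosts - 2).
#' @param decay L2 penalty of the multinomial fit (default 1e-6).
#' @return object of class `diet_predictor`: `roster`, `center`, `loadings`,
#'   `n_axes`, `fit` (nnet multinom), `aic_trace`, `classes`.
#' @export
build_predictor <- function(presence, diet_labels, max_axes = 5L,
                            decay = 1e-6) {
  presence <- (presence > 0) * 1
  labs <- factor(diet_labels[rownames(presence)], levels = DIET_CLASSES)
  labs <- droplevels(labs)
  if (nlevels(labs) < 2L) stop("need >= 2 diet classes among the hosts")
  if (any(table(labs) < 2L)) {
    warning("diet class(es) with < 2 hosts: ",
            paste(names(which(table(labs) < 2L)), collapse = ", "))
  }
  max_axes <- min(max_axes, nrow(presence) - 2L, ncol(presence))
  ctr <- colMeans(presence)
  Xc <- sweep(presence, 2L, ctr)
  pc <- prcomp(Xc, center = FALSE, scale. = FALSE)
  n_avail <- sum(pc$sdev > 1e-10)
  max_axes <- min(max_axes, n_avail)
  scores <- pc$x
  aic <- numeric(max_axes)
  fits <- vector("list", max_axes)
  for (m in seq_len(max_axes)) {
    df <- data.frame(diet = labs, scores[, seq_len(m), drop = FALSE])
    fits[[m]] <- nnet::multinom(diet ~ ., data = df, decay = decay,
                                trace = FALSE, maxit = 500L)
    aic[m] <- stats::AIC(fits[[m]])
  }
  m_best <- which.min(aic)
  structure(list(roster = colnames(presence), center = ctr,
                 loadings = pc$rotation[, seq_len(m_best), drop = FALSE],
                 n_axes = m_best, fit = fits[[m_best]],
                 aic_trace = aic, classes = levels(labs), decay = decay),
            class = "diet_predictor")
}

#' @export
print.diet_predictor <- function(x, ...) {
  cat("diet predictor:", length(x$roster), "OTUs,", x$n_axes,
      "ordination axes (AIC-selected), classes:",
      paste(x$classes, collapse = "/"), "\n")
  invisible(x)
}

#' Predict diet from a (possibly probabilistic) community
#'
#' The community vector over the predictor's OTU roster is centered with the
#' extant means, projected on the retained principal axes, and passed through
#' the multinomial model.  Fractional entries are accepted, so ancestral
#' posterior communities project directly without thresholding; set
#' `threshold = 0.5` for hard presence calls first.
#'
#' @param predictor a [build_predictor()] result.
#' @param community named numeric vector (or hosts x OTU matrix) of presence
#'   probabilities in \[0, 1\] over the roster.
#' @param threshold optional hard-call cutoff applied before projection.
#' @return for a single community, a list with `probabilities` (3-vector on
#'   carnivore/omnivore/herbivore), `score` (0 = carnivore, 0.5 = omnivore,
#'   1 = herbivore weights) and `entropy`; for a matrix, a data frame with
#'   one row per community.
#' @export
predict_diet <- function(predictor, community, threshold = NULL) {
  single <- is.null(dim(community))
  if (single) community <- matrix(community, 1L,
                                  dimnames = list("community",
                                                  names(community)))
  if (!setequal(colnames(community), predictor$roster)) {
    stop("community OTUs do not match the predictor roster")
  }
  x <- community[, predictor$roster, drop = FALSE]
  if (!is.null(threshold)) x <- (x >= threshold) * 1
  z <- sweep(x, 2L, predictor$center) %*% predictor$loadings
  newdata <- as.data.frame(z)
  colnames(newdata) <- colnames(predictor$loadings)
  pr <- predict(predictor$fit, newdata = newdata, type = "probs")
  if (is.null(dim(pr))) {
    pr <- if (length(predictor$fit$lev) == 2L) {
      ## two-class multinom returns P(second level) only
      if (nrow(newdata) == 1L) matrix(c(1 - pr, pr), 1L,
                                      dimnames = list(NULL, predictor$fit$lev))
      else cbind(1 - pr, pr)
    } else matrix(pr, 1L, dimnames = list(NULL, names(pr)))
  }
  if (is.null(colnames(pr))) colnames(pr) <- predictor$fit$lev
  probs <- matrix(0, nrow(pr), 3L,
                  dimnames = list(rownames(x), DIET_CLASSES))
  probs[, colnames(pr)] <- pr
  score <- apply(probs, 1L, diet_score)
  entropy <- apply(probs, 1L, diet_entropy)
  if (single) {
    list(probabilities = probs[1L, ], score = unname(score[1L]),
         entropy = unname(entropy[1L]))
  } else {
    data.frame(probs, score = score, entropy = entropy)
  }
}

#' Leave-one-out cross-validation of the diet predictor
#'
#' Each host is held out in turn, the predictor rebuilt on the rest and the
#' held-out host's diet predicted; the class accuracy and mean predictive
#' entropy are reported.  With `reselect = TRUE` the diet-significant OTU
#' roster is re-screened inside each fold (requires the distance matrices).
#'
#' @param presence hosts x OTU presence matrix.
#' @param diet_labels named factor of diet classes.
#' @param max_axes,decay passed to [build_predictor()].
#' @param seed integer seed (only used when `reselect = TRUE`).
#' @param reselect re-run the per-OTU diet screen per fold.
#' @param diet_dist labelled host dietary distance matrix (for `reselect`).
#' @param n_perm permutations of the per-fold screen.
#' @return list with `accuracy`, `mean_entropy`, `predictions` (data frame
#'   host / truth / call / score / entropy) and `degenerate` flag (single
#'   observed class).
#' @export
loo_cv <- function(presence, diet_labels, max_axes = 5L, decay = 1e-6,
                   seed = 1L, reselect = FALSE, diet_dist = NULL,
                   n_perm = 199L) {
  stopifnot(nrow(presence) >= 3L)
  hosts <- rownames(presence)
  labs <- factor(diet_labels[hosts], levels = DIET_CLASSES)
  if (nlevels(droplevels(labs)) < 2L) {
    cls <- as.character(labs)
    return(list(accuracy = 1, mean_entropy = 0,
                predictions = data.frame(host = hosts, truth = cls,
                                         call = cls, score = NA_real_,
                                         entropy = 0),
                degenerate = TRUE))
  }
  calls <- character(length(hosts))
  scores <- ent <- numeric(length(hosts))
  for (i in seq_along(hosts)) {
    train <- presence[-i, , drop = FALSE]
    roster <- colnames(train)
    if (reselect) {
      stopifnot(!is.null(diet_dist))
      assoc <- per_otu_association(train,
                                   diet_dist = diet_dist[hosts[-i], hosts[-i]],
                                   n_perm = n_perm, seed = seed + i)
      roster <- assoc$otu[assoc$sig_diet]
      if (length(roster) < 2L) roster <- colnames(train)
    }
    keep <- colSums(train[, roster, drop = FALSE]) > 0
    roster <- roster[keep]
    pred <- build_predictor(train[, roster, drop = FALSE], labs[-i],
                            max_axes = max_axes, decay = decay)
    res <- predict_diet(pred, presence[i, roster])
    calls[i] <- DIET_CLASSES[which.max(res$probabilities)]
    scores[i] <- res$score
    ent[i] <- res$entropy
  }
  degenerate <- nlevels(droplevels(labs)) < 2L
  list(accuracy = mean(calls == as.character(labs)),
       mean_entropy = mean(ent),
       predictions = data.frame(host = hosts, truth = as.character(labs),
                                call = calls, score = scores, entropy = ent),
       degenerate = degenerate)
}
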