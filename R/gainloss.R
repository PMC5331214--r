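## Two-state gain/loss CTMC along the host tree: pruning likelihood with
## discrete-gamma rate variation across OTUs, ML fitting, and marginal
## ancestral presence posteriors.

#' Discrete-gamma rate categories (mean method)
#'
#' Splits a Gamma(shape, shape) distribution (mean 1) into `k` equiprobable
#' classes and returns the class means, renormalised so the mixture mean is
#' exactly 1.
#'
#' @param shape gamma shape parameter (> 0).
#' @param k number of categories (default 4).
#' @return numeric vector of `k` rate multipliers with mean 1.
#' @export
discrete_gamma <- function(shape, k = 4L) {
  if (k == 1L) return(1)
  b <- qgamma(seq_len(k - 1L) / k, shape = shape, rate = shape)
  p <- pgamma(c(0, b, Inf), shape = shape + 1, rate = shape)
  m <- k * diff(p)
  m / mean(m)
}

#' Transition probabilities of the 2-state gain/loss chain
#'
#' Closed form for states (0 = absent, 1 = present) with gain rate `g`
#' (0 -> 1) and loss rate `l` (1 -> 0) over elapsed length `t`:
#' `P(0 -> 1) = g/(g+l) * (1 - exp(-(g+l) t))`,
#' `P(1 -> 1) = 1 - l/(g+l) * (1 - exp(-(g+l) t))`.
#'
#' @param g,l gain and loss rates (> 0).
#' @param t branch length (>= 0).
#' @return 2x2 matrix, rows = from-state (absent, present), rows sum to 1.
#' @export
transition_probability <- function(g, l, t) {
  stopifnot(g > 0, l > 0, t >= 0)
  e <- exp(-(g + l) * t)
  p01 <- g / (g + l) * (1 - e)
  p10 <- l / (g + l) * (1 - e)
  matrix(c(1 - p01, p10, p01, 1 - p10), 2L, 2L,
         dimnames = list(c("absent", "present"), c("absent", "present")))
}

## Internal: postorder scaffold reused by every likelihood computation.
.gl_tree <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(po$tip.label)
  list(po = po, n_tip = n_tip, root = n_tip + 1L,
       n_node = n_tip + po$Nnode,
       parent = po$edge[, 1L], child = po$edge[, 2L],
       len = po$edge.length, tips = po$tip.label)
}

## Internal: leaf partials as a 2 x nOTU x nTip array from a presence matrix
## (hosts x OTUs, hosts matched to tip labels).
.gl_leaf_partials <- function(tt, presence) {
  idx <- match(tt$tips, rownames(presence))
  if (anyNA(idx)) stop("presence matrix missing host(s): ",
                       paste(tt$tips[is.na(idx)], collapse = ", "))
  x <- t(presence[idx, , drop = FALSE]) # OTUs x tips
  storage.mode(x) <- "double"
  x
}

## Internal pruning pass for one (gain, loss) rate pair with optional
## per-edge multipliers. Returns per-OTU log-likelihood and, if keep = TRUE,
## partials and per-edge messages for the downward pass.
.gl_up <- function(tt, X, g, l, mult_g = NULL, mult_l = NULL,
                   root_prior, keep = FALSE) {
  n_otu <- nrow(X)
  ge <- if (is.null(mult_g)) rep(g, length(tt$len)) else g * mult_g
  le <- if (is.null(mult_l)) rep(l, length(tt$len)) else l * mult_l
  L <- vector("list", tt$n_node)
  for (tip in seq_len(tt$n_tip)) {
    L[[tip]] <- rbind(1 - X[, tip], X[, tip]) # 2 x nOTU
  }
  logscale <- numeric(n_otu)
  msgs <- if (keep) vector("list", length(tt$len)) else NULL
  Pm <- if (keep) vector("list", length(tt$len)) else NULL
  for (i in seq_along(tt$len)) {
    p <- tt$parent[i]; ch <- tt$child[i]
    P <- transition_probability(ge[i], le[i], tt$len[i])
    M <- P %*% L[[ch]]
    if (keep) { msgs[[i]] <- M; Pm[[i]] <- P }
    L[[p]] <- if (is.null(L[[p]])) M else L[[p]] * M
    if (ch > tt$n_tip) { # rescale after absorbing an internal child
      s <- pmax(L[[p]][1L, ], L[[p]][2L, ])
      s[s == 0] <- 1
      L[[p]] <- L[[p]] / rep(s, each = 2L)
      logscale <- logscale + log(s)
    }
  }
  prior <- if (identical(root_prior, "stationary")) c(l, g) / (g + l)
           else root_prior
  lik_root <- prior[1L] * L[[tt$root]][1L, ] + prior[2L] * L[[tt$root]][2L, ]
  out <- list(loglik_otu = log(lik_root) + logscale, prior = prior)
  if (keep) { out$L <- L; out$msgs <- msgs; out$P <- Pm }
  out
}

## Internal: category grid for a model.
.gl_categories <- function(model) {
  rg <- if (model$gamma) discrete_gamma(model$alpha_gain, model$n_cat) else 1
  rl <- if (model$gamma) discrete_gamma(model$alpha_loss, model$n_cat) else 1
  grid <- expand.grid(mg = rg, ml = rl)
  grid$w <- 1 / nrow(grid)
  grid
}

#' Log-likelihood of presence/absence patterns under a gain/loss model
#'
#' Felsenstein pruning along the host tree, averaged over the discrete-gamma
#' category pairs (independent 4-class discretisations for gain and loss, 16
#' equally weighted components by default), root weighted by the model's
#' prior.
#'
#' @param host_tree rooted host `timetree`/`phylo` with branch lengths.
#' @param presence hosts x OTU binary matrix (named rows covering all leaves);
#'   a single named vector is treated as one OTU.
#' @param model a [gainloss_model()] / [fit_gainloss()] object.
#' @return total log-likelihood (sum over OTUs); per-OTU values in attribute
#'   `"loglik_otu"`.
#' @export
pattern_loglik <- function(host_tree, presence, model) {
  presence <- .gl_orig_names(presence)
  tt <- .gl_tree(host_tree)
  X <- .gl_leaf_partials(tt, presence)
  out <- .gl_mixture_loglik(tt, X, model)
  structure(sum(out), loglik_otu = out)
}

## Per-OTU mixture log-likelihood (log-sum-exp over category pairs), with the
## optional ascertainment correction.
.gl_mixture_loglik <- function(tt, X, model) {
  cats <- .gl_categories(model)
  LL <- matrix(NA_real_, nrow(cats), nrow(X))
  for (r in seq_len(nrow(cats))) {
    LL[r, ] <- .gl_up(tt, X, model$gain * cats$mg[r], model$loss * cats$ml[r],
                      model$branch_gain, model$branch_loss,
                      model$root_prior)$loglik_otu
  }
  shift <- apply(LL, 2L, max)
  out <- shift + log(colSums(cats$w * exp(sweep(LL, 2L, shift))))
  if (model$ascertainment) {
    X0 <- matrix(0, 1L, ncol(X))
    m0 <- .strip_ascertainment(model)
    out <- out - log(1 - exp(.gl_mixture_loglik(tt, X0, m0)))
  }
  out
}

.strip_ascertainment <- function(model) { model$ascertainment <- FALSE; model }

#' Construct a gain/loss model object
#'
#' @param gain,loss rates per unit host-branch length (> 0).
#' @param alpha_gain,alpha_loss gamma shapes for across-OTU rate variation.
#' @param gamma use the discrete-gamma mixture (default TRUE).
#' @param n_cat categories per gamma (default 4).
#' @param root_prior `"stationary"` (default: `P(present) = g/(g+l)`) or a
#'   numeric vector `c(p_absent, p_present)`.
#' @param branch_gain,branch_loss optional per-edge rate multipliers
#'   (postorder edge order), for the non-homogeneous variant.
#' @param ascertainment correct the likelihood for the fact that only
#'   observed OTUs enter the table (divide by `1 - P(absent everywhere)`).
#' @return object of class `gainloss_model`.
#' @export
gainloss_model <- function(gain, loss, alpha_gain = 1, alpha_loss = 1,
                           gamma = TRUE, n_cat = 4L,
                           root_prior = "stationary",
                           branch_gain = NULL, branch_loss = NULL,
                           ascertainment = FALSE) {
  stopifnot(gain > 0, loss > 0)
  structure(list(gain = gain, loss = loss, alpha_gain = alpha_gain,
                 alpha_loss = alpha_loss, gamma = gamma, n_cat = n_cat,
                 root_prior = root_prior, branch_gain = branch_gain,
                 branch_loss = branch_loss, ascertainment = ascertainment,
                 loglik = NA_real_),
            class = "gainloss_model")
}

#' @export
print.gainloss_model <- function(x, ...) {
  cat(sprintf("gain/loss model: g = %.4g, l = %.4g%s, logLik = %.4f\n",
              x$gain, x$loss,
              if (x$gamma) sprintf(", gamma shapes (%.3g, %.3g) x %d",
                                   x$alpha_gain, x$alpha_loss, x$n_cat) else "",
              x$loglik))
  invisible(x)
}

#' Fit the gain/loss model by maximum likelihood
#'
#' Bounded quasi-Newton (`L-BFGS-B`) search on log-parameters with multiple
#' seeded restarts.  The homogeneous model has 2 (or 4, with the gamma
#' mixture) free parameters.  The optional non-homogeneous variant adds one
#' (gain, loss) multiplier pair per branch, fit by coordinate ascent after
#' the homogeneous fit; with few hosts it is heavily over-parameterised and
#' is off by default.
#'
#' @param host_tree rooted host tree with branch lengths.
#' @param presence hosts x OTU binary matrix (>= 2 OTUs).
#' @param gamma fit the discrete-gamma mixture (default TRUE).
#' @param n_cat gamma categories (default 4).
#' @param nonhomogeneous fit per-branch rate multipliers (default FALSE).
#' @param n_restarts random restarts around the moment-based start (default 5).
#' @param seed integer seed controlling the restart jitter.
#' @param root_prior `"stationary"` or `c(p_absent, p_present)`.
#' @param ascertainment see [gainloss_model()].
#' @param sweeps coordinate-ascent sweeps for the non-homogeneous mode.
#' @param reltol convergence tolerance on the log-likelihood (default 1e-8).
#' @return fitted `gainloss_model` with `loglik` and `convergence` fields.
#' @export
fit_gainloss <- function(host_tree, presence, gamma = TRUE, n_cat = 4L,
                         nonhomogeneous = FALSE, n_restarts = 5L, seed = 1L,
                         root_prior = "stationary", ascertainment = FALSE,
                         sweeps = 1L, reltol = 1e-8) {
  stopifnot(ncol(presence) >= 2L)
  tt <- .gl_tree(host_tree)
  X <- .gl_leaf_partials(tt, presence)
  height <- max(node_depths(host_tree))
  occ <- mean(presence > 0)
  occ <- min(max(occ, 0.02), 0.98)

  nll <- function(par, bg = NULL, bl = NULL) {
    g <- exp(par[1L]); l <- exp(par[2L])
    model <- gainloss_model(g, l,
                            alpha_gain = if (gamma) exp(par[3L]) else 1,
                            alpha_loss = if (gamma) exp(par[4L]) else 1,
                            gamma = gamma, n_cat = n_cat,
                            root_prior = root_prior,
                            branch_gain = bg, branch_loss = bl,
                            ascertainment = ascertainment)
    ll <- tryCatch(.loglik_fast(tt, X, model), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  rate0 <- 1 / max(height, 1e-8)
  start0 <- c(log(rate0 * occ * 2), log(rate0 * (1 - occ) * 2))
  if (gamma) start0 <- c(start0, 0, 0)
  lower <- rep(log(1e-5 * rate0), 2L); upper <- rep(log(1e4 * rate0), 2L)
  if (gamma) { lower <- c(lower, log(0.05), log(0.05))
               upper <- c(upper, log(50), log(50)) }

  starts <- with_seed(seed, {
    jit <- replicate(max(n_restarts - 1L, 0L),
                     start0 + rnorm(length(start0), 0, 1), simplify = FALSE)
    c(list(start0), jit)
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(pmin(pmax(s, lower), upper), nll, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(factr = reltol / .Machine$double.eps, maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) stop("gain/loss optimisation failed from every start")
  par <- best$par
  model <- gainloss_model(exp(par[1L]), exp(par[2L]),
                          alpha_gain = if (gamma) exp(par[3L]) else 1,
                          alpha_loss = if (gamma) exp(par[4L]) else 1,
                          gamma = gamma, n_cat = n_cat,
                          root_prior = root_prior,
                          ascertainment = ascertainment)
  model$loglik <- -best$value
  model$convergence <- best$convergence
  model$boundary <- any(abs(par[1:2] - lower[1:2]) < 1e-6) ||
                    any(abs(par[1:2] - upper[1:2]) < 1e-6)
  if (model$boundary) {
    warning("a rate estimate lies on the search boundary (degenerate data?)")
  }

  if (nonhomogeneous) {
    n_edge <- length(tt$len)
    bg <- rep(1, n_edge); bl <- rep(1, n_edge)
    for (sw in seq_len(sweeps)) {
      for (e in seq_len(n_edge)) {
        obj <- function(q) {
          bg2 <- bg; bl2 <- bl
          bg2[e] <- exp(q[1L]); bl2[e] <- exp(q[2L])
          nll(par, bg2, bl2)
        }
        o <- optim(c(log(bg[e]), log(bl[e])), obj, method = "L-BFGS-B",
                   lower = c(-3, -3), upper = c(3, 3),
                   control = list(maxit = 30L))
        bg[e] <- exp(o$par[1L]); bl[e] <- exp(o$par[2L])
      }
    }
    model$branch_gain <- bg
    model$branch_loss <- bl
    model$loglik <- -nll(par, bg, bl)
  }
  model
}

## Fast total log-likelihood used inside the optimiser.
.loglik_fast <- function(tt, X, model) sum(.gl_mixture_loglik(tt, X, model))

#' Marginal ancestral presence posteriors
#'
#' Up-down (inside-outside) algorithm: for every internal node of the host
#' tree and every OTU, the posterior probability that the OTU was present,
#' with the gamma category pairs weighted by their per-OTU posterior weight.
#' The expected ancestral community size at a node is the sum of posteriors
#' across OTUs.
#'
#' @inheritParams pattern_loglik
#' @return object of class `ancestral_community`: list with `posterior`
#'   (internal nodes x OTUs, rownames = ape node ids), `expected_size`
#'   (named vector), `node_age` (depths on the host tree), `model`.
#' @export
ancestral_posteriors <- function(host_tree, presence, model) {
  presence <- .gl_orig_names(presence)
  tt <- .gl_tree(host_tree)
  X <- .gl_leaf_partials(tt, presence)
  n_otu <- nrow(X)
  cats <- .gl_categories(model)
  n_int <- tt$n_node - tt$n_tip

  ## pass 1: per-category log-likelihoods -> per-OTU category posterior weights
  LL <- matrix(NA_real_, nrow(cats), n_otu)
  ups <- vector("list", nrow(cats))
  for (r in seq_len(nrow(cats))) {
    ups[[r]] <- .gl_up(tt, X, model$gain * cats$mg[r], model$loss * cats$ml[r],
                       model$branch_gain, model$branch_loss,
                       model$root_prior, keep = TRUE)
    LL[r, ] <- ups[[r]]$loglik_otu
  }
  shift <- apply(LL, 2L, max)
  wcat <- cats$w * exp(sweep(LL, 2L, shift))       # n_cat^2 x n_otu
  wcat <- sweep(wcat, 2L, colSums(wcat), "/")

  ## pass 2: downward (outside) messages and weighted marginals
  post <- matrix(0, n_int, n_otu)
  for (r in seq_len(nrow(cats))) {
    up <- ups[[r]]
    A <- vector("list", tt$n_node)
    A[[tt$root]] <- matrix(up$prior, 2L, n_otu)
    for (i in rev(seq_along(tt$len))) {             # reverse postorder = preorder
      p <- tt$parent[i]; ch <- tt$child[i]
      B <- A[[p]] * up$L[[p]] / pmax(up$msgs[[i]], 1e-300)
      A[[ch]] <- crossprod(up$P[[i]], B)            # t(P) %*% B
    }
    for (v in (tt$n_tip + 1L):tt$n_node) {
      m <- A[[v]] * up$L[[v]]
      post[v - tt$n_tip, ] <- post[v - tt$n_tip, ] +
        wcat[r, ] * m[2L, ] / (m[1L, ] + m[2L, ])
    }
  }
  rownames(post) <- as.character((tt$n_tip + 1L):tt$n_node)
  colnames(post) <- colnames(presence)
  depths <- node_depths(host_tree)
  structure(list(posterior = post,
                 expected_size = rowSums(post),
                 node_age = depths[(tt$n_tip + 1L):tt$n_node],
                 model = model),
            class = "ancestral_community")
}

.gl_orig_names <- function(presence) {
  if (is.vector(presence)) matrix(presence, ncol = 1L,
                                  dimnames = list(names(presence), "otu1"))
  else presence
}

#' @export
print.ancestral_community <- function(x, ...) {
  cat("ancestral community:", nrow(x$posterior), "internal nodes x",
      ncol(x$posterior), "OTUs; root expected size",
      sprintf("%.2f", x$expected_size[1L]), "\n")
  invisible(x)
}

#' Simulate presence/absence evolution under the gain/loss model
#'
#' Root states drawn from the stationary distribution, then transitions
#' sampled along each branch; optional discrete-gamma rate variation assigns
#' each OTU a (gain, loss) category pair.
#'
#' @param host_tree rooted tree with branch lengths.
#' @param n_otus number of OTUs to simulate.
#' @param gain,loss rates.
#' @param alpha_gain,alpha_loss gamma shapes (`NULL` = homogeneous rates).
#' @param n_cat gamma categories.
#' @param seed integer seed.
#' @return hosts x OTU binary matrix; full node states (all tree nodes x
#'   OTUs) in attribute `"node_states"`.
#' @export
simulate_gainloss <- function(host_tree, n_otus, gain, loss,
                              alpha_gain = NULL, alpha_loss = NULL,
                              n_cat = 4L, seed = 1L) {
  stopifnot(n_otus >= 1L)
  tt <- .gl_tree(host_tree)
  with_seed(seed, {
    mg <- if (is.null(alpha_gain)) rep(1, n_otus)
          else sample(discrete_gamma(alpha_gain, n_cat), n_otus, replace = TRUE)
    ml <- if (is.null(alpha_loss)) rep(1, n_otus)
          else sample(discrete_gamma(alpha_loss, n_cat), n_otus, replace = TRUE)
    states <- matrix(0L, tt$n_node, n_otus)
    states[tt$root, ] <- rbinom(n_otus, 1L, (gain * mg) / (gain * mg + loss * ml))
    for (i in rev(seq_along(tt$len))) { # preorder
      p <- tt$parent[i]; ch <- tt$child[i]
      rate <- (gain * mg + loss * ml)
      e <- exp(-rate * tt$len[i])
      pi1 <- gain * mg / rate
      p1 <- ifelse(states[p, ] == 1L, 1 - (1 - pi1) * (1 - e), pi1 * (1 - e))
      states[ch, ] <- rbinom(n_otus, 1L, p1)
    }
    out <- states[seq_len(tt$n_tip), , drop = FALSE]
    rownames(out) <- tt$tips
    colnames(out) <- paste0("otu", seq_len(n_otus))
    rownames(states) <- as.character(seq_len(tt$n_node))
    attr(out, "node_states") <- states
    out
  })
}
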