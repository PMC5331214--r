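## k-state all-rates-different (ARD) CTMC for discrete trait evolution on the
## host tree; used for trait-based ancestral diet reconstruction.

.mk_generator <- function(rates, k) {
  Q <- matrix(0, k, k)
  Q[row(Q) != col(Q)] <- rates # filled column-major over off-diagonals
  diag(Q) <- -rowSums(Q)
  Q
}

.mk_up <- function(tt, x_idx, Q, prior, keep = FALSE) {
  k <- nrow(Q)
  L <- vector("list", tt$n_node)
  for (tip in seq_len(tt$n_tip)) {
    v <- numeric(k); v[x_idx[tip]] <- 1
    L[[tip]] <- v
  }
  logscale <- 0
  msgs <- if (keep) vector("list", length(tt$len)) else NULL
  Pm <- if (keep) vector("list", length(tt$len)) else NULL
  for (i in seq_along(tt$len)) {
    p <- tt$parent[i]; ch <- tt$child[i]
    P <- ape::matexpo(Q * tt$len[i])
    M <- drop(P %*% L[[ch]])
    if (keep) { msgs[[i]] <- M; Pm[[i]] <- P }
    L[[p]] <- if (is.null(L[[p]])) M else L[[p]] * M
    s <- max(L[[p]])
    if (s > 0 && s < 1e-12) { L[[p]] <- L[[p]] / s; logscale <- logscale + log(s) }
  }
  lik <- sum(prior * L[[tt$root]])
  out <- list(loglik = log(lik) + logscale, prior = prior)
  if (keep) { out$L <- L; out$msgs <- msgs; out$P <- Pm }
  out
}

#' Fit an all-rates-different Mk model to a discrete host trait
#'
#' ML estimation of the `k(k-1)` free transition rates of a continuous-time
#' Markov chain on the host phylogeny (Felsenstein pruning, bounded
#' quasi-Newton on log-rates with seeded restarts).  Default use: diet as a
#' three-state character (carnivorous / omnivorous / herbivorous).
#'
#' @param host_tree rooted tree with branch lengths.
#' @param states named character/factor vector, one state per leaf.
#' @param root_prior `"flat"` (default) or a length-`k` probability vector.
#' @param n_restarts random restarts (default 3).
#' @param seed integer seed for restart jitter.
#' @return object of class `mk_model`: `Q` (generator), `rates`, `states`
#'   (level names), `loglik`, `root_prior`.
#' @export
fit_mk_ard <- function(host_tree, states, root_prior = "flat",
                       n_restarts = 3L, seed = 1L) {
  tt <- .gl_tree(host_tree)
  f <- if (is.factor(states)) states[tt$tips] else factor(states[tt$tips])
  if (anyNA(f)) stop("missing state for leaf(s): ",
                     paste(tt$tips[is.na(f)], collapse = ", "))
  lev <- levels(f)
  k <- length(lev)
  if (k < 2L) stop("need at least two states")
  absent <- setdiff(lev, unique(as.character(f)))
  if (length(absent)) {
    warning("state(s) absent from the leaves: ",
            paste(absent, collapse = ", "), "; rates toward them are unidentifiable")
  }
  x_idx <- as.integer(f)
  prior <- if (identical(root_prior, "flat")) rep(1 / k, k) else root_prior
  height <- max(node_depths(host_tree))
  n_par <- k * (k - 1L)
  nll <- function(par) {
    Q <- .mk_generator(exp(par), k)
    ll <- tryCatch(.mk_up(tt, x_idx, Q, prior)$loglik, error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  start0 <- rep(log(1 / height), n_par)
  starts <- with_seed(seed, c(list(start0),
    replicate(max(n_restarts - 1L, 0L),
              start0 + rnorm(n_par, 0, 1), simplify = FALSE)))
  lower <- rep(log(1e-8 / height), n_par); upper <- rep(log(1e3 / height), n_par)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(optim(s, nll, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 500L)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Mk optimisation failed")
  rates <- exp(best$par)
  structure(list(Q = .mk_generator(rates, k), rates = rates, states = lev,
                 loglik = -best$value, root_prior = prior,
                 convergence = best$convergence),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat("ARD Mk model,", length(x$states), "states (",
      paste(x$states, collapse = ", "), "), logLik =",
      sprintf("%.4f", x$loglik), "\n")
  invisible(x)
}

#' Marginal ancestral state probabilities under an Mk model
#'
#' Up-down algorithm; each internal node receives a proper probability vector
#' over the model's states.
#'
#' @param host_tree rooted tree with branch lengths.
#' @param states named vector of leaf states (same coding as the fit).
#' @param model a [fit_mk_ard()] result.
#' @return matrix internal nodes x states (rownames = ape node ids), each row
#'   summing to 1.
#' @export
ancestral_states <- function(host_tree, states, model) {
  tt <- .gl_tree(host_tree)
  f <- factor(states[tt$tips], levels = model$states)
  x_idx <- as.integer(f)
  k <- length(model$states)
  up <- .mk_up(tt, x_idx, model$Q, model$root_prior, keep = TRUE)
  A <- vector("list", tt$n_node)
  A[[tt$root]] <- up$prior
  for (i in rev(seq_along(tt$len))) {
    p <- tt$parent[i]; ch <- tt$child[i]
    B <- A[[p]] * up$L[[p]] / pmax(up$msgs[[i]], 1e-300)
    A[[ch]] <- drop(crossprod(up$P[[i]], B))
  }
  idx <- (tt$n_tip + 1L):tt$n_node
  post <- t(vapply(idx, function(v) {
    m <- A[[v]] * up$L[[v]]
    m / sum(m)
  }, numeric(k)))
  dimnames(post) <- list(as.character(idx), model$states)
  post
}

#' Simulate a discrete trait under an Mk generator
#'
#' @param host_tree rooted tree with branch lengths.
#' @param Q generator matrix (rows sum to 0).
#' @param states state labels (default from `colnames(Q)` or `S1..Sk`).
#' @param root_prior probability vector for the root state (default flat).
#' @param seed integer seed.
#' @return named character vector of leaf states; all node states in
#'   attribute `"node_states"`.
#' @export
simulate_mk <- function(host_tree, Q, states = NULL, root_prior = NULL,
                        seed = 1L) {
  k <- nrow(Q)
  if (is.null(states)) states <- colnames(Q)
  if (is.null(states)) states <- paste0("S", seq_len(k))
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  tt <- .gl_tree(host_tree)
  with_seed(seed, {
    node_state <- integer(tt$n_node)
    node_state[tt$root] <- sample.int(k, 1L, prob = root_prior)
    for (i in rev(seq_along(tt$len))) {
      P <- ape::matexpo(Q * tt$len[i])
      node_state[tt$child[i]] <- sample.int(k, 1L,
                                            prob = P[node_state[tt$parent[i]], ])
    }
    out <- setNames(states[node_state[seq_len(tt$n_tip)]], tt$tips)
    attr(out, "node_states") <- states[node_state]
    out
  })
}
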