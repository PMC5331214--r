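## BDTT core: slice the bacterial tree, collapse the table, profile turnover.

#' Cut a phylogeny at a given depth into clade-OTUs
#'
#' A leaf belongs to the clade rooted at the unique node `v` on its root path
#' with `depth(v) <= t < depth(parent(v))` (depth = max distance to a
#' descendant leaf; the root's parent depth is +Inf).  `t = 0` returns the
#' leaf partition; `t >=` tree height returns a single clade.  Clades are
#' maximal tipward subtrees, hence monophyletic by construction.
#'
#' @param tree a `timetree` (see [read_newick()]) or `phylo`.
#' @param t slice depth, same units as the branch lengths, `>= 0`.
#' @return object of class `slice_clustering`: list with `depth`, `leaf_clade`
#'   (named character vector leaf -> clade id) and `clades` (clade id ->
#'   member leaves).  Clade ids are stable strings `"t<depth>_n<node-id>"`.
#' @export
slice_tree <- function(tree, t) {
  if (t < 0) stop("slice depth must be >= 0")
  depth <- attr(tree, "node_depth")
  if (is.null(depth)) depth <- node_depths(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  cw <- ape::reorder.phylo(tree, "cladewise")
  clade_of <- integer(n_tip + tree$Nnode) # 0 = not yet inside a clade
  if (depth[root] <= t) clade_of[root] <- root
  for (i in seq_len(nrow(cw$edge))) {
    p <- cw$edge[i, 1L]; ch <- cw$edge[i, 2L]
    clade_of[ch] <- if (clade_of[p] != 0L) clade_of[p]
                    else if (depth[ch] <= t) ch else 0L
  }
  leaf_clade_node <- clade_of[seq_len(n_tip)]
  ids <- paste0("t", format(t, trim = TRUE), "_n", leaf_clade_node)
  names(ids) <- tree$tip.label
  clades <- split(tree$tip.label, ids)
  structure(list(depth = t, leaf_clade = ids, clades = clades),
            class = "slice_clustering")
}

#' Collapse an abundance table into slice-clade OTUs
#'
#' Counts of member sequences are summed per clade; per-host totals are
#' conserved exactly.
#'
#' @param table hosts x sequences count matrix; columns must all be leaves of
#'   the sliced tree.
#' @param clustering a [slice_tree()] result.
#' @return hosts x clades matrix with attribute `"slice_depth"`.
#' @export
collapse_table <- function(table, clustering) {
  stopifnot(inherits(clustering, "slice_clustering"))
  orphan <- setdiff(colnames(table), names(clustering$leaf_clade))
  if (length(orphan)) {
    stop("table column(s) not found among tree leaves: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  grp <- clustering$leaf_clade[colnames(table)]
  out <- t(rowsum(t(table), group = grp))
  attr(out, "slice_depth") <- clustering$depth
  out
}

.check_presence_rows <- function(x, metric) {
  empty <- rownames(x)[rowSums(x) == 0]
  if (length(empty) > 1L) {
    stop(metric, " undefined between two empty communities: ",
         paste(empty, collapse = ", "))
  }
  empty
}

#' Sorensen dissimilarity between host communities
#'
#' Presence/absence turnover `d(i,j) = 1 - 2|Pi & Pj| / (|Pi| + |Pj|)`,
#' computed through [vegan::vegdist()] (binary Bray-Curtis).  A host with an
#' empty presence set is at distance 1 from every non-empty host and is
#' recorded in the `"empty_hosts"` attribute.
#'
#' @param table hosts x OTU count (or presence) matrix, >= 2 hosts.
#' @return labelled distance matrix in \[0, 1\].
#' @export
sorensen <- function(table) {
  stopifnot(nrow(table) >= 2L)
  empty <- .check_presence_rows(table, "Sorensen")
  d <- .betadist(table > 0, binary = TRUE, empty)
  if (length(empty)) attr(d, "empty_hosts") <- empty
  d
}

#' Bray-Curtis dissimilarity between host communities
#'
#' Abundance-weighted turnover
#' `d(i,j) = 1 - 2 sum_k min(x_ik, x_jk) / (sum_k x_ik + sum_k x_jk)`
#' via [vegan::vegdist()]; rarefy first if sampling depths are uneven.
#'
#' @inheritParams sorensen
#' @return labelled distance matrix in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  stopifnot(nrow(table) >= 2L)
  empty <- .check_presence_rows(table, "Bray-Curtis")
  d <- .betadist(table, binary = FALSE, empty)
  if (length(empty)) attr(d, "empty_hosts") <- empty
  d
}

.betadist <- function(x, binary, empty) {
  mode(x) <- "double"
  nonempty <- rowSums(x) > 0
  d <- matrix(1, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  sub <- as.matrix(vegan::vegdist(x[nonempty, , drop = FALSE],
                                  method = "bray", binary = binary))
  d[nonempty, nonempty] <- sub
  diag(d) <- 0
  as_distance_matrix(d)
}

#' Unweighted UniFrac distances
#'
#' Fraction of branch length unique to either host out of the branch length
#' spanned by their union; a branch is scored present for a host when any
#' descendant leaf of that branch is present.  The per-slice BDTT profile is
#' an exact phylogenetic decomposition of this metric on ultrametric trees
#' (see [unifrac_from_slices()]).
#'
#' @param tree bacterial `timetree`; table columns must be tree leaves.
#' @param table hosts x sequence count matrix.
#' @return labelled distance matrix in \[0, 1\].
#' @export
unweighted_unifrac <- function(tree, table) {
  stopifnot(nrow(table) >= 2L)
  empty <- .check_presence_rows(table, "UniFrac")
  orphan <- setdiff(colnames(table), tree$tip.label)
  if (length(orphan)) stop("table columns absent from tree: ",
                           paste(utils::head(orphan, 5L), collapse = ", "))
  E <- .edge_presence(tree, table)                 # hosts x edges, 0/1
  len <- ape::reorder.phylo(tree, "postorder")$edge.length
  W <- E * rep(len, each = nrow(E))
  both <- W %*% t(E)                               # shared spanned length
  li <- E %*% len
  tot <- outer(drop(li), drop(li), "+")
  uniq <- tot - 2 * both
  union <- tot - both
  d <- ifelse(union > 0, uniq / union, 0)
  d[rowSums(table) == 0, ] <- 1
  d[, rowSums(table) == 0] <- 1
  dimnames(d) <- list(rownames(table), rownames(table))
  diag(d) <- 0
  d <- as_distance_matrix(d)
  if (length(empty)) attr(d, "empty_hosts") <- empty
  d
}

## hosts x edges presence: edge (ordered postorder) present for a host iff a
## descendant leaf of its child node is present
.edge_presence <- function(tree, table) {
  n_tip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  pres_node <- matrix(FALSE, nrow(table), n_tip + tree$Nnode)
  idx <- match(tree$tip.label, colnames(table))
  has <- !is.na(idx)
  pres_node[, which(has)] <- table[, idx[has], drop = FALSE] > 0
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    pres_node[, p] <- pres_node[, p] | pres_node[, ch]
  }
  E <- pres_node[, po$edge[, 2L], drop = FALSE]
  storage.mode(E) <- "double"
  E
}

#' Default slice grid
#'
#' @param tree a `timetree`.
#' @param n number of evenly spaced depths from 0 to the tree height
#'   (default 40), or `breakpoints = TRUE` for all distinct node depths.
#' @param breakpoints return the sorted distinct node depths instead.
#' @return increasing numeric vector of depths.
#' @export
slice_depths <- function(tree, n = 40L, breakpoints = FALSE) {
  d <- attr(tree, "node_depth")
  if (is.null(d)) d <- node_depths(tree)
  if (breakpoints) sort(unique(d)) else seq(0, max(d), length.out = n)
}

#' Beta-diversity through time profile
#'
#' For each requested depth, cut the bacterial tree ([slice_tree()]), collapse
#' the table ([collapse_table()]) and compute the chosen turnover metric,
#' producing one host dissimilarity matrix per phylogenetic scale.
#'
#' @param tree bacterial `timetree`.
#' @param table hosts x sequence count matrix (columns = tree leaves).
#' @param depths strictly increasing depths within `[0, tree height]`;
#'   default [slice_depths()].
#' @param metric `"sorensen"` or `"bray_curtis"`.
#' @return object of class `bdtt_profile`: list with `depths`, `metric`,
#'   `matrices` (one distance matrix per depth) and `n_clades` per depth.
#' @export
bdtt_profile <- function(tree, table,
                         depths = slice_depths(tree),
                         metric = c("sorensen", "bray_curtis")) {
  metric <- match.arg(metric)
  if (length(depths) == 0L) stop("empty depth list")
  if (is.unsorted(depths, strictly = TRUE)) stop("depths must be strictly increasing")
  fn <- switch(metric, sorensen = sorensen, bray_curtis = bray_curtis)
  mats <- vector("list", length(depths))
  ncl <- integer(length(depths))
  for (i in seq_along(depths)) {
    cl <- slice_tree(tree, depths[i])
    ct <- collapse_table(table, cl)
    ncl[i] <- ncol(ct)
    mats[[i]] <- fn(ct)
  }
  structure(list(depths = depths, metric = metric, matrices = mats,
                 n_clades = ncl),
            class = "bdtt_profile")
}

#' @export
print.bdtt_profile <- function(x, ...) {
  cat("BDTT profile:", length(x$depths), "slices,", x$metric, "metric,",
      nrow(x$matrices[[1L]]), "hosts\n")
  invisible(x)
}

#' Reassemble unweighted UniFrac from per-interval slices
#'
#' Takes one slice per interval between consecutive distinct node depths
#' (at the interval midpoint), with weight equal to the interval width, and
#' aggregates the per-slice presence/absence mismatch counts:
#' `sum_t w_t U_t(i,j) / sum_t w_t S_t(i,j)`, where `U_t` is the number of
#' slice clades present in exactly one of the two hosts and `S_t` the number
#' present in at least one.  On an ultrametric tree this equals
#' [unweighted_unifrac()] exactly, because a clade cut in the interval
#' corresponds one-to-one to the branch crossing it and the interval widths
#' sum to the branch lengths.
#'
#' @inheritParams unweighted_unifrac
#' @return labelled distance matrix.
#' @export
unifrac_from_slices <- function(tree, table) {
  bp <- slice_depths(tree, breakpoints = TRUE)
  if (length(bp) < 2L) stop("degenerate tree: a single depth")
  mids <- (bp[-1L] + bp[-length(bp)]) / 2
  w <- diff(bp)
  n <- nrow(table)
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (k in seq_along(mids)) {
    cl <- slice_tree(tree, mids[k])
    P <- collapse_table(table, cl) > 0
    storage.mode(P) <- "double"
    shared <- P %*% t(P)
    sizes <- rowSums(P)
    tot <- outer(sizes, sizes, "+")
    num <- num + w[k] * (tot - 2 * shared)     # clades in exactly one host
    den <- den + w[k] * (tot - shared)         # clades in at least one host
  }
  d <- ifelse(den > 0, num / den, 0)
  dimnames(d) <- list(rownames(table), rownames(table))
  diag(d) <- 0
  as_distance_matrix(d)
}
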