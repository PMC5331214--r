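#' The nine dietary categories used throughout the package
#'
#' EltonTraits-style fuzzy diet attributes: each host is described by a
#' percentage for each of nine food items, summing to 100.
#'
#' @export
DIET_CATEGORIES <- c(
  "Invertebrate", "Vertebrate", "RottingCarcass", "Fish",
  "UnknownVertebrate", "Fruit", "Nectar", "Seed", "OtherPlant"
)

## ---- trees -----------------------------------------------------------------

#' Compute per-node depths (maximum path length to any descendant leaf)
#'
#' Depth is defined tipward: every leaf has depth 0 and an internal node's
#' depth is the longest path down to any of its descendant leaves.  This makes
#' tree slicing well defined on non-ultrametric trees (e.g. branch lengths in
#' expected substitutions per site).  On an ultrametric tree the root depth
#' equals the tree height.
#'
#' @param tree an object of class `phylo` with branch lengths.
#' @return numeric vector of length `Ntip + Nnode`, indexed by ape node id.
#' @export
node_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  n_tip <- length(tree$tip.label)
  depth <- numeric(n_tip + tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    ch <- po$edge[i, 2L]
    depth[p] <- max(depth[p], depth[ch] + po$edge.length[i])
  }
  depth
}

#' Read a rooted phylogeny with branch lengths
#'
#' Wraps [ape::read.tree()] and augments the tree with the fields the rest of
#' the package relies on: per-node depths (max distance to a descendant
#' leaf), an ultrametricity flag (all root-to-leaf path lengths equal within
#' `1e-6 * height`) and the branch-length unit.
#'
#' @param path path to a Newick file containing a single rooted tree.
#' @param lengths_unit `"myr"` (time) or `"subs"` (expected substitutions per
#'   site); metadata only, slicing works identically in either unit.
#' @param text optional Newick string, used instead of `path`.
#' @return a `phylo` object of class `c("timetree", "phylo")` with attributes
#'   `node_depth`, `ultrametric` and `lengths_unit`.
#' @export
read_newick <- function(path, lengths_unit = c("myr", "subs"), text = NULL) {
  lengths_unit <- match.arg(lengths_unit)
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (inherits(tree, "multiPhylo")) {
    stop("expected a single tree, found ", length(tree))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1L]
    stop("negative branch length on the edge above node ", tree$edge[bad, 2L])
  }
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; the root node ", length(tree$tip.label) + 1L,
         " is ambiguous (", sum(tree$edge[, 1L] == length(tree$tip.label) + 1L),
         " basal children)")
  }
  as_timetree(tree, lengths_unit)
}

#' Annotate a phylo object with depths and ultrametricity
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param lengths_unit branch-length unit label.
#' @return the annotated `timetree`.
#' @export
as_timetree <- function(tree, lengths_unit = "myr") {
  depth <- node_depths(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  height <- depth[root]
  ## root-to-leaf path lengths: height minus depth is not valid off the
  ## ultrametric case, so measure from the root directly
  root_dist <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]
  ultra <- height > 0 && diff(range(root_dist)) <= 1e-6 * height
  attr(tree, "node_depth") <- depth
  attr(tree, "ultrametric") <- ultra
  attr(tree, "lengths_unit") <- lengths_unit
  class(tree) <- unique(c("timetree", class(tree)))
  tree
}

#' Tree height (root depth)
#' @param tree a `timetree` or `phylo`.
#' @return maximum depth of any node.
#' @export
tree_height <- function(tree) {
  d <- attr(tree, "node_depth")
  if (is.null(d)) d <- node_depths(tree)
  max(d)
}

#' Is the tree ultrametric (within tolerance)?
#' @param tree a `timetree`.
#' @return logical flag set by [read_newick()]/[as_timetree()].
#' @export
is_ultrametric_tree <- function(tree) isTRUE(attr(tree, "ultrametric"))

## ---- abundance tables ------------------------------------------------------

#' Read a host x sequence abundance table from TSV
#'
#' Plain TSV: header row holds the sequence/OTU labels, first column the host
#' labels, cells non-negative integer counts.
#'
#' @param path TSV file path.
#' @return an integer matrix, hosts in rows.
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  validate_abundance(x)
}

#' Validate an abundance matrix
#'
#' @param x hosts x sequences numeric matrix with dimnames.
#' @return `x`, invisibly checked: unique labels, non-negative counts,
#'   positive row sums.
#' @export
validate_abundance <- function(x) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate host labels")
  if (anyDuplicated(colnames(x))) stop("duplicate sequence labels")
  if (any(x < 0)) stop("negative counts")
  if (any(rowSums(x) <= 0)) {
    warning("hosts with zero total count: ",
            paste(rownames(x)[rowSums(x) <= 0], collapse = ", "))
  }
  x
}

#' Write an abundance (or any labelled) matrix as TSV
#' @param x matrix with dimnames.
#' @param path output path.
#' @export
write_table_tsv <- function(x, path) {
  df <- data.frame(label = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy an abundance table to even depth
#'
#' Subsamples each host's counts without replacement down to `depth` reads,
#' as is standard before presence/absence modelling, so unequal sequencing
#' effort does not bias downstream reconstruction.  Hosts with fewer than
#' `depth` reads are dropped with a warning.
#'
#' @param table hosts x sequences count matrix.
#' @param depth target row sum (> 0).
#' @param seed integer seed; resampling is deterministic given the seed.
#' @return rarefied matrix; every retained row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(is.matrix(table))
  if (depth <= 0) stop("depth must be > 0")
  rs <- rowSums(table)
  keep <- rs >= depth
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " host(s) below depth ", depth, ": ",
            paste(rownames(table)[!keep], collapse = ", "))
  }
  x <- table[keep, , drop = FALSE]
  with_seed(seed, {
    for (i in seq_len(nrow(x))) {
      row <- x[i, ]
      if (sum(row) == depth) next
      pool <- rep.int(seq_along(row), row)
      take <- sample(pool, depth, replace = FALSE)
      x[i, ] <- tabulate(take, nbins = length(row))
    }
  })
  x
}

#' Drop a set of columns (bacterial lineages) from a table
#'
#' Used to re-profile correlations after removing, e.g., all diet-associated
#' lineages.  Hosts whose total count becomes zero are flagged via the
#' `"empty_hosts"` attribute.
#'
#' @param table hosts x sequences matrix.
#' @param labels column labels to remove (must all exist).
#' @return the table restricted to the complement column set.
#' @export
exclude_columns <- function(table, labels) {
  unknown <- setdiff(labels, colnames(table))
  if (length(unknown)) {
    stop("unknown column label(s): ", paste(unknown, collapse = ", "))
  }
  out <- table[, setdiff(colnames(table), labels), drop = FALSE]
  if (ncol(out) == 0L) stop("all columns excluded; table is empty")
  empty <- rownames(out)[rowSums(out) == 0]
  if (length(empty)) {
    warning("host(s) left with zero counts: ", paste(empty, collapse = ", "))
  }
  if (length(empty)) attr(out, "empty_hosts") <- empty
  out
}

## ---- distance matrices -----------------------------------------------------

#' Construct/validate a labelled distance matrix
#'
#' @param x square numeric matrix with symmetric values, zero diagonal and
#'   shared row/column labels.
#' @return the validated matrix.
#' @export
as_distance_matrix <- function(x) {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  if (is.null(rownames(x))) stop("distance matrix needs labels")
  if (!isTRUE(all.equal(rownames(x), colnames(x)))) stop("row/column labels differ")
  if (max(abs(x - t(x))) > 1e-8) stop("matrix is not symmetric")
  if (any(diag(x) != 0)) stop("diagonal must be exactly 0")
  if (any(x < 0)) stop("negative distances")
  x <- (x + t(x)) / 2
  diag(x) <- 0
  x
}

#' Read a distance matrix from TSV
#' @param path TSV with labels in header and first column.
#' @return validated distance matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as_distance_matrix(as.matrix(df))
}

#' Align two (or more) labelled matrices on their common labels
#'
#' Labels present in one object but not the other are dropped to the
#' intersection with a warning, never silently.
#'
#' @param ... labelled square matrices and/or tables (rows = hosts).
#' @return list of inputs restricted to the shared labels, in a common order.
#' @export
align_labels <- function(...) {
  objs <- list(...)
  labs <- lapply(objs, rownames)
  common <- Reduce(intersect, labs)
  if (length(common) == 0L) stop("no shared labels")
  dropped <- unique(unlist(lapply(labs, setdiff, y = common)))
  if (length(dropped)) {
    warning("dropping unmatched label(s): ", paste(dropped, collapse = ", "))
  }
  lapply(objs, function(o) {
    if (nrow(o) == ncol(o) && identical(rownames(o), colnames(o))) {
      o[common, common, drop = FALSE]
    } else {
      o[common, , drop = FALSE]
    }
  })
}

## ---- diet tables -----------------------------------------------------------

#' Read a host x dietary-category percentage table
#'
#' Nine fuzzy diet categories per host (see [DIET_CATEGORIES]); each row must
#' sum to 100 within 1e-6.
#'
#' @param path TSV path, first column host labels.
#' @return hosts x 9 numeric matrix.
#' @export
read_diet_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  validate_diet_table(as.matrix(df))
}

#' Validate a diet percentage table
#' @param x hosts x 9 matrix of percentages.
#' @return `x` after checks (columns named as [DIET_CATEGORIES], rows sum to
#'   100, values within \[0, 100\]).
#' @export
validate_diet_table <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) != length(DIET_CATEGORIES)) {
    stop("expected ", length(DIET_CATEGORIES), " dietary categories")
  }
  if (is.null(colnames(x))) colnames(x) <- DIET_CATEGORIES
  if (any(x < -1e-9 | x > 100 + 1e-9)) stop("percentages outside [0, 100]")
  bad <- abs(rowSums(x) - 100) > 1e-6
  if (any(bad)) {
    stop("diet rows not summing to 100: ",
         paste(rownames(x)[bad], collapse = ", "))
  }
  x
}

## ---- misc ------------------------------------------------------------------

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores (or clears) the caller's RNG state afterwards, so seeded package
#' internals never perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
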