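# Clade partitions on ultrametric trees, Moran's I correlograms, and the
# rank statistics used for group comparisons.
#
# Species are pooled into the largest possible clades whose MRCA is strictly
# younger than a divergence-time cutoff; Moran's I on (log) coverage with
# binary same-clade weights, row-normalised, then measures whether species
# within clades resemble each other more than expected under the
# randomisation null (E[I] = -1/(n-1)).

# node ages (distance to the leaves) for a rooted ultrametric tree
.node_ages <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object",
                                     call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths",
                                      call. = FALSE)
  depth <- ape::node.depth.edgelength(tree)
  total <- max(depth)
  ntip <- length(tree$tip.label)
  leaf_depth <- depth[seq_len(ntip)]
  if (any(abs(leaf_depth - total) > tol * total))
    stop("tree is not ultrametric within tolerance: leaf depths differ by ",
         format(max(abs(leaf_depth - total))), call. = FALSE)
  total - depth
}

#' Partition tree leaves into the largest clades younger than a cutoff
#'
#' Each clade is the leaf set of a maximal node whose age (MRCA age) is
#' strictly below `cutoff_mya`; a leaf whose parent is at or above the
#' cutoff forms a singleton clade.  The clades partition the leaf set.
#'
#' @param tree A rooted ultrametric `phylo` tree with branch lengths in
#'   millions of years.
#' @param cutoff_mya Positive age cutoff in Mya.
#' @param tol Relative ultrametricity tolerance on leaf depths.
#' @return An object of class `clade_partition`: list with `cutoff_mya`,
#'   `clade_of` (named integer vector over tip labels) and `n_clades`.
#' @examples
#' tr <- ape::read.tree(text = "((a:10,b:10):90,(c:10,d:10):90);")
#' clades_at_cutoff(tr, 50)
#' @export
clades_at_cutoff <- function(tree, cutoff_mya, tol = 1e-6) {
  if (!is.numeric(cutoff_mya) || length(cutoff_mya) != 1L || cutoff_mya <= 0)
    stop("cutoff_mya must be a single positive number", call. = FALSE)
  ages <- .node_ages(tree, tol)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  qualifies <- ages < cutoff_mya
  # climb from each leaf to its topmost qualifying ancestor
  clade_root <- integer(ntip)
  for (leaf in seq_len(ntip)) {
    node <- leaf
    while (node != root && qualifies[parent[node]]) node <- parent[node]
    clade_root[leaf] <- node
  }
  idx <- match(clade_root, unique(clade_root))
  structure(list(cutoff_mya = cutoff_mya,
                 clade_of = stats::setNames(idx, tree$tip.label),
                 n_clades = length(unique(idx))),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("clade_partition: cutoff %g Mya, %d species in %d clades\n",
              x$cutoff_mya, length(x$clade_of), x$n_clades))
  invisible(x)
}

# binary same-clade weight matrix, rows rescaled to sum 1 (zero rows kept)
.partition_weights <- function(cl) {
  w <- outer(cl, cl, `==`) * 1
  diag(w) <- 0
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  w / rs
}

#' Moran's I for a clade partition
#'
#' Moran's autocorrelation index of `values` under binary same-clade
#' weights (row-normalised), with the null expectation `-1/(n-1)`, the
#' randomisation (kurtosis-robust) standard deviation and a two-sided
#' Gaussian p-value.  The caller applies any log transformation first.
#'
#' @param values Named numeric vector covering every species in the
#'   partition.
#' @param part A [clades_at_cutoff()] partition.
#' @return An object of class `correlogram_point`: list with `cutoff_mya`,
#'   `I`, `expected_I`, `sd_I`, `p_value`, `n_species`, `n_clades`.
#' @examples
#' tr <- ape::read.tree(text = "((a:10,b:10):90,(c:10,d:10):90);")
#' morans_i(c(a = 1, b = 1, c = 2, d = 2), clades_at_cutoff(tr, 50))
#' @export
morans_i <- function(values, part) {
  stopifnot(inherits(part, "clade_partition"))
  sp <- names(part$clade_of)
  if (is.null(names(values)) || !all(sp %in% names(values)))
    stop("values must be named and cover every species in the partition",
         call. = FALSE)
  x <- values[sp]
  n <- length(x)
  if (n < 3L) stop("need at least 3 species", call. = FALSE)
  if (anyNA(x)) stop("values contain NA", call. = FALSE)
  if (all(tabulate(part$clade_of) <= 1L))
    stop("Moran's I undefined: all species are in singleton clades",
         call. = FALSE)
  d <- x - mean(x)
  ss <- sum(d^2)
  if (ss == 0) stop("Moran's I undefined: zero variance in values",
                    call. = FALSE)
  w <- .partition_weights(part$clade_of)
  s0 <- sum(w)
  obs <- (n / s0) * sum(w * outer(d, d)) / ss
  ei <- -1 / (n - 1)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(d^4) / ss^2
  var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
              b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - ei^2
  sd_i <- sqrt(var_i)
  p <- 2 * stats::pnorm(-abs((obs - ei) / sd_i))
  structure(list(cutoff_mya = part$cutoff_mya, I = obs, expected_I = ei,
                 sd_I = sd_i, p_value = p, n_species = n,
                 n_clades = part$n_clades),
            class = "correlogram_point")
}

#' @export
print.correlogram_point <- function(x, ...) {
  cat(sprintf(
    "Moran's I at %g Mya: I = %.4f (E = %.4f, sd = %.4f), p = %.3g, n = %d species in %d clades\n",
    x$cutoff_mya, x$I, x$expected_I, x$sd_I, x$p_value, x$n_species,
    x$n_clades))
  invisible(x)
}

#' Moran's I correlogram over divergence-time cutoffs
#'
#' Evaluates [morans_i()] at each cutoff; cutoffs where the index is
#' undefined (all singleton clades, or zero variance) are kept as `NA` rows
#' rather than dropped.
#'
#' @inheritParams clades_at_cutoff
#' @param values Named numeric vector of the (typically log-transformed)
#'   trait, one entry per tip label.
#' @param cutoffs Numeric vector of age cutoffs in Mya.  Default: 50, then
#'   multiples of 100 up to the root age.
#' @return A data frame with columns `cutoff`, `n_species`, `n_clades`,
#'   `I`, `expected`, `sd`, `p`.
#' @export
correlogram <- function(tree, values, cutoffs = NULL, tol = 1e-6) {
  ages <- .node_ages(tree, tol)
  if (is.null(cutoffs)) {
    root_age <- max(ages)
    cutoffs <- c(50, seq(100, 100 * ceiling(root_age / 100), by = 100))
    cutoffs <- cutoffs[cutoffs <= 100 * ceiling(root_age / 100)]
  }
  if (any(cutoffs <= 0) || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be positive and strictly increasing", call. = FALSE)
  rows <- lapply(cutoffs, function(ct) {
    part <- clades_at_cutoff(tree, ct, tol)
    pt <- tryCatch(morans_i(values, part), error = function(e) NULL)
    if (is.null(pt))
      data.frame(cutoff = ct, n_species = length(part$clade_of),
                 n_clades = part$n_clades, I = NA_real_, expected = NA_real_,
                 sd = NA_real_, p = NA_real_)
    else
      data.frame(cutoff = ct, n_species = pt$n_species,
                 n_clades = pt$n_clades, I = pt$I, expected = pt$expected_I,
                 sd = pt$sd_I, p = pt$p_value)
  })
  do.call(rbind, rows)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' The statistic is the Mann-Whitney count `W = #{(i,j): x_i > y_j} + 0.5 *
#' #{x_i == y_j}` (the convention printed by R's `wilcox.test`); the
#' two-sided p-value uses exact enumeration for small untied samples and the
#' normal approximation with continuity and tie correction otherwise.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List with `W`, `p`, `n1`, `n2`.
#' @examples
#' wilcoxon_rank_sum(c(5, 6), c(1, 2, 3))
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L || !is.numeric(x) || !is.numeric(y))
    stop("x and y must be non-empty numeric vectors", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples contain NA", call. = FALSE)
  n1 <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  list(W = w, p = p, n1 = n1, n2 = length(y))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided p-value from the t approximation on n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples contain NA", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("Spearman's rho undefined: zero rank variance", call. = FALSE)
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}
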