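as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance input must be a square matrix or dist object")
  if (is.null(rownames(d))) stop("distance matrix must carry taxon labels")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  d
}

aln_to_dnabin <- function(aln) {
  ape::as.DNAbin(tolower(as_alignment_matrix(aln)))
}

check_finite_dist <- function(d, what) {
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
    stop(what, " undefined (saturated or zero comparable sites) for pair(s): ",
         paste(utils::head(apply(bad, 1, function(i)
           paste(rownames(d)[i[1]], rownames(d)[i[2]], sep = "/")), 3),
           collapse = ", "))
  }
  d
}

#' Uncorrected p-distance matrix
#'
#' Proportion of differing sites among compared sites for every pair of
#' sequences. Under \code{deletion = "complete"} all columns containing a
#' gap or ambiguity in any sequence are discarded before comparison; under
#' \code{"pairwise"} each pair uses its own comparable columns.
#'
#' @param aln Alignment (>= 2 sequences).
#' @param deletion Gap handling: \code{"pairwise"} (default) or
#'   \code{"complete"}.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
p_distance <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- as_alignment_matrix(aln)
  if (nrow(m) < 2) stop("need at least two sequences")
  d <- as.matrix(ape::dist.dna(aln_to_dnabin(m), model = "raw",
                               pairwise.deletion = deletion == "pairwise"))
  check_finite_dist(d, "p-distance")
}

#' Kimura two-parameter distance matrix
#'
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q), with P and Q the transition and
#' transversion proportions of each sequence pair.
#'
#' @inheritParams p_distance
#' @param saturated What to do when the logarithm argument is non-positive
#'   (saturation): \code{"error"} (default) or \code{"flag"}, which keeps the
#'   non-finite entries and sets attribute \code{"saturated"} on the result.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
k2p_distance <- function(aln, deletion = c("pairwise", "complete"),
                         saturated = c("error", "flag")) {
  deletion <- match.arg(deletion)
  saturated <- match.arg(saturated)
  m <- as_alignment_matrix(aln)
  if (nrow(m) < 2) stop("need at least two sequences")
  d <- as.matrix(ape::dist.dna(aln_to_dnabin(m), model = "K80",
                               pairwise.deletion = deletion == "pairwise"))
  if (saturated == "flag") {
    attr(d, "saturated") <- any(!is.finite(d))
    return(d)
  }
  check_finite_dist(d, "K2P distance")
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration on the Q-criterion: at each step the pair (i, j)
#' minimizing Q(i, j) = (n - 2) d(i, j) - R_i - R_j is joined, with pendant
#' lengths l_i = d(i, j)/2 + (R_i - R_j)/(2(n - 2)) and reduced distances
#' d(u, k) = (d(i, k) + d(j, k) - d(i, j))/2. Ties on Q are broken by the
#' lexicographically smallest pair of cluster representatives (each
#' cluster's alphabetically first taxon). The result is unrooted with a
#' trifurcating root node; negative branch lengths are clamped to zero and
#' counted in attribute \code{"clamped_branches"}.
#'
#' On an additive (tree-realizable) distance matrix the generating topology
#' and branch lengths are recovered exactly.
#'
#' @param dist Symmetric distance matrix (or \code{dist}) over >= 3 taxa,
#'   with taxon labels.
#' @return An \code{ape} \code{phylo} tree.
#' @export
nj_tree <- function(dist) {
  d <- as_dist_matrix(dist)
  n0 <- nrow(d)
  if (n0 < 3) stop("neighbour joining needs at least three taxa")
  labels <- rownames(d)

  newick <- labels          # growing subtree strings
  rep_lab <- labels         # representative = alphabetically first leaf
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  fmt <- function(x) sprintf("%.12g", x)

  while (nrow(d) > 3) {
    n <- nrow(d)
    R <- rowSums(d)
    Q <- (n - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on sorted representative labels
    keys <- apply(cand, 1, function(ij) {
      rl <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(rl, collapse = "\r")
    })
    best <- cand[order(keys)[1], ]
    i <- best[1]; j <- best[2]
    li <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))))
    merged <- paste0("(", newick[i], ":", fmt(li), ",",
                     newick[j], ":", fmt(lj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], paste0("node", n))
    newick <- c(newick[keep], merged)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
    d <- d2
  }
  # final three-cluster star: closed-form pendant lengths
  la <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- paste0("(", newick[1], ":", fmt(la), ",",
                newick[2], ":", fmt(lb), ",",
                newick[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped_branches") <- clamped
  tree
}

#' Bootstrap supports on the neighbour-joining tree
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement \code{n_reps} times, rebuilds the tree for every replicate
#' and maps onto each internal node of the full-data tree the percentage of
#' replicate trees containing its bipartition. Replicate r draws its columns
#' under seed \code{seed + r}, making the run reproducible and independent
#' of replicate order.
#'
#' @param aln Alignment.
#' @param n_reps Number of bootstrap replicates (>= 1), e.g. 1000.
#' @param seed Integer base seed.
#' @param distance \code{"k2p"} (default) or \code{"p"}.
#' @param deletion Gap handling for the distance, as in
#'   \code{\link{p_distance}}.
#' @return The full-data NJ \code{phylo} tree with node supports (percent,
#'   numeric) in \code{node.label} and attribute \code{"n_reps"}.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              distance = c("k2p", "p"),
                              deletion = c("pairwise", "complete")) {
  distance <- match.arg(distance)
  deletion <- match.arg(deletion)
  stopifnot(n_reps >= 1)
  m <- as_alignment_matrix(aln)
  dist_fun <- if (distance == "k2p") {
    function(a) k2p_distance(a, deletion)
  } else {
    function(a) p_distance(a, deletion)
  }
  full <- nj_tree(dist_fun(m))
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    idx <- sample.int(ncol(m), replace = TRUE)
    boots[[r]] <- nj_tree(dist_fun(m[, idx, drop = FALSE]))
  }
  class(boots) <- "multiPhylo"
  cnt <- ape::prop.clades(full, boots, rooted = FALSE)
  root_node <- length(full$tip.label) + 1L
  node_ids <- root_node:(root_node + full$Nnode - 1L)
  cnt[is.na(cnt) & node_ids == root_node] <- n_reps  # trivial bipartition
  cnt[is.na(cnt)] <- 0L
  full$node.label <- 100 * cnt / n_reps
  attr(full, "n_reps") <- n_reps
  full
}

#' Root a tree on an outgroup
#'
#' Roots an unrooted tree at the midpoint of the outgroup's pendant edge, so
#' the outgroup and the ingroup hang from the root by two equal-length
#' edges summing to the original pendant length. Internal node (support)
#' labels stay attached to their bipartitions.
#'
#' @param tree A \code{phylo} tree.
#' @param outgroup Tip label to root on.
#' @return A rooted \code{phylo} tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  ro <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                  edgelabel = TRUE)
  root <- length(ro$tip.label) + 1L
  re <- which(ro$edge[, 1] == root)
  if (length(re) == 2 && !is.null(ro$edge.length)) {
    p <- sum(ro$edge.length[re])
    ro$edge.length[re] <- p / 2
  }
  ro
}

#' Monophyly test
#'
#' TRUE iff the given taxa are exactly the leaf set of some clade of the
#' rooted tree. A single taxon and the full taxon set are monophyletic by
#' convention.
#'
#' @param tree A rooted \code{phylo} tree.
#' @param taxa Character vector of tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (!ape::is.rooted(tree)) stop("monophyly is defined on a rooted tree")
  if (length(taxa) %in% c(1L, length(tree$tip.label))) return(TRUE)
  ape::is.monophyletic(tree, taxa)
}

#' Write a tree as Newick
#'
#' Branch lengths are rounded to \code{digits} decimals; node support labels
#' (if any) are written as internal node labels.
#'
#' @param tree A \code{phylo} tree.
#' @param path Optional output path; when NULL the Newick string is returned.
#' @param digits Decimals for branch lengths (default 6).
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, digits)
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dist Symmetric labelled distance matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_phylip_dist <- function(dist, path) {
  d <- as_dist_matrix(dist)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}
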