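# Desk-scale tree stage: p and Kimura two-parameter (K2P) pairwise distances
# with pairwise deletion of missing data, canonical neighbor-joining with
# deterministic tie-breaking, nonparametric bootstrap support, and
# Robinson-Foulds bipartition distance.

#' Kimura two-parameter distance from substitution proportions
#'
#' d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q)), with P the transition and Q
#' the transversion proportion over valid columns. Outside the domain
#' ((1-2P-Q) <= 0 or (1-2Q) <= 0) the distance is undefined and reported as
#' `Inf`.
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @return numeric distance (possibly `Inf`).
#' @export
k2p_from_pq <- function(P, Q) {
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  ifelse(a <= 0 | b <= 0, Inf, -0.5 * log(a * sqrt(b)))
}

.code_matrix <- function(m) {
  cm <- matrix(match(m, DNA_STATES), nrow = nrow(m),
               dimnames = dimnames(m))
  cm
}

#' Pairwise distance matrix from an alignment
#'
#' Missing data ('-', '?', N, ambiguity codes) are deleted pairwise: each
#' pair is compared over the columns where both taxa carry an unambiguous
#' state. `model = "p"` is the mismatch proportion; `model = "K2P"` applies
#' the Kimura two-parameter correction. Pairs with zero shared columns give
#' `NaN`; pairs outside the K2P domain give `Inf`.
#'
#' @param aln a `locus_alignment` or `supermatrix`.
#' @param model "p" or "K2P".
#' @return symmetric numeric matrix with taxon dimnames and zero diagonal.
#' @export
pairwise_distance <- function(aln, model = c("K2P", "p")) {
  model <- match.arg(model)
  m <- if (inherits(aln, "supermatrix")) aln$matrix else aln$matrix
  if (nrow(m) < 2) stop("need >= 2 taxa", call. = FALSE)
  cm <- .code_matrix(m)
  n <- nrow(cm)
  d <- matrix(0, n, n, dimnames = list(rownames(cm), rownames(cm)))
  purine <- cm == 1 | cm == 3  # A=1,C=2,G=3,T=4 -> purines are A,G
  for (i in seq_len(n - 1)) {
    xi <- cm[i, ]
    for (j in (i + 1):n) {
      xj <- cm[j, ]
      valid <- !is.na(xi) & !is.na(xj)
      nv <- sum(valid)
      if (nv == 0) {
        d[i, j] <- d[j, i] <- NaN
        next
      }
      diff <- valid & xi != xj
      if (model == "p") {
        d[i, j] <- d[j, i] <- sum(diff) / nv
      } else {
        ti <- sum(diff & (purine[i, ] == purine[j, ]))
        tv <- sum(diff) - ti
        d[i, j] <- d[j, i] <- k2p_from_pq(ti / nv, tv / nv)
      }
    }
  }
  d
}

# deterministic canonical NJ; returns an unrooted "phylo" object
.nj_core <- function(d) {
  taxa <- rownames(d)
  n <- length(taxa)
  labels <- taxa                     # current cluster labels (for ties)
  newick <- setNames(taxa, taxa)     # partial newick per cluster
  active <- taxa
  D <- d
  while (length(active) > 3) {
    nn <- length(active)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q - qmin < 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    keys <- apply(hits, 1, function(h) {
      p <- sort(c(active[h[1]], active[h[2]]))
      paste(p, collapse = "\r")
    })
    pick <- hits[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- dij - li
    # clamp negatives to zero, moving the deficit to the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_lab <- min(active[i], active[j])
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", newick[[active[i]]], li,
                       newick[[active[j]]], lj)
    duk <- (D[i, ] + D[j, ] - dij) / 2
    duk <- pmax(duk, 0)
    keep <- setdiff(seq_len(nn), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    new_active <- c(active[keep], new_lab)
    dimnames(D2) <- list(new_active, new_active)
    newick[[new_lab]] <- new_nwk
    active <- new_active
    D <- D2
  }
  if (length(active) == 3) {
    a <- D[1, 2]; b <- D[1, 3]; cc <- D[2, 3]
    l1 <- max((a + b - cc) / 2, 0)
    l2 <- max((a + cc - b) / 2, 0)
    l3 <- max((b + cc - a) / 2, 0)
    txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", newick[[active[1]]], l1,
                   newick[[active[2]]], l2, newick[[active[3]]], l3)
  } else {
    txt <- sprintf("(%s:%.10g,%s:%.10g);", newick[[active[1]]], D[1, 2] / 2,
                   newick[[active[2]]], D[1, 2] / 2)
  }
  ape::read.tree(text = txt)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ agglomeration on the Q-criterion with deterministic
#' lexicographic tie-breaking; negative branch lengths are clamped to zero
#' with the deficit moved to the sister branch. The tree is unrooted; when
#' `outgroup` is given it is rooted on that taxon.
#'
#' @param d symmetric distance matrix with taxon dimnames (see
#'   [pairwise_distance()]).
#' @param outgroup optional taxon id to root on.
#' @return a "phylo" tree.
#' @export
neighbor_joining <- function(d, outgroup = NULL) {
  if (nrow(d) < 3) stop("need >= 3 taxa for NJ", call. = FALSE)
  bad <- which(!is.finite(d) & row(d) < col(d), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    pairs <- apply(bad, 1, function(h)
      paste(rownames(d)[h[1]], colnames(d)[h[2]], sep = "/"))
    stop("non-finite distances for pair(s): ", paste(pairs, collapse = ", "),
         call. = FALSE)
  }
  tr <- .nj_core(d)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) {
      stop("outgroup not in tree: ", outgroup, call. = FALSE)
    }
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

# canonical bipartition keys of the internal edges of a tree; each split is
# represented by the side not containing the alphabetically first taxon
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  parts <- ape::prop.part(ape::unroot(tree))
  labs <- attr(parts, "labels")
  keys <- vapply(parts, function(p) {
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  n <- length(labs)
  keys <- unique(keys[nzchar(keys)])
  # keep non-trivial splits only (neither side a single tip)
  nt <- vapply(strsplit(keys, "|", fixed = TRUE), length, integer(1))
  keys[nt >= 2 & nt <= n - 2]
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' trees; both trees must share an identical leaf set.
#'
#' @param t1,t2 "phylo" trees.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Nonparametric bootstrap support on a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal edge of the original tree with the
#' percentage of replicates containing that bipartition. Reproducible for a
#' fixed seed.
#'
#' @param sm a `supermatrix` or `locus_alignment`.
#' @param model distance model, see [pairwise_distance()].
#' @param n_reps number of replicates (>= 1).
#' @param seed integer seed.
#' @param outgroup optional taxon to root the reported tree on.
#' @return list with `tree` (the original NJ tree, node labels = integer
#'   percent support) and `support` (named vector, split key -> percent).
#' @export
bootstrap_support <- function(sm, model = "K2P", n_reps = 100, seed = 1,
                              outgroup = NULL) {
  stopifnot(n_reps >= 1)
  m <- if (inherits(sm, "supermatrix")) sm$matrix else sm$matrix
  aln <- locus_alignment(m, locus_name = "boot")
  d0 <- pairwise_distance(aln, model = model)
  tr0 <- neighbor_joining(d0)
  keys0 <- tree_splits(tr0)
  counts <- setNames(numeric(length(keys0)), keys0)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(ncol(m), replace = TRUE)
    alnb <- locus_alignment(m[, idx, drop = FALSE], locus_name = "rep")
    db <- pairwise_distance(alnb, model = model)
    if (any(!is.finite(db))) next  # saturated replicate contributes nothing
    kb <- tree_splits(neighbor_joining(db))
    hit <- keys0 %in% kb
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  tr <- tr0
  if (!is.null(outgroup)) tr <- neighbor_joining(d0, outgroup = outgroup)
  tr <- .annotate_support(tr, support)
  list(tree = tr, support = support)
}

# write integer support percentages onto internal-node labels
.annotate_support <- function(tree, support) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  nlab <- rep("", tree$Nnode)
  for (node in seq_len(tree$Nnode) + length(tree$tip.label)) {
    side <- ape::extract.clade(tree, node)$tip.label
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      nlab[node - length(tree$tip.label)] <-
        as.character(round(support[[key]]))
    }
  }
  tree$node.label <- nlab
  tree
}

#' Bootstrap support for one named clade
#'
#' Convenience accessor: the support (percent) attached to the bipartition
#' separating `ingroup` from the rest, or `NA` if that split is not an edge
#' of the tree.
#'
#' @param boot result of [bootstrap_support()].
#' @param ingroup character vector of taxon ids.
#' @return numeric percent or `NA`.
#' @export
clade_support <- function(boot, ingroup) {
  tree <- boot$tree
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  side <- intersect(tree$tip.label, ingroup)
  if (anchor %in% side) side <- setdiff(tree$tip.label, side)
  key <- paste(sort(side), collapse = "|")
  if (key %in% names(boot$support)) unname(boot$support[[key]]) else NA_real_
}
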