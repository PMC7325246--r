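# Validate a distance matrix: square, symmetric, nonnegative, zero diagonal,
# unique labels.
.check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (is.null(rownames(dm)))
    stop("distance matrix must carry labels as dimnames")
  if (anyDuplicated(rownames(dm))) stop("duplicate labels")
  if (!isTRUE(all.equal(dm, t(dm), check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("distances must be nonnegative")
  if (any(abs(diag(dm)) > 1e-12)) stop("diagonal must be zero")
  invisible(dm)
}

.fmt_bl <- function(x) sprintf("%.15g", max(x, 0))

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining: at each step the pair minimizing the
#' Q-criterion `(n-2) d(i,j) - r_i - r_j` is joined, with the standard
#' branch-length and distance-reduction formulas. NJ reconstructs the exact
#' topology and branch lengths when the input matrix is additive. Negative
#' branch lengths are clamped to zero and the total deficit recorded in the
#' `clamped_deficit` attribute. Ties in the Q-matrix are broken by
#' lexicographic label order, so the output is reproducible regardless of
#' input row order.
#'
#' @param dm symmetric nonnegative matrix with zero diagonal and unique
#'   dimnames; at least 3 taxa.
#' @return An unrooted `ape::phylo` tree (trifurcating basal node) with
#'   branch lengths.
#' @export
nj_tree <- function(dm) {
  .check_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(dm)
  D <- dm
  # Newick fragment per active node.
  nwk <- stats::setNames(as.list(labels), labels)
  active <- labels
  deficit <- 0
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pairs <- cbind(active[cand[, 1L]], active[cand[, 2L]])
    key <- apply(pairs, 1L, function(p) paste(sort(p), collapse = "\r"))
    pick <- order(key)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { deficit <- deficit - li; li <- 0 }
    if (lj < 0) { deficit <- deficit - lj; lj <- 0 }
    u <- paste0("(", nwk[[active[i]]], ":", .fmt_bl(li), ",",
                nwk[[active[j]]], ":", .fmt_bl(lj), ")")
    duk <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    newD <- matrix(0, m - 1L, m - 1L)
    newD[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    newD[m - 1L, seq_along(keep)] <- newD[seq_along(keep), m - 1L] <-
      pmax(duk[keep], 0)
    newlab <- paste0("", active[i])  # internal token, sorts stably
    nwk[[newlab]] <- u
    active <- c(active[keep], newlab)
    dimnames(newD) <- list(active, active)
    D <- newD
  }
  # Final three nodes: closed-form star lengths.
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  for (v in c("la", "lb", "lc")) {
    x <- get(v)
    if (x < 0) { deficit <- deficit - x; assign(v, 0) }
  }
  txt <- paste0("(", nwk[[a]], ":", .fmt_bl(la), ",",
                nwk[[b]], ":", .fmt_bl(lb), ",",
                nwk[[c3]], ":", .fmt_bl(lc), ");")
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped_deficit") <- deficit
  tree
}

# Canonical bipartition keys for every internal edge of an unrooted tree:
# the side of the split NOT containing the alphabetically first tip, as a
# sorted, collapsed label string. Returns keys named by the child node id.
.bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1L]
  internal_children <- tree$edge[tree$edge[, 2L] > nt, 2L]
  keys <- character(length(internal_children))
  for (k in seq_along(internal_children)) {
    node <- internal_children[k]
    clade <- ape::extract.clade(tree, node)$tip.label
    side <- if (anchor %in% clade)
      setdiff(tree$tip.label, clade) else clade
    keys[k] <- paste(sort(side), collapse = "\r")
  }
  stats::setNames(keys, internal_children)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Felsenstein column bootstrap: alignment columns are resampled with
#' replacement `n_replicates` times; a p-distance matrix and NJ tree are
#' rebuilt per replicate; each internal edge of the tree from the original
#' alignment is annotated with the percentage of replicate trees containing
#' the same bipartition. Fully deterministic for a fixed seed.
#'
#' @param msa a [multiple_alignment] with at least 4 rows.
#' @param n_replicates number of bootstrap replicates (field default 100).
#' @param seed integer RNG seed.
#' @param correction passed to [msa_distances()].
#' @return The NJ tree of the original alignment (`ape::phylo`) with integer
#'   supports in `node.label` (basal node empty) and a `supports` attribute
#'   keyed by internal node id.
#' @export
bootstrap_support <- function(msa, n_replicates = 100, seed = 1,
                              correction = FALSE) {
  stopifnot(inherits(msa, "multiple_alignment"))
  if (length(msa$row_ids) < 4L)
    stop("bootstrap support needs at least 4 sequences ",
         "(fewer have no internal edges)")
  main <- nj_tree(msa_distances(msa, correction))
  keys <- .bipartitions(main)
  hits <- stats::setNames(numeric(length(keys)), keys)
  m <- msa_matrix(msa)
  # canonicalize column order before resampling: p-distances ignore column
  # order, so this makes the seeded realization (not just its distribution)
  # invariant to how the input alignment's columns are arranged
  m <- m[, order(apply(m, 2L, paste, collapse = "")), drop = FALSE]
  withr::with_seed(seed, {
    for (rep in seq_len(n_replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      bmat <- m[, cols, drop = FALSE]
      brows <- apply(bmat, 1L, paste, collapse = "")
      bmsa <- multiple_alignment(msa$row_ids, brows)
      btree <- nj_tree(msa_distances(bmsa, correction))
      bkeys <- .bipartitions(btree)
      seen <- keys %in% bkeys
      hits[seen] <- hits[seen] + 1
    }
  })
  supports <- as.integer(round(100 * hits / n_replicates))
  names(supports) <- names(keys)
  nt <- length(main$tip.label)
  nl <- character(main$Nnode)
  nl[as.integer(names(keys)) - nt] <- as.character(supports)
  main$node.label <- nl
  attr(main, "supports") <- supports
  main
}

#' Select representative sequences from tree branches
#'
#' Partitions the leaves into `n_groups` groups by cutting the tree's longest
#' edges (internal edges first, then terminal edges if more cuts are needed)
#' and returns each group's medoid — the leaf minimizing the mean distance to
#' the other group members under `dm`. Ties are broken by label order. This
#' is the "representatives from different branches" step of the analysis.
#'
#' @param tree an `ape::phylo` tree.
#' @param dm distance matrix over (at least) the tree's tips.
#' @param n_groups number of representatives, `1 <= n_groups <= Ntip`.
#' @return Character vector of `n_groups` leaf labels, sorted.
#' @export
select_representatives <- function(tree, dm, n_groups = 8) {
  tips <- tree$tip.label
  nt <- length(tips)
  if (n_groups < 1 || n_groups > nt)
    stop("n_groups must lie in [1, number of leaves]")
  .check_distance_matrix(dm)
  if (!all(tips %in% rownames(dm)))
    stop("distance matrix missing tree tips")
  if (n_groups == nt) return(sort(tips))
  edges <- tree$edge
  len <- tree$edge.length
  internal <- edges[, 2L] > nt
  # deterministic cut order: internal before terminal, longest first,
  # ties by child node id
  ord <- order(!internal, -len, edges[, 2L])
  cut <- ord[seq_len(n_groups - 1L)]
  # union-find over tree nodes with remaining edges
  nnode <- nt + tree$Nnode
  parent <- seq_len(nnode)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in setdiff(seq_len(nrow(edges)), cut)) {
    ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_len(nt), find, integer(1L))
  groups <- split(tips, comp)
  reps <- vapply(groups, function(g) {
    if (length(g) == 1L) return(g)
    sub <- dm[g, g, drop = FALSE]
    meand <- rowSums(sub) / (length(g) - 1L)
    g[order(meand, g)][1L]
  }, character(1L))
  sort(unname(reps))
}

#' Write a tree in Newick format
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a square distance matrix as PHYLIP-style TSV
#' @param dm labelled distance matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  .check_distance_matrix(dm)
  df <- data.frame(label = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
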