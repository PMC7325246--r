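#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman–Wunsch/Gotoh global alignment of two protein sequences under a
#' [scoring_scheme]. Tie-breaking is deterministic: on equal score the
#' traceback prefers a match/mismatch column over a gap in `a`, and a gap in
#' `a` over a gap in `b`.
#'
#' @param a,b non-empty amino-acid sequences (strings over the 20 standard
#'   residues plus X).
#' @param scheme a [scoring_scheme].
#' @return A `pairwise_alignment`: list with gapped strings `aligned_a`,
#'   `aligned_b` and the optimal `score`.
#' @examples
#' al <- global_align("AAB", "AB", scoring_scheme(c(1, -1), 1, 1))
#' al$score  # 1
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  ca <- seq_chars(toupper(a))
  cb <- seq_chars(toupper(b))
  bad <- setdiff(unique(c(ca, cb)), AA_EXTENDED)
  if (length(bad)) stop("illegal residues: ", paste(bad, collapse = ", "))
  # DP runs on reversed sequences so that, on score ties, matches land as
  # early as possible in the final alignment (gaps pushed rightward) --
  # match/mismatch preferred over a gap in `a` over a gap in `b`.
  profA <- residue_profile(matrix(rev(ca), nrow = 1L))
  profB <- residue_profile(matrix(rev(cb), nrow = 1L))
  res <- profile_align_cpp(profA, profB, scheme$substitution,
                           scheme$gap_open, scheme$gap_extend, 1L, 1L)
  ops <- rev(seq_chars(res$ops))
  ga <- gb <- character(length(ops))
  i <- j <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op == "M") {
      i <- i + 1L; j <- j + 1L
      ga[k] <- ca[i]; gb[k] <- cb[j]
    } else if (op == "A") {       # gap in a, consume b
      j <- j + 1L
      ga[k] <- "-"; gb[k] <- cb[j]
    } else {                      # gap in b, consume a
      i <- i + 1L
      ga[k] <- ca[i]; gb[k] <- "-"
    }
  }
  structure(list(aligned_a = paste(ga, collapse = ""),
                 aligned_b = paste(gb, collapse = ""),
                 score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score =", x$score, "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

# Column window of an aligned pair excluding terminal-gap columns: columns
# from the last leading gap of either row to the first trailing gap.
.core_columns <- function(ra, rb) {
  nga <- which(ra != "-"); ngb <- which(rb != "-")
  lo <- max(nga[1L], ngb[1L])
  hi <- min(nga[length(nga)], ngb[length(ngb)])
  if (lo > hi) integer(0) else lo:hi
}

# Identity fraction of a pairwise global alignment: matching columns over
# columns excluding terminal gaps (internal gap columns count as mismatches).
pairwise_identity <- function(a, b, scheme = scoring_scheme()) {
  al <- global_align(a, b, scheme)
  ra <- seq_chars(al$aligned_a); rb <- seq_chars(al$aligned_b)
  core <- .core_columns(ra, rb)
  if (!length(core)) return(0)
  sum(ra[core] == rb[core] & ra[core] != "-") / length(core)
}

#' Pairwise p-distance
#'
#' Fraction of mismatched columns among the columns of the optimal global
#' alignment that lie outside terminal-gap runs (internal gap columns count
#' as mismatches). With `correction = TRUE` the Poisson multiple-hit
#' correction `-ln(1 - p)` is applied; `p >= 1` is flagged as a maximal
#' distance (`Inf`).
#'
#' @inheritParams global_align
#' @param correction apply the Poisson correction.
#' @return A distance in `[0, 1]` (or `[0, Inf]` when corrected).
#' @export
p_distance <- function(a, b, scheme = scoring_scheme(),
                       correction = FALSE) {
  al <- global_align(a, b, scheme)
  ra <- seq_chars(al$aligned_a); rb <- seq_chars(al$aligned_b)
  core <- .core_columns(ra, rb)
  p <- if (!length(core)) 1 else mean(ra[core] != rb[core])
  if (!correction) return(p)
  if (p >= 1) {
    warning("p-distance >= 1; Poisson correction is undefined, ",
            "returning Inf (maximal distance)")
    return(Inf)
  }
  -log(1 - p)
}

#' Multiple alignment container
#'
#' Equal-length gapped rows over a sequence family. Ungapping any row must
#' reproduce its source sequence exactly.
#'
#' @param row_ids character vector of unique row ids.
#' @param rows character vector of gapped sequences, all the same length.
#' @return A `multiple_alignment` object.
#' @export
multiple_alignment <- function(row_ids, rows) {
  row_ids <- as.character(row_ids); rows <- as.character(rows)
  if (length(row_ids) != length(rows)) stop("ids and rows differ in length")
  if (anyDuplicated(row_ids)) stop("duplicate row ids")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows differ in length")
  structure(list(row_ids = row_ids, rows = stats::setNames(rows, row_ids),
                 n_columns = w),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d rows x %d columns\n",
              length(x$row_ids), x$n_columns))
  invisible(x)
}

# Character matrix view (rows x columns) of a multiple_alignment.
msa_matrix <- function(msa) {
  do.call(rbind, lapply(msa$rows, seq_chars))
}

#' Remove gaps from alignment rows
#' @param msa a [multiple_alignment].
#' @return Named character vector of ungapped sequences.
#' @export
ungap <- function(msa) {
  gsub("-", "", msa$rows, fixed = TRUE)
}

# Merge two sub-alignments (character matrices) along a profile-alignment op
# string ('M' both advance, 'A' gap column inserted into A, 'B' into B).
.merge_alignments <- function(matA, matB, ops) {
  ops <- seq_chars(ops)
  L <- length(ops)
  out <- matrix("-", nrow(matA) + nrow(matB), L)
  i <- j <- 0L
  for (k in seq_len(L)) {
    op <- ops[k]
    if (op != "A") { i <- i + 1L; out[seq_len(nrow(matA)), k] <- matA[, i] }
    if (op != "B") { j <- j + 1L
      out[nrow(matA) + seq_len(nrow(matB)), k] <- matB[, j] }
  }
  out
}

.align_profiles <- function(matA, matB, scheme) {
  revA <- matA[, rev(seq_len(ncol(matA))), drop = FALSE]
  revB <- matB[, rev(seq_len(ncol(matB))), drop = FALSE]
  res <- profile_align_cpp(residue_profile(revA), residue_profile(revB),
                           scheme$substitution, scheme$gap_open,
                           scheme$gap_extend, nrow(matA), nrow(matB))
  ops <- paste(rev(seq_chars(res$ops)), collapse = "")
  .merge_alignments(matA, matB, ops)
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by neighbor joining on pairwise p-distances, then
#' merges sub-alignments up the guide tree by profile–profile affine-gap
#' alignment with sum-of-pairs column scoring. Exact optimality of the joint
#' alignment is not claimed; the guaranteed invariant is that ungapping any
#' row reproduces its input sequence.
#'
#' @param family a [seq_family] with at least one record.
#' @param scheme a [scoring_scheme].
#' @return A [multiple_alignment] with rows in input-family order.
#' @export
progressive_msa <- function(family, scheme = scoring_scheme()) {
  stopifnot(inherits(family, "seq_family"))
  n <- nrow(family)
  if (n == 0L) stop("empty family")
  if (n == 1L)
    return(multiple_alignment(family$id, family$sequence))
  seqs <- stats::setNames(family$sequence, family$id)
  mats <- lapply(seqs, function(s) matrix(seq_chars(s), nrow = 1L))
  if (n == 2L) {
    merged <- .align_profiles(mats[[1L]], mats[[2L]], scheme)
    rownames(merged) <- family$id
  } else {
    dm <- matrix(0, n, n, dimnames = list(family$id, family$id))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      dm[i, j] <- dm[j, i] <- p_distance(seqs[[i]], seqs[[j]], scheme)
    guide <- nj_tree(dm)
    merged <- .progressive_merge(guide, mats, scheme)
  }
  rows <- apply(merged, 1L, paste, collapse = "")
  multiple_alignment(family$id, rows[family$id])
}

# Post-order merge over an ape phylo guide tree (root may be multifurcating).
.progressive_merge <- function(tree, mats, scheme) {
  tips <- tree$tip.label
  nt <- length(tips)
  root <- nt + 1L
  merge_clade <- function(node) {
    if (node <= nt) return(mats[[tips[node]]])
    children <- tree$edge[tree$edge[, 1L] == node, 2L]
    acc <- merge_clade(children[1L])
    for (ch in children[-1L])
      acc <- .align_profiles(acc, merge_clade(ch), scheme)
    acc
  }
  out <- merge_clade(root)
  # recover row ids: rows appear in the post-order tip sequence
  order_tips <- function(node) {
    if (node <= nt) return(tips[node])
    children <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(children, order_tips))
  }
  rownames(out) <- order_tips(root)
  out
}

#' Pairwise p-distance matrix from a multiple alignment
#'
#' For each pair of rows, distance = mismatches / columns where both rows are
#' ungapped (pairwise deletion). A pair with no shared ungapped column gets
#' the maximal distance 1.
#'
#' @param msa a [multiple_alignment].
#' @param correction apply the Poisson correction `-ln(1 - p)` (capped at the
#'   value for p of (L-1)/L to stay finite).
#' @return Symmetric numeric matrix with zero diagonal, labelled by row ids.
#' @export
msa_distances <- function(msa, correction = FALSE) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  dm <- matrix(0, n, n, dimnames = list(msa$row_ids, msa$row_ids))
  gap <- m == "-"
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      p <- if (!any(ok)) 1 else mean(m[i, ok] != m[j, ok])
      if (correction) {
        pmax_ <- 1 - 1 / ncol(m)
        p <- -log(1 - min(p, pmax_))
      }
      dm[i, j] <- dm[j, i] <- p
    }
  }
  dm
}

#' Write a gapped alignment as FASTA
#' @param msa a [multiple_alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(msa, path) {
  writeLines(as.vector(rbind(paste0(">", msa$row_ids), msa$rows)), path)
  invisible(path)
}
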