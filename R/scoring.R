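#' @useDynLib degronscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed residue alphabet used throughout: 20 standard amino acids plus X
# (unknown). Profiles and substitution tables are indexed in this order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_EXTENDED <- c(AA_ALPHABET, "X")

# BLOSUM62 in NCBI row order, reshaped to AA_ALPHABET order below.
.blosum62_ncbi_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.blosum62_values <- c(
   4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
  -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
  -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
  -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
   0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
  -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
  -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
   0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
  -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
  -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
  -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
  -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
  -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
  -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
   1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
   0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
  -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
   0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4)

.build_blosum62 <- function() {
  m <- matrix(.blosum62_values, 20, 20, byrow = TRUE,
              dimnames = list(.blosum62_ncbi_order, .blosum62_ncbi_order))
  m <- m[AA_ALPHABET, AA_ALPHABET]
  # X scored -1 against everything, including itself.
  full <- matrix(-1L, 21, 21, dimnames = list(AA_EXTENDED, AA_EXTENDED))
  full[AA_ALPHABET, AA_ALPHABET] <- m
  full
}

BLOSUM62_X <- .build_blosum62()

#' Alignment scoring scheme
#'
#' Bundles a symmetric substitution table over the 20 standard residues (plus
#' X) with nonnegative affine gap costs. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. The default substitution table is
#' BLOSUM62 with X scored at -1 against every residue.
#'
#' @param substitution 21x21 symmetric numeric matrix with dimnames over the
#'   residue alphabet (20 standard amino acids plus X), or the shortcut pair
#'   `c(match, mismatch)` to build a uniform table.
#' @param gap_open nonnegative cost of opening a gap.
#' @param gap_extend nonnegative cost of each gap extension; must satisfy
#'   `gap_open >= gap_extend`.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()                       # BLOSUM62 defaults
#' scoring_scheme(c(1, -1), 1, 1)        # unit match/mismatch scores
#' @export
scoring_scheme <- function(substitution = BLOSUM62_X, gap_open = 10,
                           gap_extend = 1) {
  if (is.numeric(substitution) && length(substitution) == 2L) {
    m <- matrix(substitution[2L], 21, 21,
                dimnames = list(AA_EXTENDED, AA_EXTENDED))
    diag(m) <- substitution[1L]
    substitution <- m
  }
  if (!is.matrix(substitution) ||
      !identical(dim(substitution), c(21L, 21L)))
    stop("substitution must be a 21x21 matrix over the residue alphabet")
  substitution <- substitution[AA_EXTENDED, AA_EXTENDED]
  if (!isTRUE(all.equal(substitution, t(substitution))))
    stop("substitution table must be symmetric")
  if (!is.numeric(gap_open) || !is.numeric(gap_extend) ||
      gap_open < gap_extend || gap_extend < 0)
    stop("gap costs must satisfy gap_open >= gap_extend >= 0")
  structure(list(substitution = substitution,
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> gap_open =", x$gap_open,
      "gap_extend =", x$gap_extend, "\n")
  invisible(x)
}

# Split a sequence string into a character vector of residues.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# 21 x L residue-count profile from a character matrix of gapped rows.
residue_profile <- function(charmat) {
  L <- ncol(charmat)
  prof <- matrix(0L, 21L, L, dimnames = list(AA_EXTENDED, NULL))
  for (j in seq_len(L)) {
    tab <- table(factor(charmat[, j], levels = AA_EXTENDED))
    prof[, j] <- as.integer(tab)
  }
  prof
}
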