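# The bundled reference degron catalogue lives in
# inst/extdata/reference_degrons.tsv; see reference_degrons().

#' Extract the C-terminal k-mer of a sequence
#'
#' Returns the final `k` residues in N-to-C order. Sequences shorter than `k`
#' or carrying an X inside the terminal window are not usable for frequency
#' profiling; they yield `NA` with an `exclusion_reason` attribute rather
#' than an error, so callers can keep an exclusion report.
#'
#' @param sequence an amino-acid string (or a single-row subset of a
#'   [seq_family]).
#' @param k window length (the field convention for this degron is the last
#'   10 residues).
#' @return The k-mer string, or `NA` with attribute `exclusion_reason`
#'   (`"too short"` or `"X in window"`).
#' @examples
#' extract_cterm("MKLRMAAAALVS", 9)  # "RMAAAALVS"
#' @export
extract_cterm <- function(sequence, k = 10) {
  if (inherits(sequence, "seq_family")) {
    stopifnot(nrow(sequence) == 1L)
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < k)
    return(structure(NA_character_, exclusion_reason = "too short"))
  kmer <- substr(sequence, n - k + 1L, n)
  if (grepl("X", kmer, fixed = TRUE))
    return(structure(NA_character_, exclusion_reason = "X in window"))
  kmer
}

#' Per-position residue frequencies of terminal k-mers
#'
#' The core conservation statistic: counts and frequencies of the 20 standard
#' residues at each of the last `k` positions across a family, computed on
#' unaligned terminal windows (one per sequence). Exclusion is all-or-none
#' per sequence — a record shorter than `k` or with X in the window
#' contributes to no position — so every position has the same denominator.
#'
#' @param family a [seq_family].
#' @param k terminal window length (default 10).
#' @return A `terminal_profile`: list with `k`, integer `counts`
#'   (k x 20), `frequencies` (rows sum to 1), `n_sequences` included, and an
#'   `excluded` data frame (`id`, `reason`). Positions are numbered 1..k from
#'   the N-terminal end of the window.
#' @export
positional_frequency <- function(family, k = 10) {
  stopifnot(inherits(family, "seq_family"))
  kmers <- character(0)
  exc_id <- exc_reason <- character(0)
  for (i in seq_len(nrow(family))) {
    km <- extract_cterm(family$sequence[i], k)
    if (is.na(km)) {
      exc_id <- c(exc_id, family$id[i])
      exc_reason <- c(exc_reason, attr(km, "exclusion_reason"))
    } else kmers <- c(kmers, km)
  }
  if (!length(kmers))
    stop("no includable records: every sequence is shorter than k = ", k,
         " or has X in the terminal window")
  chm <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  counts <- t(vapply(seq_len(k), function(j)
    as.integer(table(factor(chm[, j], levels = AA_ALPHABET))),
    integer(20L)))
  dimnames(counts) <- list(position = seq_len(k), residue = AA_ALPHABET)
  structure(list(k = k, counts = counts,
                 frequencies = counts / length(kmers),
                 n_sequences = length(kmers),
                 excluded = data.frame(id = exc_id, reason = exc_reason,
                                       stringsAsFactors = FALSE)),
            class = "terminal_profile")
}

#' @export
print.terminal_profile <- function(x, ...) {
  cat(sprintf("<terminal_profile> k = %d over %d sequences (%d excluded)\n",
              x$k, x$n_sequences, nrow(x$excluded)))
  top <- apply(x$frequencies, 1L, function(f)
    sprintf("%s %.1f%%", names(which.max(f)), 100 * max(f)))
  cat("  modal residues:", paste(top, collapse = " "), "\n")
  invisible(x)
}

#' Threshold consensus of a terminal profile
#'
#' Per position, the modal residue; a position is flagged conserved when its
#' modal frequency is strictly greater than `threshold` (the ">50%" rule of
#' the degron analysis uses a strict inequality). Ties for the mode are
#' broken lexicographically and flagged.
#'
#' @param profile a `terminal_profile` from [positional_frequency()].
#' @param threshold conservation threshold in (0, 1); default 0.5.
#' @return A `consensus_motif`: list with the consensus `residues` string,
#'   `per_position_frequency`, logical `conserved_flags` and
#'   `ambiguity_flags`, and the `threshold`.
#' @export
consensus_motif <- function(profile, threshold = 0.5) {
  stopifnot(inherits(profile, "terminal_profile"))
  f <- profile$frequencies
  res <- character(profile$k)
  fr <- numeric(profile$k)
  amb <- logical(profile$k)
  for (i in seq_len(profile$k)) {
    mx <- max(f[i, ])
    winners <- colnames(f)[f[i, ] == mx]
    res[i] <- sort(winners)[1L]   # residue columns are alphabetical already
    fr[i] <- mx
    amb[i] <- length(winners) > 1L
  }
  structure(list(residues = paste(res, collapse = ""),
                 per_position_frequency = fr,
                 conserved_flags = fr > threshold,
                 ambiguity_flags = amb,
                 threshold = threshold),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat("<consensus_motif>", x$residues, "\n")
  cat("  conserved (>",
      sprintf("%g%%", 100 * x$threshold), "):",
      paste(ifelse(x$conserved_flags, "*", "."), collapse = ""), "\n")
  invisible(x)
}

#' Right-anchored identity between two motifs
#'
#' Aligns both motifs at their C-terminal ends (no gaps) and returns
#' matches / length of the shorter motif. This is the natural comparison for
#' C-terminal degrons, whose recognition is anchored at the extreme terminus.
#'
#' @param query,reference non-empty motif strings.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' right_anchored_identity("RMSAYGLAAA", "RMSAYGLREV")  # 0.7
#' @export
right_anchored_identity <- function(query, reference) {
  if (!nzchar(query) || !nzchar(reference))
    stop("motifs must be non-empty")
  q <- seq_chars(toupper(query))
  r <- seq_chars(toupper(reference))
  L <- min(length(q), length(r))
  qe <- q[seq(length(q) - L + 1L, length(q))]
  re <- r[seq(length(r) - L + 1L, length(r))]
  sum(qe == re) / L
}

#' Residue-composition score of a motif
#'
#' Fraction of motif residues belonging to `residue_set`. The default set
#' {L, A, V, S} matches the composition bias of C-terminal
#' proteolysis-targeting motifs in E. coli.
#'
#' @param motif non-empty motif string.
#' @param residue_set character vector of residues.
#' @return Fraction in `[0, 1]`.
#' @examples
#' composition_score("RMAAAALVS")  # 7/9
#' @export
composition_score <- function(motif, residue_set = c("L", "A", "V", "S")) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  ch <- seq_chars(toupper(motif))
  mean(ch %in% toupper(residue_set))
}

#' Locate a dipeptide within a motif
#'
#' @param motif motif string.
#' @param dipeptide exactly two residues (default "AA", the Ala-Ala pair that
#'   is a hallmark of this degron family).
#' @return List with `present` flag and 1-based start `positions`
#'   (overlapping occurrences included).
#' @export
dipeptide_present <- function(motif, dipeptide = "AA") {
  if (nchar(dipeptide) != 2L) stop("dipeptide must have length 2")
  ch <- seq_chars(toupper(motif))
  d <- seq_chars(toupper(dipeptide))
  pos <- which(ch[-length(ch)] == d[1L] & ch[-1L] == d[2L])
  list(present = length(pos) > 0L, positions = pos)
}

#' Bundled reference degron catalogue
#'
#' The comparison set shipped with the package: the AD-family consensus
#' degron (ADcon), the E. coli ssrA tag, the P. marinus AD terminal helix,
#' and the Euhalothece AD degron variant lacking the Ala-Ala dipeptides.
#' Users can point `path` at their own two-column (name, motif) TSV.
#'
#' @param path TSV file with columns `name` and `motif`.
#' @return Named character vector of motifs.
#' @export
reference_degrons <- function(path = system.file("extdata",
                                                 "reference_degrons.tsv",
                                                 package = "degronscan")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "motif") %in% names(tab)))
  stats::setNames(toupper(tab$motif), tab$name)
}

#' Score a motif against a reference degron set
#'
#' @param query motif string.
#' @param references named character vector of reference motifs (default the
#'   bundled catalogue).
#' @param residue_set composition set passed to [composition_score()].
#' @return A `degron_score`: list with the query, per-reference
#'   right-anchored identities, the composition score, and the reference set.
#' @export
degron_score <- function(query, references = reference_degrons(),
                         residue_set = c("L", "A", "V", "S")) {
  idy <- vapply(references, function(r)
    right_anchored_identity(query, r), numeric(1L))
  structure(list(query = toupper(query),
                 right_anchored_identity = idy,
                 composition_score = composition_score(query, residue_set),
                 reference_set = references),
            class = "degron_score")
}

#' @export
print.degron_score <- function(x, ...) {
  cat("<degron_score>", x$query, "\n")
  cat(sprintf("  composition ({%s}): %.3f\n", "L,A,V,S",
              x$composition_score))
  for (nm in names(x$right_anchored_identity))
    cat(sprintf("  vs %-12s %s  identity %.2f\n", nm,
                x$reference_set[[nm]], x$right_anchored_identity[[nm]]))
  invisible(x)
}

#' Write a terminal profile as a percent TSV
#'
#' Rows are window positions 1..k (N-to-C), columns the 20 residues, values
#' usage frequency in percent to two decimals.
#'
#' @param profile a `terminal_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  pct <- round(100 * profile$frequencies, 2)
  df <- data.frame(position = seq_len(profile$k), pct, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plain-text sequence logo of a terminal profile
#'
#' One line per position listing residues with frequency >= `min_freq`,
#' most frequent first — a dependency-free stand-in for a graphical logo.
#'
#' @param profile a `terminal_profile`.
#' @param min_freq smallest frequency to print.
#' @return Character vector of lines, invisibly; printed to the console.
#' @export
text_logo <- function(profile, min_freq = 0.05) {
  lines <- vapply(seq_len(profile$k), function(i) {
    f <- sort(profile$frequencies[i, ], decreasing = TRUE)
    f <- f[f >= min_freq]
    sprintf("%2d | %s", i,
            paste(sprintf("%s:%4.1f%%", names(f), 100 * f), collapse = " "))
  }, character(1L))
  cat(lines, sep = "\n")
  invisible(lines)
}
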