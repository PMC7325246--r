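#' Construct a sequence family
#'
#' A `seq_family` holds an ordered collection of protein records: unique
#' non-empty ids, free-text descriptions, and sequences over the 20 standard
#' residues plus X. It is the container that flows through deduplication,
#' alignment, phylogeny and terminal profiling.
#'
#' @param id character vector of unique, non-empty record ids.
#' @param sequence character vector of uppercase amino-acid sequences.
#' @param description optional free-text descriptions (defaults to "").
#' @param provenance free-text note on where the family came from.
#' @return A `seq_family` object (a data frame with columns `id`,
#'   `description`, `sequence` plus a `provenance` attribute).
#' @export
seq_family <- function(id, sequence, description = NULL, provenance = "") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("id and sequence must have equal length")
  if (any(!nzchar(id)) || anyNA(id))
    stop("record ids must be non-empty")
  if (anyDuplicated(id))
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(sequence)) || anyNA(sequence))
    stop("sequences must be non-empty")
  bad <- grepl(sprintf("[^%s]", paste(AA_EXTENDED, collapse = "")), sequence)
  if (any(bad))
    stop("illegal residues (outside 20 standard + X) in record(s): ",
         paste(id[bad], collapse = ", "))
  if (is.null(description)) description <- rep("", length(id))
  out <- data.frame(id = id, description = as.character(description),
                    sequence = sequence, stringsAsFactors = FALSE)
  structure(out, provenance = provenance,
            class = c("seq_family", "data.frame"))
}

#' @export
print.seq_family <- function(x, ...) {
  cat(sprintf("<seq_family> %d record(s); provenance: %s\n",
              nrow(x), attr(x, "provenance")))
  n <- min(nrow(x), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %s (%d aa)\n", x$id[i], nchar(x$sequence[i])))
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' Read a protein FASTA file into a sequence family
#'
#' Sequences are uppercased. Residues outside the 20 standard amino acids are
#' either rejected (default) or masked to X, per `x_policy`.
#'
#' @param path path to an existing FASTA file.
#' @param x_policy `"reject"` to error on non-standard residues other than X,
#'   `"mask"` to map them to X.
#' @return A [seq_family]; ids are the first whitespace-delimited token of each
#'   header, descriptions the remainder.
#' @export
read_fasta <- function(path, x_policy = c("reject", "mask")) {
  x_policy <- match.arg(x_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("FASTA format error in ", path,
                                          ": ", conditionMessage(e)))
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aa))
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pat <- sprintf("[^%s]", paste(AA_EXTENDED, collapse = ""))
  bad <- grepl(pat, seqs)
  if (any(bad)) {
    if (x_policy == "reject")
      stop("non-standard residues in record(s) ",
           paste(ids[bad], collapse = ", "),
           " (record numbers ", paste(which(bad), collapse = ", "),
           "); use x_policy = \"mask\" to map them to X")
    seqs <- gsub(pat, "X", seqs)
  }
  seq_family(ids, seqs, desc, provenance = path)
}

#' Write a sequence family to FASTA
#'
#' @param family a [seq_family]; must be non-empty.
#' @param path output path.
#' @param wrap line width for sequence wrapping (residues per line).
#' @return `path`, invisibly. Round-trips with [read_fasta()].
#' @export
write_fasta <- function(family, path, wrap = 60) {
  stopifnot(inherits(family, "seq_family"))
  if (nrow(family) == 0L) stop("refusing to write an empty family")
  aa <- Biostrings::AAStringSet(family$sequence)
  names(aa) <- ifelse(nzchar(family$description),
                      paste(family$id, family$description),
                      family$id)
  Biostrings::writeXStringSet(aa, filepath = path, width = as.integer(wrap))
  invisible(path)
}

#' Remove verbatim-duplicate sequences
#'
#' Emulates the redundancy-reduction step that shrinks a raw homolog download
#' to a non-redundant analysis set: the first occurrence of each distinct
#' sequence string is kept, later exact copies are dropped, and order is
#' otherwise preserved.
#'
#' @param family a [seq_family].
#' @return The deduplicated [seq_family], with a `dedup_report` attribute: a
#'   data frame of (`kept_id`, `removed_id`) pairs.
#' @export
dedup_exact <- function(family) {
  stopifnot(inherits(family, "seq_family"))
  first <- !duplicated(family$sequence)
  keeper <- family$id[match(family$sequence, family$sequence)]
  report <- data.frame(kept_id = keeper[!first],
                       removed_id = family$id[!first],
                       stringsAsFactors = FALSE)
  out <- seq_family(family$id[first], family$sequence[first],
                    family$description[first],
                    provenance = attr(family, "provenance"))
  attr(out, "dedup_report") <- report
  out
}

#' Greedy identity-based redundancy clustering
#'
#' Generalizes [dedup_exact()] to near-duplicates: records are scanned in
#' input order and each joins the first existing cluster whose representative
#' shares at least `threshold` pairwise identity under a global alignment
#' (identity = matching columns / alignment columns excluding terminal gaps).
#' Cluster representatives (the first member seen) are returned.
#'
#' @param family a [seq_family].
#' @param threshold identity fraction in (0, 1].
#' @param scheme a [scoring_scheme] used for the pairwise alignments.
#' @return A [seq_family] of representatives with a `cluster_report`
#'   attribute mapping each input id to its representative.
#' @export
cluster_identity <- function(family, threshold,
                             scheme = scoring_scheme()) {
  stopifnot(inherits(family, "seq_family"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  reps <- integer(0)
  assignment <- character(nrow(family))
  for (i in seq_len(nrow(family))) {
    placed <- FALSE
    for (r in reps) {
      idy <- if (family$sequence[r] == family$sequence[i]) 1 else
        pairwise_identity(family$sequence[r], family$sequence[i], scheme)
      if (idy >= threshold) {
        assignment[i] <- family$id[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignment[i] <- family$id[i]
    }
  }
  out <- seq_family(family$id[reps], family$sequence[reps],
                    family$description[reps],
                    provenance = attr(family, "provenance"))
  attr(out, "cluster_report") <- data.frame(id = family$id,
                                            representative = assignment,
                                            stringsAsFactors = FALSE)
  out
}

#' Write a deduplication report as TSV
#'
#' @param family a family returned by [dedup_exact()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dedup_report <- function(family, path) {
  rep <- attr(family, "dedup_report")
  if (is.null(rep)) rep <- data.frame(kept_id = character(0),
                                      removed_id = character(0))
  utils::write.table(rep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
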