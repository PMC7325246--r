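#' Pipeline configuration
#'
#' Collects every tunable of the sequence and assay pipelines. Defaults are
#' the analysis conventions of the AD-degron study: terminal window k = 10,
#' strict >50% conservation rule, 100 bootstrap replicates, eight
#' representatives.
#'
#' @param fasta path to the input protein FASTA (sequence pipeline).
#' @param timecourse_tsv path to the reporter time-course TSV (assay
#'   pipeline).
#' @param out_dir output directory for artifacts.
#' @param k terminal window length.
#' @param conservation_threshold consensus conservation threshold.
#' @param n_bootstrap bootstrap replicates.
#' @param n_representatives representatives selected from the tree.
#' @param dedup_mode `"exact"` or `"identity"`.
#' @param identity_threshold clustering threshold when
#'   `dedup_mode = "identity"`.
#' @param gap_open,gap_extend affine gap costs of the scoring scheme.
#' @param endpoint_time assay endpoint in hours.
#' @param od_floor OD600 floor for normalization.
#' @param seed integer seed for every stochastic stage.
#' @return A `pipeline_config` list; round-trips through JSON via
#'   [write_pipeline_config()] / [read_pipeline_config()].
#' @export
pipeline_config <- function(fasta = NULL, timecourse_tsv = NULL,
                            out_dir = tempfile("degronscan_run_"),
                            k = 10, conservation_threshold = 0.5,
                            n_bootstrap = 100, n_representatives = 8,
                            dedup_mode = c("exact", "identity"),
                            identity_threshold = 0.95,
                            gap_open = 10, gap_extend = 1,
                            endpoint_time = 25, od_floor = 0.01,
                            seed = 1) {
  dedup_mode <- match.arg(dedup_mode)
  if (k < 1) stop("k must be >= 1")
  if (conservation_threshold <= 0 || conservation_threshold >= 1)
    stop("conservation_threshold must lie in (0, 1)")
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1")
  structure(list(fasta = fasta, timecourse_tsv = timecourse_tsv,
                 out_dir = out_dir, k = as.integer(k),
                 conservation_threshold = as.numeric(conservation_threshold),
                 n_bootstrap = as.integer(n_bootstrap),
                 n_representatives = as.integer(n_representatives),
                 dedup_mode = dedup_mode,
                 identity_threshold = as.numeric(identity_threshold),
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend),
                 endpoint_time = as.numeric(endpoint_time),
                 od_floor = as.numeric(od_floor),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' Run the sequence-analysis pipeline
#'
#' Stage order follows the published analysis narrative: read homologs,
#' remove redundancy, align, build the NJ tree with bootstrap supports,
#' select branch representatives, profile the terminal window, call the
#' threshold consensus, and score it against the bundled degron catalogue.
#' All intermediate artifacts are written under `config$out_dir`.
#'
#' @param config a [pipeline_config] with `fasta` set (or pass `family`).
#' @param family optionally, an in-memory [seq_family] instead of a file.
#' @return A `run_report`: list of stage counts, the consensus, degron
#'   scores, representatives, output paths, and a config fingerprint.
#' @export
run_sequence_pipeline <- function(config, family = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- scoring_scheme(gap_open = config$gap_open,
                           gap_extend = config$gap_extend)
  if (is.null(family)) {
    if (is.null(config$fasta)) stop("config$fasta is not set")
    family <- read_fasta(config$fasta)
  }
  n_input <- nrow(family)
  message(sprintf("[input] %d records", n_input))

  deduped <- if (config$dedup_mode == "exact") dedup_exact(family)
  else cluster_identity(family, config$identity_threshold, scheme)
  n_dedup <- nrow(deduped)
  message(sprintf("[dedup:%s] %d records retained", config$dedup_mode,
                  n_dedup))
  paths <- list(deduped_fasta = file.path(config$out_dir, "deduped.fasta"),
                dedup_report = file.path(config$out_dir, "dedup_report.tsv"),
                alignment = file.path(config$out_dir, "alignment.fasta"),
                distances = file.path(config$out_dir, "distances.tsv"),
                tree = file.path(config$out_dir, "tree.nwk"),
                profile = file.path(config$out_dir, "terminal_profile.tsv"),
                consensus = file.path(config$out_dir, "consensus.json"))
  write_fasta(deduped, paths$deduped_fasta)
  write_dedup_report(deduped, paths$dedup_report)

  msa <- progressive_msa(deduped, scheme)
  write_alignment_fasta(msa, paths$alignment)
  message(sprintf("[msa] %d rows x %d columns", n_dedup, msa$n_columns))

  dm <- msa_distances(msa)
  write_distance_tsv(dm, paths$distances)
  tree <- bootstrap_support(msa, n_replicates = config$n_bootstrap,
                            seed = config$seed)
  write_newick(tree, paths$tree)
  message(sprintf("[tree] NJ + %d bootstrap replicates", config$n_bootstrap))

  reps <- select_representatives(tree, dm,
                                 min(config$n_representatives, n_dedup))
  message(sprintf("[representatives] %s", paste(reps, collapse = ", ")))

  profile <- positional_frequency(deduped, config$k)
  write_profile_tsv(profile, paths$profile)
  consensus <- consensus_motif(profile, config$conservation_threshold)
  score <- degron_score(consensus$residues)
  message(sprintf("[consensus] %s (%d/%d positions conserved)",
                  consensus$residues, sum(consensus$conserved_flags),
                  config$k))
  jsonlite::write_json(
    list(consensus = consensus$residues,
         per_position_frequency = consensus$per_position_frequency,
         conserved_flags = consensus$conserved_flags,
         ambiguity_flags = consensus$ambiguity_flags,
         threshold = consensus$threshold,
         right_anchored_identity =
           as.list(score$right_anchored_identity),
         composition_score = score$composition_score),
    paths$consensus, auto_unbox = TRUE, digits = NA)

  report <- list(stage_counts = c(input = n_input, after_dedup = n_dedup,
                                  profiled = profile$n_sequences,
                                  excluded = nrow(profile$excluded)),
                 consensus = consensus, degron_scores = score,
                 representatives = reps, tree = tree, profile = profile,
                 paths = paths, config = unclass(config))
  class(report) <- "run_report"
  report
}

#' Run the reporter-assay pipeline
#'
#' Normalizes each (condition, genotype) series by OD, computes
#' percent-of-control and degradation at the configured endpoint against the
#' untagged control of the same genotype, fits post-peak decay rates, and
#' derives recovery indices of each knockout relative to WT.
#'
#' @param config a [pipeline_config] with `timecourse_tsv` set (or pass
#'   `timecourse`).
#' @param timecourse optionally an in-memory `time_course`.
#' @param control_condition label of the untagged control series.
#' @return A `run_report` with a `degradation` data frame (condition,
#'   genotype, percent_of_control, degradation_percent, decay_rate) and a
#'   `recovery` data frame (condition, genotype, recovery_points).
#' @export
run_assay_pipeline <- function(config, timecourse = NULL,
                               control_condition = "untagged-control") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(timecourse)) {
    if (is.null(config$timecourse_tsv))
      stop("config$timecourse_tsv is not set")
    timecourse <- read_timecourse(config$timecourse_tsv)
  } else timecourse <- as_time_course(timecourse)
  combos <- unique(timecourse[, c("condition", "genotype")])
  norm <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- timecourse$condition == combos$condition[i] &
      timecourse$genotype == combos$genotype[i]
    norm[[paste(combos$condition[i], combos$genotype[i], sep = "|")]] <-
      normalize_timecourse(timecourse[sel, , drop = FALSE],
                           config$od_floor)
  }
  rows <- list(); results <- list()
  for (i in seq_len(nrow(combos))) {
    cond <- combos$condition[i]; gt <- combos$genotype[i]
    ctrl_key <- paste(control_condition, gt, sep = "|")
    if (!ctrl_key %in% names(norm))
      stop("no '", control_condition, "' series for genotype ", gt)
    key <- paste(cond, gt, sep = "|")
    res <- degradation_result(norm[[key]], norm[[ctrl_key]],
                              config$endpoint_time)
    results[[key]] <- res
    rows[[key]] <- data.frame(
      condition = cond, genotype = gt,
      percent_of_control = res$percent_of_control,
      degradation_percent = res$degradation_percent,
      decay_rate = if (is.null(res$decay_rate_estimate)) NA_real_
      else res$decay_rate_estimate$rate,
      stringsAsFactors = FALSE)
  }
  degradation <- do.call(rbind, rows)
  rownames(degradation) <- NULL
  rec <- list()
  for (key in names(results)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    if (parts[2L] == "WT" || parts[1L] == control_condition) next
    wt_key <- paste(parts[1L], "WT", sep = "|")
    if (!wt_key %in% names(results)) next
    rec[[key]] <- data.frame(
      condition = parts[1L], genotype = parts[2L],
      recovery_points = recovery_index(results[[key]], results[[wt_key]]),
      stringsAsFactors = FALSE)
  }
  recovery <- if (length(rec)) do.call(rbind, rec) else
    data.frame(condition = character(0), genotype = character(0),
               recovery_points = numeric(0))
  rownames(recovery) <- NULL
  paths <- list(degradation = file.path(config$out_dir, "degradation.tsv"),
                recovery = file.path(config$out_dir, "recovery.tsv"))
  utils::write.table(degradation, paths$degradation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(recovery, paths$recovery, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report <- list(degradation = degradation, recovery = recovery,
                 results = results, paths = paths,
                 config = unclass(config))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$stage_counts)) {
    cat("  stages:",
        paste(names(x$stage_counts), x$stage_counts, sep = "=",
              collapse = " "), "\n")
    cat("  consensus:", x$consensus$residues, "\n")
    cat("  representatives:", paste(x$representatives, collapse = ", "),
        "\n")
  }
  if (!is.null(x$degradation)) {
    cat(sprintf("  %d degradation rows, %d recovery rows\n",
                nrow(x$degradation), nrow(x$recovery)))
  }
  invisible(x)
}
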