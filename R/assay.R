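# Genotype vocabulary: wild type plus the protease-knockout strains used in
# the degradation-mechanism experiments.
GENOTYPES <- c("WT", "dClpA", "dClpX", "dClpP", "dLon", "dClpP-dLon")

#' Read a reporter time-course TSV
#'
#' Expected columns: `time_h`, `fluorescence`, `od600`, `condition`,
#' `genotype`, `replicate`. Time must be strictly increasing within each
#' (condition, genotype, replicate) series.
#'
#' @param path TSV path.
#' @return A `time_course` data frame.
#' @export
read_timecourse <- function(path) {
  tc <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_time_course(tc)
}

#' Validate a time-course data frame
#' @param tc data frame with the time-course columns.
#' @return The validated `time_course` object.
#' @export
as_time_course <- function(tc) {
  need <- c("time_h", "fluorescence", "od600", "condition", "genotype",
            "replicate")
  missing <- setdiff(need, names(tc))
  if (length(missing))
    stop("time course is missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(tc$genotype), GENOTYPES)
  if (length(bad))
    stop("unknown genotype label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(GENOTYPES, collapse = ", "), ")")
  sp <- split(tc, interaction(tc$condition, tc$genotype, tc$replicate,
                              drop = TRUE))
  for (s in sp)
    if (is.unsorted(s$time_h, strictly = TRUE))
      stop("time not strictly increasing within a replicate series (",
           s$condition[1L], "/", s$genotype[1L], "/rep ", s$replicate[1L],
           ")")
  class(tc) <- c("time_course", "data.frame")
  tc
}

#' OD-normalize a reporter time course
#'
#' Divides fluorescence by OD600 per time point within each replicate —
#' normalizing the signal to the number of cells — then averages replicates
#' per time point. Points with OD below `od_floor` are masked (dropped) and
#' reported, since dividing by a near-zero OD amplifies early-culture noise.
#'
#' @param tc a `time_course` (a single condition/genotype; see
#'   [run_assay_pipeline()] for batch use).
#' @param od_floor minimum usable OD600 (default 0.01).
#' @return A `normalized_series` data frame with columns `time_h`, `mean`,
#'   `sd`, `n`, plus a `masked` attribute counting dropped points.
#' @export
normalize_timecourse <- function(tc, od_floor = 0.01) {
  stopifnot(all(c("time_h", "fluorescence", "od600") %in% names(tc)))
  usable <- tc$od600 >= od_floor
  masked <- sum(!usable)
  tc <- tc[usable, , drop = FALSE]
  if (!nrow(tc)) stop("no usable points: all OD600 below floor ", od_floor)
  tc$norm <- tc$fluorescence / tc$od600
  agg <- stats::aggregate(norm ~ time_h, data = tc, FUN = function(x)
    c(mean = mean(x), sd = stats::sd(x), n = length(x)))
  out <- data.frame(time_h = agg$time_h,
                    mean = agg$norm[, "mean"],
                    sd = agg$norm[, "sd"],
                    n = as.integer(agg$norm[, "n"]))
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, masked = masked,
            class = c("normalized_series", "data.frame"))
}

# Linear interpolation of a normalized series at time t (error outside range).
.series_at <- function(series, t, what = "series") {
  if (t < min(series$time_h) || t > max(series$time_h))
    stop(what, " does not cover t = ", t, " h (range ",
         min(series$time_h), "-", max(series$time_h), ")")
  stats::approx(series$time_h, series$mean, xout = t)$y
}

#' Tagged signal as percent of the untagged control
#'
#' `100 * tagged(t) / control(t)` on OD-normalized series, with linear
#' interpolation to the stated endpoint hour.
#'
#' @param tagged,control `normalized_series` objects covering `t`.
#' @param t endpoint time in hours.
#' @return Percentage (numeric scalar).
#' @export
percent_of_control <- function(tagged, control, t) {
  ctrl <- .series_at(control, t, "control series")
  if (ctrl <= 0) stop("control value at t = ", t, " h is not positive")
  100 * .series_at(tagged, t, "tagged series") / ctrl
}

#' Percent degradation at an endpoint
#'
#' The complement of [percent_of_control()]:
#' `100 - percent_of_control(tagged, control, t)`.
#'
#' @inheritParams percent_of_control
#' @return Percentage points of degradation.
#' @export
degradation_percent <- function(tagged, control, t) {
  100 - percent_of_control(tagged, control, t)
}

#' Full degradation summary for a tagged/control pair
#'
#' @inheritParams percent_of_control
#' @param fit_rate also run [fit_decay_rate()] on the tagged series.
#' @return A `degradation_result`: list with `normalized_series` (the tagged
#'   series), `percent_of_control`, `degradation_percent` (their sum is 100
#'   exactly), `endpoint_time`, and optionally `decay_rate_estimate`.
#' @export
degradation_result <- function(tagged, control, t, fit_rate = TRUE) {
  poc <- percent_of_control(tagged, control, t)
  rate <- if (fit_rate) tryCatch(fit_decay_rate(tagged),
                                 error = function(e) NULL) else NULL
  structure(list(normalized_series = tagged,
                 percent_of_control = poc,
                 degradation_percent = 100 - poc,
                 decay_rate_estimate = rate,
                 endpoint_time = t),
            class = "degradation_result")
}

#' @export
print.degradation_result <- function(x, ...) {
  cat(sprintf(
    "<degradation_result> %.1f%% of control at %g h (%.1f%% degraded)\n",
    x$percent_of_control, x$endpoint_time, x$degradation_percent))
  if (!is.null(x$decay_rate_estimate))
    cat(sprintf("  post-peak decay rate %.3f /h (R2 = %.3f)\n",
                x$decay_rate_estimate$rate, x$decay_rate_estimate$r_squared))
  invisible(x)
}

#' Fluorescence recovery in a protease knockout
#'
#' Degradation in the wild type minus degradation in the knockout, in
#' percentage points; positive values mean the knockout stabilizes the
#' reporter (the protease participates in degron recognition).
#'
#' @param genotype_result,wt_result `degradation_result` objects for the
#'   same construct at the same endpoint time.
#' @return Percentage points of recovery.
#' @export
recovery_index <- function(genotype_result, wt_result) {
  stopifnot(inherits(genotype_result, "degradation_result"),
            inherits(wt_result, "degradation_result"))
  if (!isTRUE(all.equal(genotype_result$endpoint_time,
                        wt_result$endpoint_time)))
    stop("endpoint times differ between genotype and WT results")
  wt_result$degradation_percent - genotype_result$degradation_percent
}

#' Fit a first-order decay rate to the post-peak segment
#'
#' Locates the maximum of the normalized series and fits a least-squares line
#' to log(signal) over the segment from the peak onward; the decay rate is
#' the negated slope. Requires at least 3 points after the peak.
#'
#' @param series a `normalized_series`.
#' @return List with `rate` (per hour), `r_squared`, `n_points`,
#'   `peak_time`, and logical `not_degrading` (slope >= 0).
#' @export
fit_decay_rate <- function(series) {
  stopifnot(is.data.frame(series), all(c("time_h", "mean") %in%
                                         names(series)))
  peak <- which.max(series$mean)
  post <- series[peak:nrow(series), , drop = FALSE]
  if (nrow(post) < 4L)
    stop("not estimable: fewer than 3 points after the peak")
  if (any(post$mean <= 0))
    stop("not estimable: nonpositive normalized values after the peak")
  fit <- stats::lm(log(mean) ~ time_h, data = post)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  if (is.nan(r2)) r2 <- 1  # perfectly flat series
  if (abs(slope) < 1e-12) slope <- 0
  list(rate = max(-slope, 0), r_squared = r2, n_points = nrow(post),
       peak_time = series$time_h[peak], not_degrading = slope >= 0)
}

#' Fold change between two positive values
#'
#' `fold = max(before, after) / min(before, after)` with the direction taken
#' from the ordering. The display value is truncated (not rounded) to two
#' decimals, matching the printed convention of enzyme-activity comparisons
#' (e.g. 90.9 over 16.6 = 5.4759... printed as 5.47).
#'
#' @param before,after positive values.
#' @return A `fold_change`: list with `before`, `after`, `fold` (raw ratio),
#'   `direction` (`"increase"`, `"decrease"` or `"none"`), and `display`.
#' @examples
#' fold_change(90.9, 16.6)$display  # 5.47
#' @export
fold_change <- function(before, after) {
  if (!is.numeric(before) || !is.numeric(after) ||
      before <= 0 || after <= 0)
    stop("fold_change needs positive values")
  fold <- max(before, after) / min(before, after)
  direction <- if (after > before) "increase" else
    if (after < before) "decrease" else "none"
  structure(list(before = before, after = after, fold = fold,
                 direction = direction,
                 display = floor(fold * 100) / 100),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("<fold_change> %g -> %g: %.2f-fold %s\n",
              x$before, x$after, x$display, x$direction))
  invisible(x)
}

#' Net production effect of opposing abundance and activity changes
#'
#' Removing a degron typically raises enzyme abundance but can lower specific
#' activity. Under the first-order assumption production ~ abundance x
#' activity, the predicted production fold is their ratio: values above 1
#' predict a net increase, below 1 a net decrease (abundance gain cannot
#' compensate the activity loss).
#'
#' @param abundance_fold_increase abundance ratio, >= 1.
#' @param activity_fold_decrease activity ratio, >= 1.
#' @return List with `predicted_fold` and `direction`
#'   (`"increase"`, `"decrease"` or `"neutral"`).
#' @examples
#' net_effect(2.65, 5.47)  # predicted decrease
#' @export
net_effect <- function(abundance_fold_increase, activity_fold_decrease) {
  if (abundance_fold_increase < 1 || activity_fold_decrease < 1)
    stop("ratios must be >= 1; normalize direction before calling")
  pred <- abundance_fold_increase / activity_fold_decrease
  list(predicted_fold = pred,
       direction = if (pred > 1) "increase" else
         if (pred < 1) "decrease" else "neutral")
}

#' Write a time course as TSV
#' @param tc a `time_course`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_tsv <- function(tc, path) {
  utils::write.table(tc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
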