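#' @include AllClasses.R AllGenerics.R nucleus_seg.R decay_fit.R
NULL

#' Pool decay histograms per nucleus
#'
#' Sums the per-pixel decay histograms of a pooled FLIM image over each
#' labelled nucleus, yielding one high-count histogram per nucleus
#' (typically >10,000 photons) suitable for bi-exponential fitting.
#' Label 0 (background) is excluded.
#'
#' @param pooled a [PooledFLIMImage-class].
#' @param labels integer label matrix on the same grid.
#' @return named list of [DecayHistogram-class], names = label ids.
#' @export
poolNucleusDecays <- function(pooled, labels) {
  d <- dim(pooled@counts)
  stopIfNot(identical(dim(labels), d[1:2]),
            "labels must share the pooled image grid")
  ids <- sort(unique(labels[labels > 0]))
  cmat <- pooled@counts
  dim(cmat) <- c(d[1] * d[2], d[3])
  lv <- as.vector(labels)
  out <- lapply(ids, function(i)
    decayHistogram(colSums(cmat[lv == i, , drop = FALSE]),
                   period_ns = pooled@period_ns))
  names(out) <- as.character(ids)
  out
}

#' Assemble per-nucleus records
#'
#' Joins fitted FRET fractions, concentration estimates and cohort
#' metadata into one record per nucleus. Non-converged fits are flagged,
#' not dropped.
#'
#' @param fits a [BiExpGlobalFit-class] over the nuclei.
#' @param concentrations data.frame from [estimateConcentration()],
#'   aligned with the fit segments.
#' @param metadata optional data.frame keyed by `nucleus_id` with cohort
#'   columns (e.g. `field_of_view_id`, `nodule_id`, `subject_id`,
#'   `route`, `time_post_dose`); every nucleus must match exactly one
#'   row.
#' @param nucleus_id ids of the fit segments (default `1..n`).
#' @param areas optional per-nucleus pixel areas, used to report mean
#'   intensity (photons per pixel).
#' @return data.frame with one row per nucleus: `nucleus_id`,
#'   `n_photons`, `mean_intensity`, `fret_fraction`, `tau_mean_iw_ps`,
#'   `concentration_uM`, `censoring`, `flagged`, plus metadata columns.
#' @export
buildNucleusRecords <- function(fits, concentrations, metadata = NULL,
                                nucleus_id = NULL, areas = NULL) {
  stopifnot(is(fits, "BiExpGlobalFit"))
  n <- length(fits@fractions)
  if (is.null(nucleus_id)) nucleus_id <- seq_len(n)
  if (anyDuplicated(nucleus_id))
    stop("duplicate nucleus_id: ",
         paste(unique(nucleus_id[duplicated(nucleus_id)]), collapse = ", "),
         call. = FALSE)
  stopIfNot(nrow(concentrations) == n,
            "concentrations must have one row per fitted nucleus")
  rec <- data.frame(
    nucleus_id = nucleus_id,
    n_photons = fits@n_photons,
    mean_intensity = if (is.null(areas)) NA_real_ else
      fits@n_photons / areas,
    fret_fraction = fits@fractions,
    tau_mean_iw_ps = fits@tau_mean_iw_ps,
    concentration_uM = concentrations$value,
    censoring = concentrations$censoring,
    flagged = !fits@converged
  )
  if (any(rec$flagged))
    message(sum(rec$flagged), " nuclei flagged (non-converged fits)")
  if (!is.null(metadata)) {
    stopIfNot("nucleus_id" %in% names(metadata),
              "metadata must have a nucleus_id column")
    if (anyDuplicated(metadata$nucleus_id))
      stop("duplicate nucleus_id in metadata", call. = FALSE)
    miss <- setdiff(rec$nucleus_id, metadata$nucleus_id)
    if (length(miss))
      stop("metadata join mismatch for nucleus_id: ",
           paste(miss, collapse = ", "), call. = FALSE)
    rec <- merge(rec, metadata, by = "nucleus_id", sort = TRUE)
  }
  rec
}

#' Welch two-sample t-test
#'
#' Unpaired, unequal-variances, two-tailed t-test with
#' Welch-Satterthwaite degrees of freedom, as used to compare per-nucleus
#' lifetime distributions between treatment groups.
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @return list with `t_statistic`, `degrees_of_freedom` (non-integer in
#'   general) and `p_value` (two-tailed).
#' @export
welchTTest <- function(group_a, group_b) {
  stopIfNot(length(group_a) >= 2 && length(group_b) >= 2,
            "each group needs n >= 2")
  if (sd(group_a) == 0 && sd(group_b) == 0 &&
      mean(group_a) == mean(group_b))
    stop("both groups constant with equal means: test undefined",
         call. = FALSE)
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t_statistic = unname(ht$statistic),
       degrees_of_freedom = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Cohort distribution summaries and histograms
#'
#' Groups nucleus records by the given keys and reports, per group,
#' medians and interquartile ranges of the FRETing fraction and
#' concentration, a normalized FRET-fraction histogram (0.05-wide bins
#' over \[0, 1\]) and a normalized log-spaced concentration histogram
#' (5 bins per decade). Censored concentrations stay in the records with
#' their flags; they are excluded from the concentration median unless
#' they exceed 20 % of a group, in which case the median (computed with
#' censored values at their bounds) is marked as a bound.
#'
#' @param records data.frame from [buildNucleusRecords()].
#' @param group_by character vector of record columns to group on.
#' @param f_binwidth FRET-fraction histogram bin width.
#' @param conc_bins_per_decade concentration histogram resolution.
#' @return list with `summary`, `fret_hist` and `conc_hist` data.frames.
#'   Empty groups are omitted with a warning.
#' @export
summarizeCohort <- function(records, group_by = character(0),
                            f_binwidth = 0.05, conc_bins_per_decade = 5) {
  stopIfNot(nrow(records) > 0, "records must be non-empty")
  stopIfNot(all(group_by %in% names(records)),
            "group_by names missing from records")
  key <- if (length(group_by))
    interaction(records[group_by], drop = FALSE, sep = "/")
  else factor(rep("all", nrow(records)))
  if (any(table(key) == 0))
    warning("empty groups omitted: ",
            paste(names(which(table(key) == 0)), collapse = ", "))
  groups <- split(records, key, drop = TRUE)
  f_breaks <- seq(0, 1, by = f_binwidth)
  summary_rows <- list(); fhist_rows <- list(); chist_rows <- list()
  for (g in names(groups)) {
    r <- groups[[g]]
    f <- r$fret_fraction
    cens_frac <- mean(r$censoring != "exact")
    conc_exact <- r$concentration_uM[r$censoring == "exact"]
    median_is_bound <- cens_frac >= 0.2
    conc_med <- if (median_is_bound) median(r$concentration_uM)
    else if (length(conc_exact)) median(conc_exact) else NA_real_
    summary_rows[[g]] <- data.frame(
      group = g, n = nrow(r),
      f_median = median(f),
      f_q25 = unname(quantile(f, 0.25)), f_q75 = unname(quantile(f, 0.75)),
      conc_median_uM = conc_med,
      conc_median_is_bound = median_is_bound,
      censored_fraction = cens_frac
    )
    fh <- hist(pmin(pmax(f, 0), 1), breaks = f_breaks, plot = FALSE)
    fhist_rows[[g]] <- data.frame(
      group = g, bin_lo = fh$breaks[-length(fh$breaks)],
      bin_hi = fh$breaks[-1], fraction = fh$counts / sum(fh$counts)
    )
    cpos <- r$concentration_uM[r$concentration_uM > 0]
    if (length(cpos)) {
      lo <- floor(log10(min(cpos)) * conc_bins_per_decade)
      hi <- ceiling(log10(max(cpos)) * conc_bins_per_decade)
      if (hi == lo) hi <- lo + 1L
      cbreaks <- 10^(seq(lo, hi) / conc_bins_per_decade)
      ch <- hist(cpos, breaks = cbreaks, plot = FALSE)
      chist_rows[[g]] <- data.frame(
        group = g, bin_lo = ch$breaks[-length(ch$breaks)],
        bin_hi = ch$breaks[-1], fraction = ch$counts / sum(ch$counts)
      )
    }
  }
  list(summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)),
       fret_hist = do.call(rbind, c(fhist_rows, make.row.names = FALSE)),
       conc_hist = if (length(chist_rows))
         do.call(rbind, c(chist_rows, make.row.names = FALSE))
       else NULL)
}
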