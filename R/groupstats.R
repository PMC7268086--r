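#' Independent-samples (pooled-variance) t-test
#'
#' Student t with n_a + n_b - 2 degrees of freedom and a two-sided p-value.
#' Degenerate data (zero pooled variance) yield t = 0, p = 1 when the group
#' means are equal and an error otherwise. A Welch variant is available via
#' \code{var_equal = FALSE}.
#'
#' @param x,y numeric vectors (each >= 2 finite values).
#' @param var_equal pooled-variance (Student) when TRUE, Welch otherwise.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
two_sample_ttest <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2 || !all(is.finite(c(x, y))))
    stop_megdmn("each group needs at least 2 finite values",
                class = "megdmn_input_error")
  if (!var_equal) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    return(list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value))
  }
  na <- length(x); nb <- length(y)
  sp2 <- ((na - 1) * var(x) + (nb - 1) * var(y)) / (na + nb - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = na + nb - 2, p = 1))
    stop_megdmn("zero pooled variance with unequal means",
                class = "megdmn_degenerate_data")
  }
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, df = na + nb - 2, p = 2 * pt(-abs(tstat), na + nb - 2))
}

# Group comparison wrapper: a degenerate comparison (zero pooled variance
# with unequal means, e.g. saturated binary degrees) is treated as
# maximally significant in the direction of the mean difference rather than
# aborting the scan; p is floored at the smallest positive double.
safe_ttest <- function(x, y) {
  tryCatch(two_sample_ttest(x, y), megdmn_degenerate_data = function(e)
    list(t = sign(mean(x) - mean(y)) * Inf,
         df = length(x) + length(y) - 2, p = .Machine$double.xmin))
}

# Upper-triangle pair index helper for n nodes.
pair_index <- function(nm) {
  pr <- which(upper.tri(diag(length(nm))), arr.ind = TRUE)
  data.frame(roi_a = nm[pr[, 1]], roi_b = nm[pr[, 2]],
             i = pr[, 1], j = pr[, 2], stringsAsFactors = FALSE)
}

#' Two-group comparison of functional connectivity across bands
#'
#' For every band and every unordered ROI pair, compares the per-subject
#' pooled correlations between the patient and control groups with a
#' pooled-variance independent-samples t-test (two-sided). Counts of
#' significantly higher / lower pairs in patients are reported per band at
#' the uncorrected threshold; a Benjamini-Hochberg adjusted column is always
#' emitted alongside (it never replaces the uncorrected counts).
#'
#' By default the comparison is on connectivity strength |R|: beamformed
#' source time series have an arbitrary polarity (the estimated dipole
#' orientation is identifiable only up to sign), so the sign of a
#' reconstructed source-pair correlation is not physically meaningful while
#' its magnitude is. \code{measure = "signed"} compares the raw correlations
#' instead.
#'
#' @param fc_patients,fc_controls named lists (one element per band) of
#'   per-subject \code{fc_matrix} lists.
#' @param alpha_level significance threshold (default .05).
#' @param measure compare "strength" (|R|, default) or "signed" R.
#' @return Object of class \code{dmn_group_stats}: \code{table} (one row per
#'   band x pair), \code{counts} (per-band significant-pair counts by
#'   direction), \code{alpha_level}, \code{unit = "pair"}.
#' @export
compare_fc_groups <- function(fc_patients, fc_controls, alpha_level = 0.05,
                              measure = c("strength", "signed")) {
  measure <- match.arg(measure)
  bands <- names(fc_patients)
  miss <- setdiff(bands, names(fc_controls))
  if (length(miss) || is.null(bands))
    stop_megdmn("band '%s' missing in one group",
                paste(miss, collapse = ","), class = "megdmn_input_error")
  rows <- list()
  for (b in bands) {
    fp <- fc_patients[[b]]; fc <- fc_controls[[b]]
    if (length(fp) < 2 || length(fc) < 2)
      stop_megdmn("need >= 2 subjects per group in band %s", b,
                  class = "megdmn_input_error")
    nm <- rownames(fp[[1]])
    pairs <- pair_index(nm)
    take <- if (measure == "strength") function(m) abs(m[upper.tri(m)]) else
      function(m) m[upper.tri(m)]
    vp <- vapply(fp, take, numeric(nrow(pairs)))
    vc <- vapply(fc, take, numeric(nrow(pairs)))
    res <- lapply(seq_len(nrow(pairs)), function(k)
      safe_ttest(vp[k, ], vc[k, ]))
    rows[[b]] <- data.frame(
      band = b, roi_a = pairs$roi_a, roi_b = pairs$roi_b,
      mean_patient = rowMeans(vp), mean_control = rowMeans(vc),
      t = vapply(res, `[[`, 0, "t"), p = vapply(res, `[[`, 0, "p"),
      stringsAsFactors = FALSE)
    rows[[b]]$p_bh <- p.adjust(rows[[b]]$p, method = "BH")
    rows[[b]]$direction <- ifelse(rows[[b]]$t >= 0, "patient_higher",
                                  "patient_lower")
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  counts <- do.call(rbind, lapply(bands, function(b) {
    tb <- tab[tab$band == b, ]
    sig <- tb$p < alpha_level
    data.frame(band = b,
               n_higher = sum(sig & tb$direction == "patient_higher"),
               n_lower = sum(sig & tb$direction == "patient_lower"),
               n_higher_bh = sum(tb$p_bh < alpha_level &
                                   tb$direction == "patient_higher"),
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, counts = counts, alpha_level = alpha_level,
                 unit = "pair"),
            class = "dmn_group_stats")
}

#' Two-group comparison of node degree across bands
#'
#' As \code{\link{compare_fc_groups}}, over the 12 DMN nodes per band.
#'
#' @param deg_patients,deg_controls named lists (one element per band) of
#'   per-subject degree vectors (\code{\link{node_degree}}).
#' @param alpha_level significance threshold.
#' @return A \code{dmn_group_stats} with \code{unit = "node"} and a
#'   \code{table} of one row per band x node.
#' @export
compare_degree_groups <- function(deg_patients, deg_controls,
                                  alpha_level = 0.05) {
  bands <- names(deg_patients)
  miss <- setdiff(bands, names(deg_controls))
  if (length(miss) || is.null(bands))
    stop_megdmn("band '%s' missing in one group",
                paste(miss, collapse = ","), class = "megdmn_input_error")
  rows <- list()
  for (b in bands) {
    dp <- do.call(cbind, lapply(deg_patients[[b]], as.numeric))
    dc <- do.call(cbind, lapply(deg_controls[[b]], as.numeric))
    nm <- names(deg_patients[[b]][[1]])
    res <- lapply(seq_len(nrow(dp)), function(k)
      safe_ttest(dp[k, ], dc[k, ]))
    rows[[b]] <- data.frame(
      band = b, roi = nm,
      mean_patient = rowMeans(dp), mean_control = rowMeans(dc),
      t = vapply(res, `[[`, 0, "t"), p = vapply(res, `[[`, 0, "p"),
      stringsAsFactors = FALSE)
    rows[[b]]$p_bh <- p.adjust(rows[[b]]$p, method = "BH")
    rows[[b]]$direction <- ifelse(rows[[b]]$t >= 0, "patient_higher",
                                  "patient_lower")
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  counts <- do.call(rbind, lapply(bands, function(b) {
    tb <- tab[tab$band == b, ]
    sig <- tb$p < alpha_level
    data.frame(band = b,
               n_higher = sum(sig & tb$direction == "patient_higher"),
               n_lower = sum(sig & tb$direction == "patient_lower"),
               n_higher_bh = sum(tb$p_bh < alpha_level &
                                   tb$direction == "patient_higher"),
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, counts = counts, alpha_level = alpha_level,
                 unit = "node"),
            class = "dmn_group_stats")
}

#' @export
print.dmn_group_stats <- function(x, ...) {
  cat(sprintf("<dmn_group_stats> per-%s two-group t-tests (alpha = %g)\n",
              x$unit, x$alpha_level))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Spearman correlation between connectivity and a clinical covariate
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-approximation t = rho * sqrt((n - 2) / (1 - rho^2)).
#'
#' @param fc_values per-subject connectivity values (>= 4).
#' @param covariate per-subject covariate values.
#' @return List with \code{rho}, \code{p}, \code{n}.
#' @export
spearman_clinical <- function(fc_values, covariate) {
  ok <- is.finite(fc_values) & is.finite(covariate)
  x <- fc_values[ok]; y <- covariate[ok]
  n <- length(x)
  if (n < 4)
    stop_megdmn("need at least 4 paired observations (got %d)", n,
                class = "megdmn_input_error")
  if (sd(y) == 0 || sd(x) == 0)
    stop_megdmn("constant covariate or connectivity: rank correlation undefined",
                class = "megdmn_degenerate_data")
  rho <- cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = max(p, .Machine$double.xmin), n = n)
}

#' Load the packaged clinical characteristics table
#'
#' A transcription of the published clinical table for the 15 operated
#' cingulate gyrus epilepsy patients (sex, ages, epilepsy onset and
#' duration, seizure frequency as printed, histopathology, MRI and surgical
#' outcome).
#'
#' @param path optional path to a TSV with the same schema.
#' @return data.frame of class \code{clinical_table}.
#' @export
cge_clinical_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cge_clinical_table.tsv",
                        package = "megdmn", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

#' Summarize a clinical cohort table
#'
#' Means and standard deviations (sample and population variants) of age and
#' epilepsy duration, sex counts, outcome proportions and histopathology
#' counts, with report values rounded to one decimal.
#'
#' @param table a \code{clinical_table} (or data.frame with the same
#'   columns).
#' @return Object of class \code{clinical_summary}.
#' @export
summarize_clinical <- function(table) {
  need <- c("sex", "age_years", "duration_years", "histopathology_label",
            "outcome_label")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_megdmn("clinical table missing column(s): %s",
                paste(miss, collapse = ", "), class = "megdmn_schema_error")
  n <- nrow(table)
  if (n == 0)
    stop_megdmn("clinical table is empty", class = "megdmn_schema_error")
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  fcd <- grepl("^FCD", table$histopathology_label)
  out <- list(
    n = n,
    age_mean = mean(table$age_years),
    age_sd_sample = sd(table$age_years),
    age_sd_population = sd_pop(table$age_years),
    duration_mean = mean(table$duration_years, na.rm = TRUE),
    duration_sd_sample = sd(table$duration_years[!is.na(table$duration_years)]),
    duration_sd_population = sd_pop(
      table$duration_years[!is.na(table$duration_years)]),
    sex_counts = table(table$sex),
    outcome_counts = table(table$outcome_label),
    seizure_free_prop = mean(table$outcome_label == "seizure_free"),
    histopathology_counts = table(table$histopathology_label),
    fcd_count = sum(fcd),
    fcd_prop = mean(fcd))
  class(out) <- "clinical_summary"
  out
}

#' @export
print.clinical_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n))
  cat(sprintf("  age: %.1f +/- %.1f years (sample SD; population SD %.1f)\n",
              x$age_mean, x$age_sd_sample, x$age_sd_population))
  cat(sprintf("  epilepsy duration: %.1f +/- %.1f years\n",
              x$duration_mean, x$duration_sd_sample))
  cat(sprintf("  sex: %s\n",
              paste(sprintf("%s=%d", names(x$sex_counts), x$sex_counts),
                    collapse = ", ")))
  cat(sprintf("  seizure-free: %d (%.0f%%)\n",
              x$outcome_counts[["seizure_free"]], 100 * x$seizure_free_prop))
  cat(sprintf("  focal cortical dysplasia: %d (%.0f%%)\n",
              x$fcd_count, 100 * x$fcd_prop))
  invisible(x)
}
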