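#' Write / read a sensor recording container
#'
#' Recordings are persisted in a documented single-object container (RDS
#' serialization of the validated \code{sensor_recording} layout: data
#' matrix, sampling rate, sensor positions/orientations, subject metadata
#' and the head-movement flag). Reading validates the layout and refuses
#' recordings flagged for head movement beyond the 5-mm exclusion limit.
#'
#' @param rec a \code{sensor_recording}.
#' @param path file path (conventionally \code{.rds}).
#' @return \code{read_recording} returns the validated
#'   \code{sensor_recording}; \code{write_recording} returns \code{path}
#'   invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- tryCatch(readRDS(path), error = function(e)
    stop_megdmn("unreadable recording container %s: %s", path,
                conditionMessage(e), class = "megdmn_format_error"))
  if (!inherits(rec, "sensor_recording"))
    stop_megdmn("%s does not contain a sensor_recording", path,
                class = "megdmn_format_error")
  rec2 <- sensor_recording(rec$data, rec$sampling_rate, rec$array,
                           rec$subject_id, rec$group, rec$moved)
  if (isTRUE(rec2$moved))
    stop_megdmn(paste("recording %s flagged for head movement > 5 mm and is",
                      "excluded from analysis"), rec2$subject_id,
                class = "megdmn_movement_exclusion")
  rec2
}

# Per-subject band-wise FC and degree from one raw recording.
subject_connectivity <- function(rec, roi_table, lf, bands, n_epochs,
                                 epoch_length, z_threshold, regularization,
                                 degree_threshold, seed, line_freq = 50) {
  rec <- notch_filter(rec, line_freq)
  eps <- segment_epochs(rec, epoch_length)
  eps <- flag_spike_epochs(eps, z_threshold)
  eps <- select_clean_epochs(eps, n_epochs, seed)
  fc <- list(); deg <- list()
  for (bn in names(bands)) {
    be <- bandpass_epochs(eps, bands[[bn]])
    sig <- extract_roi_signals(be, roi_table, lf, regularization)
    fc[[bn]] <- fc_matrix(sig$signals, band = bands[[bn]],
                          subject_id = rec$subject_id)
    deg[[bn]] <- node_degree(fc[[bn]], degree_threshold)
  }
  list(fc = fc, degree = deg,
       counts = c(total = length(eps$status),
                  spike = sum(eps$status == "spike"),
                  retained = sum(eps$status == "ok")))
}

#' Fit the DMN connectivity group comparison to a MEG cohort
#'
#' Runs the full analysis on two groups of resting-state recordings: 50-Hz
#' notch, 500-ms epoching, robust spike rejection, random selection of
#' \code{n_epochs} clean epochs, band-pass decomposition, beamformer source
#' reconstruction at the 12 DMN seed regions, Fisher-pooled Pearson
#' connectivity, node degree at the correlation threshold, and per-pair /
#' per-node two-group t-tests per band.
#'
#' @param patients,controls lists of \code{sensor_recording}s (>= 2 each),
#'   or a \code{meg_cohort} passed as \code{patients} (then \code{controls}
#'   is ignored).
#' @param roi_table DMN seed table (default the packaged 12 ROIs).
#' @param bands named list of \code{band_spec}s.
#' @param n_epochs clean epochs retained per subject.
#' @param epoch_length epoch length in seconds.
#' @param z_threshold robust-z spike rejection threshold.
#' @param regularization covariance diagonal loading fraction.
#' @param degree_threshold correlation cutoff for node degree.
#' @param alpha_level significance threshold for the group tests.
#' @param grid_spacing source grid spacing in mm.
#' @param seed master seed for the epoch subsampling.
#' @param covariates optional clinical covariate table carried on the fit.
#' @return Object of class \code{dmn_study} with per-subject \code{fc} and
#'   \code{degree} (nested group > band > subject), group statistics
#'   \code{stats_fc} and \code{stats_degree}, per-subject epoch bookkeeping
#'   and the configuration. Methods: \code{print}, \code{summary},
#'   \code{plot}.
#' @export
dmn_study <- function(patients, controls = NULL, roi_table = dmn_roi_table(),
                      bands = dmn_bands(), n_epochs = 40, epoch_length = 0.5,
                      z_threshold = 6, regularization = 0.05,
                      degree_threshold = 0.3, alpha_level = 0.05,
                      grid_spacing = 6, seed = 1, covariates = NULL) {
  if (inherits(patients, "meg_cohort")) {
    cohort <- patients
    covariates <- covariates %||% cohort$covariates
    grp <- vapply(cohort$recordings, `[[`, "", "group")
    controls <- cohort$recordings[grp == "control"]
    patients <- cohort$recordings[grp == "patient"]
  }
  if (length(patients) < 2 || length(controls) < 2)
    stop_megdmn("need at least 2 recordings per group",
                class = "megdmn_input_error")
  array <- patients[[1]]$array
  grid <- build_source_grid(array$head_radius, grid_spacing)
  vox <- unique(unlist(roi_voxel_sets(roi_table, grid)))
  lf <- compute_lead_field(grid, array, vox)
  run_group <- function(recs, offset) {
    out <- vector("list", length(recs))
    for (i in seq_along(recs))
      out[[i]] <- subject_connectivity(
        recs[[i]], roi_table, lf, bands, n_epochs, epoch_length,
        z_threshold, regularization, degree_threshold,
        seed = derive_seed(seed, offset + i, 7L))
    names(out) <- vapply(recs, `[[`, "", "subject_id")
    out
  }
  sub_p <- run_group(patients, 0L)
  sub_c <- run_group(controls, length(patients))
  by_band <- function(subs, what)
    setNames(lapply(names(bands), function(b)
      lapply(subs, function(s) s[[what]][[b]])), names(bands))
  fc_p <- by_band(sub_p, "fc"); fc_c <- by_band(sub_c, "fc")
  dg_p <- by_band(sub_p, "degree"); dg_c <- by_band(sub_c, "degree")
  res <- list(
    fc = list(patient = fc_p, control = fc_c),
    degree = list(patient = dg_p, control = dg_c),
    stats_fc = compare_fc_groups(fc_p, fc_c, alpha_level),
    stats_degree = compare_degree_groups(dg_p, dg_c, alpha_level),
    epoch_counts = rbind(
      do.call(rbind, lapply(sub_p, `[[`, "counts")),
      do.call(rbind, lapply(sub_c, `[[`, "counts"))),
    covariates = covariates, roi_table = roi_table, bands = bands,
    settings = list(n_epochs = n_epochs, epoch_length = epoch_length,
                    z_threshold = z_threshold,
                    regularization = regularization,
                    degree_threshold = degree_threshold,
                    alpha_level = alpha_level, grid_spacing = grid_spacing,
                    seed = seed),
    call = match.call())
  class(res) <- "dmn_study"
  res
}

#' @export
print.dmn_study <- function(x, ...) {
  np <- length(x$fc$patient[[1]]); nc <- length(x$fc$control[[1]])
  cat(sprintf("DMN connectivity study: %d patients vs %d controls, bands %s\n",
              np, nc, paste(names(x$bands), collapse = "/")))
  cat(sprintf("Significant pairs (p < %g, uncorrected):\n",
              x$stats_fc$alpha_level))
  print(x$stats_fc$counts, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dmn_study <- function(object, n_top = 5, ...) {
  tab <- object$stats_fc$table
  top <- tab[order(tab$p), ][seq_len(min(n_top, nrow(tab))), ]
  out <- list(counts_fc = object$stats_fc$counts,
              counts_degree = object$stats_degree$counts,
              top_pairs = top, settings = object$settings)
  class(out) <- "summary.dmn_study"
  out
}

#' @export
print.summary.dmn_study <- function(x, ...) {
  cat("Significant FC pairs per band:\n")
  print(x$counts_fc, row.names = FALSE)
  cat("Significant node degrees per band:\n")
  print(x$counts_degree, row.names = FALSE)
  cat("Most different pairs:\n")
  print(x$top_pairs, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.dmn_study <- function(x, band = names(x$bands)[1], ...) {
  mp <- Reduce(`+`, lapply(x$fc$patient[[band]], unclass)) /
    length(x$fc$patient[[band]])
  mc <- Reduce(`+`, lapply(x$fc$control[[band]], unclass)) /
    length(x$fc$control[[band]])
  d <- mp - mc
  nm <- rownames(mp)
  op <- par(mar = c(6, 6, 3, 1))
  on.exit(par(op))
  image(seq_along(nm), seq_along(nm), t(d[rev(seq_along(nm)), ]),
        axes = FALSE, xlab = "", ylab = "",
        main = sprintf("Mean FC difference (patient - control), %s band",
                       band), ...)
  axis(1, seq_along(nm), nm, las = 2, cex.axis = 0.7)
  axis(2, seq_along(nm), rev(nm), las = 2, cex.axis = 0.7)
  invisible(d)
}

#' Pipeline configuration and batch runner
#'
#' \code{pipeline_config()} bundles input paths and analysis parameters;
#' \code{run_pipeline()} reads the recordings, fits \code{\link{dmn_study}}
#' and writes per-subject FC / degree tables, group statistics and a run
#' manifest (seed, parameters, per-stage epoch counts) as TSV into
#' \code{output_dir}.
#'
#' @param recording_paths named character vector or list of container paths;
#'   names are subject ids.
#' @param groups character vector ("patient"/"control") aligned with
#'   \code{recording_paths}.
#' @param roi_table_path optional ROI table TSV (default: packaged table).
#' @param clinical_path optional clinical covariate TSV.
#' @param output_dir directory for outputs (created if needed).
#' @param bands bands to run (subset of alpha/beta/gamma).
#' @param seed master seed, recorded in every output.
#' @param ... further parameters passed to \code{\link{dmn_study}}.
#' @return \code{run_pipeline} returns the fitted \code{dmn_study}
#'   invisibly.
#' @export
pipeline_config <- function(recording_paths, groups, roi_table_path = NULL,
                            clinical_path = NULL, output_dir = tempdir(),
                            bands = c("alpha", "beta", "gamma"), seed = 1,
                            ...) {
  stopifnot(length(recording_paths) == length(groups),
            all(groups %in% c("patient", "control")))
  missing_files <- !file.exists(unlist(recording_paths))
  if (any(missing_files))
    stop_megdmn("missing recording file(s): %s",
                paste(unlist(recording_paths)[missing_files], collapse = ", "),
                class = "megdmn_config_error")
  if (!is.null(roi_table_path) && !file.exists(roi_table_path))
    stop_megdmn("ROI table not found: %s", roi_table_path,
                class = "megdmn_config_error")
  structure(list(recording_paths = recording_paths, groups = groups,
                 roi_table_path = roi_table_path,
                 clinical_path = clinical_path, output_dir = output_dir,
                 bands = bands, seed = seed, extra = list(...)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  roi <- if (is.null(config$roi_table_path)) dmn_roi_table() else
    load_roi_table(config$roi_table_path)
  cov <- if (is.null(config$clinical_path)) NULL else
    cge_clinical_table(config$clinical_path)
  recs <- lapply(unlist(config$recording_paths), read_recording)
  bands <- dmn_bands()[config$bands]
  fit <- do.call(dmn_study, c(
    list(patients = recs[config$groups == "patient"],
         controls = recs[config$groups == "control"],
         roi_table = roi, bands = bands, seed = config$seed,
         covariates = cov),
    config$extra))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name)
    write.table(df, file.path(config$output_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  fc_long <- do.call(rbind, lapply(c("patient", "control"), function(g)
    do.call(rbind, lapply(names(fit$fc[[g]]), function(b)
      do.call(rbind, lapply(fit$fc[[g]][[b]], function(m) {
        pr <- pair_index(rownames(m))
        data.frame(subject_id = attr(m, "subject_id"), group = g, band = b,
                   roi_a = pr$roi_a, roi_b = pr$roi_b,
                   r = m[cbind(pr$i, pr$j)], stringsAsFactors = FALSE)
      }))))))
  wtsv(fc_long, "fc_long.tsv")
  deg_long <- do.call(rbind, lapply(c("patient", "control"), function(g)
    do.call(rbind, lapply(names(fit$degree[[g]]), function(b)
      do.call(rbind, lapply(fit$degree[[g]][[b]], function(d)
        data.frame(subject_id = attr(d, "subject_id"), group = g, band = b,
                   roi = names(d), degree = as.numeric(d),
                   stringsAsFactors = FALSE)))))))
  wtsv(deg_long, "degree_long.tsv")
  wtsv(fit$stats_fc$table, "stats_fc.tsv")
  wtsv(fit$stats_degree$table, "stats_degree.tsv")
  wtsv(fit$stats_fc$counts, "stats_fc_counts.tsv")
  manifest <- data.frame(
    key = c("package_version", "seed", "bands", "n_subjects",
            names(fit$settings)),
    value = c(as.character(utils::packageVersion("megdmn")),
              config$seed, paste(config$bands, collapse = ","),
              length(recs),
              vapply(fit$settings, function(v) paste(v, collapse = ","), "")),
    stringsAsFactors = FALSE)
  wtsv(manifest, "manifest.tsv")
  wtsv(cbind(subject_id = rownames(fit$epoch_counts),
             as.data.frame(fit$epoch_counts)), "epoch_counts.tsv")
  invisible(fit)
}
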