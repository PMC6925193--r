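# Pipeline configuration and the end-to-end transect run.

#' Pipeline configuration
#'
#' Every tunable of the transect pipeline in one round-trippable object.
#' Defaults are the conventional values: S/N > 6 (strict), 0.5 ppm
#' assignment tolerance, the standard DOM atomic constraints, significance
#' at p < 0.05, parameter selection at > 200 significant correlations, and
#' |r| > 0.7 Van Krevelen highlighting.
#'
#' @param max_c,max_h,max_n,max_s,o_min,o_max,oc_max,hc_max Atomic
#'   constraints (see [atomic_constraints()]).
#' @param tol_ppm Assignment tolerance, ppm.
#' @param snr_min S/N threshold (strict).
#' @param alpha Correlation significance level.
#' @param min_significant Parameter-selection count threshold (strict).
#' @param r_threshold Van Krevelen highlight threshold (strict).
#' @param exclude Station ids excluded from correlation analysis (e.g. a
#'   known outlier station); default none.
#' @param n_components Trilinear components fitted to the EEM stack.
#' @param n_starts Trilinear multistarts.
#' @param seed Seed for every stochastic step.
#' @param input_dir,output_dir Optional I/O paths.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(max_c = 120L, max_h = 200L, max_n = 2L,
                            max_s = 1L, o_min = 1L, o_max = 60L,
                            oc_max = 1, hc_max = 2, tol_ppm = 0.5,
                            snr_min = 6, alpha = 0.05,
                            min_significant = 200L, r_threshold = 0.7,
                            exclude = character(), n_components = 3L,
                            n_starts = 10L, seed = 1L,
                            input_dir = NULL, output_dir = NULL) {
  structure(list(max_c = max_c, max_h = max_h, max_n = max_n, max_s = max_s,
                 o_min = o_min, o_max = o_max, oc_max = oc_max,
                 hc_max = hc_max, tol_ppm = tol_ppm, snr_min = snr_min,
                 alpha = alpha, min_significant = min_significant,
                 r_threshold = r_threshold, exclude = exclude,
                 n_components = n_components, n_starts = n_starts,
                 seed = seed, input_dir = input_dir,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @return `config_constraints()` the [atomic_constraints()] the config
#'   implies.
#' @export
config_constraints <- function(config) {
  atomic_constraints(max_c = config$max_c, max_h = config$max_h,
                     max_n = config$max_n, max_s = config$max_s,
                     o_range = c(config$o_min, config$o_max),
                     oc_max = config$oc_max, hc_max = config$hc_max,
                     tol_ppm = config$tol_ppm, snr_min = config$snr_min)
}

#' Read / write pipeline configuration (YAML)
#'
#' The configuration round-trips losslessly through a human-readable YAML
#' file.
#'
#' @param path File path.
#' @return `read_pipeline_config()` a `pipeline_config`;
#'   `write_pipeline_config()` the path, invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, vals[!vapply(vals, is.null, TRUE)])
  cfg$exclude <- as.character(cfg$exclude)
  cfg
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  write_pipeline_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the full transect pipeline
#'
#' Executes, per station: S/N + window filter, charge determination,
#' internal recalibration, formula assignment, ensemble profiling; then
#' the cross-sample stages: common/unique formula subspaces, optical
#' descriptors (spectral slopes, FIR ratios, trilinear component ratios)
#' when spectra/EEMs are supplied, and the Spearman correlation map with
#' parameter selection and Van Krevelen overlays. Any stage failure aborts
#' naming the stage and the offending sample.
#'
#' @param data A list like the output of [simulate_transect()]:
#'   `peaklists` (list of `mass_peaklist`), `hydro` (`hydro_table`), and
#'   optionally `absorption` (list of `absorption_spectrum`) and
#'   `eem$eems` (list of `eem`).
#' @param config A [pipeline_config()].
#' @return A report bundle (list): `assignments`, `ensembles`,
#'   `number_averaged` (per-station descriptor table), `class_density`
#'   (per-station density table), `common`, `unique_keys`, `optics`
#'   (per-station optical descriptors), `parafac`, `component_ratios`,
#'   `correlation_map`, `selected_parameters`, `overlays`, `hydro_matrix`,
#'   `log`.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, sample, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for sample '%s': %s",
                   name, sample, conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(data$peaklists)) stop("pipeline stage 'input' failed: no peak lists")
  cons <- config_constraints(config)
  log_lines <- c(sprintf("domtransect %s | R %s",
                         as.character(utils::packageVersion("domtransect")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("config_hash %s | seed %d", config_hash(config),
                         config$seed))
  assignments <- vector("list", length(data$peaklists))
  for (i in seq_along(data$peaklists)) {
    pl <- data$peaklists[[i]]
    id <- pl$sample_id
    pl <- stage("filter", id, filter_peaks(pl, snr_min = config$snr_min))
    n_filtered <- nrow(pl$peaks)
    pl <- stage("charge", id, drop_multicharged(determine_charge(pl)))
    pl <- stage("calibrate", id, recalibrate(pl))
    if (pl$calibration != "calibrated") {
      stop(sprintf("pipeline stage 'calibrate' failed for sample '%s': %s",
                   id, "calibration refused"), call. = FALSE)
    }
    a <- stage("assign", id,
               assign_formulae(pl, cons, tol_ppm = config$tol_ppm))
    assignments[[i]] <- a
    log_lines <- c(log_lines, sprintf(
      "%s: %d peaks post-filter | cal RMS %.3f ppm | %d assigned | %d unassigned | %d ambiguous",
      id, n_filtered, pl$calibration_rms_ppm, nrow(a),
      attr(a, "n_unassigned"), attr(a, "n_ambiguous")))
  }
  ensembles <- lapply(assignments, function(a)
    stage("profile", attr(a, "sample_id"), as_sample_ensemble(a)))
  tab2 <- do.call(rbind, lapply(ensembles, number_averaged))
  tab3 <- do.call(rbind, lapply(ensembles, class_densities))
  common <- stage("common", "all", common_formulae(ensembles))
  uniq <- stage("unique", "all", unique_formulae(ensembles))
  uniq_keys <- lapply(uniq, formula_key)
  log_lines <- c(log_lines, sprintf("common formulae: %d", nrow(common)))
  optics_tbl <- NULL
  if (!is.null(data$absorption)) {
    optics_tbl <- do.call(rbind, lapply(data$absorption, function(sp) {
      stage("optics", sp$sample_id, {
        a254 <- absorption_coefficient(sp, 254)
        data.frame(sample_id = sp$sample_id, a254 = a254,
                   s_275_295 = spectral_slope(sp, c(275, 295))$s,
                   s_350_400 = spectral_slope(sp, c(350, 400))$s,
                   sr = slope_ratio(sp))
      })
    }))
  }
  model <- ratios <- fir <- NULL
  eems <- data$eem$eems
  if (!is.null(eems)) {
    fir <- do.call(rbind, lapply(eems, function(e)
      stage("optics", e$sample_id,
            as.data.frame(c(list(sample_id = e$sample_id),
                            as.list(fir_descriptors(e)))))))
    model <- stage("parafac", "all",
                   fit_trilinear(eems, config$n_components,
                                 seed = config$seed,
                                 n_starts = config$n_starts))
    ratios <- if (config$n_components == 3L) component_ratios(model)
    log_lines <- c(log_lines, sprintf("trilinear R2: %.4f",
                                      model$variance_explained))
  }
  if (is.null(data$hydro)) {
    stop("pipeline stage 'correlation' failed for sample 'all': missing hydrochemistry",
         call. = FALSE)
  }
  cmap <- stage("correlation", "all",
                spearman_map(ensembles, data$hydro, common = common,
                             alpha = config$alpha,
                             exclude = config$exclude))
  selected <- select_parameters(cmap, config$min_significant)
  overlays <- lapply(selected, function(p)
    vk_overlay(cmap, p, config$r_threshold))
  names(overlays) <- selected
  hmat <- hydro_matrix(data$hydro[!(data$hydro$station_id %in%
                                      config$exclude), , drop = FALSE])
  log_lines <- c(log_lines,
                 sprintf("selected parameters (> %d significant): %s",
                         config$min_significant,
                         paste(selected, collapse = ", ")))
  list(assignments = assignments, ensembles = ensembles,
       number_averaged = tab2, class_density = tab3, common = common,
       unique_keys = uniq_keys, optics = optics_tbl, fir = fir,
       parafac = model, component_ratios = ratios,
       correlation_map = cmap, selected_parameters = selected,
       overlays = overlays, hydro_matrix = hmat, log = log_lines,
       config = config)
}

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)

#' Write a report bundle to delimited text files
#'
#' Emits the per-station descriptor table, the class-density table
#' (3 decimals), the optical/ratio tables (2 decimals), the Van Krevelen
#' overlays and the run log into `dir`, each table headed by a comment
#' block recording the configuration hash.
#'
#' @param bundle The output of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(bundle$config)
  emit <- function(df, file) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(sprintf("# config_hash: %s", hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  tab2 <- bundle$number_averaged
  for (cl in c("pct_cho", "pct_chon", "pct_chos", "pct_chnos")) {
    tab2[[cl]] <- fmt_num(tab2[[cl]], 1)
  }
  tab2$m_n <- fmt_num(tab2$m_n, 0)
  for (cl in c("oc_n", "hc_n")) tab2[[cl]] <- fmt_num(tab2[[cl]], 2)
  tab2$dbe_n <- fmt_num(tab2$dbe_n, 1)
  emit(tab2, "number_averaged.tsv")
  tab3 <- bundle$class_density
  for (cl in COMPOUND_CLASSES) tab3[[cl]] <- fmt_num(tab3[[cl]], 3)
  emit(tab3, "class_density.tsv")
  if (!is.null(bundle$optics)) {
    opt <- bundle$optics
    opt$a254 <- fmt_num(opt$a254, 2)
    opt$sr <- fmt_num(opt$sr, 2)
    opt$s_275_295 <- fmt_num(opt$s_275_295, 5)
    opt$s_350_400 <- fmt_num(opt$s_350_400, 5)
    emit(opt, "optics.tsv")
  }
  if (!is.null(bundle$component_ratios)) {
    cr <- bundle$component_ratios
    for (cl in setdiff(names(cr), "sample_id")) cr[[cl]] <- fmt_num(cr[[cl]], 2)
    emit(cr, "component_ratios.tsv")
  }
  for (p in names(bundle$overlays)) {
    ov <- bundle$overlays[[p]]
    ov$r <- fmt_num(ov$r, 3)
    ov$p <- format(ov$p, digits = 3)
    emit(ov, sprintf("vk_overlay_%s.tsv", p))
  }
  emit(data.frame(key = formula_key(bundle$common),
                  mass = fmt_num(bundle$common$mass, 6)),
       "common_formulae.tsv")
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
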