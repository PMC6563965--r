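#' Configuration for a full before/after-correction analysis run
#'
#' @param scenario synthetic scenario name (`"default"`,
#'   `"missing_lower"`, `"subject10"`), or `NULL` when supplying NIfTI
#'   input.
#' @param nifti optional real-data input: a named list with one 4-D NIfTI
#'   path per protocol (names among bowtie/ring/bar/fullfield, must include
#'   `fullfield`), plus `mask` (3-D NIfTI path or logical array).
#' @param seed integer seed (drives the synthetic generator).
#' @param lattice synthetic lattice size.
#' @param flip_threshold correlation magnitude for [flip_timecourses()].
#' @param density_threshold coverage density threshold in (0, 1).
#' @param completeness_cutoff completeness cutoff in percent.
#' @param ve_floor variance-explained floor for usable fits.
#' @param detect_eclipse run automated eclipse detection (synthetic/lattice
#'   input only); a manual [eclipse_roi()] may be given as `eclipse`.
#' @param eclipse optional manual [eclipse_roi()].
#' @param eclipse_source `"detect"` (default; automated detection on the
#'   integrated mean map), `"truth"` (synthetic input only: use the
#'   generator's ground-truth eclipse as a manual ROI) or `"none"`.
#' @param fit_protocols mapping runs fitted jointly by the pRF stage.
#' @param allow_negative permit negative pRF amplitudes (default `FALSE`).
#' @param flip_nbr also keep NBR-band voxels in the corrected coverage
#'   (the map-extension demonstration); by default the NBR band is excluded
#'   from area analyses.
#' @param tr fallback repetition time in seconds for NIfTI input.
#' @param hrf an [hrf_model()].
#' @param prf_control optimiser control list passed to [fit_prf()].
#' @param out_dir optional output directory for the config echo, report
#'   JSON and fit tables.
#' @param log_level `"info"`, `"debug"` or `"quiet"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(scenario = "default", nifti = NULL, seed = 1L,
                       lattice = c(30, 30), flip_threshold = 0,
                       density_threshold = 0.8, completeness_cutoff = 20,
                       ve_floor = 0.1, detect_eclipse = TRUE,
                       eclipse = NULL,
                       eclipse_source = c("detect", "truth", "none"),
                       fit_protocols = c("bowtie", "ring", "bar"),
                       allow_negative = FALSE, flip_nbr = FALSE,
                       tr = 2, hrf = hrf_model(), prf_control = list(),
                       out_dir = NULL, log_level = "info") {
  if (is.null(nifti) &&
      !scenario %in% c("default", "missing_lower", "subject10"))
    stop("unknown scenario: ", scenario)
  if (flip_threshold < 0) stop("flip_threshold must be non-negative")
  if (density_threshold <= 0 || density_threshold >= 1)
    stop("density_threshold must lie in (0, 1)")
  if (completeness_cutoff < 0 || completeness_cutoff > 100)
    stop("completeness_cutoff must lie in [0, 100]")
  if (!log_level %in% c("quiet", "info", "debug"))
    stop("log_level must be quiet, info or debug")
  eclipse_source <- match.arg(eclipse_source)
  structure(list(scenario = scenario, nifti = nifti, seed = as.integer(seed),
                 lattice = as.integer(lattice),
                 flip_threshold = flip_threshold,
                 density_threshold = density_threshold,
                 completeness_cutoff = completeness_cutoff,
                 ve_floor = ve_floor, detect_eclipse = detect_eclipse,
                 eclipse = eclipse, eclipse_source = eclipse_source,
                 fit_protocols = fit_protocols,
                 allow_negative = allow_negative, flip_nbr = flip_nbr,
                 tr = tr, hrf = hrf, prf_control = prf_control,
                 out_dir = out_dir, log_level = log_level),
            class = "run_config")
}

pipe_log <- function(config, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[config$log_level]] >= lv[[level]])
    message("[", level, "] ", ...)
  invisible(NULL)
}

#' Congruence between lower-quadrant completeness and eclipse presence
#'
#' A hemisphere-analogue pairing is *incongruent* when the measured
#' lower-quadrant status contradicts the venous-artefact explanation:
#' an incomplete lower quadrant with no eclipse, or a complete lower
#' quadrant despite an eclipse.
#'
#' @param lower_complete logical.
#' @param eclipse_present logical.
#' @return `"congruent"` or `"incongruent"`.
#' @export
congruence_label <- function(lower_complete, eclipse_present) {
  inc <- (!lower_complete & !eclipse_present) |
    (lower_complete & eclipse_present)
  ifelse(inc, "incongruent", "congruent")
}

#' Run the full before/after-correction analysis
#'
#' Orchestrates: simulation (or NIfTI ingestion) -> normalised mean map ->
#' correlation against the full-field reference -> eclipse ROI (manual or
#' detected) -> inverted-voxel flipping -> pRF fits on the original and
#' corrected mapping runs -> per-area quadrant coverage and completeness
#' before/after -> hV4 angle-map smoothness before/after -> inverted-voxel
#' fractions per area (and per depth layer inside the eclipse, when depth
#' layers exist) -> lower-quadrant/eclipse congruence.
#'
#' @param config a [run_config()].
#' @return an object of class `run_report`; see its `print` method. When
#'   `config$out_dir` is set, the config echo (YAML), the report (JSON) and
#'   the fit tables (TSV) are written there as well.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  res <- try({
    inp <- pipeline_input(config)
    stage <- "mean map"
    mmap <- normalized_mean_map(inp$fullfield)
    stage <- "correlation"
    ref <- reference_waveform(make_protocol("fullfield"), config$hrf)
    cmap <- correlate_reference(inp$fullfield, ref)
    pipe_log(config, "info", sum(cmap$label == "inverted"),
             " negatively correlated voxels of ", length(cmap$r))

    stage <- "eclipse ROI"
    eclipse <- config$eclipse
    if (is.null(eclipse) && config$eclipse_source == "truth" &&
        !is.null(inp$patch)) {
      eclipse <- eclipse_roi(inp$patch$eclipse_voxels,
                             provenance = "manual", layer = "integrated")
    }
    if (is.null(eclipse) && config$eclipse_source == "detect" &&
        config$detect_eclipse && !is.null(inp$lattice)) {
      eclipse <- detect_eclipse(mmap, inp$lattice)
    }
    eclipse_present <- !is.null(eclipse) && length(eclipse$voxels) > 0

    stage <- "flip"
    mapping_orig <- inp$mapping
    corrected <- lapply(mapping_orig, flip_timecourses, cmap = cmap,
                        threshold = config$flip_threshold)
    n_flipped <- length(attr(corrected[[1]], "flipped"))
    pipe_log(config, "info", "flipped ", n_flipped, " voxels (threshold ",
             config$flip_threshold, ")")

    stage <- "pRF fit (original)"
    concat <- function(sl) do.call(cbind, sl)
    fit_orig <- fit_prf(concat(mapping_orig), inp$movies, model = config$hrf,
                        allow_negative = config$allow_negative,
                        ve_floor = config$ve_floor,
                        control = config$prf_control)
    stage <- "pRF fit (corrected)"
    fit_corr <- fit_prf(concat(corrected), inp$movies, model = config$hrf,
                        allow_negative = config$allow_negative,
                        ve_floor = config$ve_floor,
                        control = config$prf_control, corrected = TRUE)

    stage <- "coverage"
    quad <- quadrant_spec(inp$hemifield)
    coverage <- list()
    for (ar in names(inp$areas)) {
      if (ar == "periphery" && !config$flip_nbr) next
      roi <- inp$areas[[ar]]
      cov1 <- area_coverage(fit_orig, roi, quad, config)
      cov2 <- area_coverage(fit_corr, roi, quad, config)
      coverage[[ar]] <- list(before = cov1, after = cov2)
    }

    stage <- "smoothness"
    smooth <- NULL
    if (!is.null(inp$lattice) && "hV4" %in% names(inp$areas)) {
      s_pre <- smoothness(render_angle_map(fit_orig, inp$lattice,
                                           inp$areas$hV4))
      s_post <- smoothness(render_angle_map(fit_corr, inp$lattice,
                                            inp$areas$hV4))
      smooth <- list(before = s_pre$smoothness, after = s_post$smoothness,
                     percent_smoother = percent_smoother(s_pre, s_post))
    }

    stage <- "inverted fractions"
    area_regions <- inp$areas[setdiff(names(inp$areas), "periphery")]
    inv_area <- inverted_fraction_by_region(cmap, area_regions)
    inv_depth <- NULL
    if (!is.null(inp$layer_fullfield) && eclipse_present) {
      inv_depth <- do.call(rbind, lapply(names(inp$layer_fullfield),
        function(layer) {
          cm <- correlate_reference(inp$layer_fullfield[[layer]], ref)
          df <- inverted_fraction_by_region(
            cm, list(eclipse = eclipse$voxels))
          df$layer <- layer
          df
        }))
    }

    stage <- "congruence"
    lower_complete <- list()
    for (ar in names(coverage)) {
      lower_complete[[ar]] <- list(
        before = coverage[[ar]]$before$complete[4],
        after = coverage[[ar]]$after$complete[4])
    }
    congruence <- NULL
    if ("hV4" %in% names(coverage)) {
      congruence <- list(
        before = congruence_label(lower_complete$hV4$before,
                                  eclipse_present),
        after = congruence_label(lower_complete$hV4$after,
                                 eclipse_present))
    }

    report <- structure(list(
      config = config, hemifield = inp$hemifield,
      n_voxels = length(cmap$r), n_flipped = n_flipped,
      eclipse_present = eclipse_present, eclipse = eclipse,
      coverage = coverage, smoothness = smooth,
      inverted_by_area = inv_area, inverted_by_depth = inv_depth,
      congruence = congruence,
      fits = list(before = fit_orig, after = fit_corr),
      correlation = cmap, mean_map = mmap),
      class = "run_report")
    if (!is.null(config$out_dir)) write_report(report, config$out_dir)
    report
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message)
  res
}

# internal: coverage report of one area ROI under the config's thresholds
area_coverage <- function(fit, roi, quad, config) {
  f <- fit$fits[roi, , drop = FALSE]
  usable <- !is.na(f$variance_explained) &
    f$variance_explained >= config$ve_floor
  if (!any(usable)) {
    rep0 <- data.frame(sector = quad$sectors, percent = 0)
    rep0 <- structure(rep0, class = c("coverage_report", "data.frame"),
                      hemifield = quad$hemifield,
                      density_threshold = config$density_threshold,
                      max_ecc = 5.5)
    return(classify_completeness(rep0, config$completeness_cutoff))
  }
  dens <- prf_density(f, mode = "max", ve_floor = config$ve_floor)
  cov <- quadrant_coverage(dens, quad,
                           threshold = config$density_threshold)
  classify_completeness(cov, config$completeness_cutoff)
}

# internal: resolve the configured input into series + geometry
pipeline_input <- function(config) {
  if (!is.null(config$nifti)) return(pipeline_input_nifti(config))
  spec <- patch_spec(lattice = config$lattice, scenario = config$scenario,
                     seed = config$seed)
  patch <- make_retinotopic_patch(spec)
  sim <- simulate_bold(patch,
                       protocols = unique(c(config$fit_protocols,
                                            "fullfield")),
                       model = config$hrf)
  list(fullfield = sim$integrated$fullfield,
       mapping = sim$integrated[config$fit_protocols],
       movies = sim$movies[config$fit_protocols],
       layer_fullfield = lapply(sim$series, `[[`, "fullfield"),
       lattice = spec$lattice, areas = patch$areas,
       hemifield = patch$hemifield, patch = patch)
}

pipeline_input_nifti <- function(config) {
  paths <- config$nifti
  if (is.null(paths$fullfield))
    stop("NIfTI input must include a 'fullfield' run")
  mask <- paths$mask
  prot_names <- intersect(names(paths), c("bowtie", "ring", "bar",
                                          "fullfield"))
  series <- lapply(paths[prot_names], function(p)
    load_nifti_series(p, mask, tr = config$tr)$series)
  mapping <- series[intersect(config$fit_protocols, names(series))]
  if (length(mapping) == 0)
    stop("no mapping runs among the NIfTI inputs match fit_protocols")
  movies <- lapply(names(mapping), function(p)
    render_apertures(make_protocol(p)))
  names(movies) <- names(mapping)
  list(fullfield = series$fullfield, mapping = mapping, movies = movies,
       layer_fullfield = NULL, lattice = NULL,
       areas = list(all = seq_len(nrow(series$fullfield))),
       hemifield = "right", patch = NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$n_voxels, "voxels;", x$n_flipped,
      "flipped; eclipse", if (x$eclipse_present) "present" else "absent",
      "\n")
  for (ar in names(x$coverage)) {
    b <- x$coverage[[ar]]$before; a <- x$coverage[[ar]]$after
    cat(sprintf("  %-9s lower quadrant: %5.1f%% (%s) -> %5.1f%% (%s)\n",
                ar, b$percent[4],
                ifelse(b$complete[4], "complete", "incomplete"),
                a$percent[4],
                ifelse(a$complete[4], "complete", "incomplete")))
  }
  if (!is.null(x$smoothness))
    cat("  hV4 smoothness:", signif(x$smoothness$before, 4), "->",
        signif(x$smoothness$after, 4), "(",
        signif(x$smoothness$percent_smoother, 3), "% smoother )\n")
  if (!is.null(x$congruence))
    cat("  congruence before/after:", x$congruence$before, "/",
        x$congruence$after, "\n")
  invisible(x)
}

# internal: serialise a run report
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  cfg_list <- unclass(cfg)
  cfg_list$hrf <- unclass(cfg_list$hrf)
  cfg_list$eclipse <- if (!is.null(cfg_list$eclipse))
    unclass(cfg_list$eclipse)[c("voxels", "provenance", "layer")]
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  cov <- lapply(report$coverage, function(cc) list(
    before = list(percent = cc$before$percent,
                  complete = cc$before$complete),
    after = list(percent = cc$after$percent,
                 complete = cc$after$complete)))
  js <- list(n_voxels = report$n_voxels, n_flipped = report$n_flipped,
             eclipse_present = report$eclipse_present,
             coverage = cov, smoothness = report$smoothness,
             inverted_by_area = report$inverted_by_area,
             congruence = report$congruence)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$fits$before$fits,
                     file.path(out_dir, "prf_fits_original.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$fits$after$fits,
                     file.path(out_dir, "prf_fits_corrected.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
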