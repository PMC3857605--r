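#' Run the full efficiency analysis
#'
#' Loads or generates a cohort, computes normalized nodal global and nodal
#' local efficiency for every subject, fits the three per-region contrasts
#' (`icv`, `group`, `icv_x_group`) for both measures with FDR correction,
#' and writes all maps plus a t-map cosine-similarity report and a run
#' manifest to `output_dir`. Identical config and seed give byte-identical
#' outputs.
#'
#' @param config A [generator_config()] (synthetic mode); ignored when
#'   `input_dir` is given.
#' @param input_dir Optional cohort directory laid out as by
#'   [write_cohort()] (real-data mode).
#' @param output_dir Directory for maps, similarity report, and manifest.
#' @param weighted Use strength-informed weighted distances (default
#'   `TRUE`, the primary analysis).
#' @param q_level FDR level (default 0.05).
#' @param seed Overrides the config's master seed if given.
#' @param verbose Log stage progress (default `FALSE`).
#' @return The run manifest (a list of class `neteff_manifest`), invisibly.
#' @export
run_pipeline <- function(config = generator_config(), input_dir = NULL,
                         output_dir, weighted = TRUE, q_level = 0.05,
                         seed = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(input_dir)) {
    say("stage generate: synthetic cohort (seed %d)", config$seed)
    cohort <- generate_cohort(config)
  } else {
    say("stage load: reading cohort from %s", input_dir)
    cohort <- read_cohort(input_dir)
  }

  for (sid in names(cohort$connectomes)) {
    report <- validate_connectome(cohort$connectomes[[sid]])
    if (nrow(report) > 0) {
      abort(sprintf("stage validate: subject %s fails connectome checks (%s)",
                    sid, report$violation[1]),
            class = "neteff_error_pipeline")
    }
  }

  say("stage efficiency: %d subjects x %d regions (weighted = %s)",
      length(cohort$connectomes), nrow(cohort$atlas), weighted)
  eff <- compute_efficiency(cohort$connectomes, weighted = weighted)

  measures <- c("nodal_local", "nodal_global")
  contrasts <- c("icv", "group", "icv_x_group")
  files <- character()
  fits <- list()
  for (ms in measures) {
    for (ct in contrasts) {
      say("stage fit: %s ~ %s", ms, ct)
      res <- fit_region_models(eff, cohort$subjects, contrast = ct,
                               measure = ms, q_level = q_level,
                               atlas = cohort$atlas)
      fits[[paste(ms, ct, sep = ".")]] <- res
      path <- file.path(output_dir, paste0(ms, "_", ct, ".csv"))
      write_region_stats(res, path)
      files <- c(files, path)
    }
  }

  sim <- purrr::map(measures, function(ms) {
    tibble::tibble(
      measure = ms,
      pair = "icv_vs_group",
      cosine = cosine_similarity(fits[[paste(ms, "icv", sep = ".")]]$t,
                                 fits[[paste(ms, "group", sep = ".")]]$t)
    )
  }) |> dplyr::bind_rows()
  sim_path <- file.path(output_dir, "similarity.csv")
  writeLines(c("measure,pair,cosine",
               paste(sim$measure, sim$pair, fmt_num(sim$cosine), sep = ",")),
             sim_path)
  files <- c(files, sim_path)

  manifest <- list(
    package = "neteff",
    version = as.character(utils::packageVersion("neteff")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = if (is.null(input_dir)) "synthetic" else "real-data",
    weighted = weighted,
    q_level = q_level,
    seed = config$seed,
    config = if (is.null(input_dir)) unclass(config),
    n_subjects = nrow(cohort$subjects),
    n_regions = nrow(cohort$atlas),
    output_dir = output_dir,
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  class(manifest) <- "neteff_manifest"
  say("stage done: %d files in %s", length(files) + 1, output_dir)
  invisible(manifest)
}

#' Summarize a completed run
#'
#' Produces the human-readable per-contrast counts of FDR-significant
#' regions by t-statistic sign, plus the t-map cosine similarities.
#'
#' @param manifest A `neteff_manifest` from [run_pipeline()], or the path to
#'   a `manifest.json`.
#' @return The report as a character vector (one line per element),
#'   invisibly; the report is also printed.
#' @export
summarize_run <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest)
  }
  needed <- c("output_dir", "files", "q_level", "n_regions")
  if (!all(needed %in% names(manifest))) {
    abort(paste0("incomplete manifest; missing: ",
                 paste(setdiff(needed, names(manifest)), collapse = ", ")),
          class = "neteff_error_pipeline")
  }
  out_dir <- manifest$output_dir
  lines <- c(sprintf("neteff run (%s mode, seed %s, q <= %s)",
                     manifest$mode, manifest$seed, manifest$q_level))
  for (f in setdiff(names(manifest$files), "similarity.csv")) {
    path <- file.path(out_dir, f)
    if (!file.exists(path)) {
      abort(paste0("manifest references missing file: ", f),
            class = "neteff_error_pipeline")
    }
    df <- read_region_stats(path)
    lines <- c(lines, sprintf(
      "  %-28s significant: %d/%d negative, %d/%d positive",
      sub("\\.csv$", "", f),
      sum(df$significant & df$t < 0), nrow(df),
      sum(df$significant & df$t > 0), nrow(df)))
  }
  sim <- readr::read_csv(file.path(out_dir, "similarity.csv"),
                         show_col_types = FALSE, progress = FALSE)
  for (i in seq_len(nrow(sim))) {
    lines <- c(lines, sprintf("  cosine(t_icv, t_group) [%s] = %.4f",
                              sim$measure[i], sim$cosine[i]))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Monte-Carlo calibration of the region-wise FDR procedure
#'
#' Repeatedly generates cohorts, runs the efficiency analysis and region
#' fits, and records per replicate how many regions were declared
#' significant. With a null configuration ([null_config()]) every discovery
#' is false, so the per-replicate false discovery proportion is 1 if any
#' region is significant and 0 otherwise.
#'
#' @param config Generator configuration for each replicate.
#' @param n_reps Number of replicates.
#' @param contrasts Contrasts to evaluate.
#' @param measures Efficiency measures to evaluate.
#' @param weighted Weighted distances (default `TRUE`).
#' @param q_level FDR level (default 0.05).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return A tibble with one row per replicate x measure x contrast:
#'   `rep`, `measure`, `contrast`, `n_sig`, `n_sig_positive`, `fdp`.
#' @export
calibrate_fdr <- function(config = null_config(), n_reps = 200,
                          contrasts = c("icv", "group", "icv_x_group"),
                          measures = c("nodal_local", "nodal_global"),
                          weighted = TRUE, q_level = 0.05, seed = 1L) {
  rows <- purrr::map(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- as.integer((seed + r) %% 2147483629)
    cohort <- generate_cohort(cfg)
    eff <- compute_efficiency(cohort$connectomes, weighted = weighted)
    purrr::map(measures, function(ms) {
      purrr::map(contrasts, function(ct) {
        res <- fit_region_models(eff, cohort$subjects, contrast = ct,
                                 measure = ms, q_level = q_level)
        tibble::tibble(rep = r, measure = ms, contrast = ct,
                       n_sig = sum(res$significant),
                       n_sig_positive = sum(res$significant & res$t > 0),
                       fdp = as.numeric(any(res$significant)))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
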