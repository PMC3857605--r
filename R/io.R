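# On-disk conventions: connectome matrices are tab-delimited text with a
# single header row of region ids, in atlas order (ascending region_id);
# numeric output carries 12 significant digits so write -> read round-trips
# to well below 1e-10. Subject tables and stats maps are CSV.

fmt_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g", mode = "double")
  gsub(" ", "", out)
}

write_matrix_tsv <- function(M, ids, path) {
  header <- paste(ids, collapse = "\t")
  body <- apply(M, 1, function(row) paste(fmt_num(row), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE, sep = "\t")
  M <- as.matrix(df)
  ids <- suppressWarnings(as.integer(colnames(df)))
  list(M = unname(M), ids = ids)
}

#' Read a connectome strength/length matrix pair
#'
#' Both files are N x N tab-delimited numeric tables whose single header row
#' carries the region ids in atlas order. Lengths are retained only where
#' the corresponding strength is positive.
#'
#' @param strength_path,length_path Paths to the TSV matrices.
#' @param atlas The [region_atlas()] the matrices must conform to.
#' @return A validated `neteff_connectome`.
#' @export
read_connectome_pair <- function(strength_path, length_path, atlas) {
  s <- read_matrix_tsv(strength_path)
  l <- read_matrix_tsv(length_path)
  n_atlas <- nrow(atlas)
  for (part in list(list(x = s, what = "strength"),
                    list(x = l, what = "length"))) {
    if (nrow(part$x$M) != n_atlas || ncol(part$x$M) != n_atlas) {
      abort(sprintf("%s matrix is %dx%d but the atlas has %d regions",
                    part$what, nrow(part$x$M), ncol(part$x$M), n_atlas),
            class = "neteff_error_io")
    }
    if (any(is.na(part$x$ids)) || !identical(part$x$ids, atlas$region_id)) {
      offending <- part$x$ids[is.na(part$x$ids) | part$x$ids != atlas$region_id]
      abort(paste0(part$what, " header region ids do not match the atlas; ",
                   "offending ids: ",
                   paste(unique(offending), collapse = ", ")),
            class = "neteff_error_io")
    }
  }
  if (any(s$M < 0)) {
    abort("negative entries in strength matrix", class = "neteff_error_io")
  }
  if (any(l$M < 0)) {
    abort("negative entries in length matrix", class = "neteff_error_io")
  }
  connectome(s$M, l$M, region_ids = atlas$region_id)
}

#' @param conn A `neteff_connectome`.
#' @rdname read_connectome_pair
#' @export
write_connectome_pair <- function(conn, strength_path, length_path) {
  write_matrix_tsv(conn$W, conn$region_ids, strength_path)
  write_matrix_tsv(conn$L, conn$region_ids, length_path)
  invisible(c(strength_path, length_path))
}

#' Read or write the subject covariate table
#'
#' CSV with header `subject_id,group,age,icv,tbv`; `group` values are mapped
#' case-insensitively onto `ASD` / `control`, `icv` and `tbv` are volumes in
#' cubic mm, `age` in years.
#'
#' @param path Path to the CSV file.
#' @return `read_subject_table()` returns a tibble with one validated row per
#'   subject; `write_subject_table()` returns `path` invisibly.
#' @export
read_subject_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          subject_id = readr::col_character(),
                          .default = readr::col_guess()))
  needed <- c("subject_id", "group", "age", "icv", "tbv")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("subject table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "neteff_error_io")
  }
  if (nrow(df) == 0) return(tibble::as_tibble(df[needed]))
  grp <- tolower(trimws(df$group))
  recognized <- grp %in% c("asd", "control")
  if (!all(recognized)) {
    abort(paste0("unrecognized group value(s): ",
                 paste(unique(df$group[!recognized]), collapse = ", ")),
          class = "neteff_error_io")
  }
  df$group <- ifelse(grp == "asd", "ASD", "control")
  bad <- which(!is.finite(df$icv) | df$icv <= 0 |
                 !is.finite(df$tbv) | df$tbv <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive icv/tbv for subject(s): ",
                 paste(df$subject_id[bad], collapse = ", ")),
          class = "neteff_error_io")
  }
  bad_age <- which(!is.finite(df$age) | df$age <= 0)
  if (length(bad_age) > 0) {
    abort(paste0("non-positive age for subject(s): ",
                 paste(df$subject_id[bad_age], collapse = ", ")),
          class = "neteff_error_io")
  }
  tibble::as_tibble(df[needed])
}

#' @param subjects A data frame of subject records.
#' @rdname read_subject_table
#' @export
write_subject_table <- function(subjects, path) {
  readr::write_csv(subjects, path)
  invisible(path)
}

#' Write or read a per-region statistical map
#'
#' One row per region, in ascending `region_id` order, with columns
#' `region_id,name,beta,t,p,q,significant`. All rows must come from a single
#' contrast.
#'
#' @param results A region-stats tibble from [fit_region_models()].
#' @param path Path to the CSV file.
#' @return `write_region_stats()` returns `path` invisibly;
#'   `read_region_stats()` returns the tibble.
#' @export
write_region_stats <- function(results, path) {
  if (length(unique(results$contrast)) > 1) {
    abort(paste0("results mix contrasts: ",
                 paste(unique(results$contrast), collapse = ", ")),
          class = "neteff_error_io")
  }
  out <- results[order(results$region_id),
                 c("region_id", "name", "beta", "t", "p", "q", "significant")]
  lines <- c(
    "region_id,name,beta,t,p,q,significant",
    paste(out$region_id, out$name, fmt_num(out$beta), fmt_num(out$t),
          fmt_num(out$p), fmt_num(out$q), tolower(out$significant),
          sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_region_stats
#' @export
read_region_stats <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    region_id = readr::col_integer(),
                    name = readr::col_character(),
                    significant = readr::col_logical(),
                    .default = readr::col_double()))
}
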