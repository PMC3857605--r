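#' Construct and validate a region atlas
#'
#' An atlas is the parcellation underlying every connectome in an analysis:
#' one row per cortical region, with a unique integer `region_id`, a `name`,
#' a `hemisphere` (`"left"` or `"right"`), a positive `size` (surface extent
#' in boundary-voxel count, used to normalize tract counts into connection
#' strengths), and optional centroid coordinates `x`, `y`, `z` in mm (used
#' only by the synthetic cohort generator).
#'
#' Rows are always kept in ascending `region_id` order; every file written or
#' read by the package uses this order, so region identity is positional and
#' unambiguous.
#'
#' @param regions A data frame with columns `region_id`, `name`, `hemisphere`,
#'   `size`, and optionally `x`, `y`, `z`.
#' @return A tibble of class `neteff_atlas`, sorted by `region_id`.
#' @examples
#' atlas <- region_atlas(data.frame(
#'   region_id = 1:4,
#'   name = c("A_L", "B_L", "A_R", "B_R"),
#'   hemisphere = c("left", "left", "right", "right"),
#'   size = c(100, 150, 110, 140)
#' ))
#' @export
region_atlas <- function(regions) {
  regions <- tibble::as_tibble(regions)
  needed <- c("region_id", "name", "hemisphere", "size")
  missing_cols <- setdiff(needed, names(regions))
  if (length(missing_cols) > 0) {
    abort(paste0("atlas is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "neteff_error_atlas")
  }
  if (any(regions$region_id != as.integer(regions$region_id))) {
    abort("region_id must be integer-valued", class = "neteff_error_atlas")
  }
  regions$region_id <- as.integer(regions$region_id)
  if (anyDuplicated(regions$region_id)) {
    dup <- unique(regions$region_id[duplicated(regions$region_id)])
    abort(paste0("duplicated region_id(s): ", paste(dup, collapse = ", ")),
          class = "neteff_error_atlas")
  }
  if (!all(regions$hemisphere %in% c("left", "right"))) {
    abort("hemisphere must be 'left' or 'right'", class = "neteff_error_atlas")
  }
  if (any(!is.finite(regions$size)) || any(regions$size <= 0)) {
    bad <- regions$region_id[!is.finite(regions$size) | regions$size <= 0]
    abort(paste0("non-positive size for region(s): ",
                 paste(bad, collapse = ", ")),
          class = "neteff_error_atlas")
  }
  regions <- dplyr::arrange(regions, .data$region_id)
  class(regions) <- c("neteff_atlas", class(regions))
  regions
}

#' Read or write an atlas as CSV
#'
#' Columns: `region_id,name,hemisphere,size[,x,y,z]`; rows in ascending
#' `region_id` order.
#'
#' @param path Path to a CSV file.
#' @return `read_atlas()` returns a validated [region_atlas()] tibble;
#'   `write_atlas()` returns `path` invisibly.
#' @export
read_atlas <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  region_atlas(df)
}

#' @param atlas A [region_atlas()] tibble.
#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, path) {
  readr::write_csv(atlas, path)
  invisible(path)
}
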