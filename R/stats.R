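#' Per-region linear models for efficiency
#'
#' Fits, for every region, an ordinary least squares model of normalized
#' efficiency on the predictor of interest plus covariates, and FDR-corrects
#' the resulting p-values across regions:
#'
#' * `icv`: efficiency ~ ICV + age + TBV; the test is on the ICV slope.
#' * `group`: efficiency ~ group + age; group is coded control = 0, ASD = 1,
#'   so a negative t-statistic means lower efficiency in ASD.
#' * `icv_x_group`: efficiency ~ ICV + group + ICV:group + age + TBV; the
#'   test is on the interaction term.
#'
#' Two-sided p-values come from the t distribution with the residual degrees
#' of freedom; q-values are Benjamini-Hochberg adjusted across the regions
#' of this one map.
#'
#' @param eff Efficiency table from [compute_efficiency()] (columns
#'   `subject_id`, `region_id`, and the measure columns).
#' @param subjects Subject covariate table with columns `subject_id`,
#'   `group`, `age`, `icv`, `tbv`.
#' @param contrast One of `"icv"`, `"group"`, `"icv_x_group"`.
#' @param measure Efficiency measure to model: `"nodal_local"` or
#'   `"nodal_global"`.
#' @param q_level FDR level for the significance flag (default 0.05).
#' @param atlas Optional [region_atlas()] supplying region names.
#' @return A tibble of class `neteff_region_stats`, one row per region, with
#'   columns `region_id`, `name`, `contrast`, `measure`, `beta`, `t`, `p`,
#'   `q`, `significant`, ordered by `region_id`.
#' @export
fit_region_models <- function(eff, subjects,
                              contrast = c("icv", "group", "icv_x_group"),
                              measure = c("nodal_local", "nodal_global"),
                              q_level = 0.05, atlas = NULL) {
  contrast <- match.arg(contrast)
  measure <- match.arg(measure)
  needed <- c("subject_id", "group", "age", "icv", "tbv")
  missing_cols <- setdiff(needed, names(subjects))
  if (length(missing_cols) > 0) {
    abort(paste0("subjects table is missing covariate(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "neteff_error_stats")
  }
  if (!measure %in% names(eff)) {
    abort(paste0("efficiency table has no column '", measure, "'"),
          class = "neteff_error_stats")
  }

  wide <- tidyr::pivot_wider(
    tibble::as_tibble(eff)[, c("subject_id", "region_id", measure)],
    names_from = "region_id", values_from = dplyr::all_of(measure))
  if (anyNA(wide)) {
    abort("every subject must have an efficiency value for every region",
          class = "neteff_error_stats")
  }
  covars <- dplyr::left_join(wide["subject_id"],
                             tibble::as_tibble(subjects), by = "subject_id")
  if (anyNA(covars[needed])) {
    abort("covariates missing for some subjects in the efficiency table",
          class = "neteff_error_stats")
  }
  covars$group <- factor(covars$group, levels = c("control", "ASD"))

  region_ids <- as.integer(setdiff(names(wide), "subject_id"))
  Y <- as.matrix(wide[, as.character(region_ids)])

  spec <- switch(contrast,
    icv = list(rhs = ~ icv + age + tbv, term = "icv"),
    group = list(rhs = ~ group + age, term = "groupASD"),
    icv_x_group = list(rhs = ~ icv * group + age + tbv,
                       term = "icv:groupASD"))
  X <- model.matrix(spec$rhs, data = covars)
  if (qr(X)$rank < ncol(X)) {
    qrx <- qr(X)
    collinear <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(collinear, collapse = ", ")),
          class = "neteff_error_stats")
  }
  if (nrow(X) < ncol(X) + 2) {
    abort(sprintf("need at least %d subjects for %d model terms, got %d",
                  ncol(X) + 2, ncol(X), nrow(X)),
          class = "neteff_error_stats")
  }

  fit <- lm(Y ~ X - 1)
  coefs <- if (ncol(Y) > 1) summary(fit) else list(summary(fit))
  term <- paste0("X", spec$term)
  stats <- purrr::map(coefs, function(s) {
    row <- s$coefficients[term, ]
    tibble::tibble(beta = row[["Estimate"]], t = row[["t value"]],
                   p = row[["Pr(>|t|)"]])
  })
  out <- dplyr::bind_rows(stats)
  out$region_id <- region_ids
  adj <- fdr_adjust(out$p, q_level = q_level)
  name <- if (!is.null(atlas)) {
    atlas$name[match(region_ids, atlas$region_id)]
  } else {
    sprintf("region_%03d", region_ids)
  }
  res <- tibble::tibble(
    region_id = region_ids,
    name = name,
    contrast = contrast,
    measure = measure,
    beta = out$beta,
    t = out$t,
    p = out$p,
    q = adj$q,
    significant = adj$significant
  ) |> dplyr::arrange(.data$region_id)
  attr(res, "q_level") <- q_level
  class(res) <- c("neteff_region_stats", class(res))
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity (via
#' [stats::p.adjust()] with `method = "BH"`); a region is flagged
#' significant when its adjusted value is at or below `q_level`.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param q_level FDR level (default 0.05).
#' @return A tibble with columns `p`, `q`, `significant`.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_adjust <- function(p_values, q_level = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "neteff_error_stats")
  }
  q <- p.adjust(p_values, method = "BH")
  tibble::tibble(p = p_values, q = q, significant = q <= q_level)
}

#' Cosine similarity of two regional statistic maps
#'
#' `dot(t1, t2) / (||t1|| * ||t2||)`, in `[-1, 1]`; measures agreement of
#' the spatial pattern of two t-statistic vectors irrespective of their
#' overall scale.
#'
#' @param t1,t2 Equal-length numeric vectors, each with at least one nonzero
#'   entry.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(t1, t2) {
  if (length(t1) != length(t2)) {
    abort(sprintf("vectors differ in length (%d vs %d)",
                  length(t1), length(t2)),
          class = "neteff_error_stats")
  }
  n1 <- sqrt(sum(t1^2))
  n2 <- sqrt(sum(t2^2))
  if (n1 == 0 || n2 == 0) {
    abort("cosine similarity is undefined for a zero vector",
          class = "neteff_error_stats")
  }
  sum(t1 * t2) / (n1 * n2)
}

#' @export
tidy.neteff_region_stats <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "neteff_region_stats")
  tibble::as_tibble(out)
}

#' One-row summary of a regional statistics map
#'
#' @param x A `neteff_region_stats` tibble.
#' @param ... Unused.
#' @return A tibble with the contrast, measure, region counts by
#'   significance and sign, the fraction of negative t-statistics, and the
#'   smallest q-value.
#' @export
glance.neteff_region_stats <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast[1],
    measure = x$measure[1],
    n_regions = nrow(x),
    n_sig = sum(x$significant),
    n_sig_negative = sum(x$significant & x$t < 0),
    n_sig_positive = sum(x$significant & x$t > 0),
    frac_t_negative = mean(x$t < 0),
    min_q = min(x$q)
  )
}

#' Plot a regional t-statistic map
#'
#' @param object A `neteff_region_stats` tibble from [fit_region_models()].
#' @param ... Unused.
#' @return A ggplot: per-region t-statistics, significant regions (at the
#'   map's FDR level) filled, ordered by region id.
#' @export
autoplot.neteff_region_stats <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$region_id), y = .data$t,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = "region", y = "t-statistic",
                  fill = paste0("q ≤ ", attr(object, "q_level") %||% 0.05),
                  title = paste0(df$measure[1], " ~ ", df$contrast[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
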