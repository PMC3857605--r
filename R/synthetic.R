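#' Configuration for the synthetic connectome-cohort generator
#'
#' The generator emulates a two-group diffusion-tractography study at the
#' region level: spatially embedded regions on two hemispheric shells,
#' distance-dependent connection strengths, fiber lengths that scale with
#' the cube root of intra-cranial volume (a linear dimension scales as
#' volume^(1/3)), an ICV-dependent weakening of long-range connections, and
#' a group (ASD) deficit on the same long-range connections.
#'
#' Defaults describe a cohort of 22 ASD and 22 control adult males on a
#' 78-region cortical parcellation. Volumes are in cubic mm, lengths in mm.
#'
#' @param n_per_group Subjects per group (default 22).
#' @param n_regions Number of cortical regions, even (default 78).
#' @param icv_mean,icv_sd Population mean and SD of intra-cranial volume
#'   (defaults 1.5e6 and 1.2e5 cubic mm, typical of adult males).
#' @param icv_group_shift Added to the ASD group's mean ICV (default 4e4
#'   cubic mm, a modest adult remnant of early overgrowth).
#' @param wiring_decay Exponential length-penalty scale on log connection
#'   weight, mm (default 30).
#' @param tortuosity Multiplier from Euclidean centroid distance to fiber
#'   length (default 1.3; fibers are not straight lines).
#' @param length_noise_sd SD of additive fiber-length noise, mm (default
#'   1.5; mean lengths are averages over many streamlines and so are
#'   measured precisely).
#' @param weight_noise_cv Coefficient of variation of multiplicative
#'   log-normal weight noise (default 0.1: variability of within-subject
#'   normalized strengths; the weight-rescaling anchor is an extreme
#'   statistic, so edgewise noise propagates into every weighted distance).
#' @param homotopic_strength Expected tract count of homotopic
#'   (mirror-image, callosal) connections, which in real connectomes are
#'   among the strongest edges and carry inter-hemispheric shortest paths
#'   (default 400: strong, but below the strongest short-range edges so the
#'   weight-rescaling anchor stays a within-hemisphere edge).
#' @param icv_longrange_slope Change in log-weight of long-range edges per
#'   cubic mm of ICV above the population mean (default -5e-6: one ICV SD
#'   costs about 0.6 log-units of long-range weight).
#' @param group_weight_deficit Proportional reduction of ASD long-range
#'   weights, independent of ICV (default 0.3).
#' @param longrange_quantile Edges whose Euclidean distance exceeds this
#'   within-subject quantile count as long-range (default 0.75).
#' @param seed Master seed; every draw in the generator flows from it via a
#'   fixed per-subject substream.
#' @return A list of class `neteff_generator_config`.
#' @export
generator_config <- function(n_per_group = 22, n_regions = 78,
                             icv_mean = 1.5e6, icv_sd = 1.2e5,
                             icv_group_shift = 4e4,
                             wiring_decay = 30, tortuosity = 1.3,
                             length_noise_sd = 1.5, weight_noise_cv = 0.1,
                             homotopic_strength = 400,
                             icv_longrange_slope = -5e-6,
                             group_weight_deficit = 0.3,
                             longrange_quantile = 0.75,
                             seed = 1L) {
  cfg <- list(n_per_group = n_per_group, n_regions = n_regions,
              icv_mean = icv_mean, icv_sd = icv_sd,
              icv_group_shift = icv_group_shift,
              wiring_decay = wiring_decay, tortuosity = tortuosity,
              length_noise_sd = length_noise_sd,
              weight_noise_cv = weight_noise_cv,
              homotopic_strength = homotopic_strength,
              icv_longrange_slope = icv_longrange_slope,
              group_weight_deficit = group_weight_deficit,
              longrange_quantile = longrange_quantile,
              seed = as.integer(seed))
  if (cfg$n_per_group < 2) {
    abort("n_per_group must be at least 2", class = "neteff_error_config")
  }
  if (cfg$n_regions < 4 || cfg$n_regions %% 2 != 0) {
    abort("n_regions must be even and at least 4", class = "neteff_error_config")
  }
  positive <- c("icv_mean", "icv_sd", "wiring_decay", "tortuosity",
                "homotopic_strength")
  for (nm in positive) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      abort(paste0(nm, " must be positive"), class = "neteff_error_config")
    }
  }
  if (cfg$group_weight_deficit < 0 || cfg$group_weight_deficit >= 1) {
    abort("group_weight_deficit must lie in [0, 1)",
          class = "neteff_error_config")
  }
  if (cfg$length_noise_sd < 0 || cfg$weight_noise_cv < 0) {
    abort("noise scales must be non-negative", class = "neteff_error_config")
  }
  if (cfg$longrange_quantile <= 0 || cfg$longrange_quantile >= 1) {
    abort("longrange_quantile must lie in (0, 1)",
          class = "neteff_error_config")
  }
  class(cfg) <- "neteff_generator_config"
  cfg
}

#' A generator configuration with every effect switched off
#'
#' Convenience wrapper over [generator_config()] with
#' `icv_longrange_slope = 0`, `group_weight_deficit = 0` and
#' `icv_group_shift = 0`: ICV and group are then causally inert for
#' normalized efficiency (size scaling is isometric and cancels in the
#' ideal-network normalization), giving a null cohort for false-positive
#' calibration.
#'
#' @param ... Passed on to [generator_config()].
#' @export
null_config <- function(...) {
  generator_config(icv_longrange_slope = 0, group_weight_deficit = 0,
                   icv_group_shift = 0, ...)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

subject_seed <- function(master, i) {
  as.integer((as.numeric(master) + 104729 * i) %% 2147483629)
}

# Reference half-brain semi-axes in mm (lateral, anterior-posterior,
# inferior-superior); the shell on which region centroids are placed.
BRAIN_SEMI_AXES <- c(60, 82, 65)

# Euclidean-equivalent detour (mm) added to inter-hemispheric fiber routes
# through the corpus callosum.
CALLOSAL_DETOUR <- 60

# Reference Euclidean span (mm) of a typical long-range connection; the
# ICV and group penalties on long-range edges are graded by fiber length
# relative to this span (longer connections suffer proportionally greater
# conduction-delay cost).
LONGRANGE_REF <- 150

#' Generate a bilaterally symmetric synthetic atlas
#'
#' Places `n_regions / 2` centroids per hemisphere on an ellipsoidal shell
#' scaled to a reference adult brain; the right-hemisphere centroids mirror
#' the left across the midsagittal plane (lateral coordinate negated).
#' Centroids are placed greedily with a minimum mutual separation, as region
#' centers of a parcellation tile the surface rather than clustering; the
#' separation requirement is relaxed gradually if the shell gets crowded.
#' Region sizes are drawn log-normal.
#'
#' @param config A [generator_config()].
#' @param seed Seed for this draw (defaults to the config's master seed).
#' @return A [region_atlas()] with centroid columns `x`, `y`, `z` (mm).
#' @export
generate_atlas_geometry <- function(config, seed = config$seed) {
  n <- config$n_regions
  if (n < 4 || n %% 2 != 0) {
    abort("n_regions must be even and at least 4", class = "neteff_error_config")
  }
  half <- n / 2
  with_seed(seed, {
    left <- matrix(NA_real_, half, 3)
    placed <- matrix(NA_real_, 0, 3) # accepted points, both hemispheres
    sep <- 14 # mm; typical inter-centroid spacing for a cortical parcellation
    tries <- 0
    k <- 0
    while (k < half) {
      v <- rnorm(3)
      p <- v / sqrt(sum(v^2)) * BRAIN_SEMI_AXES
      p[1] <- -abs(p[1])
      q <- p * c(-1, 1, 1)
      ok <- 2 * abs(p[1]) >= sep &&
        (nrow(placed) == 0 ||
           min(sqrt(colSums((t(placed) - p)^2))) >= sep)
      if (ok) {
        k <- k + 1
        left[k, ] <- p
        placed <- rbind(placed, p, q)
        tries <- 0
      } else {
        tries <- tries + 1
        if (tries > 2000) {
          sep <- sep * 0.9
          tries <- 0
        }
      }
    }
    right <- left
    right[, 1] <- -right[, 1]
    sizes <- rlnorm(n, meanlog = log(250), sdlog = 0.4)
  })
  region_atlas(tibble::tibble(
    region_id = seq_len(n),
    name = c(sprintf("region_%03d_L", seq_len(half)),
             sprintf("region_%03d_R", seq_len(half))),
    hemisphere = rep(c("left", "right"), each = half),
    size = sizes,
    x = c(left[, 1], right[, 1]),
    y = c(left[, 2], right[, 2]),
    z = c(left[, 3], right[, 3])
  ))
}

#' Generate one subject's connectome
#'
#' Fiber lengths are `tortuosity * Euclidean(i, j) * (ICV / icv_mean)^(1/3)`
#' plus symmetric Gaussian noise, floored at 1 mm. Expected log tract counts
#' decay with the reference (ICV-normalized) fiber length at scale
#' `wiring_decay`; homotopic (mirror-image) region pairs are instead given
#' the strong bundle count `homotopic_strength`, emulating the callosal
#' connections that carry inter-hemispheric shortest paths. Long-range
#' edges (Euclidean distance above the `longrange_quantile` within-subject
#' quantile, plus every inter-hemispheric edge) are penalized by
#' `icv_longrange_slope * (ICV - icv_mean)` and, for ASD subjects, by
#' `log(1 - group_weight_deficit)`; the homotopic bundles belong to the
#' penalized set, so both effects propagate into every region's global
#' efficiency through inter-hemispheric paths. Counts are drawn
#' log-normal around the decayed mean, values below one streamline are
#' pruned, and the result is compiled into a size-normalized strength
#' matrix.
#'
#' @param atlas A [region_atlas()] with centroids.
#' @param subject One-row data frame (or list) with `subject_id`, `group`,
#'   `icv`.
#' @param config A [generator_config()].
#' @param seed Seed for this subject's substream.
#' @return A `neteff_connectome` that passes [validate_connectome()].
#' @export
generate_subject_connectome <- function(atlas, subject, config,
                                        seed = config$seed) {
  xyz <- as.matrix(atlas[, c("x", "y", "z")])
  euclid <- as.matrix(stats::dist(xyz))
  n <- nrow(euclid)
  icv_scale <- (subject$icv / config$icv_mean)^(1 / 3)
  # inter-hemispheric fibers route through the corpus callosum: their
  # lengths carry a fixed callosal detour, which also keeps every
  # non-bundle cross edge weak under the wiring decay
  cross <- outer(atlas$hemisphere, atlas$hemisphere, `!=`)
  ref_length <- config$tortuosity * (euclid + CALLOSAL_DETOUR * cross)

  # long-range edges: beyond the within-subject distance quantile, plus the
  # whole inter-hemispheric cut (callosal system) -- a percentile threshold
  # alone can be routed around via short medial crossings, in which case the
  # penalty would never reach global efficiency
  thresh <- quantile(euclid[upper.tri(euclid)], config$longrange_quantile)
  longrange <- euclid > thresh | cross

  mu <- log(2000) - ref_length / config$wiring_decay
  # homotopic pairs: centroids mirror across the midsagittal plane
  mirror <- xyz
  mirror[, 1] <- -mirror[, 1]
  partner <- apply(mirror, 1, function(p) {
    hits <- which(colSums((t(xyz) - p)^2) < 1e-8)
    if (length(hits) == 1) hits else NA_integer_
  })
  homotopic <- matrix(FALSE, n, n)
  ok <- which(!is.na(partner) & partner != seq_len(n))
  homotopic[cbind(ok, partner[ok])] <- TRUE
  mu[homotopic] <- log(config$homotopic_strength)

  # noise precision scales with streamline support: strengths and mean
  # lengths of well-sampled (strong, short) connections are measured far
  # more precisely than sparsely sampled long-range ones (Poisson-type
  # 1/sqrt(count) scaling around a reference count of 100, capped for
  # near-empty edges)
  precision <- pmin(sqrt(100 / exp(mu)), 3)
  with_seed(seed, {
    noise_l <- matrix(0, n, n)
    noise_l[upper.tri(noise_l)] <- rnorm(n * (n - 1) / 2, 0, 1)
    noise_l <- (noise_l + t(noise_l)) * config$length_noise_sd * precision
    sdlog <- sqrt(log(1 + config$weight_noise_cv^2))
    noise_w <- matrix(0, n, n)
    noise_w[upper.tri(noise_w)] <- rnorm(n * (n - 1) / 2, 0, 1)
    noise_w <- (noise_w + t(noise_w)) * sdlog * precision
  })

  lengths <- ref_length * icv_scale + noise_l
  lengths <- pmax(lengths, 1)
  diag(lengths) <- 0

  # edge existence is anatomical: pairs whose base expected count (before
  # any ICV or group modulation) falls below one streamline are absent.
  # Effects then modulate the weights of existing edges only, so adjacency
  # never varies with ICV or group (nodal local efficiency is not monotone
  # under neighbor removal, and real tracts do not appear or vanish with
  # modest weight changes).
  present <- exp(mu + noise_w) >= 1

  # penalties are graded by fiber length: longer long-range connections
  # carry proportionally greater conduction-delay and metabolic cost. The
  # favorable (small-brain) side saturates at a doubling -- a smaller brain
  # does not grow unboundedly strong bundles.
  grade <- ref_length / (config$tortuosity * LONGRANGE_REF)
  delta <- pmin(grade * config$icv_longrange_slope *
                  (subject$icv - config$icv_mean), log(2))
  mu[longrange] <- mu[longrange] + delta[longrange]
  if (identical(as.character(subject$group), "ASD")) {
    mu[longrange] <- mu[longrange] +
      grade[longrange] * log(1 - config$group_weight_deficit)
  }
  counts <- exp(mu + noise_w) * present
  diag(counts) <- 0

  W <- compile_strength(counts, atlas$size)
  connectome(W, lengths, region_ids = atlas$region_id)
}

#' Generate a full synthetic cohort
#'
#' Draws `2 * n_per_group` subjects (controls then ASD) with
#' `ICV ~ Normal(icv_mean + group shift, icv_sd)`, `age ~ Uniform(20, 50)`
#' years, and `TBV = 0.75 * ICV + Normal(0, 4.5e4)` (giving an ICV-TBV
#' correlation near 0.9, as observed in adults); then generates one
#' connectome per subject from a named per-subject substream of the master
#' seed, so a subject's connectome is reproducible independent of cohort
#' size.
#'
#' @param config A [generator_config()].
#' @return A list with elements `atlas`, `subjects` (covariate tibble),
#'   `connectomes` (named list), and `ground_truth` (the effect parameters
#'   used).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "neteff_generator_config"))
  atlas <- generate_atlas_geometry(config, seed = config$seed)
  n <- 2 * config$n_per_group
  subjects <- with_seed(subject_seed(config$seed, 0), {
    group <- rep(c("control", "ASD"), each = config$n_per_group)
    icv <- rnorm(n, config$icv_mean +
                   ifelse(group == "ASD", config$icv_group_shift, 0),
                 config$icv_sd)
    icv <- pmax(icv, 0.5 * config$icv_mean)
    tibble::tibble(
      subject_id = sprintf("sub%03d", seq_len(n)),
      group = group,
      age = runif(n, 20, 50),
      icv = icv,
      tbv = pmin(0.75 * icv + rnorm(n, 0, 4.5e4), 0.95 * icv)
    )
  })
  connectomes <- purrr::map(seq_len(n), function(i) {
    generate_subject_connectome(atlas, subjects[i, ], config,
                                seed = subject_seed(config$seed, i))
  })
  names(connectomes) <- subjects$subject_id
  ground_truth <- list(
    icv_longrange_slope = config$icv_longrange_slope,
    group_weight_deficit = config$group_weight_deficit,
    icv_group_shift = config$icv_group_shift,
    longrange_quantile = config$longrange_quantile,
    seed = config$seed
  )
  list(atlas = atlas, subjects = subjects, connectomes = connectomes,
       ground_truth = ground_truth)
}

#' Write or read a cohort directory
#'
#' Lays a cohort out as `atlas.csv`, `subjects.csv`,
#' `<subject_id>_strength.tsv` / `<subject_id>_length.tsv` matrix pairs, and
#' a `ground_truth.json` sidecar.
#'
#' @param cohort A cohort list from [generate_cohort()].
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a cohort list (without ground truth if the sidecar is absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.csv"))
  write_subject_table(cohort$subjects, file.path(dir, "subjects.csv"))
  for (sid in names(cohort$connectomes)) {
    write_connectome_pair(cohort$connectomes[[sid]],
                          file.path(dir, paste0(sid, "_strength.tsv")),
                          file.path(dir, paste0(sid, "_length.tsv")))
  }
  if (!is.null(cohort$ground_truth)) {
    jsonlite::write_json(cohort$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  atlas <- read_atlas(file.path(dir, "atlas.csv"))
  subjects <- read_subject_table(file.path(dir, "subjects.csv"))
  connectomes <- purrr::map(subjects$subject_id, function(sid) {
    read_connectome_pair(file.path(dir, paste0(sid, "_strength.tsv")),
                         file.path(dir, paste0(sid, "_length.tsv")),
                         atlas)
  })
  names(connectomes) <- subjects$subject_id
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path)) jsonlite::read_json(gt_path)
  list(atlas = atlas, subjects = subjects, connectomes = connectomes,
       ground_truth = ground_truth)
}
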