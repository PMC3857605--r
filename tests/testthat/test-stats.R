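test_that("BH adjustment reproduces the hand-computed step-up", {
  out <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04), q_level = 0.05)
  # step-up: q_(i) = min_{j >= i} p_(j) * m / j = (0.04, 0.04, 0.04, 0.04)
  expect_equal(out$q, rep(0.04, 4))
  expect_true(all(out$significant)) # largest p <= 4 * 0.05 / 4

  out1 <- fdr_adjust(rep(1, 5))
  expect_equal(out1$q, rep(1, 5))
  expect_false(any(out1$significant))

  out2 <- fdr_adjust(0.04) # m = 1 identity
  expect_equal(out2$q, 0.04)
  expect_true(out2$significant)

  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust(c(-0.1)), "\\[0, 1\\]")

  # q >= p and monotone in p
  set.seed(3)
  p <- runif(50)
  out3 <- fdr_adjust(p)
  expect_true(all(out3$q >= out3$p))
  expect_true(all(diff(out3$q[order(out3$p)]) >= -1e-15))
})

test_that("cosine similarity behaves as a normalized dot product", {
  v <- c(1.5, -2, 3)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))

  set.seed(14)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(cosine_similarity(3.7 * a, b), cosine_similarity(a, b))
  expect_equal(cosine_similarity(a, -b), -cosine_similarity(a, b))
  expect_true(abs(cosine_similarity(a, b)) <= 1)

  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(1:3, 1:4), "length")
})

make_subjects <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("control", "ASD"), length.out = n),
    age = runif(n, 20, 50),
    icv = rnorm(n, 1.5e6, 1.2e5),
    tbv = 0.75 * rnorm(n, 1.5e6, 1.2e5) + rnorm(n, 0, 3e4))
}

test_that("noise-free ICV relation is recovered exactly", {
  subj <- make_subjects(20, seed = 2)
  b <- 2e-8
  vals <- unlist(lapply(subj$icv, function(icv) {
    c(0.9, 0.8, 0.7) - b * icv * c(1, 1, 1)
  }))
  eff <- make_eff(vals, subj$subject_id, 1:3)
  # zero-residual fits make summary.lm warn about perfect fits; expected here
  res <- suppressWarnings(fit_region_models(eff, subj, "icv", "nodal_local"))
  expect_equal(res$beta, rep(-b, 3), tolerance = 1e-8)
  expect_true(all(abs(res$t) > 1e5))
  expect_true(all(res$significant))
})

test_that("model fits agree with a closed-form OLS oracle", {
  # the oracle formula itself is checked against a 5-point hand dataset:
  # x = 1..5, y = 2x + 1 + (0.1, -0.1, 0.1, -0.1, 0)
  X5 <- cbind(`(Intercept)` = 1, x = 1:5)
  y5 <- 2 * (1:5) + 1 + c(0.1, -0.1, 0.1, -0.1, 0)
  o5 <- oracle_ols(X5, y5, "x")
  expect_equal(o5$beta, 1.98) # 2 + Sxe/Sxx = 2 - 0.2/10
  expect_equal(o5$t, 1.98 / sqrt((0.036 / 3) / 10)) # SSR = 0.036, df = 3

  subj <- make_subjects(15, seed = 5)
  set.seed(6)
  eff <- make_eff(runif(15 * 4, 0.2, 0.8), subj$subject_id, 1:4)
  res <- fit_region_models(eff, subj, "icv", "nodal_local")
  X <- cbind(1, icv = subj$icv, age = subj$age, tbv = subj$tbv)
  colnames(X)[1] <- "(Intercept)"
  wide <- tidyr::pivot_wider(eff, names_from = region_id,
                             values_from = nodal_local)
  for (r in 1:4) {
    o <- oracle_ols(X, wide[[as.character(r)]], "icv")
    expect_equal(res$beta[r], o$beta, tolerance = 1e-9)
    expect_equal(res$t[r], unname(o$t), tolerance = 1e-9)
    expect_equal(res$p[r], unname(o$p), tolerance = 1e-9)
  }

  # group contrast against the same oracle
  Xg <- cbind(`(Intercept)` = 1, groupASD = as.numeric(subj$group == "ASD"),
              age = subj$age)
  resg <- fit_region_models(eff, subj, "group", "nodal_local")
  og <- oracle_ols(Xg, wide[["2"]], "groupASD")
  expect_equal(resg$beta[2], og$beta, tolerance = 1e-9)
  expect_equal(resg$t[2], unname(og$t), tolerance = 1e-9)
})

test_that("t-statistics are invariant to affine rescaling of covariates", {
  subj <- make_subjects(18, seed = 9)
  set.seed(10)
  eff <- make_eff(runif(18 * 3, 0.2, 0.8), subj$subject_id, 1:3)
  res_mm3 <- fit_region_models(eff, subj, "icv", "nodal_local")
  subj_cm3 <- subj
  subj_cm3$icv <- subj_cm3$icv / 1000 # cubic mm -> cubic cm
  res_cm3 <- fit_region_models(eff, subj_cm3, "icv", "nodal_local")
  expect_equal(res_cm3$t, res_mm3$t, tolerance = 1e-9)
  expect_equal(res_cm3$p, res_mm3$p, tolerance = 1e-9)
  expect_equal(res_cm3$beta, res_mm3$beta * 1000, tolerance = 1e-6)
})

test_that("group coding makes reduced efficiency in ASD a negative t", {
  subj <- make_subjects(20, seed = 11)
  base <- rep(0.6, 20)
  vals <- as.vector(vapply(seq_len(20), function(i) {
    base[i] - 0.1 * (subj$group[i] == "ASD") + c(0, 0.001, -0.001)
  }, numeric(3)))
  eff <- make_eff(vals, subj$subject_id, 1:3)
  res <- suppressWarnings(fit_region_models(eff, subj, "group", "nodal_local"))
  expect_true(all(res$t < 0))
})

test_that("null data yield nominal per-region false positive rates", {
  # permutation-style null: efficiency independent of all covariates
  subj <- make_subjects(44, seed = 20)
  n_reps <- 200
  n_regions <- 20
  pvals <- numeric(0)
  set.seed(21)
  for (r in seq_len(n_reps)) {
    eff <- make_eff(runif(44 * n_regions, 0.2, 0.8),
                    subj$subject_id, seq_len(n_regions))
    subj_perm <- subj
    subj_perm$group <- sample(subj_perm$group) # permuted labels
    res <- fit_region_models(eff, subj_perm, "group", "nodal_local")
    pvals <- c(pvals, res$p)
  }
  frac <- mean(pvals < 0.05)
  m <- length(pvals)
  bound <- 2.576 * sqrt(0.05 * 0.95 / m) # binomial 99% bounds
  expect_gt(frac, 0.05 - bound)
  expect_lt(frac, 0.05 + bound)
})

test_that("degenerate designs raise structured errors", {
  subj <- make_subjects(12, seed = 30)
  set.seed(31)
  eff <- make_eff(runif(12 * 2), subj$subject_id, 1:2)

  subj_colin <- subj
  subj_colin$tbv <- subj_colin$icv # exactly collinear
  expect_error(fit_region_models(eff, subj_colin, "icv", "nodal_local"),
               "collinear")

  expect_error(fit_region_models(eff, subj[, -5], "icv", "nodal_local"),
               "tbv")

  eff_missing <- eff[-1, ]
  expect_error(fit_region_models(eff_missing, subj, "icv", "nodal_local"),
               "every region")

  expect_error(fit_region_models(eff, subj[1:5, ], "icv", "nodal_local"),
               "covariates missing|at least")
})

test_that("glance summarizes a stats map consistently", {
  subj <- make_subjects(16, seed = 40)
  set.seed(41)
  eff <- make_eff(runif(16 * 5), subj$subject_id, 1:5)
  res <- fit_region_models(eff, subj, "icv", "nodal_local")
  g <- glance(res)
  expect_equal(g$n_regions, 5)
  expect_equal(g$n_sig, sum(res$significant))
  expect_equal(g$n_sig_negative + g$n_sig_positive, g$n_sig)
  expect_equal(g$frac_t_negative, mean(res$t < 0))
})
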