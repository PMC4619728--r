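make_covariate_data <- function(n = 41, shift = 0, seed = 1) {
  withr::with_seed(seed, {
    group <- factor(rep(c("A", "B"), length.out = n))
    vma <- rnorm(n, 36, 14) + ifelse(group == "B", 10, 0)
    nvma <- rnorm(n, 40, 13) + ifelse(group == "B", 8, 0)
    y <- 0.3 * vma + 0.1 * nvma + rnorm(n) + ifelse(group == "B", shift, 0)
    tibble::tibble(y = y, group = group, vma_months = vma, nvma_months = nvma)
  })
}

test_that("the ANCOVA group F matches car's Type III decomposition", {
  skip_if_not_installed("car")
  for (s in 1:20) {
    dat <- make_covariate_data(n = 41, shift = runif(1, 0, 2), seed = s)
    fit <- ancova_group_effect(dat, "y", include_interactions = TRUE)
    lm_fit <- lm(y ~ group * vma_months + group * nvma_months, data = dat,
                 contrasts = list(group = "contr.sum"))
    a3 <- car::Anova(lm_fit, type = 3)
    expect_equal(fit$statistic, a3["group", "F value"], tolerance = 1e-6)
    expect_equal(fit$p.value, a3["group", "Pr(>F)"], tolerance = 1e-6)
    expect_equal(fit$ss_group, a3["group", "Sum Sq"], tolerance = 1e-6)
  }
})

test_that("ANCOVA degrees of freedom follow the model variant", {
  dat <- make_covariate_data(n = 41, shift = 1, seed = 3)
  with_int <- ancova_group_effect(dat, "y", include_interactions = TRUE)
  without <- ancova_group_effect(dat, "y", include_interactions = FALSE)
  expect_identical(c(with_int$df1, with_int$df2), c(1L, 35L))
  expect_identical(c(without$df1, without$df2), c(1L, 37L))
  expect_true(with_int$partial_eta_sq >= 0 && with_int$partial_eta_sq <= 1)
  td <- tidy(with_int)
  expect_identical(names(td), c("outcome", "term", "statistic", "df1", "df2",
                                "p.value", "partial.eta.sq"))
  expect_identical(nrow(glance(with_int)), 1L)
})

test_that("ANCOVA rejects rank-deficient designs naming the collinear term", {
  dat <- make_covariate_data(n = 30, seed = 5)
  dat$dup <- dat$vma_months
  expect_error(
    ancova_group_effect(dat, "y", covariates = c("vma_months", "dup"),
                        include_interactions = FALSE),
    "dup", class = "gazenet_data_error")
})

test_that("without interactions the group F equals the classical added-SS test", {
  dat <- make_covariate_data(n = 41, shift = 1.2, seed = 11)
  fit <- ancova_group_effect(dat, "y", include_interactions = FALSE)
  full <- lm(y ~ group + vma_months + nvma_months, data = dat)
  red <- lm(y ~ vma_months + nvma_months, data = dat)
  cmp <- anova(red, full)
  expect_equal(fit$statistic, cmp$F[2], tolerance = 1e-9)
  expect_equal(fit$p.value, cmp$`Pr(>F)`[2], tolerance = 1e-9)
})

test_that("one-sample t reproduces hand arithmetic and handles degenerate input", {
  expect_equal(one_sample_t(c(0.4, 0.6), mu = 0.5)$statistic, 0)
  res <- one_sample_t(c(0.6, 0.7, 0.8), mu = 0.5)
  expect_equal(res$statistic, (0.7 - 0.5) / (0.1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$statistic, 3.464, tolerance = 1e-3)
  expect_identical(res$df, 2)
  expect_equal(res$cohens_d, 2.0, tolerance = 1e-12)
  degen <- one_sample_t(c(0.5, 0.5, 0.5))
  expect_true(is.na(degen$statistic) && is.na(degen$cohens_d))
})

test_that("pearson_r matches the hand covariance formula", {
  x <- c(1, 2, 4, 5, 9)
  y <- c(2, 1, 5, 4, 10)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, r_hand, tolerance = 1e-12)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(c(1, 1, 1), y[1:3]), class = "gazenet_data_error")
})

test_that("fisher_compare evaluates the z formula and is antisymmetric", {
  expect_equal(fisher_compare(0.3, 20, 0.3, 25)$z, 0)
  hand <- (atanh(0.5) - atanh(0)) / sqrt(1 / 27 + 1 / 27)
  expect_equal(fisher_compare(0.5, 30, 0.0, 30)$z, hand, tolerance = 1e-12)
  expect_equal(hand, 2.018, tolerance = 1e-3)
  for (s in 1:10) {
    p <- withr::with_seed(s, list(r1 = runif(1, -0.9, 0.9),
                                  r2 = runif(1, -0.9, 0.9),
                                  n1 = sample(5:50, 1), n2 = sample(5:50, 1)))
    expect_equal(fisher_compare(p$r1, p$n1, p$r2, p$n2)$z,
                 -fisher_compare(p$r2, p$n2, p$r1, p$n1)$z, tolerance = 1e-12)
  }
  expect_error(fisher_compare(1, 20, 0.5, 20), class = "gazenet_data_error")
  expect_error(fisher_compare(0.5, 3, 0.5, 20), class = "gazenet_data_error")
})

test_that("the per-AOI correlation comparison is consistent with its parts", {
  co <- generate_cohort(cohort_design(n_per_group = c(10, 10)), seed = 71)
  met <- fixation_metrics(co$plans)
  cen <- aoi_centrality(co$plans)
  cmp <- compare_aoi_correlations(met, cen, co$metadata)
  expect_identical(cmp$aoi, aoi5)
  row <- cmp[cmp$aoi == "nose", ]
  sub <- met |>
    dplyr::inner_join(dplyr::rename(co$metadata, participant = id),
                      by = "participant") |>
    dplyr::inner_join(dplyr::filter(cen, aoi == "nose"), by = "participant")
  r_asd <- pearson_r(sub$pct_nose[sub$group == "ASD"],
                     sub$c_dw[sub$group == "ASD"])
  expect_equal(row$r1, r_asd$r, tolerance = 1e-12)
  expect_equal(row$z,
               fisher_compare(row$r1, row$n1, row$r2, row$n2)$z,
               tolerance = 1e-12)
})
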