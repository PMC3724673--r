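test_that("%AT-on-codons regression is near-exact with aliased terms flagged", {
  set.seed(21)
  cfg <- cohort_config(n_phyla = 10, genera_per_phylum = 2, species_per_genus = 4,
                       n_codons_per_genome = 2000, seed = 21)
  prof <- simulate_cohort_profiles(cfg)$profiles
  fit <- fit_at_on_codons(prof)
  # %AT is a linear functional of codon frequencies, so the fit is near-exact
  expect_gt(fit$r_squared, 0.95)
  # compositional collinearity forces at least one aliased coefficient
  expect_gt(length(fit$aliased), 0)
})

test_that("permuted response falls below the permutation null tail", {
  set.seed(22)
  cfg <- cohort_config(n_phyla = 25, genera_per_phylum = 2, species_per_genus = 10,
                       n_codons_per_genome = 500, seed = 22)
  prof <- simulate_cohort_profiles(cfg)$profiles  # n = 500
  prof_perm <- prof
  prof_perm$at_fraction <- sample(prof$at_fraction)
  r2_obs <- fit_at_on_codons(prof_perm)$r_squared
  r2_null <- replicate(30, {
    p <- prof
    p$at_fraction <- sample(p$at_fraction)
    fit_at_on_codons(p)$r_squared
  })
  expect_lt(r2_obs, quantile(r2_null, 0.95) + 0.05)
  expect_lt(r2_obs, 0.5)
})

test_that("phylum ANOVA ranks group means and guards degenerate input", {
  tax <- make_balanced_taxonomy(2, 1, 1, 5)
  prof <- tibble::tibble(genome_id = tax$genome_id,
                         aaub = ifelse(tax$phylum == "P01", 0.03, 0.07))
  suppressWarnings(fit <- fit_anova_aaub_phylum(prof, tax, min_genomes = 2))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(as.character(fit$phylum_means$phylum[1]), "P02")

  # ordered generative means recovered with replication
  set.seed(23)
  tax2 <- make_balanced_taxonomy(4, 1, 1, 200)
  mu <- c(P01 = 0.02, P02 = 0.04, P03 = 0.06, P04 = 0.08)
  prof2 <- tibble::tibble(genome_id = tax2$genome_id,
                          aaub = rnorm(nrow(tax2), mu[tax2$phylum], 0.01))
  fit2 <- fit_anova_aaub_phylum(prof2, tax2, min_genomes = 20)
  expect_equal(as.character(fit2$ranked$phylum), c("P04", "P03", "P02", "P01"))
  expect_true(all(fit2$ranked$n > 20))

  one <- tax[tax$phylum == "P01", ]
  expect_error(fit_anova_aaub_phylum(prof[1:5, ], one), "single phylum")
})

test_that("GAM recovers a linear truth with edf near 1", {
  set.seed(24)
  n <- 400
  x <- runif(n)
  df <- tibble::tibble(x = x, y = 2 * x + rnorm(n, 0, 0.1))
  fit <- fit_gam(df, "y", smooth_terms = "x")
  td <- tidy(fit)
  expect_lt(td$edf[td$type == "smooth"], 6)
  # the fitted curve is effectively the straight line: slope ~2 and small
  # deviation from the OLS line over the whole grid
  sm <- fit$smooth_estimates
  line <- lm(fit ~ x, data = sm)
  expect_lt(abs(coef(line)[2] - 2), 0.2)
  expect_lt(max(abs(resid(line))), 0.05)
  # overall trend increasing
  expect_gt(cor(sm$x, sm$fit), 0.99)
})

test_that("GAM mean squared error on a known sine stays within the edf bound", {
  set.seed(25)
  n <- 2000
  sigma <- 0.1
  x <- runif(n)
  truth <- sin(2 * pi * x)
  df <- tibble::tibble(x = x, y = truth + rnorm(n, 0, sigma))
  fit <- fit_gam(df, "y", smooth_terms = "x", k = 20)
  pred <- predict(fit$model, newdata = df)
  mse <- mean((pred - truth)^2)
  edf <- sum(fit$model$edf)
  expect_lt(mse, 2 * sigma^2 * edf / n)
})

test_that("constant response collapses to an effectively flat smooth", {
  df <- tibble::tibble(x = runif(100), y = rep(1, 100))
  fit <- fit_gam(df, "y", smooth_terms = "x")
  expect_lt(diff(range(predict(fit$model, newdata = df))), 1e-6)
  expect_error(fit_gam(tibble::tibble(x = rep(1, 50), y = rnorm(50)),
                       "y", "x"), "constant")
})

test_that("GAMM estimates are invariant to group relabeling", {
  set.seed(26)
  tax <- make_balanced_taxonomy(8, 2, 2, 4)
  u <- rnorm(8, 0, 0.3)
  df <- tax
  df$at_fraction <- runif(nrow(df), 0.25, 0.85)
  df$y <- 1 + u[as.integer(factor(df$phylum))] + rnorm(nrow(df), 0, 0.1)
  f1 <- fit_gamm(df, "y", linear_terms = "at_fraction")
  relab <- df
  relab$phylum <- paste0("Z", relab$phylum)
  relab$genus <- paste0("Z", relab$genus)
  relab$species <- paste0("Z", relab$species)
  f2 <- fit_gamm(relab, "y", linear_terms = "at_fraction")
  expect_equal(f1$random_variances$std_dev, f2$random_variances$std_dev,
               tolerance = 1e-6)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-6)
})

test_that("a known fixed coefficient is recovered within 2 SE", {
  set.seed(27)
  tax <- make_balanced_taxonomy(10, 2, 2, 5)
  n <- nrow(tax)
  u <- rnorm(10, 0, 0.2)
  df <- tax
  df$at_fraction <- runif(n, 0.25, 0.85)
  df$x1 <- rnorm(n)
  df$y <- 0.5 + 1.0 * df$x1 + u[as.integer(factor(df$phylum))] + rnorm(n, 0, 0.2)
  fit <- fit_gamm(df, "y", linear_terms = "x1")
  td <- tidy(fit)
  est <- td$estimate[td$term == "x1"]
  se <- td$std_error[td$term == "x1"]
  expect_gt(est, 0)
  expect_lt(abs(est - 1), 2 * se)
})

test_that("AIC comparison prefers truth and rejects mismatched responses", {
  set.seed(28)
  tax <- make_balanced_taxonomy(12, 2, 1, 8)
  n <- nrow(tax)
  u <- rnorm(12, 0, 1)
  df <- tax
  df$at_fraction <- runif(n, 0.25, 0.85)
  df$x <- runif(n)
  df$y <- sin(2 * df$x) + u[as.integer(factor(df$phylum))] + rnorm(n, 0, 0.2)
  gamm_fit <- fit_gamm(df, "y", smooth_terms = "x")
  gam_fit <- fit_gam(df, "y", smooth_terms = "x")
  cmp <- compare_aic(gamm_fit, gam_fit, c("re", "fixed"))
  expect_equal(cmp$preferred, "re")
  expect_lt(cmp$delta_aic, -10)

  # identical models tie
  cmp2 <- compare_aic(gamm_fit, gamm_fit, c("a", "b"))
  expect_equal(cmp2$delta_aic, 0, tolerance = 1e-8)

  other <- df
  other$y <- df$y + 1
  gamm_other <- fit_gamm(other, "y", smooth_terms = "x")
  expect_error(compare_aic(gamm_fit, gamm_other), "same response")
})

test_that("uninformative random effects cost AIC on average", {
  set.seed(29)
  deltas <- replicate(5, {
    tax <- make_balanced_taxonomy(6, 2, 2, 10)
    df <- tax
    df$at_fraction <- runif(nrow(df), 0.25, 0.85)
    df$x <- runif(nrow(df))
    df$y <- 2 * df$x + rnorm(nrow(df), 0, 0.3)  # no cluster structure
    cmp <- compare_aic(fit_gamm(df, "y", smooth_terms = "x"),
                       fit_gam(df, "y", smooth_terms = "x"),
                       c("re", "fixed"))
    cmp$delta_aic
  })
  expect_gt(mean(deltas), 0)
})

test_that("KL-vs-size model detects a real size effect and guards input", {
  set.seed(30)
  cfg <- cohort_config(n_phyla = 10, genera_per_phylum = 2, species_per_genus = 2,
                       n_codons_per_genome = 20000, seed = 30)
  sim <- simulate_cohort_profiles(cfg)
  prof <- sim$profiles
  # inject a strong size dependence on top of the generator
  prof$kl <- prof$kl + 5 * (prof$genome_size / 1e6)
  fit <- fit_kl_vs_size(prof, sim$taxonomy)
  expect_lt(fit$size_p_value, 0.001)

  prof2 <- sim$profiles
  prof2$genome_size <- 1e6L
  expect_error(fit_kl_vs_size(prof2, sim$taxonomy), "constant genome size")
  expect_error(fit_kl_vs_size(sim$profiles[1:5, ], sim$taxonomy), "at least 10")
})

test_that("standardized residuals of a well-specified GAMM are mean-zero", {
  set.seed(31)
  tax <- make_balanced_taxonomy(10, 2, 2, 5)
  n <- nrow(tax)
  df <- tax
  df$at_fraction <- runif(n, 0.25, 0.85)
  df$x <- runif(n)
  df$y <- 1 + sin(df$x) + rnorm(n, 0, 0.2)
  fit <- fit_gamm(df, "y", smooth_terms = "x")
  r <- resid(fit$model)
  expect_lt(abs(mean(r / sd(r))), 3 / sqrt(n))
})

test_that("tidiers and smooth plots work on fits", {
  set.seed(32)
  df <- tibble::tibble(x = runif(120), y = rnorm(120))
  fit <- fit_gam(df, "y", smooth_terms = "x")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_true(all(c("lower", "upper") %in% names(fit$smooth_estimates)))
  # the band is fit +/- 2 SE, so it brackets the fit symmetrically
  sm <- fit$smooth_estimates
  expect_equal(sm$fit - sm$lower, sm$upper - sm$fit, tolerance = 1e-10)
})
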