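two_year_days <- c(as.Date("2021-07-01") + seq(0, 25, by = 5),
                   as.Date("2022-07-01") + seq(0, 25, by = 5))

test_that("genotype-by-day ANOVA separates day effects from genotype effects", {
  # additive day effects only: E highly significant, G and GxE null
  des <- experiment_design(genotypes = c("RC", "NAM1", "NAM2", "NAM3"),
                           sampling_days = as.Date("2021-07-01") + seq(0, 25, by = 5),
                           env_effects = list(a_qi = c(VPD_3day = 0.2)),
                           plot_sd = 0.02, disk_sd = 0.04, seed = 21)
  ex <- generate_experiment(des, traces = FALSE)
  plot_level <- average_replicates(ex$truth)
  tab <- anova_gxe(plot_level, "a_qi")
  expect_lt(tab$p_value[tab$term == "Day"], 0.001)
  expect_gt(tab$p_value[tab$term == "Day:Genotype"], 0.05)
  expect_error(anova_gxe(plot_level[plot_level$genotype == "RC", ], "a_qi"),
               "2 levels")
})

test_that("stepwise AIC finds a strong covariate and never worsens the null model", {
  withr::with_seed(31, {
    n <- 300
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(X) <- c("morning_Ta", "morning_VPD", "morning_Fsd", "Ta_3day",
                  "VPD_3day", "Precip_3day_sum")
    X$a_qi <- X$VPD_3day * 1.0 + rnorm(n)
    sel <- stepwise_env_model(X, "a_qi", covariates = setdiff(names(X), "a_qi"))
    expect_true("VPD_3day" %in% sel$selected)
    expect_gt(abs(sel$coefficients[["VPD_3day"]]), 0.5)
    expect_gt(sel$r_squared, 0.3)
    # pure-noise response: selection never beats the intercept-only AIC
    X$noise <- rnorm(n)
    sel0 <- stepwise_env_model(X, "noise", covariates = setdiff(names(X), c("a_qi", "noise")))
    null_aic <- stats::AIC(stats::lm(noise ~ 1, data = X))
    expect_lte(sel0$aic, null_aic + 1e-9)
    expect_lt(sel0$r_squared, 0.1)
  })
})

test_that("canonical correlations match the brute-force eigen oracle", {
  withr::with_seed(41, {
    n <- 120
    x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("npq", 1:6)))
    y0 <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("env", 1:6)))
    y <- 0.4 * x %*% matrix(rnorm(36), 6, 6) + y0
    res <- run_cca(x, y)
    expect_equal(res$cor, cca_eigen_oracle(x, y), tolerance = 1e-10)
    expect_true(all(diff(res$cor) <= 1e-12))
    expect_true(all(res$cor >= 0 & res$cor <= 1))
    # axes beyond p are not invented
    expect_length(res$cor, 6)
  })
})

test_that("CCA finds perfect association and is affine-invariant within blocks", {
  withr::with_seed(43, {
    n <- 80
    x <- matrix(rnorm(n * 4), n, 4)
    y <- x %*% matrix(rnorm(16), 4, 4)  # exact linear transform
    expect_equal(run_cca(x, y)$cor[1], 1, tolerance = 1e-8)
    x2 <- matrix(rnorm(n * 3), n, 3)
    y2 <- matrix(rnorm(n * 3), n, 3)
    r0 <- run_cca(x2, y2)$cor
    A <- matrix(rnorm(9), 3, 3) + diag(3)
    r1 <- run_cca(sweep(x2 %*% A, 2, c(1, -2, 5), "+"), y2)$cor
    expect_equal(r1, r0, tolerance = 1e-8)
  })
})

test_that("Wilks' Lambda p-values are small for real association, large for noise", {
  withr::with_seed(47, {
    n <- 150
    x <- matrix(rnorm(n * 3), n, 3)
    y <- x + matrix(rnorm(n * 3, 0, 0.5), n, 3)
    w <- run_cca(x, y)$wilks
    expect_lt(w$p_value[1], 1e-10)
    ynull <- matrix(rnorm(n * 3), n, 3)
    w0 <- run_cca(x, ynull)$wilks
    expect_gt(w0$p_value[1], 0.001)
    expect_true(all(w0$lambda <= 1 & w0$lambda >= 0))
  })
})

test_that("per-day PCA recovers structure, outliers and group differences", {
  des <- experiment_design(genotypes = c("RC", paste0("NAM", 1:9)),
                           groups = stats::setNames(c("RC", rep(c("elite", "diverse", "PI"), 3)),
                                                    c("RC", paste0("NAM", 1:9))),
                           sampling_days = as.Date("2021-07-01") + c(0, 7),
                           genotype_effects = list(NAM1 = c(a_qe = 0.8)),
                           plot_sd = 0.02, disk_sd = 0.03, seed = 51)
  ex <- generate_experiment(des, traces = FALSE)
  ex$truth$max_npq <- with(ex$truth, (a_qe + a_qm + a_qi) * (1 - exp(-10)))
  pl <- average_replicates(ex$truth)
  res <- pca_by_day(pl, "2021-07-01")
  # the NAM1 a_qe offset dominates one component; NAM1 is labelled an outlier
  expect_true("NAM1" %in% res$outliers$genotype)
  # scores match an independent SVD up to sign
  d <- pl[pl$date == as.Date("2021-07-01"), ]
  Z <- scale(as.matrix(d[c("a_qe", "a_qm", "a_qi", "tau_qe", "tau_qm", "max_npq")]))
  sv <- svd(Z)
  ref <- sv$u[, 1] * sv$d[1]
  expect_equal(abs(stats::cor(res$scores$PC1, ref)), 1, tolerance = 1e-8)
  expect_error(pca_by_day(pl[pl$genotype %in% c("RC", "NAM1"), ], "2021-07-01"),
               "3 genotypes")
})

test_that("perfectly collinear parameters put all variance on PC1", {
  d <- data.frame(date = as.Date("2021-07-01"), genotype = rep(c("a", "b", "c"), 4),
                  group = "diverse")
  base <- rnorm(12)
  d$a_qe <- base; d$a_qm <- 2 * base; d$a_qi <- -base
  d$tau_qe <- base + 5; d$tau_qm <- 3 * base; d$max_npq <- base
  res <- pca_by_day(d, "2021-07-01")
  expect_equal(res$explained[1], 1, tolerance = 1e-10)
})

test_that("mixed-model screen flags exactly the genotypes given effects", {
  des <- experiment_design(genotypes = c("RC", paste0("NAM", 1:3)),
                           sampling_days = two_year_days,
                           genotype_effects = list(NAM2 = c(a_qi = -0.15)),
                           plot_sd = 0.05, disk_sd = 0.05, seed = 1)
  ex <- generate_experiment(des, traces = FALSE)
  scr <- mixed_model_screen(ex$truth, "a_qi")
  flagged <- scr$summary$genotype[scr$summary$consistent]
  expect_equal(flagged, "NAM2")
  expect_equal(scr$summary$sign[scr$summary$genotype == "NAM2"], -1)
  # bookkeeping: all six scenarios usable, details complete
  expect_equal(unique(scr$summary$n_scenarios), 6)
  expect_equal(nrow(scr$details), 3 * 6)
  expect_error(mixed_model_screen(ex$truth[ex$truth$genotype != "RC", ], "a_qi"),
               "reference")
})

test_that("genotype-mean correlations hit the exact degenerate cases", {
  a <- data.frame(genotype = paste0("g", 1:12), a_qi = rnorm(12))
  b <- a
  expect_equal(genotype_mean_correlations(a, b)$r, 1, tolerance = 1e-12)
  b$a_qi <- -a$a_qi
  expect_equal(genotype_mean_correlations(a, b)$r, -1, tolerance = 1e-12)
  expect_error(genotype_mean_correlations(a[1:2, ], b[1:2, ]), "3 shared")
  # external trait column
  yield <- data.frame(genotype = a$genotype, yield = a$a_qi * 2 + rnorm(12, 0, 1e-8))
  r <- genotype_mean_correlations(a, yield)
  expect_equal(r$r[r$parameter == "a_qi"], 1, tolerance = 1e-6)
})
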