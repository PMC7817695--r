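# Reference ranges, Wilcoxon screen, effective tests, MVE-robust
# Mahalanobis, and the line-level verdicts.

test_that("reference ranges take the right branch per distribution", {
  set.seed(101)
  x <- rnorm(100)
  rr <- fit_reference_range(x)
  expect_true(rr$is_normal)
  expect_equal(rr$low, -2, tolerance = 0.15)
  expect_equal(rr$high, 2, tolerance = 0.15)
  expect_equal(rr$center, mean(x))

  # Shapiro-Wilk rejects lognormal data with high power at n = 100
  rejections <- vapply(1:40, function(i) {
    y <- exp(rnorm(100, 0, 1))
    r <- fit_reference_range(y)
    !r$is_normal
  }, TRUE)
  expect_gt(mean(rejections), 0.95)
  y <- exp(rnorm(100, 0, 1))
  ry <- fit_reference_range(y)
  expect_equal(ry$low, quantile(y, 0.025, names = FALSE))
  expect_equal(ry$high, quantile(y, 0.975, names = FALSE))
  expect_equal(ry$center, median(y))
})

test_that("degenerate and tiny reference samples are handled", {
  expect_error(fit_reference_range(c(1, 2)), "at least 3")
  expect_warning(rr <- fit_reference_range(rep(5, 10)), "constant")
  expect_equal(rr$low, rr$high)
})

test_that("percentile branch contains the central 95% of the fit sample", {
  set.seed(7)
  y <- exp(rnorm(500))
  rr <- fit_reference_range(y)
  inside <- mean(y >= rr$low & y <= rr$high)
  expect_equal(inside, 0.95, tolerance = 0.01)
})

test_that("range-outlier calls respect the boundary", {
  rr <- structure(list(is_normal = TRUE, center = 0, low = -2, high = 2,
                       n_reference = 100), class = "reference_range")
  expect_false(classify_range_outlier(c(0, 0.1), rr))
  expect_true(classify_range_outlier(2.001, rr))
  expect_false(classify_range_outlier(2, rr))  # boundary not outside

  # +3 SD lines of n = 5 are detected nearly always
  set.seed(33)
  hits <- vapply(1:200, function(i) {
    ref <- rnorm(100)
    line <- rnorm(5, 3)
    classify_range_outlier(line, fit_reference_range(ref))
  }, TRUE)
  expect_gt(mean(hits), 0.95)
})

test_that("wilcoxon screen matches enumeration and handles ties", {
  expect_equal(wilcoxon_screen(c(1, 1, 1), c(1, 1, 1)), 1)
  # complete separation 3 vs 5: exact P = 2/56
  p <- wilcoxon_screen(1:3, 4:8)
  expect_equal(p, 2 * factorial(3) * factorial(5) / factorial(8))
  # exact branch equals the permutation oracle for pooled n <= 8
  set.seed(5)
  for (n1 in 2:4) {
    x <- rnorm(n1); y <- rnorm(8 - n1, 0.8)
    expect_equal(wilcoxon_screen(x, y), oracle_wilcoxon(x, y),
                 tolerance = 1e-12)
  }
})

test_that("effective tests follow the eigenvalue formula", {
  set.seed(19)
  X <- matrix(rnorm(4000 * 6), 4000, 6)
  expect_equal(effective_tests(X), 6, tolerance = 0.02)

  rank1 <- X[, 1] %o% rep(1, 6) + matrix(rnorm(4000 * 6, 0, 1e-8), 4000)
  expect_equal(effective_tests(rank1), 1, tolerance = 0.01)

  # 18 columns with two duplicated pairs: N_eff = 16
  Y <- matrix(rnorm(5000 * 18), 5000, 18)
  Y[, 2] <- Y[, 1]; Y[, 4] <- Y[, 3]
  expect_equal(effective_tests(Y), 16, tolerance = 0.02)

  Z <- cbind(X, rep(1, 4000)); colnames(Z) <- c(paste0("p", 1:6), "const")
  expect_error(effective_tests(Z), "const")
})

test_that("N_eff stays in [1, N] and shrinks with exchangeable correlation", {
  set.seed(23)
  neffs <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    R <- matrix(rho, 8, 8); diag(R) <- 1
    L <- chol(R)
    X <- matrix(rnorm(800 * 8), 800) %*% L
    effective_tests(X)
  }, 1.0)
  expect_true(all(neffs >= 1 & neffs <= 8))
  expect_true(all(diff(neffs) < 0))
})

test_that("bonferroni thresholds reproduce the published cutoffs", {
  expect_equal(bonferroni_threshold(0.05, 8.8), 0.00568, tolerance = 5e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 18), 0.002778, tolerance = 1e-4)
})

test_that("MVE subset size follows h = floor((n+p+1)/2)", {
  set.seed(41)
  X <- matrix(rnorm(100 * 18), 100, 18)
  fit <- mve_fit(X, seed = 1, nsamp = 500)
  expect_equal(fit$h, 59)
  expect_equal(nrow(X) > ncol(X), TRUE)
  expect_error(mve_fit(matrix(rnorm(20), 4, 5)), "more observations")
})

test_that("MVE centre tracks the mean on clean data and resists
           contamination", {
  set.seed(55)
  X <- matrix(rnorm(200 * 2), 200, 2)
  fit <- mve_fit(X, seed = 2)
  expect_lt(sqrt(sum((fit$center - colMeans(X))^2)), 0.2)

  # 20% gross outliers at +10 sigma
  n <- 200; p <- 5
  X2 <- rbind(matrix(rnorm(160 * p), 160, p),
              matrix(rnorm(40 * p, 10), 40, p))
  fit2 <- mve_fit(X2, seed = 3)
  expect_lt(sqrt(sum(fit2$center^2)), 0.5)
  expect_gt(sqrt(sum(colMeans(X2)^2)), 4)  # classical mean is dragged
})

test_that("robust distances agree with an independent MVE implementation", {
  skip_if_not_installed("MASS")
  set.seed(77)
  X <- rbind(matrix(rnorm(150 * 3), 150, 3),
             matrix(rnorm(30 * 3, 6), 30, 3))
  fit <- mve_fit(X, seed = 5)
  set.seed(99)
  mv <- MASS::cov.mve(X)
  expect_lt(sqrt(sum((fit$center - mv$center)^2)), 0.5)
  flags1 <- robust_mahalanobis(X, fit)$flags
  flags2 <- mahalanobis(X, mv$center, mv$cov) > qchisq(0.975, 3)
  # both flag the planted cluster
  expect_true(all(flags1[151:180]))
  expect_true(all(flags2[151:180]))
})

test_that("Mahalanobis distances: identity-covariance arithmetic", {
  fit <- list(center = c(0, 0), cov = diag(2))
  md <- robust_mahalanobis(rbind(c(0, 0), c(3, 4)), fit)
  expect_equal(md$distances, c(0, 5))
  expect_equal(md$cutoff, qchisq(0.975, 2))
  expect_error(robust_mahalanobis(matrix(0, 1, 3), fit), "mismatch")
})

test_that("clean multivariate normal data is flagged at about 2.5%", {
  set.seed(123)
  p <- 5
  X <- matrix(rnorm(2000 * p), 2000, p)
  fit <- mve_fit(X, seed = 7)
  rate <- mean(robust_mahalanobis(X, fit)$flags)
  expect_gt(rate, 0.015); expect_lt(rate, 0.035)
})

test_that("line-level Mahalanobis call uses the inclusive 50% rule", {
  expect_true(line_mahalanobis_call(c(TRUE, TRUE, FALSE, FALSE)))
  expect_false(line_mahalanobis_call(c(TRUE, FALSE, FALSE)))
  expect_false(line_mahalanobis_call(logical(0)))
  expect_false(line_mahalanobis_call(c(FALSE, FALSE)))
})

test_that("screen_lines: constructed cartilage effect fires all criteria", {
  spec <- cohort_spec(lines = list(
    list(label = "hit", n = 6,
         effect = c(Cg.V.MTP = -3.5, Median.Cg.Th.MTP = -3.5,
                    Max.Cg.Th.MTP = -3.5)),
    list(label = "null", n = 5, effect = NULL)), seed = 29L)
  tab <- generate_cohort(spec)
  rep <- screen_lines(tab, config = screen_config(mve_nsamp = 3000L))
  hit <- rep$reports$hit
  expect_true(all(hit$criteria))
  expect_true(hit$categories[["cartilage_morphology"]])
  expect_false(hit$categories[["cartilage_integrity"]])
  expect_gte(hit$severity_points, 4)
  # a no-effect line may graze the reference range on a skewed parameter
  # or trip the (anti-conservative at p = 18, n = 100) chi-square
  # Mahalanobis cutoff, but never the Bonferroni-corrected Wilcoxon
  expect_false(rep$reports$null$criteria[["wilcoxon"]])
  expect_lte(rep$reports$null$severity_points, 3)
  expect_true(rep$n_eff >= 1 && rep$n_eff <= 18)
  # QQ diagnostic present and ordered
  expect_true(all(diff(rep$qq$md2) >= 0))
  expect_equal(length(rep$qq$md2), length(rep$qq$chisq))
})

test_that("a line identical to the reference scores zero severity", {
  tab <- generate_cohort(cohort_spec(seed = 37L))
  dup <- tab[1:5, ]
  dup$line <- "copy"
  dup$animal_id <- paste0("copy_", 1:5)
  tab2 <- rbind(tab, dup)
  class(tab2) <- c("phenotype_table", "data.frame")
  rep <- screen_lines(tab2, config = screen_config(mve_nsamp = 2000L))
  expect_equal(rep$reports$copy$severity_points, 0)
  expect_false(any(rep$reports$copy$criteria))
})

test_that("missing values drop animals from Mahalanobis with a warning", {
  spec <- cohort_spec(lines = list(list(label = "m", n = 4, effect = NULL)),
                      seed = 31L)
  tab <- generate_cohort(spec)
  tab[tab$line == "m", "Cg.V.LTP"][1] <- NA
  expect_warning(rep <- screen_lines(tab,
                                     config = screen_config(mve_nsamp = 2000L)),
                 "missing")
  expect_equal(length(rep$reports$m$mahalanobis_distances), 3)
})
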