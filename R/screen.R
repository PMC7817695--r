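# The three-criterion outlier screen for mutant lines: wild-type reference
# ranges (Shapiro-Wilk branch), two-tailed Wilcoxon rank sum tests with a
# Bonferroni correction for the effective number of tests, and robust
# minimum-volume-ellipsoid Mahalanobis distances, plus line-level severity
# scoring.

#' Fit a wild-type reference range for one parameter
#'
#' The Shapiro-Wilk test (at `alpha_normality`) decides the branch: for
#' normally distributed data the range is the mean +/- 2.0 sample standard
#' deviations; otherwise it is the 2.5th-97.5th percentile range (linear
#' interpolation between closest ranks, the type-7 convention) around the
#' median.
#'
#' @param values numeric vector of reference measurements (n >= 3).
#' @param alpha_normality Shapiro-Wilk significance level.
#' @return a list of class `reference_range` with `is_normal`, `center`,
#'   `low`, `high`, `n_reference`.
#' @export
fit_reference_range <- function(values, alpha_normality = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 finite reference values")
  if (diff(range(values)) == 0) {
    warning("constant reference sample; degenerate range")
    rr <- list(is_normal = NA, center = values[1], low = values[1],
               high = values[1], n_reference = length(values),
               shapiro_p = NA_real_)
    class(rr) <- "reference_range"
    return(rr)
  }
  sw <- shapiro.test(values)
  is_normal <- sw$p.value >= alpha_normality
  if (is_normal) {
    ctr <- mean(values)
    s <- sd(values)
    low <- ctr - 2 * s; high <- ctr + 2 * s
  } else {
    ctr <- median(values)
    q <- quantile(values, c(0.025, 0.975), type = 7, names = FALSE)
    low <- q[1]; high <- q[2]
  }
  structure(list(is_normal = is_normal, center = ctr, low = low,
                 high = high, n_reference = length(values),
                 shapiro_p = sw$p.value),
            class = "reference_range")
}

#' Reference-range outlier call for a mutant line
#'
#' A parameter is an outlier when the line's mean value lies outside the
#' reference range.
#'
#' @param line_values the line's measurements for one parameter.
#' @param range a [fit_reference_range()] result.
#' @return logical flag.
#' @export
classify_range_outlier <- function(line_values, range) {
  stopifnot(inherits(range, "reference_range"))
  line_values <- line_values[is.finite(line_values)]
  if (!length(line_values)) stop("no finite line values")
  m <- mean(line_values)
  m < range$low || m > range$high
}

#' Two-tailed Wilcoxon rank sum screen for one parameter
#'
#' Exact P for small untied samples, normal approximation with tie and
#' continuity correction otherwise (the R `wilcox.test` convention).
#'
#' @param line_values,reference_values the two samples.
#' @param exact forwarded to [wilcox.test()]; `NULL` keeps the default
#'   switch.
#' @return the two-sided P value.
#' @export
wilcoxon_screen <- function(line_values, reference_values, exact = NULL) {
  line_values <- line_values[is.finite(line_values)]
  reference_values <- reference_values[is.finite(reference_values)]
  stopifnot(length(line_values) >= 1, length(reference_values) >= 1)
  pooled <- c(line_values, reference_values)
  if (diff(range(pooled)) == 0) return(1)
  suppressWarnings(
    wilcox.test(line_values, reference_values, exact = exact)$p.value)
}

#' Effective number of tests among correlated parameters
#'
#' From the eigenvalues of the parameter correlation matrix:
#' N_eff = N - sum over eigenvalues lambda > 1 of (lambda - 1). Equals N
#' for independent parameters and 1 in the rank-one limit.
#'
#' @param reference_matrix numeric matrix, animals x parameters.
#' @return N_eff (numeric scalar in `[1, N]`).
#' @export
effective_tests <- function(reference_matrix) {
  X <- as.matrix(reference_matrix)
  stopifnot(ncol(X) >= 2, nrow(X) >= 3)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant parameter column: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  lambda <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  ncol(X) - sum(pmax(lambda - 1, 0))
}

#' Bonferroni threshold for the effective number of tests
#'
#' @param alpha family-wise level.
#' @param n_eff effective number of tests (>= 1).
#' @return per-test significance threshold `alpha / n_eff`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_eff) {
  stopifnot(n_eff >= 1)
  alpha / n_eff
}

#' Robust location and scatter by the minimum volume ellipsoid
#'
#' Seeks the ellipsoid of minimum volume containing h = floor((n+p+1)/2)
#' points. Candidate ellipsoids are grown from random (p+1)-point elemental
#' subsets (exhaustively for small n); the h points inside the best
#' candidate supply the robust mean and covariance, the latter rescaled by
#' the chi-square consistency factor so squared robust distances of clean
#' multivariate-normal data are approximately chi-square with p degrees of
#' freedom.
#'
#' @param X numeric matrix, n x p with n > p.
#' @param seed integer seed for the subset search.
#' @param nsamp subset budget (default 10000; the search is exhaustive when
#'   the number of elemental subsets is at most `nsamp`, which covers
#'   n <= 20 at small p).
#' @return a list of class `mve_fit` with `center` (T(X)), `cov` (C(X)),
#'   `h`, `n`, `p`, `best_subset` (indices of the h points).
#' @export
mve_fit <- function(X, seed = 1L, nsamp = 10000L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than variables for MVE")
  h <- floor((n + p + 1) / 2)
  res <- with_seed(split_seed(seed, 4L), .mve_search(X, h, as.integer(nsamp)))
  if (res$n_valid == 0)
    stop("no non-singular elemental subset found; data may be degenerate")
  idx <- order(res$d2)[seq_len(h)]
  ctr <- colMeans(X[idx, , drop = FALSE])
  C <- cov(X[idx, , drop = FALSE])
  ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
  if (!ok) stop("singular covariance on the best h-subset")
  alpha <- h / n
  cf <- alpha / pchisq(qchisq(alpha, p), p + 2)
  C <- C * cf
  structure(list(center = ctr, cov = C, h = h, n = n, p = p,
                 best_subset = idx, n_subsets_tried = res$n_tried,
                 exhaustive = res$exhaustive),
            class = "mve_fit")
}

#' Robust Mahalanobis distances and outlier flags
#'
#' MD_i = sqrt((x_i - T) C^-1 (x_i - T)'); under multivariate normality
#' MD^2 is approximately chi-square with p degrees of freedom, so samples
#' with MD^2 above the 0.975 chi-square quantile are flagged as outliers.
#'
#' @param X numeric matrix of samples (rows), p columns.
#' @param fit an [mve_fit()] (or any list with `center` and `cov`).
#' @param level chi-square quantile used for flagging.
#' @return a list with `distances` (MD_i), `flags` (MD^2 > cutoff),
#'   `cutoff` (the chi-square quantile).
#' @export
robust_mahalanobis <- function(X, fit, level = 0.975) {
  X <- as.matrix(X)
  p <- length(fit$center)
  if (ncol(X) != p) stop("dimension mismatch between X and the fit")
  d2 <- mahalanobis(X, fit$center, fit$cov)
  cutoff <- qchisq(level, df = p)
  list(distances = sqrt(d2), flags = d2 > cutoff, cutoff = cutoff)
}

#' Line-level Mahalanobis call
#'
#' A line has an abnormal multivariate phenotype only when 50% or more of
#' its animals are flagged.
#'
#' @param flags_for_line logical vector of per-animal flags.
#' @return logical flag.
#' @export
line_mahalanobis_call <- function(flags_for_line) {
  if (!length(flags_for_line)) return(FALSE)
  mean(flags_for_line) >= 0.5
}

#' Default parameter-to-category map for severity scoring
#'
#' Joint pathology categories: abnormal articular cartilage morphology
#' (volume and thickness), cartilage integrity (surface damage), and
#' subchondral bone structure (BV/TV, Tb.Th, Tb.N, TMD, BMC), each
#' evaluated across both plateaux.
#'
#' @return named list of base-parameter vectors.
#' @export
default_category_map <- function() {
  list(cartilage_morphology = c("Cg.V", "Median.Cg.Th", "Max.Cg.Th"),
       cartilage_integrity = "Cg.Damage.Area",
       subchondral_structure = c("SC.BV.TV", "SC.Tb.Th", "SC.Tb.N",
                                 "SC.TMD", "SC.BMC"))
}

#' Screen configuration
#'
#' @param alpha family-wise level for the Bonferroni-corrected Wilcoxon
#'   criterion.
#' @param alpha_normality Shapiro-Wilk level for the reference-range
#'   branch.
#' @param stringent_threshold second, fixed threshold also correcting for
#'   the number of lines screened.
#' @param category_map see [default_category_map()].
#' @param mahalanobis_level chi-square quantile for per-animal flags.
#' @param seed seed of the MVE subset search.
#' @param mve_nsamp MVE subset budget.
#' @param exact forwarded to [wilcoxon_screen()].
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.05, alpha_normality = 0.05,
                          stringent_threshold = 1e-4,
                          category_map = default_category_map(),
                          mahalanobis_level = 0.975, seed = 1L,
                          mve_nsamp = 10000L, exact = NULL) {
  structure(as.list(environment()), class = "screen_config")
}

strip_side <- function(parameter) sub("[._](LTP|MTP)$", "", parameter)

#' Screen all mutant lines of a phenotype table
#'
#' Evaluates the three outlier criteria for every non-reference line:
#' (i) line mean outside the wild-type reference range for any parameter;
#' (ii) two-tailed Wilcoxon rank sum test against the reference animals
#' with Bonferroni correction for the effective number of tests; (iii)
#' robust MVE-Mahalanobis outliers, with a line called only when at least
#' half its animals are flagged. Parameters abnormal by (i) or (ii) are
#' mapped to pathology categories, and severity points are the number of
#' criteria met (max 3) plus the number of abnormal categories (max 3).
#'
#' @param table a `phenotype_table` (columns `line`, `animal_id`,
#'   parameters).
#' @param reference_line label of the reference (wild-type) line.
#' @param config a [screen_config()].
#' @return a list of class `line_screen_report_set`: `n_eff`, `threshold`,
#'   `stringent_threshold`, `ranges`, `mve`, `qq` (ordered reference MD^2
#'   vs chi-square quantiles), and `reports` -- one `line_screen_report`
#'   per mutant line.
#' @export
screen_lines <- function(table, reference_line = "WT",
                         config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  params <- setdiff(names(table), c("line", "animal_id"))
  if (!reference_line %in% table$line)
    stop("reference line '", reference_line, "' not present")
  ref <- table[table$line == reference_line, params, drop = FALSE]
  ref <- as.matrix(ref)
  if (anyNA(ref)) {
    warning("reference rows with missing values dropped for Mahalanobis")
  }
  ranges <- lapply(params, function(p)
    fit_reference_range(ref[, p], config$alpha_normality))
  names(ranges) <- params
  n_eff <- effective_tests(ref[stats::complete.cases(ref), , drop = FALSE])
  thr <- bonferroni_threshold(config$alpha, n_eff)
  refc <- ref[stats::complete.cases(ref), , drop = FALSE]
  fit <- mve_fit(refc, seed = config$seed, nsamp = config$mve_nsamp)
  ref_md <- robust_mahalanobis(refc, fit, config$mahalanobis_level)
  qq <- list(md2 = sort(ref_md$distances^2),
             chisq = qchisq(stats::ppoints(nrow(refc)), df = ncol(refc)))
  lines <- setdiff(unique(table$line), reference_line)
  reports <- lapply(lines, function(ln) {
    rows <- table[table$line == ln, , drop = FALSE]
    X <- as.matrix(rows[, params, drop = FALSE])
    range_flags <- vapply(params, function(p)
      classify_range_outlier(X[, p], ranges[[p]]), TRUE)
    wp <- vapply(params, function(p)
      wilcoxon_screen(X[, p], ref[, p], exact = config$exact), 1.0)
    w_flags <- wp < thr
    w_flags2 <- wp < config$stringent_threshold
    Xc <- X[stats::complete.cases(X), , drop = FALSE]
    if (nrow(Xc) < nrow(X))
      warning("line ", ln, ": rows with missing values dropped from the ",
              "Mahalanobis criterion")
    md <- if (nrow(Xc)) robust_mahalanobis(Xc, fit,
                                           config$mahalanobis_level)
      else list(distances = numeric(), flags = logical())
    m_call <- line_mahalanobis_call(md$flags)
    abnormal <- range_flags | w_flags
    base <- strip_side(params)
    cats <- vapply(config$category_map, function(members)
      any(abnormal[base %in% members]), TRUE)
    n_crit <- sum(any(range_flags), any(w_flags), m_call)
    severity <- min(3L, n_crit) + min(3L, sum(cats))
    structure(list(
      line = ln, n_animals = nrow(rows),
      range_outlier_params = params[range_flags],
      wilcoxon_p = wp,
      wilcoxon_outlier = w_flags,
      wilcoxon_outlier_stringent = w_flags2,
      mahalanobis_distances = md$distances,
      mahalanobis_fraction = if (length(md$flags)) mean(md$flags) else 0,
      mahalanobis_call = m_call,
      categories = cats,
      criteria = c(range = any(range_flags), wilcoxon = any(w_flags),
                   mahalanobis = m_call),
      severity_points = severity),
      class = "line_screen_report")
  })
  names(reports) <- lines
  structure(list(n_eff = n_eff, threshold = thr,
                 stringent_threshold = config$stringent_threshold,
                 ranges = ranges, mve = fit, qq = qq, reports = reports,
                 reference_line = reference_line),
            class = "line_screen_report_set")
}

#' @export
print.line_screen_report <- function(x, ...) {
  cat(sprintf("<line_screen_report> %s (n=%d): criteria %s; severity %d/6\n",
              x$line, x$n_animals,
              paste(names(x$criteria)[x$criteria], collapse = "+"),
              x$severity_points))
  invisible(x)
}

#' Summarise a screen as a data frame
#'
#' @param reports a `line_screen_report_set` from [screen_lines()].
#' @return data frame, one row per line.
#' @export
screen_summary <- function(reports) {
  do.call(rbind, lapply(reports$reports, function(r)
    data.frame(line = r$line, n = r$n_animals,
               range = r$criteria[["range"]],
               wilcoxon = r$criteria[["wilcoxon"]],
               mahalanobis = r$criteria[["mahalanobis"]],
               mahalanobis_fraction = r$mahalanobis_fraction,
               severity_points = r$severity_points)))
}
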