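# Histology score arithmetic, precision/repeatability metrics, power
# calculations, the 21-point gene prioritization ledger, and enrichment
# testing.

round_to_half <- function(x) {
  # nearest 0.5, ties (x.25 / x.75) rounding up
  floor(x * 2 + 0.5) / 2
}

#' Weighted OARSI score for incomplete section sets
#'
#' When fewer than five sections are scoreable the summed score is
#' weighted up: weighted = score + (5 - N) * (score / N), rounded to the
#' nearest 0.5 (ties up).
#'
#' @param score_sum summed score over the scoreable sections.
#' @param n_scoreable number of scoreable sections, 1..5.
#' @return the weighted score on the 0.5 grid.
#' @export
weighted_oarsi <- function(score_sum, n_scoreable) {
  if (any(n_scoreable < 1 | n_scoreable > 5))
    stop("n_scoreable must be between 1 and 5")
  round_to_half(score_sum + (5 - n_scoreable) * (score_sum / n_scoreable))
}

#' Per-compartment and whole-joint OARSI summaries
#'
#' Sum scores are the sum over the (up to five) section levels; the
#' maximum score is the highest section score (each section graded 0-6).
#' Joint totals aggregate the four compartments (MTP, MFC, LTP, LFC).
#'
#' @param scores named list of numeric section-score vectors, one per
#'   compartment (length <= 5, values 0-6).
#' @param weighted apply [weighted_oarsi()] to sums when fewer than five
#'   sections are scoreable.
#' @return a list with `per_compartment` (data frame: sum, max, n) and
#'   `joint_sum`, `joint_max`.
#' @export
compartment_summary <- function(scores, weighted = TRUE) {
  stopifnot(is.list(scores), length(scores) >= 1)
  per <- lapply(names(scores), function(cmp) {
    s <- scores[[cmp]]
    if (length(s) > 5) stop(cmp, ": more than five section scores")
    if (length(s) && any(s < 0 | s > 6)) stop(cmp, ": scores must be 0-6")
    n <- length(s)
    ssum <- if (n == 0) 0 else if (weighted && n < 5)
      weighted_oarsi(sum(s), n) else sum(s)
    data.frame(compartment = cmp, sum = ssum,
               max = if (n) max(s) else 0, n_scoreable = n)
  })
  per <- do.call(rbind, per)
  list(per_compartment = per,
       joint_sum = sum(per$sum),
       joint_max = max(per$max))
}

#' Synovitis severity score
#'
#' Sum of the pannus formation (0-3), synovial lining hyperplasia (0-3)
#' and sub-synovial inflammation (0-3) subscores.
#'
#' @param pannus,hyperplasia,inflammation integer subscores 0-3.
#' @return severity score 0-9.
#' @export
synovitis_severity <- function(pannus, hyperplasia, inflammation) {
  s <- c(pannus, hyperplasia, inflammation)
  if (any(s < 0 | s > 3)) stop("synovitis subscores must be in 0-3")
  pannus + hyperplasia + inflammation
}

#' Precision errors across repeated measurements
#'
#' Per sample: PE(SD), the standard deviation over replicates, and
#' PE(%CV) = 100 * SD / mean. Parameter-level averages are root mean
#' squares of the per-sample errors.
#'
#' @param replicates numeric matrix (samples x repeats) or a list of
#'   per-sample replicate vectors (>= 2 replicates each).
#' @return a list with `per_sample` (data frame: mean, pe_sd, pe_cv) and
#'   `rms_pe_sd`, `rms_pe_cv`.
#' @export
precision_metrics <- function(replicates) {
  if (is.matrix(replicates) || is.data.frame(replicates))
    replicates <- split(as.matrix(replicates), row(as.matrix(replicates)))
  stopifnot(all(lengths(replicates) >= 2))
  per <- do.call(rbind, lapply(seq_along(replicates), function(i) {
    x <- as.numeric(replicates[[i]])
    m <- mean(x); s <- sd(x)
    cv <- if (m == 0) {
      if (s > 0) warning("sample ", i, ": zero mean with nonzero SD; ",
                         "%CV undefined")
      NA_real_
    } else 100 * s / m
    data.frame(sample = i, mean = m, pe_sd = s, pe_cv = cv)
  }))
  list(per_sample = per,
       rms_pe_sd = sqrt(mean(per$pe_sd^2)),
       rms_pe_cv = sqrt(mean(per$pe_cv^2, na.rm = TRUE)))
}

#' Intra-class correlation, two-way model, single measure, absolute
#' agreement
#'
#' ICC(A,1) from the two-way mean-square decomposition with the standard
#' F-based 95% confidence interval.
#'
#' @param matrix numeric matrix, samples (rows) x repeats (columns), no
#'   missing cells.
#' @param conf_level confidence level.
#' @return a list with `icc`, `lower`, `upper`, `excellent`
#'   (icc > 0.8, the conventional bar for excellent reproducibility).
#' @export
icc_absolute_agreement <- function(matrix, conf_level = 0.95) {
  X <- as.matrix(matrix)
  stopifnot(nrow(X) >= 2, ncol(X) >= 2, !anyNA(X))
  n <- nrow(X); k <- ncol(X)
  if (var(as.vector(X)) == 0) {
    warning("zero total variance; ICC undefined")
    return(list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                excellent = NA))
  }
  grand <- mean(X)
  row_m <- rowMeans(X); col_m <- colMeans(X)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((X - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # F-based interval (McGraw & Wong, case A-1)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, lower = lower, upper = upper, excellent = icc > 0.8)
}

#' Power index
#'
#' (Z_(1-alpha/2) + Z_(1-beta))^2; equals 7.85 at the conventional
#' alpha = 0.05, 80% power.
#'
#' @param alpha two-sided significance level.
#' @param power target power (1 - beta).
#' @return the power index.
#' @export
power_index <- function(alpha = 0.05, power = 0.8) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  (qnorm(1 - alpha / 2) + qnorm(power))^2
}

#' Mice per group to detect an effect
#'
#' N = ceiling(2 * index * sigma^2 / d^2), with the median absolute
#' deviation replacing sigma for non-normally distributed parameters.
#' At d = 2 sigma and 80% power this gives four mice per group.
#'
#' @param effect effect size d (same units as `dispersion`).
#' @param dispersion sigma (or MAD).
#' @param alpha,power see [power_index()].
#' @return integer group size.
#' @export
required_n <- function(effect, dispersion = 1, alpha = 0.05, power = 0.8) {
  stopifnot(effect > 0, dispersion > 0)
  ceiling(2 * power_index(alpha, power) * dispersion^2 / effect^2)
}

#' Minimum detectable effect at a given group size
#'
#' Inversion of [required_n()]: d = sigma * sqrt(2 * index / n).
#'
#' @param n group size (>= 2).
#' @param dispersion sigma (or MAD).
#' @param alpha,power see [power_index()].
#' @return minimum detectable effect.
#' @export
minimum_detectable_effect <- function(n, dispersion = 1, alpha = 0.05,
                                      power = 0.8) {
  stopifnot(n >= 2, dispersion > 0)
  dispersion * sqrt(2 * power_index(alpha, power) / n)
}

#' Literature subscores from structured search counts
#'
#' PubMed: 0 (no publications), 0.5 (1-24), 1 (25 or more). Google
#' Scholar: 0 (under 100 results), 0.5 (100-999), 1 (1000 or more). The
#' printed bin edges leave exactly 25 publications and exactly 1000
#' results unassigned; both resolve to the higher bin with a warning.
#'
#' @param pubmed_n,scholar_n non-negative counts.
#' @return numeric vector c(pubmed, scholar) of subscores.
#' @export
literature_subscore <- function(pubmed_n, scholar_n) {
  stopifnot(pubmed_n >= 0, scholar_n >= 0)
  if (pubmed_n == 25)
    warning("exactly 25 publications falls in a bin gap; scored 1")
  if (scholar_n == 1000)
    warning("exactly 1000 results falls in a bin gap; scored 1")
  pm <- if (pubmed_n < 1) 0 else if (pubmed_n < 25) 0.5 else 1
  gs <- if (scholar_n < 100) 0 else if (scholar_n < 1000) 0.5 else 1
  c(pubmed = pm, scholar = gs)
}

#' Build a prioritization ledger
#'
#' Inputs to the 21-point priority score. Database searches themselves are
#' out of scope; their outcomes enter as flags and counts.
#'
#' @param severity_points joint-screen severity points 0-6 (from
#'   [screen_lines()]).
#' @param skeletal_sources logical, length 5: abnormal skeletal phenotype
#'   in the bone-phenotyping data, IMPReSS, DMDD, PubMed, MGI.
#' @param expression_flags logical, length 4: expression in skeleton,
#'   chondrocytes, osteoblasts/osteocytes, osteoclasts.
#' @param monogenic_mgi,monogenic_omim monogenic skeletal disease
#'   association in MGI / OMIM.
#' @param gwas_arthritis,gwas_skeletal GWAS-catalog association flags.
#' @param pubmed_n,scholar_n structured literature search counts.
#' @return a list of class `priority_ledger`.
#' @export
priority_ledger <- function(severity_points = 0,
                            skeletal_sources = rep(FALSE, 5),
                            expression_flags = rep(FALSE, 4),
                            monogenic_mgi = FALSE, monogenic_omim = FALSE,
                            gwas_arthritis = FALSE, gwas_skeletal = FALSE,
                            pubmed_n = 0, scholar_n = 0) {
  stopifnot(severity_points >= 0, severity_points <= 6,
            length(skeletal_sources) == 5, length(expression_flags) == 4,
            pubmed_n >= 0, scholar_n >= 0)
  structure(as.list(environment()), class = "priority_ledger")
}

#' 21-point gene priority score
#'
#' Category subscores: joint phenotyping severity (max 6), abnormal
#' skeletal phenotypes (1 point per source, max 5), expression in skeletal
#' tissues and cells (max 4), association with monogenic and polygenic
#' skeletal disease (MGI + OMIM + GWAS arthritis + GWAS skeletal, max 4),
#' and structured literature searching (max 2). The total is the sum,
#' maximum 21.
#'
#' @param ledger a [priority_ledger()].
#' @return a list of class `priority_score` with `joint`, `skeletal`,
#'   `expression`, `disease`, `literature`, `total`.
#' @export
priority_score <- function(ledger) {
  stopifnot(inherits(ledger, "priority_ledger"))
  joint <- min(6, ledger$severity_points)
  skeletal <- min(5, sum(ledger$skeletal_sources))
  expression <- min(4, sum(ledger$expression_flags))
  disease <- min(4, sum(ledger$monogenic_mgi, ledger$monogenic_omim,
                        ledger$gwas_arthritis, ledger$gwas_skeletal))
  lit <- sum(suppressWarnings(
    literature_subscore(ledger$pubmed_n, ledger$scholar_n)))
  structure(list(joint = joint, skeletal = skeletal,
                 expression = expression, disease = disease,
                 literature = lit,
                 total = joint + skeletal + expression + disease + lit),
            class = "priority_score")
}

#' @export
print.priority_score <- function(x, ...) {
  cat(sprintf("<priority_score> joint %g + skeletal %g + expression %g + disease %g + literature %g = %g / 21\n",
              x$joint, x$skeletal, x$expression, x$disease, x$literature,
              x$total))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided P as the sum of hypergeometric probabilities of all tables
#' with the observed margins whose point probability does not exceed that
#' of the observed table (the convention of `fisher.test`, to which this
#' delegates).
#'
#' @param table 2x2 matrix (or length-4 vector, column-major) of
#'   non-negative integer counts.
#' @return the two-sided P value.
#' @export
fisher_exact_two_sided <- function(table) {
  m <- matrix(as.numeric(table), 2, 2)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  if (sum(m) == 0) return(1)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  fisher.test(m)$p.value
}
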