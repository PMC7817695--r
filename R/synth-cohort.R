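#' Default joint phenotype parameter set
#'
#' The 18 knee parameters measured per animal: nine quantities on each of
#' the lateral (LTP) and medial (MTP) tibial plateaux. Marginal
#' distributions follow the normal / non-normal split observed in wild-type
#' reference data (e.g. cartilage damage area and medial-side parameters
#' are skewed), with plausible units and magnitudes for 16-week-old mice.
#' For normal marginals `p1`/`p2` are mean/SD; for lognormal marginals `p1`
#' is the median and `p2` the log-scale SD.
#'
#' @return data frame with columns `parameter`, `base`, `side`, `dist`,
#'   `p1`, `p2`.
#' @export
default_parameter_table <- function() {
  base <- c("Cg.V", "Median.Cg.Th", "Max.Cg.Th", "Cg.Damage.Area",
            "SC.BV.TV", "SC.Tb.Th", "SC.Tb.N", "SC.TMD", "SC.BMC")
  ltp <- data.frame(
    base = base, side = "LTP",
    dist = c("normal", "lognormal", "normal", "lognormal", "normal",
             "normal", "normal", "normal", "normal"),
    p1 = c(0.0050, 0.050, 0.095, 0.9, 0.35, 0.045, 4.5, 750, 120),
    p2 = c(0.0005, 0.08, 0.007, 0.55, 0.035, 0.004, 0.35, 35, 10))
  mtp <- data.frame(
    base = base, side = "MTP",
    dist = c("lognormal", "lognormal", "lognormal", "lognormal", "lognormal",
             "normal", "lognormal", "lognormal", "normal"),
    p1 = c(0.0050, 0.050, 0.095, 0.9, 0.35, 0.045, 4.5, 750, 120),
    p2 = c(0.10, 0.08, 0.08, 0.55, 0.10, 0.004, 0.08, 0.05, 10))
  out <- rbind(ltp, mtp)
  out$parameter <- paste(out$base, out$side, sep = ".")
  out[, c("parameter", "base", "side", "dist", "p1", "p2")]
}

#' Default correlation structure of the 18 joint parameters
#'
#' A two-block exchangeable structure: correlation 0.55 between parameters
#' measured on the same plateau and 0.15 across plateaux. Its eigenvalues
#' give an effective number of tests of about 9 for the 18 parameters,
#' emulating the substantial inter-parameter correlation of real joint
#' phenotype data.
#'
#' @param rho_within within-side correlation.
#' @param rho_between between-side correlation.
#' @return an 18 x 18 correlation matrix.
#' @export
default_joint_correlation <- function(rho_within = 0.55, rho_between = 0.15) {
  A <- matrix(rho_within, 9, 9); diag(A) <- 1
  B <- matrix(rho_between, 9, 9)
  R <- rbind(cbind(A, B), cbind(B, A))
  p <- default_parameter_table()$parameter
  dimnames(R) <- list(p, p)
  R
}

#' Specification of a synthetic phenotype cohort
#'
#' Reference animals are drawn from the stated marginals coupled by a
#' Gaussian copula with the given correlation matrix; each mutant line is
#' shifted by its effect vector in SD units on the latent normal scale (so
#' "effect in SD units" remains well-defined for skewed parameters).
#'
#' @param n_reference number of reference (wild-type) animals, >= 3;
#'   default 100 matches the size of the wild-type reference population.
#' @param parameters marginal table as from [default_parameter_table()].
#' @param correlation positive-semidefinite correlation matrix with unit
#'   diagonal.
#' @param lines list of mutant lines; each element a list with `label`,
#'   `n`, and `effect` (length-18 numeric, SD units; or a named vector over
#'   a subset of parameters, zero elsewhere).
#' @param reference_label label of the reference line.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_reference = 100L,
                        parameters = default_parameter_table(),
                        correlation = default_joint_correlation(),
                        lines = list(),
                        reference_label = "WT",
                        seed = 1L) {
  stopifnot(n_reference >= 3, is.data.frame(parameters))
  p <- nrow(parameters)
  stopifnot(identical(dim(correlation), c(p, p)))
  if (max(abs(correlation - t(correlation))) > 1e-10)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-10)
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("correlation matrix is not positive semidefinite: smallest eigenvalue %.6g",
                 min(ev)))
  for (ln in lines) {
    stopifnot(!is.null(ln$label), ln$n >= 1)
    if (!is.null(names(ln$effect)))
      stopifnot(all(names(ln$effect) %in% parameters$parameter))
    else if (length(ln$effect) > 1)
      stopifnot(length(ln$effect) == p)
    stopifnot(all(is.finite(ln$effect)))
  }
  structure(as.list(environment()), class = "cohort_spec")
}

expand_effect <- function(effect, parameter_names) {
  p <- length(parameter_names)
  if (is.null(effect)) return(numeric(p))
  if (!is.null(names(effect))) {
    out <- numeric(p); names(out) <- parameter_names
    out[names(effect)] <- effect
    return(unname(out))
  }
  if (length(effect) == 1) return(rep(effect, p))
  effect
}

#' Generate a synthetic phenotype cohort table
#'
#' @param spec a [cohort_spec()].
#' @return a `phenotype_table` data frame: columns `line`, `animal_id`, and
#'   one column per parameter.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pars <- spec$parameters
  p <- nrow(pars)
  ed <- eigen(spec$correlation, symmetric = TRUE)
  fac <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), p)
  draw <- function(n, effect) {
    z <- matrix(rnorm(n * p), n, p) %*% t(fac)
    z <- sweep(z, 2, effect, `+`)
    x <- matrix(0, n, p)
    for (j in seq_len(p)) {
      x[, j] <- if (pars$dist[j] == "lognormal")
        exp(log(pars$p1[j]) + pars$p2[j] * z[, j])
      else pars$p1[j] + pars$p2[j] * z[, j]
    }
    x
  }
  with_seed(split_seed(spec$seed, 3L), {
    groups <- c(list(list(label = spec$reference_label,
                          n = spec$n_reference, effect = NULL)),
                spec$lines)
    rows <- lapply(groups, function(g)
      data.frame(line = g$label,
                 animal_id = paste0(g$label, "_", seq_len(g$n)),
                 draw(g$n, expand_effect(g$effect, pars$parameter)),
                 check.names = FALSE))
    out <- do.call(rbind, rows)
    names(out) <- c("line", "animal_id", pars$parameter)
    rownames(out) <- NULL
    class(out) <- c("phenotype_table", "data.frame")
    out
  })
}
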