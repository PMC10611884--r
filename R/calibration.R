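# Supporting statistics: Spearman rank correlation with an exact permutation
# p-value for small n, the runoff-loss regression, Koc source reconciliation
# and application-rate sensitivity of the effect ranking.

# all permutations of 1..n as an n! x n matrix (n <= 9)
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation with permutation p-value
#'
#' The coefficient is the Pearson correlation of average-ranked data. The
#' two-sided p-value is exact for `n` up to `exact_limit` (the fraction of
#' all n! permutations with |rho| at least as large as observed) and uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param exact_limit largest n for which the permutation distribution is
#'   enumerated (default 9).
#' @return List with `rho`, `p_value`, `n` and `method`.
#' @export
spearman <- function(x, y, exact_limit = 9) {
  if (length(x) != length(y))
    pdst_validation_error("x and y must have equal length")
  n <- length(x)
  if (n < 3) pdst_validation_error("need at least 3 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    pdst_validation_error("constant vector: rank correlation undefined")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- cor(rx, ry)

  if (n <= exact_limit) {
    perms <- perm_matrix(n)
    rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t_approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Runoff-loss regression on log10 Koc
#'
#' Ordinary least squares of percent PAI loss on log10 Koc for one soil
#' type; the fitted line is the basis of the runoff-transport model used by
#' [proportion_transported()].
#'
#' @param trials data frame with `soil_type`, `percent_loss` and `koc_L_kg`.
#' @param soil_type which soil type to fit (default: all rows).
#' @param drop optional character vector of `pai_name` values to exclude
#'   (outlier removal is an explicit user action, never automatic).
#' @return List with `slope` (% per log10 unit), `intercept` (%),
#'   `r_squared`, `n` and the underlying `lm` fit.
#' @export
fit_loss_regression <- function(trials, soil_type = NULL, drop = NULL) {
  d <- trials
  if (!is.null(soil_type)) d <- d[d$soil_type == soil_type, , drop = FALSE]
  if (!is.null(drop)) d <- d[!d$pai_name %in% drop, , drop = FALSE]
  if (nrow(d) < 3)
    pdst_data_error("need at least 3 trials to fit the loss regression")
  if (any(d$koc_L_kg <= 0))
    pdst_error("Koc must be > 0", "pdst_domain_error")
  fit <- lm(percent_loss ~ I(log10(koc_L_kg)), data = d)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((d$percent_loss - mean(d$percent_loss))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot, n = nrow(d), fit = fit)
}

#' Fold difference between experimental and modelled Koc
#'
#' @param exp_koc,model_koc positive Koc values (L/kg).
#' @return `max/min` ratio, >= 1; symmetric in its arguments.
#' @export
koc_fold_difference <- function(exp_koc, model_koc) {
  if (any(exp_koc <= 0) || any(model_koc <= 0))
    pdst_error("Koc values must be > 0", "pdst_domain_error")
  pmax(exp_koc, model_koc) / pmin(exp_koc, model_koc)
}

#' Sensitivity of the effect ranking to the application-rate choice
#'
#' Recomputes the measure-of-effect ranking under the minimum, maximum and
#' mean label rates and returns the pairwise Spearman correlations of the
#' rankings. Correlations near 1 mean the ranking is robust to the rate
#' choice.
#'
#' @param table a [pai_table()].
#' @return A 3x3 symmetric matrix of rank correlations over
#'   `{max, min, mean}`, with the matching p-values in attribute
#'   `"p_values"`.
#' @export
rate_sensitivity <- function(table) {
  stopifnot(inherits(table, "pai_table"))
  if (any(is.na(table$rates$product_rate_min)) ||
      any(is.na(table$rates$product_rate_max)))
    pdst_validation_error("every PAI needs both a min and a max rate")
  bounds <- c("max", "min", "mean")
  eff <- sapply(bounds, function(b) pdst_compute(table, rate_bound = b)$effect)
  rho <- diag(1, 3); pval <- diag(0, 3)
  dimnames(rho) <- dimnames(pval) <- list(bounds, bounds)
  for (i in 1:2) for (j in (i + 1):3) {
    s <- spearman(eff[, i], eff[, j])
    rho[i, j] <- rho[j, i] <- s$rho
    pval[i, j] <- pval[j, i] <- s$p_value
  }
  attr(rho, "p_values") <- pval
  rho
}

#' Calibration report
#'
#' Regression and rank-correlation summaries per soil type for a set of
#' runoff trials, as a list convertible to JSON.
#'
#' @param trials data frame of runoff trials.
#' @param drop optional `pai_name` values to exclude from every soil type.
#' @return Named list keyed by soil type, each with `regression` and
#'   `spearman` blocks.
#' @export
calibration_report <- function(trials, drop = NULL) {
  soils <- unique(trials$soil_type)
  out <- lapply(soils, function(s) {
    d <- trials[trials$soil_type == s & !trials$pai_name %in% drop, ]
    reg <- fit_loss_regression(d)
    sp <- spearman(d$percent_loss, log10(d$koc_L_kg))
    list(regression = list(slope = reg$slope, intercept = reg$intercept,
                           r_squared = reg$r_squared, n = reg$n),
         spearman = list(rho = sp$rho, p_value = sp$p_value, n = sp$n,
                         method = sp$method))
  })
  setNames(out, soils)
}
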