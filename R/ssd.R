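# Species sensitivity distributions.
#
# Log-logistic: F(x) = 1 / (1 + (x/alpha)^-beta), alpha > 0 scale,
# beta > 0 shape. Equivalent to log(X) ~ Logistic(log alpha, 1/beta).
#
# Burr III: F(x) = (1 + (b/x)^c)^-k, b, c, k > 0. Reduces to the
# log-logistic with alpha = b, beta = c when k = 1.

#' Log-logistic distribution
#'
#' Density, distribution function and quantile function of the log-logistic
#' distribution with scale `alpha` and shape `beta`.
#'
#' @param x,q,p numeric vectors (quantiles or probabilities).
#' @param alpha scale parameter (> 0); the distribution median.
#' @param beta shape parameter (> 0).
#' @return Numeric vector.
#' @name log-logistic
NULL

#' @rdname log-logistic
#' @export
dloglogistic <- function(x, alpha, beta) {
  z <- (x / alpha)^beta
  ifelse(x <= 0, 0, beta / x * z / (1 + z)^2)
}

#' @rdname log-logistic
#' @export
ploglogistic <- function(q, alpha, beta) {
  ifelse(q <= 0, 0, 1 / (1 + (q / alpha)^(-beta)))
}

#' @rdname log-logistic
#' @export
qloglogistic <- function(p, alpha, beta) {
  stopifnot(all(p >= 0 & p <= 1))
  alpha * (p / (1 - p))^(1 / beta)
}

#' Burr III distribution
#'
#' Density, distribution function and quantile function of the Burr III
#' (inverse Burr) distribution, `F(x) = (1 + (b/x)^c)^-k`.
#'
#' @param x,q,p numeric vectors (quantiles or probabilities).
#' @param b scale parameter (> 0).
#' @param c shape parameter (> 0).
#' @param k shape parameter (> 0).
#' @return Numeric vector.
#' @name burr-iii
NULL

#' @rdname burr-iii
#' @export
dburr3 <- function(x, b, c, k) {
  z <- (b / x)^c
  ifelse(x <= 0, 0, c * k / x * z / (1 + z)^(k + 1))
}

#' @rdname burr-iii
#' @export
pburr3 <- function(q, b, c, k) {
  ifelse(q <= 0, 0, (1 + (b / q)^c)^(-k))
}

#' @rdname burr-iii
#' @export
qburr3 <- function(p, b, c, k) {
  stopifnot(all(p >= 0 & p <= 1))
  b / (p^(-1 / k) - 1)^(1 / c)
}

# negative log-likelihood of Logistic(m, s) for y = log(x); stable in the tails
nll_logistic <- function(theta, y) {
  m <- theta[1]; s <- exp(theta[2])
  z <- (y - m) / s
  sum(z + 2 * log1p(exp(-z)) + log(s))
}

fit_loglogistic_ml <- function(values) {
  y <- log(values)
  start <- c(median(y), log(max(sd(y) * sqrt(3) / pi, 1e-3)))
  opt <- optim(start, nll_logistic, y = y, method = "Nelder-Mead",
               control = list(maxit = 1000, reltol = 1e-12))
  list(parameters = c(alpha = exp(opt$par[1]), beta = exp(-opt$par[2])),
       loglik = -opt$value, converged = opt$convergence == 0)
}

# negative log-likelihood of Burr III on the original scale, parameterised by
# log(b), log(c), log(k); (b/x)^c handled in log space to avoid overflow
nll_burr3 <- function(theta, y) {
  lb <- theta[1]; c <- exp(theta[2]); k <- exp(theta[3])
  z <- c * (lb - y)                       # log((b/x)^c), y = log(x)
  l1p <- ifelse(z > 35, z, log1p(exp(z))) # log(1 + (b/x)^c)
  -sum(theta[2] + theta[3] + z - y - (k + 1) * l1p)
}

fit_burr3_ml <- function(values) {
  y <- log(values)
  ll <- fit_loglogistic_ml(values)
  a <- unname(ll$parameters["alpha"]); be <- unname(ll$parameters["beta"])
  # Burr III with k = 1 equals the log-logistic, so start from there and
  # from mild perturbations of k
  starts <- list(c(log(a), log(be), 0),
                 c(log(a) + 0.5, log(be), log(0.5)),
                 c(log(a) - 0.5, log(be), log(2)))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      optim(s, nll_burr3, y = y, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$convergence != 0) return(NULL)
  list(parameters = c(b = exp(best$par[1]), c = exp(best$par[2]),
                      k = exp(best$par[3])),
       loglik = -best$value, converged = TRUE)
}

PROTECTION_LEVELS <- c(80, 90, 95, 99)

#' Fit a species sensitivity distribution
#'
#' Maximum-likelihood fit of a log-logistic or Burr III distribution to
#' per-species toxicity values (umol/L), optimised on log-transformed data
#' with Nelder-Mead and multiple starts. Under the `"auto"` policy a
#' log-logistic is used for fewer than `auto_threshold` species and a Burr
#' III otherwise. If the Burr III optimiser fails to converge the fit falls
#' back to the log-logistic and is flagged.
#'
#' @param values positive numeric vector, one toxicity value per species.
#' @param distribution `"auto"`, `"log_logistic"` or `"burr_iii"`.
#' @param auto_threshold species count at which `"auto"` switches from the
#'   log-logistic to the Burr III (default 8).
#' @return An object of class `ssd_fit`: distribution name, named parameter
#'   vector, `n_species`, `protective_concentrations` at the 80/90/95/99%
#'   protection levels, `convergence_flag` and the maximised log-likelihood.
#' @examples
#' fit <- fit_ssd(qloglogistic((1:99) / 100, alpha = 1, beta = 2))
#' protective_concentration(fit, 95)
#' @export
fit_ssd <- function(values, distribution = c("auto", "log_logistic",
                                             "burr_iii"),
                    auto_threshold = 8) {
  distribution <- match.arg(distribution)
  values <- as.numeric(values)
  if (any(is.na(values) | values <= 0))
    pdst_validation_error("toxicity values must be positive and non-missing")
  n <- length(values)
  if (length(unique(values)) < 2)
    pdst_error("need at least 2 distinct toxicity values to fit an SSD",
               "pdst_degenerate_data_error")
  if (distribution == "auto")
    distribution <- if (n < auto_threshold) "log_logistic" else "burr_iii"

  converged <- TRUE
  if (distribution == "burr_iii") {
    fit <- fit_burr3_ml(values)
    if (is.null(fit)) {            # optimiser failure: flagged fallback
      distribution <- "log_logistic"
      fit <- fit_loglogistic_ml(values)
      converged <- FALSE
    }
  } else {
    fit <- fit_loglogistic_ml(values)
    converged <- fit$converged
  }

  qfun <- if (distribution == "burr_iii") {
    function(u) qburr3(u, fit$parameters["b"], fit$parameters["c"],
                       fit$parameters["k"])
  } else {
    function(u) qloglogistic(u, fit$parameters["alpha"],
                             fit$parameters["beta"])
  }
  pcs <- vapply(PROTECTION_LEVELS, function(p) unname(qfun((100 - p) / 100)),
                numeric(1))
  structure(list(distribution = distribution, parameters = fit$parameters,
                 n_species = n,
                 protective_concentrations = setNames(pcs,
                   paste0("PC", PROTECTION_LEVELS)),
                 convergence_flag = converged, loglik = fit$loglik),
            class = "ssd_fit")
}

#' @export
print.ssd_fit <- function(x, ...) {
  cat(sprintf("<ssd_fit> %s, n = %d species%s\n", x$distribution,
              x$n_species,
              if (x$convergence_flag) "" else " (non-convergent, fallback)"))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$parameters), x$parameters),
            collapse = ", "), "\n")
  cat("  ", paste(sprintf("%s = %.4g", names(x$protective_concentrations),
                          x$protective_concentrations), collapse = ", "),
      "\n")
  invisible(x)
}

#' Protective concentration from a fitted SSD
#'
#' The concentration protecting `p` percent of species: the `(100 - p)/100`
#' quantile of the fitted distribution. Monotone decreasing in `p`.
#'
#' @param fit an [fit_ssd()] result.
#' @param p protection level, one of 80, 90, 95, 99.
#' @return umol/L.
#' @export
protective_concentration <- function(fit, p) {
  stopifnot(inherits(fit, "ssd_fit"))
  if (!p %in% PROTECTION_LEVELS)
    pdst_error(sprintf("unsupported protection level %s (use 80/90/95/99)",
                       p), "pdst_argument_error")
  unname(fit$protective_concentrations[paste0("PC", p)])
}
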