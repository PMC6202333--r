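# Recessive-model association testing: logistic regression with a
# likelihood-ratio p-value and a Firth-penalized fallback under
# separation; quantitative traits after rank-based inverse-normal
# standardization; impact-class weighted significance thresholds.

#' Rank-based inverse-normal standardization
#'
#' Optionally adjusts the measurements for covariates by ordinary linear
#' regression, then maps the (tie-averaged) ranks of the residuals
#' through the standard normal quantile with the Blom offset
#' `(rank - 3/8) / (n + 1/4)`. The result is approximately standard
#' normal and preserves rank order.
#'
#' @param values Numeric measurements (NAs preserved).
#' @param covariates Optional data.frame of adjustment covariates
#'   (e.g. sex, year of birth, age at measurement).
#' @return Numeric vector of standardized values, same length as input.
#' @export
inverse_normal_transform <- function(values, covariates = NULL) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("need at least 3 non-missing values")
  x <- values[ok]
  if (length(unique(x)) == 1L)
    stop("degenerate distribution: all values identical")
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)[ok, , drop = FALSE]
    x <- stats::residuals(stats::lm(x ~ ., data = cv))
  }
  n <- length(x)
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  out
}

#' Recessive-model logistic association test
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' homozygosity indicator plus covariates, compared against the
#' covariate-only model by a likelihood-ratio test on 1 df. The effect is
#' the odds ratio with a 95% Wald CI on the log-odds scale. On (quasi-)
#' separation the fit falls back to Firth's penalized likelihood, flagged
#' in `model_label`.
#'
#' @param hom_indicator 0/1 vector: recessive genotype carrier.
#' @param case_status 0/1 outcome vector.
#' @param covariates Optional data.frame (e.g. sex, age, region).
#' @return An `association_result` list: `effect` (OR), `ci_low`,
#'   `ci_high`, `p_value`, `n_cases`, `n_controls`, `model_label`.
#' @export
fit_recessive_binary <- function(hom_indicator, case_status,
                                 covariates = NULL) {
  if (sum(hom_indicator, na.rm = TRUE) == 0)
    stop("no homozygotes: genotype untestable")
  keep <- !is.na(hom_indicator) & !is.na(case_status)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  g <- hom_indicator[keep]; y <- case_status[keep]
  X0 <- if (is.null(covariates)) matrix(1, length(y), 1)
        else stats::model.matrix(~ ., data = covariates)
  X1 <- cbind(X0, genotype = g)

  fit1 <- suppressWarnings(stats::glm.fit(X1, y, family = stats::binomial()))
  fit0 <- suppressWarnings(stats::glm.fit(X0, y, family = stats::binomial()))
  separated <- .glm_separated(fit1, X1)

  if (!separated) {
    beta <- fit1$coefficients[["genotype"]]
    se <- sqrt(.glm_vcov(fit1, X1)["genotype", "genotype"])
    lrt <- fit0$deviance - fit1$deviance
    label <- "logistic_lrt"
  } else {
    f1 <- .firth_logistic(X1, y)
    f0 <- .firth_logistic(X0, y)
    beta <- f1$coef[["genotype"]]
    se <- sqrt(f1$vcov["genotype", "genotype"])
    lrt <- 2 * (f1$loglik - f0$loglik)
    label <- "logistic_firth_lrt"
  }
  p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  structure(list(effect = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 p_value = p,
                 n_cases = sum(y == 1), n_controls = sum(y == 0),
                 model_label = label),
            class = "association_result")
}

# Detect (quasi-)separation: non-convergence or a genotype log-odds
# estimate drifting to the boundary (|beta| > 10 ~ OR > 2e4).
.glm_separated <- function(fit, X) {
  !fit$converged || abs(fit$coefficients[["genotype"]]) > 10
}

.glm_vcov <- function(fit, X) {
  w <- fit$weights
  xtx <- crossprod(X * sqrt(w))
  v <- solve(xtx)
  dimnames(v) <- list(colnames(X), colnames(X))
  v
}

# Firth's penalized logistic regression by Newton iteration: score is
# augmented with h_i (1/2 - mu_i), where h are leverages of the weighted
# design; returns the penalized log-likelihood for penalized LRTs.
.firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    info_inv <- solve(info)
    h <- rowSums((XW %*% info_inv) * XW)
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- drop(info_inv %*% U)
    # step-halving for stability
    step <- 1
    while (max(abs(step * delta)) > 5) step <- step / 2
    beta <- beta + step * delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu)) +
    0.5 * determinant(info, logarithm = TRUE)$modulus
  list(coef = stats::setNames(beta, colnames(X)),
       vcov = structure(solve(info), dimnames = list(colnames(X), colnames(X))),
       loglik = as.numeric(ll))
}

#' Quantitative-trait association under the recessive model
#'
#' Ordinary least squares of a standardized trait on the homozygosity
#' indicator plus covariates. The effect is in SD units (the trait should
#' already be inverse-normal standardized); `reference_sd` converts it to
#' natural units.
#'
#' @param trait Standardized trait values.
#' @param hom_indicator 0/1 recessive-genotype indicator.
#' @param covariates Optional data.frame.
#' @param reference_sd Optional natural-unit SD; when given, the result
#'   carries `effect_natural = effect * reference_sd`.
#' @return An `association_result` list with `effect` in SD units,
#'   Wald 95% CI, likelihood-ratio p-value, `n`, `model_label = "ols"`.
#' @export
fit_quantitative <- function(trait, hom_indicator, covariates = NULL,
                             reference_sd = NULL) {
  keep <- !is.na(trait) & !is.na(hom_indicator)
  dat <- data.frame(trait = trait, genotype = hom_indicator)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
    dat <- cbind(dat, covariates)
  }
  dat <- dat[keep, , drop = FALSE]
  if (stats::sd(dat$trait) == 0) stop("constant trait")
  fit1 <- stats::lm(trait ~ ., data = dat)
  fit0 <- stats::lm(trait ~ . - genotype, data = dat)
  beta <- stats::coef(fit1)[["genotype"]]
  se <- sqrt(stats::vcov(fit1)["genotype", "genotype"])
  lrt <- 2 * as.numeric(stats::logLik(fit1) - stats::logLik(fit0))
  p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  res <- list(effect = beta,
              ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
              p_value = p, n = nrow(dat), model_label = "ols")
  if (!is.null(reference_sd)) res$effect_natural <- beta * reference_sd
  structure(res, class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: effect = %.3g (95%% CI %.3g, %.3g), p = %.3g\n",
              x$model_label, x$effect, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

# Class-weighted Bonferroni genome-wide thresholds, ordered
# high > moderate > low > dhs > remaining.
.threshold_table <- c(high = 2.5e-7, moderate = 5.0e-8, low = 4.5e-9,
                      dhs = 2.3e-9, remaining = 7.5e-10)

#' Impact-class weighted genome-wide significance threshold
#'
#' Weighted Bonferroni thresholds by predicted functional impact:
#' 2.5e-7 (high), 5.0e-8 (moderate), 4.5e-9 (low), 2.3e-9 (DHS),
#' 7.5e-10 (remaining).
#'
#' @param impact Impact class label(s): high, moderate, low, dhs,
#'   remaining.
#' @return Numeric threshold(s).
#' @export
significance_threshold <- function(impact) {
  bad <- !impact %in% names(.threshold_table)
  if (any(bad)) stop("unknown impact class: ",
                     paste(unique(impact[bad]), collapse = ", "))
  unname(.threshold_table[impact])
}
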