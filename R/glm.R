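#' Fit a logistic (binomial, logit-link) regression submodel
#'
#' Maximum-likelihood fit via iteratively reweighted least squares
#' (\code{stats::glm}) with tightened convergence control, plus the
#' diagnostics the risk models need: an explicit estimated-parameter count K,
#' natural-log likelihood, and a complete-separation flag.
#'
#' @param formula model formula with a binary (0/1 or logical/factor)
#'   response.
#' @param data data frame containing the response and predictors.
#' @param ridge optional ridge stabiliser added to the diagonal of the
#'   information matrix via a tiny L2 penalty; off (`0`) by default. Use only
#'   to stabilise near-separated fits; flagged fits are reported, not
#'   silently penalised.
#' @return an object of class `risk_fit`: list with `coefficients`,
#'   `se`, `vcov`, `zvalues`, `pvalues` (Wald, normal reference), `loglik`
#'   (natural log), `n`, `K` (number of estimated coefficients), `converged`,
#'   `separation` (TRUE if any fitted probability is within 1e-8 of 0 or 1),
#'   `formula`, and the underlying `glm` object as `fit`.
#' @details Rank-deficient designs are an error naming the aliased terms;
#'   a single-class response (all 0 or all 1) is a degenerate-fit error.
#' @examples
#' d <- data.frame(y = c(rep(1, 13), rep(0, 115), 1, rep(0, 74)),
#'                 g = rep(c(0, 1), c(128, 75)))
#' fit <- fit_logistic(y ~ g, d)
#' round(coef(fit), 3)
#' @export
fit_logistic <- function(formula, data, ridge = 0) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2L) {
    stop("degenerate fit: response is single-class (all ",
         unique(y), "); no logistic MLE exists")
  }
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  if (ridge > 0) return(fit_logistic_ridge(formula, data, ridge))
  fit <- stats::glm(formula, family = stats::binomial(), data = data,
                    control = ctrl)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  p <- stats::fitted(fit)
  separation <- any(p < 1e-8 | p > 1 - 1e-8)
  # complete separation drives coefficients to infinity and stalls IRLS at
  # a near-zero deviance: flag and report rather than abort
  if (!fit$converged && !separation) {
    stop("IRLS did not converge in ", ctrl$maxit,
         " iterations (deviance ", format(fit$deviance), ")")
  }
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  z <- cf / se
  structure(list(
    coefficients = cf,
    se = se,
    vcov = stats::vcov(fit),
    zvalues = z,
    pvalues = 2 * stats::pnorm(-abs(z)),
    loglik = as.numeric(stats::logLik(fit)),
    n = length(fit$y),
    K = length(cf),
    converged = fit$converged,
    separation = separation,
    formula = formula,
    fit = fit
  ), class = "risk_fit")
}

# Penalized IRLS with an L2 penalty on all non-intercept coefficients;
# stabiliser for near-separated designs (off by default in fit_logistic).
fit_logistic_ridge <- function(formula, data, lambda) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  trm <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  X <- stats::model.matrix(trm, mf)
  n <- nrow(X)
  pen <- diag(lambda, ncol(X))
  if ("(Intercept)" %in% colnames(X)) {
    pen[match("(Intercept)", colnames(X)), match("(Intercept)", colnames(X))] <- 0
  }
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(200)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    info <- crossprod(X * w, X) + pen
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(score)) < 1e-8) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  vc <- solve(crossprod(X * (mu * (1 - mu)), X) + pen)
  ll <- sum(y * log(clamp_prob(mu)) + (1 - y) * log(clamp_prob(1 - mu)))
  se <- sqrt(diag(vc))
  z <- beta / se
  names(beta) <- names(se) <- colnames(X)
  structure(list(
    coefficients = beta, se = se, vcov = vc, zvalues = z,
    pvalues = 2 * stats::pnorm(-abs(z)), loglik = ll, n = n,
    K = length(beta), converged = converged,
    separation = any(mu < 1e-8 | mu > 1 - 1e-8),
    formula = formula, fit = NULL, terms = trm,
    xlevels = stats::.getXlevels(trm, mf), ridge = lambda
  ), class = "risk_fit")
}

#' @export
coef.risk_fit <- function(object, ...) object$coefficients

#' @export
logLik.risk_fit <- function(object, ...) {
  structure(object$loglik, df = object$K, nobs = object$n, class = "logLik")
}

#' @export
print.risk_fit <- function(x, ...) {
  cat("Logistic submodel:", deparse(x$formula), "\n")
  cat("n =", x$n, " K =", x$K, " logLik =", format(x$loglik, digits = 6),
      if (x$separation) " [separation flagged]" else "", "\n")
  tab <- cbind(Estimate = x$coefficients, SE = x$se, z = x$zvalues,
               p = x$pvalues)
  print(round(tab, 4))
  invisible(x)
}

#' Predicted probability of high impact
#'
#' Inverse-logit of the linear predictor for new covariate values. Unknown
#' factor levels in `newdata` are an error.
#'
#' @param model a `risk_fit` object.
#' @param newdata data frame supplying every model term.
#' @return numeric vector of probabilities.
#' @export
predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "risk_fit"))
  if (!is.null(model$fit)) {
    return(as.numeric(stats::predict(model$fit, newdata = newdata,
                                     type = "response")))
  }
  trm <- stats::delete.response(model$terms)
  mf <- stats::model.frame(trm, newdata, xlev = model$xlevels)
  X <- stats::model.matrix(trm, mf)
  as.numeric(stats::plogis(drop(X %*% model$coefficients)))
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2K + 2K(K + 1) / (n - K - 1), with the natural-log
#' likelihood. Requires n > K + 1.
#'
#' @param loglik natural-log likelihood, or a `risk_fit` object (then
#'   `K_params` and `n` are taken from it).
#' @param K_params number of estimated parameters.
#' @param n number of observations.
#' @return AICc value.
#' @examples
#' aicc(-47.35, K_params = 2, n = 203)
#' @export
aicc <- function(loglik, K_params = NULL, n = NULL) {
  if (inherits(loglik, "risk_fit")) {
    K_params <- loglik$K
    n <- loglik$n
    loglik <- loglik$loglik
  }
  stopifnot(is.numeric(loglik), is.numeric(K_params), is.numeric(n))
  if (n <= K_params + 1) {
    stop("AICc undefined: n (", n, ") must exceed K + 1 (", K_params + 1, ")")
  }
  -2 * loglik + 2 * K_params + 2 * K_params * (K_params + 1) / (n - K_params - 1)
}

#' Akaike weights from a vector of AICc scores
#'
#' w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2), where Delta_i is the
#' difference from the smallest score. Invariant to adding a constant to all
#' scores; weights sum to 1.
#'
#' @param aicc_scores numeric vector of finite AICc values.
#' @return numeric vector of weights summing to 1.
#' @examples
#' round(akaike_weights(c(98.778, 103.908, 104.958)), 2)
#' @export
akaike_weights <- function(aicc_scores) {
  stopifnot(is.numeric(aicc_scores), length(aicc_scores) >= 1,
            all(is.finite(aicc_scores)))
  d <- aicc_scores - min(aicc_scores)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Rank candidate logistic models by AICc
#'
#' Fits every candidate on the same observation set, computes AICc, delta
#' AICc and Akaike weights, and marks the confidence set (delta AICc <= 2.00).
#' Candidates whose fit fails (separation error, rank deficiency, ...) are
#' dropped with a warning rather than aborting the ranking.
#'
#' @param designs named list of model formulas sharing one response.
#' @param data data frame.
#' @param confidence_delta delta-AICc cutoff for the confidence set
#'   (default 2.00).
#' @return an object of class `model_ranking`: a list with `table` (data
#'   frame: model, K, loglik, AICc, delta_AICc, weight, in_confidence_set,
#'   sorted ascending by AICc) and `fits` (named list of `risk_fit`s).
#' @export
rank_models <- function(designs, data, confidence_delta = 2.00) {
  stopifnot(is.list(designs), length(designs) >= 1)
  if (is.null(names(designs)) || any(names(designs) == "")) {
    stop("designs must be a fully named list of formulas")
  }
  fits <- list()
  for (nm in names(designs)) {
    f <- tryCatch(fit_logistic(designs[[nm]], data), error = function(e) e)
    if (inherits(f, "error")) {
      warning("candidate '", nm, "' dropped from ranking: ",
              conditionMessage(f))
    } else {
      fits[[nm]] <- f
    }
  }
  if (length(fits) == 0) stop("no candidate model could be fitted")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) > 1) {
    stop("candidates fitted on differing observation counts: ",
         paste(unique(ns), collapse = ", "))
  }
  ic <- vapply(fits, aicc, numeric(1))
  tab <- data.frame(
    model = names(fits),
    K = vapply(fits, function(f) f$K, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    AICc = ic,
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$AICc, tab$model), , drop = FALSE]
  tab$delta_AICc <- tab$AICc - tab$AICc[1]
  tab$weight <- akaike_weights(tab$AICc)
  tab$in_confidence_set <- tab$delta_AICc <= confidence_delta
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits,
                 confidence_delta = confidence_delta),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  tab <- x$table
  tab$AICc <- round(tab$AICc, 3)
  tab$delta_AICc <- round(tab$delta_AICc, 3)
  tab$weight <- round(tab$weight, 2)
  print(tab)
  invisible(x)
}

#' Confidence set of a model ranking
#'
#' @param ranking a `model_ranking`.
#' @return character vector of model names with delta AICc <= cutoff.
#' @export
confidence_set <- function(ranking) {
  stopifnot(inherits(ranking, "model_ranking"))
  ranking$table$model[ranking$table$in_confidence_set]
}

#' Nagelkerke pseudo R-squared
#'
#' R2 = [1 - exp(2 (l0 - l1) / n)] / [1 - exp(2 l0 / n)], where l1 and l0 are
#' the natural-log likelihoods of the model and the intercept-only model on
#' the same data.
#'
#' @param model a `risk_fit`.
#' @param null_model intercept-only `risk_fit` on the same data; fitted
#'   automatically when `NULL`.
#' @return Nagelkerke R-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(model, null_model = NULL) {
  stopifnot(inherits(model, "risk_fit"))
  if (is.null(null_model)) {
    resp <- model$fit$y
    null_model <- fit_logistic(y ~ 1, data.frame(y = resp))
  }
  stopifnot(inherits(null_model, "risk_fit"))
  if (model$n != null_model$n) {
    stop("model and null model fitted on different n (", model$n, " vs ",
         null_model$n, ")")
  }
  n <- model$n
  num <- 1 - exp(2 * (null_model$loglik - model$loglik) / n)
  den <- 1 - exp(2 * null_model$loglik / n)
  num / den
}

#' Likelihood-ratio (G-squared) test of nested logistic models
#'
#' G2 = 2 (logLik_full - logLik_nested), referred to a chi-squared with
#' df = K_full - K_nested. The nested model's terms must be a subset of the
#' full model's terms and both must be fitted on the same observations.
#'
#' @param nested,full `risk_fit` objects.
#' @return list with `G2`, `df`, `p_value`.
#' @export
lr_test <- function(nested, full) {
  stopifnot(inherits(nested, "risk_fit"), inherits(full, "risk_fit"))
  if (nested$n != full$n) {
    stop("models fitted on different n (", nested$n, " vs ", full$n, ")")
  }
  tn <- labels(stats::terms(nested$formula))
  tf <- labels(stats::terms(full$formula))
  if (!all(tn %in% tf)) {
    stop("designs are not nested: term(s) ",
         paste(setdiff(tn, tf), collapse = ", "), " absent from full model")
  }
  df <- full$K - nested$K
  if (df < 0) stop("'full' has fewer parameters than 'nested'")
  G2 <- max(2 * (full$loglik - nested$loglik), 0)
  p <- if (df == 0) 1 else stats::pchisq(G2, df, lower.tail = FALSE)
  list(G2 = G2, df = df, p_value = p)
}
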