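#' Composite context: submodel baselines and availability
#'
#' Bundles the quantities the composite risk equation needs besides the
#' per-pair submodel predictions: each submodel's training baseline (the
#' proportion of high-impact pairs among the pairs used to parameterize
#' it) and the overall baseline across all pairs (0.072 in the study
#' census).
#'
#' @param submodel_baselines named numeric vector (or list) of baselines in
#'   (0, 1), named by submodel.
#' @param overall_baseline overall proportion of high-impact pairs.
#' @return list of class `composite_context`.
#' @export
composite_context <- function(submodel_baselines, overall_baseline) {
  b <- unlist(submodel_baselines)
  if (is.null(names(b)) || any(names(b) == "")) {
    stop("submodel baselines must be named")
  }
  clamp_warn <- function(p, what) {
    if (any(p <= 0 | p >= 1)) {
      warning(what, " baseline of exactly 0 or 1 clamped before logit")
      p <- clamp_prob(p, lower = 1e-300, upper = 1 - 1e-15)
    }
    p
  }
  b <- clamp_warn(b, "submodel")
  overall_baseline <- clamp_warn(overall_baseline, "overall")
  structure(list(submodel_baselines = b,
                 overall_baseline = overall_baseline),
            class = "composite_context")
}

#' Composite invasion risk for one insect-host pair
#'
#' Pools the available submodel predictions in logit space: the composite
#' risk (logit units) is the overall-baseline logit plus the mean, over the
#' N available submodels, of each submodel's deviation of its predicted
#' probability from its own training baseline,
#' R = logit(P_overall) + (1/N) * sum_m [logit(P_m) - logit(P_m_baseline)].
#' If every available submodel predicts exactly its own baseline, the
#' composite probability equals the overall baseline. Probabilities are
#' clamped to [1e-300, 1 - 1e-15] before the logit so that extremely small
#' (but meaningful) predictions survive; all pooling happens in logit
#' space and is converted to a probability only at output.
#'
#' @param predictions named numeric vector of predicted probabilities, one
#'   per available submodel.
#' @param context a [composite_context()] holding the baselines.
#' @return list of class `composite_risk`: `risk_logit`, `risk_prob`,
#'   `n_available`, `contributions` (per-submodel logit deviations).
#' @examples
#' ctx <- composite_context(
#'   c(host_traits = 0.072, host_evolution = 0.084, insect_evolution = 0.069),
#'   overall_baseline = 0.072)
#' composite_risk(c(host_traits = 0.259, host_evolution = 0.119,
#'                  insect_evolution = 0.102), ctx)$risk_prob
#' @export
composite_risk <- function(predictions, context) {
  stopifnot(inherits(context, "composite_context"))
  p <- unlist(predictions)
  if (length(p) == 0) stop("no submodel predictions: composite undefined")
  if (is.null(names(p)) || any(names(p) == "")) {
    stop("predictions must be named by submodel")
  }
  miss <- setdiff(names(p), names(context$submodel_baselines))
  if (length(miss)) {
    stop("no baseline for submodel(s): ", paste(miss, collapse = ", "))
  }
  p <- clamp_prob(p)
  b <- context$submodel_baselines[names(p)]
  dev <- logit(p) - logit(b)
  r <- logit(context$overall_baseline) + mean(dev)
  structure(list(risk_logit = r, risk_prob = inv_logit(r),
                 n_available = length(p), contributions = dev),
            class = "composite_risk")
}

#' Baselines from a census and submodel training masks
#'
#' Each submodel's baseline is the proportion of high-impact pairs among
#' the pairs used to train it; the overall baseline is the proportion over
#' all pairs.
#'
#' @param high_impact binary 0/1 vector over all pairs.
#' @param masks named list of logical vectors (same length) selecting each
#'   submodel's training pairs.
#' @return a [composite_context()].
#' @export
compute_baselines <- function(high_impact, masks) {
  stopifnot(is.list(masks), length(masks) >= 1)
  b <- vapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!any(m)) stop("empty training mask for submodel: ", nm)
    mean(high_impact[m])
  }, numeric(1))
  composite_context(b, mean(high_impact))
}

#' Binned calibration of predicted risks
#'
#' Pairs are sorted by predicted risk and allocated to `n_bins` bins: the
#' first `n_bins - 1` bins hold floor(n / n_bins) pairs each and the final
#' bin holds the remainder (221 pairs -> nine bins of 22 and a final bin
#' of 23). Each bin reports its mean predicted probability and the
#' observed proportion of high-impact pairs.
#'
#' @param risks predicted probabilities.
#' @param observed binary 0/1 outcomes.
#' @param n_bins number of bins (default 10).
#' @return data frame: `bin`, `n`, `mean_predicted`, `observed_prop`.
#' @export
bin_calibration <- function(risks, observed, n_bins = 10) {
  n <- length(risks)
  stopifnot(length(observed) == n)
  if (n < n_bins) stop("fewer observations (", n, ") than bins (", n_bins, ")")
  ord <- order(risks)
  base <- n %/% n_bins
  sizes <- c(rep(base, n_bins - 1), n - base * (n_bins - 1))
  bin <- rep(seq_len(n_bins), sizes)
  data.frame(
    bin = seq_len(n_bins),
    n = sizes,
    mean_predicted = as.numeric(tapply(risks[ord], bin, mean)),
    observed_prop = as.numeric(tapply(observed[ord], bin, mean))
  )
}

#' Distributional summary of composite risks
#'
#' Mirrors the study's risk-variation table: standard deviation of the
#' risk logits, the 10th and 90th percentile logits and probabilities
#' (linear interpolation between order statistics), and the fold-range
#' p90 / p10 of the probabilities.
#'
#' @param risk_logits numeric vector (>= 10) of composite risks in logit
#'   units.
#' @return list with `sd_logit`, `p10_logit`, `p90_logit`, `p10_prob`,
#'   `p90_prob`, `fold_range`.
#' @export
risk_summary <- function(risk_logits) {
  stopifnot(length(risk_logits) >= 10)
  q <- stats::quantile(risk_logits, c(0.1, 0.9), names = FALSE, type = 7)
  p <- inv_logit(q)
  list(sd_logit = stats::sd(risk_logits),
       p10_logit = q[1], p90_logit = q[2],
       p10_prob = p[1], p90_prob = p[2],
       fold_range = p[2] / p[1])
}

#' Score a census with the three submodels and the composite equation
#'
#' Computes each pair's per-submodel predicted probability (NA where a
#' submodel does not apply), the availability count N, and the composite
#' risk in logit and probability units.
#'
#' @param pairs data frame with one row per pair and columns `guild`,
#'   `shade_tolerance`, `drought_tolerance`, `shared_genus` (0/1, NA on
#'   excluded hosts), `divergence_mya` (NA when unresolved) and
#'   `host_excluded` (logical).
#' @param context a [composite_context()] with baselines for
#'   `host_traits`, `host_evolution`, `insect_evolution`.
#' @param coefs published-coefficient fixture, or `NULL` to use
#'   [published_coefficients()]. Alternatively supply `models`: a list with
#'   functions or fitted models via `predict_fns`.
#' @param predict_fns optional named list of prediction functions
#'   `host_traits(pairs)`, `host_evolution(pairs)`,
#'   `insect_evolution(pairs)` each returning a probability per row;
#'   defaults evaluate the published coefficients.
#' @param guild_models guilds with a host-evolution model.
#' @return `pairs` with columns `p_host_traits`, `p_host_evolution`,
#'   `p_insect_evolution`, `n_available`, `risk_logit`, `risk_prob`
#'   appended.
#' @export
score_census <- function(pairs, context, coefs = NULL, predict_fns = NULL,
                         guild_models = c("folivore", "sap_feeder")) {
  if (is.null(predict_fns)) {
    coefs <- coefs %||% published_coefficients()
    gm <- lapply(guild_models, published_guild_model, coefs = coefs)
    names(gm) <- guild_models
    predict_fns <- list(
      host_traits = function(d) {
        predict_host_trait_risk(d$shade_tolerance, d$drought_tolerance,
                                coefs = coefs)
      },
      host_evolution = function(d) {
        vapply(seq_len(nrow(d)), function(i) {
          g <- d$guild[i]
          if (!g %in% names(gm) || is.na(d$divergence_mya[i]) ||
              d$divergence_mya[i] <= 0) return(NA_real_)
          predict_guild_risk(gm[[g]], d$divergence_mya[i])
        }, numeric(1))
      },
      insect_evolution = function(d) {
        ifelse(is.na(d$shared_genus), NA_real_,
               predict_congener_risk(d$shared_genus, coefs = coefs))
      }
    )
  }
  p_ht <- predict_fns$host_traits(pairs)
  p_he <- predict_fns$host_evolution(pairs)
  p_ie <- predict_fns$insect_evolution(pairs)
  n <- nrow(pairs)
  risk_logit <- numeric(n)
  n_avail <- integer(n)
  for (i in seq_len(n)) {
    avail <- applicable_submodels(pairs$guild[i],
                                  host_excluded = isTRUE(pairs$host_excluded[i]),
                                  has_divergence = !is.na(p_he[i]),
                                  guild_models = guild_models)
    preds <- c(host_traits = p_ht[i], host_evolution = p_he[i],
               insect_evolution = p_ie[i])[avail]
    if (anyNA(preds)) {
      avail <- avail[!is.na(preds)]
      preds <- preds[!is.na(preds)]
    }
    cr <- composite_risk(preds, context)
    risk_logit[i] <- cr$risk_logit
    n_avail[i] <- cr$n_available
  }
  pairs$p_host_traits <- p_ht
  pairs$p_host_evolution <- p_he
  pairs$p_insect_evolution <- p_ie
  pairs$n_available <- n_avail
  pairs$risk_logit <- risk_logit
  pairs$risk_prob <- inv_logit(risk_logit)
  pairs
}
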