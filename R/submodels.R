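#' Published coefficient and ranking fixtures
#'
#' `published_coefficients()` loads the versioned fixture holding the
#' published parameter estimates for the three risk submodels: the
#' guild-stratified quadratic divergence-time models (folivores and
#' sap-feeders), the host-trait (shade + drought tolerance) model, and the
#' native-congener model, plus the overall high-impact baseline (0.072) and
#' the congener-analysis group sizes. `published_rankings()` loads the
#' published AICc ranking columns for the three candidate sets.
#'
#' @return nested list mirroring the fixture file.
#' @export
published_coefficients <- function() {
  jsonlite::read_json(system.file("extdata", "published_coefficients.json",
                                  package = "coniferisk", mustWork = TRUE),
                      simplifyVector = TRUE)
}

#' @rdname published_coefficients
#' @export
published_rankings <- function() {
  jsonlite::read_json(system.file("extdata", "published_rankings.json",
                                  package = "coniferisk", mustWork = TRUE),
                      simplifyVector = TRUE)
}

#' The three candidate model sets
#'
#' Builds the candidate formula lists ranked by AICc multimodel inference:
#' 12 insect-trait models (including null and global), 10 host-trait models
#' (including null and global), and 3 congener models (shared genus, null,
#' shared family; no global model because insects sharing a genus
#' necessarily share a family).
#'
#' @param response name of the binary response column (default
#'   `"high_impact"`).
#' @return list with named formula lists `insect`, `host`, `congener`.
#' @export
build_candidate_sets <- function(response = "high_impact") {
  f <- function(rhs) stats::as.formula(paste(response, "~", rhs))
  insect <- list(
    "voltinism" = f("voltinism"),
    "voltinism + reproductive_strategy + dispersal" =
      f("voltinism + reproductive_strategy + dispersal"),
    "reproductive_strategy" = f("reproductive_strategy"),
    "null" = f("1"),
    "congener" = f("congener"),
    "n_native_host_genera" = f("n_native_host_genera"),
    "pest_status" = f("pest_status"),
    "dispersal" = f("dispersal"),
    "native_range" = f("native_range"),
    "guild" = f("guild"),
    "native_range + pest_status + n_native_host_genera" =
      f("native_range + pest_status + n_native_host_genera"),
    "global" = f(paste("voltinism + reproductive_strategy + dispersal +",
                       "congener + n_native_host_genera + pest_status +",
                       "native_range + guild"))
  )
  host <- list(
    "shade_tolerance + drought_tolerance" =
      f("shade_tolerance + drought_tolerance"),
    "growth_rate" = f("growth_rate"),
    "wood_density + growth_rate" = f("wood_density + growth_rate"),
    "wood_density" = f("wood_density"),
    "null" = f("1"),
    "foliage_texture + growth_rate" = f("foliage_texture + growth_rate"),
    "foliage_texture" = f("foliage_texture"),
    "drought_tolerance" = f("drought_tolerance"),
    "global" = f(paste("shade_tolerance + drought_tolerance + growth_rate +",
                       "wood_density + foliage_texture + fire_tolerance")),
    "fire_tolerance + drought_tolerance" =
      f("fire_tolerance + drought_tolerance")
  )
  congener <- list(
    "shared_genus" = f("shared_genus"),
    "null" = f("1"),
    "shared_family" = f("shared_family")
  )
  list(insect = insect, host = host, congener = congener)
}

#' Guild-stratified quadratic divergence-time model
#'
#' Constructor for the host-evolution submodel of one feeding guild: a
#' logistic regression of high impact on x = log10(divergence time, mya)
#' and x squared. Both published fits are concave (negative quadratic
#' coefficient), so predicted risk peaks at the vertex
#' 10^(-b1 / (2 b2)) mya and falls towards zero for very recently or very
#' anciently diverged hosts.
#'
#' @param guild `"folivore"` or `"sap_feeder"`.
#' @param intercept,b_log10,b_log10_sq coefficients on 1, x, x^2.
#' @param fit optional underlying `risk_fit` when estimated from data.
#' @return object of class `guild_quadratic` with a `vertex_mya` field.
#' @export
guild_quadratic_model <- function(guild, intercept, b_log10, b_log10_sq,
                                  fit = NULL) {
  stopifnot(is.character(guild), length(guild) == 1)
  vertex <- if (b_log10_sq < 0) 10^(-b_log10 / (2 * b_log10_sq)) else NA_real_
  structure(list(guild = guild, intercept = intercept, b_log10 = b_log10,
                 b_log10_sq = b_log10_sq, vertex_mya = vertex, fit = fit),
            class = "guild_quadratic")
}

#' @rdname guild_quadratic_model
#' @param coefs fixture list from [published_coefficients()].
#' @export
published_guild_model <- function(guild, coefs = published_coefficients()) {
  g <- coefs$host_evolution[[guild]]
  if (is.null(g)) stop("no published host-evolution model for guild: ", guild)
  guild_quadratic_model(guild, g$intercept, g$log10_divergence,
                        g$log10_divergence_sq)
}

#' Fit the host-evolution submodel for one guild
#'
#' Logistic fit of high impact on log10 divergence time and its square,
#' restricted to the guilds in which high-impact invasions occurred
#' (folivores and sap-feeders). Guilds whose pairs include no high-impact
#' case (wood borers, root feeders, gall makers in the study census) are
#' refused with an explicit reason, because no divergence-time model can be
#' estimated for them.
#'
#' @param pairs_with_divergence data frame with columns `guild`,
#'   `divergence_mya` (> 0) and `high_impact`.
#' @param guild guild to fit.
#' @return `guild_quadratic` model with the underlying `risk_fit` attached.
#' @export
fit_host_evolution <- function(pairs_with_divergence, guild) {
  d <- pairs_with_divergence[pairs_with_divergence$guild == guild, ,
                             drop = FALSE]
  if (nrow(d) == 0) stop("no pairs for guild: ", guild)
  if (any(is.na(d$divergence_mya) | d$divergence_mya <= 0)) {
    stop("divergence_mya must be positive for all pairs entering the ",
         "host-evolution submodel")
  }
  if (sum(d$high_impact) == 0) {
    stop("guild '", guild, "' has zero high-impact cases; the ",
         "divergence-time model is not estimable and is not fitted")
  }
  d$x <- log10(d$divergence_mya)
  fit <- fit_logistic(high_impact ~ x + I(x^2), d)
  cf <- fit$coefficients
  guild_quadratic_model(guild, cf[["(Intercept)"]], cf[["x"]],
                        cf[["I(x^2)"]], fit = fit)
}

#' Predicted risk from a guild divergence-time model
#'
#' @param model a `guild_quadratic`.
#' @param divergence_mya positive divergence time(s) in millions of years.
#' @return predicted probability of high impact.
#' @examples
#' m <- published_guild_model("folivore")
#' predict_guild_risk(m, 2.5)
#' @export
predict_guild_risk <- function(model, divergence_mya) {
  stopifnot(inherits(model, "guild_quadratic"))
  if (any(is.na(divergence_mya) | divergence_mya <= 0)) {
    stop("divergence_mya must be positive")
  }
  x <- log10(divergence_mya)
  inv_logit(model$intercept + model$b_log10 * x + model$b_log10_sq * x^2)
}

#' Predicted risk from the published host-trait model
#'
#' Shade tolerance + drought tolerance model with reference levels
#' shade = low, drought = none.
#'
#' @param shade,drought character vectors of tolerance levels.
#' @param coefs fixture list from [published_coefficients()].
#' @return predicted probability of high impact.
#' @export
predict_host_trait_risk <- function(shade, drought,
                                    coefs = published_coefficients()) {
  ht <- coefs$host_traits
  s_eff <- c(low = 0, moderate = ht$shade_tolerance$moderate,
             high = ht$shade_tolerance$high)
  d_eff <- c(none = 0, low = ht$drought_tolerance$low,
             moderate = ht$drought_tolerance$moderate,
             high = ht$drought_tolerance$high)
  if (any(!shade %in% names(s_eff))) stop("unknown shade level")
  if (any(!drought %in% names(d_eff))) stop("unknown drought level")
  unname(inv_logit(ht$intercept + s_eff[shade] + d_eff[drought]))
}

#' Predicted risk from the published congener model
#'
#' @param shared_genus 0/1 (or logical) indicator that a native insect of
#'   the invader's genus co-occurs on the host.
#' @param coefs fixture list from [published_coefficients()].
#' @return predicted probability of high impact.
#' @export
predict_congener_risk <- function(shared_genus,
                                  coefs = published_coefficients()) {
  ie <- coefs$insect_evolution
  inv_logit(ie$intercept + ie$shared_genus * as.numeric(shared_genus))
}

#' Taxonomic relationship between an invader and a host's native insects
#'
#' Classifies an insect-host pair by the closest native relative documented
#' on the host: `shared_genus` if any native genus on the host equals the
#' invader's genus, otherwise `shared_family_only` if any native genus
#' belongs to the invader's family, otherwise `none`. Genus sharing implies
#' family sharing (taxonomic nesting).
#'
#' @param insect_genus,insect_family the invader's genus and family.
#' @param host_genera data frame with columns `genus` and `family`
#'   (native insect genera documented on the host).
#' @return one of `"shared_genus"`, `"shared_family_only"`, `"none"`.
#' @export
assign_congener_status <- function(insect_genus, insect_family, host_genera) {
  stopifnot(is.data.frame(host_genera),
            all(c("genus", "family") %in% names(host_genera)))
  if (nrow(host_genera) > 0 &&
      (anyNA(host_genera$family) || any(!nzchar(host_genera$family)))) {
    stop("missing family labels in host native-genus list")
  }
  if (insect_genus %in% host_genera$genus) return("shared_genus")
  if (insect_family %in% host_genera$family) return("shared_family_only")
  "none"
}

#' Which submodels yield a prediction for a pair
#'
#' The composite model averages only over the submodels that apply to a
#' pair: the host-trait model applies to every pair; the host-evolution
#' model only to guilds with a fitted divergence-time model (folivores,
#' sap-feeders) and pairs with a resolved positive divergence time; the
#' insect-evolution (congener) model only to hosts retained by the
#' low-documentation filter.
#'
#' @param guild the insect's feeding guild.
#' @param host_excluded TRUE if the host was excluded from the congener
#'   analysis.
#' @param has_divergence TRUE if the pair has a resolved positive
#'   divergence time.
#' @param guild_models character vector of guilds with a host-evolution
#'   model.
#' @return character vector, a subset of
#'   `c("host_traits", "host_evolution", "insect_evolution")`.
#' @export
applicable_submodels <- function(guild, host_excluded, has_divergence = TRUE,
                                 guild_models = c("folivore", "sap_feeder")) {
  out <- "host_traits"
  if (guild %in% guild_models && isTRUE(has_divergence)) {
    out <- c(out, "host_evolution")
  }
  if (!isTRUE(host_excluded)) out <- c(out, "insect_evolution")
  if (length(out) == 0) stop("no submodel applies; composite risk undefined")
  out
}

#' Closest native host for every pair in a census
#'
#' Resolves each insect-host pair's closest native-range host and
#' divergence time on the dated tree, flagging conspecific matches.
#'
#' @param census a `census` list (insects, hosts, pairs).
#' @param tree dated tree whose tips cover the native and novel hosts.
#' @param overrides optional pairwise-age override table (see
#'   [mrca_age()]).
#' @return data frame: `insect_id`, `host_id`, `native_host_id`,
#'   `divergence_mya`, `conspecific`.
#' @export
closest_hosts_table <- function(census, tree, overrides = NULL) {
  native <- strsplit(census$insects$native_hosts, "|", fixed = TRUE)
  names(native) <- census$insects$species_id
  D <- divergence_matrix(tree)
  res <- lapply(seq_len(nrow(census$pairs)), function(i) {
    ins <- census$pairs$insect_id[i]
    hst <- census$pairs$host_id[i]
    nat <- native[[ins]]
    if (is.null(nat) || length(nat) == 0 || all(is.na(nat))) {
      return(data.frame(insect_id = ins, host_id = hst,
                        native_host_id = NA_character_,
                        divergence_mya = NA_real_, conspecific = FALSE))
    }
    if (is.null(overrides) && hst %in% rownames(D) &&
        all(nat %in% colnames(D))) {
      ages <- D[hst, nat]
      ord <- order(ages, nat)
      best <- ord[1]
      data.frame(insect_id = ins, host_id = hst, native_host_id = nat[best],
                 divergence_mya = unname(ages[best]),
                 conspecific = ages[best] == 0)
    } else {
      ch <- closest_native_host(tree, hst, nat, overrides = overrides)
      data.frame(insect_id = ins, host_id = hst,
                 native_host_id = ch$native_host,
                 divergence_mya = ch$divergence_mya,
                 conspecific = ch$conspecific)
    }
  })
  do.call(rbind, res)
}

#' Build triplet records (insect x novel host x native host)
#'
#' One row per combination of a census pair with each native host of the
#' insect, carrying the divergence time between the novel and native host.
#'
#' @inheritParams closest_hosts_table
#' @return data frame: `insect_id`, `novel_host_id`, `native_host_id`,
#'   `divergence_mya`.
#' @export
build_triplets <- function(census, tree, overrides = NULL) {
  native <- strsplit(census$insects$native_hosts, "|", fixed = TRUE)
  names(native) <- census$insects$species_id
  D <- divergence_matrix(tree)
  nat_per_pair <- native[census$pairs$insect_id]
  reps <- lengths(nat_per_pair)
  out <- data.frame(
    insect_id = rep(census$pairs$insect_id, reps),
    novel_host_id = rep(census$pairs$host_id, reps),
    native_host_id = unlist(nat_per_pair, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  in_tree <- if (is.null(overrides)) {
    out$novel_host_id %in% rownames(D) & out$native_host_id %in% colnames(D)
  } else {
    rep(FALSE, nrow(out))
  }
  age <- rep(NA_real_, nrow(out))
  age[in_tree] <- D[cbind(out$novel_host_id[in_tree],
                          out$native_host_id[in_tree])]
  if (any(!in_tree)) {
    age[!in_tree] <- mapply(function(a, b) {
      mrca_age(tree, a, b, overrides = overrides)
    }, out$novel_host_id[!in_tree], out$native_host_id[!in_tree])
  }
  out$divergence_mya <- age
  rownames(out) <- NULL
  out
}
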