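test_that("candidate sets match the published model lists", {
  cs <- build_candidate_sets()
  expect_length(cs$insect, 12)
  expect_length(cs$host, 10)
  expect_length(cs$congener, 3)
  expect_true("voltinism + reproductive_strategy + dispersal" %in%
                names(cs$insect))
  expect_true("shade_tolerance + drought_tolerance" %in% names(cs$host))
  expect_true(all(c("null", "global") %in% names(cs$insect)))
  expect_true(all(c("null", "global") %in% names(cs$host)))
  expect_false("global" %in% names(cs$congener))
  # K counts where the level sets are pinned down by the coefficient
  # table: shade (3 levels) + drought (4 levels) estimates 6 parameters
  cen <- default_census()
  pd <- merge(cen$pairs, cen$hosts, by.x = "host_id", by.y = "species_id")
  f2 <- fit_logistic(cs$host[["shade_tolerance + drought_tolerance"]], pd)
  expect_equal(f2$K, 6)
  f3 <- fit_logistic(cs$congener[["null"]], pd)
  expect_equal(f3$K, 1)
})

test_that("published guild curves reproduce the printed risk anchors", {
  fol <- published_guild_model("folivore")
  # ~76% chance of high impact for hosts diverged 2-3 mya
  expect_equal(predict_guild_risk(fol, 2.5), 0.767, tolerance = 5e-3)
  peak <- max(predict_guild_risk(fol, seq(2, 3, by = 1e-3)))
  expect_equal(peak, 0.769, tolerance = 2e-3)
  expect_equal(fol$vertex_mya, 2.66, tolerance = 0.01)

  sap <- published_guild_model("sap_feeder")
  expect_equal(sap$vertex_mya, 10^(84.472 / (2 * 35.803)), tolerance = 1e-9)
  expect_equal(sap$vertex_mya, 15.1, tolerance = 0.05)   # printed zenith ~16
  expect_lt(predict_guild_risk(sap, 310), 1e-27)          # infinitesimal tail

  expect_error(predict_guild_risk(fol, -1), "positive")
  expect_error(published_guild_model("wood_borer"), "no published")
})

test_that("published guild curves are unimodal around their vertex", {
  for (g in c("folivore", "sap_feeder")) {
    m <- published_guild_model(g)
    xs <- seq(log10(0.5), log10(340), length.out = 400)
    p <- predict_guild_risk(m, 10^xs)
    v <- which.max(p)
    expect_true(all(diff(p[1:v]) > 0))
    expect_true(all(diff(p[v:length(p)]) < 0))
  }
})

test_that("host-trait predictions span exactly the published range", {
  grid <- expand.grid(shade = c("low", "moderate", "high"),
                      drought = c("none", "low", "moderate", "high"),
                      stringsAsFactors = FALSE)
  p <- predict_host_trait_risk(grid$shade, grid$drought)
  expect_equal(round(min(p), 3), 0.014)
  expect_equal(round(max(p), 3), 0.259)
  # the riskiest hosts are shade-tolerant; the maximum sits at
  # high shade + moderate drought
  expect_equal(grid$shade[which.max(p)], "high")
  expect_error(predict_host_trait_risk("verylow", "none"), "unknown shade")
})

test_that("host-evolution fitting refuses guilds without high impact", {
  gall <- data.frame(guild = "gall_maker",
                     divergence_mya = 10^seq(0, 2, length.out = 30),
                     high_impact = 0L)
  expect_error(fit_host_evolution(gall, "gall_maker"), "zero high-impact")
  expect_error(fit_host_evolution(gall[0, ], "folivore"), "no pairs")
  dd <- data.frame(guild = "folivore", divergence_mya = rep(5, 20),
                   high_impact = rep(c(0, 1), 10))
  expect_error(fit_host_evolution(dd, "folivore"), "aliased")
})

test_that("folivore vertex is recovered from data generated at n = 49", {
  fol <- published_guild_model("folivore")
  set.seed(10)
  vertices <- replicate(200, {
    t <- 10^runif(49, 0, log10(340))
    p <- predict_guild_risk(fol, t)
    d <- data.frame(guild = "folivore", divergence_mya = t,
                    high_impact = rbinom(49, 1, p))
    m <- tryCatch(suppressWarnings(fit_host_evolution(d, "folivore")),
                  error = function(e) NULL)
    if (is.null(m)) NA_real_ else m$vertex_mya
  })
  expect_true(median(vertices, na.rm = TRUE) > 1.5 &&
                median(vertices, na.rm = TRUE) < 5)
})

test_that("congener status follows taxonomic nesting and monotonicity", {
  hg <- data.frame(genus = c("adelges", "pineus"),
                   family = c("adelgidae", "adelgidae"))
  expect_identical(assign_congener_status("adelges", "adelgidae", hg),
                   "shared_genus")
  expect_identical(assign_congener_status("dreyfusia", "adelgidae", hg),
                   "shared_family_only")
  expect_identical(assign_congener_status("matsucoccus", "matsucoccidae", hg),
                   "none")
  empty <- data.frame(genus = character(0), family = character(0))
  expect_identical(assign_congener_status("adelges", "adelgidae", empty),
                   "none")
  bad <- data.frame(genus = "adelges", family = NA_character_)
  expect_error(assign_congener_status("x", "y", bad), "family labels")
  # adding genera never moves a pair away from shared_genus
  grown <- rbind(hg, data.frame(genus = "zzz", family = "zzz_fam"))
  expect_identical(assign_congener_status("adelges", "adelgidae", grown),
                   "shared_genus")
})

test_that("submodel availability follows guild, filter and divergence", {
  expect_setequal(applicable_submodels("folivore", host_excluded = FALSE),
                  c("host_traits", "host_evolution", "insect_evolution"))
  expect_setequal(applicable_submodels("wood_borer", host_excluded = FALSE),
                  c("host_traits", "insect_evolution"))
  expect_setequal(applicable_submodels("sap_feeder", host_excluded = TRUE),
                  c("host_traits", "host_evolution"))
  expect_setequal(applicable_submodels("folivore", host_excluded = FALSE,
                                       has_divergence = FALSE),
                  c("host_traits", "insect_evolution"))
  ns <- vapply(seq_len(nrow(default_census()$truth)), function(i) {
    d <- default_census()$truth[i, ]
    length(applicable_submodels(d$guild, d$host_excluded,
                                !is.na(d$divergence_mya)))
  }, numeric(1))
  expect_true(all(ns %in% 1:3))
})

test_that("published coefficient fixture is immutable and complete", {
  pc <- published_coefficients()
  expect_equal(pc$host_evolution$folivore$intercept, -0.515)
  expect_equal(pc$host_evolution$sap_feeder$log10_divergence, 84.472)
  expect_equal(pc$host_traits$shade_tolerance$high, 2.434)
  expect_equal(pc$insect_evolution$shared_genus, -2.124)
  expect_equal(pc$overall_baseline, 0.072)
  expect_equal(pc$insect_evolution$group_sizes$congener_absent, 128)
})
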