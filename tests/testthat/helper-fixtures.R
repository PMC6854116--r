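# Small hand-built census used by the I/O and filter tests.
tiny_census_tables <- function() {
  insects <- data.frame(
    species_id = c("ins_a", "ins_b", "ins_c"),
    order = "hemiptera",
    family = c("fam_1", "fam_1", "fam_2"),
    genus = c("gen_a", "gen_b", "gen_c"),
    guild = c("folivore", "sap_feeder", "wood_borer"),
    voltinism = c("univoltine", "multivoltine", "univoltine"),
    reproductive_strategy = c("sexual", "parthenogenic", "sexual"),
    dispersal = c("flight", "wind", "flight"),
    native_range = c("europe", "east_asia", "europe"),
    pest_status = c("pest", "non_pest", "pest"),
    n_native_host_genera = c(2L, 1L, 1L),
    native_hosts = c("host_3|host_4", "host_4", "host_3"),
    stringsAsFactors = FALSE
  )
  hosts <- data.frame(
    species_id = paste0("host_", 1:4),
    shade_tolerance = c("low", "moderate", "high", "low"),
    drought_tolerance = c("none", "low", "moderate", "high"),
    growth_rate = c("slow", "moderate", "rapid", "slow"),
    wood_density = c(0.41, 0.45, 0.52, 0.38),
    foliage_texture = c("fine", "medium", "coarse", "fine"),
    fire_tolerance = c("none", "low", "moderate", "high"),
    native_insect_genera = c("gen_a:fam_1|gen_x:fam_9", "gen_b:fam_1",
                             NA, "gen_y:fam_2"),
    stringsAsFactors = FALSE
  )
  pairs <- data.frame(
    insect_id = c("ins_a", "ins_a", "ins_b", "ins_c"),
    host_id = c("host_1", "host_2", "host_1", "host_3"),
    impact_level = c(7L, 2L, 1L, 6L),
    stringsAsFactors = FALSE
  )
  list(insects = insects, hosts = hosts, pairs = pairs)
}

# 4-tip tree with known ages: ((A:1,B:1):2,(C:2,D:2):1); root age 3
tiny_tree <- function() {
  parse_newick("((A:1,B:1):2,(C:2,D:2):1);")
}

default_census <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(simulate_census(simulation_config(seed = 42)))
    }
    cache
  }
})
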