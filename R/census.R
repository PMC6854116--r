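#' Convert the 9-level impact scale to the binary high-impact response
#'
#' The census scores each insect-host pair on a 1-9 impact scale; levels 6
#' and above (mortality at the population or regional scale, up to
#' functional extinction of the host) define a high-impact invasion. Levels
#' 1-5 (no damage through mortality of individual trees) are not high
#' impact.
#'
#' @param impact_level integer vector with values in 1..9.
#' @return integer vector of 0/1; 1 iff `impact_level >= 6`.
#' @examples
#' binarize_impact(c(1, 5, 6, 9))
#' @export
binarize_impact <- function(impact_level) {
  if (length(impact_level) == 0) return(integer(0))
  if (anyNA(impact_level) || any(impact_level != as.integer(impact_level)) ||
      any(impact_level < 1 | impact_level > 9)) {
    stop("impact_level must be an integer in 1..9")
  }
  as.integer(impact_level >= 6)
}

GUILD_LEVELS <- c("folivore", "sap_feeder", "wood_borer", "root_feeder",
                  "gall_maker")

SHADE_LEVELS <- c("low", "moderate", "high")
DROUGHT_LEVELS <- c("none", "low", "moderate", "high")

#' Validate a census (insect, host and pair tables)
#'
#' Checks column presence, level sets, impact range, uniqueness of pairs
#' and referential integrity (every pair id resolves to the insect and host
#' tables; every host's documented genus count equals the length of its
#' native-genus list). Errors name the offending rows.
#'
#' @param insects insect table (one row per non-native conifer specialist).
#' @param hosts host table (one row per North American conifer).
#' @param pairs pair table with `insect_id`, `host_id`, `impact_level`.
#' @return invisibly, a list of the three validated tables with
#'   `high_impact` added to `pairs`; class `census`.
#' @export
validate_census <- function(insects, hosts, pairs) {
  need_i <- c("species_id", "order", "family", "genus", "guild", "voltinism",
              "reproductive_strategy", "dispersal", "native_range",
              "pest_status", "n_native_host_genera", "native_hosts")
  need_h <- c("species_id", "shade_tolerance", "drought_tolerance",
              "growth_rate", "wood_density", "foliage_texture",
              "fire_tolerance", "native_insect_genera")
  need_p <- c("insect_id", "host_id", "impact_level")
  chk_cols <- function(df, need, what) {
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s) in ", what, " table: ",
                           paste(miss, collapse = ", "))
  }
  chk_cols(insects, need_i, "insect")
  chk_cols(hosts, need_h, "host")
  chk_cols(pairs, need_p, "pair")

  if (anyDuplicated(insects$species_id))
    stop("duplicate insect species_id")
  if (anyDuplicated(hosts$species_id))
    stop("duplicate host species_id")
  bad_guild <- !insects$guild %in% GUILD_LEVELS
  if (any(bad_guild)) {
    stop("unknown guild for insect(s): ",
         paste(insects$species_id[bad_guild], collapse = ", "))
  }
  if (any(insects$n_native_host_genera < 1)) {
    stop("n_native_host_genera must be >= 1")
  }
  bad_sh <- !hosts$shade_tolerance %in% SHADE_LEVELS
  if (any(bad_sh)) stop("invalid shade_tolerance for host(s): ",
                        paste(hosts$species_id[bad_sh], collapse = ", "))
  bad_dr <- !hosts$drought_tolerance %in% DROUGHT_LEVELS
  if (any(bad_dr)) stop("invalid drought_tolerance for host(s): ",
                        paste(hosts$species_id[bad_dr], collapse = ", "))

  dup <- duplicated(pairs[c("insect_id", "host_id")])
  if (any(dup)) {
    stop("duplicate insect-host pair(s) at row(s): ",
         paste(which(dup), collapse = ", "))
  }
  unknown_i <- !pairs$insect_id %in% insects$species_id
  if (any(unknown_i)) {
    stop("pair row(s) ", paste(which(unknown_i), collapse = ", "),
         " reference unknown insect id(s): ",
         paste(unique(pairs$insect_id[unknown_i]), collapse = ", "))
  }
  unknown_h <- !pairs$host_id %in% hosts$species_id
  if (any(unknown_h)) {
    stop("pair row(s) ", paste(which(unknown_h), collapse = ", "),
         " reference unknown host id(s): ",
         paste(unique(pairs$host_id[unknown_h]), collapse = ", "))
  }
  pairs$high_impact <- binarize_impact(pairs$impact_level)

  glist <- host_genus_list(hosts)
  nlen <- vapply(glist, nrow, integer(1))
  cnt <- host_documented_count(hosts)
  if (any(cnt != nlen)) {
    stop("documented genus count mismatch for host(s): ",
         paste(hosts$species_id[cnt != nlen], collapse = ", "))
  }
  invisible(structure(list(insects = insects, hosts = hosts, pairs = pairs),
                      class = "census"))
}

# "genus:family|genus:family" tokens -> list of data.frames(genus, family)
host_genus_list <- function(hosts) {
  lapply(hosts$native_insect_genera, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(genus = character(0), family = character(0)))
    }
    tok <- strsplit(s, "|", fixed = TRUE)[[1]]
    parts <- strsplit(tok, ":", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) stop("malformed genus:family token(s): ",
                       paste(tok[bad], collapse = ", "))
    data.frame(genus = vapply(parts, `[`, "", 1),
               family = vapply(parts, `[`, "", 2))
  })
}

host_documented_count <- function(hosts) {
  if ("documented_native_genus_count" %in% names(hosts)) {
    hosts$documented_native_genus_count
  } else {
    vapply(host_genus_list(hosts), nrow, integer(1))
  }
}

#' Read / write a census from TSV files
#'
#' `read_census()` reads `insects.tsv`, `hosts.tsv` and `pairs.tsv` from a
#' directory (plus `conifers.nwk` if present) and validates them.
#' List-valued columns (`native_hosts`, `native_insect_genera`) are
#' pipe-delimited; missing values are encoded `NA`; categorical levels are
#' lower-case. `write_census()` is its inverse; a write/read round trip is
#' lossless for every declared field.
#'
#' @param dir directory containing the TSV files.
#' @return a `census` list with `insects`, `hosts`, `pairs` (with
#'   `high_impact` added) and `tree` (or `NULL`).
#' @export
read_census <- function(dir) {
  rd <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing census file: ", path)
    utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  }
  insects <- rd("insects.tsv")
  hosts <- rd("hosts.tsv")
  pairs <- rd("pairs.tsv")
  cen <- validate_census(insects, hosts, pairs)
  nwk <- file.path(dir, "conifers.nwk")
  cen$tree <- if (file.exists(nwk)) parse_newick(file = nwk) else NULL
  cen
}

#' @rdname read_census
#' @param census a `census` object (or plain list with the three tables).
#' @export
write_census <- function(census, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA")
  }
  pairs <- census$pairs
  pairs$high_impact <- NULL        # derived column, recomputed on read
  wr(census$insects, "insects.tsv")
  wr(census$hosts, "hosts.tsv")
  wr(pairs, "pairs.tsv")
  if (!is.null(census$tree)) {
    ape::write.tree(census$tree, file.path(dir, "conifers.nwk"))
  }
  invisible(dir)
}

#' Exclude pairs whose closest native host is the novel host itself
#'
#' A pair where the same species is both the novel North American host and
#' the insect's closest native-range host carries no divergence information
#' (divergence time 0) and is excluded from the host-evolution analysis.
#'
#' @param pairs pair table.
#' @param closest_host_map data frame with `insect_id`, `host_id` and
#'   `conspecific` (logical), as produced by [closest_hosts_table()].
#' @return list with `retained` and `excluded` pair tables;
#'   `nrow(retained) + nrow(excluded) == nrow(pairs)`.
#' @export
filter_conspecific_pairs <- function(pairs, closest_host_map) {
  if (nrow(pairs) == 0) {
    return(list(retained = pairs, excluded = pairs))
  }
  key <- paste(pairs$insect_id, pairs$host_id, sep = "\r")
  mkey <- paste(closest_host_map$insect_id, closest_host_map$host_id,
                sep = "\r")
  consp <- closest_host_map$conspecific[match(key, mkey)]
  consp[is.na(consp)] <- FALSE     # pairs with no resolved closest host
  list(retained = pairs[!consp, , drop = FALSE],
       excluded = pairs[consp, , drop = FALSE])
}

#' Exclude the least-documented hosts from the congener analysis
#'
#' Hosts with very few documented native insect genera are likely to yield
#' false congener absences, so the fraction of hosts with the fewest
#' documented genera is excluded from the insect-evolution (congener)
#' submodel only. The study census of 49 hosts used an explicit count of 8;
#' because 10 percent of 49 is ambiguous, the count can be overridden.
#' Ties at the cutoff break lexicographically by species id.
#'
#' @param hosts host table (needs `native_insect_genera` or an explicit
#'   `documented_native_genus_count` column).
#' @param fraction fraction of hosts to exclude (default 0.10); the count
#'   defaults to round-half-up of `fraction * nrow(hosts)`.
#' @param n_exclude explicit number of hosts to exclude, overriding
#'   `fraction`.
#' @return character vector of excluded host ids (sorted by documentation
#'   count, then id).
#' @export
filter_low_documentation_hosts <- function(hosts, fraction = 0.10,
                                           n_exclude = NULL) {
  cnt <- host_documented_count(hosts)
  n <- n_exclude %||% round_half_up(fraction * nrow(hosts))
  n <- as.integer(n)
  if (n < 0 || n > nrow(hosts)) stop("invalid exclusion count: ", n)
  if (n == 0) return(character(0))
  ord <- order(cnt, hosts$species_id)
  hosts$species_id[ord[seq_len(n)]]
}
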