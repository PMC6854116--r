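#' Parse a dated Newick phylogeny
#'
#' Reads a rooted, dated host phylogeny (branch lengths in millions of
#' years) and validates it: every branch must carry a length, tip labels
#' must be unique, and ultrametricity is checked to a relative tolerance of
#' 1e-6 times the root age. Non-ultrametric trees are accepted with a
#' warning; divergence ages are then defined as the MRCA node's maximum
#' distance to its descendant tips.
#'
#' @param text Newick string, or `NULL` when `file` is given.
#' @param file path to a Newick file.
#' @return an `ape::phylo` tree with attributes `root_age` and
#'   `ultrametric` (logical).
#' @examples
#' tr <- parse_newick("((A:1,B:1):2,C:3);")
#' attr(tr, "root_age")
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  stopifnot(xor(is.null(text), is.null(file)))
  tr <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("malformed Newick: ", conditionMessage(e)),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w))
  )
  if (is.null(tr) || !inherits(tr, "phylo")) stop("malformed Newick input")
  as_dated_tree(tr)
}

#' @rdname parse_newick
#' @param tree an `ape::phylo` object to validate in place.
#' @export
as_dated_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths; a dated tree is required")
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  depth <- ape::node.depth.edgelength(tree)
  tipd <- depth[seq_len(ape::Ntip(tree))]
  root_age <- max(tipd)
  ultra <- (root_age == 0) || (max(tipd) - min(tipd)) <= 1e-6 * root_age
  if (!ultra) {
    warning("tree is not ultrametric (root-to-tip spread ",
            format(max(tipd) - min(tipd)),
            "); MRCA ages use maximum distance-to-tip")
  }
  attr(tree, "root_age") <- root_age
  attr(tree, "ultrametric") <- ultra
  tree
}

# Age (time before present) of every internal node and tip: the maximum
# distance from the node to any of its descendant tips. For ultrametric
# trees this is root_age - node depth.
node_ages <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  age <- numeric(n_node)                 # tips age 0 under ultrametry
  # max distance-to-descendant-tip, computed tips-up over edges
  dist_down <- numeric(n_node)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1]; child <- ord$edge[i, 2]
    len <- ord$edge.length[i]
    dist_down[par] <- max(dist_down[par], dist_down[child] + len)
  }
  dist_down
}

#' Age of the most recent common ancestor of two tips
#'
#' For an ultrametric dated tree this equals the divergence time of the two
#' lineages in millions of years. An optional override table supplies ages
#' for host pairs placed from other published phylogenies; it is consulted
#' before the tree.
#'
#' @param tree dated tree from [parse_newick()].
#' @param tip_a,tip_b tip labels.
#' @param overrides optional data frame with columns `host_a`, `host_b`,
#'   `divergence_mya` (unordered pairs).
#' @return MRCA age in millions of years; 0 when `tip_a == tip_b`.
#' @export
mrca_age <- function(tree, tip_a, tip_b, overrides = NULL) {
  stopifnot(length(tip_a) == 1, length(tip_b) == 1)
  if (!is.null(overrides)) {
    hit <- (overrides$host_a == tip_a & overrides$host_b == tip_b) |
      (overrides$host_a == tip_b & overrides$host_b == tip_a)
    if (any(hit)) return(overrides$divergence_mya[which(hit)[1]])
  }
  lab <- tree$tip.label
  ia <- match(tip_a, lab); ib <- match(tip_b, lab)
  if (is.na(ia)) stop("unknown tip: ", tip_a)
  if (is.na(ib)) stop("unknown tip: ", tip_b)
  if (ia == ib) return(0)
  node <- ape::getMRCA(tree, c(ia, ib))
  node_ages(tree)[node]
}

#' All pairwise MRCA ages between tips
#'
#' Bulk version of [mrca_age()] used when scoring whole censuses; on an
#' ultrametric tree equals half the patristic (cophenetic) distance matrix.
#'
#' @param tree dated tree.
#' @return symmetric matrix of ages with tip labels as dimnames.
#' @export
divergence_matrix <- function(tree) {
  ages <- node_ages(tree)
  m <- ape::mrca(tree)              # tip x tip MRCA node numbers
  out <- matrix(ages[m], nrow = nrow(m), dimnames = dimnames(m))
  diag(out) <- 0
  out
}

#' Closest native host of a novel host
#'
#' Among an insect's native hosts, returns the one whose divergence from the
#' novel host (MRCA age) is smallest. A conspecific match (the novel host is
#' itself a native host, age 0) is returned and flagged so downstream
#' analysis can exclude the pair. Ties in age break lexicographically by
#' species name.
#'
#' @param tree dated tree.
#' @param novel_host tip label of the novel (North American) host.
#' @param native_hosts non-empty character vector of native-range hosts.
#' @param overrides optional pairwise-age override table (see [mrca_age()]).
#' @return list with `native_host`, `divergence_mya`, `conspecific`.
#' @export
closest_native_host <- function(tree, novel_host, native_hosts,
                                overrides = NULL) {
  if (length(native_hosts) == 0) {
    stop("insect has no native hosts; it cannot enter the host-evolution ",
         "submodel")
  }
  ages <- vapply(native_hosts, function(h) {
    mrca_age(tree, novel_host, h, overrides = overrides)
  }, numeric(1))
  ord <- order(ages, native_hosts)    # lexicographic tie-break
  best <- ord[1]
  list(native_host = unname(native_hosts[best]),
       divergence_mya = unname(ages[best]),
       conspecific = ages[best] == 0)
}

#' Blomberg's K phylogenetic-signal statistic
#'
#' K compares the observed ratio of the ordinary mean squared deviation of
#' tip values from the phylogenetically corrected (GLS) mean to the
#' phylogenetically weighted mean squared deviation, against the ratio
#' expected under Brownian motion on the same tree. K = 1 under Brownian
#' motion; K near 0 when trait values are random with respect to the
#' phylogeny; K > 1 when relatives are even more similar than Brownian
#' motion predicts. K is invariant to shifting and scaling the trait.
#'
#' @param tree dated tree with >= 4 tips.
#' @param trait_values named numeric vector, one finite value per tip, or an
#'   unnamed vector in `tree$tip.label` order.
#' @return Blomberg's K (non-negative scalar).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' blomberg_k(tr, c(A = 1, B = 1.1, C = 5, D = 5.2))
#' @export
blomberg_k <- function(tree, trait_values) {
  prep <- blomberg_prepare(tree)
  x <- align_trait(tree, trait_values)
  blomberg_k_stat(prep, x)
}

# Precompute the covariance structure once (reused across permutations).
blomberg_prepare <- function(tree) {
  n <- ape::Ntip(tree)
  if (n < 4) stop("Blomberg's K needs at least 4 tips")
  C <- ape::vcv(tree)
  Cinv <- tryCatch(solve(C),
                   error = function(e) stop("singular phylogenetic ",
                                            "covariance matrix"))
  list(n = n, C = C, Cinv = Cinv,
       ones_Cinv = colSums(Cinv),
       sum_Cinv = sum(Cinv),
       expected_ratio = (sum(diag(C)) - n / sum(Cinv)) / (n - 1),
       labels = rownames(C))
}

blomberg_k_stat <- function(prep, x) {
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite trait values")
  if (stats::var(x) == 0) stop("constant trait: phylogenetic signal undefined")
  ahat <- sum(prep$ones_Cinv * x) / prep$sum_Cinv   # GLS grand mean
  d <- x - ahat
  mse0 <- sum(d^2) / (prep$n - 1)
  mse <- drop(crossprod(d, prep$Cinv %*% d)) / (prep$n - 1)
  (mse0 / mse) / prep$expected_ratio
}

align_trait <- function(tree, x) {
  if (!is.null(names(x))) {
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss)) stop("trait values missing for tips: ",
                           paste(miss, collapse = ", "))
    x <- x[tree$tip.label]
  } else if (length(x) != ape::Ntip(tree)) {
    stop("trait vector length does not match number of tips")
  }
  as.numeric(x)
}

#' Randomization test for phylogenetic signal
#'
#' Tests Blomberg's K against the null hypothesis that trait values are
#' distributed randomly on the phylogeny, by permuting trait values across
#' tips. The p-value uses the add-one convention
#' p = (1 + #\{K_perm >= K_obs\}) / (n_rand + 1), so p can never be exactly 0.
#'
#' @param tree dated tree.
#' @param trait_values one value per tip (see [blomberg_k()]).
#' @param n_rand number of randomizations (default 1000).
#' @param seed optional RNG seed for reproducible permutations.
#' @return list with `K_stat`, `p_value`, `n_randomizations`.
#' @export
k_randomization_test <- function(tree, trait_values, n_rand = 1000,
                                 seed = NULL) {
  stopifnot(n_rand >= 1)
  if (!is.null(seed)) set.seed(seed)
  prep <- blomberg_prepare(tree)
  x <- align_trait(tree, trait_values)
  k_obs <- blomberg_k_stat(prep, x)
  k_perm <- vapply(seq_len(n_rand), function(i) {
    blomberg_k_stat(prep, sample(x))
  }, numeric(1))
  list(K_stat = k_obs,
       p_value = (1 + sum(k_perm >= k_obs)) / (n_rand + 1),
       n_randomizations = n_rand)
}

#' Integer coding of ordinal tolerance levels
#'
#' Maps ordered categorical tolerance levels onto consecutive integers
#' starting at 0 (none = 0, low = 1, moderate = 2, high = 3 for the default
#' four-level scale), as required for computing phylogenetic signal on
#' ordinal host traits. "medium" is accepted as a synonym for "moderate".
#'
#' @param x character vector of levels.
#' @param levels the declared ordered level set.
#' @return integer codes, 0-based.
#' @examples
#' encode_ordinal(c("none", "low", "medium", "high"))
#' @export
encode_ordinal <- function(x, levels = c("none", "low", "moderate", "high")) {
  x <- ifelse(x == "medium", "moderate", as.character(x))
  idx <- match(x, levels)
  if (anyNA(idx)) {
    stop("unknown ordinal level(s): ",
         paste(unique(x[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}
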