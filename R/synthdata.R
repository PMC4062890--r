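# Synthetic-data generators emulating the statistical structure the analyses
# assume: Poisson mutation counts down a star genealogy at a fixed clock,
# haplotypes generated down the haplogroup tree, per-transmission pedigree
# mutations, and multinomial regional compositions. Every generator takes an
# explicit seed and is a pure function of its arguments.

#' Simulate a star-shaped mutation-count tree under a linear clock
#'
#' Each of \code{n_tips} lineages accumulates a Poisson number of mutations
#' with mean \code{true_age_years / years_per_mutation}, the event-counting
#' semantics of the whole-molecule clock.
#'
#' @param n_tips Number of tips (>= 2).
#' @param true_age_years True coalescence age of the star node, years (>= 0).
#' @param years_per_mutation Clock calibration (default 3,624 yr/mutation).
#' @param seed Integer seed (required).
#' @return A [mut_tree()] with unit tip multiplicities.
#' @examples
#' tr <- simulate_star_tree(10, 10000, seed = 1)
#' rho_age(tr)
#' @export
simulate_star_tree <- function(n_tips, true_age_years,
                               years_per_mutation = SOARES_YEARS_PER_MUTATION,
                               seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_tips >= 2, true_age_years >= 0, years_per_mutation > 0)
  set.seed(seed)
  lens <- stats::rpois(n_tips, true_age_years / years_per_mutation)
  phy <- list(
    edge = cbind(rep(n_tips + 1L, n_tips), seq_len(n_tips)),
    edge.length = as.numeric(lens),
    tip.label = paste0("t", seq_len(n_tips)),
    Nnode = 1L
  )
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  mut_tree(phy)
}

# Apply a path's motif tokens cumulatively: a back-mutation removes the plain
# token at its position (if present) and records the "!" token.
apply_path_tokens <- function(path_var) {
  toks <- character(0)
  for (i in seq_len(nrow(path_var))) {
    v <- path_var[i, ]
    if (v$back) {
      plain <- sub("!$", "", v$token)
      toks <- setdiff(toks, plain)
    }
    toks <- union(toks, v$token)
  }
  toks
}

#' Simulate haplotypes down a haplogroup tree
#'
#' Each sample is assigned a named node (multinomially, by \code{node_weights})
#' and carries the union of the defining variants on that node's root path,
#' with back-mutations applied (the earlier derived state is removed and the
#' explicit \code{"!"} token kept). With \code{noise_rate > 0}, a Poisson
#' number of extra private transitions is added at positions drawn uniformly
#' from HVR-1 with probability \code{hvr1_weight} and from the rest of the
#' molecule otherwise; noise never overwrites a motif position. True labels are
#' retained for scoring.
#'
#' @param tree A \code{haplo_tree} (default the shipped U6 tree).
#' @param node_weights Named numeric vector of weights over node names
#'   (normalised internally).
#' @param n Number of samples (>= 0).
#' @param seed Integer seed (required).
#' @param noise_rate Mean number of extra private mutations per sample
#'   (default 0: noise-free).
#' @param hvr1_weight Probability that a noise position falls in HVR-1;
#'   default the HVR-1 share of the molecule.
#' @param range Covered range of the emitted profiles.
#' @return List with \code{profiles} (named list of [haplotype_profile()]) and
#'   \code{labels} (generating node per sample).
#' @examples
#' sim <- simulate_haplotypes(node_weights = c(U6b1a = 1), n = 3, seed = 1)
#' sim$labels
#' @export
simulate_haplotypes <- function(tree = u6_tree(), node_weights, n, seed,
                                noise_rate = 0, hvr1_weight = NULL,
                                range = "genome") {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n >= 0, noise_rate >= 0)
  unknown <- setdiff(names(node_weights), tree$nodes$name)
  if (length(unknown)) stop("unknown node name(s): ", paste(unknown, collapse = ", "))
  if (is.null(hvr1_weight)) {
    hvr1_weight <- (hvr1_range()[2L] - hvr1_range()[1L] + 1) / MT_GENOME_LENGTH
  }
  set.seed(seed)
  if (n == 0L) return(list(profiles = list(), labels = character(0)))
  w <- node_weights / sum(node_weights)
  labels <- sample(names(w), n, replace = TRUE, prob = w)
  rng <- as_range(range)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    toks <- apply_path_tokens(tree$path_tokens[[labels[i]]])
    if (noise_rate > 0) {
      k <- stats::rpois(1L, noise_rate)
      used <- parse_variants(toks)$position
      while (k > 0L) {
        pos <- if (stats::runif(1L) < hvr1_weight) {
          sample(hvr1_range()[1L]:hvr1_range()[2L], 1L)
        } else {
          sample(MT_GENOME_LENGTH, 1L)
        }
        if (pos %in% used || !range_contains(rng, pos)) next
        toks <- c(toks, as.character(pos))
        used <- c(used, pos)
        k <- k - 1L
      }
    }
    keep <- range_contains(rng, parse_variants(toks)$position)
    profiles[[i]] <- haplotype_profile(toks[keep], range = rng)
  }
  names(profiles) <- sprintf("S%04d", seq_len(n))
  list(profiles = profiles, labels = labels)
}

#' Simulate mutations along a pedigree's transmission events
#'
#' Each of \code{transmissions} mother-to-child transmissions mutates
#' independently with probability \code{rate}; the observed count k is
#' Binomial(T, rate) and each event is placed on its transmission.
#'
#' @param transmissions Number of transmission events T (> 0).
#' @param rate Per-transmission mutation probability in [0, 1].
#' @param seed Integer seed (required).
#' @param founders Number of founding lineages (bookkeeping only; default 1).
#' @return List: k (substitutions observed), transmissions, events (indices of
#'   mutated transmissions), founders.
#' @examples
#' simulate_pedigree(90, 1 / 90, seed = 1)$k
#' @export
simulate_pedigree <- function(transmissions, rate, seed, founders = 1L) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(transmissions > 0, rate >= 0)
  if (rate > 1) stop("per-transmission rate cannot exceed 1")
  set.seed(seed)
  hit <- stats::runif(transmissions) < rate
  list(k = sum(hit), transmissions = transmissions, events = which(hit),
       founders = founders)
}

#' Simulate one regional frequency-table row
#'
#' The number of U6 carriers is Binomial(N, u6_freq) and their subhaplogroup
#' composition multinomial with the given category probabilities.
#'
#' @param composition Named probability vector over (a subset of)
#'   [u6_categories()]-style column names; must sum to 1.
#' @param N Regional sample size (> 0).
#' @param u6_freq U6 carrier proportion in [0, 1].
#' @param seed Integer seed (required).
#' @param region Region code for the emitted row.
#' @return A one-row \code{frequency_table}.
#' @examples
#' simulate_region_table(c(U6a_without_235 = 0.125, U6a189_without_239 = 0.875),
#'                       N = 1400, u6_freq = 0.0057, seed = 1)
#' @export
simulate_region_table <- function(composition, N, u6_freq, seed,
                                  region = "SIM") {
  if (missing(seed)) stop("a seed is required")
  stopifnot(N > 0, u6_freq >= 0, u6_freq <= 1)
  if (abs(sum(composition) - 1) > 1e-8 || any(composition < 0)) {
    stop("composition must be a probability vector summing to 1")
  }
  cats <- category_columns()
  unknown <- setdiff(names(composition), cats)
  if (length(unknown)) stop("unknown category column(s): ",
                            paste(unknown, collapse = ", "))
  set.seed(seed)
  u6 <- stats::rbinom(1L, N, u6_freq)
  counts <- stats::setNames(rep(0L, length(cats)), cats)
  if (u6 > 0L) {
    draw <- stats::rmultinom(1L, u6, composition)[, 1L]
    counts[names(composition)] <- as.integer(draw)
  }
  row <- cbind(data.frame(region = region, sample_size = N, u6_count = u6,
                          stringsAsFactors = FALSE),
               as.data.frame(as.list(counts)))
  tab <- validate_frequency_table(row)
  if (u6 == 0L) attr(tab, "composition_undefined") <- TRUE
  tab
}
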