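# Rho-statistic coalescence dating with Saillard standard errors, and the
# pedigree mutation-rate estimator with unit conversions.
#
# The clock is linear: age = rho x years_per_mutation, with the whole-molecule
# calibration of one mutation every 3,624 years as the default. No
# purifying-selection correction is applied.

#' Default molecular clock: years per mutation over the whole mtDNA molecule
#' @export
SOARES_YEARS_PER_MUTATION <- 3624

## ---- mutation-count trees ---------------------------------------------------

#' Construct a mutation-count tree
#'
#' A rooted tree whose branch lengths are non-negative integer mutation counts
#' and whose tips carry multiplicities (number of sampled individuals collapsed
#' onto the tip). This is the substrate of the rho statistic and its Saillard
#' standard error.
#'
#' @param phylo A rooted \code{ape::phylo} object with integer branch lengths.
#' @param multiplicity Integer vector of tip multiplicities, named by tip label
#'   or in tip order; default 1 for every tip.
#' @return An object of class \code{mut_tree}.
#' @export
mut_tree <- function(phylo, multiplicity = NULL) {
  stopifnot(inherits(phylo, "phylo"))
  if (is.null(phylo$edge.length)) stop("tree has no branch lengths")
  if (any(phylo$edge.length < 0)) stop("negative mutation counts")
  if (any(abs(phylo$edge.length - round(phylo$edge.length)) > 1e-8)) {
    stop("branch lengths must be integer mutation counts")
  }
  nt <- length(phylo$tip.label)
  if (is.null(multiplicity)) {
    mult <- stats::setNames(rep(1L, nt), phylo$tip.label)
  } else {
    if (!is.null(names(multiplicity))) {
      if (!setequal(names(multiplicity), phylo$tip.label)) {
        stop("multiplicity names do not match tip labels")
      }
      mult <- multiplicity[phylo$tip.label]
    } else {
      stopifnot(length(multiplicity) == nt)
      mult <- stats::setNames(multiplicity, phylo$tip.label)
    }
  }
  if (any(mult < 0)) stop("negative tip multiplicity")
  mult <- stats::setNames(as.integer(round(mult)), phylo$tip.label)
  structure(list(phylo = phylo, mult = mult), class = "mut_tree")
}

#' Read a mutation-count tree from Newick text
#'
#' Branch lengths are integer mutation counts; a tip multiplicity may be
#' encoded as a \code{label*count} suffix (e.g. \code{"h3*5"} for five sampled
#' individuals collapsed on tip \code{h3}).
#'
#' @param file Path to a Newick file, or \code{text=} a Newick string.
#' @param text Optional Newick string (overrides \code{file}).
#' @return A [mut_tree()].
#' @examples
#' read_mut_tree(text = "(a:1,b:2,c*3:0);")
#' @export
read_mut_tree <- function(file = NULL, text = NULL) {
  phy <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(phy)) stop("could not parse Newick input")
  lab <- phy$tip.label
  mult <- rep(1L, length(lab))
  star <- grepl("\\*[0-9]+$", lab)
  mult[star] <- as.integer(sub("^.*\\*", "", lab[star]))
  phy$tip.label <- sub("\\*[0-9]+$", "", lab)
  mut_tree(phy, stats::setNames(mult, phy$tip.label))
}

#' Write a mutation-count tree to Newick text
#'
#' @param tree A [mut_tree()].
#' @param file Output path; when NULL the Newick string is returned.
#' @export
write_mut_tree <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "mut_tree"))
  phy <- tree$phylo
  star <- tree$mult > 1L
  phy$tip.label[star] <- paste0(phy$tip.label[star], "*", tree$mult[star])
  if (is.null(file)) ape::write.tree(phy) else ape::write.tree(phy, file = file)
}

#' @export
print.mut_tree <- function(x, ...) {
  cat("Mutation-count tree: ", length(x$phylo$tip.label), " tips, N = ",
      sum(x$mult), " sampled individuals, ", sum(x$phylo$edge.length),
      " mutations\n", sep = "")
  invisible(x)
}

# Resolve a node reference (NULL = root, label, or node number).
resolve_node <- function(tree, node) {
  phy <- tree$phylo
  nt <- length(phy$tip.label)
  if (is.null(node)) return(nt + 1L)  # root
  if (is.character(node)) {
    i <- match(node, phy$tip.label)
    if (!is.na(i)) return(i)
    if (!is.null(phy$node.label)) {
      j <- match(node, phy$node.label)
      if (!is.na(j)) return(nt + j)
    }
    stop("node not found: ", node)
  }
  node <- as.integer(node)
  if (node < 1L || node > nt + phy$Nnode) stop("node number out of range")
  node
}

# Depth (mutations) of every node below `node`; NA elsewhere. Uses one
# cladewise pass so parents are visited before children.
node_depths_below <- function(phy, node) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  depth <- rep(NA_real_, length(phy$tip.label) + phy$Nnode)
  depth[node] <- 0
  e <- phy$edge
  for (i in seq_len(nrow(e))) {
    if (!is.na(depth[e[i, 1L]])) {
      depth[e[i, 2L]] <- depth[e[i, 1L]] + phy$edge.length[i]
    }
  }
  depth
}

# Number of sampled individuals below each node (tips count their own mult).
sampled_below <- function(tree) {
  phy <- ape::reorder.phylo(tree$phylo, "postorder")
  nt <- length(phy$tip.label)
  n <- numeric(nt + phy$Nnode)
  n[seq_len(nt)] <- tree$mult[phy$tip.label]
  e <- phy$edge
  for (i in seq_len(nrow(e))) n[e[i, 1L]] <- n[e[i, 1L]] + n[e[i, 2L]]
  n
}

#' The rho statistic
#'
#' The multiplicity-weighted mean number of mutations along each sampled
#' lineage's path from tip to \code{node}.
#'
#' @param tree A [mut_tree()].
#' @param node Node reference: NULL (root), a label, or a node number.
#' @return Non-negative real.
#' @examples
#' tr <- read_mut_tree(text = "(a:1,b:2,c:3,d:2);")
#' rho(tr) # 2
#' @export
rho <- function(tree, node = NULL) {
  stopifnot(inherits(tree, "mut_tree"))
  nd <- resolve_node(tree, node)
  depth <- node_depths_below(tree$phylo, nd)
  nt <- length(tree$phylo$tip.label)
  tips <- which(!is.na(depth[seq_len(nt)]))
  mult <- tree$mult[tree$phylo$tip.label[tips]]
  N <- sum(mult)
  if (N <= 0) stop("node has no sampled descendants")
  sum(mult * depth[tips]) / N
}

#' Saillard standard error of rho
#'
#' The closed-form sampling error \eqn{\sigma = \sqrt{\sum_i l_i n_i^2} / N},
#' where the sum runs over the branches below \code{node}, \eqn{l_i} is the
#' branch's mutation count, \eqn{n_i} the number of sampled individuals below
#' it, and \eqn{N} the total number of sampled individuals under \code{node}.
#'
#' @inheritParams rho
#' @return Non-negative real.
#' @examples
#' tr <- read_mut_tree(text = "(a:1,b:1,c:1,d:1);")
#' saillard_sigma(tr) # 0.5 = 1/sqrt(4)
#' @export
saillard_sigma <- function(tree, node = NULL) {
  stopifnot(inherits(tree, "mut_tree"))
  nd <- resolve_node(tree, node)
  phy <- tree$phylo
  depth <- node_depths_below(phy, nd)
  nbelow <- sampled_below(tree)
  nt <- length(phy$tip.label)
  tips <- which(!is.na(depth[seq_len(nt)]))
  N <- sum(tree$mult[phy$tip.label[tips]])
  if (N <= 0) stop("node has no sampled descendants")
  e <- phy$edge
  in_clade <- !is.na(depth[e[, 2L]]) & !is.na(depth[e[, 1L]])
  sqrt(sum(phy$edge.length[in_clade] * nbelow[e[in_clade, 2L]]^2)) / N
}

#' Coalescence age from rho under a linear clock
#'
#' @inheritParams rho
#' @param years_per_mutation Clock calibration (default
#'   [SOARES_YEARS_PER_MUTATION], one mutation every 3,624 years over the whole
#'   molecule).
#' @return An object of class \code{rho_estimate}: rho, sigma, age_years,
#'   age_se_years, N, clock.
#' @examples
#' tr <- read_mut_tree(text = "(a:2,b:3,c:1,d:2);")
#' rho_age(tr)
#' @export
rho_age <- function(tree, node = NULL, years_per_mutation = SOARES_YEARS_PER_MUTATION) {
  stopifnot(years_per_mutation > 0)
  r <- rho(tree, node)
  s <- saillard_sigma(tree, node)
  nd <- resolve_node(tree, node)
  depth <- node_depths_below(tree$phylo, nd)
  nt <- length(tree$phylo$tip.label)
  tips <- which(!is.na(depth[seq_len(nt)]))
  structure(list(node = nd, rho = r, sigma = s,
                 age_years = r * years_per_mutation,
                 age_se_years = s * years_per_mutation,
                 N = sum(tree$mult[tree$phylo$tip.label[tips]]),
                 years_per_mutation = years_per_mutation),
            class = "rho_estimate")
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat("rho = ", format(round(x$rho, 3)), " +/- ", format(round(x$sigma, 3)),
      "  (N = ", x$N, ")\n",
      "age = ", round(x$age_years), " +/- ", round(x$age_se_years),
      " years  (clock: 1 mutation / ", x$years_per_mutation, " yr)\n", sep = "")
  invisible(x)
}

#' Rho ages for every internal node of a tree
#'
#' @inheritParams rho_age
#' @return Data frame: node, label, N, rho, sigma, age_years, age_se_years.
#' @export
rho_table <- function(tree, years_per_mutation = SOARES_YEARS_PER_MUTATION) {
  phy <- tree$phylo
  nt <- length(phy$tip.label)
  nodes <- nt + seq_len(phy$Nnode)
  rows <- lapply(nodes, function(nd) {
    est <- rho_age(tree, nd, years_per_mutation)
    lab <- if (!is.null(phy$node.label)) phy$node.label[nd - nt] else ""
    data.frame(node = nd, label = lab, N = est$N, rho = est$rho,
               sigma = est$sigma, age_years = est$age_years,
               age_se_years = est$age_se_years, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ---- pedigree mutation rate -------------------------------------------------

#' Pedigree-based mutation rate with exact confidence intervals
#'
#' Point estimate k/T substitutions per transmission (generation). Because the
#' appropriate exact interval for few events is debatable, both the
#' Clopper-Pearson exact binomial interval and the exact Poisson interval are
#' always computed and reported side-by-side; \code{method} selects which one
#' populates \code{ci95}. With k = 0 the intervals are one-sided upper bounds.
#'
#' @param k Substitutions observed (0 <= k <= T).
#' @param transmissions Transmission events T (> 0).
#' @param method \code{"clopper_pearson"} (default) or \code{"poisson_exact"}.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class \code{pedigree_rate}: rate_per_transmission,
#'   ci95, ci_binomial, ci_poisson, k, transmissions.
#' @examples
#' pedigree_rate(1, 90) # 0.0111 per transmission
#' @export
pedigree_rate <- function(k, transmissions,
                          method = c("clopper_pearson", "poisson_exact"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(transmissions > 0, k >= 0, k <= transmissions)
  rate <- k / transmissions
  ci_b <- as.numeric(stats::binom.test(k, transmissions,
                                       conf.level = conf_level)$conf.int)
  ci_p <- as.numeric(stats::poisson.test(k, transmissions,
                                         conf.level = conf_level)$conf.int)
  ci <- if (method == "clopper_pearson") ci_b else ci_p
  structure(list(rate_per_transmission = rate, ci95 = ci,
                 ci_binomial = ci_b, ci_poisson = ci_p, method = method,
                 k = k, transmissions = transmissions,
                 conf_level = conf_level),
            class = "pedigree_rate")
}

#' @export
print.pedigree_rate <- function(x, ...) {
  cat(x$k, " substitution(s) in ", x$transmissions, " transmissions: rate ",
      format(round(x$rate_per_transmission, 4)), " per transmission\n",
      "  exact binomial ", round(100 * x$conf_level), "% CI: [",
      format(signif(x$ci_binomial[1], 3)), ", ",
      format(signif(x$ci_binomial[2], 3)), "]\n",
      "  exact Poisson  ", round(100 * x$conf_level), "% CI: [",
      format(signif(x$ci_poisson[1], 3)), ", ",
      format(signif(x$ci_poisson[2], 3)), "]\n", sep = "")
  invisible(x)
}

#' Convert a per-transmission rate to substitutions per site per My
#'
#' \code{rate / (L * G) * 1e6}: divides by the genome length and the generation
#' time, scaled to million years. Reported figures round to 3 decimals.
#'
#' @param rate_per_transmission Rate per transmission (generation).
#' @param L Sequence length in bp (default the complete molecule, 16,569 bp).
#' @param G Generation time in years (commonly 20, 25 or 30).
#' @return Rate per site per million years (unrounded).
#' @examples
#' round(convert_rate(1 / 90, G = 25), 3) # 0.027
#' @export
convert_rate <- function(rate_per_transmission, L = MT_GENOME_LENGTH, G = 25) {
  stopifnot(L > 0, G > 0)
  rate_per_transmission / (L * G) * 1e6
}

#' Halve a pedigree rate for the male transmission bias
#'
#' Pedigree designs count mutations arising in either sex, but only females
#' transmit mtDNA; dividing the pedigree rate by two makes it comparable to
#' phylogenetic rates.
#'
#' @param rate Non-negative rate.
#' @return rate / 2.
#' @export
sex_bias_halve <- function(rate) {
  stopifnot(rate >= 0)
  rate / 2
}

#' Empirical generation length from a pedigree span
#'
#' @param found_year Year of the founding ancestor.
#' @param ref_year Reference ("present") year; must exceed \code{found_year}.
#' @param n_generations Number of generations elapsed (> 0).
#' @return Years per generation.
#' @examples
#' generation_length(1625, 2000, 15) # 25
#' @export
generation_length <- function(found_year, ref_year, n_generations) {
  stopifnot(n_generations > 0)
  if (ref_year <= found_year) stop("non-positive time span")
  (ref_year - found_year) / n_generations
}
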