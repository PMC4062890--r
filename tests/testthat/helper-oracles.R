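# Independent brute-force oracles for rho/sigma (path enumeration via
# ape::dist.nodes and subtree membership via phangorn::Descendants, code paths
# disjoint from the package's traversals), plus small random generators.

desc_of <- function(phy, node, type) {
  unlist(phangorn::Descendants(phy, node, type = type))
}

brute_rho <- function(tree, node) {
  phy <- tree$phylo
  nt <- length(phy$tip.label)
  if (node <= nt) return(0)
  d <- ape::dist.nodes(phy)
  tips <- desc_of(phy, node, "tips")
  mult <- tree$mult[phy$tip.label[tips]]
  sum(mult * d[node, tips]) / sum(mult)
}

brute_sigma <- function(tree, node) {
  phy <- tree$phylo
  nt <- length(phy$tip.label)
  if (node <= nt) return(0)
  desc <- desc_of(phy, node, "all")
  tips_below <- function(v) {
    if (v <= nt) v else desc_of(phy, v, "tips")
  }
  N <- sum(tree$mult[phy$tip.label[tips_below(node)]])
  acc <- 0
  for (i in seq_len(nrow(phy$edge))) {
    child <- phy$edge[i, 2L]
    if (child %in% desc) {
      n_i <- sum(tree$mult[phy$tip.label[tips_below(child)]])
      acc <- acc + phy$edge.length[i] * n_i^2
    }
  }
  sqrt(acc) / N
}

random_mut_tree <- function(n_tips) {
  phy <- ape::rtree(n_tips, br = NULL)
  phy$edge.length <- as.numeric(stats::rpois(nrow(phy$edge), 2))
  mult <- stats::setNames(sample(1:3, n_tips, replace = TRUE), phy$tip.label)
  mut_tree(phy, mult)
}

random_hvr1_profile <- function(k = 4) {
  pos <- sample(16024:16365, k)
  haplotype_profile(as.character(pos), range = "hvr1")
}

# The 20 named clades used throughout the classification recovery checks:
# leaf-level clades of the shipped tree whose root paths are mutually
# distinguishable.
recovery_clades <- function() {
  c("U6a1a1a2", "U6a1b1b", "U6a2a3a", "U6a2b1", "U6a2c", "U6a3c", "U6a3e",
    "U6a3f", "U6a5b", "U6a6a1", "U6a7a1a", "U6a7a1b", "U6a7b1a", "U6b1a1",
    "U6b1a2", "U6b2", "U6b3a", "U6b5", "U6c1c", "U6c2a")
}
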