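# u6phylo

Mitochondrial haplogroup U6 marks a Palaeolithic back-migration of modern
humans from Eurasia into North Africa, and its subclades trace later spreads
through the Maghreb, the Sahel, East and West Africa, the Canary Islands,
Mediterranean Europe and, with the European colonisation, the Americas.
`u6phylo` implements the computational core of a U6 phylogeography analysis
for population geneticists working with rCRS-relative mtDNA haplotypes:

- **Variant and haplotype handling** — PhyloTree/EMPOP-style tokens
  (`794A` transversion, `16189` transition, `455.1T` insertion, `960d`
  deletion, `750!` back-mutation) parsed, formatted and compared as sets over
  an explicit covered range (complete genome or HVR-1, 16024–16365), so
  partial control-region data are first-class.
- **Haplogroup classification** — a shipped refined U6 tree with the printed
  clade-defining motifs (e.g. U6a7a1a: 2672, 11929; U6b1: 9738, 15431).
  `classify_profile()` scores every root-to-node path by `matched − missing`
  over the diagnostic variants inside the profile's covered range;
  `classify_hvr1()` sorts control-region haplotypes into the eight
  phylogeographic categories (U6a ± 235, U6a-189 ± 239, U6b, U6b1, U6d, U6c)
  with their geographic-component labels.
- **Coalescence dating** — the rho statistic (mean mutations from each
  sampled lineage to a node) with its Saillard standard error
  σ = √(Σᵢ lᵢ nᵢ²)/N, converted to years under a fixed clock of one mutation
  per 3,624 years over the whole molecule.
- **Pedigree mutation rate** — k substitutions in T transmissions give the
  per-generation rate k/T with exact binomial (Clopper–Pearson) and exact
  Poisson 95% intervals side-by-side, plus conversions to per-site/My rates
  and the sex-bias halving.
- **Fisher wave-of-advance** — the reaction–diffusion relation r = 2√(gm)
  linking a frontier's rate of advance r, growth rate g and migration rate m,
  chained from clade ages and coastal distances.
- **Regional statistics** — frequency/composition tables (a 25-population
  HVR-1 table ships with the package), pi diversity (mean pairwise
  differences) with a Tajima-type SE, permutation comparison of diversities,
  longitudinal gradient correlation and PCA of subhaplogroup frequencies.
- **Synthetic data** — seeded generators for Poisson star genealogies,
  haplotypes generated down the shipped tree, pedigree transmissions and
  multinomial regional compositions, so the whole pipeline is testable
  without external downloads.

## Worked example

```r
library(u6phylo)

# classify a complete-genome haplotype
p <- haplotype_profile(c("3348", "16172", "16219", "16311", "9738",
                         "15431", "2352", "16163", "7700"))
classify_profile(p)
#> Best node: U6b1a1  (matched 9, missing 0, private 0)

# the same lineage from HVR-1 alone
classify_hvr1(c(16172, 16219, 16311, 16163))$category
#> [1] "U6b1"

# date a simulated 50-tip star radiation of true age 10,000 years
tr <- simulate_star_tree(n_tips = 50, true_age_years = 10000, seed = 42)
rho_age(tr)
#> rho = 3.3 +/- 0.257  (N = 50)
#> age = 11959 +/- 931 years  (clock: 1 mutation / 3624 yr)

# pedigree mutation rate: 1 substitution in 90 transmissions
pedigree_rate(1, 90)
#> 1 substitution(s) in 90 transmissions: rate 0.0111 per transmission
#>   exact binomial 95% CI: [0.000281, 0.0604]
#>   exact Poisson  95% CI: [0.000281, 0.0619]

# the wave-of-advance derivation chain
fisher_wave(5000, 9000, 0.007)
#> Fisher wave-of-advance derivation
#>   rate of advance  r = 5000 km / 9000 yr = 0.56 km/yr
#>   migration rate   m = r^2/(4g) = 11.2 (g = 0.007/yr; unrounded chain: 11.0)
#>   node gap         2 mutations x 3624 yr = 7248 yr (about 7,000)
#>   radius           4027 km (about 4,000)
```

The classification call reads: all nine diagnostic variants on the U6b1a1
root path are present and nothing is left unexplained. The dating example
shows a point estimate (ρ × 3,624 yr) whose ±1.96 σ interval covers the true
simulated age; the pedigree example reproduces the 0.0111/generation rate
with both exact intervals; the wave chain derives a frontier speed of
0.56 km/yr along a 5,000-km coastal route over 9,000 years, the implied
migration rate of 11.2 km/yr at g = 0.007/yr, and converts the two-mutation
gap between the U and U6 nodes into about 7,000 years and about 4,000 km.

A command-line front end is installed as `exec/u6phylo` (or call
`u6_cli()` directly), with subcommands `classify`, `date`, `pedigree-rate`,
`diffusion`, `diversity`, `freq-table`, `pca` and `simulate`; every run
writes a `.manifest.json` echoing its settings and seed.

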