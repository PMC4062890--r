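test_that("the shipped regional table reproduces printed frequencies", {
  tab <- u6_table1()
  expect_equal(nrow(tab), 25L)
  f <- u6_frequency(tab)
  expect_equal(unname(f["BRA"]), 0.57)
  expect_equal(unname(f["CAN"]), 16.15)
  expect_equal(unname(tab$u6_count[tab$region == "BRA"]), 8L)
  expect_equal(unname(tab$u6_count[tab$region == "CAN"]), 168L)
  # per-category counts always sum to the U6 count
  expect_true(all(rowSums(tab[, 4:11]) == tab$u6_count))
})

test_that("composition percentages are per-cent of U6 carriers", {
  tab <- u6_table1()
  comp <- composition(tab)
  expect_equal(unname(comp["BRA", c("U6a_without_235", "U6a189_without_239")]),
               c(12.5, 87.5))
  # rounded rows sum to 100 within rounding slack
  sums <- rowSums(comp, na.rm = TRUE)
  expect_true(all(abs(sums - 100) <= 0.2))
  single <- validate_frequency_table(
    data.frame(region = "X", sample_size = 10, u6_count = 3,
               U6a_without_235 = 3L, U6a_235 = 0L, U6a189_without_239 = 0L,
               U6a189_239 = 0L, U6b = 0L, U6b1 = 0L, U6d = 0L, U6c = 0L))
  expect_equal(unname(composition(single)["X", "U6a_without_235"]), 100)
  zero <- single; zero$u6_count <- 0L; zero$U6a_without_235 <- 0L
  expect_warning(composition(validate_frequency_table(zero)), "undefined")
  expect_error(u6_frequency(data.frame(region = "X", sample_size = 0,
                                       u6_count = 0)), "positive")
})

test_that("frequency tables round-trip through counts and percent layouts", {
  tab <- u6_table1()
  path <- withr::local_tempfile(fileext = ".csv")
  write_frequency_table(tab, path, format = "counts")
  expect_identical(read_frequency_table(path), tab)
  write_frequency_table(tab, path, format = "percent")
  back <- read_frequency_table(path)
  expect_equal(back$u6_count, tab$u6_count)
})

test_that("pi equals the all-pairs brute-force mean", {
  ps <- list(haplotype_profile(character(), "hvr1"),
             haplotype_profile("16189", "hvr1"),
             haplotype_profile(c("16189", "16311"), "hvr1"))
  est <- pi_diversity(ps)
  expect_equal(est$pi, 4 / 3)
  ident <- replicate(3, haplotype_profile(c("16172", "16219"), "hvr1"),
                     simplify = FALSE)
  expect_equal(pi_diversity(ident)$pi, 0)
  expect_error(pi_diversity(ident[1]), "at least two")
  # random sets against an independent all-pairs oracle
  set.seed(21)
  for (rep in 1:10) {
    ps <- replicate(sample(3:6, 1), random_hvr1_profile(sample(0:5, 1)),
                    simplify = FALSE)
    n <- length(ps)
    acc <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ti <- ps[[i]]$variants$token; tj <- ps[[j]]$variants$token
      acc <- acc + length(union(ti, tj)) - length(intersect(ti, tj))
    }
    expect_equal(pi_diversity(ps)$pi, acc / choose(n, 2))
  }
})

test_that("diversity permutation test is calibrated and reproducible", {
  set.seed(31)
  pool <- replicate(12, random_hvr1_profile(3), simplify = FALSE)
  same <- diversity_compare(pool[1:6], pool[1:6], n_perm = 199, seed = 9)
  expect_gt(same$p_value, 0.2)  # identical multisets: no signal
  ident <- replicate(8, haplotype_profile(c("16172", "16219"), "hvr1"),
                     simplify = FALSE)
  div <- lapply(1:8, function(i) {
    haplotype_profile(as.character(16024 + (4 * (i - 1)):(4 * i - 1)), "hvr1")
  })
  extreme <- diversity_compare(ident, div, n_perm = 999, seed = 9)
  expect_lt(extreme$p_value, 0.05)
  again <- diversity_compare(ident, div, n_perm = 999, seed = 9)
  expect_identical(extreme$p_value, again$p_value)
  expect_warning(diversity_compare(ident, div, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("gradient correlation matches the textbook formula", {
  lon <- c(-9, -3, 12, 23, 35)
  freq <- 10 - 0.2 * lon
  g <- gradient_correlation(freq, lon)
  expect_equal(g$r, -1)
  noisy_freq <- c(9.8, 10.1, 7.4, 5.6, 3.1)
  g2 <- gradient_correlation(noisy_freq, lon)
  n <- length(lon)
  r_hand <- sum(scale(noisy_freq) * scale(lon)) / (n - 1)
  expect_equal(g2$r, r_hand, tolerance = 1e-10)
  t_stat <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  expect_equal(g2$p_value, 2 * stats::pt(-abs(t_stat), n - 2),
               tolerance = 1e-10)
  expect_warning(gc0 <- gradient_correlation(rep(1, 5), lon), "zero variance")
  expect_true(gc0$undefined)
})

test_that("PCA scores match an eigen-decomposition oracle up to the sign rule", {
  set.seed(41)
  m <- matrix(stats::rnorm(12), 4, 3,
              dimnames = list(paste0("r", 1:4), paste0("c", 1:3)))
  pc <- pca_scores(m)
  z <- scale(m)
  eig <- eigen(stats::cor(m))
  for (j in 1:3) {
    oracle <- as.numeric(z %*% eig$vectors[, j])
    ratio <- as.numeric(pc$scores[, j]) / oracle
    expect_equal(abs(ratio), rep(1, 4), tolerance = 1e-8)
  }
  # sign convention: largest-magnitude loading positive on each component
  for (j in 1:3) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
  expect_warning(pca_scores(cbind(m, const = 1)), "constant")
})

test_that("two identical-row clusters separate on PC1 with zero spread", {
  m <- rbind(a1 = c(10, 0, 5), a2 = c(10, 0, 5),
             b1 = c(0, 10, 1), b2 = c(0, 10, 1))
  pc <- pca_scores(m)
  expect_equal(pc$scores["a1", 1], pc$scores["a2", 1])
  expect_equal(pc$scores["b1", 1], pc$scores["b2", 1])
  expect_true(sign(pc$scores["a1", 1]) != sign(pc$scores["b1", 1]))
})

test_that("Canary and Iberoamerican samples side with the U6b1 loading on PC1", {
  comp <- composition(u6_table1())
  pc <- pca_scores(comp)
  s <- sign(pc$loadings["U6b1", 1])
  expect_equal(sign(pc$scores["CAN", 1]), s)
  expect_equal(sign(pc$scores["HIS", 1]), s)
})
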