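test_that("the shipped tree carries the refined clade motifs", {
  tree <- u6_tree()
  expect_setequal(tree$motifs[["U6a7a1a"]]$token, c("2672", "11929"))
  expect_setequal(tree$motifs[["U6b1"]]$token, c("9738", "15431"))
  expect_setequal(tree$motifs[["U6b1a"]]$token, c("2352", "16163"))
  expect_setequal(tree$motifs[["U6a3c"]]$token,
                  c("146", "291.1A", "960d", "1809", "5554A", "6182",
                    "11272", "15380"))
  expect_setequal(tree$motifs[["U6"]]$token, c("3348", "16172"))
  expect_true(tree$motifs[["U6a8"]]$back[tree$motifs[["U6a8"]]$token == "750!"])
})

test_that("tree validation rejects malformed definitions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("X\t-\t100", "X\tX\t200"), path)
  expect_error(load_haplo_tree(path), "duplicate")
  writeLines(c("R\t-\t100", "A\tR\t"), path)
  expect_error(load_haplo_tree(path), "without defining variants")
  writeLines(c("R\t-\t100", "A\tB\t200", "B\tA\t300"), path)
  expect_error(load_haplo_tree(path), "cyclic|unreachable")
  writeLines(c("R\t-\t100", "A\tZ\t200"), path)
  expect_error(load_haplo_tree(path), "unknown parent")
})

test_that("tree definitions round-trip bit-exactly through load/save", {
  tree <- u6_tree()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplo_tree(tree, path)
  back <- load_haplo_tree(path)
  expect_identical(back$nodes, tree$nodes)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_haplo_tree(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("classify_profile scores root-to-node paths range-aware", {
  tree <- u6_tree()
  full <- haplotype_profile(c("3348", "16172", "16219", "16311", "9738",
                              "15431", "2352", "16163", "7700"))
  expect_equal(classify_profile(full, tree)$best_node, "U6b1a1")
  basal <- haplotype_profile(c("3348", "16172"))
  expect_equal(classify_profile(basal, tree)$best_node, "U6")
  # HVR-1 restricted: coding-region diagnostics are unscoreable, not missing,
  # and the call collapses to the deepest clade with in-range support
  hv <- haplotype_profile(c("16172", "16219", "16163", "16311"), "hvr1")
  cl <- classify_profile(hv, tree)
  expect_equal(cl$best_node, "U6b1a")
  expect_equal(cl$missing, 0)
})

test_that("matched + missing equals the scoreable path variants", {
  tree <- u6_tree()
  p <- haplotype_profile(c("16172", "16219", "16311", "16163"), "hvr1")
  cl <- classify_profile(p, tree)
  path <- tree$path_tokens[[cl$best_node]]
  in_range <- path$position >= 16024 & path$position <= 16365
  scoreable <- sum(in_range & !(path$back & !(path$token %in% p$variants$token)))
  expect_equal(cl$matched + cl$missing, scoreable)
})

test_that("classification is deterministic and order-invariant", {
  tree <- u6_tree()
  toks <- c("3348", "16172", "16219", "16278", "16189", "143", "8282",
            "10172", "11539", "750!")
  p1 <- haplotype_profile(toks)
  p2 <- haplotype_profile(rev(toks))
  c1 <- classify_profile(p1, tree)
  c2 <- classify_profile(p2, tree)
  expect_equal(c1$best_node, "U6a8")
  expect_identical(c1, c2)
  expect_identical(classify_profile(p1, tree), c1)
})

test_that("a profile with no scoreable diagnostic positions warns via flag", {
  tree <- u6_tree()
  p <- haplotype_profile("600", range = c(577, 700))
  cl <- classify_profile(p, tree)
  expect_equal(cl$best_node, "U6")
  expect_true(cl$no_signal)
})

test_that("noise-free synthetic haplotypes are recovered exactly", {
  tree <- u6_tree()
  clades <- recovery_clades()
  sim <- simulate_haplotypes(tree, stats::setNames(rep(1, 20), clades),
                             n = 200, seed = 7)
  pred <- vapply(sim$profiles,
                 function(p) classify_profile(p, tree)$best_node, character(1))
  expect_equal(unname(pred), sim$labels)
})

test_that("the HVR-1 sorting scheme reproduces the printed assignments", {
  expect_equal(classify_hvr1(c(16172, 16219, 16189, 16278, 16239))$category,
               "U6a189 239")
  expect_equal(classify_hvr1(c(16172, 16219, 16311, 16163))$category, "U6b1")
  expect_equal(classify_hvr1(c(16172, 16219, 16311, 16261))$category, "U6d")
  expect_equal(classify_hvr1(c(16172, 16219, 16311, 16174))$category, "U6d")
  expect_equal(classify_hvr1(c(16172, 16219, 16278))$category,
               "U6a without 235")
  expect_equal(classify_hvr1(c(16172, 16219, 16278, 16235))$category,
               "U6a 235")
  expect_equal(classify_hvr1(c(16172, 16219, 16189, 16278))$category,
               "U6a189 without 239")
  expect_equal(classify_hvr1(c(16172, 16219, 16311))$category, "U6b")
  # the basic U6c haplotype lacks 16219 but is still U6
  expect_equal(classify_hvr1(c(16129, 16169, 16172, 16189))$category, "U6c")
  expect_equal(classify_hvr1(c(16172, 16219, 16311, 16163))$geo_label, "CAN")
  expect_equal(classify_hvr1(c(16189, 16278))$category, "not-U6")
})

test_that("the eight categories partition all diagnostic combinations", {
  diag <- c(16169, 16189, 16311, 16261, 16174, 16163, 16239, 16235)
  cats <- u6_categories()
  seen <- character(0)
  for (mask in 0:255) {
    present <- diag[bitwAnd(mask, 2^(0:7)) > 0]
    res <- classify_hvr1(c(16172, 16219, present))
    expect_true(res$category %in% cats)
    expect_equal(res$geo_label, unname(u6_category_geo()[res$category]))
    seen <- union(seen, res$category)
  }
  expect_setequal(seen, cats)
})

test_that("complete-genome calls refine the HVR-1 category", {
  tree <- u6_tree()
  sim <- simulate_haplotypes(tree, c(U6b1a1 = 0.5, U6d1 = 0.5), n = 40,
                             seed = 3)
  res <- classify_profiles(sim$profiles, tree)
  expect_equal(unname(res$best_node), sim$labels)
  expect_true(all(res$category8[sim$labels == "U6b1a1"] == "U6b1"))
  expect_true(all(res$category8[sim$labels == "U6d1"] == "U6d"))
})
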