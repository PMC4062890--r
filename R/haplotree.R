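# Haplogroup tree representation and motif-based classification.

#' The eight HVR-1 phylogeographic categories
#'
#' Column order of the regional frequency table: the four U6a bins split on
#' 16235/16189/16239, then U6b, the Canarian U6b1, U6d and U6c.
#'
#' @return Character vector of length 8.
#' @export
u6_categories <- function() {
  c("U6a without 235", "U6a 235", "U6a189 without 239", "U6a189 239",
    "U6b", "U6b1", "U6d", "U6c")
}

#' Geographic component labels of the HVR-1 categories
#'
#' MAG = Maghreb, EAF = East Africa, COS = cosmopolitan, CAN = Canary Islands,
#' MED = Mediterranean.
#'
#' @return Named character vector keyed by category.
#' @export
u6_category_geo <- function() {
  c("U6a without 235" = "MAG", "U6a 235" = "MAG",
    "U6a189 without 239" = "EAF", "U6a189 239" = "MAG",
    "U6b" = "COS", "U6b1" = "CAN", "U6d" = "MAG", "U6c" = "MED")
}

## ---- loading ----------------------------------------------------------------

#' Load a haplogroup tree definition
#'
#' The definition format is plain text, one node per line:
#' \code{name<TAB>parent<TAB>variant tokens} (space-separated tokens; parent
#' \code{"-"} for the root). Lines starting with \code{#} are comments. The
#' loader validates name uniqueness, parent links (no cycles, single root),
#' non-empty motifs on non-root nodes, and parses every motif token.
#'
#' @param path Path to a tree definition file.
#' @return An object of class \code{haplo_tree}: a list with \code{nodes}
#'   (data frame: name, parent, motif), \code{depth}, \code{path_tokens}
#'   (root-to-node motif tokens per node) and \code{root}.
#' @seealso [u6_tree()] for the shipped default, [write_haplo_tree()].
#' @export
load_haplo_tree <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  body <- lines[keep]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed tree line(s): ", paste(which(keep)[bad], collapse = ", "))
  nodes <- data.frame(
    name = vapply(parts, `[`, character(1), 1L),
    parent = vapply(parts, `[`, character(1), 2L),
    motif = vapply(parts, function(p) if (length(p) >= 3L) trimws(p[3L]) else "",
                   character(1)),
    stringsAsFactors = FALSE
  )
  dup <- nodes$name[duplicated(nodes$name)]
  if (length(dup)) stop("duplicate node name(s): ", paste(unique(dup), collapse = ", "))
  is_root <- nodes$parent %in% c("-", "")
  if (sum(is_root) != 1L) stop("tree must have exactly one root")
  root <- nodes$name[is_root]
  unknown <- setdiff(nodes$parent[!is_root], nodes$name)
  if (length(unknown)) stop("unknown parent(s): ", paste(unknown, collapse = ", "))
  empty <- !is_root & !nzchar(nodes$motif)
  if (any(empty)) {
    stop("non-root node(s) without defining variants: ",
         paste(nodes$name[empty], collapse = ", "))
  }
  motifs <- lapply(nodes$motif, function(m) {
    if (!nzchar(m)) empty_variants()
    else parse_variants(strsplit(m, "[[:space:]]+")[[1L]])
  })
  names(motifs) <- nodes$name
  # depths + cycle detection via iterative resolution
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$name)
  depth[root] <- 0L
  for (pass in seq_len(nrow(nodes))) {
    resolvable <- is.na(depth) & !is.na(depth[nodes$parent])
    if (!any(resolvable)) break
    depth[nodes$name[resolvable]] <- depth[nodes$parent[resolvable]] + 1L
  }
  if (anyNA(depth)) {
    stop("cyclic or unreachable node(s): ",
         paste(nodes$name[is.na(depth)], collapse = ", "))
  }
  path_tokens <- vector("list", nrow(nodes))
  names(path_tokens) <- nodes$name
  for (nm in nodes$name[order(depth)]) {
    p <- nodes$parent[nodes$name == nm]
    up <- if (p %in% nodes$name) path_tokens[[p]] else empty_variants()
    path_tokens[[nm]] <- rbind(up, motifs[[nm]])
  }
  structure(list(nodes = nodes, motifs = motifs, depth = depth,
                 path_tokens = path_tokens, root = root),
            class = "haplo_tree")
}

#' Write a haplogroup tree definition
#'
#' Inverse of [load_haplo_tree()]; a loaded definition round-trips bit-exactly
#' (comments excluded).
#'
#' @param tree A \code{haplo_tree}.
#' @param path Output path.
#' @export
write_haplo_tree <- function(tree, path) {
  stopifnot(inherits(tree, "haplo_tree"))
  lines <- paste(tree$nodes$name, tree$nodes$parent, tree$nodes$motif, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("Haplogroup tree: ", nrow(x$nodes), " nodes, root '", x$root,
      "', max depth ", max(x$depth), "\n", sep = "")
  invisible(x)
}

.u6phylo_env <- new.env(parent = emptyenv())

#' The shipped refined U6 haplogroup tree
#'
#' Loads (and caches) the package's default U6 tree, whose clade-defining
#' variant lists follow the refined U6 phylogeny (e.g. U6a7a1a: 2672, 11929;
#' U6b1: 9738, 15431; U6a3c: 146, 291.1A, 960d, 1809, 5554A, 6182, 11272,
#' 15380).
#'
#' @return A \code{haplo_tree}.
#' @export
u6_tree <- function() {
  if (is.null(.u6phylo_env$u6_tree)) {
    path <- system.file("extdata", "u6_tree.tsv", package = "u6phylo",
                        mustWork = TRUE)
    .u6phylo_env$u6_tree <- load_haplo_tree(path)
  }
  .u6phylo_env$u6_tree
}

## ---- classification ---------------------------------------------------------

# Score one root-to-node path against a profile token set.
score_path <- function(path_var, tokens, range) {
  if (nrow(path_var) == 0L) {
    return(list(matched = 0L, missing = 0L, unscoreable = 0L, scoreable = 0L))
  }
  in_rng <- range_contains(range, path_var$position)
  pv <- path_var[in_rng, , drop = FALSE]
  hit <- pv$token %in% tokens
  # A back-mutation motif is scoreable only when the profile carries the
  # explicit "!" token; otherwise it counts neither matched nor missing.
  unsc_back <- pv$back & !hit
  matched <- sum(hit)
  missing <- sum(!hit & !pv$back)
  list(matched = matched, missing = missing,
       unscoreable = sum(!in_rng) + sum(unsc_back),
       scoreable = matched + missing)
}

#' Classify a haplotype profile against a haplogroup tree
#'
#' Scores every root-to-node path by \code{matched - missing} over the node's
#' defining variants, counting only variants that fall inside the profile's
#' covered range (so partial HVR-1 profiles are classifiable: out-of-range
#' variants are neither matched nor missing). The best-scoring node wins; ties
#' are broken by fewest unscoreable path variants, then greater depth, then
#' node name. Back-mutation motifs are scored only when the profile carries an
#' explicit \code{"!"} token.
#'
#' @param profile A [haplotype_profile()].
#' @param tree A \code{haplo_tree}; default the shipped U6 tree.
#' @param include_hypervariable Score poly-C tract/16519 records?
#' @return An object of class \code{u6_classification}: \code{best_node},
#'   \code{matched}, \code{missing}, \code{extra_private} (profile variants not
#'   explained by the winning path), \code{score}, \code{no_signal} (TRUE when
#'   no node had any scoreable variant, in which case the root is returned).
#' @examples
#' p <- haplotype_profile(c("3348", "16172", "16219", "16311",
#'                          "9738", "15431", "2352", "16163", "7700"))
#' classify_profile(p)$best_node # "U6b1a1"
#' @export
classify_profile <- function(profile, tree = u6_tree(),
                             include_hypervariable = FALSE) {
  stopifnot(inherits(profile, "haplotype_profile"), inherits(tree, "haplo_tree"))
  if (nrow(profile$range) == 0L) stop("profile has an empty covered range")
  tokens <- profile_tokens(profile, include_hypervariable)$token
  nms <- tree$nodes$name
  sc <- lapply(tree$path_tokens[nms], score_path, tokens = tokens,
               range = profile$range)
  matched <- vapply(sc, `[[`, integer(1), "matched")
  missing <- vapply(sc, `[[`, integer(1), "missing")
  unscore <- vapply(sc, `[[`, integer(1), "unscoreable")
  scoreable <- vapply(sc, `[[`, integer(1), "scoreable")
  no_signal <- all(scoreable == 0L)
  if (no_signal) {
    best <- tree$root
  } else {
    score <- matched - missing
    ord <- order(-score, unscore, -tree$depth[nms], nms)
    best <- nms[ord[1L]]
  }
  path <- tree$path_tokens[[best]]
  in_rng_tokens <- tokens  # profile tokens are inside the range by construction
  extra <- sum(!(in_rng_tokens %in% path$token))
  structure(list(best_node = best,
                 matched = matched[[best]],
                 missing = missing[[best]],
                 extra_private = extra,
                 score = matched[[best]] - missing[[best]],
                 no_signal = no_signal),
            class = "u6_classification")
}

#' @export
print.u6_classification <- function(x, ...) {
  cat("Best node: ", x$best_node,
      "  (matched ", x$matched, ", missing ", x$missing,
      ", private ", x$extra_private, ")\n", sep = "")
  if (x$no_signal) cat("  [warning: no scoreable diagnostic position in range]\n")
  invisible(x)
}

#' Classify many profiles to a data frame
#'
#' Batch wrapper around [classify_profile()]; when a profile's covered range
#' overlaps HVR-1 the 8-way HVR-1 category and its geographic label are added
#' via [classify_hvr1()].
#'
#' @param profiles Named list of [haplotype_profile()] objects.
#' @inheritParams classify_profile
#' @return Data frame with columns id, best_node, matched, missing,
#'   extra_private, category8, geo_label.
#' @export
classify_profiles <- function(profiles, tree = u6_tree(),
                              include_hypervariable = FALSE) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("H", seq_along(profiles))
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    cl <- classify_profile(p, tree, include_hypervariable)
    hv <- restrict_profile(p, "hvr1")
    cat8 <- NA_character_; geo <- NA_character_
    if (nrow(hv$range) > 0L) {
      h <- classify_hvr1(hv)
      cat8 <- h$category; geo <- h$geo_label
    }
    data.frame(id = ids[i], best_node = cl$best_node, matched = cl$matched,
               missing = cl$missing, extra_private = cl$extra_private,
               category8 = cat8, geo_label = geo, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sort a U6 HVR-1 haplotype into the eight phylogeographic categories
#'
#' Implements the HVR-1 sorting scheme on diagnostic positions: U6c if
#' \{16169, 16189\} are present; else U6d if 16311 co-occurs with 16261 or
#' 16174; else U6b1 if \{16311, 16163\}; else U6b if 16311; otherwise one of
#' the four U6a bins split on 16189/16239/16235. A bare-16311 haplotype goes to
#' U6b (the U6b/U6d clash on the recurrent 16311 is resolved in favour of U6d
#' only when a U6d subgroup marker co-occurs). The eight categories are
#' exhaustive and mutually exclusive over the diagnostic positions.
#'
#' The U6 membership precondition is presence of 16172 together with either
#' 16219 or the U6c motif \{16169, 16189\} (the basic U6c haplotype lacks
#' 16219); profiles failing it get category \code{"not-U6"}.
#'
#' @param profile A [haplotype_profile()] (typically HVR-1 range), or a numeric
#'   vector of transition positions.
#' @return List with \code{category} (one of [u6_categories()] or
#'   \code{"not-U6"}), \code{geo_label} (NA for non-U6) and \code{is_u6}.
#' @examples
#' classify_hvr1(c(16172, 16219, 16189, 16278, 16239))$category # "U6a189 239"
#' @export
classify_hvr1 <- function(profile) {
  if (is.numeric(profile)) {
    profile <- haplotype_profile(as.character(as.integer(profile)), "genome")
  }
  stopifnot(inherits(profile, "haplotype_profile"))
  pos <- profile_tokens(profile)$position
  has <- function(p) p %in% pos
  if (!(has(16172) && (has(16219) || (has(16169) && has(16189))))) {
    return(list(category = "not-U6", geo_label = NA_character_, is_u6 = FALSE))
  }
  category <-
    if (has(16169) && has(16189)) "U6c"
    else if (has(16311) && (has(16261) || has(16174))) "U6d"
    else if (has(16311) && has(16163)) "U6b1"
    else if (has(16311)) "U6b"
    else if (has(16189) && has(16239)) "U6a189 239"
    else if (has(16189)) "U6a189 without 239"
    else if (has(16235)) "U6a 235"
    else "U6a without 235"
  list(category = category, geo_label = unname(u6_category_geo()[category]),
       is_u6 = TRUE)
}
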