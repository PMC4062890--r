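# rCRS-relative variant and haplotype-profile handling.
#
# All coordinates are 1-based positions on the revised Cambridge Reference
# Sequence (rCRS, 16569 bp). Variant tokens follow the PhyloTree/EMPOP
# convention: a bare number is a transition, a trailing base a transversion,
# ".N" an insertion index, "d" a deletion and "!" a back-mutation.

#' Length of the rCRS mitochondrial genome in base pairs
#' @export
MT_GENOME_LENGTH <- 16569L

#' Coordinate range of hypervariable region 1
#'
#' HVR-1 is taken as rCRS positions 16024-16365 (the conventional bound used
#' for control-region surveys).
#'
#' @return Integer vector \code{c(start, end)}.
#' @export
hvr1_range <- function() c(16024L, 16365L)

IUPAC_HET <- c("R", "Y", "S", "W", "K", "M", "B", "H", "V", "N")

## ---- coordinate ranges ------------------------------------------------------

# Normalise a range spec into a 2-column matrix of closed intervals.
as_range <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- switch(tolower(x),
      genome = c(1L, MT_GENOME_LENGTH),
      hvr1 = hvr1_range(),
      stop("unknown named range: ", x)
    )
  }
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2L)
    m <- x
  } else {
    stopifnot(is.numeric(x), length(x) == 2L)
    m <- matrix(as.numeric(x), ncol = 2L)
  }
  if (nrow(m) == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  if (any(m[, 1L] > m[, 2L])) stop("range start exceeds end")
  if (any(m < 1 | m > MT_GENOME_LENGTH)) {
    stop("range outside 1..", MT_GENOME_LENGTH)
  }
  m <- m[order(m[, 1L]), , drop = FALSE]
  # merge overlapping / adjacent intervals
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) {
    for (i in 2:nrow(m)) {
      if (m[i, 1L] <= out[nrow(out), 2L] + 1) {
        out[nrow(out), 2L] <- max(out[nrow(out), 2L], m[i, 2L])
      } else {
        out <- rbind(out, m[i, ])
      }
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

range_contains <- function(range, pos) {
  if (nrow(range) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= range[, 1L] & p <= range[, 2L]), logical(1))
}

intersect_ranges <- function(a, b) {
  a <- as_range(a); b <- as_range(b)
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      lo <- max(a[i, 1L], b[j, 1L])
      hi <- min(a[i, 2L], b[j, 2L])
      if (lo <= hi) out <- rbind(out, c(lo, hi))
    }
  }
  if (nrow(out) == 0L) {
    dimnames(out) <- list(NULL, c("start", "end"))
    return(out)
  }
  as_range(out)
}

## ---- variant parsing --------------------------------------------------------

empty_variants <- function() {
  data.frame(
    token = character(0), position = integer(0), kind = character(0),
    base = character(0), ins_index = integer(0), back = logical(0),
    hypervariable = logical(0), stringsAsFactors = FALSE
  )
}

#' Parse rCRS-relative variant tokens
#'
#' Grammar: \code{digits [ "." index ] [ base | "d" ] [ "!" ]}. A bare numeric
#' token is a transition ("16189"), a trailing base a transversion ("794A"),
#' \code{"d"} a deletion ("960d"), a dotted index an insertion ("455.1T") and a
#' trailing \code{"!"} a back-mutation to the ancestral state ("750!"). IUPAC
#' ambiguity codes ("146Y") parse to heteroplasmy records that are flagged and
#' excluded from distances and classification.
#'
#' Length variants of the poly-C tracts (insertions around 303-315 and
#' 16180-16195, 16182C/16183C-type transversions) and position 16519 are parsed
#' but flagged \code{hypervariable}; by default they do not enter classification
#' or pi diversity.
#'
#' @param tokens Character vector of variant tokens.
#' @return A data frame with one row per token and columns \code{token}
#'   (canonical form), \code{position}, \code{kind} (one of \code{transition},
#'   \code{transversion}, \code{insertion}, \code{deletion},
#'   \code{heteroplasmy}), \code{base}, \code{ins_index}, \code{back},
#'   \code{hypervariable}.
#' @examples
#' parse_variants(c("794A", "16189", "455.1T", "960d", "750!"))
#' @export
parse_variants <- function(tokens) {
  stopifnot(is.character(tokens))
  if (length(tokens) == 0L) return(empty_variants())
  m <- regmatches(tokens,
                  regexec("^([0-9]+)(?:\\.([0-9]+))?([A-Za-z])?(!)?$", tokens))
  rows <- lapply(seq_along(tokens), function(i) {
    tok <- tokens[i]
    g <- m[[i]]
    if (length(g) == 0L) stop("malformed variant token: '", tok, "'")
    pos <- suppressWarnings(as.integer(g[2L]))
    if (is.na(pos) || pos < 1L || pos > MT_GENOME_LENGTH) {
      stop("variant position out of range in token: '", tok, "'")
    }
    idx <- if (nzchar(g[3L])) as.integer(g[3L]) else NA_integer_
    letter <- toupper(g[4L])
    back <- g[5L] == "!"
    if (!nzchar(letter)) {
      if (!is.na(idx)) stop("insertion without inserted base: '", tok, "'")
      kind <- "transition"; base <- NA_character_
    } else if (g[4L] %in% c("d", "D")) {
      if (!is.na(idx)) stop("deletion cannot carry an insertion index: '", tok, "'")
      kind <- "deletion"; base <- NA_character_
    } else if (letter %in% c("A", "C", "G", "T")) {
      kind <- if (!is.na(idx)) "insertion" else "transversion"
      base <- letter
    } else if (letter %in% IUPAC_HET) {
      if (!is.na(idx)) stop("heteroplasmy cannot carry an insertion index: '", tok, "'")
      kind <- "heteroplasmy"; base <- letter
    } else {
      stop("base not in {A,C,G,T,d} in token: '", tok, "'")
    }
    canon <- paste0(
      pos,
      if (!is.na(idx)) paste0(".", idx) else "",
      if (kind == "deletion") "d" else if (!is.na(base)) base else "",
      if (back) "!" else ""
    )
    hyper <- (pos == 16519L) ||
      (kind == "insertion" && pos >= 302L && pos <= 316L) ||
      (pos >= 16180L && pos <= 16195L &&
         (kind == "insertion" || (kind == "transversion" && identical(base, "C"))))
    data.frame(token = canon, position = pos, kind = kind, base = base,
               ins_index = idx, back = back, hypervariable = hyper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Parse a single variant token
#'
#' @param token A single variant token such as \code{"794A"}.
#' @return A one-row data frame; see [parse_variants()].
#' @export
parse_variant <- function(token) {
  stopifnot(length(token) == 1L)
  parse_variants(token)
}

#' Format parsed variants back to canonical tokens
#'
#' @param variants A data frame as returned by [parse_variants()].
#' @return Character vector of canonical tokens; \code{format(parse(t)) == t}
#'   for every canonical token.
#' @export
format_variants <- function(variants) {
  variants$token
}

## ---- haplotype profiles -----------------------------------------------------

#' Construct a haplotype profile
#'
#' A profile is a set of rCRS-relative variants together with the coordinate
#' range actually covered by the underlying sequence (whole genome for complete
#' sequences, 16024-16365 for HVR-1 surveys). Variants have set semantics:
#' duplicate tokens collapse to one.
#'
#' @param variants Character vector of variant tokens, or a data frame from
#'   [parse_variants()].
#' @param range Covered range: \code{"genome"}, \code{"hvr1"}, a length-2
#'   vector, or a 2-column matrix of closed intervals.
#' @return An object of class \code{haplotype_profile} with elements
#'   \code{variants} (parsed data frame, unique, ordered by position) and
#'   \code{range}.
#' @examples
#' haplotype_profile(c("16172", "16219", "16278"), range = "hvr1")
#' @export
haplotype_profile <- function(variants = character(), range = "genome") {
  rng <- as_range(range)
  df <- if (is.data.frame(variants)) variants else parse_variants(variants)
  df <- df[!duplicated(df$token), , drop = FALSE]
  df <- df[order(df$position, df$token), , drop = FALSE]
  rownames(df) <- NULL
  bad <- !range_contains(rng, df$position)
  if (any(bad)) {
    stop("variant(s) outside covered range: ",
         paste(df$token[bad], collapse = ", "))
  }
  structure(list(variants = df, range = rng), class = "haplotype_profile")
}

#' @export
print.haplotype_profile <- function(x, ...) {
  rng <- paste(apply(x$range, 1L, function(r) paste0(r[1L], "-", r[2L])),
               collapse = ", ")
  cat("Haplotype profile (", nrow(x$variants), " variants; range ", rng, ")\n",
      sep = "")
  if (nrow(x$variants) > 0L) {
    cat(" ", paste(x$variants$token, collapse = " "), "\n")
  }
  invisible(x)
}

# Tokens used for comparisons/classification: optionally drop flagged sites.
profile_tokens <- function(profile, include_hypervariable = FALSE,
                           include_heteroplasmy = FALSE) {
  v <- profile$variants
  if (!include_hypervariable) v <- v[!v$hypervariable, , drop = FALSE]
  if (!include_heteroplasmy) v <- v[v$kind != "heteroplasmy", , drop = FALSE]
  v
}

#' Restrict a profile to a coordinate region
#'
#' Keeps only variants inside \code{region} and sets the covered range to the
#' intersection of the profile's range with \code{region}. A disjoint region
#' yields an empty profile (not an error).
#'
#' @param profile A [haplotype_profile()].
#' @param region Range spec as in [haplotype_profile()].
#' @return A new \code{haplotype_profile}.
#' @export
restrict_profile <- function(profile, region) {
  stopifnot(inherits(profile, "haplotype_profile"))
  rng <- intersect_ranges(profile$range, as_range(region))
  keep <- range_contains(rng, profile$variants$position)
  structure(list(variants = profile$variants[keep, , drop = FALSE], range = rng),
            class = "haplotype_profile")
}

#' Number of pairwise differences between two profiles
#'
#' The size of the symmetric difference of the two variant sets within the
#' shared covered range (profiles with different ranges are compared on the
#' intersection). This is the substrate of the pi diversity statistic.
#' Hypervariable and heteroplasmic records are excluded by default.
#'
#' @param a,b [haplotype_profile()] objects.
#' @param include_hypervariable Include poly-C tract/16519 records?
#' @return Non-negative integer; zero iff the profiles agree on the shared
#'   range.
#' @examples
#' a <- haplotype_profile(c("16172", "16219", "16278"), "hvr1")
#' b <- haplotype_profile(c("16172", "16219", "16311"), "hvr1")
#' profile_distance(a, b) # 2
#' @export
profile_distance <- function(a, b, include_hypervariable = FALSE) {
  stopifnot(inherits(a, "haplotype_profile"), inherits(b, "haplotype_profile"))
  shared <- intersect_ranges(a$range, b$range)
  ta <- profile_tokens(restrict_profile(a, shared), include_hypervariable)$token
  tb <- profile_tokens(restrict_profile(b, shared), include_hypervariable)$token
  length(setdiff(ta, tb)) + length(setdiff(tb, ta))
}

## ---- motif text format ------------------------------------------------------

looks_like_variant <- function(token) {
  grepl("^[0-9]+(\\.[0-9]+)?[A-Za-z]?!?$", token)
}

#' Read an EMPOP-like motif file
#'
#' One haplotype per line, whitespace-separated variant tokens, with an
#' optional leading sample-ID column. Lines starting with \code{#} and blank
#' lines are skipped.
#'
#' @param path File path.
#' @param range Covered range of the haplotypes (default whole genome).
#' @param ids \code{"auto"} detects a leading ID (any first token that does not
#'   parse as a variant); \code{TRUE}/\code{FALSE} force the choice.
#' @return Named list of [haplotype_profile()] objects.
#' @export
read_motif_file <- function(path, range = "genome", ids = "auto") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    toks <- strsplit(lines[i], "[[:space:]]+")[[1L]]
    has_id <- if (identical(ids, "auto")) !looks_like_variant(toks[1L])
              else isTRUE(ids)
    if (has_id) {
      id <- toks[1L]; toks <- toks[-1L]
    } else {
      id <- paste0("H", i)
    }
    out[[id]] <- haplotype_profile(toks, range = range)
  }
  out
}

#' Write profiles to an EMPOP-like motif file
#'
#' @param profiles Named list of [haplotype_profile()] objects.
#' @param path Output path.
#' @export
write_motif_file <- function(profiles, path) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("H", seq_along(profiles))
  lines <- vapply(seq_along(profiles), function(i) {
    paste(c(ids[i], profiles[[i]]$variants$token), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---- FASTA input ------------------------------------------------------------

#' Call variants from pre-aligned HVR-1 FASTA fragments
#'
#' Reads a FASTA file of equal-length, pre-aligned control-region fragments and
#' calls rCRS-relative variants against a reference record by fixed coordinate
#' offset (alignment itself is out of scope). The first record (or the record
#' named by \code{reference}) is the reference; column \code{j} maps to rCRS
#' position \code{start + j - 1}. Substitutions are typed as transitions or
#' transversions, \code{-} in a sample as a deletion, and IUPAC ambiguity codes
#' as flagged heteroplasmies.
#'
#' @param path FASTA file path.
#' @param start rCRS position of the first alignment column (default 16024).
#' @param reference Name of the reference record; default the first record.
#' @return Named list of [haplotype_profile()] objects (reference excluded).
#' @export
read_hvr1_fasta <- function(path, start = 16024L, reference = NULL) {
  seqs <- seqinr::read.fasta(path, as.string = FALSE, forceDNAtolower = FALSE)
  if (length(seqs) < 2L) stop("need a reference record plus >=1 sample")
  nms <- names(seqs)
  ref_i <- if (is.null(reference)) 1L else match(reference, nms)
  if (is.na(ref_i)) stop("reference record not found: ", reference)
  ref <- toupper(as.character(seqs[[ref_i]]))
  len <- length(ref)
  rng <- c(start, start + len - 1L)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  out <- list()
  for (i in setdiff(seq_along(seqs), ref_i)) {
    s <- toupper(as.character(seqs[[i]]))
    if (length(s) != len) {
      stop("record '", nms[i], "' length differs from the reference")
    }
    toks <- character(0)
    for (j in seq_len(len)) {
      rb <- ref[j]; sb <- s[j]
      if (sb == rb || rb == "-") next  # insertions relative to rCRS unsupported
      pos <- start + j - 1L
      if (sb == "-") {
        toks <- c(toks, paste0(pos, "d"))
      } else if (sb %in% c("A", "C", "G", "T")) {
        if (rb %in% names(purine) && purine[[rb]] == purine[[sb]]) {
          toks <- c(toks, as.character(pos))      # transition
        } else {
          toks <- c(toks, paste0(pos, sb))        # transversion
        }
      } else if (sb %in% IUPAC_HET) {
        toks <- c(toks, paste0(pos, sb))          # flagged heteroplasmy
      }
    }
    out[[nms[i]]] <- haplotype_profile(toks, range = rng)
  }
  out
}
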