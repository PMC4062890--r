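# Regional frequency tables, pi diversity with a Tajima-type standard error,
# permutation comparison of diversities, longitudinal gradient correlation and
# PCA of subhaplogroup frequencies.

category_columns <- function() {
  c("U6a_without_235", "U6a_235", "U6a189_without_239", "U6a189_239",
    "U6b", "U6b1", "U6d", "U6c")
}

# Integer apportionment by largest remainder so counts sum to `total`.
apportion <- function(weights, total) {
  if (total == 0L || sum(weights) == 0) return(rep(0L, length(weights)))
  raw <- weights / sum(weights) * total
  counts <- floor(raw)
  deficit <- as.integer(total - sum(counts))
  if (deficit > 0L) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(deficit)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}

#' Read a regional U6 frequency table
#'
#' Accepts either count columns (\code{u6_count} plus the eight category count
#' columns) or percentage columns (\code{pct_u6} plus category percentages of
#' U6 carriers, the printed layout). Percentages are converted to counts by
#' rounding against the sample size and apportioning category counts by largest
#' remainder so they sum to the U6 count, then re-validated.
#'
#' @param path CSV path (header: region, sample_size, then counts or
#'   percentages).
#' @return A data frame of class \code{frequency_table} with columns region,
#'   sample_size, u6_count and the eight category count columns.
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("region", "sample_size") %in% names(df)))
  cats <- category_columns()
  if ("u6_count" %in% names(df)) {
    stopifnot(all(cats %in% names(df)))
    out <- df[, c("region", "sample_size", "u6_count", cats)]
  } else {
    stopifnot("pct_u6" %in% names(df), all(cats %in% names(df)))
    u6 <- as.integer(round(df$pct_u6 / 100 * df$sample_size))
    counts <- t(vapply(seq_len(nrow(df)), function(i) {
      apportion(as.numeric(df[i, cats]), u6[i])
    }, integer(length(cats))))
    colnames(counts) <- cats
    out <- cbind(data.frame(region = df$region, sample_size = df$sample_size,
                            u6_count = u6, stringsAsFactors = FALSE),
                 as.data.frame(counts))
  }
  validate_frequency_table(out)
}

validate_frequency_table <- function(tab) {
  cats <- category_columns()
  stopifnot(all(tab$u6_count <= tab$sample_size))
  sums <- rowSums(tab[, cats, drop = FALSE])
  if (any(sums != tab$u6_count)) {
    stop("category counts do not sum to the U6 count in row(s): ",
         paste(tab$region[sums != tab$u6_count], collapse = ", "))
  }
  class(tab) <- c("frequency_table", "data.frame")
  tab
}

#' Write a frequency table as counts or percentages
#'
#' @param tab A \code{frequency_table}.
#' @param path Output CSV path.
#' @param format \code{"counts"} or \code{"percent"} (the printed layout).
#' @export
write_frequency_table <- function(tab, path, format = c("counts", "percent")) {
  format <- match.arg(format)
  cats <- category_columns()
  if (format == "counts") {
    utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  } else {
    pct <- composition(tab)
    pct[is.na(pct)] <- 0
    out <- cbind(data.frame(region = tab$region, sample_size = tab$sample_size,
                            pct_u6 = u6_frequency(tab)),
                 as.data.frame(pct))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' The shipped regional HVR-1 frequency table
#'
#' The 25-population regional table of U6 frequency and 8-way subhaplogroup
#' composition, as printed (percentages), converted to counts.
#'
#' @return A \code{frequency_table}.
#' @export
u6_table1 <- function() {
  read_frequency_table(system.file("extdata", "u6_hvr1_frequencies.csv",
                                   package = "u6phylo", mustWork = TRUE))
}

#' Per-cent U6 carriers per region
#'
#' @param tab A \code{frequency_table} (or any data frame with
#'   \code{u6_count}/\code{sample_size}).
#' @return Named numeric vector, rounded to 2 decimals.
#' @export
u6_frequency <- function(tab) {
  if (any(tab$sample_size <= 0)) stop("sample size must be positive")
  stats::setNames(round(100 * tab$u6_count / tab$sample_size, 2), tab$region)
}

#' Subhaplogroup composition of U6 carriers, in per cent
#'
#' Percentages are reported to 1 decimal by largest-remainder apportionment on
#' the 0.1 grid, so each row sums to exactly 100.0.
#'
#' @param tab A \code{frequency_table}.
#' @return Matrix (region x category) of percentages of U6 carriers to
#'   1 decimal; rows with zero carriers are NA and flagged with a warning.
#' @export
composition <- function(tab) {
  cats <- category_columns()
  m <- as.matrix(tab[, cats, drop = FALSE])
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = list(tab$region, cats))
  ok <- tab$u6_count > 0
  if (any(!ok)) warning("composition undefined for region(s) with no U6 carriers: ",
                        paste(tab$region[!ok], collapse = ", "))
  for (i in which(ok)) {
    out[i, ] <- apportion(m[i, ], 1000L) / 10   # tenths of a per cent
  }
  out
}

## ---- pi diversity -----------------------------------------------------------

#' Pi diversity: mean pairwise differences with a Tajima-type SE
#'
#' The mean of [profile_distance()] over all unordered pairs of profiles, with
#' the standard error from Tajima's total variance of the mean number of
#' pairwise differences,
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2,}
#' the form implemented by the standard diversity software.
#'
#' @param profiles List of >= 2 [haplotype_profile()] objects with a shared
#'   covered range.
#' @param include_hypervariable Include poly-C tract/16519 records?
#' @return Object of class \code{diversity_estimate}: pi, se, n.
#' @examples
#' ps <- list(haplotype_profile(character(), "hvr1"),
#'            haplotype_profile("16189", "hvr1"),
#'            haplotype_profile(c("16189", "16311"), "hvr1"))
#' pi_diversity(ps) # pi = 4/3
#' @export
pi_diversity <- function(profiles, include_hypervariable = FALSE) {
  n <- length(profiles)
  if (n < 2L) stop("need at least two profiles")
  pairs <- utils::combn(n, 2L)
  d <- apply(pairs, 2L, function(ij) {
    profile_distance(profiles[[ij[1L]]], profiles[[ij[2L]]],
                     include_hypervariable)
  })
  pi <- mean(d)
  v <- (n + 1) / (3 * (n - 1)) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  structure(list(pi = pi, se = sqrt(v), n = n), class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat("pi = ", format(round(x$pi, 3)), " +/- ", format(round(x$se, 3)),
      "  (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Permutation comparison of pi diversities between two groups
#'
#' Two-sided permutation test of |pi_A - pi_B| under random reassignment of
#' profiles to groups (sizes preserved). The p-value uses the add-one
#' convention \code{(1 + #extreme) / (n_perm + 1)} and is reproducible under a
#' fixed seed.
#'
#' @param a,b Lists of [haplotype_profile()] objects.
#' @param n_perm Number of permutations (>= 100 recommended; fewer warns).
#' @param seed Integer seed (required; every stochastic call is seeded).
#' @param include_hypervariable Include flagged records?
#' @return List: p_value, observed (|pi_A - pi_B|), pi_a, pi_b, n_perm.
#' @export
diversity_compare <- function(a, b, n_perm = 999, seed,
                              include_hypervariable = FALSE) {
  if (missing(seed)) stop("a seed is required")
  if (n_perm < 100) warning("fewer than 100 permutations: p-value is coarse")
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  if (na < 2L || length(b) < 2L) stop("both groups need >= 2 profiles")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- profile_distance(pool[[i]], pool[[j]],
                                             include_hypervariable)
    }
  }
  group_pi <- function(idx) {
    sub <- D[idx, idx]
    sum(sub[upper.tri(sub)]) / choose(length(idx), 2L)
  }
  pi_a <- group_pi(seq_len(na))
  pi_b <- group_pi((na + 1L):n)
  obs <- abs(pi_a - pi_b)
  set.seed(seed)
  perm <- replicate(n_perm, {
    ia <- sample.int(n, na)
    abs(group_pi(ia) - group_pi(setdiff(seq_len(n), ia)))
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(p_value = p, observed = obs, pi_a = pi_a, pi_b = pi_b, n_perm = n_perm)
}

## ---- gradients and PCA ------------------------------------------------------

#' Longitudinal gradient correlation of haplogroup frequencies
#'
#' Pearson correlation of frequency against longitude with the two-sided
#' t-test p-value.
#'
#' @param freq Frequencies (per cent), length >= 3.
#' @param longitude Longitudes (degrees), same length.
#' @return List: r, p_value, n, undefined (TRUE with a warning when either
#'   vector has zero variance, in which case r and p are NA).
#' @export
gradient_correlation <- function(freq, longitude) {
  stopifnot(length(freq) == length(longitude), length(freq) >= 3L)
  if (stats::var(freq) == 0 || stats::var(longitude) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(freq),
                undefined = TRUE))
  }
  ct <- stats::cor.test(freq, longitude, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(freq),
       undefined = FALSE)
}

#' PCA of subhaplogroup frequencies
#'
#' Principal components of a regions-by-categories frequency matrix on the
#' correlation scale (columns centred and scaled). Constant columns are dropped
#' with a warning. Signs follow a fixed convention: on each component, the
#' largest-magnitude loading is positive.
#'
#' @param freq_matrix Numeric matrix, regions in rows, categories in columns
#'   (>= 2 of each).
#' @return Object of class \code{u6_pca}: scores, loadings, sdev,
#'   dropped_columns.
#' @export
pca_scores <- function(freq_matrix) {
  m <- as.matrix(freq_matrix)
  stopifnot(nrow(m) >= 2L, ncol(m) >= 2L, is.numeric(m))
  const <- apply(m, 2L, function(col) stats::var(col) == 0)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("fewer than two variable columns remain")
  pr <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  structure(list(scores = pr$x, loadings = pr$rotation, sdev = pr$sdev,
                 dropped_columns = colnames(freq_matrix)[const]),
            class = "u6_pca")
}

#' @export
print.u6_pca <- function(x, ...) {
  pv <- round(100 * x$sdev^2 / sum(x$sdev^2), 1)
  cat("PCA of subhaplogroup frequencies: ", nrow(x$scores), " regions, ",
      ncol(x$scores), " components\n  variance explained (%): ",
      paste(pv, collapse = ", "), "\n", sep = "")
  invisible(x)
}
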