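## Diversity indices and between-method concordance: square-root
## transform, Shannon H', Jaccard and Bray-Curtis pairwise matrices, and
## Pearson correlation between pairwise matrices with a t-based (or
## optional Mantel-permutation) significance test.

as_values <- function(x) {
  if (inherits(x, "community_matrix")) x$values
  else if (inherits(x, "nsra_matrix")) x$values
  else as.matrix(x)
}

#' Square-root transform a community matrix
#'
#' The standard variance-stabilizing step before Bray-Curtis ordination of
#' skewed count-like data; zeros stay zero.
#'
#' @param x matrix or [community_matrix()].
#' @return same shape, element-wise square root.
#' @export
sqrt_transform <- function(x) {
  v <- as_values(x)
  if (any(v < 0)) abort_zp("negative values cannot be sqrt-transformed",
                           "zp_bad_input")
  out <- sqrt(v)
  if (inherits(x, "community_matrix")) {
    x$values <- out
    x$currency <- paste0("sqrt_", x$currency)
    x
  } else out
}

#' Shannon diversity (H', natural log)
#'
#' `H' = -sum(p_i log p_i)` over the positive proportions
#' `p_i = x_i / sum(x)`. For a matrix, one value per row (station).
#'
#' @param x non-negative vector, matrix or [community_matrix()].
#' @return numeric H' in nats (per row for matrix input).
#' @export
shannon <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (any(x < 0)) abort_zp("negative abundances", "zp_bad_input")
    s <- sum(x)
    if (s == 0) abort_zp("Shannon undefined for an all-zero vector",
                         "zp_bad_input")
    p <- x[x > 0] / s
    return(-sum(p * log(p)))
  }
  v <- as_values(x)
  apply(v, 1L, function(row) shannon(as.numeric(row)))
}

#' Pairwise Jaccard similarity matrix
#'
#' `sim(a, b) = |A intersect B| / |A union B|` on the presence sets of two
#' rows; values in a row are considered present when strictly positive.
#' Pairs of two empty rows are undefined and flagged `NA` with a warning.
#'
#' @param x matrix or [community_matrix()] (rows = stations).
#' @return symmetric similarity matrix, unit diagonal; the companion
#'   dissimilarity is `1 - sim`.
#' @export
jaccard_matrix <- function(x) {
  p <- as_values(x) > 0
  n <- nrow(p)
  out <- diag(1, n)
  dimnames(out) <- list(rownames(p), rownames(p))
  flagged <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    un <- sum(p[i, ] | p[j, ])
    if (un == 0) {
      out[i, j] <- out[j, i] <- NA_real_
      flagged <- TRUE
    } else {
      out[i, j] <- out[j, i] <- sum(p[i, ] & p[j, ]) / un
    }
  }
  if (flagged) warning("[ZP_W02] Jaccard undefined for some empty-row pairs")
  out
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum|x - y| / sum(x + y)`, in `[0, 1]`, zero diagonal. Pairs
#' of two all-zero rows are undefined and flagged `NA` with a warning.
#'
#' @param x non-negative matrix or [community_matrix()] (rows = stations).
#' @return symmetric dissimilarity matrix.
#' @export
bray_curtis <- function(x) {
  v <- as_values(x)
  if (any(v < 0)) abort_zp("Bray-Curtis needs non-negative data", "zp_bad_input")
  n <- nrow(v)
  out <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  flagged <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- sum(v[i, ] + v[j, ])
    if (denom == 0) {
      out[i, j] <- out[j, i] <- NA_real_
      flagged <- TRUE
    } else {
      out[i, j] <- out[j, i] <- sum(abs(v[i, ] - v[j, ])) / denom
    }
  }
  if (flagged) warning("[ZP_W03] Bray-Curtis undefined for some all-zero pairs")
  out
}

lower_vec <- function(m) m[lower.tri(m)]

#' Pearson correlation between two pairwise matrices
#'
#' Correlates the strictly-lower-triangle vectors of two station-by-station
#' matrices over the same stations. Significance is by default the plain
#' paired-observation t test (`df = m - 2` over the `m` pairs) -- the
#' procedure used when pairwise matrices are simply fed to a correlation
#' test -- with an optional Mantel permutation mode for
#' exchangeability-correct inference.
#'
#' @param m1,m2 square symmetric matrices over the same stations, in the
#'   same order.
#' @param method `"t"` (default) or `"mantel"`.
#' @param n_perm permutations for the Mantel mode.
#' @param seed seed for the Mantel mode.
#' @return list `r`, `p`, `n_pairs`, `method`.
#' @export
matrix_correlation <- function(m1, m2, method = c("t", "mantel"),
                               n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(dim(m1) == dim(m2)))
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)))
    stopifnot(identical(rownames(m1), rownames(m2)))
  a <- lower_vec(m1); b <- lower_vec(m2)
  ok <- !(is.na(a) | is.na(b))
  a <- a[ok]; b <- b[ok]
  m <- length(a)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("[ZP_W04] constant distance vector; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n_pairs = m, method = method))
  }
  r <- cor(a, b)
  if (method == "t") {
    tt <- r * sqrt((m - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tt), df = m - 2)
  } else {
    n <- nrow(m1)
    set.seed(derive_seed(seed, 13L))
    perm_r <- vapply(seq_len(n_perm), function(i) {
      o <- sample(n)
      cor(lower_vec(m1[o, o])[ok], b)
    }, numeric(1))
    p <- (1 + sum(abs(perm_r) >= abs(r))) / (1 + n_perm)
  }
  list(r = r, p = p, n_pairs = m, method = method)
}

#' Correlation heatmap table across data streams
#'
#' All pairwise [matrix_correlation()]s among a named list of pairwise
#' matrices (e.g. the Jaccard matrices of every marker and imaging
#' currency), or plain Pearson correlations among a named list of
#' per-station vectors (e.g. Shannon indices).
#'
#' @param mats named list of square matrices, or named list of equal-length
#'   vectors when `vectors = TRUE`.
#' @param vectors treat inputs as plain per-station vectors.
#' @return data.frame `a`, `b`, `r`, `p`, `significant` (p < 0.05).
#' @export
correlation_table <- function(mats, vectors = FALSE) {
  nms <- names(mats)
  out <- list()
  for (i in seq_along(nms)[-length(nms)]) for (j in (i + 1):length(nms)) {
    if (vectors) {
      a <- mats[[i]]; b <- mats[[j]]
      r <- cor(a, b)
      m <- length(a)
      tt <- r * sqrt((m - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tt), df = m - 2)
      res <- list(r = r, p = p)
    } else {
      res <- matrix_correlation(mats[[i]], mats[[j]])
    }
    out[[length(out) + 1L]] <- data.frame(
      a = nms[i], b = nms[j], r = res$r, p = res$p,
      significant = !is.na(res$p) & res$p < 0.05,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
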