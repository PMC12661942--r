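## Ordination and environment-driver statistics: PCA on scaled
## environmental variables with passive vectors, Kruskal non-metric MDS by
## iterative majorization with monotone (PAVA) regression, permutational
## environmental vector fitting, Ward/k-means clustering, and
## influence-ranked taxa.

#' Pooled-adjacent-violators isotonic regression
#'
#' Weighted least-squares monotone (non-decreasing) fit; the workhorse of
#' the non-metric MDS monotone regression step.
#'
#' @param y numeric values in target order.
#' @param w positive weights.
#' @return fitted non-decreasing vector of the same length.
#' @export
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0) return(y)
  val <- y; wt <- w; len <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; len[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      tot <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) / tot
      wt[m - 1L] <- tot
      len[m - 1L] <- len[m - 1L] + len[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], times = len[seq_len(m)])
}

dist_vec <- function(x) as.vector(dist(x))

## Kruskal stress-1 of configuration distances against the monotone
## regression of the dissimilarity order. Ties in the dissimilarities are
## averaged (the primary treatment): tied pairs share one fitted value.
stress_parts <- function(dhat, ord, groups) {
  gmean <- rowsum(dhat[ord], groups) / as.vector(table(groups))
  fit_g <- pava(as.vector(gmean), as.vector(table(groups)))
  disp <- numeric(length(dhat))
  disp[ord] <- fit_g[groups]
  list(disp = disp,
       stress = sqrt(sum((dhat - disp)^2) / sum(dhat^2)))
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes stress-1
#' `sqrt(sum((dhat - dstar)^2) / sum(dhat^2))`, where `dhat` are the
#' configuration's Euclidean distances and `dstar` is the monotone
#' (isotonic, pooled-adjacent-violators, ties averaged) regression of
#' `dhat` on the input dissimilarity order. The configuration is updated
#' by iterative majorization (Guttman transform) alternated with the
#' isotonic fit; an update is accepted only if stress does not increase,
#' so the stress trace is non-increasing by construction. The best of one
#' metric-scaling start plus `n_starts` random starts is kept, then
#' centred, rotated to principal axes, and sign-fixed (largest-magnitude
#' score positive per axis).
#'
#' @param diss square symmetric dissimilarity matrix, zero diagonal.
#' @param k embedding dimension (default 2).
#' @param n_starts random restarts in addition to the metric start.
#' @param max_iter maximum majorization iterations per start.
#' @param tol convergence tolerance on the stress change.
#' @param seed integer seed for the random starts.
#' @return object of class `zp_ordination`: `method = "nMDS"`, `points`
#'   (n x k), `stress`, `converged`, `stress_trace` (best start), `diss`.
#' @export
nmds <- function(diss, k = 2L, n_starts = 20L, max_iter = 500L,
                 tol = 1e-7, seed = 1L) {
  diss <- as.matrix(diss)
  if (!isSymmetric(unname(diss), tol = 1e-8))
    abort_zp("dissimilarity matrix must be symmetric", "zp_bad_input")
  n <- nrow(diss)
  dvec <- as.vector(as.dist(diss))
  ord <- order(dvec)
  groups <- match(dvec[ord], unique(dvec[ord]))  # tie blocks, in d order

  run_start <- function(x0) {
    x <- x0
    dhat <- dist_vec(x)
    sp <- stress_parts(dhat, ord, groups)
    trace <- sp$stress
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ## Guttman transform with current disparities
      dm <- matrix(0, n, n)
      dm[lower.tri(dm)] <- dhat
      dm <- dm + t(dm)
      rm_ <- matrix(0, n, n)
      rm_[lower.tri(rm_)] <- sp$disp
      rm_ <- rm_ + t(rm_)
      b <- ifelse(dm > 0, -rm_ / dm, 0)
      diag(b) <- 0
      diag(b) <- -rowSums(b)
      x_new <- b %*% x / n
      dhat_new <- dist_vec(x_new)
      sp_new <- stress_parts(dhat_new, ord, groups)
      if (sp_new$stress > sp$stress + 1e-12) break  # accept only descents
      delta <- sp$stress - sp_new$stress
      x <- x_new; dhat <- dhat_new; sp <- sp_new
      trace <- c(trace, sp$stress)
      if (delta < tol) { converged <- TRUE; break }
    }
    list(x = x, stress = sp$stress, trace = trace, converged = converged)
  }

  starts <- list()
  cm <- tryCatch(cmdscale(diss, k = k), error = function(e) NULL)
  if (!is.null(cm) && ncol(cm) == k) starts[[1]] <- cm
  set.seed(derive_seed(seed, 20L))
  for (i in seq_len(n_starts))
    starts[[length(starts) + 1L]] <- matrix(rnorm(n * k), n, k)
  best <- NULL
  for (x0 in starts) {
    res <- run_start(x0)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  ## centre, principal-axis rotation, sign convention
  x <- scale(best$x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  x <- sv$u %*% diag(sv$d, k, k)
  for (j in seq_len(k)) {
    if (x[which.max(abs(x[, j])), j] < 0) x[, j] <- -x[, j]
  }
  rownames(x) <- rownames(diss)
  colnames(x) <- paste0("NMDS", seq_len(k))
  structure(list(method = "nMDS", points = x, stress = best$stress,
                 converged = best$converged, stress_trace = best$trace,
                 diss = diss),
            class = "zp_ordination")
}

#' Principal component analysis of environmental variables
#'
#' Columns are centred (and unit-scaled when `scale = TRUE`), decomposed
#' by singular values; scores are the projections onto the eigenvectors.
#' Each axis is oriented so its largest-magnitude loading is positive.
#'
#' @param env data.frame with a `station` column plus numeric covariates,
#'   or a plain numeric matrix with station rownames.
#' @param scale unit-scale the columns (default `TRUE`).
#' @return object of class `zp_ordination`: `method = "PCA"`, `points`
#'   (scores), `loadings`, `var_explained` (percent per axis,
#'   non-increasing, summing to 100).
#' @export
pca_env <- function(env, scale = TRUE) {
  if (is.data.frame(env)) {
    stn <- env$station %||% rownames(env)
    num <- env[, vapply(env, is.numeric, logical(1)), drop = FALSE]
    m <- as.matrix(num)
    rownames(m) <- stn
  } else {
    m <- as.matrix(env)
  }
  if (nrow(m) < 2) abort_zp("PCA needs at least 2 stations", "zp_bad_input")
  const <- apply(m, 2, sd) == 0
  if (scale && any(const)) {
    warning("[ZP_W05] dropping constant column(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  z <- scale(m, center = TRUE, scale = scale)
  sv <- svd(z)
  k <- length(sv$d)
  scores <- sv$u %*% diag(sv$d, k, k)
  load <- sv$v
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(k))
  dimnames(load) <- list(colnames(m), colnames(scores))
  ve <- 100 * sv$d^2 / sum(sv$d^2)
  structure(list(method = "PCA", points = scores, loadings = load,
                 var_explained = ve),
            class = "zp_ordination")
}

#' @export
print.zp_ordination <- function(x, ...) {
  if (x$method == "PCA") {
    cat(sprintf("<ordination> PCA: %d stations, axis variance %s%%\n",
                nrow(x$points),
                paste(sprintf("%.1f", x$var_explained[1:min(3, length(x$var_explained))]),
                      collapse = "/")))
  } else {
    cat(sprintf("<ordination> nMDS: %d stations, k=%d, stress=%.4f\n",
                nrow(x$points), ncol(x$points), x$stress))
  }
  invisible(x)
}

#' Passive vectors in an ordination
#'
#' Projects extra station-indexed variables (e.g. Shannon indices) into an
#' existing ordination without altering it: each arrow is the vector of
#' Pearson correlations between the variable and the axis scores.
#'
#' @param ord a `zp_ordination`.
#' @param extra data.frame or matrix of station-indexed variables (rows
#'   match `ord$points`).
#' @param naxes number of axes to project onto (default 2).
#' @return data.frame: `variable`, one correlation column per axis,
#'   `length` (arrow norm; ~0 and flagged for constant variables).
#' @export
passive_vectors <- function(ord, extra, naxes = 2L) {
  s <- ord$points[, seq_len(min(naxes, ncol(ord$points))), drop = FALSE]
  extra <- as.data.frame(extra)
  rows <- lapply(names(extra), function(v) {
    x <- extra[[v]]
    if (sd(x) == 0) {
      warning(sprintf("[ZP_W06] constant passive variable '%s'", v))
      cc <- rep(0, ncol(s))
    } else {
      cc <- as.vector(cor(x, s))
    }
    out <- data.frame(variable = v, t(cc), length = sqrt(sum(cc^2)),
                      stringsAsFactors = FALSE)
    names(out)[2:(1 + ncol(s))] <- colnames(s)
    out
  })
  do.call(rbind, rows)
}

#' Fit environmental vectors to an ordination with a permutation test
#'
#' Each (centred, unit-scaled) variable is regressed on the ordination
#' scores by least squares; `r2` is the regression share of the variable's
#' variance, the direction is the normalized coefficient vector, and the
#' p-value is the `(1 + #{permuted r2 >= observed}) / (1 + n_perm)`
#' estimator under random permutation of the variable's station labels.
#'
#' @param ord a `zp_ordination`.
#' @param env data.frame with a `station` column (matched against the
#'   ordination) or numeric matrix with matching rows.
#' @param n_perm permutations (default 999; < 99 draws a warning).
#' @param seed integer seed.
#' @param naxes axes to fit on (default 2).
#' @return data.frame: `variable`, direction per axis, `r2`, `p`,
#'   `significant` (p < 0.05); constant variables are skipped.
#' @export
fit_env_vectors <- function(ord, env, n_perm = 999L, seed = 1L, naxes = 2L) {
  if (n_perm < 99) warning("[ZP_W07] fewer than 99 permutations")
  s <- ord$points[, seq_len(min(naxes, ncol(ord$points))), drop = FALSE]
  if (is.data.frame(env) && "station" %in% names(env)) {
    stopifnot(all(rownames(s) %in% env$station))
    env <- env[match(rownames(s), env$station), ]
    env <- env[, setdiff(names(env), "station"), drop = FALSE]
    env <- env[, vapply(env, is.numeric, logical(1)), drop = FALSE]
  }
  env <- as.matrix(env)
  sc <- scale(s, center = TRUE, scale = FALSE)
  ## hat projection onto the score space (with intercept via centering)
  qr_s <- qr(sc)
  set.seed(derive_seed(seed, 21L))
  rows <- list()
  for (v in colnames(env)) {
    x <- env[, v]
    if (sd(x) == 0) {
      warning(sprintf("[ZP_W08] constant variable '%s' skipped", v))
      next
    }
    z <- as.vector(scale(x))
    r2_of <- function(zz) {
      fit <- qr.fitted(qr_s, zz - mean(zz))
      sum(fit^2) / sum((zz - mean(zz))^2)
    }
    r2 <- r2_of(z)
    beta <- qr.coef(qr_s, z - mean(z))
    beta[is.na(beta)] <- 0
    dir <- if (sum(beta^2) > 0) beta / sqrt(sum(beta^2)) else beta
    perm <- vapply(seq_len(n_perm), function(i) r2_of(z[sample(length(z))]),
                   numeric(1))
    p <- (1 + sum(perm >= r2)) / (1 + n_perm)
    out <- data.frame(variable = v, t(dir), r2 = r2, p = p,
                      significant = p < 0.05, stringsAsFactors = FALSE)
    names(out)[2:(1 + ncol(s))] <- colnames(s)
    rows[[v]] <- out
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Ward and k-means clustering of ordination axes
#'
#' Hierarchical clustering (Ward.D2 linkage on Euclidean distances) cut at
#' `k`, alongside k-means with `nstart` seeded restarts, on the first (up
#' to) three ordination axes; within-cluster sums of squares are reported
#' for choosing `k`.
#'
#' @param ord a `zp_ordination` (or a plain coordinate matrix).
#' @param k number of clusters.
#' @param seed integer seed for k-means.
#' @param naxes axes used (default 3, the usual inspection depth).
#' @param nstart k-means restarts (default 10).
#' @return list: `ward` (labels), `kmeans` (labels), `hclust` (tree),
#'   `wss` (k-means within-cluster sum of squares), `coords`.
#' @export
cluster_stations <- function(ord, k, seed = 1L, naxes = 3L, nstart = 10L) {
  coords <- if (inherits(ord, "zp_ordination")) ord$points else as.matrix(ord)
  coords <- coords[, seq_len(min(naxes, ncol(coords))), drop = FALSE]
  if (k > nrow(coords))
    abort_zp("more clusters than stations", "zp_bad_input")
  hc <- hclust(dist(coords), method = "ward.D2")
  ward <- cutree(hc, k = k)
  set.seed(derive_seed(seed, 22L))
  if (k == nrow(coords)) {
    ## every station its own cluster; stats::kmeans rejects k = n
    km_cluster <- setNames(seq_len(nrow(coords)), rownames(coords))
    wss <- 0
  } else {
    km <- kmeans(coords, centers = k, nstart = nstart)
    km_cluster <- km$cluster
    wss <- sum(km$withinss)
  }
  list(ward = ward, kmeans = km_cluster, hclust = hc,
       wss = wss, coords = coords)
}

#' Influential taxa in an ordination
#'
#' Places each taxon at the abundance-weighted average of the station
#' coordinates and scores its influence as (taxon total) x (distance of
#' that position from the origin); the top `k` are returned. The
#' weighted-average placement mirrors weighted-averaging species scores;
#' the total x displacement influence criterion is one defensible choice
#' among several and is documented as such.
#'
#' @param matrix a [community_matrix()] over the ordination's stations.
#' @param ord a `zp_ordination`.
#' @param k how many taxa (default 10).
#' @return data.frame: `taxon`, position per axis, `total`, `influence`,
#'   sorted by decreasing influence.
#' @export
influential_taxa <- function(matrix, ord, k = 10L) {
  v <- matrix$values
  s <- ord$points
  stopifnot(identical(rownames(v), rownames(s)))
  tot <- colSums(v)
  pos <- matrix(0, ncol(v), ncol(s),
                dimnames = list(colnames(v), colnames(s)))
  nz <- tot > 0
  pos[nz, ] <- sweep(t(v[, nz, drop = FALSE]) %*% s, 1, tot[nz], `/`)
  infl <- tot * sqrt(rowSums(pos^2))
  ord_i <- order(-infl, colnames(v))
  top <- ord_i[seq_len(min(k, length(ord_i)))]
  data.frame(taxon = colnames(v)[top], pos[top, , drop = FALSE],
             total = tot[top], influence = infl[top],
             row.names = NULL, stringsAsFactors = FALSE)
}
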