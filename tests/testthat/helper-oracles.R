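# Naive reference implementations, independent of the package code paths.
# Deliberately written as plain double loops / enumerations.

naive_shannon <- function(x) {
  s <- 0
  tot <- sum(x)
  for (xi in x) {
    if (xi > 0) {
      p <- xi / tot
      s <- s - p * log(p)
    }
  }
  s
}

naive_jaccard <- function(a, b) {
  inter <- 0; un <- 0
  for (i in seq_along(a)) {
    pa <- a[i] > 0; pb <- b[i] > 0
    if (pa && pb) inter <- inter + 1
    if (pa || pb) un <- un + 1
  }
  if (un == 0) NA_real_ else inter / un
}

naive_bray <- function(a, b) {
  num <- 0; den <- 0
  for (i in seq_along(a)) {
    num <- num + abs(a[i] - b[i])
    den <- den + a[i] + b[i]
  }
  if (den == 0) NA_real_ else num / den
}

# exact-subset Venn counts by direct enumeration over all non-empty subsets
naive_venn <- function(pres, methods) {
  n_m <- length(methods)
  out <- integer(2^n_m - 1)
  names(out) <- vapply(seq_len(2^n_m - 1), function(b) {
    paste(methods[as.logical(bitwAnd(b, 2^(seq_len(n_m) - 1)))],
          collapse = "+")
  }, character(1))
  for (i in seq_len(nrow(pres))) {
    b <- sum(2^(which(pres[i, ]) - 1))
    if (b > 0) out[b] <- out[b] + 1L
  }
  out
}

# naive stress-1 for a configuration: isotonic fit done with stats::isoreg
# on the tie-averaged blocks (independent of the package PAVA)
naive_stress <- function(x, diss) {
  dhat <- as.vector(dist(x))
  dstar <- as.vector(as.dist(diss))
  ord <- order(dstar)
  y <- dhat[ord]
  g <- match(dstar[ord], unique(dstar[ord]))
  gm <- tapply(y, g, mean)
  gw <- tapply(y, g, length)
  # weighted PAVA via block expansion: repeat each group mean by its size
  # and run isoreg, then read one fitted value per block
  expanded <- rep(gm, gw)
  fit <- stats::isoreg(seq_along(expanded), expanded)$yf
  idx <- cumsum(gw)
  disp_g <- fit[idx]
  disp <- numeric(length(dhat))
  disp[ord] <- disp_g[g]
  sqrt(sum((dhat - disp)^2) / sum(dhat^2))
}

# brute-force nMDS: minimize naive_stress directly with optim from many
# random starts (no majorization, no package PAVA)
brute_nmds_stress <- function(diss, k = 2, n_starts = 40, seed = 99) {
  n <- nrow(diss)
  set.seed(seed)
  best <- Inf
  for (i in seq_len(n_starts)) {
    x0 <- if (i == 1) cmdscale(diss, k = k) else matrix(rnorm(n * k), n, k)
    res <- optim(as.vector(x0),
                 function(p) naive_stress(matrix(p, n, k), diss),
                 method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
    res2 <- optim(res$par,
                  function(p) naive_stress(matrix(p, n, k), diss),
                  method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, res2$value)
  }
  best
}

# Procrustes error after optimal rotation/reflection/translation/scale
procrustes_error <- function(x, target) {
  x <- scale(x, scale = FALSE)
  target <- scale(target, scale = FALSE)
  sv <- svd(t(target) %*% x)
  rot <- sv$v %*% t(sv$u)
  s <- sum(sv$d) / sum(x^2)
  sqrt(mean((x %*% rot * s - target)^2))
}

# small scenario used by fast pipeline tests (scaled-down depths/taxa so
# the suite stays well inside its runtime budget)
small_scenario <- function(seed = 1L) {
  scenario_config(seq_depth_range = c(2000L, 5000L),
                  singletons_per_fraction = 3L,
                  seed = seed)
}
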