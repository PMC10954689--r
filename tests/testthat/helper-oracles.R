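# Independent oracles and small fixtures used across the suite.

# Projected-gradient (FISTA) solver for
#   min_{w >= 0} 1/(2m) ||y - X w||^2 + alpha ||w||_1 + (alpha2/2) ||w||_2^2
# On the non-negative orthant the L1 term is linear, so the objective is
# smooth and accelerated projected gradient applies directly. Written without
# reference to the package's coordinate-descent path.
fista_nnen <- function(y, X, alpha, alpha2 = 0, maxit = 50000L, tol = 1e-12) {
  m <- nrow(X)
  G <- crossprod(X) / m
  b <- drop(crossprod(X, y)) / m
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) + alpha2
  w <- numeric(ncol(X))
  z <- w
  t_k <- 1
  for (it in seq_len(maxit)) {
    grad <- drop(G %*% z) - b + alpha + alpha2 * z
    w_new <- pmax(0, z - grad / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- w_new + ((t_k - 1) / t_new) * (w_new - w)
    if (max(abs(w_new - w)) < tol && it > 10L) { w <- w_new; break }
    w <- w_new
    t_k <- t_new
  }
  w
}

# objective value of the pixel problem, for solver comparisons
nnen_objective <- function(w, y, X, alpha, alpha2) {
  sum((y - X %*% w)^2) / (2 * nrow(X)) + alpha * sum(w) + alpha2 / 2 * sum(w^2)
}

# glmnet route (second independent solver). glmnet internally rescales the
# response by sqrt(mean(y^2)) when intercept = FALSE, which scales the
# effective ridge term; compensate so its objective matches the pixel
# problem exactly.
glmnet_nnen <- function(y, X, alpha, alpha2 = 0) {
  sy <- sqrt(mean(y^2))
  if (sy == 0) return(numeric(ncol(X)))
  lam <- alpha + alpha2 * sy
  fit <- glmnet::glmnet(X, y, lambda = lam, alpha = alpha / lam,
                        lower.limits = 0, intercept = FALSE,
                        standardize = FALSE, thresh = 1e-16, maxit = 1e7)
  as.numeric(stats::coef(fit))[-1L]
}

# tiny two-gene codebook with disjoint on-planes (orthogonal columns)
toy_codebook <- function() {
  codebook(c("geneA", "geneB"), c("132000", "000132"))
}

# codebook whose two barcodes share one on plane (correlated columns)
overlap_codebook <- function() {
  codebook(c("geneA", "geneB"), c("132000", "102300"))
}

# brute-force Hamming distance matrix straight from strings
string_distmat <- function(barcodes) {
  outer(barcodes, barcodes,
        Vectorize(function(a, b)
          sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])))
}

# brute-force enumeration of all compact strings, the count oracle
count_barcodes_bruteforce <- function(n, k, multicolor_only = FALSE) {
  digits <- expand.grid(rep(list(0:3), n))
  on <- rowSums(digits > 0) == k
  if (multicolor_only) {
    mono <- apply(digits, 1L, function(d) {
      ch <- d[d > 0]
      length(ch) > 0 && length(unique(ch)) == 1L
    })
    on <- on & !mono
  }
  sum(on)
}
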