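#' Enumerate compact combinatorial barcodes
#'
#' A compact barcode is an n-digit string over \{0,1,2,3\}: digit 0 marks an
#' off round, digits 1-3 name the fluorescent channel of an on round. Every
#' barcode is on in exactly `k` rounds, so there are choose(n,k) * 3^k of
#' them. With `multicolor_only = TRUE`, barcodes whose k on-rounds all use the
#' same channel are excluded (choose(n,k) * 3 fewer), since single-color
#' barcodes are indistinguishable from channel bleed-through artifacts.
#'
#' @param n number of decoding rounds (1 <= n <= 12).
#' @param k number of on rounds (1 <= k <= n).
#' @param multicolor_only drop barcodes using a single channel for all on
#'   rounds.
#' @return character vector of barcodes, sorted lexicographically.
#' @examples
#' length(enumerate_barcodes(6, 3))             # 540
#' length(enumerate_barcodes(6, 3, TRUE))       # 480
#' @export
enumerate_barcodes <- function(n, k, multicolor_only = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > 12 || n != round(n))
    stop("`n` must be a single integer in 1..12")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n || k != round(k))
    stop("`k` must be a single integer in 1..n")
  supports <- utils::combn(n, k)
  channels <- as.matrix(expand.grid(rep(list(1:3), k)))[, k:1, drop = FALSE]
  if (multicolor_only)
    channels <- channels[apply(channels, 1L, function(ch) length(unique(ch)) > 1L), ,
                         drop = FALSE]
  out <- character(ncol(supports) * nrow(channels))
  idx <- 1L
  for (s in seq_len(ncol(supports))) {
    base <- integer(n)
    for (r in seq_len(nrow(channels))) {
      b <- base
      b[supports[, s]] <- channels[r, ]
      out[idx] <- paste(b, collapse = "")
      idx <- idx + 1L
    }
  }
  sort(out)
}

#' Hamming distance between two compact barcodes
#'
#' @param a,b barcode strings of equal length.
#' @return integer count of differing digit positions.
#' @export
barcode_hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("barcodes must have equal length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# digits of a barcode vector as an L x n integer matrix
barcode_digits <- function(barcodes) {
  n <- unique(nchar(barcodes))
  if (length(n) != 1L) stop("barcodes must have uniform length")
  m <- matrix(0L, length(barcodes), n)
  for (j in seq_len(n)) m[, j] <- as.integer(substr(barcodes, j, j))
  m
}

# full pairwise Hamming distance matrix (small L only)
barcode_distmat <- function(barcodes) {
  d <- barcode_digits(barcodes)
  L <- nrow(d)
  out <- matrix(0L, L, L)
  for (j in seq_len(ncol(d))) out <- out + outer(d[, j], d[, j], "!=")
  out
}

#' Build the Hamming-distance-1 conflict graph over barcodes
#'
#' Nodes are barcodes; undirected edges connect pairs at Hamming distance
#' exactly 1 (same on-round support, one channel changed). Barcodes joined by
#' an edge are one hybridization error apart and must not co-occur in a
#' codebook.
#'
#' @param barcodes character vector of uniform-length compact barcodes.
#' @return an object of class `conflict_graph`: list with `barcodes`, `edges`
#'   (2-column integer matrix, i < j) and `adj` (adjacency list).
#' @export
conflict_graph <- function(barcodes) {
  if (anyDuplicated(barcodes)) stop("barcodes must be distinct")
  dm <- barcode_distmat(barcodes)
  idx <- which(dm == 1L & upper.tri(dm), arr.ind = TRUE)
  edges <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(edges) <- NULL
  adj <- rep(list(integer(0)), length(barcodes))
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  structure(list(barcodes = barcodes, edges = edges, adj = adj),
            class = "conflict_graph")
}

#' @export
print.conflict_graph <- function(x, ...) {
  cat("conflict graph:", length(x$barcodes), "barcodes,",
      nrow(x$edges), "distance-1 edges\n")
  invisible(x)
}

#' Greedy seed set of barcodes at pairwise Hamming distance > 2
#'
#' Repeated randomized greedy construction: scan the barcodes in a random
#' order, keeping each one whose distance to all kept barcodes exceeds 2, and
#' return the largest set over `n_restarts` orders. The result is maximal (no
#' remaining barcode can be added).
#'
#' @param barcodes character vector of uniform-length barcodes.
#' @param n_restarts number of random orders to try.
#' @param rng_seed integer seed; the search is deterministic given it.
#' @return character vector, a subset of `barcodes`.
#' @export
find_seed_set <- function(barcodes, n_restarts = 200L, rng_seed = 0L) {
  if (length(barcodes) == 0L) stop("barcode list must be non-empty")
  dm <- barcode_distmat(barcodes)
  ok <- dm > 2L
  diag(ok) <- TRUE
  L <- length(barcodes)
  best <- integer(0)
  with_seed(rng_seed, {
    for (r in seq_len(n_restarts)) {
      ord <- sample.int(L)
      kept <- integer(0)
      for (v in ord) if (all(ok[v, kept])) kept <- c(kept, v)
      if (length(kept) > length(best)) best <- kept
    }
  })
  sort(barcodes[best])
}

#' Randomized maximal independent set containing a seed set
#'
#' Runs a randomized maximal-independent-set construction on the conflict
#' graph `n_runs` times, always starting from the given seed set and adding
#' eligible nodes in a fresh uniformly random order. Because the conflict
#' graph is a disjoint union of per-support components and runs decompose
#' over components, the returned set unions, per component, the largest
#' sub-set seen in any run — itself a maximal independent set containing the
#' seed, and never smaller than the best single run. Members of the result
#' are pairwise at Hamming distance >= 2.
#'
#' @param graph a [conflict_graph()].
#' @param seed character vector of seed barcodes; must be an independent set.
#' @param n_runs number of randomized runs (20000 reproduces the design-scale
#'   search).
#' @param rng_seed integer seed.
#' @return character vector of barcodes (sorted), with attributes
#'   `mis_size`, `n_runs` and `rng_seed`.
#' @export
select_mis <- function(graph, seed = character(0), n_runs = 20000L, rng_seed = 0L) {
  stopifnot(inherits(graph, "conflict_graph"))
  sidx <- match(seed, graph$barcodes)
  if (anyNA(sidx)) stop("seed barcodes must be nodes of the graph")
  if (length(sidx) > 1L) {
    for (v in sidx)
      if (any(graph$adj[[v]] %in% sidx))
        stop("seed is not an independent set of the conflict graph")
  }
  comp <- graph_components(graph$adj)
  res <- with_seed(rng_seed,
                   cpp_mis_search(graph$adj, as.integer(sidx),
                                  as.integer(n_runs), comp - 1L))
  out <- sort(graph$barcodes[res$best])
  structure(out, mis_size = length(out), n_runs = n_runs, rng_seed = rng_seed,
            best_single_run = res$best_single_run)
}

#' Augment an independent set with extra barcodes minimizing new conflicts
#'
#' Draws `n_extra` barcodes from `pool` (excluding current members) uniformly
#' at random, `n_trials` times, and keeps the draw whose induced subgraph
#' (together with `mis`) has the fewest Hamming-distance-1 edges.
#'
#' @param mis character vector of barcodes already selected.
#' @param pool candidate barcodes.
#' @param n_extra how many barcodes to add.
#' @param n_trials number of random draws.
#' @param rng_seed integer seed.
#' @return character vector `mis` plus the chosen extras, with attribute
#'   `induced_edges` (edge count of the winning draw).
#' @export
augment_barcodes <- function(mis, pool, n_extra, n_trials = 20000L, rng_seed = 0L) {
  cand <- setdiff(pool, mis)
  if (n_extra > length(cand)) stop("pool has fewer than `n_extra` barcodes outside `mis`")
  if (n_extra == 0L) return(structure(mis, induced_edges = 0L))
  all_bc <- c(mis, cand)
  dm <- barcode_distmat(all_bc)
  nm <- length(mis)
  best <- NULL
  best_edges <- Inf
  with_seed(rng_seed, {
    for (t in seq_len(n_trials)) {
      pick <- sample.int(length(cand), n_extra)
      sel <- c(seq_len(nm), nm + pick)
      sub <- dm[sel, sel, drop = FALSE]
      ne <- sum(sub == 1L) / 2L
      if (ne < best_edges) {
        best_edges <- ne
        best <- pick
      }
    }
  })
  structure(c(mis, cand[best]), induced_edges = as.integer(best_edges))
}

#' Construct a codebook
#'
#' @param gene character vector of gene names (`Empty_<i>` allowed for
#'   explicit empties).
#' @param barcode compact barcodes, one per gene, uniform length, distinct.
#' @param is_empty logical flags; empty barcodes carry no probe and exist for
#'   false-positive control.
#' @return an object of class `codebook` with fields `n`, `k`, `genes`,
#'   `barcodes`, `is_empty` and the one-hot matrix `X` (3n x N, column i has
#'   1s at plane 3*(round-1)+channel for each on digit of barcode i).
#' @export
codebook <- function(gene, barcode, is_empty = rep(FALSE, length(gene))) {
  if (length(gene) != length(barcode) || length(gene) != length(is_empty))
    stop("gene, barcode and is_empty must have equal length")
  if (anyDuplicated(barcode)) stop("duplicate barcodes in codebook")
  if (anyDuplicated(gene[!is_empty])) stop("duplicate gene names in codebook")
  if (!all(grepl("^[0-3]+$", barcode)))
    stop("barcodes must be strings over the digits 0-3")
  n <- unique(nchar(barcode))
  if (length(n) != 1L) stop("barcodes must have uniform length")
  ks <- nchar(gsub("0", "", barcode))
  k <- unique(ks)
  if (length(k) != 1L) stop("all barcodes must have the same number of on rounds")
  X <- vapply(barcode, barcode_onehot, numeric(3L * n), n = n)
  dimnames(X) <- list(NULL, NULL)
  structure(list(n = as.integer(n), k = as.integer(k),
                 genes = as.character(gene), barcodes = as.character(barcode),
                 is_empty = as.logical(is_empty), X = X,
                 N = length(barcode)),
            class = "codebook")
}

#' One-hot encoding of a single compact barcode
#'
#' @param barcode compact barcode string.
#' @param n number of rounds (defaults to the barcode length).
#' @return numeric vector of length 3n with 1 at plane 3*(round-1)+channel
#'   for every on digit.
#' @export
barcode_onehot <- function(barcode, n = nchar(barcode)) {
  d <- as.integer(strsplit(barcode, "")[[1]])
  v <- numeric(3L * n)
  on <- which(d > 0L)
  v[3L * (on - 1L) + d[on]] <- 1
  v
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: %d barcodes (%d genes + %d empty), n = %d rounds, k = %d on\n",
              x$N, sum(!x$is_empty), sum(x$is_empty), x$n, x$k))
  invisible(x)
}

#' Randomly assign genes (and empties) to barcodes
#'
#' Draws `length(genes) + n_empty` barcodes from the supplied set and pairs
#' genes with barcodes uniformly at random; the remaining `n_empty` drawn
#' barcodes are flagged empty and named `Empty_<i>`.
#'
#' @param barcodes selected barcodes (at least `length(genes) + n_empty`).
#' @param genes character vector of gene names.
#' @param n_empty number of empty control barcodes.
#' @param rng_seed integer seed.
#' @return a [codebook()].
#' @export
assign_genes <- function(barcodes, genes, n_empty = 0L, rng_seed = 0L) {
  need <- length(genes) + n_empty
  if (length(barcodes) < need)
    stop(sprintf("need %d barcodes but only %d supplied", need, length(barcodes)))
  chosen <- with_seed(rng_seed, sample(barcodes, need))
  gene_all <- c(genes, if (n_empty > 0L) sprintf("Empty_%d", seq_len(n_empty)))
  empty_all <- c(rep(FALSE, length(genes)), rep(TRUE, n_empty))
  ord <- order(chosen)
  codebook(gene_all[ord], chosen[ord], empty_all[ord])
}

#' Design a codebook end to end
#'
#' Convenience pipeline: enumerate multicolor barcodes, build the seed set
#' (pairwise Hamming distance > 2), run the randomized maximal-independent-set
#' search, optionally top up with extra barcodes minimizing induced conflicts,
#' and randomly assign genes and empties.
#'
#' @param n,k rounds and on-rounds.
#' @param genes gene names.
#' @param n_empty number of empty barcodes.
#' @param n_runs randomized MIS runs (and augmentation trials).
#' @param rng_seed integer seed.
#' @return a [codebook()], with attribute `mis_size`.
#' @export
design_codebook <- function(n, k, genes, n_empty = 0L, n_runs = 20000L,
                            rng_seed = 0L) {
  pool <- enumerate_barcodes(n, k, multicolor_only = TRUE)
  g <- conflict_graph(pool)
  seed <- find_seed_set(pool, rng_seed = rng_seed)
  mis <- select_mis(g, seed, n_runs = n_runs, rng_seed = rng_seed)
  need <- length(genes) + n_empty
  sel <- as.character(mis)
  if (need > length(sel))
    sel <- augment_barcodes(sel, pool, need - length(sel), n_trials = n_runs,
                            rng_seed = rng_seed)
  cb <- assign_genes(as.character(sel), genes, n_empty, rng_seed = rng_seed)
  attr(cb, "mis_size") <- length(mis)
  cb
}

# connected-component labels (1-based) from an adjacency list, by BFS
graph_components <- function(adj) {
  n <- length(adj)
  comp <- integer(n)
  k <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    k <- k + 1L
    queue <- v
    comp[v] <- k
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[u]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  comp
}

# local, restore-on-exit seeding used by every randomized operation
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
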