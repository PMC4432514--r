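# Independent brute-force oracles used to cross-check the production
# algorithms on small instances. These deliberately share no code with
# the implementations in R/.

# Exhaustive single-linkage clustering of masses: start from singleton
# clusters and keep merging any two clusters whose closest pair of
# members lies within the relative tolerance, until no pair qualifies.
oracle_single_linkage <- function(masses, tolerance_ppm) {
  if (!length(masses)) return(list())
  clusters <- as.list(sort(masses))
  repeat {
    merged <- FALSE
    n <- length(clusters)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        pairs <- expand.grid(a = clusters[[i]], b = clusters[[j]])
        ok <- abs(pairs$a - pairs$b) <=
          tolerance_ppm * 1e-6 * (pairs$a + pairs$b) / 2
        if (any(ok)) {
          clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
          clusters <- clusters[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  clusters[order(vapply(clusters, mean, numeric(1)))]
}

# Maximum-cardinality bipartite matching between two mass lists under
# the relative tolerance, by exhaustive recursion over the first list.
oracle_max_matching <- function(a, b, tolerance_ppm) {
  admissible <- function(x, y) {
    abs(x - y) <= tolerance_ppm * 1e-6 * (x + y) / 2
  }
  rec <- function(i, used_b) {
    if (i > length(a)) return(0L)
    best <- rec(i + 1L, used_b)  # leave a[i] unmatched
    for (j in seq_along(b)) {
      if (!used_b[j] && admissible(a[i], b[j])) {
        used_b[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used_b))
        used_b[j] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(length(b)))
}

# Cophenetic (pairwise merge-height) distances of a mass_dendrogram,
# recomputed from the Newick export through ape; x2 converts heights to
# the original distance scale for comparison with stats::cophenetic on
# an hclust average-linkage fit.
dendrogram_cophenetic <- function(tree) {
  phy <- ape::read.tree(text = to_newick(tree))
  d <- as.matrix(ape::cophenetic.phylo(phy))
  d[order(rownames(d)), order(colnames(d))]
}

# n random masses in [lo, hi] whose pairwise relative gaps all exceed
# min_gap_ppm (so they satisfy the super_spectrum separation invariant).
spaced_masses <- function(n, lo, hi, min_gap_ppm = 1600) {
  cand <- sort(stats::runif(10 * n, lo, hi))
  keep <- numeric(0); last <- -Inf
  for (m in cand) {
    if (m - last > min_gap_ppm * 1e-6 * (m + last) / 2) {
      keep <- c(keep, m); last <- m
    }
  }
  stopifnot(length(keep) >= n)
  sort(sample(keep, n))
}

# All internal merge heights of a mass_dendrogram.
tree_heights <- function(node) {
  if (!is.null(node$label)) return(numeric(0))
  c(node$height, unlist(lapply(node$children, tree_heights)))
}

# Random valid distance matrix on n labelled leaves.
random_distance_matrix <- function(n) {
  labels <- LETTERS[seq_len(n)]
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- stats::runif(n * (n - 1) / 2, 0.05, 1)
  d[lower.tri(d)] <- vals
  d <- d + t(d)
  d
}

# Peak lists for a specimen with identical replicate mass lists.
make_specimen <- function(id, masses, n_reps = 4, species = "A") {
  reps <- lapply(seq_len(n_reps), function(r) peak_list(id, r, masses))
  specimen_record(id, species, replicates = reps)
}
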