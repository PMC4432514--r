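#' Dice similarity between two peak lists
#'
#' Presence/absence Dice coefficient on tolerance-matched masses:
#' `s = 2|M| / (|a| + |b|)` where `|M|` is the size of the injective
#' maximum injective match set between the two sorted mass lists within the
#' ppm tolerance. Intensities are never used. Two empty lists are
#' identical by convention (`s = 1`). The clustering distance is
#' `1 - s`.
#'
#' @param a,b [peak_list()] objects.
#' @param tolerance_ppm Relative tolerance in ppm, default 800.
#' @return Similarity in `[0, 1]`.
#' @examples
#' x <- peak_list("x", 1, c(4000, 5000, 6000))
#' y <- peak_list("y", 1, c(4001, 5000, 7000))
#' dice_similarity(x, y)  # 2 * 2 / 6
#' @export
dice_similarity <- function(a, b, tolerance_ppm = 800) {
  stopifnot(inherits(a, "peak_list"), inherits(b, "peak_list"))
  na <- length(a$masses); nb <- length(b$masses)
  if (na + nb == 0L) return(1)
  m <- match_masses(a$masses, b$masses, tolerance_ppm)
  2 * m$n / (na + nb)
}

#' Pairwise Dice distance matrix for a set of peak lists
#'
#' @param peaklists List of [peak_list()] objects, >= 2.
#' @param tolerance_ppm Relative tolerance in ppm, default 800.
#' @param labels Leaf labels; defaults to `specimen_id/rN` per list.
#' @return A symmetric numeric matrix of `1 - Dice` distances with zero
#'   diagonal and `labels` as dimnames.
#' @export
dice_distance_matrix <- function(peaklists, tolerance_ppm = 800,
                                 labels = NULL) {
  n <- length(peaklists)
  stopifnot(n >= 2)
  if (is.null(labels)) {
    labels <- vapply(peaklists, function(p)
      sprintf("%s/r%d", p$specimen_id, p$replicate_index), character(1))
  }
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <-
        1 - dice_similarity(peaklists[[i]], peaklists[[j]], tolerance_ppm)
    }
  }
  d
}

#' Paired-group (UPGMA) dendrogram from a distance matrix
#'
#' Standard unweighted pair-group method with arithmetic mean:
#' iteratively merge the pair of clusters at minimum distance, placing
#' the merge at height `d/2`, and update distances to the merged cluster
#' as the size-weighted average of the members' distances. Ties at the
#' minimum are broken by the lexicographically smallest label pair, so
#' the result is deterministic. The returned tree is ultrametric.
#'
#' @param d Symmetric distance matrix with dimnames (as from
#'   [dice_distance_matrix()]), >= 2 labels, zero diagonal.
#' @return An object of class `mass_dendrogram`: a recursive list with
#'   `label` (leaves), `children` + `height` (internal nodes).
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' to_newick(upgma(d))  # ((A:0.1,B:0.1):0.2,C:0.3);
#' @export
upgma <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2,
            !is.null(rownames(d)), isTRUE(all.equal(d, t(d))),
            all(diag(d) == 0))
  labels <- rownames(d)
  # active clusters: list of nodes; rep = lexicographically smallest leaf
  clusters <- lapply(labels, function(l)
    list(node = list(label = l, height = 0), size = 1L, rep = l))
  dm <- d
  while (length(clusters) > 1L) {
    n <- length(clusters)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        key <- sort(c(clusters[[i]]$rep, clusters[[j]]$rep))
        if (dm[i, j] < best_d ||
            (dm[i, j] == best_d &&
             (key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))) {
          best_d <- dm[i, j]; best <- c(i, j); best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    ci <- clusters[[i]]; cj <- clusters[[j]]
    # order children so the smaller representative prints first
    kids <- if (ci$rep <= cj$rep) list(ci$node, cj$node) else list(cj$node, ci$node)
    merged <- list(
      node = list(children = kids, height = best_d / 2),
      size = ci$size + cj$size,
      rep = min(ci$rep, cj$rep)
    )
    others <- setdiff(seq_len(n), c(i, j))
    new_row <- (ci$size * dm[i, others] + cj$size * dm[j, others]) /
      (ci$size + cj$size)
    dm <- dm[others, others, drop = FALSE]
    dm <- rbind(cbind(dm, new_row), c(new_row, 0))
    clusters <- c(clusters[others], list(merged))
  }
  structure(clusters[[1]]$node, class = "mass_dendrogram")
}

#' @export
print.mass_dendrogram <- function(x, ...) {
  cat("<mass_dendrogram>", to_newick(x), "\n")
  invisible(x)
}

#' Newick export of a dendrogram
#'
#' Branch lengths are differences of merge heights, so parsing the string
#' back (e.g. with `ape::read.tree`) reproduces the topology and the
#' ultrametric heights.
#'
#' @param t A `mass_dendrogram` from [upgma()].
#' @param digits Significant digits for branch lengths (default 10).
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(t, digits = 10) {
  stopifnot(inherits(t, "mass_dendrogram"))
  fmt <- function(x) format(x, digits = digits, trim = TRUE,
                            scientific = FALSE)
  rec <- function(node, parent_height) {
    if (!is.null(node$label)) {
      return(sprintf("%s:%s", node$label, fmt(parent_height)))
    }
    inner <- paste(vapply(node$children, rec, character(1),
                          parent_height = node$height), collapse = ",")
    if (is.na(parent_height)) {
      sprintf("(%s)", inner)
    } else {
      sprintf("(%s):%s", inner, fmt(parent_height - node$height))
    }
  }
  paste0(rec(t, NA_real_), ";")
}

#' Plot a dendrogram
#'
#' Renders via [ape::read.tree()] on the Newick export.
#'
#' @param x A `mass_dendrogram`.
#' @param ... Passed to `ape`'s `plot.phylo`.
#' @return The `phylo` object, invisibly.
#' @export
plot.mass_dendrogram <- function(x, ...) {
  tr <- ape::read.tree(text = to_newick(x))
  plot(tr, ...)
  invisible(tr)
}

#' Cluster peak lists by Dice distance with UPGMA
#'
#' Convenience wrapper: distance matrix, dendrogram and Newick string in
#' one call — the cluster analysis used to compare specimen groups (e.g.
#' colony versus field batches of one species), where storage-driven loss
#' of high-mass peaks can dominate the topology.
#'
#' @inheritParams dice_distance_matrix
#' @return A list with `distance` (matrix), `dendrogram`
#'   (`mass_dendrogram`) and `newick` (character).
#' @export
cluster_peaklists <- function(peaklists, tolerance_ppm = 800,
                              labels = NULL) {
  d <- dice_distance_matrix(peaklists, tolerance_ppm, labels)
  tr <- upgma(d)
  list(distance = d, dendrogram = tr, newick = to_newick(tr))
}
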