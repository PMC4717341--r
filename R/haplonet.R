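#' Collapse an alignment into haplotypes
#'
#' Two sequences belong to the same haplotype when they are identical at
#' every site where both carry an unambiguous A/C/G/T (ambiguities and gaps
#' are ignored in the comparison). Because this relation is not transitive
#' under missing data, assignment is greedy in input order: each sequence
#' joins the first already-established haplotype it matches, otherwise it
#' founds a new one. Haplotypes are numbered by first occurrence, so the
#' result is deterministic.
#'
#' @param x a [alignment()] object.
#' @param metadata optional data.frame with `sample_id` and `bird_id`
#'   columns; enables the per-bird composition summary.
#' @return An object of class `haplotype_table`: list with `haplotypes`
#'   (representative [alignment()] of the distinct sequences), `freq`,
#'   `membership` (haplotype -> sample ids) and `bird_composition`
#'   (haplotype -> table of bird ids), plus `n` total sequences.
#' @export
collapse_haplotypes <- function(x, metadata = NULL) {
  stopifnot(inherits(x, "coi_alignment"))
  code <- x$code
  n <- nrow(code)
  reps <- integer(0)                     # row index of each haplotype's founder
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (h in seq_along(reps)) {
      a <- code[reps[h], ]
      b <- code[i, ]
      ok <- !is.na(a) & !is.na(b)
      if (!any(a[ok] != b[ok])) { hit <- h; break }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      hit <- length(reps)
    }
    assign[i] <- hit
  }
  membership <- split(x$ids, factor(assign, levels = seq_along(reps)))
  names(membership) <- paste0("H", seq_along(reps))
  bird_comp <- NULL
  if (!is.null(metadata)) {
    birds <- metadata$bird_id[match(x$ids, metadata$sample_id)]
    bird_comp <- lapply(split(birds, factor(assign, levels = seq_along(reps))),
                        function(b) table(b[!is.na(b)]))
    names(bird_comp) <- names(membership)
  }
  structure(list(haplotypes = x[reps], freq = lengths(membership),
                 membership = membership, bird_composition = bird_comp,
                 n = n, assignment = stats::setNames(names(membership)[assign],
                                                     x$ids)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("%d haplotypes among %d sequences; freq: %s\n",
              length(x$freq), x$n, paste(x$freq, collapse = " ")))
  invisible(x)
}

# Hamming distance between haplotype representatives, pairwise deletion
.haplotype_distances <- function(table) {
  pairwise_differences_matrix <- function(aln) {
    if (nrow(aln$code) < 2L)
      return(matrix(0L, 1L, 1L))
    pairwise_differences(aln)$diffs
  }
  pairwise_differences_matrix(table$haplotypes)
}

#' Minimum-spanning haplotype network
#'
#' Builds the minimum spanning tree on pairwise Hamming distances between
#' haplotypes (Kruskal, edges sorted by (weight, smaller index, larger
#' index) for determinism) and records every non-tree pair whose distance
#' equals the bottleneck (the maximum edge weight on the tree path between
#' the pair) as an equal-weight alternative link - the reticulations a
#' purely tree-shaped drawing would hide.
#'
#' @param table a [collapse_haplotypes()] result.
#' @return An object of class `haplo_network`: list with `nodes`
#'   (data.frame: haplotype, freq), `tree_edges` and `alt_edges`
#'   (data.frames: from, to, weight), and `hub` (the modal haplotype,
#'   first-occurrence tie-break).
#' @export
build_network <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  H <- length(table$freq)
  nodes <- data.frame(haplotype = names(table$freq),
                      freq = as.integer(table$freq))
  hub <- names(table$freq)[which.max(table$freq)]
  empty <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0))
  if (H == 1L)
    return(structure(list(nodes = nodes, tree_edges = empty,
                          alt_edges = empty, hub = hub),
                     class = "haplo_network"))
  d <- .haplotype_distances(table)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs], pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  parent <- seq_len(H)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  tree <- matrix(0L, 0L, 2L)
  w <- numeric(0)
  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1L]; j <- pairs[e, 2L]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      tree <- rbind(tree, c(i, j))
      w <- c(w, d[i, j])
      if (nrow(tree) == H - 1L) break
    }
  }
  # bottleneck (max edge on tree path) between all node pairs, by BFS per node
  adj <- vector("list", H)
  for (e in seq_len(nrow(tree))) {
    i <- tree[e, 1L]; j <- tree[e, 2L]
    adj[[i]] <- rbind(adj[[i]], c(j, w[e]))
    adj[[j]] <- rbind(adj[[j]], c(i, w[e]))
  }
  bottleneck <- matrix(0, H, H)
  for (s in seq_len(H)) {
    seen <- rep(FALSE, H); seen[s] <- TRUE
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      for (r in seq_len(NROW(nb))) {
        u <- nb[r, 1L]
        if (!seen[u]) {
          seen[u] <- TRUE
          bottleneck[s, u] <- max(bottleneck[s, v], nb[r, 2L])
          queue <- c(queue, u)
        }
      }
    }
  }
  in_tree <- matrix(FALSE, H, H)
  in_tree[tree] <- TRUE
  in_tree <- in_tree | t(in_tree)
  alt <- which(upper.tri(d) & !in_tree & d == bottleneck, arr.ind = TRUE)
  hap <- names(table$freq)
  structure(list(nodes = nodes,
                 tree_edges = data.frame(from = hap[tree[, 1L]],
                                         to = hap[tree[, 2L]], weight = w),
                 alt_edges = data.frame(from = hap[alt[, 1L]],
                                        to = hap[alt[, 2L]],
                                        weight = d[alt]),
                 hub = hub),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplotype network: %d nodes, %d tree edges, %d alternative links; hub %s\n",
              nrow(x$nodes), nrow(x$tree_edges), nrow(x$alt_edges), x$hub))
  invisible(x)
}

#' Summarise a haplotype network
#'
#' Reports the number of haplotypes, Nei haplotype diversity
#' n/(n-1) (1 - sum p_h^2), the maximum number of conspecific mites sharing
#' one haplotype within a single bird (the vertical-transmission signature),
#' and `star_score` - the fraction of non-hub haplotypes whose spanning-tree
#' edge attaches directly to the modal haplotype. star_score is a diagnostic
#' of this package's own design, used to quantify the qualitative star-like
#' versus reticulated contrast; it plays no role in the regression.
#'
#' @param network a [build_network()] result.
#' @param table the matching [collapse_haplotypes()] table.
#' @return A one-row `data.frame`.
#' @export
network_summary <- function(network, table) {
  stopifnot(inherits(network, "haplo_network"),
            inherits(table, "haplotype_table"))
  n <- table$n
  p <- table$freq / n
  hap_div <- if (n > 1L) n / (n - 1) * (1 - sum(p^2)) else 0
  max_share <- NA_integer_
  if (!is.null(table$bird_composition))
    max_share <- max(vapply(table$bird_composition,
                            function(tb) if (length(tb)) max(tb) else 0L,
                            numeric(1L)))
  H <- nrow(network$nodes)
  star <- NA_real_
  if (H > 1L) {
    deg_hub <- sum(network$tree_edges$from == network$hub |
                     network$tree_edges$to == network$hub)
    star <- deg_hub / (H - 1L)
  }
  data.frame(n_haplotypes = H, haplotype_diversity = hap_div,
             max_within_bird_sharing = as.integer(max_share),
             star_score = star)
}

#' Plot a haplotype network
#'
#' Nodes are placed by classical multidimensional scaling of the tree path
#' distances, sized by sqrt(frequency), and partitioned into pie slices by
#' host bird when a bird composition is available. Alternative equal-weight
#' links are drawn dashed.
#'
#' @param x a [build_network()] result.
#' @param table the matching [collapse_haplotypes()] table.
#' @param ... passed to [graphics::plot()].
#' @export
plot.haplo_network <- function(x, table = NULL, ...) {
  H <- nrow(x$nodes)
  if (H == 1L) {
    graphics::plot(0, 0, pch = 16, cex = 3, axes = FALSE, xlab = "",
                   ylab = "", ...)
    graphics::text(0, 0, x$nodes$haplotype, pos = 3, offset = 1.5)
    return(invisible(x))
  }
  idx <- stats::setNames(seq_len(H), x$nodes$haplotype)
  d <- matrix(0, H, H)
  g <- cbind(idx[x$tree_edges$from], idx[x$tree_edges$to])
  # tree path lengths via repeated BFS
  adj <- vector("list", H)
  for (e in seq_len(nrow(g))) {
    adj[[g[e, 1]]] <- rbind(adj[[g[e, 1]]], c(g[e, 2], x$tree_edges$weight[e]))
    adj[[g[e, 2]]] <- rbind(adj[[g[e, 2]]], c(g[e, 1], x$tree_edges$weight[e]))
  }
  for (s in seq_len(H)) {
    dist <- rep(NA_real_, H); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      for (r in seq_len(NROW(nb)))
        if (is.na(dist[nb[r, 1]])) {
          dist[nb[r, 1]] <- dist[v] + nb[r, 2]
          queue <- c(queue, nb[r, 1])
        }
    }
    d[s, ] <- dist
  }
  xy <- stats::cmdscale(stats::as.dist(d), k = 2)
  if (NCOL(xy) < 2) xy <- cbind(xy, 0)
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 asp = 1, ...)
  for (e in seq_len(nrow(x$tree_edges)))
    graphics::segments(xy[g[e, 1], 1], xy[g[e, 1], 2],
                       xy[g[e, 2], 1], xy[g[e, 2], 2])
  if (nrow(x$alt_edges))
    for (e in seq_len(nrow(x$alt_edges)))
      graphics::segments(xy[idx[x$alt_edges$from[e]], 1],
                         xy[idx[x$alt_edges$from[e]], 2],
                         xy[idx[x$alt_edges$to[e]], 1],
                         xy[idx[x$alt_edges$to[e]], 2], lty = 2)
  cex <- 1.5 * sqrt(x$nodes$freq / max(x$nodes$freq)) + 0.8
  if (!is.null(table) && !is.null(table$bird_composition)) {
    for (h in seq_len(H)) {
      comp <- table$bird_composition[[x$nodes$haplotype[h]]]
      .pie_node(xy[h, 1], xy[h, 2], 0.05 * cex[h] * diff(range(xy[, 1]) + 1e-9),
                as.numeric(comp),
                grDevices::hcl.colors(max(2L, length(comp)), "Dark 3"))
    }
  } else {
    graphics::points(xy, pch = 21, bg = "grey80", cex = cex * 2)
  }
  invisible(x)
}

.pie_node <- function(cx, cy, r, counts, cols) {
  if (!length(counts) || sum(counts) == 0) counts <- 1
  ang <- c(0, cumsum(counts) / sum(counts)) * 2 * pi
  for (k in seq_along(counts)) {
    th <- seq(ang[k], ang[k + 1], length.out = 24)
    graphics::polygon(c(cx, cx + r * cos(th)), c(cy, cy + r * sin(th)),
                      col = cols[(k - 1L) %% length(cols) + 1L], border = NA)
  }
}
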