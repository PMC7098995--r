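# Saitou-Nei neighbor joining and column-resampling bootstrap.

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimising the
#' rate-corrected criterion Q(i,j) = (n-2) d(i,j) - r(i) - r(j) is joined,
#' with ties broken on the lexicographically smallest label pair (internal
#' nodes inherit the smallest leaf label of their clade). Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch, so the joined pair's path length is preserved.
#'
#' @param dm A `k2p_dist`, a base `dist`, or a symmetric labelled matrix with
#'   at least 3 taxa.
#' @return An (arbitrarily rooted) `ape::phylo` tree; use
#'   [ape::root()] on an outgroup for display.
#' @export
nj_tree <- function(dm) {
  d <- dist_to_matrix(dm)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  labels <- rownames(d)
  frag <- labels          # newick fragment per active node
  key <- labels           # tie-break key: smallest leaf label in clade
  active <- seq_len(n)
  while (length(active) > 3L) {
    m <- length(active)
    dd <- d[active, active, drop = FALSE]
    r <- rowSums(dd)
    q <- (m - 2) * dd - outer(r, r, "+")
    diag(q) <- Inf
    best <- which(q <= min(q) + 1e-12, arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    if (nrow(best) > 1L) {
      pair_keys <- apply(best, 1L, function(ij) {
        ks <- sort(c(key[active[ij[1L]]], key[active[ij[2L]]]))
        paste(ks, collapse = "\r")
      })
      best <- best[order(pair_keys)[1L], , drop = FALSE]
    }
    i <- active[best[1L, 1L]]
    j <- active[best[1L, 2L]]
    ri <- r[[best[1L, 1L]]]
    rj <- r[[best[1L, 2L]]]
    dij <- d[i, j]
    bi <- dij / 2 + (ri - rj) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    # new node replaces i; distances by the standard reduction
    others <- setdiff(active, c(i, j))
    d[i, others] <- d[others, i] <- (d[i, others] + d[j, others] - dij) / 2
    frag[[i]] <- sprintf("(%s:%s,%s:%s)", frag[[i]], fmt_bl(bi),
                         frag[[j]], fmt_bl(bj))
    key[[i]] <- min(key[[i]], key[[j]])
    active <- setdiff(active, j)
  }
  x <- active[[1L]]; y <- active[[2L]]; z <- active[[3L]]
  bx <- max((d[x, y] + d[x, z] - d[y, z]) / 2, 0)
  by <- max((d[x, y] + d[y, z] - d[x, z]) / 2, 0)
  bz <- max((d[x, z] + d[y, z] - d[x, y]) / 2, 0)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[[x]], fmt_bl(bx), frag[[y]], fmt_bl(by),
                    frag[[z]], fmt_bl(bz))
  ape::read.tree(text = newick)
}

fmt_bl <- function(b) format(b, digits = 12, scientific = FALSE)

dist_to_matrix <- function(dm) {
  if (inherits(dm, "k2p_dist")) return(dm$distance)
  if (inherits(dm, "dist")) return(as.matrix(dm))
  m <- as.matrix(dm)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  m
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the K2P/NJ tree
#' for each replicate, and annotates each internal bipartition of the
#' point-estimate tree with the percentage of replicates containing it
#' (rounded to the nearest integer; bipartitions absent from the point tree
#' are not reported). Deterministic given `seed`.
#'
#' @param alignment Aligned sequences, as accepted by
#'   [k2p_distance_matrix()]; at least 3 rows.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed driving the column resampling.
#' @return An `ape::phylo` tree whose `node.label` holds integer support
#'   percentages (root label empty).
#' @export
bootstrap_support <- function(alignment, n_replicates = 100, seed = 1) {
  al <- as_alignment_tbl(alignment)
  if (nrow(al) < 3L) stop("bootstrap needs an alignment with >= 3 rows", call. = FALSE)
  stopifnot(n_replicates >= 1)
  ncol_aln <- nchar(al$sequence[[1L]])
  codes <- encode_bases(al$sequence)
  rownames(codes) <- al$label
  point <- nj_tree(k2p_distance_matrix(al))
  point_parts <- bipartitions(point)
  counts <- setNames(integer(length(point_parts)), names(point_parts))
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      sub <- codes[, cols, drop = FALSE]
      dm <- codes_distance_matrix(sub, al$label)
      tr <- nj_tree(dm)
      rep_parts <- names(bipartitions(tr))
      hit <- names(counts) %in% rep_parts
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- round(100 * counts / n_replicates)
  point$node.label <- vapply(seq_len(point$Nnode), function(i) {
    node <- ape::Ntip(point) + i
    k <- node_key(point, node)
    if (is.na(k) || !k %in% names(support)) "" else
      as.character(support[[k]])
  }, "")
  point
}

# distance matrix straight from integer-coded columns (bootstrap fast path)
codes_distance_matrix <- function(codes, labels) {
  n <- nrow(codes)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- k2p_from_codes(codes[i, ], codes[j, ])$distance
    }
  }
  structure(list(labels = labels, distance = d,
                 comparable_sites = NULL), class = "k2p_dist")
}

# Canonical keys for the non-trivial bipartitions of an unrooted tree:
# for each internal node, the tip set below it, represented by whichever
# side does not contain the alphabetically first tip.
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- vapply(seq_along(parts), function(i) {
    side <- sort(tree$tip.label[parts[[i]]])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) return(NA_character_)
    if (tips[[1L]] %in% side) side <- setdiff(tips, side)
    paste(side, collapse = "\r")
  }, "")
  names(parts) <- keys
  parts[!is.na(keys)]
}

node_key <- function(tree, node) {
  below <- sort(tree$tip.label[unlist(phangorn_descendants(tree, node))])
  tips <- sort(tree$tip.label)
  if (length(below) <= 1L || length(below) >= length(tips) - 1L) return(NA_character_)
  if (tips[[1L]] %in% below) below <- setdiff(tips, below)
  paste(below, collapse = "\r")
}

# tips below an internal node (simple edge walk; avoids extra deps)
phangorn_descendants <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Does a set of tips form a clade (bipartition) of the tree?
#'
#' Tests presence of the tip set as one side of an internal bipartition of
#' the unrooted tree.
#'
#' @param tree An `ape::phylo`.
#' @param tips Character vector of tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic_split <- function(tree, tips) {
  tips <- sort(tips)
  all_tips <- sort(tree$tip.label)
  if (length(tips) <= 1L) return(TRUE)
  side <- if (all_tips[[1L]] %in% tips) setdiff(all_tips, tips) else tips
  key <- paste(side, collapse = "\r")
  key %in% names(bipartitions(tree))
}

#' Write a tree with support labels to Newick
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
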