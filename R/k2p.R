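# Kimura 2-parameter distances and barcoding-gap statistics.

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Comparable columns are those where both rows carry an unambiguous base
#' (pairwise gap deletion: columns with a gap or N in either row are
#' excluded). With transition fraction P and transversion fraction Q over
#' the L comparable columns,
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).}
#'
#' @param aligned_a,aligned_b Equal-length gapped nucleotide strings.
#' @return A list with `distance` (substitutions/site) and
#'   `comparable_sites` (number of columns used).
#' @examples
#' k2p_distance("ACGT", "ACGA")
#' @export
k2p_distance <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  m <- encode_bases(c(aligned_a, aligned_b))
  k2p_from_codes(m[1L, ], m[2L, ])
}

# A=1 C=2 G=3 T=4, anything else NA; rows are sequences
encode_bases <- function(seqs) {
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  codes <- match(chars, c("A", "C", "G", "T"))
  dim(codes) <- dim(chars)
  codes
}

k2p_from_codes <- function(x, y, label = NULL) {
  ok <- !is.na(x) & !is.na(y)
  L <- sum(ok)
  if (L == 0L) {
    stop("no comparable columns", if (!is.null(label)) paste0(" for pair ", label),
         call. = FALSE)
  }
  xs <- x[ok]; ys <- y[ok]
  diff <- xs != ys
  purine_x <- xs == 1L | xs == 3L
  purine_y <- ys == 1L | ys == 3L
  P <- sum(diff & purine_x == purine_y) / L  # transitions: A<->G, C<->T
  Q <- sum(diff & purine_x != purine_y) / L  # transversions
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P distance saturated (log argument <= 0)",
         if (!is.null(label)) paste0(" for pair ", label), call. = FALSE)
  }
  list(distance = -0.5 * log(w1) - 0.25 * log(w2), comparable_sites = L)
}

#' Pairwise K2P distance matrix for an aligned sequence set
#'
#' @param alignment A tibble with columns `label` and `sequence` (equal
#'   aligned lengths), a named character vector, or a `DNAStringSet`.
#' @return An object of class `k2p_dist`: list with `labels`, `distance`
#'   (symmetric matrix, substitutions/site) and `comparable_sites`
#'   (per-pair column counts after pairwise gap deletion).
#' @export
k2p_distance_matrix <- function(alignment) {
  al <- as_alignment_tbl(alignment)
  if (length(unique(nchar(al$sequence))) != 1L) {
    stop("sequences must share one aligned length", call. = FALSE)
  }
  n <- nrow(al)
  codes <- encode_bases(al$sequence)
  d <- matrix(0, n, n, dimnames = list(al$label, al$label))
  L <- matrix(nchar(al$sequence[[1L]]), n, n,
              dimnames = list(al$label, al$label))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        res <- k2p_from_codes(codes[i, ], codes[j, ],
                              label = paste(al$label[i], al$label[j], sep = "/"))
        d[i, j] <- d[j, i] <- res$distance
        L[i, j] <- L[j, i] <- res$comparable_sites
      }
    }
  }
  structure(list(labels = al$label, distance = d, comparable_sites = L),
            class = "k2p_dist")
}

as_alignment_tbl <- function(alignment) {
  if (inherits(alignment, "DNAStringSet")) {
    return(tibble(label = names(alignment),
                  sequence = unname(as.character(alignment))))
  }
  if (is.character(alignment)) {
    if (is.null(names(alignment))) {
      stop("character alignments must be named", call. = FALSE)
    }
    return(tibble(label = names(alignment), sequence = unname(alignment)))
  }
  al <- as_tibble(alignment)
  stopifnot(all(c("label", "sequence") %in% names(al)))
  al
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("K2P distance matrix,", length(x$labels), "sequences\n")
  print(round(x$distance, 4))
  invisible(x)
}

#' @export
as.matrix.k2p_dist <- function(x, ...) x$distance

#' @rdname k2p_distance_matrix
#' @param x A `k2p_dist` object.
#' @param ... Unused.
#' @export
tidy.k2p_dist <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$distance), arr.ind = TRUE)
  tibble(
    a = x$labels[idx[, 1L]],
    b = x$labels[idx[, 2L]],
    distance = x$distance[idx],
    comparable_sites = x$comparable_sites[idx]
  )
}

#' Write a PHYLIP-style square distance matrix
#'
#' @param dm A `k2p_dist`.
#' @param path Output TSV path.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "k2p_dist"))
  tab <- as_tibble(as.data.frame(dm$distance), rownames = "label")
  readr::write_tsv(tab, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Barcoding gap

#' Barcoding-gap report
#'
#' Compares the largest within-group distance against the smallest
#' between-group distance. The gap is present when the minimum inter-group
#' distance exceeds every (defined) maximum intra-group distance; singleton
#' groups have no intra statistic and are reported as `NA`.
#'
#' @param dm A `k2p_dist`.
#' @param groups Tibble with columns `label` and `group` covering every
#'   label in `dm`.
#' @param exclude Group labels left out of the statistics entirely
#'   (default `outgroup` and `contaminant`, which are not barcode groups:
#'   an "intra" distance within a bin of assorted outgroup species is
#'   meaningless).
#' @return An object of class `gap_report`.
#' @export
barcoding_gap <- function(dm, groups, exclude = c("outgroup", "contaminant")) {
  stopifnot(inherits(dm, "k2p_dist"))
  groups <- as_tibble(groups)
  stopifnot(all(c("label", "group") %in% names(groups)))
  missing <- setdiff(dm$labels, groups$label)
  if (length(missing)) {
    stop("group map missing labels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grp <- groups$group[match(dm$labels, groups$label)]
  keep <- !grp %in% exclude
  if (any(!keep)) {
    d_keep <- dm$distance[keep, keep, drop = FALSE]
    dm <- structure(list(labels = dm$labels[keep], distance = d_keep,
                         comparable_sites = NULL), class = "k2p_dist")
    grp <- grp[keep]
  }
  if (length(unique(grp)) < 2L) stop("need at least two groups", call. = FALSE)
  d <- dm$distance
  n <- length(dm$labels)
  same <- outer(grp, grp, "==")
  ut <- upper.tri(d)
  intra <- lapply(split(seq_len(n), grp), function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    max(d[idx, idx][upper.tri(d[idx, idx])])
  })
  intra_tbl <- tibble(
    group = names(intra),
    n = as.integer(table(grp)[names(intra)]),
    max_intra = unlist(intra)
  )
  min_inter <- min(d[ut & !same])
  defined <- intra_tbl$max_intra[!is.na(intra_tbl$max_intra)]
  gap_present <- if (length(defined)) min_inter > max(defined) else min_inter > 0
  structure(
    list(intra = intra_tbl, min_inter = min_inter, gap_present = gap_present),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Barcoding gap report\n")
  for (i in seq_len(nrow(x$intra))) {
    cat(sprintf("  max intra %-12s (n=%d): %s\n", x$intra$group[i],
                x$intra$n[i],
                ifelse(is.na(x$intra$max_intra[i]), "undefined",
                       format(round(x$intra$max_intra[i], 4)))))
  }
  cat(sprintf("  min inter: %s\n  gap present: %s\n",
              format(round(x$min_inter, 4)), x$gap_present))
  invisible(x)
}

#' @rdname barcoding_gap
#' @param x A `gap_report`.
#' @param ... Unused.
#' @export
tidy.gap_report <- function(x, ...) x$intra

#' @rdname barcoding_gap
#' @export
glance.gap_report <- function(x, ...) {
  tibble(
    min_inter = x$min_inter,
    max_intra = suppressWarnings(max(x$intra$max_intra, na.rm = TRUE)),
    gap_present = x$gap_present
  )
}

#' Distance histogram split into intra- and inter-group comparisons
#'
#' @param object A `gap_report` is not enough to re-draw distances, so this
#'   method plots the per-group maxima against the minimum inter-group
#'   distance.
#' @param ... Unused.
#' @export
autoplot.gap_report <- function(object, ...) {
  df <- object$intra %>% filter(!is.na(.data$max_intra))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$max_intra)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_hline(yintercept = object$min_inter,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      y = "K2P distance (substitutions/site)", x = NULL,
      title = "Barcoding gap",
      subtitle = sprintf("dashed = minimum inter-group distance (%.4f); gap %s",
                         object$min_inter,
                         ifelse(object$gap_present, "present", "absent"))
    )
}
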