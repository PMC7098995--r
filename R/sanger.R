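# Sanger trace model: four-channel chromatograms, ambiguity-aware base
# calling, bidirectional assembly and A/B/C purity classification.

#' Construct a chromatogram from per-position channel intensities
#'
#' @param intensities Tibble (or data frame) with columns `pos`, `A`, `C`,
#'   `G`, `T`; every position must carry at least one positive channel.
#' @param sample_id,direction Metadata carried as attributes.
#' @return A `chromatogram` tibble.
#' @export
chromatogram <- function(intensities, sample_id = NA_character_,
                         direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  x <- as_tibble(intensities)
  stopifnot(all(c("pos", "A", "C", "G", "T") %in% names(x)))
  m <- as.matrix(x[, c("A", "C", "G", "T")])
  if (any(m < 0)) stop("negative channel intensity", call. = FALSE)
  structure(x, class = c("chromatogram", class(tibble())),
            sample_id = sample_id, direction = direction)
}

#' Read / write a chromatogram as TSV (`pos  A  C  G  T`)
#'
#' @param path TSV path.
#' @param sample_id,direction Metadata for the object read back.
#' @export
read_chromatogram <- function(path, sample_id = NA_character_,
                              direction = "forward") {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(pos = "i", .default = "d"))
  chromatogram(x, sample_id = sample_id, direction = direction)
}

#' @rdname read_chromatogram
#' @param chrom A `chromatogram`.
#' @export
write_chromatogram <- function(chrom, path) {
  readr::write_tsv(as_tibble(chrom), path)
  invisible(path)
}

#' Call bases from a chromatogram with IUPAC ambiguity codes
#'
#' Per position the strongest channel is the primary base; when the
#' second-strongest channel reaches `ambiguity_threshold` times the primary
#' intensity the two-base IUPAC code is emitted instead (e.g. A+G -> R) and
#' the position is recorded as heterozygous.
#'
#' @param chrom A `chromatogram`.
#' @param ambiguity_threshold Secondary/primary intensity ratio in (0,1)
#'   above which a secondary peak is called (default 0.25).
#' @return A `trace_call`: list with `sequence`, `het_positions`,
#'   `secondary_ratio` and the source metadata.
#' @export
call_bases <- function(chrom, ambiguity_threshold = 0.25) {
  stopifnot(inherits(chrom, "chromatogram"),
            ambiguity_threshold > 0, ambiguity_threshold < 1)
  m <- as.matrix(as_tibble(chrom)[, c("A", "C", "G", "T")])
  if (any(rowSums(m) == 0)) {
    stop("all-zero intensity at position ",
         which(rowSums(m) == 0)[[1L]], call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  prim_idx <- max.col(m, ties.method = "first")
  prim <- m[cbind(seq_len(nrow(m)), prim_idx)]
  m2 <- m
  m2[cbind(seq_len(nrow(m)), prim_idx)] <- -Inf
  sec_idx <- max.col(m2, ties.method = "first")
  sec <- m[cbind(seq_len(nrow(m)), sec_idx)]
  ratio <- ifelse(prim > 0, pmax(sec, 0) / prim, 0)
  het <- ratio >= ambiguity_threshold
  calls <- ifelse(het,
                  mapply(function(i, j) iupac_code(bases[c(i, j)]),
                         prim_idx, sec_idx),
                  bases[prim_idx])
  structure(
    list(
      sequence = paste(calls, collapse = ""),
      het_positions = which(het),
      secondary_ratio = ratio,
      sample_id = attr(chrom, "sample_id"),
      direction = attr(chrom, "direction")
    ),
    class = "trace_call"
  )
}

#' @export
print.trace_call <- function(x, ...) {
  cat("Trace call (", nchar(x$sequence), " nt, ",
      length(x$het_positions), " heterozygous)\n", sep = "")
  invisible(x)
}

#' @rdname call_bases
#' @param x A `trace_call`.
#' @param ... Unused.
#' @export
tidy.trace_call <- function(x, ...) {
  tibble(
    pos = seq_len(nchar(x$sequence)),
    base = seq_chars(x$sequence),
    secondary_ratio = x$secondary_ratio,
    het = seq_len(nchar(x$sequence)) %in% x$het_positions
  )
}

#' Assemble forward and reverse trace calls into a consensus
#'
#' The reverse call is reverse-complemented, globally aligned to the forward
#' call, and merged column-wise: agreeing columns emit the base, columns
#' where one read is gapped emit the other read's base, disagreements
#' resolve to the IUPAC code of the intersection of the two base sets, or N
#' when the sets are disjoint.
#'
#' @param fwd,rev `trace_call` objects (or plain IUPAC strings); `rev` is in
#'   reverse-strand orientation.
#' @param min_overlap_identity Minimum IUPAC-compatible identity of the
#'   aligned reads (default 0.8); below it assembly fails with an error.
#' @return Consensus sequence (character scalar).
#' @export
assemble_bidirectional <- function(fwd, rev, min_overlap_identity = 0.8) {
  f <- if (inherits(fwd, "trace_call")) fwd$sequence else fwd
  r <- if (inherits(rev, "trace_call")) rev$sequence else rev
  r <- revcomp(r)
  al <- align_pair(f, r)
  ident <- alignment_identity(al$aligned_a, al$aligned_b, iupac = TRUE)
  if (ident < min_overlap_identity) {
    stop(sprintf("reads do not assemble (overlap identity %.3f < %.2f)",
                 ident, min_overlap_identity), call. = FALSE)
  }
  ca <- seq_chars(al$aligned_a)
  cb <- seq_chars(al$aligned_b)
  merged <- mapply(function(a, b) {
    if (a == b) return(a)
    if (a == "-") return(b)
    if (b == "-") return(a)
    common <- intersect(iupac_set(a), iupac_set(b))
    if (length(common) == 0L) "N" else iupac_code(common)
  }, ca, cb, USE.NAMES = FALSE)
  paste(merged, collapse = "")
}

#' Classify a Sanger trace into purity types A, B or C
#'
#' Type A traces are clean (heterozygous fraction at most `f_a`); type B
#' traces carry a limited number of secondary peaks (fraction at most `f_b`)
#' without the run of nested peaks that a length-shifting indel produces;
#' everything else is type C. The nested score is the heterozygous fraction
#' among positions downstream of the known inter-group indel column, where a
#' 1-bp length difference between co-amplified templates phase-shifts every
#' later peak.
#'
#' @param call A `trace_call`.
#' @param sites A `site_table`; its indel entry anchors the nested-score
#'   window (no indel entry: nested score 0).
#' @param f_a,f_b,s_c Classification thresholds (defaults 0.005, 0.05, 0.3).
#' @return One-row tibble: `sample_id`, `label` (A/B/C), `het_fraction`,
#'   `nested_score`.
#' @export
classify_trace <- function(call, sites, f_a = 0.005, f_b = 0.05, s_c = 0.3) {
  stopifnot(inherits(call, "trace_call"))
  n <- nchar(call$sequence)
  het_fraction <- length(call$het_positions) / n
  indel_cols <- sites$position[sites$kind == "indel"]
  if (length(indel_cols)) {
    brk <- min(indel_cols)
    downstream <- max(n - brk, 1L)
    nested_score <- sum(call$het_positions > brk) / downstream
  } else {
    nested_score <- 0
  }
  label <- if (het_fraction <= f_a) "A"
  else if (het_fraction <= f_b && nested_score < s_c) "B"
  else "C"
  tibble(sample_id = call$sample_id %||% NA_character_, label = label,
         het_fraction = het_fraction, nested_score = nested_score)
}

#' Plot a chromatogram's four channels
#'
#' @param object A `chromatogram`.
#' @param ... Unused.
#' @export
autoplot.chromatogram <- function(object, ...) {
  df <- as_tibble(object) %>%
    tidyr::pivot_longer(c("A", "C", "G", "T"),
                        names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$intensity,
                                   colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(A = "#2e7d32", C = "#1565c0",
                                            G = "#424242", T = "#c62828")) +
    ggplot2::labs(x = "position", y = "intensity",
                  title = attr(object, "sample_id") %||% "chromatogram")
}
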