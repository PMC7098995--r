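# Single-end amplicon metabarcoding: FASTQ IO, tag demultiplexing,
# quality filtering, anchor-based ITS2 trimming, dereplication, taxonomic
# assignment and per-sample composition tables.

#' Read a Phred+33 FASTQ file into a tibble
#'
#' @param path FASTQ path.
#' @return Tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' @rdname read_fastq
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Demultiplex tagged reads into per-sample batches
#'
#' Each read is assigned to the unique sample whose 10-bp tag matches the
#' read's first 10 bases within `max_mismatch` substitutions; the tag is
#' then removed from sequence and quality. Reads matching no tag, or more
#' than one, go to the `unassigned` bin with their tag left in place. The
#' resulting partition is exhaustive and disjoint.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param manifest Tibble with columns `sample_id`, `tag` (tags must be
#'   pairwise more than `max_mismatch` substitutions apart).
#' @param max_mismatch Allowed tag mismatches (default 0, exact matching).
#' @return The reads tibble with a `sample_id` column (`"unassigned"` for
#'   the bin) and tags stripped from assigned reads.
#' @export
demultiplex <- function(reads, manifest, max_mismatch = 0) {
  reads <- as_tibble(reads)
  manifest <- as_tibble(manifest)
  stopifnot(all(c("sample_id", "tag") %in% names(manifest)))
  tags <- toupper(manifest$tag)
  if (any(nchar(tags) != 10L)) stop("tags must be exactly 10 bases", call. = FALSE)
  tag_len <- 10L
  if (nrow(manifest) > 1L) {
    tm <- do.call(rbind, strsplit(tags, ""))
    for (i in seq_len(nrow(tm) - 1L)) {
      for (j in seq(i + 1L, nrow(tm))) {
        if (sum(tm[i, ] != tm[j, ]) <= max_mismatch) {
          stop("colliding tags: ", tags[i], " / ", tags[j], call. = FALSE)
        }
      }
    }
  }
  observed <- toupper(substr(reads$sequence, 1L, tag_len))
  if (max_mismatch == 0) {
    idx <- match(observed, tags)
  } else {
    om <- do.call(rbind, strsplit(observed, ""))
    idx <- rep(NA_integer_, nrow(reads))
    mism <- sapply(seq_along(tags), function(k) {
      rowSums(om != matrix(strsplit(tags[k], "")[[1L]],
                           nrow(om), tag_len, byrow = TRUE))
    })
    mism <- matrix(mism, nrow = nrow(reads))
    hits <- mism <= max_mismatch
    n_hits <- rowSums(hits)
    ok <- n_hits == 1L
    idx[ok] <- apply(hits[ok, , drop = FALSE], 1L, which)
  }
  assigned <- !is.na(idx)
  reads$sample_id <- ifelse(assigned, manifest$sample_id[idx], "unassigned")
  reads$sequence[assigned] <- substring(reads$sequence[assigned], tag_len + 1L)
  reads$quality[assigned] <- substring(reads$quality[assigned], tag_len + 1L)
  reads
}

#' Remove short and low-quality reads
#'
#' Retains reads with length `>= min_length` and arithmetic mean Phred score
#' `>= min_avg_qv`; order-preserving and idempotent.
#'
#' @param reads Tibble with `sequence`, `quality`.
#' @param min_length Minimum retained length (default 300).
#' @param min_avg_qv Minimum retained mean quality (default 30).
#' @return Filtered reads tibble.
#' @export
quality_filter <- function(reads, min_length = 300, min_avg_qv = 30) {
  reads <- as_tibble(reads)
  keep <- nchar(reads$sequence) >= min_length & mean_qv(reads$quality) >= min_avg_qv
  reads[keep, , drop = FALSE]
}

#' Anchor model for ITS2 extraction
#'
#' Position-specific match-count matrices over the conserved 25-bp tails of
#' the 5.8S gene and heads of the 28S gene that flank ITS2. A window scores
#' 1 per matching base; an anchor is accepted when its score reaches
#' `width - max_mismatch`.
#'
#' @param anchor5,anchor3 Anchor sequences (defaults: the package's
#'   conserved flank models).
#' @param max_mismatch Substitutions tolerated per anchor (default 2).
#' @return An `anchor_model` list with the two PWMs and score thresholds.
#' @export
its2_anchor_model <- function(anchor5 = its2_flanks()$anchor5,
                              anchor3 = its2_flanks()$anchor3,
                              max_mismatch = 2) {
  list(
    pwm5 = anchor_pwm(anchor5), pwm3 = anchor_pwm(anchor3),
    min_score5 = nchar(anchor5) - max_mismatch,
    min_score3 = nchar(anchor3) - max_mismatch
  )
}

anchor_pwm <- function(anchor) {
  chars <- seq_chars(toupper(anchor))
  pwm <- matrix(0, 4L, length(chars),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(chars)) pwm[chars[[i]], i] <- 1
  pwm
}

#' Extract the ITS2 region between rRNA anchor matches
#'
#' Scans each sequence (and its reverse complement) for the best-scoring
#' non-overlapping 5.8S-tail / 28S-head anchor pair and returns the enclosed
#' region. Failure (either anchor below threshold on both strands) is a
#' value, not an error: the corresponding row carries `NA`.
#'
#' @param x Character vector of sequences, or a tibble with a `sequence`
#'   column (other columns are preserved).
#' @param model An [its2_anchor_model()].
#' @return Tibble with columns `its2`, `its2_start`, `its2_end`, `strand`
#'   appended (coordinates on the scanned strand).
#' @export
extract_its2 <- function(x, model = its2_anchor_model()) {
  tbl <- if (is.character(x)) tibble(sequence = x) else as_tibble(x)
  stopifnot("sequence" %in% names(tbl))
  uniq <- unique(tbl$sequence)
  res <- lapply(uniq, extract_its2_one, model = model)
  res <- do.call(rbind, res)
  idx <- match(tbl$sequence, uniq)
  tbl$its2 <- unname(res[idx, "its2"])
  tbl$its2_start <- as.integer(unname(res[idx, "start"]))
  tbl$its2_end <- as.integer(unname(res[idx, "end"]))
  tbl$strand <- unname(res[idx, "strand"])
  tbl
}

extract_its2_one <- function(seq, model) {
  fail <- c(its2 = NA_character_, start = NA, end = NA, strand = NA_character_)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) return(fail)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    subj <- Biostrings::DNAString(s)
    h5 <- Biostrings::matchPWM(model$pwm5, subj, min.score = model$min_score5)
    if (length(h5) == 0L) next
    h3 <- Biostrings::matchPWM(model$pwm3, subj, min.score = model$min_score3)
    if (length(h3) == 0L) next
    s5 <- Biostrings::PWMscoreStartingAt(model$pwm5, subj, BiocGenerics::start(h5))
    s3 <- Biostrings::PWMscoreStartingAt(model$pwm3, subj, BiocGenerics::start(h3))
    best <- NULL
    for (i in order(-s5)) {
      e5 <- BiocGenerics::end(h5)[i]
      ok3 <- which(BiocGenerics::start(h3) > e5 + 1L)
      if (length(ok3) == 0L) next
      j <- ok3[which.max(s3[ok3])]
      cand <- list(score = s5[i] + s3[j], start = e5 + 1L,
                   end = BiocGenerics::start(h3)[j] - 1L)
      if (is.null(best) || cand$score > best$score) best <- cand
    }
    if (!is.null(best)) {
      return(c(its2 = substr(s, best$start, best$end),
               start = best$start, end = best$end, strand = strand))
    }
  }
  fail
}

#' Collapse identical reads into abundance clusters
#'
#' Exact-string dereplication per sample. Clusters with fewer than
#' `min_count` members are discarded (default 11, i.e. unique sequences with
#' more than 10 repetitions are retained). Output is sorted by sample, then
#' descending count, ties broken by sequence lexicographic order.
#'
#' @param reads Tibble with columns `sample_id` and `sequence` (typically
#'   the ITS2-trimmed reads).
#' @param min_count Minimum retained cluster size (default 11).
#' @return Tibble with columns `sample_id`, `sequence`, `count`.
#' @export
dereplicate <- function(reads, min_count = 11) {
  reads <- as_tibble(reads)
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "sample"
  reads %>%
    dplyr::count(.data$sample_id, .data$sequence, name = "count") %>%
    filter(.data$count >= min_count) %>%
    arrange(.data$sample_id, dplyr::desc(.data$count), .data$sequence)
}

#' Assign a taxon to each dereplicated cluster
#'
#' Every cluster is globally aligned to every reference ITS2 sequence. When
#' the best hit belongs to one of the two focal subspecies groups the call
#' is refined with [call_subspecies()]; otherwise the best reference's taxon
#' is reported if its identity reaches `min_identity_genus`, else
#' `unassigned`.
#'
#' @param clusters Tibble from [dereplicate()].
#' @param db A `ref_db`.
#' @param sites A `site_table` for the focal groups.
#' @param min_identity_subspecies,min_identity_genus Identity thresholds,
#'   see [call_subspecies()].
#' @return `clusters` with `taxon_id`, `taxon` and `identity` columns.
#' @export
assign_taxon <- function(clusters, db, sites,
                         min_identity_subspecies = 0.99,
                         min_identity_genus = 0.90) {
  stopifnot(inherits(db, "ref_db"))
  clusters <- as_tibble(clusters)
  refs <- db$sequences
  focal_groups <- c(attr(sites, "group_a"), attr(sites, "group_b"))
  uniq <- unique(clusters$sequence)
  ident <- matrix(NA_real_, length(uniq), nrow(refs))
  for (k in seq_len(nrow(refs))) {
    ident[, k] <- identities_vs_subject(uniq, refs$its2[[k]])
  }
  assign_one <- function(u) {
    best_k <- which.max(ident[u, ])
    best_id <- ident[u, best_k]
    taxon <- refs$taxon_id[[best_k]]
    if (best_id < min_identity_genus) {
      tibble(taxon_id = "unassigned", identity = best_id)
    } else if (refs$group[[best_k]] %in% focal_groups) {
      call <- call_subspecies(uniq[[u]], db, sites,
                              min_identity_subspecies = min_identity_subspecies,
                              min_identity_genus = min_identity_genus)
      tibble(taxon_id = call$called_taxon, identity = call$best_identity)
    } else if (best_id >= min_identity_genus) {
      tibble(taxon_id = taxon, identity = best_id)
    } else {
      tibble(taxon_id = "unassigned", identity = best_id)
    }
  }
  res <- purrr::map_dfr(seq_along(uniq), assign_one)
  idx <- match(clusters$sequence, uniq)
  clusters$taxon_id <- res$taxon_id[idx]
  clusters$identity <- res$identity[idx]
  clusters$taxon <- taxon_name(db, clusters$taxon_id)
  clusters
}

# pretty scientific name for a taxon_id; pass through pseudo-taxa
taxon_name <- function(db, taxon_id) {
  nm <- db$taxa$name[match(taxon_id, db$taxa$taxon_id)]
  ifelse(is.na(nm), taxon_id, nm)
}

#' Per-sample species composition table
#'
#' @param assignments Tibble from [assign_taxon()] (columns `sample_id`,
#'   `taxon`, `count`).
#' @return A `composition_tbl`: tibble of `sample_id`, `taxon`, `reads`,
#'   `proportion` (proportions sum to 1 per sample over retained clusters).
#' @export
composition_table <- function(assignments) {
  out <- as_tibble(assignments) %>%
    group_by(.data$sample_id, .data$taxon) %>%
    summarise(reads = sum(.data$count), .groups = "drop_last") %>%
    mutate(proportion = .data$reads / sum(.data$reads)) %>%
    ungroup() %>%
    arrange(.data$sample_id, dplyr::desc(.data$reads))
  class(out) <- c("composition_tbl", class(out))
  out
}

#' Stacked composition bar plot
#'
#' @param object A `composition_tbl`.
#' @param ... Unused.
#' @export
autoplot.composition_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                               fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of retained reads",
                  title = "Metabarcoding composition") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Run the full metabarcoding pipeline on a tagged read set
#'
#' demultiplex -> quality filter -> ITS2 extraction -> dereplication ->
#' taxonomic assignment -> composition, with a per-stage read-count log.
#'
#' @param reads Tibble of tagged reads (`read_id`, `sequence`, `quality`)
#'   or a FASTQ path.
#' @param manifest Tag manifest (`sample_id`, `tag`).
#' @param db,sites Reference database and site table.
#' @param max_mismatch,min_length,min_avg_qv,min_count Stage parameters
#'   (defaults 0, 300, 30, 11).
#' @param model Anchor model for ITS2 extraction.
#' @return List with `composition`, `clusters`, and `log` (tibble of stage
#'   read counts).
#' @export
run_metabarcoding <- function(reads, manifest, db, sites,
                              max_mismatch = 0, min_length = 300,
                              min_avg_qv = 30, min_count = 11,
                              model = its2_anchor_model()) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  log <- list(c(stage = "input", reads = nrow(reads)))
  dm <- demultiplex(reads, manifest, max_mismatch = max_mismatch)
  batch <- dm %>% filter(.data$sample_id != "unassigned")
  log <- c(log, list(c(stage = "demultiplexed", reads = nrow(batch))))
  batch <- quality_filter(batch, min_length = min_length, min_avg_qv = min_avg_qv)
  log <- c(log, list(c(stage = "quality_filtered", reads = nrow(batch))))
  batch <- extract_its2(batch, model = model) %>%
    filter(!is.na(.data$its2)) %>%
    mutate(sequence = .data$its2)
  log <- c(log, list(c(stage = "its2_extracted", reads = nrow(batch))))
  clusters <- dereplicate(batch, min_count = min_count)
  log <- c(log, list(c(stage = "dereplicated_reads", reads = sum(clusters$count))))
  clusters <- assign_taxon(clusters, db, sites)
  comp <- composition_table(clusters)
  log_tbl <- tibble(
    stage = vapply(log, `[[`, "", "stage"),
    reads = as.integer(vapply(log, `[[`, "", "reads"))
  )
  list(composition = comp, clusters = clusters, log = log_tbl)
}
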