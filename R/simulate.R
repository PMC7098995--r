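# Synthetic-data generator: reference sets carrying the reported diagnostic
# sites, tagged FASTQ read batches with errors and contaminants, mixture
# chromatograms, and the study-scale sample panels. All outputs are pure
# functions of (design, seed).

# Conserved rRNA flanks shared by every simulated amplicon: a 115-bp 5.8S
# tail and a 116-bp 28S head. They are fixed package constants (the anchor
# model in its2_anchor_model() is built from their boundary 25-mers), chosen
# so the lobata full amplicon is exactly 115 + 246 + 116 = 477 bases.
its2_flanks <- function() {
  flank5 <- paste0(
    "AATCTTACCCATACTACGGACGTACTGCACGTATAAGGGGTCCGGTTTTATGATCTAGCT",
    "CGCTACCGGTCTGTGGGGCCCCAGCGCAAGCCTACCCTAGGAGTTGGCCTAAACC")
  flank3 <- paste0(
    "TTCCCATTCCATCGTTTGCCCTGAAACCGGTGTGAGTGAGACGTGACTGTCTGGGGCGCG",
    "CGATAGACGAATTCGGCCCTTGATGACTCGCAAGTGCAGCAGAGGATCTGCACAAG")
  list(
    flank5 = flank5, flank3 = flank3,
    anchor5 = substr(flank5, nchar(flank5) - 24L, nchar(flank5)),
    anchor3 = substr(flank3, 1L, 25L)
  )
}

#' Simulate the bundled ITS2 reference set
#'
#' Emits two near-identical subspecies haplotype groups: a 247-bp thomsonii
#' ITS2 and a 246-bp lobata ITS2 identical except for a 1-bp indel at
#' alignment column 29 (thomsonii carries T, lobata the gap) and three SNPs
#' at columns 52 (A/G), 201 (C/T) and 244 (T/G); a second lobata haplotype
#' carries G at column 244, so that site is intraspecifically polymorphic.
#' Each ITS2 is embedded in the package's conserved 5.8S/28S flanks (the
#' lobata amplicon is exactly 477 bases). Two outgroup species are ~4%
#' divergent over ITS2, three contaminant taxa (Aspergillus, Hordeum
#' vulgare, Rosa) ~25% divergent. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, writes
#'   `references.fasta`, `taxonomy.tsv`, `sites.tsv` (diagnostic-site ground
#'   truth) and `alignment.fasta` (full-amplicon alignment).
#' @return A `reference_set`: list with `db` (a [reference_db()]),
#'   `alignment` (tibble `label`, `sequence`, `group` of aligned full
#'   amplicons), and `truth` (site table and haplotype bookkeeping).
#' @export
make_references <- function(seed = 1, out_dir = NULL) {
  withr::with_seed(as.integer(seed), {
    fl <- its2_flanks()
    # thomsonii ITS2 backbone, 247 bp; its coordinates ARE the alignment
    # columns of the subspecies consensus alignment (lobata holds the gap)
    th <- seq_chars(random_dna(247))
    th[27:31] <- c("A", "C", "T", "G", "A")  # unambiguous 1-bp indel context
    th[52] <- "G"; th[201] <- "T"; th[244] <- "G"
    lob <- th[-29L]
    lob[51] <- "A"; lob[200] <- "C"; lob[243] <- "T"
    lob2 <- lob
    lob2[243] <- "G"   # intraspecific T/G polymorphism at column 244
    th_its2 <- paste(th, collapse = "")
    lob_its2 <- paste(lob, collapse = "")
    lob2_its2 <- paste(lob2, collapse = "")

    # Congeneric outgroups share a common ancestor ~3% off the subspecies
    # pair and then diverge from each other, as two real sister species
    # would. The ancestor branches off *between* the subspecies (ancestral
    # state lobata-like at column 52, thomsonii-like elsewhere): each
    # subspecies clade then shares at least one substitution of its own
    # (thomsonii: 52, lobata: 201), keeping both clade edges at positive
    # length in a distance tree; the indel is invisible to K2P under
    # pairwise deletion and the intra-polymorphic column 244 cannot anchor
    # a clade.
    subsp_anc <- th
    subsp_anc[52] <- "A"
    outgroup_anc <- mutate_its2(paste(subsp_anc, collapse = ""), rate = 0.03)
    outgroup1 <- mutate_its2(outgroup_anc, rate = 0.008)
    outgroup2 <- mutate_its2(outgroup_anc, rate = 0.012)
    aspergillus <- mutate_its2(th_its2, rate = 0.25)
    hordeum <- mutate_its2(th_its2, rate = 0.25)
    rosa <- mutate_its2(th_its2, rate = 0.25)

    amplicon <- function(its2) paste0(fl$flank5, its2, fl$flank3)
    seqs <- tibble(
      seq_id = c("lob1", "lob2", "lob3", "th1", "th2",
                 "tuberosa1", "candollei1", "asp1", "hv1", "rosa1"),
      taxon_id = c("lobata", "lobata", "lobata", "thomsonii", "thomsonii",
                   "tuberosa", "candollei", "aspergillus", "hordeum", "rosa"),
      its2_seq = c(lob_its2, lob_its2, lob2_its2, th_its2, th_its2,
                   outgroup1, outgroup2, aspergillus, hordeum, rosa)
    ) %>%
      mutate(
        sequence = amplicon(.data$its2_seq),
        its2_start = nchar(fl$flank5) + 1L,
        its2_end = nchar(fl$flank5) + nchar(.data$its2_seq)
      ) %>%
      select(-"its2_seq")

    taxa <- tibble(
      taxon_id = c("lobata", "thomsonii", "tuberosa", "candollei",
                   "aspergillus", "hordeum", "rosa"),
      name = c("Pueraria montana var. lobata",
               "Pueraria montana var. thomsonii",
               "Pueraria tuberosa", "Pueraria candollei",
               "Aspergillus sp.", "Hordeum vulgare", "Rosa sp."),
      rank = c("variety", "variety", "species", "species",
               "genus", "species", "genus"),
      group = c("lobata", "thomsonii", "outgroup", "outgroup",
                "contaminant", "contaminant", "contaminant")
    )
    db <- reference_db(seqs, taxa)

    # full-amplicon alignment in thomsonii-amplicon coordinates (478
    # columns); the lobata haplotypes carry the single gap column
    gap_col <- nchar(fl$flank5) + 29L
    insert_gap <- function(s) {
      paste0(substr(s, 1L, gap_col - 1L), "-",
             substr(s, gap_col, nchar(s)))
    }
    alignment <- tibble(
      label = seqs$seq_id,
      sequence = ifelse(seqs$taxon_id == "lobata",
                        vapply(seqs$sequence, insert_gap, ""),
                        seqs$sequence),
      group = taxa$group[match(seqs$taxon_id, taxa$taxon_id)]
    )

    truth_sites <- new_site_table(
      tibble(
        position = c(29L, 52L, 201L, 244L),
        kind = c("indel", "snp", "snp", "snp"),
        state_a = c("-", "A", "C", "T"),
        state_b = c("T", "G", "T", "G"),
        intra_polymorphic = c(FALSE, FALSE, FALSE, TRUE),
        weight = c(1, 1, 1, 0.25)
      ),
      "lobata", "thomsonii"
    )

    res <- structure(
      list(
        db = db,
        alignment = alignment,
        truth = list(
          sites = truth_sites,
          its2_lengths = c(lobata = 246L, thomsonii = 247L),
          lobata_haplotypes = c(lob_its2, lob2_its2)
        )
      ),
      class = "reference_set"
    )
  })
  if (!is.null(out_dir)) write_reference_set(res, out_dir)
  res
}

# substitution-only divergence over the ITS2 interior (flanks stay conserved)
mutate_its2 <- function(its2, rate) {
  chars <- seq_chars(its2)
  n_mut <- max(1L, round(rate * length(chars)))
  pos <- sample(seq_along(chars), n_mut)
  bases <- c("A", "C", "G", "T")
  chars[pos] <- vapply(chars[pos],
                       function(b) sample(setdiff(bases, b), 1L), "")
  paste(chars, collapse = "")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Simulated ITS2 reference set\n")
  print(x$db)
  invisible(x)
}

write_reference_set <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- res$db$sequences
  write_fasta(setNames(seqs$sequence, seqs$seq_id),
              file.path(out_dir, "references.fasta"))
  tax <- res$db$sequences %>%
    select("seq_id", "taxon_id") %>%
    dplyr::left_join(res$db$taxa, by = "taxon_id")
  readr::write_tsv(tax, file.path(out_dir, "taxonomy.tsv"))
  write_site_table(res$truth$sites, file.path(out_dir, "sites.tsv"))
  write_fasta(setNames(res$alignment$sequence, res$alignment$label),
              file.path(out_dir, "alignment.fasta"))
  readr::write_tsv(
    res$alignment %>% select("label", "group"),
    file.path(out_dir, "groups.tsv"))
  invisible(out_dir)
}

write_fasta <- function(named_seqs, path) {
  # DNAStringSet rejects "-"-free? it accepts gaps; use it for formatting
  x <- Biostrings::DNAStringSet(named_seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Specify a synthetic sample
#'
#' @param sample_id Sample identifier.
#' @param label_taxon Taxon printed on the product label.
#' @param true_composition Named numeric vector of taxon proportions
#'   (must sum to 1).
#' @param n_reads Reads to simulate for metabarcoded samples (0 otherwise).
#' @param tag 10-bp sample tag (metabarcoded samples).
#' @param product_type One of `raw_material`, `food`, `herbal`.
#' @param error_rate Per-base substitution probability in simulated reads.
#' @param low_qv_fraction Fraction of reads drawn from the low-quality state
#'   (mean Q ~12, removed by the default QV filter).
#' @return One-row tibble with `true_composition` as a list column.
#' @export
sample_spec <- function(sample_id, label_taxon, true_composition,
                        n_reads = 0, tag = NA_character_,
                        product_type = c("raw_material", "food", "herbal"),
                        error_rate = 0.002, low_qv_fraction = 0.1) {
  product_type <- match.arg(product_type)
  stopifnot(abs(sum(true_composition) - 1) < 1e-9, n_reads >= 0)
  tibble(
    sample_id = sample_id, label_taxon = label_taxon,
    true_composition = list(true_composition),
    n_reads = as.integer(n_reads), tag = tag,
    product_type = product_type, error_rate = error_rate,
    low_qv_fraction = low_qv_fraction
  )
}

#' Simulate a tagged FASTQ read batch for one sample
#'
#' Draws `n_reads` template assignments from the sample's true composition
#' (multinomial), picks a haplotype uniformly among the taxon's reference
#' amplicons, plants per-base substitution errors at `error_rate`, prepends
#' the sample tag, and assigns per-base Phred values from a two-state model:
#' good reads ~ N(35, 3), low-quality reads (probability
#' `low_qv_fraction`) ~ N(12, 2), so the latter fail a mean-QV-30 filter.
#' Deterministic per seed.
#'
#' @param spec One-row tibble from [sample_spec()].
#' @param refs A `reference_set` from [make_references()].
#' @param seed Integer seed.
#' @return Tibble of reads with truth columns `taxon_true` and `low_qv`.
#' @export
simulate_reads <- function(spec, refs, seed = 1) {
  stopifnot(inherits(refs, "reference_set"))
  comp <- spec$true_composition[[1L]]
  missing <- setdiff(names(comp), refs$db$taxa$taxon_id)
  if (length(missing)) {
    stop("composition taxa absent from references: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- spec$n_reads
  withr::with_seed(as.integer(seed), {
    counts <- as.vector(rmultinom(1L, n, comp))
    taxon_of_read <- rep(names(comp), counts)
    seqs <- character(n)
    for (i in seq_len(n)) {
      cand <- refs$db$sequences$sequence[
        refs$db$sequences$taxon_id == taxon_of_read[[i]]]
      tpl <- cand[[sample.int(length(cand), 1L)]]
      seqs[[i]] <- plant_errors(tpl, spec$error_rate)
    }
    low <- stats::runif(n) < spec$low_qv_fraction
    qual <- character(n)
    for (i in seq_len(n)) {
      len <- nchar(seqs[[i]]) + 10L
      qv <- if (low[[i]]) rnorm(len, 12, 2) else rnorm(len, 35, 3)
      qual[[i]] <- phred_encode(pmin(pmax(round(qv), 2), 41))
    }
    tibble(
      read_id = sprintf("%s_%05d", spec$sample_id, seq_len(n)),
      sequence = paste0(spec$tag, seqs),
      quality = qual,
      taxon_true = taxon_of_read,
      low_qv = low
    )
  })
}

plant_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- seq_chars(seq)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(setdiff(bases, b), 1L), "")
  }
  paste(chars, collapse = "")
}

#' Simulate a Sanger chromatogram of a (possibly mixed) template pool
#'
#' Each template contributes `100 * proportion` intensity to its base's
#' channel at every position. Templates of unequal length are laid down
#' from position 1 without re-alignment, so a 1-bp indel between
#' co-amplified templates phase-shifts every downstream contribution (the
#' mechanism behind nested peaks in mixed traces). Gaussian noise with the
#' given sd is added to all four channels and clipped at zero.
#'
#' @param composition Named numeric vector of taxon proportions (sum 1);
#'   the first reference sequence of each taxon provides its template.
#' @param refs A `reference_set`.
#' @param noise_sd Channel noise standard deviation on the 0-100 intensity
#'   scale (default 3.5).
#' @param seed Integer seed.
#' @param direction `forward` or `reverse` (reverse traces read the
#'   reverse-complemented templates, so the phase shift runs from the other
#'   end).
#' @param sample_id Metadata label.
#' @return A `chromatogram`.
#' @export
simulate_chromatogram <- function(composition, refs, noise_sd = 3.5, seed = 1,
                                  direction = c("forward", "reverse"),
                                  sample_id = NA_character_) {
  direction <- match.arg(direction)
  stopifnot(abs(sum(composition) - 1) < 1e-9)
  templates <- vapply(names(composition), function(tx) {
    cand <- refs$db$sequences$its2[refs$db$sequences$taxon_id == tx]
    if (length(cand) == 0L) stop("no reference for taxon ", tx, call. = FALSE)
    cand[[1L]]
  }, "")
  if (direction == "reverse") templates <- revcomp(templates)
  L <- max(nchar(templates))
  m <- matrix(0, L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (k in seq_along(templates)) {
    chars <- seq_chars(templates[[k]])
    idx <- match(chars, c("A", "C", "G", "T"))
    ok <- !is.na(idx)
    m[cbind(which(ok), idx[ok])] <-
      m[cbind(which(ok), idx[ok])] + 100 * composition[[k]]
  }
  withr::with_seed(as.integer(seed), {
    m <- pmax(m + matrix(rnorm(length(m), 0, noise_sd), nrow(m)), 0)
  })
  chromatogram(tibble(pos = seq_len(L), A = m[, 1L], C = m[, 2L],
                      G = m[, 3L], T = m[, 4L]),
               sample_id = sample_id, direction = direction)
}

#' Generate the full study-scale fixture panel
#'
#' Builds (a) 30 raw-material Sanger samples whose labels and true taxa
#' follow the study's verification table (samples 1-19 labelled and truly
#' lobata, 20-28 labelled and truly thomsonii, 29-30 labelled lobata but
#' truly thomsonii); (b) 10 Gegen Powder food samples, 5 truly lobata and 5
#' truly thomsonii; (c) 12 Yufeng Ningxin herbal samples: 9 pure, 2 mixed at
#' 85:15 (lobata:thomsonii within the amplifiable fraction) and 1 at 50:50,
#' the three metabarcoded ones carrying Aspergillus reads plus Rosa (B-type
#' sample) or Hordeum vulgare (C-type sample). Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param refs A `reference_set`; defaults to `make_references(seed)`.
#' @param n_reads Reads per metabarcoded sample (default 3000).
#' @param noise_sd Chromatogram noise sd (default 3.5).
#' @param error_rate Read substitution error rate (default 0.002).
#' @param out_dir Optional run directory to write all fixture files
#'   (reference files, chromatogram TSVs, tagged FASTQ, manifests, truth
#'   JSON).
#' @return A `study_design`: list with `samples` (spec tibble),
#'   `chromatograms` (named list of forward/reverse `chromatogram` pairs),
#'   `reads` (tagged read tibble for the metabarcoded samples), `manifest`
#'   (sample/tag table) and `refs`.
#' @export
make_study_fixtures <- function(seed = 1, refs = make_references(seed),
                                n_reads = 3000, noise_sd = 3.5,
                                error_rate = 0.002, out_dir = NULL) {
  seed <- as.integer(seed)
  pure <- function(tx) setNames(1, tx)

  raw <- purrr::map_dfr(1:30, function(i) {
    label <- if (i <= 19L || i >= 29L) "lobata" else "thomsonii"
    truth <- if (i <= 19L) "lobata" else "thomsonii"
    sample_spec(sprintf("HSMS%04d", i), label, pure(truth),
                product_type = "raw_material")
  })
  food <- purrr::map_dfr(1:10, function(i) {
    truth <- if (i <= 5L) "lobata" else "thomsonii"
    sample_spec(sprintf("HSFS%04d", i), "lobata", pure(truth),
                product_type = "food")
  })
  tags <- c(HSZY1006 = "ACGTACGTAC", HSZY1009 = "TGCATGCATG",
            HSZY1003 = "GATCGATCGA")
  herbal_comp <- list(
    HSZY1001 = pure("lobata"), HSZY1002 = pure("lobata"),
    HSZY1004 = pure("thomsonii"), HSZY1005 = pure("lobata"),
    HSZY1006 = c(lobata = 0.88, aspergillus = 0.12),
    HSZY1007 = pure("lobata"), HSZY1008 = pure("lobata"),
    HSZY1009 = c(lobata = 0.70, thomsonii = 0.12, rosa = 0.08,
                 aspergillus = 0.10),
    HSZY1010 = pure("thomsonii"), HSZY1011 = pure("lobata"),
    HSZY1012 = c(lobata = 0.85, thomsonii = 0.15),
    HSZY1003 = c(thomsonii = 0.30, lobata = 0.20, hordeum = 0.30,
                 aspergillus = 0.20)
  )
  herbal <- purrr::map_dfr(names(herbal_comp), function(id) {
    sample_spec(id, "lobata", herbal_comp[[id]],
                n_reads = if (id %in% names(tags)) n_reads else 0,
                tag = if (id %in% names(tags)) tags[[id]] else NA_character_,
                product_type = "herbal", error_rate = error_rate)
  })
  samples <- dplyr::bind_rows(raw, food, herbal)

  # Per-sample chromatograms of the amplifiable (Pueraria) fraction. Mixed
  # traces are sampled conditional on realizing their designed purity class
  # (the study's own samples are defined by their observed trace type), so
  # a bounded number of redraws is allowed; pure and 50:50-ish mixtures
  # classify deterministically and never redraw in practice.
  truth_sites <- refs$truth$sites
  chroms <- list()
  trace_truth <- character(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sp <- samples[i, ]
    comp <- sp$true_composition[[1L]]
    pu <- comp[names(comp) %in% c("lobata", "thomsonii")]
    pu <- pu / sum(pu)
    designed <- designed_trace_class(pu)
    trace_truth[[i]] <- designed
    sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
    fwd <- NULL
    for (attempt in 0:49) {
      cand <- simulate_chromatogram(pu, refs, noise_sd = noise_sd,
                                    seed = sub_seed + 101L * attempt,
                                    direction = "forward",
                                    sample_id = sp$sample_id)
      got <- classify_trace(call_bases(cand), truth_sites)$label
      if (got == designed) { fwd <- cand; break }
    }
    if (is.null(fwd)) {
      stop("could not realize a type-", designed, " trace for ",
           sp$sample_id, call. = FALSE)
    }
    chroms[[sp$sample_id]] <- list(
      fwd = fwd,
      rev = simulate_chromatogram(pu, refs, noise_sd = noise_sd,
                                  seed = sub_seed + 1L, direction = "reverse",
                                  sample_id = sp$sample_id)
    )
  }
  samples$trace_class_true <- trace_truth

  metabarcoded <- samples %>% filter(.data$n_reads > 0)
  reads <- purrr::map_dfr(seq_len(nrow(metabarcoded)), function(i) {
    simulate_reads(metabarcoded[i, ], refs,
                   seed = (seed + 104729L * i) %% .Machine$integer.max)
  })
  manifest <- metabarcoded %>% select("sample_id", "tag")

  design <- structure(
    list(samples = samples, chromatograms = chroms, reads = reads,
         manifest = manifest, refs = refs, seed = seed),
    class = "study_design"
  )
  if (!is.null(out_dir)) write_study_design(design, out_dir)
  design
}

# designed purity class of a two-subspecies mixture: clean single-template
# traces are A, minor components up to ~0.2 give bounded secondary peaks
# (B), larger minor fractions cross the calling threshold at every
# phase-shifted position downstream of the indel (C)
designed_trace_class <- function(pueraria_composition) {
  minor <- 1 - max(pueraria_composition)
  if (minor < 0.005) "A" else if (minor <= 0.2) "B" else "C"
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", nrow(x$samples), "samples (",
      sum(x$samples$product_type == "raw_material"), "raw material,",
      sum(x$samples$product_type == "food"), "food,",
      sum(x$samples$product_type == "herbal"), "herbal ),",
      nrow(x$reads), "simulated reads\n")
  invisible(x)
}

write_study_design <- function(design, out_dir) {
  dir.create(file.path(out_dir, "sanger"), recursive = TRUE,
             showWarnings = FALSE)
  write_reference_set(design$refs, file.path(out_dir, "refs"))
  for (id in names(design$chromatograms)) {
    write_chromatogram(design$chromatograms[[id]]$fwd,
                       file.path(out_dir, "sanger", paste0(id, "_fwd.tsv")))
    write_chromatogram(design$chromatograms[[id]]$rev,
                       file.path(out_dir, "sanger", paste0(id, "_rev.tsv")))
  }
  if (nrow(design$reads)) {
    write_fastq(design$reads, file.path(out_dir, "reads.fastq"))
    readr::write_tsv(design$manifest, file.path(out_dir, "tags.tsv"))
  }
  manifest <- design$samples %>%
    select("sample_id", "label_taxon", "product_type", "tag")
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  truth <- design$samples %>%
    mutate(true_composition = purrr::map(.data$true_composition, as.list)) %>%
    select("sample_id", "label_taxon", "product_type", "true_composition")
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
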