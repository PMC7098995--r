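# Reference database: taxon-annotated ITS2 (+ flank) sequences, per-group
# consensus, diagnostic-site detection and subspecies calling.

#' Construct a reference database from in-memory tables
#'
#' @param sequences Tibble with columns `seq_id`, `taxon_id`, `sequence` and
#'   optionally `its2_start`, `its2_end` (1-based inclusive span of the ITS2
#'   region within a full amplicon). Sequences without a span are taken to be
#'   ITS2-only.
#' @param taxa Tibble with columns `taxon_id`, `name`, `rank` (one of
#'   `variety`, `species`, `genus`) and `group` (barcode group label used to
#'   partition intra- vs inter-group distances).
#' @return An object of class `ref_db`.
#' @export
reference_db <- function(sequences, taxa) {
  sequences <- as_tibble(sequences)
  taxa <- as_tibble(taxa)
  stopifnot(all(c("seq_id", "taxon_id", "sequence") %in% names(sequences)),
            all(c("taxon_id", "name", "rank", "group") %in% names(taxa)))
  if (nrow(sequences) == 0L) stop("reference database has no sequences", call. = FALSE)
  if (anyDuplicated(sequences$seq_id)) {
    stop("duplicate seq_id in reference database: ",
         paste(unique(sequences$seq_id[duplicated(sequences$seq_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(taxa$taxon_id)) stop("duplicate taxon_id", call. = FALSE)
  missing <- setdiff(sequences$taxon_id, taxa$taxon_id)
  if (length(missing)) {
    stop("taxonomy missing for ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(taxa$group))) stop("empty group label in taxonomy", call. = FALSE)
  sequences$sequence <- toupper(sequences$sequence)
  if (any(nchar(sequences$sequence) == 0L)) {
    stop("empty reference sequence", call. = FALSE)
  }
  if (!"its2_start" %in% names(sequences)) {
    sequences$its2_start <- NA_integer_
    sequences$its2_end <- NA_integer_
  }
  sequences <- sequences %>%
    mutate(
      region = ifelse(is.na(.data$its2_start), "its2", "full_amplicon"),
      its2 = ifelse(is.na(.data$its2_start), .data$sequence,
                    substr(.data$sequence, .data$its2_start, .data$its2_end)),
      group = taxa$group[match(.data$taxon_id, taxa$taxon_id)]
    )
  bad <- !is.na(sequences$its2_start) &
    (sequences$its2_start < 1L | sequences$its2_end > nchar(sequences$sequence) |
       sequences$its2_start > sequences$its2_end)
  if (any(bad)) {
    stop("its2 span out of bounds for ",
         paste(sequences$seq_id[bad], collapse = ", "), call. = FALSE)
  }
  consensus <- lapply(
    split(sequences$its2, sequences$group), consensus_sequence
  )
  structure(
    list(sequences = sequences, taxa = taxa, consensus = consensus),
    class = "ref_db"
  )
}

#' Build a reference database from FASTA + taxonomy files
#'
#' Reads reference sequences from FASTA and their annotations from a
#' tab-separated taxonomy table with header
#' `seq_id  taxon_id  name  rank  group`. Sequences containing recognisable
#' 5.8S/28S anchor flanks are stored as full amplicons with their ITS2 span
#' annotated automatically; all others are treated as ITS2-only.
#'
#' @param fasta_path Path to a FASTA file of reference sequences.
#' @param taxonomy_path Path to the taxonomy TSV.
#' @param model Anchor model used to locate ITS2 spans, see
#'   [its2_anchor_model()].
#' @return A `ref_db` object.
#' @export
build_reference_db <- function(fasta_path, taxonomy_path,
                               model = its2_anchor_model()) {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path, call. = FALSE)
  if (!file.exists(taxonomy_path)) stop("no such file: ", taxonomy_path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  tax <- readr::read_tsv(taxonomy_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing <- setdiff(ids, tax$seq_id)
  if (length(missing)) {
    stop("taxonomy missing for ", paste(missing, collapse = ", "), call. = FALSE)
  }
  spans <- extract_its2(as.character(seqs), model = model)
  sequences <- tibble(
    seq_id = ids,
    taxon_id = tax$taxon_id[match(ids, tax$seq_id)],
    sequence = unname(as.character(seqs)),
    its2_start = spans$its2_start,
    its2_end = spans$its2_end
  )
  taxa <- tax %>%
    select("taxon_id", "name", "rank", "group") %>%
    dplyr::distinct()
  reference_db(sequences, taxa)
}

# Strict-majority consensus per column; ties resolved to the IUPAC code
# covering the tied bases. Members of unequal length are stacked in the
# coordinates of the first member via pairwise alignment.
consensus_sequence <- function(seqs) {
  seqs <- toupper(seqs)
  if (length(seqs) == 1L) return(seqs)
  if (length(unique(nchar(seqs))) > 1L) {
    anchor <- seqs[[1L]]
    rows <- lapply(seqs[-1L], function(s) {
      al <- align_pair(anchor, s)
      ca <- seq_chars(al$aligned_a)
      cb <- seq_chars(al$aligned_b)
      cb[ca != "-"]  # project onto anchor coordinates
    })
    m <- rbind(seq_chars(anchor), do.call(rbind, rows))
  } else {
    m <- do.call(rbind, strsplit(seqs, ""))
  }
  paste(apply(m, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return("-")
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else iupac_code(top)
  }), collapse = "")
}

#' Per-group ITS2 consensus sequence
#'
#' @param db A `ref_db`.
#' @param group Group label.
#' @return Consensus nucleotide string.
#' @export
group_consensus <- function(db, group) {
  stopifnot(inherits(db, "ref_db"))
  cons <- db$consensus[[group]]
  if (is.null(cons)) stop("unknown group: ", group, call. = FALSE)
  cons
}

#' @export
print.ref_db <- function(x, ...) {
  cat("ITS2 reference database: ", nrow(x$sequences), " sequences, ",
      nrow(x$taxa), " taxa, groups: ",
      paste(names(x$consensus), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname reference_db
#' @param x A `ref_db` object.
#' @param ... Unused.
#' @export
tidy.ref_db <- function(x, ...) {
  x$sequences %>%
    dplyr::left_join(x$taxa, by = c("taxon_id", "group")) %>%
    mutate(length = nchar(.data$sequence), its2_length = nchar(.data$its2)) %>%
    select("seq_id", "taxon_id", "name", "rank", "group", "region",
           "length", "its2_length", "sequence", "its2")
}

#' @rdname reference_db
#' @export
glance.ref_db <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$sequences),
    n_taxa = nrow(x$taxa),
    n_groups = length(x$consensus)
  )
}

# ---------------------------------------------------------------------------
# Variable-site detection

#' Detect variable sites between two barcode groups
#'
#' Aligns the two group ITS2 consensus sequences and reports every column
#' where they differ, as SNP or indel sites in 1-based alignment-column
#' coordinates. Columns that additionally vary *within* either group are
#' flagged `intra_polymorphic` and down-weighted (weight 0.25 instead of 1)
#' for subspecies calling, since such characters are unreliable diagnostics.
#'
#' @param db A `ref_db`.
#' @param group_a,group_b Group labels (defaults: `lobata`, `thomsonii`).
#' @return A `site_table`: a tibble with columns `position`, `kind`
#'   (`snp`/`indel`), `state_a`, `state_b`, `intra_polymorphic`, `weight`,
#'   carrying the consensus pairwise alignment as attributes.
#' @export
detect_variable_sites <- function(db, group_a = "lobata", group_b = "thomsonii") {
  stopifnot(inherits(db, "ref_db"))
  cons_a <- group_consensus(db, group_a)
  cons_b <- group_consensus(db, group_b)
  al <- align_pair(cons_a, cons_b)
  ca <- seq_chars(al$aligned_a)
  cb <- seq_chars(al$aligned_b)
  diff_cols <- which(ca != cb)
  poly_a <- intra_polymorphic_columns(db, group_a, al$aligned_a)
  poly_b <- intra_polymorphic_columns(db, group_b, al$aligned_b)
  poly <- union(poly_a, poly_b)
  sites <- tibble(
    position = as.integer(diff_cols),
    kind = ifelse(ca[diff_cols] == "-" | cb[diff_cols] == "-", "indel", "snp"),
    state_a = ca[diff_cols],
    state_b = cb[diff_cols],
    intra_polymorphic = diff_cols %in% poly,
    weight = ifelse(diff_cols %in% poly, 0.25, 1)
  )
  new_site_table(sites, group_a, group_b, al$aligned_a, al$aligned_b)
}

new_site_table <- function(sites, group_a, group_b,
                           aligned_a = NULL, aligned_b = NULL) {
  structure(
    sites,
    class = c("site_table", class(tibble())),
    group_a = group_a, group_b = group_b,
    aligned_a = aligned_a, aligned_b = aligned_b,
    coordinate_frame = sprintf(
      "1-based columns of the %s/%s ITS2 consensus pairwise alignment",
      group_a, group_b)
  )
}

# Columns of the consensus pairwise alignment at which members of `group`
# disagree with each other. Members are projected onto consensus
# coordinates, then consensus positions are mapped to alignment columns.
intra_polymorphic_columns <- function(db, group, aligned_consensus) {
  members <- db$sequences$its2[db$sequences$group == group]
  if (length(members) < 2L) return(integer(0))
  cons <- group_consensus(db, group)
  states <- lapply(members, function(s) {
    if (identical(s, cons)) return(seq_chars(s))
    al <- align_pair(cons, s)
    cc <- seq_chars(al$aligned_a)
    cm <- seq_chars(al$aligned_b)
    cm[cc != "-"]
  })
  m <- do.call(rbind, states)
  poly_pos <- which(apply(m, 2L, function(col) length(unique(col)) > 1L))
  # consensus position -> alignment column
  cons_chars <- seq_chars(aligned_consensus)
  col_of_pos <- which(cons_chars != "-")
  col_of_pos[poly_pos]
}

#' Serialise / read a site table
#'
#' TSV columns: `position  kind  state_a  state_b  intra_polymorphic  weight`.
#'
#' @param sites A `site_table`.
#' @param path Output (or input) TSV path.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(as_tibble(sites), path)
  invisible(path)
}

#' @rdname write_site_table
#' @param group_a,group_b Group labels to re-attach on read.
#' @export
read_site_table <- function(path, group_a = "lobata", group_b = "thomsonii") {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           position = "i", kind = "c", state_a = "c",
                           state_b = "c", intra_polymorphic = "l",
                           weight = "d"))
  new_site_table(tab, group_a, group_b)
}

# ---------------------------------------------------------------------------
# Subspecies calling

#' Call the subspecies of a query ITS2 sequence
#'
#' The query is globally aligned to both group consensus sequences. If the
#' best identity falls below `min_identity_genus` the query is reported as
#' `not_pueraria`; if it falls below `min_identity_subspecies` no
#' subspecies-level call is attempted (`ambiguous`). Otherwise the query's
#' states at the diagnostic sites are read off and each group receives the
#' summed reliability weight of the sites agreeing with its consensus state;
#' the higher-scoring group is called, ties are `ambiguous`. IUPAC ambiguity
#' codes in the query match any state whose base set they overlap.
#'
#' @param query Nucleotide string (ITS2 region).
#' @param db A `ref_db`.
#' @param sites A `site_table` built for the two focal groups.
#' @param min_identity_subspecies Identity needed to accept a
#'   subspecies-level call (default 0.99).
#' @param min_identity_genus Identity needed to stay within the genus
#'   (default 0.90); below it the call is `not_pueraria`.
#' @param min_length Minimum query length (default 100); shorter queries are
#'   an error.
#' @param query_id Identifier carried into the result.
#' @return One-row tibble: `query_id`, `called_taxon`, `support`,
#'   `best_identity`, `site_states`.
#' @export
call_subspecies <- function(query, db, sites,
                            min_identity_subspecies = 0.99,
                            min_identity_genus = 0.90,
                            min_length = 100,
                            query_id = "query") {
  stopifnot(inherits(db, "ref_db"), inherits(sites, "site_table"))
  query <- toupper(query)
  if (!nzchar(query)) stop("empty query sequence", call. = FALSE)
  if (nchar(query) < min_length) {
    stop("query shorter than minimum length (", min_length, " nt): ",
         nchar(query), call. = FALSE)
  }
  group_a <- attr(sites, "group_a")
  group_b <- attr(sites, "group_b")
  cons_a <- group_consensus(db, group_a)
  cons_b <- group_consensus(db, group_b)
  frame <- site_frame(sites, cons_a, cons_b)

  al_a <- align_pair(query, cons_a)
  al_b <- align_pair(query, cons_b)
  best_identity <- max(al_a$identity, al_b$identity)

  states <- observed_site_states(sites, frame, query, al_a, al_b)
  state_str <- paste(sprintf("%d:%s", sites$position, states), collapse = ",")

  if (best_identity < min_identity_genus) {
    return(call_row(query_id, "not_pueraria", 0, best_identity, state_str))
  }

  match_a <- mapply(iupac_compatible, states, sites$state_a, USE.NAMES = FALSE)
  match_b <- mapply(iupac_compatible, states, sites$state_b, USE.NAMES = FALSE)
  score_a <- sum(sites$weight[match_a])
  score_b <- sum(sites$weight[match_b])
  total <- sum(sites$weight)

  if (best_identity < min_identity_subspecies || score_a == score_b) {
    support <- if (total > 0) max(score_a, score_b) / total else 0
    return(call_row(query_id, "ambiguous", support, best_identity, state_str))
  }
  winner_group <- if (score_a > score_b) group_a else group_b
  support <- max(score_a, score_b) / total
  call_row(query_id, group_taxon(db, winner_group), support, best_identity,
           state_str)
}

call_row <- function(query_id, called_taxon, support, best_identity, states) {
  tibble(query_id = query_id, called_taxon = called_taxon,
         support = support, best_identity = best_identity,
         site_states = states)
}

# the variety-level taxon carried by a barcode group
group_taxon <- function(db, group) {
  ids <- db$taxa$taxon_id[db$taxa$group == group]
  if (length(ids) == 0L) group else ids[[1L]]
}

# Recover (or rebuild) the consensus pairwise alignment the site positions
# refer to.
site_frame <- function(sites, cons_a, cons_b) {
  aligned_a <- attr(sites, "aligned_a")
  aligned_b <- attr(sites, "aligned_b")
  if (is.null(aligned_a) || is.null(aligned_b)) {
    al <- align_pair(cons_a, cons_b)
    aligned_a <- al$aligned_a
    aligned_b <- al$aligned_b
  }
  list(a = seq_chars(aligned_a), b = seq_chars(aligned_b))
}

# Query state at each diagnostic column. Columns where the group-b consensus
# has a residue are mapped through the query/consensus-b alignment; columns
# deleted in b (state_b == "-") are mapped through consensus a instead.
observed_site_states <- function(sites, frame, query, al_a, al_b) {
  pos_b <- cumsum(frame$b != "-")
  pos_a <- cumsum(frame$a != "-")
  vapply(seq_len(nrow(sites)), function(i) {
    col <- sites$position[[i]]
    if (frame$b[[col]] != "-") {
      query_char_at(al_b, pos_b[[col]])
    } else {
      query_char_at(al_a, pos_a[[col]])
    }
  }, "")
}

# character of the aligned query over subject position `pos` ("-" if deleted)
query_char_at <- function(al, pos) {
  cq <- seq_chars(al$aligned_a)
  cs <- seq_chars(al$aligned_b)
  subj_pos <- cumsum(cs != "-")
  idx <- which(cs != "-" & subj_pos == pos)
  if (length(idx) == 0L) return("-")
  cq[[idx[[1L]]]]
}
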