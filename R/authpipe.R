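# End-to-end authentication: per-sample Sanger and metabarcoding paths,
# label-consistency reports.

#' Identify one sample from its forward/reverse chromatogram pair
#'
#' call_bases -> bidirectional assembly -> subspecies call; trace class from
#' the forward call. Failures (unassemblable reads, degenerate traces) are
#' recorded as `failed`, never raised.
#'
#' @param fwd,rev `chromatogram` objects.
#' @param db,sites Reference database and site table.
#' @param ambiguity_threshold Secondary-peak calling threshold.
#' @return One-row tibble: `called_taxon`, `support`, `best_identity`,
#'   `trace_class`, `het_fraction`, `nested_score`.
#' @export
sanger_identify <- function(fwd, rev, db, sites, ambiguity_threshold = 0.25) {
  out <- tryCatch({
    call_f <- call_bases(fwd, ambiguity_threshold)
    call_r <- call_bases(rev, ambiguity_threshold)
    cls <- classify_trace(call_f, sites)
    consensus <- assemble_bidirectional(call_f, call_r)
    call <- call_subspecies(consensus, db, sites)
    tibble(called_taxon = call$called_taxon, support = call$support,
           best_identity = call$best_identity, trace_class = cls$label,
           het_fraction = cls$het_fraction, nested_score = cls$nested_score)
  }, error = function(e) {
    tibble(called_taxon = "failed", support = NA_real_,
           best_identity = NA_real_, trace_class = NA_character_,
           het_fraction = NA_real_, nested_score = NA_real_)
  })
  out
}

#' Authenticate a Sanger panel against its labels
#'
#' Runs [sanger_identify()] on every sample of the requested panel and
#' compares the call to the label at subspecies level; genus-level,
#' ambiguous or failed calls count as inconsistent.
#'
#' @param design A `study_design` from [make_study_fixtures()].
#' @param db,sites Reference database and site table (defaults: the
#'   design's own references).
#' @param panel Which product types to authenticate (default
#'   `raw_material`).
#' @return An `auth_report`.
#' @export
authenticate_sanger_panel <- function(design, db = design$refs$db,
                                      sites = detect_variable_sites(db),
                                      panel = "raw_material") {
  stopifnot(inherits(design, "study_design"))
  sel <- design$samples %>% filter(.data$product_type %in% panel)
  rows <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    id <- sel$sample_id[[i]]
    ch <- design$chromatograms[[id]]
    res <- sanger_identify(ch$fwd, ch$rev, db, sites)
    dplyr::bind_cols(
      tibble(sample_id = id, label_taxon = sel$label_taxon[[i]]), res)
  })
  auth_report(rows, panel = paste(panel, collapse = "+"))
}

#' Authenticate metabarcoded samples and tabulate contaminants
#'
#' Runs the full metabarcoding pipeline on the design's tagged reads. The
#' dominant Pueraria subspecies (largest read share among subspecies-level
#' assignments) becomes the sample's call; non-Pueraria taxa at or above
#' `contaminant_threshold` of retained reads are listed as contaminants.
#'
#' @param design A `study_design` with simulated reads.
#' @param db,sites Reference database and site table.
#' @param contaminant_threshold Minimum proportion of retained reads for a
#'   contaminant to be reported (default 0.01).
#' @param ... Passed to [run_metabarcoding()].
#' @return List with `report` (an `auth_report` whose rows carry a
#'   `contaminants` column) and `composition` (a `composition_tbl`).
#' @export
authenticate_metabarcoding_panel <- function(design, db = design$refs$db,
                                             sites = detect_variable_sites(db),
                                             contaminant_threshold = 0.01,
                                             ...) {
  stopifnot(inherits(design, "study_design"), nrow(design$reads) > 0)
  run <- run_metabarcoding(design$reads, design$manifest, db, sites, ...)
  comp <- run$composition
  subspecies <- db$taxa$name[db$taxa$group %in% c("lobata", "thomsonii")]
  pueraria_names <- db$taxa$name[db$taxa$rank %in% c("variety", "species") &
                                   grepl("^Pueraria", db$taxa$name)]
  rows <- purrr::map_dfr(unique(design$manifest$sample_id), function(id) {
    cc <- comp %>% filter(.data$sample_id == id)
    label <- design$samples$label_taxon[design$samples$sample_id == id]
    pu <- cc %>% filter(.data$taxon %in% subspecies)
    called <- if (nrow(cc) == 0L) "failed"
    else if (nrow(pu) == 0L) "not_detected"
    else pu$taxon[[which.max(pu$reads)]]
    contam <- cc %>%
      filter(!(.data$taxon %in% pueraria_names),
             .data$proportion >= contaminant_threshold)
    tibble(
      sample_id = id,
      label_taxon = label,
      called_taxon = name_to_taxon_id(db, called),
      contaminants = paste(sort(contam$taxon), collapse = "; "),
      pueraria_proportion = sum(pu$proportion)
    )
  })
  list(report = auth_report(rows, panel = "metabarcoding"),
       composition = comp, log = run$log)
}

name_to_taxon_id <- function(db, name) {
  id <- db$taxa$taxon_id[match(name, db$taxa$name)]
  ifelse(is.na(id), name, id)
}

#' Label-consistency report
#'
#' @param samples Tibble with at least `sample_id`, `label_taxon`,
#'   `called_taxon`.
#' @param panel Free-text panel label.
#' @param chemistry_note Optional pass/fail annotation supplied by the
#'   user's chemical testing (TLC/HPLC); carried verbatim, never computed.
#' @return An `auth_report`: the per-sample table plus aggregates
#'   `n_samples`, `n_consistent` and `consistency_pct` (rounded to 1
#'   decimal).
#' @export
auth_report <- function(samples, panel = "panel", chemistry_note = NA_character_) {
  samples <- as_tibble(samples) %>%
    mutate(consistent = .data$called_taxon == .data$label_taxon)
  n <- nrow(samples)
  n_consistent <- sum(samples$consistent)
  structure(
    list(
      samples = samples,
      panel = panel,
      n_samples = n,
      n_consistent = n_consistent,
      consistency_pct = round(100 * n_consistent / n, 1),
      chemistry_note = chemistry_note
    ),
    class = "auth_report"
  )
}

#' @export
print.auth_report <- function(x, ...) {
  cat(sprintf("Authentication report [%s]: %d/%d consistent (%.1f%%)\n",
              x$panel, x$n_consistent, x$n_samples, x$consistency_pct))
  print(x$samples, n = 10)
  invisible(x)
}

#' @rdname auth_report
#' @param x An `auth_report`.
#' @param ... Unused.
#' @export
tidy.auth_report <- function(x, ...) x$samples

#' @rdname auth_report
#' @export
glance.auth_report <- function(x, ...) {
  tibble(panel = x$panel, n_samples = x$n_samples,
         n_consistent = x$n_consistent,
         consistency_pct = x$consistency_pct,
         chemistry_note = x$chemistry_note)
}

#' Bar chart of called vs labelled taxa
#'
#' @param object An `auth_report`.
#' @param ... Unused.
#' @export
autoplot.auth_report <- function(object, ...) {
  df <- object$samples %>%
    dplyr::count(.data$label_taxon, .data$called_taxon)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label_taxon, y = .data$n,
                                   fill = .data$called_taxon)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "label", y = "samples", fill = "called",
                  title = sprintf("%s: %.1f%% consistent",
                                  object$panel, object$consistency_pct))
}

#' Write an authentication report as TSV or JSON
#'
#' @param report An `auth_report`.
#' @param path Output path; format chosen by extension (`.json` or TSV).
#' @export
write_auth_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(samples = report$samples,
           aggregates = glance(report)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(report$samples, path)
  }
  invisible(path)
}
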