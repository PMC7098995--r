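test_that("reference database builds from FASTA + taxonomy files", {
  refs <- fixture_refs()
  dir <- withr::local_tempdir()
  its2auth:::write_reference_set(refs, dir)
  db <- build_reference_db(file.path(dir, "references.fasta"),
                           file.path(dir, "taxonomy.tsv"))
  expect_equal(nrow(db$sequences), 10L)
  expect_equal(nrow(db$taxa), 7L)
  # ITS2 spans recovered by the anchor model match the generator's
  expect_equal(db$sequences$its2, refs$db$sequences$its2)
  expect_equal(glance(db)$n_groups, 4L)
})

test_that("FASTA records missing from the taxonomy are an error naming them", {
  refs <- fixture_refs()
  dir <- withr::local_tempdir()
  its2auth:::write_reference_set(refs, dir)
  tax <- readr::read_tsv(file.path(dir, "taxonomy.tsv"), show_col_types = FALSE)
  readr::write_tsv(tax[tax$seq_id != "hv1", ], file.path(dir, "taxonomy.tsv"))
  expect_error(
    build_reference_db(file.path(dir, "references.fasta"),
                       file.path(dir, "taxonomy.tsv")),
    "taxonomy missing for hv1")
})

test_that("duplicate sequence ids are rejected", {
  refs <- fixture_refs()
  seqs <- refs$db$sequences[c(1, 1, 2), ]
  expect_error(reference_db(seqs, refs$db$taxa), "duplicate seq_id")
})

test_that("diagnostic sites are the indel at 29 and SNPs at 52/201/244", {
  sites <- fixture_sites()
  expect_equal(sites$position, c(29L, 52L, 201L, 244L))
  expect_equal(sites$kind, c("indel", "snp", "snp", "snp"))
  expect_equal(sites$state_a, c("-", "A", "C", "T"))
  expect_equal(sites$state_b, c("T", "G", "T", "G"))
  expect_equal(sites$intra_polymorphic, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(sites$weight, c(1, 1, 1, 0.25))
})

test_that("identical groups yield an empty site table", {
  refs <- fixture_refs()
  db <- refs$db
  seqs <- db$sequences[db$sequences$group == "thomsonii", ]
  seqs2 <- seqs
  seqs2$seq_id <- paste0(seqs$seq_id, "_copy")
  seqs2$taxon_id <- "thom2"
  taxa <- dplyr::bind_rows(
    db$taxa,
    tibble::tibble(taxon_id = "thom2", name = "copy", rank = "variety",
                   group = "thomsonii_copy"))
  db2 <- reference_db(dplyr::bind_rows(seqs, seqs2), taxa)
  sites <- detect_variable_sites(db2, "thomsonii", "thomsonii_copy")
  expect_equal(nrow(sites), 0L)
})

test_that("planted substitutions are recovered exactly (brute-force oracle)", {
  withr::with_seed(21, {
    for (trial in 1:10) {
      base <- random_seq(60)
      pos <- sort(sample(60, 2))
      variant <- mutate_at_positions(base, pos)
      taxa <- tibble::tibble(
        taxon_id = c("ga", "gb"), name = c("A", "B"),
        rank = "variety", group = c("ga", "gb"))
      seqs <- tibble::tibble(
        seq_id = c("a1", "b1"), taxon_id = c("ga", "gb"),
        sequence = c(base, variant))
      db <- reference_db(seqs, taxa)
      sites <- detect_variable_sites(db, "ga", "gb")
      # oracle: column-by-column comparison of the known true alignment
      truth <- which(strsplit(base, "")[[1]] != strsplit(variant, "")[[1]])
      expect_equal(sites$position, truth)
      expect_true(all(sites$kind == "snp"))
    }
  })
})

test_that("unknown group labels are an error", {
  expect_error(detect_variable_sites(fixture_refs()$db, "lobata", "nope"),
               "unknown group")
})

test_that("group consensuses call their own subspecies with support 1", {
  refs <- fixture_refs()
  sites <- fixture_sites()
  for (g in c("lobata", "thomsonii")) {
    call <- call_subspecies(group_consensus(refs$db, g), refs$db, sites)
    expect_equal(call$called_taxon, g)
    expect_equal(call$support, 1)
    expect_equal(call$best_identity, 1)
  }
})

test_that("the low-weight intraspecific site is outvoted", {
  refs <- fixture_refs()
  sites <- fixture_sites()
  th <- group_consensus(refs$db, "thomsonii")
  # flip site 244 (thomsonii G -> lobata-like T); high-weight sites dominate
  mutated <- mutate_at_positions(th, 244, "T")
  call <- call_subspecies(mutated, refs$db, sites)
  expect_equal(call$called_taxon, "thomsonii")
  expect_equal(call$support, 3 / 3.25)
  # weighted-vote arithmetic: enumerate all site-state combinations
  weights <- sites$weight
  for (mask in 0:15) {
    agree_b <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0)
    score_b <- sum(weights[agree_b])
    score_a <- sum(weights[!agree_b])
    expected <- if (score_a == score_b) "ambiguous"
    else if (score_b > score_a) "thomsonii" else "lobata"
    # the implementation must agree with this closed-form vote whenever the
    # observed states are exactly one group's states per site
    states <- ifelse(agree_b, sites$state_b, sites$state_a)
    q <- strsplit(th, "")[[1]]
    # build a query carrying those states in thomsonii coordinates
    q[29] <- if (states[1] == "-") NA else states[1]
    q[52] <- states[2]; q[201] <- states[3]; q[244] <- states[4]
    query <- paste(stats::na.omit(q), collapse = "")
    got <- call_subspecies(query, refs$db, sites)$called_taxon
    expect_equal(got, expected, info = paste("mask", mask))
  }
})

test_that("queries far from Pueraria are not_pueraria", {
  refs <- fixture_refs()
  sites <- fixture_sites()
  hv <- refs$db$sequences$its2[refs$db$sequences$seq_id == "hv1"]
  expect_equal(call_subspecies(hv, refs$db, sites)$called_taxon,
               "not_pueraria")
})

test_that("short queries are rejected", {
  expect_error(
    call_subspecies(random_seq(80), fixture_refs()$db, fixture_sites()),
    "shorter than minimum")
})

test_that("calls are invariant to database record order", {
  refs <- fixture_refs()
  db <- refs$db
  withr::with_seed(5, perm <- sample(nrow(db$sequences)))
  db2 <- reference_db(db$sequences[perm, ], db$taxa[sample(nrow(db$taxa)), ])
  sites2 <- detect_variable_sites(db2)
  query <- group_consensus(db, "lobata")
  expect_equal(call_subspecies(query, db2, sites2)$called_taxon, "lobata")
  expect_identical(as.data.frame(sites2), as.data.frame(fixture_sites()))
})

test_that("non-diagnostic substitutions never flip the call", {
  refs <- fixture_refs()
  sites <- fixture_sites()
  diag_lob <- c(51, 200, 243)   # lobata coordinates of columns 52/201/244
  diag_th <- c(29, 52, 201, 244)
  withr::with_seed(33, {
    for (trial in 1:100) {
      g <- if (trial %% 2 == 0) "lobata" else "thomsonii"
      cons <- group_consensus(refs$db, g)
      avoid <- if (g == "lobata") diag_lob else diag_th
      k <- sample(0:2, 1)
      pos <- sample(setdiff(seq_len(nchar(cons)), avoid), k)
      query <- mutate_at_positions(cons, pos)
      expect_equal(call_subspecies(query, refs$db, sites)$called_taxon, g,
                   info = paste(g, trial))
    }
  })
})

test_that("site tables round-trip through TSV", {
  sites <- fixture_sites()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sites, path)
  back <- read_site_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sites), ignore_attr = TRUE)
})
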