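fixture_manifest <- tibble::tibble(
  sample_id = c("s1", "s2", "s3"),
  tag = c("ACGTACGTAC", "TGCATGCATG", "GATCGATCGA")
)

tagged_reads <- function(n_per_sample, payload_len = 40, manifest = fixture_manifest) {
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    tibble::tibble(
      read_id = sprintf("%s_%03d", manifest$sample_id[i], seq_len(n_per_sample)),
      sequence = paste0(manifest$tag[i],
                        replicate(n_per_sample, random_seq(payload_len))),
      quality = replicate(n_per_sample,
                          its2auth:::phred_encode(rep(35, payload_len + 10)))
    )
  })
}

test_that("exact tags split reads 100/100/100 with nothing unassigned", {
  withr::with_seed(1, reads <- tagged_reads(100))
  out <- demultiplex(reads, fixture_manifest)
  expect_equal(unname(table(out$sample_id)[fixture_manifest$sample_id]),
               rep(100L, 3), ignore_attr = TRUE)
  expect_false("unassigned" %in% out$sample_id)
  # tag stripped from both sequence and quality
  expect_true(all(nchar(out$sequence) == 40))
  expect_true(all(nchar(out$quality) == 40))
})

test_that("one tag mismatch at max_mismatch 0 lands in the unassigned bin", {
  withr::with_seed(2, reads <- tagged_reads(1))
  substr(reads$sequence[1], 3, 3) <- ifelse(substr(reads$sequence[1], 3, 3) == "A", "C", "A")
  out <- demultiplex(reads, fixture_manifest, max_mismatch = 0)
  expect_equal(out$sample_id[1], "unassigned")
  expect_equal(nchar(out$sequence[1]), 50)  # tag left in place
})

test_that("planted tag errors are assigned per the brute-force Hamming rule", {
  withr::with_seed(3, {
    reads <- tagged_reads(40)
    flip <- runif(nrow(reads)) < 0.05
    for (i in which(flip)) {
      p <- sample(10, 1)
      old <- substr(reads$sequence[i], p, p)
      substr(reads$sequence[i], p, p) <- sample(setdiff(c("A","C","G","T"), old), 1)
    }
    out <- demultiplex(reads, fixture_manifest, max_mismatch = 1)
    # oracle: exhaustive Hamming comparison of every read against every tag
    for (i in seq_len(nrow(reads))) {
      obs <- strsplit(substr(reads$sequence[i], 1, 10), "")[[1]]
      dists <- vapply(fixture_manifest$tag, function(t) {
        sum(obs != strsplit(t, "")[[1]])
      }, numeric(1))
      hits <- which(dists <= 1)
      expected <- if (length(hits) == 1) fixture_manifest$sample_id[hits] else "unassigned"
      expect_equal(out$sample_id[i], expected)
    }
  })
})

test_that("demultiplexing conserves reads and colliding tags are rejected", {
  withr::with_seed(4, reads <- tagged_reads(25))
  out <- demultiplex(reads, fixture_manifest)
  expect_equal(nrow(out), nrow(reads))
  expect_setequal(out$read_id, reads$read_id)
  bad <- tibble::tibble(sample_id = c("x", "y"),
                        tag = c("ACGTACGTAC", "ACGTACGTAC"))
  expect_error(demultiplex(reads, bad), "colliding tags")
})

test_that("quality filter applies the stated boundary semantics", {
  mk <- function(len, qv) tibble::tibble(
    read_id = "r", sequence = random_seq(len),
    quality = its2auth:::phred_encode(rep(qv, len)))
  expect_equal(nrow(quality_filter(mk(299, 40))), 0L)  # too short
  expect_equal(nrow(quality_filter(mk(300, 30))), 1L)  # both boundaries kept
  expect_equal(nrow(quality_filter(mk(300, 29))), 0L)  # below mean QV
})

test_that("quality filter matches an independent recomputation and is idempotent", {
  withr::with_seed(5, {
    reads <- tibble::tibble(
      read_id = sprintf("r%02d", 1:50),
      sequence = replicate(50, random_seq(sample(280:320, 1))),
      quality = NA_character_
    )
    reads$quality <- vapply(seq_len(50), function(i) {
      its2auth:::phred_encode(round(runif(nchar(reads$sequence[i]), 25, 38)))
    }, "")
    out <- quality_filter(reads)
    keep <- vapply(seq_len(50), function(i) {
      nchar(reads$sequence[i]) >= 300 &&
        mean(utf8ToInt(reads$quality[i]) - 33) >= 30
    }, logical(1))
    expect_equal(out$read_id, reads$read_id[keep])
    expect_equal(quality_filter(out), out)
  })
})

test_that("ITS2 extraction trims fixture amplicons to 246 and 247 bases", {
  refs <- fixture_refs()
  amp_lob <- refs$db$sequences$sequence[refs$db$sequences$seq_id == "lob1"]
  amp_th <- refs$db$sequences$sequence[refs$db$sequences$seq_id == "th1"]
  out <- extract_its2(c(amp_lob, amp_th))
  expect_equal(nchar(out$its2), c(246L, 247L))
  expect_equal(out$strand, c("+", "+"))
  # reverse-complemented input is recovered through the minus strand
  out_rc <- extract_its2(revcomp(amp_lob))
  expect_equal(out_rc$strand, "-")
  expect_equal(out_rc$its2, out$its2[1])
})

test_that("sequences lacking anchors fail extraction as a value", {
  withr::with_seed(6, out <- extract_its2(random_seq(400)))
  expect_true(is.na(out$its2))
})

test_that("amplicons at random offsets with flank errors are still trimmed exactly", {
  refs <- fixture_refs()
  amp <- refs$db$sequences$sequence[refs$db$sequences$seq_id == "th1"]
  its2_true <- refs$db$sequences$its2[refs$db$sequences$seq_id == "th1"]
  withr::with_seed(7, {
    for (trial in 1:100) {
      lead <- random_seq(sample(0:30, 1))
      trail <- random_seq(sample(0:30, 1))
      seq <- paste0(lead, amp, trail)
      # up to 2 point errors in the flanks (never inside ITS2)
      flank_pos <- c(seq_len(115) + nchar(lead),
                     seq(nchar(lead) + 115 + 248, nchar(lead) + nchar(amp)))
      pos <- sample(flank_pos, sample(0:2, 1))
      seq <- mutate_at_positions(seq, pos)
      out <- extract_its2(seq)
      expect_equal(out$its2, its2_true, info = paste("trial", trial))
    }
  })
})

test_that("dereplication keeps clusters above the repeat threshold, sorted", {
  reads <- tibble::tibble(
    sample_id = "s1",
    sequence = rep(c("AAAA", "CCCC", "GGGG", "TTTT"), c(50, 11, 10, 5)))
  out <- dereplicate(reads)
  expect_equal(nrow(out), 2L)
  expect_equal(out$sequence, c("AAAA", "CCCC"))
  expect_equal(out$count, c(50L, 11L))
})

test_that("cluster counts recount the batch and dereplication is idempotent on clusters", {
  withr::with_seed(8, {
    pool <- replicate(6, random_seq(20))
    reads <- tibble::tibble(
      sample_id = sample(c("s1", "s2"), 400, TRUE),
      sequence = sample(pool, 400, TRUE))
    out <- dereplicate(reads, min_count = 1)
    expect_equal(sum(out$count), 400L)
    # hash-table recount oracle
    for (i in seq_len(nrow(out))) {
      expect_equal(out$count[i],
                   sum(reads$sample_id == out$sample_id[i] &
                         reads$sequence == out$sequence[i]))
    }
  })
})

test_that("clusters are assigned to subspecies, contaminants and unassigned", {
  refs <- fixture_refs()
  sites <- fixture_sites()
  th <- group_consensus(refs$db, "thomsonii")
  hv <- refs$db$sequences$its2[refs$db$sequences$seq_id == "hv1"]
  asp <- refs$db$sequences$its2[refs$db$sequences$seq_id == "asp1"]
  withr::with_seed(9, {
    asp_mut <- mutate_at_positions(asp, sample(nchar(asp), 3))
    junk <- random_seq(240)
  })
  clusters <- tibble::tibble(
    sample_id = "s1",
    sequence = c(th, hv, asp_mut, junk),
    count = c(100L, 50L, 20L, 12L))
  out <- assign_taxon(clusters, refs$db, sites)
  expect_equal(out$taxon_id,
               c("thomsonii", "hordeum", "aspergillus", "unassigned"))
  expect_equal(out$taxon[2], "Hordeum vulgare")
  # identity of the mutated Aspergillus cluster matches a direct alignment
  direct <- align_pair(asp_mut, asp)$identity
  expect_equal(round(out$identity[3], 4), round(direct, 4))
})

test_that("composition proportions sum to one per sample", {
  assignments <- tibble::tibble(
    sample_id = c("s1", "s1", "s2"),
    taxon = c("x", "y", "x"),
    count = c(30L, 10L, 5L))
  comp <- composition_table(assignments)
  sums <- tapply(comp$proportion, comp$sample_id, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_equal(comp$proportion[comp$sample_id == "s1" & comp$taxon == "x"], 0.75)
})

test_that("simulated herbal mixtures recover proportions within 3 points at 5000 reads", {
  refs <- fixture_refs()
  sites <- fixture_sites()
  truth <- c(lobata = 0.60, aspergillus = 0.25, hordeum = 0.15)
  spec <- sample_spec("mix", "lobata", truth, n_reads = 5000,
                      tag = "ACGTACGTAC", product_type = "herbal",
                      error_rate = 0.002)
  reads <- simulate_reads(spec, refs, seed = 31)
  run <- run_metabarcoding(reads, tibble::tibble(sample_id = "mix",
                                                 tag = "ACGTACGTAC"),
                           refs$db, sites)
  comp <- run$composition
  got <- setNames(comp$proportion, comp$taxon)
  expect_true(all(abs(got[c("Pueraria montana var. lobata",
                            "Aspergillus sp.", "Hordeum vulgare")] -
                        truth[c("lobata", "aspergillus", "hordeum")]) <= 0.03))
})

test_that("the pipeline is deterministic and conserves reads stage by stage", {
  refs <- fixture_refs()
  sites <- fixture_sites()
  spec <- sample_spec("det", "lobata", c(lobata = 0.7, hordeum = 0.3),
                      n_reads = 600, tag = "ACGTACGTAC",
                      product_type = "herbal")
  reads <- simulate_reads(spec, refs, seed = 17)
  manifest <- tibble::tibble(sample_id = "det", tag = "ACGTACGTAC")
  r1 <- run_metabarcoding(reads, manifest, refs$db, sites)
  r2 <- run_metabarcoding(reads, manifest, refs$db, sites)
  expect_identical(as.data.frame(r1$composition), as.data.frame(r2$composition))
  log <- r1$log
  expect_equal(log$reads[log$stage == "input"], 600L)
  expect_true(all(diff(log$reads) <= 0))  # every stage only removes reads
})

test_that("FASTQ files round-trip", {
  withr::with_seed(10, reads <- tagged_reads(5))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back, reads[, c("read_id", "sequence", "quality")])
})
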