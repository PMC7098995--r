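# Shared fixtures: one reference set per test run (deterministic seed) plus
# small independent oracles the tests compare against.

fixture_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_references(seed = 42)
    cache
  }
})

fixture_sites <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- detect_variable_sites(fixture_refs()$db)
    cache
  }
})

# Independent affine-gap global alignment scorer: exhaustive recursion over
# all alignments (small inputs only). Gap of length L costs open + L*ext.
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    open = 2, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ca)) {  # gap in b
      cost <- ext + if (state == "gb") 0 else open
      best <- max(best, -cost + rec(i + 1, j, "gb"))
    }
    if (j <= length(cb)) {  # gap in a
      cost <- ext + if (state == "ga") 0 else open
      best <- max(best, -cost + rec(i, j + 1, "ga"))
    }
    best
  }
  rec(1, 1, "m")
}

# Closed-form K2P from substitution counts
k2p_closed_form <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# p-distance over comparable (both-ACGT) columns
p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  mean(ca[ok] != cb[ok])
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

mutate_at_positions <- function(seq, pos, bases = NULL) {
  ch <- strsplit(seq, "")[[1]]
  for (k in seq_along(pos)) {
    old <- ch[pos[k]]
    ch[pos[k]] <- if (is.null(bases)) sample(setdiff(c("A","C","G","T"), old), 1) else bases[k]
  }
  paste(ch, collapse = "")
}

# support value attached to the bipartition separating `tips`
split_support <- function(tree, tips) {
  ntip <- ape::Ntip(tree)
  for (i in seq_len(tree$Nnode)) {
    node <- ntip + i
    below <- sort(tree$tip.label[its2auth:::phangorn_descendants(tree, node)])
    if (identical(below, sort(tips)) ||
        identical(below, sort(setdiff(tree$tip.label, tips)))) {
      v <- suppressWarnings(as.numeric(tree$node.label[i]))
      if (!is.na(v)) return(v)
    }
  }
  NA_real_
}
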