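# IUPAC nucleotide ambiguity algebra and small sequence helpers.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base-set -> single-letter code, e.g. c("A","G") -> "R"
iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste(bases, collapse = "")
  codes <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  hit <- names(codes)[codes == key]
  if (length(hit) == 0L) "N" else hit[[1L]]
}

iupac_set <- function(code) {
  s <- IUPAC_SETS[[toupper(code)]]
  if (is.null(s)) character(0) else s
}

# TRUE when the two codes denote overlapping base sets ("-" only matches "-")
iupac_compatible <- function(a, b) {
  if (a == "-" || b == "-") return(a == b)
  length(intersect(iupac_set(a), iupac_set(b))) > 0L
}

#' Reverse complement honouring IUPAC ambiguity codes
#'
#' @param x Character vector of nucleotide strings (may contain ambiguity
#'   codes and `-`).
#' @return Character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYKMBDHVSWNacgtrykmbdhvswn",
                 "TGCAYRMKVHDBSWNtgcayrmkvhdbswn", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# random DNA with a target GC content (ITS2 regions run GC-rich)
random_dna <- function(n, gc = 0.55) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Phred+33 helpers ------------------------------------------------------

phred_decode <- function(quality) utf8ToInt(quality) - 33L

phred_encode <- function(qv) intToUtf8(pmax(0L, as.integer(qv)) + 33L)

mean_qv <- function(quality) {
  vapply(quality, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
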