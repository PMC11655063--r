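# Internal helpers shared across modules.

# Locale-independent lexicographic sort (radix is byte-wise, deterministic
# across platforms; ties in ranking and organ-state ordering depend on it).
lex_sort <- function(x) sort(x, method = "radix")

lex_order <- function(...) order(..., method = "radix")

# Amino-acid Hamming distance between two equal-length strings.
aa_hamming <- function(a, b) {
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(sa) != length(sb)) {
    stop("Hamming distance requires equal-length sequences")
  }
  sum(sa != sb)
}

# All pairwise Hamming distances among equal-length strings, as an
# n x n integer matrix. Character-matrix comparison, vectorized per pair.
hamming_matrix <- function(x) {
  n <- length(x)
  m <- matrix(unlist(strsplit(x, "", fixed = TRUE)), nrow = n, byrow = TRUE)
  d <- matrix(0L, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      h <- sum(m[i, ] != m[j, ])
      d[i, j] <- h
      d[j, i] <- h
    }
  }
  d
}

# Truncate a V/J gene call at the allele separator ("*"): clone keys are
# germline genes, not alleles.
strip_allele <- function(x) sub("\\*.*$", "", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

stop_config <- function(...) {
  stop(structure(
    class = c("lymphrep_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
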