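# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over `A`, `C`, `G`, `T`, `N` (case-insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' revcomp("ATGAAA")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

## rotate a vector left by k positions (k = 0 is identity)
rotate_vec <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- k %% n
  if (k == 0L) x else c(x[(k + 1L):n], x[1L:k])
}

## C-locale (radix) sort, so tie-breaking is locale-independent
csort <- function(x) sort(x, method = "radix")

## lexicographic comparison of two character vectors in C locale:
## negative if a < b, 0 if equal, positive if a > b
clex_cmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- min(la, lb)
  for (i in seq_len(n)) {
    if (a[i] != b[i]) {
      return(if (csort(c(a[i], b[i]))[1L] == a[i]) -1L else 1L)
    }
  }
  la - lb
}

## signed token helpers: "-ND6" is ND6 on the L strand
tok_label <- function(x) sub("^-", "", x)
tok_strand <- function(x) ifelse(startsWith(x, "-"), "L", "H")
make_tok <- function(label, strand) ifelse(strand == "L", paste0("-", label), label)

## strip a trailing copy index ("CR2" -> "CR") only when the stripped form
## exists in `ref_labels` and the original form does not
base_label <- function(labels, ref_labels) {
  stripped <- sub("(?<=[A-Za-z])[0-9]+$", "", labels, perl = TRUE)
  ifelse(!(labels %in% ref_labels) & stripped %in% ref_labels, stripped, labels)
}

## substring of a circular sequence, 1-based inclusive; end < start wraps
circular_substr <- function(seq, start, end) {
  n <- nchar(seq)
  stopifnot(start >= 1L, start <= n, end >= 1L, end <= n)
  if (end >= start) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, n), substr(seq, 1L, end))
  }
}
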