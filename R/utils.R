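# Internal helpers shared across modules.

#' Reverse complement a nucleotide string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()] that
#' tolerates `N` and preserves case-insensitivity (output is upper case).
#'
#' @param x A single nucleotide string.
#' @return The reverse complement as an upper-case character scalar.
#' @keywords internal
revcomp_chr <- function(x) {
  stopifnot(length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

#' Sanitize a nucleotide string
#'
#' Upper-cases and replaces any symbol outside A, C, G, T, N by N.
#' A warning reports how many symbols were replaced.
#'
#' @param x character scalar.
#' @param name sequence name used in the warning.
#' @return sanitized character scalar.
#' @keywords internal
sanitize_seq <- function(x, name = "<seq>") {
  x <- toupper(x)
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad)) {
    warning(sprintf("sequence '%s': %d non-ACGTN symbol(s) treated as N",
                    name, nchar(bad)), call. = FALSE)
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

# 0-based half-open interval overlap width between [s1,e1) and [s2,e2)
ivl_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# stopifnot with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
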