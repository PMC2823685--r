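DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()]. IUPAC
#' ambiguity codes (including `N`) are complemented according to the IUPAC
#' convention.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TAATGATAACGGTTATCATTT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# A/C/G/T -> 1..4, anything else (N etc.) -> NA
seq_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTNacgtn]*$" else "^[ACGTacgt]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T%s}: %s",
                 what, if (allow_n) ",N" else "",
                 paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(toupper(x))
}

# 0-based half-open slice of a genome sequence, optionally wrapping a
# circular contig; linear contigs truncate at the edges.
slice_sequence <- function(sequence, start, end, circular = FALSE) {
  len <- nchar(sequence)
  if (circular) {
    if (end - start > len) stop("slice longer than the circular contig", call. = FALSE)
    idx0 <- (seq.int(start, end - 1L) %% len)
    seq <- paste(strsplit(sequence, "", fixed = TRUE)[[1]][idx0 + 1L], collapse = "")
    return(list(seq = seq, truncated = FALSE))
  }
  s <- max(start, 0L)
  e <- min(end, len)
  if (s >= e) return(list(seq = "", truncated = TRUE))
  list(seq = substr(sequence, s + 1L, e),
       truncated = (s != start) || (e != end))
}
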