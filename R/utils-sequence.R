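#' RNA sequence helpers
#'
#' `as_rna()` normalises a nucleotide string to the RNA alphabet
#' (uppercase, T transcribed to U); any character outside {A,C,G,U,T}
#' is an error. `revcomp_rna()` returns the reverse complement.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @examples
#' as_rna("acgt")       # "ACGU"
#' revcomp_rna("GAGGUAG")
#' @export
as_rna <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("invalid nucleotide characters in sequence(s): ",
         paste(unique(unlist(regmatches(x[bad], gregexpr("[^ACGU]", x[bad])))),
               collapse = ", "))
  }
  x
}

#' @rdname as_rna
#' @export
revcomp_rna <- function(x) {
  x <- as_rna(x)
  vapply(x, function(s) {
    comp <- chartr("ACGU", "UGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# TRUE if the two RNA bases can form a Watson-Crick or G:U wobble pair
can_pair_rna <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}
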