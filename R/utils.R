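# Shared sequence utilities. Sequences are plain upper-case character
# scalars; T and U are interchangeable on input. Comparison, folding and
# scoring all canonicalize to RNA (T -> U) first; user-facing output keeps
# the input alphabet.

IUPAC_CHARS <- "ACGTURYSWKMBDHVN"

#' Canonicalize a nucleotide string to upper-case RNA
#'
#' Upper-cases and maps T to U. All scoring, folding and base-pairing
#' logic in the package operates on this canonical form, which makes
#' every operation invariant under T/U relabeling.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
canon_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Reverse complement preserving the input alphabet
#'
#' Complements IUPAC nucleotide codes and reverses. If the input uses U
#' (and no T), the result is written in the RNA alphabet, otherwise DNA.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
    has_u <- grepl("U", x, ignore.case = TRUE) & !grepl("T", x, ignore.case = TRUE)
    comp <- chartr("ACGTURYKMBDHVacgturykmbdhv",
                   "TGCAAYRMKVHDBtgcaayrmkvhdb", x)
    out <- vapply(strsplit(comp, "", fixed = TRUE),
                  function(ch) paste(rev(ch), collapse = ""), character(1))
    out[has_u] <- chartr("Tt", "Uu", out[has_u])
    out
}

# TRUE where the two canonical RNA bases can pair (Watson-Crick or GU)
can_pair_chr <- function(a, b) {
    (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "U") | (a == "U" & b == "G")
}

is_nucleotide_string <- function(x, allow_gap = FALSE) {
    pat <- if (allow_gap) sprintf("^[%s-]*$", IUPAC_CHARS) else sprintf("^[%s]*$", IUPAC_CHARS)
    grepl(pat, toupper(x))
}

ungapped_length <- function(x) nchar(gsub("-", "", x, fixed = TRUE))

# i.i.d. random sequence with given base composition (uses the current RNG)
random_seq <- function(n, alphabet = c("A", "C", "G", "U"), prob = NULL) {
    if (n <= 0) return("")
    paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

base_composition <- function(seq) {
    ch <- strsplit(canon_rna(seq), "", fixed = TRUE)[[1]]
    tab <- table(factor(ch, levels = c("A", "C", "G", "U")))
    p <- as.numeric(tab)
    if (sum(p) == 0) p <- rep(1, 4)
    p / sum(p)
}

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# file path or character vector -> lines, preserving empty lines
as_lines <- function(input) {
    if (length(input) == 1 && !grepl("\n", input) && file.exists(input))
        return(readLines(input))
    if (!length(input)) return(character(0))
    strsplit(paste(input, collapse = "\n"), "\n", fixed = TRUE)[[1]]
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
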