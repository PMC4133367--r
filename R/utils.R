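## Shared low-level helpers and amplicon constants.

# FR primer tails from the selection amplicon design, after stripping the
# 2-base multiplexing index ("nn"). The VH primer anneals to the 3' end of
# VH-FR3 (20 nt); the VL primer to the 5' end of VL-FR4 (18 nt).
VH_PRIMER_TAIL <- "CTGTTTATTACTGTGTGAGA"
VL_PRIMER_TAIL <- "CTTGGTCCCTCCGCCGAA"

# Downstream framework anchor that terminates the VH CDR3 loop: the first two
# codons of FR4 (Trp-Gly, "WG"). Configurable in the extraction functions.
VH_FR4_ANCHOR <- "TGGGGC"
# Coding-sense FR3 3' motif used to delimit the VL loop on reverse reads
# (Tyr-Cys tail of FR3).
VL_FR3_ANCHOR <- "TACTGT"

# Fixed downstream framework filler appended after the CDR3 anchor so every
# synthesized read reaches 100 bases (VH-FR4 + start of CH1, arbitrary but
# constant so demultiplexing is exercised against realistic flanks).
FR4_FILLER <- paste0(
  "CAAGGGACCACGGTCACCGTCTCCTCAGCCTCCACCAAGGGCCCATCGGTCTTCCCCCTGGCACCCTCCTCCAAGAGCACCTCTGGGGGCACAGCGGCC"
)

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table is used via its [ syntax in non-data.table-owning code
.datatable.aware <- TRUE

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences over `A,C,G,T,N`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Per-position mismatch count of each string's prefix against a reference
# string, on fixed positions (Hamming, no indels). Strings shorter than the
# reference count the missing positions as mismatches. N never matches.
hamming_to_ref <- function(x, ref) {
  L <- nchar(ref)
  ref_int <- utf8ToInt(ref)
  n <- length(x)
  if (n == 0L) return(integer(0))
  mism <- integer(n)
  padded <- paste0(x, strrep(" ", L))  # guard against short strings
  for (p in seq_len(L)) {
    mism <- mism + (substr(padded, p, p) != intToUtf8(ref_int[p]))
  }
  mism
}

# Deterministic RNG scoping: evaluate `expr` under `seed` (when non-NULL)
# without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Sense (non-stop) codons of the standard genetic code.
sense_codons <- function() {
  all <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(all, STOP_CODONS)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
}
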