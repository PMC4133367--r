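## Translation and frame/stop flagging of extracted CDR3 loops.

#' Translate CDR3 DNA and flag stop codons and frameshifts
#'
#' Translates each loop in frame 0 with the standard genetic code
#' (via Biostrings). A loop whose length is not divisible by 3 is a
#' frameshift: `in_frame` is `FALSE` and `cdr3_aa` is `NA`. `has_stop` is
#' computed from the complete frame-0 codons for every loop, so a stop can be
#' flagged even on a frameshifted loop. Sequences containing characters other
#' than A/C/G/T are marked `valid = FALSE` and are excluded downstream.
#'
#' @param cdr3_dna character vector of CDR3 DNA loops.
#' @return data.frame with columns `cdr3_dna`, `cdr3_aa`, `has_stop`,
#'   `in_frame`, `valid`.
#' @export
translate_and_flag <- function(cdr3_dna) {
  n <- length(cdr3_dna)
  valid <- grepl("^[ACGT]+$", cdr3_dna)
  len <- nchar(cdr3_dna)
  in_frame <- valid & len %% 3L == 0L & len > 0L
  aa_full <- rep(NA_character_, n)
  has_stop <- rep(NA, n)

  idx <- which(valid & len >= 3L)
  if (length(idx)) {
    trimmed <- substr(cdr3_dna[idx], 1L, 3L * (len[idx] %/% 3L))
    aa <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                            no.init.codon = TRUE)))
    has_stop[idx] <- grepl("*", aa, fixed = TRUE)
    aa_full[idx[in_frame[idx]]] <- aa[in_frame[idx]]
  }
  has_stop[valid & len < 3L] <- FALSE

  data.frame(cdr3_dna = cdr3_dna, cdr3_aa = aa_full,
             has_stop = has_stop, in_frame = in_frame, valid = valid,
             stringsAsFactors = FALSE)
}
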