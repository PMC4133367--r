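## Demultiplexing of indexed amplicon reads and CDR3 clonotype extraction,
## reproducing the sequencing-centre sorting rules: the first 2 bases must
## match a round index exactly; the next 18-20 bases must match one of the
## two FR primer tails with at most one mismatch (Hamming, no indels; N
## always counts as a mismatch).

default_primers <- function() {
  c(VH = VH_PRIMER_TAIL, VL = VL_PRIMER_TAIL)
}

#' Demultiplex reads by round index and chain primer
#'
#' @param seqs character vector of read sequences (A/C/G/T/N).
#' @param index_map named character vector, round label -> 2-base index.
#' @param primers named character vector of FR primer tails (after the 2-base
#'   index); names are the chain labels. Default: the VH-FR3 tail (20 nt) and
#'   the VL-FR4 tail (18 nt) of the selection amplicon.
#' @param max_mismatch maximum primer mismatches (default 1; the index allows
#'   none).
#' @return data.frame with one row per read: `round` (NA when unassigned),
#'   `chain`, and `reason` (`assigned`, `bad_index`, `bad_primer`,
#'   `ambiguous`).
#' @export
demultiplex <- function(seqs, index_map, primers = default_primers(),
                        max_mismatch = 1L) {
  stopifnot(length(index_map) > 0, !is.null(names(index_map)))
  seqs <- toupper(seqs)
  n <- length(seqs)
  if (n == 0L) {
    return(data.frame(round = character(0), chain = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  idx <- substr(seqs, 1L, 2L)
  round <- names(index_map)[match(idx, unname(index_map))]

  mism <- sapply(primers, function(p) hamming_to_ref(substr(seqs, 3L, 1e6L), p))
  mism <- matrix(mism, nrow = n, dimnames = list(NULL, names(primers)))
  hit <- mism <= max_mismatch
  n_hits <- rowSums(hit)

  chain <- rep(NA_character_, n)
  one <- which(n_hits == 1L)
  chain[one] <- colnames(hit)[max.col(hit[one, , drop = FALSE], "first")]

  reason <- rep("assigned", n)
  reason[is.na(round)] <- "bad_index"
  reason[!is.na(round) & n_hits == 0L] <- "bad_primer"
  reason[!is.na(round) & n_hits > 1L] <- "ambiguous"
  assigned <- reason == "assigned"
  round[!assigned] <- NA_character_
  chain[!assigned] <- NA_character_
  data.frame(round = round, chain = chain, reason = reason,
             stringsAsFactors = FALSE)
}

#' Extract the CDR3 clonotype key from an assigned read
#'
#' After consuming the 2-base index and the matched primer tail, the default
#' (`mode = "loop"`) returns the full loop up to the first occurrence of the
#' downstream framework anchor motif; when the anchor is absent the first 25
#' bases of the variable region are used as the counting key. In
#' `mode = "prefix25"` the key is always the first 25 bases (the counting rule
#' of the original sorting script). Reads with fewer than 25 usable bases (or
#' an anchor flush against the primer) are dropped. VL-end reads are sequenced
#' from the reverse strand; their keys are reverse-complemented to coding
#' sense, using the reverse-complemented FR3 anchor as delimiter.
#'
#' @param seqs character vector of read sequences.
#' @param chain per-read chain label (`"VH"` or `"VL"`), as returned by
#'   [demultiplex()].
#' @param mode `"loop"` (full anchored loop, 25-base fallback) or
#'   `"prefix25"`.
#' @param primers as in [demultiplex()]; determines how many bases to skip.
#' @param anchors named character vector of coding-sense anchor motifs per
#'   chain.
#' @return character vector of clonotype keys; `NA` for dropped reads.
#' @export
extract_cdr3 <- function(seqs, chain, mode = c("loop", "prefix25"),
                         primers = default_primers(),
                         anchors = c(VH = VH_FR4_ANCHOR, VL = VL_FR3_ANCHOR)) {
  mode <- match.arg(mode)
  seqs <- toupper(seqs)
  out <- rep(NA_character_, length(seqs))
  for (ch in unique(chain[!is.na(chain)])) {
    sel <- which(chain == ch)
    rest <- substr(seqs[sel], 3L + nchar(primers[[ch]]), 1e6L)
    search_anchor <- if (ch == "VL") revcomp(anchors[[ch]]) else anchors[[ch]]
    key <- extract_keys(rest, search_anchor, mode)
    if (ch == "VL") {
      ok <- !is.na(key)
      key[ok] <- revcomp(key[ok])
    }
    out[sel] <- key
  }
  out
}

extract_keys <- function(rest, anchor, mode) {
  key <- rep(NA_character_, length(rest))
  if (mode == "loop") {
    pos <- regexpr(anchor, rest, fixed = TRUE)
    hit <- pos >= 2L  # anchor flush against the primer leaves no loop
    key[hit] <- substr(rest[hit], 1L, pos[hit] - 1L)
    fallback <- pos < 0L & nchar(rest) >= 25L
    key[fallback] <- substr(rest[fallback], 1L, 25L)
  } else {
    ok <- nchar(rest) >= 25L
    key[ok] <- substr(rest[ok], 1L, 25L)
  }
  key
}

#' Build a count table from assigned reads
#'
#' Exact multiset counts per (clonotype key, round), with rows ordered
#' lexicographically by sequence so the table is independent of read order.
#'
#' @param keys character vector of clonotype keys (NA = dropped).
#' @param rounds per-read round labels (NA = unassigned).
#' @param round_order the column order; defaults to sorted unique labels.
#' @return a [new_clone_counts()] table.
#' @export
build_count_table <- function(keys, rounds,
                              round_order = sort(unique(stats::na.omit(rounds)))) {
  ok <- !is.na(keys) & !is.na(rounds)
  dt <- data.table::data.table(cdr3 = keys[ok], rnd = rounds[ok])
  if (nrow(dt) == 0L) {
    counts <- matrix(integer(0), nrow = 0, ncol = length(round_order),
                     dimnames = list(NULL, round_order))
    clones <- data.frame(clone_id = character(0), cdr3_dna = character(0),
                         stringsAsFactors = FALSE)
    return(new_clone_counts(counts, clones))
  }
  agg <- dt[, .N, by = c("cdr3", "rnd")]
  keys_u <- sort(unique(agg$cdr3))
  counts <- matrix(0L, nrow = length(keys_u), ncol = length(round_order),
                   dimnames = list(NULL, round_order))
  counts[cbind(match(agg$cdr3, keys_u), match(agg$rnd, round_order))] <- agg$N
  clones <- data.frame(clone_id = sprintf("k%06d", seq_along(keys_u)),
                       cdr3_dna = keys_u, stringsAsFactors = FALSE)
  new_clone_counts(counts, clones)
}

#' Demultiplex and count a read set in one pass
#'
#' @param reads a FASTQ/FASTA path (plain or gzipped) or a character vector of
#'   read sequences.
#' @param index_map named character vector, round label -> 2-base index; also
#'   fixes the column order of the output table.
#' @inheritParams extract_cdr3
#' @return list with `counts` (a `clone_counts`), and `qc` — assigned /
#'   unassigned / dropped tallies, per round and overall; the three categories
#'   partition the input reads.
#' @export
demux_count <- function(reads, index_map, mode = c("loop", "prefix25"),
                        primers = default_primers()) {
  mode <- match.arg(mode)
  if (length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fa|fasta)(\\.gz)?$", reads)) "fasta" else "fastq"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  asg <- demultiplex(reads, index_map, primers)
  keys <- rep(NA_character_, length(reads))
  sel <- asg$reason == "assigned"
  keys[sel] <- extract_cdr3(reads[sel], asg$chain[sel], mode = mode,
                            primers = primers)
  dropped <- sel & is.na(keys)
  counts <- build_count_table(keys, asg$round, round_order = names(index_map))
  tb_un <- table(asg$reason[asg$reason != "assigned"])
  tb_rd <- table(factor(asg$round[sel & !dropped], levels = names(index_map)))
  qc <- list(
    total = length(reads),
    assigned = sum(sel & !dropped),
    dropped = sum(dropped),
    unassigned = setNames(as.integer(tb_un), names(tb_un)),
    per_round = setNames(as.integer(tb_rd), names(tb_rd))
  )
  list(counts = counts, qc = qc)
}
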