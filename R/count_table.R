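## clone_counts: the clone-by-round integer count table that every analysis
## stage consumes. Rows are CDR3 clonotypes, columns are ordered selection
## rounds; per-round depths and frequencies f(c, r) are derived on demand.

#' Construct a clone-by-round count table
#'
#' @param counts integer matrix, one row per clonotype, one column per round.
#'   Row names are clone ids; column names the ordered round labels.
#' @param clones data.frame describing the row clonotypes; must contain
#'   `clone_id` and `cdr3_dna`, and may carry `cdr3_aa`, `has_stop`,
#'   `in_frame`. Missing translation flags are filled with
#'   [translate_and_flag()].
#' @return an object of class `clone_counts`.
#' @export
new_clone_counts <- function(counts, clones) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (is.null(colnames(counts))) stop("counts must have round labels as colnames")
  if (!all(c("clone_id", "cdr3_dna") %in% names(clones))) {
    stop("`clones` needs at least clone_id and cdr3_dna columns")
  }
  if (nrow(counts) != nrow(clones)) stop("counts and clones disagree on row count")
  rownames(counts) <- clones$clone_id
  if (!all(c("cdr3_aa", "has_stop", "in_frame") %in% names(clones))) {
    fl <- translate_and_flag(clones$cdr3_dna)
    clones$cdr3_aa <- fl$cdr3_aa
    clones$has_stop <- fl$has_stop
    clones$in_frame <- fl$in_frame
    clones$valid <- fl$valid
  }
  structure(list(counts = counts, clones = clones,
                 rounds = colnames(counts)),
            class = "clone_counts")
}

#' @export
print.clone_counts <- function(x, ...) {
  cat(sprintf("<clone_counts> %d clonotypes x %d rounds (%s)\n",
              nrow(x$counts), length(x$rounds), paste(x$rounds, collapse = ", ")))
  cat("depths:", paste(sprintf("%s=%d", x$rounds, depths(x)), collapse = "  "), "\n")
  invisible(x)
}

#' Per-round sequencing depths (column sums)
#' @param x a `clone_counts` object.
#' @return named integer vector of per-round depths.
#' @export
depths <- function(x) {
  stopifnot(inherits(x, "clone_counts"))
  colSums(x$counts)
}

#' Per-round clone frequencies f(c, r)
#'
#' Frequencies are counts divided by the per-round depth; each column sums to
#' one whenever its depth is positive.
#'
#' @param x a `clone_counts` object.
#' @return numeric matrix of the same shape as the counts.
#' @export
freqs <- function(x) {
  stopifnot(inherits(x, "clone_counts"))
  d <- depths(x)
  sweep(x$counts, 2L, pmax(d, 1L), "/")
}

#' Write / read a count table as TSV
#'
#' Columns are `clone_id`, `sequence`, then one integer column per round, in
#' round order — the on-disk interchange format between pipeline stages.
#'
#' @param x a `clone_counts` object.
#' @param path file path.
#' @return `write_count_table` returns `path` invisibly; `read_count_table`
#'   returns a `clone_counts`.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "clone_counts"))
  df <- data.frame(clone_id = x$clones$clone_id,
                   sequence = x$clones$cdr3_dna,
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  rounds <- setdiff(names(df), c("clone_id", "sequence"))
  counts <- as.matrix(df[, rounds, drop = FALSE])
  clones <- data.frame(clone_id = df$clone_id, cdr3_dna = df$sequence,
                       stringsAsFactors = FALSE)
  new_clone_counts(counts, clones)
}
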