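#' Allele-class count tables
#'
#' An allele-class count table records, for each copy-number class `j`,
#' the number of alleles observed in exactly `j` identical copies. It is
#' the observed analogue of the limit frequency spectrum and the data
#' object consumed by [fit_gp()] and [gof_test()].
#'
#' @param class Vector of copy-number classes (positive integers, unique).
#' @param count Vector of allele counts per class (nonnegative integers,
#'   at least one positive).
#' @param label Optional name for the table (e.g. a subfamily name).
#' @return An object of class `"class_counts"`: a list with integer
#'   vectors `class` and `count` (sorted by class) and the `label`.
#' @examples
#' class_counts(c(1, 2, 3), c(120, 7, 1), label = "toy")
#' @export
class_counts <- function(class, count, label = NULL) {
  stopifnot(is.numeric(class), is.numeric(count),
            length(class) == length(count), length(class) >= 1L)
  if (any(class < 1 | class != floor(class)))
    stop("class_counts: classes must be positive integers", call. = FALSE)
  if (anyDuplicated(class))
    stop("class_counts: duplicate class ",
         class[duplicated(class)][1L], call. = FALSE)
  if (any(count < 0 | count != floor(count)))
    stop("class_counts: counts must be nonnegative integers", call. = FALSE)
  if (sum(count) <= 0)
    stop("class_counts: at least one count must be positive", call. = FALSE)
  o <- order(class)
  keep <- count[o] > 0
  structure(list(class = as.integer(class[o][keep]),
                 count = as.integer(count[o][keep]),
                 label = label),
            class = "class_counts")
}

#' @export
print.class_counts <- function(x, ...) {
  cat("Allele-class counts",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  print(stats::setNames(x$count, x$class))
  cat(sprintf("  %d alleles in %d classes (max class %d)\n",
              sum(x$count), length(x$class), max(x$class)))
  invisible(x)
}

#' Total number of alleles in a count table
#' @param counts A [class_counts()] object.
#' @return Integer total.
#' @export
n_alleles <- function(counts) {
  stopifnot(inherits(counts, "class_counts"))
  sum(counts$count)
}

#' Read / write allele-class count tables
#'
#' Plain tab-separated format: a header line `class<TAB>count`, one row
#' per class, optionally preceded by a `# label: <name>` comment line.
#' `read_counts()` and `write_counts()` round-trip exactly.
#'
#' @param path File path.
#' @return `read_counts()` returns a [class_counts()] object;
#'   `write_counts()` returns `path` invisibly.
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("read_counts: empty file: ", path, call. = FALSE)
  label <- NULL
  lab <- grep("^#\\s*label:", lines)
  if (length(lab))
    label <- trimws(sub("^#\\s*label:", "", lines[lab[1L]]))
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("read_counts: no data rows in ", path,
                              call. = FALSE)
  header <- strsplit(lines[body_idx[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || tolower(header[1L]) != "class" ||
      tolower(header[2L]) != "count")
    stop("read_counts: expected header 'class\\tcount' at line ",
         body_idx[1L], call. = FALSE)
  rows_idx <- body_idx[-1L]
  cl <- integer(0); ct <- integer(0)
  for (i in rows_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (length(f) < 2L || any(is.na(v)))
      stop("read_counts: malformed row at line ", i, ": '", lines[i], "'",
           call. = FALSE)
    if (v[1L] %in% cl)
      stop("read_counts: duplicate class ", v[1L], " at line ", i,
           call. = FALSE)
    cl <- c(cl, v[1L]); ct <- c(ct, v[2L])
  }
  class_counts(cl, ct, label = label)
}

#' @rdname read_counts
#' @param counts A [class_counts()] object to write.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "class_counts"))
  lines <- c(if (!is.null(counts$label)) paste0("# label: ", counts$label),
             "class\tcount",
             paste(counts$class, counts$count, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Class counts from pre-aligned sequences
#'
#' Groups equal-length, pre-aligned nucleotide sequences by exact string
#' identity (after uppercasing; gap characters and ambiguity codes are
#' compared literally) and turns the multiset of group sizes into an
#' allele-class count table: an allele observed in `k` identical copies
#' contributes one count to class `k`.
#'
#' @param path Path to a FASTA file of pre-aligned, equal-length records.
#' @param label Optional table label (defaults to the file name).
#' @return A [class_counts()] object.
#' @export
counts_from_fasta <- function(path, label = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs))
    stop("counts_from_fasta: no sequences in ", path, call. = FALSE)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L) {
    off <- names(seqs)[w != stats::median(w)]
    stop("counts_from_fasta: sequences are not equal length; offending ",
         "records: ", paste(utils::head(off, 5), collapse = ", "),
         if (length(off) > 5) " ...", call. = FALSE)
  }
  groups <- table(toupper(as.character(seqs)))
  sizes <- table(as.integer(groups))
  class_counts(as.integer(names(sizes)), as.integer(sizes),
               label = if (is.null(label)) basename(path) else label)
}
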