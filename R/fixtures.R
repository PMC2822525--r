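#' Packaged AluY subfamily class-count tables
#'
#' Allele-class count tables for nine AluY subfamilies extracted from the
#' March 2006 human reference assembly (sequences provided by the Genetic
#' Information Research Institute; classes with more than 20 copies are
#' omitted in the published table). `alu_subfamilies()` lists the nine
#' subfamily labels; `alu_counts()` returns one table, including the
#' published aggregate row under the label `"All"`. The tables are stored
#' as a plain TSV under `inst/extdata` and reproduce the published rows
#' cell for cell.
#'
#' @param subfamily One of `alu_subfamilies()` or `"All"`.
#' @return `alu_counts()`: a [class_counts()] object.
#'   `alu_subfamilies()`: a character vector of the nine labels.
#' @examples
#' alu_subfamilies()
#' alu_counts("Ya5")
#' @export
alu_counts <- function(subfamily) {
  tab <- alu_table1()
  subfamily <- match.arg(subfamily, unique(tab$subfamily))
  rows <- tab[tab$subfamily == subfamily, ]
  class_counts(rows$class, rows$count, label = paste0("Alu", subfamily))
}

#' @rdname alu_counts
#' @export
alu_subfamilies <- function() {
  setdiff(unique(alu_table1()$subfamily), "All")
}

# the raw long-format table, one row per (subfamily, class)
alu_table1 <- function() {
  path <- system.file("extdata", "alu_table1.tsv", package = "aluspectra",
                      mustWork = TRUE)
  utils::read.delim(path, colClasses = c("character", "integer", "integer"))
}
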