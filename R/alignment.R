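#' Construct a multiple sequence alignment object
#'
#' The central container of the package: a taxa-by-columns character matrix
#' over a declared alphabet plus optional gene boundaries. Gene intervals are
#' stored 1-based and closed (R convention); on disk (NEXUS CHARSET) they are
#' likewise written 1-based inclusive.
#'
#' @param matrix character matrix, rows = taxa; rownames used as taxon names
#'   unless `taxon_names` is given.
#' @param alphabet one of `"AA20"`, `"STATE6"`, `"BINARY"`.
#' @param taxon_names optional character vector of unique taxon labels.
#' @param gene_map optional data.frame with columns `gene`, `start`, `end`
#'   (1-based, closed, non-overlapping, in increasing order).
#' @param gap,missing gap and missing symbols (preserved distinctly on
#'   output; both are treated as missing data by the likelihood engine).
#' @return an object of class `"aln"`.
#' @export
alignment <- function(matrix, alphabet = "AA20", taxon_names = NULL,
                      gene_map = NULL, gap = "-", missing = "?") {
  if (!is.matrix(matrix) || !is.character(matrix))
    stop("alignment-shape error: `matrix` must be a character matrix")
  if (is.null(taxon_names)) taxon_names <- rownames(matrix)
  if (is.null(taxon_names))
    stop("identifier error: taxon names are required")
  if (anyDuplicated(taxon_names))
    stop("identifier error: duplicate taxon name: ",
         taxon_names[duplicated(taxon_names)][1])
  if (length(taxon_names) != nrow(matrix))
    stop("alignment-shape error: ", nrow(matrix), " rows but ",
         length(taxon_names), " taxon names")
  rownames(matrix) <- taxon_names
  colnames(matrix) <- NULL
  ok <- c(.alphabet_states(alphabet), .missing_symbols(alphabet), gap, missing)
  bad <- which(!(matrix %in% ok))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(matrix))
    stop(sprintf(
      "alphabet error: symbol '%s' at row %d (%s), column %d not in %s",
      matrix[bad[1]], rc[1], taxon_names[rc[1]], rc[2], alphabet))
  }
  if (!is.null(gene_map)) gene_map <- .check_gene_map(gene_map, ncol(matrix))
  structure(list(matrix = matrix, alphabet = alphabet,
                 gap = gap, missing = missing, gene_map = gene_map),
            class = "aln")
}

.check_gene_map <- function(gm, ncols) {
  stopifnot(is.data.frame(gm), all(c("gene", "start", "end") %in% names(gm)))
  gm <- gm[, c("gene", "start", "end")]
  gm$start <- as.integer(gm$start); gm$end <- as.integer(gm$end)
  if (nrow(gm) == 0) return(gm)
  if (any(gm$start < 1L | gm$end > ncols | gm$start > gm$end))
    stop("bounds error: gene interval outside alignment columns")
  gm <- gm[order(gm$start), , drop = FALSE]
  if (any(gm$start[-1] <= gm$end[-nrow(gm)]))
    stop("bounds error: overlapping gene intervals")
  if (anyDuplicated(gm$gene)) stop("identifier error: duplicate gene name")
  rownames(gm) <- NULL
  gm
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("<alignment: %d taxa x %d columns, alphabet %s%s>\n",
              nrow(x$matrix), ncol(x$matrix), x$alphabet,
              if (is.null(x$gene_map)) ""
              else sprintf(", %d genes", nrow(x$gene_map))))
  invisible(x)
}

#' @export
dim.aln <- function(x) dim(x$matrix)

n_taxa <- function(aln) nrow(aln$matrix)
n_cols <- function(aln) ncol(aln$matrix)
taxon_names <- function(aln) rownames(aln$matrix)

# logical matrix: which cells are missing-equivalent
is_missing_cell <- function(aln) {
  m <- aln$matrix %in% c(.missing_symbols(aln$alphabet), aln$gap, aln$missing)
  dim(m) <- dim(aln$matrix)
  m
}

# integer state matrix: 1..A for states, NA for missing
state_index_matrix <- function(aln) {
  states <- .alphabet_states(aln$alphabet)
  s <- match(aln$matrix, states)
  dim(s) <- dim(aln$matrix)
  rownames(s) <- rownames(aln$matrix)
  s
}

# column subset, dropping the gene map unless remapped by the caller
subset_columns <- function(aln, cols, gene_map = NULL) {
  alignment(aln$matrix[, cols, drop = FALSE], alphabet = aln$alphabet,
            gene_map = gene_map, gap = aln$gap, missing = aln$missing)
}

# observed state frequencies (missing excluded), in canonical state order
observed_frequencies <- function(aln, pseudocount = 0.5) {
  states <- .alphabet_states(aln$alphabet)
  cnt <- table(factor(aln$matrix, levels = states))
  f <- as.numeric(cnt) + pseudocount
  f / sum(f)
}
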