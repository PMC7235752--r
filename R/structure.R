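# Structural partitioning: Henikoff position-based sequence weights,
# weighted consensus sequences, per-column structural class maps, and
# extraction of concatenated per-class alignments.

STRUCT_CLASSES <- c("HELIX_EXP", "HELIX_BUR", "SHEET_EXP", "SHEET_BUR",
                    "COIL_EXP", "COIL_BUR")

#' Henikoff position-based sequence weights
#'
#' Each sequence receives, at every column where it holds a non-missing
#' residue, weight 1/(r * n_a), where r is the number of distinct residue
#' types in the column and n_a the count of the sequence's own residue.
#' Gaps and missing cells contribute nothing and do not count as residue
#' types. Raw weights are normalized to sum 1.
#'
#' @param aln an [alignment()].
#' @return numeric vector of normalized weights, named by taxon.
#' @export
henikoff_weights <- function(aln) {
  m <- aln$matrix
  miss <- is_missing_cell(aln)
  raw <- numeric(n_taxa(aln))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]; obs <- !miss[, j]
    if (!any(obs)) next
    counts <- table(col[obs])
    r <- length(counts)
    w <- 1 / (r * as.numeric(counts[col[obs]]))
    raw[obs] <- raw[obs] + w
  }
  if (sum(raw) == 0)
    stop("degenerate-input error: alignment is entirely missing")
  stats::setNames(raw / sum(raw), taxon_names(aln))
}

#' Weighted consensus sequence
#'
#' Per column, each residue is scored by the summed weights of the sequences
#' holding it (missing cells excluded); the consensus residue is the argmax,
#' with ties broken by canonical amino-acid order. All-missing columns get
#' `"X"`.
#'
#' @param aln an [alignment()] (amino-acid alphabet).
#' @param weights per-taxon weights; defaults to [henikoff_weights()].
#' @return character vector, one residue per column.
#' @export
weighted_consensus <- function(aln, weights = henikoff_weights(aln)) {
  if (length(weights) != n_taxa(aln))
    stop("shape error: ", length(weights), " weights for ",
         n_taxa(aln), " taxa")
  states <- .alphabet_states(aln$alphabet)
  miss <- is_missing_cell(aln)
  vapply(seq_len(n_cols(aln)), function(j) {
    obs <- !miss[, j]
    if (!any(obs)) return("X")
    sc <- tapply(weights[obs], factor(aln$matrix[obs, j], levels = states),
                 sum)
    sc[is.na(sc)] <- 0
    states[which.max(sc)]  # which.max takes the first maximum: canonical order
  }, "")
}

#' Build a per-column structural class map
#'
#' Combines a secondary-structure annotation string (over H/E/C) and an
#' accessibility string (`e` = exposed, `-` = buried, the two-class call of
#' accessibility predictors) into the six combined classes. Annotations
#' derive from a consensus sequence and apply to every taxon in the column.
#'
#' @param ss secondary-structure string, length `ncols`.
#' @param acc accessibility string over `e`/`-`, length `ncols`.
#' @param ncols alignment column count.
#' @return list with per-column `ss`, `acc` (as `"e"`/`"b"`), and `combined`
#'   labels, class `"class_map"`.
#' @export
build_class_map <- function(ss, acc, ncols) {
  sv <- strsplit(ss, "")[[1]]; av <- strsplit(acc, "")[[1]]
  if (length(sv) != ncols || length(av) != ncols)
    stop("annotation-length error: ss length ", length(sv), ", acc length ",
         length(av), ", but ", ncols, " columns")
  if (!all(sv %in% c("H", "E", "C")))
    stop("alphabet error: secondary-structure symbols must be H/E/C")
  if (!all(av %in% c("e", "-", "b")))
    stop("alphabet error: accessibility symbols must be e/-")
  av <- ifelse(av == "e", "e", "b")
  ssname <- c(H = "HELIX", E = "SHEET", C = "COIL")[sv]
  accname <- c(e = "EXP", b = "BUR")[av]
  structure(list(ss = sv, acc = av,
                 combined = paste(ssname, accname, sep = "_")),
            class = "class_map")
}

#' Read a structural annotation file
#'
#' Plain-text records in predictor-output style: `>gene` then one
#' secondary-structure line (H/E/C) and one accessibility line (e/-).
#'
#' @param path file path.
#' @return named list of `list(ss=, acc=)` per gene.
#' @export
read_annotations <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("parse error: no '>' records in ", path)
  out <- lapply(seq_along(hdr), function(i) {
    from <- hdr[i] + 1
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    if (to - from != 1)
      stop("parse error: record ", sub("^>", "", lines[hdr[i]]),
           " must have exactly one SS line and one ACC line")
    list(ss = lines[from], acc = lines[to])
  })
  names(out) <- sub("^>\\s*", "", lines[hdr])
  out
}

# resolve a class selector to a predicate over a class_map
.class_selector <- function(selector) {
  selector <- toupper(selector)
  if (selector %in% STRUCT_CLASSES)
    return(function(map) map$combined == selector)
  switch(selector,
    EXPOSED = function(map) map$acc == "e",
    BURIED  = function(map) map$acc == "b",
    HELIX   = function(map) map$ss == "H",
    SHEET   = function(map) map$ss == "E",
    COIL    = function(map) map$ss == "C",
    stop("unknown class selector: ", selector))
}

#' Extract and concatenate the sites of one structural class
#'
#' Columns matching the selector are taken from each gene in gene order
#' (column order preserved within genes) and concatenated. Columns that are
#' entirely missing are assigned to no class. The returned charset table
#' records the interval each gene contributed.
#'
#' @param genes list of `list(aln=, map=)` pairs: a gene alignment and its
#'   [build_class_map()]. All gene alignments must share one taxon set
#'   (pad absent taxa with all-missing rows first).
#' @param selector `"exposed"`, `"buried"`, `"helix"`, `"sheet"`, `"coil"`,
#'   or one of the six combined labels (`"helix_exp"`, ...).
#' @return list with `alignment` (concatenated [alignment()] whose
#'   `gene_map` holds the per-gene intervals) and `charsets` (the same
#'   table).
#' @export
extract_class_sites <- function(genes, selector) {
  pred <- .class_selector(selector)
  taxa <- taxon_names(genes[[1]]$aln)
  blocks <- list(); rows <- list()
  for (g in seq_along(genes)) {
    aln <- genes[[g]]$aln; map <- genes[[g]]$map
    if (!setequal(taxon_names(aln), taxa))
      stop("taxon-mismatch error: gene ", g,
           " has a different taxon set")
    keep <- pred(map) & colSums(!is_missing_cell(aln)) > 0
    if (!any(keep)) next
    nm <- names(genes)[g]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("g", g)
    blocks[[length(blocks) + 1]] <-
      list(gene = nm, m = aln$matrix[taxa, keep, drop = FALSE])
  }
  alphabet <- genes[[1]]$aln$alphabet
  if (!length(blocks)) {
    empty <- alignment(matrix(character(0), nrow = length(taxa), ncol = 0,
                              dimnames = list(taxa, NULL)),
                       alphabet = alphabet)
    return(list(alignment = empty,
                charsets = data.frame(gene = character(0),
                                      start = integer(0), end = integer(0))))
  }
  widths <- vapply(blocks, function(b) ncol(b$m), 0L)
  ends <- cumsum(widths)
  gm <- data.frame(gene = vapply(blocks, `[[`, "", "gene"),
                   start = c(1L, utils::head(ends, -1) + 1L), end = ends)
  m <- do.call(cbind, lapply(blocks, `[[`, "m"))
  out <- alignment(m, alphabet = alphabet, gene_map = gm)
  list(alignment = out, charsets = gm)
}
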