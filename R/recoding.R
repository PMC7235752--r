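# Amino-acid recoding: Dayhoff six-state classes and binary
# purine/pyrimidine (RY) coding of the back-translated codon positions.

#' Dayhoff six-state recoding
#'
#' Collapses the 20 amino acids into six physicochemical classes
#' (0 = C; 1 = AGPST; 2 = NDEQ; 3 = RHK; 4 = ILMV; 5 = FWY). Gap and
#' missing cells become `?`. Column count is preserved.
#'
#' @param aln an amino-acid [alignment()].
#' @return a `STATE6` [alignment()] with the same dimensions and gene map.
#' @export
dayhoff6_recode <- function(aln) {
  stopifnot(aln$alphabet == "AA20")
  m <- aln$matrix
  out <- DAYHOFF6_TABLE[m]
  out[is.na(out)] <- "?"     # gap, ?, X, B, Z -> missing
  dim(out) <- dim(m)
  alignment(out, alphabet = "STATE6", taxon_names = taxon_names(aln),
            gene_map = aln$gene_map)
}

#' Binary purine/pyrimidine (RY) recoding via back-translation
#'
#' Each amino-acid column expands to three binary columns (codon positions
#' 1-3): positions where every codon of the residue carries a purine become
#' `0`, every-pyrimidine positions become `1`, and positions that are mixed
#' across the residue's codons become `?` (as do gap/missing cells).
#' Columns whose cells are all `?` are then removed.
#'
#' @param aln an amino-acid [alignment()].
#' @return list with `alignment` (a `BINARY` [alignment()]) and `provenance`
#'   (data.frame `column` = original alignment column, `codon_position` =
#'   1, 2 or 3, one row per retained output column).
#' @export
ry_recode <- function(aln) {
  stopifnot(aln$alphabet == "AA20")
  m <- aln$matrix
  codes <- RY_TABLE[m]
  codes[is.na(codes)] <- "???"
  nt <- n_taxa(aln); nc <- n_cols(aln)
  # expand: output column order is (col1 pos1, col1 pos2, col1 pos3, col2 ...)
  chars <- matrix(unlist(strsplit(codes, ""), use.names = FALSE), nrow = 3)
  big <- matrix("?", nt, 3L * nc, dimnames = list(taxon_names(aln), NULL))
  for (p in 1:3) big[, seq(p, 3L * nc, by = 3L)] <- matrix(chars[p, ], nt, nc)
  prov <- data.frame(column = rep(seq_len(nc), each = 3L),
                     codon_position = rep(1:3, nc))
  keep <- colSums(big != "?") > 0
  list(alignment = alignment(big[, keep, drop = FALSE], alphabet = "BINARY",
                             taxon_names = taxon_names(aln)),
       provenance = prov[keep, , drop = FALSE])
}

# Derive the RY table from a codon->amino-acid code by positionwise
# enumeration (exposed for use as a consistency check).
derive_ry_table <- function(code = GENETIC_CODE_1) {
  aas <- sort(unique(code[code != "*"]))
  purine <- c("A", "G")
  out <- vapply(aas, function(aa) {
    codons <- names(code)[code == aa]
    paste(vapply(1:3, function(p) {
      nts <- unique(substr(codons, p, p))
      ry <- unique(ifelse(nts %in% purine, "0", "1"))
      if (length(ry) == 1) ry else "?"
    }, ""), collapse = "")
  }, "")
  names(out) <- aas
  out
}
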