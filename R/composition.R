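# Compositional heterogeneity diagnostics: GARP/FYMINK ratios on
# parsimony-informative sites and back-translated nucleotide composition
# along the strong-weak, amino-keto and purine-pyrimidine axes for codon
# positions 1-2.

# per-amino-acid sets of possible nucleotides at codon positions 1..3
.codon_position_sets <- function(code = GENETIC_CODE_1) {
  aas <- sort(unique(code[code != "*"]))
  out <- lapply(aas, function(aa) {
    codons <- names(code)[code == aa]
    lapply(1:3, function(p) sort(unique(substr(codons, p, p))))
  })
  names(out) <- aas
  out
}

.AXES <- list(
  strong_weak = list(first = c("G", "C"), second = c("A", "T")),
  amino_keto  = list(first = c("A", "C"), second = c("G", "T")),
  purine_pyrimidine = list(first = c("A", "G"), second = c("C", "T")))

#' GARP/FYMINK ratios per taxon
#'
#' Restricts the alignment to parsimony-informative columns, counts per
#' taxon the residues encoded by GC-rich codons (G, A, R, P) and by AT-rich
#' codons (F, Y, M, I, N, K), and reports their ratio (missing when the
#' FYMINK count is zero). Gap/missing cells are skipped.
#'
#' @param aln amino-acid [alignment()].
#' @param informative_only restrict to parsimony-informative columns
#'   (default TRUE, the usual convention).
#' @return data.frame with `taxon`, `garp`, `fymink`, `ratio`.
#' @export
garp_fymink_ratios <- function(aln, informative_only = TRUE) {
  stopifnot(aln$alphabet == "AA20")
  cols <- if (informative_only) parsimony_informative_columns(aln)
          else seq_len(n_cols(aln))
  if (!length(cols)) {
    warning("no parsimony-informative columns")
    return(data.frame(taxon = taxon_names(aln), garp = 0L, fymink = 0L,
                      ratio = NA_real_))
  }
  m <- aln$matrix[, cols, drop = FALSE]
  garp <- rowSums(matrix(m %in% GARP_SET, nrow(m)))
  fymink <- rowSums(matrix(m %in% FYMINK_SET, nrow(m)))
  data.frame(taxon = taxon_names(aln), garp = garp, fymink = fymink,
             ratio = ifelse(fymink > 0, garp / fymink, NA_real_),
             row.names = NULL)
}

#' Back-translated nucleotide-axis composition (codon positions 1-2)
#'
#' Back-translates each residue to its sets of possible nucleotides at
#' codon positions 1 and 2 under the standard genetic code, keeps the
#' expanded position columns that are parsimony-informative over their
#' fully determinate (single-nucleotide) cells, and reports per taxon, for
#' each axis, the proportion of axis-determinate cells falling in the
#' axis's first class: strong (G+C) vs weak, amino (A+C) vs keto, purine
#' (A+G) vs pyrimidine. A cell counts on an axis when all its possible
#' nucleotides lie on one side (e.g. leucine position 1, C-or-T, counts as
#' pyrimidine); otherwise it is skipped on that axis.
#'
#' @param aln amino-acid [alignment()].
#' @return data.frame with one row per taxon: `taxon`, `strong_weak`,
#'   `amino_keto`, `purine_pyrimidine` (proportions, `NA` when no
#'   determinate cell), and `skipped_<axis>` counts.
#' @export
codon12_axis_composition <- function(aln) {
  stopifnot(aln$alphabet == "AA20")
  psets <- .codon_position_sets()
  nt <- n_taxa(aln); nc <- n_cols(aln)
  # expanded cells: list by position with the nucleotide set per cell
  key <- function(aa, p) {
    if (is.na(aa) || !aa %in% names(psets)) return(NULL)
    psets[[aa]][[p]]
  }
  # informativeness over determinate (singleton) states per expanded column
  informative <- function(p) {
    vapply(seq_len(nc), function(j) {
      nts <- vapply(aln$matrix[, j], function(a) {
        s <- key(a, p)
        if (is.null(s) || length(s) != 1) NA_character_ else s
      }, "")
      cnt <- table(nts[!is.na(nts)])
      sum(cnt >= 2) >= 2
    }, logical(1))
  }
  keep1 <- informative(1); keep2 <- informative(2)
  first <- matrix(0, nt, 3); tot <- matrix(0, nt, 3); skip <- matrix(0, nt, 3)
  for (p in 1:2) {
    keep <- if (p == 1) keep1 else keep2
    for (j in which(keep)) {
      for (i in seq_len(nt)) {
        s <- key(aln$matrix[i, j], p)
        if (is.null(s)) next
        for (ax in seq_along(.AXES)) {
          a <- .AXES[[ax]]
          if (all(s %in% a$first)) { first[i, ax] <- first[i, ax] + 1
                                     tot[i, ax] <- tot[i, ax] + 1 }
          else if (all(s %in% a$second)) tot[i, ax] <- tot[i, ax] + 1
          else skip[i, ax] <- skip[i, ax] + 1
        }
      }
    }
  }
  prop <- first / tot
  prop[!is.finite(prop)] <- NA_real_
  out <- data.frame(taxon = taxon_names(aln),
                    strong_weak = prop[, 1], amino_keto = prop[, 2],
                    purine_pyrimidine = prop[, 3],
                    skipped_strong_weak = skip[, 1],
                    skipped_amino_keto = skip[, 2],
                    skipped_purine_pyrimidine = skip[, 3],
                    row.names = NULL)
  out
}

#' Full per-taxon composition report
#'
#' Convenience wrapper combining [garp_fymink_ratios()] and
#' [codon12_axis_composition()].
#'
#' @param aln amino-acid [alignment()].
#' @return merged data.frame.
#' @export
composition_report <- function(aln) {
  merge(garp_fymink_ratios(aln), codon12_axis_composition(aln),
        by = "taxon", sort = FALSE)
}
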