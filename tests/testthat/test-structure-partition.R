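# Henikoff weights, weighted consensus, class maps and per-class
# extraction.

aln_from_rows <- function(rows, alphabet = "AA20") {
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- paste0("t", seq_along(rows))
  alignment(m, alphabet = alphabet)
}

test_that("Henikoff weights match direct formula evaluation", {
  # identical sequences share weight equally
  expect_equal(unname(henikoff_weights(aln_from_rows(c("ACD", "ACD")))),
               c(0.5, 0.5))
  # single column (A, A, C): r = 2, A rows get 1/4, C row 1/2
  expect_equal(unname(henikoff_weights(aln_from_rows(c("A", "A", "C")))),
               c(0.25, 0.25, 0.5))
  # two columns AA/AC/GC: raw (0.75, 0.5, 0.75)
  expect_equal(unname(henikoff_weights(aln_from_rows(c("AA", "AC", "GC")))),
               c(0.375, 0.25, 0.375))
  expect_error(henikoff_weights(aln_from_rows(c("--", "??"))),
               "degenerate-input")
})

test_that("weighted consensus scores, ties and degenerate columns", {
  al <- aln_from_rows(c("ACD", "ACD", "ACD"))
  expect_equal(paste(weighted_consensus(al), collapse = ""), "ACD")

  al2 <- aln_from_rows(c("AA", "AC", "GC"))
  expect_equal(paste(weighted_consensus(al2), collapse = ""), "AC")

  # Henikoff equalization forces an exact A/C tie; canonical order wins
  al3 <- aln_from_rows(c("A", "A", "C"))
  expect_equal(weighted_consensus(al3), "A")

  # all-missing column yields X; single-sequence consensus is the sequence
  al4 <- aln_from_rows(c("A-D"))
  expect_equal(paste(weighted_consensus(al4,
                                        weights = 1), collapse = ""), "AXD")
  expect_error(weighted_consensus(al3, weights = c(1, 1)), "shape error")
})

test_that("class maps combine SS and accessibility", {
  cm <- build_class_map("HHCC", "ee--", 4)
  expect_equal(cm$combined, c("HELIX_EXP", "HELIX_EXP", "COIL_BUR",
                              "COIL_BUR"))
  expect_error(build_class_map("HHCCE", "ee--", 4), "annotation-length")
  expect_error(build_class_map("HHQC", "ee--", 4), "alphabet error")
})

test_that("class extraction: bookkeeping, exhaustivity, empty selectors", {
  al <- aln_from_rows(c("ACDE", "ACDF", "GCDE"))
  cm_all_coil <- build_class_map("CCCC", "eeee", 4)
  genes <- list(gA = list(aln = al, map = cm_all_coil))

  full <- extract_class_sites(genes, "coil_exp")
  expect_equal(full$alignment$matrix, al$matrix)
  for (other in c("helix_exp", "sheet_bur", "buried"))
    expect_equal(ncol(extract_class_sites(genes, other)$alignment$matrix), 0L)

  # exposed selector picks alternating columns in order
  cm2 <- build_class_map("CCCC", "e-e-", 4)
  sub <- extract_class_sites(list(g = list(aln = al, map = cm2)), "exposed")
  expect_equal(sub$alignment$matrix, al$matrix[, c(1, 3)])

  # two genes contribute labelled contiguous intervals
  genes2 <- list(g1 = list(aln = al, map = cm2),
                 g2 = list(aln = al, map = cm2))
  both <- extract_class_sites(genes2, "exposed")
  expect_equal(both$charsets,
               data.frame(gene = c("g1", "g2"), start = c(1L, 3L),
                          end = c(2L, 4L)))

  # inconsistent taxon sets error out
  alx <- aln_from_rows(c("ACDE", "ACDF"))
  expect_error(extract_class_sites(list(g1 = list(aln = al, map = cm2),
                                        g2 = list(aln = alx, map = cm2)),
                                   "exposed"),
               "taxon-mismatch")
})

test_that("the six combined classes partition the annotated columns", {
  set.seed(31)
  for (rep in 1:5) {
    nc <- sample(10:40, 1)
    al <- random_alignment(5, nc, missing_frac = 0.2)
    # force one all-missing column, which must join no class
    al$matrix[, 1] <- "?"
    cm <- build_class_map(paste(sample(c("H", "E", "C"), nc, TRUE),
                                collapse = ""),
                          paste(sample(c("e", "-"), nc, TRUE),
                                collapse = ""), nc)
    genes <- list(g = list(aln = al, map = cm))
    counts6 <- vapply(tolower(structphylo:::STRUCT_CLASSES), function(sel)
      ncol(extract_class_sites(genes, sel)$alignment$matrix), 0L)
    annotated <- sum(colSums(!structphylo:::is_missing_cell(al)) > 0)
    expect_equal(sum(counts6), annotated)
    # EXPOSED u BURIED and HELIX u SHEET u COIL likewise cover everything
    eb <- vapply(c("exposed", "buried"), function(sel)
      ncol(extract_class_sites(genes, sel)$alignment$matrix), 0L)
    hsc <- vapply(c("helix", "sheet", "coil"), function(sel)
      ncol(extract_class_sites(genes, sel)$alignment$matrix), 0L)
    expect_equal(sum(eb), annotated)
    expect_equal(sum(hsc), annotated)
  }
})

test_that("extraction recovers the simulated class columns exactly", {
  cfg <- simulation_config(tree = random_unrooted_tree(6), n_genes = 3,
                           gene_length = 40, missing_fraction = 0,
                           seed = 99)
  ds <- simulate_alignment(cfg)
  genes <- lapply(seq_len(nrow(ds$alignment$gene_map)), function(g) {
    gm <- ds$alignment$gene_map
    list(aln = structphylo:::subset_columns(ds$alignment,
                                            gm$start[g]:gm$end[g]),
         map = ds$class_maps[[g]])
  })
  ext <- extract_class_sites(genes, "exposed")
  truth <- ds$alignment$matrix[, ds$site_class == "exposed", drop = FALSE]
  expect_equal(ext$alignment$matrix, truth)
})
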