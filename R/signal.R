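# Signal exploration: decisive sites, class contingency testing, per-gene
# outlier scans, and parsimony summaries (Fitch steps, informative sites,
# retention index).

#' Decisive sites between two candidate topologies
#'
#' Computes the per-site log-likelihood difference `d_i = lnL_i(T_a) -
#' lnL_i(T_b)` and flags sites whose difference deviates from the chosen
#' centre by more than `m` population standard deviations. Positive
#' deviations favour the first topology.
#'
#' @param site_lnl_a,site_lnl_b per-site log-likelihood vectors of equal
#'   length under the two topologies.
#' @param m standard-deviation multiplier (default 5, the usual rule).
#' @param center `"mean"` (default: deviations measured from the mean
#'   difference) or `"zero"`.
#' @return a `decisive_sites` list: `delta`, `mu`, `sigma`, `m`,
#'   `decisive_a`, `decisive_b` (site indices), `n_a`, `n_b`.
#' @export
decisive_sites <- function(site_lnl_a, site_lnl_b, m = 5,
                           center = c("mean", "zero")) {
  center <- match.arg(center)
  if (length(site_lnl_a) != length(site_lnl_b))
    stop("shape error: unequal per-site vectors")
  n <- length(site_lnl_a)
  if (n < 2) stop("need at least two sites")
  d <- site_lnl_a - site_lnl_b
  mu <- if (center == "mean") mean(d) else 0
  sigma <- sqrt(mean((d - mean(d))^2))   # population SD about the mean
  dec <- if (sigma > 0) abs(d - mu) > m * sigma else rep(FALSE, n)
  # membership is judged by deviation from the centre; the favoured
  # topology by the sign of the difference itself
  ia <- which(dec & d > 0)
  ib <- which(dec & d < 0)
  structure(list(delta = d, mu = mu, sigma = sigma, m = m,
                 decisive_a = ia, decisive_b = ib,
                 n_a = length(ia), n_b = length(ib)),
            class = "decisive_sites")
}

#' @export
print.decisive_sites <- function(x, ...) {
  cat(sprintf(
    "<decisive sites: %d favour T_a, %d favour T_b (m = %g, mu = %.4g, sd = %.4g)>\n",
    x$n_a, x$n_b, x$m, x$mu, x$sigma))
  invisible(x)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' One-sided tests give the exact hypergeometric tail probability of the
#' observed or a more extreme table in the stated direction
#' (`"greater"` = positive association of row 1 with column 1); the
#' two-sided test sums tables with probability not exceeding the observed.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("greater", "less",
                                             "two_sided")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("shape error: need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("domain error: counts must be non-negative integers")
  alt <- switch(alternative, greater = "greater", less = "less",
                two_sided = "two.sided")
  stats::fisher.test(table, alternative = alt)$p.value
}

#' Per-gene log-likelihood outlier scan
#'
#' Sums the per-site log-likelihood difference between two candidate
#' topologies within each gene and flags any gene whose absolute summed
#' difference exceeds `fold_threshold` times the largest absolute
#' difference among the other genes.
#'
#' @param aln an [alignment()] with a populated `gene_map`.
#' @param tree_a,tree_b the two candidate topologies.
#' @param model substitution model used for both.
#' @param fold_threshold flagging multiplier (default 3).
#' @param site_lnl_a,site_lnl_b optional precomputed per-site vectors
#'   (skips the likelihood computation).
#' @return data.frame with `gene`, `n_sites`, `delta_lnl`, `flagged`.
#' @export
gene_outlier_scan <- function(aln, tree_a = NULL, tree_b = NULL,
                              model = NULL, fold_threshold = 3,
                              site_lnl_a = NULL, site_lnl_b = NULL) {
  gm <- aln$gene_map
  if (is.null(gm) || nrow(gm) == 0)
    stop("gene_map required for the outlier scan")
  if (is.null(site_lnl_a)) {
    site_lnl_a <- site_log_likelihoods(aln, tree_a, model)
    site_lnl_b <- site_log_likelihoods(aln, tree_b, model)
  }
  d <- site_lnl_a - site_lnl_b
  per_gene <- vapply(seq_len(nrow(gm)),
                     function(g) sum(d[gm$start[g]:gm$end[g]]), 0)
  out <- data.frame(gene = gm$gene,
                    n_sites = gm$end - gm$start + 1L,
                    delta_lnl = per_gene)
  out$flagged <- flag_outlier_genes(per_gene, fold_threshold)
  if (nrow(out) < 2) warning("fewer than two genes: no flags possible")
  out
}

#' @rdname gene_outlier_scan
#' @param delta_lnl per-gene summed log-likelihood differences.
#' @export
flag_outlier_genes <- function(delta_lnl, fold_threshold = 3) {
  a <- abs(delta_lnl)
  if (length(a) < 2) return(rep(FALSE, length(a)))
  vapply(seq_along(a),
         function(i) a[i] > fold_threshold * max(a[-i]),
         logical(1))
}

# ---- Fitch parsimony --------------------------------------------------------

# Fitch bottom-up state sets as bitmasks; missing = union of all states.
.fitch_column <- function(states, tree, A) {
  ntip <- length(tree$tip.label)
  full <- bitwShiftL(1L, A) - 1L
  setmask <- integer(ntip + tree$Nnode)
  tipmask <- ifelse(is.na(states), full, bitwShiftL(1L, states - 1L))
  setmask[seq_len(ntip)] <- tipmask
  steps <- 0L
  edge <- tree$edge
  parents <- unique(edge[, 1])
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    cm <- setmask[ch]
    if (setmask[p] == 0L) setmask[p] <- cm
    else {
      inter <- bitwAnd(setmask[p], cm)
      if (inter == 0L) { setmask[p] <- bitwOr(setmask[p], cm); steps <- steps + 1L }
      else setmask[p] <- inter
    }
  }
  steps
}

#' Parsimony summary of an alignment on a tree
#'
#' Per character: observed Fitch steps (missing cells treated as the union
#' of all states), the minimum steps on any tree (observed states - 1), the
#' maximum steps on any tree (non-missing taxa minus the largest state
#' count), and a parsimony-informativeness flag (at least two states each
#' in at least two taxa, missing excluded). The ensemble retention index
#' `RI = (sum G - sum S) / (sum G - sum M)` excludes characters with
#' `G = M` from both sums.
#'
#' @param aln an [alignment()].
#' @param tree ape `phylo` over the alignment's taxa.
#' @return a `parsimony_report` list: data.frame `per_character`
#'   (`s_obs`, `s_min`, `s_max`, `informative`) and scalar
#'   `retention_index`.
#' @export
parsimony_summary <- function(aln, tree) {
  tree <- .prep_tree(tree, taxon_names(aln))
  sidx <- .tip_states(aln, tree)
  A <- length(.alphabet_states(aln$alphabet))
  nchr <- ncol(sidx)
  s_obs <- integer(nchr); s_min <- integer(nchr); s_max <- integer(nchr)
  info <- logical(nchr)
  for (j in seq_len(nchr)) {
    col <- sidx[, j]
    obs <- col[!is.na(col)]
    cnt <- tabulate(obs, nbins = A)
    nstates <- sum(cnt > 0)
    s_min[j] <- max(nstates - 1L, 0L)
    s_max[j] <- if (length(obs)) length(obs) - max(cnt) else 0L
    info[j] <- sum(cnt >= 2) >= 2
    s_obs[j] <- if (nstates >= 2) .fitch_column(col, tree, A) else 0L
  }
  keep <- s_max > s_min
  ri <- if (any(keep))
    (sum(s_max[keep]) - sum(s_obs[keep])) /
      (sum(s_max[keep]) - sum(s_min[keep]))
  else NA_real_
  structure(list(per_character = data.frame(s_obs = s_obs, s_min = s_min,
                                            s_max = s_max,
                                            informative = info),
                 retention_index = ri),
            class = "parsimony_report")
}

#' @export
print.parsimony_report <- function(x, ...) {
  pc <- x$per_character
  cat(sprintf(
    "<parsimony: %d characters, %d informative, total steps %d, RI = %s>\n",
    nrow(pc), sum(pc$informative), sum(pc$s_obs),
    format(round(x$retention_index, 4))))
  invisible(x)
}

#' Indices of parsimony-informative columns
#'
#' A column is informative when at least two states each occur in at least
#' two taxa (missing cells excluded).
#'
#' @param aln an [alignment()].
#' @return integer vector of column indices.
#' @export
parsimony_informative_columns <- function(aln) {
  sidx <- state_index_matrix(aln)
  A <- length(.alphabet_states(aln$alphabet))
  which(apply(sidx, 2, function(col) {
    cnt <- tabulate(col[!is.na(col)], nbins = A)
    sum(cnt >= 2) >= 2
  }))
}
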