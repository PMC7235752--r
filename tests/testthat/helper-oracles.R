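# Independent oracles and fixture builders used across the test files.
# These deliberately avoid the package's own pruning/Fitch/recoding code
# paths: likelihoods are computed by exhaustive summation over internal
# states with Matrix::expm, parsimony by exhaustive labelling, recoding by
# direct codon enumeration.

random_alignment <- function(n_taxa, n_cols, alphabet = "AA20",
                             missing_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- switch(alphabet, AA20 = structphylo::AA_ORDER,
                   STATE6 = as.character(0:5), BINARY = c("0", "1"))
  m <- matrix(sample(states, n_taxa * n_cols, replace = TRUE), n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  if (missing_frac > 0)
    m[runif(length(m)) < missing_frac] <- "?"
  alignment(m, alphabet = alphabet)
}

random_unrooted_tree <- function(n_taxa, max_bl = 0.8) {
  tr <- ape::rtopology(n_taxa, rooted = FALSE,
                       tip.label = paste0("t", seq_len(n_taxa)))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, max_bl)
  tr
}

# exhaustive-likelihood oracle: sum over all internal-state assignments,
# Gamma categories averaged, using Matrix::expm for P(t)
brute_site_loglik <- function(aln, tree, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  A <- model$n_states
  Q <- build_rate_matrix(model)
  gr <- discrete_gamma_rates(model$alpha, model$k_categories)
  states <- switch(model$alphabet, AA20 = structphylo::AA_ORDER,
                   STATE6 = as.character(0:5), BINARY = c("0", "1"))
  sidx <- matrix(match(aln$matrix, states), nrow(aln$matrix))
  sidx <- sidx[match(tree$tip.label, rownames(aln$matrix)), , drop = FALSE]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- tree$edge[nrow(tree$edge), 1]
  internals <- (ntip + 1):nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(A)), length(internals))))
  vapply(seq_len(ncol(sidx)), function(s) {
    tot <- 0
    for (k in seq_along(gr)) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
        as.matrix(Matrix::expm(Q * gr[k] * tree$edge.length[e])))
      for (g in seq_len(nrow(grid))) {
        asgn <- integer(nnode)
        asgn[internals] <- grid[g, ]
        asgn[seq_len(ntip)] <- sidx[, s]
        p <- model$frequencies[asgn[root]]
        for (e in seq_len(nrow(tree$edge))) {
          b <- asgn[tree$edge[e, 2]]
          if (is.na(b)) next                 # missing tip sums to 1
          p <- p * Ps[[e]][asgn[tree$edge[e, 1]], b]
        }
        tot <- tot + p / length(gr)
      }
    }
    log(tot)
  }, 0)
}

# exhaustive Fitch length: minimize steps over all internal labelings
brute_fitch_steps <- function(states, tree, A) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internals <- (ntip + 1):nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(A)), length(internals))))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    asgn <- integer(nnode)
    asgn[internals] <- grid[g, ]
    asgn[seq_len(ntip)] <- states
    steps <- 0
    for (e in seq_len(nrow(tree$edge))) {
      a <- asgn[tree$edge[e, 1]]; b <- asgn[tree$edge[e, 2]]
      if (is.na(b)) next                     # missing tip joins for free
      if (a != b) steps <- steps + 1
    }
    best <- min(best, steps)
  }
  best
}

# one-sided hypergeometric tail by direct enumeration (factorial ratios)
brute_fisher_greater <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  amax <- min(r1, c1)
  amin <- max(0, r1 + c1 - n)
  p_of <- function(x)
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  sum(vapply(a:amax, p_of, 0))
}

# best rigid alignment (rotation/reflection + translation) RMS
procrustes_rms <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$u %*% t(s$v)
  sqrt(mean((Xc %*% R - Yc)^2))
}
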