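# Felsenstein pruning over P(t) = exp(Qt) for generic n-state reversible
# models, with per-node log-scaling of partial likelihoods, discrete-Gamma /
# invariant-site / profile mixtures, and the up/down message passing that
# also powers expected-sufficient-statistic (EM) computations.

# fast column maxima for small-row matrices
.colmax <- function(M) {
  m <- M[1, ]
  if (nrow(M) > 1) for (i in 2:nrow(M)) m <- pmax(m, M[i, ])
  m
}

# ---- tree bookkeeping -------------------------------------------------------

.prep_tree <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!setequal(tree$tip.label, taxa))
    stop("taxon-mismatch error: tree leaves do not match alignment taxa")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  ape::reorder.phylo(tree, "postorder")
}

# integer states (NA = missing) with rows in tree tip order
.tip_states <- function(aln, tree) {
  s <- state_index_matrix(aln)
  s[tree$tip.label, , drop = FALSE]
}

# ---- core passes ------------------------------------------------------------

# Upward (post-order) pass for one rate-matrix component.
# Returns per-node scaled partials/log-scales and per-edge child messages
# cont_e = P_e %*% up_child (scaled).
.up_pass <- function(sidx, tree, dec, pi, rate) {
  A <- length(pi); N <- ncol(sidx)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge; ne <- nrow(edge)
  part <- vector("list", nnode); pscale <- vector("list", nnode)
  cont <- vector("list", ne); cscale <- vector("list", ne)
  Plist <- vector("list", ne)
  for (e in seq_len(ne)) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    P <- transition_prob(dec, rate * tree$edge.length[e])
    Plist[[e]] <- P
    if (ch <= ntip) {
      s <- sidx[ch, ]
      cm <- matrix(1, A, N)
      obs <- which(!is.na(s))
      if (length(obs)) cm[, obs] <- P[, s[obs]]
      sc <- numeric(N)
    } else {
      cm <- P %*% part[[ch]]
      sc <- pscale[[ch]]
    }
    cont[[e]] <- cm; cscale[[e]] <- sc
    if (is.null(part[[p]])) { part[[p]] <- cm; pscale[[p]] <- sc }
    else { part[[p]] <- part[[p]] * cm; pscale[[p]] <- pscale[[p]] + sc }
    # rescale the parent partial to avoid underflow
    mx <- .colmax(part[[p]])
    mx[mx <= 0] <- 1
    part[[p]] <- part[[p]] / rep(mx, each = A)
    pscale[[p]] <- pscale[[p]] + log(mx)
  }
  root <- edge[ne, 1]
  lik <- colSums(part[[root]] * pi)
  list(loglik = log(lik) + pscale[[root]],
       part = part, pscale = pscale,
       cont = cont, cscale = cscale, Plist = Plist, root = root)
}

# Downward (pre-order) pass: for each edge e = (p, ch), the outer message
# O_e(a) = P(X_p = a, data outside subtree(ch)) up to the returned scale.
.down_pass <- function(up, tree, pi) {
  edge <- tree$edge; ne <- nrow(edge)
  A <- length(pi); N <- length(up$loglik)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  Fmsg <- vector("list", nnode); Fscale <- vector("list", nnode)
  Fmsg[[up$root]] <- matrix(pi, A, N)
  Fscale[[up$root]] <- numeric(N)
  O <- vector("list", ne); Oscale <- vector("list", ne)
  children <- split(seq_len(ne), edge[, 1])
  for (e in rev(seq_len(ne))) {      # reverse postorder = preorder
    p <- edge[e, 1]; ch <- edge[e, 2]
    sib <- setdiff(children[[as.character(p)]], e)
    om <- Fmsg[[p]]; osc <- Fscale[[p]]
    for (s2 in sib) { om <- om * up$cont[[s2]]; osc <- osc + up$cscale[[s2]] }
    O[[e]] <- om; Oscale[[e]] <- osc
    if (ch > ntip) {
      fm <- crossprod(up$Plist[[e]], om)     # t(P) %*% O
      mx <- .colmax(fm); mx[mx <= 0] <- 1
      Fmsg[[ch]] <- fm / rep(mx, each = A)
      Fscale[[ch]] <- osc + log(mx)
    }
  }
  list(O = O, Oscale = Oscale)
}

# ---- mixture assembly -------------------------------------------------------

# Expand a model into mixture components: list of (pi, dec, rate, logw).
# Gamma categories have equal weights; profile components carry their own
# weights; the invariant class is handled separately by the caller.
.components <- function(model) {
  if (inherits(model, "profile_mixture")) {
    rates_vec <- model$rates
    A <- nrow(model$profiles)
    gr <- discrete_gamma_rates(model$alpha, model$k_categories)
    K <- length(gr)
    comps <- list()
    for (c in seq_len(ncol(model$profiles))) {
      pi <- model$profiles[, c]
      Q <- build_rate_matrix(list(rates = rates_vec, frequencies = pi))
      dec <- decompose_q(Q, pi)
      for (k in seq_len(K))
        comps[[length(comps) + 1]] <- list(
          pi = pi, dec = dec, rate = gr[k],
          logw = log(model$weights[c]) - log(K))
    }
    comps
  } else {
    Q <- build_rate_matrix(model)
    dec <- decompose_q(Q, model$frequencies)
    gr <- discrete_gamma_rates(model$alpha, model$k_categories)
    lapply(seq_along(gr), function(k)
      list(pi = model$frequencies, dec = dec, rate = gr[k],
           logw = -log(length(gr))))
  }
}

# per-site log-likelihood of the invariant (zero-rate) class
.invariant_site_loglik <- function(sidx, pi_list, logw_list) {
  N <- ncol(sidx); A <- length(pi_list[[1]])
  out <- rep(-Inf, N)
  nstates <- apply(sidx, 2, function(s) length(unique(s[!is.na(s)])))
  out[nstates == 0] <- 0
  one <- which(nstates == 1)
  if (length(one)) {
    st <- apply(sidx[, one, drop = FALSE], 2,
                function(s) s[!is.na(s)][1])
    mix <- numeric(length(one))
    for (i in seq_along(pi_list))
      mix <- mix + exp(logw_list[[i]]) * pi_list[[i]][st]
    out[one] <- log(mix)
  }
  out
}

.logsumexp_rows <- function(L) {
  # L: n_comp x N matrix of logs; column-wise log-sum-exp
  M <- apply(L, 2, max)
  log(colSums(exp(L - rep(M, each = nrow(L))))) + M
}

#' Per-site log likelihoods on a fixed tree
#'
#' Felsenstein pruning with per-node scaling. Gamma categories are averaged
#' with equal weights; profile mixtures sum weighted per-profile site
#' likelihoods before taking logs; an invariant-site class is mixed in when
#' `p_inv > 0`. Gap/missing cells contribute all-ones partials.
#'
#' @param aln an [alignment()].
#' @param tree ape `phylo` whose tip labels equal the alignment's taxa.
#' @param model a [substitution_model()] or [profile_mixture_model()].
#' @return numeric vector of per-site log likelihoods (`sum()` gives the
#'   total).
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  if (n_cols(aln) == 0) stop("empty alignment")
  A_model <- if (inherits(model, "profile_mixture")) nrow(model$profiles)
             else model$n_states
  if (length(.alphabet_states(aln$alphabet)) != A_model)
    stop("alphabet mismatch between alignment and model")
  tree <- .prep_tree(tree, taxon_names(aln))
  sidx <- .tip_states(aln, tree)
  comps <- .components(model)
  L <- matrix(0, length(comps), ncol(sidx))
  for (i in seq_along(comps)) {
    cc <- comps[[i]]
    up <- .up_pass(sidx, tree, cc$dec, cc$pi, cc$rate)
    L[i, ] <- up$loglik + cc$logw
  }
  ll <- .logsumexp_rows(L)
  p_inv <- if (inherits(model, "profile_mixture")) model$p_inv else model$p_inv
  if (p_inv > 0) {
    pis <- lapply(comps, `[[`, "pi")
    lw <- lapply(comps, `[[`, "logw")
    linv <- .invariant_site_loglik(sidx, pis, lw)
    both <- rbind(log1p(-p_inv) + ll, log(p_inv) + linv)
    ll <- .logsumexp_rows(both)
  }
  if (any(!is.finite(ll)))
    stop("numerical error: non-finite site log likelihood")
  ll
}

# ---- expected sufficient statistics (E-step) --------------------------------

# Joint integrals over one edge via the eigen decomposition:
# J_kl = int_0^t exp(l_k s + l_l (t-s)) ds.
.J_matrix <- function(lambda, t) {
  A <- length(lambda)
  lk <- matrix(lambda, A, A)
  ll <- t(lk)
  dd <- lk - ll
  ek <- exp(lk * t); el <- exp(ll * t)
  J <- (ek - el) / dd
  close <- abs(dd) < 1e-9
  J[close] <- t * ek[close]
  J
}

# Expected substitution counts N_ij, waiting times W_i (in base-Q time
# units) and root-state counts R_i for one mixture component, where the
# per-site posterior weight of the component is exp(logw + lnL_comp(s) -
# lnL_total(s)). `lnl_total` is the full-mixture per-site log likelihood.
.estep_component <- function(sidx, tree, dec, pi, rate, logw, lnl_total,
                             up = NULL) {
  A <- length(pi)
  if (is.null(up)) up <- .up_pass(sidx, tree, dec, pi, rate)
  dn <- .down_pass(up, tree, pi)
  edge <- tree$edge; ne <- nrow(edge)
  ntip <- length(tree$tip.label)
  # base-unit Q: with the edge run for time rate * t, expected counts are
  # q_ij H_ij(rate * t) and waiting times (in base units) are H_ii(rate * t)
  Qbase <- (dec$U * rep(dec$lambda, each = A)) %*% dec$V
  Nij <- matrix(0, A, A); Wi <- numeric(A)
  for (e in seq_len(ne)) {
    ch <- edge[e, 2]
    if (ch <= ntip) {
      s <- sidx[ch, ]
      upc <- matrix(1, A, ncol(sidx))
      obs <- which(!is.na(s))
      if (length(obs)) { upc[, obs] <- 0; upc[cbind(s[obs], obs)] <- 1 }
      usc <- numeric(ncol(sidx))
    } else { upc <- up$part[[ch]]; usc <- up$pscale[[ch]] }
    w <- exp(logw + dn$Oscale[[e]] + usc - lnl_total)
    Mt <- (dn$O[[e]] * rep(w, each = A)) %*% t(upc)   # A x A
    tt <- rate * tree$edge.length[e]
    if (tt <= 0) next
    G <- crossprod(dec$U, Mt) %*% t(dec$V)
    H <- crossprod(dec$V, (G * .J_matrix(dec$lambda, tt))) %*% t(dec$U)
    Nij <- Nij + Qbase * H
    Wi <- Wi + diag(H)
  }
  wroot <- exp(logw + up$pscale[[up$root]] - lnl_total)
  Ri <- as.numeric((up$part[[up$root]] * pi) %*% wroot)
  diag(Nij) <- 0
  Nij[Nij < 0] <- 0
  Wi[Wi < 0] <- 0
  list(N = Nij, W = Wi, R = Ri, loglik = up$loglik)
}

#' Resampling-of-log-likelihoods (RELL) support for candidate topologies
#'
#' Bootstrap of per-site log likelihoods: each replicate resamples sites
#' with replacement, the topology with the largest summed log likelihood
#' wins, and exact ties split the win equally.
#'
#' @param site_lnl matrix of per-site log likelihoods, sites x topologies.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return named vector of support percentages (summing to 100).
#' @export
rell_bootstrap <- function(site_lnl, B = 1000L, seed = 1L) {
  site_lnl <- as.matrix(site_lnl)
  if (ncol(site_lnl) < 2) stop("need at least two topologies")
  if (B <= 0) stop("domain error: B must be positive")
  n <- nrow(site_lnl)
  wins <- numeric(ncol(site_lnl))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    tot <- colSums(site_lnl[idx, , drop = FALSE])
    best <- which(tot >= max(tot) - 1e-12)
    wins[best] <- wins[best] + 1 / length(best)
  }
  out <- 100 * wins / B
  names(out) <- colnames(site_lnl)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
    envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
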