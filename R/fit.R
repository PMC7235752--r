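# Maximum-likelihood fitting of a substitution model on a fixed topology.
# Scalar parameters (alpha, p_inv, individual branch lengths) are optimized
# by Brent 1-D ascent; the exchangeability/frequency block is optimized by
# an expectation-maximization scheme on expected substitution counts and
# waiting times, which scales to the 190-parameter amino-acid case. When
# exchangeabilities are free an overall rate scale is implicitly free as
# well; the returned model is normalized to mean rate 1 and the returned
# branch lengths absorb the scale.

# raw (unnormalized) Q for the complete-data M-step bookkeeping
.q_unnorm <- function(r, pi) {
  A <- length(pi)
  Q <- exch_vec_to_mat(r, A) * rep(pi, each = A)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# one EM update of (rates, pi) from expected statistics; returns new values
# plus the implied mean-rate scale of the raw update
.m_step <- function(N, W, R, r_old, pi_old, update_r = TRUE,
                    update_pi = TRUE, inner = 8) {
  A <- length(pi_old)
  pidx <- pair_index(A)
  r <- exch_vec_to_mat(r_old, A)
  pi <- pi_old
  Nsym <- N + t(N)
  Cin <- colSums(N) + R          # counts into each state (+ root draws)
  for (it in seq_len(inner)) {
    if (update_r) {
      den <- outer(W, pi) + t(outer(W, pi))   # W_i pi_j + W_j pi_i
      rnew <- Nsym / den
      rnew[!is.finite(rnew)] <- r[!is.finite(rnew)]
      diag(rnew) <- 0
      r <- rnew
    }
    if (update_pi) {
      D <- as.numeric(W %*% r)               # sum_i W_i r_ij
      f <- function(lam) sum(Cin / (lam + D)) - 1
      lo <- -min(D) + 1e-9
      hi <- sum(Cin) + max(D) + 1
      if (f(lo) > 0) {
        lam <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
        pi <- Cin / (lam + D)
      }
      pi <- pmax(pi, 1e-10); pi <- pi / sum(pi)
    }
  }
  rvec <- r[lower.tri(r)]
  Qraw <- .q_unnorm(rvec, pi)
  scale <- -sum(pi * diag(Qraw))
  list(rates = rvec / sum(rvec), frequencies = pi, scale = scale)
}

# total log likelihood helper
.lnl <- function(aln, tree, model) sum(site_log_likelihoods(aln, tree, model))

# free-parameter census
.k_census <- function(free, n_taxa, A) {
  k <- 0
  if ("branch_lengths" %in% free) k <- k + (2 * n_taxa - 3)
  if ("alpha" %in% free) k <- k + 1
  if ("p_inv" %in% free) k <- k + 1
  if ("pi" %in% free) k <- k + (A - 1)
  if ("rates" %in% free) k <- k + (A * (A - 1) / 2 - 1)
  k
}

#' Fit a substitution model on a fixed topology
#'
#' Iterates over the requested free-parameter blocks until the log
#' likelihood improves by less than `tol`. The free-parameter count `k`
#' used for AICc counts 2N-3 branch lengths, 1 for alpha, 1 for p_inv,
#' A-1 frequencies and A(A-1)/2 - 1 exchangeabilities.
#'
#' @param aln an [alignment()].
#' @param tree fixed topology (ape `phylo`); branch lengths are the
#'   starting values when `"branch_lengths"` is free.
#' @param model starting [substitution_model()].
#' @param free character subset of `c("branch_lengths", "alpha", "p_inv",
#'   "pi", "rates")`.
#' @param tol stop when the per-cycle log-likelihood gain drops below this.
#' @param max_iter maximum number of outer cycles.
#' @param em_steps EM updates of the rate/frequency block per outer cycle.
#' @return a `model_fit` list: `model`, `tree` (fitted branch lengths),
#'   `lnL`, `k`, `n`, `aicc`, `converged`, `iterations`, `trace`.
#' @export
fit_fixed_topology <- function(aln, tree, model,
                               free = c("branch_lengths", "alpha", "pi"),
                               tol = 1e-3, max_iter = 50L, em_steps = 5L) {
  if (n_cols(aln) == 0) stop("empty alignment")
  free <- match.arg(free, c("branch_lengths", "alpha", "p_inv", "pi",
                            "rates"), several.ok = TRUE)
  tree <- .prep_tree(tree, taxon_names(aln))
  if ("branch_lengths" %in% free && all(tree$edge.length == 0))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  sidx <- .tip_states(aln, tree)
  cur <- model
  lnl <- .lnl(aln, tree, cur)
  trace <- lnl
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lnl_start <- lnl
    if (any(c("rates", "pi") %in% free)) {
      for (s in seq_len(em_steps)) {
        res <- .em_update(aln, sidx, tree, cur,
                          update_r = "rates" %in% free,
                          update_pi = "pi" %in% free)
        cur$rates <- res$rates
        cur$frequencies <- res$frequencies
        tree$edge.length <- tree$edge.length * res$scale
        lnl_new <- .lnl(aln, tree, cur)
        if (lnl_new < lnl - 1e-6)
          warning("EM step decreased the log likelihood by ",
                  format(lnl - lnl_new))
        lnl <- lnl_new
        trace <- c(trace, lnl)
      }
    }
    if ("alpha" %in% free) {
      opt <- stats::optimize(function(la) {
        m <- cur; m$alpha <- exp(la); .lnl(aln, tree, m)
      }, interval = log(c(0.02, 50)), maximum = TRUE, tol = 1e-4)
      cur$alpha <- exp(opt$maximum)
      lnl <- opt$objective; trace <- c(trace, lnl)
    }
    if ("p_inv" %in% free) {
      opt <- stats::optimize(function(p) {
        m <- cur; m$p_inv <- p; .lnl(aln, tree, m)
      }, interval = c(0, 0.9), maximum = TRUE, tol = 1e-4)
      cur$p_inv <- opt$maximum
      lnl <- opt$objective; trace <- c(trace, lnl)
    }
    if ("branch_lengths" %in% free) {
      tree <- .optimize_branches(aln, tree, cur)
      lnl <- .lnl(aln, tree, cur); trace <- c(trace, lnl)
    }
    if (abs(lnl - lnl_start) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fit_fixed_topology: no convergence after ", max_iter,
            " cycles (status reported in result)")
  A <- cur$n_states
  k <- .k_census(free, n_taxa(aln), A)
  n <- n_cols(aln)
  structure(list(model = cur, tree = tree, lnL = lnl, k = k, n = n,
                 aicc = if (n > k + 1) aicc(lnl, k, n) else NA_real_,
                 converged = converged, iterations = iter, trace = trace),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model fit: lnL = %.3f, k = %d, n = %d, AICc = %s, %s>\n",
              x$lnL, x$k, x$n, format(x$aicc),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# one EM pass: E over all Gamma categories, M on (r, pi)
.em_update <- function(aln, sidx, tree, model, update_r, update_pi) {
  comps <- .components(model)
  lnl_comp <- matrix(0, length(comps), ncol(sidx))
  A <- model$n_states
  Ntot <- matrix(0, A, A); Wtot <- numeric(A); Rtot <- numeric(A)
  # first pass for total per-site likelihoods
  ups <- lapply(comps, function(cc)
    .up_pass(sidx, tree, cc$dec, cc$pi, cc$rate))
  for (i in seq_along(comps))
    lnl_comp[i, ] <- ups[[i]]$loglik + comps[[i]]$logw
  lnl_total <- .logsumexp_rows(lnl_comp)
  if (model$p_inv > 0) {
    pis <- lapply(comps, `[[`, "pi"); lw <- lapply(comps, `[[`, "logw")
    linv <- .invariant_site_loglik(sidx, pis, lw)
    lnl_total <- .logsumexp_rows(rbind(log1p(-model$p_inv) + lnl_total,
                                       log(model$p_inv) + linv))
    logw_extra <- log1p(-model$p_inv)
  } else logw_extra <- 0
  for (i in seq_along(comps)) {
    cc <- comps[[i]]
    es <- .estep_component(sidx, tree, cc$dec, cc$pi, cc$rate,
                           cc$logw + logw_extra, lnl_total, up = ups[[i]])
    Ntot <- Ntot + es$N; Wtot <- Wtot + es$W; Rtot <- Rtot + es$R
  }
  .m_step(Ntot, Wtot, Rtot, model$rates, model$frequencies,
          update_r = update_r, update_pi = update_pi)
}

# coordinate ascent over branch lengths: one Brent optimization per branch
# per sweep, using messages recomputed at the start of the sweep
.optimize_branches <- function(aln, tree, model, sweeps = 2L) {
  sidx <- .tip_states(aln, tree)
  comps <- .components(model)
  ntip <- length(tree$tip.label)
  has_inv <- model$p_inv > 0
  for (sw in seq_len(sweeps)) {
    msgs <- lapply(comps, function(cc) {
      up <- .up_pass(sidx, tree, cc$dec, cc$pi, cc$rate)
      dn <- .down_pass(up, tree, cc$pi)
      list(up = up, dn = dn, cc = cc)
    })
    if (has_inv) {
      pis <- lapply(comps, `[[`, "pi"); lw <- lapply(comps, `[[`, "logw")
      linv <- .invariant_site_loglik(sidx, pis, lw)
    }
    for (e in seq_len(nrow(tree$edge))) {
      ch <- tree$edge[e, 2]
      edge_lnl <- function(t) {
        L <- matrix(0, length(comps), ncol(sidx))
        for (i in seq_along(comps)) {
          mm <- msgs[[i]]; cc <- mm$cc
          P <- transition_prob(cc$dec, cc$rate * t)
          if (ch <= ntip) {
            s <- sidx[ch, ]
            A <- length(cc$pi)
            upc <- matrix(1, A, ncol(sidx))
            obs <- which(!is.na(s))
            if (length(obs)) { upc[, obs] <- 0; upc[cbind(s[obs], obs)] <- 1 }
            usc <- numeric(ncol(sidx))
          } else {
            upc <- mm$up$part[[ch]]; usc <- mm$up$pscale[[ch]]
          }
          lik <- colSums(mm$dn$O[[e]] * (P %*% upc))
          L[i, ] <- log(pmax(lik, 1e-300)) + mm$dn$Oscale[[e]] + usc +
            cc$logw
        }
        ll <- .logsumexp_rows(L)
        if (has_inv)
          ll <- .logsumexp_rows(rbind(log1p(-model$p_inv) + ll,
                                      log(model$p_inv) + linv))
        sum(ll)
      }
      opt <- stats::optimize(edge_lnl, interval = c(1e-8, 20),
                             maximum = TRUE, tol = 1e-6)
      if (opt$objective >= edge_lnl(tree$edge.length[e]))
        tree$edge.length[e] <- opt$maximum
    }
  }
  tree
}
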