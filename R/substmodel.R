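# Time-reversible n-state substitution models: rate-matrix construction,
# discrete-Gamma rates, spectral transition probabilities, effective
# alphabet size and AICc.

#' Construct a time-reversible substitution model
#'
#' @param rates exchangeabilities `r_ij`: `A(A-1)/2` non-negative values in
#'   column-wise pair order on the canonical state order, or a named preset
#'   (`"LG"`, `"WAG"`, `"F81"` = all-equal).
#' @param frequencies equilibrium frequencies (length A, positive, sum 1);
#'   defaults to the preset's published frequencies, or uniform.
#' @param alpha Gamma shape for among-site rate variation; `NULL` or `Inf`
#'   disables rate variation.
#' @param k_categories number of discrete Gamma categories (default 4).
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#' @param alphabet `"AA20"`, `"STATE6"` or `"BINARY"`.
#' @return object of class `"subst_model"`.
#' @export
substitution_model <- function(rates = "LG", frequencies = NULL, alpha = NULL,
                               k_categories = 4L, p_inv = 0,
                               alphabet = "AA20") {
  A <- length(.alphabet_states(alphabet))
  if (is.character(rates)) {
    preset <- toupper(rates)
    rates <- switch(preset,
      LG  = .LG_RATES,
      WAG = .WAG_RATES,
      F81 = rep(1, A * (A - 1) / 2),
      stop("unknown rate preset: ", preset))
    if (preset %in% c("LG", "WAG")) {
      if (alphabet != "AA20") stop(preset, " is an amino-acid model")
      if (is.null(frequencies))
        frequencies <- switch(preset, LG = .LG_FREQS, WAG = .WAG_FREQS)
    }
  }
  if (is.null(frequencies)) frequencies <- rep(1 / A, A)
  if (length(rates) != A * (A - 1) / 2)
    stop("shape error: expected ", A * (A - 1) / 2, " exchangeabilities")
  if (length(frequencies) != A)
    stop("shape error: expected ", A, " frequencies")
  if (any(rates < 0)) stop("domain error: negative exchangeability")
  if (any(frequencies <= 0))
    stop("domain error: frequencies must be strictly positive")
  frequencies <- frequencies / sum(frequencies)
  if (!is.null(alpha) && is.finite(alpha) && alpha <= 0)
    stop("domain error: alpha must be > 0")
  if (p_inv < 0 || p_inv >= 1) stop("domain error: p_inv must be in [0,1)")
  structure(list(alphabet = alphabet, n_states = A,
                 rates = as.numeric(rates),
                 frequencies = as.numeric(frequencies),
                 alpha = alpha, k_categories = as.integer(k_categories),
                 p_inv = p_inv),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<substitution model: %d states, alpha=%s, K=%d, p_inv=%g>\n",
              x$n_states,
              if (is.null(x$alpha)) "none" else format(x$alpha),
              x$k_categories, x$p_inv))
  invisible(x)
}

#' Build the normalized instantaneous rate matrix
#'
#' Off-diagonal entries are `q_ij = r_ij * pi_j`; diagonals make rows sum to
#' zero; the whole matrix is rescaled so that the mean substitution rate
#' `-sum_i pi_i q_ii` equals 1, so branch lengths are expected substitutions
#' per site.
#'
#' @param model a [substitution_model()], or a list with `rates` and
#'   `frequencies`.
#' @return A x A rate matrix.
#' @export
build_rate_matrix <- function(model) {
  pi <- model$frequencies
  if (any(pi <= 0)) stop("domain error: zero equilibrium frequency")
  A <- length(pi)
  R <- exch_vec_to_mat(model$rates, A)
  Q <- R * rep(pi, each = A)     # q_ij = r_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("domain error: degenerate rate matrix")
  Q / mu
}

#' Discrete Gamma rate categories
#'
#' Mean-of-bin rates on K equal-probability quantile bins of a
#' Gamma(shape = alpha, mean = 1) distribution, renormalized to mean
#' exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of K rates with equal weights 1/K.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (is.null(alpha) || !is.finite(alpha)) return(rep(1, k))
  if (alpha <= 0) stop("domain error: alpha must be > 0")
  if (k < 1) stop("domain error: k must be >= 1")
  if (k == 1) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha,
                     rate = alpha)
  r <- k * diff(stats::pgamma(b, shape = alpha + 1, rate = alpha))
  r / mean(r)
}

# Spectral decomposition of a reversible Q via the pi^{1/2} similarity
# transform; exact and numerically stable for symmetric problems.
decompose_q <- function(Q, pi) {
  s <- sqrt(pi)
  S <- Q * (s / rep(s, each = length(pi)))   # S_ij = Q_ij * s_i / s_j
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(lambda = e$values,
       U = e$vectors / s,                     # row-scaled: diag(1/s) %*% vec
       V = t(e$vectors * s))                  # t(diag(s) %*% vec) = inverse
}

# P(t) = exp(Qt) from a cached decomposition
transition_prob <- function(dec, t) {
  P <- (dec$U * rep(exp(dec$lambda * t), each = nrow(dec$U))) %*% dec$V
  P[P < 0] <- 0
  P
}

#' Effective alphabet size of a frequency profile
#'
#' The exponential of the Shannon entropy, `exp(-sum pi_i log pi_i)` with
#' `0 log 0 := 0`: the number of states the profile effectively permits.
#'
#' @param pi frequency vector on the simplex.
#' @return effective number of states in `[1, length(pi)]`.
#' @export
effective_alphabet_size <- function(pi) {
  if (any(pi < 0)) stop("domain error: negative frequency")
  pi <- pi / sum(pi)
  nz <- pi > 0
  exp(-sum(pi[nz] * log(pi[nz])))
}

#' Small-sample Akaike information criterion
#'
#' `AICc = 2k - 2 lnL + (2k^2 + 2k) / (n - k - 1)`.
#'
#' @param lnL maximized log likelihood.
#' @param k free-parameter count.
#' @param n sample size (site count).
#' @return the AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (n <= k + 1) stop("domain error: AICc requires n > k + 1")
  2 * k - 2 * lnL + (2 * k^2 + 2 * k) / (n - k - 1)
}
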