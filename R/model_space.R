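# Model-space comparisons: normalized 190-element exchangeability vectors,
# Euclidean distance matrices, classical multidimensional scaling, a
# random-subsampling sampling-variance null, and frequency-shift vs
# property-scale correlations.

#' Normalize exchangeabilities to a unit-sum comparison vector
#'
#' @param rates exchangeability vector (canonical pair order).
#' @return the vector rescaled to sum 1.
#' @export
exchangeability_vector <- function(rates) {
  if (any(rates < 0)) stop("domain error: negative exchangeability")
  s <- sum(rates)
  if (s <= 0) stop("domain error: all-zero exchangeabilities")
  rates / s
}

#' Euclidean distances among exchangeability vectors
#'
#' Each model is treated as a vector of exchangeabilities normalized to sum
#' 1; the result is the matrix of pairwise Euclidean distances.
#'
#' @param models list of exchangeability vectors (equal lengths), or a
#'   matrix with one model per row; names/rownames label the output.
#' @return symmetric distance matrix with zero diagonal.
#' @export
exchangeability_distance_matrix <- function(models) {
  if (is.matrix(models)) models <- asplit(models, 1)
  if (length(models) < 2) stop("need at least two models")
  len <- unique(lengths(models))
  if (length(len) != 1)
    stop("shape error: exchangeability vectors differ in length")
  V <- do.call(rbind, lapply(models, exchangeability_vector))
  D <- as.matrix(stats::dist(V))
  dimnames(D) <- list(names(models), names(models))
  D
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of a distance matrix: double-centre the squared
#' distances, eigendecompose, and scale the top eigenvectors by the square
#' roots of their eigenvalues. Requested dimensions whose eigenvalues are
#' not positive are set to zero with a warning. For determinism the first
#' nonzero coordinate of every axis is made positive.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param dims number of output dimensions (default 2).
#' @return list with `coordinates` (n x dims), `eigenvalues` (all n,
#'   descending), `distances` (the input) and `gram` (the double-centred
#'   matrix B).
#' @export
classical_mds <- function(D, dims = 2) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("validation error: distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12))
    stop("validation error: nonzero diagonal in distance matrix")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  mds <- stats::cmdscale(D, k = min(dims, n - 1), eig = TRUE)
  ev <- mds$eig
  pts <- mds$points
  if (ncol(pts) < dims)
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  bad <- which(ev[seq_len(dims)] <= 1e-12)
  if (length(bad)) {
    warning("non-positive eigenvalue(s) for dimension(s) ",
            paste(bad, collapse = ", "), "; coordinates set to 0")
    pts[, bad] <- 0
  }
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(D)
  list(coordinates = pts[, seq_len(dims), drop = FALSE],
       eigenvalues = ev, distances = D, gram = B)
}

#' Sampling-variance null for exchangeability distances
#'
#' For each requested size, repeatedly samples that many sites without
#' replacement, re-estimates the exchangeabilities on the fixed tree, and
#' records the Euclidean distance (between unit-sum vectors) to a
#' reference estimate. This is the null against which between-class model
#' distances are judged.
#'
#' @param aln an [alignment()].
#' @param tree fixed topology with branch lengths.
#' @param model starting model for each refit.
#' @param sizes site counts to sample.
#' @param reps replicates per size (default 10).
#' @param seed integer seed.
#' @param reference reference exchangeability vector (e.g. the grand fit);
#'   normalized internally.
#' @param fit_args list of extra arguments passed to
#'   [fit_fixed_topology()] (e.g. `max_iter`).
#' @return data.frame with `size`, `rep`, `distance`.
#' @export
subsample_distance_null <- function(aln, tree, model, sizes, reps = 10L,
                                    seed = 1L, reference,
                                    fit_args = list()) {
  if (any(sizes > n_cols(aln)))
    stop("size exceeds alignment length")
  ref <- exchangeability_vector(reference)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- expand.grid(rep = seq_len(reps), size = sizes)[, 2:1]
  out$distance <- NA_real_
  for (i in seq_len(nrow(out))) {
    cols <- sort(sample.int(n_cols(aln), out$size[i]))
    sub <- subset_columns(aln, cols)
    fit <- do.call(fit_fixed_topology,
                   c(list(aln = sub, tree = tree, model = model,
                          free = c("rates", "pi")), fit_args))
    est <- exchangeability_vector(fit$model$rates)
    out$distance[i] <- sqrt(sum((est - ref)^2))
  }
  out
}

#' Frequency-shift correlation with an amino-acid property scale
#'
#' Computes `Delta_i = pi_class,i - pi_reference,i` and the squared Pearson
#' correlation of the shift with a 20-element property scale (e.g. the
#' Grantham polarity scale in `GRANTHAM_POLARITY`).
#'
#' @param pi_class,pi_reference frequency vectors in canonical residue
#'   order.
#' @param scale 20-element property vector.
#' @return list with `delta`, `r_squared`, `correlation`.
#' @export
delta_pi_correlation <- function(pi_class, pi_reference,
                                 scale = GRANTHAM_POLARITY) {
  if (length(pi_class) != length(scale) ||
      length(pi_reference) != length(scale))
    stop("shape error: vectors must match the scale length")
  delta <- pi_class - pi_reference
  r <- stats::cor(delta, scale)
  list(delta = delta, r_squared = r^2, correlation = r)
}

#' Read a two-column property-scale file
#'
#' Whitespace- or tab-separated lines `amino_acid value`; returns the
#' values in canonical residue order.
#'
#' @param path file path.
#' @return named numeric vector of length 20.
#' @export
read_property_scale <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("aa", "value"),
                           stringsAsFactors = FALSE)
  if (!setequal(tab$aa, AA_ORDER))
    stop("validation error: scale file must cover the 20 amino acids")
  stats::setNames(tab$value[match(AA_ORDER, tab$aa)], AA_ORDER)
}
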