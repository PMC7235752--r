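# Exchangeability-vector distances, classical MDS, the subsampling null
# and property-scale correlations.

test_that("exchangeability distances: identity, scale invariance, closed form", {
  v <- runif(190)
  D <- exchangeability_distance_matrix(list(a = v, b = v, c = 2 * v))
  expect_equal(unname(D), matrix(0, 3, 3))

  v1 <- c(1, rep(0, 189))
  v2 <- rep(1, 190)
  D2 <- exchangeability_distance_matrix(list(v1, v2))
  expect_equal(D2[1, 2], sqrt((1 - 1 / 190)^2 + 189 * (1 / 190)^2),
               tolerance = 1e-12)
  expect_equal(D2[1, 2], 0.99737, tolerance = 1e-4)

  expect_error(exchangeability_distance_matrix(list(v1)), "at least two")
  expect_error(exchangeability_distance_matrix(list(v1, runif(10))),
               "shape error")

  # permutation equivariance
  set.seed(4)
  vs <- lapply(1:4, function(i) runif(190))
  D4 <- exchangeability_distance_matrix(vs)
  perm <- c(3, 1, 4, 2)
  expect_equal(exchangeability_distance_matrix(vs[perm]), D4[perm, perm])
})

test_that("classical MDS recovers collinear and planar configurations", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  # collinear points have a rank-1 embedding; the second axis collapses
  mds <- suppressWarnings(classical_mds(D, dims = 2))
  expect_equal(unname(as.matrix(dist(mds$coordinates[, 1]))),
               unname(D), tolerance = 1e-9)
  expect_equal(max(abs(mds$coordinates[, 2])), 0, tolerance = 1e-9)

  set.seed(11)
  X <- matrix(rnorm(20), 10, 2)
  mdsX <- classical_mds(as.matrix(dist(X)), dims = 2)
  expect_lt(procrustes_rms(mdsX$coordinates, X), 1e-8)
  # Euclidean input: eigenvalues beyond the true rank vanish
  expect_true(all(mdsX$eigenvalues > -1e-8))

  z <- suppressWarnings(classical_mds(matrix(0, 3, 3)))
  expect_equal(unname(z$coordinates), matrix(0, 3, 2))

  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2)),
               "validation error")
})

test_that("MDS axis signs are deterministic", {
  set.seed(12)
  X <- matrix(rnorm(12), 6, 2)
  m1 <- classical_mds(as.matrix(dist(X)))
  for (j in 1:2) {
    nz <- which(abs(m1$coordinates[, j]) > 1e-12)
    if (length(nz)) expect_gt(m1$coordinates[nz[1], j], 0)
  }
})

test_that("subsampling null: zero at full size, seeded, variance decays", {
  tr <- random_unrooted_tree(6)
  mod <- substitution_model(rates = runif(15, 0.3, 2),
                            frequencies = rep(1 / 6, 6),
                            alphabet = "STATE6")
  cfg <- simulation_config(tree = tr, exposed_model = mod,
                           buried_model = mod, exposed_rate_multiplier = 1,
                           n_genes = 1, gene_length = 900,
                           exposed_fraction = 1, missing_fraction = 0,
                           seed = 77)
  ds <- simulate_alignment(cfg)
  start <- substitution_model("F81", alphabet = "STATE6")
  fit_args <- list(tol = 0.05, max_iter = 6, em_steps = 3)
  grand <- suppressWarnings(
    do.call(fit_fixed_topology,
            c(list(aln = ds$alignment, tree = tr, model = start,
                   free = c("rates", "pi")), fit_args)))
  ref <- grand$model$rates

  full <- subsample_distance_null(ds$alignment, tr, start,
                                  sizes = n_cols(ds$alignment), reps = 1,
                                  seed = 3, reference = ref,
                                  fit_args = fit_args)
  expect_lt(full$distance, 1e-4)

  tab1 <- subsample_distance_null(ds$alignment, tr, start,
                                  sizes = c(60, 600), reps = 4, seed = 8,
                                  reference = ref, fit_args = fit_args)
  tab2 <- subsample_distance_null(ds$alignment, tr, start,
                                  sizes = c(60, 600), reps = 4, seed = 8,
                                  reference = ref, fit_args = fit_args)
  expect_identical(tab1, tab2)
  expect_gt(median(tab1$distance[tab1$size == 60]),
            median(tab1$distance[tab1$size == 600]))
  expect_error(subsample_distance_null(ds$alignment, tr, start,
                                       sizes = 10^6, reps = 1, seed = 1,
                                       reference = ref),
               "exceeds")
})

test_that("between-class distance exceeds the sampling-variance null", {
  # two classes simulated under visibly different exchangeabilities
  tr <- random_unrooted_tree(6)
  r1 <- rep(1, 15); r2 <- rep(1, 15); r2[c(1, 5, 9)] <- 8
  mA <- substitution_model(rates = r1, frequencies = rep(1 / 6, 6),
                           alphabet = "STATE6")
  mB <- substitution_model(rates = r2, frequencies = rep(1 / 6, 6),
                           alphabet = "STATE6")
  cfg <- simulation_config(tree = tr, exposed_model = mA, buried_model = mB,
                           exposed_rate_multiplier = 1, n_genes = 2,
                           gene_length = 600, exposed_fraction = 0.5,
                           missing_fraction = 0, seed = 13)
  ds <- simulate_alignment(cfg)
  start <- substitution_model("F81", alphabet = "STATE6")
  fit_args <- list(tol = 0.05, max_iter = 6, em_steps = 3)
  fit_cl <- function(cls) {
    sub <- structphylo:::subset_columns(ds$alignment,
                                        which(ds$site_class == cls))
    suppressWarnings(
      do.call(fit_fixed_topology,
              c(list(aln = sub, tree = tr, model = start,
                     free = c("rates", "pi")), fit_args)))$model$rates
  }
  re <- fit_cl("exposed"); rb <- fit_cl("buried")
  between <- exchangeability_distance_matrix(list(re, rb))[1, 2]
  grand <- suppressWarnings(
    do.call(fit_fixed_topology,
            c(list(aln = ds$alignment, tree = tr, model = start,
                   free = c("rates", "pi")), fit_args)))
  n_half <- sum(ds$site_class == "exposed")
  null_tab <- subsample_distance_null(ds$alignment, tr, start,
                                      sizes = n_half, reps = 5, seed = 19,
                                      reference = grand$model$rates,
                                      fit_args = fit_args)
  expect_gt(between, max(null_tab$distance))
})

test_that("frequency-shift correlations behave and use the Grantham scale", {
  sc <- GRANTHAM_POLARITY
  base <- rep(0.05, 20)
  prop <- base + 0.001 * (sc - mean(sc))
  expect_equal(delta_pi_correlation(prop, base, sc)$r_squared, 1,
               tolerance = 1e-10)
  orth <- sc - mean(sc)
  orth <- orth - sum(orth * (sc - mean(sc))) * (sc - mean(sc)) /
    sum((sc - mean(sc))^2)   # residualized: zero covariance with the scale
  v <- rnorm(20)
  v_orth <- v - sum(v * (sc - mean(sc))) / sum((sc - mean(sc))^2) *
    (sc - mean(sc))
  expect_equal(delta_pi_correlation(base + 0.001 * v_orth, base,
                                    sc)$r_squared, 0, tolerance = 1e-10)
  expect_error(delta_pi_correlation(rep(0.1, 10), base, sc), "shape error")

  # constructed correlation: delta built to correlate at r = 0.8
  set.seed(23)
  s <- scale(sc)[, 1]
  e <- rnorm(20); e <- scale(e - s * sum(e * s) / sum(s^2))[, 1]
  delta <- 0.8 * s + sqrt(1 - 0.8^2) * e
  got <- delta_pi_correlation(base + 0.001 * delta, base, sc)$r_squared
  expect_equal(got, 0.64, tolerance = 0.02)
})

test_that("property-scale files round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(AA_ORDER, GRANTHAM_POLARITY), f)
  expect_equal(read_property_scale(f), GRANTHAM_POLARITY)
  writeLines(paste(AA_ORDER[1:10], 1:10), f)
  expect_error(read_property_scale(f), "validation error")
})
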