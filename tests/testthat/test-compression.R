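test_that("pooling collects N_bar * C vectors with an invertible map", {
  ts <- tiny_ts(N = 4, M = 120, C = 3, seed = 21)
  ft <- extract_features(ts, "TDP")
  pl <- pool_features(ft, c(1, 3))
  expect_equal(nrow(pl$pool), 2 * 3)
  expect_equal(ncol(pl$pool), 3)
  # bijection: each pooled row maps back to a unique (trial, channel)
  keys <- paste(pl$coords$trial, pl$coords$channel)
  expect_equal(anyDuplicated(keys), 0)
  for (r in seq_len(nrow(pl$pool)))
    expect_identical(pl$pool[r, ],
                     ft$values[pl$coords$trial[r], pl$coords$channel[r], ])
  # SP pooling keeps dimension 11
  ftS <- extract_features(ts, "SP")
  expect_equal(ncol(pool_features(ftS, 1:2)$pool), 11)
  expect_error(pool_features(ft, integer(0)), class = "fccr_precondition_error")
})

test_that("k-means closed-form cases hold", {
  set.seed(22)
  x <- matrix(rnorm(40), 20, 2)
  # K = number of distinct points -> every point its own cluster
  km_all <- kmeans_fit(x, 20, seed = 1, n_init = 2)
  expect_equal(km_all$wcss, 0)
  # K = 1 -> centroid is the mean, WCSS the total scatter
  km1 <- kmeans_fit(x, 1, seed = 1)
  expect_equal(as.numeric(km1$centroids), colMeans(x), tolerance = 1e-12)
  expect_equal(km1$wcss, sum(sweep(x, 2, colMeans(x))^2), tolerance = 1e-9)
  expect_error(kmeans_fit(x, 21, seed = 1), class = "fccr_precondition_error")
})

test_that("k-means recovers two well-separated blobs", {
  set.seed(23)
  blob <- rbind(matrix(rnorm(200, 0, 0.5), 100, 2),
                matrix(rnorm(200, 10, 0.5), 100, 2))
  km <- kmeans_fit(blob, 2, seed = 4)
  cen <- km$centroids[order(km$centroids[, 1]), ]
  expect_lt(max(abs(cen[1, ] - c(0, 0))), 0.3)
  expect_lt(max(abs(cen[2, ] - c(10, 10))), 0.3)
  # same partition as the generating blobs
  expect_equal(length(unique(km$assign[1:100])), 1)
  expect_equal(length(unique(km$assign[101:200])), 1)
  # cross-check solution quality against the stock implementation
  ref <- stats::kmeans(blob, 2, nstart = 5)
  expect_equal(km$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("WCSS trace is non-increasing and the two objective forms agree", {
  for (s in 1:5) {
    set.seed(30 + s)
    x <- matrix(rnorm(60 * 3), 60, 3)
    km <- kmeans_fit(x, 5, seed = s)
    expect_true(all(diff(km$wcss_trace) <= 1e-9))
    # centroid form == pairwise form on the fitted partition
    e3 <- wcss_centroid(x, km$assign)
    e4 <- wcss_pairwise(x, km$assign)
    expect_lt(abs(e3 - e4) / e3, 1e-9)
    expect_equal(km$wcss, e3, tolerance = 1e-9)
  }
})

test_that("best WCSS is non-increasing along the feasible K grid", {
  set.seed(37)
  x <- matrix(rnorm(80 * 4), 80, 4)
  ks <- c(1, 2, 4, 6, 8, 10)
  w <- sapply(ks, function(K) kmeans_fit(x, K, seed = 9)$wcss)
  expect_true(all(diff(w) <= 1e-9))
})

test_that("signatures are canonical, tie-broken, and consistent with the fit", {
  set.seed(24)
  blob <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
                matrix(rnorm(100, 8, 0.3), 50, 2))
  # two different seeds must find the same separated clusters; canonical
  # labelling then makes the signatures identical
  # lay blob rows out so pooled row (trial-major, channel-fast) r maps to
  # feature vector blob[r, ]
  ftlike <- structure(list(values = aperm(array(t(blob), c(2, 4, 25)),
                                          c(3, 2, 1)),
                           method = "TDP", d = 2,
                           channel_names = paste0("c", 1:4)),
                      class = "feature_tensor")
  kmA <- kmeans_fit(blob, 2, seed = 1)
  kmB <- kmeans_fit(blob, 2, seed = 99)
  sigA <- assign_signatures(kmA, ftlike)
  sigB <- assign_signatures(kmB, ftlike)
  expect_identical(unclass(sigA)[], unclass(sigB)[])
  # canonical order: label 1 has the smaller centroid norm
  expect_lt(sum(kmA$centroids[1, ]^2), sum(kmA$centroids[2, ]^2))

  # a vector equal to a centroid maps to that signature
  one <- structure(list(values = array(kmA$centroids[2, ], c(1, 1, 2)),
                        method = "TDP", d = 2, channel_names = "c"),
                   class = "feature_tensor")
  expect_equal(as.integer(assign_signatures(kmA, one)), 2L)

  # assignment on the training pool reproduces the fitted partition
  sig_flat <- as.integer(t(unclass(sigA)))
  expect_equal(sig_flat, kmA$assign)

  # exact equidistance -> smaller canonical label
  m <- structure(list(K = 2L,
                      centroids = rbind(c(0, 0), c(2, 0)),
                      canonical_order = 1:2, assign = integer(0),
                      wcss = 0, wcss_trace = 0, seed = 1L),
                 class = "cluster_model")
  mid <- structure(list(values = array(c(1, 0), c(1, 1, 2)), method = "TDP",
                        d = 2, channel_names = "c"),
                   class = "feature_tensor")
  expect_equal(as.integer(assign_signatures(m, mid)), 1L)
  expect_error(assign_signatures(kmA,
    structure(list(values = array(0, c(1, 1, 5)), method = "TDP", d = 5,
                   channel_names = "c"), class = "feature_tensor")),
    class = "fccr_shape_error")
})

test_that("the default cluster grid matches the benchmark protocol", {
  expect_equal(default_k_grid(),
               c(2L, 4L, 6L, 8L, seq(10L, 90L, 10L), c(100L, 300L, 500L, 700L)))
})

test_that("grid search returns the feasible singleton and prefers K >= 2 on structured data", {
  # informative channels deliberately not the lowest-indexed ones: with
  # K = 1 the signature matrix is constant and the ranking degenerates to
  # index order, which must not be rewarded
  ts <- generate_synthetic(synth_spec(C = 6, informative = c(3, 5),
                                      n_per_class = 15, M = 150, seed = 31))
  ft <- extract_features(ts, "TDP")
  gs1 <- suppressWarnings(
    grid_search_k(ft, ts$labels, grid = c(4L, 5000L), n_select = 2, seed = 1))
  expect_equal(gs1$K, 4L)
  gs <- grid_search_k(ft, ts$labels, grid = c(1L, 2L, 6L, 10L), n_select = 2,
                      seed = 1)
  # K = 1 collapses the signature matrix to a constant: no class signal
  expect_gte(gs$K, 2L)
  expect_error(suppressWarnings(
    grid_search_k(ft, ts$labels, grid = 10000L, seed = 1)),
    class = "fccr_precondition_error")
})
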