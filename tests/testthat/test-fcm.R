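test_that("membership update follows the fuzzy-c-means formula", {
  V <- matrix(c(0, 1, 3), 3, 1)
  # coincident point: singularity rule gives full membership
  u <- update_memberships(matrix(1, 1, 1), V, m = 1.2)
  expect_equal(as.numeric(u), c(0, 1, 0))

  # equidistant point: symmetric memberships 1/c
  V2 <- matrix(c(0, 0, 2, 0, 1, sqrt(3)), 3, 2, byrow = TRUE)
  u2 <- update_memberships(matrix(c(1, 1 / sqrt(3)), 1, 2), V2, m = 2)
  expect_equal(as.numeric(u2), rep(1 / 3, 3), tolerance = 1e-10)

  # 1-D worked case: point 0.25 between centroids {0, 1} at M = 2 gives
  # memberships (0.9, 0.1)
  u3 <- update_memberships(matrix(0.25, 1, 1), matrix(c(0, 1), 2, 1),
                           m = 2)
  expect_equal(as.numeric(u3), c(0.9, 0.1), tolerance = 1e-12)

  # agreement with the direct formula on random configurations
  set.seed(5)
  for (rep in 1:5) {
    X <- matrix(rnorm(12), 4, 3)
    V3 <- matrix(rnorm(9), 3, 3)
    U <- update_memberships(X, V3, m = 1.2)
    for (k in 1:4)
      expect_equal(U[, k], membership_oracle(X[k, ], V3, 1.2),
                   tolerance = 1e-10)
    expect_equal(colSums(U), rep(1, 4), tolerance = 1e-9)
  }
})

test_that("centroid update is the u^M-weighted mean", {
  X <- matrix(c(0, 0, 1, 0, 4, 4), 3, 2, byrow = TRUE)
  crisp <- rbind(c(1, 1, 0), c(0, 0, 1))
  V <- update_centroids(X, crisp, m = 1.2)
  expect_equal(V, rbind(c(0.5, 0), c(4, 4)))

  uniform <- matrix(0.5, 2, 3)
  Vu <- update_centroids(X, uniform, m = 1.7)
  expect_equal(Vu[1, ], colMeans(X))
  expect_equal(Vu[2, ], colMeans(X))

  U <- rbind(c(0.8, 0.5, 0.1), c(0.2, 0.5, 0.9))
  Vw <- update_centroids(X, U, m = 1.2)
  w <- U^1.2
  oracle <- rbind(colSums(w[1, ] * X) / sum(w[1, ]),
                  colSums(w[2, ] * X) / sum(w[2, ]))
  expect_equal(Vw, oracle, tolerance = 1e-12)

  expect_error(update_centroids(X, rbind(c(0, 0, 0), c(1, 1, 1)), 1.2),
               "all-zero")
})

test_that("Xie-Beni index matches direct evaluation and is scale free", {
  # all points on their centroids with crisp memberships: zero compactness
  X <- rbind(c(0, 0), c(0, 0), c(5, 5))
  U <- rbind(c(1, 1, 0), c(0, 0, 1))
  V <- rbind(c(0, 0), c(5, 5))
  expect_equal(xie_beni(X, U, V, 1.2), 0)

  # 4 points / 2 centroids toy value, hand-computed from the formula
  X2 <- matrix(c(0, 1, 3, 4), 4, 1)
  V2 <- matrix(c(0.5, 3.5), 2, 1)
  U2 <- update_memberships(X2, V2, m = 2)
  num <- sum(U2^2 * rbind((X2[, 1] - 0.5)^2, (X2[, 1] - 3.5)^2))
  oracle <- num / (4 * 3^2)
  expect_equal(xie_beni(X2, U2, V2, 2), oracle, tolerance = 1e-12)

  # multiplying features and centroids by s > 0 leaves XB unchanged
  s <- 7.3
  expect_equal(xie_beni(s * X2, U2, s * V2, 2),
               xie_beni(X2, U2, V2, 2), tolerance = 1e-12)

  expect_error(xie_beni(X2, U2, rbind(V2[1, ], V2[1, ]), 2), "coincident")
})

test_that("fcm separates well-separated groups and decreases its objective", {
  set.seed(21)
  X <- rbind(matrix(rnorm(40, 0, 0.1), 20),
             matrix(rnorm(40, 5, 0.1), 20))
  fit <- fcm(X, 2, seed = 1)
  expect_true(fit$converged)
  expect_length(unique(hard_labels(fit)[1:20]), 1L)
  expect_length(unique(hard_labels(fit)[21:40]), 1L)
  expect_false(hard_labels(fit)[1] == hard_labels(fit)[40])

  # alternating optimization never increases J_M
  expect_true(all(diff(fit$objective_trace) <= 1e-8))

  # column stochasticity and determinism
  expect_equal(colSums(fit$u), rep(1, 40), tolerance = 1e-9)
  fit2 <- fcm(X, 2, seed = 1)
  expect_identical(fit$u, fit2$u)
})

test_that("permuting point order permutes memberships identically", {
  set.seed(33)
  X <- rbind(matrix(rnorm(30, 0, 0.3), 15), matrix(rnorm(30, 4, 0.3), 15))
  V0 <- rbind(X[1, ], X[30, ])
  fit <- fcm(X, 2, init = V0)
  perm <- sample(30)
  fitp <- fcm(X[perm, ], 2, init = V0)
  expect_equal(fitp$u, fit$u[, perm], tolerance = 1e-9)
})

test_that("small fuzzifier approaches hard k-means assignments", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, 0, 0.5), 30), matrix(rnorm(60, 6, 0.5), 30))
  V0 <- rbind(colMeans(X[1:3, , drop = FALSE]),
              colMeans(X[58:60, , drop = FALSE]))
  soft <- fcm(X, 2, m = 1.05, init = V0)
  km <- stats::kmeans(X, centers = V0)
  agree <- mean(hard_labels(soft) == km$cluster)
  agree <- max(agree, 1 - agree)          # label flip immaterial
  expect_gte(agree, 0.99)
})

test_that("random-cube initialization averages the in-mask neighborhood", {
  sim <- simulate_bold(tiny_spec(seed = 4))
  cm <- correlation_map(sim$ts)

  V1 <- init_random(cm, 3, seed = 10)
  V2 <- init_random(cm, 3, seed = 10)
  expect_identical(V1, V2)

  # oracle: centroid equals the rowwise mean over the cube membership
  info <- attr(V1, "seed_info")
  for (i in 1:3) {
    ctr <- cm$coords[info$center_voxels[i] + 1L, ]
    inside <- apply(abs(sweep(cm$coords, 2L, ctr, "-")) <= 1L, 1L, all)
    expect_equal(V1[i, ], colMeans(cm$r[inside, , drop = FALSE]))
  }

  # a cube holding a single isolated voxel returns that voxel's row
  iso <- corr_map(cm$r[1:4, 1:4],
                  coords = cbind(c(0L, 10L, 20L, 30L), 0L, 0L))
  Vi <- init_random(iso, 2, seed = 2)
  rows <- attr(Vi, "seed_info")$center_voxels + 1L
  expect_equal(Vi, iso$r[rows, ], ignore_attr = TRUE)
})

test_that("seeded-sphere initialization uses world-space distances", {
  sim <- simulate_bold(tiny_spec(seed = 4))
  cm <- correlation_map(sim$ts)
  world <- t(cm$affine %*% t(cbind(cm$coords, 1)))[, 1:3]

  # sphere around a lone voxel centre: exactly that row
  roi <- data.frame(name = "lone", x = world[5, 1], y = world[5, 2],
                    z = world[5, 3])
  V <- init_seeded(cm, roi, radius = 1)
  expect_equal(V[1, ], cm$r[5, ], ignore_attr = TRUE)

  # the seven canonical seeds are accepted and echoed verbatim
  seeds <- rsn_seed_table()
  expect_identical(dim(seeds), c(7L, 4L))
  expect_identical(seeds$name,
                   c("DMN", "FPC", "LAN", "VAN", "SMN", "VIS", "DAN"))
  expect_equal(seeds[seeds$name == "DMN", c("x", "y", "z")],
               data.frame(x = 0, y = -65, z = 31), ignore_attr = TRUE)

  expect_error(init_seeded(cm, data.frame(name = "far", x = 999, y = 999,
                                          z = 999)),
               "far")
})

test_that("two seeded ROIs in different networks give distinct centroids", {
  spec <- tiny_spec(noise_sd = 0.1, seed = 6)
  sim <- simulate_bold(spec)
  cm <- correlation_map(sim$ts)
  net <- sim$truth$true_network
  world <- t(cm$affine %*% t(cbind(cm$coords, 1)))[, 1:3]
  i1 <- which(net == 1)[1]; i2 <- which(net == 2)[1]
  rois <- data.frame(name = c("a", "b"),
                     x = world[c(i1, i2), 1], y = world[c(i1, i2), 2],
                     z = world[c(i1, i2), 3])
  V <- init_seeded(cm, rois, radius = 5)
  between <- temporal_similarity(V[1, ], V[2, ])
  within <- temporal_similarity(V[1, ], cm$r[which(net == 1)[2], ])
  expect_lt(between, within)
})

test_that("consensus of permuted runs equals a single run after matching", {
  set.seed(99)
  X <- rbind(matrix(rnorm(40, 0, 0.2), 20), matrix(rnorm(40, 3, 0.2), 20),
             matrix(rnorm(40, -3, 0.2), 20))
  sol <- fcm(X, 3, seed = 2)
  ref <- sol
  # a run differing only by index permutation is undone by the matcher
  perm_sol <- sol
  perm <- c(3L, 1L, 2L)
  perm_sol$u <- sol$u[perm, ]
  perm_sol$v <- sol$v[perm, ]
  mt <- match_clusters(perm_sol, ref, mode = "spatial")
  expect_identical(mt$assignment, perm)
  expect_equal(mt$scores, rep(1, 3), tolerance = 1e-12)
})

test_that("consensus with one run reproduces that run", {
  sim <- simulate_bold(tiny_spec(seed = 12))
  cm <- correlation_map(sim$ts)
  cons <- fcm_consensus(cm, 2, n_runs = 1, seed = 31)
  single_seed <- local({
    set.seed(31); sample.int(.Machine$integer.max, 1)
  })
  single <- fcm(cm, 2, seed = single_seed)
  expect_equal(cons$u, single$u, tolerance = 1e-12)
  expect_equal(unname(cons$n_converged), 1L)
})
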