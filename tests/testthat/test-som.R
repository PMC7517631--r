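test_that("the hexagonal lattice has the expected module and neighbor counts", {
  g <- hex_grid(7, 7)
  expect_equal(nrow(g$coords), 49)
  n_nb <- lengths(g$neighbors)
  interior <- with(g$coords, row > 1 & row < 7 & col > 1 & col < 7)
  expect_true(all(n_nb[interior] == 6))
  expect_true(all(n_nb >= 2))
  # module 1 is bottom-left, numbering is row-major
  expect_equal(g$coords$x[1], 0)
  expect_equal(g$coords$y[1], 0)
  expect_equal(unlist(g$coords[8, c("row", "col")]), c(row = 2L, col = 1L))

  g1 <- hex_grid(1, 1)
  expect_equal(nrow(g1$coords), 1)
  expect_length(g1$neighbors[[1]], 0)

  g2 <- hex_grid(2, 2)
  expect_true(all(lengths(g2$neighbors) >= 2))
})

test_that("codebook initialization is deterministic and always finite", {
  set.seed(99)
  data <- matrix(rnorm(30), 10, 3)
  cfg <- som_config(7, 7, seed = 5)
  cb1 <- init_codebook(data, cfg)
  cb2 <- init_codebook(data, cfg)
  expect_identical(cb1, cb2)
  expect_equal(nrow(cb1), 49)
  expect_true(all(is.finite(cb1)))
  # first 10 rows are the data itself, the rest jitter around its mean
  expect_equal(cb1[1:10, ], unname(data))
  expect_equal(colMeans(cb1[11:49, ]), colMeans(data), tolerance = 0.2)

  cb3 <- init_codebook(data, som_config(1, 2, seed = 5))
  expect_equal(nrow(cb3), 2)
  expect_true(all(cb3 %in% data))
})

test_that("a 1x1 SOM converges to the data mean in one batch epoch", {
  set.seed(31)
  data <- matrix(rnorm(60, 2), 20, 3)
  cfg <- som_config(1, 1, epochs_ordering = 1, epochs_tuning = 0,
                    epochs_polish = 0, radius_start = 1, radius_end = 0,
                    seed = 1)
  m <- train_batch(som_init(data, cfg), data)
  expect_equal(as.vector(m$codebook), colMeans(data), tolerance = 1e-12)
})

test_that("at radius zero batch training reproduces Lloyd's k-means", {
  set.seed(32)
  data <- rbind(matrix(rnorm(150, 0, 0.2), 50, 3),
                matrix(rnorm(150, 5, 0.2), 50, 3))
  cfg <- som_config(1, 2, epochs_ordering = 30, epochs_tuning = 0,
                    epochs_polish = 0, radius_start = 0, radius_end = 0,
                    seed = 3)
  m <- train_batch(som_init(data, cfg), data)
  km <- stats::kmeans(data, centers = init_codebook(data, cfg),
                      algorithm = "Lloyd", iter.max = 50)
  expect_equal(m$codebook, unname(km$centers), tolerance = 1e-9)
  expect_true(all(diff(m$distortion_history) <= 1e-12))
})

test_that("duplicating every data row leaves the trained codebook unchanged", {
  set.seed(33)
  data <- matrix(rnorm(90), 30, 3)
  cfg <- som_config(2, 2, epochs_ordering = 20, epochs_tuning = 5,
                    epochs_polish = 2, seed = 4, radius_start = 1.5,
                    radius_end = 0.5)
  m1 <- train_batch(som_init(data, cfg), data)
  dup <- rbind(data, data)
  m2 <- train_batch(som_init(data, cfg), dup)  # same init, doubled data
  expect_equal(m1$codebook, m2$codebook, tolerance = 1e-12)
})

test_that("assignment is a tie-broken total partition", {
  cb <- matrix(c(0, 0, 0,
                 2, 0, 0,
                 0, 2, 0,
                 4, 4, 4,
                 9, 9, 9,
                 1, 1, 1,
                 2, 0, 0), ncol = 3, byrow = TRUE)
  model <- list(codebook = cb, grid = hex_grid(1, 7),
                config = som_config(1, 7))
  class(model) <- "som_model"
  data <- matrix(c(0, 0, 0,      # exactly codebook 1
                   2, 0, 0,      # equidistant to modules 2 and 7 -> 2
                   4.1, 4, 4),
                 ncol = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), NULL))
  asg <- assign_modules(model, data)
  expect_equal(unname(asg), c(1, 2, 4))
  expect_equal(names(asg), c("a", "b", "c"))

  set.seed(34)
  big <- matrix(rnorm(300), 100, 3,
                dimnames = list(sprintf("t%03d", 1:100), NULL))
  asg2 <- assign_modules(model, big)
  expect_equal(sum(tabulate(asg2, 7)), 100)
})

test_that("quantization error matches hand arithmetic and shrinks with training", {
  model <- list(codebook = matrix(1, 1, 1), grid = hex_grid(1, 1),
                config = som_config(1, 1))
  class(model) <- "som_model"
  data <- matrix(c(0, 2), 2, 1)
  expect_equal(quantization_error(model, data), 1)

  model$codebook <- matrix(c(0, 2), 2, 1)
  model$grid <- hex_grid(1, 2)
  expect_equal(quantization_error(model, data), 0)

  set.seed(35)
  x <- matrix(rnorm(600), 200, 3)
  cfg <- som_config(3, 3, epochs_ordering = 10, epochs_tuning = 5,
                    epochs_polish = 5, radius_start = 2, radius_end = 0.5,
                    seed = 2)
  m0 <- som_init(x, cfg)
  m1 <- train_batch(m0, x)
  expect_lt(quantization_error(m1, x), quantization_error(m0, x))
  # polish phase (sigma = 0) cannot increase the k-means objective
  polish <- tail(m1$distortion_history, cfg$epochs_polish)
  expect_true(all(diff(polish) <= 1e-12))
})

test_that("the U-matrix reflects codebook distances and their invariances", {
  cfg <- som_config(1, 2)
  model <- list(codebook = matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE),
                grid = hex_grid(1, 2), config = cfg)
  class(model) <- "som_model"
  um <- compute_umatrix(model)
  expect_equal(um$pairs$distance, 5)
  expect_equal(um$module_values, c(5, 5))

  model$codebook <- model$codebook + 17    # translation invariance
  expect_equal(compute_umatrix(model)$pairs$distance, 5)

  model$codebook <- matrix(2, 2, 3)
  expect_equal(compute_umatrix(model)$pairs$distance, 0)
})

test_that("training is deterministic and preserves the data partition", {
  set.seed(36)
  x <- matrix(rnorm(450), 150, 3, dimnames = list(sprintf("t%03d", 1:150),
                                                  NULL))
  cfg <- som_config(4, 4, epochs_ordering = 15, epochs_tuning = 5,
                    epochs_polish = 2, radius_start = 2, radius_end = 0.5,
                    seed = 8)
  m1 <- som_fit(x, cfg)
  m2 <- som_fit(x, cfg)
  expect_identical(m1$codebook, m2$codebook)
  expect_identical(m1$assignment, m2$assignment)
  expect_equal(sum(tabulate(m1$assignment, 16)), nrow(x))
})

test_that("lattice-adjacent modules are closer than random pairs on smooth data", {
  set.seed(37)
  u <- runif(800); v <- runif(800)
  x <- cbind(u, v, 0.5 * u + 0.5 * v)  # 2-D manifold embedded in 3-D
  m <- som_fit(x, som_config(5, 5, epochs_ordering = 30, epochs_tuning = 10,
                             epochs_polish = 5, radius_start = 2,
                             radius_end = 0.5, seed = 9))
  um <- compute_umatrix(m)
  adj_mean <- mean(um$pairs$distance)
  all_d <- as.matrix(dist(m$codebook))
  adj <- matrix(FALSE, 25, 25)
  adj[cbind(um$pairs$module_a, um$pairs$module_b)] <- TRUE
  adj <- adj | t(adj)
  nonadj <- all_d[upper.tri(all_d) & !adj]
  expect_lt(adj_mean, mean(nonadj))
})
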