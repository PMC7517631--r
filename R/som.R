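#' Configuration for the hexagonal batch SOM
#'
#' Training runs in three phases: an ordering phase with the neighborhood
#' radius decayed linearly from `radius_start` to `radius_end`, a tuning
#' phase at constant `radius_end`, and a short radius-0 polish in which the
#' update degenerates to batch k-means on the lattice partition.
#'
#' @param rows,cols Grid dimensions (default 7 x 7, i.e. 49 modules).
#' @param epochs_ordering,epochs_tuning,epochs_polish Epochs per phase
#'   (defaults 100, 50, 10).
#' @param radius_start,radius_end Gaussian neighborhood radii in lattice
#'   units (defaults 3 and 1).
#' @param seed Seed used by [init_codebook()].
#' @return A list of class `som_config`.
#' @export
som_config <- function(rows = 7, cols = 7, epochs_ordering = 100,
                       epochs_tuning = 50, epochs_polish = 10,
                       radius_start = 3, radius_end = 1, seed = 1) {
  stopifnot(rows >= 1, cols >= 1, rows * cols >= 2 || (rows == 1 && cols == 1),
            epochs_ordering >= 1, epochs_tuning >= 0, epochs_polish >= 0,
            radius_start >= radius_end, radius_end >= 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 epochs_ordering = as.integer(epochs_ordering),
                 epochs_tuning = as.integer(epochs_tuning),
                 epochs_polish = as.integer(epochs_polish),
                 radius_start = radius_start, radius_end = radius_end,
                 seed = as.integer(seed)),
            class = "som_config")
}

#' Hexagonal lattice coordinates and neighbor structure
#'
#' Offset ("odd-row shifted") hexagonal lattice with unit spacing. Modules
#' are numbered row-major from 1 (bottom-left) to `rows * cols`
#' (top-right). Interior modules have exactly 6 lattice neighbors; lattice
#' distances are Euclidean on the hexagonal coordinates.
#'
#' @param rows,cols Grid dimensions.
#' @return List with `coords` (data frame: `module`, `row`, `col`, `x`,
#'   `y`), `dist` (module x module lattice distance matrix), and
#'   `neighbors` (list of adjacent-module indices per module).
#' @export
hex_grid <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  m <- rows * cols
  idx <- seq_len(m) - 1L
  r <- idx %/% cols
  c <- idx %% cols
  x <- c + 0.5 * (r %% 2)
  y <- r * sqrt(3) / 2
  coords <- data.frame(module = seq_len(m), row = r + 1L, col = c + 1L,
                       x = x, y = y)
  d <- as.matrix(stats::dist(cbind(x, y)))
  dimnames(d) <- NULL
  adj <- d < 1 + 1e-9 & d > 0
  neighbors <- lapply(seq_len(m), function(i) which(adj[i, ]))
  list(coords = coords, dist = d, neighbors = neighbors)
}

#' Initialize a SOM codebook from the data
#'
#' Deterministic given `config$seed`: codebook vectors are data rows
#' sampled without replacement; when the grid has more modules than there
#' are data rows, the remainder are small Gaussian jitters around the data
#' mean.
#'
#' @param data Numeric matrix (rows = observations, 3 condition columns).
#' @param config A [som_config()].
#' @return Numeric codebook matrix (`rows * cols` x `ncol(data)`).
#' @export
init_codebook <- function(data, config) {
  data <- as.matrix(data)
  stopifnot(nrow(data) >= 1)
  m <- config$rows * config$cols
  set.seed(config$seed)
  if (nrow(data) >= m) {
    cb <- data[sample.int(nrow(data), m), , drop = FALSE]
  } else {
    mu <- colMeans(data)
    sds <- apply(data, 2, stats::sd)
    sds[!is.finite(sds) | sds == 0] <- 1
    extra <- m - nrow(data)
    jitter <- matrix(stats::rnorm(extra * ncol(data), sd = 0.05),
                     nrow = extra) %*% diag(sds, ncol(data))
    jitter <- sweep(jitter, 2, mu, "+")
    cb <- rbind(data, jitter)
  }
  dimnames(cb) <- NULL
  cb
}

# Squared Euclidean distances between data rows and codebook rows.
.cross_dist2 <- function(data, cb) {
  d2 <- matrix(rowSums(data^2), nrow(data), nrow(cb)) +
    matrix(rowSums(cb^2), nrow(data), nrow(cb), byrow = TRUE) -
    2 * data %*% t(cb)
  pmax(d2, 0)
}

.bmu <- function(data, cb) {
  max.col(-.cross_dist2(data, cb), ties.method = "first")
}

#' Construct an untrained SOM model
#'
#' @param data Numeric profile matrix with observation rownames.
#' @param config A [som_config()].
#' @return List of class `som_model` with the config, grid, and initialized
#'   codebook.
#' @export
som_init <- function(data, config = som_config()) {
  data <- as.matrix(data)
  grid <- hex_grid(config$rows, config$cols)
  structure(list(config = config, grid = grid,
                 codebook = init_codebook(data, config),
                 assignment = NULL, qe_history = NULL,
                 distortion_history = NULL),
            class = "som_model")
}

#' Batch-train a SOM
#'
#' Each epoch finds every row's best-matching unit (BMU) and replaces each
#' codebook vector with the neighborhood-weighted mean of all rows, weights
#' `exp(-lattice_dist^2 / (2 sigma^2))` on the lattice distance between a
#' module and each row's BMU. At sigma = 0 the update is the hard Lloyd
#' (k-means) step on the BMU partition. Modules receiving no weight in an
#' epoch are left unchanged. Per-epoch quantization error (mean distance to
#' BMU) and distortion (mean squared distance) are recorded.
#'
#' @param model A `som_model` from [som_init()].
#' @param data Numeric matrix; must be finite.
#' @return The trained `som_model` with `qe_history` and
#'   `distortion_history`.
#' @export
train_batch <- function(model, data) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("SOM input must be finite", call. = FALSE)
  cfg <- model$config
  sigmas <- c(
    if (cfg$epochs_ordering > 1)
      seq(cfg$radius_start, cfg$radius_end, length.out = cfg$epochs_ordering)
    else cfg$radius_start,
    rep(cfg$radius_end, cfg$epochs_tuning),
    rep(0, cfg$epochs_polish)
  )
  cb <- model$codebook
  m <- nrow(cb)
  D2 <- model$grid$dist^2
  qe <- dist2 <- numeric(length(sigmas))
  for (e in seq_along(sigmas)) {
    sigma <- sigmas[e]
    cross <- .cross_dist2(data, cb)
    bmu <- max.col(-cross, ties.method = "first")
    best <- cross[cbind(seq_len(nrow(data)), bmu)]
    qe[e] <- mean(sqrt(best))
    dist2[e] <- mean(best)
    part <- rowsum(data, bmu)  # rows only for occupied modules
    sums <- matrix(0, m, ncol(data))
    sums[as.integer(rownames(part)), ] <- part
    ns <- tabulate(bmu, nbins = m)
    if (sigma > 0) {
      h <- exp(-D2 / (2 * sigma^2))
      num <- h %*% sums
      den <- as.vector(h %*% ns)
      upd <- den > 0
      cb[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    } else {
      upd <- ns > 0
      cb[upd, ] <- sums[upd, , drop = FALSE] / ns[upd]
    }
  }
  model$codebook <- cb
  model$qe_history <- qe
  model$distortion_history <- dist2
  model
}

#' Assign observations to their best-matching module
#'
#' Ties (equidistant codebooks) break to the lowest module index.
#'
#' @param model Trained `som_model`.
#' @param data Numeric matrix with observation rownames.
#' @return Named integer vector: observation -> module index.
#' @export
assign_modules <- function(model, data) {
  data <- as.matrix(data)
  bmu <- .bmu(data, model$codebook)
  stats::setNames(bmu, rownames(data))
}

#' Mean distance of observations to their best-matching codebook
#'
#' @param model Trained `som_model`.
#' @param data Numeric matrix.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(model, data) {
  data <- as.matrix(data)
  cross <- .cross_dist2(data, model$codebook)
  bmu <- max.col(-cross, ties.method = "first")
  mean(sqrt(cross[cbind(seq_len(nrow(data)), bmu)]))
}

#' U-matrix: codebook distances between lattice-adjacent modules
#'
#' @param model Trained `som_model`.
#' @return List with `pairs` (data frame `module_a`, `module_b`,
#'   `distance`, one row per unordered adjacent pair) and `module_values`
#'   (per module, mean distance to its lattice neighbors; `NA` for a module
#'   with no neighbors).
#' @export
compute_umatrix <- function(model) {
  cb <- model$codebook
  nb <- model$grid$neighbors
  m <- nrow(cb)
  pa <- pb <- integer(0)
  for (i in seq_len(m)) {
    js <- nb[[i]][nb[[i]] > i]
    pa <- c(pa, rep(i, length(js)))
    pb <- c(pb, js)
  }
  pd <- sqrt(rowSums((cb[pa, , drop = FALSE] - cb[pb, , drop = FALSE])^2))
  module_values <- vapply(seq_len(m), function(i) {
    js <- nb[[i]]
    if (length(js) == 0) return(NA_real_)
    mean(sqrt(rowSums((cb[js, , drop = FALSE] -
                         matrix(cb[i, ], length(js), ncol(cb),
                                byrow = TRUE))^2)))
  }, numeric(1))
  list(pairs = data.frame(module_a = pa, module_b = pb, distance = pd),
       module_values = module_values)
}

#' Initialize, train and assign in one call
#'
#' @param data Numeric profile matrix with observation rownames.
#' @param config A [som_config()].
#' @return Trained `som_model` with `$assignment` filled in.
#' @export
som_fit <- function(data, config = som_config()) {
  model <- som_init(data, config)
  model <- train_batch(model, data)
  model$assignment <- assign_modules(model, data)
  model
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %d x %d hexagonal grid (%d modules)\n",
              x$config$rows, x$config$cols, nrow(x$codebook)))
  if (!is.null(x$assignment)) {
    cat(sprintf("  %d observations assigned; QE = %.4g\n",
                length(x$assignment),
                x$qe_history[length(x$qe_history)]))
  }
  invisible(x)
}
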