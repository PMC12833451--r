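#' Encoder configuration
#'
#' Architecture and optimization settings for the graph-convolutional
#' autoencoder. The encoder stacks `n_layers` graph-convolution layers
#' (hidden width `d_hidden`, latent width `d_latent`); the decoder mirrors it
#' back to gene width. Training minimizes mean squared reconstruction error
#' of the normalized expression with full-batch adaptive-moment updates.
#'
#' @param d_hidden hidden layer width.
#' @param d_latent latent embedding width; this is also the width of the
#'   fused representation downstream.
#' @param n_layers number of encoder layers (>= 1).
#' @param activation non-linearity for hidden layers: `"elu"`, `"relu"` or
#'   `"identity"`. The latent and reconstruction layers are linear.
#' @param epochs full-batch training epochs.
#' @param learning_rate adaptive-moment step size.
#' @param weight_decay L2 penalty coefficient on weights.
#' @param seed integer seed governing weight initialization.
#' @return validated list of class `"EncoderConfig"`.
#' @export
encoderConfig <- function(d_hidden = 64L, d_latent = 32L, n_layers = 2L,
                          activation = c("elu", "relu", "identity"),
                          epochs = 150L, learning_rate = 1e-3,
                          weight_decay = 0, seed = 1L) {
  activation <- match.arg(activation)
  if (d_latent < 2L) stopValidation("d_latent must be >= 2")
  if (epochs < 1L) stopValidation("epochs must be >= 1")
  if (n_layers < 1L) stopValidation("n_layers must be >= 1")
  if (learning_rate <= 0) stopValidation("learning_rate must be > 0")
  structure(list(d_hidden = as.integer(d_hidden),
                 d_latent = as.integer(d_latent),
                 n_layers = as.integer(n_layers),
                 activation = activation, epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "EncoderConfig")
}

activationFun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z, a) (z > 0) + 0),
         elu = list(f = function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
                    df = function(z, a) ifelse(z > 0, 1, a + 1)),
         identity = list(f = identity, df = function(z, a) 1),
         stopValidation("unknown activation: ", name))
}

#' One graph-convolution layer
#'
#' Computes `activation(Ahat %*% H %*% W)`, the message-passing update of a
#' graph-convolutional network: neighbor features are aggregated through the
#' normalized adjacency, linearly transformed, then passed through the
#' non-linearity.
#'
#' @param H n x d_in input features.
#' @param Ahat n x n normalized adjacency ([normalizeAdjacency()]).
#' @param W d_in x d_out weight matrix.
#' @param activation `"elu"`, `"relu"` or `"identity"`.
#' @return dense n x d_out output features.
#' @export
gcnLayer <- function(H, Ahat, W, activation = "identity") {
  H <- asMatrix(H); W <- asMatrix(W)
  if (nrow(Ahat) != ncol(Ahat) || nrow(H) != nrow(Ahat) || ncol(H) != nrow(W)) {
    stopValidation("shape mismatch: Ahat ", nrow(Ahat), "x", ncol(Ahat),
                   ", H ", nrow(H), "x", ncol(H), ", W ", nrow(W), "x", ncol(W))
  }
  act <- activationFun(activation)
  act$f(as.matrix(Ahat %*% H) %*% W)
}

glorotInit <- function(d_in, d_out) {
  s <- sqrt(6 / (d_in + d_out))
  matrix(runif(d_in * d_out, -s, s), d_in, d_out)
}

#' Train the graph-convolutional autoencoder
#'
#' Learns spatially-aware spot embeddings: the encoder applies `n_layers`
#' graph-convolution layers ending at the latent width, the decoder mirrors
#' them back to gene width, and the whole stack is trained full-batch to
#' minimize the mean squared reconstruction error of the normalized
#' expression matrix. All randomness (weight initialization) flows from
#' `config$seed`, so a given seed is bit-reproducible on one machine.
#'
#' @param X n_spots x n_genes normalized expression matrix (spots as rows).
#' @param Ahat normalized spatial adjacency from [normalizeAdjacency()] or a
#'   [SpatialGraph-class].
#' @param config an [encoderConfig()].
#' @return list with `embedding` (n x d_latent latent features), `trace`
#'   (per-epoch reconstruction loss, length `epochs`), `weights`, `config`.
#' @export
trainSpatialEncoder <- function(X, Ahat, config = encoderConfig()) {
  if (is(Ahat, "SpatialGraph")) Ahat <- Ahat@Ahat
  X <- asMatrix(X)
  n <- nrow(X); m <- ncol(X)
  if (nrow(Ahat) != n) {
    stopValidation("Ahat size ", nrow(Ahat), " does not match n_spots ", n)
  }
  widths <- c(m, rep(config$d_hidden, config$n_layers - 1L), config$d_latent)
  widths <- c(widths, rev(widths)[-1L])          # decoder mirrors encoder
  L <- length(widths) - 1L
  latent_layer <- config$n_layers
  act <- activationFun(config$activation)
  # hidden layers are non-linear; the latent and the reconstruction are linear
  nonlinear <- rep(TRUE, L)
  nonlinear[c(latent_layer, L)] <- FALSE

  W <- withSeed(config$seed, {
    lapply(seq_len(L), function(l) glorotInit(widths[l], widths[l + 1L]))
  })
  mW <- lapply(W, function(w) w * 0)
  vW <- lapply(W, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate; wd <- config$weight_decay
  trace <- numeric(config$epochs)
  H <- vector("list", L + 1L)    # post-activation outputs; H[[1]] = X
  Z <- vector("list", L)         # pre-activation
  AH <- vector("list", L)        # Ahat %*% H[[l]] (cached for gradients)

  for (epoch in seq_len(config$epochs)) {
    H[[1L]] <- X
    for (l in seq_len(L)) {
      AH[[l]] <- as.matrix(Ahat %*% H[[l]])
      Z[[l]] <- AH[[l]] %*% W[[l]]
      H[[l + 1L]] <- if (nonlinear[l]) act$f(Z[[l]]) else Z[[l]]
    }
    R <- H[[L + 1L]] - X
    loss <- mean(R^2)
    if (!is.finite(loss)) {
      stopNumerical("non-finite loss at epoch ", epoch,
                    "; consider lowering learning_rate")
    }
    trace[epoch] <- loss

    G <- (2 / (n * m)) * R
    t_adam <- epoch
    for (l in L:1L) {
      dZ <- if (nonlinear[l]) G * act$df(Z[[l]], H[[l + 1L]]) else G
      gW <- crossprod(AH[[l]], dZ)
      if (wd > 0) gW <- gW + wd * W[[l]]
      if (l > 1L) G <- as.matrix(Ahat %*% (dZ %*% t(W[[l]])))  # Ahat symmetric
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mhat <- mW[[l]] / (1 - b1^t_adam)
      vhat <- vW[[l]] / (1 - b2^t_adam)
      W[[l]] <- W[[l]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }

  # final embedding from the trained encoder
  Hcur <- X
  for (l in seq_len(latent_layer)) {
    Hcur <- gcnLayer(Hcur, Ahat, W[[l]],
                     if (nonlinear[l]) config$activation else "identity")
  }
  rownames(Hcur) <- rownames(X)
  list(embedding = Hcur, trace = trace, weights = W, config = config)
}

#' Save or restore trained encoder weights
#'
#' Checkpoints are a directory of plain-text artifacts: one CSV per layer
#' weight matrix plus a JSON manifest with the configuration and layer
#' shapes, portable across platforms.
#'
#' @param encoder the list returned by [trainSpatialEncoder()].
#' @param path checkpoint directory (created if needed).
#' @return `path` (write) or a list with `weights` and `config` (read),
#'   suitable for re-embedding new data with [gcnLayer()].
#' @export
writeEncoderCheckpoint <- function(encoder, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (l in seq_along(encoder$weights)) {
    data.table::fwrite(as.data.frame(encoder$weights[[l]]),
                       file.path(path, sprintf("W%02d.csv", l)))
  }
  manifest <- list(n_layers_total = length(encoder$weights),
                   shapes = lapply(encoder$weights, dim),
                   config = unclass(encoder$config),
                   final_loss = encoder$trace[length(encoder$trace)])
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEncoderCheckpoint
#' @export
readEncoderCheckpoint <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stopIO("no checkpoint manifest at ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  W <- lapply(seq_len(manifest$n_layers_total), function(l) {
    as.matrix(data.table::fread(file.path(path, sprintf("W%02d.csv", l))))
  })
  cfg <- manifest$config
  config <- encoderConfig(d_hidden = cfg$d_hidden, d_latent = cfg$d_latent,
                          n_layers = cfg$n_layers, activation = cfg$activation,
                          epochs = cfg$epochs, learning_rate = cfg$learning_rate,
                          weight_decay = cfg$weight_decay, seed = cfg$seed)
  list(weights = W, config = config)
}

#' Normalize an expression matrix for the spatial encoder
#'
#' Library-size scales each spot to the median library, applies `log1p`, and
#' retains the `n_hvg` most dispersed genes (dispersion = variance / mean of
#' the scaled counts; all genes are kept when there are at most `n_hvg`).
#' Normalization is applied once: an already-normalized tissue is returned
#' unchanged.
#'
#' @param tissue a [SpatialTissue-class] holding raw counts.
#' @param n_hvg number of highly variable genes to keep (>= 2).
#' @return A normalized [SpatialTissue-class] (assay `"logcounts"`, possibly
#'   fewer genes, stable gene order, `isNormalized()` TRUE).
#' @export
normalizeExpression <- function(tissue, n_hvg = 3000L) {
  if (n_hvg < 2L) stopValidation("n_hvg must be >= 2")
  if (isNormalized(tissue)) return(tissue)
  counts <- SummarizedExperiment::assay(tissue, 1L)   # genes x spots
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    warning(sum(lib == 0), " spot(s) have zero library size; left as zeros",
            call. = FALSE)
    lib[lib == 0] <- 1
  }
  target <- stats::median(lib)
  scaled <- counts %*% Matrix::Diagonal(x = target / lib)
  if (nrow(scaled) > n_hvg) {
    mu <- Matrix::rowMeans(scaled)
    ex2 <- Matrix::rowMeans(scaled^2)
    v <- pmax(ex2 - mu^2, 0) * ncol(scaled) / max(ncol(scaled) - 1L, 1L)
    disp <- ifelse(mu > 0, v / mu, -Inf)
    keep <- sort(order(disp, decreasing = TRUE)[seq_len(n_hvg)])
    scaled <- scaled[keep, , drop = FALSE]
  }
  lg <- log1p(scaled)
  dimnames(lg) <- list(rownames(scaled), colnames(counts))
  out <- SpatialTissue(lg, coords = spatialCoords(tissue),
                       domains = domainTruth(tissue), is_normalized = TRUE)
  out
}
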