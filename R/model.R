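#' Model configuration for the residue-embedding network
#'
#' The embedding model is a stack of 1D residual convolutional blocks fed by a
#' learnable per-symbol lookup table. Each block computes
#' `x + Conv2(sigma(Conv1(sigma(x))))` where `Conv1` and `Conv2` are 1D
#' convolutions with identical hyper-parameters (no weight sharing anywhere)
#' and `sigma` is the ELU activation. Convolutions use symmetric zero padding
#' of `(kernel_size - 1)/2` so the per-residue output has exactly one row per
#' input residue.
#'
#' @param embed_dim embedding dimensionality d (default 256)
#' @param n_blocks number of residual blocks (default 8)
#' @param kernel_size convolution kernel width, must be odd (default 7)
#' @param activation activation function name; only `"elu"` is supported
#' @param vocab ordered amino-acid alphabet; defaults to the 20 canonical
#'   residues plus `"X"` as the unknown symbol. Non-canonical residues
#'   (B, Z, U, O, J, ...) collapse to `"X"`.
#' @return an object of class `model_config`
#' @export
model_config <- function(embed_dim = 256L, n_blocks = 8L, kernel_size = 7L,
                         activation = "elu", vocab = NULL) {
  embed_dim <- as.integer(embed_dim)
  n_blocks <- as.integer(n_blocks)
  kernel_size <- as.integer(kernel_size)
  if (is.na(embed_dim) || embed_dim < 1L) stop("embed_dim must be a positive integer")
  if (is.na(n_blocks) || n_blocks < 1L) stop("n_blocks must be a positive integer")
  if (is.na(kernel_size) || kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("kernel_size must be an odd positive integer")
  activation <- match.arg(tolower(activation), "elu")
  if (is.null(vocab)) vocab <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  if (anyDuplicated(vocab)) stop("vocab contains duplicate symbols")
  structure(list(embed_dim = embed_dim, n_blocks = n_blocks,
                 kernel_size = kernel_size, activation = activation,
                 vocab = vocab),
            class = "model_config")
}

#' @exportS3Method base::print
print.model_config <- function(x, ...) {
  cat(sprintf("residue-embedding model config: d=%d, %d residual blocks, kernel %d, %s, |vocab|=%d\n",
              x$embed_dim, x$n_blocks, x$kernel_size, toupper(x$activation),
              length(x$vocab)))
  cat(sprintf("  receptive field %d residues, %s parameters\n",
              receptive_field(x), format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Receptive field of the embedding network
#'
#' The maximal window of input residues that can influence a single output
#' embedding: `1 + 2 * n_blocks * (kernel_size - 1)` (the lookup encoder sees
#' one residue; each of the `2 * n_blocks` convolutions widens the window by
#' `kernel_size - 1`). Residue edits at or beyond this distance from position
#' i can never change embedding row i.
#'
#' @param cfg a [model_config()]
#' @return a positive integer
#' @export
receptive_field <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  1L + 2L * cfg$n_blocks * (cfg$kernel_size - 1L)
}

#' Number of learnable parameters
#'
#' Exact count of learnable scalars: the `|vocab| x d` input lookup table plus,
#' per block, two convolutions of `d * d * kernel_size` weights and `d` biases.
#' The default architecture (d = 256, 8 blocks, kernel 7) has 7,349,504
#' parameters, i.e. ~7M.
#'
#' @param cfg a [model_config()]
#' @return a non-negative integer (as double, counts can exceed .Machine$integer.max)
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  d <- as.numeric(cfg$embed_dim)
  k <- as.numeric(cfg$kernel_size)
  length(cfg$vocab) * d + cfg$n_blocks * 2 * (d * d * k + d)
}

#' Initialize model parameters
#'
#' Fan-in-scaled random initialization: convolution weights are drawn from
#' `N(0, 1/(d * kernel_size))`, biases start at zero, and lookup-table entries
#' are standard normal. All properties of the model (length preservation,
#' locality, determinism) hold for any initialization.
#'
#' @param cfg a [model_config()]
#' @param seed integer RNG seed
#' @return an object of class `model_params`: `list(config, embed, blocks)`
#'   where `embed` is a `d x |vocab|` matrix and each block holds conv weight
#'   arrays `W1`, `W2` of dim `c(d, d, kernel_size)` and bias vectors `b1`, `b2`.
#' @export
init_params <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(as.integer(seed))
  d <- cfg$embed_dim; k <- cfg$kernel_size
  sd_w <- sqrt(1 / (d * k))
  blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
    list(W1 = array(stats::rnorm(d * d * k, sd = sd_w), dim = c(d, d, k)),
         b1 = numeric(d),
         W2 = array(stats::rnorm(d * d * k, sd = sd_w), dim = c(d, d, k)),
         b2 = numeric(d))
  })
  structure(list(config = cfg,
                 embed = matrix(stats::rnorm(d * length(cfg$vocab)), nrow = d,
                                dimnames = list(NULL, cfg$vocab)),
                 blocks = blocks),
            class = "model_params")
}

## ELU activation and its derivative (alpha = 1), in place on matrices.
elu <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}

elu_grad <- function(x) {
  g <- array(1, dim = dim(x))
  neg <- x < 0
  g[neg] <- exp(x[neg])
  g
}

## 1D convolution over a d x n channels-by-positions matrix with symmetric
## zero padding. W has dim c(d_out, d_in, k); bias b length d_out.
## Y[, j] = b + sum_t W[,,t] %*% X[, j + t - h - 1]   (h = (k-1)/2)
conv1d <- function(X, W, b) {
  k <- dim(W)[3L]; h <- (k - 1L) %/% 2L
  n <- ncol(X)
  Y <- matrix(b, nrow = dim(W)[1L], ncol = n)
  for (t in seq_len(k)) {
    off <- t - h - 1L
    j0 <- max(1L, 1L - off); j1 <- min(n, n - off)
    if (j0 > j1) next
    j <- j0:j1
    Wt <- matrix(W[, , t], dim(W)[1L], dim(W)[2L])
    Y[, j] <- Y[, j] + Wt %*% X[, j + off, drop = FALSE]
  }
  Y
}

## Backward pass of conv1d: given upstream gradient dY, the input X and
## weights W, return gradients wrt X, W and b.
conv1d_backward <- function(dY, X, W) {
  k <- dim(W)[3L]; h <- (k - 1L) %/% 2L
  n <- ncol(X)
  dX <- matrix(0, nrow(X), n)
  dW <- array(0, dim = dim(W))
  for (t in seq_len(k)) {
    off <- t - h - 1L
    j0 <- max(1L, 1L - off); j1 <- min(n, n - off)
    if (j0 > j1) next
    j <- j0:j1
    Wt <- matrix(W[, , t], dim(W)[1L], dim(W)[2L])
    dX[, j + off] <- dX[, j + off] + crossprod(Wt, dY[, j, drop = FALSE])
    dW[, , t] <- dY[, j, drop = FALSE] %*% t(X[, j + off, drop = FALSE])
  }
  list(dX = dX, dW = dW, db = rowSums(dY))
}

#' Apply one residual block
#'
#' Computes `x + Conv2(sigma(Conv1(sigma(x))))` on an `n x d` matrix of
#' per-residue activations (row i = position i). Convolutions preserve length
#' via symmetric zero padding.
#'
#' @param x `n x d` real matrix
#' @param block block parameters: list with `W1`, `b1`, `W2`, `b2`
#'   (conv weight arrays `d x d x k` and length-d biases)
#' @param activation activation name, `"elu"`
#' @return `n x d` real matrix
#' @export
residual_block <- function(x, block, activation = "elu") {
  match.arg(tolower(activation), "elu")
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (ncol(x) != dim(block$W1)[2L])
    stop(sprintf("channel mismatch: x has %d channels, block expects %d",
                 ncol(x), dim(block$W1)[2L]))
  X <- t(x)
  t(residual_block_fwd(X, block)$X_out)
}

## Internal forward on d x n matrices, returning the cache needed by backprop.
residual_block_fwd <- function(X, block) {
  S1 <- elu(X)
  C1 <- conv1d(S1, block$W1, block$b1)
  S2 <- elu(C1)
  X_out <- X + conv1d(S2, block$W2, block$b2)
  list(X_out = X_out, X_in = X, S1 = S1, C1 = C1, S2 = S2)
}

residual_block_bwd <- function(dOut, cache, block) {
  ## branch: Conv2(S2); residual path passes dOut through unchanged
  g2 <- conv1d_backward(dOut, cache$S2, block$W2)
  dC1 <- g2$dX * elu_grad(cache$C1)
  g1 <- conv1d_backward(dC1, cache$S1, block$W1)
  dX_in <- dOut + g1$dX * elu_grad(cache$X_in)
  list(dX_in = dX_in,
       dW1 = g1$dW, db1 = g1$db, dW2 = g2$dW, db2 = g2$db)
}

## Map residue characters to vocab indices; non-alphabetic characters error,
## alphabetic characters outside the vocab collapse to the unknown symbol.
seq_to_indices <- function(seq, cfg) {
  if (length(seq) == 1L && is.character(seq)) seq <- strsplit(seq, "")[[1]]
  if (length(seq) == 0L) stop("empty sequence")
  seq <- toupper(seq)
  if (!all(grepl("^[A-Z]$", seq)))
    stop("sequence contains non-alphabetic characters: ",
         paste(unique(seq[!grepl("^[A-Z]$", seq)]), collapse = " "))
  idx <- match(seq, cfg$vocab)
  unk <- match("X", cfg$vocab)
  if (is.na(unk)) unk <- length(cfg$vocab)
  idx[is.na(idx)] <- unk
  idx
}

## Full forward pass on vocab indices; returns d x n embedding plus per-block
## caches when requested (training).
forward_embed <- function(idx, params, keep_cache = FALSE) {
  X <- params$embed[, idx, drop = FALSE]
  caches <- if (keep_cache) vector("list", length(params$blocks)) else NULL
  for (b in seq_along(params$blocks)) {
    fwd <- residual_block_fwd(X, params$blocks[[b]])
    if (keep_cache) caches[[b]] <- fwd
    X <- fwd$X_out
  }
  list(emb = X, caches = caches, idx = idx)
}

## Backprop dOut (d x n) through the block stack; returns parameter gradients
## in the same structure as params (embed + blocks).
backward_embed <- function(dOut, fwd, params) {
  n_blocks <- length(params$blocks)
  grads <- vector("list", n_blocks)
  for (b in rev(seq_len(n_blocks))) {
    bg <- residual_block_bwd(dOut, fwd$caches[[b]], params$blocks[[b]])
    grads[[b]] <- bg[c("dW1", "db1", "dW2", "db2")]
    names(grads[[b]]) <- c("W1", "b1", "W2", "b2")
    dOut <- bg$dX_in
  }
  dE <- matrix(0, nrow(params$embed), ncol(params$embed))
  acc <- rowsum(t(dOut), group = fwd$idx)           # one row per used symbol
  dE[, as.integer(rownames(acc))] <- t(acc)
  list(embed = dE, blocks = grads)
}

#' Embed a protein sequence residue by residue
#'
#' Runs the residual conv stack over one sequence and returns one embedding
#' row per residue. Sequences are embedded independently of one another and
#' the output is deterministic for fixed parameters.
#'
#' @param seq a character string of amino acids (or character vector of
#'   single residues); letters outside the model vocabulary map to the
#'   unknown symbol, non-alphabetic characters are an error
#' @param params a [init_params()] / trained `model_params` object
#' @param id optional sequence identifier attached as attribute `seq_id`
#' @return an `n x d` numeric matrix (class `embedding_matrix`)
#' @export
encode_sequence <- function(seq, params, id = NULL) {
  stopifnot(inherits(params, "model_params"))
  idx <- seq_to_indices(seq, params$config)
  out <- t(forward_embed(idx, params)$emb)
  attr(out, "seq_id") <- id
  class(out) <- c("embedding_matrix", class(out))
  out
}

#' Embed many sequences
#'
#' @param seqs named character vector (names are sequence ids) as returned by
#'   [read_fasta()]
#' @param params `model_params`
#' @return named list of `n x d` embedding matrices
#' @export
encode_sequences <- function(seqs, params) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  out <- lapply(seq_along(seqs),
                function(i) encode_sequence(seqs[[i]], params, id = names(seqs)[i]))
  names(out) <- names(seqs)
  out
}

## Structural validation shared by the loader and the trainer.
validate_params <- function(params) {
  stopifnot(inherits(params, "model_params"))
  cfg <- params$config
  d <- cfg$embed_dim; k <- cfg$kernel_size
  if (!identical(dim(params$embed), c(d, length(cfg$vocab))))
    stop("embed table has wrong shape")
  if (length(params$blocks) != cfg$n_blocks)
    stop("wrong number of residual blocks")
  for (b in params$blocks) {
    if (!identical(dim(b$W1), c(d, d, k)) || !identical(dim(b$W2), c(d, d, k)))
      stop("conv weight array has wrong shape")
    if (length(b$b1) != d || length(b$b2) != d)
      stop("conv bias has wrong length")
  }
  invisible(params)
}

#' Save / load model parameters
#'
#' The model file is a single self-describing RDS holding the configuration
#' and every weight array; the loader re-validates all shape invariants.
#'
#' @param params `model_params`
#' @param path file path
#' @return `load_model` returns validated `model_params`
#' @export
save_model <- function(params, path) {
  validate_params(params)
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  params <- readRDS(path)
  if (!inherits(params$config, "model_config")) stop("not a model file")
  validate_params(params)
}
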