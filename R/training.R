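#' Training configuration
#'
#' Defaults follow the published training recipe: 24,000 optimizer steps,
#' batch size 512, crop length 256 residues, AdamW with learning rate 1e-5
#' and weight decay 1e-2, and L2 loss factor gamma = 5e-3.
#'
#' @param steps number of optimizer steps
#' @param batch_size pairs per batch
#' @param crop_len maximum sequence length per training example
#' @param learning_rate AdamW learning rate
#' @param weight_decay AdamW decoupled weight decay
#' @param gamma scaling factor of the L2 embedding-norm regularizer
#' @param seed RNG seed for batch sampling and cropping
#' @param symmetric if `TRUE` the N-pair loss averages both directions
#'   (A against B's residues and B against A's); default `FALSE`, matching
#'   the one-directional softmax over the partner sequence
#' @return object of class `training_config`
#' @export
training_config <- function(steps = 24000L, batch_size = 512L, crop_len = 256L,
                            learning_rate = 1e-5, weight_decay = 1e-2,
                            gamma = 5e-3, seed = 1L, symmetric = FALSE) {
  stopifnot(steps >= 0, batch_size >= 1, crop_len >= 1,
            learning_rate > 0, weight_decay >= 0, gamma >= 0)
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 crop_len = as.integer(crop_len), learning_rate = learning_rate,
                 weight_decay = weight_decay, gamma = gamma,
                 seed = as.integer(seed), symmetric = isTRUE(symmetric)),
            class = "training_config")
}

#' Build the binary alignment target matrix for a sequence pair
#'
#' `T[i, j] = 1` exactly when residue i of A and residue j of B occupy the
#' same column of the trusted pairwise alignment; 0 everywhere else. Aligned
#' column indices must be strictly increasing in both sequences.
#'
#' @param cols two-column integer matrix (or data.frame) of 1-based aligned
#'   residue indices `(i, j)`; zero rows allowed
#' @param len_a,len_b sequence lengths
#' @return a sparse `len_a x len_b` binary matrix (`Matrix::sparseMatrix`)
#' @export
targets_from_alignment <- function(cols, len_a, len_b) {
  cols <- as.matrix(cols)
  if (length(cols) == 0L) cols <- matrix(integer(), ncol = 2L)
  if (ncol(cols) != 2L) stop("cols must have two columns (i, j)")
  storage.mode(cols) <- "integer"
  if (nrow(cols) > 0L) {
    if (any(cols[, 1L] < 1L) || any(cols[, 1L] > len_a) ||
        any(cols[, 2L] < 1L) || any(cols[, 2L] > len_b))
      stop("aligned column index out of sequence range")
    if (nrow(cols) > 1L &&
        (any(diff(cols[, 1L]) <= 0L) || any(diff(cols[, 2L]) <= 0L)))
      stop("alignment columns must be strictly increasing in both sequences")
  }
  Matrix::sparseMatrix(i = cols[, 1L], j = cols[, 2L], x = 1,
                       dims = c(len_a, len_b))
}

## log softmax denominators: log sum_w exp(D[i, w]) per row, stably.
row_logsumexp <- function(D) {
  m <- apply(D, 1L, max)
  m + log(rowSums(exp(D - m)))
}

#' Masked N-pair contrastive loss with L2 regularization
#'
#' For every aligned residue pair (i, j) the loss adds the negative log
#' softmax of the raw dot product `D[i, j] = a_i . b_j`, normalized over all
#' residues w of B: `-Ra_i * Rb_j * T_ij * log( exp(D_ij) / sum_w exp(D_iw) )`.
#' Repeat-mask bits silence contributions from repetitive regions. The L2
#' term is `(gamma / n) * (sum_i Ra_i |a_i|^2 + sum_i Rb_i |b_i|^2)` with
#' `n` the number of unmasked residues in the pair, keeping the penalty a
#' per-residue average that is stable across crop lengths.
#'
#' @param embA,embB `n x d` embedding matrices for the two sequences
#' @param T binary target matrix (`len(A) x len(B)`), dense or sparse
#' @param ra,rb repeat-mask bit vectors (1 = keep, 0 = repetitive); default
#'   all ones
#' @param gamma L2 scaling factor, >= 0
#' @param symmetric average the A->B and B->A directions (default `FALSE`:
#'   softmax over B only, as in the printed objective)
#' @return list with `loss`, `npair_term`, `l2_term` (loss = npair + l2)
#' @export
masked_npair_loss <- function(embA, embB, T, ra = NULL, rb = NULL,
                              gamma = 5e-3, symmetric = FALSE) {
  embA <- as.matrix(embA); embB <- as.matrix(embB)
  if (gamma < 0) stop("gamma must be non-negative")
  nA <- nrow(embA); nB <- nrow(embB)
  if (ncol(embA) != ncol(embB)) stop("embedding dimensionality mismatch")
  if (nrow(T) != nA || ncol(T) != nB) stop("target matrix shape mismatch")
  if (is.null(ra)) ra <- rep(1, nA)
  if (is.null(rb)) rb <- rep(1, nB)
  if (length(ra) != nA || length(rb) != nB) stop("mask length mismatch")
  if (!all(ra %in% c(0, 1)) || !all(rb %in% c(0, 1)))
    stop("masks must be binary")

  np <- npair_direction(embA, embB, T, ra, rb)
  if (symmetric) {
    np2 <- npair_direction(embB, embA, Matrix::t(T), rb, ra)
    np <- (np + np2) / 2
  }
  n_unmasked <- sum(ra) + sum(rb)
  l2 <- if (n_unmasked == 0) 0 else
    (gamma / n_unmasked) * (sum(ra * rowSums(embA^2)) + sum(rb * rowSums(embB^2)))
  list(loss = np + l2, npair_term = np, l2_term = l2)
}

## One direction of the N-pair term: softmax over the residues of B for each
## aligned pair. Only rows of D with at least one aligned column are needed.
npair_direction <- function(embA, embB, T, ra, rb) {
  al <- Matrix::which(T != 0, arr.ind = TRUE)
  if (nrow(al) == 0L) return(0)
  w <- ra[al[, 1L]] * rb[al[, 2L]]
  keep <- w != 0
  if (!any(keep)) return(0)
  al <- al[keep, , drop = FALSE]; w <- w[keep]
  rows <- sort(unique(al[, 1L]))
  D <- embA[rows, , drop = FALSE] %*% t(embB)      # |rows| x nB
  lse <- row_logsumexp(D)
  ri <- match(al[, 1L], rows)
  sum(w * (lse - D[cbind(ri, al[, 2L])]))
}

## Gradient of masked_npair_loss wrt the two embedding matrices (n x d each).
## Used by the trainer; checked against finite differences in the tests.
npair_loss_grad <- function(embA, embB, T, ra, rb, gamma, symmetric = FALSE) {
  dA <- matrix(0, nrow(embA), ncol(embA))
  dB <- matrix(0, nrow(embB), ncol(embB))
  dir <- function(eA, eB, Tm, rA, rB) {
    ## returns list(dA, dB) for one direction (softmax over eB's rows)
    al <- Matrix::which(Tm != 0, arr.ind = TRUE)
    out <- list(dA = matrix(0, nrow(eA), ncol(eA)),
                dB = matrix(0, nrow(eB), ncol(eB)))
    if (nrow(al) == 0L) return(out)
    w <- rA[al[, 1L]] * rB[al[, 2L]]
    keep <- w != 0
    if (!any(keep)) return(out)
    al <- al[keep, , drop = FALSE]; w <- w[keep]
    rows <- sort(unique(al[, 1L]))
    D <- eA[rows, , drop = FALSE] %*% t(eB)
    P <- exp(D - row_logsumexp(D))                 # row softmax
    wrow <- rowsum(w, group = al[, 1L])            # total weight per row
    dD <- P * as.vector(wrow[match(rows, as.integer(rownames(wrow))), ])
    ri <- match(al[, 1L], rows)
    dD[cbind(ri, al[, 2L])] <- dD[cbind(ri, al[, 2L])] - w
    out$dA[rows, ] <- dD %*% eB
    out$dB <- crossprod(dD, eA[rows, , drop = FALSE])
    out
  }
  g1 <- dir(embA, embB, T, ra, rb)
  if (symmetric) {
    g2 <- dir(embB, embA, Matrix::t(T), rb, ra)
    dA <- (g1$dA + g2$dB) / 2
    dB <- (g1$dB + g2$dA) / 2
  } else {
    dA <- g1$dA; dB <- g1$dB
  }
  n_unmasked <- sum(ra) + sum(rb)
  if (n_unmasked > 0 && gamma > 0) {
    dA <- dA + (2 * gamma / n_unmasked) * (ra * embA)
    dB <- dB + (2 * gamma / n_unmasked) * (rb * embB)
  }
  list(dA = dA, dB = dB)
}

#' Assemble a cropped training batch
#'
#' Samples `cfg$batch_size` pairs (with replacement) from the pool and crops
#' each to at most `cfg$crop_len` residues: a uniformly placed window on A
#' guaranteed to contain a randomly chosen aligned column, and the window on
#' B centered on the span of columns aligned to the A window (clamped to the
#' sequence). Target columns are re-indexed to cropped coordinates and at
#' least one aligned column survives per pair. Masks are cropped alongside.
#'
#' @param pairs list of training pairs: each a list with `id_a`, `id_b`,
#'   `seq_a`, `seq_b`, `cols` (two-column matrix of aligned indices) and
#'   optional `mask_a`, `mask_b` bit vectors
#' @param cfg a [training_config()] (uses `batch_size`, `crop_len`)
#' @param n_pairs optional override of the number of pairs drawn
#' @return list of cropped pairs, each with `seq_a`, `seq_b`, `cols`,
#'   `mask_a`, `mask_b`; pairs whose alignment cannot fit any window are
#'   skipped with a warning
#' @export
make_training_batch <- function(pairs, cfg, n_pairs = NULL) {
  stopifnot(length(pairs) >= 1L)
  n_draw <- if (is.null(n_pairs)) cfg$batch_size else as.integer(n_pairs)
  picks <- sample.int(length(pairs), n_draw, replace = TRUE)
  out <- vector("list", n_draw)
  kept <- logical(n_draw)
  for (m in seq_len(n_draw)) {
    cp <- crop_pair(pairs[[picks[m]]], cfg$crop_len)
    if (is.null(cp)) {
      warning("skipping pair with no croppable aligned column")
    } else {
      out[[m]] <- cp; kept[m] <- TRUE
    }
  }
  out[kept]
}

crop_pair <- function(pair, crop_len) {
  la <- nchar(pair$seq_a); lb <- nchar(pair$seq_b)
  cols <- as.matrix(pair$cols)
  if (nrow(cols) == 0L) return(NULL)
  ma <- if (!is.null(pair$mask_a)) pair$mask_a else rep(1, la)
  mb <- if (!is.null(pair$mask_b)) pair$mask_b else rep(1, lb)

  ## window on A containing a randomly chosen aligned column
  if (la <= crop_len) {
    a0 <- 1L; a1 <- la
  } else {
    c_i <- cols[sample.int(nrow(cols), 1L), 1L]
    lo <- max(1L, c_i - crop_len + 1L)
    hi <- min(c_i, la - crop_len + 1L)
    a0 <- if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    a1 <- a0 + crop_len - 1L
  }
  inA <- cols[, 1L] >= a0 & cols[, 1L] <= a1
  if (!any(inA)) return(NULL)
  js <- cols[inA, 2L]

  ## window on B centered on the aligned span, clamped
  if (lb <= crop_len) {
    b0 <- 1L; b1 <- lb
  } else {
    span0 <- min(js); span1 <- max(js)
    pad <- max(0L, (crop_len - (span1 - span0 + 1L)) %/% 2L)
    b0 <- max(1L, min(span0 - pad, lb - crop_len + 1L))
    b1 <- b0 + crop_len - 1L
  }
  keep <- inA & cols[, 2L] >= b0 & cols[, 2L] <= b1
  if (!any(keep)) return(NULL)
  newcols <- cbind(cols[keep, 1L] - a0 + 1L, cols[keep, 2L] - b0 + 1L)
  list(id_a = pair$id_a, id_b = pair$id_b,
       seq_a = substr(pair$seq_a, a0, a1), seq_b = substr(pair$seq_b, b0, b1),
       cols = newcols, mask_a = ma[a0:a1], mask_b = mb[b0:b1])
}

## --- AdamW ------------------------------------------------------------
## Decoupled weight decay; moments kept in the same nested structure as the
## parameters. No optimizer package in the dependency set provides AdamW.

adamw_state <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like)
    else array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  }
  leaves <- params[c("embed", "blocks")]
  list(m = zero_like(leaves), v = zero_like(leaves), t = 0L)
}

adamw_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- Map(upd, p, g, m, v)
      return(list(p = lapply(res, `[[`, "p"),
                  m = lapply(res, `[[`, "m"),
                  v = lapply(res, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + wd * p)
    list(p = p, m = m, v = v)
  }
  leaves <- params[c("embed", "blocks")]
  res <- Map(upd, leaves, grads[c("embed", "blocks")], state$m, state$v)
  params$embed <- res$embed$p
  params$blocks <- res$blocks$p
  state$m <- lapply(res, `[[`, "m")
  state$v <- lapply(res, `[[`, "v")
  list(params = params, state = state)
}

add_grads <- function(a, b) {
  if (is.list(a)) Map(add_grads, a, b) else a + b
}
scale_grads <- function(a, s) {
  if (is.list(a)) lapply(a, scale_grads, s = s) else a * s
}

#' Train the embedding model
#'
#' Minimizes the batch mean of [masked_npair_loss()] with AdamW. Each step
#' draws a cropped batch via [make_training_batch()], embeds both sequences of
#' every pair independently, backpropagates the loss gradient through the
#' residual stack and updates all parameters. Training aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param params initial `model_params` (see [init_params()])
#' @param pairs list of training pairs (see [make_training_batch()])
#' @param cfg a [training_config()]
#' @return list with `params` (trained) and `history`, a data.frame of
#'   per-step records (`step`, `loss`, `npair_term`, `l2_term`)
#' @export
train_model <- function(params, pairs, cfg) {
  validate_params(params)
  stopifnot(inherits(cfg, "training_config"), length(pairs) >= 1L)
  set.seed(cfg$seed)
  if (cfg$steps == 0L)
    return(list(params = params,
                history = data.frame(step = integer(), loss = numeric(),
                                     npair_term = numeric(), l2_term = numeric())))
  state <- adamw_state(params)
  hist <- vector("list", cfg$steps)
  for (step in seq_len(cfg$steps)) {
    batch <- make_training_batch(pairs, cfg)
    if (length(batch) == 0L) stop("no usable pairs in batch")
    grads <- NULL
    tot <- c(loss = 0, npair = 0, l2 = 0)
    for (item in batch) {
      idx_a <- seq_to_indices(item$seq_a, params$config)
      idx_b <- seq_to_indices(item$seq_b, params$config)
      fa <- forward_embed(idx_a, params, keep_cache = TRUE)
      fb <- forward_embed(idx_b, params, keep_cache = TRUE)
      embA <- t(fa$emb); embB <- t(fb$emb)
      Tm <- targets_from_alignment(item$cols, nrow(embA), nrow(embB))
      l <- masked_npair_loss(embA, embB, Tm, item$mask_a, item$mask_b,
                             gamma = cfg$gamma, symmetric = cfg$symmetric)
      tot <- tot + c(l$loss, l$npair_term, l$l2_term)
      g <- npair_loss_grad(embA, embB, Tm, item$mask_a, item$mask_b,
                           gamma = cfg$gamma, symmetric = cfg$symmetric)
      ga <- backward_embed(t(g$dA), fa, params)
      gb <- backward_embed(t(g$dB), fb, params)
      pg <- add_grads(ga, gb)
      grads <- if (is.null(grads)) pg else add_grads(grads, pg)
    }
    grads <- scale_grads(grads, 1 / length(batch))
    tot <- tot / length(batch)
    if (!all(is.finite(tot)))
      stop(sprintf("non-finite loss at step %d (loss=%g); aborting", step, tot[1]))
    res <- adamw_step(params, grads, state, cfg$learning_rate, cfg$weight_decay)
    params <- res$params; state <- res$state
    hist[[step]] <- c(step = step, loss = tot[[1]], npair_term = tot[[2]],
                      l2_term = tot[[3]])
  }
  list(params = params, history = as.data.frame(do.call(rbind, hist)))
}
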