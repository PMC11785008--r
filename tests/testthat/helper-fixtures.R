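## Small shared fixtures, built in code.

tiny_config <- function(d = 4L, blocks = 2L, k = 3L) {
  model_config(embed_dim = d, n_blocks = blocks, kernel_size = k)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

## Brute-force term-by-term evaluation of the masked N-pair loss, independent
## of the vectorized implementation: loops over every aligned pair and every
## softmax denominator term explicitly.
brute_npair_loss <- function(embA, embB, Tm, ra, rb, gamma) {
  Tm <- as.matrix(Tm)
  npair <- 0
  for (i in seq_len(nrow(Tm))) {
    for (j in seq_len(ncol(Tm))) {
      if (Tm[i, j] == 1) {
        denom <- 0
        for (w in seq_len(nrow(embB)))
          denom <- denom + exp(sum(embA[i, ] * embB[w, ]))
        npair <- npair - ra[i] * rb[j] *
          log(exp(sum(embA[i, ] * embB[j, ])) / denom)
      }
    }
  }
  n <- sum(ra) + sum(rb)
  l2 <- if (n == 0) 0 else {
    s <- 0
    for (i in seq_len(nrow(embA))) s <- s + ra[i] * sum(embA[i, ]^2)
    for (i in seq_len(nrow(embB))) s <- s + rb[i] * sum(embB[i, ]^2)
    gamma / n * s
  }
  list(loss = npair + l2, npair_term = npair, l2_term = l2)
}

## Brute-force k-NN by full cosine scan with the same tie rule.
brute_knn <- function(V, refs, q, k) {
  qn <- q / sqrt(sum(q^2))
  Vn <- V / sqrt(rowSums(V^2))
  cs <- as.vector(Vn %*% qn)
  o <- order(-cs, refs$seq_id, refs$pos)[seq_len(min(k, nrow(V)))]
  data.frame(seq_id = refs$seq_id[o], pos = refs$pos[o], cosine = cs[o],
             stringsAsFactors = FALSE)
}

## The shared trained tiny model for the end-to-end tests: trained once per
## test run and memoized. Scaled-down study conditions: d = 32, 2 residual
## blocks, 300 AdamW steps (batch 16, crop 128, lr 1e-3) on 500 simulated
## homolog pairs at 15% substitution / 2% indel rate.
.trained_cache <- new.env(parent = emptyenv())

trained_tiny_model <- function() {
  if (!is.null(.trained_cache$fit)) return(.trained_cache$fit)
  scfg <- sim_config(ancestor_len = 128L, sub_rate = 0.15, indel_rate = 0.02,
                     n_pairs = 500L, seed = 11L)
  pairs <- simulate_training_pairs(scfg)
  params <- init_params(model_config(embed_dim = 32L, n_blocks = 2L), seed = 1L)
  tcfg <- training_config(steps = 300L, batch_size = 16L, crop_len = 128L,
                          learning_rate = 1e-3, seed = 3L)
  fit <- train_model(params, pairs, tcfg)
  fit$init_params <- params
  fit$sim_cfg <- scfg
  .trained_cache$fit <- fit
  fit
}
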