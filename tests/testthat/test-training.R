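test_that("alignment target matrices place ones exactly at the aligned columns", {
  Tm <- targets_from_alignment(rbind(c(1, 1), c(3, 3)), 3, 3)
  expect_equal(as.matrix(Tm), diag(c(1, 0, 1)), ignore_attr = TRUE)
  expect_equal(as.matrix(targets_from_alignment(matrix(integer(), ncol = 2), 2, 4)),
               matrix(0, 2, 4), ignore_attr = TRUE)
  expect_equal(as.matrix(targets_from_alignment(cbind(1:3, 1:3), 3, 3)),
               diag(3), ignore_attr = TRUE)
})

test_that("alignment targets reject out-of-range and non-monotone columns", {
  expect_error(targets_from_alignment(rbind(c(1, 5)), 3, 3), "out of")
  expect_error(targets_from_alignment(rbind(c(0, 1)), 3, 3), "out of")
  expect_error(targets_from_alignment(rbind(c(2, 1), c(1, 2)), 3, 3),
               "strictly increasing")
  expect_error(targets_from_alignment(rbind(c(1, 2), c(2, 2)), 3, 3),
               "strictly increasing")
})

test_that("N-pair loss closed forms: uniform softmax, empty targets, mask silencing", {
  ## all-zero embeddings, one aligned pair, |B| = 4: softmax = 1/4
  embA <- matrix(0, 1, 2); embB <- matrix(0, 4, 2)
  Tm <- targets_from_alignment(cbind(1, 1), 1, 4)
  l <- masked_npair_loss(embA, embB, Tm, gamma = 0)
  expect_equal(l$loss, log(4))
  expect_equal(l$l2_term, 0)

  ## no aligned pairs: zero loss whatever the embeddings
  set.seed(1)
  eA <- matrix(rnorm(8), 4, 2); eB <- matrix(rnorm(6), 3, 2)
  T0 <- targets_from_alignment(matrix(integer(), ncol = 2), 4, 3)
  expect_equal(masked_npair_loss(eA, eB, T0, gamma = 0)$loss, 0)

  ## mask silences the only aligned pair
  T1 <- targets_from_alignment(cbind(2, 2), 4, 3)
  l <- masked_npair_loss(eA, eB, T1, ra = c(1, 0, 1, 1), gamma = 0)
  expect_equal(l$npair_term, 0)
})

test_that("loss equals a term-by-term brute-force summation on random small cases", {
  set.seed(42)
  for (rep in 1:25) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1); d <- sample(1:3, 1)
    eA <- matrix(rnorm(na * d), na, d)
    eB <- matrix(rnorm(nb * d), nb, d)
    ncols <- sample(0:min(na, nb), 1)
    cols <- if (ncols == 0) matrix(integer(), ncol = 2) else
      cbind(sort(sample(na, ncols)), sort(sample(nb, ncols)))
    Tm <- targets_from_alignment(cols, na, nb)
    ra <- sample(0:1, na, replace = TRUE); rb <- sample(0:1, nb, replace = TRUE)
    gamma <- runif(1, 0, 0.1)
    got <- masked_npair_loss(eA, eB, Tm, ra, rb, gamma)
    want <- brute_npair_loss(eA, eB, Tm, ra, rb, gamma)
    expect_equal(got$loss, want$loss, tolerance = 1e-10)
    expect_equal(got$npair_term, want$npair_term, tolerance = 1e-10)
    expect_equal(got$l2_term, want$l2_term, tolerance = 1e-10)
    expect_gte(got$npair_term, 0)
    expect_gte(got$l2_term, 0)
  }
})

test_that("npair term ignores appended masked unaligned residues of A", {
  set.seed(3)
  eA <- matrix(rnorm(6), 3, 2); eB <- matrix(rnorm(6), 3, 2)
  Tm <- targets_from_alignment(cbind(c(1, 3), c(1, 2)), 3, 3)
  base <- masked_npair_loss(eA, eB, Tm, gamma = 0)
  eA2 <- rbind(eA, matrix(rnorm(4), 2, 2))
  Tm2 <- targets_from_alignment(cbind(c(1, 3), c(1, 2)), 5, 3)
  ext <- masked_npair_loss(eA2, eB, Tm2, ra = c(1, 1, 1, 0, 0), gamma = 0)
  expect_equal(ext$npair_term, base$npair_term)
})

test_that("loss gradient is dense and matches finite differences on a 3x3 toy", {
  set.seed(7)
  eA <- matrix(rnorm(6), 3, 2); eB <- matrix(rnorm(6), 3, 2)
  Tm <- targets_from_alignment(cbind(2, 2), 3, 3)
  g <- protscout:::npair_loss_grad(eA, eB, Tm, rep(1, 3), rep(1, 3), gamma = 0)
  ## dense gradient: every residue of B gets nonzero gradient through the
  ## softmax denominator, not only the aligned one
  expect_true(all(rowSums(abs(g$dB)) > 0))
  h <- 1e-6
  for (i in 1:3) for (j in 1:2) {
    e1 <- eB; e1[i, j] <- e1[i, j] + h
    e2 <- eB; e2[i, j] <- e2[i, j] - h
    fd <- (masked_npair_loss(eA, e1, Tm, gamma = 0)$loss -
           masked_npair_loss(eA, e2, Tm, gamma = 0)$loss) / (2 * h)
    expect_equal(g$dB[i, j], fd, tolerance = 1e-5)
  }
  for (i in 1:3) for (j in 1:2) {
    e1 <- eA; e1[i, j] <- e1[i, j] + h
    e2 <- eA; e2[i, j] <- e2[i, j] - h
    fd <- (masked_npair_loss(e1, eB, Tm, gamma = 0)$loss -
           masked_npair_loss(e2, eB, Tm, gamma = 0)$loss) / (2 * h)
    expect_equal(g$dA[i, j], fd, tolerance = 1e-5)
  }
})

test_that("backprop through the residual stack matches finite differences", {
  cfg <- model_config(embed_dim = 3, n_blocks = 2, kernel_size = 3)
  params <- init_params(cfg, seed = 5)
  ia <- protscout:::seq_to_indices("ACDEFG", cfg)
  ib <- protscout:::seq_to_indices("ACDEYG", cfg)
  Tm <- targets_from_alignment(cbind(1:6, 1:6), 6, 6)
  lossfun <- function(p) {
    fa <- protscout:::forward_embed(ia, p)
    fb <- protscout:::forward_embed(ib, p)
    masked_npair_loss(t(fa$emb), t(fb$emb), Tm, gamma = 5e-3)$loss
  }
  fa <- protscout:::forward_embed(ia, params, keep_cache = TRUE)
  fb <- protscout:::forward_embed(ib, params, keep_cache = TRUE)
  g <- protscout:::npair_loss_grad(t(fa$emb), t(fb$emb), Tm,
                                   rep(1, 6), rep(1, 6), 5e-3)
  pg <- protscout:::add_grads(protscout:::backward_embed(t(g$dA), fa, params),
                              protscout:::backward_embed(t(g$dB), fb, params))
  h <- 1e-6
  probe <- function(setter, grad) {
    fd <- (lossfun(setter(params, h)) - lossfun(setter(params, -h))) / (2 * h)
    expect_equal(grad, fd, tolerance = 1e-4)
  }
  probe(function(p, d) { p$blocks[[1]]$W1[1, 2, 2] <- p$blocks[[1]]$W1[1, 2, 2] + d; p },
        pg$blocks[[1]]$W1[1, 2, 2])
  probe(function(p, d) { p$blocks[[2]]$W2[3, 1, 1] <- p$blocks[[2]]$W2[3, 1, 1] + d; p },
        pg$blocks[[2]]$W2[3, 1, 1])
  probe(function(p, d) { p$blocks[[1]]$b1[2] <- p$blocks[[1]]$b1[2] + d; p },
        pg$blocks[[1]]$b1[2])
  probe(function(p, d) { p$embed[2, 1] <- p$embed[2, 1] + d; p },
        pg$embed[2, 1])
})

test_that("training batches respect crop length and keep at least one aligned column", {
  cfg <- training_config(steps = 1, batch_size = 8, crop_len = 20, seed = 1)
  set.seed(2)
  long <- list(id_a = "a", id_b = "b",
               seq_a = random_seq(512), seq_b = random_seq(512),
               cols = cbind(300, 310))
  short <- list(id_a = "c", id_b = "d",
                seq_a = random_seq(10), seq_b = random_seq(12),
                cols = cbind(c(2, 5), c(3, 6)))
  batch <- make_training_batch(list(long, short), cfg)
  for (it in batch) {
    expect_lte(nchar(it$seq_a), 20L)
    expect_lte(nchar(it$seq_b), 20L)
    expect_gte(nrow(it$cols), 1L)
    expect_true(all(it$cols[, 1] >= 1 & it$cols[, 1] <= nchar(it$seq_a)))
    expect_true(all(it$cols[, 2] >= 1 & it$cols[, 2] <= nchar(it$seq_b)))
    expect_length(it$mask_a, nchar(it$seq_a))
    ## cropped residues still carry the original aligned residue identities
    if (it$id_a == "a") {
      expect_equal(substr(it$seq_a, it$cols[1, 1], it$cols[1, 1]),
                   substr(long$seq_a, 300, 300))
      expect_equal(substr(it$seq_b, it$cols[1, 2], it$cols[1, 2]),
                   substr(long$seq_b, 310, 310))
    } else {
      expect_equal(it$seq_a, short$seq_a)            # short pairs uncropped
    }
  }
  ## determinism under a fixed RNG state
  set.seed(99); b1 <- make_training_batch(list(long, short), cfg)
  set.seed(99); b2 <- make_training_batch(list(long, short), cfg)
  expect_identical(b1, b2)
})

test_that("training with zero steps returns parameters unchanged", {
  params <- init_params(tiny_config(), seed = 1)
  pair <- list(id_a = "a", id_b = "b", seq_a = "ACDEF", seq_b = "ACDEF",
               cols = cbind(1:5, 1:5))
  fit <- train_model(params, list(pair),
                     training_config(steps = 0, batch_size = 1, crop_len = 16))
  expect_identical(fit$params$embed, params$embed)
  expect_identical(fit$params$blocks, params$blocks)
  expect_equal(nrow(fit$history), 0L)
})

test_that("a few AdamW steps on one pair reduce the loss deterministically", {
  params <- init_params(model_config(embed_dim = 4, n_blocks = 1,
                                     kernel_size = 3), seed = 2)
  pair <- list(id_a = "a", id_b = "b",
               seq_a = "MKVLINACDEFGHIKLMN", seq_b = "MKVLINACDEFGHIKLMN",
               cols = cbind(1:18, 1:18))
  cfg <- training_config(steps = 30, batch_size = 2, crop_len = 18,
                         learning_rate = 1e-2, seed = 4)
  fit1 <- train_model(params, list(pair), cfg)
  expect_lt(tail(fit1$history$loss, 1), fit1$history$loss[1])
  expect_equal(fit1$history$loss,
               fit1$history$npair_term + fit1$history$l2_term)
  fit2 <- train_model(params, list(pair), cfg)
  expect_equal(fit1$history, fit2$history, tolerance = 1e-12)
})
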