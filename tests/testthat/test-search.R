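make_embs <- function(lens, d, seed = 1) {
  set.seed(seed)
  out <- lapply(lens, function(n) matrix(rnorm(n * d), n, d))
  names(out) <- names(lens)
  out
}

test_that("index counts every unmasked residue exactly once", {
  emb <- make_embs(c(s1 = 5L, s2 = 7L), d = 4)
  cfg <- search_config(d = 4)
  idx <- build_index(emb, cfg = cfg)
  expect_equal(idx$count, 12L)
  expect_equal(nrow(idx$refs), 12L)
  expect_false(anyDuplicated(paste(idx$refs$seq_id, idx$refs$pos)) > 0)

  masks <- list(s1 = c(0, 1, 1, 0, 1), s2 = c(rep(1, 6), 0))
  idx2 <- build_index(emb, masks, cfg)
  expect_equal(idx2$count, 9L)
  expect_false(any(idx2$refs$seq_id == "s1" & idx2$refs$pos %in% c(1, 4)))

  cfgq <- search_config(d = 4, backend = "quantized")
  expect_equal(build_index(emb, masks, cfgq)$count, 9L)

  expect_error(build_index(emb, lapply(emb, function(e) rep(0, nrow(e))), cfg),
               "no unmasked")
  expect_error(build_index(emb, cfg = search_config(d = 7)), "match")
})

test_that("exact knn equals a brute-force cosine scan with lexicographic ties", {
  set.seed(11)
  for (rep in 1:20) {
    d <- sample(c(3, 8, 16), 1)
    lens <- c(a = sample(3:40, 1), b = sample(3:40, 1))
    emb <- make_embs(lens, d, seed = rep)
    idx <- build_index(emb, cfg = search_config(d = d))
    V <- rbind(emb$a, emb$b)
    refs <- data.frame(seq_id = rep(c("a", "b"), lens), pos = c(seq_len(lens[1]), seq_len(lens[2])),
                       stringsAsFactors = FALSE)
    q <- rnorm(d)
    k <- sample(1:10, 1)
    got <- knn(idx, q, k)
    want <- brute_knn(V, refs, q, k)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("knn returns the query itself first and everything when k is large", {
  emb <- make_embs(c(s1 = 6L), d = 5, seed = 2)
  idx <- build_index(emb, cfg = search_config(d = 5))
  nb <- knn(idx, emb$s1[3, ], k = 3)
  expect_equal(nb$pos[1], 3L)
  expect_equal(nb$cosine[1], 1.0, tolerance = 1e-12)
  expect_equal(nrow(knn(idx, rnorm(5), k = 100)), 6L)
  expect_error(knn(idx, rnorm(4), 3), "width")
})

test_that("noise gate subtracts delta/sqrt(d) and clamps at zero", {
  expect_equal(noise_gated_score(1.0, 256, 3), 0.8125)
  expect_equal(noise_gated_score(0.0, 64, 3), 0)
  expect_equal(noise_gated_score(0.5, 256, 3), 0.3125)
  ## delta large enough that the gate reaches 1: every score is zero
  expect_equal(noise_gated_score(c(-1, 0, 0.99, 1), 16, delta = 4), rep(0, 4))
})

test_that("match accumulation sums gated scores per pair", {
  expect_equal(nrow(accumulate_matches(data.frame(query_id = character(),
                                                  target_id = character(),
                                                  gated_score = numeric()))), 0L)
  m <- data.frame(query_id = "q", target_id = "t", gated_score = 0.4)
  h <- accumulate_matches(m)
  expect_equal(h$score, 0.4)
  expect_equal(h$n_matches, 1L)
  m3 <- data.frame(query_id = "q", target_id = "t",
                   gated_score = c(0.2, 0.3, 0.0))
  h3 <- accumulate_matches(m3)
  expect_equal(h3$score, 0.5)
  expect_equal(h3$n_matches, 3L)
})

test_that("a query identical to a target is its top hit", {
  params <- init_params(model_config(embed_dim = 8, n_blocks = 1,
                                     kernel_size = 3), seed = 6)
  set.seed(21)
  targets <- c(t1 = random_seq(30), t2 = random_seq(30), t3 = random_seq(30))
  queries <- c(q1 = unname(targets["t2"]))
  ## gate set below the self-match cosine of 1 so exact self-matches survive
  hits <- search_sequences(queries, targets, params,
                           search_config(k = 90, d = 8, delta = 0.5))
  expect_equal(hits$target_id[1], "t2")
})

test_that("reversed search with exhaustive k matches the forward orientation", {
  params <- init_params(model_config(embed_dim = 6, n_blocks = 1,
                                     kernel_size = 3), seed = 3)
  set.seed(31)
  queries <- c(q1 = random_seq(15))
  targets <- c(t1 = random_seq(18))
  fw <- search_sequences(queries, targets, params,
                         search_config(k = 100, d = 6))
  rv <- search_sequences(queries, targets, params,
                         search_config(k = 100, d = 6, reversed = TRUE))
  expect_equal(fw$query_id, rv$query_id)
  expect_equal(fw$target_id, rv$target_id)
  expect_equal(fw$score, rv$score, tolerance = 1e-10)
})

test_that("scores grow monotonically in k and ignore target insertion order", {
  params <- init_params(model_config(embed_dim = 6, n_blocks = 1,
                                     kernel_size = 3), seed = 4)
  set.seed(41)
  queries <- c(q1 = random_seq(12))
  targets <- c(t1 = random_seq(20), t2 = random_seq(20), t3 = random_seq(20))
  scores_at_k <- sapply(c(1, 5, 20, 60), function(k) {
    h <- search_sequences(queries, targets, params, search_config(k = k, d = 6))
    vapply(names(targets), function(t)
      if (t %in% h$target_id) h$score[h$target_id == t] else 0, numeric(1))
  })
  expect_true(all(diff(t(scores_at_k)) >= -1e-12))

  h1 <- search_sequences(queries, targets, params, search_config(k = 10, d = 6))
  h2 <- search_sequences(queries, rev(targets), params, search_config(k = 10, d = 6))
  expect_equal(h1, h2)
})

test_that("fully masked queries produce no hits", {
  params <- init_params(model_config(embed_dim = 4, n_blocks = 1,
                                     kernel_size = 3), seed = 5)
  queries <- c(q1 = "ACDEF")
  targets <- c(t1 = "ACDEF")
  h <- search_sequences(queries, targets, params, search_config(k = 5, d = 4),
                        query_masks = list(q1 = rep(0, 5)))
  expect_equal(nrow(h), 0L)
})

test_that("quantized backend fulfils the index contract and its recall is measured", {
  set.seed(17)
  emb <- make_embs(c(a = 120L, b = 130L), d = 16, seed = 17)
  cfg_e <- search_config(d = 16, backend = "exact")
  cfg_q <- search_config(d = 16, backend = "quantized")
  ie <- build_index(emb, cfg = cfg_e)
  iq <- build_index(emb, cfg = cfg_q, seed = 2)
  expect_equal(ie$count, iq$count)
  nb <- knn(iq, rnorm(16), 10)
  expect_equal(nrow(nb), 10L)
  expect_true(all(diff(nb$cosine) <= 1e-12))
  Q <- matrix(rnorm(20 * 16), 20, 16)
  rec <- backend_recall(ie, iq, Q, k = 10)
  expect_gte(rec, 0)
  expect_lte(rec, 1)
  message(sprintf("quantized backend recall@10 on 250 random vectors: %.2f", rec))
})

test_that("noise-gate coverage estimate is deterministic under a seed", {
  c1 <- noise_gate_coverage(5000, d = 64, delta = 3, seed = 9)
  c2 <- noise_gate_coverage(5000, d = 64, delta = 3, seed = 9)
  expect_equal(c1, c2)
  expect_gt(c1, 95)
})
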