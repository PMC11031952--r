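test_that("initial k-mer embeddings normalize columns over neighbor support", {
  W <- matrix(0, 4, 4)
  W[2, 1] <- W[1, 2] <- 2
  W[3, 1] <- W[1, 3] <- 2
  W[2, 3] <- W[3, 2] <- 1
  W[4, 2] <- W[2, 4] <- 1
  emb <- init_kmer_embedding(W)
  expect_equal(emb$H[, 1], c(0, 0.5, 0.5, 0))
  # single neighbor: the entry becomes 1
  W2 <- matrix(0, 2, 2); W2[1, 2] <- W2[2, 1] <- 0.8
  expect_equal(init_kmer_embedding(W2)$H[, 1], c(0, 1))
  # every column sums to 1 over its support
  set.seed(8)
  W3 <- random_subgraph(10)
  H3 <- init_kmer_embedding(W3)$H
  expect_equal(unname(colSums(H3)), rep(1, 10))
})

test_that("isolated k-mers fall back to unit self-loops", {
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  expect_message(emb <- init_kmer_embedding(W), "self-loop")
  expect_equal(emb$H[, 3], c(0, 0, 1))
  expect_true(emb$A[3, 3])
})

test_that("k-mer attention scores follow the concatenated projection rule", {
  set.seed(2)
  d <- 3; m <- 5
  Wm <- matrix(rnorm(d * m), d, m)
  a <- rnorm(2 * d)
  h_x <- runif(m); h_y <- runif(m)
  # zero attention vector scores zero everywhere
  expect_equal(kmer_attention_scores(rep(0, 2 * d), Wm, h_x, h_y), 0)
  # identical embeddings make the score symmetric
  expect_equal(kmer_attention_scores(a, Wm, h_x, h_x),
               kmer_attention_scores(a, Wm, h_x, h_x))
  # hand-computed LeakyReLU of the dot product
  raw <- sum(a * c(Wm %*% h_x, Wm %*% h_y))
  expect_equal(kmer_attention_scores(a, Wm, h_x, h_y),
               if (raw > 0) raw else 0.2 * raw)
  expect_error(kmer_attention_scores(a[-1], Wm, h_x, h_y), "mismatch")
})

test_that("softmax normalization is exact, ordered and shift-invariant", {
  expect_equal(normalize_attention(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(normalize_attention(c(log(2), 0)), c(2 / 3, 1 / 3))
  set.seed(3)
  s <- rnorm(20)
  co <- normalize_attention(s)
  expect_equal(sum(co), 1, tolerance = 1e-9)
  expect_equal(which.max(co), which.max(s))
  expect_equal(normalize_attention(s + 5), co)
  expect_error(normalize_attention(numeric(0)), "empty")
})

test_that("k-mer aggregation is the ReLU of the attention-weighted sum", {
  set.seed(4)
  d <- 4; m <- 5
  Wm <- matrix(rnorm(d * m), d, m)
  H <- matrix(runif(m * m), m, m)
  # single neighbor with full weight
  expect_equal(aggregate_kmer_embedding(Wm, H, 1, 2L),
               pmax(as.numeric(Wm %*% H[, 2]), 0))
  # all-negative preactivations clip to zero
  expect_equal(aggregate_kmer_embedding(-abs(Wm), H, c(0.5, 0.5), c(1L, 3L)),
               rep(0, d))
  # loop oracle
  alpha <- normalize_attention(rnorm(3))
  nb <- c(1L, 3L, 4L)
  acc <- rep(0, d)
  for (k in 1:3) acc <- acc + alpha[k] * as.numeric(Wm %*% H[, nb[k]])
  expect_equal(aggregate_kmer_embedding(Wm, H, alpha, nb), pmax(acc, 0))
})

test_that("initial sequence embeddings project the inclusive column", {
  set.seed(5)
  m <- 6; d <- 3
  Wm_inclu <- matrix(rnorm(m * d), m, d)
  expect_equal(init_seq_embedding(rep(0, m), Wm_inclu), rep(0, d))
  # identity-padded projection reproduces the column's first d entries
  I_pad <- rbind(diag(d), matrix(0, m - d, d))
  col <- runif(m)
  expect_equal(init_seq_embedding(col, I_pad), col[1:d])
  # loop oracle
  expect_equal(init_seq_embedding(col, Wm_inclu),
               vapply(1:d, function(j) sum(col * Wm_inclu[, j]), 0))
})

test_that("sequence attention rows are separate softmaxes over the k-mer set", {
  set.seed(6)
  d <- 4; m <- 7
  E_sim <- matrix(abs(rnorm(d * m)), d, m)
  E_co <- matrix(abs(rnorm(d * m)), d, m)
  nb <- c(2L, 4L, 5L)
  # zero sequence embedding scores zero -> uniform coefficients
  be <- seq_attention(rep(0, d), E_sim, E_co, nb)
  expect_equal(be$beta_sim, rep(1 / 3, 3))
  expect_equal(be$beta_co, rep(1 / 3, 3))
  # single neighbor
  b1 <- seq_attention(rnorm(d), E_sim, E_co, 3L)
  expect_equal(b1$beta_sim, 1)
  # rows sum to 1 and match scalar recomputation
  h <- rnorm(d)
  be2 <- seq_attention(h, E_sim, E_co, nb)
  expect_equal(sum(be2$beta_sim), 1, tolerance = 1e-9)
  raw <- vapply(nb, function(x) {
    v <- sum(h * E_sim[, x]); if (v > 0) v else 0.2 * v
  }, 0)
  expect_equal(be2$beta_sim, normalize_attention(raw))
  expect_error(seq_attention(h, E_sim, E_co, integer(0)), "no k-mer")
})

test_that("sequence aggregation combines both branches before ReLU", {
  set.seed(7)
  d <- 3; m <- 5
  E_sim <- matrix(abs(rnorm(d * m)), d, m)
  E_co <- matrix(abs(rnorm(d * m)), d, m)
  expect_equal(aggregate_seq_embedding(1, 1, E_sim, E_co, 2L),
               pmax(E_sim[, 2] + E_co[, 2], 0))
  expect_equal(aggregate_seq_embedding(c(0.5, 0.5), c(0.5, 0.5),
                                       E_sim * 0, E_co * 0, c(1L, 2L)),
               rep(0, d))
  bs <- normalize_attention(rnorm(3)); bc <- normalize_attention(rnorm(3))
  nb <- c(1L, 3L, 5L)
  acc <- rep(0, d)
  for (k in 1:3) acc <- acc + bs[k] * E_sim[, nb[k]] + bc[k] * E_co[, nb[k]]
  expect_equal(aggregate_seq_embedding(bs, bc, E_sim, E_co, nb),
               pmax(acc, 0))
})

test_that("the classifier is a sigmoid over one linear layer", {
  expect_equal(predict_tfbs(rep(0, 4), 0, runif(4)), 0.5)
  expect_gt(predict_tfbs(rep(10, 4), 0, rep(10, 4)), 1 - 1e-10)
  set.seed(9)
  w <- rnorm(5); b <- rnorm(1); e <- abs(rnorm(5))
  expect_equal(predict_tfbs(w, b, e), 1 / (1 + exp(-(sum(w * e) + b))))
})

test_that("vectorized forward pass matches the explicit-loop oracle", {
  for (seed in 1:4) {
    inst <- random_gat_instance(m = 8, n = 5, d = 6, seed = seed)
    pre <- list()
    suppressMessages({
      sim <- init_kmer_embedding(inst$W_sim)
      co <- init_kmer_embedding(inst$W_co)
    })
    pre <- list(H_sim = sim$H, A_sim = sim$A, H_co = co$H, A_co = co$A)
    fw <- gatmotif:::gat_forward(inst$params, pre, inst$X, dropout = 0)
    or <- oracle_forward(inst$params, inst$W_sim, inst$W_co, inst$X)
    expect_equal(fw$prob, or$prob, tolerance = 1e-10)
    expect_equal(unname(fw$l1_sim$E), or$E_sim, tolerance = 1e-10)
    expect_equal(unname(fw$l1_co$E), or$E_co, tolerance = 1e-10)
    expect_equal(unname(fw$l2_sim$beta), or$beta_sim, tolerance = 1e-10)
    expect_equal(unname(fw$l2_co$beta), or$beta_co, tolerance = 1e-10)
  }
})

test_that("analytic gradients agree with finite differences", {
  inst <- random_gat_instance(m = 6, n = 4, d = 4, seed = 17)
  suppressMessages({
    sim <- init_kmer_embedding(inst$W_sim)
    co <- init_kmer_embedding(inst$W_co)
  })
  pre <- list(H_sim = sim$H, A_sim = sim$A, H_co = co$H, A_co = co$A)
  y <- c(1, 0, 1, 0)
  params <- inst$params
  fw <- gatmotif:::gat_forward(params, pre, inst$X, dropout = 0)
  gr <- gatmotif:::gat_backward(params, pre, inst$X, fw, y)
  lossfun <- function(p) {
    gatmotif:::bce_loss(
      gatmotif:::gat_forward(p, pre, inst$X, dropout = 0)$logits, y)
  }
  eps <- 1e-6
  set.seed(18)
  for (nm in names(params)) {
    idx <- sample(seq_along(params[[nm]]),
                  min(8, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("training separates a toy graph and is seed-deterministic", {
  # two positives share the planted word; negatives are their shuffles
  recs <- make_records(
    c("TTTGACTTT", "CCTGACTCC", "TTTTTGTTT", "CCCCTGCCC"),
    c(1L, 1L, 0L, 0L), lenk = 3L)
  graph <- build_het_graph(recs, lenk = 3L)
  cfg <- gat_config(epochs = 120, d_k = 8, lenk = 3, dropout = 0.1,
                    seed = 4)
  model <- train_gat(graph, config = cfg)
  pr <- predict(model, recs)
  expect_equal(unname(as.integer(pr > 0.5)), c(1L, 1L, 0L, 0L))

  m2 <- train_gat(graph, config = cfg)
  expect_identical(tail(model$trace$loss, 1), tail(m2$trace$loss, 1))
  expect_equal(model$params, m2$params)
})

test_that("zero-epoch training returns the initialization unchanged", {
  recs <- random_records(6, 15, lenk = 3, seed = 23)
  graph <- build_het_graph(recs, lenk = 3L)
  cfg <- gat_config(epochs = 0, d_k = 5, lenk = 3, seed = 11)
  model <- train_gat(graph, config = cfg)
  set.seed(11)
  expected <- gatmotif:::init_gat_params(length(graph$vocab$kmers), 5L)
  expect_equal(model$params, expected)
  expect_equal(nrow(model$trace), 0L)
})

test_that("checkpoints round-trip through JSON", {
  recs <- random_records(8, 15, lenk = 3, seed = 29)
  graph <- build_het_graph(recs, lenk = 3L)
  model <- train_gat(graph, config = gat_config(epochs = 5, d_k = 4,
                                                lenk = 3, seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  save_gat_model(model, f)
  back <- load_gat_model(f, graph)
  expect_equal(back$params, model$params, tolerance = 1e-12)
  expect_equal(predict(back, recs), predict(model, recs),
               tolerance = 1e-10)
})
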