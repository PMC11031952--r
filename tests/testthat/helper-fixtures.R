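# Shared fixtures: small record sets and an explicit scalar-loop forward pass
# used as the independent oracle for the vectorized network.

make_records <- function(seqs, labels, lenk = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(seqs))
  recs <- mapply(seq_record, ids, seqs, labels,
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
  if (!is.null(lenk)) recs <- split_kmers(recs, lenk)
  recs
}

random_records <- function(n, len, lenk, seed, p_pos = 0.5) {
  set.seed(seed)
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), len,
                                    replace = TRUE), collapse = ""))
  labels <- as.integer(seq_len(n) <= round(p_pos * n))
  make_records(seqs, labels, lenk = lenk)
}

lrelu_scalar <- function(x, slope = 0.2) if (x > 0) x else slope * x

# Explicit-loop forward pass over dense subgraph matrices, following the
# layer equations one scalar at a time. Independent of the package's
# vectorized implementation.
oracle_forward <- function(params, W_sim, W_co, X, slope = 0.2) {
  m <- nrow(W_sim); n <- ncol(X); d <- length(params$cls_w)
  layer1 <- function(W, a, Wm) {
    H <- matrix(0, m, m)
    for (x in 1:m) {
      nb <- which(W[, x] > 0)
      H[, x] <- W[, x] / sum(W[x, nb])
    }
    E <- matrix(0, d, m)
    alpha <- matrix(0, m, m)
    for (x in 1:m) {
      nb <- which(W[x, ] > 0)
      e <- numeric(length(nb))
      for (k in seq_along(nb)) {
        y <- nb[k]
        z <- c(Wm %*% H[, x], Wm %*% H[, y])
        e[k] <- lrelu_scalar(sum(params[[a]] * z), slope)
      }
      al <- exp(e) / sum(exp(e))
      alpha[x, nb] <- al
      acc <- numeric(d)
      for (k in seq_along(nb)) {
        acc <- acc + al[k] * as.numeric(Wm %*% H[, nb[k]])
      }
      E[, x] <- pmax(acc, 0)
    }
    list(E = E, alpha = alpha)
  }
  sim <- layer1(W_sim, "a_sim", params$Wm_sim)
  co <- layer1(W_co, "a_co", params$Wm_co)
  beta_sim <- matrix(0, n, m); beta_co <- matrix(0, n, m)
  prob <- numeric(n)
  Es_all <- matrix(0, n, d)
  for (z in 1:n) {
    h <- as.numeric(t(X[, z]) %*% params$Wm_inclu)
    nb <- which(X[, z] > 0)
    bs <- numeric(length(nb)); bc <- numeric(length(nb))
    for (k in seq_along(nb)) {
      bs[k] <- lrelu_scalar(sum(h * sim$E[, nb[k]]), slope)
      bc[k] <- lrelu_scalar(sum(h * co$E[, nb[k]]), slope)
    }
    beta_sim[z, nb] <- exp(bs) / sum(exp(bs))
    beta_co[z, nb] <- exp(bc) / sum(exp(bc))
    acc <- numeric(d)
    for (k in seq_along(nb)) {
      acc <- acc + beta_sim[z, nb[k]] * sim$E[, nb[k]] +
        beta_co[z, nb[k]] * co$E[, nb[k]]
    }
    Es <- pmax(acc, 0)
    Es_all[z, ] <- Es
    prob[z] <- 1 / (1 + exp(-(sum(params$cls_w * Es) + params$cls_b)))
  }
  list(E_sim = sim$E, E_co = co$E, alpha_sim = sim$alpha,
       alpha_co = co$alpha, beta_sim = beta_sim, beta_co = beta_co,
       Es = Es_all, prob = prob)
}

# Random dense symmetric weight matrix with zero diagonal, every node
# guaranteed at least one neighbor.
random_subgraph <- function(m, density = 0.5) {
  W <- matrix(0, m, m)
  for (x in 1:(m - 1)) for (y in (x + 1):m) {
    if (stats::runif(1) < density) W[x, y] <- W[y, x] <- stats::runif(1)
  }
  for (x in 1:m) {
    if (sum(W[x, ] > 0) == 0) {
      y <- if (x == 1) 2 else x - 1
      W[x, y] <- W[y, x] <- stats::runif(1)
    }
  }
  W
}

random_gat_instance <- function(m, n, d, seed) {
  set.seed(seed)
  W_sim <- random_subgraph(m)
  W_co <- random_subgraph(m)
  X <- matrix(stats::rpois(m * n, 0.8), m, n)
  for (z in 1:n) if (sum(X[, z]) == 0) X[sample(m, 2), z] <- 1
  params <- gatmotif:::init_gat_params(m, d)
  list(W_sim = W_sim, W_co = W_co, X = X, params = params)
}
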