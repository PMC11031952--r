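# Two-layer graph attention network over the k-mer/sequence heterogeneous
# graph. Layer 1 learns k-mer embeddings in the similarity and coexisting
# subgraphs; layer 2 learns sequence embeddings in the inclusive subgraph;
# a fully connected layer predicts the bound/unbound label. Gradients are
# analytic (derived by hand) and checked against finite differences in the
# test suite.

leaky_relu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)

leaky_relu_grad <- function(x, slope = 0.2) (x > 0) + slope * (x <= 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration for the graph attention model
#'
#' Defaults follow the reference training regime: Adam for 300 epochs,
#' initial learning rate 0.02 with natural (exponential) decay rate 0.001
#' per epoch, dropout 0.3, k-mer length 5, embedding dimensions
#' d_k = d_seq = 100.
#'
#' @param epochs Number of full-batch epochs (>= 0; 0 returns the
#'   initialization unchanged).
#' @param learning_rate Initial Adam learning rate.
#' @param decay Decay rate; with \code{decay_type = "lr_exp"} the learning
#'   rate at epoch t is \code{learning_rate * exp(-decay * t)}; with
#'   \code{"weight"} it is an additive L2 weight-decay coefficient instead.
#' @param decay_type \code{"lr_exp"} (default) or \code{"weight"}.
#' @param dropout Dropout rate in \[0, 1), applied to normalized attention
#'   coefficients and to the sequence embedding before the classifier.
#' @param lenk K-mer length.
#' @param d_k Embedding dimension for k-mer nodes (d_seq is tied to it).
#' @param leaky_slope Negative slope of the LeakyReLU activations.
#' @param seed Integer RNG seed controlling initialization and dropout.
#' @return List of class \code{gat_config}.
#' @export
gat_config <- function(epochs = 300L, learning_rate = 0.02, decay = 0.001,
                       decay_type = c("lr_exp", "weight"), dropout = 0.3,
                       lenk = 5L, d_k = 100L, leaky_slope = 0.2, seed = 1L) {
  decay_type <- match.arg(decay_type)
  stopifnot(epochs >= 0, learning_rate > 0, learning_rate < 1,
            decay >= 0, decay < 1, dropout >= 0, dropout < 1, d_k >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 decay = decay, decay_type = decay_type, dropout = dropout,
                 lenk = as.integer(lenk), d_k = as.integer(d_k),
                 leaky_slope = leaky_slope, seed = as.integer(seed)),
            class = "gat_config")
}

# Glorot-uniform initialization of all learnable tensors.
init_gat_params <- function(m, d_k) {
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  list(
    a_sim = as.numeric(glorot(2L * d_k, 1L)),
    a_co = as.numeric(glorot(2L * d_k, 1L)),
    Wm_sim = glorot(d_k, m),
    Wm_co = glorot(d_k, m),
    Wm_inclu = glorot(m, d_k),
    cls_w = as.numeric(glorot(d_k, 1L)),
    cls_b = 0
  )
}

#' Initial k-mer embeddings from a subgraph weight matrix
#'
#' Normalizes each column of the (symmetric) subgraph weight matrix by the
#' total edge weight of that k-mer's neighborhood:
#' \code{h(k(x)) = W(:, x) / sum_{y in N(x)} W(x, y)}, so the entries of
#' \code{h(k(x))} over the neighbor support sum to 1. Isolated k-mers (no
#' edge in this subgraph) receive a unit self-loop so the normalization
#' stays defined; their count is reported via a message.
#'
#' @param W m x m symmetric nonnegative weight matrix (dense or sparse).
#' @return List with \code{H} (dense m x m matrix whose column x is
#'   \code{h(k(x))}) and \code{A} (logical m x m adjacency mask including
#'   fallback self-loops).
#' @export
init_kmer_embedding <- function(W) {
  W <- as.matrix(W)
  if (max(abs(W - t(W))) > 0) stop("subgraph weight matrix must be symmetric")
  A <- W > 0
  iso <- which(colSums(A) == 0L)
  if (length(iso) > 0L) {
    message(length(iso), " isolated k-mer node(s) given unit self-loops")
    W[cbind(iso, iso)] <- 1
    A[cbind(iso, iso)] <- TRUE
  }
  H <- sweep(W, 2L, colSums(W), "/")
  list(H = H, A = A)
}

#' Raw attention score between two k-mer nodes
#'
#' \code{e(x, y) = LeakyReLU(a' [W h(k(x)) || W h(k(y))])}: both initial
#' embeddings are projected by the shared weight matrix, concatenated, and
#' scored by the attention vector.
#'
#' @param a Attention vector of length 2 d_k.
#' @param Wm Shared weight matrix, d_k x m.
#' @param h_x,h_y Initial embeddings (m-vectors) of the two k-mers.
#' @param slope LeakyReLU negative slope (default 0.2).
#' @return Scalar score.
#' @export
kmer_attention_scores <- function(a, Wm, h_x, h_y, slope = 0.2) {
  d <- nrow(Wm)
  if (length(a) != 2L * d || length(h_x) != ncol(Wm) ||
      length(h_y) != ncol(Wm)) {
    stop("shape mismatch between attention vector, weight matrix and embeddings")
  }
  z <- c(Wm %*% h_x, Wm %*% h_y)
  leaky_relu(sum(a * z), slope)
}

#' Softmax normalization of attention scores over a neighbor set
#'
#' @param scores Numeric vector, one raw score per neighbor.
#' @return Coefficients summing to 1, order-preserving in the scores.
#' @export
normalize_attention <- function(scores) {
  if (length(scores) == 0L) stop("empty neighbor set")
  ex <- exp(scores - max(scores))
  ex / sum(ex)
}

#' Attention-weighted k-mer embedding aggregation
#'
#' \code{E(k(x)) = ReLU(sum_y alpha(x, y) W h(k(y)))} over the neighbors y
#' of x.
#'
#' @param Wm Shared weight matrix, d_k x m.
#' @param H Dense matrix of initial embeddings (column y = h(k(y))).
#' @param alpha Normalized coefficients, one per neighbor.
#' @param neighbors Integer indices of the neighbors (columns of H).
#' @return d_k-vector with nonnegative entries.
#' @export
aggregate_kmer_embedding <- function(Wm, H, alpha, neighbors) {
  stopifnot(length(alpha) == length(neighbors))
  acc <- (Wm %*% H[, neighbors, drop = FALSE]) %*% alpha
  pmax(as.numeric(acc), 0)
}

#' Initial sequence embedding
#'
#' Projects the inclusive-subgraph column of sequence z (its k-mer count
#' profile) into the embedding space:
#' \code{h_seq(seq(z)) = W_inclu(:, z)' W^inclu}, a row vector of dimension
#' d_seq.
#'
#' @param w_col Inclusive weight column for the sequence (m-vector of k-mer
#'   occurrence counts).
#' @param Wm_inclu Feature transformation matrix, m x d_seq.
#' @return d_seq-vector.
#' @export
init_seq_embedding <- function(w_col, Wm_inclu) {
  as.numeric(crossprod(Wm_inclu, w_col))
}

#' Inclusive attention coefficients of a sequence over its k-mers
#'
#' Raw scores are \code{b(z, x) = LeakyReLU(h_seq(seq(z)) . E(k(x)))} for
#' each k-mer x occurring in sequence z, computed separately against the
#' similarity-side and coexisting-side embeddings, then softmax-normalized
#' separately so each coefficient row sums to 1.
#'
#' @param h_seq_z Initial sequence embedding (d_seq-vector).
#' @param E_sim,E_co d_k x m learned k-mer embedding matrices.
#' @param neighbors Integer indices of the k-mers occurring in the sequence.
#' @param slope LeakyReLU negative slope.
#' @return List with \code{beta_sim} and \code{beta_co}, each summing to 1
#'   over \code{neighbors}.
#' @export
seq_attention <- function(h_seq_z, E_sim, E_co, neighbors, slope = 0.2) {
  if (length(neighbors) == 0L) stop("sequence has no k-mer neighbors")
  b_sim <- leaky_relu(
    as.numeric(h_seq_z %*% E_sim[, neighbors, drop = FALSE]), slope)
  b_co <- leaky_relu(
    as.numeric(h_seq_z %*% E_co[, neighbors, drop = FALSE]), slope)
  list(beta_sim = normalize_attention(b_sim),
       beta_co = normalize_attention(b_co))
}

#' Attention-weighted sequence embedding aggregation
#'
#' \code{E_seq(seq(z)) = ReLU(sum_x beta_sim(z,x) E_sim(k(x)) +
#' beta_co(z,x) E_co(k(x)))}. Since the coefficients and both embedding
#' matrices are entrywise nonnegative, the ReLU never clips here; it is kept
#' for structural symmetry with the first layer.
#'
#' @param beta_sim,beta_co Normalized coefficient rows over
#'   \code{neighbors}.
#' @param E_sim,E_co d_k x m learned k-mer embedding matrices.
#' @param neighbors Integer k-mer indices.
#' @return d_seq-vector with nonnegative entries.
#' @export
aggregate_seq_embedding <- function(beta_sim, beta_co, E_sim, E_co,
                                    neighbors) {
  acc <- E_sim[, neighbors, drop = FALSE] %*% beta_sim +
    E_co[, neighbors, drop = FALSE] %*% beta_co
  pmax(as.numeric(acc), 0)
}

#' Classify a sequence embedding
#'
#' Fully connected layer with sigmoid output; probabilities above 0.5 are
#' called bound.
#'
#' @param cls_w,cls_b Classifier weights (d_seq-vector) and bias.
#' @param E_seq_z Sequence embedding.
#' @return Probability in (0, 1).
#' @export
predict_tfbs <- function(cls_w, cls_b, E_seq_z) {
  sigmoid(sum(cls_w * E_seq_z) + cls_b)
}

# ---- vectorized forward / backward over the whole graph -------------------

# Row-wise softmax restricted to a logical mask; rows of the output sum to 1
# over the mask support.
masked_row_softmax <- function(S, mask) {
  S[!mask] <- -Inf
  rmax <- apply(S, 1L, max)
  EX <- exp(S - rmax)
  EX[!mask] <- 0
  EX / rowSums(EX)
}

# Precompute everything that depends on the graph but not on the parameters.
gat_precompute <- function(graph) {
  sim <- init_kmer_embedding(graph$W_sim)
  co <- init_kmer_embedding(graph$W_co)
  list(H_sim = sim$H, A_sim = sim$A, H_co = co$H, A_co = co$A)
}

# Full forward pass for a batch of sequences given as the dense m x n
# inclusive count matrix X. With dropout > 0, inverted-dropout masks are
# drawn from the current RNG stream and applied to the attention
# coefficients and to E_seq. Returns all intermediates needed by
# gat_backward().
gat_forward <- function(params, pre, X, dropout = 0, slope = 0.2) {
  keep <- 1 - dropout
  draw_mask <- function(nr, nc) {
    if (dropout <= 0) NULL
    else matrix(stats::runif(nr * nc) >= dropout, nr, nc)
  }
  layer1 <- function(a, Wm, H, A, branch_mask) {
    d <- nrow(Wm); m <- ncol(Wm)
    G <- Wm %*% H                               # d x m projected embeddings
    s1 <- as.numeric(crossprod(G, a[seq_len(d)]))
    s2 <- as.numeric(crossprod(G, a[d + seq_len(d)]))
    S_pre <- outer(s1, rep(1, m)) + matrix(s2, m, m, byrow = TRUE)
    S <- leaky_relu(S_pre, slope)
    alpha <- masked_row_softmax(S, A)
    alpha_d <- if (is.null(branch_mask)) alpha else alpha * branch_mask / keep
    E_pre <- G %*% t(alpha_d)
    list(G = G, S_pre = S_pre, alpha = alpha, alpha_d = alpha_d,
         mask = branch_mask, E_pre = E_pre, E = pmax(E_pre, 0))
  }
  m <- ncol(params$Wm_sim)
  l1_sim <- layer1(params$a_sim, params$Wm_sim, pre$H_sim, pre$A_sim,
                   draw_mask(m, m))
  l1_co <- layer1(params$a_co, params$Wm_co, pre$H_co, pre$A_co,
                  draw_mask(m, m))
  n <- ncol(X)
  AI <- t(X > 0)                                # n x m inclusive adjacency
  if (any(rowSums(AI) == 0L)) {
    stop("sequence with no vocabulary k-mers: cannot attend over an empty neighbor set")
  }
  Hs <- crossprod(X, params$Wm_inclu)           # n x d initial seq embeddings
  layer2 <- function(E, bmask) {
    B_pre <- Hs %*% E                           # n x m raw scores
    B <- leaky_relu(B_pre, slope)
    beta <- masked_row_softmax(B, AI)
    beta_d <- if (is.null(bmask)) beta else beta * bmask / keep
    list(B_pre = B_pre, beta = beta, beta_d = beta_d, mask = bmask)
  }
  l2_sim <- layer2(l1_sim$E, draw_mask(n, m))
  l2_co <- layer2(l1_co$E, draw_mask(n, m))
  Es_pre <- l2_sim$beta_d %*% t(l1_sim$E) + l2_co$beta_d %*% t(l1_co$E)
  Es <- pmax(Es_pre, 0)
  es_mask <- draw_mask(n, ncol(Es))
  Es_d <- if (is.null(es_mask)) Es else Es * es_mask / keep
  logits <- as.numeric(Es_d %*% params$cls_w) + params$cls_b
  list(l1_sim = l1_sim, l1_co = l1_co, l2_sim = l2_sim, l2_co = l2_co,
       AI = AI, Hs = Hs, Es_pre = Es_pre, Es = Es, Es_d = Es_d,
       es_mask = es_mask, logits = logits, prob = sigmoid(logits),
       dropout = dropout, slope = slope)
}

# Numerically stable mean binary cross-entropy from logits.
bce_loss <- function(logits, y) {
  mean(pmax(logits, 0) + log1p(exp(-abs(logits))) - y * logits)
}

# Analytic gradients of the mean BCE loss w.r.t. every parameter tensor.
gat_backward <- function(params, pre, X, fw, y) {
  slope <- fw$slope
  keep <- 1 - fw$dropout
  n <- length(y)
  du <- (fw$prob - y) / n
  d_cls_w <- as.numeric(crossprod(fw$Es_d, du))
  d_cls_b <- sum(du)
  dEs_d <- outer(du, params$cls_w)
  dEs <- if (is.null(fw$es_mask)) dEs_d else dEs_d * fw$es_mask / keep
  dEs_pre <- dEs * (fw$Es_pre > 0)

  layer2_back <- function(l2, E) {
    dbeta_d <- dEs_pre %*% E                    # n x m
    dE_agg <- t(crossprod(l2$beta_d, dEs_pre))  # d x m
    dbeta <- if (is.null(l2$mask)) dbeta_d else dbeta_d * l2$mask / keep
    db <- l2$beta * (dbeta - rowSums(l2$beta * dbeta))
    db_pre <- db * leaky_relu_grad(l2$B_pre, slope)
    list(dHs = db_pre %*% t(E),                 # n x d
         dE = dE_agg + crossprod(fw$Hs, db_pre))
  }
  b2_sim <- layer2_back(fw$l2_sim, fw$l1_sim$E)
  b2_co <- layer2_back(fw$l2_co, fw$l1_co$E)
  d_Wm_inclu <- X %*% (b2_sim$dHs + b2_co$dHs)

  layer1_back <- function(a, Wm, H, l1, dE) {
    d <- nrow(Wm)
    dE_pre <- dE * (l1$E_pre > 0)
    dalpha_d <- crossprod(dE_pre, l1$G)         # m x m, [x, y]
    dG <- dE_pre %*% l1$alpha_d                 # aggregation path
    dalpha <- if (is.null(l1$mask)) dalpha_d else dalpha_d * l1$mask / keep
    de <- l1$alpha * (dalpha - rowSums(l1$alpha * dalpha))
    dS_pre <- de * leaky_relu_grad(l1$S_pre, slope)
    ds1 <- rowSums(dS_pre)
    ds2 <- colSums(dS_pre)
    da <- c(as.numeric(l1$G %*% ds1), as.numeric(l1$G %*% ds2))
    dG <- dG + outer(a[seq_len(d)], ds1) + outer(a[d + seq_len(d)], ds2)
    list(da = da, dWm = dG %*% t(H))
  }
  b1_sim <- layer1_back(params$a_sim, params$Wm_sim, pre$H_sim, fw$l1_sim,
                        b2_sim$dE)
  b1_co <- layer1_back(params$a_co, params$Wm_co, pre$H_co, fw$l1_co,
                       b2_co$dE)
  list(a_sim = b1_sim$da, a_co = b1_co$da, Wm_sim = b1_sim$dWm,
       Wm_co = b1_co$dWm, Wm_inclu = d_Wm_inclu, cls_w = d_cls_w,
       cls_b = d_cls_b)
}

# Dense inclusive count matrix for arbitrary records against a vocabulary.
inclusive_counts <- function(vocab, records) {
  as.matrix(build_inclusive_matrix(vocab, records))
}

#' Train the graph attention TFBS classifier
#'
#' Full-batch Adam training of the two-layer attention model against binary
#' cross-entropy on the training sequences of \code{graph}. The graph should
#' be built from the training records (with a vocabulary covering the full
#' dataset, so held-out sequences map onto known k-mer nodes). Model
#' selection keeps the parameters from the epoch with the best validation
#' F1 score; with no validation records the final parameters are kept.
#' Training is deterministic given \code{config$seed}.
#'
#' @param graph A [build_het_graph()] over the training records.
#' @param validation Optional list of held-out [seq_record()] used for model
#'   selection.
#' @param config A [gat_config()].
#' @return Object of class \code{gat_model}: list with \code{params} (the
#'   selected parameters), \code{final_params}, \code{config},
#'   \code{vocab}, \code{pre} (cached initial embeddings), \code{trace}
#'   (data.frame epoch/loss/lr/val_f1) and \code{best_epoch}.
#' @export
train_gat <- function(graph, validation = NULL, config = gat_config()) {
  stopifnot(inherits(graph, "het_graph"), inherits(config, "gat_config"))
  m <- length(graph$vocab$kmers)
  y <- graph$labels
  pre <- gat_precompute(graph)
  X <- as.matrix(graph$W_inclu)
  X_val <- if (length(validation) > 0L) {
    inclusive_counts(graph$vocab, validation)
  } else NULL
  y_val <- if (!is.null(X_val)) record_labels(validation) else NULL

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(config$seed)
  params <- init_gat_params(m, config$d_k)
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      lr = numeric(0), val_f1 = numeric(0))
  best <- list(params = params, f1 = -Inf, epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    fw <- gat_forward(params, pre, X, dropout = config$dropout,
                      slope = config$leaky_slope)
    loss <- bce_loss(fw$logits, y)
    if (!is.finite(loss)) {
      stop("training diverged at epoch ", epoch, " (non-finite loss)")
    }
    gr <- gat_backward(params, pre, X, fw, y)
    gr <- lapply(gr, function(g) { dimnames(g) <- NULL; unname(g) })
    lr <- if (config$decay_type == "lr_exp") {
      config$learning_rate * exp(-config$decay * epoch)
    } else config$learning_rate
    for (nm in names(params)) {
      g <- gr[[nm]]
      if (config$decay_type == "weight") g <- g + config$decay * params[[nm]]
      adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
      adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
      mhat <- adam_m[[nm]] / (1 - b1^epoch)
      vhat <- adam_v[[nm]] / (1 - b2^epoch)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    val_f1 <- NA_real_
    if (!is.null(X_val)) {
      fv <- gat_forward(params, pre, X_val, dropout = 0,
                        slope = config$leaky_slope)
      val_f1 <- f1_score(y_val, as.integer(fv$prob > 0.5))
      if (is.finite(val_f1) && val_f1 > best$f1) {
        best <- list(params = params, f1 = val_f1, epoch = epoch)
      }
    }
    trace <- rbind(trace, data.frame(epoch = epoch, loss = loss, lr = lr,
                                     val_f1 = val_f1))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  selected <- if (is.finite(best$f1)) best$params else params
  structure(
    list(params = selected, final_params = params, config = config,
         vocab = graph$vocab, pre = pre, trace = trace,
         best_epoch = if (is.finite(best$f1)) best$epoch else config$epochs),
    class = "gat_model"
  )
}

#' @export
print.gat_model <- function(x, ...) {
  cat(sprintf(
    "<gat_model> m=%d d_k=%d | %d epoch(s), best validation epoch %d\n",
    ncol(x$params$Wm_sim), x$config$d_k, nrow(x$trace), x$best_epoch))
  invisible(x)
}

#' Predict TFBS probabilities for sequence records
#'
#' Inductive prediction: the inclusive count column of each record against
#' the training vocabulary is projected and pushed through the trained
#' attention layers (no dropout). K-mers absent from the vocabulary are
#' ignored.
#'
#' @param object A trained [train_gat()] model.
#' @param records List of k-mer-split [seq_record()].
#' @param ... Unused.
#' @return Numeric vector of probabilities, named by record id.
#' @export
predict.gat_model <- function(object, records, ...) {
  X <- inclusive_counts(object$vocab, records)
  fw <- gat_forward(object$params, object$pre, X, dropout = 0,
                    slope = object$config$leaky_slope)
  stats::setNames(fw$prob, record_ids(records))
}

f1_score <- function(y, yhat) {
  tp <- sum(y == 1L & yhat == 1L)
  fp <- sum(y == 0L & yhat == 1L)
  fn <- sum(y == 1L & yhat == 0L)
  if (tp == 0L) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Save a trained model as a JSON checkpoint
#'
#' Plain-text checkpoint holding all parameter tensors, the configuration,
#' the vocabulary and a hash of the graph manifest quantities, so a model
#' can be reloaded and applied to new records.
#'
#' @param model A [train_gat()] result.
#' @param path Output JSON file.
#' @return \code{path}, invisibly.
#' @export
save_gat_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    vocab = list(kmers = model$vocab$kmers, lenk = model$vocab$lenk),
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else as.numeric(p)
    }),
    best_epoch = model$best_epoch
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilding the attention layers needs the graph the model was trained on;
#' pass the same training graph (or one rebuilt from the same records and
#' parameters).
#'
#' @param path Checkpoint JSON from [save_gat_model()].
#' @param graph The training [build_het_graph()].
#' @return A \code{gat_model}.
#' @export
load_gat_model <- function(path, graph) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(x$vocab$kmers), graph$vocab$kmers)) {
    stop("checkpoint vocabulary does not match the supplied graph")
  }
  params <- lapply(x$params, function(p) {
    if (is.list(p) && !is.null(p$dim)) {
      matrix(as.numeric(p$data), p$dim[1], p$dim[2])
    } else as.numeric(p)
  })
  cfg <- do.call(gat_config, x$config[names(x$config) != ""])
  structure(
    list(params = params, final_params = params, config = cfg,
         vocab = graph$vocab, pre = gat_precompute(graph),
         trace = data.frame(), best_epoch = x$best_epoch),
    class = "gat_model"
  )
}
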