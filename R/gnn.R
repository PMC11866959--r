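# A small graph neural network over probe neighborhoods, written as batched
# vectorized R. Graphs are packed into one block-diagonal edge list, so a
# full-batch forward/backward pass is a handful of matrix products and
# rowsum() scatter-adds regardless of graph count. Gradients are derived by
# hand and checked against finite differences in the test suite.
#
# Architecture: n_att graph-attention layers (single head; attention logits
# combine transformed endpoint features and the edge distance, softmax over
# each node's in-edges), then n_conv symmetric-normalised graph-convolution
# layers, mean pooling per graph, and a logistic read-out.

.gnn_elements <- c("C", "N", "O", "P", "H")

gnn_schema_string <- function(radius) {
  paste0("onehot:", paste(.gnn_elements, collapse = ","),
         "|dist/", radius, "|sasa")
}

graph_node_features <- function(g, radius) {
  n <- nrow(g$nodes)
  X <- matrix(0, n, length(.gnn_elements) + 2)
  el <- match(g$nodes$element, .gnn_elements)
  hit <- which(!is.na(el))
  X[cbind(hit, el[hit])] <- 1
  X[, length(.gnn_elements) + 1] <- g$nodes$dist / radius
  X[, length(.gnn_elements) + 2] <- g$nodes$sasa
  X
}

# Pack a list of probe_graph objects into one batch. Undirected input edges
# become two directed edges; every node gets a self loop (distance 0), so
# every node receives at least one message.
gnn_batch <- function(graphs, radius = 8) {
  stopifnot(length(graphs) >= 1)
  sizes <- vapply(graphs, function(g) nrow(g$nodes), integer(1))
  offs <- cumsum(c(0L, sizes))[seq_along(graphs)]
  X <- do.call(rbind, lapply(graphs, graph_node_features, radius = radius))
  src <- integer(0); dst <- integer(0); ed <- numeric(0)
  parts <- lapply(seq_along(graphs), function(k) {
    g <- graphs[[k]]; n <- sizes[k]; o <- offs[k]
    i <- g$edges$i; j <- g$edges$j; d <- g$edges$dist
    list(src = o + c(i, j, seq_len(n)),
         dst = o + c(j, i, seq_len(n)),
         d = c(d, d, rep(0, n)))
  })
  src <- unlist(lapply(parts, `[[`, "src"), use.names = FALSE)
  dst <- unlist(lapply(parts, `[[`, "dst"), use.names = FALSE)
  ed <- unlist(lapply(parts, `[[`, "d"), use.names = FALSE)
  deg <- tabulate(dst, nbins = sum(sizes))
  y <- vapply(graphs, function(g) as.numeric(g$label %||% NA_real_), numeric(1))
  list(X = X, src = src, dst = dst, edist = ed,
       norm = 1 / sqrt(deg[src] * deg[dst]),
       node2graph = rep(seq_along(graphs), sizes),
       sizes = sizes, n_graphs = length(graphs), y = y,
       schema = gnn_schema_string(radius))
}

lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
lrelu_grad <- function(x) ifelse(x > 0, 1, 0.2)
sigmoid <- function(x) 1 / (1 + exp(-x))

gnn_init <- function(n_in, hidden = 16, n_att = 1, n_conv = 1, seed = 1) {
  set.seed(seed)
  glorot <- function(fin, fout)
    matrix(runif(fin * fout, -1, 1) * sqrt(6 / (fin + fout)), fin, fout)
  fin <- n_in
  att <- lapply(seq_len(n_att), function(l) {
    layer <- list(W = glorot(fin, hidden),
                  a_src = runif(hidden, -1, 1) * 0.1,
                  a_dst = runif(hidden, -1, 1) * 0.1,
                  w_d = 0,
                  b = rep(0, hidden))
    fin <<- hidden
    layer
  })
  conv <- lapply(seq_len(n_conv), function(l) {
    layer <- list(W = glorot(fin, hidden), b = rep(0, hidden))
    fin <<- hidden
    layer
  })
  list(att = att, conv = conv,
       head = list(w = runif(hidden, -1, 1) * 0.1, b = 0))
}

rs <- function(x, group, n) {
  # scatter-add rows of x by group id, returning an n-row matrix
  out <- matrix(0, n, ncol(x))
  got <- rowsum(x, group)
  out[as.integer(rownames(got)), ] <- got
  out
}

# Full forward pass; returns per-graph probabilities plus the caches needed
# for the backward pass.
gnn_forward <- function(params, batch) {
  N <- nrow(batch$X)
  H <- batch$X
  att_cache <- list()
  for (l in seq_along(params$att)) {
    p <- params$att[[l]]
    Z <- H %*% p$W
    s <- as.vector(Z[batch$src, , drop = FALSE] %*% p$a_src) +
      as.vector(Z[batch$dst, , drop = FALSE] %*% p$a_dst) +
      p$w_d * batch$edist
    e <- pmin(lrelu(s), 80)
    ex <- exp(e)
    den <- rs(cbind(ex), batch$dst, N)[, 1]
    alpha <- ex / den[batch$dst]
    Magg <- rs(alpha * Z[batch$src, , drop = FALSE], batch$dst, N)
    P <- sweep(Magg, 2, p$b, "+")
    Hout <- pmax(P, 0)
    att_cache[[l]] <- list(Hin = H, Z = Z, s = s, e = e, alpha = alpha, P = P)
    H <- Hout
  }
  conv_cache <- list()
  for (l in seq_along(params$conv)) {
    p <- params$conv[[l]]
    Agg <- rs(batch$norm * H[batch$src, , drop = FALSE], batch$dst, N)
    P <- sweep(Agg %*% p$W, 2, p$b, "+")
    Hout <- pmax(P, 0)
    conv_cache[[l]] <- list(Hin = H, Agg = Agg, P = P)
    H <- Hout
  }
  g <- rs(H, batch$node2graph, batch$n_graphs) / batch$sizes
  logit <- as.vector(g %*% params$head$w) + params$head$b
  prob <- sigmoid(logit)
  list(prob = prob, logit = logit, g = g, H = H,
       att_cache = att_cache, conv_cache = conv_cache)
}

# Binary cross-entropy loss (optionally graph-weighted) and its gradients
# with respect to every parameter.
gnn_loss_grad <- function(params, batch, weights = NULL, grad = TRUE) {
  fw <- gnn_forward(params, batch)
  y <- batch$y
  G <- batch$n_graphs
  if (is.null(weights)) weights <- rep(1 / G, G)
  eps <- 1e-12
  loss <- -sum(weights * (y * log(fw$prob + eps) +
                            (1 - y) * log(1 - fw$prob + eps)))
  if (!grad) return(list(loss = loss, prob = fw$prob))
  N <- nrow(batch$X)
  grads <- list(att = vector("list", length(params$att)),
                conv = vector("list", length(params$conv)))
  dlogit <- weights * (fw$prob - y)
  grads$head <- list(w = as.vector(crossprod(fw$g, dlogit)),
                     b = sum(dlogit))
  dg <- outer(dlogit, params$head$w)
  dH <- (dg / batch$sizes)[batch$node2graph, , drop = FALSE]
  for (l in rev(seq_along(params$conv))) {
    p <- params$conv[[l]]; cc <- fw$conv_cache[[l]]
    dP <- dH * (cc$P > 0)
    grads$conv[[l]] <- list(W = crossprod(cc$Agg, dP), b = colSums(dP))
    dAgg <- dP %*% t(p$W)
    dH <- rs(batch$norm * dAgg[batch$dst, , drop = FALSE], batch$src, N)
  }
  for (l in rev(seq_along(params$att))) {
    p <- params$att[[l]]; cc <- fw$att_cache[[l]]
    dP <- dH * (cc$P > 0)
    db <- colSums(dP)
    # through the aggregation M_i = sum_j alpha_ij z_j
    dalpha <- rowSums(dP[batch$dst, , drop = FALSE] *
                        cc$Z[batch$src, , drop = FALSE])
    dZ <- rs(cc$alpha * dP[batch$dst, , drop = FALSE], batch$src, N)
    # softmax over each node's in-edges
    t_e <- cc$alpha * dalpha
    Tsum <- rs(cbind(t_e), batch$dst, N)[, 1]
    de <- t_e - cc$alpha * Tsum[batch$dst]
    ds <- de * lrelu_grad(cc$s) * (lrelu(cc$s) < 80)
    da_src <- as.vector(crossprod(cc$Z[batch$src, , drop = FALSE], ds))
    da_dst <- as.vector(crossprod(cc$Z[batch$dst, , drop = FALSE], ds))
    dw_d <- sum(ds * batch$edist)
    dZ <- dZ + rs(outer(ds, p$a_src), batch$src, N) +
      rs(outer(ds, p$a_dst), batch$dst, N)
    grads$att[[l]] <- list(W = crossprod(cc$Hin, dZ), a_src = da_src,
                           a_dst = da_dst, w_d = dw_d, b = db)
    dH <- dZ %*% t(p$W)
  }
  list(loss = loss, prob = fw$prob, grads = grads)
}

# Adam over the flattened parameter vector (relist restores the shapes).
gnn_train_core <- function(graphs, arch, epochs, lr, seed, balance = TRUE,
                           radius = 8) {
  batch <- gnn_batch(graphs, radius = radius)
  if (anyNA(batch$y)) stop("all training graphs must carry labels", call. = FALSE)
  params <- gnn_init(ncol(batch$X), hidden = arch$hidden,
                     n_att = arch$n_att, n_conv = arch$n_conv,
                     seed = seed)
  theta <- unlist(params, use.names = FALSE)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  y <- batch$y
  pos <- which(y == 1); neg <- which(y == 0)
  set.seed(seed + 1L)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    w <- rep(0, batch$n_graphs)
    if (balance && length(pos) != length(neg)) {
      # negative (majority-class) subsampling to 1:1 each epoch
      k <- min(length(pos), length(neg))
      maj <- if (length(pos) > length(neg)) pos else neg
      mnr <- if (length(pos) > length(neg)) neg else pos
      sel <- c(mnr, sample(maj, k))
      w[sel] <- 1 / length(sel)
    } else {
      w <- rep(1 / batch$n_graphs, batch$n_graphs)
    }
    lg <- gnn_loss_grad(params, batch, weights = w)
    g <- unlist(lg$grads[c("att", "conv", "head")], use.names = FALSE)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^ep)
    vhat <- v / (1 - b2^ep)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    params <- utils::relist(theta, params)
    history[ep] <- lg$loss
  }
  list(params = params, history = history, batch_schema = batch$schema)
}

gnn_predict_core <- function(params, graphs, radius = 8) {
  batch <- gnn_batch(graphs, radius = radius)
  gnn_forward(params, batch)$prob
}
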