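# Loss evaluation with analytic parameter gradients for one sample.
# Returns the loss breakdown plus gradients shaped like the parameter
# list; used by the training loop and checked against finite
# differences in the tests.

loss_with_grads <- function(sample, params, config, tau = 4.2,
                            smoothing = 0.1, struct_weight = 10) {
  trace <- egnn_forward(sample, params, config, with_cache = TRUE)
  N <- config$n_layers
  L <- nrow(sample$coords)
  mask <- sample$mask
  cdr <- layer_cdr_rows(mask)
  non <- which(mask == 0L)
  truth <- sample$truth_coords

  parts <- loss_breakdown(trace, sample, params, tau = tau,
                          smoothing = smoothing,
                          struct_weight = struct_weight)
  # a diverged forward pass yields non-finite losses; skip the backward
  # sweep and let the caller abort on the breakdown
  if (!is.finite(parts$l_total))
    return(list(parts = parts, grads = zero_like(params), trace = trace))

  d_x <- vector("list", N)
  d_f <- vector("list", N)
  for (k in seq_len(N)) d_x[[k]] <- matrix(0, L, 3)

  ## RMSD term: mean over layers of per-layer CDR RMSD
  for (k in seq_len(N)) {
    x <- trace$per_layer_coords[[k]]
    dev <- x[cdr, , drop = FALSE] - truth[cdr, , drop = FALSE]
    r <- sqrt(mean(rowSums(dev * dev)))
    if (r > 0)
      d_x[[k]][cdr, ] <- d_x[[k]][cdr, ] +
        struct_weight / N * dev / (length(cdr) * r)
  }

  ks <- violation_layers(N)

  ## repulsion term
  if (length(ks) && length(non)) {
    c0 <- struct_weight / (length(ks) * length(cdr) * length(non))
    for (k in ks) {
      x <- trace$per_layer_coords[[k]]
      a <- x[cdr, , drop = FALSE]; b <- x[non, , drop = FALSE]
      D2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
      D <- sqrt(pmax(D2, 1e-24))
      act <- (D < tau) * 1
      if (any(act > 0)) {
        W <- act / D
        for (cc in 1:3) {
          dm <- outer(a[, cc], b[, cc], "-")
          d_x[[k]][cdr, cc] <- d_x[[k]][cdr, cc] - c0 * rowSums(W * dm)
          d_x[[k]][non, cc] <- d_x[[k]][non, cc] + c0 * colSums(W * dm)
        }
      }
    }
  }

  ## neighbour term
  if (length(ks)) {
    path <- c(cdr[1] - 1L, cdr, cdr[length(cdr)] + 1L)
    pa <- path[-length(path)]; pb <- path[-1]
    dt <- sqrt(rowSums((truth[pb, , drop = FALSE] -
                          truth[pa, , drop = FALSE])^2))
    c1 <- struct_weight / (length(ks) * (length(cdr) + 1L))
    for (k in ks) {
      x <- trace$per_layer_coords[[k]]
      ev <- x[pb, , drop = FALSE] - x[pa, , drop = FALSE]
      dp <- sqrt(pmax(rowSums(ev * ev), 1e-24))
      sgn <- sign(dp - dt)
      gvec <- ev * (c1 * sgn / dp)
      d_x[[k]][pb, ] <- d_x[[k]][pb, ] + gvec
      d_x[[k]][pa, ] <- d_x[[k]][pa, ] - gvec
    }
  }

  ## cross-entropy terms (shared head over layer features)
  head_acc <- zero_like(params$head)
  rows_non <- which(mask == 0L & !is.na(sample$truth_tokens))
  Q_non <- if (length(rows_non))
    smoothed_targets(sample$truth_tokens[rows_non], smoothing) else NULL
  Q_cdr <- smoothed_targets(sample$truth_tokens[cdr], smoothing)
  last4 <- (N - 3L):N
  for (k in seq_len(N)) {
    feats <- trace$per_layer_feats[[k]]
    rows <- integer()
    if (length(rows_non)) rows <- rows_non
    if (k %in% last4) rows <- c(rows, cdr)
    if (!length(rows)) next
    fsub <- feats[rows, , drop = FALSE]
    hc <- head_forward(fsub, params$head, with_cache = TRUE)
    P <- exp(log_softmax(hc$logits))
    adj_logits <- matrix(0, length(rows), 20)
    if (length(rows_non)) {
      ii <- seq_along(rows_non)
      adj_logits[ii, ] <- (P[ii, , drop = FALSE] - Q_non) /
        (length(rows_non) * N)
    }
    if (k %in% last4) {
      jj <- length(rows_non) + seq_along(cdr)
      adj_logits[jj, ] <- adj_logits[jj, ] +
        (P[jj, , drop = FALSE] - Q_cdr) / (length(cdr) * 4)
    }
    hb <- head_backward(fsub, params$head, hc, adj_logits, head_acc)
    head_acc <- hb$acc
    dfk <- matrix(0, L, config$hidden_dim)
    dfk[rows, ] <- hb$adj_f
    d_f[[k]] <- dfk
  }

  grads <- egnn_backward(sample, params, config, trace, d_x, d_f)
  grads$head <- head_acc
  list(parts = parts, grads = grads, trace = trace)
}
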