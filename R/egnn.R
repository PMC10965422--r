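#' Model configuration
#'
#' Hyperparameters of the equivariant layer stack. Defaults mirror the
#' reference setting: 16 layers, a 256-dimensional learnable
#' amino-acid embedding plus a 2-dimensional chain-type embedding
#' (input feature width 258), hidden width 256, and 64 nearest
#' neighbours per node. The repulsion/neighbour violation losses act
#' on layers 5..n_layers, and the CDR cross-entropy on the last four
#' layers, so \code{n_layers} must be at least 4; with exactly 4
#' layers the violation-loss layer range is empty and those terms are
#' zero.
#'
#' @param n_layers number of equivariant layers.
#' @param aa_embed_dim amino-acid embedding width.
#' @param chain_embed_dim chain-type embedding width.
#' @param hidden_dim node feature width inside the stack.
#' @param k_neighbors neighbours per node for edge construction.
#' @return object of class \code{model_config}.
#' @export
model_config <- function(n_layers = 16L, aa_embed_dim = 256L,
                         chain_embed_dim = 2L, hidden_dim = 256L,
                         k_neighbors = 64L) {
  stopifnot(n_layers >= 4L, aa_embed_dim > 0L, chain_embed_dim > 0L,
            hidden_dim > 0L, k_neighbors >= 1L)
  structure(list(n_layers = as.integer(n_layers),
                 aa_embed_dim = as.integer(aa_embed_dim),
                 chain_embed_dim = as.integer(chain_embed_dim),
                 hidden_dim = as.integer(hidden_dim),
                 k_neighbors = as.integer(k_neighbors),
                 n_aa_types = 20L,
                 mask_token_id = MASK_TOKEN,
                 input_dim = as.integer(aa_embed_dim + chain_embed_dim)),
            class = "model_config")
}

silu <- function(x) x / (1 + exp(-x))
dsilu <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

# add a row vector b to every row of Z (column-major trick)
addb <- function(Z, b) Z + rep(b, each = nrow(Z))

rand_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Initialise model parameters
#'
#' Gaussian initialisation scaled by 1/sqrt(fan-in); the final linear
#' map of each coordinate-update head is down-scaled so early
#' coordinate updates are small. Fully determined by \code{seed}.
#'
#' @param config a \code{\link{model_config}}.
#' @param seed integer RNG seed.
#' @return nested parameter list (embeddings, input projection, per-layer
#'   message/coordinate/feature networks, amino-acid head).
#' @export
init_params <- function(config, seed = 1L) {
  set.seed(seed)
  h <- config$hidden_dim
  d_in <- config$input_dim
  layer_params <- function() list(
    We1 = rand_mat(2L * h + 1L, h, 1 / sqrt(2 * h + 1)), be1 = numeric(h),
    We2 = rand_mat(h, h, 1 / sqrt(h)),                   be2 = numeric(h),
    Wx1 = rand_mat(h, h, 1 / sqrt(h)),                   bx1 = numeric(h),
    Wx2 = rand_mat(h, 1L, 0.01 / sqrt(h)),               bx2 = numeric(1),
    Wh1 = rand_mat(2L * h, h, 1 / sqrt(2 * h)),          bh1 = numeric(h),
    Wh2 = rand_mat(h, h, 1 / sqrt(h)),                   bh2 = numeric(h))
  list(
    aa_emb = rand_mat(21L, config$aa_embed_dim,
                      1 / sqrt(config$aa_embed_dim)),
    chain_emb = rand_mat(2L, config$chain_embed_dim,
                         1 / sqrt(config$chain_embed_dim)),
    proj = list(W = rand_mat(d_in, h, 1 / sqrt(d_in)), b = numeric(h)),
    layers = lapply(seq_len(config$n_layers), function(i) layer_params()),
    head = list(W1 = rand_mat(h, h, 1 / sqrt(h)), b1 = numeric(h),
                W2 = rand_mat(h, 20L, 1 / sqrt(h)), b2 = numeric(20L)))
}

#' Embed sequence tokens and chain types into input node features
#'
#' Row i is the concatenation of the learnable amino-acid embedding of
#' token i (MASK has its own row) and the learnable chain-type
#' embedding; output width is \code{aa_embed_dim + chain_embed_dim}
#' (258 with defaults).
#'
#' @param seq_tokens integer tokens in 1..21 (21 = MASK).
#' @param chain_type integer labels, 0 antibody / 1 antigen.
#' @param params parameter list from \code{\link{init_params}}.
#' @return numeric L x (aa_embed_dim + chain_embed_dim) matrix.
#' @export
embed_inputs <- function(seq_tokens, chain_type, params) {
  if (any(is.na(seq_tokens)) || any(seq_tokens < 1L | seq_tokens > 21L))
    stop("sequence token out of range 1..21")
  if (any(!chain_type %in% c(0L, 1L)))
    stop("chain_type labels must be 0 or 1")
  cbind(params$aa_emb[seq_tokens, , drop = FALSE],
        params$chain_emb[chain_type + 1L, , drop = FALSE])
}

#' Per-layer coordinate masking
#'
#' \code{x_masked = x_k * M + x_input * (1 - M)} rowwise: CDR rows take
#' the layer output, all other rows are pinned back to the input
#' coordinates. Applied after every layer.
#'
#' @param x_k L x 3 layer output coordinates.
#' @param x_input L x 3 input coordinates.
#' @param mask length-L 0/1 vector (1 on CDR rows).
#' @return L x 3 matrix.
#' @export
apply_coord_mask <- function(x_k, x_input, mask) {
  stopifnot(nrow(x_k) == nrow(x_input), nrow(x_k) == length(mask))
  m <- as.numeric(mask)
  x_k * m + x_input * (1 - m)
}

# squared distances enter the message net in nm^2 (0.01 * Angstrom^2)
# so edge inputs stay O(1); purely a units choice, invariance unaffected
DIST2_SCALE <- 0.01

# one equivariant layer; returns outputs and (optionally) the cache
# needed by the analytic backward pass
egnn_layer_forward <- function(f, x, edges, lp, with_cache = FALSE) {
  src <- edges[, 1L]; dst <- edges[, 2L]
  diff <- x[dst, , drop = FALSE] - x[src, , drop = FALSE]
  d2 <- rowSums(diff * diff)
  d <- sqrt(pmax(d2, 1e-24))
  u <- diff / (d + 1)
  min_ <- cbind(f[dst, , drop = FALSE], f[src, , drop = FALSE],
                DIST2_SCALE * d2)
  z_e1 <- addb(min_ %*% lp$We1, lp$be1); h_e1 <- silu(z_e1)
  z_e2 <- addb(h_e1 %*% lp$We2, lp$be2); m <- silu(z_e2)
  z_x1 <- addb(m %*% lp$Wx1, lp$bx1); a_x1 <- silu(z_x1)
  s <- addb(a_x1 %*% lp$Wx2, lp$bx2)
  L <- nrow(x)
  inc <- tabulate(dst, L)
  upd <- scatter_add(u * as.vector(s), dst, L) / pmax(inc, 1L)
  x_new <- x + upd
  agg <- scatter_add(m, dst, L)
  hin <- cbind(f, agg)
  z_h1 <- addb(hin %*% lp$Wh1, lp$bh1); g_h1 <- silu(z_h1)
  g2 <- addb(g_h1 %*% lp$Wh2, lp$bh2)
  f_new <- f + g2
  out <- list(f = f_new, x = x_new)
  if (with_cache)
    out$cache <- list(f_prev = f, x_prev = x, diff = diff, d2 = d2,
                      d = d, u = u, min_ = min_, z_e1 = z_e1,
                      h_e1 = h_e1, z_e2 = z_e2, m = m, z_x1 = z_x1,
                      a_x1 = a_x1, s = s, inc = inc, agg = agg,
                      hin = hin, z_h1 = z_h1, g_h1 = g_h1)
  out
}

# feed-forward amino-acid head: two linear layers, SiLU in between
head_forward <- function(f, hp, with_cache = FALSE) {
  z1 <- addb(f %*% hp$W1, hp$b1)
  h1 <- silu(z1)
  logits <- addb(h1 %*% hp$W2, hp$b2)
  if (with_cache) list(logits = logits, z1 = z1, h1 = h1) else logits
}

#' Run the full equivariant stack on a graph sample
#'
#' Sequentially applies the configured number of equivariant layers,
#' each followed by \code{\link{apply_coord_mask}} so that non-CDR
#' coordinates remain exactly the input coordinates at every depth,
#' and finally the two-layer feed-forward head on the last layer's
#' features to obtain 20-way amino-acid logits. Per-layer coordinates
#' and features are retained for the loss suite.
#'
#' @param sample a \code{\link{encode_sample}} graph sample.
#' @param params parameters from \code{\link{init_params}}.
#' @param config the \code{\link{model_config}}.
#' @param with_cache keep layer intermediates for the backward pass.
#' @return object of class \code{forward_trace}: list with
#'   \code{per_layer_coords} (post-mask), \code{per_layer_feats},
#'   \code{final_logits}, and optionally \code{cache}.
#' @export
egnn_forward <- function(sample, params, config, with_cache = FALSE) {
  x_input <- sample$coords
  mask <- sample$mask
  emb <- embed_inputs(sample$seq_tokens, sample$chain_type, params)
  f <- addb(emb %*% params$proj$W, params$proj$b)
  x <- x_input
  N <- config$n_layers
  per_x <- vector("list", N); per_f <- vector("list", N)
  caches <- if (with_cache) vector("list", N) else NULL
  for (k in seq_len(N)) {
    out <- egnn_layer_forward(f, x, sample$edges, params$layers[[k]],
                              with_cache = with_cache)
    x <- apply_coord_mask(out$x, x_input, mask)
    f <- out$f
    per_x[[k]] <- x
    per_f[[k]] <- f
    if (with_cache) caches[[k]] <- out$cache
  }
  hd <- head_forward(f, params$head, with_cache = with_cache)
  trace <- list(per_layer_coords = per_x, per_layer_feats = per_f,
                final_logits = if (with_cache) hd$logits else hd)
  if (with_cache) {
    trace$cache <- caches
    trace$emb <- emb
  }
  class(trace) <- "forward_trace"
  trace
}

# scatter-add rows of M into an L-row accumulator by integer index
scatter_add <- function(M, idx, L) {
  out <- matrix(0, L, ncol(M))
  r <- rowsum(M, idx)
  out[as.integer(rownames(r)), ] <- r
  out
}
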