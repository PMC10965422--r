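# Fixtures are built in code: hand-written PDB text, random graph
# samples and random forward traces used by the oracle tests.

pdb_ca_line <- function(serial, resname, chain, resno, icode, x, y, z) {
  sprintf("ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
          serial, resname, chain, resno, icode, x, y, z)
}

# minimal 3-residue single-chain PDB text
mini_pdb_text <- function() {
  paste(c(
    pdb_ca_line(1, "ALA", "A", 1, " ", 0, 0, 0),
    pdb_ca_line(2, "GLY", "A", 2, " ", 3.8, 0, 0),
    pdb_ca_line(3, "TRP", "A", 3, " ", 7.6, 0, 0),
    "TER", "END"), collapse = "\n")
}

# two chains; chain A contains an insertion-coded residue 100A
insertion_pdb_text <- function() {
  paste(c(
    pdb_ca_line(1, "MET", "A", 99, " ", 0, 0, 0),
    pdb_ca_line(2, "LYS", "A", 100, " ", 3.8, 0, 0),
    pdb_ca_line(3, "SER", "A", 100, "A", 7.6, 0, 0),
    pdb_ca_line(4, "THR", "A", 101, " ", 11.4, 0, 0),
    "TER",
    pdb_ca_line(5, "PHE", "B", 1, " ", 0, 8, 0),
    pdb_ca_line(6, "TYR", "B", 2, " ", 3.8, 8, 0),
    "TER", "END"), collapse = "\n")
}

# synthetic chain record with simple author numbering 1..n
make_chain <- function(n = 120, chain_id = "H", role = "heavy",
                       aa = NULL, start_num = 1L) {
  if (is.null(aa)) aa <- rep(AA_ALPHABET, length.out = n)
  chain_record(chain_id, role, data.frame(
    res_number = start_num + seq_len(n) - 1L, icode = "",
    aa = aa, x = 3.8 * seq_len(n), y = 0, z = 0,
    stringsAsFactors = FALSE))
}

# small toy complex + located CDR, shared across tests
toy_pair <- function(seed = 7, index = 1) {
  sp <- toy_spec(n_complexes = 1, seed = seed)
  cx <- make_toy_complex(sp, index)
  list(spec = locate_cdr(cx$chains$H, "HCDR3"), complex = cx)
}

tiny_config <- function(n_layers = 5L, hidden = 10L, knn = 8L)
  model_config(n_layers = n_layers, aa_embed_dim = 8L, chain_embed_dim = 2L,
               hidden_dim = hidden, k_neighbors = knn)

# random forward-trace-shaped object for the loss oracles
rand_trace_fixture <- function(L = 12L, ncdr = 4L, n_layers = 6L, seed = 1L) {
  set.seed(seed)
  cdr_start <- sample(2:(L - ncdr), 1)
  mask <- integer(L); mask[cdr_start:(cdr_start + ncdr - 1L)] <- 1L
  truth <- matrix(rnorm(L * 3, sd = 4), L, 3)
  per_x <- lapply(seq_len(n_layers), function(k) {
    x <- truth + matrix(rnorm(L * 3), L, 3)
    x[mask == 0L, ] <- truth[mask == 0L, ]
    x
  })
  h <- 6L
  per_f <- lapply(seq_len(n_layers), function(k) matrix(rnorm(L * h), L, h))
  head_params <- list(W1 = matrix(rnorm(h * h, sd = 0.5), h, h),
                      b1 = rnorm(h),
                      W2 = matrix(rnorm(h * 20, sd = 0.5), h, 20),
                      b2 = rnorm(20))
  trace <- structure(list(per_layer_coords = per_x, per_layer_feats = per_f,
                          final_logits = NULL), class = "forward_trace")
  list(trace = trace, truth = truth, mask = mask,
       tokens = sample(20L, L, replace = TRUE), head = head_params)
}

## ---- independent naive oracles (pure loops, no vectorisation) ----

oracle_rmsd <- function(trace, truth, mask) {
  acc <- 0
  for (x in trace$per_layer_coords) {
    ss <- 0; n <- 0
    for (i in which(mask == 1L)) {
      ss <- ss + sum((x[i, ] - truth[i, ])^2); n <- n + 1
    }
    acc <- acc + sqrt(ss / n)
  }
  acc / length(trace$per_layer_coords)
}

oracle_repulsion <- function(trace, mask, tau = 4.2) {
  N <- length(trace$per_layer_coords)
  ks <- if (N >= 5) 5:N else integer()
  if (!length(ks)) return(0)
  acc <- 0
  for (k in ks) {
    x <- trace$per_layer_coords[[k]]
    s <- 0
    for (i in which(mask == 1L)) for (j in which(mask == 0L)) {
      d <- sqrt(sum((x[i, ] - x[j, ])^2))
      s <- s + max(tau - d, 0)
    }
    acc <- acc + s / (sum(mask == 1L) * sum(mask == 0L))
  }
  acc / length(ks)
}

oracle_neighbor <- function(trace, truth, mask) {
  N <- length(trace$per_layer_coords)
  ks <- if (N >= 5) 5:N else integer()
  if (!length(ks)) return(0)
  cdr <- which(mask == 1L)
  path <- c(cdr[1] - 1L, cdr, cdr[length(cdr)] + 1L)
  acc <- 0
  for (k in ks) {
    x <- trace$per_layer_coords[[k]]
    s <- 0
    for (t in 2:length(path)) {
      dp <- sqrt(sum((x[path[t], ] - x[path[t - 1], ])^2))
      dt <- sqrt(sum((truth[path[t], ] - truth[path[t - 1], ])^2))
      s <- s + abs(dp - dt)
    }
    acc <- acc + s / (length(cdr) + 1)
  }
  acc / length(ks)
}

# naive label-smoothed CE of the two-linear-layer head on given rows
oracle_ce <- function(feats_list, layers, rows, tokens, hp, smoothing = 0.1) {
  acc <- 0
  for (k in layers) {
    f <- feats_list[[k]]
    s <- 0
    for (r in seq_along(rows)) {
      i <- rows[r]
      z1 <- as.numeric(f[i, ] %*% hp$W1) + hp$b1
      h1 <- z1 / (1 + exp(-z1))
      lg <- as.numeric(h1 %*% hp$W2) + hp$b2
      p <- exp(lg - max(lg)); p <- p / sum(p)
      q <- rep(smoothing / 20, 20)
      q[tokens[r]] <- q[tokens[r]] + 1 - smoothing
      s <- s - sum(q * log(p))
    }
    acc <- acc + s / length(rows)
  }
  acc / length(layers)
}

# rigid transform helpers
rand_rigid <- function(seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, sd = 10))
}

apply_rigid <- function(X, tr)
  X %*% tr$R + matrix(tr$t, nrow(X), 3, byrow = TRUE)
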