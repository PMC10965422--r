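test_that("RMSD loss: closed-form cases and loop oracle", {
  fx <- rand_trace_fixture(L = 10, ncdr = 3, n_layers = 6, seed = 1)
  # perfect prediction
  perfect <- fx$trace
  perfect$per_layer_coords <- lapply(perfect$per_layer_coords,
                                     function(x) fx$truth)
  expect_equal(rmsd_loss(perfect, fx$truth, fx$mask), 0)

  # single layer, single CDR residue offset by (3,4,0) -> 5
  mask1 <- c(0L, 1L, 0L)
  truth1 <- matrix(0, 3, 3)
  x1 <- truth1; x1[2, ] <- c(3, 4, 0)
  tr1 <- structure(list(per_layer_coords = list(x1)),
                   class = "forward_trace")
  expect_equal(rmsd_loss(tr1, truth1, mask1), 5.0)

  for (seed in 2:6) {
    fx <- rand_trace_fixture(L = 15, ncdr = 5, n_layers = 3, seed = seed)
    expect_equal(rmsd_loss(fx$trace, fx$truth, fx$mask),
                 oracle_rmsd(fx$trace, fx$truth, fx$mask),
                 tolerance = 1e-10)
  }
  expect_error(rmsd_loss(fx$trace, fx$truth, rep(0L, 15)), "CDR")
})

test_that("repulsion loss: hinge branches at tau = 4.2 and loop oracle", {
  # one CDR and one non-CDR node; only layer 5 of 5 is in range
  mk <- function(d) {
    x <- rbind(c(0, 0, 0), c(d, 0, 0))
    structure(list(per_layer_coords = rep(list(x), 5)),
              class = "forward_trace")
  }
  mask <- c(1L, 0L)
  expect_equal(repulsion_loss(mk(5.0), mask), 0)          # 5.0 > 4.2
  expect_equal(repulsion_loss(mk(3.2), mask), 1.0)        # max(4.2-3.2, 0)
  expect_equal(repulsion_loss(mk(4.2), mask), 0)          # boundary

  for (seed in 7:11) {
    fx <- rand_trace_fixture(L = 12, ncdr = 4, n_layers = 7, seed = seed)
    expect_equal(repulsion_loss(fx$trace, fx$mask),
                 oracle_repulsion(fx$trace, fx$mask), tolerance = 1e-10)
  }
  expect_error(repulsion_loss(mk(3), c(1L, 1L)), "non-CDR")
})

test_that("repulsion is non-increasing as separations grow", {
  mask <- c(1L, 0L)
  vals <- vapply(seq(1, 6, by = 0.25), function(d) {
    x <- rbind(c(0, 0, 0), c(d, 0, 0))
    repulsion_loss(structure(list(per_layer_coords = rep(list(x), 5)),
                             class = "forward_trace"), mask)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("neighbor loss: perfect, hand-evaluated and loop-oracle cases", {
  fx <- rand_trace_fixture(L = 10, ncdr = 3, n_layers = 6, seed = 12)
  perfect <- fx$trace
  perfect$per_layer_coords <- lapply(perfect$per_layer_coords,
                                     function(x) fx$truth)
  expect_equal(neighbor_loss(perfect, fx$truth, fx$mask), 0)

  # one CDR residue between two anchors; both flanking edges change by 0.5
  truth <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  x <- truth; x[2, 1] <- 3.8 + 0.5  # +0.5 on one edge, -? on other:
  # edge a-cdr: 4.3 (delta +0.5); edge cdr-b: 3.3 (delta -0.5) -> |.|=0.5
  tr <- structure(list(per_layer_coords = rep(list(x), 5)),
                  class = "forward_trace")
  expect_equal(neighbor_loss(tr, truth, c(0L, 1L, 0L)), (0.5 + 0.5) / 2)

  for (seed in 13:17) {
    fx <- rand_trace_fixture(L = 14, ncdr = 4, n_layers = 8, seed = seed)
    expect_equal(neighbor_loss(fx$trace, fx$truth, fx$mask),
                 oracle_neighbor(fx$trace, fx$truth, fx$mask),
                 tolerance = 1e-10)
  }
})

test_that("cross-entropy: uniform and perfect-prediction closed forms", {
  fx <- rand_trace_fixture(L = 10, ncdr = 3, n_layers = 6, seed = 18)
  # uniform logits: zero both head layers -> CE = ln 20 at any smoothing
  hp0 <- fx$head
  hp0$W1[] <- 0; hp0$b1[] <- 0; hp0$W2[] <- 0; hp0$b2[] <- 0
  expect_equal(ce_noncdr_loss(fx$trace, fx$tokens, fx$mask, hp0),
               log(20), tolerance = 1e-12)
  expect_equal(ce_cdr_loss(fx$trace, fx$tokens, fx$mask, hp0),
               log(20), tolerance = 1e-12)

  # head emitting exactly the smoothed target distribution: CE equals
  # the smoothed-target entropy (the attainable minimum)
  tok <- 7L
  fx2 <- fx
  fx2$tokens <- rep(tok, 10)
  q <- rep(0.1 / 20, 20); q[tok] <- q[tok] + 0.9
  hp_q <- hp0
  hp_q$b2 <- log(q)
  ent <- -sum(q * log(q))
  expect_equal(ce_noncdr_loss(fx2$trace, fx2$tokens, fx2$mask, hp_q),
               ent, tolerance = 1e-12)
  expect_equal(ce_cdr_loss(fx2$trace, fx2$tokens, fx2$mask, hp_q),
               ent, tolerance = 1e-12)
})

test_that("cross-entropy matches a per-residue loop oracle with exact layer ranges", {
  for (seed in 19:21) {
    fx <- rand_trace_fixture(L = 12, ncdr = 4, n_layers = 6, seed = seed)
    N <- 6L
    non <- which(fx$mask == 0L)
    cdr <- which(fx$mask == 1L)
    expect_equal(
      ce_noncdr_loss(fx$trace, fx$tokens, fx$mask, fx$head),
      oracle_ce(fx$trace$per_layer_feats, 1:N, non, fx$tokens[non], fx$head),
      tolerance = 1e-10)
    expect_equal(
      ce_cdr_loss(fx$trace, fx$tokens, fx$mask, fx$head),
      oracle_ce(fx$trace$per_layer_feats, (N - 3L):N, cdr, fx$tokens[cdr],
                fx$head),
      tolerance = 1e-10)
    # layer-range semantics: zeroing features outside each range changes nothing
    tr_z <- fx$trace
    for (k in 1:(N - 4L)) tr_z$per_layer_feats[[k]][] <- 0
    expect_equal(ce_cdr_loss(tr_z, fx$tokens, fx$mask, fx$head),
                 ce_cdr_loss(fx$trace, fx$tokens, fx$mask, fx$head))
    tr_z2 <- fx$trace
    for (k in 1:4) tr_z2$per_layer_coords[[k]][] <- 99
    expect_equal(repulsion_loss(tr_z2, fx$mask),
                 repulsion_loss(fx$trace, fx$mask))
    expect_equal(neighbor_loss(tr_z2, fx$truth, fx$mask),
                 neighbor_loss(fx$trace, fx$truth, fx$mask))
  }
})

test_that("total-loss composition identities hold exactly", {
  parts <- list(l_rmsd = 0.3, l_repulsion = 0.5, l_neighbor = 0.2,
                l_ce_cdr = 1.2, l_ce_noncdr = 0.8)
  expect_equal(total_loss(parts), 10 * 1.0 + 2.0)
  parts0 <- list(l_rmsd = 0, l_repulsion = 0, l_neighbor = 0,
                 l_ce_cdr = 0, l_ce_noncdr = 0)
  expect_identical(total_loss(parts0), 0)

  pr <- toy_pair(seed = 31)
  cfg <- tiny_config()
  s <- prepare_sample(pr, cfg)
  p <- init_params(cfg, seed = 13)
  lb <- loss_breakdown(egnn_forward(s, p, cfg), s, p)
  expect_identical(lb$l_structure, lb$l_rmsd + lb$l_repulsion + lb$l_neighbor)
  expect_identical(lb$l_total, 10 * lb$l_structure + lb$l_ce_total)
})

test_that("structural losses are invariant under joint rigid transforms", {
  for (seed in 22:24) {
    fx <- rand_trace_fixture(L = 12, ncdr = 4, n_layers = 6, seed = seed)
    rigid <- rand_rigid(seed + 100)
    tr2 <- fx$trace
    tr2$per_layer_coords <- lapply(tr2$per_layer_coords, apply_rigid,
                                   tr = rigid)
    truth2 <- apply_rigid(fx$truth, rigid)
    expect_equal(rmsd_loss(tr2, truth2, fx$mask),
                 rmsd_loss(fx$trace, fx$truth, fx$mask), tolerance = 1e-6)
    expect_equal(repulsion_loss(tr2, fx$mask),
                 repulsion_loss(fx$trace, fx$mask), tolerance = 1e-6)
    expect_equal(neighbor_loss(tr2, truth2, fx$mask),
                 neighbor_loss(fx$trace, fx$truth, fx$mask),
                 tolerance = 1e-6)
  }
})
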