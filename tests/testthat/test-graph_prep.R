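test_that("context selection keeps antigen residues by distance threshold", {
  # design chain along x, antigen residues at known distances
  des <- make_chain(5, "H", "heavy")
  ag <- chain_record("A", "antigen", data.frame(
    res_number = 1:3, icode = "",
    aa = c("A", "C", "D"),
    x = c(3.8, 3.8, 3.8),
    y = c(20.0, 16.0, 4.0), z = 0, stringsAsFactors = FALSE))
  cx <- complex_record("t", list(des, ag))
  ctx <- select_context(cx, "H", cutoff = 16)
  kept <- ctx$chains$A$residues
  expect_equal(kept$aa, c("C", "D"))  # 20.0 excluded, 16.0 included (<=)
  expect_error(select_context(cx, "A"), "antibody")
})

test_that("context selection matches a brute-force all-pairs oracle", {
  pr <- toy_pair(seed = 13)
  cx <- pr$complex
  ctx <- select_context(cx, "H", cutoff = 16)
  dxyz <- as.matrix(cx$chains$H$residues[, c("x", "y", "z")])
  axyz <- as.matrix(cx$chains$A$residues[, c("x", "y", "z")])
  keep <- logical(nrow(axyz))
  for (i in seq_len(nrow(axyz))) {
    dmin <- Inf
    for (j in seq_len(nrow(dxyz)))
      dmin <- min(dmin, sqrt(sum((axyz[i, ] - dxyz[j, ])^2)))
    keep[i] <- dmin <= 16
  }
  got <- if (is.null(ctx$chains$A)) integer() else
    ctx$chains$A$residues$res_number
  expect_equal(got, cx$chains$A$residues$res_number[keep])
  # partner antibody chain kept in full
  expect_equal(nrow(ctx$chains$L$residues), nrow(cx$chains$L$residues))
})

test_that("anchor-line masking reproduces closed-form evenly spaced points", {
  s <- list(coords = rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2),
                           c(3, 3, 3), c(4, 0, 0)),
            seq_tokens = rep(1L, 5), mask = integer(5),
            truth_coords = rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2),
                                 c(3, 3, 3), c(4, 0, 0)))
  s$coords[1, ] <- c(0, 0, 0); s$coords[5, ] <- c(4, 0, 0)
  out <- mask_cdr(s, 2:4)
  expect_equal(out$coords[2:4, ], rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)))
  expect_equal(out$seq_tokens[2:4], rep(MASK_TOKEN, 3))
  # anchors and truth untouched
  expect_equal(out$coords[c(1, 5), ], s$coords[c(1, 5), ])
  expect_equal(out$truth_coords, s$truth_coords)

  # n = 1: midpoint
  s1 <- list(coords = rbind(c(0, 0, 0), c(9, 9, 9), c(1, 2, 3)),
             seq_tokens = rep(1L, 3), mask = integer(3),
             truth_coords = matrix(0, 3, 3))
  out1 <- mask_cdr(s1, 2L)
  expect_equal(out1$coords[2, ], (c(0, 0, 0) + c(1, 2, 3)) / 2)

  # coincident anchors: all masked points collapse onto the anchor
  s2 <- s1
  s2$coords[3, ] <- c(0, 0, 0)
  out2 <- mask_cdr(s2, 2L)
  expect_equal(out2$coords[2, ], c(0, 0, 0))

  # missing anchor
  expect_error(mask_cdr(s1, 1L), "anchor")
})

test_that("masked coordinates are interior affine combinations of anchors", {
  pr <- toy_pair(seed = 21)
  s <- prepare_sample(pr, tiny_config())
  rows <- which(s$mask == 1L)
  a <- s$coords[rows[1] - 1L, ]; b <- s$coords[rows[length(rows)] + 1L, ]
  for (i in seq_along(rows)) {
    w <- i / (length(rows) + 1)
    expect_equal(s$coords[rows[i], ], a + w * (b - a), tolerance = 1e-6)
    expect_gt(w, 0); expect_lt(w, 1)
  }
})

test_that("knn edges: geometry, clamping and brute-force agreement", {
  # five collinear equispaced points, k = 2: interior nodes connect to
  # their two adjacent points
  pts <- cbind(1:5 * 2.0, 0, 0)
  e <- build_knn_edges(pts, 2L)
  nb <- function(i) sort(e[e[, "dst"] == i, "src"])
  expect_equal(nb(2L), c(1L, 3L))
  expect_equal(nb(3L), c(2L, 4L))
  expect_equal(nb(4L), c(3L, 5L))

  # L = 10 < 65: complete digraph minus self loops
  set.seed(1)
  p10 <- matrix(rnorm(30), 10, 3)
  e10 <- build_knn_edges(p10, 64L)
  expect_equal(nrow(e10), 10L * 9L)
  expect_true(all(e10[, "src"] != e10[, "dst"]))
  expect_equal(as.integer(table(e10[, "dst"])), rep(9L, 10))

  # random cloud vs exhaustive-sort oracle
  set.seed(42)
  cloud <- matrix(rnorm(300, sd = 5), 100, 3)
  ek <- build_knn_edges(cloud, 8L)
  for (i in c(1L, 17L, 50L, 100L)) {
    d <- sqrt(colSums((t(cloud) - cloud[i, ])^2))
    d[i] <- Inf
    expected <- order(d, seq_len(100))[1:8]
    expect_setequal(ek[ek[, "dst"] == i, "src"], expected)
  }
  expect_error(build_knn_edges(cloud[1, , drop = FALSE], 4L), "degenerate")
})

test_that("edge construction is permutation-consistent", {
  set.seed(8)
  pts <- matrix(rnorm(60), 20, 3)
  e <- build_knn_edges(pts, 5L)
  perm <- sample(20L)
  e2 <- build_knn_edges(pts[perm, , drop = FALSE], 5L)
  # edge (src, dst) in original must appear as (pos(src), pos(dst))
  pos <- order(perm)  # pos[i] = row of original node i after permutation
  mapped <- cbind(pos[e[, "src"]], pos[e[, "dst"]])
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_equal(key(mapped), key(e2))
})

test_that("encode_sample concatenates chains and satisfies its invariants", {
  pr <- toy_pair(seed = 33)
  ctx <- select_context(pr$complex, "H")
  s <- encode_sample(ctx, pr$spec, k_neighbors = 12L)
  nH <- nrow(ctx$chains$H$residues)
  nL <- nrow(ctx$chains$L$residues)
  nA <- nrow(ctx$chains$A$residues)
  expect_equal(nrow(s$coords), nH + nL + nA)
  expect_equal(s$chain_type, c(rep(0L, nH + nL), rep(1L, nA)))
  # masked rows carry MASK tokens; unmasked rows keep truth coords
  expect_true(all(s$seq_tokens[s$mask == 1L] == MASK_TOKEN))
  expect_identical(s$coords[s$mask == 0L, ], s$truth_coords[s$mask == 0L, ])
  expect_false(any(s$edges[, "src"] == s$edges[, "dst"]))
  # deterministic re-encoding
  s2 <- encode_sample(ctx, pr$spec, k_neighbors = 12L)
  expect_identical(s, s2)
})
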