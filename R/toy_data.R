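#' Specification for synthetic antibody-like toy complexes
#'
#' The generator builds desk-scale complexes with learnable structure:
#' the design (heavy) chain is an idealised C-alpha helix trace with
#' exact 3.8 Angstrom virtual bonds; its HCDR3 window is replaced by
#' one of \code{n_loop_classes} canonical loop geometries (equal-chord
#' circular arcs of class-specific length and bulge direction, echoing
#' the canonical-conformation clustering of real CDR loops); the loop
#' class — and with it the loop sequence — is a deterministic function
#' of the flanking framework residues (the "flank code"), which is
#' what makes sequence/structure recovery learnable. A light-chain
#' partner helix and a short antigen segment placed near the loop
#' (within the 16 Angstrom context, clash-free at 3 Angstrom) complete
#' the complex. Gaussian coordinate noise of \code{coord_noise_sigma}
#' is added last.
#'
#' @param n_complexes number of complexes in a dataset.
#' @param n_before,n_after framework residues before/after the loop on
#'   the design chain.
#' @param partner_len,antigen_len lengths of the partner and antigen
#'   chains.
#' @param len_range inclusive range of loop lengths across classes.
#' @param n_loop_classes number of canonical loop classes.
#' @param flank_code_len coding residues on each side of the loop.
#' @param coord_noise_sigma coordinate noise, Angstrom.
#' @param seed master seed; with the complex index it fully determines
#'   every complex.
#' @return object of class \code{toy_spec}.
#' @export
toy_spec <- function(n_complexes = 100L, n_before = 18L, n_after = 14L,
                     partner_len = 12L, antigen_len = 12L,
                     len_range = c(7L, 11L), n_loop_classes = 6L,
                     flank_code_len = 2L, coord_noise_sigma = 0.1,
                     seed = 1L) {
  stopifnot(n_before >= flank_code_len + 2L, n_after >= flank_code_len + 1L,
            len_range[1] >= 1L, len_range[2] >= len_range[1],
            len_range[2] <= 34L, n_loop_classes >= 1L,
            coord_noise_sigma >= 0)
  structure(list(n_complexes = as.integer(n_complexes),
                 n_before = as.integer(n_before),
                 n_after = as.integer(n_after),
                 partner_len = as.integer(partner_len),
                 antigen_len = as.integer(antigen_len),
                 len_range = as.integer(len_range),
                 n_loop_classes = as.integer(n_loop_classes),
                 flank_code_len = as.integer(flank_code_len),
                 coord_noise_sigma = coord_noise_sigma,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

BOND <- 3.8  # idealised consecutive C-alpha distance, Angstrom

# idealised helix with exact BOND consecutive distance
helix_pt <- function(i, offset = c(0, 0, 0)) {
  rise <- 1.5; dphi <- 100 * pi / 180
  r <- sqrt(BOND^2 - rise^2) / (2 * sin(dphi / 2))
  cbind(rise * i, r * cos(i * dphi), r * sin(i * dphi)) +
    matrix(offset, length(i), 3, byrow = TRUE)
}

# n interior points on the circular arc from a to b with equal chords
# of length BOND, bulging toward unit direction w (orthogonal to b-a)
arc_points <- function(a, b, n, w) {
  D <- sqrt(sum((b - a)^2))
  if (D >= BOND * (n + 1)) stop("anchors too far apart for the loop length")
  e1 <- (b - a) / D
  w <- w - sum(w * e1) * e1
  w <- w / sqrt(sum(w * w))
  f <- function(th) D * sin(th / (2 * (n + 1))) - BOND * sin(th / 2)
  th <- stats::uniroot(f, c(1e-8, 2 * pi - 1e-8), tol = 1e-12)$root
  R <- D / (2 * sin(th / 2))
  mid <- (a + b) / 2
  ctr <- mid - w * R * cos(th / 2)
  phi <- -th / 2 + th * seq_len(n) / (n + 1)
  t(vapply(phi, function(p) ctr + R * (sin(p) * e1 + cos(p) * w),
           numeric(3)))
}

#' Canonical loop class table of a toy spec
#'
#' Deterministic in \code{spec$seed}: per class, the loop length,
#' the fixed loop sequence, the flank-code residue pair that selects
#' the class, and the bulge direction angle.
#'
#' @param spec a \code{\link{toy_spec}}.
#' @return data.frame with one row per class.
#' @export
toy_class_table <- function(spec) {
  set.seed(spec$seed)
  nl <- spec$n_loop_classes
  lens <- spec$len_range[1] +
    (seq_len(nl) - 1L) %% (spec$len_range[2] - spec$len_range[1] + 1L)
  codes <- sample.int(400L, nl)  # distinct flank pairs
  data.frame(
    class_id = seq_len(nl),
    loop_len = lens,
    loop_seq = vapply(lens, function(l)
      paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""),
      character(1)),
    code1 = AA_ALPHABET[(codes - 1L) %/% 20L + 1L],
    code2 = AA_ALPHABET[(codes - 1L) %% 20L + 1L],
    bulge_deg = seq(-45, 45, length.out = nl),
    gap_frac = seq(0.6, 0.85, length.out = nl),
    stringsAsFactors = FALSE)
}

# author numbering for a loop of length l in a 95..102 window with
# insertion codes at 100 (antibody-style heavy-CDR3 numbering)
loop_numbering <- function(l) {
  if (l <= 8L)
    return(data.frame(num = 94L + seq_len(l), icode = ""))
  nins <- l - 8L
  data.frame(num = c(95:100, rep(100L, nins), 101L, 102L),
             icode = c(rep("", 6L), LETTERS[seq_len(nins)], "", ""))
}

#' Generate one toy complex
#'
#' Fully reproducible from \code{(spec$seed, index)}.
#'
#' @param spec a \code{\link{toy_spec}}.
#' @param index complex index (1-based).
#' @param class_table optionally the precomputed
#'   \code{\link{toy_class_table}}.
#' @return a \code{\link{complex_record}} with chains H (heavy,
#'   design), L (light partner) and A (antigen); the attribute
#'   \code{"class_id"} records the loop class.
#' @export
make_toy_complex <- function(spec, index, class_table = toy_class_table(spec)) {
  set.seed((spec$seed * 100003L + index * 7919L) %% 2147483647L)
  cls <- sample.int(spec$n_loop_classes, 1L)
  info <- class_table[cls, ]
  l <- info$loop_len

  # design chain geometry: helix framework with an arc loop
  target_D <- info$gap_frac * BOND * (l + 1)
  cand <- 2:60
  gaps <- sqrt(rowSums((helix_pt(cand) -
                          helix_pt(rep(0, length(cand))))^2))
  g <- cand[which.min(abs(gaps - target_D))]
  ia <- spec$n_before - 1L            # helix index of start anchor
  ib <- ia + g                        # helix index of end anchor
  pre <- helix_pt(0:ia)
  post <- helix_pt(ib:(ib + spec$n_after - 1L))
  a <- pre[nrow(pre), ]; b <- post[1, ]
  psi <- info$bulge_deg * pi / 180
  # bulge direction in the plane orthogonal to the chain axis
  w0 <- c(0, cos(psi), sin(psi))
  loop <- arc_points(a, b, l, w0)
  des_xyz <- rbind(pre, loop, post)

  # sequence: random framework, class-coded flanks, class loop sequence
  n_des <- nrow(des_xyz)
  aa <- sample(AA_ALPHABET, n_des, replace = TRUE)
  loop_rows <- spec$n_before + seq_len(l)
  aa[loop_rows] <- strsplit(info$loop_seq, "")[[1]]
  fcl <- spec$flank_code_len
  code <- rep(c(info$code1, info$code2), length.out = fcl)
  aa[spec$n_before - fcl + seq_len(fcl)] <- code
  aa[spec$n_before + l + seq_len(fcl)] <- code

  num <- loop_numbering(l)
  des_res <- data.frame(
    res_number = c(95L - spec$n_before:1, num$num,
                   102L + seq_len(spec$n_after)),
    icode = c(rep("", spec$n_before), num$icode, rep("", spec$n_after)),
    aa = aa,
    x = des_xyz[, 1], y = des_xyz[, 2], z = des_xyz[, 3],
    stringsAsFactors = FALSE)

  # partner chain: parallel helix offset away from the bulge
  pidx <- seq(spec$n_before - spec$partner_len %/% 2L,
              length.out = spec$partner_len)
  par_xyz <- helix_pt(pidx, offset = c(0, -12, 0))
  par_res <- data.frame(res_number = seq_len(spec$partner_len), icode = "",
                        aa = sample(AA_ALPHABET, spec$partner_len, TRUE),
                        x = par_xyz[, 1], y = par_xyz[, 2], z = par_xyz[, 3],
                        stringsAsFactors = FALSE)

  # antigen: straight segment beyond the loop apex, facing the CDR
  apex <- loop[ceiling(l / 2), ]
  centroid <- colMeans(rbind(pre, post))
  outward <- apex - centroid
  outward <- outward / sqrt(sum(outward^2))
  e1 <- (b - a) / sqrt(sum((b - a)^2))
  offset <- 7
  repeat {
    ctr <- apex + outward * offset
    ag_xyz <- matrix(ctr, spec$antigen_len, 3, byrow = TRUE) +
      outer(BOND * (seq_len(spec$antigen_len) -
                      (spec$antigen_len + 1) / 2), e1)
    dmin <- min(apply(ag_xyz, 1L, function(p)
      sqrt(min(colSums((t(rbind(des_xyz, par_xyz)) - p)^2)))))
    if (dmin >= 3.0) break
    offset <- offset + 1
  }
  ag_res <- data.frame(res_number = seq_len(spec$antigen_len), icode = "",
                       aa = sample(AA_ALPHABET, spec$antigen_len, TRUE),
                       x = ag_xyz[, 1], y = ag_xyz[, 2], z = ag_xyz[, 3],
                       stringsAsFactors = FALSE)

  # observation noise
  if (spec$coord_noise_sigma > 0) {
    for (nm in c("des_res", "par_res", "ag_res")) {
      r <- get(nm)
      r[, c("x", "y", "z")] <- r[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(r), sd = spec$coord_noise_sigma),
               nrow(r), 3)
      assign(nm, r)
    }
  }

  cx <- complex_record(
    sprintf("toy%04d", index),
    list(chain_record("H", "heavy", des_res),
         chain_record("L", "light", par_res),
         chain_record("A", "antigen", ag_res)),
    pairing = c(H = "L"))
  attr(cx, "class_id") <- cls
  cx
}

#' Generate a toy dataset with its chain-role manifest
#'
#' @param spec a \code{\link{toy_spec}}.
#' @return list with \code{complexes} (list of
#'   \code{\link{complex_record}}), \code{manifest} (data.frame
#'   complex_id/chain_id/role) and \code{class_table}.
#' @export
make_toy_dataset <- function(spec) {
  tab <- toy_class_table(spec)
  complexes <- lapply(seq_len(spec$n_complexes), make_toy_complex,
                      spec = spec, class_table = tab)
  manifest <- do.call(rbind, lapply(complexes, function(cx) {
    data.frame(complex_id = cx$complex_id,
               chain_id = names(cx$chains),
               role = vapply(cx$chains, `[[`, character(1), "role"),
               stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  list(complexes = complexes, manifest = manifest, class_table = tab)
}
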