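#' Structure and sequence training losses
#'
#' The training objective combines three structure terms and two
#' label-smoothed cross-entropy terms, all attached layer-wise (local
#' loss):
#' \itemize{
#'   \item RMSD loss: mean over *all* layers of the CDR C-alpha RMSD
#'     against ground truth (fixed frame, no superposition — non-CDR
#'     coordinates are pinned by the coordinate mask, so the frames
#'     coincide).
#'   \item Repulsion loss: hinge penalty \code{max(tau - d_ij, 0)}
#'     over all CDR x non-CDR residue pairs, averaged per pair, for
#'     layers 5..N only, averaged over those N-4 layers;
#'     \code{tau = 4.2} Angstrom.
#'   \item Neighbour loss: mean absolute deviation of the N_CDR + 1
#'     consecutive C-alpha distances along anchor-CDR-anchor between
#'     prediction and truth, layers 5..N, averaged likewise.
#'   \item Cross-entropy: label-smoothed (0.1) 20-way CE of the shared
#'     feed-forward head applied to every layer's features — all
#'     layers for non-CDR rows, the last four layers for CDR rows.
#' }
#' The total is \code{10 * (rmsd + repulsion + neighbour) + (ce_cdr +
#' ce_noncdr)}.
#'
#' @name objectives
NULL

layer_cdr_rows <- function(mask) {
  rows <- which(mask == 1L)
  if (!length(rows)) stop("loss undefined: no CDR residues in mask")
  if (any(diff(rows) != 1L)) stop("CDR rows must be contiguous")
  rows
}

#' RMSD loss over all layers
#'
#' @param trace a \code{forward_trace}.
#' @param truth_coords L x 3 ground-truth coordinates.
#' @param mask 0/1 CDR mask.
#' @return scalar loss.
#' @rdname objectives
#' @export
rmsd_loss <- function(trace, truth_coords, mask) {
  rows <- layer_cdr_rows(mask)
  mean(vapply(trace$per_layer_coords, function(x) {
    dev <- x[rows, , drop = FALSE] - truth_coords[rows, , drop = FALSE]
    sqrt(mean(rowSums(dev * dev)))
  }, numeric(1)))
}

violation_layers <- function(n_layers) {
  if (n_layers >= 5L) 5L:n_layers else integer()
}

#' Repulsion (clash) loss, layers 5..N
#'
#' @param tau distance threshold in Angstrom.
#' @rdname objectives
#' @export
repulsion_loss <- function(trace, mask, tau = 4.2) {
  cdr <- layer_cdr_rows(mask)
  non <- which(mask == 0L)
  if (!length(non)) stop("loss undefined: no non-CDR residues")
  ks <- violation_layers(length(trace$per_layer_coords))
  if (!length(ks)) return(0)
  mean(vapply(ks, function(k) {
    x <- trace$per_layer_coords[[k]]
    a <- x[cdr, , drop = FALSE]; b <- x[non, , drop = FALSE]
    d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
    d <- sqrt(pmax(d2, 0))
    mean(pmax(tau - d, 0))
  }, numeric(1)))
}

#' Neighbour (consecutive-distance) loss, layers 5..N
#'
#' @rdname objectives
#' @export
neighbor_loss <- function(trace, truth_coords, mask) {
  cdr <- layer_cdr_rows(mask)
  path <- c(cdr[1] - 1L, cdr, cdr[length(cdr)] + 1L)
  if (path[1] < 1L || path[length(path)] > nrow(truth_coords))
    stop("anchor residue missing for neighbor loss")
  dt <- sqrt(rowSums((truth_coords[path[-1], , drop = FALSE] -
                        truth_coords[path[-length(path)], , drop = FALSE])^2))
  ks <- violation_layers(length(trace$per_layer_coords))
  if (!length(ks)) return(0)
  mean(vapply(ks, function(k) {
    x <- trace$per_layer_coords[[k]]
    dp <- sqrt(rowSums((x[path[-1], , drop = FALSE] -
                          x[path[-length(path)], , drop = FALSE])^2))
    mean(abs(dp - dt))
  }, numeric(1)))
}

smoothed_targets <- function(tokens, smoothing) {
  Q <- matrix(smoothing / 20, length(tokens), 20)
  Q[cbind(seq_along(tokens), tokens)] <- 1 - smoothing + smoothing / 20
  Q
}

log_softmax <- function(Z) {
  m <- apply(Z, 1L, max)
  Zs <- Z - m
  Zs - log(rowSums(exp(Zs)))
}

ce_rows <- function(feats, rows, tokens, head_params, smoothing) {
  logits <- head_forward(feats[rows, , drop = FALSE], head_params)
  Q <- smoothed_targets(tokens, smoothing)
  -mean(rowSums(Q * log_softmax(logits)))
}

#' Label-smoothed cross-entropy on non-CDR rows, all layers
#'
#' Rows whose true amino acid is unknown are skipped (no truth token
#' exists in the 20-way alphabet).
#'
#' @param truth_tokens integer truth tokens (1..20, NA for unknown).
#' @param head_params the shared feed-forward head parameters.
#' @param smoothing label-smoothing weight.
#' @rdname objectives
#' @export
ce_noncdr_loss <- function(trace, truth_tokens, mask, head_params,
                           smoothing = 0.1) {
  rows <- which(mask == 0L & !is.na(truth_tokens))
  if (!length(rows)) return(0)
  toks <- truth_tokens[rows]
  mean(vapply(trace$per_layer_feats, ce_rows, numeric(1),
              rows = rows, tokens = toks, head_params = head_params,
              smoothing = smoothing))
}

#' Label-smoothed cross-entropy on CDR rows, last four layers
#'
#' @rdname objectives
#' @export
ce_cdr_loss <- function(trace, truth_tokens, mask, head_params,
                        smoothing = 0.1) {
  N <- length(trace$per_layer_feats)
  stopifnot(N >= 4L)
  rows <- layer_cdr_rows(mask)
  toks <- truth_tokens[rows]
  if (any(is.na(toks))) stop("CDR truth tokens must be canonical")
  mean(vapply((N - 3L):N, function(k)
    ce_rows(trace$per_layer_feats[[k]], rows, toks, head_params,
            smoothing), numeric(1)))
}

#' Total loss from a breakdown
#'
#' \code{10 * l_structure + l_ce_total} with
#' \code{l_structure = l_rmsd + l_repulsion + l_neighbor} and
#' \code{l_ce_total = l_ce_cdr + l_ce_noncdr}.
#'
#' @param parts a \code{loss_breakdown} (or any list with the five
#'   term fields).
#' @param struct_weight weight on the structure term (default 10).
#' @rdname objectives
#' @export
total_loss <- function(parts, struct_weight = 10) {
  struct_weight * (parts$l_rmsd + parts$l_repulsion + parts$l_neighbor) +
    (parts$l_ce_cdr + parts$l_ce_noncdr)
}

#' Full loss breakdown for one sample
#'
#' @param trace forward trace for the sample.
#' @param sample the \code{graph_sample}.
#' @param params model parameters (for the shared head).
#' @param tau repulsion threshold.
#' @param smoothing label smoothing.
#' @param struct_weight structure-loss weight.
#' @return object of class \code{loss_breakdown}.
#' @rdname objectives
#' @export
loss_breakdown <- function(trace, sample, params, tau = 4.2,
                           smoothing = 0.1, struct_weight = 10) {
  parts <- list(
    l_rmsd = rmsd_loss(trace, sample$truth_coords, sample$mask),
    l_repulsion = repulsion_loss(trace, sample$mask, tau = tau),
    l_neighbor = neighbor_loss(trace, sample$truth_coords, sample$mask),
    l_ce_cdr = ce_cdr_loss(trace, sample$truth_tokens, sample$mask,
                           params$head, smoothing = smoothing),
    l_ce_noncdr = ce_noncdr_loss(trace, sample$truth_tokens, sample$mask,
                                 params$head, smoothing = smoothing))
  parts$l_structure <- parts$l_rmsd + parts$l_repulsion + parts$l_neighbor
  parts$l_ce_total <- parts$l_ce_cdr + parts$l_ce_noncdr
  parts$l_total <- total_loss(parts, struct_weight)
  class(parts) <- "loss_breakdown"
  parts
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<loss_breakdown> total=%.4f  rmsd=%.4f  rep=%.4f",
                     "  nei=%.4f  ce_cdr=%.4f  ce_noncdr=%.4f\n"),
              x$l_total, x$l_rmsd, x$l_repulsion, x$l_neighbor,
              x$l_ce_cdr, x$l_ce_noncdr))
  invisible(x)
}
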