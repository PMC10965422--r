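#' Restrict a complex to the modelling context of one design chain
#'
#' Keeps (a) the design chain in full, (b) its partner antibody chain
#' in full when a pairing exists, and (c) only those antigen residues
#' whose minimum C-alpha distance to any design-chain C-alpha is at or
#' below \code{cutoff} (inclusive boundary). Antigen chains left with
#' no residues are dropped.
#'
#' @param complex a \code{\link{complex_record}}.
#' @param design_chain id of the antibody chain to be designed.
#' @param cutoff distance threshold in Angstrom (default 16).
#' @return a reduced \code{\link{complex_record}} whose chains are
#'   ordered design chain first, then the partner, then antigens.
#' @export
select_context <- function(complex, design_chain, cutoff = 16) {
  dch <- get_chain(complex, design_chain)
  if (!dch$role %in% c("heavy", "light"))
    stop("design chain must be an antibody chain, got role '",
         dch$role, "'")
  partner_id <- partner_of(complex, design_chain)
  dxyz <- chain_coords(dch)
  keep <- list(dch)
  if (!is.null(partner_id)) keep <- c(keep, list(get_chain(complex, partner_id)))
  for (ch in complex$chains) {
    if (ch$role != "antigen") next
    axyz <- chain_coords(ch)
    dmin <- apply(axyz, 1L, function(p)
      sqrt(min(colSums((t(dxyz) - p)^2))))
    sel <- dmin <= cutoff
    if (!any(sel)) next
    keep <- c(keep, list(chain_record(ch$chain_id, ch$role,
                                      ch$residues[sel, , drop = FALSE])))
  }
  structure(list(complex_id = complex$complex_id, chains =
                   stats::setNames(keep, vapply(keep, `[[`, character(1),
                                                "chain_id")),
                 pairing = complex$pairing),
            class = "complex_record")
}

partner_of <- function(complex, chain_id) {
  p <- complex$pairing
  if (!length(p)) return(NULL)
  if (chain_id %in% names(p)) return(unname(p[chain_id]))
  if (chain_id %in% p) return(names(p)[match(chain_id, p)])
  NULL
}

#' Place masked CDR coordinates on the anchor line
#'
#' Applies the masked-loop initialisation to a graph sample: the i-th
#' of n CDR residues is placed at \code{a + (b - a) * i / (n + 1)}
#' where \code{a}, \code{b} are the anchor C-alpha positions
#' (anchors themselves excluded from the spacing), and CDR sequence
#' tokens are replaced by the MASK token. Ground-truth fields are left
#' untouched; rows outside the CDR are not modified.
#'
#' @param sample a graph sample under construction (see
#'   \code{\link{encode_sample}}).
#' @param cdr_rows integer row indices of the CDR residues (contiguous).
#' @return the modified sample.
#' @export
mask_cdr <- function(sample, cdr_rows) {
  n <- length(cdr_rows)
  stopifnot(n >= 1L, all(diff(cdr_rows) == 1L))
  a_row <- cdr_rows[1] - 1L
  b_row <- cdr_rows[n] + 1L
  if (a_row < 1L || b_row > nrow(sample$coords))
    stop("anchor residue missing from sample")
  a <- sample$coords[a_row, ]
  b <- sample$coords[b_row, ]
  frac <- seq_len(n) / (n + 1)
  sample$coords[cdr_rows, ] <- matrix(a, n, 3, byrow = TRUE) +
    outer(frac, b - a)
  sample$seq_tokens[cdr_rows] <- MASK_TOKEN
  sample$mask[cdr_rows] <- 1L
  sample
}

#' Build a k-nearest-neighbour directed edge list
#'
#' For each node, adds directed edges from its
#' \code{min(k_neighbors, L - 1)} nearest other nodes (Euclidean
#' distance); ties are broken by the lower node index, making the
#' result deterministic. No self edges.
#'
#' @param coords numeric L x 3 matrix.
#' @param k_neighbors neighbours per node (default 64).
#' @return integer matrix with columns \code{src}, \code{dst}; messages
#'   flow src -> dst.
#' @export
build_knn_edges <- function(coords, k_neighbors = 64L) {
  L <- nrow(coords)
  if (is.null(L) || L < 2L) stop("degenerate graph: need at least 2 nodes")
  k <- min(k_neighbors, L - 1L)
  d <- as.matrix(stats::dist(coords))
  src <- integer(L * k)
  for (i in seq_len(L)) {
    ord <- order(d[i, ], seq_len(L))
    ord <- ord[ord != i][seq_len(k)]
    src[((i - 1L) * k + 1L):(i * k)] <- ord
  }
  cbind(src = src, dst = rep(seq_len(L), each = k))
}

#' Encode a (complex, CDR) pair as a model-ready graph sample
#'
#' Concatenates chains design-chain-first (then partner, then antigen)
#' into flat arrays: C-alpha coordinates, sequence tokens (1..20
#' canonical, 21 = MASK), chain-type labels (0 antibody / 1 antigen)
#' and the CDR mask vector. CDR coordinates are replaced by the
#' anchor-line initialisation and CDR tokens by MASK
#' (\code{\link{mask_cdr}}); ground truth is retained alongside.
#' Edges are built once on the masked coordinates. Unknown residues
#' outside the CDR are encoded with the MASK embedding and carry
#' \code{NA} truth tokens.
#'
#' @param context a \code{\link{complex_record}} from
#'   \code{\link{select_context}}.
#' @param spec the \code{\link{cdr_spec}} to design (on the first,
#'   design chain of \code{context}).
#' @param k_neighbors neighbours for \code{\link{build_knn_edges}}.
#' @return object of class \code{graph_sample} with fields
#'   \code{coords}, \code{seq_tokens}, \code{chain_type}, \code{mask},
#'   \code{edges}, \code{truth_coords}, \code{truth_tokens},
#'   \code{index_map}.
#' @export
encode_sample <- function(context, spec, k_neighbors = 64L) {
  chains <- context$chains
  if (chains[[1]]$chain_id != spec$chain_id)
    stop("first context chain must be the design chain of spec")
  coords <- do.call(rbind, lapply(chains, chain_coords))
  dimnames(coords) <- NULL
  aa <- unlist(lapply(chains, function(ch) ch$residues$aa),
               use.names = FALSE)
  type <- unlist(lapply(chains, function(ch)
    rep(if (ch$role == "antigen") 1L else 0L, nrow(ch$residues))),
    use.names = FALSE)
  index_map <- do.call(rbind, lapply(chains, function(ch)
    data.frame(chain_id = ch$chain_id,
               seq_idx = seq_len(nrow(ch$residues)),
               stringsAsFactors = FALSE)))
  rownames(index_map) <- NULL
  truth_tokens <- aa_to_token(aa)
  seq_tokens <- truth_tokens
  seq_tokens[is.na(seq_tokens)] <- MASK_TOKEN
  sample <- structure(list(
    coords = coords,
    seq_tokens = seq_tokens,
    chain_type = type,
    mask = integer(nrow(coords)),
    edges = NULL,
    truth_coords = coords,
    truth_tokens = truth_tokens,
    index_map = index_map), class = "graph_sample")
  # CDR rows: design chain occupies the first block
  cdr_rows <- spec$start_idx:spec$end_idx
  sample <- mask_cdr(sample, cdr_rows)
  sample$edges <- build_knn_edges(sample$coords, k_neighbors)
  sample
}

#' @export
print.graph_sample <- function(x, ...) {
  cat(sprintf("<graph_sample> L=%d, %d CDR residues, %d edges\n",
              nrow(x$coords), sum(x$mask), nrow(x$edges)))
  invisible(x)
}
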