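#' CDR specification
#'
#' Describes one CDR instance on a chain by sequential residue indices
#' (1-based, inclusive). The residues at \code{start_idx - 1} and
#' \code{end_idx + 1} are the anchor residues; both must exist on the
#' chain. \code{shift} records the anchor displacement
#' \code{(delta_start, delta_end)} relative to the scheme-defined CDR,
#' \code{c(0, 0)} for an unaugmented CDR.
#'
#' @param chain_id chain the CDR lives on.
#' @param cdr_name one of HCDR1..3, LCDR1..3.
#' @param start_idx,end_idx first/last CDR residue (sequential index,
#'   1-based, inclusive).
#' @param scheme numbering scheme that produced the window
#'   (\code{"chothia"}, \code{"imgt"}, \code{"north"} or
#'   \code{"augmented"}).
#' @param shift integer pair \code{(delta_start, delta_end)}.
#' @param chain_len chain length, used to validate bounds when known.
#' @return object of class \code{cdr_spec}.
#' @export
cdr_spec <- function(chain_id, cdr_name, start_idx, end_idx,
                     scheme = "chothia", shift = c(0L, 0L),
                     chain_len = NULL) {
  cdr_name <- match.arg(cdr_name, CDR_NAMES)
  start_idx <- as.integer(start_idx); end_idx <- as.integer(end_idx)
  if (start_idx > end_idx) stop("start_idx must be <= end_idx")
  if (start_idx - 1L < 1L)
    stop("start anchor missing: CDR begins at the chain terminus")
  if (!is.null(chain_len) && end_idx + 1L > chain_len)
    stop("end anchor missing: CDR ends at the chain terminus")
  structure(list(chain_id = chain_id, cdr_name = cdr_name,
                 start_idx = start_idx, end_idx = end_idx,
                 scheme = scheme, shift = as.integer(shift)),
            class = "cdr_spec")
}

#' @rdname cdr_spec
#' @export
CDR_NAMES <- c("HCDR1", "HCDR2", "HCDR3", "LCDR1", "LCDR2", "LCDR3")

#' Default CDR definition table
#'
#' Author-numbering ranges per (scheme, CDR). Ships the community
#' Chothia loop definitions (H1 26-32, H2 52-56, H3 95-102, L1 24-34,
#' L2 50-56, L3 89-97) and the IMGT definitions (H1 27-38, H2 56-65,
#' H3 105-117, same for light chains). The table is an ordinary
#' data.frame and can be replaced or extended by the user.
#'
#' @return data.frame with columns \code{scheme}, \code{cdr_name},
#'   \code{start_num}, \code{end_num}.
#' @export
default_cdr_table <- function() {
  rbind(
    data.frame(scheme = "chothia",
               cdr_name = c("HCDR1", "HCDR2", "HCDR3",
                            "LCDR1", "LCDR2", "LCDR3"),
               start_num = c(26L, 52L, 95L, 24L, 50L, 89L),
               end_num   = c(32L, 56L, 102L, 34L, 56L, 97L),
               stringsAsFactors = FALSE),
    data.frame(scheme = "imgt",
               cdr_name = c("HCDR1", "HCDR2", "HCDR3",
                            "LCDR1", "LCDR2", "LCDR3"),
               start_num = c(27L, 56L, 105L, 27L, 56L, 105L),
               end_num   = c(38L, 65L, 117L, 38L, 65L, 117L),
               stringsAsFactors = FALSE)
  )
}

#' Locate a CDR on a chain under a numbering scheme
#'
#' Selects the residues whose author numbering falls inside the
#' scheme's range for the requested CDR (insertion-coded residues
#' within the range included) and returns the corresponding sequential
#' window as a \code{\link{cdr_spec}} with shift \code{(0, 0)}.
#'
#' @param chain a chain record carrying scheme-consistent author
#'   numbering.
#' @param cdr_name CDR name; must be compatible with the chain role
#'   (HCDR* on heavy chains, LCDR* on light chains).
#' @param scheme numbering scheme to look up in \code{table}.
#' @param table CDR definition table (see \code{\link{default_cdr_table}}).
#' @return a \code{\link{cdr_spec}}.
#' @export
locate_cdr <- function(chain, cdr_name, scheme = "chothia",
                       table = default_cdr_table()) {
  cdr_name <- match.arg(cdr_name, CDR_NAMES)
  want_role <- if (startsWith(cdr_name, "H")) "heavy" else "light"
  if (chain$role != want_role)
    stop(cdr_name, " requested on a ", chain$role, " chain")
  row <- table[table$scheme == scheme & table$cdr_name == cdr_name, ]
  if (nrow(row) != 1L)
    stop("no definition for (", scheme, ", ", cdr_name, ") in table")
  num <- chain$residues$res_number
  inside <- num >= row$start_num & num <= row$end_num
  if (!any(inside))
    stop("no residues of chain ", chain$chain_id,
         " fall in the ", scheme, " ", cdr_name, " range")
  idx <- which(inside)
  n <- nrow(chain$residues)
  if (min(idx) - 1L < 1L || max(idx) + 1L > n)
    stop("CDR at chain terminus: anchor residue missing")
  cdr_spec(chain$chain_id, cdr_name, min(idx), max(idx),
           scheme = scheme, shift = c(0L, 0L), chain_len = n)
}

#' Generate anchor-shifted augmented CDR variants
#'
#' The flexible-CDR augmentation: every combination of start- and
#' end-anchor displacements \code{(delta_start, delta_end)} in
#' \code{[-k, k]^2} is applied to the base window. A variant is kept
#' when the shifted window is non-empty and both shifted anchors still
#' exist on the chain. For an interior CDR (no clamping) this yields
#' exactly \code{(2k + 1)^2} variants; the unshifted base is always
#' among them. Output is deterministic, ordered by
#' \code{(delta_start, delta_end)}, and duplicate-free.
#'
#' @param base an unaugmented \code{\link{cdr_spec}}.
#' @param k non-negative anchor-shift threshold (the study default is 5).
#' @param chain_len length of the chain the CDR lives on.
#' @return list of \code{\link{cdr_spec}} objects with
#'   \code{scheme = "augmented"} (the base keeps its scheme).
#' @export
augment_anchors <- function(base, k = 5L, chain_len) {
  stopifnot(inherits(base, "cdr_spec"), k >= 0L)
  if (any(base$shift != 0L)) stop("base must be an unaugmented cdr_spec")
  k <- as.integer(k)
  out <- list()
  for (ds in (-k):k) {
    s <- base$start_idx + ds
    for (de in (-k):k) {
      e <- base$end_idx + de
      if (s > e) next
      if (s - 1L < 1L || e + 1L > chain_len) next
      scheme <- if (ds == 0L && de == 0L) base$scheme else "augmented"
      out[[length(out) + 1L]] <-
        cdr_spec(base$chain_id, base$cdr_name, s, e, scheme = scheme,
                 shift = c(ds, de), chain_len = chain_len)
    }
  }
  out
}

#' Amino-acid sequence of a CDR window
#'
#' @param chain chain record.
#' @param spec \code{\link{cdr_spec}} within the chain.
#' @return character scalar of one-letter codes, length
#'   \code{end_idx - start_idx + 1}.
#' @export
cdr_sequence <- function(chain, spec) {
  n <- nrow(chain$residues)
  if (spec$start_idx < 1L || spec$end_idx > n)
    stop("cdr_spec out of chain bounds")
  paste(chain$residues$aa[spec$start_idx:spec$end_idx], collapse = "")
}

# Needleman-Wunsch global identity (matches / aligned length),
# BLOSUM62-scored alignment
nw_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Build an augmented (CDR, complex) training dataset
#'
#' For every complex, locates each requested CDR on each compatible
#' chain, keeps those passing \code{\link{check_cdr_completeness}},
#' expands them via \code{\link{augment_anchors}}, and removes pairs
#' whose CDR sequence is identical to any sequence in
#' \code{test_cdr_sequences}. When \code{similarity_threshold} is
#' given, pairs whose Needleman-Wunsch global identity to any test
#' sequence is at or above the threshold are removed as well (the
#' strict split).
#'
#' @param complexes list of \code{\link{complex_record}} objects.
#' @param table CDR definition table.
#' @param k anchor-shift threshold.
#' @param test_cdr_sequences character vector of held-out CDR
#'   sequences; may be empty.
#' @param similarity_threshold optional identity fraction in (0, 1].
#' @param scheme numbering scheme used to locate CDRs.
#' @param cdr_names which CDR types to harvest.
#' @return list of pairs, each \code{list(spec =, complex =)}; the
#'   attribute \code{"manifest"} carries a data.frame
#'   (complex_id, chain_id, cdr_name, delta_start, delta_end, sequence).
#' @export
build_pair_dataset <- function(complexes, table = default_cdr_table(),
                               k = 5L, test_cdr_sequences = character(),
                               similarity_threshold = NULL,
                               scheme = "chothia",
                               cdr_names = CDR_NAMES) {
  pairs <- list()
  man <- list()
  test_cdr_sequences <- unique(test_cdr_sequences)
  for (cx in complexes) {
    for (ch in cx$chains) {
      if (!ch$role %in% c("heavy", "light")) next
      compat <- cdr_names[startsWith(cdr_names,
                                     if (ch$role == "heavy") "H" else "L")]
      for (nm in compat) {
        base <- tryCatch(locate_cdr(ch, nm, scheme, table),
                         error = function(e) NULL)
        if (is.null(base)) next
        if (!check_cdr_completeness(cx, base)) next
        for (v in augment_anchors(base, k, nrow(ch$residues))) {
          sq <- cdr_sequence(ch, v)
          if (sq %in% test_cdr_sequences) next
          if (!is.null(similarity_threshold) &&
              length(test_cdr_sequences) &&
              any(vapply(test_cdr_sequences, nw_identity, numeric(1),
                         a = sq) >= similarity_threshold)) next
          pairs[[length(pairs) + 1L]] <- list(spec = v, complex = cx)
          man[[length(man) + 1L]] <-
            data.frame(complex_id = cx$complex_id, chain_id = ch$chain_id,
                       cdr_name = nm, delta_start = v$shift[1],
                       delta_end = v$shift[2], sequence = sq,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(pairs)) warning("empty dataset after filtering")
  manifest <- if (length(man)) do.call(rbind, man) else
    data.frame(complex_id = character(), chain_id = character(),
               cdr_name = character(), delta_start = integer(),
               delta_end = integer(), sequence = character())
  attr(pairs, "manifest") <- manifest
  pairs
}

#' Write a dataset manifest as tab-separated text
#'
#' @param pairs result of \code{\link{build_pair_dataset}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pair_manifest <- function(pairs, path) {
  utils::write.table(attr(pairs, "manifest"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
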