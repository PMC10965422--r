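#' Residue-level antibody-antigen complex structures
#'
#' The package represents a complex at C-alpha resolution. A chain is a
#' list with elements \code{chain_id}, \code{role} (one of
#' \code{"heavy"}, \code{"light"}, \code{"antigen"}) and \code{residues},
#' a data.frame with one row per residue holding the author residue
#' number, insertion code (\code{""} when absent), one-letter amino acid
#' (\code{"X"} for non-canonical) and the C-alpha coordinates in Angstrom.
#' Row order is the order of appearance in the source file; the row index
#' is the *sequential index* used by every downstream module. A complex
#' bundles chains with an optional heavy-to-light pairing.
#'
#' @param complex_id identifier for the complex.
#' @param chains named or unnamed list of chain records.
#' @param pairing named character vector mapping heavy chain ids to their
#'   light-chain partner ids; may be empty.
#' @return an object of class \code{complex_record}.
#' @export
complex_record <- function(complex_id, chains, pairing = character()) {
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids)) stop("chain ids must be unique")
  names(chains) <- ids
  roles <- vapply(chains, function(ch) ch$role, character(1))
  if (!any(roles %in% c("heavy", "light")) || !any(roles == "antigen"))
    warning("complex lacks an antibody chain or an antigen chain")
  structure(list(complex_id = complex_id, chains = chains,
                 pairing = pairing),
            class = "complex_record")
}

#' @rdname complex_record
#' @param chain_id chain identifier from the source structure.
#' @param role chain role: \code{"heavy"}, \code{"light"} or \code{"antigen"}.
#' @param residues residue data.frame (columns \code{res_number},
#'   \code{icode}, \code{aa}, \code{x}, \code{y}, \code{z}).
#' @export
chain_record <- function(chain_id, role, residues) {
  role <- match.arg(role, c("heavy", "light", "antigen"))
  stopifnot(is.data.frame(residues),
            all(c("res_number", "icode", "aa", "x", "y", "z") %in%
                  names(residues)))
  key <- paste(residues$res_number, residues$icode)
  if (anyDuplicated(key))
    stop("duplicate (res_number, insertion_code) within chain ", chain_id)
  if (!all(is.finite(as.matrix(residues[, c("x", "y", "z")]))))
    stop("non-finite C-alpha coordinate in chain ", chain_id)
  rownames(residues) <- NULL
  structure(list(chain_id = chain_id, role = role, residues = residues),
            class = "chain_record")
}

#' @export
print.complex_record <- function(x, ...) {
  cat("<complex_record>", x$complex_id, "\n")
  for (ch in x$chains)
    cat(sprintf("  chain %s [%s]: %d residues\n", ch$chain_id, ch$role,
                nrow(ch$residues)))
  invisible(x)
}

get_chain <- function(complex, chain_id) {
  ch <- complex$chains[[chain_id]]
  if (is.null(ch)) stop("chain '", chain_id, "' not found in complex ",
                        complex$complex_id)
  ch
}

chain_coords <- function(chain) {
  as.matrix(chain$residues[, c("x", "y", "z")])
}

#' Read an antibody-antigen complex from a PDB file
#'
#' Parses a PDB file (or in-memory PDB text) at C-alpha resolution.
#' Only \code{ATOM} records with atom name \code{CA} are consumed; for
#' alternate locations the first encountered is kept. Chains not listed
#' in \code{chain_roles} are dropped. Residue order follows the file;
#' author numbering and insertion codes are preserved. Non-canonical
#' residues become \code{"X"} (unknown).
#'
#' @param pdb_source path to a PDB file, or a character scalar containing
#'   PDB-format text (recognised by embedded newlines).
#' @param chain_roles named character vector: \code{chain_id -> role}
#'   with roles in \code{heavy}, \code{light}, \code{antigen}.
#' @param complex_id identifier; defaults to the file base name.
#' @param pairing optional heavy-to-light pairing (named character
#'   vector). If omitted and exactly one heavy and one light chain are
#'   kept, they are paired automatically.
#' @return a \code{\link{complex_record}}.
#' @export
read_complex <- function(pdb_source, chain_roles, complex_id = NULL,
                         pairing = NULL) {
  if (length(pdb_source) == 1L && grepl("\n", pdb_source)) {
    tf <- tempfile(fileext = ".pdb")
    writeLines(strsplit(pdb_source, "\n", fixed = TRUE)[[1]], tf)
    path <- tf
    if (is.null(complex_id)) complex_id <- "inline"
  } else {
    path <- pdb_source
    if (!file.exists(path)) stop("PDB source not found: ", path)
    if (is.null(complex_id))
      complex_id <- sub("\\.pdb$", "", basename(path))
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  # altloc: keep first encountered per residue
  key <- paste(at$chain, at$resno, at$insert)
  at <- at[!duplicated(key), , drop = FALSE]

  chains <- list()
  for (cid in names(chain_roles)) {
    sub <- at[at$chain == cid, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("chain '", cid, "' has no C-alpha atoms")
    res <- data.frame(res_number = as.integer(sub$resno),
                      icode = sub$insert,
                      aa = aa_from_three(sub$resid),
                      x = sub$x, y = sub$y, z = sub$z,
                      stringsAsFactors = FALSE)
    chains[[cid]] <- chain_record(cid, unname(chain_roles[cid]), res)
  }
  if (is.null(pairing)) {
    roles <- vapply(chains, `[[`, character(1), "role")
    hv <- names(chains)[roles == "heavy"]
    lt <- names(chains)[roles == "light"]
    pairing <- if (length(hv) == 1L && length(lt) == 1L)
      stats::setNames(lt, hv) else character()
  }
  complex_record(complex_id, chains, pairing)
}

#' Check a CDR for completeness
#'
#' A CDR is complete when the CDR residues and both anchor residues are
#' present with finite C-alpha coordinates, every CDR residue carries a
#' canonical amino acid, and the anchor-to-anchor window shows no chain
#' break: residues missing from a deposited structure leave consecutive
#' C-alpha distances far above the peptide-bond geometry, so any
#' consecutive distance above \code{break_cutoff} marks the CDR as
#' incomplete. (A numbering-based gap test would wrongly flag short
#' loops, whose schemes legitimately skip author numbers.)
#'
#' @param complex a \code{\link{complex_record}}.
#' @param cdr a \code{\link{cdr_spec}} referring to a chain of
#'   \code{complex}.
#' @param break_cutoff maximum plausible consecutive C-alpha distance in
#'   Angstrom (default 4.5; the ideal value is 3.8).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
check_cdr_completeness <- function(complex, cdr, break_cutoff = 4.5) {
  ch <- get_chain(complex, cdr$chain_id)
  res <- ch$residues
  n <- nrow(res)
  lo <- cdr$start_idx - 1L
  hi <- cdr$end_idx + 1L
  if (lo < 1L || hi > n) return(FALSE)
  idx <- lo:hi
  xyz <- as.matrix(res[idx, c("x", "y", "z")])
  if (!all(is.finite(xyz))) return(FALSE)
  if (any(res$aa[cdr$start_idx:cdr$end_idx] == AA_UNKNOWN)) return(FALSE)
  steps <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                           xyz[-nrow(xyz), , drop = FALSE])^2))
  all(steps <= break_cutoff)
}

#' Write a single chain as a C-alpha PDB file
#'
#' Emits one \code{ATOM} CA record per residue, preserving author
#' numbering, insertion codes and amino-acid types (designed residues
#' included). The output round-trips through \code{\link{read_complex}}
#' with coordinates identical to 1e-3 Angstrom (PDB precision).
#'
#' @param complex a \code{\link{complex_record}}.
#' @param chain_id chain to write.
#' @param out output file path; its directory must exist.
#' @return the output path, invisibly usable in pipelines.
#' @export
write_chain_pdb <- function(complex, chain_id, out) {
  ch <- get_chain(complex, chain_id)
  if (!dir.exists(dirname(out)))
    stop("output directory does not exist: ", dirname(out))
  res <- ch$residues
  n <- nrow(res)
  bio3d::write.pdb(file = out,
                   xyz = as.numeric(t(as.matrix(res[, c("x", "y", "z")]))),
                   type = rep("ATOM", n),
                   resno = res$res_number,
                   resid = aa_to_three(res$aa),
                   insert = ifelse(res$icode == "", "", res$icode),
                   eleno = seq_len(n),
                   elety = rep("CA", n),
                   chain = rep(ch$chain_id, n),
                   end = TRUE)
  out
}

#' Write every chain of a complex as a C-alpha PDB file
#'
#' @inheritParams write_chain_pdb
#' @return the output path.
#' @export
write_complex_pdb <- function(complex, out) {
  if (!dir.exists(dirname(out)))
    stop("output directory does not exist: ", dirname(out))
  tab <- do.call(rbind, lapply(complex$chains, function(ch) {
    cbind(ch$residues, chain = ch$chain_id)
  }))
  n <- nrow(tab)
  bio3d::write.pdb(file = out,
                   xyz = as.numeric(t(as.matrix(tab[, c("x", "y", "z")]))),
                   type = rep("ATOM", n),
                   resno = tab$res_number,
                   resid = aa_to_three(tab$aa),
                   insert = ifelse(tab$icode == "", "", tab$icode),
                   eleno = seq_len(n),
                   elety = rep("CA", n),
                   chain = tab$chain,
                   end = TRUE)
  out
}

#' Read a tab-separated chain-role manifest
#'
#' Columns: \code{complex_id}, \code{chain_id}, \code{role}.
#'
#' @param path manifest path.
#' @return data.frame.
#' @export
read_role_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("complex_id", "chain_id", "role") %in% names(m)))
  m
}
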