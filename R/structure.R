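#' Read a structure model from a PDB file
#'
#' Parses a PDB file with \pkg{bio3d} and returns a flat atom table.
#' Hydrogens and waters are dropped; alternate locations are resolved to the
#' highest-occupancy (first on ties) conformer per atom. Author residue
#' numbering and insertion codes are preserved.
#'
#' @param path PDB file.
#' @return A `structure_model`: a tibble with one row per heavy atom and
#'   columns `chain`, `resno`, `ins` (insertion code, `""` if none),
#'   `resid` (3-letter residue name), `elety` (atom name), `element`,
#'   `x`, `y`, `z` (Angstrom).
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atoms in ", path, call. = FALSE)
  at$ins[is.na(at$ins)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$elesy[is.na(at$elesy)] <- ""
  element <- ifelse(at$elesy != "", toupper(at$elesy),
                    .element_from_name(at$elety))
  keep <- at$resid != "HOH" & element != "H" & element != "D" &
    at$type %in% c("ATOM", "HETATM")
  at <- at[keep, ]
  element <- element[keep]
  if (nrow(at) == 0) stop("no heavy atoms after filtering in ", path,
                          call. = FALSE)
  model <- tibble::tibble(
    chain = at$chain, resno = as.integer(at$resno), ins = at$ins,
    resid = at$resid, elety = at$elety, element = element,
    x = at$x, y = at$y, z = at$z, alt = at$alt, occ = at$o
  )
  # altloc: keep the highest-occupancy conformer per atom, first on ties;
  # file order is restored afterwards
  model$file_order <- seq_len(nrow(model))
  model <- dplyr::arrange(model, .data$chain, .data$resno, .data$ins,
                          .data$elety, dplyr::desc(.data$occ))
  model <- dplyr::distinct(model, .data$chain, .data$resno, .data$ins,
                           .data$elety, .keep_all = TRUE)
  model <- dplyr::arrange(model, .data$file_order)
  model <- dplyr::select(model, -"alt", -"occ", -"file_order")
  if (any(!is.finite(model$x) | !is.finite(model$y) | !is.finite(model$z))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  structure(model, class = c("structure_model", class(tibble::tibble())))
}

# crude element inference from PDB atom names when the element column is
# absent (e.g. minimal files)
.element_from_name <- function(elety) {
  first <- substr(gsub("[0-9]", "", trimws(elety)), 1, 1)
  toupper(first)
}

#' Write a structure model to a PDB file
#'
#' @param model A `structure_model` (or compatible tibble).
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
    resno = model$resno, resid = model$resid, chain = model$chain,
    insert = ifelse(model$ins == "", "", model$ins),
    elety = model$elety, eleno = seq_len(nrow(model)),
    elesy = model$element
  )
  invisible(path)
}

# unique residue key within a model
.res_key <- function(chain, resno, ins) paste0(chain, "/", resno, ins)

#' Per-residue summary of a structure model
#'
#' @param model A `structure_model`.
#' @return A tibble with one row per residue: `chain`, `resno`, `ins`,
#'   `resid`, `res_key`, `n_atoms`.
#' @export
structure_residues <- function(model) {
  dplyr::summarise(
    dplyr::group_by(model, .data$chain, .data$resno, .data$ins, .data$resid),
    n_atoms = dplyr::n(), .groups = "drop"
  ) |>
    dplyr::arrange(.data$chain, .data$resno, .data$ins) |>
    dplyr::mutate(res_key = .res_key(.data$chain, .data$resno, .data$ins))
}

# one-letter sequence of a structure chain, in author-number order
.structure_chain_seq <- function(model, chain_id) {
  res <- dplyr::filter(structure_residues(model), .data$chain == chain_id)
  if (nrow(res) == 0) {
    stop("chain ", chain_id, " not found in structure", call. = FALSE)
  }
  aa1 <- suppressWarnings(bio3d::aa321(res$resid))
  res$aa1 <- ifelse(is.na(aa1) | aa1 == "X", "X", aa1)
  res
}

#' Map structure residues to Kabat positions
#'
#' Aligns the one-letter sequence of a structure chain to a numbered chain
#' by exhaustive ungapped offset search (structure chains are contiguous,
#' possibly truncated at either end) and returns the injective residue
#' mapping at the best offset. Fails if the best identity is below
#' `min_identity`.
#'
#' @param model A `structure_model`.
#' @param chain A `kabat_chain` the structure chain should correspond to.
#' @param chain_id Chain identifier in the structure.
#' @param min_identity Identity floor for accepting the mapping
#'   (default 0.9).
#' @return A `kabat_mapping` tibble with one row per mapped structure
#'   residue: `chain`, `resno`, `ins`, `res_key`, `resid`, `structure_aa`,
#'   `kabat_number`, `insertion_code`, `label`, `region`, `matches`
#'   (logical); attribute `identity`.
#' @export
map_structure_to_kabat <- function(model, chain, chain_id,
                                   min_identity = 0.9) {
  .env_chain <- chain  # avoid masking by the `chain` column below
  res <- .structure_chain_seq(model, chain_id)
  ns <- nrow(res)
  nc <- nrow(chain)
  if (ns > nc) {
    stop("structure chain ", chain_id, " has more residues (", ns,
         ") than the numbered chain (", nc, ")", call. = FALSE)
  }
  offsets <- 0:(nc - ns)
  ident <- vapply(offsets, function(o) {
    mean(res$aa1 == chain$residue[o + seq_len(ns)])
  }, numeric(1))
  best <- which.max(ident)
  if (ident[best] < min_identity) {
    stop("structure chain ", chain_id, " aligns to the numbered chain at ",
         sprintf("%.0f%%", 100 * max(ident)),
         " identity, below the required ",
         sprintf("%.0f%%", 100 * min_identity), call. = FALSE)
  }
  o <- offsets[best]
  idx <- o + seq_len(ns)
  out <- tibble::tibble(
    chain = res$chain, resno = res$resno, ins = res$ins,
    res_key = res$res_key, resid = res$resid, structure_aa = res$aa1,
    kabat_number = .env_chain$kabat_number[idx],
    insertion_code = .env_chain$insertion_code[idx],
    label = .env_chain$label[idx],
    region = .env_chain$region[idx],
    matches = res$aa1 == .env_chain$residue[idx]
  )
  structure(out, identity = ident[best],
            class = c("kabat_mapping", class(tibble::tibble())))
}
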