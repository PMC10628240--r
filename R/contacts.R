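# Residue-residue heavy-atom distance analysis and the distance-based
# interaction typing used throughout the pipeline: donor-acceptor pairs at
# 2.7-3.3 A are counted as hydrogen bonds, carbon-carbon pairs at 3.3-4.0 A
# as hydrophobic packing, anything else within the analysis cutoff as
# proximal; beyond 10 A no interaction force can form.

# guard for inclusive distance comparisons: coordinates parsed from
# 3-decimal PDB fields are not exact binaries, so boundary equalities
# (e.g. a pair planted at exactly the cutoff) can miss by one ulp
EPS_DIST <- 1e-9

# all residue pairs (one residue from each side) whose minimum heavy-atom
# distance is <= cutoff, with the window indicators the class rules need:
# `no_in_window` (any N/O-N/O atom pair inside the hydrogen-bond window) and
# `cc_in_window` (any C-C pair inside the hydrophobic window)
.residue_pair_distances <- function(model, keys_a, keys_b, cutoff,
                                    hbond_range = c(2.7, 3.3),
                                    hydrophobic_range = c(3.3, 4.0)) {
  key <- .res_key(model$chain, model$resno, model$ins)
  a <- model[key %in% keys_a, ]
  b <- model[key %in% keys_b, ]
  empty <- tibble::tibble(
    res_a = character(), res_b = character(), min_distance = numeric(),
    atom_a = character(), atom_b = character(),
    no_in_window = logical(), cc_in_window = logical()
  )
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  ka <- .res_key(a$chain, a$resno, a$ins)
  kb <- .res_key(b$chain, b$resno, b$ins)
  ma <- as.matrix(a[, c("x", "y", "z")])
  mb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), "+") - 2 * tcrossprod(ma, mb)
  d <- sqrt(pmax(d2, 0))
  hit <- which(d <= cutoff + EPS_DIST, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  pairs <- unique(data.frame(ra = ka[hit[, 1]], rb = kb[hit[, 2]],
                             stringsAsFactors = FALSE))
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    ia <- which(ka == pairs$ra[i])
    ib <- which(kb == pairs$rb[i])
    sub <- d[ia, ib, drop = FALSE]
    w <- arrayInd(which.min(sub), dim(sub))
    no_a <- a$element[ia] %in% c("N", "O")
    no_b <- b$element[ib] %in% c("N", "O")
    cc_a <- a$element[ia] == "C"
    cc_b <- b$element[ib] == "C"
    d_no <- sub[no_a, no_b, drop = FALSE]
    d_cc <- sub[cc_a, cc_b, drop = FALSE]
    tibble::tibble(
      res_a = pairs$ra[i], res_b = pairs$rb[i],
      min_distance = sub[w],
      atom_a = a$elety[ia[w[1]]], atom_b = b$elety[ib[w[2]]],
      no_in_window = any(d_no >= hbond_range[1] - EPS_DIST &
                           d_no <= hbond_range[2] + EPS_DIST),
      cc_in_window = any(d_cc >= hydrophobic_range[1] - EPS_DIST &
                           d_cc <= hydrophobic_range[2] + EPS_DIST)
    )
  })
  out
}

# the distance-rule cascade; windows inclusive at both ends, hydrogen bond
# wins boundary ties with hydrophobic
.classify_distances <- function(no_in_window, cc_in_window, d_min,
                                contact_cutoff = 4.2) {
  dplyr::case_when(
    no_in_window ~ "hydrogen_bond",
    cc_in_window ~ "hydrophobic",
    d_min <= contact_cutoff + EPS_DIST ~ "proximal",
    TRUE ~ "none"
  )
}

#' Classify the interaction between two residues
#'
#' Applies the distance rules: hydrogen bond if any N/O--N/O heavy-atom pair
#' lies in the 2.7--3.3 A donor-acceptor window; otherwise hydrophobic if
#' any C--C pair lies in 3.3--4.0 A; otherwise proximal if the minimum
#' heavy-atom distance is within the analysis cutoff (4.2 A); otherwise
#' none (at more than 10 A no interaction force can form, and the 4.2--10 A
#' band is likewise reported as none). Windows are inclusive; hydrogen bond
#' wins the shared 3.3 A boundary.
#'
#' @param atoms_a,atoms_b Atom tibbles for the two residues (columns
#'   `elety`, `element`, `x`, `y`, `z`).
#' @param config A [pipeline_config()] supplying the distance windows.
#' @return One-row tibble: `interaction_class`, `min_distance`, `atom_a`,
#'   `atom_b`, `no_in_window`, `cc_in_window`.
#' @export
classify_interaction <- function(atoms_a, atoms_b,
                                 config = pipeline_config()) {
  stopifnot(nrow(atoms_a) > 0, nrow(atoms_b) > 0)
  a <- dplyr::mutate(atoms_a, chain = "a", resno = 1L, ins = "")
  b <- dplyr::mutate(atoms_b, chain = "b", resno = 1L, ins = "")
  pd <- .residue_pair_distances(dplyr::bind_rows(a, b), "a/1", "b/1",
                                cutoff = Inf,
                                hbond_range = config$hbond_range,
                                hydrophobic_range = config$hydrophobic_range)
  cls <- .classify_distances(pd$no_in_window, pd$cc_in_window,
                             pd$min_distance,
                             contact_cutoff = config$contact_cutoff)
  tibble::tibble(interaction_class = cls, min_distance = pd$min_distance,
                 atom_a = pd$atom_a, atom_b = pd$atom_b,
                 no_in_window = pd$no_in_window,
                 cc_in_window = pd$cc_in_window)
}

#' Find framework-to-CDR contacts in an Fv structure
#'
#' Detects every (framework residue, CDR residue) pair of a mapped structure
#' chain whose minimum heavy-atom distance is within the analysis cutoff
#' (default 4.2 A, inclusive) and types each contact by the distance rules
#' of [classify_interaction()].
#'
#' @param model A `structure_model`.
#' @param mapping A `kabat_mapping` from [map_structure_to_kabat()].
#' @param cutoff Analysis cutoff in Angstrom (default 4.2).
#' @param config A [pipeline_config()] supplying the class windows.
#' @return A `support_map`: a tibble of contacts with columns `fr_label`,
#'   `cdr_label`, `min_distance`, `atom_fr`, `atom_cdr`,
#'   `interaction_class`; attribute `fr_positions` lists every framework
#'   position of the mapping (so positions with zero contacts are explicit).
#' @export
find_fr_cdr_contacts <- function(model, mapping, cutoff = 4.2,
                                 config = pipeline_config()) {
  fr <- dplyr::filter(mapping, startsWith(.data$region, "FR"))
  cdr <- dplyr::filter(mapping, startsWith(.data$region, "CDR"))
  pd <- .residue_pair_distances(model, fr$res_key, cdr$res_key, cutoff,
                                hbond_range = config$hbond_range,
                                hydrophobic_range = config$hydrophobic_range)
  cls <- .classify_distances(pd$no_in_window, pd$cc_in_window,
                             pd$min_distance, contact_cutoff = cutoff)
  out <- tibble::tibble(
    fr_label = fr$label[match(pd$res_a, fr$res_key)],
    cdr_label = cdr$label[match(pd$res_b, cdr$res_key)],
    min_distance = pd$min_distance,
    atom_fr = pd$atom_a, atom_cdr = pd$atom_b,
    interaction_class = cls
  )
  support_map(out, fr_positions = fr$label)
}

#' Construct a support map from a contact table
#'
#' Used both by [find_fr_cdr_contacts()] and to transcribe published
#' contact narratives as text fixtures.
#'
#' @param contacts Tibble with columns `fr_label`, `cdr_label`,
#'   `min_distance`, `interaction_class` (optionally `atom_fr`,
#'   `atom_cdr`).
#' @param fr_positions Character vector of all framework positions the map
#'   covers (defaults to those appearing in `contacts`).
#' @return A `support_map` tibble.
#' @export
support_map <- function(contacts, fr_positions = unique(contacts$fr_label)) {
  stopifnot(all(c("fr_label", "cdr_label", "min_distance",
                  "interaction_class") %in% names(contacts)))
  structure(tibble::as_tibble(contacts),
            fr_positions = as.character(fr_positions),
            class = c("support_map", class(tibble::tibble())))
}

#' Per-framework-position contact summary
#'
#' @param support A `support_map`.
#' @return Tibble with one row per framework position: `fr_label`,
#'   `contact_count`, `has_hydrogen_bond` (positions without contacts
#'   included with zero counts).
#' @export
support_counts <- function(support) {
  pos <- attr(support, "fr_positions") %||% unique(support$fr_label)
  counts <- dplyr::summarise(
    dplyr::group_by(support, fr_label = .data$fr_label),
    contact_count = dplyr::n(),
    has_hydrogen_bond = any(.data$interaction_class == "hydrogen_bond"),
    .groups = "drop"
  )
  base <- tibble::tibble(fr_label = unique(c(pos, counts$fr_label)))
  out <- dplyr::left_join(base, counts, by = "fr_label")
  out$contact_count[is.na(out$contact_count)] <- 0L
  out$has_hydrogen_bond[is.na(out$has_hydrogen_bond)] <- FALSE
  out
}

#' Cross-side interface residue pairs
#'
#' All residue pairs with one residue in each side whose minimum heavy-atom
#' distance is within `cutoff`. Symmetric in side order up to pair
#' orientation.
#'
#' @param model A `structure_model`.
#' @param side_a,side_b Character vectors of chain identifiers; must be
#'   non-empty and disjoint.
#' @param cutoff Distance cutoff in Angstrom.
#' @return Tibble with columns `chain_a`, `resno_a`, `ins_a`, `resid_a`,
#'   `chain_b`, `resno_b`, `ins_b`, `resid_b`, `min_distance`.
#' @export
interface_residues <- function(model, side_a, side_b, cutoff = 5.5) {
  if (length(side_a) == 0 || length(side_b) == 0) {
    stop("both sides must name at least one chain", call. = FALSE)
  }
  if (length(intersect(side_a, side_b)) > 0) {
    stop("side_a and side_b share chain id(s): ",
         paste(intersect(side_a, side_b), collapse = ", "), call. = FALSE)
  }
  res <- structure_residues(model)
  keys_a <- res$res_key[res$chain %in% side_a]
  keys_b <- res$res_key[res$chain %in% side_b]
  pd <- .residue_pair_distances(model, keys_a, keys_b, cutoff)
  ra <- match(pd$res_a, res$res_key)
  rb <- match(pd$res_b, res$res_key)
  tibble::tibble(
    chain_a = res$chain[ra], resno_a = res$resno[ra], ins_a = res$ins[ra],
    resid_a = res$resid[ra],
    chain_b = res$chain[rb], resno_b = res$resno[rb], ins_b = res$ins[rb],
    resid_b = res$resid[rb],
    min_distance = pd$min_distance
  )
}

#' Write a support map as TSV
#'
#' @param support A `support_map`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(support, path) {
  readr::write_tsv(tibble::as_tibble(support), path)
  invisible(path)
}
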