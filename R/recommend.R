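#' Default physicochemical classes for conservative substitutions
#'
#' Residues within one class are treated as interchangeable when deciding
#' whether a framework difference needs a back mutation: positively charged
#' \{K, R, H\}, acidic \{D, E\}, hydroxyl \{S, T\}, amide \{N, Q\},
#' aliphatic \{L, I, V, M\}, aromatic \{F, Y, W\}, small \{A, G\}, and
#' singleton \{C\}, \{P\}.
#'
#' @return A named list of character vectors.
#' @export
conservative_classes <- function() {
  list(
    basic = c("K", "R", "H"), acidic = c("D", "E"),
    hydroxyl = c("S", "T"), amide = c("N", "Q"),
    aliphatic = c("L", "I", "V", "M"), aromatic = c("F", "Y", "W"),
    small = c("A", "G"), cysteine = "C", proline = "P"
  )
}

.same_class <- function(a, b, classes) {
  vapply(seq_along(a), function(i) {
    any(vapply(classes, function(cl) a[i] %in% cl && b[i] %in% cl,
               logical(1)))
  }, logical(1))
}

#' Recommend back mutations for a grafted framework
#'
#' For every framework position where the parental (donor) and germline
#' (acceptor) residues differ, applies the decision cascade:
#' \enumerate{
#'   \item upper hydrophobic core position: `BACK_MUTATE` / `UPPER_CORE` --
#'     these residues form the platform directly underneath the CDRs and
#'     are always restored;
#'   \item no CDR contacts within the analysis cutoff: `KEEP_HUMAN` /
#'     `NO_CDR_CONTACT` -- surface residues distant from the CDRs do not
#'     affect antigen binding;
#'   \item donor and germline residues share a physicochemical class:
#'     `KEEP_HUMAN` / `CONSERVATIVE_SWAP` (e.g. a Lys/Arg exchange at a
#'     CDR-contacting position preserves the interaction);
#'   \item contacts present but no hydrogen bond and at most
#'     `contact_weight_threshold` contacts: `KEEP_HUMAN` / `MINOR_CONTACT`;
#'   \item otherwise `BACK_MUTATE` / `CONTACT_DISRUPTING`.
#' }
#' Positions where parent and germline agree are omitted.
#'
#' @param parent A `kabat_chain` (nonhuman donor).
#' @param germline A `kabat_chain` or one-row germline record.
#' @param support A `support_map` for the parental Fv structure (or a
#'   transcribed fixture).
#' @param core An [upper_core_positions()] set.
#' @param config A [pipeline_config()]; supplies the conservative classes
#'   and `contact_weight_threshold`.
#' @return A `back_mutation_recommendations` tibble: `label`,
#'   `kabat_number`, `parent_residue`, `germline_residue`,
#'   `contact_count`, `has_hydrogen_bond`, `decision`
#'   (`BACK_MUTATE`/`KEEP_HUMAN`), `rationale`.
#' @export
recommend_back_mutations <- function(parent, germline, support,
                                     core = upper_core_positions(chain_type(parent)),
                                     config = pipeline_config()) {
  germline <- .as_numbered(germline, "germline")
  if (!identical(chain_type(parent), chain_type(germline))) {
    stop("parent and germline chain types differ", call. = FALSE)
  }
  match <- score_germline(parent, germline, core = core)
  diff <- dplyr::filter(match$positions, !.data$identical)
  bad <- setdiff(attr(support, "fr_positions"), parent$label)
  if (length(bad) > 0) {
    stop("support map position(s) not in the parent chain: ",
         paste(bad, collapse = ", "),
         " (was it built from a different chain?)", call. = FALSE)
  }
  counts <- support_counts(support)
  out <- dplyr::left_join(diff, counts,
                          by = c(label = "fr_label"))
  out$contact_count[is.na(out$contact_count)] <- 0L
  out$has_hydrogen_bond[is.na(out$has_hydrogen_bond)] <- FALSE
  conservative <- .same_class(out$parent_residue, out$germline_residue,
                              config$conservative_classes)
  thr <- config$contact_weight_threshold
  rationale <- dplyr::case_when(
    out$is_upper_core ~ "UPPER_CORE",
    out$contact_count == 0L ~ "NO_CDR_CONTACT",
    conservative ~ "CONSERVATIVE_SWAP",
    !out$has_hydrogen_bond & out$contact_count <= thr ~ "MINOR_CONTACT",
    TRUE ~ "CONTACT_DISRUPTING"
  )
  out <- tibble::tibble(
    label = out$label,
    kabat_number = out$kabat_number,
    parent_residue = out$parent_residue,
    germline_residue = out$germline_residue,
    contact_count = out$contact_count,
    has_hydrogen_bond = out$has_hydrogen_bond,
    decision = ifelse(rationale %in% c("UPPER_CORE", "CONTACT_DISRUPTING"),
                      "BACK_MUTATE", "KEEP_HUMAN"),
    rationale = rationale
  )
  class(out) <- c("back_mutation_recommendations", class(tibble::tibble()))
  out
}

#' Turn recommendations into a back-mutation plan
#'
#' @param recommendations A `back_mutation_recommendations` tibble.
#' @param donor,acceptor The chains the plan applies to.
#' @return A `graft_plan` covering the `BACK_MUTATE` positions.
#' @export
recommended_plan <- function(recommendations, donor, acceptor) {
  keep <- recommendations$decision == "BACK_MUTATE"
  graft_plan(recommendations$label[keep], donor, acceptor)
}

#' Write recommendations as TSV
#'
#' @param recommendations A `back_mutation_recommendations` tibble.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_recommendations_tsv <- function(recommendations, path) {
  readr::write_tsv(tibble::as_tibble(recommendations), path)
  invisible(path)
}
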