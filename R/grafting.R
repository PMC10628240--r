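#' Graft donor CDRs onto a human acceptor framework
#'
#' Builds the preliminary humanized chain: every CDR position carries the
#' donor residue (donor CDR loops are transplanted wholesale, including any
#' insertion codes, regardless of the acceptor's own CDR lengths), and every
#' framework position carries the acceptor residue. Framework positions
#' present in the donor but missing from the acceptor are filled from the
#' donor and flagged with a warning.
#'
#' @param donor A `kabat_chain` (nonhuman parent).
#' @param acceptor A `kabat_chain` or one-row germline record (human
#'   framework).
#' @return A `humanized_chain`: a `kabat_chain` with an extra `origin`
#'   column taking values `donor_CDR`, `acceptor_FR` or (after
#'   [apply_back_mutations()]) `back_mutated`.
#' @export
#' @examples
#' donor <- assign_kabat_numbering(kabat_template("heavy"), "heavy")
#' grafted <- graft_cdrs(donor, donor)  # self-graft is the identity
#' identical(chain_sequence(grafted), chain_sequence(donor))
graft_cdrs <- function(donor, acceptor) {
  acceptor <- .as_numbered(acceptor, "acceptor")
  if (!identical(chain_type(donor), chain_type(acceptor))) {
    stop("donor and acceptor chain types differ", call. = FALSE)
  }
  ctype <- chain_type(donor)
  cdr <- dplyr::filter(donor, startsWith(.data$region, "CDR"))
  cdr$origin <- "donor_CDR"
  fr_acc <- dplyr::filter(acceptor, startsWith(.data$region, "FR"))
  fr_acc$origin <- "acceptor_FR"
  # frameworks present in the donor but absent from the acceptor
  # (e.g. an FR3 insertion code the germline lacks): filled from donor
  fr_don <- dplyr::filter(donor, startsWith(.data$region, "FR"),
                          !.data$label %in% fr_acc$label)
  if (nrow(fr_don) > 0) {
    warning("acceptor missing framework position(s) ",
            paste(fr_don$label, collapse = ", "),
            "; filled from donor", call. = FALSE)
    fr_don$origin <- "donor_FR_fill"
  }
  out <- dplyr::bind_rows(fr_acc, fr_don, cdr)
  out <- out[.label_order(out$kabat_number, out$insertion_code), ]
  out$seq_index <- seq_len(nrow(out))
  out$region <- kabat_region_of(out$kabat_number, ctype)
  chain <- new_kabat_chain(tibble::as_tibble(out), chain_type = ctype,
                           source_id = "grafted")
  class(chain) <- c("humanized_chain", class(chain))
  chain
}

#' Build a back-mutation plan from donor and acceptor chains
#'
#' @param positions Character vector of Kabat position labels (e.g.
#'   `c("48", "82A")`) to restore to the donor residue.
#' @param donor,acceptor Numbered chains the plan refers to.
#' @return A `graft_plan` tibble with columns `label`, `human_residue`,
#'   `donor_residue`.
#' @export
graft_plan <- function(positions, donor, acceptor) {
  acceptor <- .as_numbered(acceptor, "acceptor")
  positions <- as.character(positions)
  if (anyDuplicated(positions)) {
    stop("duplicate positions in back-mutation plan", call. = FALSE)
  }
  d_idx <- match(positions, donor$label)
  a_idx <- match(positions, acceptor$label)
  if (anyNA(d_idx)) {
    stop("plan position(s) absent from donor: ",
         paste(positions[is.na(d_idx)], collapse = ", "), call. = FALSE)
  }
  reg <- donor$region[d_idx]
  if (any(startsWith(reg, "CDR"))) {
    stop("back-mutation positions must be framework positions; got CDR: ",
         paste(positions[startsWith(reg, "CDR")], collapse = ", "),
         call. = FALSE)
  }
  structure(tibble::tibble(
    label = positions,
    human_residue = ifelse(is.na(a_idx), NA_character_,
                           acceptor$residue[a_idx]),
    donor_residue = donor$residue[d_idx]
  ), class = c("graft_plan", class(tibble::tibble())))
}

#' Apply back mutations to a grafted chain
#'
#' Restores the donor residue at each planned framework position and tags it
#' `back_mutated`. Exactly the planned positions change, so the Hamming
#' distance between input and output sequences equals the number of plan
#' rows whose donor residue differs from the current residue.
#'
#' @param grafted A `humanized_chain` from [graft_cdrs()].
#' @param plan A `graft_plan` (or a tibble with columns `label`,
#'   `donor_residue`).
#' @return The updated `humanized_chain`.
#' @export
apply_back_mutations <- function(grafted, plan) {
  stopifnot(inherits(grafted, "humanized_chain"))
  if (nrow(plan) == 0) return(grafted)
  idx <- match(plan$label, grafted$label)
  if (anyNA(idx)) {
    stop("plan position(s) absent from grafted chain: ",
         paste(plan$label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (any(startsWith(grafted$region[idx], "CDR"))) {
    stop("cannot back-mutate CDR positions (already donor)", call. = FALSE)
  }
  grafted$residue[idx] <- plan$donor_residue
  grafted$origin[idx] <- "back_mutated"
  grafted
}

#' Write a humanized chain with per-residue provenance as TSV
#'
#' @param chain A `humanized_chain`.
#' @param path Output TSV (columns `label`, `residue`, `region`, `origin`).
#' @return `path`, invisibly.
#' @export
write_provenance_tsv <- function(chain, path) {
  readr::write_tsv(
    tibble::tibble(label = chain$label, residue = chain$residue,
                   region = chain$region, origin = chain$origin),
    path
  )
  invisible(path)
}
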