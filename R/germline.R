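#' Read a germline framework library from FASTA
#'
#' Each record is numbered with [assign_kabat_numbering()]. Allele names are
#' the first whitespace-delimited token of each header; chain type comes
#' from a `chain=` header tag unless given explicitly.
#'
#' @param path FASTA file of germline V-gene sequences.
#' @param chain_type Optional chain type applied to all records.
#' @return A tibble with columns `allele`, `chain_type`, `sequence`, and a
#'   list-column `numbered` of `kabat_chain` objects.
#' @export
read_germline_library <- function(path, chain_type = NULL) {
  recs <- read_fv_fasta(path, chain_type = chain_type)
  if (anyNA(recs$chain_type)) {
    stop("germline records without a chain= header tag; pass chain_type",
         call. = FALSE)
  }
  if (anyDuplicated(recs$id)) {
    stop("duplicate allele names in germline library", call. = FALSE)
  }
  tibble::tibble(
    allele = recs$id,
    chain_type = recs$chain_type,
    sequence = recs$sequence,
    numbered = purrr::map2(recs$sequence, recs$chain_type,
                           ~ assign_kabat_numbering(.x, .y, source_id = "germline"))
  )
}

#' Build a single germline record
#'
#' @param allele Allele name (e.g. `"IGHV1-46*01"`).
#' @param sequence Amino-acid string.
#' @param chain_type `"heavy"` or `"light"`.
#' @return A one-row germline library tibble (see [read_germline_library()]).
#' @export
germline_record <- function(allele, sequence, chain_type) {
  chain_type <- .chain_type(chain_type)
  tibble::tibble(
    allele = allele, chain_type = chain_type, sequence = sequence,
    numbered = list(assign_kabat_numbering(sequence, chain_type,
                                           source_id = allele))
  )
}

.as_numbered <- function(x, what = "chain") {
  if (inherits(x, "kabat_chain")) return(x)
  if (is.data.frame(x) && "numbered" %in% names(x)) {
    if (nrow(x) != 1) stop("expected a single ", what, call. = FALSE)
    return(x$numbered[[1]])
  }
  stop("cannot interpret ", what, ": pass a kabat_chain or a one-row ",
       "germline record", call. = FALSE)
}

#' Score a germline acceptor against a parental chain
#'
#' Compares the parent and a candidate human germline framework position by
#' position over the framework columns present in both chains. Framework
#' identity is the match fraction over those columns; upper-core
#' preservation counts how many upper hydrophobic core positions carry the
#' parental residue in the germline.
#'
#' @param parent A `kabat_chain` (the nonhuman donor).
#' @param germline A `kabat_chain` or one-row germline record.
#' @param core An [upper_core_positions()] set (defaults to the chain type's
#'   standard set).
#' @return A `germline_match`: list with elements `allele`,
#'   `framework_identity`, `upper_core_preserved`, `upper_core_total` and
#'   `positions`, a per-position tibble with columns `label`,
#'   `kabat_number`, `parent_residue`, `germline_residue`, `is_upper_core`,
#'   `identical`.
#' @export
score_germline <- function(parent, germline,
                           core = upper_core_positions(chain_type(parent))) {
  allele <- if (is.data.frame(germline) && "allele" %in% names(germline)) {
    germline$allele[[1]]
  } else attr(germline, "source_id")
  germline <- .as_numbered(germline, "germline")
  if (!identical(chain_type(parent), chain_type(germline))) {
    stop("chain-type mismatch between parent and germline", call. = FALSE)
  }
  fr_p <- dplyr::filter(parent, startsWith(.data$region, "FR"))
  fr_g <- dplyr::filter(germline, startsWith(.data$region, "FR"))
  pos <- dplyr::inner_join(
    dplyr::select(fr_p, "label", "kabat_number", "insertion_code",
                  parent_residue = "residue"),
    dplyr::select(fr_g, "label", germline_residue = "residue"),
    by = "label"
  )
  pos <- pos[.label_order(pos$kabat_number, pos$insertion_code), ]
  pos <- dplyr::mutate(
    pos,
    is_upper_core = .data$kabat_number %in% as.integer(core) &
      .data$insertion_code == "",
    identical = .data$parent_residue == .data$germline_residue
  )
  pos <- dplyr::select(pos, -"insertion_code")
  structure(list(
    allele = allele %||% "",
    framework_identity = mean(pos$identical),
    upper_core_preserved = sum(pos$identical[pos$is_upper_core]),
    upper_core_total = sum(pos$is_upper_core),
    positions = tibble::as_tibble(pos)
  ), class = "germline_match")
}

#' @export
print.germline_match <- function(x, ...) {
  cat(sprintf(
    "<germline_match> %s: framework identity %.3f, upper core %d/%d\n",
    x$allele, x$framework_identity, x$upper_core_preserved,
    x$upper_core_total))
  invisible(x)
}

#' Rank germline acceptors for a parental chain
#'
#' Scores every record of a germline library against the parent (see
#' [score_germline()]) and ranks by (1) upper-core positions preserved,
#' descending; (2) framework identity, descending; (3) an optional numeric
#' prior (e.g. encoding expression or clinical-precedent preferences),
#' descending; (4) allele name, ascending. The selection rule of the
#' pipeline is the top-ranked record; a record preserving the entire upper
#' core is flagged `fully_preserving`.
#'
#' @param parent A `kabat_chain`.
#' @param library A germline library tibble ([read_germline_library()]).
#' @param core An [upper_core_positions()] set.
#' @param prior Optional named numeric vector of per-allele priors
#'   (default 0).
#' @return A `germline_ranking` tibble with columns `rank`, `allele`,
#'   `framework_identity`, `upper_core_preserved`, `upper_core_total`,
#'   `fully_preserving`, `prior`, and a list-column `match` of
#'   `germline_match` objects.
#' @export
select_germline <- function(parent, library,
                            core = upper_core_positions(chain_type(parent)),
                            prior = NULL) {
  if (!is.data.frame(library) || nrow(library) == 0) {
    stop("empty germline library", call. = FALSE)
  }
  if ("chain_type" %in% names(library)) {
    library <- library[library$chain_type == chain_type(parent), ]
    if (nrow(library) == 0) {
      stop("germline library has no ", chain_type(parent), " records",
           call. = FALSE)
    }
  }
  matches <- purrr::map(seq_len(nrow(library)), function(i) {
    score_germline(parent, library[i, ], core = core)
  })
  out <- tibble::tibble(
    allele = purrr::map_chr(matches, "allele"),
    framework_identity = purrr::map_dbl(matches, "framework_identity"),
    upper_core_preserved = purrr::map_int(matches,
                                          ~ as.integer(.x$upper_core_preserved)),
    upper_core_total = purrr::map_int(matches,
                                      ~ as.integer(.x$upper_core_total)),
    match = matches
  )
  out$fully_preserving <- out$upper_core_preserved == out$upper_core_total
  out$prior <- if (is.null(prior)) 0 else {
    unname(ifelse(is.na(prior[out$allele]), 0, prior[out$allele]))
  }
  ord <- order(-out$upper_core_preserved, -out$framework_identity,
               -out$prior, out$allele, method = "radix")
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "rank")
  class(out) <- c("germline_ranking", class(tibble::tibble()))
  out
}

#' Write a germline ranking and its per-position reports as TSV
#'
#' @param ranking A `germline_ranking`.
#' @param path Ranking TSV path; the per-position report is written next to
#'   it with suffix `_positions.tsv`.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  readr::write_tsv(dplyr::select(ranking, -"match"), path)
  pos <- dplyr::bind_rows(
    purrr::map(ranking$match,
               ~ dplyr::mutate(.x$positions, allele = .x$allele,
                               .before = 1))
  )
  readr::write_tsv(pos, sub("\\.tsv$", "_positions.tsv", path))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
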