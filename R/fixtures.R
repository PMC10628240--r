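# Packaged synthetic fixtures. The parental 3D5-like VH/VL and the germline
# acceptor sequences are SYNTHETIC stand-ins (template-derived; the real
# antibody sequences and structures are not publicly deposited), constructed
# so that the parent-vs-acceptor framework differences and the transcribed
# contact narrative reproduce the published per-position back-mutation
# decisions: heavy 38/40/66/82A kept human, 48/67/69/71/78/94 back-mutated,
# light 3/60/63/70 kept human.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "abhumanize")
  if (path == "") stop("packaged fixture not found: ", file, call. = FALSE)
  path
}

#' Packaged humanization case study fixture
#'
#' Loads the synthetic parental VH/VL, the packaged germline library, and
#' the framework-to-CDR contact support maps transcribed from the published
#' structural narrative (distances are representative values consistent
#' with the stated interaction types, not measured coordinates).
#'
#' @return List with elements `heavy` and `light`, each a list of `parent`
#'   (`kabat_chain`), `acceptor` (one-row germline record), `support`
#'   (`support_map`), plus `library` (the full germline tibble).
#' @export
#' @examples
#' fx <- humanization_fixture()
#' fx$heavy$parent
humanization_fixture <- function() {
  library <- read_germline_library(.extdata("germline_library_synthetic.fasta"))
  parents <- read_fv_fasta(.extdata("parent_donor_synthetic.fasta"))
  one_chain <- function(ct, allele, support_file) {
    rec <- parents[parents$chain_type == ct, ]
    parent <- assign_kabat_numbering(rec$sequence, ct, source_id = rec$id)
    contacts <- readr::read_tsv(.extdata(support_file),
                                col_types = readr::cols(
                                  fr_label = readr::col_character(),
                                  cdr_label = readr::col_character(),
                                  min_distance = readr::col_double(),
                                  interaction_class = readr::col_character()
                                ))
    fr_labels <- parent$label[startsWith(parent$region, "FR")]
    list(
      parent = parent,
      acceptor = library[library$allele == allele, ],
      support = support_map(contacts, fr_positions = fr_labels)
    )
  }
  list(
    heavy = one_chain("heavy", "IGHV1-46*01", "support_heavy_synthetic.tsv"),
    light = one_chain("light", "IGKV1-5*01", "support_light_synthetic.tsv"),
    library = library
  )
}

#' Path to the packaged germline library FASTA
#'
#' @return File path of the synthetic germline framework library.
#' @export
germline_library_path <- function() {
  .extdata("germline_library_synthetic.fasta")
}

#' Score J-segment (FR4) acceptors
#'
#' FR4 comes from the J gene, not the V gene, so it is scored separately:
#' each packaged (or user-supplied) J-segment sequence is compared to the
#' parent's FR4 columns and ranked by identity.
#'
#' @param parent A `kabat_chain`.
#' @param path FASTA of J-segment FR4 sequences (default: packaged
#'   synthetic set).
#' @return Tibble ranked by descending identity: `allele`, `sequence`,
#'   `identity`, `n_compared`.
#' @export
score_j_segments <- function(parent,
                             path = .extdata("j_segments_synthetic.fasta")) {
  recs <- read_fv_fasta(path)
  recs <- recs[is.na(recs$chain_type) |
                 recs$chain_type == chain_type(parent), ]
  fr4 <- dplyr::filter(parent, .data$region == "FR4")
  if (nrow(fr4) == 0) stop("parent chain has no FR4 residues", call. = FALSE)
  offset <- min(fr4$kabat_number) -
    .geometry(chain_type(parent))$regions$from[7]
  out <- purrr::map_dfr(seq_len(nrow(recs)), function(i) {
    j <- strsplit(recs$sequence[i], "")[[1]]
    idx <- offset + seq_len(nrow(fr4))
    ok <- idx <= length(j)
    tibble::tibble(
      allele = recs$id[i], sequence = recs$sequence[i],
      identity = mean(fr4$residue[ok] == j[idx[ok]]),
      n_compared = sum(ok)
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$identity), .data$allele)
}
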