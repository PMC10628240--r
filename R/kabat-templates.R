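# Packaged consensus templates and the Kabat region geometry they are
# annotated with. The templates are package conventions (human consensus-like
# V-domains with zero insertion codes); all numbering is defined relative to
# them.

KABAT_AA <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
              "S","T","V","W","Y")

# region spans are closed Kabat-number intervals of the zero-insertion
# template; `site` is the canonical insertion position within the region
# (NA = no insertions supported there)
.kabat_geometry <- list(
  heavy = list(
    template = paste0(
      "EVQLVESGGGLVQPGGSLRLSCAASGFTFS",  # FR1   1-30
      "SYAMS",                           # CDR1 31-35
      "WVRQAPGKGLEWVS",                  # FR2  36-49
      "AISGSGGSTYYADSVK",               # CDR2 50-65
      "RVTISRDNSKNTLYLQMNSLRAEDTAVYY",  # FR3  66-94
      "DYGSSYFD",                        # CDR3 95-102
      "WGQGTLVTVSS"                      # FR4 103-113
    ),
    regions = data.frame(
      region = c("FR1","CDR1","FR2","CDR2","FR3","CDR3","FR4"),
      from   = c(1, 31, 36, 50, 66, 95, 103),
      to     = c(30, 35, 49, 65, 94, 102, 113),
      site   = c(NA, 35, NA, 52, 82, 100, NA)
    ),
    # segmentation search space (region residue counts)
    fr1_trunc = 0:5, cdr1_len = 1:7, cdr2_len = 14:19,
    fr3_ins = 0:3, cdr3_len = 3:19, fr4_len = 0:11
  ),
  light = list(
    template = paste0(
      "DIQMTQSPSSLSASVGDRVTITC",         # FR1   1-23
      "RASQSISSYLN",                     # CDR1 24-34
      "WYQQKPGKAPKLLIY",                 # FR2  35-49
      "AASSLQS",                         # CDR2 50-56
      "GVPSRFSGSGSGTDFTLTISSLQPEDFATYYC", # FR3 57-88
      "QQSYSTPLT",                       # CDR3 89-97
      "FGQGTKVEIK"                       # FR4  98-107
    ),
    regions = data.frame(
      region = c("FR1","CDR1","FR2","CDR2","FR3","CDR3","FR4"),
      from   = c(1, 24, 35, 50, 57, 89, 98),
      to     = c(23, 34, 49, 56, 88, 97, 107),
      site   = c(NA, 27, NA, NA, NA, 95, NA)
    ),
    fr1_trunc = 0:5, cdr1_len = 8:17, cdr2_len = 7,
    fr3_ins = 0, cdr3_len = 3:15, fr4_len = 0:10
  )
)

.chain_type <- function(chain_type) {
  match.arg(chain_type, c("heavy", "light"))
}

.geometry <- function(chain_type) .kabat_geometry[[.chain_type(chain_type)]]

.template_chars <- function(chain_type) {
  strsplit(.geometry(chain_type)$template, "")[[1]]
}

.region_chars <- function(chain_type, region) {
  geo <- .geometry(chain_type)
  row <- geo$regions[geo$regions$region == region, ]
  .template_chars(chain_type)[row$from:row$to]
}

#' Kabat region boundary table
#'
#' The closed Kabat-number intervals this package uses for the three CDRs and
#' four framework regions of each chain type (heavy CDR1 31--35, CDR2 50--65,
#' CDR3 95--102; light CDR1 24--34, CDR2 50--56, CDR3 89--97; frameworks are
#' the complements), together with the canonical insertion site of each
#' region where one exists.
#'
#' @param chain_type `"heavy"` or `"light"`.
#' @return A tibble with columns `region`, `from`, `to`, `site`.
#' @export
#' @examples
#' kabat_region_table("heavy")
kabat_region_table <- function(chain_type) {
  tibble::as_tibble(.geometry(chain_type)$regions)
}

#' Region label for a Kabat position
#'
#' @param kabat_number Integer vector of Kabat numbers.
#' @param chain_type `"heavy"` or `"light"`.
#' @return Character vector of region labels (`FR1`..`FR4`, `CDR1`..`CDR3`).
#' @export
kabat_region_of <- function(kabat_number, chain_type) {
  geo <- .geometry(chain_type)$regions
  idx <- findInterval(kabat_number, geo$from)
  bad <- is.na(kabat_number) | idx < 1 | kabat_number > max(geo$to)
  if (any(bad)) {
    stop("Kabat number outside the ", chain_type, " template range 1..",
         max(geo$to), call. = FALSE)
  }
  geo$region[idx]
}

#' Upper hydrophobic core positions
#'
#' Framework positions directly underneath the CDRs whose side chains support
#' the CDR loop conformations. Substitutions here are treated as
#' conformation-critical: germline acceptors that do not preserve them are
#' penalised during selection, and any residual difference is always
#' back-mutated. Defaults are Kabat heavy
#' \{2, 4, 24, 27, 29, 47, 48, 49, 69, 71, 78, 94\} and light
#' \{2, 4, 64, 66, 71\}.
#'
#' @param chain_type `"heavy"` or `"light"`.
#' @param extra Optional additional Kabat positions to include.
#' @return An `upper_core_set`: an integer vector of Kabat positions with a
#'   `chain_type` attribute.
#' @export
#' @examples
#' upper_core_positions("heavy")
upper_core_positions <- function(chain_type, extra = integer()) {
  chain_type <- .chain_type(chain_type)
  pos <- switch(chain_type,
    heavy = c(2L, 4L, 24L, 27L, 29L, 47L, 48L, 49L, 69L, 71L, 78L, 94L),
    light = c(2L, 4L, 64L, 66L, 71L)
  )
  pos <- sort(unique(c(pos, as.integer(extra))))
  cdr <- kabat_region_of(pos, chain_type)
  if (any(startsWith(cdr, "CDR"))) {
    stop("upper-core positions must be framework positions", call. = FALSE)
  }
  structure(pos, chain_type = chain_type, class = "upper_core_set")
}

#' @export
print.upper_core_set <- function(x, ...) {
  cat("<upper_core_set> ", attr(x, "chain_type"), " chain: ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# residues of a region numbered by the site-anchored fill rule:
# numbers up to and including the site come first, surplus residues get
# insertion codes at the site (82A, 100B, ...), and the numbers after the
# site are anchored at the region's C-terminal end; deletions remove numbers
# immediately before the post-site anchor block
.fill_region <- function(region, n, chain_type) {
  geo <- .geometry(chain_type)$regions
  row <- geo[geo$region == region, ]
  span <- row$from:row$to
  m <- length(span)
  if (n == 0L) {
    return(data.frame(kabat_number = integer(), insertion_code = character()))
  }
  if (is.na(row$site)) {
    if (n == m) {
      num <- span
    } else if (region == "FR1" && n < m) {
      num <- span[(m - n + 1):m]          # N-terminal truncation
    } else if (region == "FR4" && n < m) {
      num <- span[1:n]                     # C-terminal truncation
    } else {
      stop(region, " length ", n, " unsupported (template length ", m, ")",
           call. = FALSE)
    }
    return(data.frame(kabat_number = num,
                      insertion_code = rep("", length(num))))
  }
  i_site <- match(row$site, span)
  tail_len <- m - i_site
  if (n < tail_len + 1L) {
    stop(region, " length ", n, " too short for the ", chain_type,
         " template", call. = FALSE)
  }
  if (n > m + 26L) {
    stop(region, " length ", n, " exceeds supported insertion codes A-Z",
         call. = FALSE)
  }
  head_n <- min(n - tail_len, i_site)
  ins_n <- max(0L, n - m)
  data.frame(
    kabat_number = c(span[seq_len(head_n)], rep(row$site, ins_n),
                     if (tail_len > 0) span[(i_site + 1):m]),
    insertion_code = c(rep("", head_n), if (ins_n > 0) LETTERS[seq_len(ins_n)],
                       rep("", tail_len))
  )
}

# position label like "82" or "82A"
.kabat_label <- function(kabat_number, insertion_code) {
  paste0(kabat_number, insertion_code)
}
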