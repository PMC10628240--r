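# Generators for every input class the pipeline consumes: Fv sequences
# with known Kabat structure, toy Fv structures with planted framework-CDR
# contacts at controlled distances, and two-chain complexes with known
# interface composition. Ground truth is exact by construction, so every
# downstream stage can be tested against it without external data. Toy
# residues use 4-5 pseudo-atoms (N, CA, C, O, CB); geometry is deliberately
# non-physical -- only interatomic distances and elements matter to the
# rules under test.

#' Generate a synthetic Fv sequence with known Kabat ground truth
#'
#' Builds a VH or VL sequence from the packaged template: framework regions
#' are the template's (optionally mutated at `mutation_rate` to emulate a
#' nonhuman framework), CDRs are random loops of the requested lengths, and
#' FR3 insertion-code residues (82A...) and terminal truncations are planted
#' as requested. The returned `chain` is the exact ground-truth numbering.
#'
#' @param chain_type `"heavy"` or `"light"`.
#' @param cdr_lengths Integer vector of three CDR lengths (defaults: the
#'   template's own lengths).
#' @param fr3_insertions Number of FR3 insertion codes (heavy only, 0--3).
#' @param fr1_trunc Residues missing from the N-terminus (0--5).
#' @param fr4_len Length of FR4 (default: full template FR4).
#' @param mutation_rate Per-position framework substitution probability
#'   (0 keeps the template framework; default 0.15 emulates a murine-grade
#'   divergence).
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return List with `sequence` (string), `chain` (the ground-truth
#'   `kabat_chain`), and `spec` (the realized parameters).
#' @export
#' @examples
#' fv <- make_fv_sequence("heavy", cdr_lengths = c(5, 17, 11), seed = 1)
#' fv$chain$label[fv$chain$insertion_code != ""]
make_fv_sequence <- function(chain_type, cdr_lengths = NULL,
                             fr3_insertions = 0, fr1_trunc = 0,
                             fr4_len = NULL, mutation_rate = 0.15,
                             seed) {
  chain_type <- .chain_type(chain_type)
  geo <- .geometry(chain_type)
  if (is.null(cdr_lengths)) {
    cdr_lengths <- vapply(c("CDR1", "CDR2", "CDR3"),
                          function(r) length(.region_chars(chain_type, r)),
                          integer(1))
  }
  cdr_lengths <- unname(as.integer(cdr_lengths))
  stopifnot(length(cdr_lengths) == 3, mutation_rate >= 0, mutation_rate < 1)
  if (!cdr_lengths[1] %in% geo$cdr1_len ||
      !cdr_lengths[2] %in% geo$cdr2_len ||
      !cdr_lengths[3] %in% geo$cdr3_len) {
    stop("CDR length(s) outside the Kabat-legal ranges for ", chain_type,
         call. = FALSE)
  }
  if (!fr3_insertions %in% geo$fr3_ins) {
    stop("fr3_insertions outside the supported range for ", chain_type,
         call. = FALSE)
  }
  if (!fr1_trunc %in% geo$fr1_trunc) {
    stop("fr1_trunc outside the supported range", call. = FALSE)
  }
  full_fr4 <- length(.region_chars(chain_type, "FR4"))
  if (is.null(fr4_len)) fr4_len <- full_fr4
  if (!fr4_len %in% geo$fr4_len) {
    stop("fr4_len outside the supported range", call. = FALSE)
  }
  withr::with_seed(seed, {
    mutate_fr <- function(chars) {
      hit <- stats::runif(length(chars)) < mutation_rate
      chars[hit] <- vapply(chars[hit], function(c0) {
        sample(setdiff(KABAT_AA, c0), 1)
      }, character(1))
      chars
    }
    fr1 <- mutate_fr(utils::tail(.region_chars(chain_type, "FR1"),
                                 length(.region_chars(chain_type, "FR1")) -
                                   fr1_trunc))
    fr2 <- mutate_fr(.region_chars(chain_type, "FR2"))
    fr3 <- mutate_fr(.region_chars(chain_type, "FR3"))
    if (fr3_insertions > 0) {
      site <- geo$regions$site[geo$regions$region == "FR3"]
      from3 <- geo$regions$from[geo$regions$region == "FR3"]
      at <- site - from3 + 1L
      fr3 <- append(fr3, sample(KABAT_AA, fr3_insertions, replace = TRUE),
                    after = at)
    }
    fr4 <- mutate_fr(utils::head(.region_chars(chain_type, "FR4"), fr4_len))
    cdrs <- lapply(cdr_lengths, function(n) {
      sample(KABAT_AA, n, replace = TRUE)
    })
    chars <- c(fr1, cdrs[[1]], fr2, cdrs[[2]], fr3, cdrs[[3]], fr4)
  })
  seg <- list(t = fr1_trunc, c1 = cdr_lengths[1], c2 = cdr_lengths[2],
              k = fr3_insertions, c3 = cdr_lengths[3], n4 = fr4_len,
              identity = NA_real_)
  chain <- .chain_from_segmentation(chars, chain_type, seg)
  attr(chain, "source_id") <- "synthetic"
  list(sequence = paste(chars, collapse = ""), chain = chain,
       spec = list(chain_type = chain_type, cdr_lengths = cdr_lengths,
                   fr3_insertions = fr3_insertions, fr1_trunc = fr1_trunc,
                   fr4_len = fr4_len, mutation_rate = mutation_rate,
                   seed = seed))
}

# pseudo-atom template: offsets from the residue anchor, in A
.toy_atom_offsets <- function(aa1) {
  atoms <- data.frame(
    elety = c("N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C"),
    dx = c(-0.9, 0, 0.9, 0.9, 0),
    dy = c(0.5, 0, 0.5, 1.7, -1.0),
    dz = c(0, 0, 0, 0, 1.0)
  )
  if (aa1 == "G") atoms <- atoms[atoms$elety != "CB", ]
  atoms
}

.toy_resid3 <- function(aa1) {
  out <- suppressWarnings(bio3d::aa123(aa1))
  out[is.na(out) | out == "X"] <- "UNK"
  out
}

# atoms of one toy residue anchored at (x, y, z)
.toy_residue <- function(aa1, chain, resno, x, y, z) {
  at <- .toy_atom_offsets(aa1)
  tibble::tibble(
    chain = chain, resno = as.integer(resno), ins = "",
    resid = .toy_resid3(aa1), elety = at$elety, element = at$element,
    x = x + at$dx, y = y + at$dy, z = z + at$dz
  )
}

# designated atom names per planted-contact kind, plus the stacking order
# of the relocated residue's remaining atoms: atoms whose element could
# land in the wrong distance window are stacked farthest from the plant.
# `out` is the outward unit direction from the anchor atom, chosen so the
# approach path clears the framework residue's own atom cloud (O is its
# topmost atom, CB its bottom one).
.plant_atoms <- function(kind) {
  switch(kind,
    no = list(fr = "O", cdr = "N", stack = c("CA", "C", "O", "CB"),
              out = c(0, 1, 0)),
    cc = list(fr = "CB", cdr = "CB", stack = c("CA", "C", "N", "O"),
              out = c(0, -1, 0)),
    generic = list(fr = "O", cdr = "CA", stack = c("C", "N", "O", "CB"),
                   out = c(0, 1, 0)),
    stop("unknown contact kind: ", kind, call. = FALSE)
  )
}

# approach direction for the `slot`-th contact planted on one framework
# residue: the anchor's outward direction, tilted +/-40 degrees in x for
# the second and third contact
.plant_direction <- function(out, slot) {
  tilt <- c(0, 40, -40)[slot] * pi / 180
  u <- c(sin(tilt), out[2] * cos(tilt), 0)
  u / sqrt(sum(u^2))
}

#' Build a toy Fv structure with planted framework-CDR contacts
#'
#' Residues are laid out on a line at 8 A spacing (so all unplanted
#' framework-CDR residue pairs are more than 6 A apart); each planted CDR
#' residue is relocated next to its framework partner so that the designated
#' atom pair (`"no"`: backbone O to N; `"cc"`: CB to CB; `"generic"`: O to
#' CA) sits exactly at `target_distance`, with the rest of the residue
#' stacked away so no unintended atom pair contaminates the distance
#' windows.
#'
#' @param chain A `kabat_chain` defining sequence and regions.
#' @param contacts Tibble of planted contacts: columns `fr_label`,
#'   `cdr_label`, `target_distance`, `kind` (`"no"`, `"cc"`,
#'   `"generic"`). `NULL` plants nothing.
#' @param path Output PDB path.
#' @param chain_id PDB chain id (default `"H"`).
#' @param seed Integer seed (small deterministic baseline jitter).
#' @return List with `path`, `model` (the atom tibble as written) and
#'   `contacts` (the realized plan).
#' @export
make_fv_structure <- function(chain, contacts = NULL,
                              path = tempfile(fileext = ".pdb"),
                              chain_id = "H", seed = 1) {
  n <- nrow(chain)
  if (!is.null(contacts) && nrow(contacts) > 0) {
    stopifnot(all(c("fr_label", "cdr_label", "target_distance", "kind")
                  %in% names(contacts)))
    if (anyDuplicated(contacts$cdr_label)) {
      stop("over-constrained plant: a CDR residue appears in two planted",
           " contacts", call. = FALSE)
    }
    if (any(contacts$target_distance <= 0)) {
      stop("target distances must be positive", call. = FALSE)
    }
    fr_idx <- match(contacts$fr_label, chain$label)
    cdr_idx <- match(contacts$cdr_label, chain$label)
    if (anyNA(fr_idx) || anyNA(cdr_idx)) {
      stop("planted position(s) absent from chain", call. = FALSE)
    }
    if (any(startsWith(chain$region[fr_idx], "CDR")) ||
        any(startsWith(chain$region[cdr_idx], "FR"))) {
      stop("plants must pair a framework position with a CDR position",
           call. = FALSE)
    }
  }
  jitter <- withr::with_seed(seed, stats::runif(n, -0.2, 0.2))
  base <- lapply(seq_len(n), function(i) {
    .toy_residue(chain$residue[i], chain_id, i, 8 * (i - 1), jitter[i], 0)
  })
  if (!is.null(contacts) && nrow(contacts) > 0) {
    slot <- stats::ave(seq_len(nrow(contacts)), contacts$fr_label,
                       FUN = seq_along)
    if (any(slot > 3)) {
      stop("over-constrained plant: more than 3 contacts on one",
           " framework residue", call. = FALSE)
    }
    for (i in seq_len(nrow(contacts))) {
      fi <- match(contacts$fr_label[i], chain$label)
      ci <- match(contacts$cdr_label[i], chain$label)
      plant <- .plant_atoms(contacts$kind[i])
      fr_at <- base[[fi]]
      anchor <- fr_at[fr_at$elety == plant$fr, ]
      if (nrow(anchor) == 0) {
        stop("framework residue ", contacts$fr_label[i], " lacks atom ",
             plant$fr, " (glycine has no CB)", call. = FALSE)
      }
      u <- .plant_direction(plant$out, slot[i])
      res <- base[[ci]]
      des <- which(res$elety == plant$cdr)
      if (length(des) == 0) {
        stop("CDR residue ", contacts$cdr_label[i], " lacks atom ",
             plant$cdr, " (glycine has no CB)", call. = FALSE)
      }
      d <- contacts$target_distance[i]
      p0 <- c(anchor$x, anchor$y, anchor$z) + d * u
      others <- match(intersect(plant$stack, res$elety), res$elety)
      others <- setdiff(others, des)
      perp <- c(0, 0, 1)
      pos <- matrix(0, nrow(res), 3)
      pos[des, ] <- p0
      for (j in seq_along(others)) {
        pos[others[j], ] <- p0 + u * (1.5 * j) +
          perp * 0.3 * ((j %% 2) * 2 - 1)
      }
      res$x <- pos[, 1]; res$y <- pos[, 2]; res$z <- pos[, 3]
      base[[ci]] <- res
    }
  }
  model <- dplyr::bind_rows(base)
  class(model) <- c("structure_model", class(tibble::tibble()))
  write_structure(model, path)
  list(path = path, model = model, contacts = contacts)
}

#' Build a toy two-chain complex with a known interface
#'
#' Chain A residues sit on a line at 12 A spacing; each planted pair places
#' a chain B residue above its A partner with the closest heavy-atom pair
#' at exactly `distance` (pairs with `distance` above the IC cutoff act as
#' out-of-range decoys). Extra residues on each side are placed far from
#' the other side so the planted composition is the complete interface, and
#' the expected interfacial-contact counts are computable from the pair plan
#' alone.
#'
#' @param pairs Tibble with columns `res_a`, `res_b` (one-letter codes) and
#'   `distance` (A).
#' @param n_extra_a,n_extra_b Additional non-interface residues per side
#'   (identities drawn from the seed).
#' @param extra_a,extra_b Optional explicit identities for the extra
#'   residues (character vectors of one-letter codes; override the counts).
#' @param path Output PDB path.
#' @param seed Integer seed (extra-residue identities and jitter).
#' @param class_table A [residue_class_table()] used for the expected
#'   counts.
#' @param cutoff IC cutoff defining which planted pairs are in range.
#' @return List with `path`, `model`, `pairs` (realized plan),
#'   `expected_ic` (ground-truth `ic_counts` tibble).
#' @export
make_complex <- function(pairs, n_extra_a = 6, n_extra_b = 6,
                         extra_a = NULL, extra_b = NULL,
                         path = tempfile(fileext = ".pdb"), seed = 1,
                         class_table = residue_class_table(),
                         cutoff = 5.5) {
  stopifnot(all(c("res_a", "res_b", "distance") %in% names(pairs)),
            all(pairs$distance > 0))
  np <- nrow(pairs)
  withr::with_seed(seed, {
    if (is.null(extra_a)) extra_a <- sample(KABAT_AA, n_extra_a, replace = TRUE)
    if (is.null(extra_b)) extra_b <- sample(KABAT_AA, n_extra_b, replace = TRUE)
    n_extra_a <- length(extra_a)
    n_extra_b <- length(extra_b)
    jit <- stats::runif(np + n_extra_a + n_extra_b, -0.2, 0.2)
  })
  a_res <- c(pairs$res_a, extra_a)
  atoms_a <- lapply(seq_along(a_res), function(i) {
    .toy_residue(a_res[i], "A", i, 12 * (i - 1), jit[i], 0)
  })
  atoms_b <- vector("list", np + n_extra_b)
  for (i in seq_len(np)) {
    # anchor on A's topmost atom (O); B's designated N sits exactly
    # `distance` above it, rest of B stacked further up
    fr_at <- atoms_a[[i]]
    anchor <- fr_at[fr_at$elety == "O", ]
    d <- pairs$distance[i]
    res <- .toy_residue(pairs$res_b[i], "B", i, 0, 0, 0)
    des <- which(res$elety == "N")
    p0 <- c(anchor$x, anchor$y + d, anchor$z)
    others <- setdiff(seq_len(nrow(res)), des)
    pos <- matrix(0, nrow(res), 3)
    pos[des, ] <- p0
    for (j in seq_along(others)) {
      pos[others[j], ] <- p0 + c(0.3 * ((j %% 2) * 2 - 1), 1.5 * j, 0)
    }
    res$x <- pos[, 1]; res$y <- pos[, 2]; res$z <- pos[, 3]
    atoms_b[[i]] <- res
  }
  for (i in seq_len(n_extra_b)) {
    atoms_b[[np + i]] <- .toy_residue(extra_b[i], "B", np + i,
                                      12 * (i - 1), 35 + jit[np + n_extra_a + i],
                                      0)
  }
  model <- dplyr::bind_rows(c(atoms_a, atoms_b))
  class(model) <- c("structure_model", class(tibble::tibble()))
  write_structure(model, path)
  in_range <- pairs$distance <= cutoff
  counts <- stats::setNames(integer(length(IC_CLASS_PAIRS)), IC_CLASS_PAIRS)
  if (any(in_range)) {
    cls_a <- class_table$class[match(pairs$res_a[in_range],
                                     class_table$residue)]
    cls_b <- class_table$class[match(pairs$res_b[in_range],
                                     class_table$residue)]
    tab <- table(.class_pair(cls_a, cls_b))
    counts[names(tab)] <- as.integer(tab)
  }
  expected <- tibble::tibble(class_pair = IC_CLASS_PAIRS,
                             count = unname(counts))
  list(path = path, model = model, pairs = pairs, expected_ic = expected)
}
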