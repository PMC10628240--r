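make_mapped_structure <- function(chain_type = "light", contacts = NULL,
                                  seed = 1, mutation_rate = 0.1) {
  fv <- make_fv_sequence(chain_type, seed = seed,
                         mutation_rate = mutation_rate)
  st <- make_fv_structure(fv$chain, contacts, chain_id = "X", seed = seed)
  model <- read_structure(st$path)
  mapping <- map_structure_to_kabat(model, fv$chain, "X")
  list(fv = fv, model = model, mapping = mapping, path = st$path)
}

test_that("a single planted pair at 4.0 A yields exactly one contact", {
  contacts <- tibble::tibble(fr_label = "70", cdr_label = "52",
                             target_distance = 4.0, kind = "generic")
  ms <- make_mapped_structure("light", contacts, seed = 51)
  sm <- find_fr_cdr_contacts(ms$model, ms$mapping)
  expect_identical(nrow(sm), 1L)
  expect_identical(sm$fr_label, "70")
  expect_identical(sm$cdr_label, "52")
  expect_equal(sm$min_distance, 4.0, tolerance = 1e-2)
})

test_that("a planted pair at 4.3 A is outside the 4.2 A support map", {
  contacts <- tibble::tibble(fr_label = "70", cdr_label = "52",
                             target_distance = 4.3, kind = "generic")
  ms <- make_mapped_structure("light", contacts, seed = 52)
  sm <- find_fr_cdr_contacts(ms$model, ms$mapping)
  expect_identical(nrow(sm), 0L)
  # the cutoff itself is inclusive
  contacts$target_distance <- 4.2
  ms2 <- make_mapped_structure("light", contacts, seed = 52)
  expect_identical(nrow(find_fr_cdr_contacts(ms2$model, ms2$mapping)), 1L)
})

test_that("interaction classes follow the distance windows", {
  # backbone O...N at 3.0 A: hydrogen bond
  a <- toy_atoms(c("C", "O"), c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
  b <- toy_atoms(c("N", "CA"), c("N", "C"), rbind(c(4.2, 0, 0), c(5.5, 0, 0)))
  expect_identical(classify_interaction(a, b)$interaction_class,
                   "hydrogen_bond")
  # CB...CG at 3.6 A with no N/O pair in window: hydrophobic
  a <- toy_atoms("CB", "C", rbind(c(0, 0, 0)))
  b <- toy_atoms("CG", "C", rbind(c(3.6, 0, 0)))
  expect_identical(classify_interaction(a, b)$interaction_class,
                   "hydrophobic")
  # mixed-element pair at 4.1 A: proximal
  a <- toy_atoms("O", "O", rbind(c(0, 0, 0)))
  b <- toy_atoms("CA", "C", rbind(c(4.1, 0, 0)))
  expect_identical(classify_interaction(a, b)$interaction_class, "proximal")
  # nearest atoms 12 A apart: none
  b12 <- toy_atoms("CA", "C", rbind(c(12, 0, 0)))
  expect_identical(classify_interaction(a, b12)$interaction_class, "none")
  # the undefined 4.2-10 A band is also none
  b6 <- toy_atoms("CA", "C", rbind(c(6, 0, 0)))
  expect_identical(classify_interaction(a, b6)$interaction_class, "none")
  # boundary tie at 3.3 A N/O-N/O: hydrogen bond wins over hydrophobic
  a <- toy_atoms(c("O", "CB"), c("O", "C"), rbind(c(0, 0, 0), c(0, 0.1, 0)))
  b <- toy_atoms(c("N", "CB"), c("N", "C"),
                 rbind(c(3.3, 0, 0), c(3.4, 0.1, 0)))
  expect_identical(classify_interaction(a, b)$interaction_class,
                   "hydrogen_bond")
})

test_that("classification is invariant under rigid-body motion", {
  contacts <- tibble::tibble(
    fr_label = c("66", "70"), cdr_label = c("31", "52"),
    target_distance = c(3.0, 3.6), kind = c("no", "cc"))
  ms <- make_mapped_structure("light", contacts, seed = 53)
  sm0 <- find_fr_cdr_contacts(ms$model, ms$mapping)
  for (seed in 1:5) {
    ang <- withr::with_seed(seed, stats::runif(3, 0, 2 * pi))
    shift <- withr::with_seed(seed + 10, stats::runif(3, -30, 30))
    moved <- transform_model(ms$model, rotation_matrix(ang[1], ang[2],
                                                       ang[3]), shift)
    smr <- find_fr_cdr_contacts(moved, ms$mapping)
    expect_identical(smr$interaction_class[order(smr$fr_label)],
                     sm0$interaction_class[order(sm0$fr_label)])
    expect_equal(smr$min_distance[order(smr$fr_label)],
                 sm0$min_distance[order(sm0$fr_label)], tolerance = 1e-6)
  }
})

test_that("contact detection equals the brute-force oracle on fuzzed structures", {
  n_structs <- 100
  for (i in seq_len(n_structs)) {
    ct <- if (i %% 2 == 0) "heavy" else "light"
    fv <- make_fv_sequence(ct, seed = 7000 + i, mutation_rate = 0.1)
    fr_labels <- fv$chain$label[startsWith(fv$chain$region, "FR") &
                                  fv$chain$residue != "G"]
    cdr_labels <- fv$chain$label[startsWith(fv$chain$region, "CDR") &
                                   fv$chain$residue != "G"]
    plants <- withr::with_seed(3000 + i, {
      n <- sample(0:4, 1)
      if (n == 0) NULL else tibble::tibble(
        fr_label = sample(fr_labels, n),
        cdr_label = sample(cdr_labels, n),
        target_distance = round(runif(n, 2.8, 5.5), 2),
        kind = sample(c("no", "cc", "generic"), n, replace = TRUE)
      )
    })
    st <- make_fv_structure(fv$chain, plants, chain_id = "Q", seed = i)
    model <- read_structure(st$path)
    mapping <- map_structure_to_kabat(model, fv$chain, "Q")
    sm <- find_fr_cdr_contacts(model, mapping)
    # oracle: independent parser + all-pairs double loop
    raw <- oracle_read_pdb(st$path)
    fr_keys <- paste0("Q/", mapping$resno[startsWith(mapping$region, "FR")],
                      mapping$ins[startsWith(mapping$region, "FR")])
    cdr_keys <- paste0("Q/", mapping$resno[startsWith(mapping$region, "CDR")],
                       mapping$ins[startsWith(mapping$region, "CDR")])
    od <- oracle_pair_min_dists(raw, fr_keys, cdr_keys)
    hits <- od[od$min_distance <= 4.2 + 1e-9, ]
    expect_identical(nrow(sm), nrow(hits))
    if (nrow(sm) > 0) {
      got <- sm[order(sm$fr_label, sm$cdr_label), ]
      lab <- mapping$label
      names(lab) <- paste0("Q/", mapping$resno, mapping$ins)
      want <- data.frame(fr = unname(lab[hits$res_a]),
                         cdr = unname(lab[hits$res_b]),
                         d = hits$min_distance)
      want <- want[order(want$fr, want$cdr), ]
      expect_identical(got$fr_label, want$fr)
      expect_identical(got$cdr_label, want$cdr)
      expect_equal(got$min_distance, want$d, tolerance = 1e-6)
    }
  }
})

test_that("interface residue pairs are exact, symmetric, and empty when far", {
  pairs <- tibble::tibble(
    res_a = c("R", "S", "L", "K", "D"), res_b = c("D", "L", "L", "E", "K"),
    distance = c(4.5, 5.0, 3.8, 5.5, 5.2))
  cx <- make_complex(pairs, seed = 61)
  model <- read_structure(cx$path)
  ir <- interface_residues(model, "A", "B", cutoff = 5.5)
  expect_identical(nrow(ir), 5L)
  expect_identical(ir$resno_a, ir$resno_b)  # planted partner layout
  # symmetry up to orientation
  ir_swapped <- interface_residues(model, "B", "A", cutoff = 5.5)
  expect_setequal(paste(ir$chain_a, ir$resno_a, ir$chain_b, ir$resno_b),
                  paste(ir_swapped$chain_b, ir_swapped$resno_b,
                        ir_swapped$chain_a, ir_swapped$resno_a))
  # two far-apart chains share no pairs
  far <- make_complex(tibble::tibble(res_a = "A", res_b = "A",
                                     distance = 100), n_extra_a = 3,
                      n_extra_b = 3, seed = 62)
  expect_identical(nrow(interface_residues(read_structure(far$path),
                                           "A", "B", 5.5)), 0L)
  expect_error(interface_residues(model, c("A", "B"), "B", 5.5), "share")
})
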