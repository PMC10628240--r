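# Contact-classified interface profiling and binding-affinity prediction:
# interfacial contacts (ICs) at 5.5 A are bucketed by the polarity classes
# of the two residues, the non-interacting surface (NIS) composition is
# computed from relative SASA, and a linear model maps both to a binding
# free energy, converted to Kd at 25 C.

IC_CLASS_PAIRS <- c("charged_charged", "charged_polar", "charged_apolar",
                    "polar_polar", "polar_apolar", "apolar_apolar")

#' Residue polarity class table
#'
#' Maps each canonical amino acid to `charged`, `polar` or `apolar`.
#' Defaults: charged \{D, E, K, R\}; polar \{C, H, N, Q, S, T, W, Y\};
#' apolar \{A, F, G, I, L, M, P, V\}. Fully configurable via
#' [pipeline_config()].
#'
#' @param classes Named list with elements `charged`, `polar`, `apolar`
#'   (one-letter codes); must partition the 20 canonical residues.
#' @return A tibble with columns `residue` (one-letter), `class`.
#' @export
residue_class_table <- function(classes = pipeline_config()$residue_classes) {
  stopifnot(setequal(names(classes), c("charged", "polar", "apolar")))
  all_aa <- sort(unlist(classes, use.names = FALSE))
  if (!identical(all_aa, sort(KABAT_AA))) {
    stop("residue classes must partition the 20 canonical residues",
         call. = FALSE)
  }
  tibble::tibble(
    residue = unlist(classes, use.names = FALSE),
    class = rep(names(classes), lengths(classes))
  )
}

.residue_class <- function(resid3, class_table) {
  aa1 <- suppressWarnings(bio3d::aa321(resid3))
  cls <- class_table$class[match(aa1, class_table$residue)]
  if (anyNA(cls)) {
    stop("residue(s) without a polarity class: ",
         paste(unique(resid3[is.na(cls)]), collapse = ", "), call. = FALSE)
  }
  cls
}

# unordered class pair key, canonical order charged < polar < apolar
.class_pair <- function(class_a, class_b) {
  lev <- c("charged", "polar", "apolar")
  ia <- match(class_a, lev)
  ib <- match(class_b, lev)
  paste(lev[pmin(ia, ib)], lev[pmax(ia, ib)], sep = "_")
}

#' Count interfacial contacts by polarity class pair
#'
#' Each cross-side residue pair whose minimum heavy-atom distance is within
#' the cutoff (default 5.5 A) contributes one count to the unordered
#' class-pair bucket of its two residues' polarity classes.
#'
#' @param model A `structure_model`.
#' @param side_a,side_b Character vectors of chain ids (disjoint).
#' @param class_table A [residue_class_table()].
#' @param cutoff Interface cutoff in Angstrom (default 5.5).
#' @return An `ic_counts` tibble with columns `class_pair` (the six fixed
#'   buckets, in Table order: charged_charged, charged_polar,
#'   charged_apolar, polar_polar, polar_apolar, apolar_apolar) and `count`.
#' @export
count_interfacial_contacts <- function(model, side_a, side_b,
                                       class_table = residue_class_table(),
                                       cutoff = 5.5) {
  pairs <- interface_residues(model, side_a, side_b, cutoff = cutoff)
  counts <- stats::setNames(integer(length(IC_CLASS_PAIRS)), IC_CLASS_PAIRS)
  if (nrow(pairs) > 0) {
    key <- .class_pair(.residue_class(pairs$resid_a, class_table),
                       .residue_class(pairs$resid_b, class_table))
    tab <- table(key)
    counts[names(tab)] <- as.integer(tab)
  }
  structure(
    tibble::tibble(class_pair = IC_CLASS_PAIRS, count = unname(counts)),
    class = c("ic_counts", class(tibble::tibble()))
  )
}

#' Non-interacting surface composition
#'
#' NIS residues are residues of the complex with relative SASA at or above
#' the threshold (default 5\%) that are not part of any interfacial residue
#' pair. Returns the percentage of NIS residues that are apolar and charged.
#'
#' @param model A `structure_model`.
#' @param side_a,side_b Chain id vectors defining the two sides.
#' @param sasa A [compute_sasa()] result for the whole complex.
#' @param class_table A [residue_class_table()].
#' @param interface Interface pairs from [interface_residues()] at the IC
#'   cutoff (computed if omitted).
#' @param cutoff IC cutoff used when `interface` is omitted.
#' @param threshold Relative-SASA threshold for surface residues
#'   (default 0.05).
#' @return Named list: `nis_apolar_pct`, `nis_charged_pct`,
#'   `nis_polar_pct`, `n_nis`.
#' @export
nis_percentages <- function(model, side_a, side_b, sasa = compute_sasa(model),
                            class_table = residue_class_table(),
                            interface = NULL, cutoff = 5.5,
                            threshold = 0.05) {
  if (is.null(interface)) {
    interface <- interface_residues(model, side_a, side_b, cutoff = cutoff)
  }
  iface_keys <- unique(c(
    .res_key(interface$chain_a, interface$resno_a, interface$ins_a),
    .res_key(interface$chain_b, interface$resno_b, interface$ins_b)
  ))
  nis <- dplyr::filter(sasa, .data$rel_sasa >= threshold,
                       !.data$res_key %in% iface_keys)
  if (nrow(nis) == 0) {
    stop("no NIS residues: every surface residue is interfacial",
         call. = FALSE)
  }
  cls <- .residue_class(nis$resid, class_table)
  list(
    nis_apolar_pct = 100 * mean(cls == "apolar"),
    nis_charged_pct = 100 * mean(cls == "charged"),
    nis_polar_pct = 100 * mean(cls == "polar"),
    n_nis = nrow(nis)
  )
}

#' Predict binding free energy from interface descriptors
#'
#' Linear contact-based model: ΔG = c1·IC(charged-charged) +
#' c2·IC(charged-apolar) + c3·IC(polar-polar) + c4·IC(polar-apolar) +
#' c5·\%NIS(apolar) + c6·\%NIS(charged) + c0. The coefficient set lives in
#' [pipeline_config()] (`dg_coefficients`), never in this function.
#'
#' @param ic_counts An `ic_counts` tibble from
#'   [count_interfacial_contacts()].
#' @param nis_apolar_pct,nis_charged_pct NIS percentages in [0, 100].
#' @param coefficients Named numeric vector with entries `charged_charged`,
#'   `charged_apolar`, `polar_polar`, `polar_apolar`, `nis_apolar`,
#'   `nis_charged`, `intercept`.
#' @return Predicted ΔG in kcal/mol.
#' @export
predict_dg <- function(ic_counts, nis_apolar_pct, nis_charged_pct,
                       coefficients = pipeline_config()$dg_coefficients) {
  need <- c("charged_charged", "charged_apolar", "polar_polar",
            "polar_apolar", "nis_apolar", "nis_charged", "intercept")
  if (!all(need %in% names(coefficients))) {
    stop("missing ΔG coefficient(s): ",
         paste(setdiff(need, names(coefficients)), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(ic_counts$count >= 0),
            nis_apolar_pct >= 0, nis_apolar_pct <= 100,
            nis_charged_pct >= 0, nis_charged_pct <= 100)
  ic <- stats::setNames(ic_counts$count, ic_counts$class_pair)
  unname(
    coefficients["charged_charged"] * ic["charged_charged"] +
      coefficients["charged_apolar"] * ic["charged_apolar"] +
      coefficients["polar_polar"] * ic["polar_polar"] +
      coefficients["polar_apolar"] * ic["polar_apolar"] +
      coefficients["nis_apolar"] * nis_apolar_pct +
      coefficients["nis_charged"] * nis_charged_pct +
      coefficients["intercept"]
  )
}

# gas constant, kcal mol^-1 K^-1
RGAS_KCAL <- 1.9872e-3

#' Convert binding free energy to a dissociation constant
#'
#' Kd = exp(ΔG / (R·T)) with R = 1.9872e-3 kcal mol^-1 K^-1; the inverse of
#' ΔG = RT·ln Kd.
#'
#' @param delta_g ΔG in kcal/mol.
#' @param temperature Temperature in Kelvin (default 298.15, i.e. 25 C).
#' @return Kd in molar.
#' @export
#' @examples
#' dg_to_kd(-12.1)  # ~1.4e-9 M
dg_to_kd <- function(delta_g, temperature = 298.15) {
  stopifnot(temperature > 0)
  exp(delta_g / (RGAS_KCAL * temperature))
}

#' @rdname dg_to_kd
#' @param kd Dissociation constant in molar.
#' @export
kd_to_dg <- function(kd, temperature = 298.15) {
  stopifnot(temperature > 0, all(kd > 0))
  RGAS_KCAL * temperature * log(kd)
}

#' Fold change between two measured values
#'
#' Convenience ratio used to compare affinities or potencies on the same
#' scale (e.g. KD or EC50 values); both inputs must share units.
#'
#' @param reference,comparator Positive numerics; the result is
#'   `reference / comparator`, so values above 1 mean the comparator is the
#'   stronger (lower) value.
#' @return The ratio.
#' @export
#' @examples
#' fold_change(4.56e-9, 6.83e-10)  # ~6.7, "nearly 7 times"
fold_change <- function(reference, comparator) {
  stopifnot(reference > 0, comparator > 0)
  reference / comparator
}

#' Full interface profile of a two-sided complex
#'
#' Runs the whole affinity pipeline on a complex: interfacial contacts at
#' the IC cutoff bucketed by polarity class pair, NIS percentages from
#' per-residue relative SASA, ΔG from the linear model, and Kd at the
#' configured temperature.
#'
#' @param model A `structure_model` of the complex.
#' @param side_a,side_b Chain id vectors for the two sides.
#' @param config A [pipeline_config()].
#' @return An `interface_profile` object: list with `ic_counts`,
#'   `nis_apolar_pct`, `nis_charged_pct`, `nis_polar_pct`, `n_nis`,
#'   `delta_g` (kcal/mol), `kd` (M), `temperature` (K), `cutoff` (A).
#' @export
interface_profile <- function(model, side_a, side_b,
                              config = pipeline_config()) {
  class_table <- residue_class_table(config$residue_classes)
  ic <- count_interfacial_contacts(model, side_a, side_b,
                                   class_table = class_table,
                                   cutoff = config$ic_cutoff)
  sasa <- compute_sasa(model, probe = config$sasa_probe,
                       n_points = config$sasa_points)
  iface <- interface_residues(model, side_a, side_b,
                              cutoff = config$ic_cutoff)
  nis <- nis_percentages(model, side_a, side_b, sasa = sasa,
                         class_table = class_table, interface = iface,
                         threshold = config$nis_threshold)
  dg <- predict_dg(ic, nis$nis_apolar_pct, nis$nis_charged_pct,
                   coefficients = config$dg_coefficients)
  structure(list(
    ic_counts = ic,
    nis_apolar_pct = nis$nis_apolar_pct,
    nis_charged_pct = nis$nis_charged_pct,
    nis_polar_pct = nis$nis_polar_pct,
    n_nis = nis$n_nis,
    delta_g = dg,
    kd = dg_to_kd(dg, config$temperature),
    temperature = config$temperature,
    cutoff = config$ic_cutoff
  ), class = "interface_profile")
}

#' @export
print.interface_profile <- function(x, ...) {
  ic <- stats::setNames(x$ic_counts$count, x$ic_counts$class_pair)
  cat("<interface_profile>\n")
  cat(sprintf("  dG (kcal mol-1): %.2f   Kd (M) at %.0f K: %.2e\n",
              x$delta_g, x$temperature, x$kd))
  cat(sprintf("  ICs charged-charged %d | charged-polar %d | charged-apolar %d\n",
              ic["charged_charged"], ic["charged_polar"],
              ic["charged_apolar"]))
  cat(sprintf("  ICs polar-polar %d | polar-apolar %d | apolar-apolar %d\n",
              ic["polar_polar"], ic["polar_apolar"], ic["apolar_apolar"]))
  cat(sprintf("  NIS apolar %.1f%% | charged %.1f%% (n = %d)\n",
              x$nis_apolar_pct, x$nis_charged_pct, x$n_nis))
  invisible(x)
}

#' Write an interface profile as TSV
#'
#' Columns mirror the affinity report table: ΔG, Kd at 25 C, then the six
#' IC class buckets.
#'
#' @param profile An `interface_profile`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(glance.interface_profile(profile), path)
  invisible(path)
}
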