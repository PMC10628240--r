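#' Pipeline configuration
#'
#' Collects every tunable constant of the humanization pipeline in one
#' place. Defaults: framework-CDR analysis cutoff 4.2 A; interfacial-contact
#' cutoff 5.5 A; hydrogen-bond donor-acceptor window 2.7--3.3 A;
#' hydrophobic C--C window 3.3--4.0 A; no-interaction bound 10 A; NIS
#' relative-SASA threshold 5\%; contact-weight threshold 1; temperature
#' 298.15 K; Shrake-Rupley probe 1.4 A with 960 sphere points; the residue
#' polarity classes of [residue_class_table()]; the conservative-swap
#' classes of [conservative_classes()]; the standard upper-core sets; and
#' the linear ΔG coefficient set.
#'
#' @param ... Named overrides of any default element.
#' @return A `pipeline_config` list.
#' @export
#' @examples
#' cfg <- pipeline_config(contact_weight_threshold = 2)
#' cfg$contact_weight_threshold
pipeline_config <- function(...) {
  cfg <- list(
    contact_cutoff = 4.2,
    ic_cutoff = 5.5,
    hbond_range = c(2.7, 3.3),
    hydrophobic_range = c(3.3, 4.0),
    no_interaction_distance = 10,
    nis_threshold = 0.05,
    contact_weight_threshold = 1,
    temperature = 298.15,
    sasa_probe = 1.4,
    sasa_points = 960,
    residue_classes = list(
      charged = c("D", "E", "K", "R"),
      polar = c("C", "H", "N", "Q", "S", "T", "W", "Y"),
      apolar = c("A", "F", "G", "I", "L", "M", "P", "V")
    ),
    conservative_classes = conservative_classes(),
    upper_core = list(
      heavy = c(2, 4, 24, 27, 29, 47, 48, 49, 69, 71, 78, 94),
      light = c(2, 4, 64, 66, 71)
    ),
    dg_coefficients = c(
      charged_charged = -0.09459, charged_apolar = -0.10007,
      polar_polar = 0.19577, polar_apolar = -0.22671,
      nis_apolar = 0.18681, nis_charged = 0.13810,
      intercept = -15.9433
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  .validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

.validate_config <- function(cfg) {
  stopifnot(
    cfg$contact_cutoff > 0, cfg$ic_cutoff > 0,
    cfg$hbond_range[1] < cfg$hbond_range[2],
    cfg$hydrophobic_range[1] < cfg$hydrophobic_range[2],
    cfg$hbond_range[2] <= cfg$hydrophobic_range[2],
    cfg$no_interaction_distance > cfg$contact_cutoff,
    cfg$nis_threshold >= 0, cfg$temperature > 0,
    cfg$contact_weight_threshold >= 0
  )
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Any subset of config elements may appear in the file; missing elements
#' take their defaults, so a config round-trips through serialization
#' unchanged.
#'
#' @param path YAML file.
#' @return For `read_pipeline_config()`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$dg_coefficients)) {
    vals$dg_coefficients <- unlist(vals$dg_coefficients)
  }
  if (!is.null(vals$upper_core)) {
    vals$upper_core <- lapply(vals$upper_core, as.numeric)
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$dg_coefficients <- as.list(out$dg_coefficients)
  yaml::write_yaml(out, path)
  invisible(path)
}

.core_from_config <- function(chain_type, config) {
  upper_core_positions(chain_type,
                       extra = setdiff(config$upper_core[[chain_type]],
                                       upper_core_positions(chain_type)))
}

# one chain through numbering -> germline ranking -> graft -> contacts ->
# recommendations -> back-mutated chain
.humanize_chain <- function(sequence, chain_type, library, structure_path,
                            structure_chain_id, config, source_id) {
  parent <- assign_kabat_numbering(sequence, chain_type,
                                   source_id = source_id)
  core <- .core_from_config(chain_type, config)
  lib <- dplyr::filter(library, .data$chain_type == !!chain_type)
  if (nrow(lib) == 0) {
    stop("germline library has no ", chain_type, " records", call. = FALSE)
  }
  ranking <- select_germline(parent, lib, core = core)
  acceptor <- lib[match(ranking$allele[1], lib$allele), ]
  grafted <- graft_cdrs(parent, acceptor)
  support <- NULL
  recommendations <- NULL
  final <- grafted
  if (!is.null(structure_path)) {
    model <- read_structure(structure_path)
    if (!structure_chain_id %in% model$chain) {
      warning("structure has no chain '", structure_chain_id, "'; skipping ",
              "contact analysis for the ", chain_type, " chain",
              call. = FALSE)
      return(list(parent = parent, ranking = ranking, acceptor = acceptor,
                  grafted = grafted, support = NULL,
                  recommendations = NULL, final = grafted))
    }
    mapping <- map_structure_to_kabat(model, parent, structure_chain_id)
    support <- find_fr_cdr_contacts(model, mapping,
                                    cutoff = config$contact_cutoff,
                                    config = config)
    recommendations <- recommend_back_mutations(parent, acceptor, support,
                                                core = core,
                                                config = config)
    plan <- recommended_plan(recommendations, parent, acceptor)
    final <- apply_back_mutations(grafted, plan)
  }
  list(parent = parent, ranking = ranking, acceptor = acceptor,
       grafted = grafted, support = support,
       recommendations = recommendations, final = final)
}

#' Run the full humanization pipeline
#'
#' Orchestrates numbering, germline selection, CDR grafting, and (when a
#' structure is supplied) contact analysis, back-mutation recommendation
#' and application, per chain; optionally profiles an antibody-antigen
#' complex. All stages are deterministic given the inputs and config.
#'
#' @param heavy,light Donor VH / VL amino-acid sequences (either may be
#'   omitted).
#' @param germline_library A germline library tibble
#'   ([read_germline_library()]) or a FASTA path.
#' @param fv_structure Optional PDB path of the parental Fv model.
#' @param heavy_chain_id,light_chain_id Chain ids of VH / VL in
#'   `fv_structure` (defaults `"H"`, `"L"`).
#' @param complex Optional PDB path of an antibody-antigen complex.
#' @param complex_sides List of two chain-id vectors (antibody side,
#'   antigen side) for `complex`.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, all stage outputs are
#'   written there as TSV.
#' @return A `humanization_report`: list with per-chain elements
#'   (`parent`, `ranking`, `acceptor`, `grafted`, `support`,
#'   `recommendations`, `final`) under `$heavy` / `$light`, plus
#'   `$profile` (an [interface_profile()] or `NULL`) and `$config`.
#' @export
run_humanization <- function(heavy = NULL, light = NULL, germline_library,
                             fv_structure = NULL, heavy_chain_id = "H",
                             light_chain_id = "L", complex = NULL,
                             complex_sides = NULL,
                             config = pipeline_config(),
                             output_dir = NULL) {
  if (is.null(heavy) && is.null(light)) {
    stop("supply at least one donor chain sequence", call. = FALSE)
  }
  if (is.character(germline_library) && length(germline_library) == 1 &&
      file.exists(germline_library)) {
    germline_library <- read_germline_library(germline_library)
  }
  report <- list(config = config)
  if (!is.null(heavy)) {
    report$heavy <- .humanize_chain(heavy, "heavy", germline_library,
                                    fv_structure, heavy_chain_id, config,
                                    "donor_heavy")
  }
  if (!is.null(light)) {
    report$light <- .humanize_chain(light, "light", germline_library,
                                    fv_structure, light_chain_id, config,
                                    "donor_light")
  }
  report$profile <- NULL
  if (!is.null(complex)) {
    if (!file.exists(complex)) {
      stop("affinity stage: complex structure file not found: ", complex,
           call. = FALSE)
    }
    if (is.null(complex_sides) || length(complex_sides) != 2) {
      stop("affinity stage: complex_sides must list the two side",
           " chain-id sets", call. = FALSE)
    }
    model <- read_structure(complex)
    report$profile <- interface_profile(model, complex_sides[[1]],
                                        complex_sides[[2]], config = config)
  }
  class(report) <- "humanization_report"
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Write all report artifacts to a directory
#'
#' @param report A `humanization_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ct in c("heavy", "light")) {
    st <- report[[ct]]
    if (is.null(st)) next
    write_numbering_tsv(st$parent, file.path(dir, paste0(ct, "_numbering.tsv")))
    write_ranking_tsv(st$ranking, file.path(dir, paste0(ct, "_germlines.tsv")))
    write_provenance_tsv(st$final, file.path(dir, paste0(ct, "_humanized.tsv")))
    if (!is.null(st$support)) {
      write_contacts_tsv(st$support, file.path(dir, paste0(ct, "_contacts.tsv")))
      write_recommendations_tsv(
        st$recommendations, file.path(dir, paste0(ct, "_recommendations.tsv")))
    }
  }
  if (!is.null(report$profile)) {
    write_profile_tsv(report$profile, file.path(dir, "interface_profile.tsv"))
  }
  invisible(dir)
}

#' @export
print.humanization_report <- function(x, ...) {
  cat("<humanization_report>\n")
  for (ct in c("heavy", "light")) {
    st <- x[[ct]]
    if (is.null(st)) next
    cat(sprintf("  %s: acceptor %s (identity %.2f, core %d/%d)",
                ct, st$ranking$allele[1], st$ranking$framework_identity[1],
                st$ranking$upper_core_preserved[1],
                st$ranking$upper_core_total[1]))
    if (!is.null(st$recommendations)) {
      cat(sprintf(", %d back mutation(s)",
                  sum(st$recommendations$decision == "BACK_MUTATE")))
    }
    cat("\n")
  }
  if (!is.null(x$profile)) {
    cat(sprintf("  complex: dG %.2f kcal/mol, Kd %.2e M\n",
                x$profile$delta_g, x$profile$kd))
  }
  invisible(x)
}
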