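#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for pipeline result objects
#'
#' `tidy()` returns the per-item detail of a result as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A `germline_match`, `germline_ranking` or `interface_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.germline_match <- function(x, ...) x$positions

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.germline_match <- function(x, ...) {
  tibble::tibble(
    allele = x$allele,
    framework_identity = x$framework_identity,
    upper_core_preserved = x$upper_core_preserved,
    upper_core_total = x$upper_core_total
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.germline_ranking <- function(x, ...) {
  tibble::as_tibble(dplyr::select(x, -"match"))
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.interface_profile <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = x$ic_counts$class_pair,
                   value = as.numeric(x$ic_counts$count)),
    tibble::tibble(
      term = c("nis_apolar_pct", "nis_charged_pct", "delta_g", "kd"),
      value = c(x$nis_apolar_pct, x$nis_charged_pct, x$delta_g, x$kd)
    )
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.interface_profile <- function(x, ...) {
  ic <- stats::setNames(x$ic_counts$count, x$ic_counts$class_pair)
  tibble::tibble(
    dG_kcal_mol = x$delta_g,
    Kd_M_at_25C = x$kd,
    ICs_charged_charged = ic[["charged_charged"]],
    ICs_charged_polar = ic[["charged_polar"]],
    ICs_charged_apolar = ic[["charged_apolar"]],
    ICs_polar_polar = ic[["polar_polar"]],
    ICs_polar_apolar = ic[["polar_apolar"]],
    ICs_apolar_apolar = ic[["apolar_apolar"]]
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.humanization_report <- function(x, ...) {
  rows <- purrr::map_dfr(c("heavy", "light"), function(ct) {
    st <- x[[ct]]
    if (is.null(st)) return(tibble::tibble())
    tibble::tibble(
      chain_type = ct,
      acceptor = st$ranking$allele[1],
      framework_identity = st$ranking$framework_identity[1],
      upper_core_preserved = st$ranking$upper_core_preserved[1],
      upper_core_total = st$ranking$upper_core_total[1],
      n_back_mutations = if (is.null(st$recommendations)) NA_integer_ else {
        sum(st$recommendations$decision == "BACK_MUTATE")
      }
    )
  })
  rows
}

#' Plot a framework-to-CDR support map
#'
#' Tile plot of detected contacts (framework position vs CDR position,
#' filled by interaction class).
#'
#' @param object A `support_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.support_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$cdr_label, unique(.data$cdr_label)),
    y = factor(.data$fr_label, rev(unique(.data$fr_label))),
    fill = .data$interaction_class
  )) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$min_distance)), size = 3) +
    ggplot2::labs(x = "CDR position (Kabat)",
                  y = "Framework position (Kabat)",
                  fill = "Interaction") +
    ggplot2::theme_minimal()
}

#' Plot an interface profile
#'
#' Bar chart of the six interfacial-contact class buckets, annotated with
#' the predicted binding free energy and Kd.
#'
#' @param object An `interface_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.interface_profile <- function(object, ...) {
  df <- object$ic_counts
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$class_pair, IC_CLASS_PAIRS), y = .data$count
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Interfacial contact class", y = "Count",
      title = sprintf("dG = %.2f kcal/mol, Kd = %.2e M", object$delta_g,
                      object$kd)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a germline ranking
#'
#' Framework identity against upper-core preservation for every candidate
#' acceptor, with fully preserving candidates highlighted.
#'
#' @param object A `germline_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.germline_ranking <- function(object, ...) {
  df <- tidy.germline_ranking(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$framework_identity, y = .data$upper_core_preserved,
    color = .data$fully_preserving, label = .data$allele
  )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Framework identity", y = "Upper-core positions preserved",
                  color = "Fully preserving") +
    ggplot2::theme_minimal()
}
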