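#' Number-frequency size distribution of a pellet population
#'
#' Computes the number-weighted (q0) histogram of equivalent diameters, the
#' D10/D50/D90 percentiles (linear interpolation of the empirical CDF, the
#' default quantile definition, which reproduces exact order statistics on
#' odd-length samples), the normalized span width `(D90 - D10) / D50`, and
#' the standard deviation of the diameters. Bins are left-closed intervals
#' `[a, a + bin_width)` aligned to multiples of the bin width.
#'
#' @param diameters_um Numeric vector of equivalent diameters (um), nonempty.
#' @param bin_width_um Histogram bin width in um (`> 0`).
#' @param class Optional class name, used in error messages and stored in
#'   the result.
#' @param span_denominator `"D50"` (default, the standard particle-sizing
#'   definition) or `"2D50"` for `(D90 - D10) / (2 * D50)`.
#' @return An object of class `size_distribution`: list with `histogram`
#'   (tibble: `bin_lo`, `bin_hi`, `bin_mid`, `count`, `q0`), `n`, `D10`,
#'   `D50`, `D90`, `span`, `sd_diameter`, `bin_width_um`, `class`.
#' @export
size_distribution <- function(diameters_um, bin_width_um, class = NULL,
                              span_denominator = c("D50", "2D50")) {
  span_denominator <- match.arg(span_denominator)
  if (length(diameters_um) == 0)
    stopf("no diameters supplied%s",
          if (is.null(class)) "" else sprintf(" for class %s", class))
  if (!is.numeric(bin_width_um) || bin_width_um <= 0)
    stopf("`bin_width_um` must be positive")
  d <- as.numeric(diameters_um)
  lo <- floor(min(d) / bin_width_um) * bin_width_um
  hi <- ceiling((max(d) + 1e-9) / bin_width_um) * bin_width_um
  if (hi <= lo) hi <- lo + bin_width_um
  edges <- seq(lo, hi, by = bin_width_um)
  idx <- findInterval(d, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  qs <- quantile(d, probs = c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  denom <- if (span_denominator == "D50") qs[2] else 2 * qs[2]
  structure(list(
    histogram = tibble::tibble(
      bin_lo = edges[-length(edges)],
      bin_hi = edges[-1],
      bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
      count = counts,
      q0 = counts / sum(counts)
    ),
    n = length(d),
    D10 = qs[1], D50 = qs[2], D90 = qs[3],
    span = (qs[3] - qs[1]) / denom,
    sd_diameter = if (length(d) > 1) sd(d) else 0,
    bin_width_um = bin_width_um,
    class = class
  ), class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(
    "<size_distribution%s: n = %d, D50 = %.0f um, span = %.2f, sd = %.0f um>\n",
    if (is.null(x$class)) "" else paste0(" [", x$class, "]"),
    x$n, x$D50, x$span, x$sd_diameter))
  invisible(x)
}

#' Pellet concentration in the original sample
#'
#' Counted pellets per millilitre of undiluted culture broth. Samples are
#' prepared by a 1-in-10 dilution into saline before imaging, hence the
#' default dilution factor of 10.
#'
#' @param count Number of pellets counted.
#' @param sample_volume_mL Analysed (imaged) volume in mL (`> 0`).
#' @param dilution_factor Dilution applied before imaging.
#' @return Pellets per mL of undiluted sample.
#' @export
concentration <- function(count, sample_volume_mL, dilution_factor = 10) {
  if (!is.numeric(sample_volume_mL) || sample_volume_mL <= 0)
    stopf("`sample_volume_mL` must be positive")
  count / sample_volume_mL * dilution_factor
}

#' Aggregation frequency of the bacterial population
#'
#' Fraction of bacterial objects that are aggregates:
#' `n_aggregate / (n_aggregate + n_single)`.
#'
#' @param classes Character vector of class labels.
#' @return Fraction in `[0, 1]`, or `NA` if no bacterial objects are
#'   present (the quantity is undefined).
#' @export
aggregation_frequency <- function(classes) {
  n_sc <- sum(classes == "SC_pellet")
  n_agg <- sum(classes == "SC_aggregate")
  if (n_sc + n_agg == 0) return(NA_real_)
  n_agg / (n_sc + n_agg)
}

#' Per-class population summary
#'
#' Summarises a classified pellet table into per-class counts, size
#' percentiles, span, standard deviation, optional concentration, and the
#' aggregation frequency of the bacterial population. Pellets in contact
#' with the image border are excluded by default (their sizes are
#' truncated by the field of view).
#'
#' @param pellets Tibble with at least `class` and `equiv_diameter_um`
#'   (and `border_contact` if border exclusion is wanted).
#' @param bin_widths_um Named bin widths per class (um). Defaults follow
#'   the granularity used for the two species: 100 um for the fungal and
#'   25 um for the bacterial classes.
#' @param sample_volume_mL,dilution_factor Optional volume normalisation
#'   for concentrations; when `sample_volume_mL` is `NULL` only counts are
#'   reported.
#' @param exclude_border Drop border-contact pellets before summarising.
#' @param span_denominator Passed to [size_distribution()].
#' @return An object of class `population_summary`: list with `summary`
#'   (per-class tibble), `distributions` (named list of
#'   [size_distribution()] results), `aggregation_frequency`.
#' @export
summarize_population <- function(pellets,
                                 bin_widths_um = c(AN_pellet = 100,
                                                   SC_pellet = 25,
                                                   SC_aggregate = 25),
                                 sample_volume_mL = NULL,
                                 dilution_factor = 10,
                                 exclude_border = TRUE,
                                 span_denominator = "D50") {
  p <- tibble::as_tibble(pellets)
  if (exclude_border && "border_contact" %in% names(p))
    p <- dplyr::filter(p, !.data$border_contact)
  dists <- list()
  rows <- lapply(PELLET_CLASSES, function(cl) {
    d <- p$equiv_diameter_um[p$class == cl]
    n <- length(d)
    if (n == 0) {
      return(tibble::tibble(class = cl, n = 0L, D10 = NA_real_,
                            D50 = NA_real_, D90 = NA_real_, span = NA_real_,
                            sd_diameter = NA_real_,
                            concentration_per_mL = NA_real_))
    }
    sdist <- size_distribution(d, bin_widths_um[[cl]], class = cl,
                               span_denominator = span_denominator)
    dists[[cl]] <<- sdist
    tibble::tibble(
      class = cl, n = n, D10 = sdist$D10, D50 = sdist$D50, D90 = sdist$D90,
      span = sdist$span, sd_diameter = sdist$sd_diameter,
      concentration_per_mL = if (is.null(sample_volume_mL)) NA_real_
        else concentration(n, sample_volume_mL, dilution_factor)
    )
  })
  structure(list(
    summary = dplyr::bind_rows(rows),
    distributions = dists,
    aggregation_frequency = aggregation_frequency(p$class),
    n_total = nrow(p)
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("<population_summary>\n")
  print(x$summary)
  cat(sprintf("aggregation frequency: %s\n",
              format(x$aggregation_frequency, digits = 3)))
  invisible(x)
}

#' Tidy a population summary
#' @param x A `population_summary`.
#' @param ... Unused.
#' @return The per-class summary tibble.
#' @method tidy population_summary
#' @export
tidy.population_summary <- function(x, ...) x$summary

#' One-row overview of a population summary
#' @param x A `population_summary`.
#' @param ... Unused.
#' @return One-row tibble with total count and aggregation frequency.
#' @method glance population_summary
#' @export
glance.population_summary <- function(x, ...) {
  tibble::tibble(n_total = x$n_total,
                 aggregation_frequency = x$aggregation_frequency)
}

#' Compare replicate population summaries
#'
#' Divergence report between two summaries with identical class binning:
#' per class, the absolute D50 difference, the absolute span difference,
#' and the q0 histogram intersection distance
#' `1 - sum(min(q0_A, q0_B))` over the union of bins.
#'
#' @param summaryA,summaryB Objects from [summarize_population()].
#' @return Tibble with one row per class present in both summaries.
#' @export
compare_replicates <- function(summaryA, summaryB) {
  stopifnot(inherits(summaryA, "population_summary"),
            inherits(summaryB, "population_summary"))
  common <- intersect(names(summaryA$distributions),
                      names(summaryB$distributions))
  rows <- lapply(common, function(cl) {
    a <- summaryA$distributions[[cl]]
    b <- summaryB$distributions[[cl]]
    if (a$bin_width_um != b$bin_width_um)
      stopf("binning mismatch for class %s (%g vs %g um)",
            cl, a$bin_width_um, b$bin_width_um)
    bw <- a$bin_width_um
    lo <- min(a$histogram$bin_lo, b$histogram$bin_lo)
    hi <- max(a$histogram$bin_hi, b$histogram$bin_hi)
    mids <- seq(lo + bw / 2, hi - bw / 2, by = bw)
    qa <- a$histogram$q0[match(round(mids, 9),
                               round(a$histogram$bin_mid, 9))]
    qb <- b$histogram$q0[match(round(mids, 9),
                               round(b$histogram$bin_mid, 9))]
    qa[is.na(qa)] <- 0; qb[is.na(qb)] <- 0
    tibble::tibble(
      class = cl,
      delta_D50 = abs(a$D50 - b$D50),
      delta_span = abs(a$span - b$span),
      q0_intersection_distance = 1 - sum(pmin(qa, qb))
    )
  })
  dplyr::bind_rows(rows)
}

#' Plot a pellet size distribution (q0 bars with a D50 line)
#' @param object A `size_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot size_distribution
#' @export
autoplot.size_distribution <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$q0)) +
    ggplot2::geom_col(width = object$bin_width_um * 0.9,
                      fill = "steelblue", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$D50, linewidth = 1,
                        colour = "firebrick") +
    ggplot2::labs(
      x = "equivalent diameter [µm]", y = expression(q[0]),
      title = if (is.null(object$class)) "pellet size distribution"
              else object$class,
      subtitle = sprintf("n = %d, D50 = %.0f µm, span = %.2f",
                         object$n, object$D50, object$span)
    ) +
    ggplot2::theme_minimal()
}

#' Plot all class distributions of a population summary
#' @param object A `population_summary`.
#' @param ... Unused.
#' @return A ggplot object (classes facetted).
#' @method autoplot population_summary
#' @export
autoplot.population_summary <- function(object, ...) {
  hs <- dplyr::bind_rows(lapply(names(object$distributions), function(cl) {
    dplyr::mutate(object$distributions[[cl]]$histogram, class = cl)
  }))
  d50 <- dplyr::bind_rows(lapply(names(object$distributions), function(cl) {
    tibble::tibble(class = cl, D50 = object$distributions[[cl]]$D50)
  }))
  ggplot2::ggplot(hs, ggplot2::aes(x = .data$bin_mid, y = .data$q0)) +
    ggplot2::geom_col(fill = "steelblue", colour = "grey30") +
    ggplot2::geom_vline(data = d50, ggplot2::aes(xintercept = .data$D50),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~class, scales = "free") +
    ggplot2::labs(x = "equivalent diameter [µm]",
                  y = expression(q[0])) +
    ggplot2::theme_minimal()
}

#' Write a population summary as JSON (plus optional histogram CSV)
#' @param x A `population_summary`.
#' @param json_path JSON output path.
#' @param histogram_csv_path Optional CSV path for the binned histograms.
#' @return `x`, invisibly.
#' @export
write_population_summary <- function(x, json_path,
                                     histogram_csv_path = NULL) {
  jsonlite::write_json(list(
    summary = x$summary,
    aggregation_frequency = x$aggregation_frequency,
    n_total = x$n_total
  ), json_path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(histogram_csv_path)) {
    hs <- dplyr::bind_rows(lapply(names(x$distributions), function(cl) {
      dplyr::mutate(x$distributions[[cl]]$histogram, class = cl)
    }))
    write.csv(hs, histogram_csv_path, row.names = FALSE)
  }
  invisible(x)
}
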