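# Colour mapping of subunit half-lives onto complex structures.

# piecewise-linear red -> white -> blue ramp; pos in [0, 1], 0.5 = midpoint
.gradient_hex <- function(pos) {
  pos <- pmin(1, pmax(0, pos))
  lower <- pos <= 0.5
  f <- ifelse(lower, pos / 0.5, (pos - 0.5) / 0.5)
  r <- ifelse(lower, 255, round(255 * (1 - f)))
  g <- ifelse(lower, round(255 * f), round(255 * (1 - f)))
  b <- ifelse(lower, round(255 * f), 255)
  grDevices::rgb(r, g, b, maxColorValue = 255)
}

#' Half-life colour map for complex subunits
#'
#' Maps subunit half-lives onto a linear three-colour gradient (red = short,
#' white = midpoint, blue = long) for rendering on complex structures. Only
#' half-lives with R-squared of at least `min_r2` are used. To keep outliers
#' from distorting the gradient, the midpoint is the mean of the
#' per-replicate medians of the subunit half-lives and the interpolation
#' bounds are the means of the per-replicate 15th and 85th percentiles;
#' values outside the bounds are clipped. Subunits without a usable value are
#' flagged and coloured green. Fused segments (one rendered density covering
#' several subunits) are coloured by the mean half-life of their members.
#'
#' @param subunits Tibble (`accession`, `replicate`, `t_half`, `r_squared`).
#' @param segments Optional named list: segment name -> character vector of
#'   member accessions rendered as one unit.
#' @param min_r2 R-squared cutoff (default 0.25).
#' @param probs Lower/upper percentile bounds of the gradient.
#' @return Tibble (`unit`, `t_half`, `colour`, `clipped`, `determined`) with
#'   the legend bounds (`lower`, `midpoint`, `upper`) as attributes.
#' @export
halflife_color_map <- function(subunits, segments = NULL, min_r2 = 0.25,
                               probs = c(0.15, 0.85)) {
  usable <- subunits |>
    filter(!is.na(.data$t_half), .data$t_half > 0,
           !is.na(.data$r_squared), .data$r_squared >= min_r2)
  if (n_distinct(usable$accession) < 2) {
    abort("Need at least two subunits with usable half-lives.")
  }
  per_rep <- usable |>
    group_by(.data$replicate) |>
    summarise(median = median(.data$t_half),
              lower = quantile(.data$t_half, probs[1], type = 7),
              upper = quantile(.data$t_half, probs[2], type = 7),
              .groups = "drop")
  midpoint <- mean(per_rep$median)
  lower <- mean(per_rep$lower)
  upper <- mean(per_rep$upper)

  values <- usable |>
    group_by(.data$accession) |>
    summarise(t_half = mean(.data$t_half), .groups = "drop")
  all_units <- tibble(unit = unique(subunits$accession)) |>
    left_join(rename(values, unit = "accession"), by = "unit")
  if (!is.null(segments)) {
    fused <- purrr::imap_dfr(segments, function(members, name) {
      v <- values$t_half[values$accession %in% members]
      tibble(unit = name, t_half = if (length(v) > 0) mean(v) else NA_real_)
    })
    all_units <- all_units |>
      filter(!.data$unit %in% unlist(segments)) |>
      bind_rows(fused)
  }

  position <- function(v) {
    ifelse(v <= midpoint,
           if (midpoint > lower) 0.5 * (v - lower) / (midpoint - lower) else 0.5,
           if (upper > midpoint) 0.5 + 0.5 * (v - midpoint) / (upper - midpoint) else 0.5)
  }
  out <- all_units |>
    mutate(
      determined = !is.na(.data$t_half),
      clipped = .data$determined & (.data$t_half < lower | .data$t_half > upper),
      colour = ifelse(.data$determined,
                      .gradient_hex(position(tidyr::replace_na(.data$t_half, midpoint))),
                      "#00B200")
    )
  attr(out, "lower") <- lower
  attr(out, "midpoint") <- midpoint
  attr(out, "upper") <- upper
  out
}
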