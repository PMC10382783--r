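#' Build one-way sensitivity specifications
#'
#' One specification per base parameter (eight for the two-arm model).
#' Parameters carrying a 95\% confidence interval (the cost parameters) are
#' varied over the interval bounds; parameters without one (probabilities,
#' utility decrements) are varied by `mean * (1 +/- relative_variation)`,
#' with explicit overrides from `cfg$dsa$bounds` taking precedence.
#' Probability bounds escaping \[0, 1\] are clipped with a warning rather
#' than rejected.
#'
#' The `low`/`high` slots follow the sign of the mean, so for a negative
#' utility decrement `low` is the smaller-magnitude bound — matching the
#' published ordering of lower/upper ICER columns. Results are keyed by
#' bound value, not column position.
#'
#' @param cfg A [model_config].
#' @return data.frame of class `"dsa_specs"`: `parameter_id`, `base`, `low`,
#'   `high`, `bound_source` (`"ci95"`, `"relative20"`, or `"explicit"`).
#' @export
build_dsa_specs <- function(cfg) {
  stopifnot(inherits(cfg, "cua_config"))
  rel <- cfg$dsa$relative_variation
  rows <- lapply(param_ids(), function(id) {
    pe <- get_param(cfg, id)
    is_prob <- grepl("p_error", id)
    if (!is.null(cfg$dsa$bounds[[id]])) {
      b <- cfg$dsa$bounds[[id]]
      low <- b[1]; high <- b[2]; src <- "explicit"
    } else if (!is.null(pe$ci_low)) {
      low <- pe$ci_low; high <- pe$ci_high; src <- "ci95"
    } else {
      low <- pe$mean * (1 - rel); high <- pe$mean * (1 + rel)
      src <- sprintf("relative%d", round(100 * rel))
    }
    if (low == high)
      stop(sprintf("build_dsa_specs: degenerate bounds for '%s'", id),
           call. = FALSE)
    if (is_prob && (low < 0 || high > 1)) {
      warning(sprintf("build_dsa_specs: clipping '%s' bounds to [0, 1]", id),
              call. = FALSE)
      low <- max(low, 0); high <- min(high, 1)
    }
    data.frame(parameter_id = id, base = pe$mean, low = low, high = high,
               bound_source = src, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("dsa_specs", "data.frame"))
}

#' One-way deterministic sensitivity analysis
#'
#' For each specification, sets the parameter to each bound in turn (all
#' other parameters at base values), re-evaluates the decision tree and
#' records the ICER and dominance quadrant at both bounds. An undefined ICER
#' at a bound is recorded as `NA`, never dropped.
#'
#' @param cfg A [model_config], or a fitted `"cua"` object (its config is
#'   used).
#' @param specs Specifications from [build_dsa_specs()]; built from `cfg` by
#'   default.
#' @return data.frame of class `"cua_dsa"`, ordered for the tornado diagram
#'   (descending ICER range width, ties broken lexicographically): columns
#'   `parameter_id`, `base`, `low`, `high`, `bound_source`, `icer_low`,
#'   `icer_high`, `dominance_low`, `dominance_high`, `range_width`.
#' @examples
#' one_way_dsa(base_case_config())
#' @export
one_way_dsa <- function(cfg, specs = NULL) {
  if (inherits(cfg, "cua")) cfg <- cfg$config
  stopifnot(inherits(cfg, "cua_config"))
  if (is.null(specs)) specs <- build_dsa_specs(cfg)
  if (anyDuplicated(specs$parameter_id))
    stop("one_way_dsa: specs must cover distinct parameters", call. = FALSE)
  icer_at <- function(id, value) {
    fit <- cua(set_param_mean(cfg, id, value))
    fit$incremental
  }
  res <- lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    lo <- icer_at(sp$parameter_id, sp$low)
    hi <- icer_at(sp$parameter_id, sp$high)
    width <- if (lo$icer_defined && hi$icer_defined) abs(hi$icer - lo$icer)
             else NA_real_
    cbind(sp,
          data.frame(icer_low = lo$icer, icer_high = hi$icer,
                     dominance_low = lo$dominance,
                     dominance_high = hi$dominance,
                     range_width = width, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, res)
  out <- tornado_order(out)
  structure(out, class = c("cua_dsa", "data.frame"))
}

#' Tornado ordering of DSA results
#'
#' Descending by ICER range width; ties (and undefined widths, placed last)
#' broken by parameter id in lexicographic order.
#'
#' @param results A data.frame with `range_width` and `parameter_id` columns.
#' @return The same data.frame, reordered.
#' @export
tornado_order <- function(results) {
  stopifnot(nrow(results) >= 1)
  w <- results$range_width
  w[is.na(w)] <- -Inf
  ord <- order(-w, results$parameter_id, method = "radix")
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.cua_dsa <- function(x, ...) {
  cat("One-way deterministic sensitivity analysis (tornado order)\n")
  show <- data.frame(parameter = x$parameter_id,
                     low = signif(x$low, 6), high = signif(x$high, 6),
                     icer_low = round(x$icer_low, 2),
                     icer_high = round(x$icer_high, 2),
                     dominance_low = x$dominance_low,
                     dominance_high = x$dominance_high)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Tornado diagram
#'
#' Horizontal bars spanning each parameter's low/high ICER, widest at the
#' top, with the base-case ICER as a reference line.
#'
#' @param x A `"cua_dsa"` object.
#' @param base_icer Base-case ICER for the reference line; recomputed from
#'   nothing is not possible here, so pass it (default `NULL` draws no line).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.cua_dsa <- function(x, base_icer = NULL, ...) {
  n <- nrow(x)
  xl <- range(c(x$icer_low, x$icer_high, base_icer), na.rm = TRUE)
  y <- rev(seq_len(n))
  graphics::plot(NA, xlim = xl, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "ICER (EUR/QALY)", ylab = "",
                 main = "One-way sensitivity analysis", ...)
  graphics::segments(pmin(x$icer_low, x$icer_high), y,
                     pmax(x$icer_low, x$icer_high), y,
                     lwd = 10, col = "steelblue", lend = 1)
  if (!is.null(base_icer))
    graphics::abline(v = base_icer, lty = 2)
  graphics::axis(2, at = y, labels = x$parameter_id, las = 1, cex.axis = 0.7)
  invisible(x)
}
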