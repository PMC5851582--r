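#' Derive vulnerability criteria thresholds for a site
#'
#' Builds the criteria configuration used to flag reef cells vulnerable to
#' land-based nutrients under a warming ocean: shallow depth (bleaching
#' exposure), above-site-mean cover of the site's indicator benthic groups,
#' nutrient flux above the upper tercile, and (where active) wave power below
#' the lower tercile (limited mixing). Benthic thresholds default to the site
#' means of the predicted maps; tercile thresholds use linear-interpolation
#' percentiles over valid cells. Printed site-specific values may be supplied
#' as `overrides`.
#'
#' The wet-site preset uses coral / macroalgae / turf cover with the N and
#' wave criteria (P inactive); the dry-site preset uses coral / CCA / turf
#' with N and P (wave inactive).
#'
#' @param stack a `driver_stack` (needs `depth`, `wave_power`, `n_flux`, and
#'   `p_flux` when active).
#' @param predictions named list of predicted benthic cover rasters.
#' @param site `"wet"` or `"dry"` preset criterion set.
#' @param depth_max bleaching depth cutoff (m), default 5.
#' @param overrides named list of threshold overrides (e.g.
#'   `list(coral = 11.4, n_flux = 1322.7)`).
#' @return a `criteria_config` list: `depth_max`, `benthic` (named
#'   thresholds), `nutrient` (named), `wave` (or `NA` if inactive).
#' @export
derive_thresholds <- function(stack, predictions, site = c("wet", "dry"),
                              depth_max = 5, overrides = NULL) {
  site <- match.arg(site)
  benthic_set <- if (site == "wet") c("coral", "macroalgae", "turf")
                 else c("coral", "cca", "turf")
  nutrient_set <- if (site == "wet") "n_flux" else c("n_flux", "p_flux")
  wave_active <- site == "wet"
  site_mean <- function(r) {
    v <- r$values[!is.na(r$values)]
    if (!length(v)) stop("empty valid-cell set in prediction map")
    mean(v)
  }
  tercile <- function(r, which) {
    v <- r$values[!is.na(r$values)]
    if (!length(v)) stop("empty valid-cell set in driver layer")
    stats::quantile(v, if (which == "upper") 2 / 3 else 1 / 3, type = 7, names = FALSE)
  }
  benthic <- vapply(benthic_set, function(nm) {
    if (!is.null(overrides[[nm]])) overrides[[nm]] else site_mean(predictions[[nm]])
  }, 0)
  nutrient <- vapply(nutrient_set, function(nm) {
    if (!is.null(overrides[[nm]])) overrides[[nm]] else tercile(stack[[nm]], "upper")
  }, 0)
  wave <- if (!wave_active) NA_real_
          else overrides[["wave_power"]] %||% tercile(stack$wave_power, "lower")
  structure(list(site = site, depth_max = depth_max, benthic = benthic,
                 nutrient = nutrient, wave = wave),
            class = "criteria_config")
}

#' @export
print.criteria_config <- function(x, ...) {
  cat("<criteria_config>", x$site, "site; depth <", x$depth_max, "m\n")
  cat("  benthic cover >:", paste(sprintf("%s %.2f%%", names(x$benthic), x$benthic),
                                  collapse = ", "), "\n")
  cat("  nutrient flux >:", paste(sprintf("%s %.2f", names(x$nutrient), x$nutrient),
                                  collapse = ", "), "\n")
  if (is.finite(x$wave)) cat(sprintf("  wave power < %.0f\n", x$wave))
  invisible(x)
}

#' Classify vulnerable reef cells
#'
#' A cell is flagged when every active criterion holds: depth shallower than
#' the cutoff, every benthic prediction above its threshold, every nutrient
#' layer above its threshold, and (when active) wave power below its
#' threshold. The per-criterion masks are returned so the flag set can be
#' verified as their intersection.
#'
#' @param stack a `driver_stack`.
#' @param predictions named list of predicted benthic cover rasters.
#' @param criteria a `criteria_config` from [derive_thresholds()].
#' @return a `vulnerability_map` list: `flags` (0/1 raster), `masks` (list of
#'   logical matrices per criterion), `criteria`, `n_flagged`.
#' @export
classify_vulnerable <- function(stack, predictions, criteria) {
  depth <- stack$depth
  valid <- !is.na(depth$values)
  masks <- list(depth = valid & depth$values >= -criteria$depth_max)
  for (nm in names(criteria$benthic)) {
    r <- predictions[[nm]]
    if (is.null(r)) stop("criterion references missing prediction layer: ", nm)
    masks[[nm]] <- valid & !is.na(r$values) & r$values > criteria$benthic[nm]
  }
  for (nm in names(criteria$nutrient)) {
    r <- stack[[nm]]
    if (is.null(r)) stop("criterion references missing driver layer: ", nm)
    masks[[nm]] <- valid & !is.na(r$values) & r$values > criteria$nutrient[nm]
  }
  if (is.finite(criteria$wave)) {
    masks$wave_power <- valid & !is.na(stack$wave_power$values) &
      stack$wave_power$values < criteria$wave
  }
  flags <- Reduce(`&`, masks)
  fm <- matrix(as.numeric(flags), nrow(depth$values), ncol(depth$values))
  fm[!valid] <- NA_real_
  structure(list(flags = grid_with(depth, fm, units = "flag"),
                 masks = masks, criteria = criteria,
                 n_flagged = sum(flags, na.rm = TRUE)),
            class = "vulnerability_map")
}

#' @export
print.vulnerability_map <- function(x, ...) {
  cat("<vulnerability_map>", x$n_flagged, "flagged cell(s) under",
      length(x$masks), "criteria\n")
  invisible(x)
}

#' Match vulnerable reef cells to their priority flow tubes
#'
#' Attributes each flagged reef cell to the flow tube contributing the
#' largest nutrient plume at that cell, then ranks tubes by anthropogenic
#' nutrient flux and flagged-cell count (lexicographically descending, tube
#' id as the final tiebreak). Tubes with no attributed flags rank last with
#' zero counts.
#'
#' @param vuln a `vulnerability_map`.
#' @param budget a `tube_budget` from [zone_budget()].
#' @param per_tube_plumes list of per-tube nutrient plume rasters
#'   (`stack_plumes()$per_tube`).
#' @return data.frame ranked by priority: `id`, `flagged_cells`,
#'   `n_flux_anthropogenic`, `p_flux_anthropogenic`, `rank`.
#' @export
match_priority_tubes <- function(vuln, budget, per_tube_plumes) {
  flags <- which(!is.na(vuln$flags$values) & vuln$flags$values > 0)
  counts <- stats::setNames(rep(0L, nrow(budget)), budget$id)
  if (!length(flags)) {
    message("match_priority_tubes: no flagged cells; empty ranking")
  } else {
    pl <- vapply(per_tube_plumes, function(r) {
      v <- r$values[flags]
      v[is.na(v)] <- 0
      v
    }, numeric(length(flags)))
    pl <- matrix(pl, nrow = length(flags))
    best <- max.col(pl, ties.method = "first")
    contributes <- rowSums(pl) > 0
    tb <- table(factor(budget$id[best[contributes]], levels = budget$id))
    counts[names(tb)] <- as.integer(tb)
  }
  out <- data.frame(id = budget$id, flagged_cells = as.integer(counts),
                    n_flux_anthropogenic = budget$n_flux_anthropogenic,
                    p_flux_anthropogenic = budget$p_flux_anthropogenic)
  ord <- order(-out$n_flux_anthropogenic, -out$flagged_cells, out$id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
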