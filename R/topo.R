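# Topographic analysis: nearest-neighbour electrode pairing, top-view head
# projection, interpolated topographic maps, and spatial correlation with a
# shuffled-label permutation null.

#' Pair each subscalp contact with its closest scalp neighbour
#'
#' For every subscalp contact, the scalp contact minimising 3D Euclidean
#' distance; ties are broken by lexicographic contact name so the pairing is
#' deterministic.
#'
#' @param layout A [make_head_layout()] result (or any tibble with
#'   `contact`, `x`, `y`, `z`, `modality`).
#' @return Tibble of class `electrode_pairing` with columns `subscalp`,
#'   `scalp`, `distance_mm`; one row per subscalp contact.
#' @export
nearest_neighbor_pairing <- function(layout) {
  sub <- dplyr::filter(layout, .data$modality == "subscalp")
  sca <- dplyr::filter(layout, .data$modality == "scalp")
  if (nrow(sub) == 0 || nrow(sca) == 0) {
    abort("layout must contain at least one subscalp and one scalp contact")
  }
  Ps <- as.matrix(sub[, c("x", "y", "z")])
  Pc <- as.matrix(sca[, c("x", "y", "z")])
  rows <- purrr::map(seq_len(nrow(Ps)), function(i) {
    d <- sqrt(colSums((t(Pc) - Ps[i, ])^2))
    m <- min(d)
    cand <- sort(sca$contact[d <= m + 1e-9])
    tibble::tibble(subscalp = sub$contact[i], scalp = cand[1], distance_mm = m)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("electrode_pairing", class(out))
  out
}

#' Azimuthal-equidistant top-view projection of a layout
#'
#' Projects contact positions about the vertex: the vertex maps to the
#' origin and a contact at polar angle theta maps to radius `R * theta`
#' along its azimuthal direction, so an equator contact lands at
#' `R * pi / 2`. Positions off the sphere are projected via normalisation
#' and flagged.
#'
#' @param layout A layout tibble with `contact`, `x`, `y`, `z`.
#' @return Tibble with columns `contact`, `x`, `y` (projected mm) and
#'   `modality` if present; normalised contacts are listed in the
#'   `normalized` attribute.
#' @export
project_2d <- function(layout) {
  P <- as.matrix(layout[, c("x", "y", "z")])
  r <- sqrt(rowSums(P^2))
  radius <- attr(layout, "radius") %||% max(r)
  expected <- ifelse(
    ("modality" %in% names(layout)) & layout$modality == "subscalp",
    radius - (attr(layout, "scalp_thickness") %||% 7), radius
  )
  off_sphere <- abs(r - expected) > 1e-6 * radius
  theta <- acos(pmin(1, pmax(-1, ifelse(r > 0, P[, 3] / r, 1))))
  xy <- sqrt(P[, 1]^2 + P[, 2]^2)
  ux <- ifelse(xy > 0, P[, 1] / xy, 0)
  uy <- ifelse(xy > 0, P[, 2] / xy, 0)
  rho <- radius * theta
  out <- tibble::tibble(contact = layout$contact, x = rho * ux, y = rho * uy)
  if ("modality" %in% names(layout)) out$modality <- layout$modality
  attr(out, "radius") <- radius
  attr(out, "normalized") <- layout$contact[off_sphere]
  out
}

#' Build a topographic map from per-contact values
#'
#' @param layout Layout tibble (typically one modality, e.g.
#'   `dplyr::filter(layout, modality == "subscalp")`).
#' @param values Named numeric vector (names = contacts) or a tibble with
#'   `contact` and `value` columns.
#' @return Tibble of class `topo_map` with `contact`, projected `x`, `y`,
#'   and `value`.
#' @export
topo_map <- function(layout, values) {
  if (is.data.frame(values)) {
    values <- setNames(values$value, values$contact)
  }
  proj <- project_2d(layout)
  proj <- proj[proj$contact %in% names(values), ]
  out <- tibble::tibble(
    contact = proj$contact,
    x = proj$x, y = proj$y,
    value = as.numeric(values[proj$contact])
  )
  class(out) <- c("topo_map", class(out))
  attr(out, "radius") <- attr(proj, "radius")
  out
}

# thin-plate spline interpolation with an affine part: exact at the
# contacts and exact for any linear field
tps_fit <- function(x, y, v) {
  n <- length(x)
  D <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  K <- ifelse(D > 0, D^2 * log(D), 0)
  P <- cbind(1, x, y)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(v, 0, 0, 0)
  coef <- solve(A, rhs)
  list(x = x, y = y, w = coef[seq_len(n)], a = coef[n + 1:3])
}

tps_eval <- function(fit, gx, gy) {
  D <- sqrt(outer(gx, fit$x, "-")^2 + outer(gy, fit$y, "-")^2)
  K <- ifelse(D > 0, D^2 * log(D), 0)
  as.vector(K %*% fit$w + cbind(1, gx, gy) %*% fit$a)
}

disk_grid <- function(radius_lim, grid_resolution) {
  g <- seq(-radius_lim, radius_lim, length.out = grid_resolution)
  grid <- expand.grid(x = g, y = g)
  grid[grid$x^2 + grid$y^2 <= radius_lim^2, ]
}

#' Interpolate a topographic map onto a head-disk grid
#'
#' Thin-plate radial-basis interpolation of contact values onto a regular
#' grid masked to the head disk; exact at the contact locations.
#'
#' @param map A [topo_map()].
#' @param grid_resolution Number of grid points across the disk diameter
#'   (default 32).
#' @return The map with an added `grid` attribute (tibble `x`, `y`, `value`).
#' @export
interpolate_topomap <- function(map, grid_resolution = 32) {
  if (nrow(map) < 4) abort("topographic interpolation requires at least 4 contacts")
  fit <- tps_fit(map$x, map$y, map$value)
  radius_lim <- max(sqrt(map$x^2 + map$y^2)) * 1.05
  grid <- disk_grid(radius_lim, grid_resolution)
  grid$value <- tps_eval(fit, grid$x, grid$y)
  attr(map, "grid") <- tibble::as_tibble(grid)
  map
}

# evaluate two maps on one shared in-disk point set
common_grid_values <- function(map_a, map_b, grid_resolution = 32) {
  radius_lim <- max(sqrt(c(map_a$x, map_b$x)^2 + c(map_a$y, map_b$y)^2)) * 1.05
  grid <- disk_grid(radius_lim, grid_resolution)
  va <- tps_eval(tps_fit(map_a$x, map_a$y, map_a$value), grid$x, grid$y)
  vb <- tps_eval(tps_fit(map_b$x, map_b$y, map_b$value), grid$x, grid$y)
  list(a = va, b = vb, grid = grid)
}

#' Spatial correlation between two topographic maps
#'
#' Pearson correlation either between values interpolated on a shared
#' head-disk grid (`common_grid`, the default, which accounts for all
#' electrode locations) or between values paired through a subscalp-scalp
#' [nearest_neighbor_pairing()] (`matched_contacts`).
#'
#' @param map_a,map_b [topo_map()] objects; in matched mode `map_a` must
#'   hold the subscalp values and `map_b` the scalp values.
#' @param mode `"common_grid"` or `"matched_contacts"`.
#' @param pairing Required for matched mode.
#' @param grid_resolution Grid size for common-grid mode.
#' @return Pearson correlation (scalar). A constant map yields `NA` with a
#'   warning.
#' @export
spatial_correlation <- function(map_a, map_b,
                                mode = c("common_grid", "matched_contacts"),
                                pairing = NULL, grid_resolution = 32) {
  mode <- match.arg(mode)
  if (mode == "matched_contacts") {
    if (is.null(pairing)) abort("matched_contacts mode requires a `pairing`")
    va <- setNames(map_a$value, map_a$contact)[pairing$subscalp]
    vb <- setNames(map_b$value, map_b$contact)[pairing$scalp]
  } else {
    cg <- common_grid_values(map_a, map_b, grid_resolution)
    va <- cg$a
    vb <- cg$b
  }
  if (sd(va) == 0 || sd(vb) == 0) {
    warn("spatial correlation undefined for a constant map; returning NA")
    return(NA_real_)
  }
  cor(va, vb)
}

#' Permutation test for topographic spatial correlation
#'
#' Builds a null distribution by shuffling the value-to-contact assignment
#' of `map_a` (the subscalp map) `n_shuffles` times and recomputing the
#' spatial correlation; the one-sided p-value is
#' `(1 + #\{null >= observed\}) / (n_shuffles + 1)`, testing for positive
#' topographic similarity.
#'
#' @inheritParams spatial_correlation
#' @param n_shuffles Number of label shuffles (default 100).
#' @param seed Integer seed for reproducible shuffles.
#' @return Object of class `spatial_cor_test`: `rho`, `p_perm`,
#'   `n_shuffles`, `mode`, and the null correlations.
#' @export
permutation_spatial_test <- function(map_a, map_b, n_shuffles = 100, seed = NULL,
                                     mode = c("common_grid", "matched_contacts"),
                                     pairing = NULL, grid_resolution = 32) {
  mode <- match.arg(mode)
  if (n_shuffles < 19) {
    abort("at least 19 shuffles are required to resolve significance at 0.05")
  }
  rho <- spatial_correlation(map_a, map_b, mode, pairing, grid_resolution)
  null <- with_seed_if(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      shuf <- map_a
      shuf$value <- sample(shuf$value)
      spatial_correlation(shuf, map_b, mode, pairing, grid_resolution)
    }, numeric(1))
  })
  p <- (1 + sum(null >= rho)) / (n_shuffles + 1)
  structure(
    list(rho = rho, p_perm = p, n_shuffles = n_shuffles, mode = mode, null = null),
    class = "spatial_cor_test"
  )
}

#' @export
print.spatial_cor_test <- function(x, ...) {
  cat(sprintf(
    "Spatial correlation rho = %.3f (%s), permutation p = %.4f (%d shuffles)\n",
    x$rho, x$mode, x$p_perm, x$n_shuffles
  ))
  invisible(x)
}

#' @export
tidy.spatial_cor_test <- function(x, ...) {
  tibble::tibble(
    rho = x$rho, p_perm = x$p_perm, n_shuffles = x$n_shuffles,
    mode = x$mode, strength = cor_strength(x$rho)
  )
}

# reporting thresholds: rho > 0.5 moderate, > 0.7 strong
cor_strength <- function(rho) {
  dplyr::case_when(
    is.na(rho) ~ NA_character_,
    rho > 0.7 ~ "strong",
    rho > 0.5 ~ "moderate",
    TRUE ~ "weak"
  )
}
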