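# Electrode geometry on a spherical head model: a 25-contact 10-20 scalp
# montage, subscalp "trident" leads (one entry point, three branches of
# contacts tunnelled beneath the scalp), and intracranial contacts.
#
# Coordinate frame: x right, y anterior, z up (mm), head centre at origin.
# Scalp contacts lie on the sphere of radius R, subscalp contacts on
# R - scalp_thickness, intracranial contacts strictly inside.

sph_dir <- function(incl_deg, az_deg) {
  th <- incl_deg * pi / 180
  ph <- az_deg * pi / 180
  c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
}

# idealized 25-contact 10-20 montage: the 19 standard positions plus the
# inferior temporal row (F9/F10, T9/T10, P9/P10). Lateral mid positions are
# spherical midpoints of their midline and ring neighbours.
scalp_1020_directions <- function() {
  ring <- list(
    Fp1 = c(72, -18), Fp2 = c(72, 18), F8 = c(72, 54), T8 = c(72, 90),
    P8 = c(72, 126), O2 = c(72, 162), O1 = c(72, 198), P7 = c(72, 234),
    T7 = c(72, 270), F7 = c(72, 306)
  )
  mid <- list(Fz = c(36, 0), Cz = c(0, 0), Pz = c(36, 180))
  inf <- list(
    F9 = c(108, 306), F10 = c(108, 54), T9 = c(108, 270), T10 = c(108, 90),
    P9 = c(108, 234), P10 = c(108, 126)
  )
  dirs <- lapply(c(ring, mid, inf), function(a) sph_dir(a[1], a[2]))
  midpoint <- function(a, b) unit(dirs[[a]] + dirs[[b]])
  dirs$F3 <- midpoint("Fz", "F7")
  dirs$F4 <- midpoint("Fz", "F8")
  dirs$C3 <- midpoint("Cz", "T7")
  dirs$C4 <- midpoint("Cz", "T8")
  dirs$P3 <- midpoint("Pz", "P7")
  dirs$P4 <- midpoint("Pz", "P8")
  dirs
}

# geodesic walk on a sphere of radius r: start direction e (unit), tangent t
# (unit, orthogonal to e), arc length s in mm
geo_point <- function(e, t, s, r) {
  r * (cos(s / r) * e + sin(s / r) * t)
}

rotate_tangent <- function(e, t, angle_deg) {
  a <- angle_deg * pi / 180
  cr <- c(
    e[2] * t[3] - e[3] * t[2],
    e[3] * t[1] - e[1] * t[3],
    e[1] * t[2] - e[2] * t[1]
  )
  unit(t * cos(a) + cr * sin(a))
}

trident_sites <- function() {
  list(
    frontal = list(entry = c(70, 0), heading = "vertex"),
    temporal_left = list(entry = c(85, 290), heading = "vertex"),
    temporal_right = list(entry = c(85, 70), heading = "vertex"),
    parietal = list(entry = c(70, 180), heading = "vertex")
  )
}

#' Generate a multimodal electrode layout on a spherical head model
#'
#' Builds a 25-contact 10-20 scalp montage on a sphere of radius `radius`,
#' `n_tridents` subscalp leads of 7 contacts each on the sphere at
#' `radius - scalp_thickness` (each lead: one entry point, three branches
#' 30 degrees apart carrying 3 + 2 + 2 contacts at `contact_spacing` mm),
#' and `n_intracranial` contacts strictly inside the head. Entry sites are
#' drawn from frontal, temporal-left, temporal-right and parietal locations.
#'
#' @param n_tridents Number of subscalp leads, 1-4.
#' @param n_intracranial Number of intracranial contacts (default 0).
#' @param seed Integer seed; fully determines the layout.
#' @param radius Head sphere radius in mm (default 92).
#' @param scalp_thickness Depth of the subscalp plane in mm (default 7).
#' @param contact_spacing Contact spacing along each branch in mm (default 20).
#' @param branch_angle Angle between adjacent branches in degrees (default 30).
#' @return A tibble of class `head_layout` with columns `contact`, `x`, `y`,
#'   `z` (mm) and `modality` (`scalp`, `subscalp`, `intracranial`), plus
#'   `radius` and `scalp_thickness` attributes.
#' @export
#' @examples
#' layout <- make_head_layout(n_tridents = 4, n_intracranial = 6, seed = 1)
#' dplyr::count(layout, modality)
make_head_layout <- function(n_tridents, n_intracranial = 0, seed = NULL,
                             radius = 92, scalp_thickness = 7,
                             contact_spacing = 20, branch_angle = 30) {
  if (!is.numeric(n_tridents) || length(n_tridents) != 1 ||
      n_tridents < 1 || n_tridents > 4 || n_tridents != round(n_tridents)) {
    abort("`n_tridents` must be an integer between 1 and 4.")
  }
  n_tridents <- as.integer(n_tridents)
  stopifnot(n_intracranial >= 0)
  with_seed_if(seed, {
    dirs <- scalp_1020_directions()
    scalp <- tibble::tibble(
      contact = names(dirs),
      pos = lapply(dirs, function(d) radius * d),
      modality = "scalp"
    )
    sites <- trident_sites()
    chosen <- if (n_tridents == 4) {
      names(sites)
    } else {
      sample(names(sites), n_tridents)
    }
    r_sub <- radius - scalp_thickness
    sub_pos <- list()
    # contacts per branch: centre branch 3, side branches 2 each (7 total);
    # arc offsets keep branch lengths within the 100-120 mm tunnelled range
    offsets <- list(centre = c(50, 70, 90), side = c(60, 80))
    scalp_pos <- do.call(rbind, scalp$pos)
    trident_contacts <- function(entry_az_offset, site) {
      s <- sites[[site]]
      e <- sph_dir(s$entry[1], s$entry[2] + entry_az_offset)
      tv <- unit(c(0, 0, 1) - sum(c(0, 0, 1) * e) * e)
      if (vnorm(tv) == 0) tv <- c(0, 1, 0)
      out <- list()
      for (b in seq_len(3)) {
        ang <- (b - 2) * branch_angle
        tb <- rotate_tangent(e, tv, ang)
        arcs <- if (b == 2) offsets$centre else offsets$side
        for (a in arcs) {
          out[[length(out) + 1]] <- geo_point(e, tb, a, r_sub)
        }
      }
      out
    }
    for (site in chosen) {
      # insertion is planned: among jittered candidate orientations, tunnel
      # the lead whose contacts land closest to the scalp montage
      base <- runif(1, -5, 5)
      cand <- base + seq(-10, 10, by = 5)
      score <- vapply(cand, function(az) {
        pos <- trident_contacts(az, site)
        sum(vapply(pos, function(p) {
          min(sqrt(colSums((t(scalp_pos) - p)^2)))
        }, numeric(1)))
      }, numeric(1))
      best <- trident_contacts(cand[which.min(score)], site)
      sub_pos <- c(sub_pos, best)
    }
    sub <- tibble::tibble(
      contact = sprintf("S%02d", seq_along(sub_pos)),
      pos = sub_pos,
      modality = "subscalp"
    )
    ic <- NULL
    if (n_intracranial > 0) {
      ic_pos <- lapply(seq_len(n_intracranial), function(i) {
        d <- unit(rnorm(3))
        runif(1, 40, 75) * d
      })
      ic <- tibble::tibble(
        contact = sprintf("IC%d", seq_len(n_intracranial)),
        pos = ic_pos,
        modality = "intracranial"
      )
    }
    all <- dplyr::bind_rows(scalp, sub, ic)
    out <- tibble::tibble(
      contact = all$contact,
      x = unname(vapply(all$pos, `[`, numeric(1), 1)),
      y = unname(vapply(all$pos, `[`, numeric(1), 2)),
      z = unname(vapply(all$pos, `[`, numeric(1), 3)),
      modality = all$modality
    )
    class(out) <- c("head_layout", class(out))
    attr(out, "radius") <- radius
    attr(out, "scalp_thickness") <- scalp_thickness
    out
  })
}

layout_positions <- function(layout) {
  as.matrix(layout[, c("x", "y", "z")])
}

# per-contact sensing point: extracranial contacts (scalp and subscalp)
# sample the surface field along their radial direction; intracranial
# contacts sense at their true 3D position
sensing_points <- function(layout) {
  P <- layout_positions(layout)
  r <- sqrt(rowSums(P^2))
  radius <- attr(layout, "radius") %||% max(r)
  extr <- layout$modality %in% c("scalp", "subscalp")
  scale <- ifelse(extr & r > 0, radius / r, 1)
  P * scale
}
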