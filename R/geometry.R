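#' Golgi stack geometry
#'
#' Parametric geometry of the simulated Golgi as seen in a 2D (TIRF)
#' projection. The organelle is modeled as a ribbon of total arc length
#' `ribbon_length` made of `segments` ministack segments. With
#' `segments = 1` the ribbon is a single straight band (or a circular arc if
#' `curvature > 0`) seen edge-on, with the cis-to-trans axis along
#' `stack_axis`: each target layer is a thin parallel band displaced by its
#' layout's `axial_offset`. With `segments > 1` the ribbon is fragmented: each
#' segment gets (reproducibly, from the model seed) a random in-plane
#' orientation, a random cis-to-trans polarity, and a random projection factor
#' in `[0, 1]` describing how edge-on the ministack lies. An edge-on segment
#' (projection 1) shows the layers as thin bands separated by their full
#' axial offsets; a face-on segment (projection near 0) shows every layer
#' superimposed over the cisterna footprint, `face_extent` wide. This mixture
#' is what makes the dataset behave like real multiplexed Golgi data: the
#' overlapping face-on footprints carry the shared structure that rigid
#' round-to-round registration needs, while the edge-on bands carry the
#' ordered cis-to-trans separations that the proximity statistic measures.
#'
#' @param ribbon_length total centerline length in nm.
#' @param ribbon_width projected band thickness of an edge-on cisterna, nm.
#' @param curvature centerline curvature in 1/nm for the single-segment case
#'   (0 = straight); ignored when `segments > 1`.
#' @param stack_axis unit 2-vector, the cis-to-trans direction for the
#'   single-segment case.
#' @param field_of_view numeric length-2 vector, field of view in nm; must
#'   contain the ribbon.
#' @param segments number of independently oriented ministack segments.
#' @param face_extent in-plane extent of a cisterna face in nm; controls how
#'   wide a face-on segment's footprint is.
#' @return an object of class `golgi_geometry`.
#' @examples
#' golgi_geometry(ribbon_length = 4000, curvature = 0, segments = 1)
#' @export
golgi_geometry <- function(ribbon_length = 5600,
                           ribbon_width = 20,
                           curvature = 0,
                           stack_axis = c(0, 1),
                           field_of_view = c(6000, 6000),
                           segments = 8L,
                           face_extent = 300) {
  check_scalar(ribbon_length, "ribbon_length", min = 1e-9)
  check_scalar(ribbon_width, "ribbon_width", min = 1e-9)
  check_scalar(curvature, "curvature", min = 0)
  check_scalar(segments, "segments", min = 1)
  check_scalar(face_extent, "face_extent", min = 0)
  if (length(stack_axis) != 2L || !all(is.finite(stack_axis))) {
    abort_config("stack_axis must be a finite 2-vector")
  }
  nrm <- sqrt(sum(stack_axis^2))
  if (nrm < 1e-12) abort_config("stack_axis must have non-zero norm")
  stack_axis <- stack_axis / nrm
  if (length(field_of_view) != 2L || any(!is.finite(field_of_view)) ||
      any(field_of_view <= 0)) {
    abort_config("field_of_view must be two positive lengths (nm)")
  }
  segments <- as.integer(segments)
  geom <- structure(
    list(ribbon_length = ribbon_length, ribbon_width = ribbon_width,
         curvature = curvature, stack_axis = stack_axis,
         field_of_view = as.numeric(field_of_view),
         segments = segments, face_extent = face_extent),
    class = "golgi_geometry")
  if (segments == 1L && curvature > 0) {
    R <- 1 / curvature
    if (ribbon_length * curvature > 2 * pi) {
      abort_config("ribbon_length exceeds the full circle for this curvature")
    }
    if (2 * (R + ribbon_width / 2) > min(field_of_view)) {
      abort_config("field_of_view does not contain the curved ribbon")
    }
  } else if (segments == 1L) {
    if (ribbon_length > sqrt(sum(field_of_view^2))) {
      abort_config("field_of_view does not contain the ribbon")
    }
  } else {
    if (ribbon_length / segments > min(field_of_view) / 2) {
      abort_config("segments too long for the field_of_view")
    }
  }
  geom
}

#' @export
print.golgi_geometry <- function(x, ...) {
  shape <- if (x$segments > 1L) {
    sprintf("%d ministack segments of %.0f nm", x$segments,
            x$ribbon_length / x$segments)
  } else if (x$curvature > 0) {
    sprintf("arc of radius %.0f nm", 1 / x$curvature)
  } else "straight ribbon"
  cat(sprintf("Golgi geometry: %s, total length %.0f nm, band %.0f nm, face %.0f nm, FOV %.0f x %.0f nm\n",
              shape, x$ribbon_length, x$ribbon_width, x$face_extent,
              x$field_of_view[1], x$field_of_view[2]))
  invisible(x)
}

#' Target layout on the Golgi model
#'
#' Describes where one labeled target lives: a cisternal `layer` at a given
#' axial (cis-to-trans) offset, `interface_puncta` — discrete sites confined to
#' disks centred between two layers (how VPS13B appears at the cis/medial
#' interface) — or `uniform_background` spread over the whole field of view.
#'
#' @param target_id unique channel label, e.g. `"GM130"`.
#' @param kind one of `"layer"`, `"interface_puncta"`, `"uniform_background"`.
#' @param axial_offset displacement along the cis-to-trans axis in nm (layer
#'   kind; also the puncta-centre offset when `between` is not given).
#' @param site_density labeled sites per square micrometre of the layout's own
#'   support (band, puncta disks, or field of view respectively).
#' @param puncta_count,puncta_radius number and radius (nm) of interface
#'   puncta; required for the `interface_puncta` kind.
#' @param between optional character pair of layer `target_id`s; puncta are
#'   centred midway between those layers' axial offsets.
#' @param thickness optional axial thickness override in nm, so a single
#'   target found on every cisterna can span the whole stack while the other
#'   layers stay thin.
#' @return an object of class `target_layout`.
#' @export
target_layout <- function(target_id,
                          kind = c("layer", "interface_puncta", "uniform_background"),
                          axial_offset = 0, site_density = 200,
                          puncta_count = NULL, puncta_radius = NULL,
                          between = NULL, thickness = NULL) {
  kind <- match.arg(kind)
  if (!is.character(target_id) || length(target_id) != 1L || !nzchar(target_id)) {
    abort_config("target_id must be a non-empty string")
  }
  check_scalar(axial_offset, "axial_offset")
  check_scalar(site_density, "site_density", min = 0)
  if (kind == "interface_puncta") {
    if (is.null(puncta_count) || is.null(puncta_radius)) {
      abort_config("interface_puncta layouts need puncta_count and puncta_radius")
    }
    check_scalar(puncta_count, "puncta_count", min = 1)
    check_scalar(puncta_radius, "puncta_radius", min = 1e-9)
    if (!is.null(between) && length(between) != 2L) {
      abort_config("'between' must name exactly two layer targets")
    }
  }
  if (!is.null(thickness)) check_scalar(thickness, "thickness", min = 1e-9)
  structure(
    list(target_id = target_id, kind = kind, axial_offset = axial_offset,
         site_density = site_density,
         puncta_count = if (is.null(puncta_count)) NULL else as.integer(puncta_count),
         puncta_radius = puncta_radius, between = between,
         thickness = thickness),
    class = "target_layout")
}

#' Build a layered Golgi model
#'
#' Combines a geometry with an ordered set of target layouts into the ground
#' truth object the simulator draws labeled sites from. Segment placement (for
#' fragmented geometries) is drawn reproducibly from the seed, so the same
#' `(geometry, layouts, seed)` always yields an identical model.
#'
#' @param geometry a [golgi_geometry].
#' @param layouts list of [target_layout]s with unique `target_id`s.
#' @param seed integer seed; fixes segment placement and the default streams
#'   of [sample_sites()] and [simulate_experiment()].
#' @return an object of class `golgi_model`.
#' @seealso [default_golgi_model()], [sample_sites()], [simulate_experiment()]
#' @export
golgi_model <- function(geometry, layouts, seed = 1L) {
  if (!inherits(geometry, "golgi_geometry")) {
    abort_config("geometry must be a golgi_geometry object")
  }
  if (inherits(layouts, "target_layout")) layouts <- list(layouts)
  if (!length(layouts)) abort_config("a Golgi model needs at least one layout")
  if (!all(vapply(layouts, inherits, logical(1), "target_layout"))) {
    abort_config("layouts must all be target_layout objects")
  }
  ids <- vapply(layouts, `[[`, character(1), "target_id")
  if (anyDuplicated(ids)) {
    abort_config(sprintf("duplicate target_id: %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(layouts) <- ids
  for (id in ids) {
    lay <- layouts[[id]]
    if (lay$kind == "interface_puncta" && !is.null(lay$between)) {
      missing <- setdiff(lay$between, ids)
      if (length(missing)) {
        abort_config(sprintf("'between' names unknown target(s): %s",
                             paste(missing, collapse = ", ")))
      }
      offs <- vapply(lay$between, function(b) layouts[[b]]$axial_offset, numeric(1))
      layouts[[id]]$axial_offset <- mean(offs)
    }
  }
  if (geometry$segments == 1L && geometry$curvature > 0) {
    max_off <- max(vapply(layouts, `[[`, numeric(1), "axial_offset"))
    if (max_off >= 1 / geometry$curvature) {
      abort_config("axial offsets exceed the ribbon's radius of curvature")
    }
  }
  check_scalar(seed, "seed")
  structure(list(geometry = geometry, layouts = layouts,
                 seed = as.integer(seed),
                 frames = segment_frames(geometry, as.integer(seed))),
            class = "golgi_model")
}

#' @export
print.golgi_model <- function(x, ...) {
  cat(sprintf("Golgi model: %d targets, seed %d\n", length(x$layouts), x$seed))
  print(x$geometry)
  for (lay in x$layouts) {
    extra <- switch(lay$kind,
      layer = sprintf("offset %.0f nm", lay$axial_offset),
      interface_puncta = sprintf("%d puncta r=%.0f nm at offset %.0f nm",
                                 lay$puncta_count, lay$puncta_radius,
                                 lay$axial_offset),
      uniform_background = "whole field of view")
    cat(sprintf("  %-10s %-18s %s, %.0f sites/um^2\n", lay$target_id,
                lay$kind, extra, lay$site_density))
  }
  invisible(x)
}

# One row per ministack segment: centre, tangent angle, cis-to-trans polarity,
# projection factor (1 = edge-on, 0 = face-on) and face spread (projected
# footprint widening, nm). Orientation of the stack axis is isotropic in 3D:
# with z the cosine of its angle to the optical axis, z ~ U(-1, 1), the
# in-plane foreshortening of axial offsets is proj = sqrt(1 - z^2) and the
# cisterna face spreads the projected band by |z| * face_extent. Single-segment
# geometries are deterministic (centred, oriented by stack_axis, edge-on);
# fragmented geometries draw placement from the seed, arranging segments along
# a jittered ring to mimic a perinuclear ribbon.
segment_frames <- function(geometry, seed) {
  k <- geometry$segments
  L <- geometry$ribbon_length / k
  fov <- geometry$field_of_view
  if (k == 1L) {
    ax <- geometry$stack_axis
    return(data.frame(cx = fov[1] / 2, cy = fov[2] / 2,
                      theta = atan2(-ax[1], ax[2]),   # tangent = axis rotated -90
                      polarity = 1, proj = 1, spread = 0, zabs = 0,
                      length = L))
  }
  with_seed(derive_seed(seed, "segments"), {
    ring_r <- min(fov) / 4
    base <- stats::runif(1, 0, 2 * pi)
    phi <- base + 2 * pi * (seq_len(k) - 1) / k
    cx <- fov[1] / 2 + ring_r * cos(phi) + stats::rnorm(k, 0, ring_r / 6)
    cy <- fov[2] / 2 + ring_r * sin(phi) + stats::rnorm(k, 0, ring_r / 6)
    # predominantly edge-on: ministacks of the perinuclear ribbon are mostly
    # seen side-on in these acquisitions (cis/trans bands laterally resolved),
    # with a minority of tilted stacks contributing overlapping footprints
    z <- sample(c(-1, 1), k, replace = TRUE) * stats::rbeta(k, 1, 3)
    data.frame(cx = cx, cy = cy,
               theta = stats::runif(k, 0, 2 * pi),
               polarity = sign(z) + (z == 0),
               proj = sqrt(1 - z^2),
               spread = abs(z) * geometry$face_extent,
               zabs = abs(z),
               length = rep(L, k))
  })
}

# Map per-segment ribbon coordinates (arc position s in [-L/2, L/2], signed
# axial coordinate v in nm of 3D cis-to-trans offset) to the projected plane.
# The axial coordinate is foreshortened by the segment's projection factor and
# flipped by its polarity.
segment_to_xy <- function(frame, s, v) {
  t <- c(cos(frame$theta), sin(frame$theta))
  n <- c(-sin(frame$theta), cos(frame$theta))
  vp <- frame$polarity * frame$proj * v
  cbind(frame$cx + s * t[1] + vp * n[1],
        frame$cy + s * t[2] + vp * n[2])
}

# arc version for the single-segment curved ribbon
arc_to_xy <- function(geometry, s, v) {
  R <- 1 / geometry$curvature
  span <- geometry$ribbon_length / R
  theta0 <- pi / 2 - span / 2
  theta <- theta0 + s / R
  r <- R - v
  centre <- geometry$field_of_view / 2
  cbind(centre[1] + r * cos(theta), centre[2] + r * sin(theta))
}

# projected band width of a layer in a segment: edge-on segments show the
# thin cisternal band; tilted segments widen it by the foreshortened face
segment_band_width <- function(geometry, frame, thickness = NULL) {
  w_edge <- thickness %||% geometry$ribbon_width
  frame$proj * w_edge + frame$spread
}

# Euclidean distance from points (n x 2 matrix) to a layer's support
support_distance <- function(model, xy, axial_offset, thickness = NULL) {
  geom <- model$geometry
  if (geom$segments == 1L && geom$curvature > 0) {
    half_w <- (thickness %||% geom$ribbon_width) / 2
    R <- 1 / geom$curvature
    centre <- geom$field_of_view / 2
    dxy <- sweep(xy, 2, centre)
    rad <- sqrt(rowSums(dxy^2))
    theta <- atan2(dxy[, 2], dxy[, 1])
    span <- geom$ribbon_length / R
    theta0 <- pi / 2 - span / 2
    rel <- (theta - theta0) %% (2 * pi)
    inside_arc <- rel <= span
    d <- pmax(0, abs(rad - (R - axial_offset)) - half_w)
    if (any(!inside_arc)) {
      ends <- arc_to_xy(geom, c(0, geom$ribbon_length), rep(axial_offset, 2))
      i <- which(!inside_arc)
      d1 <- sqrt((xy[i, 1] - ends[1, 1])^2 + (xy[i, 2] - ends[1, 2])^2)
      d2 <- sqrt((xy[i, 1] - ends[2, 1])^2 + (xy[i, 2] - ends[2, 2])^2)
      d[i] <- pmax(0, pmin(d1, d2) - half_w)
    }
    return(d)
  }
  d <- rep(Inf, nrow(xy))
  for (i in seq_len(nrow(model$frames))) {
    fr <- model$frames[i, ]
    t <- c(cos(fr$theta), sin(fr$theta))
    n <- c(-sin(fr$theta), cos(fr$theta))
    rel <- cbind(xy[, 1] - fr$cx, xy[, 2] - fr$cy)
    s <- rel[, 1] * t[1] + rel[, 2] * t[2]
    v <- rel[, 1] * n[1] + rel[, 2] * n[2]
    v0 <- fr$polarity * fr$proj * axial_offset
    half_w <- segment_band_width(model$geometry, fr, thickness) / 2
    dv <- pmax(0, abs(v - v0) - half_w)
    ds <- pmax(0, abs(s) - fr$length / 2)
    d <- pmin(d, sqrt(dv^2 + ds^2))
  }
  d
}

#' Sample ground-truth labeled sites for one target
#'
#' Draws a homogeneous Poisson point process of the layout's `site_density` on
#' the layout's support: the layer bands (one per ministack segment), the
#' interface-puncta disks (punctum centres are placed uniformly along the
#' interface line), or the whole field of view.
#'
#' @param model a [golgi_model].
#' @param target_id which layout to sample.
#' @param seed integer seed; defaults to a stream derived from the model seed
#'   and the target id.
#' @return matrix with columns `x`, `y` (nm), one row per site. For
#'   interface-puncta layouts the punctum centres are attached as the
#'   `"centers"` attribute.
#' @export
sample_sites <- function(model, target_id, seed = NULL) {
  if (!target_id %in% names(model$layouts)) {
    abort_lookup(sprintf("unknown target_id '%s'", target_id))
  }
  lay <- model$layouts[[target_id]]
  geom <- model$geometry
  if (is.null(seed)) seed <- derive_seed(model$seed, "sites", target_id)
  dens_nm2 <- lay$site_density / 1e6
  with_seed(seed, {
    if (lay$kind == "layer") {
      if (geom$segments == 1L && geom$curvature > 0) {
        w <- lay$thickness %||% geom$ribbon_width
        R <- 1 / geom$curvature
        area <- (geom$ribbon_length / R) * (R - lay$axial_offset) * w
        n <- stats::rpois(1, dens_nm2 * area)
        s <- stats::runif(n, 0, geom$ribbon_length)
        r0 <- R - lay$axial_offset
        r <- sqrt(stats::runif(n, (r0 - w / 2)^2, (r0 + w / 2)^2))
        xy <- arc_to_xy(geom, s, R - r)
      } else {
        parts <- lapply(seq_len(nrow(model$frames)), function(i) {
          fr <- model$frames[i, ]
          # site count scales with the cisterna's membrane area (length x
          # band thickness), not its projected footprint, so tilting a
          # segment spreads the same label mass over a wider band
          th <- lay$thickness %||% geom$ribbon_width
          n <- stats::rpois(1, dens_nm2 * fr$length * th)
          w <- segment_band_width(geom, fr, lay$thickness)
          s <- stats::runif(n, -fr$length / 2, fr$length / 2)
          u <- stats::runif(n, -w / 2, w / 2)
          # u is the in-plane spread around the projected band centre
          t <- c(cos(fr$theta), sin(fr$theta))
          nv <- c(-sin(fr$theta), cos(fr$theta))
          v0 <- fr$polarity * fr$proj * lay$axial_offset
          cbind(fr$cx + s * t[1] + (v0 + u) * nv[1],
                fr$cy + s * t[2] + (v0 + u) * nv[2])
        })
        xy <- do.call(rbind, parts)
      }
      colnames(xy) <- c("x", "y")
      xy
    } else if (lay$kind == "interface_puncta") {
      k <- lay$puncta_count
      fr_idx <- sample.int(nrow(model$frames), k, replace = TRUE)
      centers <- matrix(0, k, 2)
      for (i in seq_len(k)) {
        fr <- model$frames[fr_idx[i], ]
        s <- stats::runif(1, -fr$length / 2, fr$length / 2)
        centers[i, ] <- if (geom$segments == 1L && geom$curvature > 0) {
          arc_to_xy(geom, s + geom$ribbon_length / 2, lay$axial_offset)
        } else {
          segment_to_xy(fr, s, lay$axial_offset)
        }
      }
      per <- stats::rpois(k, dens_nm2 * pi * lay$puncta_radius^2)
      xs <- vector("list", k)
      for (i in seq_len(k)) {
        m <- per[i]
        fr <- model$frames[fr_idx[i], ]
        # the contact-site disk lies in the interface plane (normal = stack
        # axis): its in-plane extent follows the segment tangent and its
        # projection along the stack direction is foreshortened by the tilt
        rr <- lay$puncta_radius * sqrt(stats::runif(m))
        aa <- stats::runif(m, 0, 2 * pi)
        a <- rr * cos(aa)
        b <- rr * sin(aa) * fr$zabs
        t <- c(cos(fr$theta), sin(fr$theta))
        nv <- c(-sin(fr$theta), cos(fr$theta))
        xs[[i]] <- cbind(centers[i, 1] + a * t[1] + b * nv[1],
                         centers[i, 2] + a * t[2] + b * nv[2])
      }
      xy <- do.call(rbind, xs)
      colnames(xy) <- c("x", "y")
      colnames(centers) <- c("x", "y")
      attr(xy, "centers") <- centers
      attr(xy, "punctum") <- rep.int(seq_len(k), per)
      xy
    } else {
      fov <- geom$field_of_view
      n <- stats::rpois(1, dens_nm2 * prod(fov))
      cbind(x = stats::runif(n, 0, fov[1]), y = stats::runif(n, 0, fov[2]))
    }
  })
}

#' Default layered Golgi model
#'
#' The stock simulation scenario: seven Golgi reference markers ordered along
#' the cis-to-trans axis (GM130 and GRASP65 proximal; Giantin, GALNT2 and Rab6
#' medial; Golgin97 and TGN46 distal), plus a VPS13B channel confined to
#' punctate sites at the cis/medial interface, on a fragmented ribbon of
#' ministack segments with random orientation, polarity and tilt. Offsets are
#' in nm along the stack axis. Optionally adds a FAM177A1 channel spread
#' across the whole stack.
#'
#' @param seed integer model seed.
#' @param include_fam177a1 add a FAM177A1 layer spanning all cisternae.
#' @return a [golgi_model].
#' @examples
#' m <- default_golgi_model(seed = 1)
#' names(m$layouts)
#' @export
default_golgi_model <- function(seed = 1L, include_fam177a1 = FALSE) {
  # cis face at 0-15 nm, medial cisternae at 90-130 nm, TGN at 190-210 nm:
  # a ~210 nm stack with 25-40 nm inter-cisternal spacing, consistent with
  # EM ultrastructure of the mammalian Golgi
  offs <- c(GM130 = 0, GRASP65 = 15, Giantin = 90, GALNT2 = 110, Rab6 = 130,
            Golgin97 = 190, TGN46 = 210)
  # 4000 sites/um^2 of cisternal band keeps edge-on bands continuous
  # (one site per ~12 nm of ribbon) at SMLM labeling scales
  layouts <- lapply(names(offs), function(id) {
    target_layout(id, "layer", axial_offset = offs[[id]], site_density = 4000)
  })
  # VPS13B puncta sit in the cleft between the cis cisternae (GM130/GRASP65,
  # offsets 0-15) and the first medial cisterna (Giantin, 90), on the cis
  # side of that cleft: the protein is reported closest to the cis markers,
  # then the medial set, then the TGN
  layouts <- c(layouts, list(
    target_layout("VPS13B", "interface_puncta", site_density = 5000,
                  puncta_count = 20, puncta_radius = 40,
                  axial_offset = 35)))
  if (include_fam177a1) {
    layouts <- c(layouts, list(
      target_layout("FAM177A1", "layer", axial_offset = 105,
                    site_density = 400, thickness = 230)))
  }
  golgi_model(golgi_geometry(), layouts, seed = seed)
}
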