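# GeoJSON readers/writers for the three vector layers the pipeline touches:
# building footprints/centroids, existing facilities, land-use parcels.
# All layers must arrive in a planar projected CRS with meter units; the
# package never reprojects and rejects coordinates that look geographic.

.schemas <- c("buildings", "facilities", "landuse")

.assert_projected <- function(xs, ys) {
  if (length(xs) && all(abs(xs) <= 180) && all(abs(ys) <= 90)) {
    stop("coordinates look geographic (lon/lat within ±180/±90): ",
         "reproject the layer to a planar metric CRS (meter units) first",
         call. = FALSE)
  }
  invisible(NULL)
}

.feature_geometry <- function(feat, idx) {
  g <- feat$geometry
  if (is.null(g) || is.null(g$type)) {
    stop(sprintf("schema error: feature %d has no geometry", idx), call. = FALSE)
  }
  g
}

.coords_point <- function(g) as.numeric(unlist(g$coordinates))[1:2]

.coords_ring <- function(g) {
  # exterior ring only; holes are out of scope for parcel screens
  ring <- g$coordinates[[1]]
  do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))[1:2]))
}

.prop <- function(feat, name, idx, required = TRUE, default = NA) {
  v <- feat$properties[[name]]
  if (is.null(v)) {
    if (required) {
      stop(sprintf("schema error: feature %d is missing required attribute '%s'", idx, name),
           call. = FALSE)
    }
    return(default)
  }
  v
}

#' Read a vector layer from GeoJSON
#'
#' Reads one of the three layer schemas used by the pipeline and returns a
#' validated, typed collection:
#'
#' * `buildings`: Point or Polygon features with a `floor_area` property
#'   (m^2, required) and optional `id`, `elderly_pop`. Polygon footprints
#'   are reduced to their area-weighted centroid. Returns a data frame with
#'   columns `id`, `x`, `y`, `floor_area`, `elderly_pop`.
#' * `facilities`: Point features with `kind` in `center`/`clinic`
#'   (required), optional `floor_area` and `service_radius`; the default
#'   radius is 600 m for a center and 300 m for a clinic. Returns a data
#'   frame `id`, `kind`, `x`, `y`, `floor_area`, `service_radius`.
#' * `landuse`: Polygon features with a logical `used` property (required).
#'   Returns a list of parcels `list(geometry = <2-col matrix>, used = ...)`
#'   with degenerate rings repaired or rejected.
#'
#' Layers whose coordinates all fall within lon/lat bounds are rejected with
#' a request to reproject: all analysis is planar in meters.
#'
#' @param path path to a GeoJSON FeatureCollection.
#' @param schema one of `"buildings"`, `"facilities"`, `"landuse"`.
#' @return typed collection as described above.
#' @export
read_vector_layer <- function(path, schema = c("buildings", "facilities", "landuse")) {
  schema <- match.arg(schema)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats)) stop("schema error: not a GeoJSON FeatureCollection", call. = FALSE)

  if (schema == "landuse") {
    parcels <- vector("list", length(feats))
    allx <- c(); ally <- c()
    for (i in seq_along(feats)) {
      g <- .feature_geometry(feats[[i]], i)
      if (g$type != "Polygon") {
        stop(sprintf("schema error: landuse feature %d must be a Polygon", i), call. = FALSE)
      }
      ring <- repair_ring(.coords_ring(g))
      used <- .prop(feats[[i]], "used", i)
      parcels[[i]] <- list(geometry = ring, used = isTRUE(as.logical(used)))
      allx <- c(allx, ring[, 1]); ally <- c(ally, ring[, 2])
    }
    .assert_projected(allx, ally)
    return(parcels)
  }

  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- .feature_geometry(f, i)
    if (g$type == "Point") {
      xy <- .coords_point(g)
    } else if (g$type == "Polygon" && schema == "buildings") {
      xy <- polygon_centroid(repair_ring(.coords_ring(g)))
    } else {
      stop(sprintf("schema error: %s feature %d has unsupported geometry '%s'",
                   schema, i, g$type), call. = FALSE)
    }
    id <- as.character(.prop(f, "id", i, required = FALSE, default = i))
    if (schema == "buildings") {
      fa <- as.numeric(.prop(f, "floor_area", i))
      if (!is.finite(fa) || fa < 0) {
        stop(sprintf("schema error: building %s has invalid floor_area", id), call. = FALSE)
      }
      ep <- as.numeric(.prop(f, "elderly_pop", i, required = FALSE, default = NA_real_))
      rows[[i]] <- data.frame(id = id, x = xy[1], y = xy[2],
                              floor_area = fa, elderly_pop = ep,
                              stringsAsFactors = FALSE)
    } else {
      kind <- as.character(.prop(f, "kind", i))
      if (!kind %in% c("center", "clinic")) {
        stop(sprintf("schema error: facility %s kind must be 'center' or 'clinic'", id),
             call. = FALSE)
      }
      default_r <- if (kind == "center") 600 else 300
      sr <- as.numeric(.prop(f, "service_radius", i, required = FALSE, default = default_r))
      if (!is.finite(sr) || sr <= 0) {
        stop(sprintf("schema error: facility %s service_radius must be positive", id),
             call. = FALSE)
      }
      fa <- as.numeric(.prop(f, "floor_area", i, required = FALSE, default = NA_real_))
      rows[[i]] <- data.frame(id = id, kind = kind, x = xy[1], y = xy[2],
                              floor_area = fa, service_radius = sr,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- if (schema == "buildings") {
      data.frame(id = character(), x = numeric(), y = numeric(),
                 floor_area = numeric(), elderly_pop = numeric(), stringsAsFactors = FALSE)
    } else {
      data.frame(id = character(), kind = character(), x = numeric(), y = numeric(),
                 floor_area = numeric(), service_radius = numeric(), stringsAsFactors = FALSE)
    }
  }
  .assert_projected(out$x, out$y)
  rownames(out) <- NULL
  out
}

.gj_feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

.gj_write <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  writeLines(json, path)
  invisible(NULL)
}

#' Write a vector layer to GeoJSON
#'
#' Inverse of [read_vector_layer()]: buildings and facilities are written as
#' Point features, parcels as Polygon features. Numbers are serialised at
#' full double precision, so a write/read round-trip reproduces the records
#' exactly and repeated writes of the same object are byte-identical.
#'
#' @param layer a typed collection as returned by [read_vector_layer()].
#' @param path output path.
#' @param schema one of `"buildings"`, `"facilities"`, `"landuse"`.
#' @export
write_vector_layer <- function(layer, path, schema = c("buildings", "facilities", "landuse")) {
  schema <- match.arg(schema)
  if (schema == "landuse") {
    feats <- lapply(layer, function(p) {
      ring <- rbind(p$geometry, p$geometry[1, ])  # close the ring for GeoJSON
      coords <- list(lapply(seq_len(nrow(ring)), function(i) as.list(unname(ring[i, ]))))
      .gj_feature(list(type = "Polygon", coordinates = coords),
                  list(used = isTRUE(p$used)))
    })
    return(.gj_write(feats, path))
  }
  feats <- lapply(seq_len(nrow(layer)), function(i) {
    r <- layer[i, ]
    props <- if (schema == "buildings") {
      p <- list(id = r$id, floor_area = r$floor_area)
      if (is.finite(r$elderly_pop)) p$elderly_pop <- r$elderly_pop
      p
    } else {
      p <- list(id = r$id, kind = r$kind, service_radius = r$service_radius)
      if (is.finite(r$floor_area)) p$floor_area <- r$floor_area
      p
    }
    .gj_feature(list(type = "Point", coordinates = c(r$x, r$y)), props)
  })
  .gj_write(feats, path)
}
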