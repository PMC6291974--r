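# End-to-end orchestration: demand allocation -> stage-1 suitability
# screening -> stage-2 greedy selection -> coverage report, with every
# intermediate artifact writable and a machine-readable run manifest.

#' Default pipeline configuration
#'
#' All defaults equal the published planning constants: service radii 600 m
#' (center) and 300 m (clinic), 25 m candidate spacing, suitability
#' threshold 4 over ten density classes, 30 m^2 of clinic floor per 1000
#' persons, and a 10,000-resident allocation floor. The raster resolution
#' defaults to 10 m, which resolves both the 300 m buffers and the 25 m
#' lattice cleanly.
#'
#' @return a nested configuration list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    cell_size = 10,
    outside_is_used = FALSE,
    radii = list(center = 600, clinic = 300),
    kde = list(bandwidth = "auto", bandwidth_grid = NULL),
    reclass = list(n_classes = 10, threshold = 4, method = "equal"),
    grid = list(spacing = 25),
    siting = list(service_radius = 300, area_index = 30,
                  min_covered_population = 10000, max_sites = Inf),
    remove_served = TRUE,
    scenario = NULL,  # a scenario_spec, or NULL to read from paths
    paths = NULL,     # list(buildings=, facilities=, landuse=)
    profile = NULL,   # community_profile; defaults to scenario$profile
    extent = NULL     # c(width, height); defaults to scenario extent / parcel bbox
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !inherits(override[[nm]], c("scenario_spec", "community_profile"))) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Keys missing from the file keep their [default_pipeline_config()] value.
#' A `scenario` block is turned into a [scenario_spec()]; a `profile` block
#' (`households`, `persons_per_household`, `elderly_ratio`) into a
#' [community_profile()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return configuration list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::fromJSON(path)
  if (!is.null(raw$profile) && !inherits(raw$profile, "community_profile")) {
    raw$profile <- do.call(community_profile, raw$profile)
  }
  if (!is.null(raw$scenario) && !inherits(raw$scenario, "scenario_spec")) {
    sc <- raw$scenario
    if (!is.null(sc$profile)) sc$profile <- do.call(community_profile, sc$profile)
    raw$scenario <- do.call(scenario_spec, sc)
  }
  .merge_config(default_pipeline_config(), raw)
}

.md5_of <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(object, f)
  unname(tools::md5sum(f))
}

#' Run the two-stage siting pipeline
#'
#' Executes, in order: input loading (synthetic scenario or GeoJSON paths),
#' elderly-population allocation, the four stage-1 rasters (developable
#' land, center and clinic catchment masks, weighted kernel density),
#' reclassification and overlay, candidate extraction, optional removal of
#' demand already inside existing catchments, the greedy bi-objective
#' selection, facility sizing, and a coverage report. The run is fully
#' deterministic for a given configuration.
#'
#' An empty candidate set is not an error: the result carries
#' `status = "no_feasible_sites"` and an empty plan.
#'
#' @param config configuration list (see [default_pipeline_config()]);
#'   partial lists are merged over the defaults.
#' @param out_dir optional directory: every intermediate raster (ASCII
#'   grid), the candidate set and plan (GeoJSON), the round table (CSV) and
#'   the manifest (JSON) are written there.
#' @return an `ehf_run` list: `status`, `manifest`, `buildings`, `rasters`
#'   (land, center_mask, clinic_mask, density, density_class, suitability),
#'   `candidates`, `demand`, `plan`, `report`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- .merge_config(default_pipeline_config(), config)

  # ---- inputs -------------------------------------------------------------
  if (!is.null(cfg$scenario)) {
    community <- generate_community(cfg$scenario)
    buildings <- community$buildings
    parcels <- community$parcels
    facilities <- community$facilities
    profile <- if (is.null(cfg$profile)) cfg$scenario$profile else cfg$profile
    extent <- if (is.null(cfg$extent)) cfg$scenario$extent else cfg$extent
    origin <- c(0, 0)
  } else if (!is.null(cfg$paths)) {
    buildings <- read_vector_layer(cfg$paths$buildings, "buildings")
    facilities <- read_vector_layer(cfg$paths$facilities, "facilities")
    parcels <- read_vector_layer(cfg$paths$landuse, "landuse")
    profile <- cfg$profile
    if (is.null(profile)) stop("pipeline stage inputs: a community profile is required",
                               call. = FALSE)
    allxy <- do.call(rbind, lapply(parcels, function(p) p$geometry))
    origin <- if (is.null(cfg$extent)) apply(allxy, 2, min) else c(0, 0)
    extent <- if (is.null(cfg$extent)) apply(allxy, 2, max) - origin else cfg$extent
  } else {
    stop("pipeline stage inputs: provide either a scenario or input paths", call. = FALSE)
  }

  template <- raster_grid(origin, cfg$cell_size,
                          n_rows = ceiling(extent[2] / cfg$cell_size),
                          n_cols = ceiling(extent[1] / cfg$cell_size))

  # ---- stage 0: demand ----------------------------------------------------
  buildings <- allocate_elderly_population(buildings, profile)

  # ---- stage 1: suitability -----------------------------------------------
  land <- rasterize_polygons(parcels, template, outside_is_used = cfg$outside_is_used)
  centers_df <- facilities[facilities$kind == "center", , drop = FALSE]
  clinics_df <- facilities[facilities$kind == "clinic", , drop = FALSE]
  center_mask <- buffer_uncovered_mask(centers_df, cfg$radii$center, template)
  clinic_mask <- buffer_uncovered_mask(clinics_df, cfg$radii$clinic, template)

  pts <- data.frame(x = buildings$x, y = buildings$y, w = buildings$elderly_pop)
  h <- cfg$kde$bandwidth
  if (identical(h, "auto")) {
    hg <- cfg$kde$bandwidth_grid
    if (is.null(hg)) {
      hg <- exp(seq(log(cfg$cell_size), log(max(extent) / 4), length.out = 10))
    }
    h <- select_bandwidth(pts, hg)
  }
  density <- kde_density(pts, h, template)
  density_class <- reclassify_density(density, cfg$reclass$n_classes, cfg$reclass$method)
  suitability <- overlay_suitability(land, center_mask, clinic_mask, density_class)
  candidates <- extract_candidates(suitability, cfg$grid$spacing, cfg$reclass$threshold)

  # ---- stage 2: siting ----------------------------------------------------
  demand <- data.frame(id = buildings$id, x = buildings$x, y = buildings$y,
                       pop = buildings$elderly_pop,
                       sizing_pop = buildings$resident_pop,
                       stringsAsFactors = FALSE)
  residual <- demand
  if (isTRUE(cfg$remove_served) && nrow(facilities)) {
    served <- rep(FALSE, nrow(residual))
    for (i in seq_len(nrow(facilities))) {
      served <- served |
        sqrt((residual$x - facilities$x[i])^2 + (residual$y - facilities$y[i])^2) <=
          facilities$service_radius[i]
    }
    residual <- residual[!served, , drop = FALSE]
  }

  # the allocation floor is stated in residents; coverage weights are elderly
  min_elderly <- cfg$siting$min_covered_population * profile$elderly_ratio
  scfg <- siting_config(service_radius = cfg$siting$service_radius,
                        area_index = cfg$siting$area_index,
                        min_covered_population = min_elderly,
                        max_sites = cfg$siting$max_sites)

  if (nrow(candidates) == 0) {
    status <- "no_feasible_sites"
    plan <- structure(list(
      rounds = data.frame(round = integer(), x = numeric(), y = numeric(),
                          covered_population = numeric(), sizing_population = numeric(),
                          weighted_distance = numeric(), q_set_size = integer(),
                          floor_area = numeric()),
      covered_ids = list(), assignments = integer(),
      uncovered_demand_ids = residual$id, config = scfg), class = "siting_plan")
  } else {
    status <- "ok"
    plan <- if (nrow(residual)) greedy_select(candidates, residual, scfg) else
      greedy_select(candidates, residual[0, , drop = FALSE], scfg)
  }

  report <- coverage_report(plan, facilities, demand, cfg$siting$service_radius)
  residual_report <- coverage_report(plan, facilities, residual, cfg$siting$service_radius)

  manifest <- list(
    status = status,
    inputs_hash = .md5_of(list(buildings = buildings, parcels = parcels,
                               facilities = facilities)),
    config = cfg[c("cell_size", "outside_is_used", "radii", "reclass",
                   "grid", "siting", "remove_served")],
    kde_bandwidth = h,
    n_buildings = nrow(buildings),
    total_elderly = sum(buildings$elderly_pop),
    n_existing_facilities = nrow(facilities),
    n_candidates = nrow(candidates),
    n_residual_demand = nrow(residual),
    n_planned = nrow(plan$rounds),
    planned = plan$rounds,
    fraction_covered_all = report$fraction_covered,
    fraction_covered_residual = residual_report$fraction_covered
  )

  run <- structure(list(status = status, manifest = manifest,
                        buildings = buildings,
                        rasters = list(land = land, center_mask = center_mask,
                                       clinic_mask = clinic_mask, density = density,
                                       density_class = density_class,
                                       suitability = suitability),
                        candidates = candidates, demand = demand,
                        residual_demand = residual,
                        plan = plan, report = report),
                   class = "ehf_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.ehf_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("ehf_run [%s]: %d buildings, %d candidates, %d planned site(s)\n",
              x$status, m$n_buildings, m$n_candidates, m$n_planned))
  cat(sprintf("  demand covered (existing + planned): %.1f%% overall, %.1f%% of residual\n",
              100 * m$fraction_covered_all, 100 * m$fraction_covered_residual))
  if (m$n_planned) print(x$plan$rounds, row.names = FALSE)
  invisible(x)
}

#' Write all artifacts of a pipeline run
#'
#' @param run an `ehf_run` from [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(run$rasters)) {
    write_raster(run$rasters[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  # candidates and plan as GeoJSON point layers
  cand_feats <- lapply(seq_len(nrow(run$candidates)), function(i) {
    .gj_feature(list(type = "Point",
                     coordinates = c(run$candidates$x[i], run$candidates$y[i])),
                list(suitability = run$candidates$suitability[i]))
  })
  .gj_write(cand_feats, file.path(dir, "candidates.geojson"))
  plan_feats <- lapply(seq_len(nrow(run$plan$rounds)), function(i) {
    r <- run$plan$rounds[i, ]
    .gj_feature(list(type = "Point", coordinates = c(r$x, r$y)),
                list(round = r$round, covered_population = r$covered_population,
                     sizing_population = r$sizing_population,
                     floor_area = r$floor_area))
  })
  .gj_write(plan_feats, file.path(dir, "plan.geojson"))
  utils::write.csv(run$plan$rounds, file.path(dir, "plan_rounds.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
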