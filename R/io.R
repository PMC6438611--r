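# Configuration files, history containers, VTU export, run manifests.
#
# Scalar histories are stored as full-precision CSV plus a JSON sidecar with
# units and configuration, so a write/read round trip is bit-exact.  Mesh and
# field data go to ASCII VTU (XML unstructured grid), readable by standard
# VTK tools.

.history_units <- c(
  time = "s", p_ip = "Pa", volume = "mm^3", flow = "mm^3/s", p_drop = "Pa",
  p_alv = "Pa", u_max = "mm/s", wss_max = "Pa", smax_primary = "Pa",
  smax_secondary = "Pa", subiters = "1", newton_iters = "1", resid = "1"
)

.config_to_list <- function(config) {
  list(
    dt = config$dt, n_cycles = config$n_cycles, tol = config$tol,
    max_subiter = config$max_subiter, loose = config$loose,
    fluid_mode = config$fluid_mode, solid_mode = config$solid_mode,
    mesh_level = config$mesh_level, newton_tol = config$newton_tol,
    waveform = list(p0 = config$waveform$p0, omega = config$waveform$omega),
    material = NULL,
    air = list(rho = config$props$rho, mu = config$props$mu),
    seed = config$seed
  )
}

#' Read a run configuration file
#'
#' YAML schema: top-level keys `scenario` (preset name or a block with the
#' scenario fields), plus any of the [coupling_config()] fields (`dt`,
#' `n_cycles`, `tol`, `max_subiter`, `loose`, `fluid_mode`, `solid_mode`,
#' `mesh_level`, `newton_tol`, `seed`), `waveform: {p0, omega}` and
#' `air: {rho, mu}`.  Unknown keys and invalid values raise an error naming
#' the offending key.
#'
#' @param path Path to a YAML file.
#' @return List with `scenario` (a [disease_scenario()] or name) and
#'   `config` (a [coupling_config()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("scenario", "dt", "n_cycles", "tol", "max_subiter", "loose",
             "fluid_mode", "solid_mode", "mesh_level", "newton_tol",
             "waveform", "air", "material", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_acinusim(paste0("unknown configuration key: ", bad[1]),
                  "acinusim_config_error")
  }
  scenario <- raw$scenario %||% "healthy"
  if (is.list(scenario)) {
    need <- c("name", "primary_thickness", "secondary_thickness", "E")
    miss <- setdiff(need, names(scenario))
    if (length(miss)) {
      stop_acinusim(paste0("scenario block is missing key: scenario.",
                           miss[1]), "acinusim_config_error")
    }
    scenario <- disease_scenario(
      scenario$name, scenario$primary_thickness, scenario$secondary_thickness,
      scenario$E, scenario$nu %||% 0.42,
      scenario$target_resting_volume %||% NA_real_)
  }
  if (!is.null(raw$material$nu)) {
    if (raw$material$nu >= 0.5 || raw$material$nu < 0) {
      stop_acinusim("invalid value for key material.nu (need 0 <= nu < 0.5)",
                    "acinusim_config_error")
    }
  }
  wf_args <- raw$waveform %||% list()
  air_args <- raw$air %||% list()
  cfg <- coupling_config(
    dt = raw$dt %||% 0.01, n_cycles = raw$n_cycles %||% 2L,
    tol = raw$tol %||% 1e-6, max_subiter = raw$max_subiter %||% 25L,
    loose = raw$loose %||% FALSE,
    fluid_mode = raw$fluid_mode %||% "network",
    solid_mode = raw$solid_mode %||% "shell",
    mesh_level = raw$mesh_level %||% 1L,
    newton_tol = raw$newton_tol %||% 1e-8,
    waveform = breathing_waveform(wf_args$p0 %||% 244,
                                  wf_args$omega %||% (pi / 2)),
    props = fluid_properties(air_args$rho %||% 1.145,
                             air_args$mu %||% 1.86e-5),
    seed = raw$seed %||% 1L)
  list(scenario = scenario, config = cfg)
}

#' Write a run configuration file
#'
#' @param scenario A [disease_scenario()] or preset name.
#' @param config A [coupling_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(scenario, config, path) {
  sc <- if (is.character(scenario)) scenario else {
    list(name = scenario$name,
         primary_thickness = scenario$primary_thickness,
         secondary_thickness = scenario$secondary_thickness,
         E = scenario$E, nu = scenario$nu,
         target_resting_volume = scenario$target_resting_volume)
  }
  out <- c(list(scenario = sc), .config_to_list(config))
  out$material <- NULL
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Write a scalar breathing history (CSV + JSON manifest)
#'
#' @param history A `state_history`.
#' @param path Output stem or CSV path; a `.json` sidecar is written next to
#'   it.
#' @return The CSV path, invisibly.
#' @export
write_history <- function(history, path) {
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  js <- sub("\\.csv$", ".json", csv)
  df <- history$df
  fmt <- vapply(seq_len(ncol(df)), function(j) {
    paste(sprintf("%.17g", df[[j]]))
  }, character(nrow(df)))
  out <- rbind(colnames(df), fmt)
  writeLines(apply(out, 1L, paste, collapse = ","), csv)
  meta <- list(
    container = "acinusim state_history v1",
    scenario = history$scenario[c("name", "primary_thickness",
                                  "secondary_thickness", "E", "nu",
                                  "target_resting_volume")],
    config = .config_to_list(history$config),
    resting_volume = history$V0, period = history$period,
    n_cycles = history$n_cycles,
    cycle_tv_change = history$cycle_tv_change %||% NA_real_,
    units = as.list(.history_units[colnames(df)])
  )
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(csv)
}

#' Read a scalar breathing history written by [write_history()]
#'
#' @param path CSV path (or stem).
#' @return A `state_history` (without solver state).
#' @export
read_history <- function(path) {
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  js <- sub("\\.csv$", ".json", csv)
  df <- utils::read.csv(csv, check.names = FALSE)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  sc <- meta$scenario
  scenario <- disease_scenario(sc$name, sc$primary_thickness,
                               sc$secondary_thickness, sc$E, sc$nu,
                               sc$target_resting_volume %||% NA_real_)
  cfgl <- meta$config
  config <- coupling_config(
    dt = cfgl$dt, n_cycles = cfgl$n_cycles, tol = cfgl$tol,
    max_subiter = cfgl$max_subiter, loose = cfgl$loose,
    fluid_mode = cfgl$fluid_mode, solid_mode = cfgl$solid_mode,
    mesh_level = cfgl$mesh_level, newton_tol = cfgl$newton_tol,
    waveform = breathing_waveform(cfgl$waveform$p0, cfgl$waveform$omega),
    props = fluid_properties(cfgl$air$rho, cfgl$air$mu), seed = cfgl$seed)
  structure(list(df = df, V0 = meta$resting_volume, scenario = scenario,
                 config = config, period = meta$period,
                 n_cycles = meta$n_cycles,
                 cycle_tv_change = meta$cycle_tv_change),
            class = "state_history")
}

#' Write a mesh (with optional fields) as ASCII VTU
#'
#' Supports tetrahedral volume meshes (`fluid_mesh`) and triangle surface
#' meshes (`shell_mesh` or a `list(nodes, tris)`).
#'
#' @param mesh The mesh.
#' @param path Output `.vtu` path.
#' @param point_data Named list of per-node vectors (length n) or n x 3
#'   matrices.
#' @param cell_data Named list of per-element vectors.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  if (inherits(mesh, "fluid_mesh")) {
    cells <- mesh$tets; ctype <- 10L
  } else {
    cells <- mesh$tris; ctype <- 5L
  }
  nodes <- mesh$nodes
  n <- nrow(nodes); m <- nrow(cells); k <- ncol(cells)
  num <- function(x) paste(sprintf("%.9g", x), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("<?xml version=\"1.0\"?>")
  w("<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" byte_order=\"LittleEndian\">")
  w("  <UnstructuredGrid>")
  w(sprintf("    <Piece NumberOfPoints=\"%d\" NumberOfCells=\"%d\">", n, m))
  w("      <Points>")
  w("        <DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">")
  w("          ", num(t(nodes)))
  w("        </DataArray>")
  w("      </Points>")
  w("      <Cells>")
  w("        <DataArray type=\"Int32\" Name=\"connectivity\" format=\"ascii\">")
  w("          ", paste(t(cells) - 1L, collapse = " "))
  w("        </DataArray>")
  w("        <DataArray type=\"Int32\" Name=\"offsets\" format=\"ascii\">")
  w("          ", paste(seq_len(m) * k, collapse = " "))
  w("        </DataArray>")
  w("        <DataArray type=\"UInt8\" Name=\"types\" format=\"ascii\">")
  w("          ", paste(rep(ctype, m), collapse = " "))
  w("        </DataArray>")
  w("      </Cells>")
  wdata <- function(dat, where) {
    w(sprintf("      <%s>", where))
    for (nm in names(dat)) {
      v <- dat[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      w(sprintf(paste0("        <DataArray type=\"Float64\" Name=\"%s\" ",
                       "NumberOfComponents=\"%d\" format=\"ascii\">"), nm, nc))
      w("          ", num(if (is.matrix(v)) t(v) else v))
      w("        </DataArray>")
    }
    w(sprintf("      </%s>", where))
  }
  wdata(point_data, "PointData")
  wdata(cell_data, "CellData")
  w("    </Piece>")
  w("  </UnstructuredGrid>")
  w("</VTKFile>")
  invisible(path)
}

#' Run manifest
#'
#' Summarises one simulation run: configuration hash, package version, wall
#' time, residual summaries and the emitted files.
#'
#' @param history A `state_history`.
#' @param files Character vector of output files.
#' @param wall_time Elapsed seconds.
#' @return Named list (class `run_manifest`).
#' @export
run_manifest <- function(history, files = character(0), wall_time = NA_real_) {
  cfg_tmp <- tempfile(fileext = ".yaml")
  write_config(history$scenario, history$config, cfg_tmp)
  hash <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)
  df <- history$df
  structure(list(
    package = "acinusim",
    version = as.character(utils::packageVersion("acinusim")),
    scenario = history$scenario$name,
    config_hash = hash,
    wall_time_s = wall_time,
    n_steps = nrow(df) - 1L,
    residual_max = max(df$resid, na.rm = TRUE),
    subiters_mean = mean(df$subiters[-1]),
    files = files
  ), class = "run_manifest")
}
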