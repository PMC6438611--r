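# Physiological metrics extracted from a breathing-cycle history:
# tidal volume, compliance (P-V loop slope), acinus resistance, P-V and F-V
# loops, peak flows, and cross-scenario comparison tables.

#' Tidal volume of a breathing history
#'
#' Maximum lumen volume minus the resting volume over the last full cycle.
#'
#' @param history A `state_history` covering at least one full cycle.
#' @return Tidal volume in mm^3.
#' @export
tidal_volume <- function(history) {
  df <- history$df
  if (max(df$time) < history$period - 1e-9) {
    stop_acinusim("history does not cover a full breathing cycle",
                  "acinusim_incomplete_cycle")
  }
  lc <- last_cycle(history)
  max(lc$volume) - history$V0
}

#' Pulmonary acinus compliance
#'
#' Volume change per unit pressure change: the least-squares slope of lumen
#' volume against the pressure axis over the inspiratory limb of the last
#' cycle.  The default pressure axis is the driving (intrapleural) pressure
#' magnitude, which is what the pressure-volume loop of an acinus driven by
#' parenchymal tethering spans; `pressure = "alveolar"` instead uses the
#' (much smaller) alveolar gauge pressure.
#'
#' @param history A `state_history`.
#' @param pressure `"driving"` (default) or `"alveolar"`.
#' @return Compliance in mm^3/Pa.
#' @export
compliance <- function(history, pressure = c("driving", "alveolar")) {
  pressure <- match.arg(pressure)
  lc <- last_cycle(history)
  insp <- lc[lc$flow > 0 | seq_len(nrow(lc)) == 1L, , drop = FALSE]
  pax <- if (pressure == "driving") abs(insp$p_ip) else abs(insp$p_alv)
  if (diff(range(pax)) <= 0) {
    stop_acinusim("degenerate pressure range on the inspiratory limb",
                  "acinusim_degenerate_input")
  }
  unname(coef(stats::lm(insp$volume ~ pax))[2])
}

#' Pulmonary acinus resistance
#'
#' Driving pressure drop divided by airflow rate, evaluated at peak
#' inspiratory flow of the last cycle.
#'
#' @param history A `state_history`.
#' @return Resistance in Pa s/mm^3.
#' @export
acinus_resistance <- function(history) {
  lc <- last_cycle(history)
  i <- which.max(lc$flow)
  if (lc$flow[i] <= 0) {
    stop_acinusim("no inspiratory flow in the last cycle",
                  "acinusim_degenerate_input")
  }
  abs(lc$p_drop[i]) / lc$flow[i]
}

#' Pressure-volume and flow-volume loops
#'
#' @param history A `state_history`.
#' @return List of two data frames: `pv` (`pressure` = |intrapleural| Pa,
#'   `volume` mm^3) and `fv` (`flow` mm^3/s, `volume` mm^3), over the last
#'   cycle (closed curves).
#' @export
loops <- function(history) {
  lc <- last_cycle(history)
  list(pv = data.frame(pressure = abs(lc$p_ip), volume = lc$volume),
       fv = data.frame(flow = lc$flow, volume = lc$volume))
}

#' Peak inspiratory and expiratory flow
#'
#' @param history A `state_history`.
#' @return Named vector `PIF`, `PEF` in mm^3/s (both positive).
#' @export
peak_flows <- function(history) {
  lc <- last_cycle(history)
  c(PIF = max(lc$flow), PEF = max(-lc$flow))
}

#' Full lung-function report for one run
#'
#' @param history A `state_history`.
#' @return Object of class `lung_function_report` (a named list): tidal
#'   volume, relative volume change, compliance, resistance, max pressure
#'   drop, maximum Reynolds number, PIF/PEF, peak principal stress by septal
#'   class, max wall shear stress.
#' @export
lung_function_report <- function(history) {
  lc <- last_cycle(history)
  pf <- peak_flows(history)
  tv <- tidal_volume(history)
  props <- history$config$props
  re_max <- reynolds_number(max(lc$u_max), L = 1.0)
  structure(list(
    scenario = history$scenario$name,
    resting_volume = history$V0,
    tidal_volume = tv,
    relative_volume_change = tv / history$V0,
    compliance = compliance(history),
    resistance = acinus_resistance(history),
    max_pressure_drop = max_pressure_drop(history),
    reynolds_max = re_max,
    pif = unname(pf["PIF"]), pef = unname(pf["PEF"]),
    peak_stress_primary = max(lc$smax_primary),
    peak_stress_secondary = max(lc$smax_secondary),
    max_wss = max(lc$wss_max),
    cycle_tv_change = history$cycle_tv_change %||% NA_real_,
    dt = history$config$dt, n_cycles = history$n_cycles,
    fluid_mode = history$config$fluid_mode,
    mesh_level = history$config$mesh_level
  ), class = "lung_function_report")
}

#' @export
print.lung_function_report <- function(x, ...) {
  cat(sprintf("<lung_function_report %s>\n", x$scenario))
  cat(sprintf("  tidal volume    %.4g mm^3 (%.1f%% of resting %.4g mm^3)\n",
              x$tidal_volume, 100 * x$relative_volume_change,
              x$resting_volume))
  cat(sprintf("  compliance      %.4g mm^3/Pa\n", x$compliance))
  cat(sprintf("  resistance      %.4g Pa s/mm^3\n", x$resistance))
  cat(sprintf("  max |dP|        %.4g Pa, PIF %.4g / PEF %.4g mm^3/s\n",
              x$max_pressure_drop, x$pif, x$pef))
  cat(sprintf("  Re_max          %.3g, max WSS %.3g Pa\n",
              x$reynolds_max, x$max_wss))
  cat(sprintf("  peak stress     %.4g Pa (primary) / %.4g Pa (secondary)\n",
              x$peak_stress_primary, x$peak_stress_secondary))
  invisible(x)
}

#' Compare lung-function reports across scenarios
#'
#' Percent differences for every metric with the healthy scenario as the
#' reference, plus the NSIP-vs-IPF contrast (IPF as denominator).  All
#' reports must come from identical configurations apart from the scenario.
#'
#' @param reports List of [lung_function_report()]s, one of them healthy.
#' @return Data frame: one row per metric, absolute values per scenario and
#'   percent differences.
#' @export
compare_scenarios <- function(reports) {
  stopifnot(length(reports) >= 2L)
  key <- function(r) paste(r$dt, r$n_cycles, r$fluid_mode, r$mesh_level)
  if (length(unique(vapply(reports, key, character(1)))) != 1L) {
    stop_acinusim("reports were produced with different configurations",
                  "acinusim_invalid_parameter")
  }
  names(reports) <- vapply(reports, function(r) tolower(r$scenario),
                           character(1))
  metrics <- c("tidal_volume", "compliance", "resistance",
               "max_pressure_drop", "pif", "pef", "reynolds_max", "max_wss",
               "peak_stress_primary", "peak_stress_secondary")
  out <- data.frame(metric = metrics)
  for (nm in names(reports)) {
    out[[nm]] <- vapply(metrics, function(m) reports[[nm]][[m]], numeric(1))
  }
  if ("healthy" %in% names(reports)) {
    for (nm in setdiff(names(reports), "healthy")) {
      out[[paste0("pct_", nm, "_vs_healthy")]] <-
        100 * (out[[nm]] / out[["healthy"]] - 1)
    }
  }
  if (all(c("nsip", "ipf") %in% names(reports))) {
    out$pct_nsip_vs_ipf <- 100 * (out$nsip / out$ipf - 1)
  }
  out
}
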