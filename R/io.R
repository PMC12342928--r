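#' Table schemas used by the pipeline
#'
#' Required (and optional) columns of every delimited-text table the
#' pipeline reads or writes. Missing values are encoded as empty fields,
#' never zero-filled.
#'
#' @format named list; each element has `required`, `optional`, and an
#'   optional row-level `check` function returning a character vector of
#'   violation messages per row.
#' @export
table_schemas <- list(
  endmembers = list(
    required = c("name", "T", "S", "O", "P", "N", "Si"),
    optional = c("weight"),
    check = NULL
  ),
  section = list(
    required = c("station", "depth_m", "T", "S", "O", "P", "N", "Si"),
    optional = c("lat", "ch4_nmol_l"),
    check = NULL
  ),
  tracer = list(
    required = c("station", "depth_m", "replicate", "is_control",
                 "dpm_product", "dpm_total", "t_days", "ch4_nmol_l"),
    optional = character(),
    check = function(df) {
      msg <- rep(NA_character_, nrow(df))
      bad <- !is.na(df$dpm_total) & df$dpm_total <= 0
      msg[bad] <- "dpm_total must be positive"
      bad <- !is.na(df$dpm_product) & !is.na(df$dpm_total) &
        df$dpm_product > df$dpm_total
      msg[bad] <- "dpm_product exceeds dpm_total"
      bad <- !is.na(df$t_days) & df$t_days <= 0
      msg[bad] <- "t_days must be positive"
      msg
    }
  ),
  underway = list(
    required = c("lat", "SST", "S", "xco2_umol_mol", "xh2o_mol_frac",
                 "p_eq_atm", "t_eq_k", "wind_m_s", "ch4_water_nmol_l",
                 "ch4_atm_ppb", "pco2_atm_uatm"),
    optional = c("time", "lon"),
    check = function(df) {
      msg <- rep(NA_character_, nrow(df))
      bad <- !is.na(df$t_eq_k) & df$t_eq_k <= 0
      msg[bad] <- "t_eq_k must be positive kelvin"
      bad <- !is.na(df$xh2o_mol_frac) &
        (df$xh2o_mol_frac < 0 | df$xh2o_mol_frac >= 1)
      msg[bad] <- "xh2o_mol_frac must be in [0, 1)"
      bad <- !is.na(df$wind_m_s) & df$wind_m_s < 0
      msg[bad] <- "wind_m_s must be >= 0"
      msg
    }
  ),
  amendment = list(
    required = c("treatment", "replicate", "t_days", "ch4_nmol_l"),
    optional = c("clipped"),
    check = function(df) {
      msg <- rep(NA_character_, nrow(df))
      bad <- !is.na(df$t_days) & df$t_days < 0
      msg[bad] <- "t_days must be >= 0"
      msg
    }
  )
)

#' Read and validate a delimited-text table
#'
#' Delimiter (comma or tab) is auto-detected from the header line. Column
#' names are validated against the named schema; rows violating the
#' schema's row-level invariants are dropped with a single warning that
#' lists the offending rows by their 1-based position in the data (header
#' excluded). Empty files yield an empty table with a warning, not an
#' error. Missing values must be encoded as empty fields.
#'
#' @param path file path.
#' @param schema one of `names(table_schemas)`.
#' @return validated data.frame (possibly with rows dropped).
#' @export
read_table <- function(path, schema) {
  if (!schema %in% names(table_schemas)) {
    stop("read_table: unknown schema '", schema, "'; available: ",
         paste(names(table_schemas), collapse = ", "))
  }
  if (!file.exists(path)) stop("read_table: file not found: ", path)
  sc <- table_schemas[[schema]]
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(first)) {
    warning("read_table: ", path, " is empty; returning an empty ", schema,
            " table")
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(sc$required)), sc$required))
    return(out)
  }
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE)
  missing_cols <- setdiff(sc$required, names(df))
  if (length(missing_cols)) {
    stop("read_table: ", path, " lacks required column(s) ",
         paste(missing_cols, collapse = ", "), " for schema '", schema,
         "' (expected: ", paste(sc$required, collapse = ", "), ")")
  }
  if (!is.null(sc$check) && nrow(df) > 0) {
    msgs <- sc$check(df)
    bad <- !is.na(msgs)
    if (any(bad)) {
      warning("read_table: dropped ", sum(bad), " invalid row(s) from ",
              path, ": ",
              paste(sprintf("row %d (%s)", which(bad), msgs[bad]),
                    collapse = "; "))
      df <- df[!bad, , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  df
}

#' Write a pipeline table as CSV
#'
#' Missing values are written as empty fields so that
#' `read_table(write_table(x))` round-trips.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

#' Read an endmember table
#'
#' Delimited text with columns `name, T, S, O, P, N, Si` (and an optional
#' `weight` column, currently carried through unused; OMP weighting is per
#' property, set via `property_weights`).
#'
#' @param path file path.
#' @param property_weights,mass_weight passed to [endmember_set()].
#' @return an [endmember_set()].
#' @export
read_endmembers <- function(path, property_weights = rep(1, 6),
                            mass_weight = 100) {
  df <- read_table(path, "endmembers")
  if (nrow(df) == 0) stop("read_endmembers: ", path, " holds no endmembers")
  endmember_set(names = df$name, T = df$T, S = df$S, O = df$O, P = df$P,
                N = df$N, Si = df$Si, property_weights = property_weights,
                mass_weight = mass_weight)
}

#' Write an endmember table
#'
#' @param endmembers an [endmember_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_endmembers <- function(endmembers, path) {
  stopifnot(inherits(endmembers, "endmember_set"))
  df <- data.frame(name = endmembers$names, endmembers$properties,
                   weight = 1, check.names = FALSE)
  write_table(df, path)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values that parse
#' as numbers become numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) {
    stop("read_config: malformed line(s): ", paste(lines[bad], collapse = "; "))
  }
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, keys)
}

#' Run the full methane-cycling analysis pipeline
#'
#' Orchestrates the stages in order — OMP water-mass inversion, tracer
#' kinetics, gas exchange, dilution analysis, budget — each writing its
#' result table to the output directory, plus a machine-readable run
#' manifest (config echo, seed, package version, per-stage log). Progress
#' is logged to stderr. A stage failure halts the run with the stage name
#' in the error.
#'
#' Station air-sea fluxes are taken from the underway record nearest in
#' latitude when both tables carry latitude; otherwise the transect-mean
#' flux is applied to every station (logged).
#'
#' @param config named list (or path to a key = value file, see
#'   [read_config()]) with entries `endmembers`, `section`, `tracer`,
#'   `underway` (paths; `amendment` optional), `out_dir`, and optionally
#'   `z_max` (default 300), `mass_weight` (default 100), `seed` (recorded
#'   in the manifest).
#' @return invisibly, a list of the result tables (`omp`, `mox`, `fluxes`,
#'   `dilution`, `budgets`, `regional`, and `amendment` if supplied).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  req <- c("endmembers", "section", "tracer", "underway", "out_dir")
  missing_keys <- setdiff(req, names(config))
  if (length(missing_keys)) {
    stop("run_pipeline [config]: missing entries: ",
         paste(missing_keys, collapse = ", "))
  }
  for (key in c("endmembers", "section", "tracer", "underway", "amendment")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop("run_pipeline [config]: input file for '", key,
           "' not found: ", config[[key]])
    }
  }
  z_max <- if (is.null(config$z_max)) 300 else config$z_max
  mass_weight <- if (is.null(config$mass_weight)) 100 else config$mass_weight
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  stage <- function(name, expr) {
    message("[", name, "] starting")
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("run_pipeline [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
    dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    log_lines <<- c(log_lines, paste0(name, ": ok (", dt, " s)"))
    message("[", name, "] done (", dt, " s)")
    res
  }
  results <- list()

  em <- stage("config", read_endmembers(config$endmembers,
                                        mass_weight = mass_weight))
  section <- stage("read-section", read_table(config$section, "section"))

  results$omp <- stage("omp", {
    out <- omp_section(section, em)
    write_table(out, file.path(out_dir, "omp_solutions.csv"))
    write_table(attr(out, "station_summary"),
                file.path(out_dir, "omp_station_summary.csv"))
    out
  })

  results$mox <- stage("tracer-kinetics", {
    inc <- read_table(config$tracer, "tracer")
    out <- mox_estimate(inc)
    write_table(out, file.path(out_dir, "mox_estimates.csv"))
    out
  })

  results$fluxes <- stage("gas-exchange", {
    uw <- read_table(config$underway, "underway")
    out <- process_underway(uw)
    write_table(out, file.path(out_dir, "fluxes.csv"))
    out
  })

  results$dilution <- stage("dilution", {
    if (!"ch4_nmol_l" %in% names(section) || all(is.na(section$ch4_nmol_l))) {
      message("[dilution] section has no CH4 column; using underway data")
      S <- results$fluxes$S; ch4 <- results$fluxes$ch4_water_nmol_l
      lat <- results$fluxes$lat
    } else {
      surf <- section[section$depth_m == min(section$depth_m), ]
      S <- surf$S; ch4 <- surf$ch4_nmol_l
      lat <- if ("lat" %in% names(surf)) surf$lat else NULL
    }
    model <- dilution_model_from_extremes(S, ch4)
    out <- dilution_residuals(model, S, ch4, lat = lat)
    write_table(out$residuals, file.path(out_dir, "dilution_residuals.csv"))
    out
  })

  results$budgets <- stage("budget", {
    mox <- results$mox
    fx <- results$fluxes
    # match each station to the nearest underway record by latitude
    st_lat <- NULL
    if ("lat" %in% names(section)) {
      st_lat <- tapply(section$lat, section$station, mean)
    }
    if (!is.null(st_lat) && "lat" %in% names(fx)) {
      idx <- vapply(st_lat[unique(mox$station)],
                    function(la) which.min(abs(fx$lat - la)), integer(1))
      station_flux <- data.frame(station = unique(mox$station),
                                 f_ch4_mmol_m2_d = fx$f_ch4_mmol_m2_d[idx])
    } else {
      message("[budget] no latitude available; applying transect-mean flux ",
              "to every station")
      station_flux <- data.frame(station = unique(mox$station),
                                 f_ch4_mmol_m2_d = mean(fx$f_ch4_mmol_m2_d))
    }
    out <- station_budget(mox, station_flux, z_max = z_max)
    write_table(out, file.path(out_dir, "budgets.csv"))
    out
  })

  results$regional <- stage("regional-summary", {
    grouping <- rep("all", nrow(results$budgets))
    if ("lat" %in% names(section)) {
      st_lat <- tapply(section$lat, section$station, mean)
      la <- st_lat[results$budgets$station]
      grouping <- ifelse(la >= stats::median(la), "north", "south")
    }
    out <- regional_summary(results$budgets, grouping)
    write_table(out, file.path(out_dir, "regional_summary.csv"))
    out
  })

  if (!is.null(config$amendment)) {
    results$amendment <- stage("incubation", {
      am <- read_table(config$amendment, "amendment")
      ctl <- am[am$treatment == "control", ]
      trts <- setdiff(unique(am$treatment), "control")
      out <- do.call(rbind, lapply(trts, function(tr) {
        ser <- am[am$treatment == tr, ]
        acc <- net_accumulation(ser, ctl)
        lag <- tryCatch(detect_lag(ser, ctl),
                        error = function(e) list(lag_days = NA_real_,
                                                 detected = NA))
        data.frame(treatment = tr, net_nmol_l = acc$net_nmol_l,
                   net_sd = acc$sd, t_span_days = acc$t_span_days,
                   lag_days = lag$lag_days, lag_detected = lag$detected)
      }))
      write_table(out, file.path(out_dir, "amendment_summary.csv"))
      out
    })
  }

  manifest <- list(
    package = "methanemix",
    version = as.character(utils::packageVersion("methanemix")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (is.null(config$seed)) NA else config$seed,
    z_max = z_max,
    mass_weight = mass_weight,
    inputs = config[intersect(names(config),
                              c("endmembers", "section", "tracer",
                                "underway", "amendment"))],
    stages = log_lines
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("run_pipeline: complete; outputs in ", out_dir)
  invisible(results)
}

#' Write a complete synthetic demo input bundle
#'
#' Generates all pipeline inputs from a [scenario_config()] and writes them
#' (plus a ready-to-run key = value config) into a directory, so
#' `run_pipeline(file.path(dir, "pipeline.cfg"))` works out of the box.
#'
#' @param dir output directory (created if needed).
#' @param config a [scenario_config()].
#' @return path to the written config file, invisibly.
#' @export
write_demo_inputs <- function(dir, config = scenario_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_endmembers(config$endmembers, file.path(dir, "endmembers.csv"))
  sec <- generate_section(config)
  write_table(sec$samples, file.path(dir, "section.csv"))
  write_table(sec$true_fractions, file.path(dir, "true_fractions.csv"))
  # one triplicate tracer set (plus killed control) per station and depth
  stations <- unique(sec$samples$station)
  inc <- do.call(rbind, lapply(seq_along(stations), function(i) {
    st <- stations[i]
    rows <- sec$samples[sec$samples$station == st, ]
    dd <- rows$depth_m
    do.call(rbind, lapply(seq_along(dd), function(j) {
      d_idx <- which(config$depths == dd[j])
      s_idx <- i
      generate_tracer_incubations(
        true_k = config$true_k[s_idx, d_idx],
        ch4 = rows$ch4_nmol_l[rows$depth_m == dd[j]][1],
        seed = as.integer((as.numeric(config$seed) * 1000 + i * 10 + j) %%
                            2147483587),
        station = st, depth_m = dd[j]
      )
    }))
  }))
  write_table(inc, file.path(dir, "tracer.csv"))
  write_table(generate_underway(config), file.path(dir, "underway.csv"))
  am <- rbind(
    generate_amendment_timeseries(5, 107 / 12, 0, seq(0, 12, by = 2),
                                  noise_sd = 2,
                                  seed = as.integer((as.numeric(config$seed) *
                                    1000 + 901) %% 2147483587),
                                  treatment_label = "DMSP"),
    (function(df) df[df$treatment != "control", ])(
      generate_amendment_timeseries(5, 8, 8, seq(0, 12, by = 2),
                                    noise_sd = 2,
                                    seed = as.integer((as.numeric(config$seed) *
                                      1000 + 902) %% 2147483587),
                                    treatment_label = "MPn+Pi"))
  )
  write_table(am, file.path(dir, "amendment.csv"))
  cfg_path <- file.path(dir, "pipeline.cfg")
  writeLines(c(
    "# methanemix pipeline configuration",
    paste0("endmembers = ", file.path(dir, "endmembers.csv")),
    paste0("section = ", file.path(dir, "section.csv")),
    paste0("tracer = ", file.path(dir, "tracer.csv")),
    paste0("underway = ", file.path(dir, "underway.csv")),
    paste0("amendment = ", file.path(dir, "amendment.csv")),
    paste0("out_dir = ", file.path(dir, "results")),
    paste0("seed = ", config$seed),
    "z_max = 300"
  ), cfg_path)
  invisible(cfg_path)
}
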