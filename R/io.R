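#' Read an incubation metadata/geometry config (YAML or JSON)
#'
#' The config has a `default` block (fields `geometry` — arguments to
#' [vessel_geometry()] — and `labelling_fraction`) and an optional
#' `treatments` block with per-treatment overrides, e.g. a labelling
#' fraction of 0.1 for DIC amendments.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Function `(treatment) -> list(geometry, labelling_fraction)`.
#' @export
read_incubation_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  default <- cfg$default
  if (is.null(default)) stop("config needs a 'default' block", call. = FALSE)
  build <- function(block) {
    geom_args <- utils::modifyList(as.list(default$geometry %||% list()),
                                   as.list(block$geometry %||% list()))
    list(geometry = do.call(vessel_geometry, geom_args),
         labelling_fraction = block$labelling_fraction %||%
           default$labelling_fraction %||% 1)
  }
  function(treatment) {
    over <- cfg$treatments[[treatment]] %||% list()
    build(over)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read incubation time series into incubation records
#'
#' Accepts TSV/CSV with columns `station`, `depth_category`, `treatment`,
#' `replicate`, `time_h`, and either `ch4_nmol_headspace` or `ch4_ppm`
#' (converted by the ideal-gas law at the configured geometry), and either
#' `atom_pct_13c` (atom percent) or `d13C_permil` (converted via
#' [d13c_to_atom_fraction()]). Geometry and labelling come from the config
#' (see [read_incubation_config()]).
#'
#' @param path Time-series file; delimiter inferred from the extension.
#' @param config_path Path to the YAML/JSON geometry config.
#' @return List of [incubation_record()] objects.
#' @export
read_incubations <- function(path, config_path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  lookup <- read_incubation_config(config_path)
  req <- c("station", "depth_category", "treatment", "replicate", "time_h")
  if (!all(req %in% names(tab))) {
    stop("incubation file needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(tab$station, tab$depth_category, tab$treatment,
                     tab$replicate, drop = TRUE)
  lapply(split(tab, key), function(d) {
    d <- d[order(d$time_h), ]
    meta <- lookup(d$treatment[1])
    geom <- meta$geometry
    amount <- if ("ch4_nmol_headspace" %in% names(d)) {
      d$ch4_nmol_headspace
    } else if ("ch4_ppm" %in% names(d)) {
      ppm_to_nmol(d$ch4_ppm, geom$headspace_volume, geom$temperature)
    } else {
      stop("need ch4_nmol_headspace or ch4_ppm column", call. = FALSE)
    }
    x13 <- if ("atom_pct_13c" %in% names(d)) {
      d$atom_pct_13c / 100
    } else if ("d13C_permil" %in% names(d)) {
      d13c_to_atom_fraction(d$d13C_permil)
    } else {
      stop("need atom_pct_13c or d13C_permil column", call. = FALSE)
    }
    incubation_record(
      station = d$station[1], depth_category = d$depth_category[1],
      treatment = d$treatment[1], replicate = d$replicate[1],
      geometry = geom, labelling_fraction = meta$labelling_fraction,
      measurements = data.frame(time_h = d$time_h,
                                ch4_nmol_headspace = amount,
                                atom_fraction_13c = x13)
    )
  })
}

#' Flatten incubation records to a long table
#'
#' Inverse of [read_incubations()]: one row per measurement, with atom
#' percent columns, suitable for writing with [write_tsv()].
#'
#' @param records List of [incubation_record()] objects.
#' @return data.frame in the accepted input dialect.
#' @export
incubations_to_table <- function(records) {
  rows <- lapply(records, function(rec) {
    m <- rec$measurements
    data.frame(station = rec$station, depth_category = rec$depth_category,
               treatment = rec$treatment, replicate = rec$replicate,
               time_h = m$time_h,
               ch4_nmol_headspace = m$ch4_nmol_headspace,
               atom_pct_13c = m$atom_fraction_13c * 100,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a table as TSV (deterministic formatting)
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
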