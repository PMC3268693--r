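REFLECTION_FORMAT_VERSION <- "1"

#' Write / read a wedge reflection file
#'
#' Columnar tab-separated text with `#`-prefixed header lines carrying the
#' format version, wedge index, nominal dose, resolution limit and a unit
#' cell placeholder; rows are `id`, `s2` (inverse squared angstroms), `J`,
#' `sigma`, serialized at full precision so that a write/read round trip is
#' lossless.
#'
#' @param wedge Tibble with columns `id`, `s2`, `J`, `sigma` (extra columns
#'   are dropped) and, for metadata, either columns or arguments
#'   `wedge_index`/`nominal_dose`.
#' @param path Output file path.
#' @param wedge_index,nominal_dose,d_min Header metadata; taken from the
#'   tibble columns when present.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(wedge, path, wedge_index = NULL,
                              nominal_dose = NULL, d_min = NA) {
  wedge <- tibble::as_tibble(wedge)
  wedge_index <- wedge_index %||%
    (if ("wedge_index" %in% names(wedge)) wedge$wedge_index[1] else NA)
  nominal_dose <- nominal_dose %||%
    (if ("nominal_dose" %in% names(wedge)) wedge$nominal_dose[1] else NA)
  cols <- intersect(c("id", "s2", "J", "sigma"), names(wedge))
  stopifnot(all(c("s2", "J", "sigma") %in% cols))
  if (!"id" %in% cols) wedge$id <- seq_len(nrow(wedge))
  body <- wedge[, c("id", "s2", "J", "sigma")]
  hdr <- c(
    paste0("# format_version: ", REFLECTION_FORMAT_VERSION),
    paste0("# wedge_index: ", wedge_index),
    paste0("# nominal_dose: ", format(nominal_dose, digits = 15)),
    paste0("# d_min: ", format(d_min, digits = 15)),
    "# cell: NA"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("id", "s2", "J", "sigma"), collapse = "\t"), con)
  lines <- sprintf("%s\t%.17g\t%.17g\t%.17g",
                   body$id, body$s2, body$J, body$sigma)
  if (length(lines) > 0) writeLines(lines, con)
  invisible(path)
}

#' @rdname write_reflections
#' @export
read_reflections <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  all_lines <- readLines(path)
  hdr_lines <- grep("^#", all_lines, value = TRUE)
  meta <- list()
  for (h in hdr_lines) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    meta[[key]] <- val
  }
  body <- readr::read_tsv(I(all_lines[!grepl("^#", all_lines)]),
                          col_types = readr::cols(
                            id = readr::col_character(),
                            s2 = readr::col_double(),
                            J = readr::col_double(),
                            sigma = readr::col_double()))
  probs <- readr::problems(body)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed reflection row at line %d: %s",
                  probs$row[1] + length(hdr_lines) + 1, probs$expected[1]))
  }
  if (anyNA(body$s2) || anyNA(body$J) || anyNA(body$sigma) ||
      any(!is.finite(body$sigma)) || any(body$sigma <= 0)) {
    abort("invalid reflection data: sigma must be finite and > 0, no NaN values")
  }
  out <- dplyr::mutate(body,
                       wedge_index = as.integer(meta$wedge_index),
                       nominal_dose = as.numeric(meta$nominal_dose)) |>
    dplyr::relocate("wedge_index", "nominal_dose")
  attr(out, "d_min") <- suppressWarnings(as.numeric(meta$d_min))
  attr(out, "format_version") <- meta$format_version
  out
}

#' Write / read a whole wedge series
#'
#' One reflection file per wedge (`wedge_01.tsv`, ...) plus a JSON sidecar
#' `metadata.json` recording the simulation truth and seed when available,
#' so that recovery tests can compare fitted against true parameters.
#'
#' @param reflections Long tibble with `wedge_index`, `nominal_dose`, `id`,
#'   `s2`, `J`, `sigma`.
#' @param dir Directory (created if needed).
#' @param truth Optional [damage_truth()] recorded in the sidecar.
#' @param seed Optional seed recorded in the sidecar.
#' @return `dir`, invisibly (`write`); the long tibble with a `truth`
#'   attribute when the sidecar exists (`read`).
#' @export
write_wedge_series <- function(reflections, dir, truth = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- sort(unique(reflections$wedge_index))
  for (i in idx) {
    w <- dplyr::filter(reflections, .data$wedge_index == i)
    write_reflections(w, file.path(dir, sprintf("wedge_%02d.tsv", i)))
  }
  meta <- list(n_wedges = length(idx))
  if (!is.null(truth)) {
    meta$truth <- list(beta_true = truth$beta_true,
                       scale_drift = truth$scale_drift)
  }
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_wedge_series
#' @export
read_wedge_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "^wedge_[0-9]+\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0) abort(paste0("no wedge files found in ", dir))
  out <- purrr::map_dfr(files, read_reflections)
  meta_path <- file.path(dir, "metadata.json")
  if (file.exists(meta_path)) {
    attr(out, "metadata") <- jsonlite::read_json(meta_path,
                                                 simplifyVector = TRUE)
  }
  out
}

# squared reciprocal coordinate s^2 = 1/(4 d^2) from hkl and a general
# (triclinic) unit cell c(a, b, c, alpha, beta, gamma), angles in degrees
.s2_from_hkl <- function(h, k, l, cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  g <- matrix(c(a * a, a * b * cos(ga), a * cc * cos(be),
                a * b * cos(ga), b * b, b * cc * cos(al),
                a * cc * cos(be), b * cc * cos(al), cc * cc), 3, 3)
  gstar <- solve(g)
  hkl <- rbind(h, k, l)
  dstar2 <- colSums(hkl * (gstar %*% hkl))
  dstar2 / 4
}

#' Read a subset of an XDS_ASCII reflection file
#'
#' Parses the header for the unit-cell constants and the declared column
#' positions of H, K, L, IOBS and SIGMA(IOBS), then reads the reflection
#' records and computes `s2` from the (general triclinic) unit cell.
#'
#' @param path Path to an `XDS_ASCII.HKL`-style file.
#' @param nominal_dose Dose stamp to attach (MGy); the file itself does not
#'   carry one.
#' @param wedge_index Wedge index to attach.
#'
#' @return Tibble with `wedge_index`, `nominal_dose`, `id` ("h,k,l"), `h`,
#'   `k`, `l`, `s2`, `J`, `sigma`; the unit cell is attached as attribute
#'   `cell`.
#' @export
read_xds_ascii <- function(path, nominal_dose = NA_real_, wedge_index = NA) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  hdr <- grep("^!", lines, value = TRUE)
  if (!any(grepl("FORMAT=XDS_ASCII", hdr))) {
    abort("not an XDS_ASCII file (missing !FORMAT=XDS_ASCII header)")
  }
  get_item <- function(name) {
    ln <- grep(paste0("!ITEM_", name, "="), hdr, value = TRUE, fixed = FALSE)
    if (length(ln) == 0) {
      abort(paste0("missing column declaration !ITEM_", name))
    }
    as.integer(sub(".*=", "", ln[1]))
  }
  col_h <- get_item("H"); col_k <- get_item("K"); col_l <- get_item("L")
  col_i <- get_item("IOBS"); col_s <- get_item("SIGMA\\(IOBS\\)")
  cell_ln <- grep("!UNIT_CELL_CONSTANTS=", hdr, value = TRUE)
  if (length(cell_ln) == 0) abort("missing !UNIT_CELL_CONSTANTS header")
  cell <- as.numeric(strsplit(trimws(sub(".*=", "", cell_ln[1])),
                              "\\s+")[[1]])
  if (length(cell) != 6 || anyNA(cell)) {
    abort("could not parse unit-cell constants")
  }
  body <- lines[!grepl("^!", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(tibble::tibble(wedge_index = integer(), nominal_dose = numeric(),
                          id = character(), h = integer(), k = integer(),
                          l = integer(), s2 = numeric(), J = numeric(),
                          sigma = numeric()))
  }
  fields <- strsplit(trimws(body), "\\s+")
  mat <- t(vapply(fields, function(f) as.numeric(
    f[c(col_h, col_k, col_l, col_i, col_s)]), numeric(5)))
  if (anyNA(mat)) abort("malformed reflection record in XDS_ASCII body")
  out <- tibble::tibble(
    wedge_index = wedge_index, nominal_dose = nominal_dose,
    h = as.integer(mat[, 1]), k = as.integer(mat[, 2]),
    l = as.integer(mat[, 3]),
    s2 = .s2_from_hkl(mat[, 1], mat[, 2], mat[, 3], cell),
    J = mat[, 4], sigma = mat[, 5]
  )
  out$id <- paste(out$h, out$k, out$l, sep = ",")
  out <- dplyr::relocate(out, "wedge_index", "nominal_dose", "id")
  attr(out, "cell") <- cell
  out
}

#' Serialize / load a protocol
#'
#' Structured JSON with one record per cycle plus the protocol-level
#' attributes (resolution limit, assumed decay rate, dose rate, total dose,
#' noise calibration).
#'
#' @param protocol A [generate_protocol()] object.
#' @param path File path (`.json`).
#' @return `path` invisibly; `read_protocol()` returns the `burn_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "burn_protocol"))
  obj <- list(
    d_min = attr(protocol, "d_min"),
    assumed_beta = attr(protocol, "assumed_beta"),
    dose_rate_mgy_s = attr(protocol, "dose_rate_mgy_s"),
    total_dose = attr(protocol, "total_dose"),
    gain = attr(protocol, "gain"),
    background_var = attr(protocol, "background_var"),
    cycles = as.data.frame(protocol)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- tibble::as_tibble(obj$cycles)
  structure(rows, class = c("burn_protocol", class(rows)),
            d_min = obj$d_min, assumed_beta = obj$assumed_beta,
            dose_rate_mgy_s = obj$dose_rate_mgy_s,
            total_dose = obj$total_dose, gain = obj$gain,
            background_var = obj$background_var)
}

.RUN_CONFIG_KEYS <- list(
  beam = c("flux", "energy_keV", "fwhm_h_um", "fwhm_v_um", "profile"),
  crystal = c("size_um", "composition"),
  protocol = c("assumed_beta", "rotation_range_deg", "center_angle_deg",
               "mosaicity_deg", "d_min", "n_collections", "collection_dose",
               "min_exposure_s", "max_rotation_speed_deg_s"),
  simulation = c("beta_true", "scale_drift", "b0", "scale0", "n_per_shell",
                 "background_var", "snr_target"),
  fit = c("n_shells", "weighted"),
  top = c("beam", "crystal", "protocol", "simulation", "fit",
          "output_dir", "seed")
)

#' Load and validate a run configuration
#'
#' YAML or JSON (chosen by file extension), with sections `beam`,
#' `crystal`, `protocol`, `simulation`, `fit` plus `output_dir` and `seed`.
#' Unknown keys are rejected with a message naming them; a round trip
#' through [save_run_config()] reproduces the configuration.
#'
#' @param path Config file (`.yaml`, `.yml` or `.json`).
#' @return Named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config must be .yaml/.yml or .json")
  }
  unknown_top <- setdiff(names(cfg), .RUN_CONFIG_KEYS$top)
  if (length(unknown_top) > 0) {
    abort(paste0("unknown config key(s): ",
                 paste(unknown_top, collapse = ", ")))
  }
  for (sec in c("beam", "crystal", "protocol", "simulation", "fit")) {
    if (!is.null(cfg[[sec]])) {
      unknown <- setdiff(names(cfg[[sec]]), .RUN_CONFIG_KEYS[[sec]])
      if (length(unknown) > 0) {
        abort(paste0("unknown config key(s) in '", sec, "': ",
                     paste(unknown, collapse = ", ")))
      }
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` (or plain named list).
#' @export
save_run_config <- function(config, path) {
  config <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# beam/crystal constructors from a run_config
.beam_from_config <- function(cfg) {
  b <- cfg$beam
  beam_parameters(flux = b$flux, energy_kev = b$energy_keV,
                  fwhm_h_um = b$fwhm_h_um %||% 45,
                  fwhm_v_um = b$fwhm_v_um %||% 35,
                  profile = b$profile %||% "gaussian")
}

.crystal_from_config <- function(cfg) {
  cr <- cfg$crystal
  comp <- if (is.null(cr$composition) ||
              identical(cr$composition, "default")) {
    default_composition()
  } else {
    co <- cr$composition
    protein_crystal_composition(
      solvent_fraction = co$solvent_fraction %||% 0.47,
      sulfur_per_residue = co$sulfur_per_residue %||% 0.05,
      solvent_mM = unlist(co$solvent_mM) %||% c(S = 300),
      extra_per_residue = unlist(co$extra_per_residue))
  }
  crystal_description(unlist(cr$size_um), comp = comp)
}
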