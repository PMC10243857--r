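#' Read a two-column time-series CSV
#'
#' Reads the CSV dialect shared by the photometric and kinetic assays:
#' a mandatory header row, numeric columns, decimal point `.`, optional
#' leading `#` comment lines carrying metadata, and an optional `blank`
#' column subtracted from the signal on request.
#'
#' @param path File path.
#' @return A data frame of numeric columns with attribute `metadata`
#'   (named character vector parsed from `# key: value` comment lines).
#'   When a `blank` column is present, a `signal_corrected` column (second
#'   column minus blank) is added.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines)
  meta <- character(0)
  if (length(meta_lines)) {
    kv <- sub("^#\\s*", "", lines[meta_lines])
    kv <- kv[grepl(":", kv)]
    if (length(kv)) {
      meta <- trimws(sub("^[^:]*:", "", kv))
      names(meta) <- trimws(sub(":.*$", "", kv))
    }
  }
  body_idx <- setdiff(which(nzchar(trimws(lines))), meta_lines)
  if (length(body_idx) < 2L) stop("missing header or data rows in ", path, call. = FALSE)
  header_line <- body_idx[1L]
  cols <- trimws(strsplit(lines[header_line], ",")[[1]])
  if (anyDuplicated(cols)) stop("duplicate column names in ", path, call. = FALSE)
  if (length(cols) < 2L || any(grepl("^[0-9.+-]", cols))) {
    stop("header row with >= 2 column names required in ", path, call. = FALSE)
  }
  rows <- lapply(body_idx[-1L], function(i) {
    fields <- trimws(strsplit(lines[i], ",")[[1]])
    if (length(fields) != length(cols)) {
      stop(sprintf("line %d of %s: expected %d fields, found %d",
                   i, path, length(cols), length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals) & nzchar(fields))) {
      bad <- which(is.na(vals) & nzchar(fields))[1L]
      stop(sprintf("line %d of %s: non-numeric value '%s' in column '%s'",
                   i, path, fields[bad], cols[bad]), call. = FALSE)
    }
    vals
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- cols
  if ("blank" %in% cols) {
    df$signal_corrected <- df[[setdiff(cols, "blank")[2L]]] - df$blank
  }
  attr(df, "metadata") <- meta
  df
}

#' Write a time-series CSV with metadata comments
#'
#' Numeric fields are written at full double precision so a write/read
#' round trip is lossless.
#'
#' @param df Data frame of numeric columns.
#' @param path Output path.
#' @param metadata Named list written as `# key: value` comment lines.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(df, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata)) {
    writeLines(sprintf("# %s: %s", k, format(metadata[[k]], digits = 17)), con)
  }
  writeLines(paste(names(df), collapse = ","), con)
  cols <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  writeLines(apply(cols, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read a COLVAR-style pulling-trajectory table
#'
#' Whitespace-delimited dialect with a `#! FIELDS time cv force d_<label>
#' ...` header naming the columns; additional `#` comment lines are
#' skipped. Requires `time`, `cv`, `force` and at least one `d_` distance
#' column; pair labels are taken from the distance column names.
#'
#' @param path File path.
#' @param replica_id Optional replica identifier attached to the result.
#' @return A [pulling_trajectory()].
#' @export
read_colvar <- function(path, replica_id = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  fields_line <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (length(fields_line) == 0L) {
    stop("missing '#! FIELDS' header in ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", fields_line[1L])), "\\s+")[[1]]
  need <- c("time", "cv", "force")
  if (!all(need %in% fields)) {
    stop("COLVAR header must name time, cv and force columns", call. = FALSE)
  }
  dist_cols <- grep("^d_", fields, value = TRUE)
  if (length(dist_cols) == 0L) {
    stop("COLVAR header must name at least one d_<label> distance column",
         call. = FALSE)
  }
  data_lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(data_lines) == 0L) stop("no data rows in ", path, call. = FALSE)
  mat <- do.call(rbind, lapply(seq_along(data_lines), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(data_lines[i]), "\\s+")[[1]]))
    if (length(vals) != length(fields) || any(is.na(vals))) {
      stop(sprintf("malformed data row %d in %s", i, path), call. = FALSE)
    }
    vals
  }))
  colnames(mat) <- fields
  dists <- as.data.frame(mat[, dist_cols, drop = FALSE])
  names(dists) <- sub("^d_", "", dist_cols)
  pulling_trajectory(mat[, "time"], mat[, "cv"], mat[, "force"], dists,
                     replica_id = replica_id)
}

#' Write a pulling trajectory as a COLVAR-style table
#'
#' @param traj A [pulling_trajectory()].
#' @param path Output path.
#' @param metadata Named list written as `# key: value` comment lines after
#'   the FIELDS header.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(traj, path, metadata = list()) {
  stopifnot(inherits(traj, "pulling_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  labels <- colnames(traj$pair_distances)
  writeLines(paste(c("#! FIELDS time cv force", paste0("d_", labels)),
                   collapse = " "), con)
  for (k in names(metadata)) {
    writeLines(sprintf("# %s: %s", k,
                       paste(format(metadata[[k]], digits = 17), collapse = " ")), con)
  }
  mat <- cbind(traj$time, traj$cv, traj$force, as.matrix(traj$pair_distances))
  writeLines(apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  invisible(path)
}

# Concentration strings with unit suffixes ("200 uM", "1.7e-6", "3 nM")
# normalised to molar. Bare numbers pass through unchanged.
.parse_concentration <- function(x) {
  if (is.numeric(x)) return(x)
  s <- trimws(as.character(x))
  m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*(µM|uM|nM|mM|pM|M)?$", s))[[1]]
  if (length(m) == 0L || m[2] == "") stop("cannot parse concentration: ", x, call. = FALSE)
  val <- as.numeric(m[2])
  if (is.na(val)) stop("cannot parse concentration: ", x, call. = FALSE)
  mult <- switch(if (m[3] == "") "M" else m[3],
                 "M" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6,
                 "nM" = 1e-9, "pM" = 1e-12)
  val * mult
}

#' Read a run configuration (YAML)
#'
#' Loads probe definitions, mixture totals and fit/analysis options from a
#' YAML file. Concentrations may carry unit suffixes (`uM`, `nM`, `mM`,
#' `pM`, `M`) and are normalised to molar on load. Probes referenced under
#' `mixture$probe` must be defined in the `probes` block; a probe without a
#' stated dissociation constant is rejected rather than defaulted.
#'
#' @param path YAML file path.
#' @return A list with elements `probes` (named list of [probe_model()]),
#'   `mixture` (a [mixture_totals()] plus the probe name, or `NULL`),
#'   `temperature`, `seed` and any remaining options.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  probes <- list()
  for (nm in names(raw$probes)) {
    pr <- raw$probes[[nm]]
    if (is.null(pr$kd)) {
      stop(sprintf("probe '%s' has no dissociation constant in the config; ",
                   nm), "refusing to assume one", call. = FALSE)
    }
    probes[[nm]] <- probe_model(
      name = nm,
      ligands_per_metal = if (is.null(pr$ligands_per_metal)) 1L else pr$ligands_per_metal,
      kd_cumulative = .parse_concentration(pr$kd),
      epsilon = if (is.null(pr$epsilon)) NA_real_ else pr$epsilon,
      wavelength = if (is.null(pr$wavelength)) NA_real_ else pr$wavelength)
  }
  mixture <- NULL
  if (!is.null(raw$mixture)) {
    mx <- raw$mixture
    if (!is.null(mx$probe) && !mx$probe %in% names(probes)) {
      stop(sprintf("mixture references undefined probe '%s'", mx$probe), call. = FALSE)
    }
    mixture <- list(
      totals = mixture_totals(.parse_concentration(mx$protein_total),
                              .parse_concentration(mx$probe_total),
                              .parse_concentration(mx$zinc_total)),
      probe = mx$probe)
  }
  extra <- raw[setdiff(names(raw), c("probes", "mixture", "temperature", "seed"))]
  c(list(probes = probes, mixture = mixture,
         temperature = if (is.null(raw$temperature)) 298.15 else raw$temperature,
         seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)),
    extra)
}

#' Write an analysis result as JSON with its configuration
#'
#' @param result Named list of results (numbers, vectors, nested lists).
#' @param path Output path.
#' @param config Configuration list embedded under `config` for
#'   reproducibility.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path, config = NULL) {
  payload <- list(result = result)
  if (!is.null(config)) payload$config <- config
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write an equilibrium state as a species table CSV
#'
#' One row per species (free zinc, free probe, probe complex and each
#' protein loading state) with concentrations in M.
#'
#' @param state An `equilibrium_state` from [solve_equilibrium()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_equilibrium_csv <- function(state, path) {
  stopifnot(inherits(state, "equilibrium_state"))
  df <- data.frame(
    species = c("free_zn", "free_probe", "probe_complex",
                names(state$protein_species)),
    concentration_M = c(state$free_zn, state$free_probe, state$probe_complex,
                        unname(state$protein_species)))
  write_timeseries_csv(df, path)
  invisible(path)
}
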