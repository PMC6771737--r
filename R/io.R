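# Plain-text readers/writers. All outputs are deterministic functions of
# their inputs (no timestamps), so a rerun with the same seed reproduces
# files byte-for-byte.

#' Write / read a demographic panel
#'
#' The panel CSV has one row per year x submodel with columns `year`,
#' `submodel_id`, `submodel`, `trials`, `successes`; the density series is
#' stored separately (see [write_density()]).
#'
#' @param panel A `"demographic_panel"`.
#' @param path Output CSV path.
#' @return `write_panel`: `path`, invisibly. `read_panel`: a
#'   `"demographic_panel"`.
#' @export
write_panel <- function(panel, path) {
  sub <- panel$submodels
  df <- data.frame(
    year = rep(panel$years, each = nrow(sub)),
    submodel_id = rep(sub$id, length(panel$years)),
    submodel = rep(sub$name, length(panel$years)),
    trials = as.integer(panel$trials),
    successes = as.integer(panel$successes)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @param density_path CSV written by [write_density()].
#' @param submodels Submodel table.
#' @export
read_panel <- function(path, density_path, submodels = soay_submodels()) {
  df <- read.csv(path)
  den <- read_density(density_path)
  years <- sort(unique(df$year))
  trials <- matrix(0L, nrow(submodels), length(years),
                   dimnames = list(submodels$name, years))
  successes <- trials
  for (r in seq_len(nrow(df))) {
    trials[df$submodel[r], as.character(df$year[r])] <- df$trials[r]
    successes[df$submodel[r], as.character(df$year[r])] <- df$successes[r]
  }
  demographic_panel(years, den$log10_count[match(years, den$year)],
                    trials, successes, submodels)
}

#' Write / read a density series
#' @param density Data frame from [simulate_density()].
#' @param path CSV path.
#' @export
write_density <- function(density, path) {
  write.csv(density, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) read.csv(path)

#' Write / read a daily climate series
#' @param series A `"daily_climate"`.
#' @param path CSV path (ISO-8601 dates, `missing` flag column).
#' @export
write_daily_climate <- function(series, path) {
  write.csv(data.frame(date = format(series$date, "%Y-%m-%d"),
                       value = series$value,
                       missing = is.na(series$value)), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_daily_climate
#' @param variable_name Label restored on read.
#' @export
read_daily_climate <- function(path, variable_name = "climate") {
  df <- read.csv(path)
  daily_climate(as.Date(df$date), df$value, variable_name)
}

#' Write / read a climate matrix
#'
#' CSV with a `year` column followed by window columns `w1..wW`; the
#' window scheme and centering flag are stored as leading comment lines.
#'
#' @param matrix A `"climate_matrix"`.
#' @param path CSV path.
#' @export
write_climate_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scheme=%s centered=%s variable=%s", matrix$scheme,
                     matrix$centered, matrix$variable_name), con)
  df <- data.frame(year = matrix$years, matrix$values, check.names = FALSE)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_matrix
#' @export
read_climate_matrix <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, regexec(
    "scheme=(\\w+) centered=(\\w+) variable=(\\S+)", hdr))[[1]]
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$year
  structure(list(values = values, years = as.integer(df$year),
                 scheme = meta[2], centered = as.logical(meta[3]),
                 variable_name = meta[4]),
            class = "climate_matrix")
}

#' Write / read ground-truth parameters
#'
#' Round-trips a `"semflm_params"` object through YAML so simulated truth
#' can be compared against fitted posteriors.
#'
#' @param params A `"semflm_params"`.
#' @param path YAML path.
#' @export
write_truth <- function(params, path) {
  yaml::write_yaml(lapply(unclass(params), function(x)
    if (is.null(x)) NULL else as.list(x)), path, precision = 15)
  invisible(path)
}

#' @rdname write_truth
#' @param submodels Submodel table the parameters refer to.
#' @export
read_truth <- function(path, submodels = soay_submodels()) {
  y <- yaml::read_yaml(path)
  unl <- function(x) if (is.null(x)) NULL else unlist(x)
  vital_params(submodels,
               beta0 = unl(y$beta0), beta_t = unl(y$beta_t),
               beta_e = unl(y$beta_e), theta = unl(y$theta),
               beta_f = unl(y$beta_f),
               alpha_t = unl(y$alpha_t), sigma_e = unl(y$sigma_e),
               rho_ef = unl(y$rho_ef), beta_m = unl(y$beta_m),
               gamma = unl(y$gamma), eps_e = unl(y$eps_e),
               eps_f = unl(y$eps_f))
}

#' Write / read a posterior draw matrix
#'
#' One row per retained draw with a leading `chain` column and one named
#' column per parameter.
#'
#' @param post A `"semflm_posterior"`.
#' @param path CSV path.
#' @export
write_posterior <- function(post, path) {
  df <- data.frame(chain = post$chain, post$draws, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  list(draws = as.matrix(df[, -1, drop = FALSE]), chain = df$chain)
}

#' Write a run manifest
#'
#' JSON record of the command, its configuration and seeds — enough to
#' re-run the stage bit-identically. No timestamps are written, so
#' identical runs produce identical files.
#'
#' @param path JSON path.
#' @param command Stage name.
#' @param config Configuration list.
#' @param extra Optional named list of additional fields.
#' @export
write_manifest <- function(path, command, config, extra = NULL) {
  jsonlite::write_json(
    c(list(command = command,
           package = "semflm",
           version = as.character(utils::packageVersion("semflm")),
           config = config), extra),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
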