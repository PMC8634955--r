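# Delimited-text input/output --------------------------------------------------
#
# Every artifact is comma-separated UTF-8 with a header row; no binary
# formats, for auditability.  Readers validate the schema strictly and report
# errors with file and line context (line 1 is the header).  Numeric output
# uses readr's shortest round-trip representation, so write-then-read is the
# identity on the data model; the decade comparison tables round to one
# decimal only in their printed form.

input_error <- function(file, line, msg) {
  abort(sprintf("%s%s: %s", basename(file),
                if (is.na(line)) "" else sprintf(" line %d", line), msg))
}

check_columns <- function(df, need, file) {
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    input_error(file, NA, paste0("missing mandatory column(s): ",
                                 paste(missing_cols, collapse = ", ")))
  }
}

check_range <- function(df, col, lo, hi, file) {
  bad <- which(is.na(df[[col]]) | df[[col]] < lo | df[[col]] > hi)
  if (length(bad) > 0L) {
    input_error(file, bad[1] + 1L,
                sprintf("column `%s` value %s outside [%g, %g]",
                        col, format(df[[col]][bad[1]]), lo, hi))
  }
}

read_table_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a population pyramid file
#' @param path CSV with columns `gender, age, count`.
#' @return A tibble.
#' @export
read_pyramid <- function(path) {
  df <- read_table_file(path)
  check_columns(df, c("gender", "age", "count"), path)
  check_range(df, "age", 0, 100, path)
  bad <- which(is.na(df$count) | df$count < 0)
  if (length(bad) > 0L) input_error(path, bad[1] + 1L, "negative or missing `count`")
  df
}

#' Read a life table file
#' @param path CSV with columns `gender, age, year, mortality, life_expectancy`.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  df <- read_table_file(path)
  check_columns(df, c("gender", "age", "mortality", "life_expectancy"), path)
  check_range(df, "mortality", 0, 1, path)
  life_table(df)
}

#' Read a smoking prevalence file
#' @param path CSV with columns `gender, age, current, former`.
#' @return A tibble.
#' @export
read_prevalence <- function(path) {
  df <- read_table_file(path)
  check_columns(df, c("gender", "age", "current", "former"), path)
  check_range(df, "current", 0, 1, path)
  check_range(df, "former", 0, 1, path)
  df
}

#' Read a quit-time distribution file
#' @param path CSV with columns `bin, share`.
#' @return A tibble.
#' @export
read_quit_time <- function(path) {
  df <- read_table_file(path)
  check_columns(df, c("bin", "share"), path)
  df$bin <- as.character(df$bin)
  check_range(df, "share", 0, 1, path)
  df
}

#' Read a transition-rate table file
#'
#' The `products` column (pipe-separated labels, identical on every row)
#' declares the state space the flows belong to.
#'
#' @param path CSV with columns `products, from, to, gender, age_lo, age_hi,
#'   year, mean, lo95, hi95`.
#' @return A [rate_table()].
#' @export
read_rate_table <- function(path) {
  df <- read_table_file(path)
  check_columns(df, c("products", "from", "to", "gender", "age_lo", "age_hi",
                      "mean", "lo95", "hi95"), path)
  for (col in c("mean", "lo95", "hi95")) check_range(df, col, 0, 1, path)
  products <- strsplit(df$products[1], "|", fixed = TRUE)[[1]]
  df$products <- NULL
  rate_table(df, products)
}

#' Write a transition-rate table file
#' @param rates A [rate_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  out <- tibble::as_tibble(rates)
  out <- tibble::add_column(
    out, products = paste(rate_products(rates), collapse = "|"), .before = 1
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

bundle_files <- c(
  pyramid = "pyramid.csv", life_table = "life_table.csv",
  prevalence = "prevalence.csv", quit_time = "quit_time.csv",
  births = "births.csv", migration_total = "migration_total.csv",
  migration_age = "migration_age.csv", risk_rr = "risk_rr.csv",
  config = "config.yaml"
)

#' Write a fixture bundle to a directory
#'
#' Writes the full set of delimited inputs ([read_input_bundle()] reads them
#' back identically): the demographic tables, the risk inputs and scalar
#' configuration (`config.yaml`), and one `rates_<name>.csv` per rate table.
#'
#' @param bundle An [input_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_csv(bundle$pyramid, p("pyramid.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(bundle$life_table), p("life_table.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$prevalence, p("prevalence.csv"), progress = FALSE)
  readr::write_csv(bundle$quit_time, p("quit_time.csv"), progress = FALSE)
  readr::write_csv(bundle$births, p("births.csv"), progress = FALSE)
  readr::write_csv(bundle$migration_total, p("migration_total.csv"), progress = FALSE)
  readr::write_csv(bundle$migration_age, p("migration_age.csv"), progress = FALSE)
  readr::write_csv(bundle$risk$rr_current, p("risk_rr.csv"), progress = FALSE)
  cfg <- list(
    decay_halflife = bundle$risk$decay_halflife,
    prrp_excess_fraction = as.list(bundle$risk$prrp_excess_fraction),
    quit20plus_years = bundle$risk$quit20plus_years,
    dual_use_rule = bundle$risk$dual_use_rule,
    relapse_multiplier = as.list(bundle$relapse_multiplier)
  )
  yaml::write_yaml(cfg, p("config.yaml"), precision = 17L)
  for (nm in names(bundle$rates)) {
    write_rate_table(bundle$rates[[nm]], p(sprintf("rates_%s.csv", nm)))
  }
  invisible(dir)
}

#' Read an input bundle from a directory
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return An [input_bundle()].
#' @export
read_input_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  cfg <- yaml::read_yaml(p("config.yaml"))
  risk <- risk_model(
    read_table_file(p("risk_rr.csv")),
    decay_halflife = cfg$decay_halflife,
    prrp_excess_fraction = unlist(cfg$prrp_excess_fraction),
    quit20plus_years = cfg$quit20plus_years,
    dual_use_rule = cfg$dual_use_rule
  )
  rate_files <- list.files(dir, pattern = "^rates_.*\\.csv$")
  rates <- lapply(rate_files, function(f) read_rate_table(p(f)))
  names(rates) <- sub("^rates_(.*)\\.csv$", "\\1", rate_files)
  input_bundle(
    pyramid = read_pyramid(p("pyramid.csv")),
    life_table = read_life_table(p("life_table.csv")),
    prevalence = read_prevalence(p("prevalence.csv")),
    quit_time = read_quit_time(p("quit_time.csv")),
    births = read_table_file(p("births.csv")),
    migration_total = read_table_file(p("migration_total.csv")),
    migration_age = read_table_file(p("migration_age.csv")),
    risk = risk,
    relapse_multiplier = unlist(cfg$relapse_multiplier),
    rates = rates
  )
}

#' Write projection outputs to a directory
#'
#' Writes the tidy yearly series (`series.csv`), the deaths-by-age table
#' (`deaths.csv`) and a run manifest (`manifest.json`: input digests, seed,
#' package version, timestamp).
#'
#' @param result A `projection_result`.
#' @param dir Output directory.
#' @param seed Seed recorded in the manifest (`NA` for deterministic runs).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$series, file.path(dir, "series.csv"), progress = FALSE)
  df <- as.data.frame.table(result$deaths_by_age, responseName = "deaths",
                            stringsAsFactors = FALSE)
  names(df) <- c("year", "gender", "age", "deaths")
  df$year <- as.integer(df$year); df$age <- as.integer(df$age)
  readr::write_csv(tibble::as_tibble(df), file.path(dir, "deaths.csv"),
                   progress = FALSE)
  write_manifest(dir, seed = seed,
                 config = list(scenario = result$scenario,
                               products = result$products,
                               start_year = result$start_year,
                               end_year = result$end_year))
  invisible(dir)
}

#' Write a scenario comparison as a decade table
#'
#' @param comparison A [compare_scenarios()] result.
#' @param path Output CSV (long format, full precision).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  readr::write_csv(tibble::as_tibble(comparison), path, progress = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' @param dir Directory whose data files are digested.
#' @param seed Seed used (or `NA`).
#' @param config Arbitrary run configuration recorded verbatim.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, seed = NA, config = list()) {
  files <- setdiff(list.files(dir), "manifest.json")
  digests <- as.list(tools::md5sum(file.path(dir, files)))
  names(digests) <- files
  manifest <- list(
    artifact = "prrpsim",
    version = as.character(utils::packageVersion("prrpsim")),
    seed = seed,
    config = config,
    file_digests = digests,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
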