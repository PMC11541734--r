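# Shared readers/writers with schema validation, and the run manifest.
# All tables are comma-delimited UTF-8 CSV with a header row; dates are
# ISO-8601 (yyyy-mm or yyyy-mm-dd); site/plot labels are free text.

.table_schemas <- list(
  forcing = list(
    required = c(site = "character", year = "integer", month = "integer",
                 tc = "numeric", vpd = "numeric", co2 = "numeric",
                 patm = "numeric", ppfd = "numeric"),
    optional = c(ppfd_product = "numeric"),
    check = function(d) {
      if (any(d$month < 1 | d$month > 12)) return("month outside 1-12")
      if (any(d$vpd < 0)) return("vpd must be >= 0")
      if (any(d$ppfd < 0)) return("ppfd must be >= 0")
      if (any(d$co2 <= 0) || any(d$patm <= 0)) {
        return("co2 and patm must be positive")
      }
      if (any(d$tc <= -10 | d$tc >= 60)) return("tc outside (-10, 60)")
      NULL
    }),
  gas_exchange = list(
    required = c(site = "character", species = "character",
                 plot = "character", asat = "numeric", amax = "numeric",
                 tleaf = "numeric", ppfd_meas = "numeric",
                 leaf_class = "character", basal_area_frac = "numeric"),
    optional = c(ci_sat = "numeric", ci_max = "numeric"),
    check = function(d) {
      if (any(d$ppfd_meas <= 0)) return("ppfd_meas must be positive")
      if (any(d$basal_area_frac < 0 | d$basal_area_frac > 1)) {
        return("basal_area_frac must lie in [0, 1]")
      }
      if (!all(d$leaf_class %in% c("sun", "shade"))) {
        return("leaf_class must be 'sun' or 'shade'")
      }
      NULL
    }),
  fapar = list(
    required = c(site = "character", date = "character",
                 value = "numeric", source = "character",
                 cloud_state = "character"),
    optional = character(0),
    check = function(d) {
      if (any(d$value < 0 | d$value > 1)) return("fAPAR value outside [0, 1]")
      if (!all(d$source %in% c("insitu", "satellite"))) {
        return("source must be 'insitu' or 'satellite'")
      }
      if (!all(d$cloud_state %in% c("00", "01", "10", "11"))) {
        return("cloud_state must be a two-bit code 00/01/10/11")
      }
      NULL
    }),
  isotope = list(
    required = c(site = "character", species = "character",
                 plot = "character", delta13c_leaf = "numeric"),
    optional = c(delta13c_air = "numeric"),
    check = function(d) {
      if (any(d$delta13c_leaf <= -1000)) {
        return("delta13c_leaf at or below -1000 permil is undefined")
      }
      NULL
    }),
  components = list(
    required = c(site = "character", plot = "character",
                 component = "character", value = "numeric",
                 sigma = "numeric"),
    optional = character(0),
    check = function(d) {
      if (any(d$sigma < 0)) return("sigma must be >= 0")
      NULL
    })
)

#' Read and validate a typed CSV table
#'
#' Strict reader for the packaged table schemas (`"forcing"`,
#' `"gas_exchange"`, `"fapar"`, `"isotope"`, `"components"`): missing
#' columns, unparseable values and unit-range violations are errors, with
#' the offending column and line numbers named. Cloud-state codes are
#' read as character so the literal two-bit codes (`"00"`, ...) survive.
#'
#' @param path CSV file path.
#' @param schema Schema name.
#' @return A validated data frame.
#' @export
read_table <- function(path, schema = names(.table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- .table_schemas[[schema]]
  d <- utils::read.csv(path, colClasses = "character",
                       stringsAsFactors = FALSE)
  miss <- setdiff(names(sc$required), names(d))
  if (length(miss) > 0) {
    stop("'", path, "': missing column(s): ", paste(miss, collapse = ", "))
  }
  types <- c(sc$required, sc$optional)
  for (col in intersect(names(types), names(d))) {
    if (types[[col]] == "character") next
    val <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(val) & !(d[[col]] %in% c("", "NA")))
    if (length(bad) > 0) {
      stop("'", path, "': column '", col, "': unparseable value at line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "))
    }
    d[[col]] <- if (types[[col]] == "integer") as.integer(val) else val
  }
  problem <- sc$check(d)
  if (!is.null(problem)) stop("'", path, "': ", problem)
  d
}

#' Write a table as CSV
#'
#' @param x Data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @rdname read_table
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the input tables of one site from a directory
#'
#' Reads the CSV files written by [write_site_csvs()] (forcing.csv,
#' gasex.csv, isotope.csv, fapar_insitu.csv, fapar_satellite.csv,
#' components.csv) into the list [run_site_attribution()] consumes.
#'
#' @param dir Directory containing the CSVs.
#' @return A list of validated data frames.
#' @export
read_site_inputs <- function(dir) {
  list(forcing = read_table(file.path(dir, "forcing.csv"), "forcing"),
       gasex = read_table(file.path(dir, "gasex.csv"), "gas_exchange"),
       isotope = read_table(file.path(dir, "isotope.csv"), "isotope"),
       fapar_insitu = read_table(file.path(dir, "fapar_insitu.csv"),
                                 "fapar"),
       fapar_satellite = read_table(file.path(dir, "fapar_satellite.csv"),
                                    "fapar"),
       components = read_table(file.path(dir, "components.csv"),
                               "components"))
}

#' Write a reproducibility manifest
#'
#' Records the seed, configuration and package/R versions of a run as
#' JSON - enough to regenerate outputs bit-for-bit.
#'
#' @param path Output JSON path.
#' @param seed Integer seed of the run.
#' @param config Arbitrary configuration list to embed.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, seed, config = list()) {
  info <- list(
    package = "gppattrib",
    version = as.character(utils::packageVersion("gppattrib")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed),
    config = config,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
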