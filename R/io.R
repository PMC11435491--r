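#' Read a chemical reference table
#'
#' Parses the delimited chemical-table dialect: one row per chemical with
#' columns `name`, `cas`, `mw` (g/mol), `cdv0_runs` (replicate cDV0
#' concentrations in ug/mL, semicolon-separated), `llna_nesil`, `human_noel`
#' and `human_loel` (doses in ug/cm2). `"-"` or an empty field marks a
#' missing value; the token `"NS"` in the LLNA column flags a chemical tested
#' non-sensitizing in the LLNA, which excludes the value from all numeric
#' work. Unknown extra columns are preserved.
#'
#' @param path Path to the delimited text file.
#' @param delim Field delimiter (default comma).
#' @return A tibble with typed columns: `cdv0_runs` as a list-column of
#'   numeric vectors, `cdv0` (the geometric-mean merged value, see
#'   [merge_runs()]), `llna_nesil`/`human_noel`/`human_loel` as numeric with
#'   `NA` for missing, and `llna_ns` flagging LLNA non-sensitizers.
#' @export
read_chemical_table <- function(path, delim = ",") {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  req <- c("name", "cas", "mw", "cdv0_runs", "llna_nesil", "human_noel",
           "human_loel")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("Missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("Chemical table contains no data rows.", call. = FALSE)
    return(tibble::tibble(
      name = character(), cas = character(), mw = numeric(),
      cdv0_runs = list(), cdv0 = numeric(), llna_nesil = numeric(),
      llna_ns = logical(), human_noel = numeric(), human_loel = numeric()
    ))
  }
  dup <- raw$name[duplicated(raw$name)]
  if (length(dup) > 0) {
    stop("Duplicate chemical names: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }

  parse_num <- function(x, col, allow_ns = FALSE) {
    x <- trimws(x)
    miss <- is.na(x) | x == "-" | x == ""
    ns <- allow_ns & !miss & toupper(x) == "NS"
    out <- rep(NA_real_, length(x))
    todo <- !miss & !ns
    val <- suppressWarnings(as.numeric(gsub(",", "", x[todo])))
    if (anyNA(val)) {
      bad <- which(todo)[is.na(val)]
      stop("Malformed number in column `", col, "`, data row(s) ",
           paste(bad, collapse = ", "), ".", call. = FALSE)
    }
    if (any(val <= 0)) {
      bad <- which(todo)[val <= 0]
      stop("Non-positive value in column `", col, "`, data row(s) ",
           paste(bad, collapse = ", "), ".", call. = FALSE)
    }
    out[todo] <- val
    list(value = out, ns = ns)
  }

  mw <- parse_num(raw$mw, "mw")$value
  runs <- lapply(seq_along(raw$cdv0_runs), function(i) {
    parts <- strsplit(trimws(raw$cdv0_runs[i]), ";")[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (length(v) == 0 || anyNA(v) || any(v <= 0)) {
      stop("Malformed cdv0_runs entry in data row ", i, ".", call. = FALSE)
    }
    v
  })
  llna <- parse_num(raw$llna_nesil, "llna_nesil", allow_ns = TRUE)
  noel <- parse_num(raw$human_noel, "human_noel")
  loel <- parse_num(raw$human_loel, "human_loel")

  out <- tibble::tibble(
    name = raw$name,
    cas = raw$cas,
    mw = mw,
    cdv0_runs = runs,
    cdv0 = vapply(runs, merge_runs, numeric(1)),
    llna_nesil = llna$value,
    llna_ns = llna$ns,
    human_noel = noel$value,
    human_loel = loel$value
  )
  extra <- setdiff(names(raw), req)
  if (length(extra) > 0) out <- dplyr::bind_cols(out, raw[extra])
  out
}

#' Write a chemical table
#'
#' Inverse of [read_chemical_table()]: serialises a chemical tibble back to
#' the delimited dialect (replicate runs semicolon-joined, `-` for missing
#' values, `NS` for LLNA non-sensitizers). Extra columns are written as-is.
#'
#' @param data Chemical tibble as produced by [read_chemical_table()] or
#'   [simulate_references()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_chemical_table <- function(data, path, delim = ",") {
  fmt <- function(x) ifelse(is.na(x), "-", format(x, scientific = FALSE,
                                                  trim = TRUE, digits = 15))
  out <- tibble::tibble(
    name = data$name,
    cas = data$cas,
    mw = fmt(data$mw),
    cdv0_runs = vapply(data$cdv0_runs, function(v)
      paste(format(v, scientific = FALSE, trim = TRUE, digits = 15),
            collapse = ";"), character(1)),
    llna_nesil = ifelse(data$llna_ns, "NS", fmt(data$llna_nesil)),
    human_noel = fmt(data$human_noel),
    human_loel = fmt(data$human_loel)
  )
  extra <- setdiff(names(data), c(names(out), "cdv0", "cdv0_runs", "llna_ns"))
  if (length(extra) > 0) out <- dplyr::bind_cols(out, data[extra])
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' The bundled 30-chemical reference dataset
#'
#' The packaged chemical table underlying the reference analysis: 30 skin
#' sensitizers with molecular weights, replicate cDV0 concentrations from the
#' GARDskin Dose-Response assay (ug/mL), LLNA-derived NESILs and human HRIPT
#' NOELs/LOELs (ug/cm2). 25 chemicals carry both in vivo references and 10
#' have replicate assay runs.
#'
#' @return A tibble, see [read_chemical_table()] for the columns.
#' @examples
#' chemical_dataset()
#' @export
chemical_dataset <- function() {
  read_chemical_table(system.file("extdata", "chemical_dataset.csv",
                                  package = "skinpod", mustWork = TRUE))
}

#' Read dose-response decision-value curves
#'
#' Reads the delimited dose-response dialect: columns `item_id`,
#' `concentration` (ug/mL) and `dv`, one row per replicate measurement.
#'
#' @param path Path to the delimited text file.
#' @param delim Field delimiter.
#' @return A tibble with one row per measurement, ready for
#'   [estimate_cdv0()].
#' @export
read_dose_response <- function(path, delim = ",") {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  out <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    item_id = readr::col_character(),
    concentration = readr::col_double(),
    dv = readr::col_double()
  ), progress = FALSE)
  if (anyNA(out$concentration) || any(out$concentration <= 0)) {
    stop("Concentrations must be positive and non-missing.", call. = FALSE)
  }
  out
}
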