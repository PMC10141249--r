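# Unit handling for delimited tables. Units ride on column-name suffixes
# (E_el_hartree, G_kcal, q_Ni_e, NiS_dist_A, freq_cm1 ...). Energy columns
# are converted to kcal/mol on load and renamed to their base name; every
# numeric column of a loaded table carries an entry in attr(,"units").

.energy_units <- c(kcal = 1, hartree = 627.5095, ev = 23.0605,
                   cm1 = 2.85914e-3)

.energy_basenames <- c("E_el", "G", "zpve", "thermal", "dG", "dG0",
                       "dG_act", "G_ox", "G_red")

.split_unit <- function(name) {
  m <- regmatches(name, regexpr("_(kcal|hartree|ev|cm1|e|A|V|K|bar|pct)$",
                                name))
  if (!length(m)) return(c(base = name, unit = NA_character_))
  c(base = substr(name, 1, nchar(name) - nchar(m)), unit = sub("^_", "", m))
}

#' Read a validated delimited table
#'
#' Comma- or tab-delimited (autodetected) with a header row. Column names
#' declare units as suffixes (`E_el_hartree`, `G_kcal`, `q_Ni_e`,
#' `NiS_dist_A`). Energy columns are converted to kcal/mol (1 hartree =
#' 627.5095 kcal/mol, 1 eV = 23.0605 kcal/mol, 1 cm^-1 = 2.85914e-3
#' kcal/mol) and renamed to the bare quantity name; the original units of
#' every numeric column are recorded in `attr(x, "units")`.
#'
#' @param path file path.
#' @param schema one of `"ledger"`, `"charges"`, `"orbitals"`, `"bonds"`,
#'   `"modes"`; selects the required-column validation.
#' @return a `data.frame` of class `react_table` with attributes `units`
#'   (named character) and `schema`.
#' @export
read_table <- function(path, schema = c("ledger", "charges", "orbitals",
                                        "bonds", "modes")) {
  schema <- match.arg(schema)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#", strip.white = TRUE)
  units <- character(0)
  out_names <- names(df)
  for (j in seq_along(df)) {
    su <- .split_unit(names(df)[j])
    base <- su[["base"]]; unit <- su[["unit"]]
    if (is.character(df[[j]]) &&
        base %in% c(.energy_basenames, "freq") ||
        (is.character(df[[j]]) && !is.na(unit))) {
      num <- suppressWarnings(as.numeric(df[[j]]))
      if (anyNA(num))
        stop("unparseable number in column '", names(df)[j], "'")
      df[[j]] <- num
    }
    if (!is.numeric(df[[j]])) next
    if (base %in% .energy_basenames) {
      if (is.na(unit) || !unit %in% names(.energy_units))
        stop("unknown or missing unit tag on energy column '",
             names(df)[j], "' (use _kcal, _hartree, _ev or _cm1)")
      df[[j]] <- df[[j]] * .energy_units[[unit]]
      out_names[j] <- base
      units[base] <- "kcal/mol"
    } else if (!is.na(unit)) {
      out_names[j] <- if (unit %in% c("e", "A", "V", "K", "bar")) base
                      else names(df)[j]
      units[out_names[j]] <- unit
    } else if (grepl("^q_?P?_?[0-9.]+$", names(df)[j]) ||
               grepl("^(qP|q)[._][0-9.]+$", names(df)[j])) {
      units[names(df)[j]] <- "e"           # charge-response probe column
    } else if (grepl("^(di|bo)_", names(df)[j])) {
      units[names(df)[j]] <- "1"           # dimensionless index
    } else if (grepl("^d[0-9]+$", names(df)[j])) {
      units[names(df)[j]] <- "A"           # mode displacement component
    } else if (grepl("^p_", names(df)[j])) {
      units[names(df)[j]] <- "%"           # orbital percentage
    } else {
      units[names(df)[j]] <- "1"
    }
  }
  names(df) <- out_names

  required <- switch(schema,
    ledger   = c("species", "E_el"),
    charges  = character(0),
    orbitals = c("model", "p_C", "p_S"),
    bonds    = c("model"),
    modes    = c("freq_cm1"))
  # percentage columns may carry an explicit _pct suffix
  if (schema == "orbitals") {
    for (b in c("p_C", "p_S"))
      if (!b %in% names(df) && paste0(b, "_pct") %in% names(df)) {
        names(df)[names(df) == paste0(b, "_pct")] <- b
        names(units)[names(units) == paste0(b, "_pct")] <- b
        units[b] <- "%"
      }
  }
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema '", schema, "': missing required column(s): ",
         paste(missing, collapse = ", "))
  if (schema == "charges") {
    probe <- grep("^q_?P?_?[0-9.]+$|^(qP|q)[._][0-9.]+$", names(df))
    if (length(probe) < 2)
      stop("schema 'charges': need at least two probe-charge columns ",
           "(named like q_0.0, q_0.1, ...)")
  }
  structure(df, units = units, schema = schema,
            class = c("react_table", "data.frame"))
}

#' Write a table in the delimited format of [read_table()]
#'
#' @param df data.frame; column names should carry unit suffixes.
#' @param path output path.
#' @param sep delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Units of a loaded table
#'
#' @param x a `react_table` from [read_table()].
#' @return named character vector mapping numeric columns to unit strings.
#' @export
table_units <- function(x) attr(x, "units")
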