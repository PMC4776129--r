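#' Catalogue of supported metal-ion descriptors
#'
#' One row per physicochemical descriptor the package understands: the column
#' name used in tables, a human-readable label, units where they exist, and
#' (for derived descriptors such as polarization-force ratios) the parent
#' columns the value is computed from. Radii are in angstroms, CMCs in
#' micrograms per litre; ratio descriptors are treated as unitless.
#'
#' @return A tibble with columns `descriptor`, `label`, `units`, `derived`
#'   and `parents` (list-column of parent descriptor names, empty for
#'   measured quantities).
#' @export
#' @examples
#' descriptor_info()
descriptor_info <- function() {
  tibble::tribble(
    ~descriptor,    ~label,                                         ~units,    ~parents,
    "AN",           "atomic number",                                "",        character(),
    "AW",           "relative atomic weight",                       "",        character(),
    "AR",           "atomic radius",                                "Å",  character(),
    "CR",           "covalent radius",                              "Å",  character(),
    "r",            "Pauling ionic radius",                         "Å",  character(),
    "MP",           "melting point",                                "°C", character(),
    "D",            "density at 300 K",                             "g/cm3",   character(),
    "Eh",           "heat of vaporization",                         "kJ/mol",  character(),
    "BP",           "boiling point",                                "°C", character(),
    "dIP",          "ionization-potential difference OX vs OX-1",   "eV",      character(),
    "dE0",          "electrochemical potential",                    "V",       character(),
    "Xm",           "electronegativity",                            "",        character(),
    "logKOH_abs",   "|log first hydrolysis constant|",              "",        character(),
    "Xm2r",         "covalent index Xm^2 r",                        "",        c("Xm", "r"),
    "Z2_r",         "polarization force Z^2/r",                     "",        c("Z", "r"),
    "AN_dIP",       "atomic ionization potential AN/dIP",           "",        c("AN", "dIP"),
    "sigma_p",      "softness index",                               "",        character(),
    "IP",           "ionization potential",                         "eV",      character(),
    "AR_AW",        "electron density AR/AW",                       "",        c("AR", "AW"),
    "Z",            "ionic charge",                                 "",        character(),
    "Z_r2",         "polarization force Z/r^2",                     "",        c("Z", "r"),
    "Z_AR2",        "polarization force Z/AR^2",                    "",        c("Z", "AR"),
    "Z_r",          "polarization force Z/r",                       "",        c("Z", "r"),
    "Z_AR",         "polarization force Z/AR",                      "",        c("Z", "AR"),
    "x",            "electronegativity index",                      "",        character(),
    "Z_rx",         "relative softness Z/(r x)",                    "",        c("Z", "r", "x")
  ) |>
    dplyr::mutate(derived = lengths(.data$parents) > 0L)
}

derived_formulas <- list(
  AR_AW = function(d) d$AR / d$AW,
  Xm2r  = function(d) d$Xm^2 * d$r,
  Z_r   = function(d) d$Z / d$r,
  Z_r2  = function(d) d$Z / d$r^2,
  Z2_r  = function(d) d$Z^2 / d$r,
  Z_AR  = function(d) d$Z / d$AR,
  Z_AR2 = function(d) d$Z / d$AR^2,
  Z_rx  = function(d) d$Z / (d$r * d$x)
)

#' Read a metal descriptor table
#'
#' Reads a comma-separated descriptor table (UTF-8, `.` decimal, header row)
#' into a tibble with one row per metal/oxidation state. Every column other
#' than `metal_id` must parse as numeric; blank cells become `NA` (never
#' zero). Columns not in [descriptor_info()] are kept untouched as extras.
#'
#' @param path Path to a CSV file with a `metal_id` column.
#' @return A tibble, one row per metal. If a `cmc` column (criteria maximum
#'   concentration, ug/L) is present it is validated as strictly positive.
#' @export
#' @examples
#' read_descriptor_table(metcrit_example("table1_training.csv"))
read_descriptor_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"metal_id" %in% names(tbl)) {
    abort("descriptor table must have a 'metal_id' column")
  }
  num_cols <- setdiff(names(tbl), "metal_id")
  for (col in num_cols) {
    raw <- tbl[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' in column '%s', row %d",
                    raw[bad[1]], col, bad[1]))
    }
    tbl[[col]] <- parsed
  }
  validate_descriptor_table(tbl)
  tbl
}

#' Write a metal descriptor table
#'
#' Inverse of [read_descriptor_table()]: writes the tibble as UTF-8 CSV with
#' full numeric precision so that a read/write round trip reproduces every
#' cell bit-exactly.
#'
#' @param data Descriptor tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(data, path) {
  out <- data
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

validate_descriptor_table <- function(tbl) {
  if (anyDuplicated(tbl$metal_id)) {
    dup <- tbl$metal_id[duplicated(tbl$metal_id)][1]
    abort(sprintf("duplicate metal_id: '%s'", dup))
  }
  strict_pos <- intersect(c("AW", "AR", "CR", "r", "D", "cmc"), names(tbl))
  for (col in strict_pos) {
    bad <- which(!is.na(tbl[[col]]) & tbl[[col]] <= 0)
    if (length(bad)) {
      abort(sprintf("column '%s' must be strictly positive (row %d, metal '%s')",
                    col, bad[1], tbl$metal_id[bad[1]]))
    }
  }
  if ("AN" %in% names(tbl)) {
    an <- tbl$AN[!is.na(tbl$AN)]
    if (any(an <= 0 | an != round(an))) {
      abort("column 'AN' must contain positive integers")
    }
  }
  invisible(tbl)
}

#' Path to a bundled example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
metcrit_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "metcrit")))
  }
  path <- system.file("extdata", file, package = "metcrit")
  if (path == "") abort(paste0("no bundled file named '", file, "'"))
  path
}

#' The eight-metal USEPA training table
#'
#' The training set behind the integrated-radius model: USEPA-recommended
#' acute criteria maximum concentrations (CMCs, ug/L) and 26 physicochemical
#' descriptors for Cd, Cr(III), Cr(VI), Cu, Hg, Ni, Ag and Zn. The two
#' chromium valences are separate records sharing structural descriptors, so
#' n = 8 throughout. Derived ratio descriptors are recomputed from their
#' parents at full floating precision (see [recompute_derived()]); the
#' published table rounds them, and rounded ratios are never used in any fit.
#'
#' @param recompute Recompute derived descriptor columns from parents
#'   (default `TRUE`; set `FALSE` to see the values exactly as bundled).
#' @return A tibble with 8 rows: `metal_id`, `cmc` and 26 descriptors.
#' @export
#' @examples
#' ppcr_training_table()
ppcr_training_table <- function(recompute = TRUE) {
  tbl <- read_descriptor_table(metcrit_example("table1_training.csv"))
  if (recompute) tbl <- suppressWarnings(recompute_derived(tbl))
  tbl
}

#' Amphipod LC50 comparison table
#'
#' Published screening-level CMC predictions for fourteen transition metals
#' alongside one-week median lethal concentrations (LC50, ug/L) for the
#' freshwater amphipod *Hyalella azteca* in soft water, as nominal and as
#' measured exposure concentrations. `group` is the periodic-table group;
#' `block` separates the two group-VIII pairs (Co/Rh and Ni/Pt) that are
#' compared independently.
#'
#' @return A tibble with columns `group`, `block`, `period`, `metal_id`,
#'   `predicted_cmc`, `lc50_nominal`, `lc50_measured` (concentrations ug/L).
#' @export
#' @examples
#' hyalella_lc50()
hyalella_lc50 <- function() {
  path <- metcrit_example("table4_lc50.csv")
  tbl <- readr::read_csv(path, col_types = "ccicddd", progress = FALSE)
  conc <- c("predicted_cmc", "lc50_nominal", "lc50_measured")
  for (col in conc) {
    if (any(tbl[[col]] <= 0, na.rm = TRUE)) {
      abort(sprintf("column '%s' must be strictly positive", col))
    }
  }
  tbl
}

#' Recompute derived descriptors from their parents
#'
#' Derived descriptors (electron density AR/AW, covalent index Xm^2 r, the
#' polarization-force ratios Z/r, Z/r^2, Z^2/r, Z/AR, Z/AR^2 and relative
#' softness Z/(r x)) are recomputed from parent columns at full floating
#' precision, overwriting any rounded stored value. Published tables print
#' these ratios rounded to two decimals, which is far too coarse for the
#' regression downstream. Fields whose parents are missing or would divide
#' by zero are left as stored and collected in a per-field issue report
#' attached as attribute `"issues"` (also raised as a warning); all other
#' fields are still computed.
#'
#' @param data Descriptor tibble.
#' @return The tibble with derived columns overwritten; attribute `"issues"`
#'   holds a tibble of `metal_id`, `descriptor`, `problem` for cells that
#'   could not be recomputed. Idempotent.
#' @export
#' @examples
#' recompute_derived(ppcr_training_table(recompute = FALSE))
recompute_derived <- function(data) {
  stopifnot(is.data.frame(data))
  issues <- list()
  ids <- if ("metal_id" %in% names(data)) data$metal_id else as.character(seq_len(nrow(data)))
  info <- descriptor_info()
  for (field in names(derived_formulas)) {
    if (!field %in% names(data)) next
    parents <- info$parents[[match(field, info$descriptor)]]
    if (!all(parents %in% names(data))) {
      issues[[field]] <- tibble::tibble(
        metal_id = ids, descriptor = field,
        problem = paste0("parent column(s) absent: ",
                         paste(setdiff(parents, names(data)), collapse = ", ")))
      next
    }
    val <- derived_formulas[[field]](data)
    bad <- !is.finite(val)
    if (any(bad)) {
      issues[[paste0(field, ".cell")]] <- tibble::tibble(
        metal_id = ids[bad], descriptor = field,
        problem = "missing parent or division by zero")
    }
    data[[field]] <- ifelse(bad, data[[field]], val)
  }
  issues <- dplyr::bind_rows(issues)
  if (nrow(issues)) {
    warn(sprintf("%d derived cell(s) could not be recomputed; see attr(x, 'issues')",
                 nrow(issues)))
  }
  attr(data, "issues") <- issues
  data
}

#' Natural-log transform for strictly positive measurements
#'
#' Concentration-like variables are log-normally distributed, so descriptors
#' and CMCs are modelled on the natural-log scale. Fails loudly on
#' non-positive input rather than producing `-Inf`/`NaN`.
#'
#' @param values Numeric vector, all elements strictly positive (`NA`
#'   propagates).
#' @param what Label used in the error message.
#' @return `log(values)`.
#' @export
#' @examples
#' ln_transform(c(1, exp(1)))
ln_transform <- function(values, what = "value") {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    abort(sprintf("%s must be strictly positive for ln transform (element %d is %g)",
                  what, bad[1], values[bad[1]]))
  }
  log(values)
}
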