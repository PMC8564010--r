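#' Individual-level survival table
#'
#' A `survival_table` is a validated data frame with one row per assayed
#' individual and columns `block`, `vial`, `fert_temp`, `embryo_temp`,
#' `assay_temp`, `outcome` (0 = died before completing development,
#' 1 = completed development), plus the declared [experiment_design()]
#' carried as an attribute.
#'
#' @param records Data frame with the six columns above.
#' @param design An [experiment_design()]; defaults to the standard design.
#' @return An object of classes `survival_table` and `data.frame`.
#' @export
survival_table <- function(records, design = experiment_design()) {
  records <- as.data.frame(records)
  validate_survival_records(records, design)
  structure(records,
            design = design,
            class = c("survival_table", "data.frame"))
}

survival_columns <- c("block", "vial", "fert_temp", "embryo_temp",
                      "assay_temp", "outcome")

validate_survival_records <- function(records, design) {
  missing_cols <- setdiff(survival_columns, names(records))
  if (length(missing_cols))
    stop_validation("missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0)
    stop_validation("survival table must be non-empty")

  for (col in c("fert_temp", "embryo_temp", "assay_temp")) {
    v <- records[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop_validation("column '%s' has a non-finite/unparseable temperature at row %d",
                      col, bad %||% 1L)
    }
  }
  out <- records$outcome
  ok <- is.numeric(out) & !is.na(out) & out %in% c(0, 1)
  if (!all(ok))
    stop_validation("column 'outcome' must be 0 or 1; first violation at row %d",
                    which(!ok)[1])
  if (length(unique(records$assay_temp)) < 2)
    stop_validation("need at least 2 distinct assay temperatures")

  rng <- range(design$assay_temps)
  off <- !(records$assay_temp >= rng[1] & records$assay_temp <= rng[2])
  if (any(off))
    stop_validation("assay_temp outside declared assay range [%g, %g] at row %d",
                    rng[1], rng[2], which(off)[1])

  ## vials are nested in block x treatment x assay-temperature cells:
  ## a vial label may not recur in two different cells
  cell <- interaction(records$block, records$fert_temp, records$embryo_temp,
                      records$assay_temp, drop = TRUE)
  tab <- unique(data.frame(vial = as.character(records$vial),
                           cell = as.character(cell)))
  dup <- tab$vial[duplicated(tab$vial)]
  if (length(dup))
    stop_validation("vial '%s' appears in more than one block/treatment/assay cell",
                    dup[1])
  invisible(TRUE)
}

#' @export
print.survival_table <- function(x, ...) {
  cat(sprintf("Survival table: %d individuals, %d vials, %d blocks\n",
              nrow(x), length(unique(paste(x$block, x$vial))),
              length(unique(x$block))))
  cat(sprintf("  assay range %g-%g degC, overall survival %.3f\n",
              min(x$assay_temp), max(x$assay_temp), mean(x$outcome)))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read an individual-level survival CSV
#'
#' Expects a comma-separated UTF-8 file with header
#' `block,vial,fert_temp,embryo_temp,assay_temp,outcome` ("." decimal mark).
#' Column names can be remapped through `schema`.
#'
#' @param path Path to the CSV file.
#' @param design Declared [experiment_design()] used for validation.
#' @param schema Named character vector mapping canonical column names to
#'   the names used in the file, e.g. `c(outcome = "survived")`.
#' @return A [survival_table()].
#' @export
read_survival_csv <- function(path, design = experiment_design(), schema = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  colmap <- stats::setNames(survival_columns, survival_columns)
  if (!is.null(schema)) colmap[names(schema)] <- schema
  missing_cols <- setdiff(unname(colmap), names(raw))
  if (length(missing_cols))
    stop_validation("CSV %s lacks column(s): %s", path,
                    paste(missing_cols, collapse = ", "))

  rec <- data.frame(block = raw[[colmap["block"]]],
                    vial  = raw[[colmap["vial"]]],
                    stringsAsFactors = FALSE)
  for (col in c("fert_temp", "embryo_temp", "assay_temp", "outcome")) {
    v <- raw[[colmap[col]]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num))
      stop_validation("column '%s' unparseable at row %d (value '%s')",
                      colmap[col], which(is.na(num))[1], v[which(is.na(num))[1]])
    rec[[col]] <- num
  }
  bad <- which(!(rec$outcome %in% c(0, 1)))
  if (length(bad))
    stop_validation("column '%s' must be 0/1; row %d has '%s'",
                    colmap["outcome"], bad[1], rec$outcome[bad[1]])
  rec$outcome <- as.integer(rec$outcome)
  survival_table(rec, design)
}

#' Write a survival table to CSV
#'
#' Inverse of [read_survival_csv()]: one row per individual, fixed header
#' `block,vial,fert_temp,embryo_temp,assay_temp,outcome`.
#'
#' @param table A [survival_table()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(table, path) {
  stopifnot(inherits(table, "survival_table"))
  if (!nzchar(path)) stop_validation("empty output path")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_validation("directory does not exist: %s", dir)
  out <- as.data.frame(table)[, survival_columns]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
design_of <- function(x) UseMethod("design_of")

#' @export
design_of.survival_table <- function(x) attr(x, "design")
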