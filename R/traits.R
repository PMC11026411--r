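#' Default column mapping for Amniote-style life-history tables
#'
#' Returns the mapping from the package's internal field names to the column
#' names used in the Amniote life-history database export. Pass a modified
#' copy to [read_traits()] for tables with different headers.
#'
#' @return Named character vector. Names are internal fields
#'   (`species`, `adult_mass`, `female_mass`, `male_mass`, `weaning_mass`,
#'   `litter_size`, `gestation`, `lactation`, `subclass`, `order`); values are
#'   the expected column names in the file.
#' @export
#' @examples
#' cm <- amniote_columns()
#' cm[["species"]] <- "binomial"
amniote_columns <- function() {
  c(species      = "species",
    adult_mass   = "adult_body_mass_g",
    female_mass  = "female_body_mass_g",
    male_mass    = "male_body_mass_g",
    weaning_mass = "weaning_weight_g",
    litter_size  = "litter_or_clutch_size_n",
    gestation    = "gestation_d",
    lactation    = "weaning_d",
    subclass     = "subclass",
    order        = "order")
}

# Fields that must be present as columns; the rest default to NA when absent.
.mandatory_fields <- c("species", "adult_mass", "weaning_mass", "litter_size")

#' Read a species life-history trait table
#'
#' Reads a CSV or TSV table of per-species life-history measurements (one row
#' per species) into the standard internal layout. Masses are in grams,
#' durations in days. Unparseable numeric fields become `NA`, never zero;
#' non-positive masses or durations and litter sizes below one are invalid and
#' are also set to `NA` with a warning.
#'
#' @param path Path to a CSV or TSV file (separator sniffed from the header
#'   line unless `sep` is given).
#' @param column_map Named character vector mapping internal field names to
#'   file column names; see [amniote_columns()].
#' @param sep Field separator; `NULL` (default) auto-detects `","` vs `"\t"`.
#' @return A `data.frame` with columns `species`, `subclass`, `order`,
#'   `adult_mass`, `female_mass`, `male_mass`, `weaning_mass`, `litter_size`,
#'   `gestation`, `lactation`.
#' @seealso [clean_traits()], [analysis_table()]
#' @export
read_traits <- function(path, column_map = amniote_columns(), sep = NULL) {
  if (!file.exists(path)) stop_allomi(paste0("file not found: ", path), "allomi_io_error")
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(trimws(header))) {
    warning("empty trait table: ", path)
    return(empty_traits())
  }
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  traits_from_data_frame(raw, column_map)
}

#' Coerce a raw data.frame into the standard trait layout
#'
#' Same validation as [read_traits()] but starting from an in-memory
#' `data.frame` (useful for programmatic construction and testing).
#'
#' @param raw A data.frame whose columns follow `column_map`.
#' @inheritParams read_traits
#' @return See [read_traits()].
#' @export
traits_from_data_frame <- function(raw, column_map = amniote_columns()) {
  missing_cols <- setdiff(unname(column_map[.mandatory_fields]), names(raw))
  if (length(missing_cols)) {
    stop_allomi(paste0("trait table is missing mandatory column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "allomi_schema_error")
  }
  get_col <- function(field) {
    cn <- column_map[[field]]
    if (!is.null(cn) && cn %in% names(raw)) raw[[cn]] else rep(NA, nrow(raw))
  }
  rec <- data.frame(
    species      = trimws(as.character(get_col("species"))),
    subclass     = as.character(get_col("subclass")),
    order        = as.character(get_col("order")),
    adult_mass   = as_num_quiet(get_col("adult_mass")),
    female_mass  = as_num_quiet(get_col("female_mass")),
    male_mass    = as_num_quiet(get_col("male_mass")),
    weaning_mass = as_num_quiet(get_col("weaning_mass")),
    litter_size  = as_num_quiet(get_col("litter_size")),
    gestation    = as_num_quiet(get_col("gestation")),
    lactation    = as_num_quiet(get_col("lactation")),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(rec$species)))
    stop_allomi("trait table contains empty species names", "allomi_validation_error")
  dup <- unique(rec$species[duplicated(normalize_species(rec$species))])
  if (length(dup)) {
    stop_allomi(paste0("duplicated species in trait table: ",
                       paste(dup, collapse = ", ")),
                "allomi_validation_error")
  }
  rec <- invalidate_nonpositive(rec)
  rownames(rec) <- NULL
  rec
}

empty_traits <- function() {
  traits_from_data_frame(
    data.frame(species = character(), adult_body_mass_g = numeric(),
               weaning_weight_g = numeric(), litter_or_clutch_size_n = numeric(),
               check.names = FALSE))
}

invalidate_nonpositive <- function(rec) {
  bad <- 0L
  for (f in c("adult_mass", "female_mass", "male_mass", "weaning_mass",
              "gestation", "lactation")) {
    idx <- which(!is.na(rec[[f]]) & rec[[f]] <= 0)
    bad <- bad + length(idx)
    rec[[f]][idx] <- NA_real_
  }
  idx <- which(!is.na(rec$litter_size) & rec$litter_size < 1)
  bad <- bad + length(idx)
  rec$litter_size[idx] <- NA_real_
  if (bad > 0L)
    warning(bad, " non-positive mass/duration or litter-size < 1 value(s) set to NA")
  rec
}

#' Apply data corrections and the 15% consistency filters
#'
#' Cleans a trait table in two steps. User-supplied corrections (for known
#' data-entry errors such as a mass recorded in the wrong unit) are applied
#' first and logged. Two exclusion rules are then evaluated, both with a
#' strict "more than 15%" threshold:
#' \describe{
#'   \item{rule A (`sex_mass`)}{the default adult mass lies outside
#'     `[0.85 * min(sex-specific masses), 1.15 * max(sex-specific masses)]`,
#'     evaluated only when at least one sex-specific mass is present;}
#'   \item{rule B (`weaning_mass`)}{the per-offspring weaning mass exceeds
#'     `1.15 *` the default adult mass.}
#' }
#' A species failing rule A is not additionally evaluated under rule B, so
#' every exclusion cites exactly one rule. Filtering is idempotent and
#' independent of row order.
#'
#' @param records Trait table from [read_traits()] or
#'   [traits_from_data_frame()].
#' @param corrections Optional `data.frame` with columns `species`, `field`,
#'   `value`: replacement values applied before filtering.
#' @return A list of class `"clean_traits"` with elements `records` (the
#'   retained rows) and `report` (a `"clean_report"`: input/retained counts,
#'   exclusion log with rule ids and offending values, corrections applied).
#' @export
#' @examples
#' tab <- traits_from_data_frame(data.frame(
#'   species = c("a", "b"), adult_body_mass_g = c(1000, 1000),
#'   weaning_weight_g = c(100, 1200), litter_or_clutch_size_n = c(2, 1),
#'   check.names = FALSE))
#' cleaned <- clean_traits(tab)
#' cleaned$report$exclusions
clean_traits <- function(records, corrections = NULL) {
  n_input <- nrow(records)
  applied <- data.frame(species = character(), field = character(),
                        old = numeric(), new = numeric(),
                        stringsAsFactors = FALSE)
  if (!is.null(corrections) && nrow(corrections)) {
    stopifnot(all(c("species", "field", "value") %in% names(corrections)))
    for (k in seq_len(nrow(corrections))) {
      sp <- corrections$species[k]
      f  <- corrections$field[k]
      i  <- match(normalize_species(sp), normalize_species(records$species))
      if (is.na(i))
        stop_allomi(paste0("correction for unknown species: ", sp),
                    "allomi_validation_error")
      if (!f %in% names(records))
        stop_allomi(paste0("correction for unknown field: ", f),
                    "allomi_validation_error")
      applied <- rbind(applied, data.frame(
        species = records$species[i], field = f,
        old = records[[f]][i], new = as.numeric(corrections$value[k]),
        stringsAsFactors = FALSE))
      records[[f]][i] <- as.numeric(corrections$value[k])
    }
  }

  excl <- data.frame(species = character(), rule_id = character(),
                     detail = character(), stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    sex <- c(r$female_mass, r$male_mass)
    sex <- sex[!is.na(sex)]
    if (length(sex) && !is.na(r$adult_mass)) {
      if (r$adult_mass > 1.15 * max(sex) || r$adult_mass < 0.85 * min(sex)) {
        drop[i] <- TRUE
        excl <- rbind(excl, data.frame(
          species = r$species, rule_id = "sex_mass",
          detail = sprintf("default %g g outside [0.85*%g, 1.15*%g]",
                           r$adult_mass, min(sex), max(sex)),
          stringsAsFactors = FALSE))
        next
      }
    }
    if (!is.na(r$weaning_mass) && !is.na(r$adult_mass) &&
        r$weaning_mass > 1.15 * r$adult_mass) {
      drop[i] <- TRUE
      excl <- rbind(excl, data.frame(
        species = r$species, rule_id = "weaning_mass",
        detail = sprintf("weaning %g g > 1.15 * adult %g g",
                         r$weaning_mass, r$adult_mass),
        stringsAsFactors = FALSE))
    }
  }

  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  report <- structure(list(n_input = n_input, n_retained = nrow(kept),
                           exclusions = excl, corrections_applied = applied),
                      class = "clean_report")
  structure(list(records = kept, report = report), class = "clean_traits")
}

#' @export
print.clean_report <- function(x, ...) {
  cat("Trait cleaning report\n")
  cat(sprintf("  input species:    %d\n", x$n_input))
  cat(sprintf("  retained species: %d\n", x$n_retained))
  cat(sprintf("  excluded:         %d", nrow(x$exclusions)))
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$rule_id)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  if (nrow(x$corrections_applied))
    cat(sprintf("  corrections applied: %d\n", nrow(x$corrections_applied)))
  invisible(x)
}

#' Derive the log10 analysis variables
#'
#' Builds the fitting table from cleaned trait records:
#' `y = log10(weaning_mass * litter_size)` (litter mass at weaning, g),
#' `x = log10(adult mass)` under the chosen proxy, and
#' `z = log10(gestation + lactation)` (investment duration, d; `NA` when a
#' duration is missing and `duration_required = FALSE`). Species lacking a
#' required field are dropped with a message, so per-analysis subsets (e.g.
#' with and without duration data) are reproducible.
#'
#' @param records Trait table (typically `clean_traits(...)$records`).
#' @param mass_proxy `"default"` for the sex-agnostic adult mass, `"female"`
#'   for the female adult mass.
#' @param duration_required If `TRUE`, species without both gestation and
#'   lactation durations are dropped (needed for the two-predictor methods).
#' @return A `data.frame` of class `"analysis_table"` with columns `species`,
#'   `subclass`, `order`, `y`, `x`, `z`; attributes `mass_proxy` and
#'   `n_dropped`.
#' @export
analysis_table <- function(records,
                           mass_proxy = c("default", "female"),
                           duration_required = TRUE) {
  if (inherits(records, "clean_traits")) records <- records$records
  mass_proxy <- match.arg(mass_proxy)
  mass <- if (mass_proxy == "default") records$adult_mass else records$female_mass
  if (mass_proxy == "female" && all(is.na(mass)))
    stop_allomi("no female adult masses available for mass_proxy = \"female\"",
                "allomi_validation_error")
  litter_mass <- records$weaning_mass * records$litter_size
  dur <- records$gestation + records$lactation
  ok <- !is.na(litter_mass) & !is.na(mass)
  if (duration_required) ok <- ok & !is.na(dur)
  n_drop <- sum(!ok)
  if (n_drop > 0L)
    message(n_drop, " species dropped for missing required variables")
  out <- data.frame(species  = records$species[ok],
                    subclass = records$subclass[ok],
                    order    = records$order[ok],
                    y = log10(litter_mass[ok]),
                    x = log10(mass[ok]),
                    z = log10(dur[ok]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mass_proxy") <- mass_proxy
  attr(out, "n_dropped") <- n_drop
  class(out) <- c("analysis_table", "data.frame")
  out
}
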