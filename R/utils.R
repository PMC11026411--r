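# Internal helpers shared across the package.

# Short stable identifier for a fitted model: polynomial rolling hash over a
# canonical string (exact double arithmetic below 2^53, reduced mod 2^31).
# Used to enforce the single-fit comparability rule for MI values.
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 2147483647
  sprintf("%08x", h)
}

make_fit_id <- function(method, proxy, species, coefs) {
  key <- paste(method, proxy, length(species),
               paste(sort(species), collapse = "|"),
               paste(format(coefs, digits = 12), collapse = ","),
               sep = ";")
  paste0(method, "-", fnv1a(key))
}

# Numeric coercion that maps unparseable fields to NA (never 0) without noise.
as_num_quiet <- function(x) suppressWarnings(as.numeric(x))

# Species names are matched after normalising case and space/underscore.
normalize_species <- function(x) {
  x <- gsub("[ _]+", "_", trimws(as.character(x)))
  tolower(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_allomi <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "allomi_error")))
}

signif_str <- function(x, digits = 3) formatC(signif(x, digits), format = "fg", flag = "#", digits = digits)
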