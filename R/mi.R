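#' Compute the maternal investment metric
#'
#' MI is the log10 ratio of a species' observed litter mass at weaning to the
#' mass predicted by the fitted allometric relationship,
#' `MI = log10(observed / predicted)`. Predictions are always marginal (fixed
#' effects only): for the mixed models the phylogenetic random effect is left
#' at its zero expectation, so ecology and genetics correlated with the
#' phylogeny remain part of what MI measures. On the log10 scale MI is
#' identical to the vertical residual, so it is a unitless number: 0 means
#' "exactly average for its adult mass (and investment duration)", +1 means
#' ten times the expected litter weaning mass.
#'
#' MI values are comparable only within a single fit; the returned table is
#' tagged with the generating `fit_id` and [rank_species()] refuses to mix
#' tables from different fits.
#'
#' @param fit An [allometry()] fit.
#' @param table Data to score; defaults to the fit's own training table.
#'   Species lacking a predictor required by the fit are dropped with a
#'   message.
#' @return A `data.frame` of class `"mi_table"`: `species`, `observed` (g),
#'   `predicted` (g), `MI`; attributes `fit_id`, `method`, `mass_proxy`.
#' @export
#' @examples
#' set.seed(1)
#' tab <- data.frame(species = paste0("s", 1:40), x = runif(40, 1, 6))
#' tab$y <- -0.2 + 0.78 * tab$x + rnorm(40, 0, 0.2)
#' fit <- allometry(tab, "slr")
#' head(maternal_investment(fit))
maternal_investment <- function(fit, table = NULL) {
  stopifnot(inherits(fit, "allomfit"))
  if (is.null(table)) table <- fit$data
  table <- as.data.frame(table)
  needs_z <- fit$method %in% c("mslr", "mplmm")
  req <- c("species", "y", "x", if (needs_z) "z",
           if (!is.null(fit$groups)) fit$groups)
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop_allomi(paste0("table lacks column(s): ", paste(missing_cols, collapse = ", ")),
                "allomi_validation_error")
  ok <- stats::complete.cases(table[, req, drop = FALSE])
  if (any(!ok)) {
    message(sum(!ok), " species dropped: missing a predictor required by the fit")
    table <- table[ok, , drop = FALSE]
  }
  yhat <- marginal_linear_predictor(fit, table)
  out <- data.frame(species = table$species,
                    observed = 10^table$y,
                    predicted = 10^yhat,
                    MI = table$y - yhat,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit_id") <- fit$fit_id
  attr(out, "method") <- fit$method
  attr(out, "mass_proxy") <- fit$proxy
  class(out) <- c("mi_table", "data.frame")
  out
}

#' Rank species by maternal investment
#'
#' Orders an MI table by decreasing MI with a stable alphabetical tie-break.
#' All rows must stem from the same fit: supplying results with mixed
#' `fit_id`s is an error, because MI values from different fits are not
#' comparable.
#'
#' @param results One `"mi_table"`, or a list of them to be combined (they
#'   must share the `fit_id`).
#' @return The ordered `"mi_table"` with a `rank` column.
#' @export
rank_species <- function(results) {
  if (!inherits(results, "mi_table") && is.list(results)) {
    ids <- vapply(results, function(r) attr(r, "fit_id") %||% NA_character_, "")
    if (length(unique(ids)) != 1L || anyNA(ids))
      stop_allomi("MI values stem from different fits and are not comparable",
                  "allomi_comparability_error")
    combined <- do.call(rbind, lapply(results, as.data.frame))
    attr(combined, "fit_id") <- ids[1]
    attr(combined, "method") <- attr(results[[1]], "method")
    attr(combined, "mass_proxy") <- attr(results[[1]], "mass_proxy")
    class(combined) <- c("mi_table", "data.frame")
    results <- combined
  }
  stopifnot(inherits(results, "mi_table"))
  ord <- order(-results$MI, results$species)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "fit_id") <- attr(results, "fit_id")
  attr(out, "method") <- attr(results, "method")
  attr(out, "mass_proxy") <- attr(results, "mass_proxy")
  class(out) <- c("mi_table", "data.frame")
  out
}

#' Render the MI formula of a fit
#'
#' Presents the fitted allometric denominator in the conventional form, e.g.
#' `MI_SLR = log10( m_lw / (0.637 * m_a^0.778) )`: the constant `10^a` at 3
#' significant figures and the exponents at 3 decimals. The underlying fit
#' keeps full precision.
#'
#' @param fit An [allometry()] fit (no group-specific slopes).
#' @return List with the [allometric_form()] and `text`, the rendered
#'   formula.
#' @export
mi_formula <- function(fit) {
  form <- allometric_form(fit)
  list(form = form, text = paste0("MI_", toupper(fit$method), " = log10( ",
                                  format_mi_formula(form), " )"))
}

format_mi_formula <- function(form) {
  txt <- paste0("m_lw / (", signif_str(form$constant, 3),
                " * m_a^", formatC(form$exponent_mass, format = "f", digits = 3))
  if (!is.na(form$exponent_duration))
    txt <- paste0(txt, " * d^", formatC(form$exponent_duration, format = "f", digits = 3))
  paste0(txt, ")")
}

#' Compare MI under the default and female adult-mass proxies
#'
#' Given two fits of the same method on the same species — one using the
#' default (sex-agnostic) adult mass and one the female adult mass — computes
#' the per-species difference in MI, the fraction of species whose MI differs
#' by more than `threshold` (strictly), the differences expressed in SD units
#' of the default-proxy MI, and the exact Wilcoxon-Pratt signed-rank test of
#' a systematic shift.
#'
#' @param fit_default,fit_female Fits with `mass_proxy` `"default"` and
#'   `"female"` on the identical species set.
#' @param threshold Difference considered noticeable (default 0.1 MI units).
#' @return List of class `"mi_proxy_comparison"`: `differences` (data frame
#'   with `species`, `mi_default`, `mi_female`, `delta`, `delta_sd_units`),
#'   `fraction_above`, `sd_mi_default`, `test` (the signed-rank test).
#' @export
compare_mass_proxies <- function(fit_default, fit_female, threshold = 0.1) {
  stopifnot(inherits(fit_default, "allomfit"), inherits(fit_female, "allomfit"))
  if (!identical(fit_default$proxy, "default") || !identical(fit_female$proxy, "female"))
    stop_allomi("expected one fit per mass proxy (default, female)",
                "allomi_validation_error")
  mi_d <- maternal_investment(fit_default)
  mi_f <- maternal_investment(fit_female)
  if (!setequal(mi_d$species, mi_f$species))
    stop_allomi(paste0("species sets differ between the two fits: ",
                       paste(c(setdiff(mi_d$species, mi_f$species),
                               setdiff(mi_f$species, mi_d$species)), collapse = ", ")),
                "allomi_validation_error")
  mi_f <- mi_f[match(mi_d$species, mi_f$species), ]
  delta <- mi_d$MI - mi_f$MI
  sd_mi <- stats::sd(mi_d$MI)
  diffs <- data.frame(species = mi_d$species,
                      mi_default = mi_d$MI, mi_female = mi_f$MI,
                      delta = delta, delta_sd_units = delta / sd_mi,
                      stringsAsFactors = FALSE)
  structure(list(differences = diffs,
                 fraction_above = mean(abs(delta) > threshold),
                 threshold = threshold,
                 sd_mi_default = sd_mi,
                 test = signed_rank_pratt(delta)),
            class = "mi_proxy_comparison")
}

#' @export
print.mi_proxy_comparison <- function(x, ...) {
  cat("Adult-mass proxy comparison (default vs female)\n")
  cat(sprintf("  species: %d\n", nrow(x$differences)))
  cat(sprintf("  |delta MI| > %g: %.1f%% of species\n",
              x$threshold, 100 * x$fraction_above))
  cat(sprintf("  SD of MI (default proxy): %.3f (threshold = %.2f SD)\n",
              x$sd_mi_default, x$threshold / x$sd_mi_default))
  cat(sprintf("  signed-rank test: z = %.3f, p = %.4g (%s)\n",
              unname(x$test$statistic), x$test$p.value,
              if (isTRUE(x$test$exact)) "exact" else "asymptotic"))
  invisible(x)
}

#' Write an MI table to TSV
#'
#' @param mi An `"mi_table"`.
#' @param path Output path.
#' @return `path`, invisibly. The `fit_id` is stored in a header comment so
#'   that comparability survives the round trip.
#' @export
write_mi_tsv <- function(mi, path) {
  stopifnot(inherits(mi, "mi_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fit_id: %s\tmethod: %s\tmass_proxy: %s",
                     attr(mi, "fit_id"), attr(mi, "method"),
                     attr(mi, "mass_proxy")), con)
  utils::write.table(as.data.frame(mi), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
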