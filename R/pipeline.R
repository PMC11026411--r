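# End-to-end workflow: clean -> derive -> fit -> MI -> comparisons.
# All outputs are plain CSV/TSV/JSON for diffability.

fit_to_list <- function(fit) {
  out <- list(kind = toupper(fit$method),
              coefficients = as.list(fit$coefficients),
              ci = apply(fit$ci, 1, function(r) list(lo = r[1], hi = r[2])),
              n = fit$n, r_squared = fit$r_squared,
              residual_sd = fit$sigma,
              mass_proxy = fit$proxy, fit_id = fit$fit_id)
  if (inherits(fit, "allomfit_dhglm")) {
    out <- c(out, list(lambda = fit$lambda_phy, Lambda = fit$Lambda,
                       delta0 = fit$delta0, delta1 = fit$delta1,
                       gamma = fit$gamma_disp, logLik = fit$logLik,
                       converged = fit$converged,
                       boundary = as.list(fit$boundary),
                       lambda_unidentifiable = fit$lambda_unidentifiable,
                       lambda_profile = if (!is.null(fit$profile))
                         apply(fit$profile, 1, as.list)))
  }
  if (is.null(fit$groups)) {
    form <- allometric_form(fit)
    out$allometric_form <- list(constant = form$constant,
                                exponent_mass = form$exponent_mass,
                                exponent_duration = form$exponent_duration)
  }
  out
}

#' Serialise a fit to JSON
#'
#' @param fit An [allometry()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full maternal-investment workflow
#'
#' Executes the analysis sequence on a trait table (and optionally a tree):
#' cleaning with the 15% consistency filters, derivation of the log10
#' analysis variables, fitting of the requested regression methods, MI
#' computation per fit, the Quade comparison of MI across the four
#' non-phylogenetic methods (when all four were fitted), and subclass group
#' comparisons (Kruskal-Wallis, plus pairwise Wilcoxon-Mann-Whitney for
#' subclasses with at least `pairwise_min_n` species). Every output file is
#' plain text; the run log records the seed, a configuration hash and the
#' species count after every stage.
#'
#' @param traits Path to a CSV/TSV trait table, or a trait data.frame.
#' @param tree Path to a Newick file, or an `ape::phylo`, or `NULL` (the
#'   phylogenetic methods are then skipped with a message).
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param methods `"all"` or a subset of the six method names.
#' @param mass_proxy `"default"` or `"female"`.
#' @param corrections Optional corrections data.frame (see [clean_traits()]).
#' @param column_map See [read_traits()].
#' @param seed Integer seed recorded in the run log and used for any
#'   bootstrap stages.
#' @param n_boot Bootstrap replicates for the PLMM-vs-SLR and MPLMM-vs-MSLR
#'   LRTs; `0` (default) skips them.
#' @param pairwise_min_n Minimum group size for pairwise subclass tests.
#' @return Invisibly, a list with `report`, `table`, `fits`, `mi`, `tests`,
#'   `log`.
#' @export
run_pipeline <- function(traits, tree = NULL, out_dir = NULL,
                         methods = "all", mass_proxy = "default",
                         corrections = NULL, column_map = amniote_columns(),
                         seed = 1L, n_boot = 0L, pairwise_min_n = 15L) {
  all_methods <- c("slr", "mslr", "sma", "ma", "plmm", "mplmm")
  if (identical(methods, "all")) methods <- all_methods
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(cnd) {
      stop_allomi(paste0("pipeline stage '", name, "' failed: ",
                         conditionMessage(cnd)),
                  "allomi_pipeline_error")
    })
  }
  log <- list(seed = seed, mass_proxy = mass_proxy, methods = methods,
              n = list())

  records <- stage("read", {
    if (is.character(traits)) read_traits(traits, column_map) else
      traits_from_data_frame(traits, column_map)
  })
  log$n$input <- nrow(records)
  cleaned <- stage("clean", clean_traits(records, corrections))
  log$n$retained <- cleaned$report$n_retained
  phylo_wanted <- any(methods %in% c("plmm", "mplmm"))
  if (phylo_wanted && is.null(tree)) {
    message("no tree supplied: skipping the phylogenetic methods")
    methods <- setdiff(methods, c("plmm", "mplmm"))
    phylo_wanted <- FALSE
  }
  if (is.character(tree)) tree <- stage("read", ape::read.tree(tree))
  needs_z <- any(methods %in% c("mslr", "mplmm"))
  tab <- stage("derive", analysis_table(cleaned, mass_proxy,
                                        duration_required = needs_z))
  if (phylo_wanted) {
    present <- normalize_species(tab$species) %in% normalize_species(tree$tip.label)
    if (any(!present)) {
      message(sum(!present), " species absent from the tree dropped")
      tab <- tab[present, , drop = FALSE]
    }
  }
  log$n$analysed <- nrow(tab)

  fits <- list(); mi <- list()
  for (m in methods) {
    fits[[m]] <- stage(paste0("fit_", m),
                       allometry(tab, m, tree = if (m %in% c("plmm", "mplmm")) tree))
    mi[[m]] <- maternal_investment(fits[[m]])
  }

  tests <- list()
  nonphylo <- c("slr", "sma", "ma", "mslr")
  if (all(nonphylo %in% names(mi))) {
    mimat <- sapply(mi[nonphylo], function(d) d$MI)
    tests$quade_methods <- stage("compare", quade_compare(mimat))
  }
  mi_main <- mi[[if ("mplmm" %in% names(mi)) "mplmm" else methods[1]]]
  sub <- tab$subclass[match(mi_main$species, tab$species)]
  if (length(unique(stats::na.omit(sub))) >= 2) {
    tests$kruskal_subclass <- stage("compare", kruskal_wallis(mi_main$MI, sub))
    cnt <- table(sub)
    big <- names(cnt)[cnt >= pairwise_min_n]
    if (length(big) >= 2) {
      pairs <- utils::combn(big, 2, simplify = FALSE)
      tests$pairwise_subclass <- lapply(pairs, function(pr) {
        mann_whitney(mi_main$MI[sub == pr[1]], mi_main$MI[sub == pr[2]],
                     mode = "asymptotic")
      })
      names(tests$pairwise_subclass) <- vapply(pairs, paste, "", collapse = "_vs_")
    }
  }
  if (n_boot > 0 && all(c("slr", "plmm") %in% names(fits)))
    tests$lrt_plmm_vs_slr <- stage("lrt",
      bootstrap_lrt(fits$slr, fits$plmm, n_boot = n_boot, seed = seed))
  if (n_boot > 0 && all(c("mslr", "mplmm") %in% names(fits)))
    tests$lrt_mplmm_vs_mslr <- stage("lrt",
      bootstrap_lrt(fits$mslr, fits$mplmm, n_boot = n_boot, seed = seed + 1L))

  log$config_hash <- fnv1a(paste(deparse(list(methods, mass_proxy, seed, n_boot)),
                                 collapse = ""))
  result <- list(report = cleaned$report, table = tab, fits = fits, mi = mi,
                 tests = tests, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stage("write", {
      utils::write.csv(tab, file.path(out_dir, "cleaned.csv"), row.names = FALSE)
      jsonlite::write_json(unclass(cleaned$report),
                           file.path(out_dir, "clean_report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows",
                           pretty = TRUE)
      for (m in names(fits)) {
        write_fit_json(fits[[m]], file.path(out_dir, paste0("fit_", m, ".json")))
        write_mi_tsv(mi[[m]], file.path(out_dir, paste0("mi_", m, ".tsv")))
      }
      test_summaries <- lapply(tests, summarise_test)
      jsonlite::write_json(test_summaries, file.path(out_dir, "tests.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      jsonlite::write_json(log, file.path(out_dir, "run.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }
  invisible(result)
}

summarise_test <- function(x) {
  if (inherits(x, "htest")) {
    list(method = x$method, statistic = unname(x$statistic),
         df = if (!is.null(x$parameter)) unname(x$parameter),
         p_value = x$p.value)
  } else if (inherits(x, "mi_boot_lrt")) {
    list(method = "parametric-bootstrap LRT", statistic = x$statistic,
         df = x$df, p_value = x$p.value)
  } else if (is.list(x)) {
    lapply(x, summarise_test)
  }
}
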