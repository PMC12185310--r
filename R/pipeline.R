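#' Configuration for an end-to-end study run
#'
#' @param cohort a cohort data.frame, a [sim_config()] (simulated on demand),
#'   or a path to a TSV written by [write_cohort()].
#' @param cells phenotype columns to analyse; `NULL` selects every column
#'   matching the `<trait>_age<age>_<reporter>` naming convention.
#' @param covariates covariate specification passed to the regression models.
#' @param B bootstrap replications per cell (>= 1000 recommended for reported
#'   intervals).
#' @param seed base seed; every cell derives its own sub-seed from it.
#' @param controls control variables for the conditional reruns where an
#'   indirect effect is detected.
#' @param factor_views factor analyses to run (`"common"`, `"by_reporter"`,
#'   `"by_age"`), or `NULL` to skip.
#' @param sibling_interaction `"auto"` applies the contrast term to
#'   parent-reported ADHD-type cells (trait `"adhd"`), `TRUE`/`FALSE` force it.
#' @param conf confidence level used throughout; an estimate is flagged
#'   significant when its BCa interval excludes zero.
#' @return object of class `study_config`.
#' @export
study_config <- function(cohort,
                         cells = NULL,
                         covariates = "default",
                         B = 10000,
                         seed = 1L,
                         controls = c("ses", "imd_decile", "parenting_factor"),
                         factor_views = "common",
                         sibling_interaction = "auto",
                         conf = 0.95) {
  structure(list(cohort = cohort, cells = cells, covariates = covariates,
                 B = B, seed = seed, controls = controls,
                 factor_views = factor_views,
                 sibling_interaction = sibling_interaction, conf = conf),
            class = "study_config")
}

resolve_cohort <- function(x) {
  if (inherits(x, "sim_config")) return(simulate_cohort(x))
  if (is.character(x) && length(x) == 1) return(read_cohort(x))
  if (is.data.frame(x)) return(x)
  stopf("cohort must be a data.frame, a sim_config, or a TSV path")
}

study_cells <- function(cohort, cells) {
  if (!is.null(cells)) return(cells)
  Filter(function(cl) !is.null(parse_phenotype_column(cl)), names(cohort))
}

sig_excludes_zero <- function(lower, upper) {
  is.finite(lower) && is.finite(upper) && (lower > 0 || upper < 0)
}

#' Run the full study design over a phenotype grid
#'
#' For every phenotype cell (trait x age x reporter): the polygenic-score
#' decomposition with BCa bootstrap on the DZ subset, and a univariate twin
#' model on MZ+DZ pairs with the ACE/ADE choice made from the twin
#' correlations (and a sibling-interaction term where configured). Factor
#' views add the corresponding factor-score outcomes. Cell failures are
#' recorded and skipped, never fatal. Everything is deterministic given the
#' config seed.
#'
#' @param config a [study_config()].
#' @return object of class `study_report` with long-format `estimates`,
#'   `twin_components`, per-cell `twin_models` summaries, `skipped`, and run
#'   `meta`data.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- resolve_cohort(config$cohort)
  cells <- study_cells(cohort, config$cells)
  if (!length(cells)) stopf("no phenotype cells to analyse")
  dz <- cohort[cohort$zygosity == "DZ", , drop = FALSE]
  if (!nrow(dz)) stopf("polygenic-score decomposition needs DZ pairs; cohort has none")

  estimates <- list(); twin_comp <- list(); twin_models <- list(); skipped <- list()
  cell_seeds <- stats::setNames(vapply(seq_along(cells), function(i)
    derive_seed(config$seed, 100L + i), integer(1)), cells)

  for (i in seq_along(cells)) {
    cell <- cells[i]
    tags <- parse_phenotype_column(cell) %||% list(trait = cell, age = NA, reporter = NA)
    dec <- tryCatch(
      decompose(dz, cell, config$covariates, B = config$B,
                seed = cell_seeds[[cell]], conf = config$conf),
      error = function(e) e)
    if (inherits(dec, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        cell = cell, stage = "decompose", reason = conditionMessage(dec))
    } else {
      estimates[[length(estimates) + 1L]] <- cell_estimates(cell, tags, dec)
    }
    tw <- tryCatch(
      run_twin_cell(cohort, cell, config),
      error = function(e) e)
    if (inherits(tw, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        cell = cell, stage = "twin", reason = conditionMessage(tw))
    } else {
      twin_comp[[length(twin_comp) + 1L]] <- cbind(cell = cell, tw$components)
      twin_models[[length(twin_models) + 1L]] <- tw$summary
    }
  }

  # factor-score outcomes
  if (!is.null(config$factor_views)) {
    traits <- unique(vapply(Filter(Negate(is.null),
                                   lapply(cells, parse_phenotype_column)),
                            `[[`, character(1), "trait"))
    for (trait in traits) {
      for (view in config$factor_views) {
        res <- tryCatch(
          run_factor_view(cohort, dz, trait, view, config),
          error = function(e) e)
        if (inherits(res, "error")) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            cell = paste0(trait, "_factor_", view), stage = "factor",
            reason = conditionMessage(res))
        } else {
          estimates[[length(estimates) + 1L]] <- res$estimates
          if (!is.null(res$twin_components)) {
            twin_comp[[length(twin_comp) + 1L]] <- res$twin_components
            twin_models[[length(twin_models) + 1L]] <- res$twin_summary
          }
        }
      }
    }
  }

  rb <- function(lst) if (length(lst)) do.call(rbind, lst) else NULL
  structure(list(
    estimates = rb(estimates),
    twin_components = rb(twin_comp),
    twin_models = rb(twin_models),
    skipped = rb(skipped),
    cohort = cohort,
    config = config,
    meta = list(seed = config$seed, cell_seeds = as.list(cell_seeds),
                B = config$B, conf = config$conf,
                n_persons = nrow(cohort),
                n_dz_pairs = sum(cohort$zygosity == "DZ") / 2,
                n_mz_pairs = sum(cohort$zygosity == "MZ") / 2)
  ), class = "study_report")
}

cell_estimates <- function(cell, tags, dec) {
  rows <- lapply(c("population", "within", "between", "indirect", "r2_pgs"),
                 function(nm) {
    b <- dec$boot[[nm]]
    data.frame(cell = cell, trait = tags$trait, age = tags$age,
               reporter = tags$reporter,
               estimate = c(population = "population", within = "direct",
                            between = "between", indirect = "indirect",
                            r2_pgs = "r2_pgs")[[nm]],
               value = b$point, se = b$se, lower = b$lower, upper = b$upper,
               n_persons = dec$within_between$n_persons,
               n_families = dec$within_between$n_families,
               significant = sig_excludes_zero(b$lower, b$upper))
  })
  do.call(rbind, rows)
}

run_twin_cell <- function(cohort, cell, config, seed = NULL) {
  td <- make_twin_dataset(cohort, cell)
  rc <- twin_correlations(td)
  model <- choose_model(rc$r[rc$zygosity == "MZ"], rc$r[rc$zygosity == "DZ"])
  tags <- parse_phenotype_column(cell)
  sib <- if (identical(config$sibling_interaction, "auto")) {
    !is.null(tags) && identical(tags$trait, "adhd") && identical(tags$reporter, "parent")
  } else isTRUE(config$sibling_interaction)
  fit <- fit_twin_model(td, model, sibling_interaction = sib,
                        ci_method = "delta", seed = config$seed)
  comp <- fit$ci
  if (is.null(comp)) {
    vals <- twin_std_map(fit$par, fit$layout)
    comp <- data.frame(component = names(vals), estimate = unname(vals),
                       se = NA_real_, lower = NA_real_, upper = NA_real_,
                       method = "none")
  }
  list(
    components = comp,
    summary = data.frame(
      cell = cell, model = model, sibling_interaction = sib,
      r_mz = rc$r[rc$zygosity == "MZ"], r_dz = rc$r[rc$zygosity == "DZ"],
      loglik = fit$loglik, n_pairs = fit$n_pairs,
      n_complete_pairs = fit$n_complete_pairs),
    fit = fit)
}

run_factor_view <- function(cohort, dz, trait, view, config) {
  seed <- derive_seed(config$seed, 7000L)
  scores <- build_factor_views(cohort, trait, view, seed = seed)
  score_sets <- if (inherits(scores, "factor_scores")) {
    stats::setNames(list(scores), "common")
  } else scores
  est <- list(); tw_comp <- NULL; tw_sum <- NULL
  for (nm in names(score_sets)) {
    col <- paste0("fscore_", trait, "_", view, if (nm != "common") paste0("_", nm))
    cohort[[col]] <- score_sets[[nm]]$score
    dz2 <- dz
    dz2[[col]] <- score_sets[[nm]]$score[match(dz$person_id, cohort$person_id)]
    dec <- decompose(dz2, col, covariates = NULL, B = config$B,
                     seed = derive_seed(config$seed, 7100L), conf = config$conf)
    tags <- list(trait = trait, age = NA, reporter = if (view == "by_reporter") nm else NA)
    if (view == "by_age") tags$age <- as.numeric(nm)
    est[[length(est) + 1L]] <- cell_estimates(col, tags, dec)
    if (view == "common") {
      tw <- tryCatch(run_twin_cell(cohort, col, config), error = function(e) NULL)
      if (!is.null(tw)) {
        tw_comp <- cbind(cell = col, tw$components)
        tw_sum <- tw$summary
      }
    }
  }
  list(estimates = do.call(rbind, est), twin_components = tw_comp,
       twin_summary = tw_sum)
}

#' Conditional covariate-controlled reruns
#'
#' For every cell whose indirect-effect interval excludes zero, reruns the
#' decomposition with each control variable appended to the covariate set,
#' reporting whether the controlled indirect interval includes zero and the
#' percentage attenuation of the direct estimate (relative to the uncontrolled
#' fit). A no-op when no cell shows an indirect effect.
#'
#' @param report a `study_report` from [run_study()].
#' @return the report with a `controls` table appended.
#' @export
conditional_controls <- function(report) {
  stopifnot(inherits(report, "study_report"))
  config <- report$config
  est <- report$estimates
  sig_cells <- unique(est$cell[est$estimate == "indirect" & est$significant])
  sig_cells <- Filter(function(cl) !is.null(parse_phenotype_column(cl)) ||
                        grepl("^fscore_", cl), sig_cells)
  rows <- list()
  cohort <- report$cohort
  dz <- cohort[cohort$zygosity == "DZ", , drop = FALSE]
  if ("parenting_factor" %in% config$controls &&
      !"parenting_factor" %in% names(dz) &&
      any(grepl("^parenting_age", names(dz)))) {
    sc <- parenting_factor(dz, seed = derive_seed(config$seed, 7500L))
    dz$parenting_factor <- sc$score
  }
  for (cell in sig_cells) {
    covariates <- if (grepl("^fscore_", cell)) NULL else config$covariates
    for (ctrl in config$controls) {
      res <- tryCatch(
        control_for(dz, cell, ctrl, covariates = covariates,
                    B = config$B, seed = derive_seed(config$seed, 8000L)),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell = cell, control = ctrl, skipped = TRUE,
          reason = conditionMessage(res),
          indirect_uncontrolled = NA_real_, indirect_controlled = NA_real_,
          controlled_lower = NA_real_, controlled_upper = NA_real_,
          controlled_includes_zero = NA, attenuation_direct_pct = NA_real_)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          cell = cell, control = ctrl, skipped = FALSE, reason = "",
          indirect_uncontrolled = res$uncontrolled$boot$indirect$point,
          indirect_controlled = res$controlled$boot$indirect$point,
          controlled_lower = res$controlled$boot$indirect$lower,
          controlled_upper = res$controlled$boot$indirect$upper,
          controlled_includes_zero = !res$controlled_indirect_significant,
          attenuation_direct_pct = res$attenuation_direct_pct)
      }
    }
  }
  report$controls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = character(0), control = character(0))
  report
}

#' Agreement between twin-model C and polygenic indirect effects
#'
#' Tabulates, over the cells where both analyses ran, the 2x2 agreement
#' between "shared environment (C) significant in the twin model" and
#' "indirect genetic effect significant in the polygenic-score model". Cells
#' fitted as ADE (no C) or with only one analysis available are counted
#' separately, not in the table.
#'
#' @param report a `study_report`.
#' @return the report with a `consistency` list appended: the 2x2 `table`,
#'   `n_excluded`, and the per-cell flags.
#' @export
consistency_check <- function(report) {
  stopifnot(inherits(report, "study_report"))
  est <- report$estimates
  ind <- est[est$estimate == "indirect", c("cell", "significant")]
  tc <- report$twin_components
  flags <- list(); excluded <- 0L
  for (cell in unique(ind$cell)) {
    crow <- if (is.null(tc)) tc[0] else
      tc[tc$cell == cell & tc$component == "c2", , drop = FALSE]
    if (is.null(tc) || nrow(crow) == 0 || !is.finite(crow$lower[1])) {
      excluded <- excluded + 1L
      next
    }
    flags[[length(flags) + 1L]] <- data.frame(
      cell = cell,
      sig_indirect = ind$significant[ind$cell == cell][1],
      sig_c = sig_excludes_zero(crow$lower[1], crow$upper[1]))
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(cell = character(0), sig_indirect = logical(0), sig_c = logical(0))
  tab <- table(factor(flags$sig_c, levels = c(FALSE, TRUE)),
               factor(flags$sig_indirect, levels = c(FALSE, TRUE)),
               dnn = c("sig_C_twin", "sig_indirect_pgs"))
  report$consistency <- list(table = tab, n_excluded = excluded, flags = flags)
  report
}

#' Write a study report to disk
#'
#' Emits `estimates.tsv`, `twin_components.tsv`, `twin_models.tsv`,
#' `controls.tsv` (when present), `consistency.tsv` (when present),
#' `skipped.tsv` (when present) and `report.json` (run metadata: seeds, B,
#' sample sizes). Output is deterministic for a fixed config and seed, so two
#' identical runs produce byte-identical files.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$estimates)) wt(report$estimates, "estimates.tsv")
  if (!is.null(report$twin_components)) wt(report$twin_components, "twin_components.tsv")
  if (!is.null(report$twin_models)) wt(report$twin_models, "twin_models.tsv")
  if (!is.null(report$controls)) wt(report$controls, "controls.tsv")
  if (!is.null(report$consistency)) {
    wt(as.data.frame(report$consistency$table), "consistency.tsv")
  }
  if (!is.null(report$skipped)) wt(report$skipped, "skipped.tsv")
  jsonlite::write_json(report$meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  n_cells <- length(unique(x$estimates$cell %||% character(0)))
  cat(sprintf("<study_report: %d cells, %d estimate rows, %d twin-component rows>\n",
              n_cells, nrow(x$estimates %||% data.frame()),
              nrow(x$twin_components %||% data.frame())))
  if (!is.null(x$skipped)) {
    cat(sprintf("  %d skipped stage(s)\n", nrow(x$skipped)))
  }
  invisible(x)
}
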