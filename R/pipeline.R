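## End-to-end orchestration: load or simulate the flora, run every
## analysis stage, write one CSV per result table plus a machine-readable
## run report.  Identical config + seed gives identical outputs.

#' Pipeline run configuration
#'
#' Either `paths` (named list/vector with `tree`, `species`, `plots`,
#' `grid`) or a `simulate` block (a [sim_config()]) must be supplied.
#'
#' @param paths named list of input file paths, or `NULL` to simulate.
#' @param simulate a [sim_config()] when simulating.
#' @param stages character vector of stages to run (subset of
#'   `"relatedness"`, `"signal"`, `"spatial"`, `"models"`).
#' @param n_randomizations randomizations for the D statistic (>= 100
#'   for reported p-values).
#' @param max_model_size cap on variables per candidate model.
#' @param seed root seed.
#' @param out_dir output directory (`NULL` for no file output).
#' @return list of class `phynat_runconfig`.
#' @export
run_config <- function(paths = NULL, simulate = sim_config(),
                       stages = c("relatedness", "signal", "spatial",
                                  "models"),
                       n_randomizations = 10000, max_model_size = 5,
                       seed = 1, out_dir = NULL) {
  if (is.null(paths) && is.null(simulate)) {
    stop("either input paths or a simulate block is required")
  }
  if (n_randomizations < 100) {
    stop("n_randomizations must be >= 100 for reported p-values")
  }
  cfg <- list(paths = paths, simulate = simulate, stages = stages,
              n_randomizations = n_randomizations,
              max_model_size = max_model_size, seed = seed,
              out_dir = out_dir)
  class(cfg) <- "phynat_runconfig"
  cfg
}

#' Validate an input bundle
#'
#' Checks tree/table label agreement (with coverage percentages), status
#' vocabulary, Ellenberg ranges, duplicate occurrence records, and
#' previews the plot filter (fraction of plots with at least one native
#' and one alien).  Hard schema violations raise errors; soft issues are
#' returned as warnings in the report.
#'
#' @param tree a `phylo` object.
#' @param species species table.
#' @param plots optional occurrence table.
#' @param grid optional hectad grid.
#' @return list with `coverage`, `warnings`, `plot_filter` (retained /
#'   total / fraction), `errors` (always empty on return).
#' @export
validate_inputs <- function(tree, species, plots = NULL, grid = NULL) {
  validate_tree(tree)
  if (!all(c("species", "status") %in% names(species))) {
    stop("species table must have 'species' and 'status' columns")
  }
  vocab <- c("native", "non-invasive alien", "invasive alien")
  bad <- which(!species$status %in% vocab)
  if (length(bad)) {
    stop("unknown status token '", species$status[bad[1]], "' in row ",
         bad[1])
  }
  warnings <- character()
  for (v in c("L", "F", "N", "R")) {
    if (v %in% names(species)) {
      x <- species[[v]]
      if (any(!is.na(x) & (x < 1 | x > 9))) {
        warnings <- c(warnings,
                      paste0("Ellenberg ", v, " outside 1-9"))
      }
    }
  }
  if ("S" %in% names(species) &&
      any(!is.na(species$S) & (species$S < 0 | species$S > 9))) {
    warnings <- c(warnings, "Ellenberg S outside 0-9")
  }
  m <- match_species(tree, species)
  if (length(m$unmatched)) {
    warnings <- c(warnings, paste0(length(m$unmatched),
                                   " species not in tree"))
  }
  plot_filter <- NULL
  if (!is.null(plots)) {
    if (anyDuplicated(plots[c("square", "plot", "species")])) {
      warnings <- c(warnings, "duplicate occurrence records")
    }
    status <- setNames(species$status, species$species)
    key <- paste(plots$square, plots$plot, sep = "\r")
    ok <- tapply(status[plots$species], key, function(s) {
      any(s == "native", na.rm = TRUE) && any(s != "native", na.rm = TRUE)
    })
    plot_filter <- list(total = length(ok), retained = sum(ok),
                        fraction = mean(ok))
  }
  if (!is.null(grid)) {
    if (any(grid$richness_invasive < 0 | grid$richness_noninvasive < 0)) {
      stop("negative richness counts in grid")
    }
    if (anyDuplicated(grid[c("x", "y")])) {
      warnings <- c(warnings, "duplicate grid centroids")
    }
  }
  list(coverage = m$coverage, warnings = warnings,
       plot_filter = plot_filter, errors = character())
}

read_flora <- function(paths) {
  list(tree = read_newick(paths[["tree"]]),
       species = utils::read.csv(paths[["species"]],
                                 stringsAsFactors = FALSE),
       plots = if (!is.null(paths[["plots"]]) &&
                     file.exists(paths[["plots"]])) {
         utils::read.csv(paths[["plots"]], stringsAsFactors = FALSE)
       },
       grid = if (!is.null(paths[["grid"]]) &&
                    file.exists(paths[["grid"]])) {
         utils::read.csv(paths[["grid"]], stringsAsFactors = FALSE)
       })
}

#' Run the full naturalization analysis
#'
#' Executes, in order: data load (or simulation) and validation;
#' country- and plot-scale relatedness; group comparisons and nested
#' mixed models; phylogenetic signal of invasiveness per alien group;
#' spatial congruence (Dutilleul-corrected correlation) and loess
#' residual hot spots; the nearest-native design matrix and the
#' model-averaged invasiveness GLM; and the change-index rank-sum check.
#' A stage failure is recorded in the report and its dependent stages
#' are skipped; independent stages still run.
#'
#' @param config a [run_config()] object.
#' @return list of class `phynat_run` with `results` (one element per
#'   output table), `report` (seeds, filter counts, warnings, errors,
#'   timing), and `data` (the input bundle used).
#' @export
run_pipeline <- function(config = run_config()) {
  t0 <- Sys.time()
  report <- list(seed = config$seed, warnings = character(),
                 errors = character(), stages_run = character(),
                 stages_skipped = character())
  results <- list()
  note_warning <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(
      withCallingHandlers(expr, warning = note_warning),
      error = function(e) {
        report$errors <<- c(report$errors,
                            paste0(name, ": ", conditionMessage(e)))
        NULL
      })
    if (is.null(res)) {
      report$stages_skipped <<- c(report$stages_skipped, name)
    } else {
      report$stages_run <<- c(report$stages_run, name)
    }
    res
  }

  data <- run_stage("load", {
    if (!is.null(config$paths)) read_flora(config$paths)
    else simulate_flora(config$simulate)
  })
  if (is.null(data)) {
    return(structure(list(results = results, report = report,
                          data = NULL), class = "phynat_run"))
  }
  report$validation <- run_stage("validate", {
    validate_inputs(data$tree, data$species, data$plots, data$grid)
  })

  if ("relatedness" %in% config$stages) {
    results$country_relatedness <- run_stage("country_relatedness", {
      country_relatedness(data$tree, data$species)
    })
    if (!is.null(data$plots)) {
      results$plot_relatedness <- run_stage("plot_relatedness", {
        plot_relatedness(data$tree, data$species, data$plots)
      })
      if (!is.null(results$plot_relatedness)) {
        report$plot_filter <-
          attr(results$plot_relatedness, "filter_report")
      }
    } else {
      report$stages_skipped <- c(report$stages_skipped,
                                 "plot_relatedness (no plots input)")
    }
  }

  if ("models" %in% config$stages &&
      !is.null(results$country_relatedness)) {
    results$country_groups <- run_stage("country_group_lm", {
      country_group_lm(results$country_relatedness)
    })
    if (!is.null(results$plot_relatedness) &&
        nrow(results$plot_relatedness)) {
      results$lmm <- run_stage("nested_lmm", {
        lapply(setNames(c("pnnd", "mpd"), c("pnnd", "mpd")),
               function(resp) {
                 f <- fit_nested_lmm(results$plot_relatedness, resp)
                 f$fit <- NULL   # keep the report lightweight
                 f
               })
      })
    }
  }

  if ("signal" %in% config$stages) {
    results$d_by_group <- run_stage("d_by_group", {
      d_by_group(data$tree, data$species, n = config$n_randomizations,
                 seed = child_seed(config$seed, "signal"))
    })
  }

  if ("spatial" %in% config$stages && !is.null(data$grid)) {
    clean <- run_stage("drop_empty_cells", drop_empty_cells(data$grid))
    if (!is.null(clean)) {
      report$grid_cells_dropped <- attr(clean, "n_dropped")
      results$spatial_test <- run_stage("dutilleul", {
        d <- dutilleul_test(clean$richness_invasive,
                            clean$richness_noninvasive,
                            clean[, c("x", "y")])
        data.frame(r = d$r, F = d$F, df1 = 1, df2 = d$effective_df,
                   p = d$p, method = d$method, n_cells = d$n)
      })
      results$residuals <- run_stage("residual_hotspots", {
        residual_hotspots(clean)
      })
    }
  }

  if ("models" %in% config$stages &&
      !is.null(results$country_relatedness)) {
    design <- run_stage("trait_contrasts", {
      trait_contrasts(data$species, results$country_relatedness)
    })
    if (!is.null(design)) {
      report$design_rows_excluded <- attr(design, "n_excluded")
      results$model_average <- run_stage("model_average", {
        ma <- invasiveness_model(design,
                                 max_size = config$max_model_size)
        ma$coefficients
      })
    }
    if ("change_index" %in% names(data$species)) {
      results$change_index_test <- run_stage("wilcoxon", {
        ci <- data$species
        w <- wilcoxon_rank_sum(
          ci$change_index[ci$status == "invasive alien"],
          ci$change_index[ci$status == "non-invasive alien"])
        data.frame(W = w$W, p = w$p, n_invasive = w$n1,
                   n_noninvasive = w$n2)
      })
    }
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  run <- structure(list(results = results, report = report, data = data),
                   class = "phynat_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(run$results)) {
    tab <- run$results[[nm]]
    if (is.data.frame(tab)) {
      utils::write.csv(tab, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    } else if (nm == "lmm") {
      for (resp in names(tab)) {
        utils::write.csv(
          cbind(response = resp, tab[[resp]]$means),
          file.path(dir, paste0("lmm_", resp, ".csv")),
          row.names = FALSE)
      }
    }
  }
  rep_lines <- c(
    paste0("seed: ", run$report$seed),
    paste0("stages_run: ", paste(run$report$stages_run, collapse = ", ")),
    paste0("stages_skipped: ",
           paste(run$report$stages_skipped, collapse = ", ")),
    paste0("warnings: ", length(run$report$warnings)),
    paste0("errors: ", length(run$report$errors)),
    run$report$errors)
  writeLines(rep_lines, file.path(dir, "run_report.txt"))
  invisible(dir)
}

#' @export
print.phynat_run <- function(x, ...) {
  cat("phynat pipeline run\n")
  cat("  stages run:    ", paste(x$report$stages_run, collapse = ", "),
      "\n")
  if (length(x$report$stages_skipped)) {
    cat("  stages skipped:", paste(x$report$stages_skipped,
                                   collapse = ", "), "\n")
  }
  cat("  warnings:", length(x$report$warnings),
      " errors:", length(x$report$errors), "\n")
  cat("  tables:", paste(names(x$results), collapse = ", "), "\n")
  invisible(x)
}
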