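#' Read and validate a CSV table
#'
#' RFC-4180 CSV reader with schema validation: checks that required
#' columns are present, coerces them to the declared types with
#' cell-level error locations, and optionally enforces uniqueness of a
#' key column. Missing values are encoded as empty cells.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector mapping required column names to
#'   types (`"character"`, `"numeric"`, or `"integer"`). Columns not in
#'   the schema are kept as read.
#' @param key Optional column name whose values must be unique (e.g.
#'   `"plot_id"`).
#' @return The validated data frame.
#' @export
read_table <- function(path, schema = NULL, key = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                       na.strings = "")
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(d))
    if (length(missing) > 0)
      stop("missing column(s) in ", basename(path), ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    for (col in names(schema)) {
      if (schema[[col]] == "character") {
        d[[col]] <- as.character(d[[col]])
        next
      }
      raw <- d[[col]]
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & is.na(val))
      if (length(bad) > 0)
        stop("non-numeric value ", dQuote(raw[bad[1L]]), " in ",
             basename(path), ", column '", col, "', row ", bad[1L],
             call. = FALSE)
      d[[col]] <- if (schema[[col]] == "integer") as.integer(round(val)) else val
    }
  }
  if (!is.null(key)) {
    if (!key %in% names(d))
      stop("missing key column '", key, "' in ", basename(path),
           call. = FALSE)
    dup <- d[[key]][duplicated(d[[key]])]
    if (length(dup) > 0)
      stop("duplicate ", key, " value(s) in ", basename(path), ": ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  d
}

write_table <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every option of the end-to-end pipeline in one object.
#'
#' @param seed Master seed for the simulation stage.
#' @param out_dir Output directory (created if absent).
#' @param input_dir Optional directory with existing `design.csv`,
#'   `covers.csv`, `traits.csv`, `functions.csv`; when `NULL` the
#'   simulation stage generates them.
#' @param params [sim_params()] used when simulating (defaults to
#'   `sim_params(seed)`).
#' @param threshold_grid Focal thresholds (percent) reported per plot.
#' @param t_range Threshold range for the slope profile.
#' @param slope_regressor `"log_richness"` or `"richness"`.
#' @param detect_threshold Cover detection threshold for realized
#'   richness.
#' @param correction PCoA correction for the functional space.
#' @param anova_responses Response columns analysed by [type3_anova()].
#' @param exclude_monocultures,use_realized_richness,satterthwaite
#'   ANOVA sensitivity switches.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir, input_dir = NULL,
                            params = sim_params(seed),
                            threshold_grid = c(20, 40, 60, 80),
                            t_range = 1:99,
                            slope_regressor = "log_richness",
                            detect_threshold = 0,
                            correction = "cailliez",
                            anova_responses = c("root_biomass", "respiration",
                                                "microbial_biomass", "wsa",
                                                "multifunctionality"),
                            exclude_monocultures = FALSE,
                            use_realized_richness = FALSE,
                            satterthwaite = FALSE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 input_dir = input_dir, params = params,
                 threshold_grid = threshold_grid, t_range = t_range,
                 slope_regressor = slope_regressor,
                 detect_threshold = detect_threshold,
                 correction = correction,
                 anova_responses = anova_responses,
                 exclude_monocultures = exclude_monocultures,
                 use_realized_richness = use_realized_richness,
                 satterthwaite = satterthwaite),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains all stages: simulate (or load) the experiment tables, compute
#' taxonomic diversity, functional diversity, multifunctionality metrics
#' and the threshold-slope profile, fit the per-response split-plot
#' ANOVAs, the correlation structure, and the recursive path model, and
#' write every stage output plus a `run.log` into the output directory.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("soilmultifun %s",
                         as.character(utils::packageVersion("soilmultifun"))),
                 sprintf("seed: %d", config$seed))
  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %s: ok", name))
    res
  }

  sim <- stage("simulate", {
    if (is.null(config$input_dir)) {
      s <- simulate_experiment(config$params)
    } else {
      s <- list(
        design = read_table(file.path(config$input_dir, "design.csv"),
                            c(plot_id = "character", ring = "integer",
                              co2 = "character", n = "character",
                              sown_richness = "integer",
                              sown_species = "character"), key = "plot_id"),
        covers = read_table(file.path(config$input_dir, "covers.csv"),
                            c(plot_id = "character"), key = "plot_id"),
        traits = read_table(file.path(config$input_dir, "traits.csv"),
                            c(species = "character"), key = "species"),
        functions = read_table(file.path(config$input_dir, "functions.csv"),
                               c(plot_id = "character"), key = "plot_id"))
      for (col in setdiff(names(s$covers), "plot_id"))
        s$covers[[col]] <- as.numeric(s$covers[[col]])
      s
    }
  })
  for (nm in names(sim))
    write_table(sim[[nm]], file.path(config$out_dir, paste0(nm, ".csv")))
  log_lines <- c(log_lines, sprintf("design rows: %d", nrow(sim$design)))

  diversity <- stage("metrics",
    community_diversity(sim$covers, config$detect_threshold))
  write_table(diversity, file.path(config$out_dir, "diversity.csv"))

  fd <- stage("fd", community_fd(sim$covers, sim$traits,
                                 correction = config$correction,
                                 detect_threshold = config$detect_threshold))
  write_table(fd, file.path(config$out_dir, "fd.csv"))

  multifun <- stage("multifun", {
    std <- standardize_functions(sim$functions)
    avg <- average_multifunctionality(std)
    fe <- function_evenness(std)
    counts <- lapply(config$threshold_grid, function(t) {
      ct <- threshold_counts(sim$functions, t)
      names(ct)[2L] <- sprintf("count_t%02d", t)
      ct
    })
    Reduce(function(a, b) merge(a, b, by = "plot_id"),
           c(list(avg), counts, list(fe)))
  })
  write_table(multifun, file.path(config$out_dir, "multifun.csv"))

  profile <- stage("threshold_profile",
    threshold_slope_profile(sim$functions, sim$design,
                            t_range = config$t_range,
                            regressor = config$slope_regressor))
  write_table(profile, file.path(config$out_dir, "threshold_profile.csv"))

  analysis <- stage("merge", {
    a <- merge(sim$design, diversity, by = "plot_id")
    a <- merge(a, fd, by = "plot_id")
    a <- merge(a, sim$functions, by = "plot_id")
    a <- merge(a, multifun, by = "plot_id")
    a$log_richness <- log(a$sown_richness)
    a[order(a$plot_id), ]
  })
  write_table(analysis, file.path(config$out_dir, "analysis.csv"))

  anovas <- stage("anova", {
    lapply(stats::setNames(nm = config$anova_responses), function(resp) {
      at <- type3_anova(analysis, resp,
                        richness = if (config$use_realized_richness)
                          "realized" else "sown",
                        exclude_monocultures = config$exclude_monocultures,
                        co2_test = if (config$satterthwaite)
                          "satterthwaite" else "classical")
      write_table(as.data.frame(at),
                  file.path(config$out_dir, paste0("anova_", resp, ".csv")))
      at
    })
  })

  correlations <- stage("correlate",
    pearson_matrix(sim$functions))
  write_table(correlations, file.path(config$out_dir, "correlations.csv"))

  path_fit <- stage("path", fit_path_model(analysis, default_paths()))
  jsonlite::write_json(
    list(paths = path_fit$coefficients,
         chisq = path_fit$chisq, df = path_fit$df,
         p_value = path_fit$p_value, aic = path_fit$aic,
         r_squared = as.list(path_fit$r_squared), n = path_fit$n),
    file.path(config$out_dir, "path_fit.json"),
    auto_unbox = TRUE, digits = NA)

  log_lines <- c(log_lines,
                 sprintf("analysis rows: %d", nrow(analysis)))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(sim = sim, diversity = diversity, fd = fd,
                 multifun = multifun, threshold_profile = profile,
                 analysis = analysis, anova = anovas,
                 correlations = correlations, path_fit = path_fit))
}
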