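#' Parse a model term from its config string
#'
#' Config files declare model terms as strings: `"sex"` (main effect),
#' `"year:age"` (interaction), `"rcs(year, 2)"` (restricted cubic spline).
#'
#' @param s Term string.
#' @return A `model_term`.
#' @export
parse_term <- function(s) {
  s <- gsub(" ", "", s)
  if (grepl("^rcs\\(", s)) {
    inner <- sub("^rcs\\((.*)\\)$", "\\1", s)
    parts <- strsplit(inner, ",")[[1L]]
    term_spline(parts[1L], df = if (length(parts) > 1L) as.integer(parts[2L]) else 2L)
  } else if (grepl(":", s, fixed = TRUE)) {
    term_interaction(strsplit(s, ":", fixed = TRUE)[[1L]])
  } else {
    term_main(s)
  }
}

models_from_config <- function(cfg_models, schema, ridge = 1e-5) {
  models <- default_models(schema, ridge = ridge)
  for (v in names(cfg_models)) {
    spec <- schema[[v]]
    if (is.null(spec)) stop("config model for unknown variable '", v, "'", call. = FALSE)
    fam <- if (spec$vtype == "binary") "binary-logistic" else "polytomous-logistic"
    models[[v]] <- imputation_model(v, lapply(cfg_models[[v]], parse_term),
                                    family = fam, ridge = ridge)
  }
  models
}

#' Run the projection pipeline from a structured config
#'
#' Executes the requested stages in order, persisting every intermediate
#' artifact as delimited text under `out_dir` and writing a run manifest
#' (seed, config digest, file digests, timestamps) last. Stages:
#' `simulate` (synthetic survey + forecast + truth tables), `build-pseudo`
#' (append fully missing future waves), `impute` (chained equations; one
#' file per completed dataset plus traces), `pool` (pooled projections per
#' indicator), `validate` (hold-out comparison when the config names a
#' `holdout_year`).
#'
#' The YAML config may set: `seed`, `m`, `iterations`, `level`, `years`,
#' `size`, `holdout_year`, `waves` (list of year/n_male/n_female), and
#' `models` (per-variable term-string lists, see [parse_term()]).
#'
#' @param config_path Path to a YAML config.
#' @param stages Ordered subset of
#'   `c("simulate", "build-pseudo", "impute", "pool", "validate")`.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides the config seed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config_path,
                         stages = c("simulate", "build-pseudo", "impute", "pool", "validate"),
                         out_dir = ".", seed = NULL) {
  cfg <- yaml::read_yaml(config_path)
  stages <- match.arg(stages, c("simulate", "build-pseudo", "impute", "pool", "validate"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  m <- as.integer(cfg$m %||% 50L)
  iterations <- as.integer(cfg$iterations %||% 10L)
  level <- as.numeric(cfg$level %||% 0.95)
  years <- as.numeric(unlist(cfg$years %||% list()))
  size <- as.integer(cfg$size %||% 10000L)
  schema <- finrisk_schema()
  pth <- function(f) file.path(out_dir, f)

  gen_cfg <- if (!is.null(cfg$waves)) {
    generator_config(waves = do.call(rbind, lapply(cfg$waves, as.data.frame)))
  } else finrisk_like_config()

  for (stage in stages) {
    switch(stage,
      "simulate" = {
        pop <- generate_population(gen_cfg, seed = seed)
        tab <- impose_missingness(pop$table, gen_cfg, seed = seed + 1L)
        write_survey(tab, pth("survey.csv"))
        utils::write.csv(pop$truth, pth("truth.csv"), row.names = FALSE)
        if (length(years)) write_forecast(make_forecast(gen_cfg, years), pth("forecast.csv"))
      },
      "build-pseudo" = {
        if (!file.exists(pth("survey.csv"))) {
          stop("stage 'build-pseudo': missing input survey.csv; run 'simulate' first",
               call. = FALSE)
        }
        tab <- read_survey(pth("survey.csv"), schema)
        fc <- read_forecast(pth("forecast.csv"))
        pseudo <- lapply(years, build_pseudo_sample, size = size, forecast = fc,
                         schema = schema)
        write_survey(append_future(tab, pseudo), pth("combined.csv"))
      },
      "impute" = {
        if (!file.exists(pth("combined.csv"))) {
          stop("stage 'impute': missing input combined.csv; run 'build-pseudo' first",
               call. = FALSE)
        }
        comb <- read_survey(pth("combined.csv"), schema)
        models <- models_from_config(cfg$models %||% list(), schema)
        stack <- fcs_impute(comb, models, m = m, iterations = iterations, seed = seed + 2L)
        for (i in seq_len(m)) {
          write_survey(complete_data(stack, i), pth(sprintf("imputed_%03d.csv", i)))
        }
        utils::write.csv(stack$traces, pth("traces.csv"), row.names = FALSE)
      },
      "pool" = {
        files <- list.files(out_dir, "^imputed_\\d+\\.csv$", full.names = TRUE)
        if (length(files) < 2L) {
          stop("stage 'pool': no imputed datasets found; run 'impute' first", call. = FALSE)
        }
        datasets <- lapply(files, read_survey, schema = schema)
        indicators <- schema_names(schema)[vapply(schema, function(v)
          v$role == "outcome-indicator", logical(1))]
        fake <- list(datasets = datasets, m = length(datasets))
        class(fake) <- "imputed_stack"
        proj <- do.call(rbind, lapply(indicators, function(ind) {
          cbind(indicator = ind, project_prevalences(fake, ind, level = level))
        }))
        utils::write.csv(proj, pth("projections.csv"), row.names = FALSE)
      },
      "validate" = {
        if (is.null(cfg$holdout_year)) {
          stop("stage 'validate': config has no holdout_year", call. = FALSE)
        }
        tab <- read_survey(pth("survey.csv"), schema)
        rep <- holdout_validation(tab, as.numeric(cfg$holdout_year),
                                  models = models_from_config(cfg$models %||% list(), schema),
                                  m = m, iterations = iterations, seed = seed + 3L,
                                  level = level)
        utils::write.csv(rep, pth("validation.csv"), row.names = FALSE)
      })
  }
  outputs <- list.files(out_dir, "\\.csv$", full.names = TRUE)
  manifest <- list(config = normalizePath(config_path),
                   config_md5 = unname(tools::md5sum(config_path)),
                   seed = seed, stages = stages,
                   outputs = as.list(tools::md5sum(outputs)),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
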