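#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline with their defaults:
#' synthetic-population size and years, spline knots and centring, fold
#' count for knot selection, life-table separation factors and open age,
#' random-intercept prediction mode, and display scale. Any subset can be
#' overridden via `...` or loaded from a YAML file with [read_config()].
#'
#' @param ... Named overrides of the defaults.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    simulate = TRUE,
    counts_file = NULL,          # used when simulate = FALSE
    n_areas = 300,
    n_provinces = 10,
    mean_pop = 1311,
    years = 2011:2013,
    seed = 1,
    frailty_sd = 0.12,
    gap = list(male = 3.8, female = 3.2),
    knots = c(2, 12, 22, 32, 42, 52, 67, 82),
    center_age = 60,
    open_band_age = 90,
    folds = 5,
    a0 = 0.1,
    ax = 0.5,
    open_age = 100,
    re_mode = "zero",
    scale = 1000,
    sexes = c("male", "female")
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' @rdname default_config
#' @param path YAML file of overrides.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(default_config, over)
}

#' Run the full life-table pipeline
#'
#' Chains every stage: simulate (or ingest) abridged counts, descriptive
#' rates and SMRs, the Poisson mixed-effects fit per sex, quintile and
#' per-area life tables, population-weighted province life expectancy, and
#' rank-based LE quintile maps. Writes all products as CSV under `outdir`
#' plus a JSON run log (seeds, knots, convergence, package version). Any
#' stage failure aborts with the stage name and removes partial outputs.
#'
#' Outputs under `outdir`: `counts.csv`, `rates_table.csv`,
#' `lifetable_<quintile>_<sex>.csv` (10 files), `area_le.csv`,
#' `province_le.csv`, `le_quintile_map.csv`, `summary.csv`, `run_log.json`.
#' In synthetic mode `summary.csv` pairs each sex's estimated Q1-Q5
#' life-expectancy gap with the generator's ground-truth gap from
#' [true_life_expectancy()].
#'
#' @param config List from [default_config()] or [read_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the fitted models, life tables, LE tables
#'   and the summary data frame.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    path <- file.path(outdir, name)
    utils::write.csv(x, path, row.names = FALSE, na = "")
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    hazards <- NULL
    if (isTRUE(config$simulate)) {
      stage <- "simulate"
      hazards <- list(
        male = default_hazard("male", gap = config$gap$male,
                              frailty_sd = config$frailty_sd),
        female = default_hazard("female", gap = config$gap$female,
                                frailty_sd = config$frailty_sd))
      tracts <- generate_tracts(config$n_areas, config$n_provinces,
                                config$mean_pop, config$years, config$seed)
      counts <- simulate_counts(tracts, hazards, seed = config$seed + 1)
    } else {
      stage <- "ingest"
      if (is.null(config$counts_file)) stop("counts_file is required")
      counts <- read_counts(config$counts_file)
    }
    emit(counts, "counts.csv")

    stage <- "rates"
    rt <- stratum_rates(counts, by = c("sex", "year", "quintile"),
                        scale = config$scale)
    rt$smr <- NA_real_; rt$smr_low <- NA_real_; rt$smr_high <- NA_real_
    for (i in seq_len(nrow(rt))) {
      sel <- counts$sex == rt$sex[i] & counts$year == rt$year[i]
      ref <- counts[sel & counts$quintile == "Q1", ]
      idx <- counts[sel & counts$quintile == rt$quintile[i], ]
      s <- smr_indirect(idx, ref, reference_label = "Q1")
      rt$smr[i] <- s$smr; rt$smr_low[i] <- s$ci_low; rt$smr_high[i] <- s$ci_high
    }
    emit(rt, "rates_table.csv")

    stage <- "fit"
    models <- lapply(stats::setNames(config$sexes, config$sexes),
      function(sx) {
        d <- build_design(counts[counts$sex == sx, ],
                          spline_spec(config$knots, config$center_age),
                          config$open_band_age)
        fit_poisson_mixed(d)
      })

    stage <- "lifetables"
    le_all <- NULL
    area_le <- NULL
    for (sx in config$sexes) {
      qlt <- quintile_lifetables(models[[sx]], sex = sx,
                                 open_age = config$open_age,
                                 re_mode = config$re_mode,
                                 a0 = config$a0, ax = config$ax)
      for (q in names(qlt$tables))
        emit(as.data.frame(qlt$tables[[q]])[, c("age", "m", "q", "l", "d",
                                                "L", "T", "e")],
             sprintf("lifetable_%s_%s.csv", q, sx))
      le_all <- rbind(le_all, qlt$le)
      area_le <- rbind(area_le,
                       area_lifetables(models[[sx]], sex = sx,
                                       open_age = config$open_age,
                                       a0 = config$a0, ax = config$ax))
    }
    emit(area_le, "area_le.csv")

    stage <- "aggregate"
    w <- stats::aggregate(list(weight = counts$population),
                          counts[, c("area_id", "province_id")], sum)
    prov <- province_le(area_le, w)
    emit(prov, "province_le.csv")
    qmap <- do.call(rbind, lapply(config$sexes, function(sx) {
      do.call(rbind, lapply(unique(area_le$at_age), function(a) {
        v <- area_le[area_le$sex == sx & area_le$at_age == a,
                     c("area_id", "le")]
        names(v)[1] <- "unit_id"
        b <- le_quintile_bins(v)
        b$sex <- sx; b$at_age <- a
        b
      }))
    }))
    emit(qmap, "le_quintile_map.csv")

    stage <- "summary"
    summary_df <- do.call(rbind, lapply(config$sexes, function(sx) {
      le <- le_all[le_all$sex == sx & le_all$at_age == 0, ]
      est_gap <- le$le[le$stratum == "Q1"] - le$le[le$stratum == "Q5"]
      truth <- if (!is.null(hazards))
        true_life_expectancy(hazards[[sx]], "Q1") -
          true_life_expectancy(hazards[[sx]], "Q5") else NA_real_
      data.frame(sex = sx, le_birth_q1 = le$le[le$stratum == "Q1"],
                 le_birth_q5 = le$le[le$stratum == "Q5"],
                 gap_q1_q5 = est_gap, gap_truth = truth,
                 sigma_u = models[[sx]]$sigma_u,
                 stringsAsFactors = FALSE)
    }))
    emit(summary_df, "summary.csv")

    log <- list(
      package_version = as.character(utils::packageVersion("deplife")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config = config[setdiff(names(config), "counts_file")],
      convergence = lapply(models, function(m)
        m$convergence[c("converged", "inner_iterations",
                        "outer_evaluations", "message")]),
      sigma_u = lapply(models, function(m) m$sigma_u)
    )
    log_path <- file.path(outdir, "run_log.json")
    jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, log_path)
    list(models = models, le = le_all, area_le = area_le, province_le = prov,
         le_quintiles = qmap, summary = summary_df, outdir = outdir)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' National mortality counts by deprivation quintile, Spain 2011-2013
#'
#' Aggregate national death counts and population (person-years) by sex,
#' calendar year and deprivation quintile of the census tract of residence,
#' Spain, 2011-2013. These published aggregates drive the worked examples of
#' crude-rate computation; they carry no age detail, so age-standardization
#' requires the tract-level inputs.
#'
#' @return Data frame: `sex`, `year`, `quintile`, `deaths`, `population`.
#' @export
national_quintile_counts <- function() {
  utils::read.csv(system.file("extdata",
                              "spain_quintile_counts_2011_2013.csv",
                              package = "deplife"),
                  stringsAsFactors = FALSE)
}
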