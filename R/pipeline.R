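# Pipeline configuration ---------------------------------------------------

#' Pipeline configuration
#'
#' Collects every tunable constant of the full analysis in one object:
#' input paths (or `NULL` to simulate), window geometry, distance grid and
#' envelope settings, age-class bounds, per-class detrending methods,
#' screening thresholds, response-function settings and the master seed.
#' All stage seeds are derived deterministically from the master seed, so
#' changing the simulation count of one stage does not perturb another.
#'
#' @param stem_map,rwl,climate Input file paths, or `NULL` to simulate the
#'   corresponding data from the default scenarios.
#' @param out_dir Output directory for the report bundle.
#' @param window_radius Plot radius (m).
#' @param d_max,step,n_sims,level Distance grid and Monte Carlo envelope
#'   settings for the spatial stage.
#' @param age_breaks Upper age bounds of classes Y and M (O is older).
#' @param detrend_by_class Named character: detrending method per class.
#' @param master_r Cross-dating screen threshold (discard below).
#' @param min_rings Strict ring-count threshold of the biometric screen.
#' @param n_boot,period,temperature Response-function settings;
#'   `temperature = "both"` runs the P-Tmax and P-Tmin designs.
#' @param seed Master seed.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(stem_map = NULL, rwl = NULL, climate = NULL,
                            out_dir = tempfile("dendrostand_run_"),
                            window_radius = 40,
                            d_max = 40, step = 1, n_sims = 99, level = 0.95,
                            age_breaks = c(Y = 40, M = 80),
                            detrend_by_class = c(Y = "rcs", M = "negexp",
                                                 O = "spline"),
                            master_r = 0.40, min_rings = 20,
                            n_boot = 1000, period = c(1958, 1997),
                            temperature = "both",
                            seed = 1L) {
  stopifnot(window_radius > 0, d_max > 0, step > 0, n_sims >= 19,
            level > 0, level < 1, master_r > 0, min_rings > 0,
            n_boot >= 1, length(period) == 2, period[1] <= period[2])
  stopifnot(temperature %in% c("tmax", "tmin", "both"))
  structure(list(stem_map = stem_map, rwl = rwl, climate = climate,
                 out_dir = out_dir, window_radius = window_radius,
                 d_max = d_max, step = step, n_sims = n_sims, level = level,
                 age_breaks = age_breaks,
                 detrend_by_class = detrend_by_class,
                 master_r = master_r, min_rings = min_rings,
                 n_boot = n_boot, period = as.integer(period),
                 temperature = temperature, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' The on-disk representation round-trips: reading a written config gives
#' an identical object.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config`: a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  # named vectors must become maps, not sequences, to keep their names
  x$age_breaks <- as.list(x$age_breaks)
  x$detrend_by_class <- as.list(x$detrend_by_class)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  # yaml collapses named vectors to lists; restore
  x$age_breaks <- unlist(x$age_breaks)
  x$detrend_by_class <- unlist(x$detrend_by_class)
  do.call(pipeline_config, x)
}

# Deterministic per-stage substreams from the master seed.
stage_seed <- function(seed, stage) {
  offs <- c(simulate_map = 101L, simulate_rings = 202L,
            simulate_climate = 303L, spatial = 404L, bivariate = 505L,
            response = 606L, age_pairs = 707L)
  (seed * 1009L + offs[[stage]]) %% 2147483647L
}

#' Run the full stand analysis pipeline
#'
#' Orchestrates simulate (when no input files are configured), spatial
#' statistics, chronology building and response functions, writing a
#' report bundle of plain CSV tables to `config$out_dir`:
#' `age_structure.csv`, per-class `spatial_<class>.csv` and pairwise
#' `bivariate_<c1>_<c2>.csv`, `biometric_summary.csv` (Table-1 style, with
#' CV), `chronology_summary.csv` (Table-2 style), `discarded_cores.csv`
#' and `schema.yml` describing every column. The run is deterministic
#' under the configured master seed.
#'
#' @param config A [pipeline_config()].
#' @return The report bundle, invisibly: a list with `pattern`, `spatial`,
#'   `bivariate`, `screen`, `chronologies`, `responses`, `tables`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message("[dendrostand] ", sprintf(...))

  ## ---- inputs ----
  stage <- "input"
  res <- tryCatch({
    if (is.null(config$climate)) {
      climate <- generate_climate(climate_scenario(
        seed = stage_seed(config$seed, "simulate_climate")))
    } else climate <- read_climate(config$climate)

    if (is.null(config$rwl)) {
      rsc <- ring_scenario(seed = stage_seed(config$seed, "simulate_rings"))
      series <- generate_ring_series(rsc, climate)
      true_ages <- attr(series, "tree_ages")
    } else {
      series <- read_rwl(config$rwl)
      true_ages <- NULL
    }

    if (is.null(config$stem_map)) {
      # stem map consistent with the ring cohort: one point per cored tree,
      # plus an established-regeneration cohort
      tree_ids <- unique(vapply(series, `[[`, "", "tree"))
      cls <- substr(tree_ids, 1, 1)
      ncls <- table(factor(cls, levels = c("Y", "M", "O")))
      ssc <- spatial_scenario(
        window_radius = config$window_radius,
        n_per_class = c(Y = unname(ncls["Y"]), M = unname(ncls["M"]),
                        O = unname(ncls["O"]), ER = 50),
        process_per_class = list(
          Y = thomas_process(n_parents = 7, cluster_sd = 4),
          ER = thomas_process(n_parents = 5, cluster_sd = 3)),
        seed = stage_seed(config$seed, "simulate_map"))
      pattern <- generate_point_pattern(ssc)
      trees <- generate_tree_records(
        true_ages, seed = stage_seed(config$seed, "simulate_map"))
      trees$cw_m2 <- crown_area(trees$cr_n_m, trees$cr_e_m,
                                trees$cr_s_m, trees$cr_w_m)
    } else {
      sm <- read_stem_map(config$stem_map, config$window_radius)
      pattern <- sm$pattern
      trees <- sm$trees
    }
    list(climate = climate, series = series, pattern = pattern,
         trees = trees, true_ages = true_ages)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  climate <- res$climate; series <- res$series
  pattern <- res$pattern; trees <- res$trees

  ## ---- spatial statistics ----
  stage <- "spatial"
  spatial_res <- tryCatch({
    classes <- unique(pattern$marks)
    out <- list()
    for (cl in c("all", classes)) {
      p <- if (cl == "all") {
        adult <- pattern$marks != "ER"
        point_pattern(pattern$x[adult], pattern$y[adult], pattern$window)
      } else subset_pattern(pattern, cl)
      if (p$n <= 1) next
      out[[cl]] <- csr_envelope(p, n_sims = config$n_sims,
                                level = config$level,
                                d_max = config$d_max, step = config$step,
                                seed = stage_seed(config$seed, "spatial"))
      utils::write.csv(as.data.frame(out[[cl]]),
                       file.path(config$out_dir,
                                 sprintf("spatial_%s.csv", cl)),
                       row.names = FALSE)
    }
    out
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))

  stage <- "bivariate"
  bivar_res <- tryCatch({
    pairs <- list(c("Y", "M"), c("Y", "O"), c("M", "O"))
    out <- list()
    for (pr in pairs) {
      if (!all(pr %in% pattern$marks)) next
      key <- paste(pr, collapse = "_")
      out[[key]] <- bivariate_null_envelope(
        pattern, pr[1], pr[2], n_sims = config$n_sims,
        level = config$level, d_max = config$d_max, step = config$step,
        seed = stage_seed(config$seed, "bivariate"))
      utils::write.csv(as.data.frame(out[[key]]),
                       file.path(config$out_dir,
                                 sprintf("bivariate_%s.csv", key)),
                       row.names = FALSE)
    }
    # regeneration vs all adults
    if ("ER" %in% pattern$marks) {
      recoded <- point_pattern(pattern$x, pattern$y, pattern$window,
                               marks = ifelse(pattern$marks == "ER",
                                              "ER", "adult"))
      out[["ER_adult"]] <- bivariate_null_envelope(
        recoded, "ER", "adult", n_sims = config$n_sims,
        level = config$level, d_max = config$d_max, step = config$step,
        seed = stage_seed(config$seed, "bivariate"))
      utils::write.csv(as.data.frame(out[["ER_adult"]]),
                       file.path(config$out_dir, "bivariate_ER_adult.csv"),
                       row.names = FALSE)
    }
    out
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))

  ## ---- chronologies ----
  stage <- "chronology"
  chron_res <- tryCatch({
    screen <- crossdating_screen(series, threshold = config$master_r)
    kept <- series[screen$keep]
    utils::write.csv(
      within(screen[!screen$keep, ],
             reason <- ifelse(undatable, "undatable",
                              sprintf("r=%.2f < %.2f", r, config$master_r))),
      file.path(config$out_dir, "discarded_cores.csv"), row.names = FALSE)

    by_tree <- merge_cores(kept)
    # corrected tree age: measured rings + pith offset + years to coring
    # height from the ground-vs-DBH regression
    rings <- vapply(by_tree, function(s) length(s$widths) +
                      s$pith_offset_rings, numeric(1))
    pairs <- with_seed(stage_seed(config$seed, "age_pairs"), {
      idx <- sample(seq_along(rings), max(3L, length(rings) %/% 2))
      data.frame(age = rings[idx],
                 diff = pmax(0, round(16 - 0.1 * rings[idx] +
                                        stats::rnorm(length(idx), 0, 1))))
    })
    am <- fit_age_correction(pairs$age, pairs$diff)
    corrected_age <- rings + predict(am, rings)
    # chronological classes follow the age at coring height (ring count at
    # DBH incl. pith offset); the coring-height correction enters only the
    # stand age structure
    cls <- assign_age_class(rings)

    age_tab <- age_structure(corrected_age, bin_width = 5)
    utils::write.csv(age_tab, file.path(config$out_dir, "age_structure.csv"),
                     row.names = FALSE)

    # biometric summary (Table-1 style) and screen
    bio <- NULL; keep_ids <- names(by_tree)
    if (!is.null(trees) && all(c("dbh_cm", "h_m", "cw_m2") %in% names(trees))) {
      # restrict to trees that survived the cross-dating screen
      trees <- trees[trees$id %in% names(by_tree), , drop = FALSE]
      tcls <- assign_age_class(rings[match(trees$id, names(by_tree))])
      summ <- do.call(rbind, lapply(c("Y", "M", "O"), function(cl) {
        tt <- trees[which(tcls == cl), ]
        if (!nrow(tt)) return(NULL)
        data.frame(age_class = cl, n = nrow(tt),
                   dbh_mean = mean(tt$dbh_cm), dbh_sd = stats::sd(tt$dbh_cm),
                   dbh_cv = coefficient_of_variation(tt$dbh_cm),
                   h_mean = mean(tt$h_m), h_sd = stats::sd(tt$h_m),
                   h_cv = coefficient_of_variation(tt$h_m),
                   cw_mean = mean(tt$cw_m2), cw_sd = stats::sd(tt$cw_m2),
                   cw_cv = coefficient_of_variation(tt$cw_m2))
      }))
      utils::write.csv(summ, file.path(config$out_dir,
                                       "biometric_summary.csv"),
                       row.names = FALSE)
      bio <- biometric_screen(
        data.frame(id = trees$id,
                   age = rings[match(trees$id, names(by_tree))],
                   dbh_cm = trees$dbh_cm, h_m = trees$h_m,
                   cw_m2 = trees$cw_m2),
        ring_counts = stats::setNames(
          vapply(by_tree, function(s) length(s$widths), numeric(1)),
          names(by_tree)),
        min_rings = config$min_rings)
      keep_ids <- bio$id[bio$keep]
    }

    chrons <- list()
    for (cl in c("Y", "M", "O")) {
      ids <- names(by_tree)[cls == cl & names(by_tree) %in% keep_ids]
      if (length(ids) < 2) next
      ss <- by_tree[ids]
      idxs <- switch(config$detrend_by_class[[cl]],
        rcs = { rc <- rcs_curve(ss); lapply(ss, detrend, method = "rcs",
                                            rc = rc) },
        lapply(ss, detrend, method = config$detrend_by_class[[cl]]))
      chrons[[cl]] <- build_chronology(idxs, raw = ss, label = cl)
    }
    list(screen = screen, by_tree = by_tree, corrected_age = corrected_age,
         class = cls, chronologies = chrons, biometric = bio)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))

  ## ---- response functions ----
  stage <- "response"
  resp_res <- tryCatch({
    designs <- if (config$temperature == "both") c("tmax", "tmin") else
      config$temperature
    out <- list()
    for (cl in names(chron_res$chronologies)) {
      ch <- chron_res$chronologies[[cl]]
      per <- c(max(config$period[1], min(ch$years)),
               min(config$period[2], max(ch$years)))
      for (tv in designs) {
        X <- build_regressor_matrix(climate, per[1], per[2],
                                    temperature = tv)
        y <- stats::setNames(ch$index, ch$years)[rownames(X)]
        out[[paste(cl, tv, sep = "_")]] <- bootstrap_response_function(
          y, X, n_boot = config$n_boot,
          seed = stage_seed(config$seed, "response"))
      }
    }
    out
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))

  ## ---- summary table (Table-2 style) ----
  tab2 <- do.call(rbind, lapply(names(chron_res$chronologies), function(cl) {
    ch <- chron_res$chronologies[[cl]]
    s <- ch$stats
    row <- data.frame(age_class = cl, n_trees = ch$n_series,
                      span = sprintf("%d-%d", min(ch$years), max(ch$years)),
                      MRW = round(s$MRW, 3), MSm = round(s$MSm, 3),
                      MSi = round(s$MSi, 3), CC = round(s$CC, 3),
                      CM = round(s$CM, 3), AC1_raw = round(s$AC1_raw, 3),
                      AC1_std = round(s$AC1_std, 3))
    for (tv in c("tmax", "tmin")) {
      rf <- resp_res[[paste(cl, tv, sep = "_")]]
      row[[paste0("RV_", tv)]] <- if (is.null(rf)) NA else round(rf$R_V, 2)
      row[[paste0("rs_", tv)]] <- if (is.null(rf)) NA else
        round(rf$r_over_s, 2)
      row[[paste0("p_", tv)]] <- if (is.null(rf)) NA else rf$p_band
    }
    row
  }))
  utils::write.csv(tab2, file.path(config$out_dir,
                                   "chronology_summary.csv"),
                   row.names = FALSE)

  schema <- list(
    age_structure.csv = "midpoint: age-bin midpoint (yr); count: trees",
    spatial_CLASS.csv = paste("d: distance (m); K: Ripley K (m2); L:",
                              "Besag L (m); env_low/env_high: envelope;",
                              "classification: clustered|random|regular"),
    bivariate_C1_C2.csv = paste("d: distance (m); K: combined K12 (m2);",
                                "L: L12 (m); classification:",
                                "attraction|independent|repulsion"),
    biometric_summary.csv = paste("per class: n; mean/sd/CV(%) of DBH (cm),",
                                  "H (m), CW (m2)"),
    chronology_summary.csv = paste("per class: MRW (mm); MSm/MSi; CC; CM;",
                                   "AC1 raw/std; RV, r/s, p per design"),
    discarded_cores.csv = "cores removed by the cross-dating screen")
  yaml::write_yaml(schema, file.path(config$out_dir, "schema.yml"))

  msg("run complete: %s", config$out_dir)
  invisible(list(pattern = pattern, spatial = spatial_res,
                 bivariate = bivar_res, screen = chron_res$screen,
                 chronologies = chron_res$chronologies,
                 responses = resp_res,
                 tables = list(chronology_summary = tab2),
                 config = config))
}
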