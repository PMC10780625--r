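# Point-process specifications -------------------------------------------

#' Point-process specifications for the stem-map simulator
#'
#' Constructors for the per-class generating processes of
#' [spatial_scenario()]: complete spatial randomness, a Thomas cluster
#' process (Poisson cluster centres with Gaussian offspring dispersal), and
#' a hard-core (minimum inter-tree distance) inhibition process.
#'
#' The Thomas parents are allowed to fall outside the window (offspring are
#' clipped to the window) so that cluster intensity is not depressed near
#' the plot edge, the standard practice for cluster processes on bounded
#' windows. Either a fixed `n_parents` or a `parent_intensity` (parents per
#' m2, realized as a Poisson count on the buffered window) may be given.
#'
#' @param n_parents Fixed number of cluster centres.
#' @param parent_intensity Cluster-centre intensity (m^-2); used when
#'   `n_parents` is `NULL`.
#' @param cluster_sd Gaussian dispersal sd around each centre (m).
#' @param min_distance Hard-core inhibition distance (m).
#' @return A process specification (list with a `type` field) consumed by
#'   [generate_point_pattern()].
#' @name point_processes
NULL

#' @rdname point_processes
#' @export
poisson_process <- function() {
  structure(list(type = "poisson"), class = "pp_process")
}

#' @rdname point_processes
#' @export
thomas_process <- function(n_parents = NULL, parent_intensity = NULL,
                           cluster_sd = 3) {
  if (is.null(n_parents) && is.null(parent_intensity))
    stop("give n_parents or parent_intensity")
  stopifnot(cluster_sd > 0)
  structure(list(type = "thomas", n_parents = n_parents,
                 parent_intensity = parent_intensity,
                 cluster_sd = cluster_sd),
            class = "pp_process")
}

#' @rdname point_processes
#' @export
hardcore_process <- function(min_distance) {
  stopifnot(min_distance > 0)
  structure(list(type = "hardcore", min_distance = min_distance),
            class = "pp_process")
}

#' Stem-map simulation scenario
#'
#' Bundles the window, per-class counts, per-class generating processes and
#' the between-class placement rule for [generate_point_pattern()].
#'
#' @param window_radius Plot radius (m).
#' @param n_per_class Named integer vector of exact per-class counts.
#' @param process_per_class Named list of process specifications (see
#'   [poisson_process()]); classes not listed default to Poisson.
#' @param cross_class_rule `"independent"` (default), or
#'   `list(type = "repulsion", min_distance = )` forcing each class's points
#'   at least `min_distance` m from all previously generated classes, or
#'   `list(type = "attraction")` making all Thomas classes share one parent
#'   set.
#' @param seed Integer seed; fixed seed gives bit-identical patterns.
#' @return An object of class `spatial_scenario`.
#' @export
spatial_scenario <- function(window_radius = 40,
                             n_per_class = c(Y = 56, M = 31, O = 24),
                             process_per_class = list(),
                             cross_class_rule = "independent",
                             seed = NULL) {
  stopifnot(window_radius > 0, all(n_per_class >= 0))
  if (is.null(names(n_per_class)) || any(names(n_per_class) == ""))
    stop("n_per_class must be a named vector")
  if (is.character(cross_class_rule))
    cross_class_rule <- list(type = cross_class_rule)
  stopifnot(cross_class_rule$type %in% c("independent", "repulsion",
                                         "attraction"))
  structure(list(window_radius = window_radius,
                 n_per_class = n_per_class,
                 process_per_class = process_per_class,
                 cross_class_rule = cross_class_rule,
                 seed = seed),
            class = "spatial_scenario")
}

# Draw one point of class `proc`, given fixed obstacles (previous classes,
# for the repulsion rule) and already-accepted points of this class (for
# the hard core). Bounded retries guard against infeasible packings.
draw_class_points <- function(n, proc, window, obstacles, repulse_d,
                              parents = NULL, max_tries = 10000L) {
  x <- numeric(0); y <- numeric(0)
  ok_cross <- function(px, py) {
    is.null(repulse_d) || length(obstacles$x) == 0 ||
      all((obstacles$x - px)^2 + (obstacles$y - py)^2 >= repulse_d^2)
  }
  for (i in seq_len(n)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n, " points: packing infeasible ",
             "(process '", proc$type, "') after ", max_tries, " retries")
      if (proc$type == "thomas") {
        j <- sample.int(nrow(parents), 1L)
        px <- parents[j, 1] + stats::rnorm(1, 0, proc$cluster_sd)
        py <- parents[j, 2] + stats::rnorm(1, 0, proc$cluster_sd)
        if (px^2 + py^2 > window$radius^2) next
      } else {
        u <- runif_disc(1, window)
        px <- u$x; py <- u$y
      }
      if (proc$type == "hardcore" && length(x) &&
          any((x - px)^2 + (y - py)^2 < proc$min_distance^2)) next
      if (!ok_cross(px, py)) next
      break
    }
    x <- c(x, px); y <- c(y, py)
  }
  list(x = x, y = y)
}

draw_parents <- function(proc, window, buffer = 4) {
  R <- window$radius + buffer * proc$cluster_sd
  np <- if (!is.null(proc$n_parents)) proc$n_parents else
    max(1L, stats::rpois(1, proc$parent_intensity * pi * R^2))
  r <- R * sqrt(stats::runif(np)); th <- stats::runif(np, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

#' Simulate a marked stem map
#'
#' Generates the requested number of trees per age class inside the
#' circular window, class by class in the order of `n_per_class`, using the
#' per-class point process and the cross-class rule of the scenario.
#' Per-class counts are matched exactly (rejection sampling); all points
#' lie inside the window.
#'
#' @param scenario A [spatial_scenario()].
#' @return A marked [point_pattern()].
#' @examples
#' sc <- spatial_scenario(n_per_class = c(Y = 20, M = 10), seed = 1)
#' generate_point_pattern(sc)
#' @export
generate_point_pattern <- function(scenario) {
  stopifnot(inherits(scenario, "spatial_scenario"))
  window <- stand_window(scenario$window_radius)
  rule <- scenario$cross_class_rule
  with_seed(scenario$seed, {
    shared_parents <- NULL
    xs <- numeric(0); ys <- numeric(0); ms <- character(0)
    for (cl in names(scenario$n_per_class)) {
      n <- scenario$n_per_class[[cl]]
      if (n == 0) next
      proc <- scenario$process_per_class[[cl]]
      if (is.null(proc)) proc <- poisson_process()
      parents <- NULL
      if (proc$type == "thomas") {
        if (rule$type == "attraction") {
          if (is.null(shared_parents)) shared_parents <- draw_parents(proc, window)
          parents <- shared_parents
        } else parents <- draw_parents(proc, window)
      }
      pts <- draw_class_points(
        n, proc, window,
        obstacles = list(x = xs, y = ys),
        repulse_d = if (rule$type == "repulsion") rule$min_distance else NULL,
        parents = parents)
      xs <- c(xs, pts$x); ys <- c(ys, pts$y); ms <- c(ms, rep(cl, n))
    }
    point_pattern(xs, ys, window, marks = ms)
  })
}

# Climate ------------------------------------------------------------------

# Monthly precipitation means (mm) with a November maximum and July minimum,
# scaled so the annual total is 644.6 mm (coastal Tuscan profile).
med_p_profile <- function() {
  p <- c(60, 55, 50, 45, 35, 20, 8, 15, 45, 80, 95, 75)
  p * 644.6 / sum(p)
}

#' Monthly climate simulation scenario
#'
#' Defines a Mediterranean-seasonality monthly climate: precipitation
#' concentrated in autumn-winter with a November maximum and July minimum
#' (annual total 644.6 mm by default), and warm-summer temperature cycles.
#' Monthly values are independent Gaussian draws around the monthly means
#' (precipitation truncated at zero).
#'
#' @param years Integer vector of calendar years to simulate.
#' @param p_mean,p_sd Length-12 monthly precipitation means and sds (mm),
#'   January first.
#' @param tmax_mean,tmax_sd,tmin_mean,tmin_sd Length-12 monthly temperature
#'   means and sds (deg C).
#' @param seed Integer seed.
#' @return An object of class `climate_scenario`.
#' @export
climate_scenario <- function(years = 1850:1998,
                             p_mean = med_p_profile(),
                             p_sd = 0.5 * p_mean,
                             tmax_mean = c(12, 13, 15.5, 18.5, 23, 27.5,
                                           30.5, 30, 26.5, 21.5, 16, 12.5),
                             tmax_sd = rep(1.5, 12),
                             tmin_mean = c(4, 4.5, 6.5, 9, 12.5, 16,
                                           18.5, 18.5, 15.5, 11.5, 7.5, 5),
                             tmin_sd = rep(1.5, 12),
                             seed = NULL) {
  stopifnot(length(years) >= 1,
            length(p_mean) == 12, length(p_sd) == 12,
            length(tmax_mean) == 12, length(tmin_mean) == 12,
            all(p_mean >= 0), all(p_sd >= 0),
            all(tmax_mean >= tmin_mean))
  structure(list(years = as.integer(years), p_mean = p_mean, p_sd = p_sd,
                 tmax_mean = tmax_mean, tmax_sd = tmax_sd,
                 tmin_mean = tmin_mean, tmin_sd = tmin_sd, seed = seed),
            class = "climate_scenario")
}

#' Simulate a monthly climate table
#'
#' @param scenario A [climate_scenario()].
#' @return A data.frame with columns `year`, `month` (1-12), `p_mm`,
#'   `tmax_c`, `tmin_c`; one row per month of every requested year, no
#'   missing cells, `p_mm >= 0` and `tmax_c >= tmin_c` everywhere.
#' @examples
#' cl <- generate_climate(climate_scenario(years = 1990, seed = 1))
#' nrow(cl) # 12
#' @export
generate_climate <- function(scenario) {
  stopifnot(inherits(scenario, "climate_scenario"))
  ny <- length(scenario$years)
  with_seed(scenario$seed, {
    month <- rep(1:12, times = ny)
    year <- rep(scenario$years, each = 12)
    p <- pmax(0, stats::rnorm(12 * ny, scenario$p_mean[month],
                              scenario$p_sd[month]))
    tmax <- stats::rnorm(12 * ny, scenario$tmax_mean[month],
                         scenario$tmax_sd[month])
    tmin <- stats::rnorm(12 * ny, scenario$tmin_mean[month],
                         scenario$tmin_sd[month])
    # enforce Tmax >= Tmin by redrawing the rare violating months
    bad <- which(tmax < tmin)
    tries <- 0L
    while (length(bad)) {
      tries <- tries + 1L
      if (tries > 1000L) { tmax[bad] <- tmin[bad]; break }
      tmax[bad] <- stats::rnorm(length(bad), scenario$tmax_mean[month[bad]],
                                scenario$tmax_sd[month[bad]])
      tmin[bad] <- stats::rnorm(length(bad), scenario$tmin_mean[month[bad]],
                                scenario$tmin_sd[month[bad]])
      bad <- bad[tmax[bad] < tmin[bad]]
    }
    data.frame(year = year, month = month, p_mm = p,
               tmax_c = tmax, tmin_c = tmin)
  })
}

# Ring-width series --------------------------------------------------------

#' Ring-width simulation scenario
#'
#' Defines a cohort of trees in three age classes whose annual ring widths
#' follow a multiplicative signal model:
#' \deqn{w_t = g(\mathrm{cambial\ age}_t) \times \exp(\beta' z_t + e_t),}
#' where \eqn{g(a) = A e^{-b a} + k} is the class age-trend curve,
#' \eqn{z_t} the 24 standardized monthly climate regressors of the
#' biological year ending in year t, and \eqn{e_t} an AR(1) process with
#' coefficient `phi` and innovation sd `sigma`. Log-normal (multiplicative)
#' noise guarantees positive widths.
#'
#' @param n_per_class Named counts of trees per age class.
#' @param age_range Named list of `c(min, max)` tree ages at coring height
#'   (Y up to 40, M 41-80, O over 80 years).
#' @param age_curve Named list of `c(a, b, k)` age-trend parameters (mm):
#'   juvenile peak `a + k` decaying at rate `b` towards the asymptote `k`.
#' @param beta Named length-24 coefficient vector over the biological-year
#'   regressors (see [build_regressor_matrix()] for the column order), or a
#'   named list of such vectors per class.
#' @param temperature `"tmax"` or `"tmin"`: which temperature enters the
#'   signal regressors.
#' @param phi AR(1) coefficient of the log-scale noise.
#' @param sigma AR(1) innovation sd (log scale).
#' @param coring_year Calendar year of the outermost ring.
#' @param cores_per_tree Number of cores measured per tree (default 2).
#' @param core_sd Extra independent log-scale noise per core, emulating
#'   within-tree circumferential variability.
#' @param p_pith Probability that a core reaches the pith; other cores get
#'   a positive missing-ring offset and correspondingly fewer rings.
#' @param n_shuffled Number of cores whose ring order is randomly permuted
#'   after generation (planted cross-dating defects; their ids are recorded
#'   in the `shuffled_cores` attribute of the result). Shuffles are placed
#'   only in cores with at least `shuffle_min_rings` rings: over a long
#'   overlap a permuted series cannot correlate with the master by chance,
#'   so the planted set is recoverable exactly by the r < 0.40 screen.
#' @param shuffle_min_rings Minimum length of a core eligible for a
#'   planted shuffle (default 70).
#' @param seed Integer seed.
#' @return An object of class `ring_scenario`.
#' @export
ring_scenario <- function(n_per_class = c(Y = 52, M = 28, O = 23),
                          age_range = list(Y = c(21, 40), M = c(41, 74),
                                           O = c(108, 140)),
                          age_curve = list(Y = c(a = 2.2, b = 0.15, k = 0.82),
                                           M = c(a = 2.0, b = 0.05, k = 1.20),
                                           O = c(a = 1.6, b = 0.045, k = 0.85)),
                          beta = default_ring_beta(),
                          temperature = c("tmax", "tmin"),
                          phi = 0.5, sigma = 0.20,
                          coring_year = 1997,
                          cores_per_tree = 2,
                          core_sd = 0.08,
                          p_pith = 0.13,
                          n_shuffled = 0,
                          shuffle_min_rings = 70,
                          seed = NULL) {
  temperature <- match.arg(temperature)
  stopifnot(all(n_per_class >= 0), phi > -1, phi < 1, sigma >= 0,
            cores_per_tree >= 1, p_pith >= 0, p_pith <= 1, n_shuffled >= 0)
  for (cl in names(n_per_class))
    if (is.null(age_range[[cl]]) || is.null(age_curve[[cl]]))
      stop("age_range/age_curve missing for class ", cl)
  if (!is.list(beta)) beta <- stats::setNames(
    rep(list(beta), length(n_per_class)), names(n_per_class))
  for (b in beta) stopifnot(length(b) == 24)
  structure(list(n_per_class = n_per_class, age_range = age_range,
                 age_curve = age_curve, beta = beta,
                 temperature = temperature,
                 phi = phi, sigma = sigma, coring_year = coring_year,
                 cores_per_tree = cores_per_tree, core_sd = core_sd,
                 p_pith = p_pith, n_shuffled = n_shuffled,
                 shuffle_min_rings = shuffle_min_rings, seed = seed),
            class = "ring_scenario")
}

#' Default climate signal of the ring simulator
#'
#' Positive sensitivity to previous-October and previous-November
#' precipitation and to January maximum (or minimum) temperature: the
#' autumn-recharge / winter-warmth signal typical of Mediterranean pines
#' with access to a deep water table. Coefficients are on the standardized
#' regressor scale (log ring-width units per regressor sd).
#'
#' @return Named length-24 numeric vector.
#' @export
default_ring_beta <- function() {
  b <- stats::setNames(numeric(24), regressor_names("tmax"))
  b["p_oct_prev"] <- 0.16
  b["p_nov_prev"] <- 0.12
  b["p_mar"] <- 0.08
  b["t_jan"] <- 0.05
  b
}

age_curve_eval <- function(par, cambial_age) {
  par[["a"]] * exp(-par[["b"]] * cambial_age) + par[["k"]]
}

#' Simulate ring-width series for a cohort of trees
#'
#' Applies the signal model of [ring_scenario()] tree by tree. Each tree
#' draws an age uniformly from its class range; its series spans the
#' `coring_year - age + 1 + pith_offset` to `coring_year` calendar years
#' (cores that miss the pith lose their innermost `pith_offset_rings`
#' rings). All cores of a tree share the tree-level climate and AR(1)
#' signal and differ by independent per-core noise.
#'
#' @param scenario A [ring_scenario()].
#' @param climate Monthly climate table covering every calendar year of
#'   every generated series plus the preceding October-December (an error
#'   names the missing years otherwise).
#' @return A list of [ring_series()] objects with attributes
#'   `tree_ages` (named true ages at coring height) and `shuffled_cores`
#'   (core ids with planted dating defects).
#' @export
generate_ring_series <- function(scenario, climate) {
  stopifnot(inherits(scenario, "ring_scenario"))
  validate_climate(climate)
  with_seed(scenario$seed, {
    used <- names(scenario$n_per_class)[scenario$n_per_class > 0]
    oldest <- max(vapply(scenario$age_range[used], max, numeric(1)))
    need <- (scenario$coring_year - oldest):scenario$coring_year
    have <- sort(unique(climate$year))
    miss <- setdiff(c(min(need) - 1L, need), have)
    if (length(miss))
      stop("climate does not cover required years: ",
           paste(range(miss), collapse = "-"))
    Z <- scale(build_regressor_matrix(climate, min(need), scenario$coring_year,
                                      temperature = scenario$temperature))
    zyears <- as.integer(rownames(Z))
    series <- list(); ages <- integer(0)
    for (cl in names(scenario$n_per_class)) {
      ncl <- scenario$n_per_class[[cl]]
      if (ncl == 0) next
      rng <- scenario$age_range[[cl]]
      bcl <- scenario$beta[[cl]]
      for (i in seq_len(ncl)) {
        tid <- sprintf("%s%03d", cl, i)
        age <- if (rng[1] == rng[2]) rng[1] else
          sample(seq(rng[1], rng[2]), 1L)
        yrs <- (scenario$coring_year - age + 1L):scenario$coring_year
        sig <- as.numeric(Z[match(yrs, zyears), , drop = FALSE] %*% bcl)
        eps <- as.numeric(stats::filter(
          stats::rnorm(age, 0, scenario$sigma), scenario$phi,
          method = "recursive"))
        g <- age_curve_eval(scenario$age_curve[[cl]], seq_len(age))
        w_tree <- g * exp(sig + eps)
        for (cc in seq_len(scenario$cores_per_tree)) {
          pith <- stats::runif(1) < scenario$p_pith
          off <- if (pith) 0L else 1L + stats::rpois(1, 3)
          off <- min(off, max(0L, age - 15L))  # keep >= 15 measured rings
          w <- w_tree * exp(stats::rnorm(age, 0, scenario$core_sd))
          w <- w[(off + 1L):age]
          series[[length(series) + 1L]] <- ring_series(
            tree = tid, core = sprintf("%s%s", tid, LETTERS[cc]),
            first_year = yrs[off + 1L],
            widths = round(w, 2),
            pith_reached = pith, pith_offset_rings = off)
        }
        ages[tid] <- age
      }
    }
    shuffled <- character(0)
    if (scenario$n_shuffled > 0) {
      long_enough <- which(vapply(series, function(s)
        length(s$widths), numeric(1)) >= scenario$shuffle_min_rings)
      if (length(long_enough) < scenario$n_shuffled)
        stop("not enough cores of >= ", scenario$shuffle_min_rings,
             " rings to plant ", scenario$n_shuffled, " shuffles")
      pick <- sample(long_enough, scenario$n_shuffled)
      for (j in pick) {
        s <- series[[j]]
        s$widths <- s$widths[sample.int(length(s$widths))]
        series[[j]] <- s
        shuffled <- c(shuffled, s$core)
      }
    }
    attr(series, "tree_ages") <- ages
    attr(series, "shuffled_cores") <- shuffled
    series
  })
}

#' Simulate biometric records for a cohort of trees
#'
#' Generates DBH, height and crown radii from tree age through saturating
#' allometries with log-normal scatter, used for Table-1-style biometric
#' summaries and for exercising the biometric screen. A planted subset of
#' `stunted_ids` has all three parameters multiplied by `stunt_factor`,
#' placing those trees well below the mean-minus-sd screening threshold of
#' their 10-year age group.
#'
#' @param ages Named integer vector of tree ages (names are tree ids).
#' @param stunted_ids Tree ids to stunt (default none); see
#'   [plant_stunted_ids()] for an allocation that guarantees the planted
#'   trees fall below the screening threshold of every age group.
#' @param stunt_factor Multiplier applied to stunted trees' biometrics.
#' @param cv Log-scale sd of the healthy trees' biometric scatter.
#' @param seed Integer seed.
#' @return A data.frame with columns `id`, `age`, `dbh_cm`, `h_m`,
#'   `cr_n_m`, `cr_e_m`, `cr_s_m`, `cr_w_m` and attribute `stunted_ids`.
#' @export
generate_tree_records <- function(ages, stunted_ids = character(0),
                                  stunt_factor = 0.1, cv = 0.12,
                                  seed = NULL) {
  stopifnot(!is.null(names(ages)), all(ages > 0))
  with_seed(seed, {
    n <- length(ages)
    dbh <- 55 * (1 - exp(-0.012 * ages)) * exp(stats::rnorm(n, 0, cv))
    h   <- 18 * (1 - exp(-0.015 * ages)) * exp(stats::rnorm(n, 0, cv))
    cr  <-  5 * (1 - exp(-0.014 * ages)) * exp(stats::rnorm(n, 0, cv))
    stunt <- names(ages) %in% stunted_ids
    fac <- ifelse(stunt, stunt_factor, 1)
    radii <- sapply(1:4, function(i) cr * exp(stats::rnorm(n, 0, 0.08)))
    out <- data.frame(id = names(ages), age = as.integer(ages),
                      dbh_cm = round(dbh * fac, 1),
                      h_m = round(h * fac, 1),
                      cr_n_m = round(radii[, 1] * fac, 2),
                      cr_e_m = round(radii[, 2] * fac, 2),
                      cr_s_m = round(radii[, 3] * fac, 2),
                      cr_w_m = round(radii[, 4] * fac, 2),
                      stringsAsFactors = FALSE)
    attr(out, "stunted_ids") <- names(ages)[stunt]
    out
  })
}

#' Choose trees to stunt, stratified over age groups
#'
#' Allocates a planted set of stunted trees across the 10-year age groups
#' used by [biometric_screen()], capping the contamination of any group at
#' `frac_cap`. Keeping every group mostly healthy guarantees that its
#' mean-minus-sd threshold stays far above the stunted trees' biometrics,
#' so the planted set is below threshold by construction and the screen
#' can be checked for exact recovery.
#'
#' @param ages Named tree ages (names are ids).
#' @param n Number of trees to stunt.
#' @param frac_cap Maximum fraction of any 10-year group (default 1/3).
#' @param bin_width Age-group width (default 10, matching the screen).
#' @param seed Integer seed.
#' @return Character vector of `n` tree ids.
#' @export
plant_stunted_ids <- function(ages, n = 33, frac_cap = 0.4,
                              bin_width = 10, seed = NULL) {
  stopifnot(!is.null(names(ages)), n <= length(ages))
  with_seed(seed, {
    bins <- split(names(ages), ceiling(ages / bin_width))
    quota <- lapply(bins, function(ids)
      sample(ids, floor(length(ids) * frac_cap)))
    pool <- unlist(quota, use.names = FALSE)
    if (length(pool) < n)
      stop("cannot plant ", n, " stunted trees at frac_cap ", frac_cap)
    sample(pool, n)
  })
}
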