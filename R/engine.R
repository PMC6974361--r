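# Ensemble engine: seeded realizations, trajectories and summary metrics.

#' Simulation configuration
#'
#' Bundles everything one run needs: the genetic system, drive and
#' life-history parameters, the landscape (number of patches and
#' migration), the release schedule, the horizon and the ensemble size.
#' The inheritance cube, the density calibration and the equilibrium
#' initial state are pre-solved when the configuration is built.
#'
#' @param system `"split"`, `"linked"` or `"refractory"` (or a
#'   `drive_system`).
#' @param drive a [drive_params()] object.
#' @param life a [life_history_params()] object (per-patch equilibrium
#'   `N_eq`).
#' @param n_patches number of patches (default 2).
#' @param migration_rate_per_gen per-mosquito per-generation migration
#'   rate between each patch pair (default 0.01); converted to a daily
#'   probability over the life-history generation time.
#' @param migration optional explicit daily migration matrix, overriding
#'   `migration_rate_per_gen`.
#' @param releases a [release_schedule()] (or `NULL` for none).
#' @param horizon_days simulated days (default 1825 = 5 years).
#' @param n_realizations default ensemble size.
#' @param seed base RNG seed; realization `r` runs on `seed + r - 1`, and
#'   patch `p` within a realization on its own stream derived from that.
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(life = life_history_params(N_eq = 1000),
#'                   horizon_days = 100, n_realizations = 5, seed = 1)
#' @export
sim_config <- function(system = "split", drive = drive_params(),
                       life = life_history_params(), n_patches = 2,
                       migration_rate_per_gen = 0.01, migration = NULL,
                       releases = weekly_releases(), horizon_days = 1825,
                       n_realizations = 100, seed = 1) {
  sys <- as_drive_system(system)
  stopifnot(horizon_days >= 1, n_realizations >= 1, n_patches >= 1)
  if (is.null(migration)) {
    daily <- if (n_patches > 1) {
      per_generation_to_daily_migration(migration_rate_per_gen,
                                        life$gen_time)
    } else 0
    migration <- migration_matrix(n_patches, daily)
  }
  validate_migration(migration)
  if (!is.null(releases) && nrow(releases) > 0) {
    genotype_index(sys, unique(releases$genotype))  # errors early
    if (any(releases$patch > n_patches)) {
      stop("release schedule targets a patch outside the landscape",
           call. = FALSE)
    }
  }
  cube <- build_cube(drive, sys)
  structure(list(system = sys, drive = drive, life = life,
                 n_patches = n_patches, migration = migration,
                 releases = releases, horizon_days = horizon_days,
                 n_realizations = n_realizations, seed = seed,
                 cube = cube),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$system$system, "system,", x$n_patches,
      "patch(es), horizon", x$horizon_days, "d,",
      x$n_realizations, "realizations, seed", x$seed, "\n")
  if (!is.null(x$releases) && nrow(x$releases)) {
    cat("  releases:", nrow(x$releases), "events, days",
        min(x$releases$day), "-", max(x$releases$day), "\n")
  }
  invisible(x)
}

# offset between per-patch RNG streams (kept < 2^31 for small base seeds)
PATCH_SEED_STRIDE <- 1000003L

#' Run one seeded realization
#'
#' Day-by-day application of the daily step to every patch, followed by
#' adult migration and scheduled releases (released males enter the
#' mating pool from the next day). Each patch runs on its own RNG stream
#' (`seed + 1000003*(patch-1)`), so a fully isolated landscape evolves
#' each patch identically to independent single-patch runs. The run is
#' bit-reproducible from `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for this realization (default the config
#'   seed).
#' @param stochastic `FALSE` runs the deterministic expected-value
#'   recursion instead of sampling.
#' @return an object of class `sim_trajectory`: list with `males` and
#'   `females_own` (day x patch x genotype adult count arrays), the day
#'   the last release happened (`last_release_day`, `NA` if none) and the
#'   config's system.
#' @export
run_realization <- function(config, seed = config$seed,
                            stochastic = TRUE) {
  sys <- config$system
  n_g <- sys$n_genotypes
  np <- config$n_patches
  horizon <- config$horizon_days
  ctx <- make_step_context(config$cube, config$life, config$drive)
  init <- equilibrium_state(config$life, sys, validate = FALSE)
  states <- rep(list(init), np)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  streams <- vector("list", np)
  for (p in seq_len(np)) {
    set.seed(as.integer(seed + PATCH_SEED_STRIDE * (p - 1)))
    streams[[p]] <- get(".Random.seed", envir = globalenv())
  }

  males <- array(0, dim = c(horizon, np, n_g),
                 dimnames = list(NULL, NULL, sys$labels))
  fem_own <- males
  migrate <- np > 1 &&
    any(config$migration[row(config$migration) != col(config$migration)] > 0)

  for (day in seq_len(horizon)) {
    for (p in seq_len(np)) {
      assign(".Random.seed", streams[[p]], globalenv())
      states[[p]] <- daily_step_ctx(states[[p]], ctx, stochastic)
      streams[[p]] <- get(".Random.seed", envir = globalenv())
    }
    if (migrate) {
      # migration draws come from patch 1's stream (single draw site)
      assign(".Random.seed", streams[[1L]], globalenv())
      states <- apply_migration(states, config$migration, stochastic)
      streams[[1L]] <- get(".Random.seed", envir = globalenv())
    }
    states <- apply_releases(states, config$releases, day, sys)
    for (p in seq_len(np)) {
      males[day, p, ] <- states[[p]]$males
      fem_own[day, p, ] <- females_by_own(states[[p]])
    }
  }

  lr <- if (!is.null(config$releases) && nrow(config$releases))
    max(config$releases$day) else NA_integer_
  structure(list(males = males, females_own = fem_own,
                 system = sys, last_release_day = lr, seed = seed),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  d <- dim(x$males)
  cat("<sim_trajectory>", d[1], "days x", d[2], "patch(es),",
      x$system$system, "system\n")
  invisible(x)
}

#' Fraction of adult females carrying an allele
#'
#' Fraction of adult females in a patch on a day with at least one copy
#' of `allele` (default the system's cargo allele). Returns `NaN` when
#' the patch holds no females that day.
#'
#' @param trajectory a `sim_trajectory`.
#' @param day,patch indices.
#' @param allele allele symbol (default cargo: `G`/`H`/`R`).
#' @return a fraction in `[0, 1]`, or `NaN`.
#' @export
carrier_fraction <- function(trajectory, day, patch,
                             allele = trajectory$system$cargo) {
  sys <- trajectory$system
  has <- sys$allele_counts[, allele] > 0
  f <- trajectory$females_own[day, patch, ]
  tot <- sum(f)
  if (tot == 0) return(NaN)
  sum(f[has]) / tot
}

# allele frequency among all adults (males + females, own genotype) for
# one day/patch slice of a trajectory
adult_allele_frequency <- function(trajectory, day, patch, allele) {
  sys <- trajectory$system
  ad <- trajectory$males[day, patch, ] + trajectory$females_own[day, patch, ]
  tot <- sum(ad)
  if (tot == 0) return(NaN)
  sum(ad * sys$allele_counts[, allele]) / (2 * tot)
}

#' Run a seeded ensemble
#'
#' Runs `n_realizations` independent realizations (realization `r` on
#' seed `config$seed + r - 1`) and collects per-day, per-patch summary
#' trajectories: total adult females, cargo-carrier fraction among adult
#' females, and the frequency of every allele among all adults.
#'
#' @param config a [sim_config()].
#' @param n_realizations number of realizations (default from config).
#' @param stochastic `FALSE` gives the deterministic trajectory (a
#'   single "realization").
#' @return an object of class `ensemble_summary`: list with arrays
#'   `fem_total`, `carrier_frac` (day x patch x realization),
#'   `allele_freq` (day x patch x allele x realization) and their
#'   realization means `mean_fem_total`, `mean_carrier`,
#'   `mean_allele_freq`.
#' @export
run_ensemble <- function(config, n_realizations = config$n_realizations,
                         stochastic = TRUE) {
  sys <- config$system
  np <- config$n_patches
  horizon <- config$horizon_days
  if (!stochastic) n_realizations <- 1L
  alleles <- sys$alleles
  carrier <- sys$carrier
  ac <- sys$allele_counts

  fem_total <- array(NA_real_, c(horizon, np, n_realizations))
  carrier_frac <- fem_total
  allele_freq <- array(NA_real_, c(horizon, np, length(alleles),
                                   n_realizations),
                       dimnames = list(NULL, NULL, alleles, NULL))

  for (r in seq_len(n_realizations)) {
    traj <- run_realization(config, seed = config$seed + r - 1L,
                            stochastic = stochastic)
    for (p in seq_len(np)) {
      f <- traj$females_own[, p, , drop = TRUE]
      m <- traj$males[, p, , drop = TRUE]
      ftot <- rowSums(f)
      fem_total[, p, r] <- ftot
      carrier_frac[, p, r] <- ifelse(ftot > 0,
                                     rowSums(f[, carrier, drop = FALSE]) /
                                       ftot, NaN)
      ad <- f + m
      atot <- rowSums(ad)
      allele_freq[, p, , r] <- (ad %*% ac) / (2 * atot)
    }
  }

  structure(list(
    system = sys, config = config, n_realizations = n_realizations,
    stochastic = stochastic,
    fem_total = fem_total, carrier_frac = carrier_frac,
    allele_freq = allele_freq,
    mean_fem_total = apply(fem_total, c(1, 2), mean),
    mean_carrier = apply(carrier_frac, c(1, 2), mean, na.rm = TRUE),
    mean_allele_freq = apply(allele_freq, c(1, 2, 3), mean, na.rm = TRUE),
    last_release_day = if (!is.null(config$releases) &&
                           nrow(config$releases))
      max(config$releases$day) else NA_integer_
  ), class = "ensemble_summary")
}

#' @rdname run_ensemble
#' @export
run_deterministic <- function(config) {
  run_ensemble(config, n_realizations = 1L, stochastic = FALSE)
}

#' @export
print.ensemble_summary <- function(x, ...) {
  d <- dim(x$fem_total)
  cat("<ensemble_summary>", d[1], "days x", d[2], "patch(es) x", d[3],
      if (x$stochastic) "stochastic realizations" else
        "deterministic trajectory", "\n")
  peak <- apply(x$mean_carrier, 2, max, na.rm = TRUE)
  cat("  peak mean cargo-carrier fraction (females):",
      paste(sprintf("patch %d: %.3f", seq_along(peak), peak),
            collapse = ", "), "\n")
  invisible(x)
}

#' Window of protection
#'
#' Number of days a carrier-fraction trajectory spends strictly above a
#' threshold. Both the longest contiguous supra-threshold run (the
#' headline figure) and the total number of supra-threshold days are
#' reported; they differ when the trajectory dips below the threshold
#' and recovers.
#'
#' @param x an `ensemble_summary` (the mean female cargo-carrier
#'   trajectory of `patch` is used) or a numeric trajectory.
#' @param patch patch index (when `x` is an ensemble).
#' @param threshold carrier-fraction threshold (default 0.80).
#' @param per_realization with an ensemble, also return the per-
#'   realization longest runs.
#' @return list with `longest`, `total` (days), and optionally
#'   `per_realization`.
#' @examples
#' window_of_protection(c(0.5, rep(0.9, 10), 0.5))$longest  # 10
#' @export
window_of_protection <- function(x, patch = 1, threshold = 0.80,
                                 per_realization = FALSE) {
  per_rlz <- NULL
  if (inherits(x, "ensemble_summary")) {
    if (per_realization) {
      per_rlz <- apply(x$carrier_frac[, patch, , drop = FALSE], 3,
                       function(v) longest_run_above(v, threshold))
    }
    x <- x$mean_carrier[, patch]
  }
  out <- list(longest = longest_run_above(x, threshold),
              total = sum(x > threshold, na.rm = TRUE))
  if (per_realization) out$per_realization <- per_rlz
  out
}

longest_run_above <- function(v, threshold) {
  above <- !is.na(v) & v > threshold
  if (!any(above)) return(0L)
  r <- rle(above)
  max(r$lengths[r$values])
}

#' Highest threshold sustained for a minimum duration
#'
#' The largest carrier-fraction level that a trajectory stays at or above
#' for more than `min_days` contiguous days (0 if even the trajectory
#' minimum run is shorter).
#'
#' @param x an `ensemble_summary` or numeric trajectory.
#' @param patch patch index.
#' @param min_days required contiguous duration (days).
#' @return the sustained level (fraction).
#' @export
sustained_threshold <- function(x, patch = 1, min_days = 1095) {
  if (inherits(x, "ensemble_summary")) x <- x$mean_carrier[, patch]
  n <- length(x)
  L <- min_days + 1L      # "more than min_days" contiguous days
  if (n < L) return(0)
  x[is.na(x)] <- -Inf
  wins <- vapply(seq_len(n - L + 1L),
                 function(i) min(x[i:(i + L - 1L)]), numeric(1))
  max(0, max(wins))
}

#' Window-of-protection heatmap experiment
#'
#' Re-runs the configured release scenario over a grid of homozygote
#' lifespan fitness costs (x) and numbers of weekly releases (y) and
#' records the window of protection (longest run of the mean release-
#' patch female carrier fraction above `threshold`) for each cell.
#'
#' @param config a [sim_config()] used as template; its release schedule
#'   is replaced by `weekly_releases(start_day, n, size, patch, genotype)`
#'   per grid row.
#' @param fitness_cost_grid homozygote lifespan-cost values.
#' @param release_count_grid numbers of weekly releases.
#' @param n_realizations realizations per cell (default 20; 1 with
#'   `stochastic = FALSE`).
#' @param threshold carrier threshold (default 0.80).
#' @param release_size,release_patch,release_genotype,start_day release
#'   scheme of each cell (defaults taken from the template schedule when
#'   possible).
#' @param stochastic sample (default) or deterministic per cell.
#' @return matrix of window-of-protection days (rows = release counts,
#'   columns = fitness costs), with the grids as dimnames.
#' @export
heatmap_experiment <- function(config, fitness_cost_grid,
                               release_count_grid, n_realizations = 20,
                               threshold = 0.80, release_size = 10000,
                               release_patch = 1,
                               release_genotype = NULL, start_day = 50,
                               stochastic = TRUE) {
  stopifnot(length(fitness_cost_grid) >= 1, length(release_count_grid) >= 1)
  if (is.null(release_genotype)) {
    release_genotype <- switch(config$system$system,
                               split = "CC;GG", linked = "HH",
                               refractory = "RR")
  }
  out <- matrix(NA_real_, length(release_count_grid),
                length(fitness_cost_grid),
                dimnames = list(releases = release_count_grid,
                                fitness_cost = fitness_cost_grid))
  for (i in seq_along(release_count_grid)) {
    for (j in seq_along(fitness_cost_grid)) {
      drv <- config$drive
      drv$lifespan_cost_hom <- fitness_cost_grid[j]
      cfg <- sim_config(system = config$system, drive = drv,
                        life = config$life,
                        n_patches = config$n_patches,
                        migration = config$migration,
                        releases = weekly_releases(
                          start_day = start_day,
                          n_releases = release_count_grid[i],
                          size = release_size, patch = release_patch,
                          genotype = release_genotype),
                        horizon_days = config$horizon_days,
                        n_realizations = n_realizations,
                        seed = config$seed)
      ens <- run_ensemble(cfg, n_realizations =
                            if (stochastic) n_realizations else 1L,
                          stochastic = stochastic)
      out[i, j] <- window_of_protection(ens, patch = release_patch,
                                        threshold = threshold)$longest
    }
  }
  out
}

#' Export a deterministic trajectory as CSV
#'
#' Writes the day-by-patch adult genotype counts of a trajectory in long
#' format (day, patch, stage, genotype, count).
#'
#' @param trajectory a `sim_trajectory`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_trajectory <- function(trajectory, path) {
  d <- dim(trajectory$males)
  long <- expand.grid(day = seq_len(d[1]), patch = seq_len(d[2]),
                      genotype = trajectory$system$labels,
                      stringsAsFactors = FALSE)
  long <- rbind(
    cbind(long, stage = "adult_male", count = as.vector(trajectory$males)),
    cbind(long, stage = "adult_female",
          count = as.vector(trajectory$females_own))
  )
  long <- long[long$count != 0, c("day", "patch", "stage", "genotype",
                                  "count")]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
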