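# Metapopulation landscape: patches, adult migration, scheduled releases.

#' Convert a per-generation migration rate to a daily probability
#'
#' Field migration rates are quoted per mosquito per generation; the
#' engine moves adults daily. The daily probability `p` solves
#' `1 - (1 - p)^G = rate` with `G` the generation time in days
#' (`tE + tL + tP + 1/muAd`, rounded, by default 26 d at the standard
#' life-history values).
#'
#' @param rate_per_generation probability of migrating during one
#'   generation, in `[0, 1)`.
#' @param generation_time_days generation time `G` in days.
#' @return daily migration probability.
#' @examples
#' per_generation_to_daily_migration(0.01, 26)  # ~3.87e-4
#' @export
per_generation_to_daily_migration <- function(rate_per_generation,
                                              generation_time_days) {
  stopifnot(rate_per_generation >= 0, rate_per_generation < 1,
            generation_time_days > 0)
  1 - (1 - rate_per_generation)^(1 / generation_time_days)
}

#' Build a migration matrix for a symmetric landscape
#'
#' Row `i`, column `j` holds the daily probability that an adult in patch
#' `i` moves to patch `j`; the diagonal is the stay probability and rows
#' sum to 1.
#'
#' @param n_patches number of patches.
#' @param daily_rate daily probability of moving to each other patch.
#' @return an `n_patches x n_patches` stochastic matrix.
#' @export
migration_matrix <- function(n_patches, daily_rate) {
  stopifnot(n_patches >= 1, daily_rate >= 0,
            daily_rate * (n_patches - 1) < 1)
  m <- matrix(daily_rate, n_patches, n_patches)
  diag(m) <- 1 - daily_rate * (n_patches - 1)
  m
}

validate_migration <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || any(m < 0) || any(m > 1) ||
      any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("migration matrix must be square with entries in [0,1] and rows ",
         "summing to 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Move adults between patches
#'
#' Adult males and adult females (each female carrying her stored mate
#' genotype) move between patches by binomial/multinomial draws at the
#' daily migration probabilities; juveniles do not move; total counts are
#' conserved exactly. With `stochastic = FALSE` expected flows are moved
#' instead.
#'
#' @param patches list of `patch_state` objects.
#' @param migration daily migration probability matrix (rows sum to 1).
#' @param stochastic sample migrant counts (default) or move expectations.
#' @return the list of updated `patch_state` objects.
#' @export
apply_migration <- function(patches, migration, stochastic = TRUE) {
  validate_migration(migration)
  np <- length(patches)
  if (np != nrow(migration)) {
    stop("migration matrix size does not match number of patches",
         call. = FALSE)
  }
  off_diag <- migration[row(migration) != col(migration)]
  if (np == 1L || all(off_diag == 0)) return(patches)  # keeps RNG untouched

  moves_m <- vector("list", np)   # moves_m[[src]][[dst]]
  moves_f <- vector("list", np)
  moves_u <- vector("list", np)
  for (src in seq_len(np)) {
    m_rem <- patches[[src]]$males
    f_rem <- patches[[src]]$females
    u_rem <- patches[[src]]$unmated
    p_rem <- 1
    moves_m[[src]] <- vector("list", np)
    moves_f[[src]] <- vector("list", np)
    moves_u[[src]] <- vector("list", np)
    for (dst in seq_len(np)) {
      if (dst == src) next
      p <- migration[src, dst] / p_rem
      mm <- thin_vec(m_rem, p, stochastic)
      ff <- thin_mat(f_rem, matrix(p, nrow(f_rem), ncol(f_rem)), stochastic)
      uu <- thin_vec(u_rem, p, stochastic)
      moves_m[[src]][[dst]] <- mm
      moves_f[[src]][[dst]] <- ff
      moves_u[[src]][[dst]] <- uu
      m_rem <- m_rem - mm
      f_rem <- f_rem - ff
      u_rem <- u_rem - uu
      p_rem <- p_rem - migration[src, dst]
    }
    patches[[src]]$males <- m_rem
    patches[[src]]$females <- f_rem
    patches[[src]]$unmated <- u_rem
  }
  for (src in seq_len(np)) {
    for (dst in seq_len(np)) {
      if (dst == src) next
      patches[[dst]]$males <- patches[[dst]]$males + moves_m[[src]][[dst]]
      patches[[dst]]$females <- patches[[dst]]$females + moves_f[[src]][[dst]]
      patches[[dst]]$unmated <- patches[[dst]]$unmated + moves_u[[src]][[dst]]
    }
  }
  patches
}

#' Release schedules
#'
#' `release_schedule()` validates a data frame of release events with
#' columns `day` (non-negative), `patch`, `sex` (`"male"` or `"female"`),
#' `genotype` (label in the system's genotype space) and `count`
#' (positive integers). `weekly_releases()` builds the standard scheme
#' used throughout: `n_releases` weekly releases of `size` males of a
#' given genotype into one patch.
#'
#' @param events data frame of release events.
#' @return a `release_schedule` data frame.
#' @examples
#' weekly_releases(n_releases = 10, size = 10000, genotype = "CC;GG")
#' @export
release_schedule <- function(events) {
  need <- c("day", "patch", "sex", "genotype", "count")
  if (!all(need %in% names(events))) {
    stop("release schedule needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(events$count <= 0) || any(events$count != round(events$count))) {
    stop("release counts must be positive integers", call. = FALSE)
  }
  if (any(events$day < 0)) stop("release days must be >= 0", call. = FALSE)
  if (!all(events$sex %in% c("male", "female"))) {
    stop("release sex must be 'male' or 'female'", call. = FALSE)
  }
  events <- events[order(events$day), , drop = FALSE]
  class(events) <- c("release_schedule", "data.frame")
  events
}

#' @rdname release_schedule
#' @param start_day day of the first release (default 50, after burn-in).
#' @param n_releases number of weekly releases.
#' @param size males released per event.
#' @param patch target patch.
#' @param genotype released genotype label (homozygous drive males:
#'   `"CC;GG"` split, `"HH"` linked, `"RR"` refractory).
#' @param sex released sex (default `"male"`).
#' @export
weekly_releases <- function(start_day = 50, n_releases = 10, size = 10000,
                            patch = 1, genotype = "CC;GG", sex = "male") {
  if (n_releases == 0) {
    return(release_schedule(data.frame(day = integer(), patch = integer(),
                                       sex = character(),
                                       genotype = character(),
                                       count = integer())))
  }
  release_schedule(data.frame(
    day = start_day + 7 * (seq_len(n_releases) - 1),
    patch = patch, sex = sex, genotype = genotype, count = size
  ))
}

#' Apply scheduled releases for one day
#'
#' Released males are added to the adult-male pool of the target patch
#' (females to the unmated pool, entering the mating draw the next day);
#' released individuals compete for matings from the next mating draw
#' onward. Other patches, juveniles and existing adults are untouched.
#'
#' @param patches list of `patch_state` objects.
#' @param schedule a [release_schedule()].
#' @param day simulation day.
#' @param system a `drive_system` or system name.
#' @return the list of updated `patch_state` objects.
#' @export
apply_releases <- function(patches, schedule, day, system) {
  if (is.null(schedule) || nrow(schedule) == 0) return(patches)
  sys <- as_drive_system(system)
  todays <- schedule[schedule$day == day, , drop = FALSE]
  for (i in seq_len(nrow(todays))) {
    ev <- todays[i, ]
    g <- genotype_index(sys, ev$genotype)   # errors on unknown genotype
    if (ev$patch < 1 || ev$patch > length(patches)) {
      stop("release targets patch ", ev$patch, " but landscape has ",
           length(patches), " patches", call. = FALSE)
    }
    if (ev$sex == "male") {
      patches[[ev$patch]]$males[g] <- patches[[ev$patch]]$males[g] + ev$count
    } else {
      patches[[ev$patch]]$unmated[g] <-
        patches[[ev$patch]]$unmated[g] + ev$count
    }
  }
  patches
}
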