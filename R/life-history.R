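#' Mosquito life-history parameters
#'
#' Daily-rate parameterisation of the *Aedes aegypti* life cycle used by
#' the simulation engine: egg, larva and pupa stages of fixed duration
#' with a shared density-independent daily juvenile mortality `muJ`,
#' additional density-dependent mortality at the larval stage, and adults
#' with constant daily mortality `muAd`. `muJ` is calibrated so that the
#' generational balance
#' \deqn{(\beta/\mu_{Ad}) (1-\mu_J)^{t_E+t_L+t_P} \cdot \tfrac12 = R_m}
#' holds (lifetime egg output per female, times juvenile survival, times
#' the female fraction, equals the per-generation growth rate `Rm`), and
#' the density-dependence strength `alpha` so that the deterministic
#' wild-type model has a fixed point with `N_eq` adults.
#'
#' The default `Rm` is derived from the framework's standard daily
#' population growth rate of 1.096/day compounded over one generation
#' (`G = tE + tL + tP + 1/muAd`, rounded): `Rm = 1.096^G`, about 10.8 per
#' generation at the defaults.
#'
#' @param beta eggs laid per adult female per day.
#' @param tE,tL,tP egg, larva and pupa stage durations (days, positive
#'   integers).
#' @param muAd daily adult mortality.
#' @param Rm per-generation population growth rate in the absence of
#'   density dependence; default `daily_growth^round(tE+tL+tP+1/muAd)`.
#' @param N_eq equilibrium adult population size of one patch.
#' @param daily_growth daily low-density growth rate used to derive the
#'   default `Rm`.
#' @return An object of class `life_history_params` with the inputs plus
#'   the calibrated `muJ`, the density parameter `alpha`, the generation
#'   time `gen_time` (rounded days) and the equilibrium larval census
#'   `L_eq`.
#' @examples
#' life_history_params()
#' @export
life_history_params <- function(beta = 20, tE = 5L, tL = 6L, tP = 4L,
                                muAd = 0.09, Rm = NULL, N_eq = 10000,
                                daily_growth = 1.096) {
  stopifnot(beta > 0, muAd > 0, muAd < 1, N_eq > 0)
  for (d in c(tE, tL, tP)) {
    if (length(d) != 1L || d < 1 || d != round(d)) {
      stop("stage durations tE, tL, tP must be positive integers",
           call. = FALSE)
    }
  }
  gen_time <- round(tE + tL + tP + 1 / muAd)
  if (is.null(Rm)) Rm <- daily_growth^gen_time
  p <- structure(list(beta = beta, tE = as.integer(tE), tL = as.integer(tL),
                      tP = as.integer(tP), muAd = muAd, Rm = Rm,
                      N_eq = N_eq, gen_time = gen_time,
                      muJ = NA_real_, alpha = NA_real_, L_eq = NA_real_),
                 class = "life_history_params")
  p$muJ <- calibrate_juvenile_mortality(p)
  sol <- solve_density_parameter(p)
  p$alpha <- sol$alpha
  p$L_eq <- sol$L_eq
  p
}

#' @export
print.life_history_params <- function(x, ...) {
  cat("<life_history_params>\n")
  cat(sprintf("  beta=%.3g /female/day  tE=%d tL=%d tP=%d  muAd=%.3g/day\n",
              x$beta, x$tE, x$tL, x$tP, x$muAd))
  cat(sprintf("  Rm=%.4g /generation (gen_time=%d d)  N_eq=%g\n",
              x$Rm, x$gen_time, x$N_eq))
  cat(sprintf("  calibrated muJ=%.6g/day  alpha=%.6g  L_eq=%.6g\n",
              x$muJ, x$alpha, x$L_eq))
  invisible(x)
}

#' Calibrate density-independent juvenile mortality
#'
#' Solves the generational balance
#' `(beta/muAd) * (1 - muJ)^(tE+tL+tP) * 1/2 = Rm` for the shared daily
#' juvenile mortality `muJ`. The equation has the closed-form solution
#' `muJ = 1 - (2 * Rm * muAd / beta)^(1/(tE+tL+tP))`, exact to machine
#' precision (residual well below 1e-10).
#'
#' @param params a `life_history_params` object (or any list with `beta`,
#'   `muAd`, `tE`, `tL`, `tP`, `Rm`).
#' @return `muJ`, the daily juvenile mortality in `[0, 1)`.
#' @export
calibrate_juvenile_mortality <- function(params) {
  T_juv <- params$tE + params$tL + params$tP
  ratio <- 2 * params$Rm * params$muAd / params$beta
  if (!is.finite(ratio) || ratio <= 0 || ratio > 1) {
    stop("no juvenile mortality in [0, 1) satisfies the growth balance: ",
         sprintf("need 2*Rm*muAd/beta <= 1 but got %.4g (Rm=%.4g, muAd=%.4g, beta=%.4g)",
                 ratio, params$Rm, params$muAd, params$beta), call. = FALSE)
  }
  1 - ratio^(1 / T_juv)
}

#' Solve the larval density-dependence parameter
#'
#' Daily density-dependent larval survival takes the form
#' `s(L) = (alpha / (alpha + L))^(1/tL)` where `L` is the total larval
#' census. With `muJ` calibrated, the deterministic wild-type fixed point
#' with `N_eq` adults requires the per-larval-stage density survival
#' `s^tL = 1/Rm`, which yields the closed form
#' `alpha = L_eq / (Rm - 1)` with
#' `L_eq = beta * (N_eq/2) * (1-muJ)^tE * sum_{a=0}^{tL-1} ((1-muJ) s)^a`.
#' The solution is validated by running the deterministic recursion to
#' stationarity (see [equilibrium_state()]).
#'
#' @param params a `life_history_params` object with `muJ` set (called
#'   automatically by [life_history_params()]).
#' @return list with `alpha` and the equilibrium larval census `L_eq`.
#' @export
solve_density_parameter <- function(params) {
  if (params$Rm <= 1) {
    stop("no positive density parameter: Rm must exceed 1 for a ",
         "density-regulated equilibrium (got Rm = ", params$Rm, ")",
         call. = FALSE)
  }
  muJ <- if (is.na(params$muJ)) calibrate_juvenile_mortality(params)
         else params$muJ
  q <- 1 - muJ
  s <- params$Rm^(-1 / params$tL)             # daily density survival at eq.
  F_eq <- params$N_eq / 2
  L_eq <- params$beta * F_eq * q^params$tE * sum((q * s)^(0:(params$tL - 1)))
  list(alpha = L_eq / (params$Rm - 1), L_eq = L_eq)
}

#' Construct an empty patch state
#'
#' Genotype-resolved counts of day-binned juvenile cohorts and adults.
#' Adult females are indexed by (own genotype, mate genotype); females
#' that emerged when no males were present wait in an unmated pool and
#' retry mating daily.
#'
#' @param system a `drive_system` or system name.
#' @param life a `life_history_params` object (stage durations).
#' @return An object of class `patch_state`.
#' @export
patch_state <- function(system, life) {
  sys <- as_drive_system(system)
  n_g <- sys$n_genotypes
  gl <- sys$labels
  structure(list(
    eggs    = matrix(0, life$tE, n_g, dimnames = list(NULL, gl)),
    larvae  = matrix(0, life$tL, n_g, dimnames = list(NULL, gl)),
    pupae   = matrix(0, life$tP, n_g, dimnames = list(NULL, gl)),
    males   = stats::setNames(numeric(n_g), gl),
    females = matrix(0, n_g, n_g, dimnames = list(own = gl, mate = gl)),
    unmated = stats::setNames(numeric(n_g), gl)
  ), class = "patch_state")
}

#' @export
print.patch_state <- function(x, ...) {
  cat("<patch_state>",
      sprintf("eggs=%.0f larvae=%.0f pupae=%.0f males=%.0f females=%.0f (unmated %.0f)\n",
              sum(x$eggs), sum(x$larvae), sum(x$pupae), sum(x$males),
              sum(x$females) + sum(x$unmated), sum(x$unmated)))
  invisible(x)
}

# total adult females by own genotype (mated + unmated)
females_by_own <- function(state) rowSums(state$females) + state$unmated

#' Deterministic equilibrium patch state
#'
#' The stationary age distribution of the deterministic wild-type model,
#' rounded to integer counts, with every individual wild-type and all
#' females mated to wild-type males. The adult count is `N_eq` up to
#' rounding. Validates the density calibration by running the
#' deterministic recursion from this state: the relative drift of the
#' adult census must be below `1e-6` over 50 days.
#'
#' @param params a `life_history_params` object.
#' @param system a `drive_system` or system name.
#' @param genotype label of the genotype to populate (default the
#'   system's all-wild-type genotype).
#' @param validate run the deterministic drift check (default `TRUE`).
#' @return A `patch_state` at equilibrium.
#' @examples
#' eq <- equilibrium_state(life_history_params(N_eq = 1000), "split")
#' sum(eq$males) + sum(eq$females)  # ~1000
#' @export
equilibrium_state <- function(params, system = "split", genotype = NULL,
                              validate = TRUE) {
  sys <- as_drive_system(system)
  if (is.null(genotype)) genotype <- sys$wild_type
  g <- genotype_index(sys, genotype)
  st <- patch_state(sys, params)
  q <- 1 - params$muJ
  s <- params$Rm^(-1 / params$tL)
  F_eq <- params$N_eq / 2
  st$eggs[, g]   <- round(params$beta * F_eq * q^(seq_len(params$tE) - 1))
  in_l <- params$beta * F_eq * q^params$tE
  st$larvae[, g] <- round(in_l * (q * s)^(seq_len(params$tL) - 1))
  in_p <- in_l * (q * s)^params$tL
  st$pupae[, g]  <- round(in_p * q^(seq_len(params$tP) - 1))
  st$males[g] <- round(params$N_eq / 2)
  st$females[g, g] <- round(params$N_eq / 2)

  if (validate) {
    cube <- mendelian_cube(sys$system)
    ctx <- make_step_context(cube, params,
                             drive_params(c_F = 0, c_M = 0,
                                          fec_cost_per_cas9 = 0,
                                          lifespan_cost_hom = 0))
    s2 <- st
    census <- numeric(50)
    for (d in seq_len(50)) {
      s2 <- daily_step_ctx(s2, ctx, stochastic = FALSE)
      census[d] <- sum(s2$males) + sum(s2$females) + sum(s2$unmated)
    }
    drift <- abs(census[50] - census[1]) / census[1]
    if (drift > 1e-6) {
      stop("density calibration failed validation: deterministic adult ",
           "census drifts by ", format(drift), " over 50 days",
           call. = FALSE)
    }
    if (abs(census[50] - params$N_eq) / params$N_eq > 1e-3) {
      stop("density calibration failed validation: deterministic ",
           "equilibrium ", format(census[50]), " != N_eq ", params$N_eq,
           call. = FALSE)
    }
  }
  st
}

# Precompute everything daily_step needs that is constant across days.
make_step_context <- function(cube, life, drive) {
  sys <- cube$system
  n_g <- sys$n_genotypes
  fec <- life$beta * fecundity_multipliers(drive, sys)
  surv_ad <- pmin(pmax(1 - life$muAd * mortality_multipliers(drive, sys),
                       0), 1)
  list(
    sys = sys, cube_flat = cube$flat, n_g = n_g,
    tE = life$tE, tL = life$tL, tP = life$tP,
    qJ = 1 - life$muJ, alpha = life$alpha, inv_tL = 1 / life$tL,
    fec = fec,                      # eggs/day by female own genotype
    surv_ad = surv_ad,              # daily adult survival by genotype
    surv_f_mat = matrix(surv_ad, n_g, n_g)  # by row (own genotype)
  )
}

#' Advance a patch by one day
#'
#' One daily time step, in order: (1) egg laying — each (own, mate) female
#' class lays `Poisson(beta * fecundity_multiplier * count)` eggs with
#' offspring genotypes drawn from the inheritance-cube row (equivalently,
#' independent Poisson draws per offspring genotype at the marginal
#' rates); (2) survival — binomial thinning of every cohort at its stage
#' mortality, larvae additionally by the density-dependent survival
#' `(alpha/(alpha+L))^(1/tL)` evaluated at the pre-thinning larval census,
#' adults at `muAd * mortality_multiplier`; (3) advancement — survivors
#' age one day, final-day eggs become larvae, larvae pupae, and final-day
#' pupae emerge as adults with independent fair-coin sex assignment;
#' (4) mating — each newly emerged (or previously unmated) female draws a
#' mate genotype from the current adult-male genotype frequencies. Newly
#' laid eggs enter the first egg day-bin and receive their first
#' mortality draw the following day.
#'
#' @param state a `patch_state`.
#' @param cube an `inheritance_cube` for the same system.
#' @param life a `life_history_params` object.
#' @param drive a [drive_params()] object (fitness effects).
#' @param stochastic `TRUE` for integer sampling (the default), `FALSE`
#'   for the deterministic expected-value recursion.
#' @return the updated `patch_state`.
#' @export
daily_step <- function(state, cube, life, drive, stochastic = TRUE) {
  ctx <- make_step_context(cube, life, drive)
  daily_step_ctx(state, ctx, stochastic)
}

# internal fast path: context precomputed once per run
daily_step_ctx <- function(state, ctx, stochastic = TRUE) {
  n_g <- ctx$n_g

  # (1) egg laying: Poisson-thinned multinomial == independent Poissons
  lay <- state$females * ctx$fec   # recycles fec down columns = by own genotype
  egg_rate <- if (any(lay > 0)) {
    as.vector(crossprod(ctx$cube_flat, as.vector(lay)))
  } else numeric(n_g)
  new_eggs <- if (stochastic) stats::rpois(n_g, egg_rate) else egg_rate

  # (2)+(3) juvenile survival and advancement, processed oldest-first
  L_census <- sum(state$larvae)
  s_dd <- if (L_census > 0) (ctx$alpha / (ctx$alpha + L_census))^ctx$inv_tL
          else 1
  q_l <- ctx$qJ * s_dd

  emerging <- thin_vec(state$pupae[ctx$tP, ], ctx$qJ, stochastic)
  pupae <- shift_stage(state$pupae, thin_vec(state$larvae[ctx$tL, ], q_l,
                                             stochastic),
                       ctx$qJ, stochastic)
  larvae <- shift_stage(state$larvae, thin_vec(state$eggs[ctx$tE, ], ctx$qJ,
                                               stochastic),
                        q_l, stochastic)
  eggs <- shift_stage(state$eggs, new_eggs, ctx$qJ, stochastic,
                      thin_new = FALSE)

  # adults: thin, then add emergents
  males <- thin_vec(state$males, ctx$surv_ad, stochastic)
  females <- thin_mat(state$females, ctx$surv_f_mat, stochastic)
  unmated <- thin_vec(state$unmated, ctx$surv_ad, stochastic)

  if (stochastic) {
    new_males <- stats::rbinom(n_g, as.integer(emerging), 0.5)
  } else {
    new_males <- emerging / 2
  }
  new_females <- emerging - new_males
  males <- males + new_males

  # (4) mating against current male genotype frequencies
  to_mate <- new_females + unmated
  unmated <- numeric(n_g)
  m_tot <- sum(males)
  if (m_tot > 0 && sum(to_mate) > 0) {
    m_freq <- males / m_tot
    if (stochastic) {
      for (g in which(to_mate > 0)) {
        females[g, ] <- females[g, ] +
          as.vector(stats::rmultinom(1, to_mate[g], m_freq))
      }
    } else {
      females <- females + outer(to_mate, m_freq)
    }
  } else {
    unmated <- to_mate
  }

  state$eggs <- eggs
  state$larvae <- larvae
  state$pupae <- pupae
  state$males <- males
  state$females <- females
  state$unmated <- unmated
  if (stochastic && (any(males < 0) || any(females < 0))) {
    stop("internal invariant violation: negative adult counts",
         call. = FALSE)
  }
  state
}

# binomial thinning of a count vector (names preserved)
thin_vec <- function(n, p, stochastic) {
  if (!stochastic) return(n * p)
  out <- n
  pos <- which(n > 0)
  if (length(pos)) {
    pp <- if (length(p) == 1L) rep(p, length(pos)) else p[pos]
    out[pos] <- stats::rbinom(length(pos), as.integer(n[pos]), pp)
  }
  out
}

thin_mat <- function(n, p, stochastic) {
  if (!stochastic) return(n * p)
  out <- n
  pos <- which(n > 0)
  if (length(pos)) {
    out[pos] <- stats::rbinom(length(pos), as.integer(n[pos]), p[pos])
  }
  out
}

# thin all day-bins of a stage matrix and advance one day; `incoming`
# becomes the new first bin (already thinned unless it is freshly laid)
shift_stage <- function(mat, incoming, p, stochastic, thin_new = TRUE) {
  nd <- nrow(mat)
  out <- mat
  if (nd > 1L) {
    surv <- thin_mat(mat[-nd, , drop = FALSE],
                     matrix(p, nd - 1L, ncol(mat)), stochastic)
    out[2:nd, ] <- surv
  }
  out[1L, ] <- incoming
  out
}
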