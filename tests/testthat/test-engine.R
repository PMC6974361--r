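# Ensemble engine metrics and stochastic properties.

test_that("carrier fraction counts females with at least one cargo copy", {
  sys <- drive_system("split")
  lh <- small_life(500)
  cfg <- sim_config(life = lh, n_patches = 1, releases = NULL,
                    horizon_days = 1, n_realizations = 1, seed = 1)
  traj <- run_realization(cfg, seed = 1)
  # hand-built adult state: 30 G/G-carrying, 30 G/w, 40 w/w females
  traj$females_own[1, 1, ] <- 0
  traj$females_own[1, 1, genotype_index(sys, "++;GG")] <- 30
  traj$females_own[1, 1, genotype_index(sys, "++;Gw")] <- 30
  traj$females_own[1, 1, genotype_index(sys, "++;ww")] <- 40
  expect_equal(carrier_fraction(traj, 1, 1), 0.6)
  expect_equal(carrier_fraction(traj, 1, 1, allele = "w"), 0.7)
  # all carriers
  traj$females_own[1, 1, ] <- 0
  traj$females_own[1, 1, genotype_index(sys, "CC;GG")] <- 10
  expect_equal(carrier_fraction(traj, 1, 1), 1.0)
  # no females: undefined
  traj$females_own[1, 1, ] <- 0
  expect_true(is.nan(carrier_fraction(traj, 1, 1)))
})

test_that("window of protection reports longest run and total days", {
  expect_equal(window_of_protection(rep(0.5, 100))$longest, 0)
  x <- rep(0.5, 30); x[10:19] <- 0.9
  w <- window_of_protection(x)
  expect_equal(w$longest, 10)
  expect_equal(w$total, 10)
  # two disjoint supra-threshold runs
  y <- rep(0.5, 40); y[5:10] <- 0.95; y[20:33] <- 0.85
  w2 <- window_of_protection(y)
  expect_equal(w2$longest, 14)
  expect_equal(w2$total, 20)
  expect_lt(w2$longest, w2$total)
  # threshold is strict
  expect_equal(window_of_protection(rep(0.8, 10))$longest, 0)

  # sustained_threshold: highest level held for more than min_days
  z <- c(0.2, rep(0.9, 8), rep(0.85, 3), 0.2)
  expect_equal(sustained_threshold(z, min_days = 10), 0.85)
  # longer than any supra-plateau run: falls back to the window minimum
  expect_equal(sustained_threshold(z, min_days = 12), 0.2)
})

test_that("ensembles are reproducible and summarize realizations", {
  cfg <- sim_config(life = small_life(500), horizon_days = 40,
                    releases = weekly_releases(start_day = 5,
                                               n_releases = 1, size = 500),
                    n_realizations = 3, seed = 2)
  e1 <- run_ensemble(cfg)
  e2 <- run_ensemble(cfg)
  expect_equal(e1$carrier_frac, e2$carrier_frac)
  expect_equal(dim(e1$carrier_frac), c(40, 2, 3))
  # mean trajectories are realization means
  expect_equal(e1$mean_carrier[, 1],
               apply(e1$carrier_frac[, 1, ], 1, mean), tolerance = 1e-12)
  # carrier + non-carrier = all females (by construction of the metric)
  expect_true(all(e1$carrier_frac >= 0 & e1$carrier_frac <= 1, na.rm = TRUE))
})

test_that("a costless refractory allele drifts without systematic increase", {
  lh <- small_life(2000)
  drv <- drive_params(c_F = 0, c_M = 0, fec_cost_per_cas9 = 0,
                      lifespan_cost_hom = 0)
  cfg <- sim_config(system = "refractory", drive = drv, life = lh,
                    n_patches = 1,
                    releases = weekly_releases(start_day = 10,
                                               n_releases = 1, size = 1000,
                                               genotype = "RR"),
                    horizon_days = 400, n_realizations = 12, seed = 31)
  ens <- run_ensemble(cfg)
  freq <- ens$mean_allele_freq[, 1, "R"]
  # after the release settles, the ensemble-mean frequency is flat:
  # compare the post-release plateau to the final value
  plateau <- mean(freq[60:120])
  final <- mean(freq[340:400])
  expect_gt(plateau, 0.05)
  se <- stats::sd(ens$allele_freq[400, 1, "R", ]) /
    sqrt(ens$n_realizations)
  expect_lt(abs(final - plateau), 4 * se + 0.02)
})

test_that("scaled stochastic runs converge to the deterministic trajectory", {
  horizon <- 250
  drv <- drive_params()
  sched <- function(size) weekly_releases(start_day = 20, n_releases = 3,
                                          size = size)
  dev_at_scale <- function(N) {
    lh <- life_history_params(N_eq = N)
    cfg <- sim_config(drive = drv, life = lh, n_patches = 1,
                      releases = sched(N), horizon_days = horizon,
                      n_realizations = 1, seed = 17)
    det <- run_deterministic(cfg)
    sto <- run_ensemble(cfg, n_realizations = 2)
    max(abs(sto$mean_carrier[30:horizon, 1] -
              det$mean_carrier[30:horizon, 1]), na.rm = TRUE)
  }
  d_small <- dev_at_scale(400)
  d_large <- dev_at_scale(8000)
  expect_lt(d_large, d_small)
  expect_lt(d_large, 0.05)
})

test_that("deterministic and stochastic modes share the release machinery", {
  cfg <- sim_config(life = small_life(500), horizon_days = 30,
                    releases = weekly_releases(start_day = 3,
                                               n_releases = 1, size = 800),
                    n_realizations = 1, seed = 1)
  det <- run_deterministic(cfg)
  g <- genotype_index("split", "CC;GG")
  traj <- run_realization(cfg, seed = 1, stochastic = FALSE)
  expect_equal(unname(traj$males[3, 1, g]), 800)   # release lands day 3
  expect_equal(dim(det$carrier_frac)[3], 1)
})

test_that("heatmap experiment degenerates and bounds correctly", {
  lh <- small_life(500)
  cfg <- sim_config(life = lh, horizon_days = 120, n_patches = 1,
                    releases = weekly_releases(n_releases = 2, size = 500,
                                               start_day = 10),
                    n_realizations = 1, seed = 9)
  # zero releases row: no carriers, window 0
  hm <- heatmap_experiment(cfg, fitness_cost_grid = 0.1,
                           release_count_grid = c(0, 2),
                           release_size = 500, start_day = 10,
                           stochastic = FALSE)
  expect_equal(dim(hm), c(2, 1))
  expect_equal(hm[1, 1], 0)
  # 1x1 grid equals a direct window_of_protection call
  hm1 <- heatmap_experiment(cfg, fitness_cost_grid = 0.1,
                            release_count_grid = 2, release_size = 500,
                            start_day = 10, stochastic = FALSE)
  drv <- drive_params(lifespan_cost_hom = 0.1)
  cfg1 <- sim_config(drive = drv, life = lh, n_patches = 1,
                     releases = weekly_releases(n_releases = 2, size = 500,
                                                start_day = 10),
                     horizon_days = 120, n_realizations = 1, seed = 9)
  det1 <- run_deterministic(cfg1)
  expect_equal(unname(hm1[1, 1]),
               window_of_protection(det1, patch = 1)$longest)
})

test_that("split-system Cas9 frequency declines after releases end (reversibility)", {
  cfg <- sim_config(system = "split", horizon_days = 700, seed = 13)
  det <- run_deterministic(cfg)
  C1 <- det$mean_allele_freq[, 1, "C"]
  # last release day 113; allow a 60-day burn-out window
  post <- C1[173:700]
  expect_true(all(diff(post) < 0))
})
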