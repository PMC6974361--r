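# Inheritance cubes: gamete distributions, cube construction, fitness.

test_that("gamete distributions match the chromatid-fate closed form", {
  dp <- drive_params()  # c_F=1, h_F=0.805, c_M=0.51, h_M=0.669, rho1=1/6

  # no drive machinery: pure Mendelian transmission
  g0 <- gamete_distribution("++;ww", "female", dp, "split")
  expect_equal(unname(g0["+|w"]), 1)
  expect_equal(sum(g0), 1, tolerance = 1e-14)

  # trans-heterozygous female: P(G)=1/2+ch/2, resistant mass split 1:5
  gf <- gamete_distribution("C+;Gw", "female", dp, "split")
  target_marg <- c(G = sum(gf[c("C|G", "+|G")]),
                   w = sum(gf[c("C|w", "+|w")]),
                   r1 = sum(gf[c("C|r1", "+|r1")]),
                   r2 = sum(gf[c("C|r2", "+|r2")]))
  expect_equal(unname(target_marg),
               c(0.90250, 0, 0.01625, 0.08125), tolerance = 1e-12)
  expect_equal(unname(sum(gf[startsWith(names(gf), "C|")])), 0.5,
               tolerance = 1e-12)

  # trans-heterozygous male at the male rates
  gm <- gamete_distribution("C+;Gw", "male", dp, "split")
  male_marg <- c(sum(gm[c("C|G", "+|G")]), sum(gm[c("C|w", "+|w")]),
                 sum(gm[c("C|r1", "+|r1")]), sum(gm[c("C|r2", "+|r2")]))
  expect_equal(male_marg, c(0.670595, 0.245, 0.01406750, 0.07033750),
               tolerance = 1e-12)

  # brute-force enumeration oracle over a (c, h) grid
  for (c_ in c(0.3, 0.51, 1)) {
    for (h in c(0, 0.5, 0.805)) {
      dpx <- drive_params(c_F = c_, h_F = h)
      g <- gamete_distribution("C+;Gw", "female", dpx, "split")
      marg <- c(G = sum(g[c("C|G", "+|G")]), w = sum(g[c("C|w", "+|w")]),
                r1 = sum(g[c("C|r1", "+|r1")]),
                r2 = sum(g[c("C|r2", "+|r2")]))
      expect_equal(marg, homing_gametes_oracle(c_, h, 1 / 6),
                   tolerance = 1e-12)
    }
  }

  # no Cas9 in the genotype: G/w transmits Mendelian even at c_F = 1
  gnc <- gamete_distribution("++;Gw", "female", dp, "split")
  expect_equal(unname(sum(gnc[c("C|G", "+|G")])), 0.5, tolerance = 1e-14)
})

test_that("cubes are row-stochastic for all systems and random parameters", {
  set.seed(42)
  for (system in c("split", "linked", "refractory")) {
    for (i in 1:3) {
      dp <- drive_params(c_F = runif(1), c_M = runif(1), h_F = runif(1),
                         h_M = runif(1), rho1 = runif(1),
                         deposition_rate = sample(c(0, runif(1)), 1))
      cube <- build_cube(dp, system)
      expect_no_error(validate_cube(cube, tol = 1e-12))
    }
  }
})

test_that("drive-off cubes reduce exactly to the Mendelian cube", {
  for (system in c("split", "linked", "refractory")) {
    cube <- build_cube(inert_drive(), system)
    expect_equal(unname(cube$tensor), mendelian_cube_oracle(system),
                 tolerance = 1e-14)
  }
})

test_that("cube marginalization recovers the 1/2 + c*h/2 transmission", {
  sys <- drive_system("split")
  hasG <- sys$allele_counts[, "G"] > 0
  for (c_ in c(0.2, 0.51, 1)) {
    for (h in c(0.1, 0.669, 0.805)) {
      cube <- build_cube(drive_params(c_F = c_, h_F = h, c_M = c_,
                                      h_M = h), "split")
      row_f <- cube$tensor["C+;Gw", "++;ww", ]
      expect_equal(sum(row_f[hasG]), 0.5 + 0.5 * c_ * h,
                   tolerance = 1e-12)
      # father as the drive parent under the same rates
      row_m <- cube$tensor["++;ww", "C+;Gw", ]
      expect_equal(sum(row_m[hasG]), 0.5 + 0.5 * c_ * h,
                   tolerance = 1e-12)
    }
  }
})

test_that("mother/father swap is symmetric when sex rates are equal", {
  dp <- drive_params(c_F = 0.7, c_M = 0.7, h_F = 0.6, h_M = 0.6,
                     deposition_rate = 0)
  cube <- build_cube(dp, "split")
  n_g <- cube$system$n_genotypes
  for (mo in c(1, 7, 13, 25)) {
    for (fa in c(2, 7, 19, 30)) {
      expect_equal(cube$tensor[mo, fa, ], cube$tensor[fa, mo, ],
                   tolerance = 1e-14)
    }
  }
})

test_that("refractory cube is Mendelian", {
  cube <- build_cube(drive_params(), "refractory")
  row <- cube$tensor["Rw", "ww", ]
  expect_equal(unname(row[c("Rw", "ww")]), c(0.5, 0.5), tolerance = 1e-14)
  expect_equal(unname(row["RR"]), 0, tolerance = 1e-14)
})

test_that("maternal deposition converts offspring w alleles for Cas9 mothers only", {
  d <- 0.2
  dp <- drive_params(deposition_rate = d)
  cube <- build_cube(dp, "split")
  base <- build_cube(drive_params(deposition_rate = 0), "split")
  expect_no_error(validate_cube(cube))

  # mother without Cas9: rows unchanged
  expect_equal(cube$tensor["++;Gw", , ], base$tensor["++;Gw", , ],
               tolerance = 1e-14)

  # Cas9 father, no Cas9 mother: no deposition either
  expect_equal(cube$tensor["++;ww", "CC;GG", ],
               base$tensor["++;ww", "CC;GG", ], tolerance = 1e-14)

  # Cas9-homozygous mother x wild type: every offspring is C+;?w with the
  # single paternal w exposed: P(converted) = d, split 1:5 r1:r2
  row <- cube$tensor["CC;GG", "++;ww", ]
  expect_equal(unname(row["C+;Gw"]), 1 - d, tolerance = 1e-12)
  expect_equal(unname(row["C+;Gr1"]), d / 6, tolerance = 1e-12)
  expect_equal(unname(row["C+;Gr2"]), d * 5 / 6, tolerance = 1e-12)
})

test_that("fitness modifiers follow per-allele fecundity and homozygote lifespan costs", {
  dp <- drive_params()
  expect_equal(fitness_modifiers("++;ww", dp),
               list(fecundity_multiplier = 1,
                    adult_mortality_multiplier = 1))
  expect_equal(fitness_modifiers("C+;Gw", dp)$fecundity_multiplier, 0.922)
  hom <- fitness_modifiers("CC;GG", dp)
  expect_equal(hom$fecundity_multiplier, 0.922^2, tolerance = 1e-12)
  expect_equal(hom$adult_mortality_multiplier, 1 / 0.9, tolerance = 1e-12)
  # r2 shares the homozygous cargo cost class; r1 does not
  expect_equal(fitness_modifiers("++;Gr2", dp)$adult_mortality_multiplier,
               1 / 0.9, tolerance = 1e-12)
  expect_equal(fitness_modifiers("++;Gr1", dp)$adult_mortality_multiplier,
               1)
  # linked system: H carries the fecundity cost and the cost class
  expect_equal(fitness_modifiers("Hw", dp, "linked")$fecundity_multiplier,
               0.922)
  expect_equal(fitness_modifiers("HH", dp,
                                 "linked")$adult_mortality_multiplier,
               1 / 0.9, tolerance = 1e-12)
})

test_that("cube export/import round-trips through plain text", {
  cube <- build_cube(drive_params(), "split")
  path <- withr::local_tempfile(fileext = ".tsv")
  export_cube(cube, path)
  back <- import_cube(path, "split")
  expect_equal(back$tensor, cube$tensor, tolerance = 1e-14)
})

test_that("invalid parameters and genotypes are rejected", {
  expect_error(drive_params(c_F = 1.2), "probability")
  expect_error(drive_params(fec_cost_per_cas9 = 1), "fraction")
  expect_error(gamete_distribution("C+;GX", "female", drive_params(),
                                   "split"), "unknown genotype")
  expect_error(genotype_index("linked", "CC;GG"), "unknown genotype")
})

test_that("transmission-mode HDR reproduces the observed heterozygote rate", {
  dp <- drive_params(h_F = 0.805, hdr_mode = "transmission")
  g <- gamete_distribution("C+;Gw", "female", dp, "split")
  expect_equal(sum(g[c("C|G", "+|G")]), 0.805, tolerance = 1e-12)
})
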