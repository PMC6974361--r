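# Shared fixtures: small populations and short horizons for unit tests.

small_life <- function(N_eq = 2000) life_history_params(N_eq = N_eq)

# a zero-cost, zero-drive parameter set (pure Mendelian bookkeeping)
inert_drive <- function() {
  drive_params(c_F = 0, c_M = 0, fec_cost_per_cas9 = 0,
               lifespan_cost_hom = 0)
}

# independent Mendelian cube oracle: gamete frequencies = allele counts / 2,
# built directly from the allele-count matrix without the gamete machinery
mendelian_cube_oracle <- function(system) {
  sys <- drive_system(system)
  n_g <- sys$n_genotypes
  n_loci <- length(sys$loci)
  tensor <- array(0, dim = c(n_g, n_g, n_g))
  for (mo in seq_len(n_g)) {
    for (fa in seq_len(n_g)) {
      pd <- vector("list", n_loci)
      off <- 0L
      for (l in seq_along(sys$loci)) {
        alle <- sys$loci[[l]]
        k <- length(alle)
        gm <- sys$allele_counts[mo, off + seq_len(k)] / 2
        gf <- sys$allele_counts[fa, off + seq_len(k)] / 2
        pp <- sys$locus_pairs[[l]]
        pd[[l]] <- vapply(seq_len(nrow(pp)), function(r) {
          i <- pp[r, 1]; j <- pp[r, 2]
          if (i == j) gm[i] * gf[i] else gm[i] * gf[j] + gm[j] * gf[i]
        }, numeric(1))
        off <- off + k
      }
      tensor[mo, fa, ] <- if (n_loci == 1) pd[[1]] else
        kronecker(pd[[1]], pd[[2]])
    }
  }
  tensor
}

# brute-force oracle for the target-locus gamete distribution of a
# drive/wild-type heterozygote: enumerate ordered chromatid fates
homing_gametes_oracle <- function(c_, h, rho1) {
  # chromatid 1 = drive allele, chromatid 2 = w; each picked w.p. 1/2;
  # fates of the w chromatid: uncut, HDR, r1, r2
  p <- c(G = 0, w = 0, r1 = 0, r2 = 0)
  fates <- list(
    list(allele = "w",  prob = 1 - c_),
    list(allele = "G",  prob = c_ * h),
    list(allele = "r1", prob = c_ * (1 - h) * rho1),
    list(allele = "r2", prob = c_ * (1 - h) * (1 - rho1))
  )
  p["G"] <- p["G"] + 0.5                    # drive chromatid transmitted
  for (f in fates) p[f$allele] <- p[f$allele] + 0.5 * f$prob
  p
}

# total individuals in a patch state
state_total <- function(st) {
  sum(st$eggs) + sum(st$larvae) + sum(st$pupae) + sum(st$males) +
    sum(st$females) + sum(st$unmated)
}

# minimal hand-built life params for pure bookkeeping checks
bookkeeping_life <- function(tE = 2L, tL = 2L, tP = 2L) {
  structure(list(beta = 0, tE = tE, tL = tL, tP = tP, muAd = 0,
                 Rm = NA_real_, N_eq = NA_real_, gen_time = 26L,
                 muJ = 0, alpha = 1e18, L_eq = NA_real_),
            class = "life_history_params")
}
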