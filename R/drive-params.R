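#' Drive parameters: cleavage, HDR, resistance and fitness costs
#'
#' Bundles the molecular parameters of the drive. Defaults are the rates
#' measured for the best-performing split-drive system (gRNA cassette at
#' the target locus driven by a U6b promoter, Cas9 under a nup50 germline
#' promoter): germline cleavage of the wild-type chromatid in 100% of
#' female and 51.0% of male trans-heterozygous germlines; homology-directed
#' repair (given cleavage) in 80.5% of female and 66.9% of male events; a
#' sixth of non-HDR repair events yielding in-frame, cost-free resistant
#' alleles (`r1`), the rest out-of-frame costly alleles (`r2`); a 7.8%
#' female fecundity reduction per Cas9 (or `H`) allele; and a 10% reduction
#' in mean adult lifespan for the homozygous cargo cost class.
#'
#' @param c_F,c_M probability that a cleavable `w` chromatid is cut in the
#'   female/male germline of a drive-heterozygote with machinery present.
#' @param h_F,h_M probability of HDR (conversion to the drive allele) given
#'   cleavage, female/male. See `hdr_mode`.
#' @param rho1 fraction of non-HDR (end-joining) events yielding the
#'   in-frame resistant allele `r1`; the remainder yield `r2`.
#' @param fec_cost_per_cas9 fractional reduction in female fecundity per
#'   Cas9-bearing allele (`C`, or `H` in the linked system).
#' @param lifespan_cost_hom fractional reduction in mean adult lifespan for
#'   genotypes in the homozygous cargo cost class (target-locus pair drawn
#'   entirely from `{G, r2}`; `{H, r2}` linked; `R/R` refractory). Under
#'   exponential adult survival this inflates the daily mortality rate by
#'   `1/(1 - lifespan_cost_hom)`.
#' @param deposition_rate probability that a `w` allele in the offspring of
#'   a Cas9-bearing mother is mutated by maternally deposited Cas9/gRNA
#'   complex (converted to `r1`/`r2` in proportion `rho1 : 1-rho1`).
#'   Default 0 (off).
#' @param hdr_mode `"conditional"` (default): `h_F`/`h_M` are P(HDR |
#'   cleavage) per chromatid, so the effective heterozygote transmission of
#'   the drive allele is `1/2 + c*h/2` (0.9025 in females at the defaults).
#'   `"transmission"`: `h_F`/`h_M` are instead read as the effective
#'   heterozygote transmission rate itself and back-converted internally.
#' @return An object of class `drive_params`.
#' @examples
#' drive_params()                      # published split-drive rates
#' drive_params(c_F = 0, c_M = 0)      # Mendelian (drive switched off)
#' @export
drive_params <- function(c_F = 1.0, c_M = 0.51, h_F = 0.805, h_M = 0.669,
                         rho1 = 1 / 6, fec_cost_per_cas9 = 0.078,
                         lifespan_cost_hom = 0.10, deposition_rate = 0,
                         hdr_mode = c("conditional", "transmission")) {
  hdr_mode <- match.arg(hdr_mode)
  p <- list(c_F = c_F, c_M = c_M, h_F = h_F, h_M = h_M, rho1 = rho1,
            fec_cost_per_cas9 = fec_cost_per_cas9,
            lifespan_cost_hom = lifespan_cost_hom,
            deposition_rate = deposition_rate, hdr_mode = hdr_mode)
  for (nm in c("c_F", "c_M", "h_F", "h_M", "rho1", "deposition_rate")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("drive_params: '", nm, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  for (nm in c("fec_cost_per_cas9", "lifespan_cost_hom")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v >= 1) {
      stop("drive_params: '", nm, "' must be a fraction in [0, 1)",
           call. = FALSE)
    }
  }
  structure(p, class = "drive_params")
}

#' @export
print.drive_params <- function(x, ...) {
  cat("<drive_params>\n")
  cat(sprintf("  cleavage  c_F=%.4g  c_M=%.4g\n", x$c_F, x$c_M))
  cat(sprintf("  HDR (%s)  h_F=%.4g  h_M=%.4g\n", x$hdr_mode, x$h_F, x$h_M))
  cat(sprintf("  rho1=%.4g  fec cost/Cas9=%.4g  lifespan cost hom=%.4g  deposition=%.4g\n",
              x$rho1, x$fec_cost_per_cas9, x$lifespan_cost_hom,
              x$deposition_rate))
  invisible(x)
}

# effective P(HDR | cleavage) for a given sex under either hdr_mode
hdr_given_cut <- function(params, sex) {
  c_ <- if (sex == "female") params$c_F else params$c_M
  h <- if (sex == "female") params$h_F else params$h_M
  if (params$hdr_mode == "conditional") return(h)
  # h given as effective heterozygote transmission T = 1/2 + c*h'/2
  if (c_ <= 0) return(0)
  hc <- (2 * h - 1) / c_
  min(max(hc, 0), 1)
}

#' Fitness modifiers of a genotype
#'
#' Returns the female fecundity multiplier and the adult mortality-rate
#' multiplier for a genotype. Each Cas9-bearing allele multiplies female
#' fecundity by `1 - fec_cost_per_cas9` (applied to females only; the
#' multiplier is reported regardless of sex). Genotypes in the homozygous
#' cargo cost class have their daily adult mortality rate multiplied by
#' `1/(1 - lifespan_cost_hom)`, the rate inflation equivalent to the
#' stated reduction in mean lifespan under exponential survival.
#'
#' @param genotype genotype label (e.g. `"C+;Gw"`) or index.
#' @param params a [drive_params()] object.
#' @param system a `drive_system` or system name (default `"split"`).
#' @return list with elements `fecundity_multiplier` and
#'   `adult_mortality_multiplier` (numeric vectors if `genotype` has
#'   length > 1).
#' @examples
#' fitness_modifiers("C+;Gw", drive_params())  # fecundity 0.922
#' @export
fitness_modifiers <- function(genotype, params, system = "split") {
  sys <- as_drive_system(system)
  g <- if (is.character(genotype)) genotype_index(sys, genotype)
       else as.integer(genotype)
  fec <- fecundity_multipliers(params, sys)[g]
  mort <- mortality_multipliers(params, sys)[g]
  list(fecundity_multiplier = unname(fec),
       adult_mortality_multiplier = unname(mort))
}

# vectorized over the whole genotype space (used by the engine)
fecundity_multipliers <- function(params, sys) {
  (1 - params$fec_cost_per_cas9)^sys$n_machinery
}

mortality_multipliers <- function(params, sys) {
  ifelse(sys$cost_class, 1 / (1 - params$lifespan_cost_hom), 1)
}
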