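# Breeding-cross simulator and rate estimators: the parameter-recovery
# surface for cleavage/HDR rates, needing no external data.

#' Design of a genetic cross experiment
#'
#' Describes a single cross repeated over replicate parents: the mother
#' and father genotypes, the number of scored offspring per replicate and
#' the number of replicates (20 by default, the standard replicate count
#' for statistical means in this literature).
#'
#' @param mother,father parent genotype labels (e.g. the split-drive
#'   trans-heterozygous mother `"C+;Gw"` crossed to a wild-type father
#'   `"++;ww"`).
#' @param n_offspring scored offspring per replicate (positive).
#' @param n_replicates replicate parents.
#' @param system `"split"`, `"linked"` or `"refractory"`.
#' @return an object of class `cross_design`.
#' @export
cross_design <- function(mother = "C+;Gw", father = "++;ww",
                         n_offspring = 100, n_replicates = 20,
                         system = "split") {
  sys <- as_drive_system(system)
  stopifnot(n_offspring >= 1, n_replicates >= 1)
  genotype_index(sys, c(mother, father))
  structure(list(mother = mother, father = father,
                 n_offspring = as.integer(n_offspring),
                 n_replicates = as.integer(n_replicates), system = sys),
            class = "cross_design")
}

# eye phenotype of an offspring genotype: white iff both target-locus
# alleles are non-functional (drive insertion or out-of-frame r2); the
# in-frame r1 allele restores pigment
white_eyed <- function(sys) {
  cost_set <- c(sys$cargo, if ("r2" %in% sys$alleles) "r2")
  ta <- sys$loci[["target"]]
  tpp <- sys$locus_pairs[["target"]]
  white_pair <- ta[tpp[, 1]] %in% cost_set & ta[tpp[, 2]] %in% cost_set
  white_pair[sys$combo[, "target"]]
}

#' Forward-simulate a genetic cross
#'
#' Draws replicate offspring tallies from the inheritance-cube row of the
#' designed cross (multinomial per replicate), then scores each offspring
#' for the cargo marker (carries the drive allele), the Cas9 marker
#' (carries `C`; always `FALSE` outside the split system) and eye
#' phenotype: `white` when both target-locus alleles are non-functional
#' (`G`/`H`/`R` insertion or out-of-frame `r2`; in-frame `r1` restores
#' pigment), otherwise `mosaic` with probability `somatic_cleavage_rate`
#' for offspring exposed to somatic cleavage (at least one `w` allele and
#' a Cas9-bearing mother or both drive components inherited), else
#' `black`. Mosaicism is scored phenomenologically, not mechanistically.
#' Maternal deposition (if `drive$deposition_rate > 0`) acts through the
#' cube's offspring-genotype transformation.
#'
#' @param design a [cross_design()].
#' @param drive a [drive_params()] object.
#' @param somatic_cleavage_rate probability that an exposed offspring
#'   shows the mosaic eye phenotype.
#' @return an object of class `cross_counts`: data frame with columns
#'   `replicate`, `genotype`, `cargo`, `cas9`, `phenotype`, `count`
#'   (tallies sum to `n_offspring` per replicate).
#' @examples
#' set.seed(1)
#' cc <- simulate_cross(cross_design(), drive_params())
#' estimate_rates(cc)$transmission$estimate   # ~0.9 at the default rates
#' @export
simulate_cross <- function(design, drive, somatic_cleavage_rate = 0) {
  sys <- design$system
  cube <- build_cube(drive, sys)
  mo <- genotype_index(sys, design$mother)
  fa <- genotype_index(sys, design$father)
  p <- cube$tensor[mo, fa, ]

  has_cargo <- sys$allele_counts[, sys$cargo] > 0
  has_cas9 <- if (sys$system == "split") sys$allele_counts[, "C"] > 0
              else rep(FALSE, sys$n_genotypes)
  white <- white_eyed(sys)
  has_w <- "w" %in% sys$alleles & sys$allele_counts[, "w"] > 0
  mother_cas9 <- sys$n_machinery[mo] > 0

  rows <- vector("list", design$n_replicates)
  for (r in seq_len(design$n_replicates)) {
    tally <- as.vector(stats::rmultinom(1, design$n_offspring, p))
    keep <- which(tally > 0)
    recs <- lapply(keep, function(g) {
      n <- tally[g]
      if (white[g]) {
        data.frame(genotype = sys$labels[g],
                   cargo = unname(has_cargo[g]),
                   cas9 = unname(has_cas9[g]), phenotype = "white",
                   count = n)
      } else {
        exposed <- has_w[g] && (mother_cas9 ||
                                  (has_cargo[g] && has_cas9[g]))
        n_mosaic <- if (exposed && somatic_cleavage_rate > 0) {
          stats::rbinom(1, n, somatic_cleavage_rate)
        } else 0L
        out <- data.frame(genotype = sys$labels[g],
                          cargo = unname(has_cargo[g]),
                          cas9 = unname(has_cas9[g]),
                          phenotype = c("black", "mosaic"),
                          count = c(n - n_mosaic, n_mosaic))
        out[out$count > 0, , drop = FALSE]
      }
    })
    df <- do.call(rbind, recs)
    df <- cbind(replicate = r, df)
    rows[[r]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cross_counts", "data.frame")
  attr(out, "design") <- design
  out
}

#' Estimate transmission and cleavage rates from cross counts
#'
#' Pooled and per-replicate estimates from a `cross_counts` table (or any
#' data frame with `replicate`, `cargo`, `phenotype`, `count`):
#' transmission is the fraction of offspring carrying the cargo marker;
#' the cleavage/mosaicism rate is the fraction showing a cleavage
#' phenotype (mosaic or white eyes). Confidence intervals are exact
#' binomial (Clopper-Pearson) on the pooled counts.
#'
#' @param counts a [simulate_cross()] result or compatible data frame.
#' @param conf_level CI level (default 0.95).
#' @return list with components `transmission` and `cleavage`, each a
#'   list of `k` (successes), `n` (scored), `estimate`, `ci` and
#'   `per_replicate` (fractions by replicate); plus `n_total`.
#' @export
estimate_rates <- function(counts, conf_level = 0.95) {
  if (sum(counts$count) < 1) stop("no scored offspring", call. = FALSE)
  # selectors evaluated on the pooled table and per replicate
  trans_sel <- function(d = counts) d$cargo
  cleav_sel <- function(d = counts) d$phenotype %in% c("mosaic", "white")
  list(transmission = one_rate(counts, trans_sel, conf_level),
       cleavage = one_rate(counts, cleav_sel, conf_level),
       n_total = sum(counts$count))
}

one_rate <- function(counts, select, conf_level) {
  k <- sum(counts$count[select(counts)])
  n <- sum(counts$count)
  bt <- stats::binom.test(k, n, conf.level = conf_level)
  per <- vapply(split(counts, counts$replicate), function(d) {
    sum(d$count[select(d)]) / sum(d$count)
  }, numeric(1))
  list(k = k, n = n, estimate = k / n, ci = as.vector(bt$conf.int),
       per_replicate = unname(per))
}

#' Test for super-Mendelian inheritance
#'
#' Tests whether cargo-marker transmission exceeds the Mendelian 50%.
#' `method = "binomial"` (default) is a one-sided exact binomial test on
#' the pooled count — appropriate for a single pooled tally.
#' `method = "t"` is a one-sample t-test of the per-replicate
#' transmission fractions against 0.5 (the replicate-mean convention of
#' the experimental literature).
#'
#' @param counts a [simulate_cross()] result or compatible data frame.
#' @param method `"binomial"` or `"t"`.
#' @param alpha significance level for the reported decision.
#' @return list with `estimate`, `p_value`, `method` and
#'   `super_mendelian` (logical decision at `alpha`).
#' @examples
#' df <- data.frame(replicate = 1, cargo = c(TRUE, FALSE),
#'                  phenotype = "black", count = c(900, 100))
#' super_mendelian_test(df)$super_mendelian   # TRUE
#' @export
super_mendelian_test <- function(counts, method = c("binomial", "t"),
                                 alpha = 0.05) {
  method <- match.arg(method)
  k <- sum(counts$count[counts$cargo])
  n <- sum(counts$count)
  if (n < 1) stop("no scored offspring", call. = FALSE)
  if (method == "binomial") {
    p <- stats::binom.test(k, n, p = 0.5, alternative = "greater")$p.value
  } else {
    per <- vapply(split(counts, counts$replicate), function(d) {
      sum(d$count[d$cargo]) / sum(d$count)
    }, numeric(1))
    if (length(per) < 2 || stats::sd(per) == 0) {
      stop("t-test method needs >= 2 replicates with variation",
           call. = FALSE)
    }
    p <- stats::t.test(per, mu = 0.5, alternative = "greater")$p.value
  }
  list(estimate = k / n, p_value = p, method = method,
       super_mendelian = p < alpha)
}

#' Deposition rate matching an observed resistant-phenotype fraction
#'
#' Finds the maternal deposition rate at which the expected fraction of
#' offspring that inherit neither drive marker yet show the white
#' (resistant) eye phenotype equals `target_rate`, for a given cross.
#' Computed on the exact cube row (infinite-sample limit) and solved by
#' root finding.
#'
#' @param target_rate observed fraction among no-marker offspring (e.g.
#'   0.0031 for a 0.31% rate).
#' @param drive baseline [drive_params()] (its `deposition_rate` is the
#'   free parameter).
#' @param design the cross (default trans-heterozygous mother x wild-type
#'   father).
#' @return the deposition rate in (0, 1).
#' @export
deposition_for_resistant_rate <- function(target_rate,
                                          drive = drive_params(),
                                          design = cross_design()) {
  sys <- design$system
  mo <- genotype_index(sys, design$mother)
  fa <- genotype_index(sys, design$father)
  has_cargo <- sys$allele_counts[, sys$cargo] > 0
  has_cas9 <- if (sys$system == "split") sys$allele_counts[, "C"] > 0
              else has_cargo
  white <- white_eyed(sys)
  predicted <- function(d) {
    drv <- drive
    drv$deposition_rate <- d
    p <- build_cube(drv, sys)$tensor[mo, fa, ]
    no_marker <- !has_cargo & !has_cas9
    denom <- sum(p[no_marker])
    if (denom == 0) return(0)
    sum(p[no_marker & white]) / denom
  }
  if (predicted(1) < target_rate) {
    stop("target resistant fraction unreachable for this cross",
         call. = FALSE)
  }
  stats::uniroot(function(d) predicted(d) - target_rate,
                 interval = c(1e-10, 1), tol = 1e-10)$root
}

#' Write cross counts to CSV
#'
#' @param counts a `cross_counts` table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_cross_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
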