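#' Define a gene-drive genetic system
#'
#' Enumerates the allele alphabets, diploid genotypes and bookkeeping
#' matrices for one of the three modelled systems:
#'
#' * `"split"` — two unlinked loci: a Cas9 locus with alleles `C`
#'   (endonuclease transgene) and `+` (wild type), and a target locus with
#'   alleles `G` (gRNA/cargo drive allele inserted in the target gene),
#'   `w` (cleavable wild type), `r1` (in-frame, cost-free resistant) and
#'   `r2` (out-of-frame, costly resistant). 3 x 10 = 30 genotypes.
#' * `"linked"` — a single locus carrying a hypothetical homing construct
#'   `H` (Cas9 + gRNA + cargo in one cassette) plus `w`, `r1`, `r2`.
#'   10 genotypes.
#' * `"refractory"` — a single locus with an inert disease-refractory
#'   transgene `R` and wild type `w`; no homing machinery. 3 genotypes.
#'
#' Genotypes are unordered allele pairs per locus in a canonical order
#' (pairs sorted by declared allele order), so each genotype has exactly
#' one label, e.g. `"C+;Gw"` for the split-system trans-heterozygote.
#'
#' @param system one of `"split"`, `"linked"`, `"refractory"`.
#' @return An object of class `drive_system`: a list with the allele
#'   alphabets, genotype labels, per-locus pair tables, an allele-count
#'   matrix (genotype x allele), the cargo-carrier indicator, the Cas9
#'   (machinery) allele count per genotype, and the homozygous-cargo cost
#'   class indicator.
#' @examples
#' sys <- drive_system("split")
#' sys$n_genotypes          # 30
#' head(sys$labels)
#' @export
drive_system <- function(system = c("split", "linked", "refractory")) {
  system <- match.arg(system)
  loci <- switch(system,
    split      = list(cas9 = c("C", "+"), target = c("G", "w", "r1", "r2")),
    linked     = list(target = c("H", "w", "r1", "r2")),
    refractory = list(target = c("R", "w"))
  )
  cargo <- switch(system, split = "G", linked = "H", refractory = "R")
  machinery <- switch(system, split = "C", linked = "H", refractory = NULL)
  # out-of-frame resistant allele, where the system has one
  r2 <- if (system == "refractory") NULL else "r2"

  locus_pairs <- lapply(loci, function(a) {
    k <- length(a)
    do.call(rbind, lapply(seq_len(k), function(i) cbind(i, i:k)))
  })
  pair_labels <- mapply(function(a, pp) paste0(a[pp[, 1]], a[pp[, 2]]),
                        loci, locus_pairs, SIMPLIFY = FALSE)

  # combined genotype index: first locus major, last locus fastest
  n_per_locus <- vapply(locus_pairs, nrow, integer(1))
  combo <- expand.grid(lapply(rev(n_per_locus), seq_len))  # last locus fastest
  combo <- as.matrix(combo[, rev(seq_along(n_per_locus)), drop = FALSE])
  colnames(combo) <- names(loci)
  labels <- apply(mapply(function(l, idx) pair_labels[[l]][combo[, l]],
                         names(loci), seq_along(loci)), 1, paste,
                  collapse = ";")
  n_g <- nrow(combo)

  # allele-count matrix: genotype x allele symbol (symbols unique per system)
  all_alleles <- unlist(loci, use.names = FALSE)
  ac <- matrix(0L, n_g, length(all_alleles),
               dimnames = list(labels, all_alleles))
  off <- 0L
  for (l in names(loci)) {
    pp <- locus_pairs[[l]]
    for (g in seq_len(n_g)) {
      pr <- pp[combo[g, l], ]
      ac[g, off + pr[1]] <- ac[g, off + pr[1]] + 1L
      ac[g, off + pr[2]] <- ac[g, off + pr[2]] + 1L
    }
    off <- off + length(loci[[l]])
  }

  carrier <- ac[, cargo] > 0L
  n_machinery <- if (is.null(machinery)) integer(n_g) else ac[, machinery]

  # homozygous cargo cost class: target-locus pair drawn entirely from
  # {cargo, r2} ({R,R} for the refractory system)
  cost_set <- c(cargo, r2)
  ta <- loci[["target"]]
  tpp <- locus_pairs[["target"]]
  target_cost <- ta[tpp[, 1]] %in% cost_set & ta[tpp[, 2]] %in% cost_set
  cost_class <- target_cost[combo[, "target"]]

  wt_label <- switch(system, split = "++;ww", linked = "ww", refractory = "ww")

  structure(list(
    system      = system,
    loci        = loci,
    cargo       = cargo,
    machinery   = machinery,
    locus_pairs = locus_pairs,
    pair_labels = pair_labels,
    combo       = combo,
    labels      = labels,
    n_genotypes = n_g,
    allele_counts = ac,
    alleles     = all_alleles,
    carrier     = carrier,
    n_machinery = as.integer(n_machinery),
    cost_class  = cost_class,
    wild_type   = wt_label
  ), class = "drive_system")
}

#' @export
print.drive_system <- function(x, ...) {
  cat("<drive_system:", x$system, ">\n")
  cat("  loci:", paste(vapply(names(x$loci), function(l)
    paste0(l, "={", paste(x$loci[[l]], collapse = ","), "}"), ""),
    collapse = "  "), "\n")
  cat("  genotypes:", x$n_genotypes, " cargo allele:", x$cargo, "\n")
  invisible(x)
}

as_drive_system <- function(x) {
  if (inherits(x, "drive_system")) x else drive_system(x)
}

#' Look up genotype indices by label
#'
#' @param system a `drive_system` or system name.
#' @param labels character vector of genotype labels (e.g. `"CC;GG"`).
#' @return integer indices into the system's genotype order.
#' @export
genotype_index <- function(system, labels) {
  sys <- as_drive_system(system)
  idx <- match(labels, sys$labels)
  if (anyNA(idx)) {
    stop("unknown genotype label(s) for system '", sys$system, "': ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}
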