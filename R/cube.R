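# Inheritance cubes: offspring-genotype probability tensors.
#
# Homing model per germline: in a drive/wild-type heterozygote at the
# target locus (G/w, or H/w in the linked system) with Cas9 machinery
# present, the w chromatid is cleaved with probability c_sex; given
# cleavage it is converted to the drive allele by HDR with probability
# h_sex, otherwise it resolves to r1 with probability rho1 and r2 with
# probability 1 - rho1. Uncut w transmits as w. All other genotypes
# transmit Mendelian; the two split-system loci assort independently.

# gamete allele distribution at one locus for one parent
locus_gamete_dist <- function(sys, locus, pair_idx, homing, c_, h, rho1) {
  alleles <- sys$loci[[locus]]
  pp <- sys$locus_pairs[[locus]][pair_idx, ]
  p <- stats::setNames(numeric(length(alleles)), alleles)
  drv <- sys$cargo
  is_het_drive_w <- locus == "target" &&
    setequal(alleles[pp], c(drv, "w")) && pp[1] != pp[2]
  if (homing && is_het_drive_w) {
    p[drv] <- 0.5 + 0.5 * c_ * h
    p["w"] <- 0.5 * (1 - c_)
    p["r1"] <- p["r1"] + 0.5 * c_ * (1 - h) * rho1
    p["r2"] <- p["r2"] + 0.5 * c_ * (1 - h) * (1 - rho1)
  } else {
    p[alleles[pp[1]]] <- p[alleles[pp[1]]] + 0.5
    p[alleles[pp[2]]] <- p[alleles[pp[2]]] + 0.5
  }
  p
}

# per-locus gamete distributions for one parent genotype
parent_gametes <- function(sys, g, sex, params) {
  c_ <- if (sex == "female") params$c_F else params$c_M
  h <- hdr_given_cut(params, sex)
  machinery_present <- sys$n_machinery[g] > 0L
  lapply(names(sys$loci), function(l) {
    locus_gamete_dist(sys, l, sys$combo[g, l], machinery_present, c_, h,
                      params$rho1)
  }) |> stats::setNames(names(sys$loci))
}

#' Gamete distribution of a parent genotype
#'
#' Probability distribution over haploid allele combinations produced by a
#' parent's germline, under the homing model (see [build_cube()]).
#' Alleles at the two split-system loci assort independently.
#'
#' @param parent genotype label or index.
#' @param sex `"female"` or `"male"` (selects `c_F`/`h_F` vs `c_M`/`h_M`).
#' @param params a [drive_params()] object.
#' @param system a `drive_system` or system name.
#' @return named numeric vector over haplotypes (e.g. `"C|G"`), summing
#'   to 1. For single-locus systems the names are the allele symbols.
#' @examples
#' gamete_distribution("C+;Gw", "female", drive_params(), "split")
#' @export
gamete_distribution <- function(parent, sex = c("female", "male"), params,
                                system = "split") {
  sex <- match.arg(sex)
  sys <- as_drive_system(system)
  g <- if (is.character(parent)) genotype_index(sys, parent)
       else as.integer(parent)
  if (length(g) != 1L || is.na(g) || g < 1L || g > sys$n_genotypes) {
    stop("unknown parent genotype", call. = FALSE)
  }
  gam <- parent_gametes(sys, g, sex, params)
  if (length(gam) == 1L) return(gam[[1L]])
  out <- outer(gam[[1L]], gam[[2L]])
  stats::setNames(as.vector(t(out)),
                  as.vector(t(outer(names(gam[[1L]]), names(gam[[2L]]),
                                    paste, sep = "|"))))
}

# unordered offspring pair distribution at one locus from two gamete vectors
pair_dist_from_gametes <- function(gm, gf, pp) {
  O <- outer(gm, gf)
  vapply(seq_len(nrow(pp)), function(r) {
    i <- pp[r, 1]; j <- pp[r, 2]
    if (i == j) O[i, i] else O[i, j] + O[j, i]
  }, numeric(1))
}

# genotype-level maternal-deposition transition matrix (identity when off):
# each w allele in the offspring of a Cas9-bearing mother is converted to
# r1/r2 with probability d, partitioned rho1 : 1-rho1.
deposition_matrix <- function(sys, d, rho1) {
  n_g <- sys$n_genotypes
  if (d <= 0 || !("w" %in% colnames(sys$allele_counts)) ||
      !all(c("r1", "r2") %in% colnames(sys$allele_counts))) {
    return(diag(n_g))
  }
  fate <- c(w = 1 - d, r1 = d * rho1, r2 = d * (1 - rho1))
  ta <- sys$loci[["target"]]
  D <- matrix(0, n_g, n_g, dimnames = list(sys$labels, sys$labels))
  for (g in seq_len(n_g)) {
    pr <- sys$locus_pairs[["target"]][sys$combo[g, "target"], ]
    a1 <- ta[pr[1]]; a2 <- ta[pr[2]]
    f1 <- if (a1 == "w") fate else stats::setNames(1, a1)
    f2 <- if (a2 == "w") fate else stats::setNames(1, a2)
    for (n1 in names(f1)) for (n2 in names(f2)) {
      lab <- target_pair_label(sys, n1, n2)
      tgt_lab <- sub(".*;", "", sys$labels[g])
      new_lab <- sub(paste0(tgt_lab, "$"), lab, sys$labels[g])
      D[g, new_lab] <- D[g, new_lab] + f1[[n1]] * f2[[n2]]
    }
  }
  D
}

# canonical label for an unordered target-locus pair
target_pair_label <- function(sys, a1, a2) {
  ta <- sys$loci[["target"]]
  i <- match(a1, ta); j <- match(a2, ta)
  if (i > j) { k <- i; i <- j; j <- k }
  paste0(ta[i], ta[j])
}

#' Build an inheritance cube
#'
#' Constructs the offspring-genotype probability tensor for every
#' (mother genotype, father genotype) pair: the outer product of the
#' maternal and paternal gamete distributions (per locus, loci
#' independent), followed by the optional maternal-deposition
#' transformation of offspring `w` alleles for Cas9-bearing mothers.
#'
#' @param params a [drive_params()] object.
#' @param system a `drive_system` or system name.
#' @return An object of class `inheritance_cube`: list with `system`,
#'   `params`, `tensor` (array mother x father x offspring with genotype
#'   dimnames) and `flat` (matrix with one row per (mother, father) pair,
#'   mother index varying fastest, used by the simulation engine).
#' @examples
#' cube <- build_cube(drive_params(), "split")
#' rowSums(cube$tensor["C+;Gw", , ])  # each row sums to 1
#' @export
build_cube <- function(params, system = "split") {
  sys <- as_drive_system(system)
  if (!inherits(params, "drive_params")) {
    stop("'params' must be a drive_params object", call. = FALSE)
  }
  n_g <- sys$n_genotypes
  nl <- names(sys$loci)
  gam_f <- lapply(seq_len(n_g), parent_gametes, sys = sys, sex = "female",
                  params = params)
  gam_m <- lapply(seq_len(n_g), parent_gametes, sys = sys, sex = "male",
                  params = params)

  tensor <- array(0, dim = c(n_g, n_g, n_g),
                  dimnames = list(mother = sys$labels, father = sys$labels,
                                  offspring = sys$labels))
  for (mo in seq_len(n_g)) {
    for (fa in seq_len(n_g)) {
      pd <- lapply(nl, function(l) {
        pair_dist_from_gametes(gam_f[[mo]][[l]], gam_m[[fa]][[l]],
                               sys$locus_pairs[[l]])
      })
      # combined index: first locus major, last locus fastest
      off <- if (length(pd) == 1L) pd[[1L]] else kronecker(pd[[1L]], pd[[2L]])
      tensor[mo, fa, ] <- off
    }
  }

  if (params$deposition_rate > 0 && !is.null(sys$machinery)) {
    D <- deposition_matrix(sys, params$deposition_rate, params$rho1)
    dep_mothers <- which(sys$n_machinery > 0L)
    for (mo in dep_mothers) {
      tensor[mo, , ] <- tensor[mo, , , drop = FALSE][1, , ] %*% D
    }
  }

  flat <- matrix(0, n_g * n_g, n_g)
  for (fa in seq_len(n_g)) {
    flat[(fa - 1L) * n_g + seq_len(n_g), ] <- tensor[, fa, ]
  }
  structure(list(system = sys, params = params, tensor = tensor,
                 flat = flat),
            class = "inheritance_cube")
}

#' @export
print.inheritance_cube <- function(x, ...) {
  cat("<inheritance_cube:", x$system$system, ">",
      x$system$n_genotypes, "genotypes\n")
  invisible(x)
}

#' Validate an inheritance cube
#'
#' Checks row-stochasticity (every (mother, father) offspring distribution
#' sums to 1 within `tol`) and non-negativity.
#'
#' @param cube an `inheritance_cube`.
#' @param tol tolerance on row sums.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_cube <- function(cube, tol = 1e-12) {
  rs <- apply(cube$tensor, c(1, 2), sum)
  if (any(abs(rs - 1) > tol)) {
    stop("inheritance cube rows do not sum to 1 (max |err| = ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  if (any(cube$tensor < 0)) stop("negative cube entries", call. = FALSE)
  invisible(TRUE)
}

#' Export / import an inheritance cube as plain text
#'
#' The cube is written as a tab-separated table with one row per
#' (mother, father) pair and one column per offspring genotype, for
#' inspection and regression testing.
#'
#' @param cube an `inheritance_cube`.
#' @param path file path.
#' @return `export_cube`: the path, invisibly. `import_cube`: the
#'   reconstructed `inheritance_cube` (with `params` set to `NULL`;
#'   validated on read).
#' @export
export_cube <- function(cube, path) {
  n_g <- cube$system$n_genotypes
  df <- data.frame(
    mother = rep(cube$system$labels, times = n_g),
    father = rep(cube$system$labels, each = n_g),
    check.names = FALSE
  )
  probs <- cube$flat
  colnames(probs) <- cube$system$labels
  utils::write.table(cbind(df, probs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname export_cube
#' @param system system of the stored cube (`"split"`, `"linked"`,
#'   `"refractory"`).
#' @export
import_cube <- function(path, system) {
  sys <- as_drive_system(system)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  n_g <- sys$n_genotypes
  if (nrow(df) != n_g * n_g) {
    stop("cube file has ", nrow(df), " rows; expected ", n_g * n_g,
         call. = FALSE)
  }
  probs <- as.matrix(df[, sys$labels, drop = FALSE])
  # restore canonical (mother fastest) ordering
  ord <- order(match(df$father, sys$labels), match(df$mother, sys$labels))
  flat <- unname(probs[ord, , drop = FALSE])
  tensor <- array(0, dim = c(n_g, n_g, n_g),
                  dimnames = list(mother = sys$labels, father = sys$labels,
                                  offspring = sys$labels))
  for (fa in seq_len(n_g)) {
    tensor[, fa, ] <- flat[(fa - 1L) * n_g + seq_len(n_g), ]
  }
  cube <- structure(list(system = sys, params = NULL, tensor = tensor,
                         flat = flat),
                    class = "inheritance_cube")
  validate_cube(cube, tol = 1e-9)
  cube
}

# exact Mendelian cube (gamete frequencies = allele counts / 2); used as
# the independent reduction reference and for inert systems
mendelian_cube <- function(system) {
  build_cube(drive_params(c_F = 0, c_M = 0, deposition_rate = 0), system)
}
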