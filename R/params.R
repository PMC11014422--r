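#' Fixed (known) simulation parameters
#'
#' Bundles the known constants of the two-population divergence model: the
#' per-bp recombination rate, the migration-selection cycle structure, the
#' population size, and the SNP map.  The total number of simulated
#' generations is derived as `t_final = n_cycles * t_star - 1`, i.e. the run
#' ends on the last generation before what would be the final migration.
#'
#' @param r Recombination rate in Morgans per bp per generation, in (0, 1).
#' @param t_star Generations per migration-selection cycle (>= 2).  The first
#'   `t_star - 1` generations of each cycle are isolated asexual selection;
#'   the `t_star`-th is the migration generation.
#' @param n_cycles Number of migration-selection cycles (>= 1).
#' @param Ne Effective (census) population size per population (>= 2).
#' @param L Number of bi-allelic SNP loci (>= 2).
#' @param snp_spacing Base pairs between adjacent SNPs (>= 1); the simulated
#'   genome segment spans `L * snp_spacing` bp.
#'
#' @return An object of class `fixed_params`: a list with the six inputs plus
#'   the derived `t_final`.
#' @examples
#' fx <- fixed_params(r = 3e-4, t_star = 5, n_cycles = 4, Ne = 100, L = 100,
#'                    snp_spacing = 165)
#' fx$t_final  # 19
#' @export
fixed_params <- function(r, t_star, n_cycles, Ne, L, snp_spacing) {
  stopifnot(is.numeric(r), length(r) == 1, r > 0, r < 1)
  t_star <- as.integer(t_star); n_cycles <- as.integer(n_cycles)
  Ne <- as.integer(Ne); L <- as.integer(L); snp_spacing <- as.integer(snp_spacing)
  stopifnot(t_star >= 2L, n_cycles >= 1L, Ne >= 2L, L >= 2L, snp_spacing >= 1L)
  structure(list(r = r, t_star = t_star, n_cycles = n_cycles, Ne = Ne, L = L,
                 snp_spacing = snp_spacing,
                 t_final = n_cycles * t_star - 1L),
            class = "fixed_params")
}

#' @export
print.fixed_params <- function(x, ...) {
  cat("Fixed simulation parameters\n")
  cat(sprintf("  r = %g M/bp, SNPs L = %d spaced %d bp (%g bp total)\n",
              x$r, x$L, x$snp_spacing, as.double(x$L) * x$snp_spacing))
  cat(sprintf("  Ne = %d per population\n", x$Ne))
  cat(sprintf("  cycles: %d x t* = %d generations, t_final = %d\n",
              x$n_cycles, x$t_star, x$t_final))
  invisible(x)
}

#' One joint draw of the estimated model parameters
#'
#' Holds a single realisation of the unknown parameters: which loci are under
#' divergent selection in population X, their signed selection coefficients,
#' the symmetric migration rate applied at migration generations, and the
#' reproduction mode used at those generations.
#'
#' @param sel_loci Integer vector of 1-based SNP indices under selection
#'   (0 to 2 entries, distinct).
#' @param sel_coeffs Numeric vector of signed selection coefficients aligned
#'   with `sel_loci`.  Positive values favour the selected allele in
#'   population X; population Y is always neutral.
#' @param m Migration rate: the proportion of each population replaced by
#'   migrants at a migration generation, in \[0, 1).
#' @param sex Reproduction mode at migration generations: 0 = asexual
#'   (clonal), 1 = sexual (random mating with recombination).
#' @param sel_alleles Allele (0/1) whose carriers receive the fitness
#'   increment at each selected locus; defaults to allele 1 at every locus
#'   (the reference-allele convention).
#' @param L Optional number of loci; when given, `sel_loci` are checked to
#'   lie in `[1, L]`.
#'
#' @return An object of class `drawn_params`.
#' @examples
#' drawn_params(sel_loci = 50, sel_coeffs = 0.2, m = 0, sex = 0, L = 100)
#' @export
drawn_params <- function(sel_loci = integer(), sel_coeffs = numeric(),
                         m = 0, sex = 0, sel_alleles = NULL, L = NULL) {
  sel_loci <- as.integer(sel_loci)
  sel_coeffs <- as.numeric(sel_coeffs)
  stopifnot(length(sel_loci) == length(sel_coeffs),
            !anyDuplicated(sel_loci),
            all(sel_loci >= 1L),
            length(m) == 1, m >= 0, m < 1,
            sex %in% c(0, 1))
  if (!is.null(L)) stopifnot(all(sel_loci <= L))
  if (is.null(sel_alleles)) sel_alleles <- rep(1L, length(sel_loci))
  sel_alleles <- as.integer(sel_alleles)
  stopifnot(length(sel_alleles) == length(sel_loci), all(sel_alleles %in% 0:1))
  structure(list(sel_loci = sel_loci, sel_coeffs = sel_coeffs,
                 sel_alleles = sel_alleles, m = m, sex = as.integer(sex)),
            class = "drawn_params")
}

#' @export
print.drawn_params <- function(x, ...) {
  if (length(x$sel_loci) == 0) {
    cat("Drawn parameters: no loci under selection")
  } else {
    cat("Drawn parameters: selection at locus",
        paste(sprintf("%d (s = %+.4g, allele %d)", x$sel_loci, x$sel_coeffs,
                      x$sel_alleles), collapse = ", "))
  }
  cat(sprintf("; m = %g, sex = %d\n", x$m, x$sex))
  invisible(x)
}

#' Construct a population pair
#'
#' A `pop_pair` is the full simulator state: two `Ne x L` binary haplotype
#' matrices (population X under selection, population Y neutral) and the
#' current generation counter.
#'
#' @param X,Y Integer matrices over \{0, 1\} with identical dimensions; one
#'   row per haploid carrier, one column per SNP.
#' @param t Current generation (0 = founding F2).
#' @return An object of class `pop_pair`.
#' @export
pop_pair <- function(X, Y, t = 0L) {
  stopifnot(is.matrix(X), is.matrix(Y), identical(dim(X), dim(Y)),
            all(X %in% 0:1), all(Y %in% 0:1), t >= 0)
  storage.mode(X) <- "integer"; storage.mode(Y) <- "integer"
  structure(list(X = X, Y = Y, t = as.integer(t)), class = "pop_pair")
}

#' @export
print.pop_pair <- function(x, ...) {
  cat(sprintf("Population pair: Ne = %d, L = %d, generation t = %d\n",
              nrow(x$X), ncol(x$X), x$t))
  cat(sprintf("  mean allele-1 frequency: X %.3f, Y %.3f\n",
              mean(x$X), mean(x$Y)))
  invisible(x)
}
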