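#' Convert a cell-level positive fraction between ploidies
#'
#' Under independence of editing events across alleles, a cell is positive
#' when at least one allele is edited, so an observed positive-cell
#' fraction f at ploidy n implies a per-allele editing probability
#' p = 1 - (1 - f)^(1/n), and the equivalent positive-cell fraction at a
#' different ploidy m is 1 - (1 - p)^m. This converts, e.g., FACS
#' measurements in triploid K562 loci to their diploid-cell equivalents.
#'
#' @param f_obs observed positive-cell fraction in `[0, 1]`.
#' @param n_from ploidy at which `f_obs` was measured (>= 1).
#' @param n_to ploidy to convert to (>= 1).
#' @return converted fraction; monotone in `f_obs`, identity when
#'   `n_from == n_to`.
#' @export
ploidy_convert <- function(f_obs, n_from, n_to) {
  stopifnot(all(f_obs >= 0 & f_obs <= 1), n_from >= 1, n_to >= 1)
  # log-domain guard: f = 1 maps to 1 for any finite ploidy
  ifelse(f_obs >= 1, 1, {
    p <- 1 - (1 - f_obs)^(1 / n_from)
    1 - (1 - p)^n_to
  })
}

#' Homozygous knock-in fraction from a dual-donor FACS experiment
#'
#' Two distinguishable donors (e.g. mCherry and miRFP670) are delivered
#' together; in a diploid with equal, independent donor choice per
#' knock-in allele, a dual-positive cell is homozygous knock-in with
#' discordant donors, which is half of all homozygous knock-ins. Hence
#' h = 2 * f_double, and the fraction of cells with at least one knock-in
#' allele is the sum of the three positive populations.
#'
#' @param f_A_only,f_B_only,f_double fractions of cells positive for donor
#'   A only, donor B only, and both.
#' @return list with `homozygous` (h), `any_ki`, and the model assumptions
#'   in `assumptions`.
#' @export
homozygous_fraction <- function(f_A_only, f_B_only, f_double) {
  v <- c(f_A_only, f_B_only, f_double)
  stopifnot(all(v >= 0), sum(v) <= 1)
  h <- 2 * f_double
  any_ki <- f_A_only + f_B_only + f_double
  if (h > any_ki)
    stop("inconsistent input: homozygous fraction exceeds fraction with any knock-in",
         call. = FALSE)
  list(homozygous = h, any_ki = any_ki,
       assumptions = "diploid locus; equal, independent donor choice per knock-in allele")
}

#' Combine FACS and genotyping fractions into a replacement estimate
#'
#' The fraction of all cells with a correct replacement is the product of
#' the reporter-positive fraction (FACS) and the fraction of positive
#' clones genotyped as correct.
#'
#' @param f_pos reporter-positive cell fraction.
#' @param f_correct_given_pos fraction of positive clones with the correct
#'   replacement.
#' @return the product.
#' @export
combined_replacement <- function(f_pos, f_correct_given_pos) {
  stopifnot(f_pos >= 0, f_pos <= 1,
            f_correct_given_pos >= 0, f_correct_given_pos <= 1)
  f_pos * f_correct_given_pos
}

#' Format a fraction as an integer percent
#'
#' Rounds half away from zero (so 0.435 prints as 44%), matching the
#' conventional presentation of FACS percentages; the raw fraction should
#' always be retained alongside.
#'
#' @param f fraction in `[0, 1]`.
#' @return integer percent.
#' @export
as_percent <- function(f) {
  as.integer(round_half_away(100 * f))
}
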