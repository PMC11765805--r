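# Conversion of bound fractions into absolute complexes per fork and ssDNA
# nucleotides, using proteome copy numbers for the imaged cell line.

#' Proteome and fork-count constants
#'
#' Defaults are HeLa values: ~2.6 million PCNA molecules arranged in
#' ~865,300 homotrimers, 926,424 RPA1 molecules (one per RPA heterotrimer),
#' ~4000 concurrently active replication forks, and a 30 nt ssDNA footprint
#' per RPA heterotrimer. The fork count is applied uniformly across
#' S-phase. Override any field for other cell lines.
#'
#' Note: tagged/endogenous expression ratios are deliberately NOT applied
#' in these conversions; the tagged fraction is assumed representative of
#' the whole pool, and the copy numbers refer to the total proteome.
#'
#' @param pcna_molecules total PCNA molecules per nucleus.
#' @param pcna_homotrimers PCNA homotrimer count (must be about
#'   `pcna_molecules / 3`).
#' @param rpa_heterotrimers RPA heterotrimer (= RPA1 molecule) count.
#' @param forks concurrently active replication forks.
#' @param rpa_footprint_nt nucleotides of ssDNA covered per RPA
#'   heterotrimer.
#' @return an object of class `stoich_constants`.
#' @export
#' @examples
#' k <- stoich_constants()
#' complexes_per_fork(0.35, k, "RPA")     # ~81 complexes per fork
#' ssdna_per_fork(80.7, k)                # 2421 nt
stoich_constants <- function(pcna_molecules = 2.6e6,
                             pcna_homotrimers = 865300,
                             rpa_heterotrimers = 926424,
                             forks = 4000,
                             rpa_footprint_nt = 30) {
  stopifnot(pcna_molecules > 0, pcna_homotrimers > 0,
            rpa_heterotrimers > 0, forks > 0, rpa_footprint_nt > 0)
  if (abs(pcna_homotrimers - pcna_molecules / 3) / (pcna_molecules / 3) > 0.01)
    stopf("pcna_homotrimers must be pcna_molecules / 3 within 1%%")
  structure(list(pcna_molecules = pcna_molecules,
                 pcna_homotrimers = pcna_homotrimers,
                 rpa_heterotrimers = rpa_heterotrimers,
                 forks = forks, rpa_footprint_nt = rpa_footprint_nt),
            class = "stoich_constants")
}

species_count <- function(constants, species) {
  switch(toupper(species),
         PCNA = constants$pcna_homotrimers,
         RPA = , RPA1 = constants$rpa_heterotrimers,
         stopf("unknown species '%s' (use 'PCNA' or 'RPA')", species))
}

#' Complexes engaged per replication fork
#'
#' `G_t = F_t * N_complexes / N_forks`: the bound fraction of the nuclear
#' pool times the total complex count, divided by the number of active
#' forks. Linear, so an SD trace propagates by the same factor.
#'
#' @param F_t bound-fraction trace (values in about `[-0.05, 1]`; small
#'   negative values from noise are allowed).
#' @param constants a [stoich_constants()].
#' @param species `"PCNA"` or `"RPA"`.
#' @param sd optional SD trace, propagated linearly.
#' @return numeric trace of complexes per fork (with attribute `"sd"` when
#'   `sd` was given).
#' @export
complexes_per_fork <- function(F_t, constants = stoich_constants(),
                               species, sd = NULL) {
  stopifnot(inherits(constants, "stoich_constants"))
  if (any(F_t < -0.05 | F_t > 1, na.rm = TRUE))
    stopf("bound fractions outside [-0.05, 1]")
  fac <- species_count(constants, species) / constants$forks
  out <- F_t * fac
  if (!is.null(sd)) attr(out, "sd") <- sd * fac
  out
}

#' ssDNA length per fork from RPA complexes
#'
#' `H_t = G_t * footprint`, with the default 30 nt per RPA heterotrimer.
#'
#' @param G_t RPA complexes-per-fork trace.
#' @param constants a [stoich_constants()].
#' @return nucleotides of ssDNA per fork.
#' @export
ssdna_per_fork <- function(G_t, constants = stoich_constants()) {
  stopifnot(inherits(constants, "stoich_constants"))
  sd <- attr(G_t, "sd")
  out <- as.numeric(G_t) * constants$rpa_footprint_nt
  if (!is.null(sd)) attr(out, "sd") <- sd * constants$rpa_footprint_nt
  out
}

#' Residual complexes after partial dissociation
#'
#' @param pre_level complexes per fork before treatment.
#' @param residual_fraction fraction remaining (0-1).
#' @return residual complexes per fork (report at one decimal).
#' @export
#' @examples
#' residual_complexes(59, 0.176)  # 10.4
residual_complexes <- function(pre_level, residual_fraction) {
  stopifnot(residual_fraction >= 0, residual_fraction <= 1)
  pre_level * residual_fraction
}

#' DNA unwinding rate from an ssDNA generation rate
#'
#' Converts nt/min of RPA-covered ssDNA into nt/s, or into bp/s of duplex
#' unwinding when ssDNA accumulates on both strands (`strands = 2`).
#'
#' @param ssdna_rate ssDNA generation rate, nt per minute.
#' @param strands 1 (single-strand rate, nt/s) or 2 (duplex unwinding,
#'   bp/s).
#' @return rate per second.
#' @export
#' @examples
#' unwinding_rate(290, 1)  # 4.8 nt/s
#' unwinding_rate(288, 2)  # 2.4 bp/s
unwinding_rate <- function(ssdna_rate, strands = 1) {
  if (!strands %in% c(1, 2)) stopf("strands must be 1 or 2")
  ssdna_rate / 60 / strands
}
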