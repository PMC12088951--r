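#' Published dynamic rates of twelve focal adhesion proteins
#'
#' Reference table of FRAP-derived observables and inverted rates for the
#' twelve core focal adhesion proteins (tensin1, talin1, vinculin,
#' alpha-actinin, ILK, alpha-parvin, kindlin2, paxillin, p130Cas, VASP, FAK,
#' zyxin): turnover rate `k_t`, entry rate `k_in`, exit rate `k_out`
#' (published display unit 1e-3 /s) and the stationary interior fraction
#' `n_in_bar`, each with its published 1-sigma uncertainty.  Useful as
#' realistic parameter sets for simulation and as the reference for the
#' rate-inversion consistency checks.
#'
#' @param units `"1e-3/s"` (as published, default) or `"/s"`.
#' @return A `data.frame` with columns `protein`, `k_t`, `sigma_k_t`,
#'   `k_in`, `sigma_k_in`, `k_out`, `sigma_k_out`, `n_in_bar`,
#'   `sigma_n_in_bar`.
#' @export
#' @examples
#' head(fa_reference_rates())
fa_reference_rates <- function(units = c("1e-3/s", "/s")) {
  units <- match.arg(units)
  path <- system.file("extdata", "fa_published_rates.tsv", package = "facme",
                      mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (units == "/s") {
    rate_cols <- c("k_t", "sigma_k_t", "k_in", "sigma_k_in",
                   "k_out", "sigma_k_out")
    tab[rate_cols] <- lapply(tab[rate_cols], function(x) x * 1e-3)
  }
  tab
}

#' Look up one protein's published rates as a dynamic_rates object
#'
#' @param protein Protein name as in [fa_reference_rates()] (case
#'   insensitive).
#' @return A [dynamic_rates()] object in /s, rebuilt from the published
#'   observables (`k_t`, `n_in_bar`) via [invert_rates()].
#' @export
fa_protein_rates <- function(protein) {
  tab <- fa_reference_rates(units = "/s")
  i <- match(tolower(protein), tolower(tab$protein))
  if (is.na(i))
    stop("unknown protein '", protein, "'; see fa_reference_rates()$protein")
  dynamic_rates(k_t = tab$k_t[i], n_in_bar = tab$n_in_bar[i],
                sigma_k_t = tab$sigma_k_t[i],
                sigma_n_in_bar = tab$sigma_n_in_bar[i],
                protein = tab$protein[i])
}
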