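#' Cytology simulation configuration
#'
#' Describes the statistical structure of fixed-image scores: a
#' per-chromosome-pair chiasma probability driving diakinesis DAPI-body
#' counts on a 2n=12 karyotype, per-zone pairing probabilities, and
#' per-genotype SUN-1 focus/patch count distributions.
#'
#' @param chiasma_prob Probability that a homolog pair forms at least one
#'   chiasma (per pair, in `[0, 1]`).
#' @param n_oocytes Number of diakinesis oocytes to simulate.
#' @param pairing_prob_by_zone Numeric vector of pairing probabilities, one
#'   per germline zone.
#' @param foci_count_dist List with Poisson means `focus_lambda` and
#'   `patch_lambda` for per-nucleus SUN-1 focus and patch counts.
#' @param n_per_zone Nuclei scored per zone.
#' @param seed Integer seed.
#' @return An object of class `netrack_cyto_config`.
#' @export
cyto_config <- function(chiasma_prob = 0.8, n_oocytes = 52,
                        pairing_prob_by_zone = c(0.55, 0.90, 0.93, 0.95, 0.95),
                        foci_count_dist = list(focus_lambda = 1, patch_lambda = 2.5),
                        n_per_zone = 100, seed = 1L) {
  check_number(chiasma_prob, "chiasma_prob", min = 0, max = 1)
  check_number(n_oocytes, "n_oocytes", positive = TRUE, integer = TRUE)
  if (any(pairing_prob_by_zone < 0 | pairing_prob_by_zone > 1))
    stop_invalid("pairing probabilities must be in [0, 1]")
  check_number(n_per_zone, "n_per_zone", positive = TRUE, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(chiasma_prob = chiasma_prob,
                 n_oocytes = as.integer(n_oocytes),
                 pairing_prob_by_zone = pairing_prob_by_zone,
                 foci_count_dist = foci_count_dist,
                 n_per_zone = as.integer(n_per_zone),
                 seed = as.integer(seed)),
            class = "netrack_cyto_config")
}

#' Simulate diakinesis DAPI-body counts
#'
#' Each oocyte draws its bivalent count from Binomial(6, chiasma_prob) —
#' six homolog pairs, each independently retained as a bivalent with the
#' chiasma probability — and shows `12 - bivalents` DAPI-stained bodies
#' (six bodies = six bivalents; twelve = twelve univalents).
#'
#' @param config A [cyto_config()] (only `chiasma_prob`, `n_oocytes`,
#'   `seed` are used).
#' @return Data frame with `oocyte_id`, `bivalents`, `bodies`.
#' @examples
#' counts <- simulate_oocyte_counts(cyto_config(chiasma_prob = 1, n_oocytes = 5))
#' counts$bodies   # all 6
#' @export
simulate_oocyte_counts <- function(config) {
  stopifnot(inherits(config, "netrack_cyto_config"))
  set.seed(config$seed)
  bivalents <- stats::rbinom(config$n_oocytes, 6L, config$chiasma_prob)
  data.frame(oocyte_id = seq_len(config$n_oocytes),
             bivalents = bivalents,
             bodies = 12L - bivalents)
}

#' Simulate a zone table of pairing calls and aggregate counts
#'
#' Per zone, draws Bernoulli pairing calls at the zone's pairing
#' probability and Poisson SUN-1 focus/patch counts, producing the table
#' shape consumed by the zone-based statistics.
#'
#' @param config A [cyto_config()].
#' @return Data frame with `nucleus_id`, `zone`, `paired` (logical),
#'   `focus_count`, `patch_count`.
#' @export
simulate_zone_scores <- function(config) {
  stopifnot(inherits(config, "netrack_cyto_config"))
  set.seed(config$seed + 1L)
  zones <- seq_along(config$pairing_prob_by_zone)
  out <- list()
  nid <- 1L
  for (z in zones) {
    n <- config$n_per_zone
    out[[z]] <- data.frame(
      nucleus_id = nid:(nid + n - 1L),
      zone = z,
      paired = stats::runif(n) < config$pairing_prob_by_zone[z],
      focus_count = stats::rpois(n, config$foci_count_dist$focus_lambda),
      patch_count = stats::rpois(n, config$foci_count_dist$patch_lambda))
    nid <- nid + n
  }
  do.call(rbind, out)
}
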