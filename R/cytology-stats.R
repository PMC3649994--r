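#' Assign normalized gonad positions to equal-length zones
#'
#' The scored gonad region is divided into `n_zones` zones of equal length;
#' position 1.0 belongs to the last zone.
#'
#' @param positions Positions normalized to `[0, 1]` along the region.
#' @param n_zones Number of zones (>= 1).
#' @return Integer zone labels in `1:n_zones`.
#' @examples
#' assign_zones(c(0, 0.19, 0.2, 1), 5)
#' @export
assign_zones <- function(positions, n_zones = 5L) {
  check_number(n_zones, "n_zones", positive = TRUE, integer = TRUE)
  if (any(!is.finite(positions)) || any(positions < 0 | positions > 1))
    stop_invalid("positions must lie in [0, 1]", "netrack_invalid_input")
  pmin(floor(positions * n_zones) + 1L, as.integer(n_zones))
}

#' Score FISH pairing from per-nucleus signal coordinates
#'
#' A locus is scored paired when its homologous signals appear as one focus:
#' either a single detected signal, or two signals whose 3D separation is at
#' most `merge_dist_um` (inclusive). The paper-scale criterion gives no
#' numeric threshold; 0.75 um is the conventional C. elegans FISH pairing
#' distance and is configurable.
#'
#' @param signals Numeric matrix of signal coordinates in um (1 or 2 rows,
#'   columns y/x/z or y/x).
#' @param merge_dist_um Pairing distance threshold, um.
#' @return `"paired"`, `"unpaired"`, or `NA` (flagged, with a warning) for
#'   nuclei with more than two signals.
#' @export
score_pairing <- function(signals, merge_dist_um = 0.75) {
  check_number(merge_dist_um, "merge_dist_um", positive = TRUE)
  signals <- as.matrix(signals)
  if (nrow(signals) > 2L) {
    warning(sprintf("%d signals in one nucleus; flagged and excluded",
                    nrow(signals)))
    return(NA_character_)
  }
  if (nrow(signals) == 1L) return("paired")
  d <- sqrt(sum((signals[1, ] - signals[2, ])^2))
  if (d <= merge_dist_um) "paired" else "unpaired"
}

#' Two-tailed Fisher's exact test on pairing counts
#'
#' Exact two-sided test on the 2x2 table (paired/unpaired x genotype),
#' as used for per-zone pairing comparisons.
#'
#' @param paired_a,n_a Paired count and total for group A.
#' @param paired_b,n_b Paired count and total for group B.
#' @return Two-sided p-value in `(0, 1]`.
#' @examples
#' pairing_contingency_test(5, 10, 5, 10)   # identical proportions -> 1
#' @export
pairing_contingency_test <- function(paired_a, n_a, paired_b, n_b) {
  check_number(n_a, "n_a", positive = TRUE, integer = TRUE)
  check_number(n_b, "n_b", positive = TRUE, integer = TRUE)
  check_number(paired_a, "paired_a", nonneg = TRUE, max = n_a, integer = TRUE)
  check_number(paired_b, "paired_b", nonneg = TRUE, max = n_b, integer = TRUE)
  tab <- matrix(c(paired_a, n_a - paired_a, paired_b, n_b - paired_b), 2, 2)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Convert mean DAPI-body counts to mean bivalents (2n = 12)
#'
#' At diakinesis each bivalent is one DAPI-stained body and each univalent
#' another, so `bodies = bivalents + univalents` with
#' `2 * bivalents + univalents = 12`; hence
#' `bivalents = chromosome_number - bodies`. Six bodies mean six bivalents,
#' twelve bodies mean twelve univalents.
#'
#' @param mean_bodies Mean DAPI-stained-body count (between
#'   `chromosome_number / 2` and `chromosome_number`).
#' @param chromosome_number Diploid chromosome number (default 12).
#' @return Mean bivalents per oocyte.
#' @examples
#' bivalents_from_bodies(7.2)   # 4.8
#' @export
bivalents_from_bodies <- function(mean_bodies, chromosome_number = 12) {
  check_number(chromosome_number, "chromosome_number", positive = TRUE)
  if (any(!is.finite(mean_bodies)) ||
      any(mean_bodies < chromosome_number / 2) ||
      any(mean_bodies > chromosome_number))
    stop_invalid(sprintf("mean_bodies must lie in [%g, %g]",
                         chromosome_number / 2, chromosome_number),
                 "netrack_invalid_input")
  chromosome_number - mean_bodies
}

#' Mean DAPI bodies implied by mean bivalents (inverse conversion)
#'
#' @param mean_bivalents Mean bivalents in `[0, chromosome_number / 2]`.
#' @param chromosome_number Diploid chromosome number (default 12).
#' @return Mean DAPI-stained-body count.
#' @export
bodies_from_bivalents <- function(mean_bivalents, chromosome_number = 12) {
  check_number(chromosome_number, "chromosome_number", positive = TRUE)
  if (any(!is.finite(mean_bivalents)) || any(mean_bivalents < 0) ||
      any(mean_bivalents > chromosome_number / 2))
    stop_invalid("mean_bivalents out of range", "netrack_invalid_input")
  chromosome_number - mean_bivalents
}

# Exact permutation distribution of the group-A rank sum with ties:
# dynamic programme over doubled midranks, counting subsets of size n1.
mw_exact_pvalue <- function(a, b) {
  ranks <- rank(c(a, b))
  n1 <- length(a); N <- length(ranks)
  r2 <- as.integer(round(2 * ranks))
  w_obs <- sum(r2[seq_len(n1)])
  total <- sum(r2)
  # counts[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  counts <- matrix(0, n1 + 1L, total + 1L)
  counts[1L, 1L] <- 1
  processed <- 0L
  for (r in r2) {
    processed <- processed + 1L
    for (k in min(n1, processed):1) {   # high to low: each item used once
      row <- counts[k, ]
      nz <- which(row > 0)
      if (length(nz))
        counts[k + 1L, nz + r] <- counts[k + 1L, nz + r] + row[nz]
    }
  }
  dist <- counts[n1 + 1L, ]
  sums <- 0:total
  mu <- n1 * (N + 1)             # doubled-scale mean rank sum
  dev_obs <- abs(w_obs - mu)
  sum(dist[abs(sums - mu) >= dev_obs - 1e-9]) / sum(dist)
}

#' Two-tailed Mann-Whitney comparison of DAPI-body counts
#'
#' Compares two samples of per-oocyte body counts with a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test. Because body counts are small
#' tied integers, the exact permutation p-value (tie-aware, computed by a
#' counting dynamic programme over midranks) is used when both samples have
#' at most `exact_limit` observations; larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param sample_a,sample_b Numeric vectors (>= 2 values each, or >= 1 for
#'   `sample_b`... both must be non-empty; singletons are allowed only in
#'   the exact path).
#' @param exact_limit Per-sample size at and below which the exact
#'   permutation distribution is enumerated.
#' @return A list with `p.value`, `U`, `method`.
#' @examples
#' compare_body_counts(c(6, 6, 6), c(12, 12, 12))$p.value
#' @export
compare_body_counts <- function(sample_a, sample_b, exact_limit = 20L) {
  if (!length(sample_a) || !length(sample_b))
    stop_invalid("both samples must be non-empty", "netrack_invalid_input")
  if (any(!is.finite(c(sample_a, sample_b))))
    stop_invalid("samples must be finite", "netrack_invalid_input")
  n1 <- length(sample_a); n2 <- length(sample_b)
  ranks <- rank(c(sample_a, sample_b))
  W <- sum(ranks[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= exact_limit) {
    p <- mw_exact_pvalue(sample_a, sample_b)
    method <- "exact permutation (tie-aware)"
  } else {
    N <- n1 + n2
    ties <- table(ranks)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    mu <- n1 * n2 / 2
    z <- U - mu
    cc <- sign(z) * 0.5
    z <- (z - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie and continuity correction"
  }
  list(p.value = p, U = U, method = method)
}

#' Per-zone percent-of-nuclei count histograms
#'
#' For each zone, tallies the percentage of nuclei whose count of the given
#' category falls in each bin. The default SUN-1 bins are
#' `0, 1-2, 3-5, 6-10, >10`. For the RAD-51 scheme, nuclei flagged as
#' carrying elongated structures (`stretch` column `TRUE`) are tallied in a
#' separate `"stretch"` category.
#'
#' @param zone_table Data frame with `zone` and the count column for
#'   `category` (`focus_count`, `patch_count`, or `rad51_count`), plus an
#'   optional logical `stretch` column.
#' @param category One of `"sun1_focus"`, `"sun1_patch"`, `"rad51"`.
#' @param breaks Integer bin lower edges; bin i spans
#'   `[breaks[i], breaks[i+1] - 1]`, the last bin is open-ended.
#' @return A data frame with `zone`, `bin`, `percent`, `n` (nuclei per
#'   zone); percentages sum to 100 within each zone with n > 0.
#' @export
count_category_histogram <- function(zone_table,
                                     category = c("sun1_focus", "sun1_patch",
                                                  "rad51"),
                                     breaks = c(0, 1, 3, 6, 11)) {
  category <- match.arg(category)
  col <- switch(category, sun1_focus = "focus_count",
                sun1_patch = "patch_count", rad51 = "rad51_count")
  if (!col %in% names(zone_table))
    stop_invalid(sprintf("zone table lacks column '%s'", col),
                 "netrack_invalid_input")
  labels <- character(length(breaks))
  for (i in seq_along(breaks)) {
    lo <- breaks[i]
    hi <- if (i < length(breaks)) breaks[i + 1] - 1 else Inf
    labels[i] <- if (is.infinite(hi)) paste0(">", lo - 1)
      else if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  }
  has_stretch <- "stretch" %in% names(zone_table) && category == "rad51"
  zones <- sort(unique(zone_table$zone))
  rows <- list()
  for (z in zones) {
    zt <- zone_table[zone_table$zone == z, , drop = FALSE]
    n <- nrow(zt)
    stretch_n <- if (has_stretch) sum(zt$stretch %in% TRUE) else 0L
    counted <- if (has_stretch) zt[!(zt$stretch %in% TRUE), , drop = FALSE] else zt
    bin_idx <- findInterval(counted[[col]], breaks)
    tallies <- tabulate(bin_idx, nbins = length(breaks))
    pct <- if (n > 0) 100 * tallies / n else rep(0, length(breaks))
    rows[[length(rows) + 1L]] <- data.frame(
      zone = z, bin = labels, percent = pct, n = n)
    if (has_stretch)
      rows[[length(rows) + 1L]] <- data.frame(
        zone = z, bin = "stretch",
        percent = if (n > 0) 100 * stretch_n / n else 0, n = n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Minimum distance from point p (length-d vector) to a polyline (matrix of
# ordered vertices).
point_polyline_distance <- function(p, polyline) {
  v <- as.matrix(polyline)
  if (nrow(v) == 1L) return(sqrt(sum((p - v[1, ])^2)))
  best <- Inf
  for (i in seq_len(nrow(v) - 1L)) {
    a <- v[i, ]; b <- v[i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab * ab), 1e-12)
    t <- min(1, max(0, t))
    q <- a + t * ab
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}

#' Classify HIM-8 / synaptonemal-complex association of one nucleus
#'
#' Each X-chromosome pairing-centre (HIM-8) signal is associated with an SC
#' stretch (SYP-1 polyline) when it lies within `assoc_dist_um` of it. One
#' signal (paired X) on an SC gives `single-SC-paired`; two signals on
#' different SC stretches give `both-on-different-SC` (non-homologous
#' synapsis); two signals sharing one stretch are also `single-SC-paired`;
#' partial and absent associations give `one-on-SC` / `none-on-SC`.
#'
#' @param him8_coords Matrix of 1 or 2 signal coordinates (um).
#' @param sc_polylines List of SC polylines (matrices of ordered um
#'   vertices, same dimensionality as the signals).
#' @param assoc_dist_um Association distance, um.
#' @return A list with `him8_signal_count` and `association_class`.
#' @export
classify_synapsis_association <- function(him8_coords, sc_polylines,
                                          assoc_dist_um = 0.3) {
  him8_coords <- as.matrix(him8_coords)
  ns <- nrow(him8_coords)
  if (!ns %in% c(1L, 2L))
    stop_invalid("expected 1 or 2 HIM-8 signals", "netrack_invalid_input")
  assoc <- lapply(seq_len(ns), function(i) {
    d <- vapply(sc_polylines, point_polyline_distance,
                numeric(1), p = him8_coords[i, ])
    which(d <= assoc_dist_um)
  })
  cls <- if (ns == 1L) {
    if (length(assoc[[1]])) "single-SC-paired" else "none-on-SC"
  } else {
    a1 <- assoc[[1]]; a2 <- assoc[[2]]
    if (length(a1) && length(a2)) {
      if (length(setdiff(a1, a2)) || length(setdiff(a2, a1)))
        "both-on-different-SC" else "single-SC-paired"
    } else if (length(a1) || length(a2)) "one-on-SC" else "none-on-SC"
  }
  list(him8_signal_count = ns, association_class = cls)
}

#' Tally synapsis-association classes over nuclei
#'
#' @param nuclei List of nuclei, each a list with `him8_coords` and
#'   `sc_polylines` as for [classify_synapsis_association()].
#' @param assoc_dist_um Association distance, um.
#' @return Named integer table of association classes.
#' @export
summarize_synapsis_associations <- function(nuclei, assoc_dist_um = 0.3) {
  cls <- vapply(nuclei, function(nu)
    classify_synapsis_association(nu$him8_coords, nu$sc_polylines,
                                  assoc_dist_um)$association_class,
    character(1))
  table(factor(cls, levels = c("single-SC-paired", "both-on-different-SC",
                               "one-on-SC", "none-on-SC")))
}

#' Normalize respiration rates per worm and compare genotypes
#'
#' Each well contributes the mean of its 7 oxygen-consumption measurements
#' divided by the number of worms counted in that well; genotypes are
#' compared across well replicates with a two-sided two-sample t-test, and
#' the per-genotype mean with the standard error over wells is reported.
#'
#' @param records Data frame with columns `well_id`, `genotype`,
#'   `worms_in_well`, and seven measurement columns `m1`..`m7`
#'   (pmol O2/min).
#' @return A list with `per_well` (adds `per_worm_rate`), `by_genotype`
#'   (mean, SEM, n wells), and `p.value` (NA unless exactly 2 genotypes).
#' @export
normalize_respiration <- function(records) {
  mcols <- paste0("m", 1:7)
  if (!all(c("well_id", "genotype", "worms_in_well", mcols) %in% names(records)))
    stop_invalid("records need well_id, genotype, worms_in_well, m1..m7",
                 "netrack_invalid_input")
  if (any(records$worms_in_well <= 0))
    stop_invalid("worms_in_well must be positive", "netrack_invalid_input")
  per_well <- records
  per_well$per_worm_rate <-
    rowMeans(as.matrix(records[, mcols])) / records$worms_in_well
  gs <- split(per_well$per_worm_rate, per_well$genotype)
  by_genotype <- data.frame(
    genotype = names(gs),
    mean = vapply(gs, mean, numeric(1)),
    sem = vapply(gs, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)),
    n_wells = vapply(gs, length, numeric(1)),
    row.names = NULL)
  p <- if (length(gs) == 2L && min(lengths(gs)) >= 2L)
    stats::t.test(gs[[1]], gs[[2]])$p.value else NA_real_
  list(per_well = per_well, by_genotype = by_genotype, p.value = p)
}
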