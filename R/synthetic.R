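# Synthetic forced-degradation benchmark: antibody-like chains plus
# site-specific deamidation time courses with the statistical structure the
# analysis assumes (motif-dependent first-order kinetics, measurement
# noise, LOQ censoring, occasional coverage loss).

# Amino-acid composition loosely matching antibody variable+constant
# domains; N and Q each ~4% so roughly 8% of residues are candidate sites.
AB_COMPOSITION <- c(
  A = 0.060, C = 0.020, D = 0.042, E = 0.042, F = 0.038, G = 0.088,
  H = 0.016, I = 0.030, K = 0.052, L = 0.072, M = 0.012, N = 0.040,
  P = 0.060, Q = 0.040, R = 0.030, S = 0.118, T = 0.082, V = 0.082,
  W = 0.014, Y = 0.042)

# Base deamidation rate constants (per week) by N/X+1 dipeptide, calibrated
# so the default 45-molecule dataset has ~12% active sites. Ordering follows
# the canonical liability ranking NG > NS ~ NN > other N >> Q.
DEFAULT_BASE_RATES <- c(NG = 0.30, NS = 0.011, NN = 0.009, NT = 0.0055,
                        ND = 0.0035, NH = 0.003)
DEFAULT_RATE_N_OTHER <- 0.0022
DEFAULT_RATE_Q <- 0.0006
# X-1 (predecessor) multipliers: serine, glutamate and tryptophan
# precedents promote deamidation.
DEFAULT_XM1_MULT <- c(S = 2.0, E = 1.7, W = 1.5, G = 1.2)

#' Specification of a synthetic forced-degradation dataset
#'
#' @param n_molecules number of antibodies (default 45, the size of a
#'   realistic training panel).
#' @param seed integer seed (default 7).
#' @param target_active_fraction expected fraction of hot spots (~0.12,
#'   the imbalance of a curated deamidation dataset).
#' @param base_rates named per-week rate constants for N/X+1 dipeptides.
#' @param rate_n_other rate for N sites with a non-listed successor.
#' @param rate_q rate for glutamine sites.
#' @param xm1_mult named X-1 residue multipliers (unlisted residues: 1).
#' @param context_sd standard deviation of the log-normal context effect
#'   drawn from a seeded function of the +/-5 neighborhood.
#' @param context_offsets neighborhood offsets (relative positions, 0
#'   excluded) the context effect depends on; default every position
#'   within +/-5 of the site.
#' @param noise_sd Gaussian measurement noise on extents, in percent.
#' @param loq limit of quantitation in percent; measured extents below it
#'   are reported as 0.
#' @param dmax plateau deamidation extent in percent.
#' @param missingness probability that a site is lost from the peptide map
#'   (`covered = FALSE`).
#' @param hc_length,lc_length length ranges (min, max) for the heavy and
#'   light chain of each molecule.
#' @param label_threshold percent increment defining a ground-truth hot
#'   spot on the noiseless kinetics.
#' @return An object of class `deamid_synth_spec`.
#' @export
synthetic_spec <- function(n_molecules = 45L, seed = 7L,
                           target_active_fraction = 0.12,
                           base_rates = DEFAULT_BASE_RATES,
                           rate_n_other = DEFAULT_RATE_N_OTHER,
                           rate_q = DEFAULT_RATE_Q,
                           xm1_mult = DEFAULT_XM1_MULT,
                           context_sd = 0.6,
                           context_offsets = c(-5:-1, 1:5),
                           noise_sd = 0.3,
                           loq = 0.1,
                           dmax = 80,
                           missingness = 0.02,
                           hc_length = c(330L, 450L),
                           lc_length = c(110L, 230L),
                           label_threshold = 1.0) {
  spec <- list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
               target_active_fraction = target_active_fraction,
               base_rates = base_rates, rate_n_other = rate_n_other,
               rate_q = rate_q, xm1_mult = xm1_mult,
               context_sd = context_sd,
               context_offsets = as.integer(context_offsets),
               noise_sd = noise_sd, loq = loq,
               dmax = dmax, missingness = missingness,
               hc_length = hc_length, lc_length = lc_length,
               label_threshold = label_threshold)
  assert_that(all(c(base_rates, rate_n_other, rate_q) >= 0),
              "rates must be >= 0", class = "deamid_validation_error")
  assert_that(loq >= 0, "LOQ must be >= 0", class = "deamid_validation_error")
  assert_that(dmax > 0 && dmax <= 100, "dmax must be in (0, 100]",
              class = "deamid_validation_error")
  assert_that(target_active_fraction >= 0 && target_active_fraction <= 1,
              "target fraction must be in [0, 1]",
              class = "deamid_validation_error")
  assert_that(length(context_offsets) > 0 && !any(context_offsets == 0) &&
                all(abs(context_offsets) <= 5),
              "context_offsets must be non-zero and within +/-5",
              class = "deamid_validation_error")
  structure(spec, class = "deamid_synth_spec")
}

#' First-order deamidation kinetics
#'
#' Noiseless deamidation extent after `t` weeks under a saturating
#' first-order model: `dmax * (1 - exp(-k * t))`.
#'
#' @param k per-week rate constant (>= 0).
#' @param t time in weeks (>= 0).
#' @param dmax plateau extent in percent (0 < dmax <= 100).
#' @return Extent in percent.
#' @examples
#' kinetic_extent(log(2), 1, dmax = 100)  # 50
#' @export
kinetic_extent <- function(k, t, dmax = 100) {
  assert_that(all(k >= 0) && all(t >= 0), "k and t must be >= 0",
              class = "deamid_validation_error")
  assert_that(all(dmax > 0 & dmax <= 100), "dmax must be in (0, 100]",
              class = "deamid_validation_error")
  dmax * (1 - exp(-k * t))
}

# Smooth seeded context effect: a fixed random table over
# (context offset, residue token) defines a linear function of the one-hot
# neighborhood, standardised to unit variance.
context_table <- function(seed, offsets) {
  n_tok <- length(AA_ALPHABET) + 1L  # + boundary
  with_seed(seed + 211L, matrix(rnorm(length(offsets) * n_tok),
                                length(offsets), n_tok))
}

site_rate <- function(seq_chars, pos, spec, ctx) {
  res <- seq_chars[pos]
  n <- length(seq_chars)
  base <- if (res == "Q") {
    spec$rate_q
  } else {
    succ <- if (pos < n) seq_chars[pos + 1] else ""
    unname(spec$base_rates[paste0("N", succ)]) %||% NA
  }
  if (res == "N" && is.na(base)) base <- spec$rate_n_other
  mult <- 1
  if (res == "N" && pos > 1) {
    m <- spec$xm1_mult[seq_chars[pos - 1]]
    if (!is.na(m)) mult <- unname(m)
  }
  offs <- spec$context_offsets
  ids <- vapply(offs, function(o) {
    p <- pos + o
    if (p < 1 || p > n) length(AA_ALPHABET) + 1L
    else match(seq_chars[p], AA_ALPHABET)
  }, 0L)
  z <- sum(ctx[cbind(seq_along(offs), ids)]) / sqrt(length(offs))
  base * mult * exp(spec$context_sd * z)
}

#' Generate a synthetic forced-degradation dataset
#'
#' Draws antibody-like heavy/light chains, assigns each N/Q site a
#' first-order rate constant determined by its X+1 dipeptide, X-1 residue
#' and a seeded smooth function of the +/-5 neighborhood, then simulates
#' measured extents at t = 0, 1, 2, 4, 8 weeks with Gaussian measurement
#' noise, LOQ censoring (values below `loq` reported as 0) and occasional
#' loss of peptide-map coverage. Fully deterministic for a fixed spec.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `chains` (FASTA-dialect data frame), `timecourse`
#'   (time-course CSV dialect) and `truth` (per-site `true_k`, `true_label`
#'   and noiseless extents).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "deamid_synth_spec"))
  ctx <- context_table(spec$seed, spec$context_offsets)
  tps <- c(0, 1, 2, 4, 8)
  with_seed(spec$seed, {
    chains <- do.call(rbind, lapply(seq_len(spec$n_molecules), function(i) {
      mk <- function(range) {
        len <- sample(range[1]:range[2], 1)
        paste(sample(names(AB_COMPOSITION), len, replace = TRUE,
                     prob = AB_COMPOSITION), collapse = "")
      }
      data.frame(molecule_id = sprintf("synmAb%03d", i),
                 chain_id = c("HC", "LC"),
                 sequence = c(mk(spec$hc_length), mk(spec$lc_length)),
                 stringsAsFactors = FALSE)
    }))
    tc <- list(); truth <- list()
    for (i in seq_len(nrow(chains))) {
      seq_chars <- strsplit(chains$sequence[i], "")[[1]]
      sites <- enumerate_candidate_sites(chains$sequence[i])
      if (nrow(sites) == 0) next
      k <- vapply(sites$position, site_rate, 0,
                  seq_chars = seq_chars, spec = spec, ctx = ctx)
      noiseless <- outer(k, tps, function(kk, tt) kinetic_extent(kk, tt, spec$dmax))
      true_label <- ifelse(
        (noiseless[, 2] - noiseless[, 1] > spec$label_threshold) |
          (noiseless[, 3] - noiseless[, 2] > spec$label_threshold),
        "active", "inactive")
      measured <- noiseless +
        matrix(rnorm(length(noiseless), 0, spec$noise_sd), nrow(noiseless))
      measured <- pmin(pmax(measured, 0), 100)
      measured[measured < spec$loq] <- 0
      covered <- runif(nrow(sites)) >= spec$missingness
      measured[!covered, ] <- NA_real_
      base <- data.frame(molecule_id = chains$molecule_id[i],
                         chain_id = chains$chain_id[i],
                         position = sites$position,
                         residue = sites$residue,
                         stringsAsFactors = FALSE)
      tc[[length(tc) + 1L]] <- cbind(
        base,
        setNames(as.data.frame(measured), names(TIMEPOINT_COLS)),
        data.frame(covered = covered))
      truth[[length(truth) + 1L]] <- cbind(
        base,
        data.frame(true_k = k, true_label = true_label),
        setNames(as.data.frame(noiseless),
                 paste0("noiseless_", names(TIMEPOINT_COLS))))
    }
    tc <- do.call(rbind, tc)
    truth <- do.call(rbind, truth)
    realized <- mean(label_sites(tc, spec$label_threshold)$label == "active")
    tol <- max(0.08, 3 * sqrt(spec$target_active_fraction *
                                (1 - spec$target_active_fraction) / nrow(tc)))
    if (abs(realized - spec$target_active_fraction) > tol) {
      stop_deamid(sprintf(paste0("target active fraction %.3f unreachable ",
                                 "with these rates: realized %.3f over %d ",
                                 "sites"),
                          spec$target_active_fraction, realized, nrow(tc)),
                  class = "deamid_generation_error")
    }
    list(chains = chains, timecourse = tc, truth = truth)
  })
}
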