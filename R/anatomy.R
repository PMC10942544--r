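#' Bouton count along an axon
#'
#' The expected number of presynaptic boutons an axon carries inside a
#' parcel is its axonal length there divided by the mean inter-bouton
#' distance for the target class: `N_b = L_a / d_ib` (real-valued).
#'
#' @param L_a Axonal length (um), positive.
#' @param d_ib Inter-bouton distance (um), positive.
#' @return Expected bouton count.
#' @examples
#' bouton_count(3236, 284)  # mossy fiber onto CA3 (non-c) pyramidal targets
#' @export
bouton_count <- function(L_a, d_ib) {
  if (any(L_a <= 0) || any(d_ib <= 0)) {
    stop("axonal length and inter-bouton distance must be positive",
         call. = FALSE)
  }
  L_a / d_ib
}

#' Split a total axonal length over a target region and its layers
#'
#' Reported innervation patterns give the fraction of the total axonal
#' length entering a target region and, within it, the per-layer split:
#' `L_a(layer) = total * region_fraction * layer_fraction`.
#'
#' @param total Total axonal length (um).
#' @param region_fraction Fraction of `total` inside the target region,
#'   in \[0, 1\].
#' @param layer_fractions Named numeric vector of within-region layer
#'   fractions, each in \[0, 1\], summing to at most 1 (the remainder is
#'   length not assigned to a named layer).
#' @return Named vector of per-layer axonal lengths (um).
#' @examples
#' split_axonal_length(1e5, 0.275, c(SR = 0.64, SP = 0.15, SO = 0.21))
#' @export
split_axonal_length <- function(total, region_fraction, layer_fractions) {
  if (total < 0) stop("`total` must be >= 0", call. = FALSE)
  if (region_fraction < 0 || region_fraction > 1) {
    stop("`region_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (any(layer_fractions < 0) || any(layer_fractions > 1)) {
    stop("layer fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(layer_fractions) > 1 + 1e-9) {
    stop("layer fractions must sum to <= 1", call. = FALSE)
  }
  total * region_fraction * layer_fractions
}

#' Expected synaptic appositions per reachable pair
#'
#' Poisson-thinning contact model: boutons are treated as uniformly
#' scattered in the axonal arbor's hull volume, and a postsynaptic dendrite
#' of length `L_d` with interaction cross-section `pi r^2` intercepts on
#' average `lambda = N_b * (L_d * pi * r^2) / V_hull` of them. Additive
#' over parcels under the independence assumption.
#'
#' @param N_b Bouton count (from [bouton_count()]).
#' @param L_d Postsynaptic dendritic length in the shared parcel (um).
#' @param r Interaction radius (um): maximum axon-dendrite distance counted
#'   as an apposition. Default 1 um; a calibration knob.
#' @param V_hull Axonal convex-hull volume (um^3).
#' @return Expected apposition count lambda (dimensionless).
#' @export
expected_contacts <- function(N_b, L_d, r = 1, V_hull) {
  if (any(c(N_b, L_d, r, V_hull) <= 0)) {
    stop("all contact-model inputs must be positive", call. = FALSE)
  }
  N_b * (L_d * pi * r^2) / V_hull
}

#' Connection probability and contacts per connected pair
#'
#' Under the Poisson apposition model the number of contacts between one
#' ordered cell pair is Poisson(lambda) when the postsynaptic dendrites lie
#' within the axonal hull, which happens for a fraction `f` of pairs.
#' Hence `p = f * (1 - exp(-lambda))` and the mean number of contacts per
#' *connected* pair is the zero-truncated Poisson mean
#' `n_contacts = lambda / (1 - exp(-lambda)) >= 1`.
#'
#' @param lambda Expected appositions per reachable pair, positive.
#' @param f Reachable fraction of ordered pairs, in (0, 1]. Defaults to 1;
#'   typically `V_hull / V_parcel` — a calibration knob.
#' @return A `pair_estimate`: list with `lambda`, `p`, `n_contacts`.
#' @examples
#' pair_estimate(0.2)  # p = 0.181, n_contacts = 1.103
#' @export
pair_estimate <- function(lambda, f = 1) {
  if (!is.numeric(lambda) || any(lambda <= 0)) {
    stop("`lambda` must be positive (n_contacts is undefined at 0)",
         call. = FALSE)
  }
  if (any(f <= 0) || any(f > 1)) {
    stop("`f` must lie in (0, 1]", call. = FALSE)
  }
  hit <- -expm1(-lambda)            # 1 - exp(-lambda), stable for small lambda
  structure(
    list(lambda = lambda, p = f * hit, n_contacts = lambda / hit),
    class = "pair_estimate"
  )
}

#' @export
print.pair_estimate <- function(x, ...) {
  cat(sprintf("<pair_estimate> lambda = %.4g, p = %.3g, contacts = %.3g\n",
              x$lambda, x$p, x$n_contacts))
  invisible(x)
}

#' Invert the contact model against a reported (p, n_contacts) row
#'
#' Solves the zero-truncated Poisson mean for lambda given `n_contacts`
#' (Newton iteration on `lambda / (1 - exp(-lambda)) = n`), then recovers
#' the reachable fraction `f = p / (1 - exp(-lambda))` and, when bouton
#' count, dendritic length and hull volume are supplied, the interaction
#' radius `r = sqrt(lambda * V_hull / (N_b * L_d * pi))`. This is how the
#' model's two knobs are calibrated against published probability/contact
#' tables.
#'
#' @param p Reported connection probability.
#' @param n_contacts Reported mean contacts per connected pair (> 1).
#' @param N_b,L_d,V_hull Optional anatomical inputs for recovering `r`.
#' @return List with `lambda`, `f`, and `r` (NA when anatomy not given).
#' @export
calibrate_pair_estimate <- function(p, n_contacts, N_b = NULL, L_d = NULL,
                                    V_hull = NULL) {
  if (n_contacts <= 1) stop("`n_contacts` must exceed 1", call. = FALSE)
  lambda <- 2 * (n_contacts - 1)    # small-lambda expansion as start
  for (i in 1:60) {
    hit <- -expm1(-lambda)
    fval <- lambda / hit - n_contacts
    grad <- (hit - lambda * exp(-lambda)) / hit^2
    step <- fval / grad
    lambda <- max(lambda - step, 1e-12)
    if (abs(step) < 1e-12 * max(1, lambda)) break
  }
  f <- p / -expm1(-lambda)
  r <- NA_real_
  if (!is.null(N_b) && !is.null(L_d) && !is.null(V_hull)) {
    r <- sqrt(lambda * V_hull / (N_b * L_d * pi))
  }
  list(lambda = lambda, f = f, r = r)
}

# Inter-bouton distances (um) of DG Granule cell mossy fibers in CA3:
# large mossy boutons on pyramidal targets (CA3c vs rest of CA3) and the
# effective spacing of en-passant/filopodial boutons onto interneurons
# (partner-count correction already folded in).
.mossy_d_ib <- c(pyramidal_ca3c = 162, pyramidal_ca3 = 284,
                 interneuron = 67.4)

#' Mossy-fiber connection estimates (DG Granule cell onto CA3 targets)
#'
#' Applies the Poisson contact model to the mossy-fiber pathway under the
#' assumption that granule-cell axons innervate only CA3 stratum lucidum
#' (SL): the target's dendritic length in SL is the only one that counts,
#' and innervation of stratum pyramidale is excluded. Inter-bouton
#' distances default to 162 um (CA3c pyramidal targets), 284 um (other
#' pyramidal targets) and 67.4 um (interneuron targets).
#'
#' @param targets Data frame with columns `post_type`, `target_class`
#'   (`"pyramidal_ca3"`, `"pyramidal_ca3c"` or `"interneuron"`), and
#'   `L_d_SL` (dendritic length in CA3 SL, um; `NA` flags the row as
#'   missing rather than defaulting it).
#' @param L_a_SL Granule-cell axonal length within CA3 (um), default 3236.
#' @param V_hull Axonal convex-hull volume in SL (um^3).
#' @param r Interaction radius (um).
#' @param f Reachable fraction in (0, 1]; scalar or per-row vector.
#' @param d_ib Named inter-bouton distances (um) by target class.
#' @return Data frame: `post_type`, `target_class`, `L_d_SL`, `lambda`,
#'   `p`, `n_contacts`, `flagged` (TRUE when dendritic length was missing
#'   or nonpositive; estimates are NA there).
#' @export
mossy_fiber_estimates <- function(targets, L_a_SL = 3236, V_hull,
                                  r = 1, f = 1, d_ib = .mossy_d_ib) {
  needed <- c("post_type", "target_class", "L_d_SL")
  missing <- setdiff(needed, names(targets))
  if (length(missing) > 0L) {
    stop("`targets` lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_class <- setdiff(targets$target_class, names(d_ib))
  if (length(bad_class) > 0L) {
    stop("no inter-bouton distance for target class(es): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  n <- nrow(targets)
  f <- rep_len(f, n)
  r <- rep_len(r, n)
  out <- data.frame(
    post_type = targets$post_type,
    target_class = targets$target_class,
    L_d_SL = targets$L_d_SL,
    lambda = NA_real_, p = NA_real_, n_contacts = NA_real_,
    flagged = is.na(targets$L_d_SL) | targets$L_d_SL <= 0,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    if (out$flagged[i]) next
    N_b <- bouton_count(L_a_SL, d_ib[[targets$target_class[i]]])
    lam <- expected_contacts(N_b, targets$L_d_SL[i], r[i], V_hull)
    est <- pair_estimate(lam, f[i])
    out$lambda[i] <- est$lambda
    out$p[i] <- est$p
    out$n_contacts[i] <- est$n_contacts
  }
  out
}

#' Schaffer-collateral connection estimates (CA3/CA3c pyramidal onto CA1)
#'
#' Splits the presynaptic total axonal length into CA1 SR, SP and SO with
#' source-specific fractions, converts each layer's length to boutons with
#' layer-specific inter-bouton distances, accumulates the expected
#' appositions over layers against each target's per-layer dendritic
#' lengths, and reports one pair estimate per target.
#'
#' @param total_axon Total presynaptic axonal length (um).
#' @param region_fraction Fraction of `total_axon` inside CA1.
#' @param layer_fractions Named within-CA1 fractions over `SR`, `SP`, `SO`.
#' @param d_ib Named inter-bouton distances (um) per layer, e.g.
#'   `c(SR = 4.1, SP = 4.1, SO = 5.8)`.
#' @param targets Data frame: `post_type` plus dendritic-length columns
#'   `L_d_SR`, `L_d_SP`, `L_d_SO` (um; `NA` treated as 0 for that layer,
#'   all-NA rows flagged).
#' @param V_hull Axonal hull volume within CA1 (um^3).
#' @param r Interaction radius (um).
#' @param f Reachable fraction.
#' @return Data frame: `post_type`, `lambda`, `p`, `n_contacts`, `flagged`.
#' @export
schaffer_estimates <- function(total_axon, region_fraction, layer_fractions,
                               d_ib, targets, V_hull, r = 1, f = 1) {
  layers <- c("SR", "SP", "SO")
  if (!all(names(layer_fractions) %in% layers)) {
    stop("layer fractions must be named among SR, SP, SO", call. = FALSE)
  }
  L_a <- split_axonal_length(total_axon, region_fraction, layer_fractions)
  missing_dib <- setdiff(names(L_a), names(d_ib))
  if (length(missing_dib) > 0L) {
    stop("no inter-bouton distance for layer(s): ",
         paste(missing_dib, collapse = ", "), call. = FALSE)
  }
  n <- nrow(targets)
  f <- rep_len(f, n)
  out <- data.frame(post_type = targets$post_type,
                    lambda = NA_real_, p = NA_real_, n_contacts = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    lam <- 0
    seen <- FALSE
    for (q in names(L_a)) {
      col <- paste0("L_d_", q)
      L_d <- if (col %in% names(targets)) targets[[col]][i] else NA_real_
      if (is.na(L_d) || L_d <= 0 || L_a[[q]] <= 0) next
      seen <- TRUE
      N_b <- bouton_count(L_a[[q]], d_ib[[q]])
      lam <- lam + expected_contacts(N_b, L_d, r, V_hull)
    }
    if (!seen) {
      out$flagged[i] <- TRUE
      next
    }
    est <- pair_estimate(lam, f[i])
    out$lambda[i] <- est$lambda
    out$p[i] <- est$p
    out$n_contacts[i] <- est$n_contacts
  }
  out
}

#' Average of reported inter-bouton distances
#'
#' Pools independent literature reports of the same pathway's inter-bouton
#' distance by arithmetic mean, rounded to one decimal as conventionally
#' quoted.
#'
#' @param values Positive distances (um), non-empty.
#' @return Mean distance (um) at one-decimal precision.
#' @examples
#' average_interbouton(c(3.7, 4.4, 4.29))  # 4.1
#' @export
average_interbouton <- function(values) {
  if (length(values) == 0L) stop("empty value list", call. = FALSE)
  if (any(values <= 0)) stop("distances must be positive", call. = FALSE)
  round(mean(values), 1)
}

#' Read an anatomical measurements table
#'
#' CSV columns: `pre_type`, `post_type`, `parcel`, `L_a`, `d_ib`, `L_d`,
#' `V`, `V_hull`, `r`. Used to drive the contact model pathway by pathway.
#'
#' @param path CSV file path.
#' @return Data frame of measurements.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("pre_type", "post_type", "parcel", "L_a", "d_ib", "L_d")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("measurements table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
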