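#' Fit Izhikevich parameters to target features by an evolutionary strategy
#'
#' A (mu + lambda) evolutionary strategy over the nine model parameters.
#' Each candidate is simulated under the same stimulus as the target, its
#' features extracted, and fitness scored as the weighted mean of relative
#' feature errors. Parents and offspring compete jointly; mutation is
#' Gaussian with per-parameter sigma equal to a fraction of the bound
#' width. Candidates violating the ordering `v_r < v_t < v_peak` are
#' repaired by clipping into the bounds and resampling the ordering.
#'
#' @param target Named list of target feature values (a subset of
#'   [extract_features()] output; non-finite entries are ignored).
#' @param bounds Named list of `c(lo, hi)` per parameter
#'   (`C,k,v_r,v_t,v_peak,v_min,a,b,d`); parameters absent from `bounds`
#'   are fixed at `fixed[[name]]`.
#' @param fixed Named list of fixed parameter values for parameters not in
#'   `bounds`.
#' @param stimulus List describing the evaluation protocol: `I` (pA),
#'   `T` (ms), `dt` (ms), `onset`/`offset` (stimulus window, default the
#'   full span).
#' @param weights Named feature weights (default 1 for every target
#'   feature).
#' @param mu,lambda Parent and offspring counts.
#' @param generations Number of generations (0 returns the best of the
#'   initial population).
#' @param sigma_frac Mutation sigma as a fraction of each bound width.
#' @param seed Mandatory RNG seed; the fit is reproducible given it.
#' @return List with `params` (best [izhikevich_params()]), `fitness`
#'   (best score), `per_feature_error` (named relative errors of the best
#'   candidate), and `history` (best fitness per generation).
#' @examples
#' \donttest{
#' p <- izhikevich_preset("regular_spiking")
#' tr <- izhikevich_integrate(p, 120, dt = 0.1, T = 600)
#' target <- extract_features(tr)
#' fit <- fit_izhikevich(target,
#'   bounds = list(k = c(0.3, 1.5), a = c(0.005, 0.1), b = c(-5, 5),
#'                 d = c(10, 300)),
#'   fixed = list(C = 100, v_r = -60, v_t = -40, v_peak = 35, v_min = -50),
#'   stimulus = list(I = 120, T = 600, dt = 0.1),
#'   generations = 10, seed = 1)
#' }
#' @export
fit_izhikevich <- function(target, bounds, fixed = list(),
                           stimulus, weights = NULL,
                           mu = 20, lambda = 40, generations = 100,
                           sigma_frac = 0.10, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  par_names <- c("C", "k", "v_r", "v_t", "v_peak", "v_min", "a", "b", "d")
  free <- intersect(par_names, names(bounds))
  if (length(free) == 0L) stop("no free parameters in `bounds`", call. = FALSE)
  if (!all(setdiff(par_names, free) %in% names(fixed))) {
    stop("parameters not in `bounds` must appear in `fixed`", call. = FALSE)
  }
  lo <- vapply(bounds[free], `[`, numeric(1), 1L)
  hi <- vapply(bounds[free], `[`, numeric(1), 2L)
  if (any(hi <= lo)) stop("infeasible bounds (hi <= lo)", call. = FALSE)

  feat_names <- names(target)[vapply(target, function(x)
    is.numeric(x) && is.finite(x), logical(1))]
  if (length(feat_names) == 0L) stop("no finite target features", call. = FALSE)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(feat_names)),
                                                   feat_names)
  w <- weights[feat_names]
  w[is.na(w)] <- 1

  onset <- if (is.null(stimulus$onset)) 0 else stimulus$onset
  offset <- if (is.null(stimulus$offset)) stimulus$T else stimulus$offset

  as_params <- function(x) {
    full <- fixed
    full[free] <- as.list(x)
    # repair ordering violations by nudging inside the feasible cone
    if (full$v_t <= full$v_r) full$v_t <- full$v_r + 1
    if (full$v_peak <= full$v_t) full$v_peak <- full$v_t + 1
    do.call(izhikevich_params, full[par_names])
  }
  feature_errors <- function(x) {
    p <- as_params(x)
    tr <- tryCatch(
      izhikevich_integrate(p, stimulus$I, dt = stimulus$dt, T = stimulus$T,
                           stim_window = c(onset, offset)),
      error = function(e) NULL)
    if (is.null(tr)) return(stats::setNames(rep(Inf, length(feat_names)),
                                            feat_names))
    got <- extract_features(tr)
    vapply(feat_names, function(f) {
      g <- got[[f]]
      t <- target[[f]]
      if (is.null(g) || !is.finite(g)) return(1)
      denom <- max(abs(t), 1e-6)
      abs(g - t) / denom
    }, numeric(1))
  }
  score <- function(err) sum(w * err) / sum(w)

  # scoped RNG: restore the caller's stream afterwards
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)

  n_free <- length(free)
  pop <- matrix(stats::runif(mu * n_free, lo, hi), nrow = mu, byrow = TRUE,
                dimnames = list(NULL, free))
  errs <- apply(pop, 1L, feature_errors)
  errs <- matrix(errs, nrow = length(feat_names),
                 dimnames = list(feat_names, NULL))
  fit <- apply(errs, 2L, score)
  history <- numeric(0)

  sigma <- sigma_frac * (hi - lo)
  gen <- 0L
  while (gen < generations) {
    gen <- gen + 1L
    parents <- pop[sample.int(mu, lambda, replace = TRUE), , drop = FALSE]
    noise <- matrix(stats::rnorm(lambda * n_free, sd = rep(sigma, each = lambda)),
                    nrow = lambda)
    kids <- pmin(pmax(parents + noise, rep(lo, each = lambda)),
                 rep(hi, each = lambda))
    kid_errs <- apply(kids, 1L, feature_errors)
    kid_errs <- matrix(kid_errs, nrow = length(feat_names),
                       dimnames = list(feat_names, NULL))
    kid_fit <- apply(kid_errs, 2L, score)

    all_pop <- rbind(pop, kids)
    all_errs <- cbind(errs, kid_errs)
    all_fit <- c(fit, kid_fit)
    keep <- order(all_fit)[seq_len(mu)]
    pop <- all_pop[keep, , drop = FALSE]
    errs <- all_errs[, keep, drop = FALSE]
    fit <- all_fit[keep]
    history <- c(history, fit[1L])
  }

  best <- which.min(fit)
  list(
    params = as_params(pop[best, ]),
    fitness = fit[best],
    per_feature_error = errs[, best],
    history = history
  )
}
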