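#' Membrane biophysics record
#'
#' Subthreshold and spike-shape properties of a neuron type as reported in
#' slice recordings. Every field is optional (`NA` when not measured) and
#' carries the units used throughout the package: mV for potentials, ms for
#' times, MOhm for input resistance, Hz for rates.
#'
#' @param V_rest Resting membrane potential (mV).
#' @param V_thresh Firing threshold potential (mV).
#' @param AP_ampl Action potential amplitude (mV).
#' @param AP_width Action potential width (ms); must be positive when given.
#' @param R_in Input resistance (MOhm).
#' @param tau_m Membrane time constant (ms); must be positive when given.
#' @param max_FR Maximum firing rate (Hz).
#' @param fAHP Fast after-hyperpolarization (mV).
#' @param sAHP Slow after-hyperpolarization (mV).
#' @param sag_ratio Ratio of steady-state to minimum membrane potential
#'   during a hyperpolarizing step; in (0, 1] when given.
#' @param condition Free-text recording-condition note (temperature etc.).
#' @return A `membrane_biophysics` object (named list).
#' @export
membrane_biophysics <- function(V_rest = NA_real_, V_thresh = NA_real_,
                                AP_ampl = NA_real_, AP_width = NA_real_,
                                R_in = NA_real_, tau_m = NA_real_,
                                max_FR = NA_real_, fAHP = NA_real_,
                                sAHP = NA_real_, sag_ratio = NA_real_,
                                condition = NA_character_) {
  out <- structure(
    list(V_rest = V_rest, V_thresh = V_thresh, AP_ampl = AP_ampl,
         AP_width = AP_width, R_in = R_in, tau_m = tau_m, max_FR = max_FR,
         fAHP = fAHP, sAHP = sAHP, sag_ratio = sag_ratio,
         condition = condition),
    class = "membrane_biophysics"
  )
  iss <- validate_biophysics(out)
  if (length(iss) > 0L) stop(iss[[1L]]$message, call. = FALSE)
  out
}

#' @noRd
validate_biophysics <- function(b) {
  issues <- list()
  chk <- function(field, ok, msg) {
    v <- b[[field]]
    if (!is.na(v) && !ok(v)) {
      issues[[length(issues) + 1L]] <<-
        list(field = field, severity = "error", message = msg)
    }
  }
  chk("AP_width", function(v) v > 0, "AP_width must be > 0 when present")
  chk("tau_m", function(v) v > 0, "tau_m must be > 0 when present")
  chk("sag_ratio", function(v) v > 0 && v <= 1,
      "sag_ratio must lie in (0, 1] when present")
  issues
}

#' Construct a neuron type
#'
#' The unit of classification: a named type with a home subregion, an
#' excitatory/inhibitory class, a laminar axon/dendrite pattern, optional
#' molecular markers (three-state: positive / negative / unknown — unknown
#' is never coerced to negative), membrane biophysics, a census count, and
#' an importance rank from 1 (essential) to 5 (dispensable).
#'
#' @param name Free-text type name, unique within a knowledge base.
#' @param pattern A [laminar_pattern()]; fixes the home subregion.
#' @param class `"excitatory"` or `"inhibitory"` (abbreviations `"e"`/`"i"`
#'   accepted).
#' @param markers Named character vector, marker ->
#'   `c("positive", "negative", "unknown")`.
#' @param biophysics A [membrane_biophysics()] record.
#' @param census_count Nonnegative estimated population count.
#' @param rank Importance rank, integer 1..5.
#' @return A `neuron_type` object.
#' @examples
#' gc <- neuron_type("DG Granule", parse_laminar_code("2230", "DG"), "e")
#' gc$home_subregion
#' @export
neuron_type <- function(name, pattern, class = c("excitatory", "inhibitory"),
                        markers = character(), biophysics = membrane_biophysics(),
                        census_count = NA_real_, rank = NA_integer_) {
  if (identical(class, "e")) class <- "excitatory"
  if (identical(class, "i")) class <- "inhibitory"
  class <- match.arg(class)
  stopifnot(inherits(pattern, "laminar_pattern"))
  t <- structure(
    list(
      name = as.character(name),
      home_subregion = pattern$home_subregion,
      class = class,
      pattern = pattern,
      markers = markers,
      biophysics = biophysics,
      census_count = as.numeric(census_count),
      rank = as.integer(rank)
    ),
    class = "neuron_type"
  )
  hard <- Filter(function(i) i$severity == "error", validate_type(t))
  if (length(hard) > 0L) stop(hard[[1L]]$message, call. = FALSE)
  t
}

#' @export
print.neuron_type <- function(x, ...) {
  cat(sprintf("<neuron_type> %s (%s, %s) code %s%s\n",
              x$name, x$home_subregion,
              substr(x$class, 1, 1),
              encode_laminar_code(x$pattern),
              if (is_projecting(x$pattern)) "p" else ""))
  invisible(x)
}

#' Validate a neuron type
#'
#' Checks every invariant of the type record and reports violations without
#' stopping; intended for screening imported knowledge bases.
#'
#' @param t A `neuron_type` (or a structurally similar list).
#' @return A list of issues, each with `field`, `severity` and `message`;
#'   empty when all invariants hold.
#' @export
validate_type <- function(t) {
  issues <- list()
  add <- function(field, message, severity = "error") {
    issues[[length(issues) + 1L]] <<-
      list(field = field, severity = severity, message = message)
  }
  if (!is.character(t$name) || length(t$name) != 1L || !nzchar(t$name)) {
    add("name", "name must be a non-empty string")
  }
  if (!is.na(t$rank) && (t$rank < 1L || t$rank > 5L)) {
    add("rank", sprintf("rank must lie in 1..5 (got %d)", t$rank))
  }
  if (!is.na(t$census_count) && t$census_count < 0) {
    add("census_count",
        sprintf("census_count must be >= 0 (got %g)", t$census_count))
  }
  if (length(t$markers) > 0L &&
      !all(t$markers %in% c("positive", "negative", "unknown"))) {
    add("markers", "marker states must be positive/negative/unknown")
  }
  if (!identical(t$home_subregion, t$pattern$home_subregion)) {
    add("home_subregion", "home subregion disagrees with the pattern's")
  }
  issues <- c(issues, validate_biophysics(t$biophysics))
  issues
}

#' Flag pairs of types with identical laminar patterns
#'
#' Two types are distinct whenever their patterns differ in any parcel; a
#' pair with identical patterns (home and projecting) in the same subregion
#' is therefore a candidate for merging and is reported here.
#'
#' @param types List of `neuron_type` objects.
#' @return Data frame with columns `type_a`, `type_b`, one row per
#'   same-pattern pair.
#' @export
merge_candidates <- function(types) {
  key <- vapply(types, function(t) {
    paste(t$home_subregion, encode_laminar_code(t$pattern),
          paste(names(t$pattern$projecting), t$pattern$projecting,
                sep = ":", collapse = ";"),
          sep = "|")
  }, character(1))
  nm <- vapply(types, `[[`, character(1), "name")
  out <- data.frame(type_a = character(), type_b = character(),
                    stringsAsFactors = FALSE)
  for (k in unique(key[duplicated(key)])) {
    members <- nm[key == k]
    pairs <- utils::combn(members, 2L)
    out <- rbind(out, data.frame(type_a = pairs[1L, ], type_b = pairs[2L, ],
                                 stringsAsFactors = FALSE))
  }
  out
}
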