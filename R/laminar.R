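#' Laminar axon/dendrite patterns
#'
#' A laminar pattern records, for each parcel a neuron type reaches, whether
#' the type has axons, dendrites, both, or neither there. Within the home
#' subregion the pattern is written compactly as a digit string over the
#' subregion's canonical layer order (0 = no axons or dendrites, 1 = only
#' axons, 2 = only dendrites, 3 = both axons and dendrites). Parcels invaded
#' outside the home subregion ("projecting" parcels) are stored as an
#' explicit named list, since the digit string covers home layers only.
#'
#' @param presence Named character vector, parcel id -> state in
#'   `c("NONE", "AXON", "DENDRITE", "BOTH")`, covering the home subregion's
#'   parcels.
#' @param home_subregion Subregion name.
#' @param soma_parcel Parcel id of the soma; must lie in the home subregion.
#' @param projecting Named character vector of out-of-home parcel states
#'   (same state alphabet); empty for non-projecting types.
#' @return An object of class `laminar_pattern`.
#' @seealso [parse_laminar_code()], [encode_laminar_code()]
#' @export
laminar_pattern <- function(presence, home_subregion,
                            soma_parcel = NULL, projecting = character()) {
  home_subregion <- match.arg(home_subregion, subregions())
  layers <- subregion_layers(home_subregion)
  home_parcels <- paste(home_subregion, layers, sep = ".")

  presence <- as.character(presence) |> stats::setNames(names(presence))
  if (!setequal(names(presence), home_parcels)) {
    stop("`presence` must name exactly the home-subregion parcels: ",
         paste(home_parcels, collapse = ", "), call. = FALSE)
  }
  presence <- presence[home_parcels]
  bad <- !presence %in% .presence_states
  if (any(bad)) {
    stop("invalid presence state(s): ",
         paste(unique(presence[bad]), collapse = ", "), call. = FALSE)
  }

  projecting <- as.character(projecting) |> stats::setNames(names(projecting))
  if (length(projecting) > 0L) {
    assert_parcel(names(projecting))
    reg <- parcel_registry()
    home_hit <- reg$subregion[match(names(projecting), reg$parcel)] == home_subregion
    if (any(home_hit)) {
      stop("projecting parcels must lie outside the home subregion: ",
           paste(names(projecting)[home_hit], collapse = ", "), call. = FALSE)
    }
    if (!all(projecting %in% .presence_states)) {
      stop("invalid projecting state(s)", call. = FALSE)
    }
    projecting <- projecting[projecting != "NONE"]
  }

  if (!is.null(soma_parcel)) {
    assert_parcel(soma_parcel)
    if (!soma_parcel %in% home_parcels) {
      stop("`soma_parcel` must lie in the home subregion", call. = FALSE)
    }
  }

  structure(
    list(
      presence = presence,
      home_subregion = home_subregion,
      soma_parcel = soma_parcel,
      projecting = projecting
    ),
    class = "laminar_pattern"
  )
}

#' @export
print.laminar_pattern <- function(x, ...) {
  cat("<laminar_pattern> ", x$home_subregion, " code ",
      encode_laminar_code(x), sep = "")
  if (length(x$projecting) > 0L) {
    cat("p [", paste0(names(x$projecting), ":", x$projecting,
                      collapse = ", "), "]", sep = "")
  }
  if (!is.null(x$soma_parcel)) cat("  soma", x$soma_parcel)
  cat("\n")
  invisible(x)
}

#' Is a type projecting (invading parcels outside its home subregion)?
#'
#' @param pattern A [laminar_pattern()].
#' @return Logical flag; `TRUE` iff the out-of-home parcel list is non-empty.
#' @export
is_projecting <- function(pattern) {
  stopifnot(inherits(pattern, "laminar_pattern"))
  length(pattern$projecting) > 0L
}

# digit <-> state lookup for the 0/1/2/3 scheme
.digit_states <- c(`0` = "NONE", `1` = "AXON", `2` = "DENDRITE", `3` = "BOTH")

#' Parse a laminar digit code into a pattern
#'
#' Reads a digit string (e.g. `"2232"`) positionally against the canonical
#' layer order of `subregion`: 0 = no axons or dendrites, 1 = only axons,
#' 2 = only dendrites, 3 = both axons and dendrites. Projecting parcels are
#' not part of the digit string and must be supplied separately to
#' [laminar_pattern()].
#'
#' @param code Digit string whose length equals the subregion's layer count.
#' @param subregion Home subregion name.
#' @param soma_parcel Optional soma parcel id (home subregion).
#' @param projecting Optional named state vector of out-of-home parcels.
#' @return A [laminar_pattern()].
#' @examples
#' p <- parse_laminar_code("2232", "DG")  # dendrites SMo/SMi/H, both in SG
#' p$presence
#' @export
parse_laminar_code <- function(code, subregion,
                               soma_parcel = NULL, projecting = character()) {
  subregion <- match.arg(subregion, subregions())
  layers <- subregion_layers(subregion)
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    stop("`code` must be a single string", call. = FALSE)
  }
  if (nchar(code) != length(layers)) {
    stop(sprintf("code '%s' has %d digits; subregion %s has %d layers",
                 code, nchar(code), subregion, length(layers)), call. = FALSE)
  }
  digits <- strsplit(code, "")[[1L]]
  bad <- which(!digits %in% names(.digit_states))
  if (length(bad) > 0L) {
    stop(sprintf("invalid digit '%s' at position %d of code '%s'",
                 digits[bad[1L]], bad[1L], code), call. = FALSE)
  }
  presence <- stats::setNames(unname(.digit_states[digits]),
                              paste(subregion, layers, sep = "."))
  laminar_pattern(presence, subregion,
                  soma_parcel = soma_parcel, projecting = projecting)
}

#' Encode a laminar pattern as its digit code
#'
#' Inverse of [parse_laminar_code()] over the home subregion: the returned
#' string has one digit per home layer in canonical order. Projecting
#' parcels are not serialized into the string.
#'
#' @param pattern A [laminar_pattern()].
#' @return A digit string.
#' @examples
#' encode_laminar_code(parse_laminar_code("2210", "DG"))  # "2210"
#' @export
encode_laminar_code <- function(pattern) {
  stopifnot(inherits(pattern, "laminar_pattern"))
  digits <- names(.digit_states)[match(pattern$presence, .digit_states)]
  paste(digits, collapse = "")
}
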