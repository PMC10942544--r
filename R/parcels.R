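#' Parcel registry of the hippocampal formation
#'
#' The atomic spatial unit of the morphology coding scheme is the parcel:
#' one layer within one subregion. The default registry covers 26 parcels
#' across the 6 subregions of the hippocampal formation, each with a fixed
#' canonical layer order that the digit codes are read against:
#'
#' * DG: SMo, SMi, SG, H (4)
#' * CA3: SLM, SR, SL, SP, SO (5)
#' * CA2: SLM, SR, SP, SO (4)
#' * CA1: SLM, SR, SP, SO (4)
#' * Sub: SM, SP, PL (3)
#' * EC: I, II, III, IV, V, VI (6)
#'
#' @return A data frame with one row per parcel and columns `parcel`
#'   (unique id, `"SUBREGION.LAYER"`), `subregion`, `layer`, and `index`
#'   (1-based position in the subregion's canonical layer order).
#' @examples
#' reg <- parcel_registry()
#' nrow(reg)           # 26
#' table(reg$subregion)
#' @export
parcel_registry <- function() {
  layers <- .parcel_layers
  sub <- rep(names(layers), lengths(layers))
  lay <- unlist(layers, use.names = FALSE)
  data.frame(
    parcel = paste(sub, lay, sep = "."),
    subregion = sub,
    layer = lay,
    index = unlist(lapply(layers, seq_along), use.names = FALSE),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# Canonical layer orders; digit strings are read positionally against these.
.parcel_layers <- list(
  DG  = c("SMo", "SMi", "SG", "H"),
  CA3 = c("SLM", "SR", "SL", "SP", "SO"),
  CA2 = c("SLM", "SR", "SP", "SO"),
  CA1 = c("SLM", "SR", "SP", "SO"),
  Sub = c("SM", "SP", "PL"),
  EC  = c("I", "II", "III", "IV", "V", "VI")
)

#' Subregion names of the default parcel registry
#'
#' @return Character vector of the 6 subregion names.
#' @export
subregions <- function() names(.parcel_layers)

#' Canonical layer order of one subregion
#'
#' @param subregion Subregion name (one of [subregions()]).
#' @return Character vector of layer names, in the order the digit code
#'   is written.
#' @examples
#' subregion_layers("DG")  # "SMo" "SMi" "SG" "H"
#' @export
subregion_layers <- function(subregion) {
  subregion <- match.arg(subregion, names(.parcel_layers))
  .parcel_layers[[subregion]]
}

#' @noRd
assert_parcel <- function(parcel) {
  reg <- parcel_registry()
  bad <- setdiff(parcel, reg$parcel)
  if (length(bad) > 0L) {
    stop("unknown parcel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(parcel)
}

# Presence states a parcel can take in a laminar pattern.
.presence_states <- c("NONE", "AXON", "DENDRITE", "BOTH")

#' @noRd
state_has_axon <- function(state) state %in% c("AXON", "BOTH")

#' @noRd
state_has_dendrite <- function(state) state %in% c("DENDRITE", "BOTH")
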