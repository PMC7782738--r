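# Ion permeation event detection on canonicalized ensembles.

#' Detect ion permeation events through the gate
#'
#' An event is recorded when a tracked ion fully traverses the gate's
#' z-interval while remaining inside the gate cylinder: it must enter the
#' gate zone from one side (\code{z >= zMax} for inward, \code{z <= zMin}
#' for outward) and exit on the opposite side without leaving the
#' cylinder radius or returning to the entry side in between
#' (hysteresis). \code{entryFrame} is the frame in which the ion first
#' occupies the gate zone; \code{exitFrame} the frame in which it first
#' reaches the far side. An ion jumping across the whole gate between
#' consecutive in-cylinder frames counts as one event spanning those two
#' frames.
#'
#' @param ensemble canonicalized \code{FrameEnsemble}.
#' @param ionSelection selection expression or \code{AtomSelection}
#'   identifying the ions (e.g. \code{"resname NA SOD"}); must be
#'   non-empty.
#' @param gate a \code{\link{gateRegion}}.
#' @return data.frame with columns \code{ionIndex} (atom index),
#'   \code{entryFrame}, \code{exitFrame}, \code{direction}
#'   (\code{"inward"} = decreasing z, \code{"outward"}); zero rows when
#'   nothing permeates.
#' @export
detectPermeation <- function(ensemble, ionSelection, gate = gateRegion()) {
  stopifnot(is(ensemble, "FrameEnsemble"), inherits(gate, "GateRegion"))
  sel <- selectAtoms(ensemble, ionSelection)
  if (!length(sel@indices)) stop("ion selection is empty")
  nf <- nFrames(ensemble)
  events <- list()
  r2max <- gate$radius^2
  for (ion in sel@indices) {
    xyz <- t(ensemble@coords[ion, , ])        # 3 x nf -> transpose safe
    if (nf == 1) xyz <- matrix(ensemble@coords[ion, , 1], nrow = 1)
    inCyl <- (xyz[, 1]^2 + xyz[, 2]^2) <= r2max
    # crossing completes only strictly beyond the gate bounds; the
    # boundary values belong to the gate zone (open interval as printed)
    zone <- ifelse(xyz[, 3] > gate$zMax, "above",
                   ifelse(xyz[, 3] < gate$zMin, "below", "gate"))
    state <- "idle"
    entry <- NA_integer_
    origin <- NA_character_
    for (t in seq_len(nf)) {
      if (state == "idle") {
        if (t > 1 && inCyl[t] && inCyl[t - 1]) {
          if (zone[t] == "gate" && zone[t - 1] != "gate") {
            state <- "traversing"
            origin <- zone[t - 1]
            entry <- t
          } else if (zone[t] != "gate" && zone[t - 1] != "gate" &&
                     zone[t] != zone[t - 1]) {
            # jumped clean across the gate between consecutive frames
            events[[length(events) + 1L]] <- data.frame(
              ionIndex = ion, entryFrame = t - 1L, exitFrame = t,
              direction = if (zone[t] == "below") "inward" else "outward",
              stringsAsFactors = FALSE)
          }
        }
      } else {
        if (!inCyl[t] || zone[t] == origin) {
          state <- "idle"
        } else if (zone[t] != "gate") {
          events[[length(events) + 1L]] <- data.frame(
            ionIndex = ion, entryFrame = entry, exitFrame = t,
            direction = if (zone[t] == "below") "inward" else "outward",
            stringsAsFactors = FALSE)
          state <- "idle"
        }
      }
    }
  }
  if (!length(events))
    return(data.frame(ionIndex = integer(0), entryFrame = integer(0),
                      exitFrame = integer(0), direction = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, events)
}
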