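#' Gait phase codes
#'
#' The four phases of the gait cycle and their integer labels: swing (SW, 5),
#' heel strike (HS, 4), full contact (FC, 3) and heel off (HO, 2; toe-off is
#' merged into heel-off, as it occupies only a sliver of the cycle).
#'
#' @return Named integer vector `c(SW = 5, HS = 4, FC = 3, HO = 2)`, in the
#'   reporting order used throughout the package.
#' @export
gait_phases <- function() c(SW = 5L, HS = 4L, FC = 3L, HO = 2L)

#' Map 3-channel insole contact states to gait phases
#'
#' The insole carries binary force-sensitive resistors at the toe, the
#' metatarsophalangeal joint and the heel. The pressure pattern determines the
#' phase: no contact is swing; heel-only contact is heel strike; heel plus any
#' forefoot contact is full contact; forefoot-only contact is heel off.
#' Anatomically odd combinations (heel and toe without metatarsal) count as
#' full contact. The mapping is total over all 8 states and surjective onto
#' the four phases.
#'
#' @param state a data.frame (or named list) with binary columns `toe`,
#'   `metatarsal`, `heel`; vectorised.
#' @return Integer phase labels (see [gait_phases()]).
#' @export
fsr_to_phase <- function(state) {
  toe <- as.integer(state$toe); met <- as.integer(state$metatarsal)
  heel <- as.integer(state$heel)
  if (anyNA(toe) || anyNA(met) || anyNA(heel) ||
      !all(c(toe, met, heel) %in% c(0L, 1L)))
    stop("contact states must be binary toe/metatarsal/heel", call. = FALSE)
  fore <- toe | met
  out <- ifelse(heel == 1L, ifelse(fore, 3L, 4L), ifelse(fore, 2L, 5L))
  as.integer(out)
}

#' Label a contact-state stream
#'
#' Elementwise [fsr_to_phase()] with an optional debounce: runs of identical
#' labels shorter than `min_run` are absorbed into the preceding run
#' (`min_run = 1` disables debouncing).
#'
#' @param states data.frame of binary `toe`/`metatarsal`/`heel` columns.
#' @param min_run minimum run length, samples (default 1 = off).
#' @return Integer phase labels, one per row.
#' @export
label_stream <- function(states, min_run = 1L) {
  if (NROW(states) == 0L) return(integer(0))
  labels <- fsr_to_phase(states)
  if (min_run > 1L) {
    r <- rle(labels)
    for (k in seq_along(r$lengths)) {
      if (r$lengths[k] < min_run && k > 1L) {
        r$values[k] <- r$values[k - 1L]
      }
    }
    labels <- inverse.rle(r)
    # merge newly adjacent equal runs
    labels <- inverse.rle(rle(labels))
  }
  labels
}
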