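#' Construct a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition Palindromic recognition sequence.
#' @param cutOffset Cut position in bp from the start of the recognition
#'   sequence.
#' @return A [RestrictionEnzyme-class] object.
#' @examples
#' restrictionEnzyme("DpnII", "GATC", 0)
#' @export
restrictionEnzyme <- function(name, recognition, cutOffset) {
  new("RestrictionEnzyme", name = name,
      recognition = toupper(recognition), cutOffset = as.integer(cutOffset))
}

#' Default 4C restriction enzymes
#'
#' `DpnII` (GATC, cut offset 0) is the primary enzyme and `Csp6I`
#' (GTAC, cut offset 1) the secondary 4 bp-cutter of the 4C protocol.
#'
#' @return A [RestrictionEnzyme-class] object.
#' @export
DpnII <- function() restrictionEnzyme("DpnII", "GATC", 0L)

#' @rdname DpnII
#' @export
Csp6I <- function() restrictionEnzyme("Csp6I", "GTAC", 1L)
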