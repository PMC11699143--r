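#' Construct a LengthGroupScheme
#'
#' Boundaries `b_1 < ... < b_{K+1}` define K half-open fragment-length groups
#' `[b_k, b_{k+1})`. A fragment of length L belongs to group k iff
#' `b_k <= L < b_{k+1}`; lengths outside `[b_1, b_{K+1})` are "ungrouped".
#' The half-open convention makes the groups a partition: a 140 bp fragment
#' with boundaries c(50, 140, 250) falls in the upper (140-250) group, so
#' that NRS's "a" counts fragments at or above the break point.
#'
#' @param boundaries strictly increasing bp values, length >= 2, first >= 1.
#' @return a [LengthGroupScheme-class].
#' @examples
#' LengthGroupScheme(c(50, 140, 250))
#' defaultLengthGroups()
#' @export
LengthGroupScheme <- function(boundaries)
  new("LengthGroupScheme", boundaries = as.numeric(boundaries))

#' @describeIn LengthGroupScheme the standard ten-group scheme
#'   (50-80, 80-90, ..., 150-160, 160-250 bp), whose boundaries include every
#'   usual break point (80-160 bp in 10 bp steps).
#' @export
defaultLengthGroups <- function()
  LengthGroupScheme(c(50, 80, 90, 100, 110, 120, 130, 140, 150, 160, 250))

#' @rdname LengthGroupScheme-class
#' @export
setMethod("boundaries", "LengthGroupScheme", function(x) x@boundaries)

.nGroups <- function(scheme) length(scheme@boundaries) - 1L

.groupLabels <- function(scheme) {
  b <- scheme@boundaries
  paste0("len", b[-length(b)], "_", b[-1L])
}

setMethod("show", "LengthGroupScheme", function(object) {
  b <- object@boundaries
  cat("LengthGroupScheme:", .nGroups(object), "half-open groups over [",
      b[1L], ",", b[length(b)], ") bp\n")
})
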