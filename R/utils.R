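#' @useDynLib tomatovision, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# condition helpers: distinct classes so callers (and the CLI) can map
# failures to exit codes
tvStop <- function(class, ...) {
  stop(structure(class = c(class, "tvError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stopParameter <- function(...) tvStop("tvParameterError", ...)
stopShape     <- function(...) tvStop("tvShapeError", ...)
stopIO        <- function(...) tvStop("tvIOError", ...)
stopData      <- function(...) tvStop("tvDataError", ...)
stopEmpty     <- function(...) tvStop("tvEmptyRegionError", ...)
stopState     <- function(...) tvStop("tvStateError", ...)

#' Disease archetypes rendered by the generator and recognised by the
#' disease classifier
#'
#' @return character vector of the five archetype labels.
#' @export
diseaseArchetypes <- function() {
  c("early_blight", "late_blight", "bacterial_canker", "gray_mold",
    "bacterial_speck")
}

#' Maturity grades
#'
#' `extended = FALSE` gives the three-level grade used by the decision
#' layer (`u` unripe, `m` medium, `r` ripe); `extended = TRUE` gives the
#' four-stage scheme (unripe, ripen, fully_ripen, rotten).
#'
#' @param extended logical.
#' @return character vector of grade labels.
#' @export
maturityLevels <- function(extended = FALSE) {
  if (extended) c("unripe", "ripen", "fully_ripen", "rotten")
  else c("u", "m", "r")
}

# maturity in [0,1] -> categorical grade (generator ground truth and
# report vocabulary share these break points)
maturityToLabel <- function(maturity, extended = FALSE) {
  if (extended) {
    cuts <- c(-Inf, 0.25, 0.5, 0.75, Inf)
    maturityLevels(TRUE)[findInterval(maturity, cuts, left.open = TRUE)]
  } else {
    cuts <- c(-Inf, 1 / 3, 2 / 3, Inf)
    maturityLevels(FALSE)[findInterval(maturity, cuts, left.open = TRUE)]
  }
}

# run expr with a private RNG stream; restores the caller's stream
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Rec. 601 luma; input h x w x 3 in [0,255], output matrix in [0,255]
rgbToGray <- function(image) {
  assertRgb(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

assertRgb <- function(image, arg = "image") {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stopShape(arg, " must be a height x width x 3 array")
  r <- range(image)
  if (r[1] < 0 || r[2] > 255)
    stopParameter(arg, " intensities must lie in [0, 255]")
  invisible(image)
}

assertGray <- function(image, arg = "image") {
  if (!is.matrix(image))
    stopShape(arg, " must be a height x width matrix")
  r <- range(image)
  if (r[1] < 0 || r[2] > 255)
    stopParameter(arg, " intensities must lie in [0, 255]")
  invisible(image)
}

# tolerant binary coercion: logical matrix from 0/1, 0/255 or logical
asBinaryMatrix <- function(image, arg = "image") {
  if (is.logical(image)) {
    if (!is.matrix(image)) stopShape(arg, " must be a matrix")
    return(image)
  }
  if (!is.matrix(image)) stopShape(arg, " must be a matrix")
  u <- unique(as.vector(image))
  if (!all(u %in% c(0, 1)) && !all(u %in% c(0, 255)))
    stopParameter(arg, " must be binary ({0,1}, {0,255} or logical)")
  image > 0
}

# FNV-1a 32-bit over a character scalar; returned as 8-hex-digit string.
# Used for config digests in reports (stable across platforms).
fnv1a32 <- function(text) {
  bytes <- as.integer(charToRaw(paste(text, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches the low byte only (b < 256); keep h as a double
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by 16777619, split to avoid overflow
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
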