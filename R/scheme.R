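#' Build a multi-shell acquisition scheme
#'
#' Constructs the gradient table of a multi-shell acquisition: one b = 0
#' volume followed by `nDirs` directions for every nonzero shell. Directions
#' come from a Fibonacci spiral polished by a fixed number of deterministic
#' electrostatic-repulsion iterations ([repulsionDirections()]), so a given
#' `(nDirs, shells)` pair always yields the same well-spread scheme. The reference clinical protocol uses
#' `makeScheme(60, c(0, 1000, 2500))`: 121 volumes.
#'
#' @param nDirs Directions per nonzero shell (>= 6).
#' @param shells b-factors in s/mm^2; must contain 0 and at least two
#'   distinct positive values (the kurtosis term is not identifiable from a
#'   single shell).
#' @return An [AcquisitionScheme-class] object.
#' @examples
#' s <- makeScheme(60, c(0, 1000, 2500))
#' nVolumes(s)  # 121
#' @export
makeScheme <- function(nDirs = 60L, shells = c(0, 1000, 2500)) {
  shells <- sort(unique(shells))
  nz <- shells[shells > 0]
  if (any(shells < 0)) stop("invalid b-factor")
  if (length(nz) < 2L) stop("insufficient shells for kurtosis")
  if (nDirs < 6L) stop("under-determined: need at least 6 directions per shell")
  dirs <- t(repulsionDirections(nDirs))
  bv <- c(0, rep(nz, each = nDirs))
  gv <- cbind(matrix(0, 3, 1), dirs[, rep(seq_len(nDirs), length(nz))])
  new("AcquisitionScheme", bvalues = bv, bvectors = gv)
}

#' Read and write FSL-style b-value / b-vector tables
#'
#' `readBvalBvec()` parses a `.bval` file (one whitespace-separated row of
#' b-factors) and a `.bvec` file (three rows: x, y, z components per
#' volume) into an [AcquisitionScheme-class]. Directions on nonzero shells
#' are renormalised to unit length; deviations above `1e-3` trigger a
#' warning, a zero vector on a nonzero shell is an error.
#' `writeBvalBvec()` writes the exact inverse, so a read/write round trip
#' is lossless to full printed precision.
#'
#' @param bvalPath,bvecPath File paths.
#' @param scheme An [AcquisitionScheme-class] object.
#' @return `readBvalBvec()` returns an [AcquisitionScheme-class];
#'   `writeBvalBvec()` returns the two paths invisibly.
#' @export
readBvalBvec <- function(bvalPath, bvecPath) {
  parseRow <- function(path, row, txt) {
    toks <- strsplit(trimws(txt), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop(sprintf("non-numeric token in %s, line %d: '%s'",
                   path, row, toks[which(is.na(vals))[1]]))
    vals
  }
  blines <- readLines(bvalPath, warn = FALSE)
  blines <- blines[nzchar(trimws(blines))]
  bvals <- parseRow(bvalPath, 1L, paste(blines, collapse = " "))
  glines <- readLines(bvecPath, warn = FALSE)
  glines <- glines[nzchar(trimws(glines))]
  if (length(glines) != 3L)
    stop(sprintf("%s must have exactly 3 rows (x, y, z)", bvecPath))
  gmat <- do.call(rbind, lapply(seq_len(3L), function(r)
    parseRow(bvecPath, r, glines[r])))
  if (ncol(gmat) != length(bvals))
    stop("bval/bvec mismatch: ", length(bvals), " b-values vs ",
         ncol(gmat), " directions")
  nz <- bvals > 0
  norms <- sqrt(colSums(gmat^2))
  if (any(nz & norms < 1e-12))
    stop("zero direction on nonzero shell (volume ",
         which(nz & norms < 1e-12)[1], ")")
  dev <- abs(norms[nz] - 1)
  if (any(dev > 1e-3))
    warning(sprintf("%d gradient direction(s) deviate from unit norm by up to %.2g; renormalised",
                    sum(dev > 1e-3), max(dev)))
  gmat[, nz] <- sweep(gmat[, nz, drop = FALSE], 2L, norms[nz], "/")
  new("AcquisitionScheme", bvalues = bvals, bvectors = gmat)
}

#' @rdname readBvalBvec
#' @export
writeBvalBvec <- function(scheme, bvalPath, bvecPath) {
  fmt <- function(x) paste(format(x, digits = 17, scientific = FALSE,
                                  trim = TRUE), collapse = " ")
  writeLines(fmt(scheme@bvalues), bvalPath)
  writeLines(vapply(1:3, function(r) fmt(scheme@bvectors[r, ]),
                    character(1)), bvecPath)
  invisible(c(bvalPath, bvecPath))
}
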