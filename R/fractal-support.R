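#' Construct a generator mask
#'
#' Builds the [GeneratorMask-class] of a generalized Sierpinski carpet from a
#' logical grid. `TRUE` (or 1) marks an accessible cell. At most half of the
#' `nu^dim` cells may be deleted.
#'
#' @param allowed logical/0-1 matrix (`dim = 2`) or 3-d array (`dim = 3`) of
#'   equal extents `nu` in every dimension. The first array index is the
#'   0-based x-coordinate plus one, the second y, the third z.
#' @return a validated [GeneratorMask-class].
#' @examples
#' generatorMask(standardCarpetMask())
#' @export
generatorMask <- function(allowed) {
  allowed <- as.array(allowed)
  d <- dim(allowed)
  if (is.null(d) || !length(d) %in% c(2L, 3L) || length(unique(d)) != 1L)
    stop("allowed must be a square matrix or cubic array")
  storage.mode(allowed) <- "logical"
  new("GeneratorMask", nu = as.integer(d[1]), dim = as.integer(length(d)),
      allowed = allowed)
}

#' The standard 3x3 Sierpinski carpet generator (center cell deleted)
#'
#' @return a 3x3 logical matrix usable with [generatorMask()].
#' @export
standardCarpetMask <- function() {
  m <- matrix(TRUE, 3, 3)
  m[2, 2] <- FALSE
  m
}

#' A fully allowed generator (free lattice embedded as a trivial carpet)
#'
#' @param nu base, integer >= 2.
#' @param dim 2 or 3.
#' @return a logical array of `TRUE`.
#' @export
fullMask <- function(nu = 3L, dim = 2L) {
  array(TRUE, dim = rep(as.integer(nu), as.integer(dim)))
}

#' Construct a fractal support
#'
#' Wraps a generator mask and an iteration depth into a virtual GSC support.
#' No lattice is materialized; accessibility is computed on demand by
#' renormalization (see [isAccessible()]).
#'
#' @param mask a [GeneratorMask-class], or a logical grid accepted by
#'   [generatorMask()].
#' @param kmax iteration depth (stage), integer >= 1.
#' @return a [FractalSupport-class].
#' @examples
#' fractalSupport(standardCarpetMask(), kmax = 6)
#' @export
fractalSupport <- function(mask, kmax = 1L) {
  if (!is(mask, "GeneratorMask")) mask <- generatorMask(mask)
  new("FractalSupport", generator = mask, kmax = as.integer(kmax))
}

#' Iteration stage of a lattice point
#'
#' The smallest stage `k >= 1` such that every 0-based coordinate is below
#' `nu^k`; equivalently, the stage whose coarse-grained pattern first
#' contains the point (a point with its largest coordinate between
#' `nu^(k-1)` and `nu^k` belongs to stage `k`).
#'
#' @param point integer vector of 0-based coordinates (or a matrix, one
#'   point per row).
#' @param nu carpet base.
#' @return integer stage(s).
#' @examples
#' stageOf(c(8, 2), 3)   # 2
#' stageOf(c(27, 0, 0), 3)  # 4
#' @export
stageOf <- function(point, nu) {
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  if (any(pts != floor(pts)) || any(pts < 0))
    stop("coordinates must be non-negative integers")
  mx <- apply(pts, 1, max)
  k <- pmax(1L, as.integer(ceiling(log(mx + 1) / log(nu) - 1e-12)))
  # guard against log rounding at exact powers of nu
  while (any(bad <- mx >= nu^k)) k[bad] <- k[bad] + 1L
  while (any(bad <- k > 1L & mx < nu^(k - 1L))) k[bad] <- k[bad] - 1L
  k
}

#' Is a lattice site accessible on a fractal support?
#'
#' Implements stage-wise coarse graining: starting from the point's stage,
#' the coarse cell (integer part of each coordinate over `nu^(k-1)`) is
#' looked up in the generator; if deleted, the site is blocked. Otherwise the
#' coordinates are reduced modulo `nu^(k-1)` and the check proceeds one stage
#' down; sites surviving to stage 1 are accessible.
#'
#' @param point integer vector of 0-based coordinates, or a matrix with one
#'   point per row.
#' @param support a [FractalSupport-class].
#' @return logical vector, one value per point.
#' @examples
#' supp <- fractalSupport(standardCarpetMask(), kmax = 2)
#' isAccessible(c(4, 4), supp)  # FALSE: coarse cell is the deleted center
#' @export
isAccessible <- function(point, support) {
  stopifnot(is(support, "FractalSupport"))
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  gen <- support@generator
  if (ncol(pts) != gen@dim)
    stop("point dimension does not match the support")
  if (any(pts != floor(pts)) || any(pts < 0) ||
      any(pts >= gen@nu^support@kmax))
    stop("point out of the support bounds [0, nu^kmax)")
  storage.mode(pts) <- "integer"
  cpp_is_accessible(pts, as.logical(gen@allowed), gen@nu, gen@dim,
                    support@kmax)
}

# Pure-R recursive reference of the renormalization rule; used as the
# independent oracle in tests, never called by the walkers.
accessibleRecursive <- function(point, mask, nu, k) {
  if (k == 0L) return(TRUE)
  coarse <- point %/% nu^(k - 1L)
  if (!mask[matrix(coarse + 1L, nrow = 1)]) return(FALSE)
  accessibleRecursive(point %% nu^(k - 1L), mask, nu, k - 1L)
}

#' Count accessible sites by exhaustive enumeration
#'
#' Brute-force enumeration of the stage-`k` bounding box. For a GSC this
#' count equals `allowedCells(mask)^k` (self-similarity); the function
#' exists as an oracle for the on-demand accessibility rule and refuses
#' boxes that are too large to enumerate.
#'
#' @param support a [FractalSupport-class].
#' @param k stage to enumerate, `1 <= k <= stageDepth(support)`.
#' @param maxSites refuse enumeration beyond this many candidate sites.
#' @return integer count of accessible sites in `[0, nu^k)^dim`.
#' @examples
#' enumerateAccessible(fractalSupport(standardCarpetMask(), 2), 2)  # 64
#' @export
enumerateAccessible <- function(support, k, maxSites = 1e7) {
  stopifnot(is(support, "FractalSupport"), k >= 1, k <= support@kmax)
  nu <- generatorBase(support)
  d <- spaceDim(support)
  n <- as.numeric(nu)^(k * d)
  if (n > maxSites)
    stop(sprintf("enumeration of %.3g sites exceeds maxSites = %.3g", n,
                 maxSites))
  side <- nu^k
  coords <- as.matrix(do.call(expand.grid, rep(list(0:(side - 1L)), d)))
  storage.mode(coords) <- "integer"
  sum(cpp_is_accessible(coords, as.logical(support@generator@allowed),
                        nu, d, support@kmax))
}

#' Read / write a generator mask as plain text
#'
#' Text format: one generator row per line, characters `0` (deleted) and `1`
#' (allowed). For `dim = 3`, the `nu` z-slices are separated by blank lines.
#' Row `i` of a slice holds cells with y-coordinate `i - 1`, column `j` the
#' x-coordinate `j - 1`.
#'
#' @param path file path.
#' @return `readGeneratorMask` returns a [GeneratorMask-class];
#'   `writeGeneratorMask` returns `path` invisibly.
#' @export
readGeneratorMask <- function(path) {
  lines <- trimws(readLines(path))
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[vapply(blocks, length, 1L) > 0]
  parseBlock <- function(b) {
    rows <- lapply(strsplit(b, ""), function(ch) {
      if (!all(ch %in% c("0", "1"))) stop("mask rows must be 0/1 strings")
      ch == "1"
    })
    # row i is y = i-1, column j is x = j-1 -> transpose into [x, y]
    t(do.call(rbind, rows))
  }
  slices <- lapply(blocks, parseBlock)
  nu <- nrow(slices[[1]])
  if (length(slices) == 1L) {
    generatorMask(slices[[1]])
  } else {
    if (length(slices) != nu)
      stop("a dim = 3 mask needs exactly nu slices of nu lines")
    arr <- array(FALSE, dim = c(nu, nu, nu))
    for (z in seq_len(nu)) arr[, , z] <- slices[[z]]
    generatorMask(arr)
  }
}

#' @rdname readGeneratorMask
#' @param mask a [GeneratorMask-class].
#' @export
writeGeneratorMask <- function(mask, path) {
  stopifnot(is(mask, "GeneratorMask"))
  fmtSlice <- function(sl)
    apply(sl, 2, function(col) paste(as.integer(col), collapse = ""))
  lines <- if (mask@dim == 2L) {
    fmtSlice(mask@allowed)
  } else {
    unlist(lapply(seq_len(mask@nu), function(z)
      c(fmtSlice(mask@allowed[, , z]), "")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a support configuration file
#'
#' JSON or YAML file with fields `mask` (path to a text mask, resolved
#' relative to the config file), `kmax`, and optionally `dim` and `nu`
#' (cross-checked against the mask file when present).
#'
#' @param path path to a `.json`, `.yaml` or `.yml` config file.
#' @return a [FractalSupport-class].
#' @export
readSupportConfig <- function(path) {
  cfg <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$mask) || is.null(cfg$kmax))
    stop("support config must name 'mask' and 'kmax'")
  maskPath <- cfg$mask
  if (!file.exists(maskPath))
    maskPath <- file.path(dirname(path), cfg$mask)
  mask <- readGeneratorMask(maskPath)
  if (!is.null(cfg$nu) && cfg$nu != mask@nu)
    stop("config nu does not match the mask file")
  if (!is.null(cfg$dim) && cfg$dim != mask@dim)
    stop("config dim does not match the mask file")
  fractalSupport(mask, kmax = cfg$kmax)
}
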