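#' Write a trajectory to CSV with a JSON sidecar
#'
#' The CSV has header `t,x,y[,z]`, one row per event; the sidecar
#' `<path>.json` stores kind, gamma, seed, ell0, rmax and, when present,
#' the support generator (as 0/1 rows) so the trajectory can be validated
#' on reading.
#'
#' @param traj a [Trajectory-class].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  d <- spaceDim(traj)
  df <- data.frame(t = traj@times, x = traj@positions[, 1],
                   y = traj@positions[, 2])
  if (d == 3L) df$z <- traj@positions[, 3]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(kind = traj@kind, gamma = traj@gamma,
               seed = if (is.na(traj@seed)) NULL else traj@seed,
               ell0 = traj@ell0,
               rmax = if (is.finite(traj@rmax)) traj@rmax else NULL,
               dim = d)
  if (!is.null(traj@support)) {
    gen <- traj@support@generator
    meta$support <- list(nu = gen@nu, dim = gen@dim,
                         kmax = traj@support@kmax,
                         allowed = as.integer(gen@allowed))
  }
  meta <- Filter(Negate(is.null), meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

.rebuildSupport <- function(s) {
  arr <- array(as.logical(s$allowed), dim = rep(s$nu, s$dim))
  fractalSupport(generatorMask(arr), kmax = s$kmax)
}

#' Read trajectories from CSV files
#'
#' Accepts a single CSV path or a directory of `*.csv` files written by
#' [writeTrajectory()]. Each file is validated: monotone increasing times
#' starting at 0, unit (or zero) steps between consecutive events, and the
#' dimension inferred from the columns must match the sidecar.
#'
#' @param path CSV file or directory.
#' @return list of [Trajectory-class] objects.
#' @export
readTrajectories <- function(path) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  else path
  if (length(files) == 0) stop("no trajectory CSV files found")
  lapply(files, .readOneTrajectory)
}

.readOneTrajectory <- function(file) {
  df <- utils::read.csv(file)
  cols <- names(df)
  if (!identical(cols[1], "t") || !all(c("x", "y") %in% cols))
    stop(sprintf("%s: malformed header (expected t,x,y[,z])", file))
  d <- if ("z" %in% cols) 3L else 2L
  bad <- which(diff(df$t) <= 0)
  if (length(bad))
    stop(sprintf("%s: non-monotone time at row %d", file, bad[1] + 1L))
  if (df$t[1] != 0) stop(sprintf("%s: times must start at 0", file))
  P <- as.matrix(df[, c("x", "y", if (d == 3L) "z")])
  meta <- list(kind = "ctrw", gamma = 1, seed = NULL, ell0 = 1,
               rmax = NULL, dim = d, support = NULL)
  side <- paste0(file, ".json")
  if (file.exists(side)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(side,
                                                        simplifyVector = TRUE))
    if (!is.null(meta$dim) && meta$dim != d)
      stop(sprintf("%s: sidecar dim %d does not match columns (%d)",
                   file, meta$dim, d))
  }
  steps <- abs(diff(P))
  badStep <- which(rowSums(steps) > 1L)
  if (length(badStep))
    stop(sprintf("%s: non-unit step at row %d", file, badStep[1] + 1L))
  support <- if (!is.null(meta$support)) .rebuildSupport(meta$support)
  newTrajectory(df$t, P, meta$kind, gamma = meta$gamma, support = support,
                seed = meta$seed, ell0 = meta$ell0,
                rmax = meta$rmax %||% Inf)
}

#' Write an MSD curve or a scaling fit report
#'
#' @param curve an [MSDCurve-class].
#' @param path output path (CSV for curves, JSON for fits).
#' @return `path`, invisibly.
#' @export
writeMSDCurve <- function(curve, path) {
  utils::write.csv(data.frame(t = msdTimes(curve), msd = msdValues(curve),
                              n_tracks = curve@nTracks),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMSDCurve
#' @param fit a [ScalingFit-class].
#' @export
writeFitReport <- function(fit, path) {
  jsonlite::write_json(list(exponent = fit@exponent,
                            prefactor = fit@prefactor,
                            window = fit@window, r2 = fit@r2),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate deterministic synthetic fixtures
#'
#' Seeded, versioned synthetic inputs used by tests and examples:
#' \describe{
#'   \item{`ideal_powerlaw_family`}{a [TrackFamily-class]; params `gmin`,
#'     `gmax`, `lmax`, optional `grid`, `prefactor`.}
#'   \item{`ctrw_tracks`}{a list of CTRW trajectories on the free lattice;
#'     params `gamma`, `T`, `nTracks`, optional `dim`.}
#'   \item{`fcs_curve`}{a noiseless correlation curve; params `N`, `tauD`,
#'     `gamma`, optional `s`, `dim`, `lags`, `noise` (multiplicative sd).}
#'   \item{`carpet_mask`}{the standard 3x3 carpet [GeneratorMask-class].}
#' }
#'
#' @param kind fixture kind (see above).
#' @param params named list of parameters.
#' @param seed integer seed (every stochastic fixture requires one).
#' @return the fixture object.
#' @export
makeFixtures <- function(kind, params = list(), seed = 1L) {
  switch(kind,
    ideal_powerlaw_family = buildFamily(
      params$gmin, params$gmax, params$lmax,
      grid = params$grid %||% subpopGrid(),
      prefactor = params$prefactor %||% "gamma"),
    ctrw_tracks = {
      model <- waitingTimeModel(params$gamma)
      set.seed(seed)
      lapply(seq_len(params$nTracks), function(i)
        ctrwWalk(NULL, model, T = params$T, dim = params$dim %||% 3L))
    },
    fcs_curve = {
      p <- fcsParams(params$N, params$tauD, params$gamma,
                     s = params$s %||% 5, dim = params$dim %||% 3L)
      lags <- params$lags %||% logSpacedGrid(params$tauD / 1e3,
                                             params$tauD * 1e3, 10)
      G <- correlationModel(lags, p)
      if (!is.null(params$noise) && params$noise > 0) {
        set.seed(seed)
        G <- 1 + (G - 1) * exp(stats::rnorm(length(G), 0, params$noise))
      }
      data.frame(tau = lags, G = G)
    },
    carpet_mask = generatorMask(standardCarpetMask()),
    stop(sprintf("unknown fixture kind '%s'", kind))
  )
}
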