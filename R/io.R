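#' Read a plain-text reflection (hkl) file
#'
#' Whitespace-delimited text: comment/header lines start with `#`; a
#' `# cell a b c alpha beta gamma` header is mandatory and an optional
#' `# grid Na Nb Nc` header overrides the default 32^3 voxel grid.  Data
#' lines carry `h k l amplitude` and optionally a fifth `phase` column in
#' radians.  Parse errors report the offending line number.
#'
#' @param path file path.
#' @return a [reflection_set()] (phased if the file has a phase column).
#' @export
read_hkl <- function(path) {
  lines <- readLines(path)
  cell <- NULL
  grid <- c(32L, 32L, 32L)
  rows <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "") next
    if (startsWith(s, "#")) {
      tok <- strsplit(trimws(sub("^#", "", s)), "[[:space:]]+")[[1]]
      if (length(tok) >= 1 && tok[1] == "cell") {
        v <- suppressWarnings(as.numeric(tok[-1]))
        if (length(v) != 6 || anyNA(v))
          stop(sprintf("line %d: '# cell' needs a b c alpha beta gamma", ln))
        cell <- v
      } else if (length(tok) >= 1 && tok[1] == "grid") {
        v <- suppressWarnings(as.integer(tok[-1]))
        if (length(v) != 3 || anyNA(v))
          stop(sprintf("line %d: '# grid' needs three integers", ln))
        grid <- v
      }
      next
    }
    v <- suppressWarnings(as.numeric(strsplit(s, "[[:space:]]+")[[1]]))
    if (anyNA(v) || !(length(v) %in% c(4, 5)))
      stop(sprintf("line %d: expected 'h k l amplitude [phase]'", ln))
    rows[[length(rows) + 1]] <- v
  }
  if (is.null(cell)) stop("missing '# cell' header")
  if (length(rows) == 0) stop("no reflection records")
  ncol_seen <- unique(lengths(rows))
  if (length(ncol_seen) != 1)
    stop("mixed record lengths: phase column must be present on all rows or none")
  m <- do.call(rbind, rows)
  uc <- unit_cell(cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
                  grid = grid)
  hkl <- m[, 1:3, drop = FALSE]
  if (any(hkl != round(hkl))) {
    bad <- which(rowSums(hkl != round(hkl)) > 0)[1]
    stop(sprintf("non-integer Miller indices in record %d", bad))
  }
  reflection_set(uc, hkl, m[, 4],
                 phase = if (ncol_seen == 5) m[, 5] else NULL)
}

#' Write a reflection set as a plain-text hkl file
#'
#' @param refl a [reflection_set()].
#' @param path output path.
#' @param include_phases write the phase column (requires phases; default
#'   writes them whenever present).
#' @return `path`, invisibly.
#' @export
write_hkl <- function(refl, path, include_phases = !is.null(refl$phase)) {
  stopifnot(inherits(refl, "reflection_set"))
  if (include_phases && is.null(refl$phase))
    stop("reflection set has no phases to write")
  cell <- refl$cell
  hdr <- c("# tpmsflip reflection list",
           sprintf("# cell %.9g %.9g %.9g %.9g %.9g %.9g",
                   cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma),
           sprintf("# grid %d %d %d", cell$grid[1], cell$grid[2],
                   cell$grid[3]),
           if (include_phases) "# columns: h k l amplitude phase_rad"
           else "# columns: h k l amplitude")
  body <- if (include_phases) {
    sprintf("%d %d %d %.9g %.9g", refl$hkl[, 1], refl$hkl[, 2],
            refl$hkl[, 3], refl$amplitude, refl$phase)
  } else {
    sprintf("%d %d %d %.9g", refl$hkl[, 1], refl$hkl[, 2], refl$hkl[, 3],
            refl$amplitude)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a density grid as a CCP4/MRC map
#'
#' Binary mode-2 (32-bit float) CCP4 map, x fastest, origin at the cell
#' origin, cell constants recorded in ångström per the format convention
#' (this package works in nm; the factor of 10 is applied on write and
#' undone on read).  Orthogonal and hexagonal (gamma = 120) cells only.
#'
#' @param grid a [density_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  cell <- grid$cell
  ortho <- all(c(cell$alpha, cell$beta, cell$gamma) == 90)
  hexa <- cell$alpha == 90 && cell$beta == 90 && cell$gamma == 120
  if (!ortho && !hexa)
    stop("only orthogonal or hexagonal (gamma = 120) cells can be written")
  v <- as.vector(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(cell$grid)                              # NC NR NS
  wi(2L)                                     # MODE 2: float32
  wi(c(0L, 0L, 0L))                          # start indices
  wi(cell$grid)                              # sampling NX NY NZ
  wf(c(cell$a, cell$b, cell$c) * 10)         # cell (angstrom)
  wf(c(cell$alpha, cell$beta, cell$gamma))
  wi(c(1L, 2L, 3L))                          # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))             # AMIN AMAX AMEAN
  wi(1L)                                     # ISPG
  wi(0L)                                     # NSYMBT
  wi(rep(0L, 28))                            # words 25-52 unused
  writeBin(charToRaw("MAP "), con)           # word 53
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # machine stamp (LE)
  wf(stats::sd(v))                           # RMS
  wi(0L)                                     # NLABL
  writeBin(raw(800), con)                    # labels
  wf(v)                                      # data, x fastest
  invisible(path)
}

#' Read a CCP4/MRC map as a density grid
#'
#' @param path map file written by [write_map()] or any mode-2 CCP4 map
#'   with axis order x, y, z and zero start indices.
#' @param grid optional voxel-grid override for the returned [unit_cell()];
#'   defaults to the map sampling.
#' @return a [density_grid()] (cell constants converted to nm).
#' @export
read_map <- function(path, grid = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("only mode-2 (float32) maps are supported")
  start <- ri(3)
  if (any(start != 0L)) stop("nonzero start indices are not supported")
  samp <- ri(3)
  cella <- rf(3)
  angles <- rf(3)
  maporder <- ri(3)
  if (any(maporder != 1:3)) stop("axis order must be x, y, z")
  invisible(rf(3)); invisible(ri(1)); nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  v <- rf(prod(dims))
  uc <- unit_cell(cella[1] / 10, cella[2] / 10, cella[3] / 10,
                  angles[1], angles[2], angles[3],
                  grid = if (is.null(grid)) dims else grid)
  density_grid(uc, array(v, dim = dims))
}

#' Write a retrieval trace as CSV
#'
#' One row per iteration with `iteration`, `i_rho`, `k_f`, `k_t` — the
#' data behind convergence plots.
#'
#' @param fit a `"charge_flip"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(fit, path) {
  stopifnot(inherits(fit, "charge_flip"))
  utils::write.csv(fit$trace, path, row.names = FALSE)
  invisible(path)
}
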