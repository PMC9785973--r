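#' Construct a trajectory
#'
#' A trajectory stores uniformly sampled frames of positions and (for
#' spectral work) velocities in an orthorhombic periodic box. Internal
#' units are Angstrom and femtoseconds regardless of the source format.
#'
#' @param times Frame times in fs, uniformly spaced (constant spacing to
#'   a relative 1e-6).
#' @param positions Numeric array `n_atoms x 3 x n_frames`, Angstrom.
#' @param velocities Numeric array `n_atoms x 3 x n_frames`, Angstrom/fs,
#'   or `NULL` for geometry-only data (rejected by spectral operations).
#' @param box Box edge lengths: length-3 vector (constant box) or
#'   `n_frames x 3` matrix, Angstrom.
#' @param atom_ids Integer atom ids matching a topology; defaults to
#'   `1:n_atoms`.
#' @return An object of class `hydro_trajectory`.
#' @export
trajectory <- function(times, positions, velocities = NULL, box, atom_ids = NULL) {
  if (length(dim(positions)) != 3 || dim(positions)[2] != 3) {
    abort("positions must be an n_atoms x 3 x n_frames array")
  }
  n_atoms <- dim(positions)[1]
  n_frames <- dim(positions)[3]
  if (length(times) != n_frames) abort("length(times) must equal n_frames")
  check_uniform_times(times)
  if (!all(is.finite(positions))) abort("positions must be finite")
  if (!is.null(velocities)) {
    if (!identical(dim(velocities), dim(positions))) {
      abort("velocities must have the same dimensions as positions")
    }
    if (!all(is.finite(velocities))) abort("velocities must be finite")
  }
  if (is.matrix(box)) {
    if (ncol(box) != 3 || nrow(box) != n_frames) {
      abort("box matrix must be n_frames x 3")
    }
  } else {
    if (length(box) != 3) abort("box must be a length-3 vector or n_frames x 3 matrix")
    box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  }
  if (any(box <= 0)) abort("box lengths must be positive")
  if (is.null(atom_ids)) atom_ids <- seq_len(n_atoms)
  structure(
    list(
      times = as.numeric(times),
      positions = positions,
      velocities = velocities,
      box = box,
      atom_ids = as.integer(atom_ids)
    ),
    class = "hydro_trajectory"
  )
}

check_uniform_times <- function(times) {
  if (length(times) < 2) return(invisible(times))
  dt <- diff(times)
  ref <- dt[1]
  if (ref <= 0) abort("frame times must be strictly increasing")
  off <- which(abs(dt - ref) > 1e-6 * abs(ref))
  if (length(off) > 0) {
    abort(paste0(
      "non-uniform sampling: interval before frame ", off[1] + 1,
      " is ", format(dt[off[1]]), " fs, expected ", format(ref), " fs"
    ))
  }
  invisible(times)
}

#' @export
print.hydro_trajectory <- function(x, ...) {
  cat("<hydro_trajectory>\n")
  cat("  atoms:     ", n_atoms(x), "\n")
  cat("  frames:    ", n_frames(x), "\n")
  cat("  dt:        ", format(frame_dt(x)), "fs\n")
  cat("  span:      ", format(diff(range(x$times))), "fs\n")
  cat("  box[1,]:   ", paste(format(x$box[1, ]), collapse = " x "), "A\n")
  cat("  velocities:", if (is.null(x$velocities)) "absent" else "present", "\n")
  invisible(x)
}

#' Trajectory accessors
#'
#' @param traj A `hydro_trajectory`.
#' @return `n_atoms()` and `n_frames()` return counts; `frame_dt()` the
#'   sampling interval in fs (0 for a single frame).
#' @export
n_atoms <- function(traj) dim(traj$positions)[1]

#' @rdname n_atoms
#' @export
n_frames <- function(traj) dim(traj$positions)[3]

#' @rdname n_atoms
#' @export
frame_dt <- function(traj) {
  if (n_frames(traj) < 2) return(0)
  traj$times[2] - traj$times[1]
}

require_velocities <- function(traj, what = "this operation") {
  if (is.null(traj$velocities)) {
    abort(paste0("no velocities: trajectory is position-only, but ", what,
                 " requires stored velocities"))
  }
  invisible(traj)
}

# rows of traj arrays for the given atom ids
atom_rows <- function(traj, atom_ids) {
  idx <- match(atom_ids, traj$atom_ids)
  if (anyNA(idx)) {
    abort(paste0("atom id(s) not in trajectory: ",
                 paste(atom_ids[is.na(idx)][seq_len(min(5, sum(is.na(idx))))],
                       collapse = ", ")))
  }
  idx
}

# subset frames by absolute time window [start_fs, end_fs] (inclusive)
frame_window <- function(traj, start_fs, end_fs) {
  sel <- which(traj$times >= start_fs - 1e-9 & traj$times <= end_fs + 1e-9)
  if (length(sel) == 0) abort("no frames in the requested time window")
  sel
}

subset_frames <- function(traj, frames) {
  trajectory(
    times = traj$times[frames],
    positions = traj$positions[, , frames, drop = FALSE],
    velocities = if (is.null(traj$velocities)) NULL else
      traj$velocities[, , frames, drop = FALSE],
    box = traj$box[frames, , drop = FALSE],
    atom_ids = traj$atom_ids
  )
}

#' Read a trajectory file
#'
#' Supported formats: GROMACS TRR (binary, nm/ps; converted to A/fs on
#' read), a series of GRO frames with velocity columns in a single file,
#' and the package's own self-describing columnar text fixture format
#' (see [write_fixture_trajectory()]). `format = "auto"` guesses from
#' the file extension and content.
#'
#' Spectral operations need velocities; TRR frames without a velocity
#' block, or GRO files without velocity columns, are rejected with a
#' "no velocities" error unless `require_velocities = FALSE`.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"trr"`, `"gro_series"`, `"fixture"`.
#' @param require_velocities Reject velocity-free inputs (default TRUE).
#' @return A `hydro_trajectory`.
#' @export
read_trajectory <- function(path,
                            format = c("auto", "trr", "gro_series", "fixture"),
                            require_velocities = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      trr = "trr",
      gro = "gro_series",
      "fixture"
    )
  }
  traj <- switch(format,
    trr = read_trr(path),
    gro_series = read_gro_series(path),
    fixture = read_fixture_trajectory(path)
  )
  if (require_velocities) require_velocities(traj, "read_trajectory(require_velocities = TRUE)")
  traj
}

## ---- fixture text format -------------------------------------------------
## Self-describing columnar text, all in internal units:
##   # hydrolayer trajectory v1
##   n_atoms <n>
##   box_A <Lx> <Ly> <Lz>
##   frame <i> time_fs <t>
##   <atom_id> <x> <y> <z> <vx> <vy> <vz>     (n lines; v columns optional)

#' Write / read the columnar text fixture trajectory format
#'
#' A self-describing plain-text format in internal units (A, fs), used
#' for small fixtures and generator output so that no binary dependency
#' is needed. Writing then reading is the identity on all fields.
#'
#' @param traj A `hydro_trajectory`.
#' @param path File path.
#' @return `read_fixture_trajectory()` returns a `hydro_trajectory`.
#' @export
write_fixture_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- n_atoms(traj)
  has_v <- !is.null(traj$velocities)
  writeLines("# hydrolayer trajectory v1", con)
  writeLines(paste("n_atoms", na), con)
  writeLines(paste("box_A", paste(format(traj$box[1, ], digits = 17), collapse = " ")), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(paste("frame", f - 1L, "time_fs",
                     format(traj$times[f], digits = 17)), con)
    block <- cbind(traj$positions[, , f, drop = TRUE])
    if (na == 1) block <- matrix(block, nrow = 1)
    if (has_v) {
      vb <- traj$velocities[, , f, drop = TRUE]
      if (na == 1) vb <- matrix(vb, nrow = 1)
      block <- cbind(block, vb)
    }
    lines <- paste(traj$atom_ids,
                   apply(format(block, digits = 17, scientific = TRUE,
                                trim = TRUE), 1, paste, collapse = " "))
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_fixture_trajectory
#' @export
read_fixture_trajectory <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (hdr[1] != "n_atoms") abort("fixture trajectory: expected 'n_atoms' header")
  na <- as.integer(hdr[2])
  bhdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (bhdr[1] != "box_A") abort("fixture trajectory: expected 'box_A' header")
  box <- as.numeric(bhdr[2:4])
  body <- lines[-(1:2)]
  per_frame <- na + 1L
  if (length(body) %% per_frame != 0) {
    abort("fixture trajectory: truncated frame block")
  }
  nf <- length(body) %/% per_frame
  times <- numeric(nf)
  first_block <- strsplit(trimws(body[2]), "\\s+")[[1]]
  has_v <- length(first_block) == 7
  pos <- array(NA_real_, c(na, 3, nf))
  vel <- if (has_v) array(NA_real_, c(na, 3, nf)) else NULL
  ids <- NULL
  for (f in seq_len(nf)) {
    off <- (f - 1L) * per_frame
    fh <- strsplit(trimws(body[off + 1L]), "\\s+")[[1]]
    if (fh[1] != "frame" || fh[3] != "time_fs") {
      abort(paste0("fixture trajectory: malformed frame header at frame ", f - 1L))
    }
    times[f] <- as.numeric(fh[4])
    block <- utils::read.table(text = body[off + 1L + seq_len(na)])
    if (f == 1) ids <- as.integer(block[[1]])
    pos[, , f] <- as.matrix(block[, 2:4])
    if (has_v) vel[, , f] <- as.matrix(block[, 5:7])
  }
  trajectory(times, pos, vel, box, atom_ids = ids)
}
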