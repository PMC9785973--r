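## GROMACS TRR reader (native, big-endian XDR layout).
## Per frame: magic 1993; version string (int len+1, int len, bytes padded
## to 4); ints ir_size, e_size, box_size, vir_size, pres_size, top_size,
## sym_size, x_size, v_size, f_size, natoms, step, nre; reals t, lambda;
## then box (3x3), virial, pressure, x, v, f blocks as indicated by the
## sizes. Reals are float or double, inferred from box_size / x_size.
## TRR stores nm and ps; converted to A and fs on read.
read_trr <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(n = 1) readBin(con, "integer", n = n, size = 4, endian = "big")
  times <- c(); boxes <- list(); xs <- list(); vs <- list()
  natoms_ref <- NULL
  frame <- 0L
  repeat {
    magic <- rint()
    if (length(magic) == 0) break
    frame <- frame + 1L
    if (magic != 1993L) {
      abort(paste0("not a TRR file (bad magic ", magic, " at frame ", frame, ")"))
    }
    slen <- rint() # strlen + 1
    nbytes <- rint()
    pad <- (4 - nbytes %% 4) %% 4
    readBin(con, "raw", n = nbytes + pad)
    sizes <- rint(10)
    names(sizes) <- c("ir", "e", "box", "vir", "pres", "top", "sym",
                      "x", "v", "f")
    natoms <- rint()
    step <- rint()
    nre <- rint()
    if (is.null(natoms_ref)) natoms_ref <- natoms
    if (natoms != natoms_ref) abort("TRR: natoms changed mid-file")
    rsize <- if (sizes[["box"]] > 0) {
      sizes[["box"]] %/% 9L
    } else if (sizes[["x"]] > 0) {
      sizes[["x"]] %/% (3L * natoms)
    } else 4L
    if (!rsize %in% c(4L, 8L)) abort("TRR: cannot infer real precision")
    rreal <- function(n = 1) readBin(con, "double", n = n, size = rsize, endian = "big")
    t_ps <- rreal()
    rreal() # lambda
    if (sizes[["box"]] > 0) {
      bm <- matrix(rreal(9), 3, 3, byrow = TRUE)
      if (max(abs(bm[upper.tri(bm) | lower.tri(bm)])) > 1e-9) {
        abort("TRR: triclinic box not supported (orthorhombic only)")
      }
      boxes[[frame]] <- diag(bm) * .nm_to_A
    } else {
      abort("TRR: frame without box record")
    }
    for (blk in c("ir", "e", "vir", "pres")) {
      if (sizes[[blk]] > 0) readBin(con, "raw", n = sizes[[blk]])
    }
    if (sizes[["x"]] > 0) {
      xs[[frame]] <- matrix(rreal(3 * natoms), ncol = 3, byrow = TRUE) * .nm_to_A
    } else {
      abort("TRR: frame without positions")
    }
    vs[frame] <- list(if (sizes[["v"]] > 0) {
      matrix(rreal(3 * natoms), ncol = 3, byrow = TRUE) * .nmps_to_Afs
    } else NULL)
    if (sizes[["f"]] > 0) readBin(con, "raw", n = sizes[["f"]])
    times <- c(times, t_ps * .ps_to_fs)
  }
  if (frame == 0L) abort("TRR: empty file")
  has_v <- !vapply(vs, is.null, logical(1))
  vel <- NULL
  if (all(has_v)) {
    vel <- array(NA_real_, c(natoms_ref, 3, frame))
    for (f in seq_len(frame)) vel[, , f] <- vs[[f]]
  } else if (any(has_v)) {
    abort("TRR: velocities present in some frames but not all")
  }
  pos <- array(NA_real_, c(natoms_ref, 3, frame))
  for (f in seq_len(frame)) pos[, , f] <- xs[[f]]
  trajectory(times, pos, vel, do.call(rbind, boxes))
}

## Multi-frame GRO reader. Fixed-width records; velocity columns
## (positions 45-68) are required unless the caller disabled the check
## downstream. Times parsed from "t=" in each title line. nm/ps -> A/fs.
read_gro_series <- function(path) {
  lines <- readLines(path)
  i <- 1L
  times <- c(); xs <- list(); vs <- list(); boxes <- list()
  frame <- 0L
  while (i <= length(lines)) {
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) abort(paste0("GRO: bad atom count at line ", i + 1L))
    frame <- frame + 1L
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(tm) == 1) {
      times[frame] <- as.numeric(sub("t=\\s*", "", tm)) * .ps_to_fs
    } else {
      times[frame] <- NA_real_
    }
    atom_lines <- lines[i + 1L + seq_len(natoms)]
    wide <- all(nchar(atom_lines) >= 68)
    x <- matrix(NA_real_, natoms, 3)
    v <- if (wide) matrix(NA_real_, natoms, 3) else NULL
    for (a in seq_len(natoms)) {
      ln <- atom_lines[a]
      x[a, ] <- as.numeric(c(substr(ln, 21, 28), substr(ln, 29, 36),
                             substr(ln, 37, 44)))
      if (wide) {
        v[a, ] <- as.numeric(c(substr(ln, 45, 52), substr(ln, 53, 60),
                               substr(ln, 61, 68)))
      }
    }
    bx <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])
    if (length(bx) > 3 && any(abs(bx[4:length(bx)]) > 1e-9)) {
      abort("GRO: triclinic box not supported (orthorhombic only)")
    }
    boxes[[frame]] <- bx[1:3] * .nm_to_A
    xs[[frame]] <- x * .nm_to_A
    vs[[frame]] <- if (wide) v * .nmps_to_Afs else NULL
    i <- i + 3L + natoms
  }
  if (frame == 0L) abort("GRO: empty file")
  if (anyNA(times)) {
    if (frame == 1L) times <- 0 else
      abort("GRO: multi-frame file without 't=' times in title lines")
  }
  natoms <- nrow(xs[[1]])
  pos <- array(NA_real_, c(natoms, 3, frame))
  for (f in seq_len(frame)) pos[, , f] <- xs[[f]]
  vel <- NULL
  if (!is.null(vs[[1]])) {
    vel <- array(NA_real_, c(natoms, 3, frame))
    for (f in seq_len(frame)) vel[, , f] <- vs[[f]]
  }
  trajectory(times, pos, vel, do.call(rbind, boxes))
}
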