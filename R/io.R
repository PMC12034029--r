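#' Write / read a trajectory as CSV
#'
#' Plain-text interchange with one row per sample and columns
#' `spoke,sample,kx,ky,angle_deg,t` (0-based spoke and sample indices,
#' coordinates in cycles/FOV, 12 significant digits, C locale).
#'
#' @param traj a `raga_trajectory`.
#' @param path output file path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a `raga_trajectory` (without scheme
#'   provenance).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "raga_trajectory"))
  S <- dim(traj$coords)[1]
  n <- dim(traj$coords)[2]
  df <- data.frame(
    spoke = rep(seq_len(S) - 1L, each = n),
    sample = rep(seq_len(n) - 1L, times = S),
    kx = sprintf("%.12g", as.vector(t(traj$coords[, , 1]))),
    ky = sprintf("%.12g", as.vector(t(traj$coords[, , 2]))),
    angle_deg = sprintf("%.12g", rep(traj$angles_deg, each = n)),
    t = rep(traj$acquisition_order, each = n)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("spoke", "sample", "kx", "ky", "angle_deg", "t")
  if (!all(need %in% names(df))) {
    stop("not a trajectory CSV: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  S <- max(df$spoke) + 1L
  n <- max(df$sample) + 1L
  ord <- order(df$spoke, df$sample)
  df <- df[ord, ]
  coords <- array(0, dim = c(S, n, 2))
  coords[, , 1] <- matrix(df$kx, nrow = S, ncol = n, byrow = TRUE)
  coords[, , 2] <- matrix(df$ky, nrow = S, ncol = n, byrow = TRUE)
  first <- df$sample == 0
  structure(list(coords = coords,
                 angles_deg = df$angle_deg[first],
                 acquisition_order = as.numeric(df$t[first]),
                 readout = NULL, scheme = NULL),
            class = "raga_trajectory")
}

#' Write / read arrays in CFL format
#'
#' The CFL dialect used by common reconstruction toolchains: a text header
#' `<base>.hdr` with a `# Dimensions` line, and a binary body `<base>.cfl` of
#' interleaved little-endian 32-bit float (real, imaginary) pairs in
#' column-major order.
#'
#' @param base path without extension; `.hdr` and `.cfl` are appended.
#' @param x a numeric or complex array.
#' @param dims dimension vector to record (default `dim(x)`).
#' @return `write_cfl` returns `base` invisibly; `read_cfl` returns a complex
#'   array with the header dimensions (trailing singletons dropped).
#' @export
write_cfl <- function(base, x, dims = NULL) {
  if (is.null(dims)) dims <- if (is.null(dim(x))) length(x) else dim(x)
  dims <- c(dims, rep(1L, max(0L, 5L - length(dims))))
  hdr <- file(paste0(base, ".hdr"), "w")
  writeLines(c("# Dimensions", paste(dims, collapse = " ")), hdr)
  close(hdr)
  z <- as.complex(x)
  buf <- as.numeric(rbind(Re(z), Im(z)))   # interleave re/im
  con <- file(paste0(base, ".cfl"), "wb")
  writeBin(buf, con, size = 4L, endian = "little")
  close(con)
  invisible(base)
}

#' @rdname write_cfl
#' @export
read_cfl <- function(base) {
  hdr <- readLines(paste0(base, ".hdr"))
  dl <- which(grepl("^# Dimensions", hdr))
  if (length(dl) == 0) stop("no '# Dimensions' line in ", base, ".hdr")
  dims <- as.integer(strsplit(trimws(hdr[dl + 1L]), "\\s+")[[1]])
  n <- prod(dims)
  con <- file(paste0(base, ".cfl"), "rb")
  buf <- readBin(con, "numeric", n = 2L * n, size = 4L, endian = "little")
  close(con)
  z <- complex(real = buf[c(TRUE, FALSE)], imaginary = buf[c(FALSE, TRUE)])
  dims_out <- dims
  while (length(dims_out) > 1L && dims_out[length(dims_out)] == 1L) {
    dims_out <- dims_out[-length(dims_out)]
  }
  array(z, dim = dims_out)
}

#' Trajectory to and from CFL
#'
#' Stores a trajectory as a `(3, samples, spokes)` CFL array whose first
#' coordinate triplet is `(kx, ky, 0)`, matching the de-facto layout of
#' radial trajectories in CFL-based toolchains.
#'
#' @param traj a `raga_trajectory`.
#' @param base path without extension.
#' @return `write_trajectory_cfl` returns `base` invisibly;
#'   `read_trajectory_cfl` a `raga_trajectory`.
#' @export
write_trajectory_cfl <- function(traj, base) {
  stopifnot(inherits(traj, "raga_trajectory"))
  S <- dim(traj$coords)[1]
  n <- dim(traj$coords)[2]
  arr <- array(0, dim = c(3, n, S))
  arr[1, , ] <- t(traj$coords[, , 1])
  arr[2, , ] <- t(traj$coords[, , 2])
  write_cfl(base, arr, dims = c(3L, n, S))
}

#' @rdname write_trajectory_cfl
#' @export
read_trajectory_cfl <- function(base) {
  arr <- read_cfl(base)
  if (dim(arr)[1] != 3) stop("not a trajectory CFL: first dimension != 3")
  n <- dim(arr)[2]
  S <- dim(arr)[3]
  coords <- array(0, dim = c(S, n, 2))
  coords[, , 1] <- t(Re(arr[1, , ]))
  coords[, , 2] <- t(Re(arr[2, , ]))
  # recover spoke angles from the sample at largest radius
  ang <- (atan2(coords[, n, 2], coords[, n, 1]) * 180 / pi) %% 360
  structure(list(coords = coords, angles_deg = ang,
                 acquisition_order = seq_len(S) - 1,
                 readout = NULL, scheme = NULL),
            class = "raga_trajectory")
}

#' Read a key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numbers where possible. Mirrors the command-line flags of the shipped
#' `raga` script.
#'
#' @param path file path.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
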