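# Trajectory I/O: extended XYZ (native, read/write) and LAMMPS-style text
# dump (read-only).  Coordinates are written wrapped; unwrapping is an
# analysis-time operation.

fmt_num <- function(x) sprintf("%.12g", x)

#' Write a trajectory as extended XYZ
#'
#' One block per frame: the particle count, a comment line carrying the
#' cubic box (`Lattice=...`), the frame time, and the per-frame energies,
#' then one `id x y z vx vy vz` line per particle.  Positions are printed
#' with 12 significant digits so a write/read round trip preserves them to
#' printed precision.
#'
#' @param traj An `lj_trajectory`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  L <- traj$box_side
  species <- if (is.null(traj$chain_id)) rep("A", traj$n) else
    paste0("C", traj$chain_id)
  # regeneration metadata: the full parameter set and seed
  meta <- sprintf("Seed=%d dt=%s r_cut=%s n_steps=%d damping=%s k_bond=%s",
                  traj$params$seed, fmt_num(traj$params$dt),
                  fmt_num(traj$params$r_cut), traj$params$n_steps,
                  fmt_num(traj$params$thermostat_damping),
                  fmt_num(traj$params$k_bond))
  for (i in seq_len(n_frames(traj))) {
    p <- traj$positions[[i]]
    v <- traj$velocities[[i]]
    writeLines(as.character(traj$n), con)
    writeLines(sprintf(
      'Lattice="%s 0 0 0 %s 0 0 0 %s" Properties=species:S:1:pos:R:3:vel:R:3 Time=%s PE=%s KE=%s %s',
      fmt_num(L), fmt_num(L), fmt_num(L), fmt_num(traj$times[i]),
      fmt_num(traj$pe[i]), fmt_num(traj$ke[i]), meta), con)
    writeLines(paste(species,
                     fmt_num(p[, 1]), fmt_num(p[, 2]), fmt_num(p[, 3]),
                     fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
  }
  invisible(path)
}

#' Write per-frame energies as a CSV time series
#'
#' Columns: `time`, `KE`, `PE`, `E_total`, `T_kinetic` (kinetic temperature
#' with \eqn{3(n-1)} degrees of freedom).
#'
#' @param traj An `lj_trajectory`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_energy_csv <- function(traj, path) {
  g <- 3 * (traj$n - 1)
  df <- data.frame(time = traj$times, KE = traj$ke, PE = traj$pe,
                   E_total = traj$ke + traj$pe,
                   T_kinetic = traj$ke / (g / 2))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

parse_xyz <- function(lines) {
  frames_pos <- list(); frames_vel <- list()
  times <- c(); pe <- c(); ke <- c(); box <- NA_real_
  chain_id <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected particle count at line ", i)
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(m) < 2) stop("XYZ frame missing Lattice (box) information")
    lat <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
    if (length(lat) != 9) stop("Lattice must contain 9 numbers")
    if (abs(lat[1] - lat[5]) > 1e-9 || abs(lat[5] - lat[9]) > 1e-9 ||
        any(abs(lat[-c(1, 5, 9)]) > 1e-12))
      stop("only cubic boxes are supported")
    box_i <- lat[1]
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    t_i <- if (length(tm) >= 2) as.numeric(tm[2]) else length(times) + 1
    pm <- regmatches(comment, regexec("PE=([-0-9.eE+]+)", comment))[[1]]
    km <- regmatches(comment, regexec("KE=([-0-9.eE+]+)", comment))[[1]]
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    nums <- t(vapply(toks, function(tk) as.numeric(tk[2:7]), numeric(6)))
    sp <- vapply(toks, `[`, character(1), 1L)
    if (is.null(chain_id) && all(grepl("^C[0-9]+$", sp)))
      chain_id <- as.integer(sub("^C", "", sp))
    frames_pos[[length(frames_pos) + 1L]] <- nums[, 1:3, drop = FALSE]
    frames_vel[[length(frames_vel) + 1L]] <-
      if (!any(is.na(nums[, 4:6]))) nums[, 4:6, drop = FALSE] else
        matrix(0, n, 3)
    times <- c(times, t_i)
    pe <- c(pe, if (length(pm) >= 2) as.numeric(pm[2]) else NA_real_)
    ke <- c(ke, if (length(km) >= 2) as.numeric(km[2]) else NA_real_)
    box <- box_i
    i <- i + 2L + n
  }
  list(pos = frames_pos, vel = frames_vel, times = times, pe = pe, ke = ke,
       box = box, chain_id = chain_id)
}

parse_lammps_dump <- function(lines) {
  frames_pos <- list(); frames_vel <- list(); times <- c(); box <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP")) { i <- i + 1L; next }
    step <- as.numeric(trimws(lines[i + 1L]))
    j <- i + 2L
    n <- NA_integer_; lo <- hi <- rep(NA_real_, 3); have_box <- FALSE
    cols <- NULL
    while (j <= length(lines)) {
      if (startsWith(lines[j], "ITEM: NUMBER OF ATOMS")) {
        n <- as.integer(trimws(lines[j + 1L])); j <- j + 2L
      } else if (startsWith(lines[j], "ITEM: BOX BOUNDS")) {
        for (k in 1:3) {
          b <- as.numeric(strsplit(trimws(lines[j + k]), "\\s+")[[1]])
          lo[k] <- b[1]; hi[k] <- b[2]
        }
        have_box <- TRUE
        j <- j + 4L
      } else if (startsWith(lines[j], "ITEM: ATOMS")) {
        cols <- strsplit(trimws(sub("ITEM: ATOMS", "", lines[j])), "\\s+")[[1]]
        j <- j + 1L
        break
      } else stop("unrecognized dump section: ", lines[j])
    }
    if (!have_box) stop("LAMMPS dump frame has no ITEM: BOX BOUNDS; box required")
    if (is.na(n)) stop("LAMMPS dump frame has no atom count")
    sides <- hi - lo
    if (max(abs(sides - sides[1])) > 1e-9 * max(abs(sides)))
      stop("only cubic boxes are supported")
    box_i <- sides[1]
    body <- lines[j:(j + n - 1L)]
    vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
    colnames(vals) <- cols
    pick <- function(options) {
      hit <- options[options %in% cols]
      if (length(hit)) hit[1] else NA_character_
    }
    xs <- c(pick(c("x", "xs", "xu")), pick(c("y", "ys", "yu")),
            pick(c("z", "zs", "zu")))
    if (any(is.na(xs)))
      stop("cannot find coordinate columns in dump header: ",
           paste(cols, collapse = " "))
    pos <- vals[, xs, drop = FALSE]
    for (k in 1:3) {
      if (grepl("s$", xs[k])) pos[, k] <- lo[k] + pos[, k] * sides[k]  # scaled
      pos[, k] <- (pos[, k] - lo[k]) %% box_i                          # shift origin, wrap
    }
    if ("id" %in% cols) pos <- pos[order(vals[, "id"]), , drop = FALSE]
    vel <- if (all(c("vx", "vy", "vz") %in% cols)) {
      v <- vals[, c("vx", "vy", "vz"), drop = FALSE]
      if ("id" %in% cols) v[order(vals[, "id"]), , drop = FALSE] else v
    } else matrix(0, n, 3)
    frames_pos[[length(frames_pos) + 1L]] <- unname(pos)
    frames_vel[[length(frames_vel) + 1L]] <- unname(vel)
    times <- c(times, step)
    box <- box_i
    i <- j + n
  }
  if (length(frames_pos) == 0) stop("no frames found in LAMMPS dump")
  list(pos = frames_pos, vel = frames_vel, times = times,
       pe = rep(NA_real_, length(times)), ke = rep(NA_real_, length(times)),
       box = box, chain_id = NULL)
}

#' Read a trajectory from extended XYZ or LAMMPS text dump
#'
#' Extended XYZ frames must carry the box in a `Lattice="..."` comment
#' entry.  LAMMPS dumps must contain `ITEM: BOX BOUNDS`; the coordinate
#' columns (`x`/`xs`/`xu` variants) are auto-detected from the
#' `ITEM: ATOMS` header, scaled coordinates are unscaled by the box, and
#' particles are re-ordered by `id`.
#'
#' @param path Input file.
#' @param format `"xyz"` or `"lammps"`; `"auto"` guesses from the content.
#' @param chain_length If the file encodes a chain system without chain
#'   labels, assign consecutive blocks of this many beads to chains.
#' @return An `lj_trajectory` (velocities zero when absent from the file).
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "lammps"),
                            chain_length = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto")
    format <- if (any(startsWith(head(lines, 5), "ITEM: TIMESTEP")))
      "lammps" else "xyz"
  raw <- if (format == "xyz") parse_xyz(lines) else parse_lammps_dump(lines)
  n <- nrow(raw$pos[[1]])
  chain_id <- raw$chain_id
  if (is.null(chain_id) && !is.null(chain_length)) {
    stopifnot(n %% chain_length == 0)
    chain_id <- rep(seq_len(n %/% chain_length), each = chain_length)
  }
  nfm <- length(raw$pos)
  structure(list(times = raw$times, positions = raw$pos,
                 velocities = raw$vel, pe = raw$pe,
                 ke = raw$ke, thermostat = matrix(NA_real_, nfm, 3),
                 box_side = raw$box, rho_star = n / raw$box^3,
                 T_star = NULL, n = n, chain_id = chain_id,
                 chain_length = if (!is.null(chain_id))
                   as.integer(n / max(chain_id)) else NULL,
                 params = sim_params(
                   n_steps = max(1, length(raw$times)),
                   equilibration_fraction = 0),
                 ensemble = "file", E0 = NA_real_,
                 min_distance = NA_real_),
            class = "lj_trajectory")
}
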