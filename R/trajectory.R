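# Trajectory container and text-format readers/writers (extended XYZ, GRO).

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06)

#' Trajectory of per-atom velocities (and optionally positions)
#'
#' Holds the time series needed for the velocity-autocorrelation analysis:
#' per-atom masses and, for every output frame, the 3-component velocities in
#' nm/ps. Positions (nm) are optional and only needed by structural analyses.
#'
#' @param velocities numeric array `[n_frames, n_atoms, 3]`, nm/ps.
#' @param masses per-atom masses in amu (length `n_atoms`, or scalar).
#' @param dt_out interval between stored frames, ps.
#' @param box orthorhombic box lengths, nm (length 3).
#' @param positions optional array `[n_frames, n_atoms, 3]`, nm.
#' @param species optional character vector of element symbols.
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(velocities, masses, dt_out, box,
                       positions = NULL, species = NULL) {
  if (length(dim(velocities)) != 3L || dim(velocities)[3] != 3L)
    stop("velocities must be an [n_frames, n_atoms, 3] array")
  n_frames <- dim(velocities)[1]
  n_atoms <- dim(velocities)[2]
  if (n_atoms < 1L) stop("trajectory must contain at least one atom")
  if (length(masses) == 1L) masses <- rep(masses, n_atoms)
  if (length(masses) != n_atoms) stop("masses must have one entry per atom")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be strictly positive")
  if (!is.numeric(dt_out) || length(dt_out) != 1L || dt_out <= 0)
    stop("dt_out must be a positive scalar (ps)")
  if (length(box) != 3L || any(box <= 0))
    stop("box must be three positive orthorhombic lengths (nm)")
  if (!is.null(positions) &&
      !identical(dim(positions), dim(velocities)))
    stop("positions must have the same dimensions as velocities")
  structure(list(velocities = velocities, masses = masses, dt_out = dt_out,
                 box = as.numeric(box), positions = positions,
                 species = species, n_atoms = n_atoms, n_frames = n_frames),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, dt_out = %g ps, box = %s nm\n",
              x$n_atoms, x$n_frames, x$dt_out,
              paste(signif(x$box, 6), collapse = " x ")))
  invisible(x)
}

#' Duration of a trajectory in ps
#' @param traj a [trajectory()].
#' @export
trajectory_duration <- function(traj) (traj$n_frames - 1) * traj$dt_out

.parse_lattice <- function(comment, where) {
  m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
  if (length(m) < 2) stop("no Lattice entry in ", where)
  v <- as.numeric(strsplit(trimws(m[2]), "[[:space:]]+")[[1]])
  if (length(v) != 9) stop("Lattice must contain 9 numbers (", where, ")")
  off <- v[-c(1, 5, 9)]
  if (any(abs(off) > 1e-10 * max(abs(v))))
    stop("triclinic box rejected: only orthorhombic cells are supported (", where, ")")
  v[c(1, 5, 9)]
}

.parse_properties <- function(comment, where) {
  m <- regmatches(comment, regexec("Properties=([^[:space:]]+)", comment))[[1]]
  if (length(m) < 2) stop("no Properties entry in ", where)
  toks <- strsplit(m[2], ":")[[1]]
  if (length(toks) %% 3 != 0) stop("malformed Properties string in ", where)
  nfield <- length(toks) / 3
  name <- toks[seq(1, by = 3, length.out = nfield)]
  ncol <- as.integer(toks[seq(3, by = 3, length.out = nfield)])
  col0 <- cumsum(c(1L, ncol))[seq_len(nfield)]
  stats::setNames(lapply(seq_len(nfield), function(i) col0[i]:(col0[i] + ncol[i] - 1L)),
                  name)
}

.mass_from_species <- function(sp, where) {
  key <- sub("[0-9].*$", "", sp)
  key <- substr(key, 1, 1)
  key <- toupper(key)
  m <- .ELEMENT_MASS[key]
  if (any(is.na(m)))
    stop("unknown element symbol(s) ", paste(unique(sp[is.na(m)]), collapse = ", "),
         " in ", where, "; supply an explicit mass column")
  unname(m)
}

.read_extxyz <- function(path, dt_out) {
  lines <- readLines(path)
  i <- 1L
  frames_v <- list(); frames_x <- list()
  masses <- NULL; species <- NULL; box <- NULL; times <- c(); dt_meta <- NA_real_
  frame <- 0L
  n_ref <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("frame ", frame, ": invalid atom-count line")
    if (is.na(n_ref)) n_ref <- n
    if (n != n_ref)
      stop("inconsistent atom counts: frame ", frame, " has ", n,
           " atoms but frame 1 has ", n_ref)
    comment <- lines[i + 1L]
    where <- paste0("frame ", frame)
    b <- .parse_lattice(comment, where)
    if (is.null(box)) box <- b
    props <- .parse_properties(comment, where)
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    if (length(tm) == 2) times <- c(times, as.numeric(tm[2]))
    dm <- regmatches(comment, regexec("dt_out=([-0-9.eE+]+)", comment))[[1]]
    if (length(dm) == 2) dt_meta <- as.numeric(dm[2])
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    ntok <- lengths(toks)
    if (any(ntok != ntok[1])) stop("frame ", frame, ": ragged atom lines")
    tab <- matrix(unlist(toks), nrow = n, byrow = TRUE)
    vel_key <- intersect(c("vel", "velo", "velocities"), names(props))
    if (length(vel_key) == 0)
      stop("frame ", frame, ": missing velocity columns (Properties has no vel field)")
    v <- matrix(as.numeric(tab[, props[[vel_key[1]]], drop = FALSE]), nrow = n)
    frames_v[[frame]] <- v
    if ("pos" %in% names(props))
      frames_x[[frame]] <- matrix(as.numeric(tab[, props$pos, drop = FALSE]), nrow = n)
    if (frame == 1L) {
      if ("mass" %in% names(props)) {
        masses <- as.numeric(tab[, props$mass[1]])
      } else if ("species" %in% names(props)) {
        species <- tab[, props$species[1]]
        masses <- .mass_from_species(species, where)
      } else stop("frame 1: neither mass column nor species symbols present")
      if ("species" %in% names(props)) species <- tab[, props$species[1]]
    }
    i <- i + 2L + n
  }
  if (frame == 0L) stop("no frames found in ", path)
  if (is.null(dt_out)) {
    if (length(times) >= 2) dt_out <- diff(times)[1]
    else if (!is.na(dt_meta)) dt_out <- dt_meta
    else stop("dt_out not present in file metadata; supply dt_out explicitly")
  }
  nf <- frame
  v_arr <- array(0, dim = c(nf, n_ref, 3))
  for (f in seq_len(nf)) v_arr[f, , ] <- frames_v[[f]]
  x_arr <- NULL
  if (length(frames_x) == nf && !is.null(frames_x[[1]])) {
    x_arr <- array(0, dim = c(nf, n_ref, 3))
    for (f in seq_len(nf)) x_arr[f, , ] <- frames_x[[f]]
  }
  trajectory(v_arr, masses, dt_out, box, positions = x_arr, species = species)
}

.read_gro_seq <- function(path, dt_out) {
  lines <- readLines(path)
  i <- 1L; frame <- 0L
  frames_v <- list(); frames_x <- list(); names1 <- NULL
  box <- NULL; times <- c(); n_ref <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    if (length(tm) == 2) times <- c(times, as.numeric(tm[2]))
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    frame <- frame + 1L
    if (is.na(n) || n < 1) stop("frame ", frame, ": invalid GRO atom-count line")
    if (is.na(n_ref)) n_ref <- n
    if (n != n_ref)
      stop("inconsistent atom counts: frame ", frame, " has ", n,
           " atoms but frame 1 has ", n_ref)
    at <- lines[(i + 2L):(i + 1L + n)]
    num <- function(a, b) as.numeric(substr(at, a, b))
    x <- cbind(num(21, 28), num(29, 36), num(37, 44))
    if (any(nchar(at) < 68))
      stop("frame ", frame, ": GRO lines lack velocity columns")
    v <- cbind(num(45, 52), num(53, 60), num(61, 68))
    if (any(!is.finite(v))) stop("frame ", frame, ": unreadable velocity fields")
    frames_x[[frame]] <- x; frames_v[[frame]] <- v
    if (frame == 1L) names1 <- trimws(substr(at, 11, 15))
    bx <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "[[:space:]]+")[[1]])
    if (length(bx) >= 9 && any(abs(bx[4:9]) > 1e-10))
      stop("triclinic box rejected: only orthorhombic cells are supported (frame ",
           frame, ")")
    if (is.null(box)) box <- bx[1:3]
    i <- i + 3L + n
  }
  if (frame == 0L) stop("no frames found in ", path)
  if (is.null(dt_out)) {
    if (length(times) >= 2) dt_out <- diff(times)[1]
    else stop("dt_out not derivable from GRO titles; supply dt_out explicitly")
  }
  masses <- .mass_from_species(names1, "frame 1")
  nf <- frame
  v_arr <- array(0, dim = c(nf, n_ref, 3)); x_arr <- array(0, dim = c(nf, n_ref, 3))
  for (f in seq_len(nf)) { v_arr[f, , ] <- frames_v[[f]]; x_arr[f, , ] <- frames_x[[f]] }
  trajectory(v_arr, masses, dt_out, box, positions = x_arr, species = names1)
}

#' Read a velocity trajectory from a text format
#'
#' Supports extended XYZ (per-atom columns declared through the
#' `Properties=` comment entry; a `vel` field is mandatory, masses come from
#' a `mass` field or from element symbols) and sequences of GRO frames with
#' velocity columns. Only orthorhombic cells are accepted.
#'
#' @param path file path.
#' @param format `"extxyz"` or `"gro"`.
#' @param dt_out override for the output interval (ps); otherwise derived
#'   from `Time=`/`dt_out=` metadata (extxyz) or `t=` title entries (GRO).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = c("extxyz", "gro"), dt_out = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, extxyz = .read_extxyz(path, dt_out), gro = .read_gro_seq(path, dt_out))
}

#' Write a trajectory as extended XYZ
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param digits significant digits for numeric fields (default 12, enough
#'   for a lossless float round trip at text precision).
#' @export
write_trajectory <- function(traj, path, digits = 12) {
  con <- file(path, "w"); on.exit(close(con))
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  sp <- traj$species
  if (is.null(sp)) sp <- rep("X", traj$n_atoms)
  has_pos <- !is.null(traj$positions)
  props <- if (has_pos) "species:S:1:pos:R:3:vel:R:3:mass:R:1" else "species:S:1:vel:R:3:mass:R:1"
  lat <- sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s"',
                 fmt(traj$box[1]), fmt(traj$box[2]), fmt(traj$box[3]))
  for (f in seq_len(traj$n_frames)) {
    writeLines(as.character(traj$n_atoms), con)
    writeLines(sprintf('%s Properties=%s Time=%s dt_out=%s', lat, props,
                       fmt((f - 1) * traj$dt_out), fmt(traj$dt_out)), con)
    v <- traj$velocities[f, , , drop = TRUE]
    if (traj$n_atoms == 1L) v <- matrix(v, 1)
    if (has_pos) {
      x <- traj$positions[f, , , drop = TRUE]
      if (traj$n_atoms == 1L) x <- matrix(x, 1)
      writeLines(paste(sp, fmt(x[, 1]), fmt(x[, 2]), fmt(x[, 3]),
                       fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3]), fmt(traj$masses)), con)
    } else {
      writeLines(paste(sp, fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3]),
                       fmt(traj$masses)), con)
    }
  }
  invisible(path)
}
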