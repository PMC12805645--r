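# Temperature- and time-indexed scalar series (enthalpy, specific volume,
# hot-cold temperature difference) and their CSV readers.
#
# CSV dialect: comma separated, "." decimal, one header row whose column
# names carry the unit as a suffix (T_K, H_J, v_m3kg, t_ns, t_ps, dT_K).

#' Temperature-indexed scalar series
#'
#' @param T temperature grid (K), strictly increasing.
#' @param y scalar values (enthalpy J, specific volume m^3/kg, or heat
#'   capacity in k_B per atom, depending on `label`).
#' @param label semantic role, e.g. `"enthalpy"`, `"specific_volume"`,
#'   `"heat_capacity"`.
#' @return object of class `"thermo_series"`.
#' @export
thermo_series <- function(T, y, label = "series") {
  if (length(T) != length(y)) stop("T and y must have the same length")
  if (any(diff(T) <= 0)) stop("temperature grid must be strictly increasing")
  if (any(!is.finite(T)) || any(!is.finite(y))) stop("values must be finite")
  structure(list(T = as.numeric(T), y = as.numeric(y), label = label),
            class = "thermo_series")
}

#' Approach-to-equilibrium decay series
#'
#' Hot-cold temperature difference versus time, plus the geometry and the
#' extensive heat capacity needed to convert the fitted decay constant into
#' a thermal conductivity.
#'
#' @param t time grid (ns), strictly increasing.
#' @param dT hot-cold temperature difference (K).
#' @param Lx box length along the transport axis (m).
#' @param A_cross cross-sectional area (m^2).
#' @param c_total extensive heat capacity of the sample (J/K).
#' @return object of class `"ate_series"`.
#' @export
ate_series <- function(t, dT, Lx, A_cross, c_total) {
  if (length(t) != length(dT)) stop("t and dT must have the same length")
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  if (Lx <= 0 || A_cross <= 0 || c_total <= 0)
    stop("Lx, A_cross and c_total must be positive")
  structure(list(t = as.numeric(t), dT = as.numeric(dT), Lx = Lx,
                 A_cross = A_cross, c_total = c_total),
            class = "ate_series")
}

.KNOWN_UNITS <- c(K = 1, J = 1, m3kg = 1, ns = 1, ps = 1e-3, GPa = 1, kB = 1)

.split_unit <- function(colname) {
  parts <- strsplit(colname, "_")[[1]]
  unit <- parts[length(parts)]
  if (!unit %in% names(.KNOWN_UNITS))
    stop("unknown unit tag '", unit, "' in column '", colname, "'")
  list(name = paste(parts[-length(parts)], collapse = "_"),
       factor = unname(.KNOWN_UNITS[unit]))
}

#' Read a temperature-indexed series from CSV
#'
#' Expects a header with unit-suffixed column names; the first column is the
#' temperature grid (e.g. `T_K`) and `value_col` (default: second column)
#' the values, e.g. `H_J` or `v_m3kg`.
#'
#' @param path CSV path.
#' @param value_col optional name of the value column.
#' @param label semantic label; defaults to the value column's base name.
#' @return a [thermo_series()].
#' @export
read_thermo_series <- function(path, value_col = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("series CSV needs at least two columns")
  tcol <- names(d)[1]
  if (.split_unit(tcol)$name != "T") stop("first column must be the temperature grid (T_K)")
  if (is.null(value_col)) value_col <- names(d)[2]
  u <- .split_unit(value_col)
  if (any(diff(d[[tcol]]) <= 0))
    stop("non-monotonic temperature column in ", path)
  thermo_series(d[[tcol]], d[[value_col]] * u$factor,
                label = if (is.null(label)) u$name else label)
}

#' Read an approach-to-equilibrium series from CSV
#'
#' Expects columns `t_ns` (or `t_ps`) and `dT_K`; the sample geometry and
#' extensive heat capacity are supplied as arguments since they are not part
#' of the time series.
#'
#' @param path CSV path.
#' @inheritParams ate_series
#' @return an [ate_series()].
#' @export
read_ate_series <- function(path, Lx, A_cross, c_total) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  tcol <- names(d)[1]
  ut <- .split_unit(tcol)
  if (ut$name != "t") stop("first column must be the time grid (t_ns or t_ps)")
  if (any(diff(d[[tcol]]) <= 0)) stop("non-monotonic time column in ", path)
  dcol <- grep("^dT_", names(d), value = TRUE)
  if (length(dcol) == 0) stop("no dT_K column in ", path)
  ate_series(d[[tcol]] * ut$factor, d[[dcol[1]]], Lx, A_cross, c_total)
}

#' Write a thermo series to CSV
#' @param x a [thermo_series()].
#' @param path output path.
#' @param value_col column name with unit suffix (default from label).
#' @export
write_thermo_series <- function(x, path, value_col = NULL) {
  if (is.null(value_col))
    value_col <- switch(x$label, enthalpy = "H_J", specific_volume = "v_m3kg",
                        heat_capacity = "c_kB", paste0(x$label, "_J"))
  d <- data.frame(T_K = x$T, y = x$y)
  names(d)[2] <- value_col
  utils::write.csv(format(d, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ATE series to CSV
#' @param x an [ate_series()].
#' @param path output path.
#' @export
write_ate_series <- function(x, path) {
  utils::write.csv(format(data.frame(t_ns = x$t, dT_K = x$dT),
                          digits = 12, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
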