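# Configuration container (single frame with chain topology) and chain-map IO.

#' Chain configuration of a polymer system
#'
#' A single frame of per-site positions together with the chain topology
#' (chain index and monomer index within the chain) and the orthorhombic box.
#' This is the input to the structure factor, crystallinity detection and
#' chain-geometry statistics.
#'
#' @param sites numeric matrix `[n_sites, 3]` of positions (nm).
#' @param chain_id integer vector, chain index per site.
#' @param monomer_id integer vector, monomer index within each chain
#'   (contiguous, starting at 1).
#' @param box orthorhombic box lengths (nm), length 3.
#' @param allow_ragged if `FALSE` (default) all chains must have the same
#'   number of monomers.
#' @return an object of class `"configuration"` with fields `sites`,
#'   `chain_id`, `monomer_id`, `box`, `Nc` (chains), `Nl` (monomers/chain).
#' @export
configuration <- function(sites, chain_id, monomer_id, box,
                          allow_ragged = FALSE) {
  sites <- as.matrix(sites)
  if (ncol(sites) != 3L) stop("sites must be an [n, 3] matrix")
  n <- nrow(sites)
  if (any(!is.finite(sites))) stop("site positions must be finite")
  if (length(chain_id) != n || length(monomer_id) != n)
    stop("chain_id and monomer_id must have one entry per site")
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive lengths (nm)")
  chain_id <- as.integer(chain_id); monomer_id <- as.integer(monomer_id)
  # order sites by (chain, monomer) so per-chain blocks are contiguous
  o <- order(chain_id, monomer_id)
  sites <- sites[o, , drop = FALSE]
  chain_id <- chain_id[o]; monomer_id <- monomer_id[o]
  lens <- integer(0)
  for (cid in unique(chain_id)) {
    mid <- monomer_id[chain_id == cid]
    expect <- seq(min(mid), length.out = length(mid))
    if (!identical(as.integer(mid), as.integer(expect))) {
      gap <- setdiff(seq(min(mid), max(mid)), mid)
      stop("chain ", cid, ": monomer_id not contiguous (missing ",
           paste(gap, collapse = ", "), ")")
    }
    lens <- c(lens, length(mid))
  }
  if (!allow_ragged && length(unique(lens)) > 1L)
    stop("ragged chains: chains have differing monomer counts (",
         paste(unique(lens), collapse = ", "),
         "); pass allow_ragged = TRUE to accept")
  structure(list(sites = sites, chain_id = chain_id, monomer_id = monomer_id,
                 box = as.numeric(box), Nc = length(unique(chain_id)),
                 Nl = if (length(unique(lens)) == 1L) lens[1] else NA_integer_,
                 chain_lengths = lens),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration: %d sites, Nc = %d chains, Nl = %s monomers/chain\n",
              nrow(x$sites), x$Nc, ifelse(is.na(x$Nl), "ragged", x$Nl)))
  invisible(x)
}

#' Read a chain-topology map
#'
#' CSV with integer columns `atom_id, chain_id, monomer_id`, one row per
#' site. Monomer ids must be contiguous within each chain.
#'
#' @param path CSV path.
#' @param n_sites optional expected site count (e.g. from the coordinate
#'   file); a mismatch is an error.
#' @return data.frame ordered by `atom_id`, with attributes `Nc` and `Nl`.
#' @export
read_chain_map <- function(path, n_sites = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.csv(path)
  need <- c("atom_id", "chain_id", "monomer_id")
  if (!all(need %in% names(m)))
    stop("chain map must have columns ", paste(need, collapse = ", "))
  m <- m[order(m$atom_id), ]
  if (!is.null(n_sites) && nrow(m) != n_sites)
    stop("site count mismatch: chain map has ", nrow(m),
         " sites but coordinates have ", n_sites)
  lens <- integer(0)
  for (cid in unique(m$chain_id)) {
    mid <- sort(m$monomer_id[m$chain_id == cid])
    gap <- setdiff(seq(min(mid), max(mid)), mid)
    if (length(gap) > 0)
      stop("chain ", cid, ": missing monomer_id ", paste(gap, collapse = ", "))
    lens <- c(lens, length(mid))
  }
  attr(m, "Nc") <- length(unique(m$chain_id))
  attr(m, "Nl") <- if (length(unique(lens)) == 1L) lens[1] else NA_integer_
  m
}

#' Promote positions plus a chain map to a configuration
#'
#' @param positions `[n, 3]` matrix of site positions (nm), ordered by atom id.
#' @param chain_map data.frame from [read_chain_map()].
#' @param box box lengths (nm).
#' @inheritParams configuration
#' @export
configuration_from_map <- function(positions, chain_map, box,
                                   allow_ragged = FALSE) {
  if (nrow(positions) != nrow(chain_map))
    stop("site count mismatch: ", nrow(positions), " positions vs ",
         nrow(chain_map), " chain-map rows")
  configuration(positions, chain_map$chain_id, chain_map$monomer_id, box,
                allow_ragged = allow_ragged)
}

#' Write a configuration (extended XYZ + chain-map CSV)
#'
#' @param conf a [configuration()].
#' @param xyz_path path for the coordinate file (single extended-XYZ frame,
#'   zero velocities).
#' @param map_path path for the chain-map CSV.
#' @export
write_configuration <- function(conf, xyz_path, map_path) {
  n <- nrow(conf$sites)
  pos <- array(0, dim = c(1, n, 3)); pos[1, , ] <- conf$sites
  traj <- trajectory(array(0, dim = c(1, n, 3)), masses = rep(1, n),
                     dt_out = 1, box = conf$box, positions = pos)
  write_trajectory(traj, xyz_path)
  utils::write.csv(data.frame(atom_id = seq_len(n), chain_id = conf$chain_id,
                              monomer_id = conf$monomer_id),
                   map_path, row.names = FALSE)
  invisible(xyz_path)
}

#' Read a configuration from extended XYZ + chain map
#'
#' @param xyz_path extended-XYZ file (first frame used).
#' @param map_path chain-map CSV.
#' @inheritParams configuration
#' @export
read_configuration <- function(xyz_path, map_path, allow_ragged = FALSE) {
  traj <- read_trajectory(xyz_path, "extxyz", dt_out = 1)
  if (is.null(traj$positions)) stop("coordinate file has no position columns")
  pos <- traj$positions[1, , , drop = TRUE]
  if (traj$n_atoms == 1L) pos <- matrix(pos, 1)
  map <- read_chain_map(map_path, n_sites = traj$n_atoms)
  configuration_from_map(pos, map, traj$box, allow_ragged = allow_ragged)
}

# minimum-image displacement of b relative to a (rows), orthorhombic box
.min_image <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Unwrap chains across periodic boundaries
#'
#' Rebuilds contiguous chain coordinates by walking each backbone and
#' applying the minimum-image convention to successive bonds. Valid when
#' every bond is shorter than half the box.
#'
#' @param conf a [configuration()].
#' @return a configuration with unwrapped `sites`.
#' @export
unwrap_chains <- function(conf) {
  s <- conf$sites
  for (cid in unique(conf$chain_id)) {
    idx <- which(conf$chain_id == cid)
    if (length(idx) < 2) next
    d <- diff(s[idx, , drop = FALSE])
    d <- .min_image(d, conf$box)
    cs <- apply(d, 2, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
    s[idx, ] <- rbind(s[idx[1], , drop = FALSE],
                      sweep(cs, 2, s[idx[1], ], `+`))
  }
  out <- conf; out$sites <- s
  out
}
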